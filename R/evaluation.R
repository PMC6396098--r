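#' Split positive pairs into cross-validation folds
#'
#' Random disjoint folds covering all positives, sizes differing by at
#' most one; reproducible for a given seed.
#'
#' @param positives data.frame of positive pairs (`herb`, `protein`).
#' @param n_folds number of folds (default 10), >= 2.
#' @param seed integer seed.
#' @return List of length `n_folds`; each element has `train` and `test`
#'   data.frames partitioning `positives`. The fold assignment vector is
#'   attached as attribute `fold_id`.
#' @export
make_folds <- function(positives, n_folds = 10L, seed = 1L) {
  n_folds <- as.integer(n_folds)
  if (n_folds < 2) stop("n_folds must be >= 2")
  n <- nrow(positives)
  if (n < n_folds) stop("need at least as many positives as folds")
  perm <- withr_seed(derive_seed(seed, "folds"), sample.int(n))
  fold_id <- integer(n)
  fold_id[perm] <- rep(seq_len(n_folds), length.out = n)
  folds <- lapply(seq_len(n_folds), function(f) {
    list(train = positives[fold_id != f, , drop = FALSE],
         test = positives[fold_id == f, , drop = FALSE])
  })
  attr(folds, "fold_id") <- fold_id
  folds
}

#' Area under the ROC curve
#'
#' Mann-Whitney formulation: the probability that a uniformly chosen
#' positive outscores a uniformly chosen negative, ties counted 1/2.
#' Invariant to strictly monotone transforms of the scores.
#'
#' @param scores numeric prediction scores.
#' @param labels binary labels (1 = positive); both classes required.
#' @return AUROC in \[0, 1\].
#' @export
auroc <- function(scores, labels) {
  y <- as.numeric(labels)
  stopifnot(length(scores) == length(y))
  np <- sum(y == 1); nn <- sum(y == 0)
  if (np == 0 || nn == 0) stop("AUROC undefined: need both classes")
  r <- rank(scores)
  (sum(r[y == 1]) - np * (np + 1) / 2) / (np * nn)
}

#' Area under the precision-recall curve
#'
#' Step-wise (non-interpolated) integration over descending score
#' thresholds: tied scores enter as one threshold group, and the area is
#' the sum of precision times recall increment across groups.
#'
#' @inheritParams auroc
#' @return AUPR in \[0, 1\].
#' @export
aupr <- function(scores, labels) {
  y <- as.numeric(labels)
  stopifnot(length(scores) == length(y))
  np <- sum(y == 1)
  if (np == 0 || np == length(y)) stop("AUPR undefined: need both classes")
  ord <- order(-scores)
  s <- scores[ord]; y <- y[ord]
  ends <- cumsum(rle(s)$lengths)  # last index of each tied-score group
  tp <- cumsum(y)[ends]
  n_at <- ends
  prec <- tp / n_at
  rec <- tp / np
  sum(diff(c(0, rec)) * prec)
}

#' Two-sided Wilcoxon signed-rank test for paired metrics
#'
#' Compares paired per-fold metric values of two models. Zero differences
#' are dropped; at least five non-zero pairs are required. For n <= 25
#' the p-value is exact, computed from the full signed-rank distribution
#' over sign assignments (tied absolute differences take midranks, so the
#' exact branch remains valid under ties); above that a normal
#' approximation with tie correction and continuity correction is used.
#'
#' @param paired_a,paired_b equal-length numeric vectors.
#' @return List with `statistic` (V, the positive-rank sum), `p.value`,
#'   `n` (non-zero pairs) and `method`.
#' @export
wilcoxon_signed_rank <- function(paired_a, paired_b) {
  stopifnot(length(paired_a) == length(paired_b))
  d <- paired_a - paired_b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) stop("all paired differences are zero; test undefined")
  if (n < 5) stop("need at least 5 non-zero paired differences")
  r <- rank(abs(d))  # midranks under ties
  V <- sum(r[d > 0])
  if (n <= 25) {
    # exact null distribution of 2V (doubled so midranks become integers)
    r2 <- as.integer(round(2 * r))
    maxs <- sum(r2)
    f <- numeric(maxs + 1)
    f[1] <- 1
    for (ri in r2) {
      shifted <- c(numeric(ri), f[seq_len(maxs + 1 - ri)])
      f <- f + shifted
    }
    f <- f / 2^n
    v2 <- as.integer(round(2 * V))
    p_le <- sum(f[seq_len(v2 + 1)])
    p_ge <- sum(f[seq(v2 + 1, maxs + 1)])
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    z <- (V - mu - sign(V - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal approximation"
  }
  list(statistic = V, p.value = p, n = n, method = method)
}

#' Scoring pipeline built from an embedding model and a classifier spec
#'
#' Bundles the feature provider (Hadamard products of node vectors) with
#' a [model_spec()] so [cross_validate()] can retrain the classifier per
#' fold while the embeddings stay fixed (they are learned once, on a
#' network that does not contain the label edges).
#'
#' @param embedding an `embedding_model`.
#' @param spec a [model_spec()].
#' @return An `hti_pipeline`.
#' @export
htinet_pipeline <- function(embedding, spec = model_spec("knn")) {
  stopifnot(inherits(embedding, "embedding_model"),
            inherits(spec, "model_spec"))
  structure(list(
    name = paste0(toupper(spec$family), "-HTINet"),
    fit = function(train_pairs, train_labels) {
      x <- featurize_pairs(embedding, train_pairs)
      scorer <- train_model(spec, x, train_labels)
      function(pairs) as.numeric(scorer(featurize_pairs(embedding, pairs)))
    }), class = "hti_pipeline")
}

#' 10-fold cross-validation of a scoring pipeline
#'
#' For each fold: train on the other 9/10 of the positives plus a matched
#' number of sampled negatives, test on the held-out 1/10 plus a matched
#' number of freshly sampled negatives disjoint from the training
#' negatives, and record AUROC and AUPR. Fold splits and negative samples
#' depend only on `seed`, so two pipelines evaluated with the same seed
#' see identical folds and test sets and their per-fold metrics pair.
#'
#' @param pipeline an `hti_pipeline` (see [htinet_pipeline()],
#'   [prince_pipeline()]).
#' @param positives data.frame of positive pairs (`herb`, `protein`).
#' @param universe list with `herbs` and `proteins` (candidate node ids).
#' @param n_folds number of folds (default 10).
#' @param seed integer seed controlling folds and negative sampling.
#' @return An `htinet_cv` report: `per_fold` data.frame (fold, auroc,
#'   aupr, n_test), `mean_auroc`, `mean_aupr`, `name`, `seed`.
#' @export
cross_validate <- function(pipeline, positives, universe, n_folds = 10L,
                           seed = 1L) {
  stopifnot(inherits(pipeline, "hti_pipeline"),
            is.list(universe), !is.null(universe$herbs),
            !is.null(universe$proteins))
  folds <- make_folds(positives, n_folds = n_folds, seed = seed)
  rows <- vector("list", length(folds))
  for (f in seq_along(folds)) {
    train_pos <- folds[[f]]$train
    test_pos <- folds[[f]]$test
    train_neg <- sample_negatives(
      positives, universe$herbs, universe$proteins,
      n = nrow(train_pos),
      seed = derive_seed(seed, paste0("train_neg_", f)))
    test_neg <- sample_negatives(
      positives, universe$herbs, universe$proteins,
      n = nrow(test_pos), exclude = train_neg,
      seed = derive_seed(seed, paste0("test_neg_", f)))
    scorer <- pipeline$fit(
      rbind(train_pos, train_neg),
      c(rep(1, nrow(train_pos)), rep(0, nrow(train_neg))))
    test_pairs <- rbind(test_pos, test_neg)
    test_y <- c(rep(1, nrow(test_pos)), rep(0, nrow(test_neg)))
    sc <- scorer(test_pairs)
    rows[[f]] <- data.frame(fold = f, auroc = auroc(sc, test_y),
                            aupr = aupr(sc, test_y),
                            n_test = length(test_y))
  }
  per_fold <- do.call(rbind, rows)
  structure(list(per_fold = per_fold,
                 mean_auroc = mean(per_fold$auroc),
                 mean_aupr = mean(per_fold$aupr),
                 name = pipeline$name, n_folds = as.integer(n_folds),
                 seed = as.integer(seed)),
            class = "htinet_cv")
}

#' @export
print.htinet_cv <- function(x, digits = 4, ...) {
  cat(x$name, ": ", x$n_folds, "-fold cross-validation\n", sep = "")
  cat("  mean AUROC = ", round(x$mean_auroc, digits),
      ", mean AUPR = ", round(x$mean_aupr, digits), "\n", sep = "")
  invisible(x)
}

#' Paired comparison of two cross-validation reports
#'
#' Wilcoxon signed-rank test on per-fold metric values. The two reports
#' must come from [cross_validate()] runs with the same seed and fold
#' count so the folds pair.
#'
#' @param report_a,report_b `htinet_cv` reports.
#' @param metric `"aupr"` (default) or `"auroc"`.
#' @return The [wilcoxon_signed_rank()] result.
#' @export
compare_models <- function(report_a, report_b, metric = c("aupr", "auroc")) {
  metric <- match.arg(metric)
  stopifnot(inherits(report_a, "htinet_cv"), inherits(report_b, "htinet_cv"))
  if (report_a$seed != report_b$seed ||
      report_a$n_folds != report_b$n_folds) {
    stop("reports must share seed and fold count for a paired comparison")
  }
  wilcoxon_signed_rank(report_a$per_fold[[metric]],
                       report_b$per_fold[[metric]])
}
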