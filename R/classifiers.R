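#' Sample non-interacting (herb, protein) pairs as negatives
#'
#' Draws `n` distinct pairs uniformly from the herb x protein cross
#' product, excluding the known positive interactions. Matched negative
#' sampling (|negatives| = |positives|) is the default protocol for both
#' training and testing.
#'
#' @param positive_pairs data.frame with columns `herb`, `protein`.
#' @param herb_universe,protein_universe character vectors of node ids.
#' @param n number of negatives to draw.
#' @param seed integer seed; identical seeds reproduce the sample.
#' @param exclude optional additional pairs to avoid (e.g. a fold's
#'   training negatives when drawing its disjoint test negatives).
#' @return data.frame `herb`, `protein` with `n` rows.
#' @export
sample_negatives <- function(positive_pairs, herb_universe, protein_universe,
                             n, seed = 1L, exclude = NULL) {
  n <- as.integer(n)
  if (n == 0) {
    return(data.frame(herb = character(), protein = character(),
                      stringsAsFactors = FALSE))
  }
  herbs <- sort(unique(herb_universe))
  prots <- sort(unique(protein_universe))
  total <- as.double(length(herbs)) * length(prots)
  banned <- unique(c(
    if (!is.null(positive_pairs) && nrow(positive_pairs) > 0)
      paste(positive_pairs$herb, positive_pairs$protein, sep = "\r"),
    if (!is.null(exclude) && nrow(exclude) > 0)
      paste(exclude$herb, exclude$protein, sep = "\r")))
  if (total - length(banned) < n) {
    stop("universe too small: only ", total - length(banned),
         " non-positive pairs available, need ", n)
  }
  got <- character(0)
  rng_seed <- derive_seed(seed, "negatives")
  tries <- 0L
  while (length(got) < n) {
    tries <- tries + 1L
    if (tries > 50L) stop("negative sampling failed to converge")
    need <- n - length(got)
    draw <- withr_seed(rng_seed + tries, {
      hi <- sample.int(length(herbs), need * 2L, replace = TRUE)
      pi <- sample.int(length(prots), need * 2L, replace = TRUE)
      paste(herbs[hi], prots[pi], sep = "\r")
    })
    draw <- setdiff(unique(draw), c(banned, got))
    got <- c(got, head(draw, need))
  }
  parts <- strsplit(got, "\r", fixed = TRUE)
  data.frame(herb = vapply(parts, `[[`, character(1), 1),
             protein = vapply(parts, `[[`, character(1), 2),
             stringsAsFactors = FALSE)
}

# Evaluate an expression under a local RNG seed, restoring global state.
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Model specification for pair classification
#'
#' The supervised families scored over Hadamard pair features: k-nearest
#' neighbors (`knn`), support vector machine (`svm`), logistic regression
#' (`lr`), decision tree (`dt`), random forest (`rf`), gradient-boosted
#' trees (`gbdt`) and an optional single-hidden-layer neural network
#' (`mlp`). Family hyperparameters follow common library defaults unless
#' overridden via `...`; KNN defaults to k = 5 with Euclidean distance.
#'
#' @param family one of `"knn"`, `"svm"`, `"lr"`, `"dt"`, `"rf"`,
#'   `"gbdt"`, `"mlp"`.
#' @param k neighbors for KNN (odd by default).
#' @param metric KNN distance: `"euclidean"` or `"cosine"`.
#' @param seed integer seed for stochastic families.
#' @param ... additional family-specific hyperparameters.
#' @return A `model_spec` list.
#' @export
model_spec <- function(family = c("knn", "svm", "lr", "dt", "rf", "gbdt",
                                  "mlp"),
                       k = 5L, metric = c("euclidean", "cosine"),
                       seed = 1L, ...) {
  family <- match.arg(family)
  metric <- match.arg(metric)
  stopifnot(k >= 1)
  structure(list(family = family, k = as.integer(k), metric = metric,
                 seed = as.integer(seed), extra = list(...)),
            class = "model_spec")
}

# squared Euclidean distances between rows of q and rows of x
pairwise_dist2 <- function(q, x) {
  d2 <- outer(rowSums(q^2), rep(1, nrow(x))) +
    outer(rep(1, nrow(q)), rowSums(x^2)) - 2 * tcrossprod(q, x)
  d2[d2 < 0] <- 0
  d2
}

#' Quantized KNN interaction probability
#'
#' The probability assigned to a query pair is the fraction of
#' positive-labeled pairs among its k nearest training features, so with
#' k = 5 every prediction lies in \{0, 0.2, 0.4, 0.6, 0.8, 1\}. Distance
#' ties at the k-th neighbor are broken by training-point insertion order.
#'
#' @param query numeric matrix of query features (or a single vector).
#' @param train_x numeric matrix of training features.
#' @param train_y binary labels (1 = positive) for `train_x` rows.
#' @param k number of neighbors; must not exceed `nrow(train_x)`.
#' @param metric `"euclidean"` (default) or `"cosine"` distance.
#' @return Numeric vector of probabilities, one per query row.
#' @export
knn_probability <- function(query, train_x, train_y, k = 5L,
                            metric = c("euclidean", "cosine")) {
  metric <- match.arg(metric)
  if (is.null(dim(query))) query <- matrix(query, nrow = 1)
  train_x <- as.matrix(train_x)
  if (k > nrow(train_x)) {
    stop("k = ", k, " exceeds the number of training points (",
         nrow(train_x), ")")
  }
  stopifnot(length(train_y) == nrow(train_x))
  y <- as.numeric(train_y)
  if (metric == "euclidean") {
    d <- pairwise_dist2(query, train_x)
  } else {
    qn <- sqrt(rowSums(query^2)); qn[qn == 0] <- 1
    tn <- sqrt(rowSums(train_x^2)); tn[tn == 0] <- 1
    d <- 1 - tcrossprod(query / qn, train_x / tn)
  }
  apply(d, 1, function(row) {
    nn <- order(row)[seq_len(k)]  # order() breaks ties by insertion order
    mean(y[nn])
  })
}

#' Train a pair classifier
#'
#' Fits the family in `spec` on a balanced training set of pair features
#' and returns a scorer: a function mapping a feature matrix to scores in
#' \[0, 1\]. Stochastic families are seeded from the spec.
#'
#' @param spec a [model_spec()].
#' @param train_x numeric feature matrix.
#' @param train_y binary labels (1 = positive).
#' @return An `hti_scorer`: function(feature matrix) -> scores, with the
#'   spec attached as an attribute.
#' @export
train_model <- function(spec, train_x, train_y) {
  stopifnot(inherits(spec, "model_spec"))
  train_x <- as.matrix(train_x)
  y <- as.numeric(train_y)
  if (length(unique(y)) < 2) {
    stop("training set is single-class; need both positives and negatives")
  }
  colnames(train_x) <- paste0("f", seq_len(ncol(train_x)))
  scorer <- switch(
    spec$family,
    knn = {
      force(spec)
      function(x) knn_probability(as.matrix(x), train_x, y,
                                  k = spec$k, metric = spec$metric)
    },
    lr = {
      df <- data.frame(train_x)
      df$.y <- y
      fit <- stats::glm(.y ~ ., data = df, family = stats::binomial())
      function(x) {
        x <- as.matrix(x); colnames(x) <- colnames(train_x)
        as.numeric(stats::predict(fit, newdata = data.frame(x),
                                  type = "response"))
      }
    },
    svm = {
      fit <- withr_seed(spec$seed,
        e1071::svm(train_x, factor(y, levels = c(0, 1)),
                   probability = TRUE, kernel = "radial"))
      function(x) {
        x <- as.matrix(x); colnames(x) <- colnames(train_x)
        pr <- attr(stats::predict(fit, x, probability = TRUE),
                   "probabilities")
        as.numeric(pr[, "1"])
      }
    },
    dt = {
      df <- data.frame(train_x)
      df$.y <- factor(y, levels = c(0, 1))
      fit <- rpart::rpart(.y ~ ., data = df, method = "class")
      function(x) {
        x <- as.matrix(x); colnames(x) <- colnames(train_x)
        as.numeric(stats::predict(fit, data.frame(x))[, "1"])
      }
    },
    rf = {
      fit <- withr_seed(spec$seed,
        randomForest::randomForest(train_x, factor(y, levels = c(0, 1)),
                                   ntree = 500))
      function(x) {
        x <- as.matrix(x); colnames(x) <- colnames(train_x)
        as.numeric(stats::predict(fit, x, type = "prob")[, "1"])
      }
    },
    gbdt = {
      nrounds <- spec$extra$nrounds %||% 100
      dtrain <- xgboost::xgb.DMatrix(train_x, label = y, nthread = 1)
      fit <- withr_seed(spec$seed,
        xgboost::xgb.train(params = list(objective = "binary:logistic",
                                         max_depth = 3, eta = 0.3,
                                         nthread = 1),
                           data = dtrain, nrounds = nrounds, verbose = 0))
      function(x) {
        as.numeric(stats::predict(fit,
                                  xgboost::xgb.DMatrix(as.matrix(x),
                                                       nthread = 1)))
      }
    },
    mlp = {
      if (!requireNamespace("nnet", quietly = TRUE)) {
        stop("the mlp family needs the 'nnet' package")
      }
      size <- spec$extra$size %||% max(2L, ncol(train_x) %/% 2L)
      fit <- withr_seed(spec$seed,
        nnet::nnet(train_x, y, size = size, maxit = 200, decay = 1e-4,
                   trace = FALSE))
      function(x) {
        pmin(pmax(as.numeric(stats::predict(fit, as.matrix(x))), 0), 1)
      }
    })
  structure(scorer, class = c("hti_scorer", "function"), spec = spec)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Rank unknown candidate pairs by predicted probability
#'
#' Scores each candidate pair and returns them sorted by descending
#' probability, ties broken by (herb, protein) lexicographic order so the
#' ranking is reproducible. The fraction of candidates scoring below 0.5
#' is attached as an attribute (`frac_below_half`).
#'
#' @param scorer an `hti_scorer` from [train_model()].
#' @param model an `embedding_model` used to featurize candidates.
#' @param candidates data.frame `herb`, `protein`; must exclude known
#'   positives.
#' @param block_size candidates featurized and scored per block.
#' @return data.frame `herb`, `protein`, `probability`, sorted.
#' @export
rank_unknown_pairs <- function(scorer, model, candidates,
                               block_size = 50000L) {
  if (is.null(candidates) || nrow(candidates) == 0) {
    out <- data.frame(herb = character(), protein = character(),
                      probability = numeric())
    attr(out, "frac_below_half") <- NA_real_
    return(out)
  }
  scored <- list()
  for (start in seq(1, nrow(candidates), by = block_size)) {
    end <- min(start + block_size - 1, nrow(candidates))
    blk <- candidates[start:end, , drop = FALSE]
    x <- featurize_pairs(model, blk)
    blk$probability <- as.numeric(scorer(x))
    scored[[length(scored) + 1]] <- blk
  }
  out <- do.call(rbind, scored)
  out <- out[order(-out$probability, out$herb, out$protein), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "frac_below_half") <- mean(out$probability < 0.5)
  out
}
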