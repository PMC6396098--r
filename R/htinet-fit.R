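#' Fit an HTINet herb-target interaction model
#'
#' The full modelling pipeline in one call: learn node2vec embeddings of
#' the heterogeneous network (second-order biased walks + skip-gram
#' negative sampling), featurize (herb, protein) pairs by the Hadamard
#' product of their node vectors, and train the chosen classifier on the
#' known positive interactions plus a matched sample of non-interacting
#' pairs. The positive interactions are the supervised label set and are
#' not edges of the network, so no edge masking is needed before
#' embedding.
#'
#' @param network an [hti_network()].
#' @param positives data.frame of known interactions (`herb`, `protein`,
#'   namespaced ids).
#' @param model classifier family (see [model_spec()]); default `"knn"`.
#' @param d embedding dimension (default 64).
#' @param num_walks walks per node (default 10).
#' @param walk_length nodes per walk (default 40).
#' @param p,q walk bias parameters (default 1, 1).
#' @param window,negatives,epochs skip-gram hyperparameters.
#' @param k KNN neighbor count (default 5).
#' @param n_negatives training negatives (default: matched,
#'   `nrow(positives)`).
#' @param seed top-level seed; per-stage seeds are derived from it.
#' @return An object of class `htinet` with the embedding model, fitted
#'   scorer, spec and training metadata. Methods: [predict.htinet()],
#'   [print.htinet()], [summary.htinet()].
#' @examples
#' \donttest{
#' cfg <- synth_config(herbs = 40, symptoms = 20, diseases = 20,
#'                     drugs = 15, proteins = 60, n_positives = 80,
#'                     seed = 7)
#' gen <- generate_network(cfg)
#' fit <- htinet(gen$network, gen$positives, d = 16, epochs = 2, seed = 7)
#' predict(fit, gen$positives[1:3, ])
#' }
#' @export
htinet <- function(network, positives, model = "knn", d = 64L,
                   num_walks = 10L, walk_length = 40L, p = 1, q = 1,
                   window = 10L, negatives = 5L, epochs = 5L, k = 5L,
                   n_negatives = nrow(positives), seed = 1L) {
  stopifnot(inherits(network, "hti_network"),
            all(c("herb", "protein") %in% names(positives)),
            nrow(positives) >= 1)
  missing <- setdiff(c(positives$herb, positives$protein),
                     network$nodes$id)
  if (length(missing) > 0) {
    stop("positive-pair endpoints missing from the network: ",
         paste(head(missing, 5), collapse = ", "))
  }
  wcfg <- walk_config(p = p, q = q, num_walks = num_walks,
                      walk_length = walk_length,
                      seed = derive_seed(seed, "walks"))
  embedding <- node2vec(network, d = d, config = wcfg, window = window,
                        negatives = negatives, epochs = epochs,
                        seed = seed)
  universe <- list(herbs = nodes_of_type(network, "herb"),
                   proteins = nodes_of_type(network, "protein"))
  neg <- sample_negatives(positives, universe$herbs, universe$proteins,
                          n = n_negatives,
                          seed = derive_seed(seed, "fit_negatives"))
  spec <- model_spec(model, k = k, seed = derive_seed(seed, "model"))
  train_pairs <- rbind(positives[, c("herb", "protein")], neg)
  train_y <- c(rep(1, nrow(positives)), rep(0, nrow(neg)))
  x <- featurize_pairs(embedding, train_pairs)
  scorer <- train_model(spec, x, train_y)
  structure(list(embedding = embedding, scorer = scorer, spec = spec,
                 positives = positives[, c("herb", "protein")],
                 negatives = neg, universe = universe,
                 network_summary = summary(network),
                 seed = as.integer(seed), call = match.call()),
            class = "htinet")
}

#' Predict interaction probabilities for (herb, protein) pairs
#'
#' @param object a fitted [htinet()] model.
#' @param newdata data.frame with columns `herb`, `protein`.
#' @param ... unused.
#' @return Numeric vector of interaction scores in \[0, 1\] (for the KNN
#'   family, quantized to multiples of 1/k).
#' @export
predict.htinet <- function(object, newdata, ...) {
  x <- featurize_pairs(object$embedding, newdata)
  as.numeric(object$scorer(x))
}

#' @export
print.htinet <- function(x, ...) {
  cat("HTINet model (", x$spec$family, ")\n", sep = "")
  cat("  embedding: ", nrow(x$embedding$vectors), " nodes x ",
      x$embedding$d, " dims\n", sep = "")
  cat("  training: ", nrow(x$positives), " positives + ",
      nrow(x$negatives), " sampled negatives\n", sep = "")
  invisible(x)
}

#' Summarize a fitted HTINet model
#' @param object a fitted `htinet` model.
#' @param ... unused.
#' @return `object`, invisibly.
#' @export
summary.htinet <- function(object, ...) {
  print(object)
  cat("network:\n")
  print(object$network_summary)
  invisible(object)
}

#' Rank all unknown candidate pairs of a fitted model
#'
#' Enumerates the herb x protein cross product minus the known positives
#' (in memory-bounded blocks), scores every candidate, and returns the
#' ranking with deterministic tie-breaking.
#'
#' @param object a fitted [htinet()] model.
#' @param block_size candidates per scoring block.
#' @param top_n optionally truncate the returned ranking (the
#'   `frac_below_half` attribute is still computed over all candidates).
#' @return data.frame `herb`, `protein`, `probability` sorted descending,
#'   with attribute `frac_below_half`.
#' @export
rank_candidates <- function(object, block_size = 50000L, top_n = NULL) {
  stopifnot(inherits(object, "htinet"))
  cand <- enumerate_candidates(object$universe$herbs,
                               object$universe$proteins,
                               exclude = object$positives,
                               block_size = block_size)
  out <- rank_unknown_pairs(object$scorer, object$embedding, cand,
                            block_size = block_size)
  if (!is.null(top_n) && nrow(out) > top_n) {
    fb <- attr(out, "frac_below_half")
    out <- out[seq_len(top_n), , drop = FALSE]
    attr(out, "frac_below_half") <- fb
  }
  out
}
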