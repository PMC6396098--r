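#' PRINCE propagation configuration
#'
#' @param alpha diffusion/prior trade-off in (0, 1): the weight on
#'   network smoothing versus retention of the prior. Default 0.9.
#' @param tol convergence tolerance on the max-norm change per iteration.
#' @param max_iter iteration cap; non-convergence warns and returns the
#'   last iterate.
#' @return A `prince_config` list.
#' @export
prince_config <- function(alpha = 0.9, tol = 1e-8, max_iter = 1000L) {
  stopifnot(alpha > 0, alpha < 1, tol > 0, max_iter >= 1)
  structure(list(alpha = alpha, tol = tol, max_iter = as.integer(max_iter)),
            class = "prince_config")
}

# symmetrically degree-normalized weighted adjacency D^-1/2 W D^-1/2
normalized_adjacency <- function(network) {
  g <- network$graph
  W <- igraph::as_adjacency_matrix(g, attr = "weight", sparse = TRUE)
  W <- methods::as(W, "CsparseMatrix")
  stopifnot(identical(rownames(W), network$nodes$id))
  deg <- Matrix::rowSums(W)
  dinv <- ifelse(deg > 0, 1 / sqrt(deg), 0)
  Matrix::Diagonal(x = dinv) %*% W %*% Matrix::Diagonal(x = dinv)
}

#' PRINCE network propagation
#'
#' Iterates `F <- alpha * W' F + (1 - alpha) * Y` with `W'` the
#' symmetrically degree-normalized weighted adjacency and `Y` the prior,
#' until the max-norm change drops below `tol` or `max_iter` is reached.
#' Since the spectral radius of `W'` is at most 1, the update is a
#' contraction for `alpha < 1` and converges to the unique fixed point
#' `(1 - alpha) (I - alpha W')^{-1} Y`.
#'
#' @param network an [hti_network()].
#' @param prior named numeric vector of prior scores in \[0, 1\]; nodes
#'   not named get prior 0.
#' @param config a [prince_config()].
#' @return Named numeric vector of propagated scores over all nodes.
#' @export
prince_propagate <- function(network, prior, config = prince_config()) {
  stopifnot(inherits(network, "hti_network"),
            inherits(config, "prince_config"))
  ids <- network$nodes$id
  y <- setNames(numeric(length(ids)), ids)
  if (length(prior) > 0) {
    if (is.null(names(prior))) stop("prior must be a named vector")
    unknown <- setdiff(names(prior), ids)
    if (length(unknown) > 0) {
      stop("prior names not in network: ",
           paste(head(unknown, 5), collapse = ", "))
    }
    y[names(prior)] <- prior
  }
  Wn <- normalized_adjacency(network)
  # igraph vertex order == network$nodes order (both sorted ids)
  f <- propagate_iterate(Wn, matrix(y, ncol = 1), config)
  setNames(as.numeric(f), ids)
}

propagate_iterate <- function(Wn, Y, config) {
  F0 <- Y
  for (it in seq_len(config$max_iter)) {
    F1 <- config$alpha * (Wn %*% F0) + (1 - config$alpha) * Y
    delta <- max(abs(F1 - F0))
    F0 <- F1
    if (delta < config$tol) return(as.matrix(F0))
  }
  warning("PRINCE did not converge in ", config$max_iter,
          " iterations (last change ", signif(delta, 3), ")")
  as.matrix(F0)
}

#' Rank protein targets for a herb by network propagation
#'
#' Places a point-mass prior on the herb node, propagates, and returns
#' the protein nodes ranked by their propagated score (descending; ties
#' broken by protein id for reproducibility).
#'
#' @param network an [hti_network()].
#' @param herb namespaced herb node id present in the network.
#' @param config a [prince_config()].
#' @return data.frame `protein`, `score`, ranked.
#' @export
prince_rank_targets <- function(network, herb, config = prince_config()) {
  if (!herb %in% network$nodes$id) stop("herb not in network: ", herb)
  f <- prince_propagate(network, setNames(1.0, herb), config)
  prots <- nodes_of_type(network, "protein")
  out <- data.frame(protein = prots, score = as.numeric(f[prots]),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$score, out$protein), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Propagation scores for a batch of (herb, protein) pairs
#'
#' Runs one propagation per distinct herb (as a multi-column iteration)
#' and reads off the scores at the protein endpoints.
#'
#' @param network an [hti_network()].
#' @param pairs data.frame `herb`, `protein`.
#' @param config a [prince_config()].
#' @return Numeric vector of scores aligned with `pairs` rows.
#' @export
prince_scores <- function(network, pairs, config = prince_config()) {
  stopifnot(inherits(network, "hti_network"))
  ids <- network$nodes$id
  herbs <- sort(unique(pairs$herb))
  missing <- setdiff(c(herbs, unique(pairs$protein)), ids)
  if (length(missing) > 0) {
    stop("pair endpoints not in network: ",
         paste(head(missing, 5), collapse = ", "))
  }
  Wn <- normalized_adjacency(network)
  Y <- matrix(0, length(ids), length(herbs),
              dimnames = list(ids, herbs))
  Y[cbind(match(herbs, ids), seq_along(herbs))] <- 1
  f <- propagate_iterate(Wn, Y, config)
  dimnames(f) <- dimnames(Y)
  f[cbind(match(pairs$protein, ids), match(pairs$herb, herbs))]
}

#' PRINCE as a cross-validation pipeline
#'
#' The propagation baseline needs no supervised training: its `fit` step
#' ignores the training pairs and scores test pairs by propagating a
#' point-mass prior from each herb. Usable directly in
#' [cross_validate()] for paired comparison against classifier pipelines.
#'
#' @param network an [hti_network()].
#' @param config a [prince_config()].
#' @return An `hti_pipeline`.
#' @export
prince_pipeline <- function(network, config = prince_config()) {
  structure(list(
    name = "PRINCE",
    fit = function(train_pairs, train_labels) {
      function(pairs) prince_scores(network, pairs, config)
    }), class = "hti_pipeline")
}
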