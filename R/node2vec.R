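#' Random-walk configuration
#'
#' Parameters of the second-order biased walk: return parameter `p`
#' (higher p discourages immediately revisiting the previous node),
#' in-out parameter `q` (higher q keeps the walk near its source),
#' `num_walks` walks started from every node and `walk_length` nodes per
#' walk. Defaults p = q = 1 (the unbiased first-order walk) with 10 walks
#' of length 80.
#'
#' @param p return parameter, > 0.
#' @param q in-out parameter, > 0.
#' @param num_walks walks per node, >= 1.
#' @param walk_length nodes per walk, >= 2.
#' @param seed integer RNG seed for the walk simulation.
#' @return A `walk_config` list.
#' @export
walk_config <- function(p = 1, q = 1, num_walks = 10, walk_length = 80,
                        seed = 1L) {
  stopifnot(p > 0, q > 0, num_walks >= 1, walk_length >= 2)
  structure(list(p = p, q = q, num_walks = as.integer(num_walks),
                 walk_length = as.integer(walk_length),
                 seed = as.integer(seed)),
            class = "walk_config")
}

#' Second-order walk bias factor
#'
#' The bias applied to the edge weight toward a candidate next node `x`
#' given the previous node `t`: 1/p when x is t itself (distance 0), 1
#' when x neighbors t (distance 1), and 1/q when x is two steps from t.
#'
#' @param d_tx shortest-path distance between t and x; must be 0, 1 or 2.
#' @param p,q walk bias parameters, > 0.
#' @return The multiplicative bias.
#' @export
bias_factor <- function(d_tx, p, q) {
  stopifnot(p > 0, q > 0)
  if (!all(d_tx %in% c(0, 1, 2))) {
    stop("d_tx must be 0, 1 or 2 (t and x are at most two steps apart)")
  }
  ifelse(d_tx == 0, 1 / p, ifelse(d_tx == 1, 1, 1 / q))
}

#' Exact second-order transition distribution
#'
#' For a walk currently at `v` having arrived from `t`, the probability of
#' stepping to each neighbor x of v is proportional to
#' `bias_factor(d(t, x), p, q) * w(v, x)`. With `t = NULL` (first step)
#' the bias is identically 1 and the draw is by edge weight alone.
#'
#' This is the exact reference distribution; the walk simulator draws from
#' it and is checked against it empirically.
#'
#' @param network an [hti_network()].
#' @param t previous node id or `NULL` for the first step.
#' @param v current node id; must have at least one neighbor.
#' @param p,q walk bias parameters.
#' @return Named numeric vector of probabilities over the neighbors of v,
#'   summing to 1.
#' @export
transition_distribution <- function(network, t, v, p = 1, q = 1) {
  stopifnot(inherits(network, "hti_network"), p > 0, q > 0)
  g <- network$graph
  vv <- match(v, igraph::V(g)$name)
  if (is.na(vv)) stop("node not in network: ", v)
  inc <- igraph::incident(g, vv)
  if (length(inc) == 0) stop("node has no neighbors: ", v)
  ends <- igraph::ends(g, inc, names = TRUE)
  nbr <- ifelse(ends[, 1] == v, ends[, 2], ends[, 1])
  w <- igraph::E(g)$weight[as.integer(inc)]
  if (is.null(w)) w <- rep(1, length(nbr))
  if (!is.null(t)) {
    if (!igraph::are_adjacent(g, t, v)) {
      stop("(t, v) must be an edge of the network")
    }
    t_nbr <- igraph::V(g)$name[as.integer(igraph::neighbors(g, t))]
    d_tx <- ifelse(nbr == t, 0, ifelse(nbr %in% t_nbr, 1, 2))
    w <- w * bias_factor(d_tx, p, q)
  }
  pr <- w / sum(w)
  names(pr) <- nbr
  pr[order(names(pr))]
}

#' Simulate a corpus of biased random walks
#'
#' Starts `num_walks` walks from every node of the network (node order
#' shuffled per round), each following the second-order transition rule.
#' Isolated nodes yield length-1 walks. Fully deterministic for a given
#' seed.
#'
#' @param network an [hti_network()].
#' @param config a [walk_config()].
#' @return An object of class `walk_corpus`: list with `walks` (list of
#'   character vectors of node ids) and the `config`.
#' @export
simulate_walks <- function(network, config = walk_config()) {
  stopifnot(inherits(network, "hti_network"), inherits(config, "walk_config"))
  wg <- walk_graph(network)
  if (wg$n == 0) stop("network has no nodes")
  starts <- integer(0)
  ord_rng <- local({
    s <- derive_seed(config$seed, "walk_order")
    function(n) {
      # deterministic permutation per round without touching R's RNG
      r <- numeric(n)
      for (i in seq_len(n)) {
        s <<- (s * 69069 + 1) %% 2^31
        r[i] <- s
      }
      order(r)
    }
  })
  for (r in seq_len(config$num_walks)) {
    starts <- c(starts, seq_len(wg$n)[ord_rng(wg$n)] - 1L)
  }
  walks <- cpp_simulate_walks(wg$offsets, wg$neighbors, wg$weights,
                              starts, config$walk_length,
                              config$p, config$q,
                              as.double(derive_seed(config$seed, "walk")))
  walks <- lapply(walks, function(ix) wg$ids[ix + 1L])
  structure(list(walks = walks, config = config, node_ids = wg$ids),
            class = "walk_corpus")
}

#' @export
print.walk_corpus <- function(x, ...) {
  cat("<walk_corpus> ", length(x$walks), " walks, mean length ",
      round(mean(lengths(x$walks)), 1), "\n", sep = "")
  invisible(x)
}

#' Write a walk corpus as plain text (one walk per line)
#' @param corpus a `walk_corpus`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_walks <- function(corpus, path) {
  writeLines(vapply(corpus$walks, paste, character(1), collapse = " "), path)
  invisible(path)
}

#' Learn node embeddings from a walk corpus
#'
#' Fits d-dimensional vectors maximizing the skip-gram
#' negative-sampling objective over node co-occurrences within a context
#' window along the walks — the standard stochastic surrogate for the
#' softmax neighborhood-likelihood objective. Training is single-threaded
#' and exactly reproducible for a given seed.
#'
#' @param corpus a `walk_corpus` from [simulate_walks()], covering every
#'   node for which a vector is required.
#' @param d embedding dimension, >= 2.
#' @param window context window half-width (default 10).
#' @param negatives negative samples per positive pair (default 5).
#' @param epochs passes over the corpus (default 5).
#' @param alpha initial learning rate (default 0.025, linearly decayed).
#' @param seed integer seed for initialization and sampling.
#' @param normalize if `TRUE`, unit-normalize vectors after training
#'   (off by default; Hadamard pair features use raw vectors).
#' @return An `embedding_model`: list with `vectors` (matrix, one row per
#'   node id), `d`, and the training hyperparameters.
#' @export
learn_embeddings <- function(corpus, d = 128, window = 10, negatives = 5,
                             epochs = 5, alpha = 0.025, seed = 1L,
                             normalize = FALSE) {
  stopifnot(inherits(corpus, "walk_corpus"), d >= 2)
  if (length(corpus$walks) == 0) stop("empty walk corpus")
  ids <- sort(unique(unlist(corpus$walks, use.names = FALSE)))
  missing <- setdiff(corpus$node_ids, ids)
  if (length(missing) > 0) {
    stop("node(s) absent from walk corpus, no vector can be learned: ",
         paste(head(missing, 5), collapse = ", "))
  }
  idx <- lapply(corpus$walks, function(w) match(w, ids) - 1L)
  mat <- cpp_train_sgns(idx, length(ids), as.integer(d), as.integer(window),
                        as.integer(negatives), as.integer(epochs),
                        alpha, as.double(seed))
  rownames(mat) <- ids
  if (normalize) {
    nrm <- sqrt(rowSums(mat^2))
    nrm[nrm == 0] <- 1
    mat <- mat / nrm
  }
  structure(list(vectors = mat, d = as.integer(d),
                 window = as.integer(window),
                 negatives = as.integer(negatives),
                 epochs = as.integer(epochs), alpha = alpha,
                 seed = as.integer(seed), normalized = normalize),
            class = "embedding_model")
}

#' @export
print.embedding_model <- function(x, ...) {
  cat("<embedding_model> ", nrow(x$vectors), " nodes x ", x$d,
      " dimensions\n", sep = "")
  invisible(x)
}

#' Embed a heterogeneous network with node2vec
#'
#' Convenience wrapper: simulate biased walks over the whole network (all
#' node types walked uniformly as a single graph) and fit skip-gram
#' embeddings.
#'
#' @param network an [hti_network()].
#' @param d embedding dimension.
#' @param config a [walk_config()].
#' @inheritParams learn_embeddings
#' @return An `embedding_model`.
#' @export
node2vec <- function(network, d = 128, config = walk_config(),
                     window = 10, negatives = 5, epochs = 5,
                     alpha = 0.025, seed = config$seed,
                     normalize = FALSE) {
  corpus <- simulate_walks(network, config)
  learn_embeddings(corpus, d = d, window = window, negatives = negatives,
                   epochs = epochs, alpha = alpha,
                   seed = derive_seed(seed, "sgns"), normalize = normalize)
}

#' Write embeddings as a word2vec-style text matrix
#'
#' First line `n d`, then one line per node: id followed by d floats.
#'
#' @param model an `embedding_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_embeddings <- function(model, path) {
  stopifnot(inherits(model, "embedding_model"))
  m <- model$vectors
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(nrow(m), ncol(m)), con)
  writeLines(paste(rownames(m),
                   apply(m, 1, function(r) {
                     paste(sprintf("%.9g", r), collapse = " ")
                   })), con)
  invisible(path)
}

#' Read embeddings from a word2vec-style text matrix
#' @param path file written by [write_embeddings()].
#' @return An `embedding_model` (training hyperparameters unknown).
#' @export
read_embeddings <- function(path) {
  lines <- readLines(path)
  hdr <- as.integer(strsplit(lines[1], " ")[[1]])
  parts <- strsplit(trimws(lines[-1]), "[[:space:]]+")
  ids <- vapply(parts, `[[`, character(1), 1)
  mat <- do.call(rbind, lapply(parts, function(p) as.numeric(p[-1])))
  stopifnot(nrow(mat) == hdr[1], ncol(mat) == hdr[2])
  rownames(mat) <- ids
  structure(list(vectors = mat, d = hdr[2], window = NA_integer_,
                 negatives = NA_integer_, epochs = NA_integer_,
                 alpha = NA_real_, seed = NA_integer_, normalized = NA),
            class = "embedding_model")
}

#' Derive a stage seed from a top-level seed
#'
#' Splitmix-style derivation so pipeline stages (walks, training, negative
#' sampling, folds) get independent, reproducible streams from one
#' user-facing seed. Result is a non-negative integer below 2^31.
#'
#' @param seed integer top-level seed.
#' @param stage character stage label.
#' @return Derived integer seed.
#' @export
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  x <- (as.double(seed) * 2654435761 + h * 40503 + 97) %% 2147483647
  as.integer(floor(x))
}
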