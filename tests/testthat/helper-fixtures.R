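# Shared fixtures built in code.

# Small planted-signal config: quick to generate and embed, still carries
# recoverable signal.
small_synth <- function(seed = 11, ...) {
  synth_config(herbs = 40, symptoms = 20, diseases = 20, drugs = 15,
               proteins = 60, n_clusters = 3, n_positives = 90,
               seed = seed, ...)
}

# Single-layer protein-protein network from a symmetric adjacency matrix
# (rows/cols named), used for walk/propagation oracle checks.
ppi_network <- function(adj, weights = NULL) {
  idx <- which(upper.tri(adj) & adj != 0, arr.ind = TRUE)
  ids <- rownames(adj)
  w <- if (is.null(weights)) adj[idx] else weights
  edges <- data.frame(source = ids[idx[, 1]], target = ids[idx[, 2]],
                      layer = "protein_protein", weight = w,
                      stringsAsFactors = FALSE)
  extra <- data.frame(id = ids, type = "protein")
  hti_network(edges, extra_nodes = extra)
}

# Random connected-ish weighted graph as a protein-protein network.
random_ppi <- function(n, p_edge = 0.5, seed = 1, weighted = TRUE) {
  set.seed(seed)
  adj <- matrix(0, n, n)
  ids <- sprintf("protein:n%02d", seq_len(n))
  dimnames(adj) <- list(ids, ids)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      if (runif(1) < p_edge) {
        w <- if (weighted) round(runif(1, 0.1, 1), 3) else 1
        adj[i, j] <- w
        adj[j, i] <- w
      }
    }
  }
  # keep no isolated nodes: chain any isolates to node 1
  iso <- which(rowSums(adj) == 0)
  for (i in setdiff(iso, 1)) {
    adj[1, i] <- adj[i, 1] <- 0.5
  }
  adj
}

# Barbell adjacency: two k-cliques joined by a single bridge edge.
barbell_adj <- function(k = 10) {
  n <- 2 * k
  adj <- matrix(0, n, n)
  ids <- sprintf("protein:b%02d", seq_len(n))
  dimnames(adj) <- list(ids, ids)
  adj[seq_len(k), seq_len(k)] <- 1
  adj[seq(k + 1, n), seq(k + 1, n)] <- 1
  diag(adj) <- 0
  adj[k, k + 1] <- adj[k + 1, k] <- 1
  adj
}

# Independent reference for the second-order transition law, structured
# differently from the package implementation: uses igraph shortest-path
# distances for the bias classification.
oracle_transition <- function(network, t, v, p, q) {
  g <- network$graph
  nb <- igraph::neighbors(g, v)
  nb_ids <- igraph::V(g)$name[as.integer(nb)]
  w <- vapply(nb_ids, function(x) {
    eid <- igraph::get_edge_ids(g, c(v, x))
    igraph::E(g)$weight[eid]
  }, numeric(1))
  if (!is.null(t)) {
    dist_t <- igraph::distances(g, v = t, weights = NA)[1, ]
    d_tx <- dist_t[nb_ids]
    stopifnot(all(d_tx <= 2))
    alpha <- ifelse(d_tx == 0, 1 / p, ifelse(d_tx == 1, 1, 1 / q))
    w <- w * alpha
  }
  pr <- w / sum(w)
  names(pr) <- nb_ids
  pr[order(names(pr))]
}

# Two-sided Fisher p-value by direct hypergeometric enumeration over all
# tables with the observed margins.
oracle_fisher_p <- function(a, b, c, d) {
  m <- a + b
  n <- c + d
  k <- a + c
  lo <- max(0, k - n)
  hi <- min(k, m)
  probs <- stats::dhyper(lo:hi, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Exact two-sided signed-rank p by enumeration of all 2^n sign patterns.
oracle_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  vs <- numeric(2^n)
  for (m in 0:(2^n - 1)) {
    signs <- as.logical(bitwAnd(m, 2^(0:(n - 1))))
    vs[m + 1] <- sum(r[signs])
  }
  p_le <- mean(vs <= v_obs + 1e-9)
  p_ge <- mean(vs >= v_obs - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

# Brute-force AUROC over all positive-negative score pairs.
oracle_auroc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# Brute-force AUPR by exhaustive threshold sweep over distinct scores.
oracle_aupr <- function(scores, labels) {
  np <- sum(labels == 1)
  th <- sort(unique(scores), decreasing = TRUE)
  prec <- rec <- numeric(length(th))
  for (i in seq_along(th)) {
    sel <- scores >= th[i]
    prec[i] <- sum(labels[sel] == 1) / sum(sel)
    rec[i] <- sum(labels[sel] == 1) / np
  }
  sum(diff(c(0, rec)) * prec)
}

# Brute-force KNN probability: per-query loop with full distance scan.
oracle_knn_prob <- function(query, train_x, train_y, k) {
  apply(query, 1, function(qr) {
    d <- sqrt(colSums((t(train_x) - qr)^2))
    mean(train_y[order(d)[seq_len(k)]])
  })
}

# Tiny four-node toy network written as an edge-list file.
write_toy_edges <- function(path) {
  writeLines(c("h1\ts1\therb_symptom\t1.0",
               "s1\td1\tdisease_symptom\t0.5",
               "h1\th1\therb_herb\t1.0"), path)
  path
}
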