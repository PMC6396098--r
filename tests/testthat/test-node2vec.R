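test_that("bias factor follows the distance-0/1/2 rule", {
  expect_equal(bias_factor(1, p = 3, q = 7), 1.0)
  expect_equal(bias_factor(0, p = 0.25, q = 1), 4.0)
  expect_equal(bias_factor(2, p = 1, q = 2), 0.5)
  expect_error(bias_factor(3, 1, 1), "d_tx")
})

test_that("transition distribution matches hand evaluation on triangle plus pendant", {
  # t--v--x triangle (t-x edge closes it) plus pendant v--y
  adj <- matrix(0, 4, 4,
                dimnames = list(c("protein:t", "protein:v", "protein:x",
                                  "protein:y"),
                                c("protein:t", "protein:v", "protein:x",
                                  "protein:y")))
  adj["protein:t", "protein:v"] <- adj["protein:v", "protein:t"] <- 1
  adj["protein:v", "protein:x"] <- adj["protein:x", "protein:v"] <- 1
  adj["protein:t", "protein:x"] <- adj["protein:x", "protein:t"] <- 1
  adj["protein:v", "protein:y"] <- adj["protein:y", "protein:v"] <- 1
  net <- ppi_network(adj)

  pr <- transition_distribution(net, "protein:t", "protein:v", p = 1, q = 1)
  expect_equal(unname(pr), rep(1 / 3, 3))

  pr2 <- transition_distribution(net, "protein:t", "protein:v",
                                 p = 4, q = 0.25)
  expect_equal(pr2[["protein:t"]], 1 / 21)
  expect_equal(pr2[["protein:x"]], 4 / 21)
  expect_equal(pr2[["protein:y"]], 16 / 21)

  # first step: weighted draw with no bias
  pr0 <- transition_distribution(net, NULL, "protein:v")
  expect_equal(unname(pr0), rep(1 / 3, 3))
})

test_that("transition distribution equals exhaustive evaluation on all small random graphs", {
  for (seed in 1:12) {
    n <- sample(3:8, 1)
    adj <- random_ppi(n, p_edge = 0.5, seed = seed)
    net <- ppi_network(adj)
    ids <- net$nodes$id
    p <- sample(c(0.25, 1, 4), 1)
    q <- sample(c(0.25, 1, 2), 1)
    for (v in ids) {
      nbrs <- names(which(adj[v, ] > 0))
      if (length(nbrs) == 0) next
      for (t in nbrs) {
        got <- transition_distribution(net, t, v, p, q)
        want <- oracle_transition(net, t, v, p, q)
        expect_equal(got, want, tolerance = 1e-12)
        expect_equal(sum(got), 1.0)
      }
    }
  }
})

test_that("p = q = 1 reduces the second-order walk to a first-order weighted walk", {
  adj <- random_ppi(7, p_edge = 0.6, seed = 3)
  net <- ppi_network(adj)
  ids <- net$nodes$id
  for (v in ids) {
    nbrs <- names(which(adj[v, ] > 0))
    first_order <- transition_distribution(net, NULL, v)
    for (t in nbrs) {
      expect_equal(transition_distribution(net, t, v, p = 1, q = 1),
                   first_order, tolerance = 1e-12)
    }
  }
})

test_that("walk simulation honors its count, validity and determinism contracts", {
  gen <- generate_network(small_synth(seed = 5))
  net <- gen$network
  cfg <- walk_config(num_walks = 2, walk_length = 12, seed = 42)
  corp <- simulate_walks(net, cfg)
  expect_equal(length(corp$walks), 2 * nrow(net$nodes))
  # every consecutive pair is an edge of the collapsed graph
  g <- net$graph
  for (w in corp$walks[1:40]) {
    if (length(w) < 2) next
    for (i in seq_len(length(w) - 1)) {
      expect_true(igraph::are_adjacent(g, w[i], w[i + 1]))
    }
  }
  # each node starts its designated walks
  starts <- vapply(corp$walks, `[[`, character(1), 1)
  tab <- table(starts)
  expect_setequal(names(tab), net$nodes$id)
  expect_true(all(tab == 2))
  # determinism
  corp2 <- simulate_walks(net, cfg)
  expect_identical(corp$walks, corp2$walks)
  # path graph: from an endpoint the only continuation is its neighbor
  path_adj <- matrix(0, 3, 3, dimnames = list(
    c("protein:a", "protein:b", "protein:c"),
    c("protein:a", "protein:b", "protein:c")))
  path_adj[1, 2] <- path_adj[2, 1] <- 1
  path_adj[2, 3] <- path_adj[3, 2] <- 1
  pnet <- ppi_network(path_adj)
  pcorp <- simulate_walks(pnet, walk_config(num_walks = 1, walk_length = 3,
                                            seed = 1))
  wa <- pcorp$walks[[which(vapply(pcorp$walks, `[[`, character(1), 1) ==
                             "protein:a")]]
  expect_equal(wa[1:2], c("protein:a", "protein:b"))
})

test_that("empirical transition frequencies match the exact distribution", {
  adj <- barbell_adj(5)
  net <- ppi_network(adj)
  skip_if(nrow(net$nodes) == 0)
  cfg <- walk_config(p = 2, q = 0.5, num_walks = 60, walk_length = 40,
                     seed = 99)
  corp <- simulate_walks(net, cfg)
  # tally observed transitions conditioned on one frequent (t, v) context
  t_id <- "protein:b01"; v_id <- "protein:b02"
  nxt <- character(0)
  for (w in corp$walks) {
    if (length(w) < 3) next
    hits <- which(w[-c(length(w) - 1, length(w))] == t_id &
                    w[-c(1, length(w))] == v_id)
    nxt <- c(nxt, w[hits + 2])
  }
  skip_if(length(nxt) < 200)
  want <- transition_distribution(net, t_id, v_id, p = 2, q = 0.5)
  obs <- table(factor(nxt, levels = names(want))) / length(nxt)
  se <- sqrt(want * (1 - want) / length(nxt))
  expect_true(all(abs(as.numeric(obs) - want) <= 3 * se + 1e-9))
})

test_that("embeddings have the right shape and are reproducible", {
  adj <- barbell_adj(6)
  net <- ppi_network(adj)
  corp <- simulate_walks(net, walk_config(num_walks = 8, walk_length = 20,
                                          seed = 5))
  emb <- learn_embeddings(corp, d = 16, epochs = 2, seed = 10)
  expect_equal(ncol(emb$vectors), 16)
  expect_equal(sort(rownames(emb$vectors)), sort(net$nodes$id))
  expect_true(all(is.finite(emb$vectors)))
  emb2 <- learn_embeddings(corp, d = 16, epochs = 2, seed = 10)
  expect_identical(emb$vectors, emb2$vectors)
  emb3 <- learn_embeddings(corp, d = 16, epochs = 2, seed = 11)
  expect_false(identical(emb$vectors, emb3$vectors))
})

test_that("embeddings separate the two communities of a barbell graph", {
  adj <- barbell_adj(10)
  net <- ppi_network(adj)
  emb <- node2vec(net, d = 16,
                  config = walk_config(num_walks = 20, walk_length = 30,
                                       seed = 21),
                  epochs = 5, seed = 21)
  v <- emb$vectors
  nrm <- v / sqrt(rowSums(v^2))
  ids <- rownames(v)
  left <- ids[as.integer(sub("protein:b", "", ids)) <= 10]
  right <- setdiff(ids, left)
  cs <- tcrossprod(nrm)
  within <- c(cs[left, left][upper.tri(cs[left, left])],
              cs[right, right][upper.tri(cs[right, right])])
  across <- as.vector(cs[left, right])
  expect_gt(mean(within), mean(across))
})

test_that("co-occurrence dominance: shared neighborhoods pull vectors together", {
  # a and b share the same context vocabulary; c lives in a disjoint one
  others <- sprintf("protein:o%02d", 1:10)
  zs <- sprintf("protein:z%02d", 1:10)
  set.seed(17)
  walks <- c(
    replicate(150, c("protein:a", sample(others, 4)), simplify = FALSE),
    replicate(150, c("protein:b", sample(others, 4)), simplify = FALSE),
    replicate(150, c("protein:c", sample(zs, 4)), simplify = FALSE))
  corp <- structure(list(walks = walks, config = walk_config(),
                         node_ids = c("protein:a", "protein:b",
                                      "protein:c", others, zs)),
                    class = "walk_corpus")
  emb <- learn_embeddings(corp, d = 8, window = 3, epochs = 5, seed = 2)
  v <- emb$vectors
  cos <- function(x, y) sum(x * y) / sqrt(sum(x^2) * sum(y^2))
  expect_gt(cos(v["protein:a", ], v["protein:b", ]),
            cos(v["protein:a", ], v["protein:c", ]))
})

test_that("nodes absent from the corpus raise a missing-vector error", {
  corp <- structure(list(walks = list(c("protein:a", "protein:b")),
                         config = walk_config(),
                         node_ids = c("protein:a", "protein:b",
                                      "protein:z")),
                    class = "walk_corpus")
  expect_error(learn_embeddings(corp, d = 4), "protein:z")
})

test_that("embedding text serialization round-trips", {
  adj <- random_ppi(6, seed = 8)
  net <- ppi_network(adj)
  emb <- node2vec(net, d = 8,
                  config = walk_config(num_walks = 4, walk_length = 10,
                                       seed = 3),
                  epochs = 1, seed = 3)
  f <- withr::local_tempfile(fileext = ".txt")
  write_embeddings(emb, f)
  emb2 <- read_embeddings(f)
  expect_equal(emb2$d, 8)
  expect_equal(emb2$vectors[rownames(emb$vectors), ], emb$vectors,
               tolerance = 1e-6)
})

test_that("planted-signal embeddings separate positive from negative pairs (permutation test)", {
  gen <- generate_network(small_synth(seed = 31))
  emb <- node2vec(gen$network, d = 16,
                  config = walk_config(num_walks = 8, walk_length = 30,
                                       seed = 31),
                  epochs = 3, seed = 31)
  pos <- gen$positives
  neg <- sample_negatives(pos, nodes_of_type(gen$network, "herb"),
                          nodes_of_type(gen$network, "protein"),
                          n = nrow(pos), seed = 31)
  x <- featurize_pairs(emb, rbind(pos, neg))
  y <- c(rep(1, nrow(pos)), rep(0, nrow(neg)))
  # linear separation score via logistic regression on the pair features
  df <- data.frame(x); df$.y <- y
  fit <- suppressWarnings(stats::glm(.y ~ ., data = df,
                                     family = stats::binomial()))
  sc <- stats::predict(fit, type = "link")
  a_obs <- auroc(sc, y)
  set.seed(99)
  a_null <- replicate(200, auroc(sc, sample(y)))
  p_perm <- (1 + sum(a_null >= a_obs)) / 201
  expect_lt(p_perm, 0.01)
})
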