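test_that("negative sampling avoids positives and reproduces under a seed", {
  herbs <- paste0("herb:h", 1:2)
  prots <- paste0("protein:p", 1:2)
  pos <- data.frame(herb = herbs[c(1, 1, 2)], protein = prots[c(1, 2, 1)])
  expect_equal(nrow(sample_negatives(pos, herbs, prots, 0)), 0)
  neg <- sample_negatives(pos, herbs, prots, 1, seed = 5)
  expect_equal(neg$herb, "herb:h2")
  expect_equal(neg$protein, "protein:p2")
  expect_error(sample_negatives(pos, herbs, prots, 2), "universe")

  herbs <- paste0("herb:h", 1:20)
  prots <- paste0("protein:p", 1:30)
  pos <- data.frame(herb = sample(herbs, 50, TRUE),
                    protein = sample(prots, 50, TRUE))
  n1 <- sample_negatives(pos, herbs, prots, 40, seed = 9)
  n2 <- sample_negatives(pos, herbs, prots, 40, seed = 9)
  expect_identical(n1, n2)
  expect_equal(nrow(unique(n1)), 40)
  expect_false(any(paste(n1$herb, n1$protein) %in%
                     paste(pos$herb, pos$protein)))
  # exclusion of an extra set (disjoint test negatives)
  n3 <- sample_negatives(pos, herbs, prots, 40, seed = 10, exclude = n1)
  expect_false(any(paste(n3$herb, n3$protein) %in%
                     paste(n1$herb, n1$protein)))
})

test_that("KNN probabilities are quantized neighbor fractions", {
  # geometric construction: query at origin, k nearest are controlled
  d <- 4
  mk <- function(n, radius, seed) {
    set.seed(seed)
    u <- matrix(rnorm(n * d), n, d)
    u / sqrt(rowSums(u^2)) * radius
  }
  for (npos_near in c(5, 4, 2, 0)) {
    near <- mk(5, 1, seed = npos_near + 1)
    far <- mk(30, 10, seed = 50 + npos_near)
    x <- rbind(near, far)
    y <- c(rep(1, npos_near), rep(0, 5 - npos_near), rep(1, 15),
           rep(0, 15))
    pr <- knn_probability(rep(0, d), x, y, k = 5)
    expect_equal(pr, npos_near / 5)
  }
  expect_error(knn_probability(rep(0, d), mk(3, 1, 1), c(1, 0, 1), k = 5),
               "exceeds")
})

test_that("KNN agrees with a brute-force scan on random instances", {
  set.seed(33)
  for (rep in 1:3) {
    n <- sample(c(200, 500, 1000), 1)
    d <- 8
    x <- matrix(rnorm(n * d), n, d)
    y <- rbinom(n, 1, 0.5)
    q <- matrix(rnorm(20 * d), 20, d)
    for (k in c(1, 5, 9)) {
      expect_equal(knn_probability(q, x, y, k = k),
                   oracle_knn_prob(q, x, y, k))
    }
  }
})

test_that("KNN is invariant to isotropic feature rescaling", {
  set.seed(4)
  x <- matrix(rnorm(200 * 6), 200, 6)
  y <- rbinom(200, 1, 0.5)
  q <- matrix(rnorm(10 * 6), 10, 6)
  expect_equal(knn_probability(q, x, y, k = 5),
               knn_probability(q * 3.7, x * 3.7, y, k = 5))
})

test_that("every classifier family separates a separable toy problem", {
  set.seed(21)
  d <- 8
  n <- 60
  pos <- matrix(rnorm(n * d, mean = 1, sd = 0.3), n, d)
  neg <- matrix(rnorm(n * d, mean = -1, sd = 0.3), n, d)
  x <- rbind(pos, neg)
  y <- c(rep(1, n), rep(0, n))
  q_pos <- matrix(1, 2, d)
  q_neg <- matrix(-1, 2, d)
  for (fam in c("knn", "lr", "svm", "dt", "rf", "gbdt")) {
    # glm warns about perfect separation on this deliberately easy set
    scorer <- suppressWarnings(train_model(model_spec(fam, seed = 3), x, y))
    sp <- scorer(q_pos)
    sn <- scorer(q_neg)
    expect_true(all(sp > sn), label = paste(fam, "separates"))
    expect_true(all(sp >= 0 & sp <= 1 & sn >= 0 & sn <= 1),
                label = paste(fam, "scores in [0,1]"))
  }
  # KNN scores come from the quantized set
  knn_scorer <- train_model(model_spec("knn", k = 5), x, y)
  pr <- knn_scorer(rbind(q_pos, q_neg))
  expect_true(all(pr %in% seq(0, 1, by = 0.2)))
  # stochastic families are deterministic under the spec seed
  for (fam in c("rf", "gbdt", "svm")) {
    s1 <- train_model(model_spec(fam, seed = 7), x, y)(q_pos)
    s2 <- train_model(model_spec(fam, seed = 7), x, y)(q_pos)
    expect_identical(s1, s2, label = paste(fam, "deterministic"))
  }
  expect_error(train_model(model_spec("lr"), x, rep(1, nrow(x))),
               "single-class")
})

test_that("candidate ranking sorts by probability with lexicographic ties", {
  ids <- c("herb:a", "herb:b", "protein:x", "protein:y", "protein:z")
  set.seed(2)
  emb <- structure(list(vectors = matrix(rnorm(5 * 4), 5, 4,
                                         dimnames = list(ids, NULL)),
                        d = 4), class = "embedding_model")
  probs <- c("herb:a\rprotein:x" = 0.2, "herb:a\rprotein:y" = 1.0,
             "herb:a\rprotein:z" = 0.6, "herb:b\rprotein:x" = 0.6)
  scorer <- structure(function(x) {
    key <- paste(attr(x, "pairs")$herb, attr(x, "pairs")$protein,
                 sep = "\r")
    unname(probs[key])
  }, class = c("hti_scorer", "function"))
  cand <- data.frame(herb = c("herb:a", "herb:a", "herb:a", "herb:b"),
                     protein = c("protein:x", "protein:y", "protein:z",
                                 "protein:x"))
  rk <- rank_unknown_pairs(scorer, emb, cand, block_size = 2L)
  expect_equal(rk$probability, c(1.0, 0.6, 0.6, 0.2))
  # tie at 0.6 broken by herb then protein id
  expect_equal(rk$herb[2:3], c("herb:a", "herb:b"))
  expect_equal(attr(rk, "frac_below_half"), 0.25)
  empty <- rank_unknown_pairs(scorer, emb,
                              data.frame(herb = character(),
                                         protein = character()))
  expect_equal(nrow(empty), 0)
})
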