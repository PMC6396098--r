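test_that("fold splitting partitions positives evenly and reproducibly", {
  pos <- data.frame(herb = paste0("herb:h", 1:101),
                    protein = paste0("protein:p", 1:101))
  folds <- make_folds(pos[1:100, ], 10, seed = 3)
  expect_equal(vapply(folds, function(f) nrow(f$test), numeric(1)),
               rep(10, 10))
  folds2 <- make_folds(pos, 10, seed = 3)
  sizes <- sort(vapply(folds2, function(f) nrow(f$test), numeric(1)))
  expect_equal(sizes, c(rep(10, 9), 11))
  # test folds partition the positive set
  all_test <- do.call(rbind, lapply(folds2, `[[`, "test"))
  expect_setequal(paste(all_test$herb, all_test$protein),
                  paste(pos$herb, pos$protein))
  # train + test = everything, disjoint
  f1 <- folds2[[1]]
  expect_equal(nrow(f1$train) + nrow(f1$test), 101)
  expect_length(intersect(paste(f1$train$herb, f1$train$protein),
                          paste(f1$test$herb, f1$test$protein)), 0)
  expect_identical(make_folds(pos, 10, seed = 3), folds2)
  expect_error(make_folds(pos, 1), "n_folds")
})

test_that("AUROC matches its pairwise-comparison definition", {
  expect_equal(auroc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1.0)
  expect_equal(auroc(c(0.1, 0.2, 0.8, 0.9), c(1, 1, 0, 0)), 0.0)
  expect_equal(auroc(c(0.9, 0.8, 0.3), c(1, 0, 1)), 0.5)
  expect_error(auroc(c(1, 2), c(1, 1)), "both classes")
  set.seed(8)
  for (i in 1:30) {
    n <- sample(4:12, 1)
    sc <- sample(seq(0, 1, 0.1), n, replace = TRUE)  # force some ties
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) next
    expect_equal(auroc(sc, y), oracle_auroc(sc, y), tolerance = 1e-12)
  }
  # invariance to strictly monotone transforms
  sc <- runif(30); y <- rbinom(30, 1, 0.4)
  expect_equal(auroc(exp(3 * sc) + 1, y), auroc(sc, y))
})

test_that("AUPR matches exhaustive threshold enumeration", {
  expect_equal(aupr(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1.0)
  expect_equal(aupr(rep(0.5, 10), c(rep(1, 5), rep(0, 5))), 0.5)
  sc4 <- c(0.9, 0.6, 0.4, 0.2)
  y4 <- c(1, 0, 1, 0)
  expect_equal(aupr(sc4, y4), oracle_aupr(sc4, y4))
  set.seed(12)
  for (i in 1:30) {
    n <- sample(4:12, 1)
    sc <- sample(seq(0, 1, 0.2), n, replace = TRUE)
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) next
    expect_equal(aupr(sc, y), oracle_aupr(sc, y), tolerance = 1e-12)
  }
})

test_that("signed-rank test matches sign-flip enumeration, including ties", {
  a <- 1:10
  expect_error(wilcoxon_signed_rank(a, a), "zero")
  res <- wilcoxon_signed_rank(a, a + 1)
  expect_equal(res$p.value, 2 / 1024)
  set.seed(5)
  for (i in 1:20) {
    n <- sample(5:12, 1)
    d <- round(rnorm(n), sample(0:1, 1))  # rounding induces ties
    d[d == 0] <- 0.5
    res <- wilcoxon_signed_rank(d, rep(0, n))
    expect_equal(res$p.value, oracle_signed_rank_p(d), tolerance = 1e-9,
                 label = paste("case", i))
  }
  # untied exact branch cross-checked against the standard implementation
  set.seed(6)
  a <- rnorm(15); b <- rnorm(15)
  res <- wilcoxon_signed_rank(a, b)
  ref <- stats::wilcox.test(a, b, paired = TRUE, exact = TRUE)
  expect_equal(res$p.value, ref$p.value, tolerance = 1e-10)
  # large-n branch is a sane approximation
  set.seed(7)
  a <- rnorm(60); b <- a + rnorm(60, 0.2)
  res_n <- wilcoxon_signed_rank(a, b)
  ref_n <- stats::wilcox.test(a, b, paired = TRUE, exact = FALSE,
                              correct = TRUE)
  expect_equal(res_n$p.value, ref_n$p.value, tolerance = 1e-6)
})

# pipeline stub scoring by an arbitrary function of the pairs
stub_pipeline <- function(name, score_fun, record = NULL) {
  structure(list(name = name,
                 fit = function(train_pairs, train_labels) {
                   if (!is.null(record)) {
                     record$train <- rbind(record$train, train_pairs)
                   }
                   function(pairs) score_fun(pairs)
                 }),
            class = "hti_pipeline")
}

cv_setup <- function(seed = 1) {
  herbs <- paste0("herb:h", sprintf("%02d", 1:15))
  prots <- paste0("protein:p", sprintf("%02d", 1:20))
  set.seed(seed)
  pos <- unique(data.frame(herb = sample(herbs, 60, TRUE),
                           protein = sample(prots, 60, TRUE)))[1:50, ]
  list(pos = pos, universe = list(herbs = herbs, proteins = prots))
}

test_that("cross-validation is deterministic and respects the oracle upper bound", {
  s <- cv_setup()
  pos_key <- paste(s$pos$herb, s$pos$protein)
  oracle <- stub_pipeline("oracle", function(pairs) {
    as.numeric(paste(pairs$herb, pairs$protein) %in% pos_key)
  })
  rep1 <- cross_validate(oracle, s$pos, s$universe, n_folds = 5, seed = 2)
  expect_equal(rep1$per_fold$auroc, rep(1, 5))
  expect_equal(rep1$per_fold$aupr, rep(1, 5))
  rep2 <- cross_validate(oracle, s$pos, s$universe, n_folds = 5, seed = 2)
  expect_identical(rep1, rep2)
})

test_that("a random scorer hovers at the null AUROC of one half", {
  s <- cv_setup(3)
  rnd <- stub_pipeline("random", function(pairs) {
    # deterministic hash-based pseudo-random score per pair
    sapply(paste(pairs$herb, pairs$protein), function(k) {
      sum(utf8ToInt(k) * 31^(seq_along(utf8ToInt(k)) %% 5)) %% 997 / 997
    })
  })
  rep <- cross_validate(rnd, s$pos, s$universe, n_folds = 10, seed = 4)
  se <- sd(rep$per_fold$auroc) / sqrt(10)
  expect_lt(abs(rep$mean_auroc - 0.5), 3 * max(se, 0.02))
})

test_that("no test positive leaks into its fold's training set", {
  s <- cv_setup(5)
  rec <- new.env()
  seen <- list()
  leak_checker <- structure(list(
    name = "leakcheck",
    fit = function(train_pairs, train_labels) {
      train_key <- paste(train_pairs$herb, train_pairs$protein)
      function(pairs) {
        expect_length(intersect(paste(pairs$herb, pairs$protein)[
          seq_len(nrow(pairs) / 2)], train_key), 0)
        runif(nrow(pairs))
      }
    }), class = "hti_pipeline")
  expect_no_error(cross_validate(leak_checker, s$pos, s$universe,
                                 n_folds = 5, seed = 6))
})

test_that("paired model comparison requires matching folds and computes a p-value", {
  s <- cv_setup(7)
  good <- stub_pipeline("good", function(pairs) {
    0.7 * (paste(pairs$herb, pairs$protein) %in%
             paste(s$pos$herb, s$pos$protein)) +
      0.3 * (seq_len(nrow(pairs)) %% 7) / 7
  })
  soso <- stub_pipeline("soso", function(pairs) {
    (seq_len(nrow(pairs)) %% 11) / 11
  })
  ra <- cross_validate(good, s$pos, s$universe, n_folds = 8, seed = 9)
  rb <- cross_validate(soso, s$pos, s$universe, n_folds = 8, seed = 9)
  cmp <- compare_models(ra, rb, metric = "auroc")
  expect_lt(cmp$p.value, 0.05)
  rb2 <- cross_validate(soso, s$pos, s$universe, n_folds = 8, seed = 10)
  expect_error(compare_models(ra, rb2), "seed")
})
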