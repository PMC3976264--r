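rand_instance <- function(n, p, sep = 0.5) {
  y <- rep(c(-1, 1), length.out = n)
  X <- matrix(rnorm(n * p, mean = y * sep), n, p,
              dimnames = list(NULL, paste0("f", seq_len(p))))
  list(X = X, y = y)
}

test_that("t-score and centroid rankings follow their defining formulas", {
  withr::with_seed(31, {
    ins <- rand_instance(20, 5)
    r <- tscore_rank(ins$X, ins$y)
    # brute-force recomputation from per-class means and variances
    hi <- ins$X[ins$y == 1, ]; lo <- ins$X[ins$y == -1, ]
    tref <- (colMeans(hi) - colMeans(lo)) /
      sqrt(apply(hi, 2, var) / nrow(hi) + apply(lo, 2, var) / nrow(lo))
    expect_equal(r$scores, tref)
    expect_equal(r$order, names(sort(-abs(tref))))

    c1 <- centroid_rank(ins$X, ins$y)
    expect_equal(c1$scores, abs(colMeans(hi) - colMeans(lo)))
  })

  # a feature identical across classes scores 0 and ranks last
  X <- cbind(sig = c(0, 0.1, -0.1, 5, 5.1, 4.9), flat = rep(2, 6))
  y <- rep(c(-1, 1), each = 3)
  r <- suppressWarnings(tscore_rank(X, y))
  expect_equal(unname(r$scores["flat"]), 0)
  expect_equal(r$order, c("sig", "flat"))
  c2 <- centroid_rank(X, y)
  expect_equal(unname(c2$scores["flat"]), 0)

  # variance can reverse the t ordering but not the centroid ordering
  withr::with_seed(33, {
    noisy <- c(rnorm(10, 0, 6), rnorm(10, 4, 6))   # big mean gap, huge variance
    tight <- c(rnorm(10, 0, 0.1), rnorm(10, 1, 0.1))
    X2 <- cbind(noisy = noisy, tight = tight)
    y2 <- rep(c(-1, 1), each = 10)
    expect_equal(centroid_rank(X2, y2)$order[1], "noisy")
    expect_equal(tscore_rank(X2, y2)$order[1], "tight")
  })

  # rankings are invariant to an additive constant on a feature
  withr::with_seed(35, {
    ins <- rand_instance(16, 4)
    X3 <- ins$X; X3[, 2] <- X3[, 2] + 100
    expect_equal(tscore_rank(X3, ins$y)$order, tscore_rank(ins$X, ins$y)$order)
    expect_equal(centroid_rank(X3, ins$y)$order, centroid_rank(ins$X, ins$y)$order)
  })
})

test_that("the primal SVM solver meets its objective contract", {
  # 1-D closed form: minimizing w^2/2 + 2 max(0, 1 - w) gives w = 1, b = 0
  m <- train_linear_svm(matrix(c(-1, 1), 2, 1, dimnames = list(NULL, "x")),
                        c(-1, 1), C = 1, standardize = FALSE)
  expect_equal(unname(m$weights), 1, tolerance = 1e-5)
  expect_equal(m$intercept, 0, tolerance = 1e-5)
  expect_equal(m$objective, 0.5, tolerance = 1e-6)

  # label flip negates weights and intercept
  withr::with_seed(41, {
    ins <- rand_instance(14, 3)
    m1 <- train_linear_svm(ins$X, ins$y, standardize = FALSE)
    m2 <- train_linear_svm(ins$X, -ins$y, standardize = FALSE)
    expect_equal(m2$weights, -m1$weights, tolerance = 1e-4)
    expect_equal(m2$intercept, -m1$intercept, tolerance = 1e-4)
    expect_true(all(diff(m1$objective_trace) <= 1e-12))  # never increases
  })

  # objective within 1e-5 of an independent solver on random instances
  withr::with_seed(43, {
    for (i in 1:8) {
      ins <- rand_instance(sample(8:30, 1), sample(1:6, 1))
      C <- sample(c(0.5, 1, 2), 1)
      m <- train_linear_svm(ins$X, ins$y, C = C, standardize = FALSE)
      expect_lt(abs(m$objective - libsvm_objective(ins$X, ins$y, C)), 1e-5)
    }
  })
  expect_error(train_linear_svm(matrix(1:4, 2, 2,
    dimnames = list(NULL, c("a", "b"))), c(1, 1)), "both classes")
})

test_that("decision values match features by name and refuse missing ones", {
  m <- structure(list(weights = c(a = 1, b = 0), intercept = -1,
                      feature_names = c("a", "b"),
                      center = c(a = 0, b = 0), scale = c(a = 1, b = 1),
                      C = 1), class = "linear_model")
  X <- matrix(c(3, 9), 1, 2, dimnames = list(NULL, c("a", "b")))
  expect_equal(decision_values(m, X), 2)
  # order-insensitive matching by name
  expect_equal(decision_values(m, X[, c("b", "a"), drop = FALSE]), 2)
  m0 <- m; m0$weights[] <- 0; m0$intercept <- 0
  expect_equal(decision_values(m0, X), 0)
  expect_error(decision_values(m, X[, "a", drop = FALSE]), "missing feature")

  # model round-trips through its plain-text serialization
  path <- withr::local_tempfile(fileext = ".json")
  mm <- train_linear_svm(matrix(rnorm(20), 10, 2,
          dimnames = list(NULL, c("a", "b"))), rep(c(-1, 1), 5))
  write_model(mm, path)
  back <- read_model(path)
  expect_equal(back$weights, mm$weights)
  expect_equal(back$center, mm$center)
  Xr <- matrix(rnorm(6), 3, 2, dimnames = list(NULL, c("a", "b")))
  expect_equal(decision_values(back, Xr), decision_values(mm, Xr))
})

test_that("ROC/AUC equals pair counting and behaves under score negation", {
  r1 <- roc_auc(c(3, 2, 1, 0), c(1, 1, -1, -1))
  expect_equal(r1$auc, 1.0)
  r2 <- roc_auc(rep(1, 6), rep(c(1, -1), 3))
  expect_equal(r2$auc, 0.5)
  r3 <- roc_auc(c(0.9, 0.8, 0.3, 0.2), c(1, -1, 1, -1))
  expect_equal(r3$auc, 0.75)

  withr::with_seed(47, {
    for (i in 1:60) {
      n <- sample(4:12, 1)
      y <- c(-1, 1, sample(c(-1, 1), n - 2, replace = TRUE))
      scores <- sample(seq(0, 1, 0.1), n, replace = TRUE)  # ties likely
      r <- roc_auc(scores, y)
      expect_equal(r$auc, auc_paircount(scores, y), tolerance = 1e-12)
      # curve is a valid ROC: (0,0) to (1,1), both coordinates non-decreasing
      expect_equal(unlist(r$curve[1, ]), c(fpr = 0, tpr = 0))
      expect_equal(unlist(r$curve[nrow(r$curve), ]), c(fpr = 1, tpr = 1))
      expect_true(!is.unsorted(r$curve$fpr) && !is.unsorted(r$curve$tpr))
      if (!anyDuplicated(scores)) {
        expect_equal(roc_auc(-scores, y)$auc, 1 - r$auc, tolerance = 1e-12)
      }
    }
    # cross-check against an established ROC implementation
    y <- sample(c(-1, 1), 40, replace = TRUE); y[1:2] <- c(-1, 1)
    s <- rnorm(40, mean = y)
    expect_equal(roc_auc(s, y)$auc,
                 as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE))),
                 tolerance = 1e-12)
  })
  expect_error(roc_auc(c(1, 2), c(1, 1)), "both classes")
})

test_that("stability percentages are reproducible, monotone and signal-tracking", {
  withr::with_seed(51, {
    X <- cbind(strong = rep(c(0, 10), each = 10) + rnorm(20, 0, 0.1),
               n1 = rnorm(20), n2 = rnorm(20), n3 = rnorm(20))
    y <- rep(c(-1, 1), each = 10)
  })
  s1 <- stability_table(X, y, "tscore", n_splits = 20, seed = 9)
  expect_equal(unname(s1$percent["strong", "top1"]), 100)
  expect_true(all(apply(s1$fraction, 1, function(r) !is.unsorted(r))))
  s1b <- stability_table(X, y, "tscore", n_splits = 20, seed = 9)
  expect_identical(s1, s1b)  # bit-exact under a fixed seed
  sfull <- stability_table(X, y, "centroid", n_splits = 10, top_max = 4, seed = 9)
  expect_true(all(sfull$percent[, "top4"] == 100))  # top-(panel size)

  # well-separated injected shifts occupy the two highest top-2 percentages
  g2 <- generate_cohort(cohort_spec(17, 16, c("big", "mid", "n1", "n2", "n3"),
                                    c(24, 25, 26, 27, 28), c(4, 2.5, 0, 0, 0),
                                    biological_sd = 1.5, replicate_sd = 0.3,
                                    seed = 1))
  ct2 <- preprocess_replicates(g2$replicates)$ct
  st2 <- stability_table(ct2$values, g2$labels, "centroid",
                         n_splits = 30, seed = 1)
  expect_setequal(names(sort(-st2$fraction[, "top2"]))[1:2], c("big", "mid"))

  # urine scenario: the two top-shift panel members (miR16/miR222, whose
  # published shifts are separated from the rest by well under the
  # sampling noise) still surface among the stability leaders
  sc <- qpcr_scenario("discovery_urine", seed = 1)
  g <- generate_cohort(sc$cohort)
  ct <- preprocess_replicates(g$replicates)$ct
  st <- stability_table(ct$values, g$labels, "centroid",
                        n_splits = 30, seed = 1)
  lead4 <- names(sort(-st$fraction[, "top3"]))[1:4]
  expect_true(all(c("miR16", "miR222") %in% lead4))
  expect_true(names(sort(-st$fraction[, "top1"]))[1] %in% c("miR16", "miR222"))
})

test_that("cross-validated AUC pools out-of-split scores sensibly", {
  # perfectly separable features give AUC 1
  withr::with_seed(55, {
    X <- cbind(f1 = rep(c(0, 50), each = 12) + rnorm(24),
               f2 = rnorm(24))
    y <- rep(c(-1, 1), each = 12)
    expect_equal(cv_auc(X, y, "f1", n_splits = 10, seed = 2)$auc, 1.0)
  })
  # pure-noise features hover at chance
  aucs <- vapply(1:30, function(s) {
    withr::with_seed(100 + s, {
      X <- matrix(rnorm(33 * 3), 33, 3, dimnames = list(NULL, c("a", "b", "c")))
      y <- c(rep(-1, 17), rep(1, 16))
      cv_auc(X, y, c("a", "b", "c"), n_splits = 10, seed = s)$auc
    })
  }, numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.05)
  expect_error(cv_auc(matrix(1, 2, 1, dimnames = list(NULL, "a")),
                      c(-1, 1), character()), "non-empty")
})

test_that("subset evaluation ranks signal-bearing combinations first", {
  withr::with_seed(59, {
    X <- cbind(sig = rep(c(0, 3), each = 15) + rnorm(30, 0, 1.5),
               n1 = rnorm(30), n2 = rnorm(30))
    y <- rep(c(-1, 1), each = 15)
  })
  res <- evaluate_subsets(X, y, all_subsets(c("sig", "n1", "n2")),
                          n_splits = 15, seed = 3)
  expect_equal(nrow(res), 7L)  # 2^3 - 1
  has_sig <- grepl("sig", res$subset)
  expect_true(min(res$auc[has_sig]) > max(res$auc[!has_sig]))
})

test_that("a multi-miR panel usually beats its best single member", {
  wins <- vapply(1:40, function(s) {
    g <- generate_cohort(cohort_spec(17, 16, c("a", "b", "c"),
                                     c(24, 26, 28), c(3.0, 2.7, 2.4),
                                     biological_sd = 1.5, replicate_sd = 0.3,
                                     seed = s))
    ct <- preprocess_replicates(g$replicates)$ct
    res <- evaluate_subsets(ct$values, g$labels,
                            list("a", "b", "c", c("a", "b", "c")),
                            n_splits = 10, seed = s)
    combo <- res$auc[res$subset == "a+b+c"]
    combo >= max(res$auc[res$subset != "a+b+c"])
  }, logical(1))
  expect_gte(mean(wins), 0.7)
})
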