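test_that("replicate files round-trip and malformed input is rejected", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample,mir,replicate,ct",
               "S1,miR16,1,22.5",
               "S1,miR16,2,Undetermined",
               "S1,miR21,1,25.0"), path)
  tbl <- read_replicates(path, quiet = TRUE)
  expect_equal(nrow(tbl), 3L)
  expect_true(is.na(tbl$ct[2]))  # undetermined preserved, not yet 34
  expect_equal(tbl$ct[c(1, 3)], c(22.5, 25.0))

  out <- withr::local_tempfile(fileext = ".csv")
  write_replicates(tbl, out)
  back <- read_replicates(out, quiet = TRUE)
  expect_equal(back, tbl)

  writeLines(c("sample,mir,replicate,ct", "S1,miR16,1,20",
               "S1,miR16,1,21"), path)
  expect_error(read_replicates(path, quiet = TRUE), "duplicate.*S1, miR16, 1")
  writeLines(c("sample,mir,replicate,ct", "S1,miR16,1,twenty"), path)
  expect_error(read_replicates(path, quiet = TRUE), "unparseable.*line 2")
  writeLines(c("sample,mir,ct", "S1,miR16,20"), path)
  expect_error(read_replicates(path, quiet = TRUE), "missing column")
})

test_that("expression ceiling maps high and undetermined values to 34 idempotently", {
  tbl <- make_replicates("S1", "miR16", c(35.2, NA, 28.0))
  out <- apply_ceiling(tbl, ceiling = 34)
  expect_equal(out$ct, c(34, 34, 28))
  expect_identical(apply_ceiling(out, 34)$ct, out$ct)  # idempotent
  # exactly-34 values are kept, monotone (never increases a value)
  ct <- withr::with_seed(1, runif(50, 20, 40))
  tbl2 <- data.frame(sample = "S", mir = paste0("m", 1:50),
                     replicate = 1L, ct = ct)
  out2 <- apply_ceiling(tbl2, 34)
  expect_true(all(out2$ct <= pmax(ct, 34)))
  expect_true(all(out2$ct <= 34))
  expect_equal(out2$ct[ct <= 34], ct[ct <= 34])
})

test_that("the 20% replicate rule removes only the single worst offender", {
  t1 <- apply_ceiling(make_replicates("S1", "miR16", c(20, 20, 30)), 34)
  r1 <- remove_replicate_outliers(t1)
  expect_equal(sort(r1$replicates$ct), c(20, 20))   # 30 vs mean 20: 50% > 20%
  expect_equal(r1$report$ct, 30)
  expect_gt(r1$report$deviation, 0.2)

  t2 <- apply_ceiling(make_replicates("S1", "miR16", c(25, 25, 25)), 34)
  expect_equal(nrow(remove_replicate_outliers(t2)$report), 0L)

  t3 <- apply_ceiling(make_replicates("S1", "miR16", c(20, 22, 23)), 34)
  expect_equal(nrow(remove_replicate_outliers(t3)$report), 0L)  # 11.1% <= 20%

  # duplets pass through; random triplets never lose more than one value
  t4 <- apply_ceiling(make_replicates("S1", "miR16", c(10, 30)), 34)
  expect_equal(nrow(remove_replicate_outliers(t4)$replicates), 2L)
  withr::with_seed(7, {
    for (i in 1:50) {
      ct <- runif(3, 15, 34)
      tt <- apply_ceiling(make_replicates("S", "m", ct), 34)
      out <- remove_replicate_outliers(tt)
      expect_gte(nrow(out$replicates), 2L)
    }
  })
})

test_that("replicate aggregation respects method and stays within replicate range", {
  t1 <- apply_ceiling(make_replicates("S1", "miR16", c(20, 22)), 34)
  t1 <- remove_replicate_outliers(t1)$replicates
  expect_equal(unname(aggregate_replicates(t1)$values[1, 1]), 21.0)

  # composition with the outlier rule: (20, 20, 30) aggregates to 20
  t2 <- apply_ceiling(make_replicates("S1", "miR16", c(20, 20, 30)), 34)
  t2 <- remove_replicate_outliers(t2)$replicates
  expect_equal(unname(aggregate_replicates(t2)$values[1, 1]), 20.0)

  t3 <- apply_ceiling(make_replicates("S1", "miR16", c(20, 22, 23)), 34)
  t3 <- remove_replicate_outliers(t3)$replicates
  expect_equal(unname(aggregate_replicates(t3, method = "median")$values[1, 1]), 22.0)

  withr::with_seed(11, {
    for (i in 1:20) {
      ct <- runif(3, 15, 33)
      tt <- remove_replicate_outliers(apply_ceiling(
        make_replicates("S", "m", ct), 34))$replicates
      v <- unname(aggregate_replicates(tt)$values[1, 1])
      expect_gte(v, min(tt$ct)); expect_lte(v, max(tt$ct))
    }
  })
})

test_that("low-detection samples are flagged and removed", {
  v <- matrix(25, 3, 12, dimnames = list(paste0("S", 1:3), paste0("m", 1:12)))
  v[1, ] <- 34  # every panel miR undetected
  qc <- flag_low_detection_samples(make_ct(v), 0.5)
  expect_equal(qc$report$removed, c(TRUE, FALSE, FALSE))
  expect_equal(qc$ct$sample_ids, c("S2", "S3"))

  # plasma-like cohort: 3 of 70 samples spiked with 90% dropout
  spiked <- withr::with_seed(3, {
    m <- matrix(runif(70 * 12, 24, 32), 70, 12,
                dimnames = list(sprintf("P%02d", 1:70), paste0("m", 1:12)))
    bad <- sample(70, 3)
    for (s in bad) m[s, sample(12, 11)] <- 34
    list(m = m, bad = sort(rownames(m)[bad]))
  })
  qc2 <- flag_low_detection_samples(make_ct(spiked$m), 0.5)
  expect_equal(sort(qc2$report$sample[qc2$report$removed]), spiked$bad)
  expect_equal(length(qc2$ct$sample_ids), 67L)

  expect_error(flag_low_detection_samples(make_ct(matrix(34, 2, 3,
    dimnames = list(c("a", "b"), c("x", "y", "z")))), 0.5), "all samples")
})

test_that("PSA doubling time follows the log-slope method", {
  expect_equal(psa_doubling_time(c(0, 0.5), c(0.2, 0.4)), 6.0)   # one doubling in half a year
  expect_identical(psa_doubling_time(c(0, 1), c(1, 1)), Inf)      # flat PSA
  expect_identical(psa_doubling_time(c(0, 1), c(1.0, 0.5)), Inf)  # falling PSA
  # exact exponential samples recovered by regression within 1%
  dt <- psa_doubling_time(c(0, 0.25, 0.5), c(0.2, 0.283, 0.4))
  expect_lt(abs(dt - 6.0) / 6.0, 0.01)
  expect_error(psa_doubling_time(0, 0.2), "at least 2")
  expect_error(psa_doubling_time(c(0, 1), c(-1, 2)), "positive")
  expect_error(psa_doubling_time(c(1, 0), c(1, 2)), "increasing")
})

test_that("ct_table write/read round-trips values exactly", {
  v <- withr::with_seed(5, matrix(runif(12, 20, 34), 3, 4,
       dimnames = list(paste0("S", 1:3), paste0("m", 1:4))))
  ct <- make_ct(v)
  path <- withr::local_tempfile(fileext = ".csv")
  write_ct_table(ct, path)
  back <- read_ct_table(path)
  expect_equal(back$values, ct$values, tolerance = 1e-12)
  expect_equal(back$sample_ids, ct$sample_ids)
})
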