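test_that("PQN leaves identical samples unchanged and undoes known dilution", {
  ab <- matrix(rep(c(10, 20, 30, 40), each = 3), nrow = 3)
  res <- pqn_normalize(make_table(ab))
  expect_equal(unname(res$quotient), rep(1, 3))
  expect_equal(res$table$abundance, make_table(ab)$abundance)

  # one sample at exactly twice the reference spectrum
  ab2 <- rbind(c(10, 20, 30, 40), c(10, 20, 30, 40), c(20, 40, 60, 80))
  res2 <- pqn_normalize(make_table(ab2))
  expect_equal(unname(res2$quotient[3]), 2)
  expect_equal(unname(res2$table$abundance[3, ]), c(10, 20, 30, 40),
               ignore_attr = TRUE)
})

test_that("PQN quotients match a brute-force median-of-ratios oracle", {
  set.seed(10)
  ab <- matrix(10^runif(12, 1, 3), nrow = 3, ncol = 4)
  ab[2, 3] <- NA
  res <- pqn_normalize(make_table(ab))
  # oracle: reference = per-feature median over observed; quotient =
  # median of elementwise ratios over the sample's observed features
  ref <- apply(ab, 2, median, na.rm = TRUE)
  for (i in 1:3) {
    ratios <- ab[i, ] / ref
    expect_equal(unname(res$quotient[i]), median(ratios, na.rm = TRUE))
  }
})

test_that("PQN is idempotent and recovers dilution on dilution-structured data", {
  # dilution is exactly the phenomenon PQN models: samples that are scalar
  # multiples of a common spectrum are restored to a single spectrum
  set.seed(14)
  spectrum <- 10^runif(20, 2, 5)
  d <- runif(10, 0.3, 3)
  tab <- make_table(outer(d, spectrum))
  once <- pqn_normalize(tab)
  expect_equal(unname(once$quotient), d / median(d), tolerance = 1e-12)
  twice <- pqn_normalize(once$table)
  expect_equal(unname(twice$quotient), rep(1, 10), tolerance = 1e-10)
  expect_equal(once$table$abundance, twice$table$abundance,
               tolerance = 1e-12)

  # renormalizing after a second synthetic dilution recovers the same
  # table up to a common factor
  d2 <- runif(10, 0.5, 2)
  rediluted <- once$table
  rediluted$abundance <- once$table$abundance * d2
  undone <- pqn_normalize(rediluted)
  ratio <- undone$table$abundance / once$table$abundance
  expect_equal(max(ratio), min(ratio), tolerance = 1e-10)
})

test_that("normalized samples have unit median ratio to the input reference", {
  ch <- small_cohort(seed = 6, missing_rate = 0.2)
  res <- pqn_normalize(ch$table)
  ref <- apply(ch$table$abundance, 2, median, na.rm = TRUE)
  for (i in seq_len(nrow(res$table$abundance))) {
    r <- res$table$abundance[i, ] / ref
    expect_equal(median(r, na.rm = TRUE), 1, tolerance = 1e-12)
  }
})

test_that("presence filter keeps the >= 50% boundary and honors min_fraction", {
  ab <- matrix(1, nrow = 6, ncol = 3)
  ab[1:3, 1] <- NA  # observed in 3 of 6 -> retained at 0.5
  ab[1:4, 2] <- NA  # observed in 2 of 6 -> dropped
  filt <- presence_filter(make_table(ab), 0.5)
  expect_setequal(colnames(filt$abundance), c("F01", "F03"))
  expect_equal(attr(filt, "retained"), c(1L, 3L), ignore_attr = TRUE)

  ab3 <- matrix(1, 4, 2)
  ab3[1, 1] <- NA; ab3[2, 2] <- NA
  expect_equal(ncol(presence_filter(make_table(ab3), 1)$abundance), 0)

  ch <- small_cohort(seed = 9, missing_rate = 0.6)
  filt2 <- presence_filter(ch$table, 0.5)
  counts <- colSums(!is.na(ch$table$abundance))  # direct counting oracle
  expect_equal(ncol(filt2$abundance), sum(counts >= 0.5 * 36))
})

test_that("blank and early-elution filter applies the 358 s boundary", {
  ab <- matrix(1:12, nrow = 3)
  tab <- make_table(ab, rt1 = c(357.9, 358.0, 1000, 1200),
                    blank = c(FALSE, FALSE, TRUE, FALSE))
  filt <- blank_and_early_filter(tab)
  expect_setequal(colnames(filt$abundance), c("F02", "F04"))

  tab2 <- make_table(ab, rt1 = c(400, 500, 600, 700))
  expect_equal(ncol(blank_and_early_filter(tab2)$abundance), 4)
})

test_that("outlier filter drops above-ceiling cortisol and honors exclusions", {
  meta <- data.frame(sample_id = c("a", "b", "c"),
                     cortisol_ug = c(97, 44.3, 12),
                     stringsAsFactors = FALSE)
  filt <- outlier_filter(meta)
  expect_identical(filt$dropped$sample_id, "a")  # 97 ug out, 44.3 kept
  expect_identical(filt$kept$sample_id, c("b", "c"))

  # the borderline 44.3 ug sample can be removed by explicit exclusion
  filt2 <- outlier_filter(meta, exclude = "b")
  expect_setequal(filt2$dropped$sample_id, c("a", "b"))

  filt3 <- outlier_filter(data.frame(sample_id = "x", cortisol_ug = 10))
  expect_equal(nrow(filt3$dropped), 0)
})

test_that("log standardization matches hand arithmetic and imputes half-min", {
  ab <- matrix(c(10, 100, 1000), ncol = 1)
  pm <- log_standardize(make_table(ab))
  expect_equal(unname(pm$z[, 1]), c(-1, 0, 1))  # log10 -> {1,2,3}, sd 1
  expect_equal(unname(pm$feature_mean), 2)
  expect_equal(unname(pm$feature_sd), 1)

  ab2 <- matrix(c(8, 16, NA, 32), ncol = 1)
  pm2 <- log_standardize(make_table(ab2))
  lg <- log10(c(8, 16, 4, 32))  # half the minimum observed (8/2 = 4)
  expect_equal(unname(pm2$z[, 1]), unname(scale(lg)[, 1]))

  pm3 <- log_standardize(make_table(ab2), impute = "min")
  expect_equal(unname(pm3$z[3, 1]),
               unname(scale(log10(c(8, 16, 8, 32)))[3, 1]))

  expect_error(log_standardize(make_table(matrix(c(5, 5, 5), ncol = 1))),
               "zero variance")
})

test_that("processed matrices have exactly standardized columns", {
  ch <- small_cohort(seed = 3, missing_rate = 0.3)
  prep <- preprocess_cohort(ch$meta, ch$table)
  expect_equal(unname(colMeans(prep$z$z)), rep(0, ncol(prep$z$z)),
               tolerance = 1e-8)
  expect_equal(unname(apply(prep$z$z, 2, sd)), rep(1, ncol(prep$z$z)),
               tolerance = 1e-8)
  expect_true(all(prep$z$pqn_factor > 0))
  expect_equal(length(prep$z$pqn_factor), nrow(prep$meta))
})

test_that("presence and blank filters commute on the same table snapshot", {
  for (seed in 1:3) {
    ch <- small_cohort(seed = seed, missing_rate = 0.5)
    a <- presence_filter(blank_and_early_filter(ch$table), 0.5)
    b <- blank_and_early_filter(presence_filter(ch$table, 0.5))
    expect_identical(a$abundance, b$abundance)
  }
})

test_that("frozen standardization parameters transfer to new samples", {
  ch <- small_cohort(seed = 12, missing_rate = 0)
  pm <- log_standardize(ch$table)
  z_new <- apply_standardization(pm, ch$table)
  expect_equal(z_new, pm$z, tolerance = 1e-12, ignore_attr = TRUE)
})
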