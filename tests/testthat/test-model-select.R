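make_meta_for_design <- function(n_sub = 10) {
  data.frame(
    sample_id = sprintf("s%02d", 1:(3 * n_sub)),
    subject_id = rep(sprintf("p%02d", 1:n_sub), each = 3),
    sex = rep(rep(c("male", "female"), each = 3), n_sub / 2),
    timepoint = rep(c("morning", "afternoon", "evening"), n_sub),
    run_order = 1:(3 * n_sub), stringsAsFactors = FALSE)
}

test_that("design matrix uses female-evening reference and product coding", {
  meta <- make_meta_for_design(2)  # p01 male, p02 female
  Z <- matrix(seq(0.1, 1.2, length.out = 12), 6, 2)
  colnames(Z) <- c("F01", "F02")
  d <- build_design(Z, meta, c("F01", "F02"), factors = c("sex", "time"))
  expect_equal(ncol(d$X), 2 + 3 + 2 * 3)  # mains + dummies + products

  fe <- which(meta$sex == "female" & meta$timepoint == "evening")
  dummy_cols <- c("Male", "Morning", "Afternoon",
                  d$terms$label[d$terms$type == "interaction"])
  expect_equal(unname(d$X[fe, dummy_cols]), rep(0, length(dummy_cols)))

  mm <- which(meta$sex == "male" & meta$timepoint == "morning")
  expect_equal(d$X[mm, "F01:Male"], Z[mm, "F01"], ignore_attr = TRUE)
  expect_equal(d$X[mm, "F01:Morning"], Z[mm, "F01"], ignore_attr = TRUE)
  expect_equal(d$X[mm, "F01:Afternoon"], 0, ignore_attr = TRUE)

  expect_error(build_design(Z, meta, c("F01"), factors = "batch"),
               "unknown factor")
  expect_error(build_design(Z, meta, character(0)), "nonempty")
})

test_that("information criteria match their closed forms", {
  expect_equal(aicc(100, 100, 1), 100 * log(1) + 2 + 4 / 98)
  # correction is positive and vanishes as n grows
  for (k in 1:5) {
    n <- 50
    a <- n * log(2) + 2 * k
    expect_gt(aicc(2 * n, n, k), a)
    expect_equal(aicc(2 * n, n, k) - a, 2 * k * (k + 1) / (n - k - 1))
  }
  expect_lt(abs(aicc(1e7, 1e7, 5) - (1e7 * log(1) + 10)), 1e-3)
  expect_equal(bic(50, 25, 3), 25 * log(2) + 3 * log(25))
  expect_error(aicc(10, 6, 5), "n > k")
  expect_error(bic(0, 10, 2), "rss")
})

test_that("OLS inference matches hand arithmetic on a textbook instance", {
  x <- c(1, 2, 3, 4, 5)
  y <- c(2, 4, 5, 4, 5)
  X <- matrix(x, ncol = 1, dimnames = list(NULL, "x"))
  fit <- fit_ols(X, y)
  # hand computation: slope = Sxy/Sxx, se from residual variance
  sxx <- sum((x - mean(x))^2)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  intercept <- mean(y) - slope * mean(x)
  r <- y - intercept - slope * x
  s2 <- sum(r^2) / 3
  se_slope <- sqrt(s2 / sxx)
  expect_equal(unname(fit$beta), c(intercept, slope))
  expect_equal(unname(fit$se[2]), se_slope)
  expect_equal(unname(fit$ci95_low[2]), slope - qt(0.975, 3) * se_slope)
  expect_equal(unname(fit$p_raw[2]),
               2 * pt(-abs(slope / se_slope), 3))
})

test_that("OLS handles the intercept-only and perfect-fit branches", {
  y <- c(1, 2, 3, 4)
  fit <- fit_ols(matrix(numeric(0), nrow = 4, ncol = 0), y)
  expect_equal(unname(fit$beta), mean(y))
  expect_equal(fit$adj_r2, 0)

  X <- matrix(c(1, 2, 3, 4, 5, 6), ncol = 1, dimnames = list(NULL, "x"))
  yp <- 2 + 3 * X[, 1]
  fitp <- fit_ols(X, yp)
  expect_equal(fitp$adj_r2, 1)
  expect_lt(fitp$p_raw[2], 1e-10)
  expect_true(is.finite(fitp$aicc))

  Xdup <- cbind(a = X[, 1], b = X[, 1])
  expect_error(fit_ols(Xdup, yp), "collinear")
})

test_that("OLS equals the normal-equations solution", {
  set.seed(55)
  for (r in 1:5) {
    X <- matrix(rnorm(30 * 4), 30, 4)
    colnames(X) <- paste0("c", 1:4)
    y <- rnorm(30)
    fit <- fit_ols(X, y)
    X1 <- cbind(1, X)
    beta_ne <- solve(crossprod(X1), crossprod(X1, y))  # independent route
    expect_equal(unname(fit$beta), as.vector(beta_ne), tolerance = 1e-8)
  }
})

test_that("BH adjustment follows the step-up rule and is monotone", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(rep(0.04, 5)), rep(0.04, 5))
  expect_equal(bh_adjust(0.2), 0.2)
  p <- c(0.001, 0.02, 0.5, 0.04, 1)
  adj <- bh_adjust(p)
  expect_true(all(adj >= p))
  expect_equal(order(adj), order(p))  # rank order preserved
  expect_error(bh_adjust(c(0.5, 1.5)), "0, 1")
})

test_that("stepwise on pure noise mostly returns the intercept-only model (BIC)", {
  meta <- make_meta_for_design(10)
  n_empty <- 0
  for (r in 1:30) {
    set.seed(600 + r)
    Z <- scale(matrix(rnorm(30 * 6), 30, 6))
    colnames(Z) <- sprintf("F%02d", 1:6)
    y <- rnorm(30)
    d <- build_design(Z, meta[1:30, ], colnames(Z), factors = character(0))
    fit <- stepwise(d, y, criterion = "bic")
    if (length(attr(fit, "selected")) == 0) n_empty <- n_empty + 1
  }
  expect_gt(n_empty, 15)
})

test_that("stepwise criterion is monotone along the path and respects hierarchy", {
  ch <- generate_cohort(cohort_config(
    n_subjects = 24, n_features = 12, n_informative = 3,
    n_sex_interactions = 1, n_time_interactions = 1,
    effect_scale = 0.5, sex_effect = 0, noise_sd = 0.05,
    subject_sd = 0.02, missing_rate = 0, outlier_rate = 0, seed = 19))
  pm <- log_standardize(ch$table)
  y <- log10(ch$meta$cortisol_ug)
  d <- build_design(pm, ch$meta, colnames(pm$z))
  fit <- stepwise(d, y, criterion = "aicc")
  path <- attr(fit, "path")
  expect_true(all(diff(path$criterion) < 0))

  sel <- attr(fit, "selected")
  terms <- d$terms
  for (lab in sel[terms$type[match(sel, terms$label)] == "interaction"]) {
    expect_true(terms$feature[terms$label == lab] %in% sel)
  }
})

test_that("stepwise at high SNR recovers the planted terms", {
  ch <- generate_cohort(cohort_config(
    n_subjects = 30, n_features = 10, n_informative = 3,
    n_sex_interactions = 1, n_time_interactions = 1,
    effect_scale = 0.4, sex_effect = 0, noise_sd = 0.05,
    subject_sd = 0.02, missing_rate = 0, outlier_rate = 0, seed = 23))
  pm <- log_standardize(ch$table)
  y <- log10(ch$meta$cortisol_ug)
  d <- build_design(pm, ch$meta, colnames(pm$z))
  fit <- stepwise(d, y, criterion = "aicc")
  sel <- attr(fit, "selected")
  expect_true(all(ch$truth$support_names %in% sel))
  planted_inter <- paste0(ch$truth$interactions$feature, ":",
                          ch$truth$interactions$dummy)
  expect_true(all(planted_inter %in% sel))
})

test_that("log-response switching changes only the response, not the design", {
  ch <- small_cohort(seed = 15, missing_rate = 0, outlier_rate = 0)
  pm <- log_standardize(ch$table)
  cand <- colnames(pm$z)[1:3]
  d1 <- build_design(pm, ch$meta, cand)
  fit_log <- fit_ols(d1, log10(ch$meta$cortisol_ug))
  fit_raw <- fit_ols(d1, ch$meta$cortisol_ug)
  expect_identical(fit_log$terms, fit_raw$terms)
  expect_false(isTRUE(all.equal(fit_log$beta, fit_raw$beta)))
})

test_that("model comparison ranks by AICc with BIC as tie-breaker", {
  mk <- function(aicc, bic, k = 5, n = 100) {
    structure(list(aicc = aicc, bic = bic, adj_r2 = 0.5, k = k, n = n,
                   y = rep(1, 4)), class = "fit_result")
  }
  fits <- list(a = mk(10, 20), b = mk(10, 15), c = mk(12, 5))
  cmp <- compare_models(fits)
  expect_identical(cmp$model, c("b", "a", "c"))  # equal AICc -> BIC decides

  fits2 <- list(lean = mk(10, 20, k = 10, n = 60),
                fat = mk(11, 21, k = 25, n = 60))
  cmp2 <- compare_models(fits2)
  expect_false(cmp2$overfit[cmp2$model == "lean"])
  expect_true(cmp2$overfit[cmp2$model == "fat"])  # k > n/3

  fits3 <- list(x = mk(1, 1), y = structure(
    list(aicc = 2, bic = 2, adj_r2 = 0, k = 2, n = 50, y = rep(1, 4)),
    class = "fit_result"))
  expect_error(compare_models(fits3), "same sample set")
})
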