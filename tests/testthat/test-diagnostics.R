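test_that("VIF is 1 for orthogonal predictors and matches the auxiliary oracle", {
  set.seed(65)
  n <- 40
  # orthonormal columns that are also orthogonal to the intercept
  X <- qr.Q(qr(cbind(1, matrix(rnorm(n * 3), n, 3))))[, 2:4]
  colnames(X) <- c("a", "b", "c")
  y <- rnorm(n)
  fit <- fit_ols(X, y)
  d <- compute_diagnostics(fit, X, y)
  expect_equal(unname(d$vif), rep(1, 3), tolerance = 1e-10)

  set.seed(66)
  X5 <- matrix(rnorm(n * 5), n, 5)
  X5[, 5] <- X5[, 1] + 0.5 * X5[, 2] + rnorm(n, 0, 0.3)  # induce collinearity
  colnames(X5) <- paste0("v", 1:5)
  fit5 <- fit_ols(X5, rnorm(n))
  d5 <- compute_diagnostics(fit5, X5, rnorm(n) * 0 + fit5$y)
  # oracle: VIF_j = 1/(1 - R2_j) from an explicit auxiliary regression
  for (j in 1:5) {
    aux <- lm(X5[, j] ~ X5[, -j])
    r2 <- summary(aux)$r.squared
    expect_equal(unname(d5$vif[j]), 1 / (1 - r2), tolerance = 1e-8)
  }
})

test_that("perfectly collinear columns report the capped VIF sentinel", {
  n <- 30
  x <- rnorm(n)
  X <- cbind(a = x, b = x, c = rnorm(n))
  vif <- vocortisol:::compute_vif(X)
  expect_gte(max(vif[c("a", "b")]), 1e6)
  y <- rnorm(n)
  fit <- fit_ols(cbind(a = x, c = X[, "c"]), y)
  d <- compute_diagnostics(fit, cbind(a = x, c = X[, "c"]), y)
  expect_true(d$flags$vif_ok)
})

test_that("residuals sum to zero, are orthogonal to the design, and studentized", {
  set.seed(70)
  X <- matrix(rnorm(50 * 3), 50, 3)
  colnames(X) <- c("a", "b", "c")
  y <- 1 + X %*% c(0.5, -0.2, 0.1) + rnorm(50, 0, 0.4)
  fit <- fit_ols(X, as.vector(y))
  d <- compute_diagnostics(fit, X, as.vector(y))
  expect_lt(abs(sum(d$residual)), 1e-8)
  expect_lt(max(abs(crossprod(cbind(1, X), d$residual))), 1e-7)
  manual <- d$residual / (sqrt(fit$sigma2) * sqrt(1 - d$leverage))
  expect_equal(d$std_residual, manual)
  expect_true(all(d$leverage > 0 & d$leverage < 1))
})

test_that("VIF is invariant to predictor rescaling", {
  set.seed(71)
  X <- matrix(rnorm(40 * 4), 40, 4)
  X[, 2] <- X[, 1] + rnorm(40, 0, 0.5)
  colnames(X) <- paste0("v", 1:4)
  v1 <- vocortisol:::compute_vif(X)
  Xs <- sweep(X, 2, c(10, 0.1, 3, 1000), `*`)
  v2 <- vocortisol:::compute_vif(Xs)
  expect_equal(v1, v2, tolerance = 1e-8)
})

test_that("prediction band has the closed-form half-width at the centroid", {
  set.seed(72)
  n <- 30
  X <- scale(matrix(rnorm(n * 2), n, 2), scale = FALSE)  # centered
  colnames(X) <- c("a", "b")
  y <- 2 + X %*% c(1, -1) + rnorm(n, 0, 0.3)
  fit <- fit_ols(X, as.vector(y))
  pv <- predicted_vs_observed(fit, X, as.vector(y))
  # at the design centroid (x = 0) the band half-width is t * sigma/sqrt(n)
  # for an orthogonalized design; check via a synthetic centroid row
  Xc <- rbind(X, 0)
  yc <- c(as.vector(y), mean(y))
  pvc <- predicted_vs_observed(fit, Xc, yc)
  hw <- (pvc$upr - pvc$lwr)[n + 1] / 2
  x0 <- c(1, 0, 0)
  expected <- qt(0.975, fit$df) *
    sqrt(fit$sigma2 * drop(t(x0) %*% fit$cov_unscaled %*% x0))
  expect_equal(hw, expected, tolerance = 1e-10)

  yp <- 1 + 2 * X[, 1]
  fitp <- fit_ols(X[, 1, drop = FALSE], yp)
  pvp <- predicted_vs_observed(fitp, X[, 1, drop = FALSE], yp)
  expect_equal(pvp$predicted, pvp$observed, tolerance = 1e-10)
})

test_that("assumption flags pass on well-specified data and fail when violated", {
  set.seed(73)
  n <- 120
  X <- matrix(rnorm(n * 2), n, 2)
  colnames(X) <- c("a", "b")
  y <- 1 + X %*% c(0.5, 0.3) + rnorm(n, 0, 0.3)
  fit <- fit_ols(X, as.vector(y))
  d <- compute_diagnostics(fit, X, as.vector(y))
  expect_true(d$flags$normal_residuals)
  expect_true(d$flags$homoskedastic)

  # strongly heteroskedastic errors trip the Breusch-Pagan flag
  yh <- 1 + X %*% c(0.5, 0.3) + rnorm(n, 0, exp(X[, 1]))
  fith <- fit_ols(X, as.vector(yh))
  dh <- compute_diagnostics(fith, X, as.vector(yh))
  expect_false(dh$flags$homoskedastic)
})

test_that("Welch subgroup t-tests match hand arithmetic and control the family", {
  n_sub <- 6
  meta <- data.frame(
    sample_id = sprintf("s%02d", 1:(3 * n_sub)),
    subject_id = rep(sprintf("p%02d", 1:n_sub), each = 3),
    sex = rep(rep(c("male", "female"), each = 3), n_sub / 2),
    timepoint = rep(c("morning", "afternoon", "evening"), n_sub),
    run_order = 1:(3 * n_sub), stringsAsFactors = FALSE)
  set.seed(80)
  Z <- matrix(rnorm(18 * 2), 18, 2)
  colnames(Z) <- c("F01", "F02")
  tt <- subgroup_ttests(Z, meta, c("F01", "F02"))
  # family: per feature, 3 sex-within-timepoint + 2 sexes x 3 time pairs
  expect_equal(nrow(tt), 2 * (3 + 6))

  row <- which(tt$feature == "F01" & tt$comparison == "sex@morning")
  x1 <- Z[meta$sex == "male" & meta$timepoint == "morning", "F01"]
  x2 <- Z[meta$sex == "female" & meta$timepoint == "morning", "F01"]
  se <- sqrt(var(x1) / 3 + var(x2) / 3)
  t_hand <- (mean(x1) - mean(x2)) / se
  df_hand <- se^4 / ((var(x1) / 3)^2 / 2 + (var(x2) / 3)^2 / 2)
  expect_equal(tt$t[row], t_hand, tolerance = 1e-10)
  expect_equal(tt$df[row], df_hand, tolerance = 1e-10)
  expect_equal(tt$p[row], 2 * pt(-abs(t_hand), df_hand), tolerance = 1e-10)
  expect_equal(tt$p_bh, bh_adjust(tt$p))
})

test_that("identical subgroups yield p = 1; a planted shift is significant", {
  n_sub <- 8
  meta <- data.frame(
    sample_id = sprintf("s%02d", 1:(3 * n_sub)),
    subject_id = rep(sprintf("p%02d", 1:n_sub), each = 3),
    sex = rep(rep(c("male", "female"), each = 3), n_sub / 2),
    timepoint = rep(c("morning", "afternoon", "evening"), n_sub),
    run_order = 1:(3 * n_sub), stringsAsFactors = FALSE)
  # males and females carry identical value sets within every timepoint:
  # value = timepoint base + within-sex subject offset
  tp_base <- c(morning = 0.2, afternoon = 0.5, evening = 0.8)
  within_sex_rank <- (match(meta$subject_id, unique(meta$subject_id)) - 1) %/% 2
  vals <- tp_base[meta$timepoint] + 0.1 * within_sex_rank
  Z <- matrix(rep(vals, 2), 24, 2)
  colnames(Z) <- c("F01", "F02")
  tt <- subgroup_ttests(Z, meta, "F01")
  sex_rows <- startsWith(tt$comparison, "sex@")
  expect_equal(tt$p[sex_rows], rep(1, 3))
  expect_false(any(tt$significant[sex_rows]))

  set.seed(81)
  Z2 <- matrix(rnorm(24 * 2, sd = 0.2), 24, 2)
  colnames(Z2) <- c("F01", "F02")
  Z2[meta$sex == "male", "F01"] <- Z2[meta$sex == "male", "F01"] + 3
  tt2 <- subgroup_ttests(Z2, meta, c("F01", "F02"), fdr = 0.10)
  expect_true(all(tt2$significant[tt2$feature == "F01" &
                                    startsWith(tt2$comparison, "sex@")]))
})

test_that("residual summaries back-transform to micrograms at 3 sig figs", {
  meta <- data.frame(sex = c("male", "male", "female"),
                     timepoint = c("morning", "morning", "evening"))
  res <- residual_summary(c(-0.408, 0.650, -0.929), meta)
  male_row <- res[res$group == "male.morning", ]
  expect_equal(male_row$min_ug, 0.391)
  expect_equal(male_row$max_ug, 4.47)
  female_row <- res[res$group == "female.evening", ]
  expect_equal(female_row$min_ug, 0.118)
  expect_equal(female_row$n, 1)
  expect_equal(female_row$min, female_row$max)
  expect_equal(female_row$min, female_row$mean)

  zero <- residual_summary(rep(0, 4),
                           data.frame(sex = rep("male", 4),
                                      timepoint = rep("morning", 4)))
  expect_equal(zero$mean_ug, 1.0)
})
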