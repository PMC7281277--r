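#' Regression diagnostics for a fitted cortisol model
#'
#' Computes the data behind the standard diagnostic plots (residual vs.
#' fitted, QQ, residual histogram, lag and drift plots, added-variable
#' point sets), variance inflation factors, and formal assumption flags:
#' normality of residuals (Shapiro-Wilk), homoskedasticity (Breusch-Pagan)
#' and collinearity (max VIF against a cutoff of 5). The formal tests back
#' the visual diagnostics at a deliberately loose alpha so only gross
#' violations flag.
#'
#' VIF for term j is `1/(1 - R2_j)` where `R2_j` comes from regressing
#' column j on the remaining (non-intercept) columns; it is computed here
#' from the inverse correlation matrix of the predictors, with perfectly
#' collinear columns reported as a capped sentinel (1e6 or larger).
#' Standardized residuals use internal studentization:
#' `r / (sigma * sqrt(1 - h))` with `h` the leverage.
#'
#' @param fit A `fit_result` from [fit_ols()] or [stepwise()].
#' @param design The design it was fitted on (`voc_design` or matrix).
#' @param y The response vector used in the fit.
#' @param run_order Optional acquisition order for the drift plot.
#' @param alpha Significance level for the formal assumption tests
#'   (default 0.01).
#' @param vif_cutoff Collinearity cutoff (default 5).
#' @return An object of class `diagnostics_report`.
#' @export
compute_diagnostics <- function(fit, design, y, run_order = NULL,
                                alpha = 0.01, vif_cutoff = 5) {
  X <- design_matrix(design)
  if (ncol(X) > 0 && !identical(colnames(X), fit$terms[-1]))
    X <- X[, fit$terms[-1], drop = FALSE]
  n <- length(y)
  if (nrow(X) != n && ncol(X) > 0) stop("design/response dimension mismatch")
  if (fit$n != n) stop("fit was not produced on this sample set")
  X1 <- cbind(1, X)
  fitted <- as.vector(X1 %*% fit$beta)
  resid <- y - fitted
  h <- rowSums((X1 %*% fit$cov_unscaled) * X1)
  sigma <- sqrt(fit$sigma2)
  denom <- sigma * sqrt(pmax(1 - h, .Machine$double.eps))
  std_resid <- if (sigma > 0) resid / denom else resid * 0

  vif <- compute_vif(X)
  qq <- stats::qqnorm(std_resid, plot.it = FALSE)
  hs <- graphics::hist(resid, plot = FALSE)
  ord <- if (!is.null(run_order)) order(run_order) else seq_len(n)

  normal_p <- if (n >= 3 && n <= 5000 && stats::sd(resid) > 0)
    stats::shapiro.test(resid)$p.value else NA_real_
  bp_p <- if (ncol(X) > 0 && fit$rss > 0) {
    lmobj <- stats::lm(y ~ X)
    unname(lmtest::bptest(lmobj)$p.value)
  } else NA_real_

  av <- list()
  if (ncol(X) >= 1) {
    for (j in seq_len(ncol(X))) {
      others <- cbind(1, X[, -j, drop = FALSE])
      ry <- stats::lm.fit(others, y)$residuals
      rx <- stats::lm.fit(others, X[, j])$residuals
      av[[colnames(X)[j]]] <- data.frame(x_resid = rx, y_resid = ry)
    }
  }

  structure(list(
    fitted = fitted,
    residual = resid,
    std_residual = std_resid,
    leverage = h,
    qq_pairs = data.frame(theoretical = qq$x, sample = qq$y),
    hist_bins = list(breaks = hs$breaks, counts = hs$counts),
    lag_pairs = if (n > 1) data.frame(r_t = resid[-n], r_t1 = resid[-1])
                else NULL,
    drift_pairs = data.frame(run_order = seq_len(n), residual = resid[ord]),
    vif = vif,
    av_data = av,
    adj_r2 = fit$adj_r2,
    tests = c(shapiro_p = normal_p, breusch_pagan_p = bp_p),
    flags = list(
      homoskedastic = is.na(bp_p) || bp_p > alpha,
      normal_residuals = is.na(normal_p) || normal_p > alpha,
      vif_ok = length(vif) == 0 || max(vif) <= vif_cutoff)),
    class = "diagnostics_report")
}

compute_vif <- function(X, sentinel = 1e6) {
  p <- ncol(X)
  if (p == 0) return(numeric(0))
  out <- rep(1, p)
  names(out) <- colnames(X)
  if (p == 1) return(out)
  R <- suppressWarnings(stats::cor(X))
  inv <- tryCatch(solve(R), error = function(e) NULL)
  if (!is.null(inv) && all(is.finite(diag(inv))) && all(diag(inv) > 0) &&
      max(diag(inv)) < sentinel) {
    out[] <- diag(inv)
    return(out)
  }
  # perfect (or near-perfect) collinearity: fall back to per-column
  # projections and cap at the sentinel
  for (j in seq_len(p)) {
    others <- cbind(1, X[, -j, drop = FALSE])
    rx <- stats::lm.fit(others, X[, j])$residuals
    xc <- X[, j] - mean(X[, j])
    tss <- sum(xc^2)
    r2 <- if (tss > 0) 1 - sum(rx^2) / tss else 0
    out[j] <- min(1 / max(1 - r2, 1 / sentinel), sentinel)
  }
  pmax(out, 1)
}

#' Predicted vs. observed values with a confidence band
#'
#' Returns the (predicted, observed) pairs on the model scale together
#' with the 95% confidence band for the mean prediction, derived from the
#' fit's coefficient covariance.
#'
#' @inheritParams compute_diagnostics
#' @param level Band coverage (default 0.95).
#' @return Data frame with `predicted`, `observed`, `lwr`, `upr`.
#' @export
predicted_vs_observed <- function(fit, design, y, level = 0.95) {
  X <- design_matrix(design)
  if (ncol(X) > 0 && !identical(colnames(X), fit$terms[-1]))
    X <- X[, fit$terms[-1], drop = FALSE]
  X1 <- cbind(1, X)
  pred <- as.vector(X1 %*% fit$beta)
  se_fit <- sqrt(pmax(fit$sigma2 * rowSums((X1 %*% fit$cov_unscaled) * X1), 0))
  tcrit <- stats::qt(1 - (1 - level) / 2, fit$df)
  data.frame(predicted = pred, observed = y,
             lwr = pred - tcrit * se_fit, upr = pred + tcrit * se_fit)
}

welch_t <- function(x1, x2, var_equal = FALSE) {
  m1 <- mean(x1); m2 <- mean(x2)
  v1 <- stats::var(x1); v2 <- stats::var(x2)
  if ((v1 + v2) == 0) {
    # degenerate-variance guard: equal means are indistinguishable
    return(list(t = if (m1 == m2) 0 else sign(m1 - m2) * Inf,
                df = length(x1) + length(x2) - 2,
                p = if (m1 == m2) 1 else 0))
  }
  tt <- stats::t.test(x1, x2, var.equal = var_equal)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value)
}

#' Subgroup t-tests for model metabolites
#'
#' For each model metabolite, compares standardized abundances between
#' sexes within each timepoint and between timepoint pairs within each
#' sex, using unpaired Welch t-tests (pooled-variance optional).
#' Benjamini-Hochberg FDR control is applied once over the whole
#' comparison family.
#'
#' @param z A `processed_matrix` or standardized matrix.
#' @param meta Sample metadata aligned to rows.
#' @param features Feature names to test (the model metabolites).
#' @param fdr Target false discovery rate (default 0.10).
#' @param var_equal Use the pooled-variance t-test instead of Welch.
#' @return Data frame with one row per comparison: `feature`,
#'   `comparison`, group labels and sizes, `t`, `df`, `p`, `p_bh`,
#'   `significant` (at the target FDR). Skipped (degenerate) comparisons
#'   are recorded with `NA` statistics.
#' @export
subgroup_ttests <- function(z, meta, features, fdr = 0.10,
                            var_equal = FALSE) {
  Z <- if (inherits(z, "processed_matrix")) z$z else as.matrix(z)
  stopifnot(nrow(Z) == nrow(meta))
  tps <- unique(meta$timepoint)
  sexes <- unique(meta$sex)
  rows <- list()
  for (f in features) {
    v <- Z[, f]
    for (tp in tps) {
      g1 <- v[meta$timepoint == tp & meta$sex == "male"]
      g2 <- v[meta$timepoint == tp & meta$sex == "female"]
      rows[[length(rows) + 1]] <- data.frame(
        feature = f, comparison = paste0("sex@", tp),
        group1 = "male", group2 = "female",
        n1 = length(g1), n2 = length(g2), stringsAsFactors = FALSE)
    }
    if (length(tps) >= 2) {
      prs <- utils::combn(tps, 2)
      for (s in sexes) {
        for (cix in seq_len(ncol(prs))) {
          rows[[length(rows) + 1]] <- data.frame(
            feature = f, comparison = paste0("time@", s),
            group1 = prs[1, cix], group2 = prs[2, cix],
            n1 = sum(meta$sex == s & meta$timepoint == prs[1, cix]),
            n2 = sum(meta$sex == s & meta$timepoint == prs[2, cix]),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  tab <- do.call(rbind, rows)
  tab$t <- tab$df <- tab$p <- NA_real_
  for (i in seq_len(nrow(tab))) {
    f <- tab$feature[i]
    if (startsWith(tab$comparison[i], "sex@")) {
      tp <- sub("sex@", "", tab$comparison[i])
      x1 <- Z[meta$timepoint == tp & meta$sex == "male", f]
      x2 <- Z[meta$timepoint == tp & meta$sex == "female", f]
    } else {
      s <- sub("time@", "", tab$comparison[i])
      x1 <- Z[meta$sex == s & meta$timepoint == tab$group1[i], f]
      x2 <- Z[meta$sex == s & meta$timepoint == tab$group2[i], f]
    }
    if (length(x1) < 2 || length(x2) < 2) next  # degenerate: skip
    res <- welch_t(x1, x2, var_equal)
    tab$t[i] <- res$t; tab$df[i] <- res$df; tab$p[i] <- res$p
  }
  ok <- !is.na(tab$p)
  tab$p_bh <- NA_real_
  tab$p_bh[ok] <- bh_adjust(tab$p[ok])
  tab$significant <- !is.na(tab$p_bh) & tab$p_bh <= fdr
  tab
}

#' Per-group residual summaries with microgram back-transforms
#'
#' Summarizes (standardized or raw) log10-scale residuals by subgroup and
#' reports the ratio-scale microgram equivalents `10^r` (an observed /
#' predicted fold difference) to 3 significant figures.
#'
#' @param residuals Residual vector on the log10 scale.
#' @param meta Sample metadata aligned to residuals.
#' @param groupby Metadata columns to group by (default sex and
#'   timepoint).
#' @return Data frame with per-group `min`, `max`, `mean`, `se` and the
#'   corresponding `*_ug` back-transforms.
#' @export
residual_summary <- function(residuals, meta,
                             groupby = c("sex", "timepoint")) {
  stopifnot(length(residuals) == nrow(meta))
  key <- interaction(meta[, groupby, drop = FALSE], sep = ".", drop = TRUE)
  parts <- split(residuals, key)
  out <- do.call(rbind, lapply(names(parts), function(g) {
    r <- parts[[g]]
    data.frame(group = g,
               n = length(r),
               min = min(r), max = max(r), mean = mean(r),
               se = if (length(r) > 1) stats::sd(r) / sqrt(length(r))
                    else NA_real_,
               stringsAsFactors = FALSE)
  }))
  out$min_ug <- signif(to_micrograms(out$min), 3)
  out$max_ug <- signif(to_micrograms(out$max), 3)
  out$mean_ug <- signif(to_micrograms(out$mean), 3)
  rownames(out) <- NULL
  out
}
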