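#' Build the interaction design matrix
#'
#' Columns are the candidate metabolite main effects, binary dummy main
#' effects for the screened factors (Male for sex; Morning and Afternoon
#' for time of day), and every candidate-by-dummy product. The reference
#' cell is a female evening sample (all dummies zero), for which a
#' prediction reduces to the intercept plus the metabolite main effects.
#'
#' @param z A `processed_matrix` or standardized matrix.
#' @param meta Sample metadata with `sex` and `timepoint` aligned to rows.
#' @param candidates Character vector of candidate feature names (columns
#'   of `z`).
#' @param factors Screened factors, a subset of `c("sex", "time")`.
#' @return An object of class `voc_design`: list with `X` (the matrix),
#'   and `terms` (data frame: label, type, feature, dummy).
#' @export
build_design <- function(z, meta, candidates, factors = c("sex", "time")) {
  Z <- if (inherits(z, "processed_matrix")) z$z else as.matrix(z)
  stopifnot(nrow(Z) == nrow(meta))
  if (!length(candidates)) stop("candidates must be nonempty")
  unknown <- setdiff(factors, c("sex", "time"))
  if (length(unknown))
    stop("unknown factor label(s): ", paste(unknown, collapse = ", "))
  miss <- setdiff(candidates, colnames(Z))
  if (length(miss))
    stop("candidate feature(s) not in z: ", paste(miss, collapse = ", "))

  main <- Z[, candidates, drop = FALSE]
  dummies <- NULL
  if ("sex" %in% factors)
    dummies <- cbind(dummies, Male = as.numeric(meta$sex == "male"))
  if ("time" %in% factors)
    dummies <- cbind(dummies,
                     Morning = as.numeric(meta$timepoint == "morning"),
                     Afternoon = as.numeric(meta$timepoint == "afternoon"))

  terms <- data.frame(label = candidates, type = "main",
                      feature = candidates, dummy = NA_character_,
                      stringsAsFactors = FALSE)
  X <- main
  if (!is.null(dummies)) {
    terms <- rbind(terms,
                   data.frame(label = colnames(dummies), type = "dummy",
                              feature = NA_character_,
                              dummy = colnames(dummies),
                              stringsAsFactors = FALSE))
    inter_cols <- list()
    inter_terms <- list()
    for (f in candidates) {
      for (d in colnames(dummies)) {
        lab <- paste0(f, ":", d)
        inter_cols[[lab]] <- main[, f] * dummies[, d]
        inter_terms[[lab]] <- data.frame(label = lab, type = "interaction",
                                         feature = f, dummy = d,
                                         stringsAsFactors = FALSE)
      }
    }
    X <- cbind(main, dummies, do.call(cbind, inter_cols))
    colnames(X) <- c(candidates, colnames(dummies), names(inter_cols))
    terms <- rbind(terms, do.call(rbind, inter_terms))
  }
  rownames(terms) <- NULL
  structure(list(X = X, terms = terms), class = "voc_design")
}

design_matrix <- function(design) {
  if (inherits(design, "voc_design")) design$X else as.matrix(design)
}

#' Small-sample corrected Akaike information criterion
#'
#' `aic = n log(rss/n) + 2k`, `aicc = aic + 2k(k+1)/(n-k-1)`, where `k`
#' counts the intercept and slopes (the Gaussian error variance is absorbed
#' into an additive constant common across compared models).
#'
#' @param rss Residual sum of squares (> 0).
#' @param n Number of samples.
#' @param k Number of estimated coefficients including the intercept.
#' @return The AICc value.
#' @export
aicc <- function(rss, n, k) {
  if (n <= k + 1) stop("AICc undefined: need n > k + 1 (n = ", n,
                       ", k = ", k, ")")
  if (rss <= 0) stop("AICc undefined for rss <= 0")
  n * log(rss / n) + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Bayesian information criterion
#'
#' `bic = n log(rss/n) + k log(n)` with the same `k` convention as
#' [aicc()].
#'
#' @inheritParams aicc
#' @return The BIC value.
#' @export
bic <- function(rss, n, k) {
  if (n <= k) stop("BIC undefined: need n > k")
  if (rss <= 0) stop("BIC undefined for rss <= 0")
  n * log(rss / n) + k * log(n)
}

#' Ordinary least squares with t-test inference
#'
#' Fits `y` on the design (plus intercept), returning coefficients,
#' standard errors from `sigma^2 (X'X)^-1`, 95% confidence intervals and
#' two-sided t-test p-values on `n - k` residual degrees of freedom,
#' Benjamini-Hochberg adjusted p-values over all model terms, adjusted
#' R-squared, and the AICc/BIC values used by the stepwise search.
#'
#' @param design A `voc_design` or plain matrix (no intercept column).
#' @param y Response vector (log10 cortisol in the standard pipeline).
#' @return An object of class `fit_result`.
#' @export
fit_ols <- function(design, y) {
  X <- design_matrix(design)
  n <- length(y)
  stopifnot(nrow(X) == n || ncol(X) == 0)
  X1 <- cbind("(Intercept)" = rep(1, n), X)
  k <- ncol(X1)
  if (n <= k) stop("need n > k (n = ", n, ", k = ", k, ")")
  qx <- qr(X1)
  if (qx$rank < k) {
    bad <- colnames(X1)[qx$pivot[(qx$rank + 1):k]]
    stop("rank-deficient design; collinear term(s): ",
         paste(bad, collapse = ", "))
  }
  beta <- qr.coef(qx, y)
  fitted <- as.vector(X1 %*% beta)
  resid <- y - fitted
  rss <- sum(resid^2)
  tss <- sum((y - mean(y))^2)
  df <- n - k
  sigma2 <- rss / df
  xtx_inv <- chol2inv(qr.R(qx))[order(qx$pivot), order(qx$pivot), drop = FALSE]
  dimnames(xtx_inv) <- list(colnames(X1), colnames(X1))
  se <- sqrt(pmax(sigma2 * diag(xtx_inv), 0))
  tval <- ifelse(se > 0, beta / se, ifelse(beta == 0, 0, sign(beta) * Inf))
  p_raw <- 2 * stats::pt(-abs(tval), df)
  tcrit <- stats::qt(0.975, df)
  adj_r2 <- if (tss > 0) 1 - (rss / df) / (tss / (n - 1)) else 1
  if (rss <= 0) adj_r2 <- 1
  eps <- .Machine$double.eps
  crit_rss <- max(rss, eps)  # guard the perfect-fit branch
  structure(list(terms = colnames(X1),
                 beta = beta,
                 se = se,
                 ci95_low = beta - tcrit * se,
                 ci95_high = beta + tcrit * se,
                 p_raw = p_raw,
                 p_bh = bh_adjust(p_raw),
                 rss = rss, tss = tss,
                 n = n, k = k, df = df,
                 sigma2 = sigma2,
                 adj_r2 = adj_r2,
                 aicc = aicc(crit_rss, n, k),
                 bic = bic(crit_rss, n, k),
                 fitted = fitted,
                 residuals = resid,
                 cov_unscaled = xtx_inv,
                 y = y),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, digits = 3, ...) {
  cat(sprintf("fit_result: %d terms (incl. intercept), n = %d\n", x$k, x$n))
  tab <- data.frame(term = x$terms,
                    beta = round(x$beta, digits),
                    ci95_low = round(x$ci95_low, digits),
                    ci95_high = round(x$ci95_high, digits),
                    p_bh = signif(x$p_bh, digits))
  print(tab, row.names = FALSE)
  cat(sprintf("adj R2 = %.3f, AICc = %.2f, BIC = %.2f\n",
              x$adj_r2, x$aicc, x$bic))
  invisible(x)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' The step-up false-discovery-rate adjustment:
#' `p_bh(i) = min over j with p(j) >= p(i) of min(1, m p(j) / rank(j))`.
#' Monotone in the raw p-values and never smaller than them.
#'
#' @param p_raw Vector of raw p-values in `[0, 1]`.
#' @return Adjusted p-values.
#' @export
bh_adjust <- function(p_raw) {
  if (any(is.na(p_raw)) || any(p_raw < 0 | p_raw > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p_raw, method = "BH")
}

step_criterion <- function(X1, y, criterion) {
  n <- length(y)
  k <- ncol(X1)
  if (n <= k + 1) return(NULL)
  fit <- stats::lm.fit(X1, y)
  if (fit$rank < k) return(NULL)  # rank-deficient candidate move
  rss <- sum(fit$residuals^2)
  if (rss <= 0) rss <- .Machine$double.eps
  if (criterion == "aicc") aicc(rss, n, k) else bic(rss, n, k)
}

#' Stepwise model search by AICc or BIC minimization
#'
#' Greedy single-term moves: at each step every legal addition (and, for
#' `"backward"`/`"both"`, removal) is scored by refitting and the move with
#' the largest criterion decrease is accepted; the search stops when no
#' move decreases the criterion. Ties are broken by the earlier term label
#' so the result is deterministic. With `hierarchy = TRUE` (default) an
#' interaction term may enter only while its metabolite main effect is in
#' the model, and a main effect may not leave while one of its interactions
#' remains; dummy main effects are ordinary candidate terms (the published
#' model retains interactions without dummy main effects).
#'
#' @param design A `voc_design` from [build_design()].
#' @param y Response vector.
#' @param direction `"both"` (default; starts from the intercept-only
#'   model), `"forward"`, or `"backward"` (starts from the full model).
#' @param criterion `"aicc"` (default) or `"bic"`.
#' @param hierarchy Enforce main-effect/interaction hierarchy.
#' @return A `fit_result` for the selected model, with the search path as
#'   `attr(, "path")` and the selected labels as `attr(, "selected")`.
#' @export
stepwise <- function(design, y, direction = c("both", "forward", "backward"),
                     criterion = c("aicc", "bic"), hierarchy = TRUE) {
  direction <- match.arg(direction)
  criterion <- match.arg(criterion)
  stopifnot(inherits(design, "voc_design"))
  X <- design$X
  terms <- design$terms
  labels <- terms$label
  n <- length(y)

  current <- if (direction == "backward") labels else character(0)
  can_add <- direction %in% c("both", "forward")
  can_drop <- direction %in% c("both", "backward")

  crit_for <- function(sel) {
    X1 <- cbind(1, X[, sel, drop = FALSE])
    step_criterion(X1, y, criterion)
  }
  best_crit <- crit_for(current)
  if (is.null(best_crit))
    stop("initial model is infeasible (too many terms or rank-deficient)")

  legal_adds <- function(sel) {
    cand <- setdiff(labels, sel)
    if (!hierarchy) return(cand)
    keep <- vapply(cand, function(lab) {
      row <- terms[terms$label == lab, ]
      row$type != "interaction" || row$feature %in% sel
    }, logical(1))
    cand[keep]
  }
  legal_drops <- function(sel) {
    if (!hierarchy) return(sel)
    keep <- vapply(sel, function(lab) {
      row <- terms[terms$label == lab, ]
      if (row$type != "main") return(TRUE)
      inter <- terms$label[terms$type == "interaction" &
                             terms$feature == lab]
      !any(inter %in% sel)
    }, logical(1))
    sel[keep]
  }

  path <- list(data.frame(step = 0, action = "start", term = "",
                          criterion = best_crit, stringsAsFactors = FALSE))
  step_i <- 0
  repeat {
    moves <- list()
    if (can_add) for (lab in sort(legal_adds(current)))
      moves[[paste0("+", lab)]] <- list(action = "add", term = lab,
                                        sel = c(current, lab))
    if (can_drop) for (lab in sort(legal_drops(current)))
      moves[[paste0("-", lab)]] <- list(action = "drop", term = lab,
                                        sel = setdiff(current, lab))
    if (!length(moves)) break
    crits <- vapply(moves, function(m) {
      v <- crit_for(m$sel)
      if (is.null(v)) NA_real_ else v
    }, numeric(1))
    if (all(is.na(crits))) break
    best <- which.min(crits)  # first index wins ties (label order)
    if (!(crits[best] < best_crit - 1e-10)) break
    best_crit <- crits[best]
    current <- moves[[best]]$sel
    step_i <- step_i + 1
    path[[length(path) + 1]] <-
      data.frame(step = step_i, action = moves[[best]]$action,
                 term = moves[[best]]$term, criterion = best_crit,
                 stringsAsFactors = FALSE)
  }

  # keep design order of retained terms
  current <- labels[labels %in% current]
  sub <- structure(list(X = X[, current, drop = FALSE],
                        terms = terms[terms$label %in% current, ,
                                      drop = FALSE]),
                   class = "voc_design")
  fit <- fit_ols(sub, y)
  attr(fit, "path") <- do.call(rbind, path)
  attr(fit, "selected") <- current
  fit
}

#' Rank competing fits by information criteria
#'
#' Ranks by AICc, breaking near-ties (and exact ties) by BIC, mirroring the
#' model-selection rule of the pipeline: AICc as the initial metric, BIC to
#' decide between models with similar AICc. Each fit is annotated with its
#' adjusted R-squared, term count and an overfitting flag (more than n/3
#' estimated coefficients).
#'
#' @param fits A named list of `fit_result` objects on the same samples.
#' @param diagnostics Optional named list of `diagnostics_report` objects
#'   (see [compute_diagnostics()]) used to annotate assumption flags.
#' @return A data frame ranked best-first, of class `model_comparison`.
#' @export
compare_models <- function(fits, diagnostics = NULL) {
  if (length(fits) < 2 && is.null(names(fits)))
    names(fits) <- paste0("model", seq_along(fits))
  if (is.null(names(fits)))
    names(fits) <- paste0("model", seq_along(fits))
  ns <- vapply(fits, function(f) f$n, numeric(1))
  if (length(unique(ns)) != 1)
    stop("fits must be on the same sample set (differing n)")
  ys <- vapply(fits, function(f) sum(f$y), numeric(1))
  if (max(ys) - min(ys) > 1e-8 * (1 + max(abs(ys))))
    stop("fits must be on the same sample set (differing response)")
  tab <- data.frame(
    model = names(fits),
    aicc = vapply(fits, function(f) f$aicc, numeric(1)),
    bic = vapply(fits, function(f) f$bic, numeric(1)),
    adj_r2 = vapply(fits, function(f) f$adj_r2, numeric(1)),
    k = vapply(fits, function(f) f$k, numeric(1)),
    n = ns,
    overfit = vapply(fits, function(f) f$k > f$n / 3, logical(1)),
    stringsAsFactors = FALSE)
  if (!is.null(diagnostics)) {
    flg <- function(name, what) {
      d <- diagnostics[[name]]
      if (is.null(d)) NA else d$flags[[what]]
    }
    tab$homoskedastic <- vapply(tab$model, flg, logical(1),
                                what = "homoskedastic")
    tab$normal_residuals <- vapply(tab$model, flg, logical(1),
                                   what = "normal_residuals")
    tab$vif_ok <- vapply(tab$model, flg, logical(1), what = "vif_ok")
  }
  tab <- tab[order(tab$aicc, tab$bic), ]
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  class(tab) <- c("model_comparison", "data.frame")
  tab
}
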