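#' Configuration for bootstrapped elastic-net stability selection
#'
#' @param n_iter Number of resampling iterations (default 250).
#' @param train_fraction Fraction of subjects assigned to the training set
#'   each iteration (default 0.8; with 60 subjects, 48 train / 12 test).
#' @param alpha_mix Elastic-net mixing weight between lasso (1) and ridge
#'   (0) penalties (default 0.5).
#' @param lambda_grid Optional fixed penalty grid (strictly positive,
#'   ascending). By default a 100-point log-spaced grid from the
#'   data-driven maximum down to `1e-4` of it is built per iteration.
#' @param n_lambda Grid size when `lambda_grid` is `NULL`.
#' @param lambda_min_ratio Ratio of smallest to largest grid value.
#' @param top_k Candidate subset sizes (default 25, 35 and 50).
#' @param resample `"subsample"` (default): repeated random train/test
#'   subject splits without replacement, matching the 48/12 arithmetic of
#'   an 80/20 split; `"bootstrap"`: subjects drawn with replacement for
#'   training, out-of-bag subjects as test.
#' @param seed Integer seed.
#' @return An object of class `selection_config`.
#' @export
selection_config <- function(n_iter = 250, train_fraction = 0.8,
                             alpha_mix = 0.5, lambda_grid = NULL,
                             n_lambda = 100, lambda_min_ratio = 1e-4,
                             top_k = c(25, 35, 50),
                             resample = c("subsample", "bootstrap"),
                             seed = 1L) {
  resample <- match.arg(resample)
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("train_fraction must lie in (0, 1)")
  if (alpha_mix < 0 || alpha_mix > 1)
    stop("alpha_mix must lie in [0, 1]")
  if (!is.null(lambda_grid)) {
    if (any(lambda_grid <= 0) || is.unsorted(lambda_grid))
      stop("lambda_grid must be strictly positive and sorted ascending")
  }
  structure(list(n_iter = as.integer(n_iter),
                 train_fraction = train_fraction,
                 alpha_mix = alpha_mix,
                 lambda_grid = lambda_grid,
                 n_lambda = as.integer(n_lambda),
                 lambda_min_ratio = lambda_min_ratio,
                 top_k = as.integer(top_k),
                 resample = resample,
                 seed = as.integer(seed)),
            class = "selection_config")
}

#' Elastic-net objective value
#'
#' The penalized least-squares objective minimized by [elastic_net_fit()]:
#' `RSS/(2n) + lambda * (alpha * sum(|beta|) + (1-alpha)/2 * sum(beta^2))`,
#' with an unpenalized intercept.
#'
#' @param X Predictor matrix.
#' @param y Response vector.
#' @param a0 Intercept.
#' @param beta Coefficient vector.
#' @param lambda Penalty strength.
#' @param alpha_mix L1 weight.
#' @return Scalar objective value.
#' @export
elastic_net_objective <- function(X, y, a0, beta, lambda, alpha_mix) {
  r <- y - a0 - as.vector(X %*% beta)
  mean(r^2) / 2 +
    lambda * (alpha_mix * sum(abs(beta)) + (1 - alpha_mix) / 2 * sum(beta^2))
}

enet_lambda_max <- function(X, y, alpha_mix) {
  n <- nrow(X)
  max(abs(crossprod(X, y - mean(y)))) / (n * max(alpha_mix, 1e-3))
}

#' Fit an elastic net at a single penalty value
#'
#' Minimizes the objective of [elastic_net_objective()] via coordinate
#' descent (delegated to glmnet with standardization disabled, since the
#' preprocessing chain standardizes once on the full analysis set), at a
#' convergence tolerance of 1e-7 on coefficient change. At `lambda = 0`
#' (and full column rank) the minimizer is the ordinary least-squares
#' solution, computed directly.
#'
#' @param X Column-standardized predictor matrix.
#' @param y Finite response vector (log10 cortisol).
#' @param lambda Penalty strength (non-negative scalar).
#' @param alpha_mix L1 weight (default 0.5).
#' @return List with `a0` (intercept) and `beta` (named coefficients).
#' @export
elastic_net_fit <- function(X, y, lambda, alpha_mix = 0.5) {
  X <- as.matrix(X)
  if (!all(is.finite(X)) || !all(is.finite(y)))
    stop("non-finite values in X or y")
  if (length(lambda) != 1 || lambda < 0)
    stop("lambda must be a non-negative scalar")
  if (lambda == 0 && nrow(X) > ncol(X)) {
    fit <- stats::lm.fit(cbind(1, X), y)
    beta <- fit$coefficients[-1]
    names(beta) <- colnames(X)
    return(list(a0 = unname(fit$coefficients[1]), beta = beta))
  }
  lmax <- enet_lambda_max(X, y, alpha_mix)
  hi <- max(lmax, lambda) * 1.001
  lo <- max(min(lambda, lmax * 1e-4), hi * 1e-9)
  path <- exp(seq(log(hi), log(lo), length.out = 60))
  fit <- glmnet::glmnet(X, y, alpha = alpha_mix, lambda = path,
                        standardize = FALSE, thresh = 1e-12)
  cf <- as.vector(glmnet::coef.glmnet(fit, s = lambda, exact = TRUE,
                                      x = X, y = y, alpha = alpha_mix,
                                      standardize = FALSE, thresh = 1e-12))
  beta <- cf[-1]
  names(beta) <- colnames(X)
  list(a0 = cf[1], beta = beta)
}

#' Bootstrapped elastic-net selection frequencies
#'
#' The stability-selection core: over `n_iter` iterations, subjects (never
#' individual samples, so repeated measures from one subject cannot
#' straddle the split) are partitioned into training and test sets; the
#' elastic-net regularization path is fitted on the training samples, the
#' penalty minimizing held-out test mean squared error is chosen, and the
#' features with nonzero coefficients at that penalty are recorded.
#' Aggregated counts over iterations give each feature's selection
#' frequency.
#'
#' @param z A `processed_matrix` (or standardized matrix) whose rows align
#'   with `meta`.
#' @param meta Sample metadata with `subject_id` and `cortisol_ug`.
#' @param config A [selection_config()].
#' @param log_response Model log10 cortisol (default) or the raw value.
#' @return An object of class `selection_frequency`: list with `table`
#'   (feature, count, frequency, mean_abs_coef), `iterations` (chosen
#'   lambda and test MSE per iteration), `train_subjects` (per-iteration
#'   training subject sets), `n_iter_effective` and the config.
#' @export
bootstrap_select <- function(z, meta, config = selection_config(),
                             log_response = TRUE) {
  X <- if (inherits(z, "processed_matrix")) z$z else as.matrix(z)
  stopifnot(nrow(X) == nrow(meta))
  y <- if (log_response) log10(meta$cortisol_ug) else meta$cortisol_ug
  subjects <- unique(meta$subject_id)
  if (length(subjects) < 5) stop("need at least 5 subjects")
  n_train <- round(config$train_fraction * length(subjects))
  if (n_train < 1 || n_train >= length(subjects))
    stop("train_fraction leaves an empty train or test set")

  p <- ncol(X)
  counts <- integer(p)
  abs_sum <- numeric(p)
  iters <- vector("list", config$n_iter)
  train_sets <- vector("list", config$n_iter)
  skipped <- 0L

  set.seed(config$seed)
  for (it in seq_len(config$n_iter)) {
    if (config$resample == "subsample") {
      tr_subj <- sample(subjects, n_train)
      te_subj <- setdiff(subjects, tr_subj)
      tr_rows <- which(meta$subject_id %in% tr_subj)
    } else {
      tr_subj <- sample(subjects, n_train, replace = TRUE)
      te_subj <- setdiff(subjects, tr_subj)
      tr_rows <- unlist(lapply(tr_subj, function(s)
        which(meta$subject_id == s)), use.names = FALSE)
    }
    te_rows <- which(meta$subject_id %in% te_subj)
    y_tr <- y[tr_rows]
    if (length(te_rows) == 0 || stats::sd(y_tr) == 0) {
      skipped <- skipped + 1L
      next
    }
    X_tr <- X[tr_rows, , drop = FALSE]
    fit <- if (is.null(config$lambda_grid)) {
      glmnet::glmnet(X_tr, y_tr, alpha = config$alpha_mix,
                     nlambda = config$n_lambda,
                     lambda.min.ratio = config$lambda_min_ratio,
                     standardize = FALSE)
    } else {
      glmnet::glmnet(X_tr, y_tr, alpha = config$alpha_mix,
                     lambda = rev(config$lambda_grid),
                     standardize = FALSE)
    }
    pred <- stats::predict(fit, X[te_rows, , drop = FALSE])
    mse <- colMeans((y[te_rows] - pred)^2)
    best <- which.min(mse)
    b <- fit$beta[, best]
    nz <- which(b != 0)
    counts[nz] <- counts[nz] + 1L
    abs_sum[nz] <- abs_sum[nz] + abs(b[nz])
    iters[[it]] <- data.frame(iter = it, lambda = fit$lambda[best],
                              test_mse = mse[best], n_selected = length(nz))
    train_sets[[it]] <- sort(unique(tr_subj))
  }
  if (skipped > 0.1 * config$n_iter)
    stop("more than 10% of iterations skipped (degenerate training sets)")

  tab <- data.frame(feature = colnames(X),
                    index = seq_len(p),
                    count = counts,
                    frequency = counts / (config$n_iter - skipped),
                    mean_abs_coef = ifelse(counts > 0, abs_sum / counts, 0),
                    stringsAsFactors = FALSE)
  structure(list(table = tab,
                 iterations = do.call(rbind, iters),
                 train_subjects = train_sets[!vapply(train_sets, is.null,
                                                     logical(1))],
                 n_iter_effective = config$n_iter - skipped,
                 config = config),
            class = "selection_frequency")
}

#' @export
print.selection_frequency <- function(x, ...) {
  cat(sprintf("selection_frequency: %d features over %d iterations\n",
              nrow(x$table), x$n_iter_effective))
  top <- utils::head(x$table[order(-x$table$frequency), ], 5)
  print(top, row.names = FALSE)
  invisible(x)
}

#' Top-k features by selection frequency
#'
#' Ties in frequency are broken by the larger mean absolute elastic-net
#' coefficient over the iterations in which the feature was selected, then
#' by the lower feature index, so the output is deterministic.
#'
#' @param freq A `selection_frequency` object.
#' @param k Number of features to return.
#' @return Character vector of feature names (highest frequency first),
#'   with the original column indices as the `index` attribute.
#' @export
top_k <- function(freq, k) {
  tab <- freq$table
  if (k <= 0) stop("k must be positive")
  if (k > nrow(tab)) stop("k exceeds the number of features")
  ord <- order(-tab$frequency, -tab$mean_abs_coef, tab$index)
  sel <- tab[ord[seq_len(k)], ]
  structure(sel$feature, index = sel$index)
}
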