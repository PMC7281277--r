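#' Load the frozen published cortisol predictor
#'
#' The final fitted multiple regression model for log10 total free urinary
#' cortisol: an intercept, 14 metabolite main effects on standardized log10
#' abundances, and 7 sex/time-of-day interaction terms (22 coefficients in
#' all), shipped as versioned data at printed 3-decimal precision and
#' validated against a fixed checksum on load. The coefficients are data,
#' never re-derived.
#'
#' @param path Path to the model JSON (defaults to the copy shipped with
#'   the package).
#' @return An object of class `published_model` with `intercept`, `main`
#'   (14-row data frame) and `interactions` (7-row data frame).
#' @export
published_model <- function(path = system.file("extdata",
                                               "published_model.json",
                                               package = "vocortisol")) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  main <- as.data.frame(raw$main, stringsAsFactors = FALSE)
  inter <- as.data.frame(raw$interactions, stringsAsFactors = FALSE)
  if (nrow(main) != 14)
    stop("published model must have exactly 14 main terms")
  if (nrow(inter) != 7)
    stop("published model must have exactly 7 interaction terms")
  feats <- sub(":.*$", "", inter$label)
  if (!all(feats %in% main$label))
    stop("every interaction's metabolite must be a main term")
  millis <- sum(round(1000 * c(raw$intercept$beta, main$beta, inter$beta)))
  if (millis != raw$checksum_millis)
    stop("published model checksum mismatch: coefficients corrupted")
  structure(list(intercept = raw$intercept$beta,
                 intercept_ci = c(raw$intercept$ci95_low,
                                  raw$intercept$ci95_high),
                 main = main,
                 interactions = inter,
                 version = raw$version),
            class = "published_model")
}

#' @export
print.published_model <- function(x, ...) {
  cat(sprintf(paste0("published_model v%s: intercept %.3f, ",
                     "14 main + 7 interaction terms\n"),
              x$version, x$intercept))
  invisible(x)
}

#' Predict log10 cortisol with the published model
#'
#' Evaluates `intercept + sum(beta_j x_j) + sum(beta_jk x_j d_k)` where
#' `x_1..x_14` are standardized log10 metabolite abundances and the
#' dummies are Male, Morning and Afternoon indicators (a female evening
#' sample has all dummies zero).
#'
#' @param model A [published_model()].
#' @param x Numeric vector of 14 standardized abundances (ordered
#'   x1..x14, or named by label), or an n-by-14 matrix for several
#'   samples.
#' @param sex `"male"` or `"female"` (recycled across rows).
#' @param timepoint `"morning"`, `"afternoon"` or `"evening"`.
#' @return Predicted log10 cortisol (ug), one value per sample.
#' @export
predict_log10_cortisol <- function(model, x, sex, timepoint) {
  stopifnot(inherits(model, "published_model"))
  X <- if (is.matrix(x)) x else matrix(x, nrow = 1)
  if (ncol(X) != 14)
    stop("x must supply exactly 14 standardized metabolite values")
  if (!is.null(colnames(X))) {
    miss <- setdiff(model$main$label, colnames(X))
    if (length(miss))
      stop("x lacks label(s): ", paste(miss, collapse = ", "))
    X <- X[, model$main$label, drop = FALSE]
  }
  n <- nrow(X)
  sex <- rep_len(sex, n)
  timepoint <- rep_len(timepoint, n)
  if (!all(sex %in% c("male", "female")))
    stop("sex must be 'male' or 'female'")
  if (!all(timepoint %in% c("morning", "afternoon", "evening")))
    stop("timepoint must be morning, afternoon or evening")
  d <- cbind(Male = as.numeric(sex == "male"),
             Morning = as.numeric(timepoint == "morning"),
             Afternoon = as.numeric(timepoint == "afternoon"))
  pred <- model$intercept + as.vector(X %*% model$main$beta)
  for (i in seq_len(nrow(model$interactions))) {
    row <- model$interactions[i, ]
    j <- match(sub(":.*$", "", row$label), model$main$label)
    pred <- pred + row$beta * X[, j] * d[, row$dummy]
  }
  unname(pred)
}

#' Back-transform log10 micrograms to micrograms
#'
#' `10^v`. Applied to a residual (a log10-scale difference) the result is
#' the observed/predicted ratio on the microgram scale; summaries report
#' it to 3 significant figures.
#'
#' @param v Value(s) on the log10 ug scale.
#' @return `10^v`.
#' @export
to_micrograms <- function(v) {
  stopifnot(all(is.finite(v)))
  10^v
}

#' Structural summary of the published model
#'
#' @param model A [published_model()].
#' @return List with term counts (14 main, 7 interaction, 21 non-intercept,
#'   22 including the intercept), labels, and the printed coefficient/CI/p
#'   columns.
#' @export
model_card <- function(model = published_model()) {
  full <- rbind(
    data.frame(label = "(Intercept)", compound = "Intercept",
               beta = model$intercept,
               ci95_low = model$intercept_ci[1],
               ci95_high = model$intercept_ci[2],
               p_bh = NA_real_, stringsAsFactors = FALSE),
    model$main[, c("label", "compound", "beta", "ci95_low", "ci95_high",
                   "p_bh")],
    model$interactions[, c("label", "compound", "beta", "ci95_low",
                           "ci95_high", "p_bh")])
  rownames(full) <- NULL
  list(n_main = nrow(model$main),
       n_interactions = nrow(model$interactions),
       n_terms = nrow(model$main) + nrow(model$interactions),
       n_coefficients = nrow(model$main) + nrow(model$interactions) + 1L,
       labels = c(model$main$label, model$interactions$label),
       table = full)
}

#' Apply the published model to a processed cohort
#'
#' Maps table columns onto the model variables x1..x14, predicts log10
#' cortisol per sample, and returns observed-minus-predicted residuals
#' ready for [residual_summary()].
#'
#' @param model A [published_model()].
#' @param z A `processed_matrix` (or standardized matrix) whose rows align
#'   with `meta`.
#' @param meta Sample metadata with `sex`, `timepoint`, `cortisol_ug`.
#' @param map Named character or integer vector mapping every model label
#'   (`x1`..`x14`) to a column of `z`.
#' @return Data frame with `sample_id`, `predicted`, `observed`,
#'   `residual` (log10 scale).
#' @export
evaluate_on_cohort <- function(model, z, meta, map) {
  Z <- if (inherits(z, "processed_matrix")) z$z else as.matrix(z)
  stopifnot(nrow(Z) == nrow(meta))
  missing_x <- setdiff(model$main$label, names(map))
  if (length(missing_x)) {
    pretty <- vapply(missing_x, function(l) {
      sprintf("%s (%s)", l, model$main$compound[model$main$label == l])
    }, character(1))
    stop("map lacks model variable(s): ", paste(pretty, collapse = ", "))
  }
  cols <- map[model$main$label]
  X <- Z[, cols, drop = FALSE]
  colnames(X) <- model$main$label
  pred <- predict_log10_cortisol(model, X, meta$sex, meta$timepoint)
  obs <- log10(meta$cortisol_ug)
  data.frame(sample_id = meta$sample_id,
             predicted = pred,
             observed = obs,
             residual = obs - pred,
             stringsAsFactors = FALSE)
}

#' Map feature-table columns to the published model by retention times
#'
#' Unknown and unnamed compounds in the published model are addressed by
#' their chromatographic coordinates; a user's aligned feature table can be
#' mapped by matching first- and second-dimension retention times within
#' the alignment windows (default +/-2 s and +/-0.2 s).
#'
#' @param model A [published_model()].
#' @param feature_meta Feature metadata data frame with `name`, `rt1_s`,
#'   `rt2_s`.
#' @param rt1_tol First-dimension tolerance in seconds.
#' @param rt2_tol Second-dimension tolerance in seconds.
#' @return Named character vector (model label -> feature name); unmatched
#'   labels are `NA` with a warning.
#' @export
map_features_by_retention <- function(model, feature_meta,
                                      rt1_tol = 2, rt2_tol = 0.2) {
  map <- vapply(seq_len(nrow(model$main)), function(i) {
    d1 <- abs(feature_meta$rt1_s - model$main$rt1_s[i])
    d2 <- abs(feature_meta$rt2_s - model$main$rt2_s[i])
    ok <- which(d1 <= rt1_tol & d2 <= rt2_tol)
    if (!length(ok)) return(NA_character_)
    feature_meta$name[ok[which.min(d1[ok] + 10 * d2[ok])]]
  }, character(1))
  names(map) <- model$main$label
  if (anyNA(map))
    warning("unmatched model variable(s): ",
            paste(names(map)[is.na(map)], collapse = ", "))
  map
}
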