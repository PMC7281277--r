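#' Probabilistic quotient normalization
#'
#' Corrects per-sample dilution by dividing each sample's abundances by its
#' probabilistic quotient: the median, over that sample's observed features,
#' of the ratio of the abundance to a reference spectrum. The reference is
#' the per-feature median over samples in which the feature was observed
#' (the classic median-spectrum formulation). Missing entries stay missing.
#'
#' @param table A [feature_table()] with at least two samples, each with at
#'   least one observed feature.
#' @return A list with `table` (the normalized [feature_table()]) and
#'   `quotient` (the per-sample dilution quotient, named by sample).
#' @export
pqn_normalize <- function(table) {
  ab <- table$abundance
  if (nrow(ab) < 2) stop("PQN requires at least 2 samples")
  if (any(rowSums(!is.na(ab)) < 1))
    stop("every sample must have at least one observed feature")
  ref <- apply(ab, 2, stats::median, na.rm = TRUE)
  usable <- !is.na(ref) & ref > 0
  quotient <- vapply(seq_len(nrow(ab)), function(i) {
    x <- ab[i, usable]
    r <- ref[usable]
    ok <- !is.na(x)
    if (!any(ok))
      stop("sample '", rownames(ab)[i],
           "': all observed features have zero reference abundance")
    q <- stats::median(x[ok] / r[ok])
    if (!is.finite(q) || q <= 0)
      stop("sample '", rownames(ab)[i],
           "': non-positive probabilistic quotient")
    q
  }, numeric(1))
  names(quotient) <- rownames(ab)
  out <- table
  out$abundance <- ab / quotient
  list(table = out, quotient = quotient)
}

#' Presence filter
#'
#' Retains features observed (non-missing) in at least `min_fraction` of
#' samples; a feature exactly at the boundary is retained.
#'
#' @param table A [feature_table()].
#' @param min_fraction Minimum fraction of samples in which a feature must
#'   be observed (default 0.5, i.e. present in at least half of samples).
#' @return The filtered [feature_table()]; retained original indices are
#'   available as `attr(, "retained")`.
#' @export
presence_filter <- function(table, min_fraction = 0.5) {
  if (min_fraction <= 0 || min_fraction > 1)
    stop("min_fraction must lie in (0, 1]")
  frac <- colMeans(!is.na(table$abundance))
  keep <- which(frac >= min_fraction)
  out <- subset_features(table, keep)
  attr(out, "retained") <- keep
  out
}

#' Blank and early-elution filter
#'
#' Drops features eluting before `min_rt1_s` seconds in the first dimension
#' (default 358 s, removing solvent-front artifacts) and features flagged as
#' present in blank samples.
#'
#' @param table A [feature_table()].
#' @param min_rt1_s Minimum first-dimension retention time in seconds.
#' @return The filtered [feature_table()] with `attr(, "retained")`.
#' @export
blank_and_early_filter <- function(table, min_rt1_s = 358) {
  fm <- table$feature_meta
  keep <- which(fm$rt1_s >= min_rt1_s & !fm$blank_flag)
  out <- subset_features(table, keep)
  attr(out, "retained") <- keep
  out
}

#' Cortisol outlier filter
#'
#' Drops samples whose measured cortisol lies outside the configured
#' healthy range (default ceiling 45 ug per the adult reference range for
#' 24-h total free urinary cortisol), plus any explicitly excluded sample
#' ids (for exclusions made on grounds other than the numeric rule).
#'
#' @param meta Sample metadata data frame with `cortisol_ug`.
#' @param max_ug Upper cortisol bound in ug (default 45).
#' @param min_ug Lower cortisol bound in ug (default 0).
#' @param exclude Character vector of `sample_id`s to drop regardless of
#'   their value.
#' @return A list with `kept` and `dropped` metadata data frames.
#' @export
outlier_filter <- function(meta, max_ug = 45, min_ug = 0,
                           exclude = character(0)) {
  if (any(is.na(meta$cortisol_ug)))
    stop("cortisol_ug must be present for all samples")
  drop <- meta$cortisol_ug > max_ug | meta$cortisol_ug < min_ug |
    meta$sample_id %in% exclude
  list(kept = meta[!drop, , drop = FALSE],
       dropped = meta[drop, , drop = FALSE])
}

#' Log-transform, centre and scale a feature table
#'
#' Imputes remaining missing entries (default: half the feature's minimum
#' observed value, consistent with left-censoring at a detection limit),
#' log10-transforms, then centres and scales each feature to mean 0 and
#' unit sample (n-1) standard deviation. The per-feature means and SDs are
#' stored so the same transform can be applied to new samples.
#'
#' @param table A [feature_table()].
#' @param impute Imputation strategy: `"half_min"` (default), `"min"`, or
#'   `"value"` (a fixed abundance given via `impute_value`).
#' @param impute_value Abundance used when `impute = "value"`.
#' @return An object of class `processed_matrix`: list with `z` (the
#'   standardized matrix), `feature_mean`, `feature_sd` (log10 scale),
#'   `retained` (feature names), `pqn_factor` and `dropped_samples`
#'   (filled by [preprocess_cohort()]).
#' @export
log_standardize <- function(table, impute = c("half_min", "min", "value"),
                            impute_value = NULL) {
  impute <- match.arg(impute)
  ab <- table$abundance
  for (j in seq_len(ncol(ab))) {
    nas <- is.na(ab[, j])
    if (any(nas)) {
      obs <- ab[!nas, j]
      if (!length(obs))
        stop("feature '", colnames(ab)[j], "' has no observed values")
      fill <- switch(impute,
                     half_min = min(obs) / 2,
                     min = min(obs),
                     value = {
                       if (is.null(impute_value))
                         stop("impute = 'value' requires impute_value")
                       impute_value
                     })
      ab[nas, j] <- fill
    }
  }
  if (any(ab <= 0))
    stop("all abundances must be positive after imputation")
  lg <- log10(ab)
  mu <- colMeans(lg)
  sd_ <- apply(lg, 2, stats::sd)
  zero_var <- sd_ <= 0 | !is.finite(sd_)
  if (any(zero_var))
    stop("feature(s) with zero variance after log transform cannot be ",
         "scaled: ", paste(colnames(ab)[zero_var], collapse = ", "))
  z <- sweep(sweep(lg, 2, mu, `-`), 2, sd_, `/`)
  structure(list(z = z,
                 feature_mean = mu,
                 feature_sd = sd_,
                 retained = colnames(ab),
                 pqn_factor = NULL,
                 dropped_samples = character(0),
                 impute = impute),
            class = "processed_matrix")
}

#' @export
print.processed_matrix <- function(x, ...) {
  cat(sprintf("processed_matrix: %d samples x %d standardized features\n",
              nrow(x$z), ncol(x$z)))
  invisible(x)
}

#' Full preprocessing chain for a cohort
#'
#' Applies, in order: blank/early-elution filter, probabilistic quotient
#' normalization, presence filter, cortisol outlier removal, then
#' log10/centre/scale. Sample-level normalization precedes feature pruning;
#' standardization is computed once on the final analysis set.
#'
#' @param meta Sample metadata data frame.
#' @param table A [feature_table()] aligned with `meta` rows.
#' @param min_fraction Presence threshold (default 0.5).
#' @param min_rt1_s Early-elution cutoff in seconds (default 358).
#' @param max_ug Cortisol ceiling in ug (default 45).
#' @param exclude Explicit sample-id exclusion list.
#' @param impute Imputation strategy for [log_standardize()].
#' @return A list with `z` (a `processed_matrix` carrying PQN factors and
#'   dropped sample ids) and `meta` (the retained sample metadata).
#' @export
preprocess_cohort <- function(meta, table, min_fraction = 0.5,
                              min_rt1_s = 358, max_ug = 45,
                              exclude = character(0),
                              impute = "half_min") {
  stopifnot(nrow(meta) == nrow(table$abundance))
  table <- blank_and_early_filter(table, min_rt1_s)
  pq <- pqn_normalize(table)
  table <- presence_filter(pq$table, min_fraction)
  filt <- outlier_filter(meta, max_ug = max_ug, exclude = exclude)
  keep <- meta$sample_id %in% filt$kept$sample_id
  table <- subset_samples(table, keep)
  pm <- log_standardize(table, impute = impute)
  pm$pqn_factor <- pq$quotient[keep]
  pm$dropped_samples <- filt$dropped$sample_id
  list(z = pm, meta = filt$kept)
}

#' Apply frozen standardization parameters to new samples
#'
#' Uses the per-feature log10 means and SDs stored in a `processed_matrix`
#' to place new samples on the same standardized scale, so a frozen model
#' can be applied to data it was not trained on.
#'
#' @param pm A `processed_matrix`.
#' @param table A [feature_table()] containing at least the retained
#'   features (matched by name); missing entries are imputed with the
#'   stored strategy applied to the new data.
#' @return Standardized matrix for the new samples.
#' @export
apply_standardization <- function(pm, table) {
  miss <- setdiff(pm$retained, colnames(table$abundance))
  if (length(miss))
    stop("table lacks retained feature(s): ", paste(miss, collapse = ", "))
  sub <- subset_features(table, match(pm$retained, colnames(table$abundance)))
  new_pm <- log_standardize(sub, impute = pm$impute)
  lg <- sweep(sweep(new_pm$z, 2, new_pm$feature_sd, `*`), 2,
              new_pm$feature_mean, `+`)
  sweep(sweep(lg, 2, pm$feature_mean, `-`), 2, pm$feature_sd, `/`)
}
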