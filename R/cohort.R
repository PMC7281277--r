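#' Configuration for a synthetic diurnal-cortisol VOC cohort
#'
#' Bundles and validates the parameters of the synthetic cohort generator.
#' Defaults emulate the design of the motivating study: 60 subjects
#' (30 male, 30 female), one urine sample each at morning, afternoon and
#' evening, and a feature table on the scale of the ~512 volatile features
#' retained after filtering, of which a small planted subset drives
#' log10 cortisol through a sparse linear model with sex and time-of-day
#' interactions.
#'
#' @param n_subjects Number of subjects (default 60).
#' @param male_fraction Fraction of male subjects (default 0.5).
#' @param timepoints Ordered collection timepoints.
#' @param n_features Number of volatile features (default 512).
#' @param n_informative Size of the planted support (default 14).
#' @param n_sex_interactions Number of planted feature-by-Male interaction
#'   terms (default 3); their features are drawn from the support.
#' @param n_time_interactions Number of planted feature-by-Morning/Afternoon
#'   interaction terms (default 4).
#' @param effect_scale Magnitude scale of planted coefficients on the
#'   standardized log10 abundance scale (default 0.1, the magnitude range of
#'   the published model's metabolite coefficients). Individual magnitudes
#'   are `effect_scale * U(0.4, 1.6)` with random sign.
#' @param sex_effect Male-minus-female difference in mean log10 cortisol,
#'   applied symmetrically (+/- half to each sex) so per-timepoint marginal
#'   means remain `diurnal_means` at a balanced sex ratio. Default 0.2,
#'   giving the factor screen a detectable sex signal.
#' @param noise_sd SD of the log10-cortisol error term (log10 ug).
#' @param diurnal_means Named per-timepoint mean log10 cortisol (ug); must
#'   decrease morning to evening (the typical diurnal shift).
#' @param subject_sd Between-subject random-effect SD (log10 ug).
#' @param missing_rate Per-feature fraction of entries censored below the
#'   detection limit (lowest abundances set missing).
#' @param outlier_rate Fraction of samples re-assigned a cortisol value above
#'   the physiologic ceiling, emulating the outliers the study removed.
#' @param max_healthy_ug Reference-range ceiling for total free urinary
#'   cortisol (ug); non-outlier samples are kept below it.
#' @param seed Integer seed governing all draws.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 60,
                          male_fraction = 0.5,
                          timepoints = c("morning", "afternoon", "evening"),
                          n_features = 512,
                          n_informative = 14,
                          n_sex_interactions = 3,
                          n_time_interactions = 4,
                          effect_scale = 0.1,
                          sex_effect = 0.2,
                          noise_sd = 0.2,
                          diurnal_means = c(morning = 0.80, afternoon = 0.50,
                                            evening = 0.30),
                          subject_sd = 0.1,
                          missing_rate = 0.2,
                          outlier_rate = 2 / 180,
                          max_healthy_ug = 45,
                          seed = 1L) {
  cfg <- list(n_subjects = as.integer(n_subjects),
              male_fraction = male_fraction,
              timepoints = timepoints,
              n_features = as.integer(n_features),
              n_informative = as.integer(n_informative),
              n_sex_interactions = as.integer(n_sex_interactions),
              n_time_interactions = as.integer(n_time_interactions),
              effect_scale = effect_scale,
              sex_effect = sex_effect,
              noise_sd = noise_sd,
              diurnal_means = diurnal_means,
              subject_sd = subject_sd,
              missing_rate = missing_rate,
              outlier_rate = outlier_rate,
              max_healthy_ug = max_healthy_ug,
              seed = as.integer(seed))
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

validate_cohort_config <- function(cfg) {
  stopifnot(length(cfg$timepoints) >= 1)
  if (cfg$n_subjects < 2)
    stop("infeasible config: n_subjects must be >= 2, got ", cfg$n_subjects)
  if (cfg$n_informative > cfg$n_features)
    stop("infeasible config: n_informative (", cfg$n_informative,
         ") must not exceed n_features (", cfg$n_features, ")")
  if (cfg$male_fraction < 0 || cfg$male_fraction > 1)
    stop("infeasible config: male_fraction must lie in [0, 1], got ",
         cfg$male_fraction)
  if (cfg$missing_rate < 0 || cfg$missing_rate >= 1)
    stop("infeasible config: missing_rate must lie in [0, 1), got ",
         cfg$missing_rate)
  if (cfg$outlier_rate < 0 || cfg$outlier_rate >= 1)
    stop("infeasible config: outlier_rate must lie in [0, 1), got ",
         cfg$outlier_rate)
  if (cfg$n_sex_interactions > cfg$n_informative)
    stop("infeasible config: n_sex_interactions (", cfg$n_sex_interactions,
         ") must not exceed n_informative (", cfg$n_informative, ")")
  if (cfg$n_time_interactions > cfg$n_informative)
    stop("infeasible config: n_time_interactions (", cfg$n_time_interactions,
         ") must not exceed n_informative (", cfg$n_informative, ")")
  if (is.null(names(cfg$diurnal_means)) ||
      !setequal(names(cfg$diurnal_means), cfg$timepoints))
    stop("infeasible config: diurnal_means must be named by the timepoints")
  if (cfg$noise_sd < 0 || cfg$subject_sd < 0 || cfg$effect_scale < 0)
    stop("infeasible config: scales must be non-negative")
  invisible(cfg)
}

#' Construct a volatile feature table
#'
#' A feature table holds a samples-by-features matrix of raw (non-negative)
#' peak abundances with `NA` marking missing (undetected) entries, plus
#' per-feature chromatographic metadata.
#'
#' @param abundance Numeric matrix, samples x features; `NA` = missing.
#' @param feature_meta Data frame with one row per feature and columns
#'   `name`, `rt1_s`, `rt2_s`, `spectral_match`, `blank_flag`.
#' @return An object of class `feature_table`.
#' @export
feature_table <- function(abundance, feature_meta) {
  abundance <- as.matrix(abundance)
  if (nrow(feature_meta) != ncol(abundance))
    stop("feature_meta must have one row per abundance column")
  required <- c("name", "rt1_s", "rt2_s", "spectral_match", "blank_flag")
  missing_cols <- setdiff(required, names(feature_meta))
  if (length(missing_cols))
    stop("feature_meta lacks required column(s): ",
         paste(missing_cols, collapse = ", "))
  obs <- abundance[!is.na(abundance)]
  if (any(!is.finite(obs)))
    stop("observed abundances must be finite")
  if (any(obs < 0))
    stop("observed abundances must be non-negative")
  if (any(feature_meta$rt1_s <= 0))
    stop("rt1_s must be positive")
  colnames(abundance) <- feature_meta$name
  structure(list(abundance = abundance, feature_meta = feature_meta),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("feature_table: %d samples x %d features (%.1f%% missing)\n",
              nrow(x$abundance), ncol(x$abundance),
              100 * mean(is.na(x$abundance))))
  invisible(x)
}

subset_features <- function(table, keep) {
  feature_table(table$abundance[, keep, drop = FALSE],
                table$feature_meta[keep, , drop = FALSE])
}

subset_samples <- function(table, keep) {
  out <- table
  out$abundance <- table$abundance[keep, , drop = FALSE]
  out
}

#' Generate a synthetic VOC cohort with planted ground truth
#'
#' Simulates a cohort in which log10 total free urinary cortisol is an
#' exact sparse linear function of standardized log10 feature abundances
#' plus diurnal timepoint means, a between-subject random effect, planted
#' sex/time interaction effects, and Gaussian noise. Feature abundances are
#' log-normal; per feature, the lowest `missing_rate` fraction of entries is
#' censored (left-censoring at a detection limit). A fraction
#' `outlier_rate` of samples is re-assigned cortisol above the healthy
#' ceiling so the outlier filter has known true positives; all other
#' samples are kept below the ceiling by drawing the noise term from an
#' upper-truncated normal (emulating the screened healthy range). With
#' `noise_sd = 0` no truncation is applied and the planted relation is
#' exactly linear.
#'
#' @param config A [cohort_config()].
#' @return A list with elements `meta` (sample metadata data frame:
#'   `sample_id`, `subject_id`, `sex`, `timepoint`, `cortisol_ug`,
#'   `run_order`), `table` (a [feature_table()]) and `truth` (planted
#'   support, coefficients, interactions, noise scale and outlier ids).
#' @export
generate_cohort <- function(config = cohort_config()) {
  validate_cohort_config(config)
  set.seed(config$seed)

  n_sub <- config$n_subjects
  n_male <- round(config$male_fraction * n_sub)
  sexes <- c(rep("male", n_male), rep("female", n_sub - n_male))
  subject_id <- c(sprintf("M%02d", seq_len(n_male)),
                  sprintf("F%02d", seq_len(n_sub - n_male)))
  tps <- config$timepoints
  n_tp <- length(tps)
  n_samples <- n_sub * n_tp
  p <- config$n_features

  meta <- data.frame(
    subject_id = rep(subject_id, each = n_tp),
    sex = rep(sexes, each = n_tp),
    timepoint = rep(tps, times = n_sub),
    stringsAsFactors = FALSE)
  meta$sample_id <- paste(meta$subject_id, meta$timepoint, sep = "_")

  # log-normal abundances: per-feature location on a raw peak-area scale
  mu <- stats::runif(p, 4, 7)
  sigma <- stats::runif(p, 0.2, 0.6)
  logab <- matrix(stats::rnorm(n_samples * p), n_samples, p)
  logab <- sweep(sweep(logab, 2, sigma, `*`), 2, mu, `+`)

  feat_names <- sprintf("V%04d", seq_len(p))
  feature_meta <- data.frame(
    name = feat_names,
    rt1_s = stats::runif(p, 300, 2400),
    rt2_s = stats::runif(p, 0.4, 2.0),
    spectral_match = round(stats::runif(p, 300, 950)),
    blank_flag = stats::runif(p) < 0.01,
    stringsAsFactors = FALSE)

  support <- sort(sample.int(p, config$n_informative))
  # planted features must survive the blank/early-elution filter
  feature_meta$rt1_s[support] <- stats::runif(length(support), 400, 2400)
  feature_meta$blank_flag[support] <- FALSE

  z <- scale(logab)  # standardized log10 abundances define the planted design
  beta <- config$effect_scale * stats::runif(config$n_informative, 0.4, 1.6) *
    sample(c(-1, 1), config$n_informative, replace = TRUE)
  names(beta) <- feat_names[support]

  dummies <- cbind(Male = as.numeric(meta$sex == "male"),
                   Morning = as.numeric(meta$timepoint == "morning"),
                   Afternoon = as.numeric(meta$timepoint == "afternoon"))

  sex_feats <- sample(support, config$n_sex_interactions)
  time_feats <- sample(support, config$n_time_interactions)
  interactions <- data.frame(
    feature = feat_names[c(sex_feats, time_feats)],
    dummy = c(rep("Male", config$n_sex_interactions),
              sample(c("Morning", "Afternoon"), config$n_time_interactions,
                     replace = TRUE)),
    stringsAsFactors = FALSE)
  interactions$beta <- config$effect_scale *
    stats::runif(nrow(interactions), 0.4, 1.6) *
    sample(c(-1, 1), nrow(interactions), replace = TRUE)

  subj_eff <- stats::rnorm(n_sub, 0, config$subject_sd)
  names(subj_eff) <- subject_id

  det <- unname(config$diurnal_means[meta$timepoint]) +
    config$sex_effect * (as.numeric(meta$sex == "male") - 0.5) +
    subj_eff[meta$subject_id] +
    as.vector(z[, support, drop = FALSE] %*% beta)
  for (i in seq_len(nrow(interactions))) {
    j <- match(interactions$feature[i], feat_names)
    det <- det + interactions$beta[i] * z[, j] * dummies[, interactions$dummy[i]]
  }

  cap <- log10(config$max_healthy_ug)
  if (config$noise_sd > 0) {
    # upper-truncated normal keeps non-outlier samples in the healthy range
    pmax_u <- pmax(stats::pnorm(cap - det, 0, config$noise_sd), 1e-12)
    eps <- stats::qnorm(stats::runif(n_samples) * pmax_u) * config$noise_sd
  } else {
    eps <- rep(0, n_samples)
  }
  y <- det + eps
  cortisol <- 10^y

  n_out <- round(config$outlier_rate * n_samples)
  outlier_idx <- if (n_out > 0) sample.int(n_samples, n_out) else integer(0)
  cortisol[outlier_idx] <- stats::runif(n_out, config$max_healthy_ug * 1.1,
                                        config$max_healthy_ug * 2.2)

  meta$cortisol_ug <- unname(cortisol)
  meta$run_order <- sample.int(n_samples)

  # left-censor the lowest abundances per feature
  abundance <- 10^logab
  m <- floor(config$missing_rate * n_samples)
  if (m > 0) {
    for (j in seq_len(p)) {
      abundance[order(abundance[, j])[seq_len(m)], j] <- NA_real_
    }
  }
  rownames(abundance) <- meta$sample_id
  table <- feature_table(abundance, feature_meta)

  truth <- structure(list(
    support = support,
    support_names = feat_names[support],
    beta = beta,
    interactions = interactions,
    intercepts = config$diurnal_means,
    sex_effect = config$sex_effect,
    subject_effects = subj_eff,
    noise_sd = config$noise_sd,
    outlier_samples = meta$sample_id[outlier_idx],
    seed = config$seed), class = "ground_truth")

  meta <- meta[, c("sample_id", "subject_id", "sex", "timepoint",
                   "cortisol_ug", "run_order")]
  list(meta = meta, table = table, truth = truth)
}

fmt_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "" else sprintf("%.17g", v)
  }, character(1))
  out
}

#' Write a cohort to CSV files
#'
#' Writes `cohort_meta.csv`, `features.csv` (wide samples-by-features
#' matrix, empty cell = missing), `feature_meta.csv` and, when ground truth
#' is supplied, `truth.json`. Numeric values are written at full precision
#' so that the round trip through [read_cohort()] is lossless.
#'
#' @param meta Sample metadata data frame.
#' @param table A [feature_table()].
#' @param path Directory to write into (created if absent).
#' @param truth Optional ground-truth list to serialize alongside.
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(meta, table, path, truth = NULL) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  meta_out <- meta
  meta_out$cortisol_ug <- fmt_num(meta$cortisol_ug)
  utils::write.csv(meta_out, file.path(path, "cohort_meta.csv"),
                   row.names = FALSE)

  ab <- table$abundance
  feat_df <- as.data.frame(apply(ab, 2, fmt_num, simplify = FALSE),
                           check.names = FALSE, optional = TRUE)
  feat_df <- cbind(sample_id = rownames(ab), feat_df)
  utils::write.csv(feat_df, file.path(path, "features.csv"),
                   row.names = FALSE, quote = FALSE, na = "")

  fm <- table$feature_meta
  fm$rt1_s <- fmt_num(fm$rt1_s)
  fm$rt2_s <- fmt_num(fm$rt2_s)
  utils::write.csv(fm, file.path(path, "feature_meta.csv"), row.names = FALSE)

  if (!is.null(truth)) {
    jsonlite::write_json(unclass(truth), file.path(path, "truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(file.path(path, c("cohort_meta.csv", "features.csv",
                              "feature_meta.csv")))
}

#' Read a cohort written by [write_cohort()]
#'
#' @param path Directory containing `cohort_meta.csv`, `features.csv` and
#'   `feature_meta.csv`.
#' @return A list with `meta` and `table`, as produced by
#'   [generate_cohort()]. Empty abundance cells are restored as missing.
#' @export
read_cohort <- function(path) {
  meta <- utils::read.csv(file.path(path, "cohort_meta.csv"),
                          stringsAsFactors = FALSE, na.strings = "")
  required <- c("sample_id", "subject_id", "sex", "timepoint",
                "cortisol_ug", "run_order")
  miss <- setdiff(required, names(meta))
  if (length(miss))
    stop("cohort_meta.csv lacks required column(s): ",
         paste(miss, collapse = ", "))

  feats <- utils::read.csv(file.path(path, "features.csv"),
                           stringsAsFactors = FALSE, na.strings = "",
                           check.names = FALSE)
  if (!"sample_id" %in% names(feats))
    stop("features.csv lacks required column(s): sample_id")
  ab <- as.matrix(feats[, setdiff(names(feats), "sample_id"), drop = FALSE])
  storage.mode(ab) <- "double"
  rownames(ab) <- feats$sample_id
  neg <- which(!is.na(ab) & ab < 0, arr.ind = TRUE)
  if (nrow(neg))
    stop(sprintf("features.csv: negative abundance at row %d, column '%s'",
                 neg[1, 1], colnames(ab)[neg[1, 2]]))

  fm <- utils::read.csv(file.path(path, "feature_meta.csv"),
                        stringsAsFactors = FALSE, na.strings = "")
  fm$blank_flag <- as.logical(fm$blank_flag)
  list(meta = meta, table = feature_table(ab, fm))
}
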