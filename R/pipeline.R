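#' Configuration for an end-to-end pipeline run
#'
#' Collects every stage's options with the study constants as defaults:
#' 50% presence threshold, 358 s early-elution cutoff, 45 ug cortisol
#' ceiling, alpha 0.05 factor screen, elastic-net alpha 0.5 with an 80/20
#' subject split over 250 iterations, top 25/35/50 candidate subsets,
#' AICc-guided stepwise search with a log10 response, VIF cutoff 5 and FDR
#' 0.10 for the subgroup t-tests. Unknown option names are rejected.
#'
#' @param seed Integer seed for the run.
#' @param cohort A [cohort_config()] for the simulate stage.
#' @param ... Named overrides of the defaults listed above
#'   (`min_fraction`, `min_rt1_s`, `max_ug`, `exclude`, `impute`,
#'   `alpha_screen`, `selection` (a [selection_config()]), `criterion`,
#'   `direction`, `hierarchy`, `log_response`, `vif_cutoff`, `fdr`,
#'   `diag_alpha`).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, cohort = NULL, ...) {
  defaults <- list(
    min_fraction = 0.5, min_rt1_s = 358, max_ug = 45,
    exclude = character(0), impute = "half_min",
    alpha_screen = 0.05,
    selection = NULL,
    criterion = "aicc", direction = "both", hierarchy = TRUE,
    log_response = TRUE,
    vif_cutoff = 5, fdr = 0.10, diag_alpha = 0.01)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, dots)
  cfg$seed <- as.integer(seed)
  if (is.null(cohort)) cohort <- cohort_config(seed = cfg$seed)
  cfg$cohort <- cohort
  if (is.null(cfg$selection)) cfg$selection <- selection_config(seed = cfg$seed)
  structure(cfg, class = "pipeline_config")
}

write_json_artifact <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null", force = TRUE)
}

fit_to_list <- function(fit) {
  list(terms = fit$terms,
       beta = as.list(stats::setNames(fit$beta, fit$terms)),
       ci95_low = unname(fit$ci95_low), ci95_high = unname(fit$ci95_high),
       p_raw = unname(fit$p_raw), p_bh = unname(fit$p_bh),
       rss = fit$rss, n = fit$n, k = fit$k,
       adj_r2 = fit$adj_r2, aicc = fit$aicc, bic = fit$bic)
}

#' Run the full analysis pipeline
#'
#' Executes simulate -> preprocess -> screen -> select -> fit -> compare ->
#' diagnose -> predict, writing each stage's artifact into `out_dir`:
#' the cohort CSVs, `processed.csv` and `transform_params.json`,
#' `anova.json`, `selection_frequency.csv`, one `fit_result_top<k>.json`
#' per candidate subset, `model_comparison.csv`, `diagnostics.json`,
#' `subgroup_ttests.csv`, `predictions.csv` and a `manifest.json`
#' capturing the configuration and seed. Stage failures halt the run with
#' the stage name; previously written artifacts are retained alongside a
#' `FAILED` marker. Apart from the manifest timestamp, a rerun with the
#' same seed reproduces the artifacts byte for byte.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @param cohort Optional pre-generated cohort (list with `meta`, `table`)
#'   to use instead of simulating.
#' @return Invisibly, a list with the key in-memory objects of every
#'   stage.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir,
                         cohort = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- "simulate"
  result <- tryCatch({
    if (is.null(cohort)) cohort <- generate_cohort(config$cohort)
    write_cohort(cohort$meta, cohort$table, out_dir,
                 truth = cohort$truth)

    stage <- "preprocess"
    prep <- preprocess_cohort(cohort$meta, cohort$table,
                              min_fraction = config$min_fraction,
                              min_rt1_s = config$min_rt1_s,
                              max_ug = config$max_ug,
                              exclude = config$exclude,
                              impute = config$impute)
    z <- prep$z
    meta <- prep$meta
    proc <- data.frame(sample_id = meta$sample_id, z$z,
                       check.names = FALSE)
    utils::write.csv(proc, file.path(out_dir, "processed.csv"),
                     row.names = FALSE)
    write_json_artifact(
      list(pqn_factor = as.list(z$pqn_factor),
           feature_mean = as.list(z$feature_mean),
           feature_sd = as.list(z$feature_sd),
           retained = z$retained,
           dropped_samples = z$dropped_samples,
           impute = z$impute),
      file.path(out_dir, "transform_params.json"))

    stage <- "screen"
    anova_tab <- two_way_anova(meta,
                               response = if (config$log_response) "log10"
                                          else "raw")
    factors <- screen_factors(anova_tab, alpha = config$alpha_screen)
    write_json_artifact(list(anova = anova_tab, factors = factors,
                             alpha = config$alpha_screen),
                        file.path(out_dir, "anova.json"))

    stage <- "select"
    freq <- bootstrap_select(z, meta, config$selection,
                             log_response = config$log_response)
    utils::write.csv(freq$table,
                     file.path(out_dir, "selection_frequency.csv"),
                     row.names = FALSE)

    stage <- "fit"
    y <- if (config$log_response) log10(meta$cortisol_ug)
         else meta$cortisol_ug
    fits <- list()
    diags <- list()
    for (k in config$selection$top_k) {
      cand <- top_k(freq, k)
      design <- build_design(z, meta, cand,
                             factors = if (length(factors)) factors
                                       else c("sex", "time"))
      fit <- stepwise(design, y, direction = config$direction,
                      criterion = config$criterion,
                      hierarchy = config$hierarchy)
      name <- paste0("top", k)
      fits[[name]] <- fit
      sel <- attr(fit, "selected")
      sub_design <- structure(list(X = design$X[, sel, drop = FALSE],
                                   terms = design$terms[
                                     design$terms$label %in% sel, ,
                                     drop = FALSE]),
                              class = "voc_design")
      diags[[name]] <- compute_diagnostics(fit, sub_design, y,
                                           run_order = meta$run_order,
                                           alpha = config$diag_alpha,
                                           vif_cutoff = config$vif_cutoff)
      write_json_artifact(c(fit_to_list(fit), list(subset = name)),
                          file.path(out_dir,
                                    paste0("fit_result_", name, ".json")))
    }

    stage <- "compare"
    comparison <- compare_models(fits, diagnostics = diags)
    utils::write.csv(as.data.frame(comparison),
                     file.path(out_dir, "model_comparison.csv"),
                     row.names = FALSE)
    best_name <- comparison$model[1]
    best <- fits[[best_name]]
    best_diag <- diags[[best_name]]

    stage <- "diagnose"
    write_json_artifact(
      list(model = best_name,
           vif = as.list(best_diag$vif),
           tests = as.list(best_diag$tests),
           flags = best_diag$flags,
           adj_r2 = best_diag$adj_r2),
      file.path(out_dir, "diagnostics.json"))
    model_feats <- unique(stats::na.omit(
      design_terms_features(best)))
    ttests <- if (length(model_feats))
      subgroup_ttests(z, meta, model_feats, fdr = config$fdr)
      else NULL
    if (!is.null(ttests))
      utils::write.csv(ttests, file.path(out_dir, "subgroup_ttests.csv"),
                       row.names = FALSE)

    stage <- "predict"
    preds <- data.frame(sample_id = meta$sample_id,
                        observed = y,
                        predicted = best$fitted,
                        residual = best$residuals)
    utils::write.csv(preds, file.path(out_dir, "predictions.csv"),
                     row.names = FALSE)

    stage <- "manifest"
    write_json_artifact(
      list(seed = config$seed,
           package_version = as.character(utils::packageVersion("vocortisol")),
           r_version = R.version.string,
           timestamp = format(Sys.time(), tz = "UTC"),
           config = serialize_config(config)),
      file.path(out_dir, "manifest.json"))

    list(cohort = cohort, z = z, meta = meta, anova = anova_tab,
         factors = factors, frequency = freq, fits = fits,
         diagnostics = diags, comparison = comparison,
         subgroup_ttests = ttests, predictions = preds)
  }, error = function(e) {
    writeLines(paste0("stage: ", stage, "\n", conditionMessage(e)),
               file.path(out_dir, "FAILED"))
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(result)
}

design_terms_features <- function(fit) {
  labs <- fit$terms[-1]
  feats <- sub(":(Male|Morning|Afternoon)$", "", labs)
  feats[!feats %in% c("Male", "Morning", "Afternoon")]
}

serialize_config <- function(config) {
  out <- unclass(config)
  out$cohort <- unclass(out$cohort)
  out$selection <- unclass(out$selection)
  out
}
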