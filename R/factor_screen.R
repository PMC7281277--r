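#' Two-way ANOVA factor screen
#'
#' Tests whether subject sex and collection time of day are significant
#' sources of variation in (log10) cortisol, for use as interaction-term
#' factors downstream. Uses Type-II sums of squares, which are appropriate
#' for the mildly unbalanced designs left behind by outlier removal and
#' reduce to the textbook decomposition on balanced designs.
#'
#' @param meta Sample metadata data frame with `sex`, `timepoint` and
#'   `cortisol_ug`.
#' @param response `"log10"` (default, consistent with the final model's
#'   response transform) or `"raw"`.
#' @return A data frame with one row per source (`sex`, `time`,
#'   `sex:time`, `residuals`) and columns `ss`, `df`, `F`, `p`.
#' @export
two_way_anova <- function(meta, response = c("log10", "raw")) {
  response <- match.arg(response)
  y <- if (response == "log10") log10(meta$cortisol_ug) else meta$cortisol_ug
  d <- data.frame(y = y,
                  sex = factor(meta$sex),
                  timepoint = factor(meta$timepoint))
  cells <- table(d$sex, d$timepoint)
  if (any(cells == 0)) {
    empty <- which(cells == 0, arr.ind = TRUE)[1, ]
    stop(sprintf("empty design cell: sex '%s', timepoint '%s'",
                 rownames(cells)[empty[1]], colnames(cells)[empty[2]]))
  }
  n_tp <- nlevels(d$timepoint)
  if (stats::var(y) < 1e-24) {
    # constant response: every source explains nothing
    return(data.frame(
      factor = c("sex", "time", "sex:time", "residuals"),
      ss = 0,
      df = c(1L, n_tp - 1L, n_tp - 1L, nrow(d) - 2L * n_tp),
      F = c(0, 0, 0, NA),
      p = c(1, 1, 1, NA),
      stringsAsFactors = FALSE))
  }
  mod <- stats::lm(y ~ sex * timepoint, data = d)
  a2 <- car::Anova(mod, type = 2)
  rn <- rownames(a2)
  pick <- function(label) which(rn == label)
  out <- data.frame(
    factor = c("sex", "time", "sex:time", "residuals"),
    ss = c(a2[pick("sex"), "Sum Sq"], a2[pick("timepoint"), "Sum Sq"],
           a2[pick("sex:timepoint"), "Sum Sq"], a2[pick("Residuals"), "Sum Sq"]),
    df = c(a2[pick("sex"), "Df"], a2[pick("timepoint"), "Df"],
           a2[pick("sex:timepoint"), "Df"], a2[pick("Residuals"), "Df"]),
    F = c(a2[pick("sex"), "F value"], a2[pick("timepoint"), "F value"],
          a2[pick("sex:timepoint"), "F value"], NA),
    p = c(a2[pick("sex"), "Pr(>F)"], a2[pick("timepoint"), "Pr(>F)"],
          a2[pick("sex:timepoint"), "Pr(>F)"], NA),
    stringsAsFactors = FALSE)
  # constant response: all SS are 0 and F is 0/0; report F = 0, p = 1
  degenerate <- !is.na(out$ss) & out$ss < 1e-24
  resid_zero <- out$ss[out$factor == "residuals"] < 1e-24
  fix <- degenerate & out$factor != "residuals" &
    (resid_zero | !is.finite(out$F))
  out$F[fix] <- 0
  out$p[fix] <- 1
  out
}

#' Select interaction factors from ANOVA results
#'
#' Returns the experimental factors whose main-effect p-value falls below
#' `alpha`; downstream model building constructs interaction terms only for
#' the returned factors.
#'
#' @param results Data frame from [two_way_anova()].
#' @param alpha Significance threshold (default 0.05).
#' @return Character vector, a subset of `c("sex", "time")`.
#' @export
screen_factors <- function(results, alpha = 0.05) {
  if (!nrow(results)) stop("results must be nonempty")
  main <- results[results$factor %in% c("sex", "time"), , drop = FALSE]
  main$factor[!is.na(main$p) & main$p < alpha]
}
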