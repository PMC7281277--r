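#' n-Alkane ladder for retention indexing
#'
#' A calibration of first-dimension retention time against n-alkane carbon
#' number (typically C8-C20), anchoring the retention index scale at
#' `RI(Cn) = 100 n`.
#'
#' @param carbon Integer carbon numbers (>= 2 rungs).
#' @param rt1_s First-dimension retention times in seconds, strictly
#'   increasing with carbon number.
#' @return An object of class `alkane_ladder`.
#' @export
alkane_ladder <- function(carbon, rt1_s) {
  if (length(carbon) != length(rt1_s))
    stop("carbon and rt1_s must have equal length")
  if (length(carbon) < 2)
    stop("an alkane ladder needs at least 2 rungs")
  ord <- order(carbon)
  carbon <- carbon[ord]; rt1_s <- rt1_s[ord]
  if (any(diff(carbon) <= 0) || any(diff(rt1_s) <= 0))
    stop("retention must be strictly increasing in carbon number")
  structure(data.frame(carbon = carbon, rt1_s = rt1_s),
            class = c("alkane_ladder", "data.frame"))
}

#' Linear retention index from an alkane ladder
#'
#' Van den Dool-Kratz style linear interpolation on the temperature
#' programmed first dimension: `RI = 100 (n + (t - t_n)/(t_{n+1} - t_n))`
#' for the bracketing alkanes. Retention times outside the ladder span are
#' linearly extrapolated from the nearest rung pair and flagged.
#'
#' @param ladder An [alkane_ladder()].
#' @param rt1 First-dimension retention time(s) in seconds.
#' @return Data frame with `rt1_s`, `ri`, `extrapolated`.
#' @export
retention_index <- function(ladder, rt1) {
  stopifnot(inherits(ladder, "alkane_ladder"))
  t <- ladder$rt1_s
  cn <- ladder$carbon
  m <- length(t)
  ri <- vapply(rt1, function(x) {
    i <- findInterval(x, t, rightmost.closed = FALSE)
    i <- min(max(i, 1), m - 1)  # nearest rung pair outside the span
    100 * (cn[i] + (cn[i + 1] - cn[i]) * (x - t[i]) / (t[i + 1] - t[i]))
  }, numeric(1))
  data.frame(rt1_s = rt1, ri = ri,
             extrapolated = rt1 < t[1] | rt1 > t[m])
}

#' Polarity-scaled retention index position
#'
#' Places an experimental retention index between reference non-polar and
#' polar column indices:
#' `100 (RI_exp - RI_nonpolar) / (RI_polar - RI_nonpolar)`. A value inside
#' the consistency window (default 5-35%, reflecting a mid-polar
#' stationary phase) counts as confirmatory RI evidence.
#'
#' @param ri_exp Experimental retention index.
#' @param ri_nonpolar Reference non-polar column index.
#' @param ri_polar Reference polar column index (must exceed
#'   `ri_nonpolar`).
#' @param window Consistency window in percent.
#' @return Data frame with `percent` and `consistent`.
#' @export
polarity_percent <- function(ri_exp, ri_nonpolar, ri_polar,
                             window = c(5, 35)) {
  if (any(ri_polar <= ri_nonpolar))
    stop("degenerate polarity span: ri_polar must exceed ri_nonpolar")
  pct <- 100 * (ri_exp - ri_nonpolar) / (ri_polar - ri_nonpolar)
  data.frame(percent = pct,
             consistent = pct >= window[1] & pct <= window[2])
}

#' Assign MSI identification-confidence levels
#'
#' Applies the Metabolomics Standards Initiative tiering to annotated
#' compounds, on a 0-1000 spectral-match scale (800 = 80%):
#' \itemize{
#'   \item level 4: spectral match below `match_threshold`; the library
#'     name is replaced by a functional-group label when one is supplied,
#'     otherwise by "unknown";
#'   \item level 3: match at/above the threshold but without confirmatory
#'     polarity-window RI evidence; agreement of the experimental RI with
#'     the reference non-polar RI within `nonpolar_tol` supports retaining
#'     the library name at this level but does not promote the compound;
#'   \item level 2: match at/above the threshold with polarity-window
#'     consistent RI evidence ([polarity_percent()]);
#'   \item level 1: level-2 evidence plus verification against an
#'     analytical-grade standard.
#' }
#' Adding evidence never increases the level number.
#'
#' @param annotations Data frame with columns `name`, `spectral_match`,
#'   and optionally `ri_experimental`, `ri_nonpolar_ref`, `ri_polar_ref`,
#'   `standard_verified`, `functional_group`.
#' @param match_threshold Spectral-match cutoff (default 800).
#' @param window Polarity consistency window in percent.
#' @param nonpolar_tol Relative tolerance of the non-polar RI naming-support
#'   route (default 0.06).
#' @return The annotations with `id_level`, `display_name`,
#'   `ri_consistent` and `nonpolar_supported` columns added.
#' @export
assign_id_level <- function(annotations, match_threshold = 800,
                            window = c(5, 35), nonpolar_tol = 0.06) {
  a <- annotations
  if (!all(c("name", "spectral_match") %in% names(a)))
    stop("annotations need at least 'name' and 'spectral_match'")
  n <- nrow(a)
  get <- function(col, default) if (col %in% names(a)) a[[col]]
                                else rep(default, n)
  ri_exp <- get("ri_experimental", NA_real_)
  ri_np <- get("ri_nonpolar_ref", NA_real_)
  ri_p <- get("ri_polar_ref", NA_real_)
  verified <- get("standard_verified", FALSE)
  fg <- get("functional_group", NA_character_)

  ri_consistent <- rep(FALSE, n)
  has_refs <- !is.na(ri_exp) & !is.na(ri_np) & !is.na(ri_p) & ri_p > ri_np
  if (any(has_refs))
    ri_consistent[has_refs] <- polarity_percent(ri_exp[has_refs],
                                                ri_np[has_refs],
                                                ri_p[has_refs],
                                                window)$consistent
  nonpolar_supported <- !is.na(ri_exp) & !is.na(ri_np) &
    abs(ri_exp - ri_np) / ri_np <= nonpolar_tol

  level <- integer(n)
  display <- a$name
  for (i in seq_len(n)) {
    if (a$spectral_match[i] < match_threshold) {
      level[i] <- 4L
      display[i] <- if (!is.na(fg[i])) fg[i] else "unknown"
    } else if (!ri_consistent[i]) {
      level[i] <- 3L
    } else {
      level[i] <- if (isTRUE(verified[i])) 1L else 2L
    }
  }
  a$id_level <- level
  a$display_name <- display
  a$ri_consistent <- ri_consistent
  a$nonpolar_supported <- nonpolar_supported
  a
}
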