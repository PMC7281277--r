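# Shared fixtures: tiny feature tables and cohorts built in code.

make_feature_meta <- function(p, rt1 = NULL, blank = NULL) {
  data.frame(name = sprintf("F%02d", seq_len(p)),
             rt1_s = if (is.null(rt1)) seq(400, 2000, length.out = p) else rt1,
             rt2_s = seq(0.5, 1.5, length.out = p),
             spectral_match = rep(700, p),
             blank_flag = if (is.null(blank)) rep(FALSE, p) else blank,
             stringsAsFactors = FALSE)
}

make_table <- function(abundance, rt1 = NULL, blank = NULL) {
  abundance <- as.matrix(abundance)
  if (is.null(rownames(abundance)))
    rownames(abundance) <- sprintf("S%02d", seq_len(nrow(abundance)))
  feature_table(abundance, make_feature_meta(ncol(abundance), rt1, blank))
}

small_cohort <- function(seed = 1, ...) {
  generate_cohort(cohort_config(n_subjects = 12, n_features = 40,
                                n_informative = 4, n_sex_interactions = 1,
                                n_time_interactions = 1, seed = seed, ...))
}

# standardized design + response with a known sparse linear signal
make_regression <- function(n, p, support, beta, noise_sd, seed) {
  set.seed(seed)
  X <- scale(matrix(rnorm(n * p), n, p))
  colnames(X) <- sprintf("F%02d", seq_len(p))
  y <- as.vector(X[, support, drop = FALSE] %*% beta) +
    rnorm(n, 0, noise_sd)
  list(X = X, y = y)
}
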