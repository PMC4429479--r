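# shared scenario builders for simulation-based tests

mk_test_haps <- function(n = 10, planted_high = 0, planted_medium = 0,
                         block = NULL) {
  lapply(seq_len(n), function(i)
    hap_spec(sprintf("hap%02d", i), median = 1, dispersion = 1,
             block_id = if (!is.null(block) && i %in% block$members)
               "b1" else NULL,
             target_rho = if (!is.null(block) && i %in% block$members)
               block$rho else 0,
             log_or_high = if (i == 1) planted_high else 0,
             log_or_medium = if (i == 1) planted_medium else 0))
}

mk_test_covs <- function() {
  list(covariate_spec("year", as.character(1999:2004)),
       covariate_spec("education", c("lt_hs", "hs", "gt_hs"),
                      c(0.32, 0.33, 0.35)),
       covariate_spec("smoking", c("no", "yes"), c(0.94, 0.06)),
       covariate_spec("poverty", c("q1", "q2", "q3", "q4")))
}

# case:control ratio ~1:7 as in the emulated registry design
mk_test_spec <- function(n_total, n_haps = 10, planted_high = 0,
                         planted_medium = 0, tract_sd = 0.3, ...) {
  n_cases <- round(n_total / 8)
  cohort_spec(n_cases = n_cases, n_controls = n_total - n_cases,
              n_tracts = max(2L, round(n_total * 2381 / 4228)),
              tract_sd = tract_sd, baseline_logit = qlogis(0.03),
              hap_specs = mk_test_haps(n_haps, planted_high, planted_medium),
              covariate_specs = mk_test_covs(), ...)
}

# construct two vectors with exact Pearson correlation r (Gram-Schmidt)
vectors_with_correlation <- function(r, n = 8) {
  x <- seq_len(n)
  xc <- x - mean(x)
  e <- rep(c(1, -1), length.out = n) * rev(abs(xc)) # mean 0 by symmetry
  e <- e - mean(e)
  e <- e - sum(e * xc) / sum(xc * xc) * xc          # orthogonalize
  y <- r * xc / sqrt(sum(xc^2)) + sqrt(1 - r^2) * e / sqrt(sum(e^2))
  list(x = x, y = y)
}
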