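#' Specify one pollutant's marginal distribution and true effect
#'
#' A HAP (hazardous air pollutant) is generated with a log-normal marginal
#' concentration distribution, optionally correlated with other members of
#' the same block through a shared latent Gaussian factor (a Gaussian
#' copula, which preserves Spearman correlation under the monotone
#' marginal transform).
#'
#' @param name pollutant identifier (unique within a cohort spec).
#' @param median marginal median concentration in ug/m3 (> 0).
#' @param dispersion log-scale standard deviation of the marginal (> 0).
#' @param block_id optional identifier; HAPs sharing a `block_id` are
#'   generated with correlated latent factors. `NULL` means independent.
#' @param target_rho target pairwise Spearman correlation with block
#'   mates, in `[0, 1]`. Ignored when `block_id` is `NULL`.
#' @param log_or_medium,log_or_high true conditional log odds ratios for
#'   the medium and high exposure categories (vs low) in the outcome
#'   generating model.
#' @return an object of class `hap_spec`.
#' @export
hap_spec <- function(name, median, dispersion, block_id = NULL,
                     target_rho = 0, log_or_medium = 0, log_or_high = 0) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stopf("'name' must be a non-empty string")
  check_scalar(median, "median", lo = .Machine$double.xmin)
  if (dispersion <= 0) stopf("hap_spec '%s': dispersion must be > 0", name)
  check_scalar(dispersion, "dispersion")
  check_scalar(target_rho, "target_rho", 0, 1)
  check_scalar(log_or_medium, "log_or_medium")
  check_scalar(log_or_high, "log_or_high")
  structure(list(name = name, median = median, dispersion = dispersion,
                 block_id = block_id, target_rho = target_rho,
                 log_or_medium = log_or_medium, log_or_high = log_or_high),
            class = "hap_spec")
}

#' Specify a categorical covariate for cohort generation
#'
#' @param name covariate name.
#' @param levels character vector of level labels; the first is the
#'   reference level in the outcome generating model.
#' @param probs marginal level probabilities (normalized internally).
#' @param log_or per-level log odds effects on the outcome; the first
#'   entry (reference) must be 0.
#' @return an object of class `covariate_spec`.
#' @export
covariate_spec <- function(name, levels, probs = NULL, log_or = NULL) {
  if (!is.character(name) || length(name) != 1L) stopf("'name' must be a string")
  levels <- as.character(levels)
  if (length(levels) < 2L || anyDuplicated(levels))
    stopf("covariate '%s': need >= 2 distinct levels", name)
  probs <- probs %||% rep(1 / length(levels), length(levels))
  if (length(probs) != length(levels) || any(probs < 0) || sum(probs) <= 0)
    stopf("covariate '%s': invalid level probabilities", name)
  log_or <- log_or %||% rep(0, length(levels))
  if (length(log_or) != length(levels) || any(!is.finite(log_or)))
    stopf("covariate '%s': invalid log_or vector", name)
  if (abs(log_or[1L]) > 1e-12)
    stopf("covariate '%s': reference level (first) must have log_or 0", name)
  structure(list(name = name, levels = levels, probs = probs / sum(probs),
                 log_or = log_or), class = "covariate_spec")
}

#' Specify a synthetic case-control cohort
#'
#' Describes the world the generator simulates: a source population of
#' births spread over census tracts, per-subject pollutant concentrations
#' with block correlation, categorical covariates, and a logistic outcome
#' model with a tract-level random intercept. Case-control data are then
#' drawn retrospectively (all-or-n cases; controls frequency matched on
#' the `match_var` covariate, by default year of birth).
#'
#' @param n_cases,n_controls target sample sizes (>= 1).
#' @param n_tracts number of census tracts in the source population.
#' @param tract_sd standard deviation of the tract random intercepts on
#'   the logit scale (>= 0).
#' @param baseline_logit intercept of the outcome model (logit scale);
#'   controls the population case rate.
#' @param hap_specs list of [hap_spec()] objects with unique names.
#' @param covariate_specs list of [covariate_spec()] objects.
#' @param match_var name of the frequency-matching covariate, or `NULL`
#'   for unmatched control sampling.
#' @param seed default RNG seed used by [simulate_cohort()].
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_cases, n_controls, n_tracts, tract_sd = 0.3,
                        baseline_logit = qlogis(0.03),
                        hap_specs = list(), covariate_specs = list(),
                        match_var = "year", seed = 1L) {
  check_scalar(n_cases, "n_cases", 1, integerish = TRUE)
  check_scalar(n_controls, "n_controls", 1, integerish = TRUE)
  check_scalar(n_tracts, "n_tracts", 1, integerish = TRUE)
  check_scalar(tract_sd, "tract_sd", 0)
  check_scalar(baseline_logit, "baseline_logit")
  if (!all(vapply(hap_specs, inherits, TRUE, "hap_spec")))
    stopf("'hap_specs' must be a list of hap_spec objects")
  nm <- vapply(hap_specs, `[[`, "", "name")
  if (anyDuplicated(nm)) stopf("duplicate HAP names: %s",
                               paste(unique(nm[duplicated(nm)]), collapse = ", "))
  if (!all(vapply(covariate_specs, inherits, TRUE, "covariate_spec")))
    stopf("'covariate_specs' must be a list of covariate_spec objects")
  cn <- vapply(covariate_specs, `[[`, "", "name")
  if (anyDuplicated(cn)) stopf("duplicate covariate names")
  if (!is.null(match_var) && length(cn) && !match_var %in% cn)
    stopf("match_var '%s' is not a covariate", match_var)
  structure(list(n_cases = as.integer(n_cases),
                 n_controls = as.integer(n_controls),
                 n_tracts = as.integer(n_tracts), tract_sd = tract_sd,
                 baseline_logit = baseline_logit, hap_specs = hap_specs,
                 covariate_specs = covariate_specs, match_var = match_var,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Pollutant specs emulating the packaged ambient-concentration table
#'
#' Builds log-normal [hap_spec()]s from the packaged distributional table
#' of the 32 EPA-priority HAPs estimated for Texas census tracts (median
#' and 5th/95th percentiles), with the four highly correlated blocks of
#' the packaged correlation table attached as copula blocks.
#'
#' @param names optional subset of pollutant names.
#' @return list of `hap_spec` objects.
#' @export
table1_hap_specs <- function(names = NULL) {
  tab <- hap_fixture("table1_distributions")
  blocks <- list(
    b1 = c("acetaldehyde", "acrolein", "formaldehyde", "benzene",
           "methylene chloride"),
    b2 = c("ethylene dibromide", "propylene dichloride",
           "1,1,2,2-tetrachloroethane"),
    b3 = c("ethylene dichloride", "vinyl chloride"),
    b4 = c("diesel particulate matter", "nickel compounds"))
  block_rho <- c(b1 = 0.85, b2 = 0.99, b3 = 0.98, b4 = 0.87)
  if (!is.null(names)) tab <- tab[tab$pollutant %in% names, , drop = FALSE]
  lapply(seq_len(nrow(tab)), function(i) {
    r <- tab[i, ]
    # two-sided log-scale spread; percentiles equal (flat marginals like
    # carbon tetrachloride) get a small floor so dispersion stays positive
    disp <- max((log(r$p95) - log(r$p5)) / (2 * qnorm(0.95)), 0.02)
    bid <- names(blocks)[vapply(blocks, function(b) r$pollutant %in% b, TRUE)]
    hap_spec(r$pollutant, median = r$median, dispersion = disp,
             block_id = if (length(bid)) bid else NULL,
             target_rho = if (length(bid)) unname(block_rho[bid]) else 0)
  })
}

#' Default covariate specs emulating the packaged case-control table
#'
#' Marginal level frequencies follow the packaged control column of the
#' characteristics table (sex, race/ethnicity, education, parity,
#' smoking, census-tract poverty quartile, season of conception) plus a
#' uniform year-of-birth matching variable. All outcome effects default
#' to zero.
#'
#' @return list of `covariate_spec` objects.
#' @export
table3_covariate_specs <- function() {
  list(
    covariate_spec("year", as.character(1999:2004)),
    covariate_spec("sex", c("female", "male"), c(0.495, 0.505)),
    covariate_spec("race_ethnicity",
                   c("nh_white", "nh_black", "hispanic", "other"),
                   c(0.365, 0.117, 0.481, 0.037)),
    covariate_spec("education", c("lt_high_school", "high_school",
                                  "gt_high_school"),
                   c(0.317, 0.328, 0.355)),
    covariate_spec("parity", c("0", "1", "2", "3plus"),
                   c(0.369, 0.329, 0.191, 0.111)),
    covariate_spec("smoking", c("no", "yes"), c(0.939, 0.061)),
    covariate_spec("poverty", c("low", "medium_low", "medium_high", "high"),
                   rep(0.25, 4)),
    covariate_spec("season", c("spring", "summer", "fall", "winter"),
                   c(0.240, 0.237, 0.260, 0.263)))
}

#' The default synthetic world
#'
#' A cohort spec emulating the structure of the motivating registry
#' study: 533 cases, 3,695 controls (about 1:7), 2,381 census tracts,
#' all 32 packaged pollutants with their four correlated blocks, and
#' the packaged covariate marginals. All pollutant and covariate
#' effects are null unless overridden.
#'
#' @inheritParams cohort_spec
#' @param ... further arguments passed to [cohort_spec()].
#' @return a `cohort_spec`.
#' @export
default_cohort_spec <- function(n_cases = 533L, n_controls = 3695L,
                                n_tracts = 2381L, tract_sd = 0.3,
                                baseline_logit = qlogis(0.03),
                                hap_specs = table1_hap_specs(),
                                covariate_specs = table3_covariate_specs(),
                                ...) {
  cohort_spec(n_cases = n_cases, n_controls = n_controls,
              n_tracts = n_tracts, tract_sd = tract_sd,
              baseline_logit = baseline_logit, hap_specs = hap_specs,
              covariate_specs = covariate_specs, ...)
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf("cohort_spec: %d cases / %d controls, %d tracts (tract_sd %.3g)\n",
              x$n_cases, x$n_controls, x$n_tracts, x$tract_sd))
  cat(sprintf("  baseline logit %.3g; %d HAPs; %d covariates; match on %s\n",
              x$baseline_logit, length(x$hap_specs),
              length(x$covariate_specs), x$match_var %||% "<none>"))
  invisible(x)
}
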