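#' Stochastic search variable selection over all pollutant terms
#'
#' Fits the joint hierarchical logistic model in which every pollutant
#' design column carries an independent spike-and-slab mixture prior
#' with latent inclusion indicator gamma, while the adjustment
#' covariates keep their plain diffuse priors and the tract random
#' intercept is retained. Each gamma is updated from its exact full
#' conditional, `Bernoulli` with odds equal to the prior inclusion odds
#' times the ratio of the slab and spike normal densities at the current
#' coefficient value. Medium and high dummies of one HAP have
#' independent indicators; they are reconciled at selection time by
#' [select_final()].
#'
#' The pollutant set should already be reduced by correlation binning;
#' a warning is emitted when any pair of included concentration columns
#' still has absolute Spearman correlation above 0.80.
#'
#' @param cohort a `hap_cohort`.
#' @param haps pollutant names to search over.
#' @param covariates adjustment covariate names (always included, never
#'   subject to selection).
#' @param priors a [prior_spec()].
#' @param settings an [mcmc_settings()].
#' @param categorization optional [categorize_cohort()] result.
#' @param exposure_mode `"categorical"` or `"continuous"`.
#' @param quiet suppress the startup note stating the spike prior's
#'   implied null OR interval.
#' @return an `ssvs_fit` (an `hb_fit` whose chains carry `gamma` draws
#'   and Rao-Blackwellized inclusion probabilities).
#' @export
sample_ssvs <- function(cohort, haps,
                        covariates = attr(cohort, "covariate_names"),
                        priors = prior_spec(), settings = mcmc_settings(),
                        categorization = NULL,
                        exposure_mode = "categorical", quiet = FALSE) {
  if (!length(haps)) stopf("SSVS needs at least one pollutant term")
  rho <- spearman_matrix(as.matrix(cohort[, haps, drop = FALSE]))
  hi <- abs(rho) > 0.80 & upper.tri(rho)
  if (any(hi, na.rm = TRUE))
    warning(sprintf("%d pollutant pair(s) exceed |rho| = 0.80; bin before SSVS for stable selection",
                    sum(hi, na.rm = TRUE)), call. = FALSE)
  if (!quiet) {
    ni <- spike_null_interval(priors$spike_variance)
    message(sprintf("SSVS spike variance %.4g: 'not selected' means OR in (%.3f, %.3f) with 99%% prior probability",
                    priors$spike_variance, ni[1L], ni[2L]))
  }
  design <- build_design(cohort, haps = haps, covariates = covariates,
                         exposure_mode = exposure_mode,
                         categorization = categorization)
  fit <- run_chains(design, priors, settings, mixture = TRUE)
  class(fit) <- c("ssvs_fit", class(fit))
  fit
}

#' Posterior inclusion probabilities per pollutant term
#'
#' Two estimators over the pooled retained draws: the raw frequency of
#' `gamma = 1`, and the Rao-Blackwellized average of the gamma full
#' conditional probability (smoother; never exactly 0 or 1 in finite
#' samples, which keeps the Bayes factor finite).
#'
#' @param fit an `ssvs_fit`.
#' @param burn_in burn-in fraction; defaults to the fit's settings.
#' @return data.frame: `term`, `hap`, `level`, `p_raw`, `p_rb`,
#'   `n_draws`.
#' @export
inclusion_probabilities <- function(fit, burn_in = fit$settings$burn_in) {
  if (!inherits(fit, "ssvs_fit")) stopf("'fit' must come from sample_ssvs()")
  rows <- retained_rows(fit$settings, burn_in)
  gam <- do.call(rbind, lapply(fit$chains, function(ch)
    ch$gamma[rows, , drop = FALSE]))
  rb <- do.call(rbind, lapply(fit$chains, function(ch)
    ch$rb_prob[rows, , drop = FALSE]))
  term <- colnames(gam)
  hap_of <- rep(names(fit$design$hap_cols),
                lengths(fit$design$hap_cols))[match(term, unlist(fit$design$hap_cols))]
  level <- ifelse(grepl(":high$", term), "high",
                  ifelse(grepl(":medium$", term), "medium", "continuous"))
  data.frame(term = term, hap = hap_of, level = level,
             p_raw = colMeans(gam), p_rb = colMeans(rb),
             n_draws = nrow(gam), row.names = NULL)
}

#' Marginal Bayes factor for inclusion
#'
#' `BF = [p/(1-p)] / [pi/(1-pi)]`: the ratio of posterior to prior
#' inclusion odds, so that BF > 1 is evidence for inclusion. An
#' estimated `p` of exactly 1 (possible with the raw gamma frequency) is
#' shrunk to `1 - 1/(2*n_draws)` when `n_draws` is supplied, otherwise
#' it yields `Inf` with a warning; prefer the Rao-Blackwellized
#' estimator, which avoids the degeneracy.
#'
#' @param inclusion_probability posterior inclusion probability in
#'   `[0, 1]` (vectorized).
#' @param prior_probability prior inclusion probability in (0, 1).
#' @param n_draws optional number of retained draws behind the estimate.
#' @return numeric Bayes factor(s), >= 0.
#' @export
bayes_factor <- function(inclusion_probability, prior_probability,
                         n_draws = NULL) {
  p <- inclusion_probability
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stopf("'inclusion_probability' must be in [0, 1]")
  check_scalar(prior_probability, "prior_probability")
  if (prior_probability <= 0 || prior_probability >= 1)
    stopf("'prior_probability' must be in (0, 1)")
  if (any(p == 1)) {
    if (!is.null(n_draws)) {
      p[p == 1] <- 1 - 1 / (2 * n_draws)
    } else {
      warning("inclusion probability of exactly 1: Bayes factor is Inf; supply n_draws for the finite-sample correction",
              call. = FALSE)
    }
  }
  prior_odds <- prior_probability / (1 - prior_probability)
  (p / (1 - p)) / prior_odds
}

#' Inverse of [bayes_factor()]
#'
#' @param bf Bayes factor(s).
#' @param prior_probability prior inclusion probability in (0, 1).
#' @return the posterior inclusion probability mapping to `bf`.
#' @export
bf_to_inclusion <- function(bf, prior_probability) {
  po <- bf * prior_probability / (1 - prior_probability)
  po / (1 + po)
}

#' Compute per-term Bayes factors from an SSVS fit
#'
#' @param fit an `ssvs_fit`.
#' @param estimator `"rb"` (Rao-Blackwellized, default) or `"raw"`.
#' @param burn_in burn-in fraction.
#' @return data.frame of class `bf_result`: `term`, `hap`, `level`,
#'   inclusion probabilities, `bf`, `prior_prob`, `selected`
#'   (term-level, `bf > 1`).
#' @export
ssvs_bayes_factors <- function(fit, estimator = c("rb", "raw"),
                               burn_in = fit$settings$burn_in) {
  estimator <- match.arg(estimator)
  ip <- inclusion_probabilities(fit, burn_in)
  p <- if (estimator == "rb") ip$p_rb else ip$p_raw
  pi0 <- fit$priors$inclusion_prob
  ip$bf <- bayes_factor(p, pi0, n_draws = ip$n_draws[1L])
  ip$prior_prob <- pi0
  ip$selected <- ip$bf > 1
  class(ip) <- c("bf_result", "data.frame")
  ip
}

#' Final selection with the either-level linkage rule
#'
#' A pollutant is selected when any of its terms has a Bayes factor
#' strictly greater than the threshold; for categorized pollutants both
#' the medium and high terms of a selected pollutant then enter the
#' final joint model together.
#'
#' @param bf_results a `bf_result` data.frame (or any data.frame with
#'   `hap` and `bf` columns).
#' @param threshold selection threshold (default 1; strict inequality).
#' @return character vector of selected pollutant names (possibly
#'   empty), with the per-HAP maximum BF as attribute `max_bf`.
#' @export
select_final <- function(bf_results, threshold = 1.0) {
  if (!all(c("hap", "bf") %in% names(bf_results)))
    stopf("'bf_results' needs 'hap' and 'bf' columns")
  mx <- tapply(bf_results$bf, bf_results$hap, max)
  sel <- names(mx)[mx > threshold]
  sel <- sel[order(match(sel, bf_results$hap))]
  attr(sel, "max_bf") <- mx
  sel
}

#' Final joint model over the selected pollutants
#'
#' Refits the hierarchical logistic model with every selected pollutant
#' (both exposure levels) and the adjustment covariates, with plain
#' `N(0, slab variance)` priors on the pollutant terms (no mixture).
#' Passing `selected_haps = <all candidates>` reproduces the
#' no-selection joint comparison model.
#'
#' @param cohort a `hap_cohort`.
#' @param selected_haps pollutant names from [select_final()]; if empty,
#'   no model is fit and a "no HAP selected" result is returned.
#' @param covariates adjustment covariate names.
#' @param priors a [prior_spec()].
#' @param settings an [mcmc_settings()].
#' @param categorization optional [categorize_cohort()] result.
#' @param exposure_mode `"categorical"` or `"continuous"`.
#' @return list of class `final_joint_fit`: `selected`, `summary` (rows
#'   for pollutant terms; `NULL` when nothing selected), `full_summary`,
#'   `convergence`, `fit`.
#' @export
fit_final_joint <- function(cohort, selected_haps,
                            covariates = attr(cohort, "covariate_names"),
                            priors = prior_spec(),
                            settings = mcmc_settings(),
                            categorization = NULL,
                            exposure_mode = "categorical") {
  if (!length(selected_haps)) {
    out <- list(selected = character(0), summary = NULL,
                full_summary = NULL, convergence = NULL, fit = NULL,
                message = "no HAP selected; final model not fit")
    class(out) <- "final_joint_fit"
    return(out)
  }
  design <- build_design(cohort, haps = selected_haps,
                         covariates = covariates,
                         exposure_mode = exposure_mode,
                         categorization = categorization)
  fit <- sample_posterior(design, priors, settings)
  smry <- summarize_posterior(fit)
  hap_terms <- unlist(design$hap_cols)
  structure(list(selected = selected_haps,
                 summary = smry[smry$term %in% hap_terms, ],
                 full_summary = smry,
                 convergence = if (settings$n_chains >= 2L)
                   check_convergence(fit) else NULL,
                 fit = fit),
            class = "final_joint_fit")
}

#' @export
print.final_joint_fit <- function(x, ...) {
  if (!length(x$selected)) {
    cat(x$message, "\n")
    return(invisible(x))
  }
  cat(sprintf("final joint model over: %s\n",
              paste(x$selected, collapse = ", ")))
  print(format_summary(x$summary))
  if (!is.null(x$convergence)) print(x$convergence)
  invisible(x)
}

#' Write the machine-readable selection report
#'
#' @param bf_results a `bf_result` data.frame.
#' @param selected output of [select_final()].
#' @param path file path for the JSON report.
#' @export
write_selection_json <- function(bf_results, selected, path) {
  jsonlite::write_json(
    list(prior_inclusion_prob = bf_results$prior_prob[1L],
         terms = bf_results[, c("term", "hap", "level", "p_raw", "p_rb",
                                "bf", "selected")],
         selected_haps = as.character(selected)),
    path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}
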