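#' Build the model design from a cohort
#'
#' Dummy-codes covariates (reference = first level in sort order) and
#' pollutant terms. In categorical mode each HAP contributes
#' `<hap>:medium` and `<hap>:high` indicator columns against the low
#' reference; in continuous mode each HAP contributes one centered and
#' scaled concentration column. A fixed global intercept column is
#' always included; tract identifiers are mapped to a 0-based index for
#' the random intercept.
#'
#' @param cohort a `hap_cohort`.
#' @param haps character vector of pollutant names to include (may be
#'   empty for a covariates-only model).
#' @param covariates character vector of adjustment covariate names.
#' @param exposure_mode `"categorical"` (low/medium/high dummies) or
#'   `"continuous"` (standardized concentration).
#' @param categorization optional list from [categorize_cohort()];
#'   computed from the cohort when omitted (control-based cutoffs).
#' @param use_tract include the tract random intercept (default TRUE).
#' @return list: `y`, `X` (named columns, full rank enforced), `tract`
#'   (0-based integer or empty), `n_tracts`, `term_names`, `hap_cols`
#'   (named list: HAP -> its column names), `exposure_mode`.
#' @export
build_design <- function(cohort, haps = character(0),
                         covariates = attr(cohort, "covariate_names"),
                         exposure_mode = c("categorical", "continuous"),
                         categorization = NULL, use_tract = TRUE) {
  exposure_mode <- match.arg(exposure_mode)
  y <- as.numeric(cohort$case)
  n <- nrow(cohort)
  cols <- list("(Intercept)" = rep(1, n))
  for (v in covariates) {
    x <- as.character(cohort[[v]])
    lev <- sort(unique(x))
    for (l in lev[-1L]) cols[[paste0(v, ":", l)]] <- as.numeric(x == l)
  }
  hap_cols <- list()
  if (length(haps)) {
    if (exposure_mode == "categorical") {
      categorization <- categorization %||% categorize_cohort(cohort)
      for (h in haps) {
        cat3 <- categorization[[h]]$category
        if (is.null(cat3)) stopf("no categorization for HAP '%s'", h)
        nm <- paste0(h, ":", c("medium", "high"))
        cols[[nm[1L]]] <- as.numeric(cat3 == "medium")
        cols[[nm[2L]]] <- as.numeric(cat3 == "high")
        hap_cols[[h]] <- nm
      }
    } else {
      for (h in haps) {
        cols[[h]] <- standardize_exposure(cohort[[h]])
        hap_cols[[h]] <- h
      }
    }
  }
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    bad <- colnames(X)[qr_x$pivot[(qr_x$rank + 1L):ncol(X)]]
    stopf("design is rank deficient; collinear column(s): %s",
          paste(bad, collapse = ", "))
  }
  if (use_tract) {
    tract_f <- match(cohort$tract, sort(unique(cohort$tract))) - 1L
    n_tracts <- length(unique(tract_f))
    if (n_tracts < 2L)
      stopf("need >= 2 tracts for a tract random intercept")
  } else {
    tract_f <- integer(0)
    n_tracts <- 0L
  }
  list(y = y, X = X, tract = tract_f, n_tracts = n_tracts,
       term_names = colnames(X), hap_cols = hap_cols,
       exposure_mode = exposure_mode)
}

# per-column prior precisions for a (possibly mixture) design
prior_precisions <- function(design, priors, mixture = FALSE) {
  p <- ncol(design$X)
  prec <- rep(1 / priors$covariate_variance, p)
  mix_cols <- if (mixture) unlist(design$hap_cols) else character(0)
  mix_idx <- match(mix_cols, design$term_names)
  list(prec = prec, mix_idx = mix_idx, mix_cols = mix_cols)
}

#' Log joint density of the hierarchical logistic model
#'
#' Bernoulli-logit log-likelihood plus normal log-priors on the fixed
#' effects, `N(0, sigma^2)` on the tract intercepts, and the uniform
#' log-hyperprior on `sigma` (a constant inside its support, `-Inf`
#' outside). Up to an additive constant this is the density every
#' sampler in the package targets. With zero subjects it reduces to the
#' log-prior.
#'
#' @param design from [build_design()].
#' @param priors a [prior_spec()].
#' @param beta fixed-effect vector (length `ncol(design$X)`).
#' @param u tract intercepts (length `design$n_tracts`), if any.
#' @param sigma tract intercept SD (required when `n_tracts > 0`).
#' @param gamma optional 0/1 inclusion indicators for the mixture
#'   (SSVS) pollutant columns, in `unlist(design$hap_cols)` order; when
#'   supplied those columns use the spike/slab variance instead of the
#'   covariate variance.
#' @return scalar log density (possibly `-Inf`).
#' @export
log_posterior <- function(design, priors, beta, u = numeric(0), sigma = NULL,
                          gamma = NULL) {
  X <- design$X
  if (length(beta) != ncol(X)) stopf("beta has wrong length")
  pp <- prior_precisions(design, priors, mixture = !is.null(gamma))
  v <- 1 / pp$prec
  if (!is.null(gamma)) {
    if (length(gamma) != length(pp$mix_idx)) stopf("gamma has wrong length")
    v[pp$mix_idx] <- ifelse(gamma == 1, priors$slab_variance,
                            priors$spike_variance)
  }
  lp <- sum(dnorm(beta, 0, sqrt(v), log = TRUE))
  if (!is.null(gamma)) {
    pi0 <- priors$inclusion_prob
    lp <- lp + sum(ifelse(gamma == 1, log(pi0), log1p(-pi0)))
  }
  if (design$n_tracts > 0L) {
    if (is.null(sigma)) stopf("sigma required when the model has tracts")
    b <- priors$sigma_bounds
    if (sigma < b[1L] || sigma > b[2L] || sigma <= 0) return(-Inf)
    if (length(u) != design$n_tracts) stopf("u has wrong length")
    lp <- lp + sum(dnorm(u, 0, sigma, log = TRUE)) - log(b[2L] - b[1L])
  }
  if (nrow(X) > 0L) {
    eta <- drop(X %*% beta)
    if (design$n_tracts > 0L) eta <- eta + u[design$tract + 1L]
    # stable log(1 + e^eta) = max(eta, 0) + log1p(e^{-|eta|})
    lp <- lp + sum(design$y * eta - (pmax(eta, 0) + log1p(exp(-abs(eta)))))
  }
  lp
}

# run the Polya-Gamma Gibbs sampler over all chains
run_chains <- function(design, priors, settings, mixture = FALSE) {
  pp <- prior_precisions(design, priors, mixture)
  p <- ncol(design$X)
  n_burn <- floor(settings$n_iter * settings$burn_in)
  b <- priors$sigma_bounds
  chains <- vector("list", settings$n_chains)
  for (k in seq_len(settings$n_chains)) {
    set.seed(settings$seeds[k])
    if (k == 1L) {
      beta0 <- rep(0, p)
      sigma0 <- mean(b)
    } else { # overdispersed start: draw from the prior
      v0 <- 1 / pp$prec
      if (mixture && length(pp$mix_idx)) {
        g0 <- rbinom(length(pp$mix_idx), 1L, priors$inclusion_prob)
        v0[pp$mix_idx] <- ifelse(g0 == 1, priors$slab_variance,
                                 priors$spike_variance)
      }
      beta0 <- rnorm(p, 0, sqrt(v0))
      sigma0 <- runif(1, b[1L], b[2L])
    }
    raw <- .pg_gibbs(design$X, design$y, design$tract, design$n_tracts,
                     pp$prec, as.integer(pp$mix_idx - 1L),
                     priors$spike_variance, priors$slab_variance,
                     priors$inclusion_prob, b[1L], b[2L],
                     settings$n_iter, n_burn, beta0,
                     max(sigma0, 1e-3))
    colnames(raw$beta) <- design$term_names
    if (length(pp$mix_cols)) {
      colnames(raw$gamma) <- pp$mix_cols
      colnames(raw$rb_prob) <- pp$mix_cols
    }
    chains[[k]] <- raw
  }
  structure(list(chains = chains, design = design, priors = priors,
                 settings = settings, mixture = mixture,
                 mix_cols = pp$mix_cols),
            class = "hb_fit")
}

#' Sample the posterior of a hierarchical logistic model
#'
#' Gibbs sampling with Polya-Gamma data augmentation for the
#' Bernoulli-logit likelihood; all conditional updates (fixed effects,
#' tract intercepts, truncated inverse-gamma for the intercept SD) are
#' exact, so the kernel satisfies detailed balance with respect to
#' [log_posterior()]. Chain 1 starts at zero, later chains at draws from
#' the prior; given identical seeds the output is reproducible.
#'
#' @param design from [build_design()].
#' @param priors a [prior_spec()].
#' @param settings an [mcmc_settings()].
#' @return an `hb_fit`: per-chain draws of the fixed effects and sigma,
#'   plus post-burn-in posterior means of the tract intercepts.
#' @export
sample_posterior <- function(design, priors = prior_spec(),
                             settings = mcmc_settings()) {
  run_chains(design, priors, settings, mixture = FALSE)
}

retained_rows <- function(settings, burn_in) {
  n_burn <- floor(settings$n_iter * burn_in)
  if (n_burn >= settings$n_iter) stopf("burn-in leaves no retained draws")
  (n_burn + 1L):settings$n_iter
}

#' Posterior summaries: OR and 95% credible interval per coefficient
#'
#' Discards the burn-in fraction of each chain, pools the retained
#' draws, and reports for each coefficient the posterior mean of beta,
#' `OR = exp(mean)`, and the credible interval from the 2.5th/97.5th
#' posterior quantiles of beta, exponentiated.
#'
#' @param fit an `hb_fit` (or `ssvs_fit`).
#' @param burn_in fraction discarded per chain; defaults to the fit's
#'   settings.
#' @param level credible level (default 0.95).
#' @return data.frame of class `posterior_summary` with columns `term`,
#'   `mean`, `or`, `ci_low`, `ci_high`, `n_draws`; the pooled sigma
#'   summary is in `attr(, "sigma")`.
#' @export
summarize_posterior <- function(fit, burn_in = fit$settings$burn_in,
                                level = 0.95) {
  rows <- retained_rows(fit$settings, burn_in)
  if (length(rows) < 2L) stopf("need >= 2 retained draws")
  beta <- do.call(rbind, lapply(fit$chains, function(ch)
    ch$beta[rows, , drop = FALSE]))
  qs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  mu <- colMeans(beta)
  ci <- apply(beta, 2L, quantile, probs = qs, names = FALSE)
  out <- data.frame(term = colnames(beta), mean = mu,
                    or = exp(mu), ci_low = exp(ci[1L, ]),
                    ci_high = exp(ci[2L, ]), n_draws = nrow(beta),
                    row.names = NULL)
  if (fit$design$n_tracts > 0L) {
    sig <- unlist(lapply(fit$chains, function(ch) ch$sigma[rows]))
    attr(out, "sigma") <- c(mean = mean(sig),
                            quantile(sig, qs, names = FALSE))
  }
  class(out) <- c("posterior_summary", "data.frame")
  out
}

#' Cross-chain convergence check
#'
#' Computes the Pearson correlation, across parameters, of the vectors
#' of per-chain posterior means (fixed effects, sigma, and tract
#' intercepts); with more than two chains the minimum pairwise
#' correlation is reported. The check passes when the correlation
#' exceeds the threshold (default 0.95). With fewer than two parameters
#' the correlation is undefined and the report is flagged
#' not-assessable.
#'
#' @param x an `hb_fit`, or a list of per-chain posterior-mean numeric
#'   vectors.
#' @param threshold pass threshold (default 0.95, strict inequality).
#' @param burn_in burn-in fraction when `x` is a fit.
#' @return list of class `convergence_report`: `correlation`, `pass`,
#'   `assessable`, `threshold`, `n_parameters`.
#' @export
check_convergence <- function(x, threshold = 0.95, burn_in = NULL) {
  if (inherits(x, "hb_fit")) {
    burn_in <- burn_in %||% x$settings$burn_in
    rows <- retained_rows(x$settings, burn_in)
    means <- lapply(x$chains, function(ch) {
      m <- colMeans(ch$beta[rows, , drop = FALSE])
      if (x$design$n_tracts > 0L)
        m <- c(m, mean(ch$sigma[rows]), ch$u_mean)
      m
    })
  } else if (is.list(x) && all(vapply(x, is.numeric, TRUE))) {
    means <- x
  } else stopf("'x' must be an hb_fit or a list of numeric vectors")
  if (length(means) < 2L) stopf("need >= 2 chains")
  np <- length(means[[1L]])
  if (np < 2L || any(vapply(means, sd, 0) == 0)) {
    rep <- list(correlation = NA_real_, pass = NA, assessable = FALSE,
                threshold = threshold, n_parameters = np)
  } else {
    cors <- c()
    for (i in seq_along(means)[-1L])
      for (j in seq_len(i - 1L))
        cors <- c(cors, cor(means[[i]], means[[j]]))
    r <- min(cors)
    rep <- list(correlation = r, pass = r > threshold, assessable = TRUE,
                threshold = threshold, n_parameters = np)
  }
  class(rep) <- "convergence_report"
  rep
}

#' @export
print.convergence_report <- function(x, ...) {
  if (!x$assessable)
    cat("convergence: not assessable (fewer than 2 varying parameters)\n")
  else
    cat(sprintf("convergence: cross-chain correlation %.4f over %d parameters -> %s (threshold %.2f)\n",
                x$correlation, x$n_parameters,
                if (x$pass) "PASS" else "FAIL", x$threshold))
  invisible(x)
}

#' Single-pollutant hierarchical model
#'
#' Fits the full hierarchical logistic model for one pollutant
#' (medium/high vs low, or a standardized continuous term) with the
#' adjustment covariates always included under `N(0, covariate
#' variance)` priors and the tract random intercept. This is the model
#' run once per pollutant to build the single-pollutant results table.
#'
#' @param cohort a `hap_cohort`.
#' @param hap pollutant name.
#' @param covariates adjustment covariate names.
#' @param priors a [prior_spec()].
#' @param settings an [mcmc_settings()].
#' @param categorization optional [categorize_cohort()] result.
#' @param exposure_mode `"categorical"` or `"continuous"`.
#' @return list of class `single_pollutant_fit`: `hap`, `summary` (rows
#'   for the pollutant terms), `full_summary`, `convergence`, `fit`.
#' @export
fit_single_pollutant <- function(cohort, hap,
                                 covariates = attr(cohort, "covariate_names"),
                                 priors = prior_spec(),
                                 settings = mcmc_settings(),
                                 categorization = NULL,
                                 exposure_mode = "categorical") {
  design <- build_design(cohort, haps = hap, covariates = covariates,
                         exposure_mode = exposure_mode,
                         categorization = categorization)
  fit <- sample_posterior(design, priors, settings)
  smry <- summarize_posterior(fit)
  structure(list(hap = hap,
                 summary = smry[smry$term %in% design$hap_cols[[hap]], ],
                 full_summary = smry,
                 convergence = if (settings$n_chains >= 2L)
                   check_convergence(fit) else NULL,
                 fit = fit),
            class = "single_pollutant_fit")
}

#' @export
print.single_pollutant_fit <- function(x, ...) {
  cat(sprintf("single-pollutant fit: %s\n", x$hap))
  print(format_summary(x$summary))
  if (!is.null(x$convergence)) print(x$convergence)
  invisible(x)
}

format_summary <- function(s, digits = 3) {
  data.frame(term = s$term, OR = round(s$or, digits),
             `2.5%` = round(s$ci_low, digits),
             `97.5%` = round(s$ci_high, digits), check.names = FALSE)
}

#' @export
print.posterior_summary <- function(x, ...) {
  print(format_summary(x))
  sig <- attr(x, "sigma")
  if (!is.null(sig))
    cat(sprintf("tract intercept SD: posterior mean %.3f (%.3f, %.3f)\n",
                sig[1L], sig[2L], sig[3L]))
  invisible(x)
}
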