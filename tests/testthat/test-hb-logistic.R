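# a minimal hand-built design (no helper so the pieces stay visible)
manual_design <- function(X, y, tract = integer(0), n_tracts = 0L) {
  list(y = y, X = X, tract = tract, n_tracts = n_tracts,
       term_names = colnames(X), hap_cols = list(),
       exposure_mode = "continuous")
}

test_that("log_posterior reduces to the prior with zero subjects", {
  d <- manual_design(matrix(numeric(0), 0, 2,
                            dimnames = list(NULL, c("a", "b"))), numeric(0))
  pr <- prior_spec()
  beta <- c(0.5, -1)
  expect_equal(log_posterior(d, pr, beta),
               sum(dnorm(beta, 0, sqrt(10), log = TRUE)))
})

test_that("log_posterior matches a scalar hand computation", {
  # one subject, x = 2, y = 1: ll(b) = 2b - log(1 + e^{2b})
  d <- manual_design(matrix(2, 1, 1, dimnames = list(NULL, "x")), 1)
  pr <- prior_spec()
  hand <- function(b) 2 * b - log(1 + exp(2 * b)) + dnorm(b, 0, sqrt(10), log = TRUE)
  expect_equal(log_posterior(d, pr, 1) - log_posterior(d, pr, 0),
               hand(1) - hand(0))
})

test_that("sigma outside the uniform hyperprior support gives -Inf", {
  d <- manual_design(matrix(1, 4, 1, dimnames = list(NULL, "x")),
                     c(0, 1, 0, 1), tract = c(0L, 0L, 1L, 1L), n_tracts = 2L)
  pr <- prior_spec()
  expect_equal(log_posterior(d, pr, 0, u = c(0, 0), sigma = 3.5), -Inf)
  expect_true(is.finite(log_posterior(d, pr, 0, u = c(0, 0), sigma = 1)))
})

test_that("rank-deficient designs fail naming the collinear column", {
  spec <- mk_test_spec(400, n_haps = 2)
  ch <- simulate_cohort(spec, seed = 3)
  ch$dup <- ch$smoking # duplicate dummy block
  attr(ch, "covariate_names") <- c(attr(ch, "covariate_names"), "dup")
  expect_error(build_design(ch, covariates = attr(ch, "covariate_names")),
               "rank deficient.*dup")
})

test_that("sampler matches deterministic quadrature in one dimension", {
  set.seed(42)
  n <- 40
  x <- rnorm(n)
  y <- rbinom(n, 1, plogis(0.8 * x))
  oracle <- quadrature_posterior_1d(x, y)
  d <- manual_design(matrix(x, ncol = 1, dimnames = list(NULL, "x")), y)
  fit <- sample_posterior(d, prior_spec(),
                          mcmc_settings(n_chains = 2, n_iter = 10000, seed = 7))
  s <- summarize_posterior(fit)
  expect_lt(abs(s$mean - oracle$mean), 0.02)
  expect_lt(abs(log(s$ci_low) - oracle$q025), 0.02)
  expect_lt(abs(log(s$ci_high) - oracle$q975), 0.02)
})

test_that("sampler matches quadrature with two free parameters", {
  set.seed(43)
  n <- 60
  X <- cbind(`(Intercept)` = 1, x = rnorm(n))
  y <- rbinom(n, 1, plogis(-0.5 + X[, 2]))
  oracle <- quadrature_posterior_2d(X, y)
  fit <- sample_posterior(manual_design(X, y), prior_spec(),
                          mcmc_settings(n_chains = 2, n_iter = 8000, seed = 9))
  s <- summarize_posterior(fit)
  expect_lt(abs(s$mean[1] - oracle$mean1), 0.03)
  expect_lt(abs(s$mean[2] - oracle$mean2), 0.03)
})

test_that("balanced intercept-only posterior is centered at zero", {
  y <- rep(c(0, 1), 50)
  d <- manual_design(matrix(1, 100, 1, dimnames = list(NULL, "(Intercept)")), y)
  fit <- sample_posterior(d, prior_spec(),
                          mcmc_settings(n_chains = 2, n_iter = 4000, seed = 5))
  expect_lt(abs(summarize_posterior(fit)$mean), 0.08)
})

test_that("with a flat likelihood the posterior recovers the prior SD", {
  # near-zero design column: data carry no information about beta
  d <- manual_design(matrix(1e-8, 2, 1, dimnames = list(NULL, "x")), c(0, 1))
  fit <- sample_posterior(d, prior_spec(),
                          mcmc_settings(n_chains = 2, n_iter = 6000, seed = 2))
  draws <- unlist(lapply(fit$chains, function(ch) ch$beta[3001:6000, 1]))
  expect_lt(abs(sd(draws) - sqrt(10)) / sqrt(10), 0.1)
})

test_that("summaries follow the OR and quantile conventions", {
  fake <- structure(list(
    chains = list(list(beta = matrix(log(2), 100, 1,
                                     dimnames = list(NULL, "b")))),
    settings = mcmc_settings(n_chains = 1, n_iter = 100, seed = 1),
    design = list(n_tracts = 0L)), class = "hb_fit")
  s <- summarize_posterior(fake)
  expect_equal(s$or, 2)
  expect_equal(s$ci_low, 2)
  expect_equal(s$ci_high, 2)
  expect_equal(s$n_draws, 50) # burn-in 0.5 of a single 100-draw chain

  set.seed(31)
  z <- matrix(rnorm(100000), ncol = 1, dimnames = list(NULL, "b"))
  fake$chains <- list(list(beta = z))
  fake$settings <- mcmc_settings(n_chains = 1, n_iter = 100000, seed = 1)
  s <- summarize_posterior(fake)
  expect_equal(log(s$ci_low), -1.96, tolerance = 0.02)
  expect_equal(log(s$ci_high), 1.96, tolerance = 0.02)
})

test_that("retained draw count is chains x iterations x (1 - burn_in)", {
  d <- manual_design(matrix(1, 20, 1, dimnames = list(NULL, "(Intercept)")),
                     rep(c(0, 1), 10))
  fit <- sample_posterior(d, prior_spec(),
                          mcmc_settings(n_chains = 2, n_iter = 200, seed = 4))
  expect_equal(summarize_posterior(fit)$n_draws, 200)
})

test_that("convergence rule: correlation of per-chain posterior means", {
  expect_true(check_convergence(list(c(1, 2, 3), c(1, 2, 3)))$pass)
  expect_equal(check_convergence(list(c(1, 2, 3), c(1, 2, 3)))$correlation, 1)

  r <- check_convergence(list(c(1, 2, 3, 4), c(4, 3, 2, 1)))
  expect_equal(r$correlation, -1)
  expect_false(r$pass)

  # a pair engineered to sit just under the threshold fails
  v <- vectors_with_correlation(0.9449)
  expect_equal(cor(v$x, v$y), 0.9449, tolerance = 1e-12)
  expect_false(check_convergence(list(v$x, v$y))$pass)
  expect_true(check_convergence(list(v$x, v$y), threshold = 0.90)$pass)

  # fewer than two varying parameters: not assessable
  expect_false(check_convergence(list(1, 2))$assessable)

  # note: means (0,1,2) vs (0,1,4) correlate at 0.9608 and PASS at 0.95
  r2 <- check_convergence(list(c(0, 1, 2), c(0, 1, 4)))
  expect_equal(r2$correlation, 4 / sqrt(2 * 78 / 9), tolerance = 1e-12)
  expect_true(r2$pass)
})

test_that("fits are reproducible, bounded, and label-invariant", {
  spec <- mk_test_spec(600, n_haps = 2)
  ch <- simulate_cohort(spec, seed = 17)
  st <- mcmc_settings(n_chains = 2, n_iter = 1500, seed = 23)
  f1 <- fit_single_pollutant(ch, "hap01", settings = st)
  f2 <- fit_single_pollutant(ch, "hap01", settings = st)
  expect_identical(f1$summary, f2$summary)

  # sigma draws always inside the uniform hyperprior support
  sig <- unlist(lapply(f1$fit$chains, `[[`, "sigma"))
  expect_true(all(sig >= 0 & sig <= 3))

  # permuting subject rows only moves results by Monte-Carlo noise
  perm <- sample(nrow(ch))
  chp <- ch[perm, ]
  attributes(chp)[c("hap_names", "covariate_names", "class")] <-
    attributes(ch)[c("hap_names", "covariate_names", "class")]
  f3 <- fit_single_pollutant(chp, "hap01", settings = st)
  expect_equal(f1$summary$mean, f3$summary$mean, tolerance = 0.15)
})

test_that("single-pollutant models see real effects and skip absent ones", {
  # planted OR_high = 3 on hap01 at n = 1600: its CI should exclude 1
  spec <- mk_test_spec(1600, n_haps = 2, planted_high = log(3))
  ch <- simulate_cohort(spec, seed = 29)
  st <- mcmc_settings(n_chains = 2, n_iter = 2500, seed = 31)
  f <- fit_single_pollutant(ch, "hap01", settings = st)
  hi <- f$summary[f$summary$term == "hap01:high", ]
  expect_gt(hi$ci_low, 1)
  # the null pollutant's CI covers 1
  f0 <- fit_single_pollutant(ch, "hap02", settings = st)
  hi0 <- f0$summary[f0$summary$term == "hap02:high", ]
  expect_true(hi0$ci_low < 1 && hi0$ci_high > 1)
})
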