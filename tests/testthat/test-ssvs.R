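test_that("bayes factor algebra is exact", {
  expect_equal(bayes_factor(0.25, 0.25), 1)
  expect_equal(bayes_factor(0.5, 0.25), 3)
  # inverse map round trip through the published trichloroethylene value
  p <- bf_to_inclusion(3.79, 0.25)
  expect_equal(round(p, 3), 0.558)
  expect_equal(bayes_factor(p, 0.25), 3.79)
  expect_equal(round(bayes_factor(0.558, 0.25), 2), 3.79)
  # strictly increasing in p at fixed prior
  ps <- seq(0.01, 0.99, by = 0.01)
  expect_true(all(diff(bayes_factor(ps, 0.25)) > 0))
  # degenerate estimates
  expect_error(bayes_factor(0.5, 0), "prior_probability")
  expect_error(bayes_factor(0.5, 1), "prior_probability")
  expect_error(bayes_factor(1.2, 0.25), "inclusion_probability")
  expect_warning(bf_inf <- bayes_factor(1, 0.25), "Inf")
  expect_identical(bf_inf, Inf)
  expect_equal(bayes_factor(1, 0.25, n_draws = 1000),
               bayes_factor(1 - 1 / 2000, 0.25))
})

test_that("selection applies strict BF > 1 with the either-level rule", {
  bf <- data.frame(
    hap = c("quinoline", "quinoline", "tce", "tce", "benzene", "benzene"),
    term = c("quinoline:medium", "quinoline:high", "tce:medium", "tce:high",
             "benzene:medium", "benzene:high"),
    bf = c(0.32, 1.01, 3.79, 0.60, 0.85, 0.99))
  sel <- select_final(bf)
  expect_identical(as.character(sel), c("quinoline", "tce"))
  expect_identical(as.character(select_final(transform(bf, bf = bf / 10))),
                   character(0))
  # boundary: BF exactly 1 is not selected
  expect_identical(as.character(select_final(
    data.frame(hap = "x", bf = 1.0))), character(0))
})

test_that("the gamma full conditional matches the closed form", {
  pr <- prior_spec()
  cond <- function(b)
    plogis(log(pr$inclusion_prob / (1 - pr$inclusion_prob)) +
             dnorm(b, 0, sqrt(pr$slab_variance), log = TRUE) -
             dnorm(b, 0, sqrt(pr$spike_variance), log = TRUE))
  # at beta = 0 the inclusion odds are (1/3) * sqrt(0.001/10) = 1/300
  expect_equal(cond(0), (1 / 300) / (1 + 1 / 300), tolerance = 1e-6)
  expect_equal(round(cond(0), 5), 0.00332)

  # the sampler's stored Rao-Blackwellized probabilities must agree with
  # the same closed form evaluated at the previous draw of beta
  spec <- mk_test_spec(400, n_haps = 2)
  ch <- simulate_cohort(spec, seed = 41)
  sfit <- sample_ssvs(ch, c("hap01", "hap02"),
                      settings = mcmc_settings(n_chains = 1, n_iter = 60,
                                               seed = 43),
                      quiet = TRUE)
  chain <- sfit$chains[[1]]
  j <- match("hap01:high", colnames(chain$rb_prob))
  bcol <- chain$beta[, "hap01:high"]
  expect_equal(chain$rb_prob[2:60, j], cond(bcol[1:59]), tolerance = 1e-10)
})

test_that("with slab = spike the indicators follow the prior", {
  spec <- mk_test_spec(400, n_haps = 2)
  ch <- simulate_cohort(spec, seed = 47)
  pr <- prior_spec(slab_variance = 10, spike_variance = 10,
                   inclusion_prob = 0.25)
  sfit <- sample_ssvs(ch, c("hap01", "hap02"), priors = pr,
                      settings = mcmc_settings(n_chains = 2, n_iter = 2000,
                                               seed = 49),
                      quiet = TRUE)
  ip <- inclusion_probabilities(sfit)
  expect_equal(ip$p_rb, rep(0.25, 4), tolerance = 1e-10)
  expect_equal(ip$p_raw, rep(0.25, 4), tolerance = 0.05)
})

test_that("ssvs recovers a planted effect and ranks it first", {
  spec <- mk_test_spec(2400, n_haps = 5, planted_high = log(3))
  ch <- simulate_cohort(spec, seed = 53)
  sfit <- sample_ssvs(ch, attr(ch, "hap_names"),
                      settings = mcmc_settings(n_chains = 2, n_iter = 2500,
                                               seed = 59),
                      quiet = TRUE)
  bf <- ssvs_bayes_factors(sfit)
  top <- bf$term[which.max(bf$bf)]
  expect_identical(top, "hap01:high")
  expect_true("hap01" %in% select_final(bf))
})

test_that("sensitivity prior 0.50 preserves the planted-effect ranking", {
  spec <- mk_test_spec(2400, n_haps = 5, planted_high = log(3))
  ch <- simulate_cohort(spec, seed = 61)
  st <- mcmc_settings(n_chains = 2, n_iter = 2000, seed = 67)
  bf25 <- ssvs_bayes_factors(sample_ssvs(ch, attr(ch, "hap_names"),
                                         priors = prior_spec(inclusion_prob = 0.25),
                                         settings = st, quiet = TRUE))
  bf50 <- ssvs_bayes_factors(sample_ssvs(ch, attr(ch, "hap_names"),
                                         priors = prior_spec(inclusion_prob = 0.50),
                                         settings = st, quiet = TRUE))
  expect_identical(bf25$term[which.max(bf25$bf)], "hap01:high")
  expect_identical(bf50$term[which.max(bf50$bf)], "hap01:high")
})

test_that("highly correlated pollutant pairs trigger the pre-binning warning", {
  spec <- cohort_spec(50, 350, 50,
                      hap_specs = mk_test_haps(3, block = list(members = 1:2,
                                                               rho = 0.95)),
                      covariate_specs = mk_test_covs())
  ch <- simulate_cohort(spec, seed = 71)
  expect_warning(
    sample_ssvs(ch, attr(ch, "hap_names"),
                settings = mcmc_settings(n_chains = 1, n_iter = 50, seed = 3),
                quiet = TRUE),
    "bin before SSVS")
})

test_that("spike null interval reports the implied null OR range", {
  ni <- spike_null_interval(0.001)
  expect_equal(ni, exp(c(-1, 1) * qnorm(0.995) * sqrt(0.001)))
  # the default spike does NOT give (0.97, 1.03); 1e-4 does
  expect_lt(ni[1], 0.93)
  ni4 <- spike_null_interval(1e-4)
  expect_equal(round(ni4, 2), c(0.97, 1.03))
})

test_that("final joint model: empty selection and config equivalence", {
  empty <- fit_final_joint(ch <- NULL, character(0))
  expect_s3_class(empty, "final_joint_fit")
  expect_match(empty$message, "no HAP selected")
  expect_null(empty$summary)

  spec <- mk_test_spec(600, n_haps = 2)
  ch <- simulate_cohort(spec, seed = 73)
  st <- mcmc_settings(n_chains = 2, n_iter = 1200, seed = 79)
  # "no SSVS" comparison model = final-joint machinery over all HAPs
  j1 <- fit_final_joint(ch, attr(ch, "hap_names"), settings = st)
  j2 <- fit_final_joint(ch, attr(ch, "hap_names"), settings = st)
  expect_identical(j1$summary, j2$summary) # seeded determinism
  expect_setequal(j1$summary$term,
                  c("hap01:medium", "hap01:high", "hap02:medium", "hap02:high"))
})
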