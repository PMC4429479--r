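test_that("categorization uses control-only percentile cutoffs", {
  vals <- c(1:100, 1000, -5) # two extra subjects are cases
  mask <- c(rep(TRUE, 100), FALSE, FALSE)
  ct <- categorize(vals, mask)
  expect_equal(ct$cutoff_low, unname(quantile(1:100, 0.05)))
  expect_equal(ct$cutoff_high, unname(quantile(1:100, 0.95)))
  # roughly 5 controls in each tail
  expect_equal(sum(ct$category[mask] == "low"), 5)
  expect_equal(sum(ct$category[mask] == "high"), 5)
  # cases are categorized against the control cutoffs
  expect_identical(as.character(ct$category[101:102]), c("high", "low"))

  # permuting (or changing) case rows never changes the cutoffs
  vals2 <- c(1:100, -99, 99)
  ct2 <- categorize(vals2, mask)
  expect_identical(ct2[c("cutoff_low", "cutoff_high")],
                   ct[c("cutoff_low", "cutoff_high")])
})

test_that("categorization boundary values are medium and errors fire", {
  vals <- c(rep(1, 10), rep(2, 10), rep(3, 10))
  ct <- categorize(vals, rep(TRUE, 30))
  cut_lo <- ct$cutoff_low
  expect_identical(as.character(ct$category[vals == cut_lo])[1], "medium")
  expect_error(categorize(rep(1, 25), rep(TRUE, 25)), "degenerate")
  expect_error(categorize(c(rep(1, 10), 2), c(rep(TRUE, 10), FALSE)),
               ">= 20 control")
  expect_error(categorize(c(1:19, NA), rep(TRUE, 20)), "finite")
})

test_that("control tail fractions are near 5% up to ties", {
  set.seed(8)
  vals <- rlnorm(2000, 0, 1)
  mask <- rep(c(TRUE, FALSE), 1000)
  ct <- categorize(vals, mask)
  n_ctrl <- sum(mask)
  expect_lt(abs(sum(ct$category[mask] == "low") / n_ctrl - 0.05), 0.005)
  expect_lt(abs(sum(ct$category[mask] == "high") / n_ctrl - 0.05), 0.005)
})

test_that("standardization centers, scales, and is idempotent", {
  z <- standardize_exposure(c(1, 2, 3))
  expect_equal(mean(z), 0)
  expect_equal(sd(z), 1)
  x <- rlnorm(50, 0, 2)
  expect_equal(standardize_exposure(standardize_exposure(x)),
               standardize_exposure(x))
  expect_equal(standardize_exposure(c(10, 20, 30, 40)),
               c(-1.1619, -0.3873, 0.3873, 1.1619), tolerance = 1e-4)
  expect_error(standardize_exposure(rep(2, 10)), "degenerate")
})

test_that("spearman matrix is monotone-invariant with unit diagonal", {
  set.seed(10)
  a <- rlnorm(100)
  m <- cbind(a = a, b = exp(a), c = -a, d = runif(100))
  rho <- spearman_matrix(m)
  expect_equal(rho["a", "b"], 1)
  expect_equal(rho["a", "c"], -1)
  expect_identical(rho, t(rho))
  expect_equal(unname(diag(rho)), rep(1, 4))
  expect_error(spearman_matrix(m[1:2, ]), ">= 3")
  expect_warning(spearman_matrix(cbind(x = c(1, 1, 1), y = c(1, 2, 3))),
                 "constant")
})

test_that("spearman agrees with the hand rank formula", {
  # 1 - 6*sum(d^2)/(n(n^2-1)) with d = (0,-1,1,-1,1): rho = 0.8
  rho <- spearman_matrix(cbind(a = c(1, 2, 3, 4, 5), b = c(1, 3, 2, 5, 4)))
  expect_equal(rho["a", "b"], 0.8)
})

test_that("greedy binning reproduces the packaged 12-HAP structure", {
  corr <- hap_fixture("table2_correlations")
  bins <- bin_correlated(corr)
  expect_length(bins$bins, 4)
  members <- lapply(bins$bins, `[[`, "members")
  expect_true(any(vapply(members, setequal, TRUE,
                         c("acetaldehyde", "acrolein", "formaldehyde",
                           "benzene", "methylene chloride"))))
  expect_true(any(vapply(members, setequal, TRUE,
                         c("ethylene dibromide", "propylene dichloride",
                           "1,1,2,2-tetrachloroethane"))))
  expect_true(any(vapply(members, setequal, TRUE,
                         c("ethylene dichloride", "vinyl chloride"))))
  expect_true(any(vapply(members, setequal, TRUE,
                         c("diesel particulate matter", "nickel compounds"))))
  # the big bin is seeded at formaldehyde (4 neighbors above 0.80), which
  # is what pulls in methylene chloride (rho 0.82 with the seed)
  seeds <- vapply(bins$bins, `[[`, "", "seed_member")
  expect_true("formaldehyde" %in% seeds)
  expect_length(bins$unbinned, 0)
})

test_that("binning trivia: identity matrix, simple triple, validation", {
  id <- diag(4); dimnames(id) <- list(letters[1:4], letters[1:4])
  bins <- bin_correlated(id)
  expect_length(bins$bins, 0)
  expect_identical(bins$unbinned, letters[1:4])

  m <- matrix(c(1, .9, .5, .9, 1, .85, .5, .85, 1), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  bins <- bin_correlated(m)
  expect_length(bins$bins, 1)
  expect_identical(bins$bins[[1]]$seed_member, "B")
  expect_setequal(bins$bins[[1]]$members, c("A", "B", "C"))

  bad <- m; bad[1, 2] <- 0.2
  expect_error(bin_correlated(bad), "symmetric")
  bad2 <- m; diag(bad2) <- c(1, 1, 2)
  expect_error(bin_correlated(bad2), "diagonal|\\[-1, 1\\]")
})

test_that("greedy binning matches the exhaustive oracle on small matrices", {
  for (s in 1:25) {
    p <- sample(3:8, 1)
    corr <- random_corr(p, seed = s)
    got <- bin_correlated(corr, binning_config(threshold = 0.8))
    want <- binning_oracle(corr, threshold = 0.8)
    expect_identical(lapply(got$bins, function(b) sort(b$members)),
                     want$bins, info = paste("seed", s))
    expect_identical(sort(got$unbinned), want$unbinned)
  }
})

test_that("representative selection honors overrides and correlations", {
  corr <- hap_fixture("table2_correlations")
  bins <- bin_correlated(corr)
  big <- Filter(function(b) length(b$members) == 5, bins$bins)[[1]]

  ov <- binning_config(manual_representatives =
                         list(formaldehyde = c("benzene", "methylene chloride")))
  expect_identical(select_representatives(big, corr, ov),
                   c("benzene", "methylene chloride"))
  # automatic: formaldehyde has the maximal mean |rho| = 0.91
  expect_identical(select_representatives(big, corr), "formaldehyde")
  singleton <- list(members = "x", seed_member = "x")
  expect_identical(select_representatives(singleton, corr), "x")
  bad <- binning_config(manual_representatives = list(formaldehyde = "arsenic"))
  expect_error(select_representatives(big, corr, bad), "not in bin")
})

test_that("apply_binning arithmetic and validation", {
  all12 <- rownames(hap_fixture("table2_correlations"))
  expect_identical(apply_binning(all12, list()), all12)
  one_bin <- list(list(members = all12[1:5], seed_member = all12[1],
                       representatives = all12[2:3]))
  expect_length(apply_binning(all12, one_bin), 9)
  overlapping <- c(one_bin, list(list(members = all12[5:6],
                                      seed_member = all12[5],
                                      representatives = all12[6])))
  expect_error(apply_binning(all12, overlapping), "overlap")
  no_reps <- list(list(members = all12[1:2], seed_member = all12[1],
                       representatives = NULL))
  expect_error(apply_binning(all12, no_reps), "representatives")
})

test_that("correlation matrices round-trip through text", {
  corr <- hap_fixture("table2_correlations")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_corr_matrix(corr, f)
  expect_equal(read_corr_matrix(f), corr)
})
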