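# independent oracles, written before (and kept independent of) the
# sampler / binning code paths they check

# deterministic grid quadrature for a logistic regression posterior with
# independent N(0, prior_var) priors; exact up to grid resolution.
# 1 parameter: fine grid; 2 parameters: tensor grid.
quadrature_posterior_1d <- function(x, y, prior_var = 10,
                                    grid = seq(-10, 10, length.out = 40001)) {
  logpost <- vapply(grid, function(b) {
    eta <- x * b
    sum(y * eta - (pmax(eta, 0) + log1p(exp(-abs(eta))))) +
      dnorm(b, 0, sqrt(prior_var), log = TRUE)
  }, 0)
  w <- exp(logpost - max(logpost))
  w <- w / sum(w)
  cdf <- cumsum(w)
  qfun <- function(p) grid[which(cdf >= p)[1L]]
  list(mean = sum(grid * w), q025 = qfun(0.025), q975 = qfun(0.975))
}

quadrature_posterior_2d <- function(X, y, prior_var = 10,
                                    grid = seq(-6, 6, length.out = 401)) {
  lp <- outer(grid, grid, Vectorize(function(b1, b2) {
    eta <- X[, 1L] * b1 + X[, 2L] * b2
    sum(y * eta - (pmax(eta, 0) + log1p(exp(-abs(eta))))) +
      dnorm(b1, 0, sqrt(prior_var), log = TRUE) +
      dnorm(b2, 0, sqrt(prior_var), log = TRUE)
  }))
  w <- exp(lp - max(lp)); w <- w / sum(w)
  list(mean1 = sum(outer(grid, rep(1, length(grid))) * w),
       mean2 = sum(outer(rep(1, length(grid)), grid) * w))
}

# exhaustive re-implementation of greedy correlation binning: enumerates
# candidates in degree order at every step, maximum degree first with
# lexicographic tie-break; used as the oracle on small matrices
binning_oracle <- function(corr, threshold = 0.80) {
  nm <- rownames(corr)
  a <- abs(corr); a[is.na(a)] <- 0; diag(a) <- 0
  unassigned <- nm
  bins <- list()
  repeat {
    if (length(unassigned) < 2L) break
    degs <- vapply(unassigned, function(v)
      sum(a[v, unassigned] > threshold), 0)
    ord <- unassigned[order(-degs, unassigned)]
    if (degs[ord[1L]] == 0) break
    seed <- ord[1L]
    members <- union(seed, unassigned[a[seed, unassigned] > threshold])
    bins[[length(bins) + 1L]] <- sort(members)
    unassigned <- setdiff(unassigned, members)
  }
  list(bins = bins, unbinned = sort(unassigned))
}

# random symmetric correlation-like matrix with unit diagonal
random_corr <- function(p, seed) {
  set.seed(seed)
  m <- matrix(runif(p * p), p, p)
  m <- (m + t(m)) / 2
  diag(m) <- 1
  dimnames(m) <- list(letters[seq_len(p)], letters[seq_len(p)])
  m
}
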