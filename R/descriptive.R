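#' Pearson chi-square test on a levels-by-status count table
#'
#' Plain Pearson statistic `sum((O-E)^2/E)` with expected counts from
#' the row/column totals, `df = (r-1)(c-1)`, upper-tail p-value, and no
#' continuity correction — the test used for the case/control
#' characteristics comparisons.
#'
#' @param table numeric matrix of counts, rows = levels, columns =
#'   status groups (e.g. controls, cases); at least 2 rows and 2
#'   columns, no negative entries, no zero marginal totals.
#' @return an object of class `htest`.
#' @export
chi_square_test <- function(table) {
  m <- as.matrix(table)
  if (nrow(m) < 2L || ncol(m) < 2L) stopf("need a table of at least 2 x 2")
  if (any(m < 0) || any(!is.finite(m))) stopf("counts must be finite and >= 0")
  rs <- rowSums(m); cs <- colSums(m); n <- sum(m)
  if (any(rs == 0) || any(cs == 0))
    stopf("zero marginal total: expected counts undefined")
  e <- outer(rs, cs) / n
  stat <- sum((m - e)^2 / e)
  df <- (nrow(m) - 1L) * (ncol(m) - 1L)
  structure(list(statistic = c("X-squared" = stat),
                 parameter = c(df = df),
                 p.value = pchisq(stat, df, lower.tail = FALSE),
                 method = "Pearson's Chi-squared test (no continuity correction)",
                 data.name = deparse(substitute(table)),
                 observed = m, expected = e),
            class = "htest")
}

#' Crude odds ratio from a 2x2 comparison with Woolf interval
#'
#' `OR = (exposed_cases * ref_controls) / (exposed_controls * ref_cases)`
#' with the 95% interval `exp(log(OR) +/- 1.96 * sqrt(1/a+1/b+1/c+1/d))`.
#' Zero cells are an error; no automatic continuity correction is
#' applied (the caller decides how to handle sparse tables).
#'
#' @param exposed_cases,exposed_controls,ref_cases,ref_controls counts.
#' @param conf_level confidence level, default 0.95.
#' @return list with `or`, `ci` (length 2), `log_or`, `se_log_or`.
#' @export
odds_ratio_2x2 <- function(exposed_cases, exposed_controls,
                           ref_cases, ref_controls, conf_level = 0.95) {
  cells <- c(exposed_cases, exposed_controls, ref_cases, ref_controls)
  if (any(!is.finite(cells)) || any(cells < 0))
    stopf("counts must be finite and >= 0")
  if (any(cells == 0))
    stopf("zero cell: odds ratio undefined without a continuity correction")
  or <- (exposed_cases * ref_controls) / (exposed_controls * ref_cases)
  se <- sqrt(sum(1 / cells))
  z <- qnorm(1 - (1 - conf_level) / 2)
  list(or = or, ci = exp(log(or) + c(-z, z) * se),
       log_or = log(or), se_log_or = se)
}

#' Case/control characteristics table with chi-square p-values
#'
#' For each covariate of a cohort, tabulates level counts by case
#' status and attaches the Pearson chi-square p-value. Subjects with a
#' missing level are dropped per variable (complete-case per variable).
#'
#' @param cohort a `hap_cohort`.
#' @param covariates covariate names; default all in the cohort.
#' @return data.frame: `variable`, `level`, `controls`, `cases`,
#'   `p_value` (repeated within a variable).
#' @export
describe_cohort <- function(cohort, covariates = attr(cohort, "covariate_names")) {
  out <- list()
  for (v in covariates) {
    x <- cohort[[v]]
    keep <- !is.na(x)
    tab <- table(x[keep], factor(cohort$case[keep], levels = c(0L, 1L)))
    p <- if (nrow(tab) >= 2L) chi_square_test(unclass(tab))$p.value else NA_real_
    out[[v]] <- data.frame(variable = v, level = rownames(tab),
                           controls = as.integer(tab[, 1L]),
                           cases = as.integer(tab[, 2L]),
                           p_value = p, row.names = NULL)
  }
  do.call(rbind, out)
}
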