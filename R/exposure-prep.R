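#' Categorize one pollutant at control percentiles
#'
#' Cutoffs are the 5th and 95th percentiles of the concentration among
#' controls only; every subject (case or control) is then assigned
#' low (strictly below the 5th), high (strictly above the 95th), or
#' medium (between the cutoffs, inclusive). Low is the reference level
#' downstream.
#'
#' @param values numeric concentrations, one per subject.
#' @param control_mask logical, `TRUE` for controls; cutoffs use only
#'   these subjects.
#' @param probs the two percentile probabilities, default `c(.05, .95)`.
#' @param type quantile algorithm passed to [stats::quantile()]
#'   (default 7, linear interpolation between closest ranks).
#' @return object of class `exposure_categorization`: `cutoff_low`,
#'   `cutoff_high`, `category` (factor low/medium/high per subject),
#'   `probs`.
#' @export
categorize <- function(values, control_mask, probs = c(0.05, 0.95), type = 7) {
  if (!is.numeric(values) || any(!is.finite(values)))
    stopf("'values' must be finite numeric")
  if (length(control_mask) != length(values) || !is.logical(control_mask))
    stopf("'control_mask' must be logical, same length as 'values'")
  ctrl <- values[control_mask]
  if (length(ctrl) < 20L)
    stopf("need >= 20 control values to anchor the 5th/95th percentiles, got %d",
          length(ctrl))
  if (diff(range(ctrl)) == 0)
    stopf("degenerate distribution: all control values identical (%.6g); no low/high categories possible",
          ctrl[1L])
  cuts <- quantile(ctrl, probs = probs, type = type, names = FALSE)
  category <- factor(ifelse(values < cuts[1L], "low",
                            ifelse(values > cuts[2L], "high", "medium")),
                     levels = c("low", "medium", "high"))
  structure(list(cutoff_low = cuts[1L], cutoff_high = cuts[2L],
                 category = category, probs = probs),
            class = "exposure_categorization")
}

#' Categorize every pollutant column of a cohort or matrix
#'
#' @param x a `hap_cohort` (control mask taken from `case == 0`) or a
#'   numeric matrix (all rows treated as controls, e.g. to derive
#'   population cutoffs for the data generator).
#' @param ... passed to [categorize()].
#' @return named list of `exposure_categorization`, one per HAP.
#' @export
categorize_cohort <- function(x, ...) {
  if (inherits(x, "hap_cohort")) {
    haps <- attr(x, "hap_names")
    mask <- x$case == 0L
    setNames(lapply(haps, function(h) categorize(x[[h]], mask, ...)), haps)
  } else {
    x <- as.matrix(x)
    mask <- rep(TRUE, nrow(x))
    setNames(lapply(seq_len(ncol(x)),
                    function(j) categorize(x[, j], mask, ...)),
             colnames(x))
  }
}

#' @export
print.exposure_categorization <- function(x, ...) {
  cat(sprintf("exposure_categorization: cutoffs [%.4g, %.4g]; counts low %d / medium %d / high %d\n",
              x$cutoff_low, x$cutoff_high,
              sum(x$category == "low"), sum(x$category == "medium"),
              sum(x$category == "high")))
  invisible(x)
}

#' Center and scale a concentration vector
#'
#' Subtracts the mean and divides by the standard deviation (n-1
#' denominator), the transform used when modelling pollutants on the
#' continuous scale.
#'
#' @param values numeric vector with at least 2 distinct finite values.
#' @return numeric vector with mean 0 and SD 1.
#' @export
standardize_exposure <- function(values) {
  if (!is.numeric(values) || any(!is.finite(values)))
    stopf("'values' must be finite numeric")
  s <- sd(values)
  if (length(unique(values)) < 2L || s == 0)
    stopf("degenerate distribution: cannot standardize a constant vector")
  (values - mean(values)) / s
}

#' Spearman rank correlation matrix of pollutant concentrations
#'
#' @param exposures numeric matrix or data.frame, subjects x HAPs, with
#'   at least 3 rows. Constant columns yield `NA` correlations (flagged
#'   with a warning); the diagonal is always 1.
#' @return symmetric correlation matrix with unit diagonal.
#' @export
spearman_matrix <- function(exposures) {
  m <- as.matrix(exposures)
  if (nrow(m) < 3L) stopf("need >= 3 subjects for rank correlation")
  storage.mode(m) <- "double"
  constant <- apply(m, 2L, function(v) diff(range(v)) == 0)
  rho <- suppressWarnings(cor(m, method = "spearman"))
  diag(rho) <- 1
  if (any(constant))
    warning(sprintf("constant column(s) with undefined correlations: %s",
                    paste(colnames(m)[constant], collapse = ", ")),
            call. = FALSE)
  rho
}

#' Configuration for correlation binning
#'
#' @param threshold absolute Spearman correlation above which two HAPs
#'   are considered collinear, in (0, 1); default 0.80.
#' @param manual_representatives optional named list: bin seed name ->
#'   character vector of representatives, overriding the automatic
#'   maximum-mean-correlation choice (used to encode subject-matter
#'   representative choices).
#' @param max_representatives_per_bin automatic representatives kept per
#'   bin (default 1); manual overrides are used verbatim.
#' @return object of class `binning_config`.
#' @export
binning_config <- function(threshold = 0.80, manual_representatives = NULL,
                           max_representatives_per_bin = 1L) {
  check_scalar(threshold, "threshold")
  if (threshold <= 0 || threshold >= 1) stopf("'threshold' must be in (0,1)")
  check_scalar(max_representatives_per_bin, "max_representatives_per_bin",
               1, integerish = TRUE)
  if (!is.null(manual_representatives) &&
      (is.null(names(manual_representatives)) ||
       !all(nzchar(names(manual_representatives)))))
    stopf("'manual_representatives' must be a named list keyed by bin seed")
  structure(list(threshold = threshold,
                 manual_representatives = manual_representatives,
                 max_representatives_per_bin =
                   as.integer(max_representatives_per_bin)),
            class = "binning_config")
}

validate_corr <- function(corr) {
  if (!is.matrix(corr) || nrow(corr) != ncol(corr))
    stopf("correlation matrix must be square")
  if (is.null(rownames(corr)) || !identical(rownames(corr), colnames(corr)))
    stopf("correlation matrix needs matching row/column names")
  offdiag_ok <- all(is.na(corr) | abs(corr) <= 1 + 1e-8)
  if (!offdiag_ok) stopf("correlations must lie in [-1, 1]")
  if (any(abs(diag(corr) - 1) > 1e-8)) stopf("diagonal must be 1")
  if (any(abs(corr - t(corr)) > 1e-8, na.rm = TRUE))
    stopf("correlation matrix must be symmetric")
  invisible(corr)
}

#' Greedy correlation binning of collinear pollutants
#'
#' Repeatedly picks the not-yet-assigned HAP with the most
#' not-yet-assigned neighbors whose absolute correlation exceeds the
#' threshold (ties broken by name); that HAP seeds a bin consisting of
#' itself and those neighbors. The process stops when no unassigned pair
#' exceeds the threshold; HAPs never exceeding it stay unbinned. This is
#' the tag-selection style greedy rule used for collinear markers in
#' genetic association studies.
#'
#' @param corr symmetric correlation matrix with unit diagonal and
#'   row/column names.
#' @param config a [binning_config()].
#' @return object of class `correlation_bins`: list with `bins` (each a
#'   list of `members`, `seed_member`, `representatives` (unset),
#'   `threshold`) and `unbinned` (character).
#' @export
bin_correlated <- function(corr, config = binning_config()) {
  validate_corr(corr)
  thr <- config$threshold
  nm <- rownames(corr)
  a <- abs(corr); a[is.na(a)] <- 0; diag(a) <- 0
  unassigned <- nm
  bins <- list()
  repeat {
    if (length(unassigned) < 2L) break
    sub <- a[unassigned, unassigned, drop = FALSE]
    deg <- rowSums(sub > thr)
    if (max(deg) == 0) break
    cand <- sort(unassigned[deg == max(deg)])
    seed <- cand[1L]
    members <- c(seed, unassigned[sub[seed, ] > thr])
    members <- members[order(match(members, nm))]
    bins[[length(bins) + 1L]] <-
      list(members = members, seed_member = seed,
           representatives = NULL, threshold = thr)
    unassigned <- setdiff(unassigned, members)
  }
  structure(list(bins = bins, unbinned = unassigned, threshold = thr),
            class = "correlation_bins")
}

#' Choose the representative pollutant(s) of a bin
#'
#' With a manual override for the bin's seed, the override is used
#' verbatim (after checking it names only bin members). Otherwise the
#' `max_representatives_per_bin` members with the largest mean absolute
#' correlation to the other members are kept, ties broken by name.
#'
#' @param bin one element of `bin_correlated(...)$bins`.
#' @param corr the correlation matrix used for binning.
#' @param config a [binning_config()].
#' @return character vector of representatives.
#' @export
select_representatives <- function(bin, corr, config = binning_config()) {
  members <- bin$members
  if (!length(members)) stopf("empty bin")
  ov <- config$manual_representatives[[bin$seed_member]]
  if (!is.null(ov)) {
    bad <- setdiff(ov, members)
    if (length(bad))
      stopf("manual representatives not in bin '%s': %s",
            bin$seed_member, paste(bad, collapse = ", "))
    return(ov)
  }
  if (length(members) == 1L) return(members)
  sub <- abs(corr[members, members, drop = FALSE])
  mean_rho <- (rowSums(sub, na.rm = TRUE) - 1) / (length(members) - 1L)
  k <- min(config$max_representatives_per_bin, length(members))
  members[order(-mean_rho, members)][seq_len(k)]
}

#' Apply binning: the retained pollutant list
#'
#' @param all_haps character vector of every candidate HAP.
#' @param bins a `correlation_bins` object whose bins carry
#'   `representatives` (see [select_representatives()]), or a list of
#'   such bins.
#' @return character vector: unbinned HAPs plus bin representatives, in
#'   `all_haps` order.
#' @export
apply_binning <- function(all_haps, bins) {
  bl <- if (inherits(bins, "correlation_bins")) bins$bins else bins
  members <- lapply(bl, `[[`, "members")
  flat <- unlist(members)
  if (anyDuplicated(flat))
    stopf("overlapping bins: %s", paste(unique(flat[duplicated(flat)]),
                                        collapse = ", "))
  bad <- setdiff(flat, all_haps)
  if (length(bad))
    stopf("bin members not in 'all_haps': %s", paste(bad, collapse = ", "))
  reps <- unlist(lapply(bl, function(b) {
    if (is.null(b$representatives))
      stopf("bin '%s' has no representatives; call select_representatives() first",
            b$seed_member)
    b$representatives
  }))
  keep <- setdiff(all_haps, setdiff(flat, reps))
  keep[order(match(keep, all_haps))]
}

#' Run the full binning step
#'
#' Convenience wrapper: bins a correlation matrix, selects
#' representatives for every bin, and computes the retained HAP list.
#'
#' @inheritParams bin_correlated
#' @return `correlation_bins` with representatives filled in and a
#'   `retained` element.
#' @export
bin_and_select <- function(corr, config = binning_config()) {
  res <- bin_correlated(corr, config)
  res$bins <- lapply(res$bins, function(b) {
    b$representatives <- select_representatives(b, corr, config)
    b
  })
  res$retained <- apply_binning(rownames(corr), res)
  res
}

#' @export
print.correlation_bins <- function(x, ...) {
  cat(sprintf("correlation_bins: %d bin(s) at |rho| > %.2f, %d unbinned HAP(s)\n",
              length(x$bins), x$threshold, length(x$unbinned)))
  for (b in x$bins)
    cat(sprintf("  [%s] %s%s\n", b$seed_member,
                paste(b$members, collapse = ", "),
                if (!is.null(b$representatives))
                  paste0(" -> ", paste(b$representatives, collapse = " + "))
                else ""))
  invisible(x)
}

#' Read / write a named correlation matrix as delimited text
#'
#' Tab-separated with a header row and a leading name column.
#'
#' @param corr matrix with row/column names.
#' @param path file path.
#' @export
write_corr_matrix <- function(corr, path) {
  df <- data.frame(pollutant = rownames(corr), corr, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_corr_matrix
#' @export
read_corr_matrix <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1L]]
  colnames(m) <- names(df)[-1]
  m
}

#' Serialize binning results to JSON
#'
#' @param bins a `correlation_bins` object.
#' @param path file path.
#' @export
write_bins_json <- function(bins, path) {
  jsonlite::write_json(
    list(threshold = bins$threshold,
         bins = lapply(bins$bins, function(b)
           list(seed = b$seed_member, members = b$members,
                representatives = b$representatives)),
         unbinned = bins$unbinned,
         retained = bins$retained),
    path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}
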