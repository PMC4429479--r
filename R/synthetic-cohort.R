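#' Generate per-subject pollutant concentrations
#'
#' Draws a subjects-by-HAPs matrix of concentrations. Within a block,
#' correlation is induced by a shared standard-normal latent factor
#' before the log-normal marginal transform (a one-factor Gaussian
#' copula); because the transform is monotone, the Spearman correlation
#' of the concentrations equals that of the latent Gaussians. The latent
#' Pearson correlation needed to reach a target Spearman rho is
#' `2*sin(pi*rho/6)`.
#'
#' @param spec a [cohort_spec()].
#' @param n number of subjects; defaults to `n_cases + n_controls`.
#' @return numeric matrix (`n` x number of HAPs) with HAP names as
#'   column names; all entries positive.
#' @export
generate_exposures <- function(spec, n = spec$n_cases + spec$n_controls) {
  stopifnot(inherits(spec, "cohort_spec"))
  check_scalar(n, "n", 1, integerish = TRUE)
  haps <- spec$hap_specs
  if (!length(haps)) return(matrix(numeric(0), n, 0))
  block_ids <- vapply(haps, function(h) h$block_id %||% NA_character_, "")
  factors <- list()
  for (b in unique(block_ids[!is.na(block_ids)]))
    factors[[b]] <- rnorm(n)
  out <- matrix(NA_real_, n, length(haps),
                dimnames = list(NULL, vapply(haps, `[[`, "", "name")))
  for (j in seq_along(haps)) {
    h <- haps[[j]]
    if (is.na(block_ids[j]) || h$target_rho == 0) {
      z <- rnorm(n)
    } else {
      a <- 2 * sin(pi * h$target_rho / 6) # latent loading^2
      z <- sqrt(a) * factors[[block_ids[j]]] + sqrt(1 - a) * rnorm(n)
    }
    out[, j] <- exp(log(h$median) + h$dispersion * z)
  }
  out
}

# covariate draws for n subjects, as a data.frame of character columns
generate_covariates <- function(spec, n) {
  cols <- lapply(spec$covariate_specs, function(cv)
    sample(cv$levels, n, replace = TRUE, prob = cv$probs))
  names(cols) <- vapply(spec$covariate_specs, `[[`, "", "name")
  as.data.frame(cols, optional = TRUE, stringsAsFactors = FALSE)
}

#' Generate outcomes for a source population
#'
#' Applies the logistic outcome model: the case probability for subject
#' i is `plogis(baseline_logit + covariate effects + HAP category
#' effects + u[tract(i)])` with tract intercepts `u ~ N(0, tract_sd^2)`.
#' HAP category effects use the supplied categorization (low = 0,
#' medium/high = the spec's true log odds ratios).
#'
#' @param exposures matrix from [generate_exposures()].
#' @param categorized list of [categorize()] results, one per HAP column
#'   (as produced by [categorize_cohort()] on the same exposures).
#' @param spec the [cohort_spec()].
#' @param covariates optional data.frame of covariate level labels; drawn
#'   from the spec when omitted.
#' @return data.frame: `subject_id`, `case` (0/1), `tract`, covariate
#'   columns, plus attribute `linpred` (the latent logits).
#' @export
generate_outcomes <- function(exposures, categorized, spec, covariates = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- nrow(exposures)
  covariates <- covariates %||% generate_covariates(spec, n)
  tract <- sample.int(spec$n_tracts, n, replace = TRUE)
  u <- rnorm(spec$n_tracts, 0, spec$tract_sd)
  lp <- rep(spec$baseline_logit, n) + u[tract]
  for (cv in spec$covariate_specs)
    lp <- lp + cv$log_or[match(covariates[[cv$name]], cv$levels)]
  for (h in spec$hap_specs) {
    if (h$log_or_medium == 0 && h$log_or_high == 0) next
    cat3 <- categorized[[h$name]]$category
    lp <- lp + ifelse(cat3 == "high", h$log_or_high,
                      ifelse(cat3 == "medium", h$log_or_medium, 0))
  }
  y <- rbinom(n, 1L, plogis(lp))
  out <- data.frame(subject_id = seq_len(n), case = y, tract = tract)
  if (ncol(covariates)) out <- cbind(out, covariates)
  attr(out, "linpred") <- lp
  out
}

#' Simulate a case-control cohort
#'
#' Generates a source population large enough to contain the requested
#' number of cases (retrying with a doubled population up to
#' `max_attempts` times), then samples cases at random and controls
#' frequency matched to the realized case distribution of the matching
#' covariate (year of birth by default). This mirrors a retrospective
#' registry design; odds ratios are preserved under such outcome-based
#' sampling.
#'
#' @param spec a [cohort_spec()].
#' @param seed RNG seed (defaults to `spec$seed`).
#' @param max_attempts population doublings before giving up.
#' @param pop_size initial source-population size; sized automatically
#'   from the expected case rate when omitted.
#' @return a `hap_cohort` data.frame: `subject_id`, `case`, `tract`,
#'   covariates, then one numeric column per HAP. Attributes `hap_names`
#'   and `covariate_names` record the column roles.
#' @export
simulate_cohort <- function(spec, seed = spec$seed, max_attempts = 5L,
                            pop_size = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(seed)
  if (is.null(pop_size)) {
    rate_guess <- max(plogis(spec$baseline_logit), 1e-4)
    n_pop <- ceiling(spec$n_cases / rate_guess * 1.4)
    n_pop <- max(n_pop, ceiling(spec$n_controls * 1.2 + spec$n_cases))
  } else n_pop <- as.integer(pop_size)
  for (attempt in seq_len(max_attempts)) {
    expo <- generate_exposures(spec, n_pop)
    cat_pop <- if (ncol(expo)) categorize_cohort(expo) else list()
    pop <- generate_outcomes(expo, cat_pop, spec)
    n_case_avail <- sum(pop$case == 1L)
    n_ctrl_avail <- sum(pop$case == 0L)
    if (n_case_avail >= spec$n_cases && n_ctrl_avail >= spec$n_controls) {
      idx <- sample_case_control(pop, spec)
      out <- cbind(pop[idx, , drop = FALSE],
                   as.data.frame(expo[idx, , drop = FALSE], optional = TRUE))
      rownames(out) <- NULL
      out$subject_id <- seq_len(nrow(out))
      attr(out, "linpred") <- NULL
      attr(out, "hap_names") <- colnames(expo)
      attr(out, "covariate_names") <-
        vapply(spec$covariate_specs, `[[`, "", "name")
      class(out) <- c("hap_cohort", "data.frame")
      return(out)
    }
    n_pop <- n_pop * 2L
  }
  stopf("could not generate %d cases / %d controls in %d attempts (population reached %d); raise baseline_logit or max_attempts",
        spec$n_cases, spec$n_controls, max_attempts, n_pop %/% 2L)
}

# retrospective sampling: all-or-n cases, controls frequency matched on
# spec$match_var (falling back to unmatched top-up if a stratum is short)
sample_case_control <- function(pop, spec) {
  case_idx <- which(pop$case == 1L)
  ctrl_idx <- which(pop$case == 0L)
  case_take <- if (length(case_idx) > spec$n_cases)
    sample(case_idx, spec$n_cases) else case_idx
  mv <- spec$match_var
  if (is.null(mv) || !mv %in% names(pop)) {
    ctrl_take <- sample(ctrl_idx, spec$n_controls)
  } else {
    tab <- table(pop[[mv]][case_take])
    target <- round(as.numeric(tab) / sum(tab) * spec$n_controls)
    ctrl_take <- integer(0)
    for (k in seq_along(tab)) {
      pool <- ctrl_idx[pop[[mv]][ctrl_idx] == names(tab)[k]]
      ctrl_take <- c(ctrl_take, sample(pool, min(length(pool), target[k])))
    }
    short <- spec$n_controls - length(ctrl_take)
    if (short > 0) {
      pool <- setdiff(ctrl_idx, ctrl_take)
      ctrl_take <- c(ctrl_take, sample(pool, min(short, length(pool))))
    } else if (short < 0) {
      ctrl_take <- ctrl_take[seq_len(spec$n_controls)]
    }
  }
  sort(c(case_take, ctrl_take))
}

#' Write / read a cohort as delimited text
#'
#' Tab-separated, one header row: `subject_id`, `case`, `tract`,
#' covariate columns (character), then one numeric column per HAP.
#' `read_cohort()` infers the column roles: character columns between
#' `tract` and the first numeric column are covariates; remaining
#' numeric columns are HAP concentrations (override via `hap_names`).
#'
#' @param cohort a `hap_cohort` (or compatible data.frame).
#' @param path file path.
#' @param hap_names optional explicit HAP column names for reading.
#' @return `read_cohort()` returns a `hap_cohort`.
#' @export
write_cohort <- function(cohort, path) {
  write.table(cohort, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path, hap_names = NULL) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                   colClasses = NA)
  need <- c("subject_id", "case", "tract")
  if (!all(need %in% names(df)))
    stopf("cohort file must have columns %s", paste(need, collapse = ", "))
  rest <- setdiff(names(df), need)
  if (is.null(hap_names)) {
    is_num <- vapply(df[rest], is.numeric, TRUE)
    # 'year' is the conventional matching covariate even though numeric
    hap_names <- setdiff(rest[is_num], "year")
  }
  covars <- setdiff(rest, hap_names)
  df[covars] <- lapply(df[covars], as.character)
  attr(df, "hap_names") <- hap_names
  attr(df, "covariate_names") <- covars
  class(df) <- c("hap_cohort", "data.frame")
  df
}

#' @export
print.hap_cohort <- function(x, ...) {
  cat(sprintf("hap_cohort: %d subjects (%d cases / %d controls), %d tracts\n",
              nrow(x), sum(x$case == 1L), sum(x$case == 0L),
              length(unique(x$tract))))
  cat(sprintf("  covariates: %s\n",
              paste(attr(x, "covariate_names"), collapse = ", ")))
  cat(sprintf("  HAPs (%d): %s%s\n", length(attr(x, "hap_names")),
              paste(utils::head(attr(x, "hap_names"), 6), collapse = ", "),
              if (length(attr(x, "hap_names")) > 6) ", ..." else ""))
  invisible(x)
}
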