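#' Read a pipeline run configuration
#'
#' JSON with exactly one input source: an inline `cohort_spec` (the
#' synthetic generator is run) or a `cohort_file` (delimited cohort
#' table). Remaining blocks — `binning`, `priors`, `mcmc`, `mode`
#' (`exposure`: "categorical"/"continuous"; `selection`: true for SSVS,
#' false for the no-selection joint comparison), `covariates_adjust`,
#' `stages`, `out_dir`, `seed` — all have defaults.
#'
#' @param path JSON file path.
#' @return validated config list of class `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  cfg$config_hash <- unname(tools::md5sum(path))
  validate_run_config(cfg)
}

#' @rdname read_run_config
#' @param cfg a config list (as from JSON).
#' @export
validate_run_config <- function(cfg) {
  has_spec <- !is.null(cfg$cohort_spec)
  has_file <- !is.null(cfg$cohort_file)
  if (has_spec == has_file)
    stopf("config must contain exactly one of 'cohort_spec' or 'cohort_file'")
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  cfg$out_dir <- cfg$out_dir %||% "hapselect_out"
  b <- cfg$binning %||% list()
  cfg$binning <- binning_config(
    threshold = b$threshold %||% 0.80,
    manual_representatives = b$manual_representatives,
    max_representatives_per_bin = b$max_representatives_per_bin %||% 1L)
  pr <- cfg$priors %||% list()
  cfg$priors <- prior_spec(
    covariate_variance = pr$covariate_variance %||% 10,
    slab_variance = pr$slab_variance %||% 10,
    spike_variance = pr$spike_variance %||% 0.001,
    inclusion_prob = pr$inclusion_prob %||% 0.25,
    sigma_bounds = pr$sigma_bounds %||% c(0, 3))
  mc <- cfg$mcmc %||% list()
  cfg$mcmc <- list(n_chains = mc$n_chains %||% 2L,
                   n_iter = mc$n_iter %||% 10000L,
                   burn_in = mc$burn_in %||% 0.5)
  md <- cfg$mode %||% list()
  cfg$mode <- list(exposure = md$exposure %||% "categorical",
                   selection = isTRUE(md$selection %||% TRUE))
  if (!cfg$mode$exposure %in% c("categorical", "continuous"))
    stopf("mode$exposure must be 'categorical' or 'continuous'")
  cfg$stages <- cfg$stages %||%
    c("cohort", "prep", "describe", "fit_single", "ssvs", "select", "joint")
  if (has_spec) cfg$cohort_spec <- cohort_spec_from_list(cfg$cohort_spec)
  class(cfg) <- "run_config"
  cfg
}

# build a cohort_spec from the parsed JSON representation
cohort_spec_from_list <- function(l) {
  haps <- lapply(seq_len(NROW(l$haps)), function(i) {
    h <- if (is.data.frame(l$haps)) as.list(l$haps[i, ]) else l$haps[[i]]
    hap_spec(h$name, h$median, h$dispersion,
             block_id = if (!is.null(h$block_id) && !is.na(h$block_id))
               h$block_id else NULL,
             target_rho = h$target_rho %||% 0,
             log_or_medium = h$log_or_medium %||% 0,
             log_or_high = h$log_or_high %||% 0)
  })
  covs <- lapply(l$covariates, function(cv)
    covariate_spec(cv$name, cv$levels, cv$probs, cv$log_or))
  if (!is.null(l$use_default_covariates) && isTRUE(l$use_default_covariates))
    covs <- table3_covariate_specs()
  cohort_spec(n_cases = l$n_cases, n_controls = l$n_controls,
              n_tracts = l$n_tracts, tract_sd = l$tract_sd %||% 0.3,
              baseline_logit = l$baseline_logit %||% qlogis(0.03),
              hap_specs = haps, covariate_specs = covs,
              match_var = l$match_var %||%
                (if (length(covs)) covs[[1L]]$name else NULL),
              seed = l$seed %||% 1L)
}

#' Run the full analysis pipeline from one configuration
#'
#' Stages, in order: cohort (simulate or read), prep (categorization
#' cutoffs, Spearman matrix, correlation binning with representatives),
#' describe (case/control characteristics with chi-square p-values),
#' fit_single (one hierarchical model per retained pollutant), ssvs
#' (joint spike-and-slab search), select (Bayes factor > 1 with the
#' either-level rule), joint (final model over the selected
#' pollutants). Every intermediate is persisted under `out_dir` and a
#' manifest records the config hash, seeds, versions, and per-stage
#' convergence. A stage failure aborts with the stage name; outputs of
#' completed stages remain on disk.
#'
#' @param config a `run_config`, or a path to a JSON config file.
#' @return the manifest (invisibly).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  if (!inherits(config, "run_config")) config <- validate_run_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)
  stage_seeds <- derive_seeds(config$seed, 8L)
  manifest <- list(package_version = as.character(packageVersion("hapselect")),
                   r_version = as.character(getRversion()),
                   seed = config$seed, stage_seeds = stage_seeds,
                   config_hash = config$config_hash %||% NA_character_,
                   started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                   mcmc = config$mcmc, mode = config$mode,
                   stages = list())
  st <- function(name, expr) {
    if (!name %in% config$stages) return(NULL)
    tryCatch(expr, error = function(e)
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  }
  mk_settings <- function(seed)
    mcmc_settings(n_chains = config$mcmc$n_chains,
                  n_iter = config$mcmc$n_iter,
                  burn_in = config$mcmc$burn_in, seed = seed)
  log_mcmc <- function(stage, conv) {
    message(sprintf(
      "[%s] chains %d x %d iterations, burn-in %.0f%%, convergence correlation %s",
      stage, config$mcmc$n_chains, config$mcmc$n_iter,
      100 * config$mcmc$burn_in,
      if (is.null(conv) || !isTRUE(conv$assessable)) "n/a"
      else sprintf("%.4f", conv$correlation)))
    if (is.null(conv)) NULL else
      list(correlation = conv$correlation, pass = conv$pass)
  }

  # --- cohort -------------------------------------------------------------
  cohort <- st("cohort", {
    ch <- if (!is.null(cfg_file <- config$cohort_file))
      read_cohort(cfg_file)
    else simulate_cohort(config$cohort_spec, seed = stage_seeds[1L])
    write_cohort(ch, out("cohort.tsv"))
    message(sprintf("[cohort] %d subjects (%d cases / %d controls)",
                    nrow(ch), sum(ch$case == 1L), sum(ch$case == 0L)))
    ch
  })
  if (is.null(cohort)) stopf("the 'cohort' stage cannot be skipped")
  haps_all <- attr(cohort, "hap_names")
  adjust <- config$covariates_adjust %||% attr(cohort, "covariate_names")

  # --- prep ---------------------------------------------------------------
  categ <- NULL; retained <- haps_all
  prep <- st("prep", {
    categ <- categorize_cohort(cohort)
    cuts <- data.frame(hap = names(categ),
                       cutoff_low = vapply(categ, `[[`, 0, "cutoff_low"),
                       cutoff_high = vapply(categ, `[[`, 0, "cutoff_high"),
                       row.names = NULL)
    write.table(cuts, out("cutoffs.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    rho <- spearman_matrix(as.matrix(cohort[, haps_all, drop = FALSE]))
    write_corr_matrix(rho, out("spearman.tsv"))
    bins <- bin_and_select(rho, config$binning)
    write_bins_json(bins, out("bins.json"))
    message(sprintf("[prep] %d HAPs -> %d bins -> %d retained",
                    length(haps_all), length(bins$bins),
                    length(bins$retained)))
    list(categ = categ, bins = bins)
  })
  if (!is.null(prep)) { categ <- prep$categ; retained <- prep$bins$retained }
  if (is.null(categ) && config$mode$exposure == "categorical")
    categ <- categorize_cohort(cohort)
  manifest$retained_haps <- retained

  # --- describe -----------------------------------------------------------
  st("describe", {
    desc <- describe_cohort(cohort)
    write.table(desc, out("characteristics.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  })

  # --- fit_single ---------------------------------------------------------
  st("fit_single", {
    hap_seeds <- derive_seeds(stage_seeds[2L], length(retained))
    singles <- lapply(seq_along(retained), function(i) {
      f <- fit_single_pollutant(cohort, retained[i], covariates = adjust,
                                priors = config$priors,
                                settings = mk_settings(hap_seeds[i]),
                                categorization = categ,
                                exposure_mode = config$mode$exposure)
      conv <- log_mcmc(paste0("fit_single:", retained[i]), f$convergence)
      cbind(f$summary, hap = retained[i],
            conv_correlation = conv$correlation %||% NA_real_)
    })
    tab <- do.call(rbind, singles)
    jsonlite::write_json(tab, out("single_pollutant.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    manifest$stages$fit_single <- list(n_models = length(retained))
  })

  # --- ssvs / select / joint ---------------------------------------------
  selected <- retained
  if (config$mode$selection) {
    bf <- st("ssvs", {
      sfit <- sample_ssvs(cohort, retained, covariates = adjust,
                          priors = config$priors,
                          settings = mk_settings(stage_seeds[3L]),
                          categorization = categ,
                          exposure_mode = config$mode$exposure)
      conv <- if (config$mcmc$n_chains >= 2L) check_convergence(sfit)
      manifest$stages$ssvs <- log_mcmc("ssvs", conv)
      ssvs_bayes_factors(sfit)
    })
    if (!is.null(bf)) {
      selected <- st("select", {
        sel <- select_final(bf)
        write_selection_json(bf, sel, out("selection.json"))
        message(sprintf("[select] %d HAP(s) with BF > 1: %s",
                        length(sel),
                        if (length(sel)) paste(sel, collapse = ", ")
                        else "<none>"))
        sel
      }) %||% selected
    }
  }
  st("joint", {
    jfit <- fit_final_joint(cohort, selected, covariates = adjust,
                            priors = config$priors,
                            settings = mk_settings(stage_seeds[4L]),
                            categorization = categ,
                            exposure_mode = config$mode$exposure)
    manifest$stages$joint <- log_mcmc("joint", jfit$convergence)
    if (is.null(jfit$summary)) {
      jsonlite::write_json(list(message = jfit$message), out("final_model.json"),
                           auto_unbox = TRUE, pretty = TRUE)
    } else {
      jsonlite::write_json(jfit$summary, out("final_model.json"),
                           auto_unbox = TRUE, pretty = TRUE, digits = NA)
      write_final_table(jfit, categ, cohort, out("final_model.txt"))
    }
  })

  manifest$selected_haps <- selected
  manifest$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(manifest)
}

# human-readable final table: level, range, counts, OR, CI (per pollutant)
write_final_table <- function(jfit, categ, cohort, path) {
  lines <- c(sprintf("%-28s %-8s %-22s %-14s %-8s %s",
                     "pollutant", "level", "range (ug/m3)",
                     "cases/controls", "OR", "95% CI"))
  for (h in jfit$selected) {
    ct <- categ[[h]]
    if (is.null(ct)) next
    tab <- table(ct$category, factor(cohort$case, levels = c(0L, 1L)))
    rng <- c(low = sprintf("< %.3g", ct$cutoff_low),
             medium = sprintf("%.3g - %.3g", ct$cutoff_low, ct$cutoff_high),
             high = sprintf("> %.3g", ct$cutoff_high))
    for (lv in c("low", "medium", "high")) {
      row <- jfit$summary[jfit$summary$term == paste0(h, ":", lv), ]
      or_txt <- if (lv == "low") "1.00" else sprintf("%.2f", row$or)
      ci_txt <- if (lv == "low") "Ref." else
        sprintf("(%.2f, %.2f)", row$ci_low, row$ci_high)
      lines <- c(lines, sprintf("%-28s %-8s %-22s %-14s %-8s %s",
                                h, lv, rng[lv],
                                sprintf("%d/%d", tab[lv, "1"], tab[lv, "0"]),
                                or_txt, ci_txt))
    }
  }
  writeLines(lines, path)
  invisible(path)
}
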