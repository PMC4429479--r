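#' Packaged fixtures
#'
#' Small plain-text data shipped with the package:
#' \describe{
#'   \item{`table1_distributions`}{distributional characteristics (mean,
#'     median, 5th/25th/75th/95th percentiles, ug/m3) of 32 EPA-priority
#'     HAPs from 1999 census-tract model estimates for Texas.}
#'   \item{`table2_correlations`}{12 x 12 Spearman correlation matrix of
#'     the highly correlated HAPs; entries not reported in the source
#'     table are stored as 0 (they are below the 0.80 binning
#'     threshold).}
#'   \item{`table2_representatives`}{the subject-matter representative
#'     choices for the four bins, keyed by bin seed.}
#'   \item{`table3_characteristics`}{case/control covariate counts with
#'     the published p-values.}
#'   \item{`table4_ssvs`}{published final-model rows: category cutoffs,
#'     case/control counts, adjusted ORs, credible intervals and Bayes
#'     factors for the two selected pollutants.}
#'   \item{`demo_config`}{a small end-to-end pipeline configuration.}
#' }
#'
#' @param name one of the fixture names above.
#' @return a data.frame, list, or matrix depending on the fixture.
#' @export
hap_fixture <- function(name = c("table1_distributions",
                                 "table2_correlations",
                                 "table2_representatives",
                                 "table3_characteristics",
                                 "table4_ssvs", "demo_config")) {
  name <- match.arg(name)
  path <- function(f) system.file("extdata", f, package = "hapselect",
                                  mustWork = TRUE)
  switch(name,
    table1_distributions =
      read.delim(path("table1_distributions.tsv"), check.names = TRUE,
                 stringsAsFactors = FALSE),
    table2_correlations = read_corr_matrix(path("table2_correlations.tsv")),
    table2_representatives =
      lapply(jsonlite::read_json(path("table2_representatives.json")),
             function(x) unlist(x)),
    table3_characteristics =
      read.delim(path("table3_characteristics.tsv"),
                 stringsAsFactors = FALSE),
    table4_ssvs = read.delim(path("table4_ssvs.tsv"),
                             stringsAsFactors = FALSE),
    demo_config = jsonlite::read_json(path("demo_config.json"),
                                      simplifyVector = TRUE))
}
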