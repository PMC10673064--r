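#' Reference ranking statistics from the published resection cohort
#'
#' Per-variable summary statistics reported for a published cohort of 371
#' patients after a first curative-intent liver resection for colorectal
#' liver metastases: counts at the unfavorable level, log-rank chi-square
#' and p, the integral between Kaplan-Meier curves (months), univariate and
#' multivariate Cox hazard ratios with 95% confidence limits, and the rank
#' each method assigned.  The underlying patient-level data are confidential
#' and not redistributable; these published summaries are the fixture the
#' ranking rules are validated against and the source of the study-like
#' simulation's prevalences and effect sizes (see [study_config()]).
#'
#' p-values reported only as "< 0.001" are stored as 0.0005; p enters the
#' ranking solely as a tie-break and every such row has a distinct primary
#' statistic, so the placeholder never decides a rank.
#'
#' @return data frame with one row per prognostic variable; columns
#'   `variable`, `label`, `n_unfavorable`, `n_total`, `chi_square`,
#'   `logrank_p`, `km_rank`, `is_months`, `is_rank`, `uni_p`, `uni_hr`,
#'   `uni_lo`, `uni_hi`, `uni_rank`, `multi_p`, `multi_hr`, `multi_lo`,
#'   `multi_hi`, `multi_rank`, `final_rank`.
#' @examples
#' ref <- reference_ranking()
#' ref[ref$variable == "crp", c("chi_square", "is_months", "multi_hr")]
#' @export
reference_ranking <- function() {
  path <- system.file("extdata", "reference_ranking_stats.csv",
                      package = "survrank", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
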