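#' Render the ranking report
#'
#' Produces the human-readable report for a [rank_factors()] result:
#' (i) a Kaplan-Meier block (count and percent unfavorable, chi-square, p,
#' rank; integral IS and its rank), (ii) a Cox block (univariate and
#' multivariate p, hazard ratio, 95% CI and ranks), and (iii) the rank
#' summary across all methods.  Percentages are half-away-from-zero to one
#' decimal, hazard ratios to 2 decimals (3 below 1), p-values to 3
#' decimals with `<0.001` formatting.  Output is deterministic: the same
#' ranking renders byte-identically.
#'
#' @param ranking a [rank_factors()] result.
#' @param path optional file to write the report to.
#' @param sep field separator for the tabular blocks.
#' @return character vector of report lines, invisibly when `path` is
#'   given.
#' @export
render_report <- function(ranking, path = NULL, sep = "\t") {
  stopifnot(inherits(ranking, "factor_ranking"))
  tab <- ranking$table
  s <- ranking$summaries

  n_pct <- vapply(tab$variable, function(v)
    sprintf("%d (%s%%)", s[[v]]$count,
            formatC(s[[v]]$pct, digits = 1L, format = "f")), character(1))

  join <- function(...) paste(..., sep = sep)
  block1 <- c(
    "# Kaplan-Meier analysis and integral IS",
    join("variable", "n_pct", "chi_square", "p", "rank_km", "is_months", "rank_is"),
    vapply(seq_len(nrow(tab)), function(i) join(
      tab$variable[i], n_pct[i],
      sprintf("%.1f", tab$chi_square[i]), format_p(tab$logrank_p[i]),
      tab$km_rank[i], sprintf("%.1f", tab$is_months[i]), tab$is_rank[i]),
      character(1)))

  block2 <- c(
    "# Univariate and multivariate Cox regression",
    join("variable", "uni_p", "uni_hr", "rank_uni",
         "multi_p", "multi_hr", "multi_ci", "rank_multi"),
    vapply(seq_len(nrow(tab)), function(i) {
      ci <- sprintf("%.1f-%.1f", ranking$multi$ci_lower[tab$variable[i]],
                    ranking$multi$ci_upper[tab$variable[i]])
      join(tab$variable[i],
           format_p(tab$uni_p[i]), format_hr(tab$uni_hr[i]), tab$uni_rank[i],
           format_p(tab$multi_p[i]), format_hr(tab$multi_hr[i]), ci,
           tab$multi_rank[i])
    }, character(1)))

  ord <- order(tab$final_rank)
  block3 <- c(
    sprintf("# Rank summary (final method: %s)", ranking$final_method),
    join("variable", "R1a_km", "R1b_is", "R2a_uni", "R2b_multi", "final"),
    vapply(ord, function(i) join(
      tab$variable[i], tab$km_rank[i], tab$is_rank[i],
      tab$uni_rank[i], tab$multi_rank[i], tab$final_rank[i]), character(1)))

  lines <- c(sprintf("Prognostic factor ranking: %d subjects, %d events",
                     ranking$n, ranking$n_events),
             "", block1, "", block2, "", block3)
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}
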