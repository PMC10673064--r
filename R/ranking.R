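#' Deterministic ranking of variables by a statistic
#'
#' Sorts by the primary value (descending means rank 1 = largest), breaks
#' ties by the smaller secondary value (typically the p-value), then
#' lexicographically by variable name, and assigns ranks 1..K by position —
#' always a permutation, always reproducible.
#'
#' @param values named numeric vector (>= 2 finite values).
#' @param direction `"desc"` (default: largest value gets rank 1) or
#'   `"asc"`.
#' @param tiebreak optional named numeric vector; smaller wins the better
#'   rank among primary ties.
#' @return named integer ranks.
#' @examples
#' rank_by(c(a = 1.14, b = 1.79, c = 1.14),
#'         tiebreak = c(a = 0.270, b = 0.001, c = 0.217))
#' @export
rank_by <- function(values, direction = c("desc", "asc"), tiebreak = NULL) {
  direction <- match.arg(direction)
  if (length(values) < 2L) fail("ranking needs at least 2 variables")
  if (is.null(names(values)) || any(!nzchar(names(values))))
    fail("values must be named")
  if (any(!is.finite(values))) fail("non-finite ranking value")
  nm <- names(values)
  tb <- if (is.null(tiebreak)) rep(0, length(values)) else {
    if (is.null(names(tiebreak))) fail("tiebreak must be named")
    unname(tiebreak[nm])
  }
  primary <- if (direction == "desc") -values else values
  ord <- order(primary, tb, nm)
  stats::setNames(order(ord), nm)[nm]
}

#' Assemble the four-method rank table
#'
#' Combines the per-variable statistics of the four ranking engines into
#' one table with their rank columns: `km_rank` by log-rank chi-square
#' (descending), `is_rank` by integral IS (descending), `uni_rank` by
#' univariate hazard ratio (descending) and `multi_rank` by multivariate
#' hazard ratio (descending), each tie-broken by the smaller p-value then
#' by name.
#'
#' @param km named list of [logrank_test()] results.
#' @param is_ named list of `is_result` objects (or named numeric IS
#'   months).
#' @param uni named list of single-covariate [fit_cox()] results.
#' @param multi one multivariate [fit_cox()] covering the same variables.
#' @return object of class `rank_table` (a data frame, one row per
#'   variable).
#' @export
build_rank_table <- function(km, is_, uni, multi) {
  vars <- names(km)
  if (is.null(vars)) fail("inputs must be named by variable")
  same <- function(x) setequal(names(x), vars)
  if (!same(is_) || !same(uni) || !setequal(names(multi$coefficients), vars))
    fail("variable sets differ across the four inputs")

  chi <- vapply(km, function(r) r$chi_square, numeric(1))[vars]
  km_p <- vapply(km, function(r) r$p_value, numeric(1))[vars]
  ism <- if (is.list(is_) && inherits(is_[[1L]], "is_result"))
    vapply(is_, function(r) r$is_months, numeric(1))[vars]
  else unlist(is_)[vars]
  uni_hr <- vapply(uni, function(f) unname(f$hr), numeric(1))[vars]
  uni_p <- vapply(uni, function(f) unname(f$p_value), numeric(1))[vars]
  multi_hr <- multi$hr[vars]
  multi_p <- multi$p_value[vars]

  tab <- data.frame(variable = vars,
                    chi_square = chi, logrank_p = km_p,
                    is_months = ism,
                    uni_hr = uni_hr, uni_p = uni_p,
                    multi_hr = multi_hr, multi_p = multi_p,
                    km_rank = rank_by(stats::setNames(chi, vars),
                                      tiebreak = stats::setNames(km_p, vars)),
                    is_rank = rank_by(stats::setNames(ism, vars),
                                      tiebreak = stats::setNames(km_p, vars)),
                    uni_rank = rank_by(stats::setNames(uni_hr, vars),
                                       tiebreak = stats::setNames(uni_p, vars)),
                    multi_rank = rank_by(stats::setNames(multi_hr, vars),
                                         tiebreak = stats::setNames(multi_p, vars)),
                    row.names = NULL)
  structure(tab, class = c("rank_table", "data.frame"))
}

#' Final aggregated ranking
#'
#' The default rule orders variables by the multivariate Cox rank, which
#' reflects each variable's behaviour with all others held in the model.
#' The alternative `"mean_is_multivariate"` blends the IS rank and the
#' multivariate rank (their mean, ties resolved by the multivariate rank):
#' IS quantifies each variable's impact on survival while resolving
#' overlapping curves, and the multivariate fit supplies the adjusted
#' effect.
#'
#' @param table a [build_rank_table()] result.
#' @param method `"multivariate"` (default) or `"mean_is_multivariate"`.
#' @return named integer final ranks (permutation of 1..K).
#' @export
final_ranking <- function(table, method = c("multivariate",
                                            "mean_is_multivariate")) {
  method <- match.arg(method)
  vars <- table$variable
  if (method == "multivariate") {
    ranks <- stats::setNames(table$multi_rank, vars)
  } else {
    blend <- stats::setNames((table$is_rank + table$multi_rank) / 2, vars)
    ranks <- rank_by(-blend, direction = "desc",
                     tiebreak = stats::setNames(table$multi_rank, vars))
  }
  ranks[vars]
}

#' Rank prognostic factors of a cohort
#'
#' The end-to-end pipeline: for each binary factor it runs the four
#' ranking engines — (1) Kaplan-Meier curves compared by the log-rank
#' chi-square, (2) the integral IS between the two curves, (3) a
#' univariate Cox fit, (4) one multivariate Cox fit with all factors
#' entered simultaneously — then aggregates the four rank columns into the
#' final ranking.
#'
#' @param cohort a [cohort][as_cohort] object.
#' @param factors names of binary covariates to rank (default: every 0/1
#'   covariate column).
#' @param tmax IS horizon per factor, or `"auto"` (see [is_integral()]).
#' @param ties Cox tie handling.
#' @param final_method final aggregation rule, see [final_ranking()].
#' @return object of class `factor_ranking`: the `rank_table` (with a
#'   `final_rank` column), the per-factor engine results (`km`, `is`,
#'   `uni`), the `multi` fit, factor summaries, and the call.
#' @examples
#' co <- generate_cohort(study_config(seed = 11))
#' r <- rank_factors(co)
#' print(r)
#' @export
rank_factors <- function(cohort, factors = NULL, tmax = "auto",
                         ties = c("breslow", "efron"),
                         final_method = c("multivariate",
                                          "mean_is_multivariate")) {
  ties <- match.arg(ties)
  final_method <- match.arg(final_method)
  if (is.null(factors)) {
    covars <- setdiff(names(cohort), c("subject_id", "time", "event"))
    factors <- covars[vapply(covars, function(v)
      all(cohort[[v]] %in% c(0, 1)), logical(1))]
  }
  if (length(factors) < 2L) fail("ranking needs at least 2 binary factors")

  km <- stats::setNames(lapply(factors, logrank_factor, cohort = cohort), factors)
  is_ <- stats::setNames(lapply(factors, is_factor, cohort = cohort,
                                tmax = tmax), factors)
  uni <- univariate_screen(cohort, factors, ties = ties)
  failed <- vapply(uni, inherits, logical(1), "cox_fit_error")
  if (any(failed))
    fail("univariate fit failed for: %s",
         paste(factors[failed], collapse = ", "))
  multi <- fit_cox(cohort, factors, ties = ties)

  tab <- build_rank_table(km, is_, uni, multi)
  tab$final_rank <- final_ranking(tab, final_method)
  summaries <- lapply(stats::setNames(factors, factors),
                      function(f) summarize_factor(cohort, f))
  structure(list(table = tab, km = km, is = is_, uni = uni, multi = multi,
                 summaries = summaries, final_method = final_method,
                 n = nrow(cohort), n_events = sum(cohort$event),
                 call = match.call()),
            class = "factor_ranking")
}

#' @export
print.factor_ranking <- function(x, ...) {
  cat(sprintf("Prognostic factor ranking: %d subjects, %d events, %d factors\n",
              x$n, x$n_events, nrow(x$table)))
  if (!x$multi$converged)
    cat("  warning: multivariate Cox fit did not converge\n")
  tab <- x$table[order(x$table$final_rank), ]
  out <- data.frame(variable = tab$variable,
                    `chi2` = sprintf("%.1f", tab$chi_square),
                    `IS.months` = sprintf("%.1f", tab$is_months),
                    `uni.HR` = format_hr(tab$uni_hr),
                    `multi.HR` = format_hr(tab$multi_hr),
                    `p.multi` = format_p(tab$multi_p),
                    R1a = tab$km_rank, R1b = tab$is_rank,
                    R2a = tab$uni_rank, R2b = tab$multi_rank,
                    final = tab$final_rank, check.names = FALSE)
  print(out, row.names = FALSE)
  invisible(x)
}

#' @export
summary.factor_ranking <- function(object, ...) object$table

#' Plot the per-method ranks
#'
#' One line per variable across the four ranking methods and the final
#' rank, mirroring the usual rank-summary figure.
#'
#' @param x a `factor_ranking`.
#' @param ... passed to [graphics::matplot()].
#' @return `x` invisibly.
#' @export
plot.factor_ranking <- function(x, ...) {
  tab <- x$table[order(x$table$final_rank), ]
  m <- t(as.matrix(tab[, c("km_rank", "is_rank", "uni_rank", "multi_rank",
                           "final_rank")]))
  graphics::matplot(m, type = "b", lty = 1, pch = 19, xaxt = "n",
                    xlab = "Ranking method", ylab = "Rank (1 = best)",
                    ylim = rev(range(m)), ...)
  graphics::axis(1, at = 1:5, labels = c("R1a", "R1b", "R2a", "R2b", "final"))
  graphics::legend("bottomleft", legend = tab$variable, col = seq_len(ncol(m)),
                   lty = 1, pch = 19, cex = 0.7, bty = "n")
  invisible(x)
}
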