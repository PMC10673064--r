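#' Kaplan-Meier product-limit estimate
#'
#' Estimates the survival function S(t) from right-censored follow-up
#' without assuming an underlying distribution:
#' `S(t) = prod over event times t_i <= t of (1 - d_i / r_i)`, where d_i
#' subjects die at t_i out of r_i at risk.  Subjects censored at an event
#' time are counted in the risk set for that time (events before
#' censorings, the standard tie convention) and leave afterwards.
#'
#' @param time positive follow-up times in months.
#' @param event 0/1 event indicators (1 = death observed).
#' @return object of class `km_curve` with components
#'   \describe{
#'     \item{time, surv}{distinct event times and S(t) just after each;
#'       S(0) = 1 is implicit.}
#'     \item{n_risk, n_event, n_censor}{per event time counts.}
#'     \item{table}{life table over all distinct observed times (events and
#'       censorings) with survival and Greenwood variance.}
#'     \item{n, n_events, max_time}{totals and last observed time.}
#'   }
#' @examples
#' km <- fit_km(c(5, 8, 12), c(1, 0, 1))
#' survival_at(km, 7)   # 2/3
#' @export
fit_km <- function(time, event) {
  check_times(time)
  event <- check_events(event)
  if (length(time) != length(event)) fail("time and event lengths differ")
  n <- length(time)

  ord <- order(time)
  rl <- rle(time[ord])
  ut <- rl$values
  ends <- cumsum(rl$lengths)
  d <- diff(c(0, cumsum(event[ord])[ends]))   # events per distinct time
  cns <- rl$lengths - d                        # censorings per distinct time
  # at risk just before each distinct time
  r <- n - c(0, ends)[seq_along(ut)]

  frac <- ifelse(d > 0, 1 - d / r, 1)
  surv <- cumprod(frac)
  gw_terms <- ifelse(d > 0 & r > d, d / (r * (r - d)),
                     ifelse(d > 0, NA_real_, 0))  # NA when S hits 0
  gw <- cumsum(ifelse(is.na(gw_terms), 0, gw_terms))
  gw[cumsum(is.na(gw_terms)) > 0] <- NA_real_

  tab <- data.frame(time = ut, n_risk = r, n_event = d, n_censor = cns,
                    surv = surv, greenwood = gw)
  ev <- d > 0
  structure(list(time = ut[ev], surv = surv[ev],
                 n_risk = r[ev], n_event = d[ev], n_censor = cns[ev],
                 table = tab, n = n, n_events = sum(d),
                 max_time = max(time)),
            class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("Kaplan-Meier curve: n = %d, events = %d, last follow-up %.1f months\n",
              x$n, x$n_events, x$max_time))
  med <- median_survival(x)
  if (med$defined)
    cat(sprintf("Median survival %.1f months (95%% CI %.1f-%.1f)\n",
                med$median, med$ci_lower, med$ci_upper))
  else cat("Median survival not reached\n")
  invisible(x)
}

#' @export
summary.km_curve <- function(object, ...) {
  object$table
}

#' Plot a Kaplan-Meier curve
#'
#' @param x a `km_curve`.
#' @param add logical; add to an existing plot.
#' @param ... passed to [graphics::lines()] / [graphics::plot()].
#' @return `x` invisibly.
#' @export
plot.km_curve <- function(x, add = FALSE, ...) {
  tt <- c(0, rep(x$time, each = 2), x$max_time)
  ss <- c(1, 1, rep(x$surv, each = 2))
  if (!add)
    graphics::plot(tt, ss, type = "l", xlab = "Months", ylab = "S(t)",
                   ylim = c(0, 1), ...)
  else graphics::lines(tt, ss, ...)
  invisible(x)
}

#' Evaluate S(t) at arbitrary times
#'
#' Right-continuous step evaluation: the value at an event time is the
#' post-jump value.  Beyond the last observed follow-up the last value is
#' carried forward and the result carries an `extrapolated` attribute.
#'
#' @param curve a `km_curve`.
#' @param t non-negative time(s) in months.
#' @return survival probabilities, with attribute `extrapolated` (logical
#'   vector) flagging times past the last observed follow-up.
#' @export
survival_at <- function(curve, t) {
  stopifnot(inherits(curve, "km_curve"))
  if (any(t < 0)) fail("t must be non-negative")
  idx <- findInterval(t, curve$time)
  out <- c(1, curve$surv)[idx + 1L]
  attr(out, "extrapolated") <- t > curve$max_time
  out
}

#' Median survival with Brookmeyer-Crowley confidence interval
#'
#' The median is the smallest observed time with S(t) <= 0.5.  The
#' confidence interval inverts the pointwise interval for S(t) on the
#' log(-log) scale with Greenwood variance: each confidence-limit curve is
#' read off with the same smallest-time rule.
#'
#' @param curve a `km_curve` from at least 2 subjects.
#' @param ci_level confidence level (default 0.95).
#' @return list with `median`, `ci_lower`, `ci_upper` (months, `NA` where
#'   the corresponding curve never crosses 0.5) and `defined` (FALSE when
#'   S(t) never reaches 0.5, a flagged result rather than an error).
#' @export
median_survival <- function(curve, ci_level = 0.95) {
  stopifnot(inherits(curve, "km_curve"))
  tt <- curve$table$time
  ss <- curve$table$surv
  gw <- curve$table$greenwood

  first_below <- function(s) {
    i <- which(!is.na(s) & s <= 0.5 + 1e-12)
    if (length(i)) tt[min(i)] else NA_real_
  }
  med <- first_below(ss)
  if (is.na(med))
    return(list(median = NA_real_, ci_lower = NA_real_, ci_upper = NA_real_,
                defined = FALSE))

  z <- stats::qnorm(1 - (1 - ci_level) / 2)
  interior <- !is.na(gw) & ss > 0 & ss < 1
  se_ll <- rep(NA_real_, length(ss))
  se_ll[interior] <- sqrt(gw[interior]) / abs(log(ss[interior]))
  lower_cl <- ifelse(interior, ss^exp(z * se_ll), ifelse(ss == 0, 0, NA_real_))
  upper_cl <- ifelse(interior, ss^exp(-z * se_ll), ifelse(ss == 0, 0, NA_real_))

  list(median = med,
       ci_lower = first_below(lower_cl),
       ci_upper = first_below(upper_cl),
       defined = TRUE)
}

#' Two-sample log-rank test
#'
#' At each distinct event time the expected number of events in group A is
#' the hypergeometric mean `d_j n_Aj / n_j` and the variance the
#' hypergeometric variance; the chi-square statistic is
#' `(sum(O - E))^2 / sum(V)` on 1 degree of freedom.
#'
#' @param time_a,event_a follow-up and event indicator for group A.
#' @param time_b,event_b follow-up and event indicator for group B.
#' @return object of class `logrank_test`: `chi_square`, `df`, `p_value`,
#'   `observed` and `expected` event counts per group, `variance`, and
#'   `defined` (FALSE when no events occur so the statistic is undefined —
#'   flagged, not an error).
#' @examples
#' lr <- logrank_test(c(1, 3, 5), c(1, 1, 1), c(2, 4, 6), c(1, 1, 1))
#' lr$chi_square
#' @export
logrank_test <- function(time_a, event_a, time_b, event_b) {
  check_times(time_a, "group A time"); check_times(time_b, "group B time")
  event_a <- check_events(event_a); event_b <- check_events(event_b)
  if (length(time_a) == 0L || length(time_b) == 0L)
    fail("both groups must be non-empty")

  time <- c(time_a, time_b)
  event <- c(event_a, event_b)
  grp <- rep(c(1L, 2L), c(length(time_a), length(time_b)))

  et <- sort(unique(time[event == 1]))
  if (length(et) == 0L)
    return(structure(list(chi_square = NA_real_, df = 1L, p_value = NA_real_,
                          observed = c(A = 0, B = 0), expected = c(A = 0, B = 0),
                          variance = 0, defined = FALSE),
                     class = "logrank_test"))

  st <- sort(time)
  sa <- sort(time_a)
  n_j <- length(time) - findInterval(et, st, left.open = TRUE)
  n_aj <- length(time_a) - findInterval(et, sa, left.open = TRUE)

  count_at <- function(keys) {        # events per distinct event time
    if (length(keys) == 0L) return(numeric(length(et)))
    tab <- rle(sort(keys))
    out <- numeric(length(et))
    out[match(tab$values, et)] <- tab$lengths
    out
  }
  d_j <- count_at(time[event == 1])
  d_aj <- count_at(time_a[event_a == 1])

  e_aj <- d_j * n_aj / n_j
  v_j <- ifelse(n_j > 1,
                d_j * (n_aj / n_j) * (1 - n_aj / n_j) * (n_j - d_j) / (n_j - 1),
                0)

  O <- c(A = sum(d_aj), B = sum(d_j - d_aj))
  E <- c(A = sum(e_aj), B = sum(d_j - e_aj))
  V <- sum(v_j)
  chi <- if (V > 0) (O[["A"]] - E[["A"]])^2 / V else 0
  structure(list(chi_square = unname(chi), df = 1L,
                 p_value = stats::pchisq(chi, 1L, lower.tail = FALSE),
                 observed = O, expected = E, variance = V, defined = TRUE),
            class = "logrank_test")
}

#' @export
print.logrank_test <- function(x, ...) {
  if (!x$defined) {
    cat("Log-rank test: no events observed; statistic undefined\n")
    return(invisible(x))
  }
  cat("Two-sample log-rank test\n")
  cat(sprintf("  Observed events: A = %g, B = %g; expected: A = %.2f, B = %.2f\n",
              x$observed[1], x$observed[2], x$expected[1], x$expected[2]))
  cat(sprintf("  Chi-square = %.3f on %d df, p = %s\n",
              x$chi_square, x$df, format_p(x$p_value)))
  invisible(x)
}

#' Log-rank test of a binary factor within a cohort
#'
#' Convenience wrapper: group A is the favorable level (coded 0), group B
#' the unfavorable level (coded 1).
#'
#' @param cohort a [cohort][as_cohort] object.
#' @param factor name of a binary covariate.
#' @return a [logrank_test()] result.
#' @export
logrank_factor <- function(cohort, factor) {
  x <- cohort[[factor]]
  if (is.null(x)) fail("no covariate named `%s`", factor)
  if (!all(x %in% c(0, 1))) fail("covariate `%s` is not binary 0/1", factor)
  if (min(table(factor(x, levels = c(0, 1)))) < 2L)
    fail("each level of `%s` needs at least 2 subjects", factor)
  logrank_test(cohort$time[x == 0], cohort$event[x == 0],
               cohort$time[x == 1], cohort$event[x == 1])
}
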