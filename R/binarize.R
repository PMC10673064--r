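#' Define a binary prognostic factor
#'
#' A binary factor is a named cut rule turning a continuous marker into a
#' 0/1 covariate, with 1 always the unfavorable level.
#'
#' @param name variable name.
#' @param rule one of `"threshold_ge"`, `"threshold_le"`, `"median_ge"`,
#'   `"median_le"`.
#' @param cutpoint cut value in covariate units; for median rules it is
#'   filled in from the data by [binarize_median()] / [apply_factors()].
#' @param unfavorable_level text describing which side codes 1; derived from
#'   the rule if omitted.
#' @return object of class `binary_factor`.
#' @export
binary_factor <- function(name, rule, cutpoint = NA_real_,
                          unfavorable_level = NULL) {
  rule <- match.arg(rule, c("threshold_ge", "threshold_le", "median_ge", "median_le"))
  if (grepl("^threshold", rule) && !is.finite(cutpoint))
    fail("rule `%s` requires a finite cutpoint", rule)
  if (is.null(unfavorable_level)) {
    op <- if (grepl("ge$", rule)) ">=" else "<="
    unfavorable_level <- if (is.finite(cutpoint))
      sprintf("%s %s %g", name, op, cutpoint)
    else sprintf("%s %s median", name, op)
  }
  structure(list(name = name, rule = rule, cutpoint = cutpoint,
                 unfavorable_level = unfavorable_level),
            class = "binary_factor")
}

#' @export
print.binary_factor <- function(x, ...) {
  cat(sprintf("Binary factor `%s`: rule %s, cutpoint %s (1 = %s)\n",
              x$name, x$rule,
              if (is.finite(x$cutpoint)) format(x$cutpoint) else "<from data>",
              x$unfavorable_level))
  invisible(x)
}

#' Binarize against a fixed threshold
#'
#' Codes each value 1 (unfavorable) or 0 (favorable) against a laboratory
#' reference threshold: under `"ge"` a value is unfavorable when it is at or
#' above the cutpoint (e.g. C-reactive protein >= 6 mg/L), under `"le"` when
#' at or below (e.g. albumin <= 38 g/L).  Values exactly at the cutpoint
#' take the unfavorable side under either direction.
#'
#' @param values numeric vector, all finite.
#' @param cutpoint finite cut value in the marker's units.
#' @param direction `"ge"` or `"le"`.
#' @return integer vector of 0/1 assignments.
#' @examples
#' binarize_threshold(c(5.9, 6.0, 6.1), 6, "ge")  # 0 1 1
#' binarize_threshold(c(38, 38.1), 38, "le")      # 1 0
#' @export
binarize_threshold <- function(values, cutpoint, direction = c("ge", "le")) {
  direction <- match.arg(direction)
  bad <- which(!is.finite(values))
  if (length(bad))
    fail("non-finite value at position(s) %s",
         paste(utils::head(bad, 10L), collapse = ", "))
  if (!is.finite(cutpoint)) fail("cutpoint must be finite")
  as.integer(if (direction == "ge") values >= cutpoint else values <= cutpoint)
}

#' Binarize at the sample median
#'
#' For markers with no laboratory reference range the cohort median is used
#' as the cutpoint (even n: mean of the two central order statistics).
#' Values equal to the median take the ">=" side, so ties are unfavorable
#' under `"ge"`.
#'
#' @param values numeric vector of at least 2 finite values, not all equal.
#' @param direction `"ge"` or `"le"`; which side of the median is
#'   unfavorable.
#' @param name variable name recorded in the returned rule.
#' @return list with `factor` (a [binary_factor()] carrying the realised
#'   cutpoint) and `assignment` (integer 0/1 vector).
#' @examples
#' binarize_median(c(1, 2, 3, 4), "ge")$assignment  # 0 0 1 1
#' @export
binarize_median <- function(values, direction = c("ge", "le"), name = "x") {
  direction <- match.arg(direction)
  bad <- which(!is.finite(values))
  if (length(bad))
    fail("non-finite value at position(s) %s",
         paste(utils::head(bad, 10L), collapse = ", "))
  if (length(values) < 2L) fail("need at least 2 values to take a median")
  if (length(unique(values)) == 1L)
    fail("all values identical: a median split would leave one group empty")
  cut <- stats::median(values)
  assignment <- binarize_threshold(values, cut, direction)
  if (all(assignment == assignment[1L]))
    fail("median split is degenerate: one group is empty")
  list(factor = binary_factor(name, paste0("median_", direction), cut),
       assignment = assignment)
}

#' Apply binarization rules to a cohort
#'
#' Replaces (or adds) a 0/1 column per rule; median rules realise their
#' cutpoint from the cohort.  The applied rules are stored in the cohort's
#' `variables` attribute.
#'
#' @param cohort a [cohort][as_cohort] object.
#' @param factors list of [binary_factor()] definitions, or the path handled
#'   by [read_factor_config()].
#' @param suffix appended to source column names for the binary columns;
#'   `""` overwrites in place.
#' @return the cohort with binary columns and updated metadata.
#' @export
apply_factors <- function(cohort, factors, suffix = "") {
  if (is.character(factors) && length(factors) == 1L)
    factors <- read_factor_config(factors)
  meta <- list()
  for (f in factors) {
    stopifnot(inherits(f, "binary_factor"))
    if (!f$name %in% names(cohort)) fail("no covariate named `%s`", f$name)
    v <- cohort[[f$name]]
    out <- switch(f$rule,
      threshold_ge = binarize_threshold(v, f$cutpoint, "ge"),
      threshold_le = binarize_threshold(v, f$cutpoint, "le"),
      median_ge = , median_le = {
        dir <- sub("^median_", "", f$rule)
        b <- binarize_median(v, dir, f$name)
        f <- b$factor
        b$assignment
      })
    cohort[[paste0(f$name, suffix)]] <- out
    meta[[f$name]] <- f
  }
  attr(cohort, "variables") <- meta
  cohort
}

#' Read binarization rules from a key-value config file
#'
#' One rule per line, `name = rule [cutpoint]`, e.g.
#' \preformatted{
#' crp      = ge 6
#' albumin  = le 38
#' size     = median_ge
#' }
#' `ge`/`le` with a cutpoint are threshold rules; `median_ge`/`median_le`
#' take the cutpoint from the data.  Blank lines and `#` comments ignored.
#'
#' @param path path to the config file.
#' @return list of [binary_factor()] objects.
#' @export
read_factor_config <- function(path) {
  if (!file.exists(path)) fail("config file not found: %s", path)
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  lapply(lines, function(ln) {
    parts <- strsplit(ln, "=", fixed = TRUE)[[1L]]
    if (length(parts) != 2L) fail("cannot parse config line: %s", ln)
    name <- trimws(parts[1L])
    spec <- strsplit(trimws(parts[2L]), "[[:space:]]+")[[1L]]
    rule <- spec[1L]
    if (rule %in% c("ge", "le")) {
      if (length(spec) < 2L) fail("rule `%s` for `%s` needs a cutpoint", rule, name)
      binary_factor(name, paste0("threshold_", rule), as.numeric(spec[2L]))
    } else if (rule %in% c("median_ge", "median_le")) {
      binary_factor(name, rule)
    } else fail("unknown rule `%s` for `%s`", rule, name)
  })
}
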