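#' Construct a survival cohort
#'
#' A cohort is a validated data frame with one row per subject: a unique
#' `subject_id`, follow-up `time` in months, an `event` indicator (1 = death
#' observed, 0 = censored) and any number of covariate columns.  Binary
#' factors are coded 0 = favorable level, 1 = unfavorable level, so that
#' positive Cox coefficients always mean worse survival; continuous markers
#' keep their natural units (mg/L, g/L, cm).
#'
#' @param data a data frame with columns `subject_id`, `time`, `event` and
#'   covariates.
#' @param variables optional data frame of per-covariate metadata (columns
#'   `name`, `type`, `unit`, `rule`, `cutpoint`); assembled automatically by
#'   [apply_factors()] and [generate_cohort()].
#' @return an object of class `cohort` (a data frame).
#' @details Validation is strict: rows violating an invariant are reported
#'   with their row index, and missing covariate values are an error rather
#'   than being imputed.
#' @examples
#' d <- data.frame(subject_id = 1:3, time = c(12, 30, 45), event = c(1, 0, 1),
#'                 crp = c(2, 11, 7))
#' as_cohort(d)
#' @export
as_cohort <- function(data, variables = NULL) {
  if (!is.data.frame(data)) fail("`data` must be a data frame")
  needed <- c("subject_id", "time", "event")
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols))
    fail("mandatory column(s) missing: %s", paste(missing_cols, collapse = ", "))
  data <- as.data.frame(data)

  if (!is.numeric(data$time))
    fail("column `time` must be numeric")
  bad <- which(!is.finite(data$time) | data$time <= 0)
  if (length(bad))
    fail("invalid follow-up time (must be a positive number) on row(s) %s",
         paste(utils::head(bad, 10L), collapse = ", "))
  bad <- which(!(data$event %in% c(0, 1)))
  if (length(bad))
    fail("event indicator outside {0, 1} on row(s) %s",
         paste(utils::head(bad, 10L), collapse = ", "))
  data$event <- as.integer(data$event)
  dup <- which(duplicated(data$subject_id))
  if (length(dup))
    fail("duplicate subject_id on row(s) %s",
         paste(utils::head(dup, 10L), collapse = ", "))

  covars <- setdiff(names(data), needed)
  for (v in covars) {
    if (!is.numeric(data[[v]]))
      fail("covariate `%s` must be numeric", v)
    bad <- which(!is.finite(data[[v]]))
    if (length(bad))
      fail("missing or non-finite value for covariate `%s` on row(s) %s",
           v, paste(utils::head(bad, 10L), collapse = ", "))
  }

  structure(data,
            variables = variables,
            class = c("cohort", "data.frame"))
}

#' @export
print.cohort <- function(x, ...) {
  covars <- setdiff(names(x), c("subject_id", "time", "event"))
  cat(sprintf("Survival cohort: %d subjects, %d events (%.1f%%), %d covariate(s)\n",
              nrow(x), sum(x$event), 100 * mean(x$event), length(covars)))
  if (length(covars)) cat("Covariates:", paste(covars, collapse = ", "), "\n")
  cat(sprintf("Follow-up: %.1f to %.1f months\n", min(x$time), max(x$time)))
  invisible(x)
}

#' @export
summary.cohort <- function(object, ...) {
  covars <- setdiff(names(object), c("subject_id", "time", "event"))
  bin <- covars[vapply(covars, function(v) all(object[[v]] %in% c(0, 1)), logical(1))]
  tab <- do.call(rbind, lapply(bin, function(v) {
    s <- summarize_factor(object, v)
    data.frame(variable = v, n_unfavorable = s$count, pct = s$pct)
  }))
  structure(list(n = nrow(object), n_events = sum(object$event),
                 median_followup = stats::median(object$time),
                 binary = tab), class = "summary.cohort")
}

#' @export
print.summary.cohort <- function(x, ...) {
  cat(sprintf("n = %d subjects, %d events; median follow-up %.1f months\n",
              x$n, x$n_events, x$median_followup))
  if (!is.null(x$binary)) {
    cat("Binary factors (count and percent unfavorable):\n")
    print(x$binary, row.names = FALSE)
  }
  invisible(x)
}

#' Read a cohort table from delimited text
#'
#' Expects a header row naming at least the subject id, follow-up time
#' (months) and event columns; every remaining column is taken as a
#' covariate.  Comma-separated by default, tab accepted.
#'
#' @param path path to a delimited text file.
#' @param schema named character vector remapping non-standard column names,
#'   e.g. `c(subject_id = "id", time = "os_months", event = "dead")`.
#' @param sep field separator; `NULL` (default) tries comma then tab.
#' @return a [cohort][as_cohort] object.
#' @seealso [write_cohort()]
#' @export
read_cohort <- function(path, schema = NULL, sep = NULL) {
  if (!file.exists(path)) fail("file not found: %s", path)
  if (is.null(sep)) {
    header <- readLines(path, n = 1L)
    sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  }
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(schema)) {
    for (std in names(schema)) {
      if (!schema[[std]] %in% names(df))
        fail("schema column `%s` (for `%s`) not present in file", schema[[std]], std)
      names(df)[names(df) == schema[[std]]] <- std
    }
  }
  if ("time_months" %in% names(df) && !"time" %in% names(df))
    names(df)[names(df) == "time_months"] <- "time"
  as_cohort(df)
}

#' Write a cohort table as delimited text
#'
#' Inverse of [read_cohort()]: `read_cohort(write_cohort(x, f))` returns a
#' cohort equal to `x`.
#'
#' @param cohort a [cohort][as_cohort] object.
#' @param path output file path.
#' @param sep field separator (default comma).
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, sep = ",") {
  utils::write.table(as.data.frame(cohort), path, sep = sep,
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Tabulate a binary factor
#'
#' Count of subjects at the unfavorable level (coded 1) with the percentage
#' of the cohort, rounded half-away-from-zero to one decimal as in clinical
#' summary tables.
#'
#' @param cohort a [cohort][as_cohort] object.
#' @param factor name of a binary (0/1) covariate column, or a 0/1 vector of
#'   length `nrow(cohort)`.
#' @return list with `count` and `pct`.
#' @examples
#' co <- as_cohort(data.frame(subject_id = 1:4, time = 1:4,
#'                            event = c(1, 1, 0, 1), m = c(1, 0, 1, 1)))
#' summarize_factor(co, "m")
#' @export
summarize_factor <- function(cohort, factor) {
  if (nrow(cohort) == 0L) fail("empty cohort")
  x <- if (is.character(factor)) {
    if (!factor %in% names(cohort)) fail("no covariate named `%s`", factor)
    cohort[[factor]]
  } else factor
  if (length(x) != nrow(cohort)) fail("factor assignment length mismatch")
  if (!all(x %in% c(0, 1))) fail("factor is not binary 0/1")
  cnt <- sum(x == 1)
  list(count = cnt, pct = round_half_up(100 * cnt / nrow(cohort), 1L))
}

#' Export a life table
#'
#' Writes the Kaplan-Meier bookkeeping (time, number at risk, events,
#' censorings, survival) for each level of a binary factor as delimited
#' text.
#'
#' @param cohort a [cohort][as_cohort] object.
#' @param factor name of a binary covariate.
#' @param path output file path.
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
write_life_table <- function(cohort, factor, path, sep = ",") {
  x <- cohort[[factor]]
  if (is.null(x)) fail("no covariate named `%s`", factor)
  rows <- lapply(c(0, 1), function(g) {
    sub <- cohort[x == g, , drop = FALSE]
    km <- fit_km(sub$time, sub$event)
    cbind(group = ifelse(g == 0, "favorable", "unfavorable"),
          km$table[, c("time", "n_risk", "n_event", "n_censor", "surv")])
  })
  out <- do.call(rbind, rows)
  names(out) <- c("group", "time", "n_at_risk", "n_events", "n_censored", "survival")
  utils::write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}
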