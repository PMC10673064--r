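# Internal helpers shared across modules.

#' Round half away from zero
#'
#' Base `round()` rounds half to even; clinical tables conventionally round
#' half away from zero (65.45 -> 65.5). Used for all reported percentages.
#'
#' @param x numeric vector.
#' @param digits integer, decimal places.
#' @return numeric vector rounded half-away-from-zero.
#' @keywords internal
#' @noRd
round_half_up <- function(x, digits = 0L) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Stop with a message assembled sprintf-style, without the call.
fail <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# Validate a time vector: finite, strictly positive.
check_times <- function(time, what = "time") {
  if (length(time) == 0L) fail("no %s values supplied", what)
  bad <- which(!is.finite(time))
  if (length(bad)) fail("non-finite %s at position(s) %s", what,
                        paste(utils::head(bad, 5L), collapse = ", "))
  bad <- which(time <= 0)
  if (length(bad)) fail("%s must be positive; offending position(s) %s", what,
                        paste(utils::head(bad, 5L), collapse = ", "))
  invisible(time)
}

# Validate an event indicator: 0/1 only.
check_events <- function(event) {
  bad <- which(!(event %in% c(0, 1)))
  if (length(bad)) fail("event indicator must be 0 or 1; offending position(s) %s",
                        paste(utils::head(bad, 5L), collapse = ", "))
  invisible(as.integer(event))
}

# Format a p-value the way clinical tables print it.
format_p <- function(p, digits = 3L) {
  thr <- 10^(-digits)
  ifelse(p < thr, paste0("<", format(thr, scientific = FALSE)),
         formatC(p, digits = digits, format = "f"))
}

# Format a hazard ratio: 2 decimals, 3 for values below 1.
format_hr <- function(hr) {
  ifelse(hr < 1, formatC(hr, digits = 3L, format = "f"),
         formatC(hr, digits = 2L, format = "f"))
}
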