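# Shared fixtures and independent oracles for the test suite.

# Random censored cohort with one binary group indicator, used by the
# cross-checks against the survival package and the brute-force oracles.
random_cohort <- function(n, p_group = 0.5, log_hr = 0, rate = 0.05,
                          censor = 30, round_times = FALSE) {
  g <- rbinom(n, 1L, p_group)
  t_event <- rexp(n, rate * exp(g * log_hr))
  c_time <- runif(n, 0, censor)
  time <- pmax(pmin(t_event, c_time), 1e-6)
  if (round_times) time <- pmax(round(time, 1), 0.1)  # induces ties
  as_cohort(data.frame(subject_id = seq_len(n), time = time,
                       event = as.integer(t_event <= c_time), g = g))
}

# Brute-force two-sample log-rank statistic: explicit loop over distinct
# event times with naive subsetting; independent of the vectorised
# implementation in the package.
brute_logrank <- function(time_a, event_a, time_b, event_b) {
  time <- c(time_a, time_b); event <- c(event_a, event_b)
  ingrp <- rep(c(TRUE, FALSE), c(length(time_a), length(time_b)))
  OE <- 0; V <- 0
  for (t in sort(unique(time[event == 1]))) {
    at_risk <- time >= t
    n <- sum(at_risk); n1 <- sum(at_risk & ingrp)
    d <- sum(event == 1 & time == t)
    d1 <- sum(event == 1 & time == t & ingrp)
    OE <- OE + d1 - d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  OE^2 / V
}

# Piecewise adaptive quadrature of M(t) - m(t): stats::integrate applied on
# each interval between consecutive breakpoints of the union step grid
# (adaptive quadrature is exact on each constant piece).  Independent of
# the package's signed rectangle-sum assembly.
quadrature_is <- function(curve_M, curve_m, tmax) {
  brk <- sort(unique(c(0, curve_M$time[curve_M$time < tmax],
                       curve_m$time[curve_m$time < tmax], tmax)))
  f <- function(t) as.numeric(survival_at(curve_M, t)) -
    as.numeric(survival_at(curve_m, t))
  total <- 0
  for (i in seq_len(length(brk) - 1L)) {
    # evaluate strictly inside the piece so the step discontinuity at the
    # left endpoint cannot leak into the panel
    total <- total + stats::integrate(f, brk[i], brk[i + 1L],
                                      subdivisions = 50L,
                                      rel.tol = 1e-12, abs.tol = 1e-12)$value
  }
  total
}

# Minimal two-factor simulation config for quick pipeline tests.
tiny_config <- function(n = 200, seed = 1) {
  sim_config(n = n,
             factors = data.frame(name = c("f1", "f2"),
                                  prevalence = c(0.4, 0.6),
                                  log_hr = c(log(2), 0)),
             baseline_rate = log(2) / 40, censor_admin = 200,
             censor_rate = 0.002, seed = seed)
}
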