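test_that("the analytic gradient and Hessian are exact derivatives", {
  set.seed(51)
  for (rep in 1:8) {
    n <- sample(15:40, 1)
    co <- as_cohort(data.frame(subject_id = 1:n,
                               time = pmax(round(rexp(n, 0.1), 1), 0.1),
                               event = rbinom(n, 1, 0.7),
                               x1 = rbinom(n, 1, 0.5),
                               x2 = rnorm(n)))
    if (sum(co$event) < 2) next
    b <- runif(2, -1, 1)
    ties <- if (rep %% 2 == 0) "efron" else "breslow"
    ll <- cox_loglik(co, c("x1", "x2"), b, ties = ties)
    h <- 1e-6
    for (j in 1:2) {
      bp <- b; bm <- b
      bp[j] <- b[j] + h; bm[j] <- b[j] - h
      num_grad <- (cox_loglik(co, c("x1", "x2"), bp, ties)$loglik -
                     cox_loglik(co, c("x1", "x2"), bm, ties)$loglik) / (2 * h)
      expect_lt(abs(num_grad - ll$gradient[j]), 1e-5)
      num_hess <- -(cox_loglik(co, c("x1", "x2"), bp, ties)$gradient -
                      cox_loglik(co, c("x1", "x2"), bm, ties)$gradient) / (2 * h)
      expect_lt(max(abs(num_hess - ll$neg_hessian[j, ])), 1e-4)
    }
  }
})

test_that("a single subject with one event has zero partial log-likelihood", {
  co <- as_cohort(data.frame(subject_id = 1, time = 5, event = 1, x = 1))
  for (b in c(-2, 0, 1.3))
    expect_equal(cox_loglik(co, "x", b)$loglik, 0)
})

test_that("the score at b = 0 is the log-rank O - E for a binary covariate", {
  set.seed(52)
  co <- random_cohort(90, log_hr = 0.5, round_times = TRUE)
  a <- co$g == 0
  lr <- logrank_test(co$time[a], co$event[a], co$time[!a], co$event[!a])
  sc <- cox_loglik(co, "g", 0)
  # gradient w.r.t. the indicator of group B equals O_B - E_B
  expect_equal(unname(sc$gradient),
               unname(lr$observed["B"] - lr$expected["B"]), tolerance = 1e-10)
})

test_that("the score test at b = 0 equals the log-rank chi-square", {
  # the identity is exact for untied event times (the hypergeometric
  # variance acquires an (n-d)/(n-1) factor under ties that the Breslow
  # score variance does not)
  set.seed(53)
  for (rep in 1:10) {
    co <- random_cohort(80, log_hr = runif(1, -0.8, 0.8))
    a <- co$g == 0
    if (sum(co$event) == 0) next
    lr <- logrank_test(co$time[a], co$event[a], co$time[!a], co$event[!a])
    st <- cox_score_test(co, "g")
    expect_lt(abs(st$statistic - lr$chi_square), 1e-8)
  }
})

test_that("two identical groups fit to b = 0", {
  t <- c(3, 7, 11, 15); e <- c(1, 1, 0, 1)
  co <- as_cohort(data.frame(subject_id = 1:8, time = rep(t, 2),
                             event = rep(e, 2), g = rep(c(0, 1), each = 4)))
  fit <- fit_cox(co, "g")
  expect_true(fit$converged)
  expect_equal(unname(coef(fit)), 0, tolerance = 1e-8)
  expect_equal(unname(fit$hr), 1, tolerance = 1e-8)
})

test_that("Newton-Raphson matches brute-force maximisation on tiny cohorts", {
  set.seed(54)
  checked <- 0L
  for (rep in 1:40) {
    n <- sample(4:8, 1)
    co <- as_cohort(data.frame(subject_id = 1:n,
                               time = round(runif(n, 1, 20), 1),
                               event = rbinom(n, 1, 0.8),
                               x = rbinom(n, 1, 0.5)))
    if (sum(co$event) < 2 || var(co$x) == 0) next
    obj <- function(b) cox_loglik(co, "x", b)$loglik
    opt <- optimize(obj, c(-5, 5), maximum = TRUE, tol = 1e-10)
    if (opt$maximum < -4.5 || opt$maximum > 4.5) next  # boundary: no interior MLE
    fit <- fit_cox(co, "x")
    if (!fit$converged) next
    expect_lt(abs(unname(coef(fit)) - opt$maximum), 1e-6)
    checked <- checked + 1L
  }
  expect_gte(checked, 10L)
})

test_that("fit_cox agrees with survival::coxph under both tie methods", {
  skip_if_not_installed("survival")
  set.seed(55)
  for (ties in c("breslow", "efron")) {
    co <- random_cohort(150, log_hr = 0.7, round_times = TRUE)
    co$x2 <- rnorm(nrow(co))
    fit <- fit_cox(co, c("g", "x2"), ties = ties)
    ref <- survival::coxph(survival::Surv(time, event) ~ g + x2,
                           data = as.data.frame(co), ties = ties)
    expect_equal(unname(coef(fit)), unname(coef(ref)), tolerance = 1e-6)
    expect_equal(unname(fit$se), unname(sqrt(diag(vcov(ref)))),
                 tolerance = 1e-6)
    expect_equal(fit$loglik, ref$loglik[2], tolerance = 1e-8)
  }
})

test_that("likelihood ascends monotonically and invariances hold", {
  set.seed(56)
  co <- random_cohort(100, log_hr = 1)
  fit <- fit_cox(co, "g")
  expect_true(fit$converged)
  expect_gte(fit$loglik, fit$loglik_null)

  # rescaling time leaves b unchanged
  co2 <- co; co2$time <- co2$time * 12
  expect_equal(coef(fit_cox(co2, "g")), coef(fit), tolerance = 1e-8)

  # relabelling 0 <-> 1 flips the sign
  co3 <- co; co3$g <- 1 - co3$g
  expect_equal(unname(coef(fit_cox(co3, "g"))), -unname(coef(fit)),
               tolerance = 1e-8)
})

test_that("Breslow and Efron agree exactly without tied event times", {
  set.seed(57)
  co <- random_cohort(80, log_hr = 0.5)  # continuous times, no ties
  expect_equal(coef(fit_cox(co, "g", ties = "breslow")),
               coef(fit_cox(co, "g", ties = "efron")), tolerance = 1e-10)
})

test_that("degenerate designs are rejected or flagged, not silently fitted", {
  co <- as_cohort(data.frame(subject_id = 1:6, time = 1:6,
                             event = rep(1L, 6), x = rep(1L, 6)))
  expect_error(fit_cox(co, "x"), "zero variance")
  expect_error(fit_cox(co, "missing_cov"), "not in cohort")
  co0 <- as_cohort(data.frame(subject_id = 1:4, time = 1:4,
                              event = rep(0L, 4), x = c(0, 1, 0, 1)))
  expect_error(fit_cox(co0, "x"), "no events")

  # perfect separation: all deaths in one group, early -> monotone likelihood
  sep <- as_cohort(data.frame(subject_id = 1:10,
                              time = c(1:5, 11:15),
                              event = c(rep(1L, 5), rep(0L, 5)),
                              x = c(rep(1L, 5), rep(0L, 5))))
  fit <- fit_cox(sep, "x")
  expect_false(fit$converged)
  expect_true(any(grepl("separation", fit$flags)))
})

test_that("Wald inference fields are mutually consistent", {
  set.seed(58)
  co <- random_cohort(200, log_hr = 0.6)
  fit <- fit_cox(co, "g")
  expect_equal(unname(fit$hr), exp(unname(coef(fit))))
  expect_equal(unname(fit$ci_lower),
               exp(unname(coef(fit)) - qnorm(0.975) * unname(fit$se)))
  expect_true(fit$ci_lower < fit$hr && fit$hr < fit$ci_upper)
  expect_equal(unname(fit$p_value),
               2 * pnorm(-abs(unname(coef(fit)) / unname(fit$se))))
})

test_that("the univariate screen fits each factor alone and isolates failures", {
  co <- generate_cohort(tiny_config(n = 250, seed = 14))
  co$dup <- co$f1
  scr <- univariate_screen(co, c("f1", "dup", "f2"))
  expect_equal(coef(scr$f1), coef(scr$dup), ignore_attr = TRUE)
  expect_s3_class(scr$f2, "cox_fit")

  co$flat <- 0L
  scr2 <- univariate_screen(co, c("f1", "flat"))
  expect_s3_class(scr2$flat, "cox_fit_error")
  expect_s3_class(scr2$f1, "cox_fit")
  expect_length(univariate_screen(co, character(0)), 0L)
})

test_that("hazard ratios translate to percent excess hazard", {
  expect_equal(interpret_hr(1.15), 15)
  expect_equal(interpret_hr(1.0), 0)
  expect_equal(interpret_hr(1.79), 79)
  expect_equal(interpret_hr(0.8), -20)
  expect_error(interpret_hr(-1), "positive")
})
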