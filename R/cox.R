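# Cox proportional-hazards machinery: the partial log-likelihood with exact
# analytic gradient and negative Hessian (Breslow or Efron tie handling),
# and a Newton-Raphson fitter with step-halving.

# Workhorse on raw vectors/matrix; X is n x p, b length p.
# Returns loglik, gradient, neg_hessian; all three are consistent exact
# derivatives of each other.
cox_ll_raw <- function(time, event, X, b, ties = c("breslow", "efron")) {
  ties <- match.arg(ties)
  n <- length(time)
  p <- ncol(X)
  ord <- order(time)
  time <- time[ord]; event <- event[ord]
  X <- X[ord, , drop = FALSE]

  eta <- drop(X %*% b)
  # guard overflow in exp for wandering Newton steps
  w <- exp(pmin(eta, 500))
  wX <- X * w

  # suffix sums: S0[i] = sum_{k >= i} w_k, likewise per column of X and of
  # the p(p+1)/2 distinct products x_j x_k
  revcs <- function(v) rev(cumsum(rev(v)))
  S0s <- revcs(w)
  S1s <- apply(wX, 2L, revcs)
  if (n == 1L) S1s <- matrix(S1s, nrow = 1L)
  pairs <- which(upper.tri(diag(p), diag = TRUE), arr.ind = TRUE)
  XX <- X[, pairs[, 1L], drop = FALSE] * X[, pairs[, 2L], drop = FALSE] * w
  S2s <- apply(XX, 2L, revcs)
  if (n == 1L) S2s <- matrix(S2s, nrow = 1L)

  ev_rle <- rle(time[event == 1])           # time is sorted: rle groups ties
  ev_times <- ev_rle$values
  if (length(ev_times) == 0L) fail("no events: partial likelihood undefined")
  first_idx <- match(ev_times, time)        # risk set entry index per event time

  unpack <- function(v) {                   # p(p+1)/2 vector -> symmetric matrix
    M <- matrix(0, p, p)
    M[cbind(pairs[, 1L], pairs[, 2L])] <- v
    M[cbind(pairs[, 2L], pairs[, 1L])] <- v
    M
  }

  d_j <- ev_rle$lengths
  has_ties <- any(d_j > 1)
  use_efron <- ties == "efron" && has_ties

  ll <- sum(eta[event == 1])
  grad <- colSums(X[event == 1, , drop = FALSE])
  negH <- matrix(0, p, p)

  if (!use_efron) {
    S0 <- S0s[first_idx]
    S1 <- S1s[first_idx, , drop = FALSE]
    S2 <- S2s[first_idx, , drop = FALSE]
    ll <- ll - sum(d_j * log(S0))
    E1 <- S1 / S0                                    # rows: S1_j / S0_j
    grad <- grad - colSums(d_j * E1)
    negH_pairs <- colSums(d_j * (S2 / S0)) |> unpack()
    negH <- negH_pairs - crossprod(E1 * sqrt(d_j))
  } else {
    for (j in seq_along(ev_times)) {
      i <- first_idx[j]; d <- d_j[j]
      S0 <- S0s[i]; S1 <- S1s[i, ]; S2 <- unpack(S2s[i, ])
      tied <- which(time == ev_times[j] & event == 1)
      s0 <- sum(w[tied])
      s1 <- colSums(wX[tied, , drop = FALSE])
      s2 <- unpack(colSums(XX[tied, , drop = FALSE]))
      for (k in seq_len(d) - 1L) {
        f <- k / d
        den <- S0 - f * s0
        num <- S1 - f * s1
        ll <- ll - log(den)
        grad <- grad - num / den
        negH <- negH + (S2 - f * s2) / den - tcrossprod(num / den)
      }
    }
  }
  list(loglik = unname(ll), gradient = unname(grad),
       neg_hessian = unname(negH))
}

#' Cox partial log-likelihood, gradient and information
#'
#' Evaluates the partial log-likelihood of the proportional-hazards model
#' at a coefficient vector, together with its exact analytic gradient
#' (score) and negative Hessian (observed information).  Breslow's tie
#' approximation is the default; Efron's is available and the two agree
#' exactly when no event times are tied.
#'
#' @param cohort a [cohort][as_cohort] object.
#' @param covariates names of numeric covariate columns.
#' @param b coefficient vector (same length as `covariates`).
#' @param ties `"breslow"` (default) or `"efron"`.
#' @return list with `loglik`, `gradient`, `neg_hessian`.
#' @examples
#' co <- generate_cohort(sim_config(50, data.frame(name = "g",
#'   prevalence = 0.5, log_hr = 0.5), baseline_rate = 0.02, seed = 1))
#' cox_loglik(co, "g", b = 0)
#' @export
cox_loglik <- function(cohort, covariates, b, ties = c("breslow", "efron")) {
  ties <- match.arg(ties)
  X <- cox_design(cohort, covariates)
  if (length(b) != ncol(X)) fail("length(b) must equal the number of covariates")
  if (sum(cohort$event) == 0L) fail("no events: partial likelihood undefined")
  cox_ll_raw(cohort$time, cohort$event, X, b, ties)
}

# Validate covariates and assemble the design matrix.
cox_design <- function(cohort, covariates) {
  if (length(covariates) == 0L) fail("no covariates given")
  missing_cov <- setdiff(covariates, names(cohort))
  if (length(missing_cov))
    fail("covariate(s) not in cohort: %s", paste(missing_cov, collapse = ", "))
  X <- as.matrix(as.data.frame(cohort)[, covariates, drop = FALSE])
  if (!is.numeric(X)) fail("covariates must be numeric")
  X
}

#' Fit a Cox proportional-hazards model
#'
#' Maximises the partial likelihood by Newton-Raphson from b = 0 with
#' step-halving (each iteration's step is halved until the log partial
#' likelihood does not decrease, so the likelihood ascends monotonically).
#' Convergence is declared when the change in log partial likelihood falls
#' below 1e-9 or the gradient max-norm below 1e-8, within 50 iterations.
#' All covariates are entered simultaneously and none are added or removed
#' (the "Enter" strategy); inference is Wald: z = b/se with two-sided
#' normal p-values and 95% confidence intervals exp(b -/+ 1.96 se) on the
#' hazard-ratio scale.
#'
#' @param cohort a [cohort][as_cohort] object.
#' @param covariates names of covariate columns to enter.
#' @param ties `"breslow"` (default, the convention of the major clinical
#'   statistics packages) or `"efron"`.
#' @param max_iter,tol_loglik,tol_grad Newton-Raphson controls.
#' @return object of class `cox_fit`: `coefficients`, `se`, `z`, `p_value`,
#'   `hr` (= exp(b)), `ci_lower`/`ci_upper` (95% Wald, hazard-ratio scale),
#'   `var` (inverse information), `loglik`, `loglik_null`, `iterations`,
#'   `converged`, `flags`, `ties`, `n`, `n_events`.
#' @details Monotone likelihood (separation) is reported through
#'   `converged = FALSE` and a diagnostic flag rather than silently
#'   returning a huge coefficient; zero-variance covariates are rejected as
#'   inestimable.
#' @examples
#' co <- generate_cohort(sim_config(300, data.frame(name = "g",
#'   prevalence = 0.5, log_hr = log(2)), baseline_rate = 0.02, seed = 2))
#' fit <- fit_cox(co, "g")
#' coef(fit); confint(fit)
#' @export
fit_cox <- function(cohort, covariates, ties = c("breslow", "efron"),
                    max_iter = 50L, tol_loglik = 1e-9, tol_grad = 1e-8) {
  ties <- match.arg(ties)
  X <- cox_design(cohort, covariates)
  if (sum(cohort$event) < 1L) fail("no events: model cannot be fitted")
  if (sum(cohort$event) < ncol(X))
    fail("fewer events (%d) than covariates (%d)", sum(cohort$event), ncol(X))
  const <- covariates[apply(X, 2L, function(v) stats::var(v) == 0)]
  if (length(const))
    fail("covariate(s) with zero variance, coefficient inestimable: %s",
         paste(const, collapse = ", "))

  p <- ncol(X)
  b <- rep(0, p)
  cur <- cox_ll_raw(cohort$time, cohort$event, X, b, ties)
  loglik_null <- cur$loglik
  converged <- FALSE
  flags <- character(0)
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    step <- tryCatch(solve(cur$neg_hessian, cur$gradient),
                     error = function(e) NULL)
    if (is.null(step)) { flags <- c(flags, "singular information"); break }
    new_b <- b + step
    new <- cox_ll_raw(cohort$time, cohort$event, X, new_b, ties)
    halvings <- 0L
    while (new$loglik < cur$loglik && halvings < 30L) {
      halvings <- halvings + 1L
      step <- step / 2
      new_b <- b + step
      new <- cox_ll_raw(cohort$time, cohort$event, X, new_b, ties)
    }
    delta <- new$loglik - cur$loglik
    b <- new_b
    cur <- new
    if (abs(delta) < tol_loglik || max(abs(cur$gradient)) < tol_grad) {
      converged <- TRUE
      break
    }
  }
  if (max(abs(b)) > 15) {
    converged <- FALSE
    flags <- c(flags, "possible monotone likelihood / separation (|b| > 15)")
  }

  V <- tryCatch(solve(cur$neg_hessian), error = function(e) {
    flags <<- c(flags, "information not invertible at optimum")
    matrix(NA_real_, p, p)
  })
  se <- sqrt(diag(V))
  z <- b / se
  zq <- stats::qnorm(0.975)
  names(b) <- colnames(V) <- rownames(V) <- covariates

  structure(list(coefficients = b,
                 se = stats::setNames(se, covariates),
                 z = stats::setNames(z, covariates),
                 p_value = stats::setNames(2 * stats::pnorm(-abs(z)), covariates),
                 hr = stats::setNames(exp(b), covariates),
                 ci_lower = stats::setNames(exp(b - zq * se), covariates),
                 ci_upper = stats::setNames(exp(b + zq * se), covariates),
                 var = V, loglik = cur$loglik, loglik_null = loglik_null,
                 gradient = cur$gradient, iterations = iter,
                 converged = converged, flags = flags, ties = ties,
                 n = nrow(cohort), n_events = sum(cohort$event)),
            class = "cox_fit")
}

#' @export
coef.cox_fit <- function(object, ...) object$coefficients

#' @export
vcov.cox_fit <- function(object, ...) object$var

#' @export
confint.cox_fit <- function(object, parm, level = 0.95, ...) {
  zq <- stats::qnorm(1 - (1 - level) / 2)
  ci <- cbind(object$coefficients - zq * object$se,
              object$coefficients + zq * object$se)
  colnames(ci) <- paste0(100 * c((1 - level) / 2, 1 - (1 - level) / 2), " %")
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' @export
predict.cox_fit <- function(object, newdata, type = c("lp", "risk"), ...) {
  type <- match.arg(type)
  X <- as.matrix(as.data.frame(newdata)[, names(object$coefficients),
                                        drop = FALSE])
  lp <- drop(X %*% object$coefficients)
  if (type == "lp") lp else exp(lp)
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("Cox proportional-hazards fit (%s ties): n = %d, events = %d\n",
              x$ties, x$n, x$n_events))
  tab <- data.frame(coef = sprintf("%.4f", x$coefficients),
                    `se` = sprintf("%.4f", x$se),
                    p = format_p(x$p_value),
                    `Exp.b` = format_hr(x$hr),
                    lower.95 = sprintf("%.1f", x$ci_lower),
                    upper.95 = sprintf("%.1f", x$ci_upper),
                    check.names = FALSE)
  rownames(tab) <- names(x$coefficients)
  print(tab)
  cat(sprintf("Log partial likelihood %.4f (null %.4f), %d iteration(s)%s\n",
              x$loglik, x$loglik_null, x$iterations,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  for (f in x$flags) cat("  flag:", f, "\n")
  invisible(x)
}

#' @export
summary.cox_fit <- function(object, ...) {
  object
}

#' Score test at b = 0
#'
#' The quadratic form `U' I^{-1} U` of the partial-likelihood score and
#' information evaluated at b = 0.  For a single binary covariate with
#' Breslow ties this equals the two-sample log-rank chi-square exactly.
#'
#' @param cohort a [cohort][as_cohort] object.
#' @param covariates covariate names.
#' @param ties tie handling as in [cox_loglik()].
#' @return list with `statistic` (chi-square), `df`, `p_value`.
#' @export
cox_score_test <- function(cohort, covariates, ties = c("breslow", "efron")) {
  ties <- match.arg(ties)
  at0 <- cox_loglik(cohort, covariates, rep(0, length(covariates)), ties)
  stat <- drop(crossprod(at0$gradient,
                         solve(at0$neg_hessian, at0$gradient)))
  df <- length(covariates)
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' Univariate Cox screen
#'
#' One single-covariate Cox fit per factor.  A factor whose fit fails
#' (e.g. zero variance) yields an error record; the other factors are
#' unaffected.
#'
#' @param cohort a [cohort][as_cohort] object.
#' @param factors character vector of covariate names.
#' @param ties tie handling as in [fit_cox()].
#' @return named list of `cox_fit` objects (or `cox_fit_error` records).
#' @export
univariate_screen <- function(cohort, factors, ties = c("breslow", "efron")) {
  ties <- match.arg(ties)
  out <- lapply(factors, function(f)
    tryCatch(fit_cox(cohort, f, ties = ties),
             error = function(e) structure(list(variable = f,
                                                message = conditionMessage(e)),
                                           class = "cox_fit_error")))
  stats::setNames(out, factors)
}

#' Interpret a hazard ratio as percent excess hazard
#'
#' A hazard ratio of 1.15 means a subject at the unfavorable level is 15%
#' more likely to die at any moment than one at the favorable level:
#' `100 * (exp_b - 1)`, rounded to the nearest integer percent for
#' reporting.
#'
#' @param exp_b positive hazard ratio(s).
#' @return excess hazard in percent (integer-rounded, half away from zero).
#' @examples
#' interpret_hr(1.15)  # 15
#' interpret_hr(1.79)  # 79
#' @export
interpret_hr <- function(exp_b) {
  if (any(!is.finite(exp_b) | exp_b <= 0)) fail("hazard ratio must be positive")
  round_half_up(100 * (exp_b - 1), 0L)
}
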