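## Weighted least-squares fitting -------------------------------------------

#' Inverse-variance observation weights
#'
#' Time to exhaustion (and hence distance) is heteroscedastic: its variance
#' grows with its value. Taking the variance proportional to the dependent
#' variable itself, inverse-variance weights are proportional to `1/y`.
#' Weights are normalised to sum to the number of observations so the
#' weighted objective is scale-free in `y` (and reduces to ordinary least
#' squares for a constant dependent variable).
#'
#' @param dependent_values Strictly positive dependent-variable values
#'   (times for the `t(s)` formulation, distances for `d(s)`).
#' @return Weight vector of the same length, summing to `length(y)`.
#' @examples
#' observation_weights(c(100, 200, 400))  # 12/7, 6/7, 3/7
#' @export
observation_weights <- function(dependent_values) {
  y <- as.numeric(dependent_values)
  if (length(y) == 0L || any(!is.finite(y)) || any(y <= 0))
    stop("dependent values must be strictly positive and finite")
  w <- 1 / y
  w * length(w) / sum(w)
}

#' Fitting options
#'
#' @param max_iterations Maximum Levenberg-Marquardt iterations.
#' @param convergence_tol Relative step/gradient tolerance (applied as
#'   `ftol`, `ptol` and `gtol`).
#' @param weight_source `"observed"` computes weights once from the observed
#'   dependent values; `"iterative_fitted"` re-derives them from fitted
#'   values over a few reweighting passes; `"none"` uses uniform weights
#'   (ordinary least squares, useful for heteroscedasticity contrasts).
#' @param n_restarts Number of jittered restarts tried when the default
#'   start fails to converge or lands on a bound.
#' @param restart_jitter Relative jitter (+/-) applied to starting values on
#'   restarts.
#' @param restart_seed Seed for the (local, restored-afterwards) RNG used to
#'   draw restart jitter, making restarts reproducible.
#' @return A list of class `cs_fit_options`.
#' @export
fit_options <- function(max_iterations = 500L, convergence_tol = 1e-10,
                        weight_source = c("observed", "iterative_fitted",
                                          "none"),
                        n_restarts = 5L, restart_jitter = 0.2,
                        restart_seed = 1L) {
  weight_source <- match.arg(weight_source)
  stopifnot(max_iterations >= 1, convergence_tol > 0,
            n_restarts >= 0, restart_jitter >= 0)
  structure(list(max_iterations = as.integer(max_iterations),
                 convergence_tol = convergence_tol,
                 weight_source = weight_source,
                 n_restarts = as.integer(n_restarts),
                 restart_jitter = restart_jitter,
                 restart_seed = as.integer(restart_seed)),
            class = "cs_fit_options")
}

#' Starting values for the nonlinear fits
#'
#' The two-parameter start comes from the ordinary regression of distance on
#' time, for which the model is linear: `d = d_prime + cs * t`, so the slope
#' starts `cs` and the intercept starts `d_prime` (exact on noise-free
#' two-parameter data). The three-parameter family reuses those and starts
#' `s_max` at 1.5x the fastest observed speed; the exponential family starts
#' `s_max` at 1.4x the fastest speed and `tau` at the observed time at the
#' second-fastest speed. All starts are clipped into the fitting bounds.
#'
#' @param trials A [trial_set()].
#' @param spec A [cs_model()] (family is what matters).
#' @return A named numeric vector of starting values.
#' @export
initial_params <- function(trials, spec) {
  stopifnot(inherits(trials, "cs_trial_set"))
  family <- if (inherits(spec, "cs_model_spec")) spec$family else
    match.arg(spec, cs_families())
  obs <- trials$observations
  if (nrow(obs) < 2L) stop("need at least 2 observations for starting values")
  ols <- stats::lm(distance ~ time, data = obs)
  cs0 <- unname(stats::coef(ols)[2L])
  dp0 <- unname(stats::coef(ols)[1L])
  if (!is.finite(cs0) || !is.finite(dp0))
    stop("degenerate trial data: distance-on-time regression failed")
  smin <- min(obs$speed); smax_obs <- max(obs$speed)
  cs0 <- min(max(cs0, 0.5 * smin), 0.99 * smin)
  dp0 <- max(dp0, 1)
  switch(family,
    two_param = c(cs = cs0, d_prime = dp0),
    three_param = c(cs = cs0, d_prime = dp0, s_max = 1.5 * smax_obs),
    three_param_exp = {
      tau0 <- obs$time[order(obs$speed, decreasing = TRUE)][2L]
      c(cs = cs0, tau = tau0, s_max = 1.4 * smax_obs)
    })
}

## box constraints: cs below the slowest trial speed, s_max above the fastest
fit_bounds <- function(family, obs) {
  smin <- min(obs$speed); smax_obs <- max(obs$speed)
  eps <- 1e-6 * smin
  switch(family,
    two_param = list(lower = c(cs = 1e-8, d_prime = 1e-8),
                     upper = c(cs = smin - eps, d_prime = Inf)),
    three_param = list(lower = c(cs = 1e-8, d_prime = 1e-8,
                                 s_max = smax_obs + eps),
                       upper = c(cs = smin - eps, d_prime = Inf, s_max = Inf)),
    three_param_exp = list(lower = c(cs = 1e-8, tau = 1e-8,
                                     s_max = smax_obs + eps),
                           upper = c(cs = smin - eps, tau = Inf, s_max = Inf)))
}

model_fun <- function(family, formulation) {
  tfun <- switch(family,
    two_param = function(par, s) par[["d_prime"]] / (s - par[["cs"]]),
    three_param = function(par, s)
      par[["d_prime"]] * (par[["s_max"]] - s) /
        ((s - par[["cs"]]) * (par[["s_max"]] - par[["cs"]])),
    three_param_exp = function(par, s)
      par[["tau"]] * log((par[["s_max"]] - par[["cs"]]) / (s - par[["cs"]])))
  if (formulation == "time_of_speed") tfun
  else function(par, s) s * tfun(par, s)
}

run_lm <- function(start, fn, lower, upper, control) {
  res <- tryCatch(
    minpack.lm::nls.lm(par = start, lower = lower, upper = upper,
                       fn = fn, control = control),
    error = function(e) NULL)
  if (is.null(res)) return(NULL)
  res
}

#' Fit a speed-duration model to one participant's trials
#'
#' Minimises the weighted residual sum of squares
#' \eqn{\sum_i w_i (y_i - \hat y_i)^2} by bounded Levenberg-Marquardt, where
#' `y` is time to exhaustion (`time_of_speed`) or distance
#' (`distance_of_speed`) and the weights follow [observation_weights()].
#' Box constraints keep `cs` below the slowest trial speed (the model is
#' undefined at a data point otherwise) and `s_max` above the fastest.
#' If the default start fails to converge or ends on a bound, up to
#' `options$n_restarts` jittered restarts are tried and the best converged
#' interior solution kept.
#'
#' Standard errors come from the weighted Gauss-Newton covariance
#' \eqn{s^2 (J^T W J)^{-1}} with \eqn{s^2 = RSS_w / df}, `df = n - p`.
#' With `df = 0` estimates are returned but standard errors are `NA`.
#'
#' @param trials A [trial_set()].
#' @param spec A [cs_model()].
#' @param options A [fit_options()].
#' @return An object of class `cs_fit` with elements `spec`, `params`
#'   (named vector), `se`, `vcov`, `weighted_rss`, `n_obs`, `df`,
#'   `residuals` (raw), `weighted_residuals`, `fitted`, `weights`,
#'   `converged`, `at_bound`, `flagged`, `iterations`, `message`.
#' @examples
#' tr <- group_mean_trialset()
#' fit_cs(tr, cs_model("two_param"))
#' @export
fit_cs <- function(trials, spec, options = fit_options()) {
  stopifnot(inherits(trials, "cs_trial_set"), inherits(spec, "cs_model_spec"))
  obs <- trials$observations
  family <- spec$family
  p <- n_model_params(family)
  n <- nrow(obs)
  if (n < p)
    stop(sprintf("under-determined: %d observations for a %d-parameter model", n, p))
  y <- if (spec$formulation == "time_of_speed") obs$time else obs$distance
  fmod <- model_fun(family, spec$formulation)
  w <- if (options$weight_source == "none") rep(1, n) else
    observation_weights(y)
  bounds <- fit_bounds(family, obs)
  control <- minpack.lm::nls.lm.control(
    maxiter = min(options$max_iterations, 1024L),
    ftol = options$convergence_tol, ptol = options$convergence_tol,
    gtol = options$convergence_tol)

  do_solve <- function(start, w) {
    sw <- sqrt(w)
    fn <- function(par) sw * (y - fmod(par, obs$speed))
    run_lm(start, fn, bounds$lower, bounds$upper, control)
  }
  at_bound <- function(par) {
    tol <- 1e-6
    lo <- bounds$lower; up <- bounds$upper
    any((is.finite(lo) & par - lo <= tol * pmax(abs(par), 1)) |
        (is.finite(up) & up - par <= tol * pmax(abs(par), 1)))
  }
  start <- initial_params(trials, spec)

  solve_with_restarts <- function(w) {
    res <- do_solve(start, w)
    ok <- function(r) !is.null(r) && r$info %in% 1:3 && !at_bound(coef(r))
    if (ok(res)) return(list(res = res, restarts = 0L))
    best <- res; restarts <- 0L
    if (options$n_restarts > 0L) {
      jit <- withr::with_seed(options$restart_seed,
        matrix(stats::runif(options$n_restarts * length(start),
                            1 - options$restart_jitter,
                            1 + options$restart_jitter),
               nrow = options$n_restarts))
      for (k in seq_len(options$n_restarts)) {
        st <- pmin(pmax(start * jit[k, ], bounds$lower * 1.000001 + 1e-10),
                   ifelse(is.finite(bounds$upper), bounds$upper * 0.999999,
                          start * jit[k, ]))
        names(st) <- names(start)
        cand <- do_solve(st, w)
        restarts <- k
        if (!is.null(cand) &&
            (is.null(best) || cand$deviance < best$deviance ||
             (ok(cand) && !ok(best))))
          best <- cand
        if (ok(best)) break
      }
    }
    list(res = best, restarts = restarts)
  }

  sol <- solve_with_restarts(w)
  if (options$weight_source == "iterative_fitted" && !is.null(sol$res)) {
    for (pass in 1:3) {
      yhat <- fmod(coef(sol$res), obs$speed)
      if (any(!is.finite(yhat)) || any(yhat <= 0)) break
      w <- observation_weights(yhat)
      sol <- solve_with_restarts(w)
      if (is.null(sol$res)) break
    }
  }
  res <- sol$res
  if (is.null(res))
    stop("Levenberg-Marquardt failed to produce any solution")

  par <- stats::coef(res)
  converged <- res$info %in% 1:3
  bound_hit <- at_bound(par)
  yhat <- fmod(par, obs$speed)
  raw_res <- y - yhat
  wres <- sqrt(w) * raw_res
  wrss <- sum(wres^2)
  df <- n - p
  se <- rep(NA_real_, p); names(se) <- names(par)
  vcov <- NULL
  if (df >= 1L && wrss > 0) {
    s2 <- wrss / df
    vc <- tryCatch(s2 * solve(res$hessian), error = function(e) NULL)
    if (!is.null(vc) && all(is.finite(diag(vc))) && all(diag(vc) >= 0)) {
      vcov <- vc
      se <- sqrt(diag(vc))
    }
  } else if (df >= 1L && wrss == 0) {
    se[] <- 0
    vcov <- matrix(0, p, p, dimnames = list(names(par), names(par)))
  }
  structure(list(
    spec = spec,
    participant_id = trials$participant_id,
    params = par,
    se = se,
    vcov = vcov,
    weighted_rss = wrss,
    n_obs = n,
    df = df,
    residuals = raw_res,
    weighted_residuals = wres,
    fitted = yhat,
    weights = w,
    converged = converged,
    at_bound = bound_hit,
    flagged = !converged || bound_hit,
    iterations = res$niter,
    restarts = sol$restarts,
    message = res$message
  ), class = "cs_fit")
}

#' @export
print.cs_fit <- function(x, ...) {
  cat(sprintf("<cs_fit> %s / %s (%s)\n", x$spec$family, x$spec$formulation,
              if (x$flagged) "FLAGGED" else "converged"))
  est <- data.frame(estimate = x$params, se = x$se)
  print(round(est, 4))
  cat(sprintf("n = %d, df = %d, weighted RSS = %.6g, iterations = %d\n",
              x$n_obs, x$df, x$weighted_rss, x$iterations))
  invisible(x)
}

#' @export
coef.cs_fit <- function(object, ...) object$params

battery_specs <- function() {
  list(cs_model("two_param", "time_of_speed"),
       cs_model("two_param", "distance_of_speed"),
       cs_model("three_param", "time_of_speed"),
       cs_model("three_param", "distance_of_speed"),
       cs_model("three_param_exp", "time_of_speed"),
       cs_model("three_param_exp", "distance_of_speed"))
}

#' Fit the full model battery
#'
#' Runs all six (family x formulation) fits on one trial set, in the fixed
#' order: two-parameter t(s), two-parameter d(s), three-parameter t(s),
#' three-parameter d(s), exponential t(s), exponential d(s). A cell whose
#' fit fails outright (e.g. a three-parameter family on three observations)
#' is carried as a flagged `cs_fit_failure` entry rather than aborting the
#' battery.
#'
#' @inheritParams fit_cs
#' @return A list of class `cs_fit_battery`; elements are `cs_fit` or
#'   `cs_fit_failure` objects, named `<family>.<formulation>`.
#' @export
fit_battery <- function(trials, options = fit_options()) {
  specs <- battery_specs()
  n <- nrow(trials$observations)
  out <- lapply(specs, function(sp) {
    p <- n_model_params(sp$family)
    if (n < p + 1L)  # a CI-capable fit needs at least p + 1 observations
      return(structure(
        list(spec = sp, participant_id = trials$participant_id,
             error = sprintf(
               "under-determined: %d observations for a %d-parameter model (need %d)",
               n, p, p + 1L),
             converged = FALSE, flagged = TRUE),
        class = "cs_fit_failure"))
    tryCatch(fit_cs(trials, sp, options),
             error = function(e) structure(
               list(spec = sp, participant_id = trials$participant_id,
                    error = conditionMessage(e),
                    converged = FALSE, flagged = TRUE),
               class = "cs_fit_failure"))
  })
  names(out) <- vapply(specs, function(sp)
    paste(sp$family, sp$formulation, sep = "."), character(1))
  structure(out, class = "cs_fit_battery",
            participant_id = trials$participant_id)
}

#' @export
print.cs_fit_battery <- function(x, ...) {
  cat(sprintf("<cs_fit_battery> participant %s\n", attr(x, "participant_id")))
  for (nm in names(x)) {
    f <- x[[nm]]
    if (inherits(f, "cs_fit_failure"))
      cat(sprintf("  %-40s failed: %s\n", nm, f$error))
    else
      cat(sprintf("  %-40s cs = %.3f%s\n", nm, f$params[["cs"]],
                  if (f$flagged) " [flagged]" else ""))
  }
  invisible(x)
}
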