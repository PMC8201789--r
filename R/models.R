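#' @keywords internal
"_PACKAGE"

## Model families and formulations ------------------------------------------

#' Supported model families and fitting formulations
#'
#' @return Character vectors naming the three speed-duration model families
#'   and the two fitting formulations.
#' @export
cs_families <- function() c("two_param", "three_param", "three_param_exp")

#' @rdname cs_families
#' @export
cs_formulations <- function() c("time_of_speed", "distance_of_speed")

#' Specify a speed-duration model
#'
#' A model specification pairs a model family with a fitting formulation.
#' Three families are supported: the two-parameter hyperbolic model
#' \eqn{t(s) = d'/(s - CS)}, the three-parameter model
#' \eqn{t(s) = d'(s_{max} - s) / ((s - CS)(s_{max} - CS))}, and the
#' three-parameter exponential model
#' \eqn{t(s) = \tau \log((s_{max} - CS)/(s - CS))}.
#' Each family can be fitted either with time to exhaustion as the dependent
#' variable (`"time_of_speed"`) or with distance \eqn{d(s) = s\,t(s)}
#' (`"distance_of_speed"`). The six combinations make up the standard fit
#' battery; see [fit_battery()].
#'
#' The `d(t)` and `t(d)` formulations are deliberately not supported: with
#' speed error-free, the errors of time and distance are perfectly
#' correlated (distance = speed x time), so neither can serve as the
#' independent variable in a regression without endogeneity.
#'
#' @param family One of `"two_param"`, `"three_param"`, `"three_param_exp"`.
#' @param formulation One of `"time_of_speed"`, `"distance_of_speed"`.
#' @return An object of class `cs_model_spec`.
#' @examples
#' cs_model("two_param")
#' cs_model("three_param_exp", "distance_of_speed")
#' @export
cs_model <- function(family = cs_families(), formulation = cs_formulations()) {
  family <- match.arg(family)
  formulation <- match.arg(formulation)
  structure(list(family = family, formulation = formulation),
            class = "cs_model_spec")
}

#' @export
print.cs_model_spec <- function(x, ...) {
  cat(sprintf("<cs_model_spec> family: %s, formulation: %s\n",
              x$family, x$formulation))
  invisible(x)
}

#' Number of free parameters of a model family
#'
#' @param family Model family name (or a `cs_model_spec`).
#' @return 2 for the two-parameter model, 3 otherwise.
#' @export
n_model_params <- function(family) {
  if (inherits(family, "cs_model_spec")) family <- family$family
  family <- match.arg(family, cs_families())
  if (family == "two_param") 2L else 3L
}

#' Parameter names of a model family
#'
#' @inheritParams n_model_params
#' @return Character vector of parameter names in canonical order.
#' @export
model_param_names <- function(family) {
  if (inherits(family, "cs_model_spec")) family <- family$family
  family <- match.arg(family, cs_families())
  switch(family,
         two_param       = c("cs", "d_prime"),
         three_param     = c("cs", "d_prime", "s_max"),
         three_param_exp = c("cs", "tau", "s_max"))
}

#' Construct and validate model parameters
#'
#' Parameters carry SI units throughout: speeds in m/s, distances in m,
#' times in s. `cs` is the critical speed (asymptote of the speed-duration
#' curve), `d_prime` the finite distance that can be run above CS,
#' `s_max` the maximal instantaneous running speed of the three-parameter
#' families, and `tau` the time constant of the exponential model.
#'
#' @param cs Critical speed (m/s), > 0.
#' @param d_prime Distance above CS (m), > 0; required for `two_param` and
#'   `three_param`.
#' @param s_max Maximal instantaneous speed (m/s), > `cs`; required for the
#'   three-parameter families.
#' @param tau Time constant (s), > 0; required for `three_param_exp`.
#' @param family Optional family name; when given, the presence of exactly
#'   the parameters that family needs is enforced.
#' @return A named list of class `cs_params`.
#' @examples
#' cs_params(cs = 4.4, d_prime = 225)
#' cs_params(cs = 4.5, tau = 250, s_max = 7, family = "three_param_exp")
#' @export
cs_params <- function(cs, d_prime = NULL, s_max = NULL, tau = NULL,
                      family = NULL) {
  stopifnot(is.numeric(cs), length(cs) == 1L, is.finite(cs))
  if (cs <= 0) stop("'cs' must be strictly positive")
  chk_pos <- function(x, nm) {
    if (!is.null(x)) {
      stopifnot(is.numeric(x), length(x) == 1L, is.finite(x))
      if (x <= 0) stop(sprintf("'%s' must be strictly positive", nm))
    }
  }
  chk_pos(d_prime, "d_prime")
  chk_pos(tau, "tau")
  if (!is.null(s_max)) {
    stopifnot(is.numeric(s_max), length(s_max) == 1L, is.finite(s_max))
    if (s_max <= cs) stop("'s_max' must exceed 'cs'")
  }
  if (!is.null(family)) {
    need <- model_param_names(family)
    p <- list(cs = cs, d_prime = d_prime, s_max = s_max, tau = tau)
    missing <- need[vapply(p[need], is.null, logical(1))]
    if (length(missing))
      stop(sprintf("family '%s' requires parameter(s): %s",
                   family, paste(missing, collapse = ", ")))
  }
  structure(list(cs = cs, d_prime = d_prime, s_max = s_max, tau = tau),
            class = "cs_params")
}

as_cs_params <- function(x, family = NULL) {
  if (inherits(x, "cs_params")) return(x)
  x <- as.list(x)
  cs_params(cs = x$cs, d_prime = x$d_prime, s_max = x$s_max, tau = x$tau,
            family = family)
}

check_speed_domain <- function(family, params, speed) {
  if (any(!is.finite(speed)) || any(speed <= params$cs))
    stop("speed must be strictly greater than cs (time is undefined or infinite at or below CS)")
  if (family %in% c("three_param", "three_param_exp") &&
      any(speed > params$s_max))
    stop("speed must not exceed s_max for three-parameter families")
  invisible(TRUE)
}

#' Predicted time to exhaustion at a given speed
#'
#' Evaluates the chosen family's time-of-speed curve. The prediction is
#' strictly positive and strictly decreasing in speed on the model's valid
#' domain (`cs` exclusive up to `s_max`, or unbounded above for the
#' two-parameter model). At `speed == s_max` the three-parameter families
#' return exactly 0.
#'
#' @param spec A [cs_model()] specification (the formulation is ignored;
#'   prediction is a property of the family).
#' @param params A [cs_params()] object (or coercible list).
#' @param speed Speed(s) in m/s, strictly above `cs` (and at most `s_max`
#'   where applicable).
#' @return Time(s) to exhaustion in seconds.
#' @examples
#' p <- cs_params(cs = 4.39, d_prime = 226)
#' predict_time(cs_model("two_param"), p, 4.644)  # ~889.8 s
#' @export
predict_time <- function(spec, params, speed) {
  family <- if (inherits(spec, "cs_model_spec")) spec$family else
    match.arg(spec, cs_families())
  params <- as_cs_params(params, family = family)
  check_speed_domain(family, params, speed)
  switch(family,
    two_param = params$d_prime / (speed - params$cs),
    three_param = params$d_prime * (params$s_max - speed) /
      ((speed - params$cs) * (params$s_max - params$cs)),
    three_param_exp = params$tau *
      log((params$s_max - params$cs) / (speed - params$cs)))
}

#' Predicted distance at a given speed
#'
#' Distance as a function of speed is speed times the time-of-speed
#' prediction, `d(s) = s * t(s)`; the identity holds to machine precision.
#'
#' @inheritParams predict_time
#' @return Distance(s) in metres.
#' @export
predict_distance <- function(spec, params, speed) {
  speed * predict_time(spec, params, speed)
}

#' Speed sustainable for a given time (two-parameter model)
#'
#' The inverse of the two-parameter hyperbola: `s(t) = d'/t + CS`. As
#' `t` grows the sustainable speed approaches CS from above.
#'
#' @param params A [cs_params()] with `cs` and `d_prime`.
#' @param time Time(s) in seconds, strictly positive.
#' @return Speed(s) in m/s.
#' @examples
#' speed_from_time_two_param(cs_params(4, d_prime = 200), 100)  # 6 m/s
#' @export
speed_from_time_two_param <- function(params, time) {
  params <- as_cs_params(params, family = "two_param")
  if (any(!is.finite(time)) || any(time <= 0))
    stop("'time' must be strictly positive")
  params$d_prime / time + params$cs
}

#' Time-dependent distance above CS in the exponential model
#'
#' The exponential model has no fixed `d_prime`; the distance that can be
#' run above CS depends on exercise duration:
#' \eqn{d'(t) = t (s_{max} - CS) e^{-t/\tau}}. It is 0 at `t = 0` and
#' attains its maximum at `t = tau`.
#'
#' @param params A [cs_params()] with `cs`, `tau`, `s_max`.
#' @param time Time(s) in seconds, >= 0.
#' @return Distance(s) in metres.
#' @seealso [dprime_max()] for the maximum, used as the model's `d_prime`
#'   estimate in cross-model comparisons.
#' @export
dprime_transient <- function(params, time) {
  params <- as_cs_params(params, family = "three_param_exp")
  if (any(!is.finite(time)) || any(time < 0))
    stop("'time' must be non-negative")
  time * (params$s_max - params$cs) * exp(-time / params$tau)
}

#' Maximal distance above CS in the exponential model
#'
#' Closed form of the maximum of [dprime_transient()], reached at
#' `t = tau`: \eqn{d'_{max} = \tau (s_{max} - CS) / e}. This is the
#' quantity reported as the exponential model's `d_prime` whenever models
#' are compared.
#'
#' @param params A [cs_params()] with `cs`, `tau`, `s_max` (a degenerate
#'   `s_max == cs` is accepted here and yields 0).
#' @return Distance in metres.
#' @export
dprime_max <- function(params) {
  params <- as.list(params)
  if (is.null(params$tau) || is.null(params$s_max) || is.null(params$cs))
    stop("dprime_max() requires 'cs', 'tau' and 's_max'")
  if (params$tau <= 0) stop("'tau' must be strictly positive")
  if (params$s_max < params$cs) stop("'s_max' must be >= 'cs'")
  params$tau * (params$s_max - params$cs) * exp(-1)
}
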