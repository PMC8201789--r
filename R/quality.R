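## Fit-quality metrics ------------------------------------------------------

#' Confidence intervals for fitted parameters
#'
#' Student-t intervals on the asymptotic standard errors:
#' `half_width = t(1 - (1-level)/2, df) * SE` with `df = n - p`. The 90%
#' level is the conventional reporting choice for speed-duration fits.
#'
#' @param fit A [fit_cs()] result with `df >= 1` and available standard
#'   errors.
#' @param level Confidence level, default 0.90.
#' @return A data frame of class `cs_intervals` with columns `parameter`,
#'   `estimate`, `se`, `half_width`, `lower`, `upper` and attribute `level`.
#' @export
parameter_intervals <- function(fit, level = 0.90) {
  stopifnot(inherits(fit, "cs_fit"), level >= 0, level < 1)
  if (fit$df < 1L || any(is.na(fit$se)))
    stop("confidence intervals unavailable: df < 1 or standard errors missing")
  tq <- stats::qt(1 - (1 - level) / 2, df = fit$df)
  hw <- tq * fit$se
  out <- data.frame(parameter = names(fit$params),
                    estimate = unname(fit$params),
                    se = unname(fit$se),
                    half_width = unname(hw),
                    lower = unname(fit$params - hw),
                    upper = unname(fit$params + hw))
  attr(out, "level") <- level
  class(out) <- c("cs_intervals", "data.frame")
  out
}

#' Combined percent standard error of estimate
#'
#' The sum over fitted parameters of the standard errors expressed as a
#' percentage of their estimates: \eqn{\sum_i 100 \, SE_i / |\hat\theta_i|}.
#' For the exponential family the fitted parameters are (CS, tau, s_max);
#' setting `dprime_max_variant = TRUE` replaces the tau term with the
#' delta-method relative standard error of the derived
#' `d_max' = tau (s_max - CS)/e`, for comparability with families that fit
#' `d_prime` directly.
#'
#' @param fit A [fit_cs()] result with available standard errors.
#' @param dprime_max_variant Logical; only meaningful for
#'   `three_param_exp`.
#' @return Combined SEE in percent (scalar, >= 0).
#' @export
combined_percent_see <- function(fit, dprime_max_variant = FALSE) {
  stopifnot(inherits(fit, "cs_fit"))
  if (any(is.na(fit$se)))
    stop("standard errors unavailable for this fit")
  if (any(fit$params == 0))
    stop("zero parameter estimate: percent SEE undefined")
  terms <- 100 * fit$se / abs(fit$params)
  if (dprime_max_variant && fit$spec$family == "three_param_exp" &&
      !is.null(fit$vcov)) {
    p <- fit$params
    dmax <- dprime_max(list(cs = p[["cs"]], tau = p[["tau"]],
                            s_max = p[["s_max"]]))
    grad <- c(cs = -p[["tau"]] / exp(1),
              tau = (p[["s_max"]] - p[["cs"]]) / exp(1),
              s_max = p[["tau"]] / exp(1))
    v <- drop(t(grad) %*% fit$vcov[names(grad), names(grad)] %*% grad)
    terms[["tau"]] <- 100 * sqrt(max(v, 0)) / dmax
  }
  sum(terms)
}

#' RSS-based Akaike information criterion
#'
#' `AIC = n log(RSS_w / n) + 2p` on the weighted residual sum of squares.
#' Because the units of the residuals depend on the formulation (seconds
#' for `t(s)`, metres for `d(s)`), the value is comparable only across
#' model families *within* one formulation, never between formulations.
#'
#' @param fit A [fit_cs()] result with `weighted_rss > 0`.
#' @return The AIC (scalar); `NA` with a warning for a perfect fit
#'   (`weighted_rss == 0`), where the criterion diverges.
#' @export
fit_aic <- function(fit) {
  stopifnot(inherits(fit, "cs_fit"))
  n <- fit$n_obs
  p <- length(fit$params)
  if (fit$weighted_rss <= 0) {
    warning("weighted RSS is zero: AIC undefined for a perfect fit")
    return(NA_real_)
  }
  n * log(fit$weighted_rss / n) + 2 * p
}

#' Heteroscedasticity diagnostic
#'
#' Pairs each prediction with its absolute weighted residual
#' `|sqrt(w_i) (y_i - yhat_i)|` and summarises the association by the
#' Spearman rank correlation between the two (the heteroscedasticity
#' index). Under the assumed error law (variance proportional to the
#' dependent variable) the weighted residual has constant spread, so the
#' index should fluctuate around 0; a systematic index indicates residual
#' spread still varying with the predicted value.
#'
#' By default the fit's own weights are used. Supplying `weights` instead
#' evaluates the diagnostic under an externally assumed error model - the
#' natural way to inspect an *unweighted* fit's residuals against the
#' inverse-variance law its weighted counterpart assumes.
#'
#' Note that with very few observations per fit the index is dominated by
#' leverage: near the hyperbola's asymptote the slowest-speed point is fit
#' almost exactly, shrinking its residual regardless of the noise law.
#' Pool profiles across participants before interpreting cohort-level
#' heteroscedasticity.
#'
#' @param fit A [fit_cs()] result.
#' @param weights Optional weight vector (length `n_obs`) replacing the
#'   fit's own weights in the diagnostic quantity.
#' @return A list of class `cs_resid_profile` with `profile` (data frame
#'   `predicted`, `abs_weighted_residual`) and `index` (scalar; 0 when the
#'   correlation is undefined, e.g. all residuals zero).
#' @export
residual_heteroscedasticity <- function(fit, weights = NULL) {
  stopifnot(inherits(fit, "cs_fit"))
  awr <- if (is.null(weights)) abs(fit$weighted_residuals) else {
    stopifnot(length(weights) == fit$n_obs, all(weights > 0))
    abs(sqrt(weights) * fit$residuals)
  }
  prof <- data.frame(predicted = fit$fitted, abs_weighted_residual = awr)
  scale_ref <- max(abs(prof$predicted), 1)
  if (all(prof$abs_weighted_residual <= 1e-8 * scale_ref)) {
    idx <- 0  # numerically perfect fit: no spread left to rank
  } else {
    idx <- suppressWarnings(
      stats::cor(prof$predicted, prof$abs_weighted_residual,
                 method = "spearman"))
    if (is.na(idx)) idx <- 0
  }
  structure(list(profile = prof, index = idx), class = "cs_resid_profile")
}

#' Percent excess of one value over another
#'
#' `100 (a - b) / b`: by how many percent `a` exceeds the reference `b`.
#' Used e.g. to express how much larger one model's AIC is than another's.
#' Note this is not antisymmetric: `percent_excess(a, b)` and
#' `percent_excess(b, a)` only cancel multiplicatively at 0.
#'
#' @param a Value of interest.
#' @param b Strictly positive reference value.
#' @return Percent excess (may be negative).
#' @examples
#' percent_excess(32.3, 24.1)  # ~34
#' @export
percent_excess <- function(a, b) {
  if (any(!is.finite(b)) || any(b <= 0))
    stop("reference value 'b' must be strictly positive")
  100 * (a - b) / b
}
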