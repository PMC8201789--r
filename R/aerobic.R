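## Incremental-test physiology mapping --------------------------------------

#' Incremental treadmill protocol
#'
#' The default protocol is a 2.78 m/s warm-up speed followed by 0.28 m/s
#' increments every 2 min, implying the straight line
#' `speed = 2.78 + 0.14 t` with `t` in minutes.
#'
#' @param warmup_speed Warm-up/starting speed (m/s).
#' @param increment Speed increment per step (m/s).
#' @param step_duration Step duration (min).
#' @return A list of class `cs_protocol` with the three fields plus the
#'   implied `slope` (m/s per min).
#' @export
incremental_protocol <- function(warmup_speed = 2.78, increment = 0.28,
                                 step_duration = 2) {
  stopifnot(warmup_speed > 0, increment > 0, step_duration > 0)
  structure(list(warmup_speed = warmup_speed, increment = increment,
                 step_duration = step_duration,
                 slope = increment / step_duration),
            class = "cs_protocol")
}

#' Peak speed of an incremental test
#'
#' `PS = s_vo2max + alpha * delta_s`: the speed of the last fully completed
#' increment plus the fraction of the following uncompleted increment that
#' was sustained, credited proportionally.
#'
#' @param s_vo2max Speed of the last completed increment (m/s).
#' @param alpha Fraction of the uncompleted increment completed, in `[0, 1)`.
#' @param delta_s Speed increment (m/s), default 0.28.
#' @return Peak speed (m/s).
#' @examples
#' peak_speed(5.05, 0.3929)  # ~5.16
#' @export
peak_speed <- function(s_vo2max, alpha, delta_s = 0.28) {
  if (any(alpha < 0) || any(alpha >= 1))
    stop("'alpha' must lie in [0, 1)")
  stopifnot(s_vo2max > 0, delta_s > 0)
  s_vo2max + alpha * delta_s
}

#' Incremental-test time at which a speed is reached
#'
#' Inverts the protocol's speed-time line: under the default protocol,
#' `t = (speed - 2.78) / 0.14` minutes.
#'
#' @param speed Speed (m/s), at least the warm-up speed.
#' @param protocol An [incremental_protocol()].
#' @return Time in minutes.
#' @examples
#' incremental_time_at_speed(4.39)  # 11.5 min
#' @export
incremental_time_at_speed <- function(speed, protocol = incremental_protocol()) {
  stopifnot(inherits(protocol, "cs_protocol"))
  if (any(speed < protocol$warmup_speed))
    stop("speed below the protocol warm-up speed")
  (speed - protocol$warmup_speed) / protocol$slope
}

#' Per-participant incremental-test summary
#'
#' Holds the physiological landmarks of one maximal incremental test:
#' the speed of the last completed increment (`s_vo2max`), the fractional
#' credit `alpha` (giving peak speed via [peak_speed()]), V-dot-O2max,
#' the ventilatory threshold (VT) and respiratory compensation point (RCP),
#' and the linear regression of V-dot-O2 on incremental-test time
#' (intercept in ml/min/kg, slope in ml/min/kg per minute).
#'
#' @param participant_id Label.
#' @param s_vo2max Speed of last completed increment (m/s).
#' @param alpha Fraction of uncompleted increment, `[0, 1)`.
#' @param vo2max Maximal oxygen uptake (ml/min/kg).
#' @param vt,rcp Ventilatory threshold / respiratory compensation point
#'   (ml/min/kg); a violated ordering `vt < rcp < vo2max` warns.
#' @param vo2_intercept,vo2_slope The V-dot-O2-vs-time line; a
#'   non-positive slope warns.
#' @param r_squared Coefficient of determination of that line.
#' @param delta_s Speed increment (m/s).
#' @return A list of class `cs_incremental_profile` including the derived
#'   `peak_speed`.
#' @export
incremental_profile <- function(participant_id, s_vo2max, alpha, vo2max,
                                vt = NA_real_, rcp = NA_real_,
                                vo2_intercept, vo2_slope,
                                r_squared = NA_real_, delta_s = 0.28) {
  ps <- peak_speed(s_vo2max, alpha, delta_s)
  stopifnot(vo2max > 0)
  if (!is.na(vt) && !is.na(rcp) && !(vt < rcp && rcp < vo2max))
    warning("expected ordering vt < rcp < vo2max is violated")
  if (vo2_slope <= 0)
    warning("V-dot-O2-vs-time slope is not positive")
  structure(list(participant_id = as.character(participant_id)[1L],
                 s_vo2max = s_vo2max, alpha = alpha, delta_s = delta_s,
                 peak_speed = ps, vo2max = vo2max, vt = vt, rcp = rcp,
                 vo2_intercept = vo2_intercept, vo2_slope = vo2_slope,
                 r_squared = r_squared),
            class = "cs_incremental_profile")
}

#' Oxygen uptake at critical speed
#'
#' Converts a CS estimate to the incremental-test time at which that speed
#' occurred (via the protocol line) and reads the participant's
#' V-dot-O2-vs-time regression at that time. Because the mapping is affine
#' in CS, any between-model differences in CS translate one-to-one into
#' differences in V-dot-O2 at CS.
#'
#' @param profile An [incremental_profile()].
#' @param cs Critical speed estimate (m/s); must be at least the warm-up
#'   speed. A CS above the participant's peak speed is extrapolation beyond
#'   the test end and is returned with `extrapolated = TRUE`.
#' @param protocol An [incremental_protocol()].
#' @return A list with `vo2` (ml/min/kg), `percent_vo2max`, `time_min`,
#'   and `extrapolated`.
#' @export
vo2_at_cs <- function(profile, cs, protocol = incremental_protocol()) {
  stopifnot(inherits(profile, "cs_incremental_profile"))
  t_min <- incremental_time_at_speed(cs, protocol)
  vo2 <- profile$vo2_intercept + profile$vo2_slope * t_min
  extrapolated <- cs > profile$peak_speed
  if (extrapolated)
    warning("CS exceeds the incremental-test peak speed; V-dot-O2 extrapolated")
  list(vo2 = vo2,
       percent_vo2max = 100 * vo2 / profile$vo2max,
       time_min = t_min,
       extrapolated = extrapolated)
}

#' Critical speed as a percentage of a reference speed
#'
#' Typically the reference is `s_vo2max`, giving CS as %s_vo2max. Group
#' summaries of such ratios should be formed as means of per-participant
#' percentages, not as the ratio of group means.
#'
#' @param cs Critical speed (m/s).
#' @param reference Strictly positive reference speed (m/s).
#' @return Percentage.
#' @export
relative_cs <- function(cs, reference) {
  if (any(!is.finite(reference)) || any(reference <= 0))
    stop("'reference' must be strictly positive")
  100 * cs / reference
}
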