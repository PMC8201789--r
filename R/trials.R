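## Trial containers and CSV readers -----------------------------------------

#' One participant's exhaustive-run trials
#'
#' Bundles the (speed, time-to-exhaustion) observations of one participant,
#' the typical design being four constant-speed runs at 90, 100, 110 and
#' 120% of the peak speed of an incremental test. Distance per observation
#' is derived as speed x time.
#'
#' @param participant_id Participant label.
#' @param speed Speeds in m/s; strictly positive, pairwise distinct.
#' @param time Times to exhaustion in s; strictly positive.
#' @param peak_speed Optional incremental-test peak speed (m/s).
#' @return An object of class `cs_trial_set` with an `observations`
#'   data frame (`speed`, `time`, `distance`).
#' @examples
#' trial_set("p01", speed = c(4.6, 5.2, 5.7, 6.2),
#'           time = c(880, 360, 170, 100))
#' @export
trial_set <- function(participant_id, speed, time, peak_speed = NULL) {
  stopifnot(length(speed) == length(time), length(speed) >= 1L)
  speed <- as.numeric(speed); time <- as.numeric(time)
  if (any(!is.finite(speed)) || any(speed <= 0))
    stop("speeds must be strictly positive")
  if (any(!is.finite(time)) || any(time <= 0))
    stop("times must be strictly positive")
  if (anyDuplicated(speed))
    stop("speeds must be pairwise distinct")
  if (!is.null(peak_speed))
    stopifnot(is.numeric(peak_speed), length(peak_speed) == 1L, peak_speed > 0)
  structure(list(
    participant_id = as.character(participant_id)[1L],
    observations = data.frame(speed = speed, time = time,
                              distance = speed * time),
    peak_speed = peak_speed
  ), class = "cs_trial_set")
}

#' @export
print.cs_trial_set <- function(x, ...) {
  cat(sprintf("<cs_trial_set> participant %s, %d trials\n",
              x$participant_id, nrow(x$observations)))
  print(x$observations, row.names = FALSE)
  invisible(x)
}

#' Group-mean reference trial set
#'
#' A single pseudo-participant built from published group means for trained
#' male runners: peak speed 5.16 m/s, trial speeds at 90/100/110/120% of
#' peak speed, and mean times to exhaustion of 14.8, 5.94, 2.78 and
#' 1.68 min (converted to seconds). Useful as a deterministic fixture for
#' fitting and reporting examples; note that a fit to group means is not
#' the mean of individual fits.
#'
#' @return A [trial_set()] with four observations.
#' @examples
#' group_mean_trialset()
#' @export
group_mean_trialset <- function() {
  ps <- 5.16
  trial_set("group_mean",
            speed = c(0.90, 1.00, 1.10, 1.20) * ps,
            time = c(14.8, 5.94, 2.78, 1.68) * 60,
            peak_speed = ps)
}

#' Read exhaustive-run trials from CSV
#'
#' The canonical long format has a header and columns
#' `participant_id,speed_mps,time_s`, one row per exhaustive run. Two
#' variants are accepted and converted: `time_min` instead of `time_s`
#' (minutes, multiplied by 60), and percent-of-peak-speed coding
#' `percent_ps,peak_speed_mps` instead of `speed_mps`
#' (`speed = percent_ps/100 * peak_speed_mps`).
#'
#' @param path Path to a CSV file.
#' @return A named list of [trial_set()] objects, one per participant.
#' @export
read_trials <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"participant_id" %in% names(df))
    stop("trial CSV must have a 'participant_id' column")
  if (!"time_s" %in% names(df)) {
    if ("time_min" %in% names(df)) df$time_s <- df$time_min * 60
    else stop("trial CSV must have 'time_s' or 'time_min'")
  }
  if (!"speed_mps" %in% names(df)) {
    if (all(c("percent_ps", "peak_speed_mps") %in% names(df)))
      df$speed_mps <- df$percent_ps / 100 * df$peak_speed_mps
    else stop("trial CSV must have 'speed_mps' or ('percent_ps','peak_speed_mps')")
  }
  trials_from_frame(df)
}

#' Split a long trial data frame into per-participant trial sets
#'
#' @param df Data frame with columns `participant_id`, `speed_mps`,
#'   `time_s` and optionally `peak_speed_mps`.
#' @return Named list of [trial_set()] objects.
#' @export
trials_from_frame <- function(df) {
  stopifnot(all(c("participant_id", "speed_mps", "time_s") %in% names(df)))
  ids <- unique(df$participant_id)
  out <- lapply(ids, function(id) {
    sub <- df[df$participant_id == id, , drop = FALSE]
    ps <- if ("peak_speed_mps" %in% names(sub)) sub$peak_speed_mps[1L] else NULL
    if (!is.null(ps) && is.na(ps)) ps <- NULL
    trial_set(id, sub$speed_mps, sub$time_s, peak_speed = ps)
  })
  names(out) <- as.character(ids)
  out
}

#' Flatten trial sets to a long data frame
#'
#' Inverse of [trials_from_frame()]; the format written by the `simulate`
#' pipeline and accepted by [read_trials()].
#'
#' @param trials A `cs_trial_set` or list of them.
#' @return Data frame with columns `participant_id`, `speed_mps`, `time_s`,
#'   `peak_speed_mps`.
#' @export
trials_to_frame <- function(trials) {
  if (inherits(trials, "cs_trial_set")) trials <- list(trials)
  do.call(rbind, lapply(trials, function(tr) {
    data.frame(participant_id = tr$participant_id,
               speed_mps = tr$observations$speed,
               time_s = tr$observations$time,
               peak_speed_mps = if (is.null(tr$peak_speed)) NA_real_ else tr$peak_speed)
  }))
}

#' Read incremental-test summaries from CSV
#'
#' Expected columns: `participant_id,s_vo2max_mps,alpha,vo2max,vt,rcp,`
#' `vo2_intercept,vo2_slope,r2`. Oxygen uptake values are in ml/min/kg; the
#' V-dot-O2 line is (intercept ml/min/kg, slope ml/min/kg per minute of
#' incremental-test time).
#'
#' @param path Path to a CSV file.
#' @return Named list of [incremental_profile()] objects.
#' @export
read_incremental <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("participant_id", "s_vo2max_mps", "alpha", "vo2max",
            "vo2_intercept", "vo2_slope")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("incremental CSV missing column(s): ", paste(missing, collapse = ", "))
  out <- lapply(seq_len(nrow(df)), function(i) {
    incremental_profile(
      participant_id = df$participant_id[i],
      s_vo2max = df$s_vo2max_mps[i],
      alpha = df$alpha[i],
      vo2max = df$vo2max[i],
      vt = if ("vt" %in% names(df)) df$vt[i] else NA_real_,
      rcp = if ("rcp" %in% names(df)) df$rcp[i] else NA_real_,
      vo2_intercept = df$vo2_intercept[i],
      vo2_slope = df$vo2_slope[i],
      r_squared = if ("r2" %in% names(df)) df$r2[i] else NA_real_)
  })
  names(out) <- as.character(df$participant_id)
  out
}
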