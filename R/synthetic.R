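## Synthetic cohorts --------------------------------------------------------

rtrunc_norm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (sd == 0) return(rep(mean, n))
  out <- numeric(n); got <- 0L; tries <- 0L
  while (got < n) {
    draw <- stats::rnorm(n - got, mean, sd)
    keep <- draw > lower & draw < upper
    k <- sum(keep)
    if (k) { out[got + seq_len(k)] <- draw[keep]; got <- got + k }
    tries <- tries + 1L
    if (tries > 1000L) stop("truncated-normal rejection sampling failed; check bounds")
  }
  out
}

#' Configuration of a synthetic cohort
#'
#' Defaults describe a cohort of trained male runners: critical speed
#' around 4.4 m/s (SD 0.4), `d_prime` around 225 m (SD 55), `s_max` around
#' 7.5 m/s (SD 0.8, truncated above `cs + 1`), `tau` around 250 s (SD 50,
#' positive), four trials at 90/100/110/120% of peak speed, and
#' multiplicative noise whose variance is proportional to the time to
#' exhaustion (the heteroscedasticity law the inverse-variance weights
#' assume). Peak speed is derived from CS through a ratio draw
#' `CS/PS ~ N(0.85, 0.03)` truncated to (0.7, 0.95), so the slowest trial
#' speed always exceeds CS. Draws whose slowest trial would last longer
#' than 40 min are redrawn: such a speed sits too close to CS to function
#' as an exhaustive severe-domain trial.
#'
#' @param n_participants Cohort size.
#' @param generating_family Model family generating the noise-free times.
#' @param cs_mean,cs_sd CS distribution (m/s).
#' @param dprime_mean,dprime_sd `d_prime` distribution (m); used by the
#'   two- and three-parameter families.
#' @param smax_mean,smax_sd `s_max` distribution (m/s); truncated above
#'   `cs + 1`.
#' @param tau_mean,tau_sd `tau` distribution (s); truncated positive.
#' @param trial_percents Trial speeds as percent of peak speed.
#' @param noise_model `"variance_prop_t"` multiplies each time by a
#'   lognormal factor with mean 1 and variance `noise_scale^2 / t`, so the
#'   observed-time variance is proportional to `t`; `"constant_cv"` uses a
#'   fixed coefficient of variation `noise_scale`; `"none"` is noise-free.
#' @param noise_scale Noise scale (dimensionless; see `noise_model`).
#' @param seed Integer seed; identical seeds give bitwise-identical cohorts.
#' @param exclude_short_trials Drop trials whose noise-free time is under
#'   120 s (such very short efforts are often considered unreliable);
#'   default `FALSE`.
#' @return A list of class `cs_synthetic_config`.
#' @export
synthetic_config <- function(n_participants = 16L,
                             generating_family = cs_families(),
                             cs_mean = 4.4, cs_sd = 0.4,
                             dprime_mean = 225, dprime_sd = 55,
                             smax_mean = 7.5, smax_sd = 0.8,
                             tau_mean = 250, tau_sd = 50,
                             trial_percents = c(90, 100, 110, 120),
                             noise_model = c("variance_prop_t",
                                             "constant_cv", "none"),
                             noise_scale = 1.5,
                             seed = NULL,
                             exclude_short_trials = FALSE) {
  generating_family <- match.arg(generating_family)
  noise_model <- match.arg(noise_model)
  stopifnot(n_participants >= 1, cs_sd >= 0, dprime_sd >= 0, smax_sd >= 0,
            tau_sd >= 0, noise_scale >= 0,
            length(trial_percents) >= 1, all(trial_percents > 0),
            !anyDuplicated(trial_percents))
  structure(as.list(environment()), class = "cs_synthetic_config")
}

sample_participant <- function(config, id) {
  fam <- config$generating_family
  for (attempt in 1:50) {
    cs <- rtrunc_norm(1, config$cs_mean, config$cs_sd, lower = 0.5)
    ratio <- rtrunc_norm(1, 0.85, 0.03, lower = 0.7, upper = 0.95)
    ps <- cs / ratio
    speeds <- config$trial_percents / 100 * ps
    if (min(speeds) <= cs) next
    params <- list(cs = cs)
    if (fam %in% c("two_param", "three_param"))
      params$d_prime <- rtrunc_norm(1, config$dprime_mean, config$dprime_sd,
                                    lower = 10)
    if (fam != "two_param") {
      params$s_max <- rtrunc_norm(1, config$smax_mean, config$smax_sd,
                                  lower = cs + 1)
      if (max(speeds) >= params$s_max) next
    }
    if (fam == "three_param_exp")
      params$tau <- rtrunc_norm(1, config$tau_mean, config$tau_sd, lower = 1)
    t_true <- predict_time(cs_model(fam), as_cs_params(params, fam), speeds)
    ## the slowest trial must terminate within 40 min: longer efforts mean
    ## the speed sits too close to CS to be a usable severe-domain trial
    if (max(t_true) > 2400) next
    t_obs <- switch(config$noise_model,
      none = t_true,
      constant_cv = {
        cv2 <- config$noise_scale^2
        sdl <- sqrt(log1p(cv2))
        t_true * stats::rlnorm(length(t_true), -sdl^2 / 2, sdl)
      },
      variance_prop_t = {
        cv2 <- config$noise_scale^2 / t_true
        sdl <- sqrt(log1p(cv2))
        t_true * stats::rlnorm(length(t_true), -sdl^2 / 2, sdl)
      })
    keep <- if (config$exclude_short_trials) t_true >= 120 else
      rep(TRUE, length(t_true))
    if (sum(keep) < n_model_params(fam) + 1L) next
    ## incremental-test physiology consistent with the drawn peak speed
    alpha <- stats::runif(1, 0, 0.999)
    s_vo2max <- ps - alpha * 0.28
    ## V-dot-O2max drawn conditionally on CS (r ~ 0.9 marginally): CS is an
    ## expression of aerobic capacity, so the two co-vary in real cohorts
    vo2max <- rtrunc_norm(1, 63 + 11 * (cs - 4.4), 2.1, lower = 40)
    vt_frac <- rtrunc_norm(1, 0.748, 0.041, lower = 0.55, upper = 0.86)
    rcp_frac <- rtrunc_norm(1, 0.893, 0.036, lower = vt_frac + 0.02,
                            upper = 0.99)
    t_end <- (ps - 2.78) / 0.14
    intercept <- rtrunc_norm(1, 40, 3, lower = 25)
    slope <- (vo2max - intercept) / t_end * stats::rlnorm(1, 0, 0.03)
    profile <- incremental_profile(
      participant_id = id, s_vo2max = s_vo2max, alpha = alpha,
      vo2max = vo2max, vt = vt_frac * vo2max, rcp = rcp_frac * vo2max,
      vo2_intercept = intercept, vo2_slope = slope, r_squared = 0.94)
    return(list(id = id,
                truth = c(params, list(family = fam, peak_speed = ps,
                                       true_times = t_true[keep])),
                trials = trial_set(id, speeds[keep], t_obs[keep],
                                   peak_speed = ps),
                profile = profile,
                attempts = attempt))
  }
  stop("participant rejection rate too high; trial percents or CS/PS ratio ",
       "leave no speed above CS - adjust the configuration")
}

#' Draw a synthetic cohort
#'
#' Samples per-participant true parameters, derives trial speeds from the
#' configured percent-of-peak-speed design, computes noise-free times from
#' the generating family and applies the configured noise. True parameters
#' are retained for recovery scoring. With a non-`NULL` seed the cohort is
#' fully reproducible.
#'
#' @param config A [synthetic_config()].
#' @return A list of class `cs_synthetic_cohort` with `participants`
#'   (each: `id`, `truth`, `trials`, `profile`) and `config`.
#' @export
sample_cohort <- function(config) {
  stopifnot(inherits(config, "cs_synthetic_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  participants <- lapply(seq_len(config$n_participants), function(i)
    sample_participant(config, sprintf("p%02d", i)))
  structure(list(participants = participants, config = config),
            class = "cs_synthetic_cohort")
}

#' @export
print.cs_synthetic_cohort <- function(x, ...) {
  cat(sprintf("<cs_synthetic_cohort> %d participants, generator %s, noise %s (scale %g)\n",
              length(x$participants), x$config$generating_family,
              x$config$noise_model, x$config$noise_scale))
  invisible(x)
}

#' True parameters of a synthetic cohort
#'
#' @param cohort A [sample_cohort()] result.
#' @return Data frame `participant_id`, `family`, `true_cs`, `true_dprime`,
#'   `true_smax`, `true_tau`, `peak_speed_mps` (absent parameters `NA`).
#' @export
cohort_truth <- function(cohort) {
  stopifnot(inherits(cohort, "cs_synthetic_cohort"))
  do.call(rbind, lapply(cohort$participants, function(p) {
    tr <- p$truth
    data.frame(participant_id = p$id, family = tr$family,
               true_cs = tr$cs,
               true_dprime = if (is.null(tr$d_prime)) NA_real_ else tr$d_prime,
               true_smax = if (is.null(tr$s_max)) NA_real_ else tr$s_max,
               true_tau = if (is.null(tr$tau)) NA_real_ else tr$tau,
               peak_speed_mps = tr$peak_speed)
  }))
}

#' Trial sets of a synthetic cohort
#'
#' @param cohort A [sample_cohort()] result.
#' @return Named list of [trial_set()] objects.
#' @export
cohort_trials <- function(cohort) {
  stopifnot(inherits(cohort, "cs_synthetic_cohort"))
  out <- lapply(cohort$participants, `[[`, "trials")
  names(out) <- vapply(cohort$participants, `[[`, character(1), "id")
  out
}

#' Incremental profiles of a synthetic cohort
#'
#' @param cohort A [sample_cohort()] result.
#' @return Named list of [incremental_profile()] objects.
#' @export
cohort_profiles <- function(cohort) {
  stopifnot(inherits(cohort, "cs_synthetic_cohort"))
  out <- lapply(cohort$participants, `[[`, "profile")
  names(out) <- vapply(cohort$participants, `[[`, character(1), "id")
  out
}

#' Parameter-recovery experiment
#'
#' The end-to-end harness: repeatedly draws a cohort, runs [fit_battery()]
#' on every participant, and scores estimates against the generating truth.
#' CS is scored for every battery cell; the remaining parameters are scored
#' for cells whose family matches the generating family. Flagged fits are
#' excluded and counted.
#'
#' @param config A [synthetic_config()]; its seed (default drawn as-is)
#'   governs the whole experiment.
#' @param reps Number of replicate cohorts.
#' @param options [fit_options()] passed to the fits.
#' @param ci_level Level of the coverage-scored intervals (default 0.90).
#' @return Data frame of class `cs_recovery` keyed by family x formulation
#'   x parameter with columns `bias`, `rmse`, `coverage`, `mean_ci_half_width`,
#'   `n_scored`, `n_excluded`.
#' @export
recovery_experiment <- function(config, reps, options = fit_options(),
                                ci_level = 0.90) {
  stopifnot(inherits(config, "cs_synthetic_config"), reps >= 1)
  if (!is.null(config$seed)) set.seed(config$seed)
  config$seed <- NULL
  records <- list()
  for (rep_i in seq_len(reps)) {
    cohort <- sample_cohort(config)
    for (p in cohort$participants) {
      bat <- fit_battery(p$trials, options)
      truth <- p$truth
      for (f in bat) {
        fam <- f$spec$family
        if (inherits(f, "cs_fit_failure") || f$flagged) {
          records[[length(records) + 1L]] <- data.frame(
            family = fam, formulation = f$spec$formulation,
            parameter = NA_character_, error = NA_real_, hw = NA_real_,
            covered = NA, excluded = TRUE)
          next
        }
        hw <- rep(NA_real_, length(f$params)); names(hw) <- names(f$params)
        if (f$df >= 1L && !any(is.na(f$se)))
          hw <- stats::qt(1 - (1 - ci_level) / 2, f$df) * f$se
        score_par <- function(name, true_val) {
          data.frame(family = fam, formulation = f$spec$formulation,
                     parameter = name,
                     error = f$params[[name]] - true_val,
                     hw = unname(hw[name]),
                     covered = if (is.na(hw[name])) NA else
                       abs(f$params[[name]] - true_val) <= hw[name],
                     excluded = FALSE)
        }
        records[[length(records) + 1L]] <- score_par("cs", truth$cs)
        if (fam == truth$family) {
          for (nm in setdiff(model_param_names(fam), "cs")) {
            tv <- switch(nm, d_prime = truth$d_prime, s_max = truth$s_max,
                         tau = truth$tau)
            records[[length(records) + 1L]] <- score_par(nm, tv)
          }
        }
      }
    }
  }
  rec <- do.call(rbind, records)
  scored <- rec[!rec$excluded, , drop = FALSE]
  keys <- unique(scored[c("family", "formulation", "parameter")])
  out <- do.call(rbind, lapply(seq_len(nrow(keys)), function(i) {
    k <- keys[i, ]
    sub <- scored[scored$family == k$family &
                  scored$formulation == k$formulation &
                  scored$parameter == k$parameter, ]
    excl <- rec[rec$excluded & rec$family == k$family &
                rec$formulation == k$formulation, ]
    data.frame(family = k$family, formulation = k$formulation,
               parameter = k$parameter,
               bias = mean(sub$error),
               rmse = sqrt(mean(sub$error^2)),
               coverage = mean(sub$covered, na.rm = TRUE),
               mean_ci_half_width = mean(sub$hw, na.rm = TRUE),
               n_scored = nrow(sub),
               n_excluded = nrow(excl))
  }))
  rownames(out) <- NULL
  class(out) <- c("cs_recovery", "data.frame")
  out
}
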