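## End-to-end study pipeline ------------------------------------------------

fit_row <- function(fit, ci_level) {
  base <- data.frame(participant_id = fit$participant_id,
                     family = fit$spec$family,
                     formulation = fit$spec$formulation)
  if (inherits(fit, "cs_fit_failure"))
    return(cbind(base, data.frame(
      cs = NA_real_, cs_se = NA_real_, cs_ci90 = NA_real_,
      d_prime = NA_real_, d_prime_se = NA_real_, d_prime_ci90 = NA_real_,
      s_max = NA_real_, s_max_se = NA_real_, s_max_ci90 = NA_real_,
      tau = NA_real_, tau_se = NA_real_, tau_ci90 = NA_real_,
      percent_see = NA_real_, aic = NA_real_, converged = FALSE,
      flagged = TRUE, note = fit$error)))
  hw <- rep(NA_real_, length(fit$params)); names(hw) <- names(fit$params)
  if (fit$df >= 1L && !any(is.na(fit$se)))
    hw <- parameter_intervals(fit, ci_level)$half_width
  g <- function(nm, v = fit$params) if (nm %in% names(v)) unname(v[nm]) else NA_real_
  gh <- function(nm) if (nm %in% names(fit$params))
    unname(hw[which(names(fit$params) == nm)]) else NA_real_
  dmax <- if (fit$spec$family == "three_param_exp")
    dprime_max(as.list(fit$params)) else g("d_prime")
  psee <- tryCatch(combined_percent_see(fit), error = function(e) NA_real_)
  aic <- tryCatch(suppressWarnings(fit_aic(fit)), error = function(e) NA_real_)
  cbind(base, data.frame(
    cs = g("cs"), cs_se = g("cs", fit$se), cs_ci90 = gh("cs"),
    d_prime = dmax, d_prime_se = g("d_prime", fit$se),
    d_prime_ci90 = gh("d_prime"),
    s_max = g("s_max"), s_max_se = g("s_max", fit$se),
    s_max_ci90 = gh("s_max"),
    tau = g("tau"), tau_se = g("tau", fit$se), tau_ci90 = gh("tau"),
    percent_see = psee, aic = aic,
    converged = fit$converged, flagged = fit$flagged, note = ""))
}

round_report <- function(df) {
  speed_cols <- intersect(c("cs", "cs_se", "cs_ci90", "s_max", "s_max_se",
                            "s_max_ci90"), names(df))
  dist_cols <- intersect(c("d_prime", "d_prime_se", "d_prime_ci90",
                           "tau", "tau_se", "tau_ci90"), names(df))
  pct_cols <- intersect(c("percent_see", "percent_vo2max",
                          "percent_s_vo2max", "see_percent",
                          "delta_percent"), names(df))
  for (cc in speed_cols) df[[cc]] <- round(df[[cc]], 2)
  for (cc in dist_cols) df[[cc]] <- round(df[[cc]], 1)
  for (cc in pct_cols) df[[cc]] <- round(df[[cc]], 1)
  if ("aic" %in% names(df)) df$aic <- round(df$aic, 2)
  df
}

#' Run the full critical-speed study pipeline
#'
#' For every participant, fits the six-cell model battery; assembles the
#' cohort long table; fits the mixed models for `cs`, `d_prime` and
#' `s_max`; and, when incremental-test profiles are supplied, maps CS onto
#' oxygen uptake and computes log-scale correlations of CS with VT, RCP and
#' V-dot-O2max per battery cell. Deterministic given inputs and seed.
#'
#' @param trials Named list of [trial_set()] objects, a long data frame
#'   accepted by [trials_from_frame()], or a path to a trial CSV.
#' @param incremental Optional named list of [incremental_profile()]
#'   objects (or path to an incremental CSV).
#' @param options [fit_options()].
#' @param ci_level Confidence level for reported intervals.
#' @param out_dir Optional directory; when given, writes `fits.csv`,
#'   `mixed_models.csv`, `physiology.csv`, `correlations.csv` and
#'   `exclusions.csv` (UTF-8, headers; speeds rounded to 0.01, distances to
#'   0.1, percents to 0.1 at serialisation only).
#' @param seed Optional seed (the pipeline itself is deterministic; the
#'   seed is recorded and applied for reproducibility of any downstream
#'   randomness).
#' @return A list of class `cs_study`: `fits` (per-cell data frame),
#'   `long_table`, `mixed` (list per outcome), `physiology`,
#'   `correlations`, `exclusions`, `metadata`.
#' @export
run_study <- function(trials, incremental = NULL, options = fit_options(),
                      ci_level = 0.90, out_dir = NULL, seed = NULL) {
  if (is.character(trials)) trials <- read_trials(trials)
  if (is.data.frame(trials)) trials <- trials_from_frame(trials)
  if (inherits(trials, "cs_trial_set")) trials <- list(trials)
  if (length(trials) == 0L) stop("empty cohort")
  if (is.character(incremental)) incremental <- read_incremental(incremental)
  if (!is.null(seed)) set.seed(seed)

  batteries <- lapply(trials, fit_battery, options = options)
  names(batteries) <- vapply(trials, `[[`, character(1), "participant_id")

  fits <- do.call(rbind, lapply(batteries, function(b)
    do.call(rbind, lapply(b, fit_row, ci_level = ci_level))))
  rownames(fits) <- NULL

  long_table <- assemble_long_table(batteries)
  exclusions <- attr(long_table, "exclusions")

  mixed <- list()
  for (oc in intersect(c("cs", "d_prime", "s_max"), unique(long_table$outcome))) {
    mixed[[oc]] <- tryCatch(mixed_model_effects(long_table, oc),
                            error = function(e) NULL)
  }

  physiology <- NULL; correlations <- NULL
  if (!is.null(incremental)) {
    cs_tab <- long_table[long_table$outcome == "cs", , drop = FALSE]
    rows <- lapply(seq_len(nrow(cs_tab)), function(i) {
      pid <- cs_tab$participant_id[i]
      prof <- incremental[[pid]]
      if (is.null(prof)) return(NULL)
      v <- withCallingHandlers(
        vo2_at_cs(prof, cs_tab$value[i]),
        warning = function(w) invokeRestart("muffleWarning"))
      data.frame(participant_id = pid, family = cs_tab$family[i],
                 formulation = cs_tab$formulation[i],
                 cs = cs_tab$value[i], vo2_at_cs = v$vo2,
                 percent_vo2max = v$percent_vo2max,
                 percent_s_vo2max = relative_cs(cs_tab$value[i],
                                                prof$s_vo2max),
                 extrapolated = v$extrapolated)
    })
    physiology <- do.call(rbind, rows)
    ## correlations of CS with aerobic fitness parameters, per battery cell
    ref_vals <- function(pids, what)
      vapply(pids, function(pid) {
        prof <- incremental[[pid]]
        if (is.null(prof)) NA_real_ else prof[[what]]
      }, numeric(1))
    cells <- unique(cs_tab[c("family", "formulation")])
    crows <- list()
    for (i in seq_len(nrow(cells))) {
      sub <- cs_tab[cs_tab$family == cells$family[i] &
                    cs_tab$formulation == cells$formulation[i], ]
      for (ref in c("vt", "rcp", "vo2max")) {
        rv <- ref_vals(sub$participant_id, ref)
        okk <- is.finite(rv) & is.finite(sub$value)
        if (sum(okk) < 3L) next
        cr <- log_scale_association(rv[okk], sub$value[okk], level = ci_level)
        crows[[length(crows) + 1L]] <- data.frame(
          family = cells$family[i], formulation = cells$formulation[i],
          reference = ref, r = cr$r, ci_lower = cr$ci[1], ci_upper = cr$ci[2],
          p = cr$p, see_percent = cr$see_percent,
          delta_percent = cr$delta_percent, n = cr$n, label = cr$label)
      }
    }
    correlations <- do.call(rbind, crows)
  }

  metadata <- list(seed = seed, ci_level = ci_level,
                   weight_source = options$weight_source,
                   convergence_tol = options$convergence_tol,
                   max_iterations = options$max_iterations,
                   ci_convention = "t-quantile x asymptotic SE, df = n - p",
                   aic_convention = "n*log(weighted RSS/n) + 2p; within-formulation comparisons only",
                   n_participants = length(trials),
                   n_excluded = attr(long_table, "n_excluded"))

  out <- structure(list(fits = fits, long_table = long_table, mixed = mixed,
                        physiology = physiology, correlations = correlations,
                        exclusions = exclusions, metadata = metadata),
                   class = "cs_study")
  if (!is.null(out_dir)) write_study(out, out_dir)
  out
}

mixed_summary_frame <- function(mixed) {
  rows <- lapply(mixed, function(m) {
    if (is.null(m)) return(NULL)
    data.frame(outcome = m$outcome,
               p_family = m$fixed_effect_p[["family"]],
               p_formulation = m$fixed_effect_p[["formulation"]],
               p_interaction = m$fixed_effect_p[["interaction"]],
               r2_marginal = round(m$r2_marginal, 3),
               r2_conditional = round(m$r2_conditional, 3),
               icc = round(m$icc, 3), icc_class = m$icc_class,
               singular = m$singular)
  })
  do.call(rbind, rows)
}

#' Write study reports to CSV
#'
#' @param study A [run_study()] result.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_study <- function(study, out_dir) {
  stopifnot(inherits(study, "cs_study"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  wr <- function(df, name) {
    if (is.null(df)) return()
    path <- file.path(out_dir, name)
    utils::write.csv(df, path, row.names = FALSE)
    paths[[length(paths) + 1L]] <<- path
  }
  wr(round_report(study$fits), "fits.csv")
  wr(mixed_summary_frame(study$mixed), "mixed_models.csv")
  wr(round_report(study$physiology), "physiology.csv")
  wr(round_report(study$correlations), "correlations.csv")
  excl <- study$exclusions
  if (is.null(excl))
    excl <- data.frame(participant_id = character(0), family = character(0),
                       formulation = character(0), reason = character(0))
  wr(excl, "exclusions.csv")
  meta <- study$metadata
  meta_df <- data.frame(key = names(meta),
                        value = vapply(meta, function(v)
                          if (is.null(v)) "" else as.character(v), character(1)))
  wr(meta_df, "metadata.csv")
  invisible(paths)
}

#' @export
print.cs_study <- function(x, ...) {
  cat(sprintf("<cs_study> %d participants, %d battery cells (%d excluded)\n",
              x$metadata$n_participants, nrow(x$fits), x$metadata$n_excluded))
  ms <- mixed_summary_frame(x$mixed)
  if (!is.null(ms)) { cat("mixed-model summary:\n"); print(ms, row.names = FALSE) }
  invisible(x)
}
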