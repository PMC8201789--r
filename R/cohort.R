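## Cohort-level statistics --------------------------------------------------

#' Assemble per-participant fit batteries into a long table
#'
#' Produces one record per participant x family x formulation x outcome,
#' the input layout for [mixed_model_effects()]. Outcomes are `cs`,
#' `d_prime` (for the exponential family the derived [dprime_max()] is
#' used, its conventional `d_prime` stand-in) and `s_max` (absent for the
#' two-parameter family). Flagged or failed fits are excluded and counted;
#' the exclusion log is attached as an attribute.
#'
#' @param batteries A named list of [fit_battery()] results, one per
#'   participant (names are participant ids; unnamed lists take the
#'   batteries' own participant ids).
#' @return A data frame (`participant_id`, `family`, `formulation`,
#'   `outcome`, `value`) with attributes `n_excluded` and `exclusions`
#'   (data frame of excluded cells with reasons).
#' @export
assemble_long_table <- function(batteries) {
  if (length(batteries) == 0L) stop("empty cohort")
  if (inherits(batteries, "cs_fit_battery")) batteries <- list(batteries)
  ids <- names(batteries)
  if (is.null(ids))
    ids <- vapply(batteries, function(b) attr(b, "participant_id"), character(1))
  if (anyDuplicated(ids)) stop("duplicate participant ids in cohort")
  rows <- list(); excl <- list()
  for (i in seq_along(batteries)) {
    bat <- batteries[[i]]
    for (nm in names(bat)) {
      f <- bat[[nm]]
      if (inherits(f, "cs_fit_failure") || isTRUE(f$flagged)) {
        excl[[length(excl) + 1L]] <- data.frame(
          participant_id = ids[i],
          family = f$spec$family, formulation = f$spec$formulation,
          reason = if (inherits(f, "cs_fit_failure")) f$error
                   else if (!f$converged) "not converged" else "bound active")
        next
      }
      vals <- c(cs = f$params[["cs"]])
      if (f$spec$family == "three_param_exp")
        vals["d_prime"] <- dprime_max(as.list(f$params))
      else vals["d_prime"] <- f$params[["d_prime"]]
      if (f$spec$family != "two_param")
        vals["s_max"] <- f$params[["s_max"]]
      rows[[length(rows) + 1L]] <- data.frame(
        participant_id = ids[i],
        family = f$spec$family, formulation = f$spec$formulation,
        outcome = names(vals), value = unname(vals))
    }
  }
  if (length(rows) == 0L) stop("no usable fits in cohort")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (anyDuplicated(out[c("participant_id", "family", "formulation", "outcome")]))
    stop("duplicate participant x model cell in long table")
  attr(out, "n_excluded") <- length(excl)
  attr(out, "exclusions") <- if (length(excl)) do.call(rbind, excl) else NULL
  out
}

#' Variance-explained summaries from variance components
#'
#' Marginal R2 is the fixed-effect variance over the total
#' (fixed + random + residual); conditional R2 adds the random-intercept
#' variance to the numerator; the ICC is the random-intercept variance over
#' itself plus residual.
#'
#' @param var_fixed,var_random,var_resid Non-negative variance components
#'   (outcome units squared).
#' @return List with `r2_marginal`, `r2_conditional`, `icc`.
#' @examples
#' variance_explained(14, 82, 4)  # r2m 0.14, r2c 0.96, icc ~0.953
#' @export
variance_explained <- function(var_fixed, var_random, var_resid) {
  stopifnot(var_fixed >= 0, var_random >= 0, var_resid >= 0)
  tot <- var_fixed + var_random + var_resid
  if (tot == 0) return(list(r2_marginal = 0, r2_conditional = 0, icc = 0))
  icc_den <- var_random + var_resid
  list(r2_marginal = var_fixed / tot,
       r2_conditional = (var_fixed + var_random) / tot,
       icc = if (icc_den == 0) 0 else var_random / icc_den)
}

#' Mixed-model comparison of families and formulations
#'
#' Fits, by REML, the random-intercept model
#' `value ~ family * formulation + (1 | participant_id)` to one outcome of
#' the long table, and summarises: Satterthwaite-approximated fixed-effect
#' p-values (type III), variance components, marginal/conditional R2 and
#' ICC via [variance_explained()] (fixed-effect variance taken as the
#' sample variance of the fixed-effect linear predictor), and - when the
#' family effect is significant at 0.05 - Holm-adjusted pairwise family
#' comparisons (estimated marginal means averaged over formulations).
#'
#' @param table A long table from [assemble_long_table()] (or same layout).
#' @param outcome One of `"cs"`, `"d_prime"`, `"s_max"`.
#' @param posthoc_alpha Significance level gating the post-hoc pairwise
#'   comparisons.
#' @return A list of class `cs_mixed_result`: `outcome`, `fixed_effect_p`
#'   (named: family, formulation, interaction), `var_fixed`, `var_random`,
#'   `var_resid`, `r2_marginal`, `r2_conditional`, `icc`, `icc_class`,
#'   `posthoc` (data frame or `NULL`), `singular`, `n_participants`,
#'   `model` (the fitted `lmerModLmerTest`).
#' @export
mixed_model_effects <- function(table, outcome = c("cs", "d_prime", "s_max"),
                                posthoc_alpha = 0.05) {
  outcome <- match.arg(outcome)
  d <- table[table$outcome == outcome, , drop = FALSE]
  if (nrow(d) == 0L) stop("no records for outcome ", outcome)
  d$family <- droplevels(factor(d$family))
  d$formulation <- droplevels(factor(d$formulation))
  d$participant_id <- factor(d$participant_id)
  if (nlevels(d$family) < 2L)
    stop("need at least two model families for a family effect")
  n_cells <- nlevels(d$family) * nlevels(d$formulation) *
    nlevels(d$participant_id)
  if (nrow(d) < 0.8 * n_cells)
    warning("more than 20% of participant x model cells are missing")
  m <- lmerTest::lmer(value ~ family * formulation + (1 | participant_id),
                      data = d, REML = TRUE)
  an <- stats::anova(m, type = 3)
  pv <- an[["Pr(>F)"]]
  names(pv) <- rownames(an)
  fixed_p <- c(family = unname(pv["family"]),
               formulation = unname(pv["formulation"]),
               interaction = unname(pv["family:formulation"]))
  vc <- as.data.frame(lme4::VarCorr(m))
  var_random <- vc$vcov[vc$grp == "participant_id"][1L]
  var_resid <- stats::sigma(m)^2
  X <- stats::model.matrix(m)
  var_fixed <- stats::var(as.vector(X %*% lme4::fixef(m)))
  ve <- variance_explained(var_fixed, var_random, var_resid)
  posthoc <- NULL
  if (is.finite(fixed_p[["family"]]) && fixed_p[["family"]] <= posthoc_alpha) {
    emm <- suppressMessages(emmeans::emmeans(m, ~family))
    pr <- as.data.frame(suppressMessages(
      emmeans::contrast(emm, method = "pairwise", adjust = "holm")))
    posthoc <- data.frame(pair = pr$contrast, estimate = pr$estimate,
                          holm_adjusted_p = pr$p.value)
  }
  structure(list(outcome = outcome,
                 fixed_effect_p = fixed_p,
                 var_fixed = var_fixed, var_random = var_random,
                 var_resid = var_resid,
                 r2_marginal = ve$r2_marginal,
                 r2_conditional = ve$r2_conditional,
                 icc = ve$icc, icc_class = icc_label(ve$icc),
                 posthoc = posthoc,
                 singular = lme4::isSingular(m),
                 n_participants = nlevels(d$participant_id),
                 p_value_method = "Satterthwaite (type III)",
                 model = m),
            class = "cs_mixed_result")
}

#' @export
print.cs_mixed_result <- function(x, ...) {
  cat(sprintf("<cs_mixed_result> outcome: %s (n = %d participants%s)\n",
              x$outcome, x$n_participants,
              if (x$singular) ", singular fit" else ""))
  cat(sprintf("  fixed effects (%s): family p = %.3g, formulation p = %.3g, interaction p = %.3g\n",
              x$p_value_method, x$fixed_effect_p[["family"]],
              x$fixed_effect_p[["formulation"]],
              x$fixed_effect_p[["interaction"]]))
  cat(sprintf("  R2 marginal = %.3f, R2 conditional = %.3f, ICC = %.3f (%s)\n",
              x$r2_marginal, x$r2_conditional, x$icc, x$icc_class))
  if (!is.null(x$posthoc)) {
    cat("  Holm-adjusted pairwise family comparisons:\n")
    print(x$posthoc, row.names = FALSE)
  }
  invisible(x)
}

#' Log-scale Pearson association with SEE% and systematic difference
#'
#' Both variables are natural-log transformed; the Pearson correlation,
#' its Fisher-z confidence interval and two-sided p-value are computed on
#' the log scale. The standard error of estimate in percent is
#' `100 (exp(s_res) - 1)` with `s_res` the residual SD (df = n - 2) of the
#' `log(y) ~ log(x)` regression, i.e. the typical percent error of
#' predicting `y` from `x`. The systematic difference Delta% is
#' `100 (exp(mean LOO log prediction error) - 1)`, the mean leave-one-out
#' log prediction error back-transformed to percent (in-sample mean log
#' residual being identically zero).
#'
#' @param x,y Strictly positive numeric vectors of equal length >= 3.
#' @param level Confidence level for the Fisher-z interval (default 0.90).
#' @return A list of class `cs_correlation`: `r`, `ci` (length 2), `p`,
#'   `see_percent`, `delta_percent`, `n`, `label` (strength class of `r`).
#' @export
log_scale_association <- function(x, y, level = 0.90) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  if (any(!is.finite(x)) || any(!is.finite(y)) || any(x <= 0) || any(y <= 0))
    stop("log-scale association requires strictly positive finite values")
  lx <- log(x); ly <- log(y)
  if (stats::sd(lx) == 0) stop("zero variance in x")
  n <- length(x)
  r <- stats::cor(lx, ly)
  if (abs(r) >= 1 - 1e-15) {
    ci <- c(sign(r), sign(r)); p <- 0
  } else {
    z <- atanh(r)
    zse <- 1 / sqrt(n - 3)
    q <- stats::qnorm(1 - (1 - level) / 2)
    ci <- tanh(c(z - q * zse, z + q * zse))
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  reg <- stats::lm(ly ~ lx)
  s_res <- sqrt(sum(stats::residuals(reg)^2) / (n - 2))
  see_percent <- 100 * (exp(s_res) - 1)
  loo <- vapply(seq_len(n), function(i) {
    fi <- stats::lm(ly[-i] ~ lx[-i])
    ly[i] - (stats::coef(fi)[1L] + stats::coef(fi)[2L] * lx[i])
  }, numeric(1))
  delta_percent <- 100 * (exp(mean(loo)) - 1)
  structure(list(r = r, ci = ci, p = p, see_percent = see_percent,
                 delta_percent = delta_percent, n = n,
                 level = level, label = correlation_label(r)),
            class = "cs_correlation")
}

#' @export
print.cs_correlation <- function(x, ...) {
  cat(sprintf("<cs_correlation> r = %.3f (%s), %d%% CI [%.3f, %.3f], p = %.3g\n",
              x$r, x$label, round(100 * x$level), x$ci[1], x$ci[2], x$p))
  cat(sprintf("  SEE = %.2f%%, Delta = %.2f%% (n = %d)\n",
              x$see_percent, x$delta_percent, x$n))
  invisible(x)
}

#' Percent by which a value falls short of a larger one
#'
#' `100 (larger - smaller) / larger`: how many percent smaller the first
#' argument is than the reference.
#'
#' @param smaller Value of interest.
#' @param larger Strictly positive reference.
#' @return Percent difference.
#' @examples
#' percent_difference(4.12, 4.39)  # ~6.15
#' @export
percent_difference <- function(smaller, larger) {
  if (any(!is.finite(larger)) || any(larger <= 0))
    stop("'larger' must be strictly positive")
  100 * (larger - smaller) / larger
}

#' Conventional ICC strength labels
#'
#' Poor below 0.5, moderate in `[0.5, 0.75)`, good in `[0.75, 0.9)`,
#' excellent at and above 0.9.
#'
#' @param icc ICC value(s) in `[0, 1]`.
#' @return Character vector of labels.
#' @export
icc_label <- function(icc) {
  stopifnot(all(icc >= 0 & icc <= 1))
  cut(icc, breaks = c(-Inf, 0.5, 0.75, 0.9, Inf), right = FALSE,
      labels = c("poor", "moderate", "good", "excellent")) |>
    as.character()
}

#' Conventional correlation strength labels
#'
#' On `|r|`: negligible below 0.3, low in `[0.3, 0.5)`, moderate in
#' `[0.5, 0.7)`, high in `[0.7, 0.9)`, very high at and above 0.9.
#'
#' @param r Correlation value(s) in `[-1, 1]`.
#' @return Character vector of labels.
#' @export
correlation_label <- function(r) {
  stopifnot(all(abs(r) <= 1))
  cut(abs(r), breaks = c(-Inf, 0.3, 0.5, 0.7, 0.9, Inf), right = FALSE,
      labels = c("negligible", "low", "moderate", "high", "very high")) |>
    as.character()
}
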