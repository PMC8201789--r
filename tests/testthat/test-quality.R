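# A minimal hand-built cs_fit, for metrics that only need a few fields.
fake_fit <- function(params, se, df = 2L, n_obs = 4L, wrss = 1,
                     family = "two_param", formulation = "time_of_speed",
                     fitted = NULL, wres = NULL, resid = NULL,
                     weights = NULL, vcov = NULL) {
  structure(list(spec = cs_model(family, formulation), params = params,
                 se = se, vcov = vcov, weighted_rss = wrss, n_obs = n_obs,
                 df = df, fitted = fitted, weighted_residuals = wres,
                 residuals = resid, weights = weights,
                 converged = TRUE, at_bound = FALSE, flagged = FALSE),
            class = "cs_fit")
}

test_that("confidence intervals use the t quantile on asymptotic SEs", {
  f <- fake_fit(params = c(cs = 4.39, d_prime = 226),
                se = c(cs = 0.0342, d_prime = 22.9), df = 2L)
  iv <- parameter_intervals(f, level = 0.90)
  expect_equal(iv$half_width[iv$parameter == "cs"], 0.0999, tolerance = 1e-3)
  expect_equal(iv$lower, iv$estimate - iv$half_width)
  # degenerate level gives zero half-widths
  iv0 <- parameter_intervals(f, level = 0)
  expect_equal(iv0$half_width, c(0, 0))
})

test_that("a perfect fit yields zero-width intervals", {
  tr <- noise_free_trials("two_param", list(cs = 4, d_prime = 200),
                          c(4.5, 5, 5.5, 6))
  fit <- fit_cs(tr, cs_model("two_param"))
  iv <- parameter_intervals(fit)
  expect_equal(iv$half_width, c(0, 0), tolerance = 1e-6)
})

test_that("combined percent SEE sums per-parameter relative errors", {
  f <- fake_fit(params = c(cs = 4.39, d_prime = 226),
                se = c(cs = 0.0342, d_prime = 22.9))
  expect_equal(combined_percent_see(f),
               100 * (0.0342 / 4.39 + 22.9 / 226), tolerance = 1e-9)
  expect_equal(combined_percent_see(f), 10.9, tolerance = 1e-2)
  expect_equal(combined_percent_see(
    fake_fit(params = c(cs = 4, d_prime = 200), se = c(cs = 0, d_prime = 0))), 0)
  f3 <- fake_fit(params = c(cs = 4, d_prime = 200, s_max = 7),
                 se = c(cs = 0.04, d_prime = 2, s_max = 0.07),
                 family = "three_param")
  expect_equal(combined_percent_see(f3), 3)
  expect_error(combined_percent_see(
    fake_fit(params = c(cs = 0, d_prime = 1), se = c(cs = 1, d_prime = 1))),
    "zero")
})

test_that("the d-prime-max percent-SEE variant propagates the delta method", {
  tr <- noise_free_trials("three_param_exp",
                          list(cs = 4.5, tau = 250, s_max = 7.0),
                          c(4.8, 5.2, 5.7, 6.2, 6.6))
  set.seed(9)
  noisy <- trial_set("x", tr$observations$speed,
                     tr$observations$time * exp(rnorm(5, 0, 0.05)))
  fit <- fit_cs(noisy, cs_model("three_param_exp"))
  base <- combined_percent_see(fit)
  alt <- combined_percent_see(fit, dprime_max_variant = TRUE)
  expect_true(is.finite(alt) && alt >= 0)
  # cs and s_max terms are shared; only the third term differs
  cs_smax <- 100 * (fit$se[["cs"]] / fit$params[["cs"]] +
                    fit$se[["s_max"]] / fit$params[["s_max"]])
  expect_gt(base, cs_smax)
  expect_gt(alt, cs_smax)
})

test_that("AIC follows n log(RSS/n) + 2p and its exact identities", {
  f <- fake_fit(params = c(cs = 4, d_prime = 200), se = c(cs = 1, d_prime = 1),
                n_obs = 4L, wrss = 4 * exp(1))
  expect_equal(fit_aic(f), 8)
  f3 <- fake_fit(params = c(cs = 4, d_prime = 200, s_max = 7),
                 se = c(cs = 1, d_prime = 1, s_max = 1),
                 n_obs = 4L, wrss = 4 * exp(1), family = "three_param")
  expect_equal(fit_aic(f3) - fit_aic(f), 2)
  fh <- fake_fit(params = c(cs = 4, d_prime = 200), se = c(cs = 1, d_prime = 1),
                 n_obs = 4L, wrss = 2 * exp(1))
  expect_equal(fit_aic(f) - fit_aic(fh), 4 * log(2))
  f0 <- fake_fit(params = c(cs = 4, d_prime = 200), se = c(cs = 0, d_prime = 0),
                 wrss = 0)
  expect_warning(a <- fit_aic(f0), "perfect")
  expect_true(is.na(a))
})

test_that("heteroscedasticity index is zero for a perfect fit", {
  tr <- noise_free_trials("two_param", list(cs = 4, d_prime = 200),
                          c(4.5, 5, 5.5, 6))
  fit <- fit_cs(tr, cs_model("two_param"))
  prof <- residual_heteroscedasticity(fit)
  expect_equal(nrow(prof$profile), 4)
  expect_equal(prof$profile$abs_weighted_residual, rep(0, 4), tolerance = 1e-7)
  expect_equal(prof$index, 0)
})

test_that("the index recognises the variance law in estimate-free residuals", {
  # oracle check with no fitting step: residuals taken against the true
  # curve, pooled across a cohort with variance-proportional-to-t noise
  cohort <- sample_cohort(synthetic_config(n_participants = 400,
                                           noise_scale = 2, seed = 31))
  t_true <- unlist(lapply(cohort$participants, function(p) p$truth$true_times))
  t_obs <- unlist(lapply(cohort$participants, function(p)
    p$trials$observations$time))
  w <- unlist(lapply(cohort$participants, function(p)
    observation_weights(p$trials$observations$time)))
  resid <- t_obs - t_true
  n <- length(resid)
  weighted <- fake_fit(params = c(cs = 1), se = c(cs = 1), n_obs = n,
                       fitted = t_true, resid = resid, weights = w,
                       wres = sqrt(w) * resid)
  expect_lt(abs(residual_heteroscedasticity(weighted)$index), 0.1)
  unweighted <- residual_heteroscedasticity(weighted, weights = rep(1, n))
  expect_gt(unweighted$index, 0.1)
})

test_that("matching weights keep fitted residuals closer to homoscedastic", {
  # pooled profiles across a cohort: the weighted fit's own diagnostic
  # stays nearer zero than the unweighted fit's residuals examined under
  # the same inverse-variance error model
  cfg <- synthetic_config(n_participants = 250, noise_scale = 3, seed = 77)
  cohort <- sample_cohort(cfg)
  profs <- lapply(cohort$participants, function(p) {
    fw <- fit_cs(p$trials, cs_model("two_param"))
    fu <- fit_cs(p$trials, cs_model("two_param"),
                 fit_options(weight_source = "none"))
    w <- observation_weights(p$trials$observations$time)
    list(w = residual_heteroscedasticity(fw)$profile,
         u = residual_heteroscedasticity(fu, weights = w)$profile)
  })
  pool_idx <- function(key) {
    pr <- do.call(rbind, lapply(profs, `[[`, key))
    cor(pr$predicted, pr$abs_weighted_residual, method = "spearman")
  }
  expect_lt(abs(pool_idx("w")), abs(pool_idx("u")))
})

test_that("percent excess reproduces its arithmetic and rejects bad input", {
  expect_equal(percent_excess(32.3, 24.1), 100 * 8.2 / 24.1)
  expect_equal(percent_excess(32.3, 24.1), 34.0, tolerance = 1e-2)
  expect_equal(percent_excess(45.8, 37.8), 21.2, tolerance = 1e-2)
  expect_equal(percent_excess(5, 5), 0)
  expect_error(percent_excess(5, 0), "positive")
  # not antisymmetric: the two directions only cancel at zero
  x <- percent_excess(32.3, 24.1); y <- percent_excess(24.1, 32.3)
  expect_equal((1 + x / 100) * (1 + y / 100), 1, tolerance = 1e-12)
  expect_false(isTRUE(all.equal(x, -y)))
})
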