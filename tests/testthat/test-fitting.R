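test_that("observation weights follow the inverse-value rule, normalised", {
  w <- observation_weights(c(100, 200, 400))
  expect_equal(w, c(12, 6, 3) / 7)
  expect_equal(sum(w), 3)
  expect_equal(observation_weights(c(5, 5, 5)), c(1, 1, 1))
  # scale-free in the dependent variable
  y <- c(888, 356.4, 166.8, 100.8)
  expect_equal(observation_weights(y * 60), observation_weights(y))
  expect_error(observation_weights(c(100, 0, 400)), "positive")
  expect_error(observation_weights(c(100, -3)), "positive")
})

test_that("starting values are exact on noise-free two-parameter data", {
  tr <- noise_free_trials("two_param", list(cs = 4, d_prime = 200),
                          c(4.5, 5, 5.5, 6))
  st <- initial_params(tr, cs_model("two_param"))
  expect_equal(unname(st["cs"]), 4, tolerance = 1e-9)
  expect_equal(unname(st["d_prime"]), 200, tolerance = 1e-9)
  # three-parameter s_max start rule: 1.5x fastest observed speed
  st3 <- initial_params(tr, cs_model("three_param"))
  expect_equal(unname(st3["s_max"]), 9)
  ste <- initial_params(tr, cs_model("three_param_exp"))
  expect_equal(unname(ste["s_max"]), 1.4 * 6)
  expect_equal(unname(ste["tau"]), tr$observations$time[3])  # 2nd-fastest speed
})

test_that("group-mean starting cs agrees with the distance-on-time regression", {
  tr <- group_mean_trialset()
  obs <- tr$observations
  # closed-form OLS slope, computed independently of lm()
  slope <- sum((obs$time - mean(obs$time)) * (obs$distance - mean(obs$distance))) /
    sum((obs$time - mean(obs$time))^2)
  st <- initial_params(tr, cs_model("two_param"))
  expect_equal(unname(st["cs"]), slope, tolerance = 1e-9)
  expect_equal(slope, 4.45, tolerance = 0.01)
})

test_that("all families are recovered exactly from noise-free data", {
  cases <- list(
    list(family = "two_param", params = list(cs = 4, d_prime = 200),
         speeds = c(4.5, 5, 5.5, 6)),
    list(family = "three_param",
         params = list(cs = 4.1, d_prime = 550, s_max = 7.7),
         speeds = c(4.6, 5.2, 5.7, 6.2, 6.8)),
    list(family = "three_param_exp",
         params = list(cs = 4.5, tau = 250, s_max = 7.0),
         speeds = c(4.8, 5.2, 5.7, 6.2, 6.6)))
  for (case in cases) {
    tr <- noise_free_trials(case$family, case$params, case$speeds)
    for (form in cs_formulations()) {
      fit <- fit_cs(tr, cs_model(case$family, form))
      expect_true(fit$converged)
      for (nm in names(case$params)) {
        expect_equal(unname(fit$params[nm]), case$params[[nm]],
                     tolerance = 1e-6,
                     info = sprintf("%s / %s / %s", case$family, form, nm))
      }
    }
  }
})

test_that("both formulations give identical estimates on noise-free data", {
  tr <- noise_free_trials("two_param", list(cs = 4, d_prime = 200),
                          c(4.5, 5, 5.5, 6))
  bat <- fit_battery(tr)
  expect_equal(bat[["two_param.time_of_speed"]]$params,
               bat[["two_param.distance_of_speed"]]$params,
               tolerance = 1e-9)
})

test_that("Levenberg-Marquardt matches the exhaustive grid-search oracle", {
  tr <- group_mean_trialset()
  for (form in cs_formulations()) {
    fit <- fit_cs(tr, cs_model("two_param", form))
    oracle <- grid_search_two_param(tr, form,
                                    cs_range = c(4.0, 4.6),
                                    dp_range = c(120, 350))
    # LM objective must be at least as good as the best grid cell can
    # guarantee: compare objectives within one grid-cell perturbation
    obj_lm <- wls_objective_two_param(tr, form, fit$params[["cs"]],
                                      fit$params[["d_prime"]])
    # the continuous optimum can only improve on the best grid cell ...
    expect_lte(obj_lm, oracle$obj + 1e-9)
    # ... and snapping it onto the grid can never beat the exhaustive search
    snap <- function(x, from, to, by) {
      g <- seq(from, to, by = by); g[which.min(abs(g - x))]
    }
    obj_snap <- wls_objective_two_param(
      tr, form,
      snap(fit$params[["cs"]], 4.0, 4.6, 1e-3),
      snap(fit$params[["d_prime"]], 120, 350, 0.1))
    expect_gte(obj_snap + 1e-9, oracle$obj)
    expect_lt(abs(fit$params[["cs"]] - oracle$cs), 2e-3)  # within one cs cell
  }
})

test_that("estimates are invariant to observation order", {
  set.seed(404)
  tr <- group_mean_trialset()
  fit0 <- fit_cs(tr, cs_model("two_param"))
  for (i in 1:5) {
    perm <- sample(nrow(tr$observations))
    trp <- trial_set(tr$participant_id, tr$observations$speed[perm],
                     tr$observations$time[perm], tr$peak_speed)
    fitp <- fit_cs(trp, cs_model("two_param"))
    expect_equal(fitp$params, fit0$params, tolerance = 1e-8)
  }
})

test_that("a three-observation set fits two-parameter but flags three-parameter", {
  tr <- noise_free_trials("two_param", list(cs = 4, d_prime = 200),
                          c(4.5, 5, 6))
  bat <- fit_battery(tr)
  expect_false(bat[["two_param.time_of_speed"]]$flagged)
  expect_s3_class(bat[["three_param.time_of_speed"]], "cs_fit_failure")
  expect_match(bat[["three_param.time_of_speed"]]$error, "under-determined")
  expect_s3_class(bat[["three_param_exp.distance_of_speed"]], "cs_fit_failure")
  # df = 1 for the two-parameter fit on 3 observations: CI still available
  expect_equal(bat[["two_param.time_of_speed"]]$df, 1L)
})

test_that("df = 0 fits return estimates with unavailable standard errors", {
  tr <- noise_free_trials("two_param", list(cs = 4, d_prime = 200), c(4.5, 6))
  fit <- fit_cs(tr, cs_model("two_param"))
  expect_equal(unname(fit$params["cs"]), 4, tolerance = 1e-6)
  expect_equal(fit$df, 0L)
  expect_true(all(is.na(fit$se)))
  expect_error(parameter_intervals(fit), "df")
})

test_that("median CS error grows with multiplicative noise", {
  errs <- sapply(c(0.02, 0.10, 0.30), function(cv) {
    cfg <- synthetic_config(n_participants = 70, noise_model = "constant_cv",
                            noise_scale = cv, seed = 50)
    cohort <- sample_cohort(cfg)
    abs_err <- mapply(function(p) {
      fit <- fit_cs(p$trials, cs_model("two_param"))
      abs(fit$params[["cs"]] - p$truth$cs)
    }, cohort$participants)
    median(abs_err)
  })
  expect_true(all(diff(errs) >= 0))
})
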