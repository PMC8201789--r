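test_that("long-table assembly keeps converged cells and logs exclusions", {
  cfg <- synthetic_config(n_participants = 6,
                          generating_family = "three_param",
                          noise_scale = 1.0, seed = 11)
  cohort <- sample_cohort(cfg)
  bats <- lapply(cohort$participants, function(p) fit_battery(p$trials))
  names(bats) <- sapply(cohort$participants, `[[`, "id")
  tab <- assemble_long_table(bats)
  n_excl <- attr(tab, "n_excluded")
  # every battery cell is either a cs record or an exclusion
  expect_equal(sum(tab$outcome == "cs") + n_excl, 6 * 6)
  # d_prime present wherever cs is (dprime_max fills in for the exponential)
  expect_equal(sum(tab$outcome == "d_prime"), sum(tab$outcome == "cs"))
  # s_max only for three-parameter families
  expect_equal(sum(tab$outcome == "s_max"),
               sum(tab$outcome == "cs" & tab$family != "two_param"))
  expect_false(anyDuplicated(
    tab[c("participant_id", "family", "formulation", "outcome")]) > 0)
  # duplicated participant rejected
  expect_error(assemble_long_table(c(bats, bats[1])), "duplicate")
  expect_error(assemble_long_table(list()), "empty")
})

test_that("variance-explained summaries follow their closed forms", {
  ve <- variance_explained(14, 82, 4)
  expect_equal(ve$r2_marginal, 0.14)
  expect_equal(ve$r2_conditional, 0.96)
  expect_equal(ve$icc, 82 / 86)
  null <- variance_explained(0, 0, 1)
  expect_equal(null$r2_marginal, 0)
  expect_equal(null$r2_conditional, 0)
  expect_equal(null$icc, 0)
  expect_equal(variance_explained(0, 0, 0)$icc, 0)
})

test_that("mixed model detects family but not formulation effects", {
  set.seed(88)
  tab <- simulate_long_table()
  res <- mixed_model_effects(tab, "cs")
  expect_lt(res$fixed_effect_p[["family"]], 0.05)
  expect_gt(res$fixed_effect_p[["formulation"]], 0.05)
  expect_true(res$r2_marginal <= res$r2_conditional)
  expect_true(res$r2_conditional >= 0 && res$r2_conditional <= 1)
  expect_true(res$icc >= 0 && res$icc <= 1)
  # strong participant signal relative to residual noise
  expect_gt(res$icc, 0.9)
  # significant family effect triggers Holm post-hocs over the 3 pairs
  expect_s3_class(res$posthoc, "data.frame")
  expect_equal(nrow(res$posthoc), 3)
  expect_true(all(res$posthoc$holm_adjusted_p >= 0 &
                  res$posthoc$holm_adjusted_p <= 1))
})

test_that("r2 bounds and icc bounds hold across simulated cohorts", {
  set.seed(99)
  for (i in 1:8) {
    tab <- simulate_long_table(n = 10,
                               participant_sd = runif(1, 0, 0.6),
                               resid_sd = runif(1, 0.01, 0.3))
    res <- mixed_model_effects(tab, "cs", posthoc_alpha = 0)
    expect_true(res$r2_marginal >= 0 && res$r2_marginal <= 1)
    expect_true(res$r2_marginal <= res$r2_conditional)
    expect_true(res$r2_conditional <= 1)
    expect_true(res$icc >= 0 && res$icc <= 1)
  }
})

test_that("mixed-model variance components recover the generating values", {
  set.seed(123)
  tab <- simulate_long_table(n = 64, participant_sd = 0.4, resid_sd = 0.05)
  res <- mixed_model_effects(tab, "cs", posthoc_alpha = 0)
  expect_equal(sqrt(res$var_random), 0.4, tolerance = 0.25)
  expect_equal(sqrt(res$var_resid), 0.05, tolerance = 0.25)
})

test_that("log-scale association handles exact and null relationships", {
  x <- c(40, 50, 55, 63, 70)
  r1 <- log_scale_association(x, 3.1 * x)
  expect_equal(r1$r, 1)
  expect_equal(r1$see_percent, 0, tolerance = 1e-9)
  expect_equal(r1$delta_percent, 0, tolerance = 1e-9)
  expect_equal(r1$label, "very high")
  r2 <- log_scale_association(x, 1 / x)
  expect_equal(r2$r, -1)
  set.seed(55)
  xl <- rlnorm(500); yl <- rlnorm(500)
  r0 <- log_scale_association(xl, yl)
  expect_lt(abs(r0$r), 0.2)
  expect_true(r0$ci[1] < r0$r && r0$r < r0$ci[2])
  expect_error(log_scale_association(c(1, 2, -3), c(1, 2, 3)), "positive")
  expect_error(log_scale_association(c(2, 2, 2), c(1, 2, 3)), "variance")
})

test_that("percent difference reproduces its arithmetic", {
  expect_equal(percent_difference(4.12, 4.39), 100 * 0.27 / 4.39)
  expect_equal(round(percent_difference(4.12, 4.39)), 6)
  expect_equal(round(percent_difference(4.12, 4.55)), 9)
  expect_equal(percent_difference(5, 5), 0)
  expect_error(percent_difference(1, 0), "positive")
})

test_that("strength labels respect their boundaries", {
  expect_equal(icc_label(c(0, 0.49, 0.5, 0.74, 0.75, 0.89, 0.9, 1)),
               c("poor", "poor", "moderate", "moderate", "good", "good",
                 "excellent", "excellent"))
  expect_equal(correlation_label(c(0, 0.29, 0.3, 0.49, 0.5, 0.69, 0.7,
                                   0.89, 0.9, 1)),
               c("negligible", "negligible", "low", "low", "moderate",
                 "moderate", "high", "high", "very high", "very high"))
  expect_equal(correlation_label(-0.95), "very high")
  expect_error(icc_label(1.2))
  expect_error(correlation_label(1.5))
})
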