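test_that("noise-free ramp trials are exactly the shared linear ramp", {
  sh <- c(0.4, 0.3, 0.2, 0.1)
  tr <- simulate_ramp_trial(trial_spec(sigma_good = 0, sigma_bad = 0,
                                       ramp_start_n = 5, ramp_end_n = 20,
                                       sharing = sh, seed = 1))
  ramp <- 5 + 15 * tr$time_s / 6
  expect_equal(tr$forces_n, outer(ramp, sh), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(nrow(tr$forces_n), 6 * 170)
  expect_lt(max(abs(total_force(tr) - ramp)), 1e-9)
})

test_that("good-only fluctuations sum to zero at every sample", {
  # ramp kept well above 0 N so the nonnegativity floor never engages
  spec <- trial_spec(sigma_good = 0.5, sigma_bad = 0,
                     ramp_start_n = 10, ramp_end_n = 25, seed = 21)
  base <- trial_spec(sigma_good = 0, sigma_bad = 0,
                     ramp_start_n = 10, ramp_end_n = 25, seed = 21)
  tr <- simulate_ramp_trial(spec)
  expect_equal(attr(tr, "n_clipped"), 0)
  fluct <- tr$forces_n - simulate_ramp_trial(base)$forces_n
  expect_lt(max(abs(rowSums(fluct))), 1e-9)
})

test_that("bad-only fluctuations carry the requested total-force variance", {
  # oracle: direct variance of the common-mode channel, recovered as the
  # difference between the generated and the noise-free total force
  spec <- trial_spec(sigma_good = 0, sigma_bad = 0.5, seed = 31)
  base <- trial_spec(sigma_good = 0, sigma_bad = 0, seed = 31)
  ctot <- total_force(simulate_ramp_trial(spec)) -
    total_force(simulate_ramp_trial(base))
  expect_equal(mean(ctot^2), 0.25, tolerance = 0.2)
  # common-mode: all four channels identical
  fluct <- simulate_ramp_trial(spec)$forces_n -
    simulate_ramp_trial(base)$forces_n
  expect_lt(max(abs(fluct - fluct[, 1])), 1e-12)
})

test_that("trial generation is bit-identical given the same spec and seed", {
  a <- simulate_ramp_trial(trial_spec(seed = 5))
  b <- simulate_ramp_trial(trial_spec(seed = 5))
  expect_identical(a$forces_n, b$forces_n)
  d <- simulate_ramp_trial(trial_spec(seed = 6))
  expect_false(identical(a$forces_n, d$forces_n))
})

test_that("trial_spec rejects invalid parameters", {
  expect_error(trial_spec(duration_s = 0), "duration_s")
  expect_error(trial_spec(sample_rate_hz = -1), "sample_rate_hz")
  expect_error(trial_spec(sigma_good = -0.1), "sigmas")
  expect_error(trial_spec(sharing = c(0.5, 0.5, 0.1, 0.1)), "sum to 1")
  expect_error(trial_spec(sharing = c(1.2, -0.2, 0, 0)), "nonnegative")
})

test_that("MVC trials peak at the requested maximum", {
  tr <- simulate_mvc_trial(40, noise_sd_n = 0, seed = 1)
  expect_equal(max(total_force(tr)), 40, tolerance = 1e-12)
  only_index <- simulate_mvc_trial(40, sharing = c(1, 0, 0, 0),
                                   noise_sd_n = 0.2, seed = 2)
  expect_true(all(only_index$forces_n[, 2:4] == 0))
  expect_gt(max(only_index$forces_n[, 1]), 0)
  # oracle: direct max over the generated samples
  noisy <- simulate_mvc_trial(40, noise_sd_n = 0.2, seed = 3)
  expect_gte(max(total_force(noisy)), 40)
  expect_lte(max(total_force(noisy)), 41)
  expect_error(simulate_mvc_trial(-5), "positive")
})

test_that("delta_v inversion round-trips through the generating sigmas", {
  for (dv in c(-3.9, -2, -0.5, 0, 0.7, 1.3)) {
    s <- sigmas_from_delta_v(dv, fluct_power_n2 = 0.42)
    expect_equal(delta_v_from_sigmas(s["sigma_good"], s["sigma_bad"]), dv,
                 tolerance = 1e-9, ignore_attr = TRUE)
    # power constraint: 3 v_good + v_bad equals the requested power
    expect_equal(3 * s[["sigma_good"]]^2 + s[["sigma_bad"]]^2 / 4, 0.42,
                 tolerance = 1e-12)
  }
  expect_error(sigmas_from_delta_v(-4), "attainable")
  expect_error(sigmas_from_delta_v(4 / 3), "attainable")
})

test_that("cohort ground truth carries the generating age trends", {
  coh <- simulate_cohort(cohort_spec(n_per_group = 12, trials_per_subject = 2,
                                     seed = 41))
  gt <- coh$subjects
  # oracle: regression of the ground-truth delta_v* on age, per group
  sl <- sapply(split(gt, gt$group), function(d)
    unname(coef(lm(dv_star ~ age_years, d))[2]))
  expect_gt(sl[["control"]], 0)
  expect_gt(sl[["CP"]], 0)
  expect_lt(sl[["TBI"]], 0)
  expect_equal(length(coh$trials), 36 * 2)
  expect_setequal(unique(coh$ground_truth$trials$task),
                  c("lettuce", "rainbow"))
})

test_that("subject-mean recovered delta_v converges to delta_v* with many trials", {
  spec <- cohort_spec(n_per_group = 1, groups = "control",
                      dv_intercept = c(control = -1.5),
                      dv_age_slope = c(control = 0),
                      residual_sd = 0, trial_jitter_sd = 0.3,
                      trials_per_subject = 24, mvc_base_n = 40, seed = 7)
  coh <- simulate_cohort(spec)
  dvs <- vapply(coh$trials, function(tr) coef(ucm(tr, filter = FALSE))["delta_v"],
                numeric(1))
  # trial-level estimates scatter around delta_v* and their mean approaches it
  expect_equal(mean(dvs), -1.5, tolerance = 3 * 0.3 / sqrt(24))
  expect_equal(dvs, coh$ground_truth$trials$dv_target, tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("cohort_spec validates groups and parameters", {
  expect_error(cohort_spec(groups = c("control", "control")), "at most once")
  expect_error(cohort_spec(groups = c("control", "stroke")), "subset")
  expect_error(cohort_spec(trials_per_subject = 1), ">= 2")
  expect_error(cohort_spec(dv_intercept = c(control = -2),
                           groups = c("control", "TBI")), "missing")
  expect_error(
    simulate_cohort(cohort_spec(n_per_group = 2, groups = "control",
                                dv_intercept = c(control = -5),
                                dv_age_slope = c(control = 0),
                                trials_per_subject = 2, seed = 1)),
    "attainable")
})
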