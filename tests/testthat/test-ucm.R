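test_that("the total-force Jacobian is [1 1 1 1]", {
  J <- total_force_jacobian()
  expect_equal(J, matrix(1, 1, 4))
  expect_equal(drop(J %*% c(1, 2, 3, 4)), 10)
  expect_equal(drop(J %*% c(1, -1, 2, -2)), 0)
})

test_that("the null-space basis is the conventional orthonormal triple", {
  B <- null_space_basis()
  expect_equal(B, rbind(c(-1/2,  5/6, -1/6, -1/6),
                        c(-1/2, -1/6,  5/6, -1/6),
                        c(-1/2, -1/6, -1/6,  5/6)), tolerance = 1e-15)
  # brute-force: pairwise dot products give the identity
  expect_lt(max(abs(B %*% t(B) - diag(3))), 1e-12)
  expect_lt(max(abs(total_force_jacobian() %*% t(B))), 1e-12)
})

test_that("per-finger detrending removes exactly the OLS line", {
  n <- 500
  t <- (seq_len(n) - 1) / 170
  lin <- make_trial(outer(t, c(1, 2, 3, 4)) + 1)
  expect_lt(max(abs(detrend_linear(lin)$df)), 1e-9)
  const <- make_trial(matrix(7, n, 4))
  expect_lt(max(abs(detrend_linear(const)$df)), 1e-9)

  s <- sin(2 * pi * 3 * t)  # integer cycles over fs-divisible n? no - generic
  f <- outer(2 + 5 * t, c(1, 1, 1, 1)); f[, 2] <- f[, 2] + s
  det <- detrend_linear(make_trial(f))
  # brute-force OLS oracle per channel
  oracle <- resid(lm(f[, 2] ~ t))
  expect_equal(det$df[, 2], oracle, tolerance = 1e-9, ignore_attr = TRUE)
  # residuals have zero mean and zero covariance with time
  expect_lt(max(abs(colMeans(det$df))), 1e-9)
  expect_lt(max(abs(crossprod(t - mean(t), det$df))) / n, 1e-9)
})

test_that("UCM projection splits df into zero-sum and common-mode parts", {
  d <- as_detrended(rbind(c(1, 0, 0, 0)))
  p <- project_ucm(d)
  expect_equal(p$f_par[1, ], c(3/4, -1/4, -1/4, -1/4), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(p$f_perp[1, ], rep(1/4, 4), tolerance = 1e-12,
               ignore_attr = TRUE)

  zs <- as_detrended(rbind(c(1, -1, 0, 0)))
  pz <- project_ucm(zs)
  expect_equal(pz$f_par, zs$df, tolerance = 1e-12, ignore_attr = TRUE)
  expect_lt(max(abs(pz$f_perp)), 1e-12)

  cm <- as_detrended(rbind(c(2, 2, 2, 2)))
  pc <- project_ucm(cm)
  expect_lt(max(abs(pc$f_par)), 1e-12)
  expect_equal(pc$f_perp, cm$df, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("explicit-basis projection equals a generic SVD null-space projection", {
  withr::with_seed(99, {
    for (i in 1:25) {
      df <- matrix(rnorm(40), 10, 4)
      p <- project_ucm(as_detrended(df))
      expect_lt(max(abs(p$f_par - svd_nullspace_project(df))), 1e-12)
      # structural invariants
      expect_lt(max(abs(rowSums(p$f_par))), 1e-9)
      expect_lt(max(abs(p$f_perp - p$f_perp[, 1])), 1e-9)
      expect_equal(p$f_par + p$f_perp, df, tolerance = 1e-12)
    }
  })
})

test_that("variance decomposition normalizes by dimension and sample count", {
  df <- matrix(rep(c(1, 0, 0, 0), each = 8), 8, 4)
  v <- variance_decomposition(project_ucm(as_detrended(df)))
  expect_equal(v$v_good, 1/4, tolerance = 1e-12)
  expect_equal(v$v_bad, 1/4, tolerance = 1e-12)
  expect_equal(v$delta_v, 0, tolerance = 1e-12)
  expect_equal(v$n_samples, 8L)
  # Pythagorean conservation: 3 v_good + v_bad = sum |df|^2 / n
  expect_equal(3 * v$v_good + v$v_bad, sum(df^2) / nrow(df),
               tolerance = 1e-12)

  z <- variance_decomposition(project_ucm(as_detrended(matrix(0, 5, 4))))
  expect_equal(z$v_good, 0)
  expect_equal(z$v_bad, 0)
  expect_true(is.na(z$delta_v))

  zs <- variance_decomposition(project_ucm(as_detrended(
    matrix(rep(c(1, -1, 0, 0), each = 5), 5, 4))))
  expect_equal(zs$v_bad, 0, tolerance = 1e-12)
})

test_that("synergy index attains its formula-forced values and bounds", {
  expect_equal(synergy_index(1, 0), 4/3)
  expect_equal(synergy_index(0, 1), -4)
  expect_equal(synergy_index(0.25, 0.25), 0)
  expect_error(synergy_index(0, 0), "undefined")
  expect_error(synergy_index(-1, 1), "nonnegative")
})

test_that("delta_v Fisher transform maps the attainable interval to the line", {
  dv <- c(-3.9, -1, 0, 1.3)
  z <- delta_v_fisher(dv)
  expect_true(all(diff(z) > 0))
  expect_equal(delta_v_fisher(0), 0.5 * log(3))
  expect_error(delta_v_fisher(-4), "inside")
})

test_that("good/bad variance and delta_v are scale- and permutation-equivariant", {
  tr <- simulate_ramp_trial(trial_spec(seed = 17))
  fit <- ucm(tr)
  k <- 2.7
  scaled <- tr; scaled$forces_n <- tr$forces_n * k
  fs <- ucm(scaled)
  expect_equal(coef(fs)[["v_good"]], k^2 * coef(fit)[["v_good"]],
               tolerance = 1e-9)
  expect_equal(coef(fs)[["v_bad"]], k^2 * coef(fit)[["v_bad"]],
               tolerance = 1e-9)
  expect_equal(coef(fs)[["delta_v"]], coef(fit)[["delta_v"]],
               tolerance = 1e-9)

  perm <- tr; perm$forces_n <- tr$forces_n[, c(3, 1, 4, 2)]
  fp <- ucm(perm)
  expect_equal(coef(fp), coef(fit), tolerance = 1e-9)
})

test_that("single-trial analysis recovers the injected variance structure", {
  good_only <- ucm(simulate_ramp_trial(trial_spec(sigma_good = 0.4,
                                                  sigma_bad = 0, seed = 51)))
  expect_gte(coef(good_only)[["delta_v"]], 1.2)

  bad_only <- ucm(simulate_ramp_trial(trial_spec(sigma_good = 0,
                                                 sigma_bad = 0.8, seed = 52)))
  expect_lte(coef(bad_only)[["delta_v"]], -3.5)

  # matched per-dimension variances (v_good = v_bad needs sigma_bad = 2 sigma_good)
  dvs <- vapply(1:50, function(s)
    coef(ucm(simulate_ramp_trial(trial_spec(sigma_good = 0.3, sigma_bad = 0.6,
                                            seed = 100 + s))))[["delta_v"]],
    numeric(1))
  expect_lt(abs(mean(dvs)), 0.15)
})

test_that("analyze_trials produces one results row per trial with metadata", {
  coh <- simulate_cohort(small_cohort_spec(seed = 61))
  res <- analyze_trials(coh$trials,
                        mvc = setNames(coh$subjects$mvc_n,
                                       coh$subjects$subject))
  expect_equal(nrow(res), length(coh$trials))
  expect_true(all(c("subject", "group", "age_years", "task", "trial",
                    "v_good_n2", "v_bad_n2", "delta_v",
                    "straight_line_dev_n", "peak_total_n", "mvc_n")
                  %in% names(res)))
  expect_false(anyNA(res$delta_v))
  expect_equal(res$mvc_n,
               coh$subjects$mvc_n[match(res$subject, coh$subjects$subject)])
  subj <- summarize_subjects(res)
  expect_equal(nrow(subj), nrow(coh$subjects) * 2)  # two tasks per subject
})
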