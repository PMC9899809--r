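# Independent oracles and small fixture builders used across the suite.

# generic orthogonal projection onto the null space of [1 1 1 1],
# constructed from an SVD of the Jacobian (independent of the explicit basis)
svd_nullspace_project <- function(df) {
  J <- matrix(1, 1, 4)
  V <- svd(J, nu = 0, nv = 4)$v[, 2:4]   # right singular vectors of the kernel
  df %*% V %*% t(V)
}

# wrap a raw fluctuation matrix as a detrended trial, bypassing detrending
as_detrended <- function(df) {
  structure(list(df = df, time_s = seq_len(nrow(df))), class = "detrended_trial")
}

# uniform-time force_trial from a matrix
make_trial <- function(forces, fs = 170, meta = list()) {
  force_trial((seq_len(nrow(forces)) - 1) / fs, forces, fs, meta = meta)
}

# analytic gain of the two-way digital Butterworth low-pass (bilinear warping)
analytic_two_pass_gain <- function(f, fc, ord, fs) {
  w <- tan(pi * f / fs) / tan(pi * fc / fs)
  1 / (1 + w^(2 * ord))
}

# least-squares amplitude of a sinusoid at freq f in samples y (interior fit;
# intercept and trend regressors soak up any DC/drift component)
fit_amplitude <- function(y, t, f, frac = c(0.25, 0.75)) {
  n <- length(t)
  idx <- seq(round(n * frac[1]), round(n * frac[2]))
  X <- cbind(1, t[idx], sin(2 * pi * f * t[idx]), cos(2 * pi * f * t[idx]))
  sqrt(sum(qr.solve(X, y[idx])[3:4]^2))
}

# tiny two-group cohort spec used by stats/pipeline tests
small_cohort_spec <- function(...) {
  cohort_spec(n_per_group = 4L, groups = c("control", "TBI"),
              dv_intercept = c(control = -2.0, TBI = -1.0),
              dv_age_slope = c(control = 0.10, TBI = -0.10),
              trials_per_subject = 4L, ...)
}
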