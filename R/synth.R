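# Synthetic force trials and cohorts with known ground truth.
#
# Fluctuations are injected as two independent smooth processes:
#   good: a 4-channel low-pass Gaussian process projected onto the null space
#         of [1 1 1 1], each retained null-space dimension rescaled to have
#         (sample) std. dev. sigma_good -> contributes only good variance;
#   bad:  a common-mode process c(t)/4 on every finger whose total-force
#         std. dev. is sigma_bad -> contributes only bad variance.
# Both processes are detrended and RMS-normalized before scaling, so the
# generated per-trial variances hit their targets exactly and the analytic
# delta-v of the generating parameters is recoverable.

# low-pass, detrended, unit-RMS noise channels (n x k matrix).
# White noise is filtered zero-phase over an extended stretch and the burn-in
# trimmed from both ends (reflection padding would inject a DC pedestal of
# ~2*x[1] at the edges of a white input), leaving a stationary smooth process.
.smooth_noise <- function(n, k, sample_rate_hz, corner_hz, time_s) {
  pad <- as.integer(ceiling(3 * sample_rate_hz / corner_hz))
  bf <- signal::butter(2L, corner_hz / (sample_rate_hz / 2), type = "low")
  x <- matrix(stats::rnorm((n + 2L * pad) * k), n + 2L * pad, k)
  x <- apply(x, 2L, function(ch) {
    y <- as.numeric(signal::filter(bf$b, bf$a, ch))
    rev(as.numeric(signal::filter(bf$b, bf$a, rev(y))))[pad + seq_len(n)]
  })
  x <- matrix(x, n, k)
  X <- cbind(1, time_s)
  x <- x - X %*% stats::lm.fit(X, x)$coefficients     # detrend
  rms <- sqrt(colMeans(x^2))
  sweep(x, 2L, ifelse(rms > 0, rms, 1), "/")
}

#' Specification of a synthetic ramp trial
#'
#' Parameters of one simulated 6-s force-ramp tracking trial in which the
#' total force should rise linearly while per-finger fluctuations have a
#' controlled split between task-irrelevant (zero-sum, "good") and
#' common-mode ("bad") components.
#'
#' @param duration_s Trial duration (s).
#' @param sample_rate_hz Sampling rate (Hz).
#' @param ramp_start_n,ramp_end_n Target total force at trial start/end (N).
#' @param sharing Nonnegative 4-vector of per-finger force fractions summing
#'   to 1.
#' @param sigma_good Std. dev. (N) of each of the three retained null-space
#'   fluctuation dimensions.
#' @param sigma_bad Std. dev. (N) of the common-mode fluctuation of the
#'   *total* force.
#' @param noise_corner_hz Bandwidth of the fluctuation processes (Hz); keep
#'   below the 4 Hz analysis filter cutoff so injected structure survives
#'   preprocessing.
#' @param seed Integer seed; generation is bit-reproducible from it.
#' @return A list of class `trial_spec`.
#' @export
trial_spec <- function(duration_s = 6, sample_rate_hz = 170,
                       ramp_start_n = 5, ramp_end_n = 20,
                       sharing = c(0.30, 0.30, 0.25, 0.15),
                       sigma_good = 0.25, sigma_bad = 0.8,
                       noise_corner_hz = 1.5, seed = 1L) {
  if (duration_s <= 0) stop("duration_s must be positive")
  if (sample_rate_hz <= 0) stop("sample_rate_hz must be positive")
  if (length(sharing) != 4L || any(sharing < 0))
    stop("sharing must be 4 nonnegative fractions")
  if (abs(sum(sharing) - 1) > 1e-12)
    stop("sharing must sum to 1 (got ", sum(sharing), ")")
  if (sigma_good < 0 || sigma_bad < 0) stop("sigmas must be nonnegative")
  structure(list(duration_s = duration_s, sample_rate_hz = sample_rate_hz,
                 ramp_start_n = ramp_start_n, ramp_end_n = ramp_end_n,
                 sharing = sharing, sigma_good = sigma_good,
                 sigma_bad = sigma_bad, noise_corner_hz = noise_corner_hz,
                 seed = as.integer(seed)),
            class = "trial_spec")
}

#' Simulate one force-ramp trial
#'
#' Expected per-finger force is `sharing[i]` times the linear ramp from
#' `ramp_start_n` to `ramp_end_n`; superimposed fluctuations decompose as
#' described in [trial_spec()]. Forces are floored at 0 N (pressing sensors
#' cannot pull); the number of clipped samples is recorded in attribute
#' `n_clipped` — heavy clipping biases the variance structure, so default
#' parameters keep it rare.
#'
#' @param spec A [trial_spec()].
#' @param meta Metadata list attached to the trial.
#' @return A [force_trial()].
#' @examples
#' tr <- simulate_ramp_trial(trial_spec(sigma_good = 0, sigma_bad = 0))
#' all.equal(range(total_force(tr)), c(5, 20))
#' @export
simulate_ramp_trial <- function(spec, meta = list()) {
  stopifnot(inherits(spec, "trial_spec"))
  n <- round(spec$duration_s * spec$sample_rate_hz)
  time_s <- (seq_len(n) - 1L) / spec$sample_rate_hz
  ramp <- spec$ramp_start_n +
    (spec$ramp_end_n - spec$ramp_start_n) * time_s / spec$duration_s
  base <- outer(ramp, spec$sharing)
  fluct <- withr::with_seed(spec$seed, {
    basis <- null_space_basis()
    g <- matrix(0, n, 4)
    if (spec$sigma_good > 0) {
      raw <- .smooth_noise(n, 4L, spec$sample_rate_hz, spec$noise_corner_hz,
                           time_s)
      coords <- raw %*% t(basis)
      rms <- sqrt(colMeans(coords^2))
      coords <- sweep(coords, 2L, ifelse(rms > 0, rms, 1), "/")
      g <- (spec$sigma_good * coords) %*% basis
    }
    b <- matrix(0, n, 4)
    if (spec$sigma_bad > 0) {
      ctot <- spec$sigma_bad *
        .smooth_noise(n, 1L, spec$sample_rate_hz, spec$noise_corner_hz, time_s)
      b <- matrix(ctot / 4, n, 4)
    }
    g + b
  })
  forces <- base + fluct
  n_clipped <- sum(forces < 0)
  forces[forces < 0] <- 0
  out <- force_trial(time_s, forces, spec$sample_rate_hz, meta)
  attr(out, "n_clipped") <- n_clipped
  out
}

#' Simulate one maximal-voluntary-contraction trial
#'
#' Total force rises smoothly over `rise_s` seconds to a plateau at
#' `max_total_n`, split across fingers by `sharing`, with small low-pass
#' noise added to the total.
#'
#' @param max_total_n Plateau total force (N); must be positive.
#' @param sharing Per-finger fractions summing to 1.
#' @param duration_s,sample_rate_hz Trial length (s) and rate (Hz).
#' @param noise_sd_n Std. dev. (N) of the low-pass noise on the total force.
#' @param rise_s Rise time to the plateau (s).
#' @param noise_corner_hz Noise bandwidth (Hz).
#' @param seed Integer seed.
#' @param meta Metadata list.
#' @return A [force_trial()].
#' @export
simulate_mvc_trial <- function(max_total_n,
                               sharing = c(0.30, 0.30, 0.25, 0.15),
                               duration_s = 5, sample_rate_hz = 170,
                               noise_sd_n = 0.2, rise_s = 1,
                               noise_corner_hz = 1.5, seed = 1L,
                               meta = list()) {
  if (max_total_n <= 0) stop("max_total_n must be positive")
  if (length(sharing) != 4L || any(sharing < 0) ||
      abs(sum(sharing) - 1) > 1e-12)
    stop("sharing must be 4 nonnegative fractions summing to 1")
  n <- round(duration_s * sample_rate_hz)
  time_s <- (seq_len(n) - 1L) / sample_rate_hz
  x <- pmin(time_s / rise_s, 1)
  shape <- x * x * (3 - 2 * x)                     # smoothstep to plateau
  total <- shape * max_total_n
  if (noise_sd_n > 0)
    total <- total + noise_sd_n * withr::with_seed(seed,
      .smooth_noise(n, 1L, sample_rate_hz, noise_corner_hz, time_s))[, 1]
  forces <- outer(pmax(total, 0), sharing)
  force_trial(time_s, forces, sample_rate_hz, meta)
}

#' Analytic synergy index of generating parameters
#'
#' For the generator of [simulate_ramp_trial()], the good variance is
#' `sigma_good^2` and the bad variance is `(sigma_bad / 2)^2`, giving
#' `delta_v = (v_good - v_bad) / ((3 v_good + v_bad) / 4)`.
#'
#' @param sigma_good,sigma_bad Generator noise scales (N).
#' @return The synergy index the generated trials embody.
#' @export
delta_v_from_sigmas <- function(sigma_good, sigma_bad) {
  synergy_index(sigma_good^2, sigma_bad^2 / 4)
}

#' Invert the synergy index at fixed fluctuation power
#'
#' Solves for `(sigma_good, sigma_bad)` such that the generated trial has the
#' requested `delta_v` and total detrended fluctuation power
#' `3 v_good + v_bad = fluct_power_n2` (N^2 per sample). Round-trips with
#' [delta_v_from_sigmas()] to machine precision.
#'
#' @param delta_v Target synergy index, strictly inside `(-4, 4/3)` (the
#'   attainable interval).
#' @param fluct_power_n2 Total fluctuation power (N^2).
#' @return Named vector `sigma_good`, `sigma_bad`.
#' @export
sigmas_from_delta_v <- function(delta_v, fluct_power_n2 = 0.3) {
  if (any(delta_v <= -4 | delta_v >= 4/3))
    stop("delta_v must lie in the attainable open interval (-4, 4/3)")
  if (fluct_power_n2 <= 0) stop("fluct_power_n2 must be positive")
  v_good <- fluct_power_n2 * (4 + delta_v) / 16
  v_bad <- fluct_power_n2 * (4 - 3 * delta_v) / 16
  c(sigma_good = sqrt(v_good), sigma_bad = 2 * sqrt(v_bad))
}

#' Specification of a synthetic cohort
#'
#' Per-group generating parameters for a cohort in which each subject's
#' target synergy index is linear in age, `delta_v* = dv_intercept[group] +
#' dv_age_slope[group] * age + N(0, residual_sd)`, mapped to trial noise
#' scales by [sigmas_from_delta_v()] at fixed fluctuation power. Each subject
#' contributes `trials_per_subject` ramp trials, split evenly between the two
#' tracking tasks (`lettuce`, `rainbow`). Subject MVC is
#' `mvc_base_n + mvc_age_slope_n * age` and sets the ramp range (25% to 75%
#' of MVC).
#'
#' @param n_per_group Subjects per group: a single count or a named vector.
#' @param groups Group labels, a subset of `control`, `CP`, `TBI` (each at
#'   most once).
#' @param age_range_years Age interval subjects are drawn uniformly from.
#' @param dv_intercept,dv_age_slope Named per-group generating parameters
#'   (dimensionless; slope per year).
#' @param trials_per_subject Ramp trials per subject (>= 2).
#' @param mvc_base_n,mvc_age_slope_n MVC model (N, N per year).
#' @param residual_sd Subject-level residual std. dev. of delta_v*.
#' @param trial_jitter_sd Trial-to-trial std. dev. of the per-trial target
#'   delta_v around the subject's delta_v*.
#' @param fluct_power_n2 Total detrended fluctuation power per trial (N^2).
#' @param duration_s,sample_rate_hz,noise_corner_hz Trial-level settings, see
#'   [trial_spec()].
#' @param seed Integer master seed.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_group = 15L,
                        groups = c("control", "CP", "TBI"),
                        age_range_years = c(4, 12),
                        dv_intercept = c(control = -2.0, CP = -2.2, TBI = -1.0),
                        dv_age_slope = c(control = 0.10, CP = 0.10, TBI = -0.10),
                        trials_per_subject = 20L,
                        mvc_base_n = 10, mvc_age_slope_n = 2.5,
                        residual_sd = 0.3, trial_jitter_sd = 0.15,
                        fluct_power_n2 = 0.3,
                        duration_s = 6, sample_rate_hz = 170,
                        noise_corner_hz = 1.5, seed = 1L) {
  if (!all(groups %in% c("control", "CP", "TBI")))
    stop("groups must be a subset of {control, CP, TBI}")
  if (anyDuplicated(groups))
    stop("each group may appear at most once")
  if (trials_per_subject < 2L)
    stop("trials_per_subject must be >= 2 (needed for subject-level variance)")
  if (length(n_per_group) == 1L && is.null(names(n_per_group)))
    n_per_group <- stats::setNames(rep(as.integer(n_per_group),
                                       length(groups)), groups)
  missing_par <- setdiff(groups, intersect(names(dv_intercept),
                                           names(dv_age_slope)))
  if (length(missing_par))
    stop("dv_intercept/dv_age_slope missing for group(s): ",
         paste(missing_par, collapse = ", "))
  if (length(age_range_years) != 2L || diff(age_range_years) <= 0)
    stop("age_range_years must be an increasing interval")
  if (residual_sd < 0 || trial_jitter_sd < 0)
    stop("residual_sd and trial_jitter_sd must be nonnegative")
  structure(list(n_per_group = n_per_group, groups = groups,
                 age_range_years = age_range_years,
                 dv_intercept = dv_intercept, dv_age_slope = dv_age_slope,
                 trials_per_subject = as.integer(trials_per_subject),
                 mvc_base_n = mvc_base_n, mvc_age_slope_n = mvc_age_slope_n,
                 residual_sd = residual_sd, trial_jitter_sd = trial_jitter_sd,
                 fluct_power_n2 = fluct_power_n2, duration_s = duration_s,
                 sample_rate_hz = sample_rate_hz,
                 noise_corner_hz = noise_corner_hz, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Simulate a full cohort of ramp trials with known ground truth
#'
#' Draws subjects (age, group, subject-level delta_v*), maps each trial's
#' target synergy index to `(sigma_good, sigma_bad)` via
#' [sigmas_from_delta_v()], and generates every ramp trial. The returned
#' ground truth records all generating parameters, so recovery can be scored
#' exactly.
#'
#' @param spec A [cohort_spec()].
#' @return A list of class `ucm_cohort` with elements `trials` (list of
#'   [force_trial()]), `subjects` (one row per subject: group, age, MVC,
#'   delta_v*), and `ground_truth` (per-trial targets, noise scales and
#'   seeds).
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  bound <- 4 / 3
  plan <- withr::with_seed(spec$seed, {
    subj_rows <- list()
    for (g in spec$groups) {
      ng <- spec$n_per_group[[g]]
      age <- stats::runif(ng, spec$age_range_years[1], spec$age_range_years[2])
      dv_star <- spec$dv_intercept[[g]] + spec$dv_age_slope[[g]] * age +
        stats::rnorm(ng, 0, spec$residual_sd)
      if (any(dv_star <= -4 | dv_star >= bound))
        stop("generated delta_v* outside the attainable interval (-4, 4/3); ",
             "adjust dv_intercept/dv_age_slope/residual_sd")
      subj_rows[[g]] <- data.frame(
        subject = sprintf("%s%02d", g, seq_len(ng)), group = g,
        age_years = age, hand = "right", paretic = FALSE,
        mvc_n = spec$mvc_base_n + spec$mvc_age_slope_n * age,
        dv_star = dv_star)
    }
    subjects <- do.call(rbind, subj_rows)
    rownames(subjects) <- NULL
    k <- spec$trials_per_subject
    trials_gt <- do.call(rbind, lapply(seq_len(nrow(subjects)), function(i) {
      dv_t <- subjects$dv_star[i] + stats::rnorm(k, 0, spec$trial_jitter_sd)
      dv_t <- pmin(pmax(dv_t, -4 + 1e-3), bound - 1e-3)
      data.frame(subject = subjects$subject[i], trial = seq_len(k),
                 task = rep(c("lettuce", "rainbow"), length.out = k),
                 dv_target = dv_t,
                 seed = sample.int(.Machine$integer.max - 1L, k))
    }))
    list(subjects = subjects, trials = trials_gt)
  })
  sig <- t(vapply(plan$trials$dv_target, sigmas_from_delta_v, numeric(2),
                  fluct_power_n2 = spec$fluct_power_n2))
  plan$trials$sigma_good <- sig[, "sigma_good"]
  plan$trials$sigma_bad <- sig[, "sigma_bad"]
  subj_idx <- match(plan$trials$subject, plan$subjects$subject)
  trials <- vector("list", nrow(plan$trials))
  for (i in seq_len(nrow(plan$trials))) {
    s <- plan$subjects[subj_idx[i], ]
    tsp <- trial_spec(
      duration_s = spec$duration_s, sample_rate_hz = spec$sample_rate_hz,
      ramp_start_n = 0.25 * s$mvc_n, ramp_end_n = 0.75 * s$mvc_n,
      sigma_good = plan$trials$sigma_good[i],
      sigma_bad = plan$trials$sigma_bad[i],
      noise_corner_hz = spec$noise_corner_hz,
      seed = plan$trials$seed[i])
    trials[[i]] <- simulate_ramp_trial(tsp, meta = list(
      subject = s$subject, group = s$group, age_years = s$age_years,
      hand = s$hand, paretic = s$paretic, task = plan$trials$task[i],
      trial = plan$trials$trial[i]))
  }
  structure(list(trials = trials, subjects = plan$subjects,
                 ground_truth = list(subjects = plan$subjects,
                                     trials = plan$trials, spec = spec)),
            class = "ucm_cohort")
}

#' @export
print.ucm_cohort <- function(x, ...) {
  cat(sprintf("<ucm_cohort> %d subjects (%s), %d trials\n",
              nrow(x$subjects),
              paste(names(table(x$subjects$group)),
                    table(x$subjects$group), sep = "=", collapse = ", "),
              length(x$trials)))
  invisible(x)
}
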