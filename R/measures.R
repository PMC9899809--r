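# Per-trial performance measures: MVC, straight-line deviation, finger sharing.

#' Maximum voluntary contraction from repeated maximal-effort trials
#'
#' The MVC is the maximum, over all samples of all repetitions, of the
#' per-sample sum of the four finger forces. Trials are low-pass filtered
#' first by default (all force data are filtered before analysis); set
#' `filter = FALSE` to use the raw recordings.
#'
#' @param trials A [force_trial()] or list of them — the MVC-task repetitions
#'   for one subject and hand (normally three).
#' @param filter Filter each repetition with [lowpass_filter()] first?
#' @param cutoff_hz,order Passed to [lowpass_filter()].
#' @return The MVC in Newtons.
#' @examples
#' reps <- lapply(c(30, 40, 35), function(m)
#'   simulate_mvc_trial(m, noise_sd_n = 0, seed = 1))
#' compute_mvc(reps, filter = FALSE)
#' @export
compute_mvc <- function(trials, filter = TRUE, cutoff_hz = 4, order = 4L) {
  if (inherits(trials, "force_trial")) trials <- list(trials)
  if (length(trials) == 0L) stop("compute_mvc needs at least one trial")
  stopifnot(all(vapply(trials, inherits, logical(1), "force_trial")))
  subj <- unique(unlist(lapply(trials, function(x) x$meta$subject)))
  if (length(subj) > 1L)
    stop("MVC trials mix subjects: ", paste(subj, collapse = ", "))
  if (length(trials) != 3L)
    warning("MVC is normally computed over 3 repetitions; got ",
            length(trials))
  if (filter)
    trials <- lapply(trials, lowpass_filter, cutoff_hz = cutoff_hz,
                     order = order)
  max(vapply(trials, function(x) max(total_force(x)), numeric(1)))
}

#' Straight-line deviation of the total force
#'
#' Deviation of the total-force trace from its own least-squares line over
#' time: the mean distance (vertical OLS residual) between the best-fit line
#' of the sum of forces and the actual sum of forces, in Newtons. A perfect
#' constant-velocity ramp scores 0.
#'
#' @param trial A (filtered) [force_trial()] with at least 3 samples.
#' @param method `"mean_abs"` (default) uses the mean absolute residual;
#'   `"rms"` the root-mean-square residual.
#' @return Deviation in Newtons (nonnegative).
#' @export
straight_line_deviation <- function(trial, method = c("mean_abs", "rms")) {
  stopifnot(inherits(trial, "force_trial"))
  method <- match.arg(method)
  if (length(trial$time_s) < 3L)
    stop("straight_line_deviation needs at least 3 samples")
  tot <- total_force(trial)
  r <- stats::lm.fit(cbind(1, trial$time_s), tot)$residuals
  if (method == "mean_abs") mean(abs(r)) else sqrt(mean(r^2))
}

#' Finger sharing percentages
#'
#' The mean percentage of the total force produced by each finger: per sample,
#' each finger's force is expressed as a percentage of that sample's total,
#' then averaged over samples and renormalized so the four components sum to
#' exactly 100. Samples whose total force is below `floor_n` are excluded to
#' avoid 0/0 ratios near ramp onset.
#'
#' @param trial A [force_trial()].
#' @param floor_n Total-force floor (N) below which samples are excluded.
#' @return Numeric 4-vector (index, middle, ring, little) of percentages
#'   summing to 100.
#' @export
finger_sharing <- function(trial, floor_n = 0.5) {
  stopifnot(inherits(trial, "force_trial"))
  tot <- total_force(trial)
  keep <- tot >= floor_n
  if (!any(keep))
    stop("no samples with total force >= ", floor_n, " N")
  pct <- colMeans(trial$forces_n[keep, , drop = FALSE] / tot[keep] * 100)
  pct <- pct / sum(pct) * 100
  names(pct) <- FINGERS
  pct
}

#' Peak total force of a trial
#'
#' @param trial A [force_trial()].
#' @return Maximum per-sample four-finger sum (N).
#' @export
peak_total_force <- function(trial) max(total_force(trial))
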