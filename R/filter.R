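# Zero-phase Butterworth low-pass filtering.
#
# Coefficients come from signal::butter; the forward-backward pass is done
# here because edge behaviour matters on 6-s ramp trials: we use odd
# (point-reflected) extension at both ends plus steady-state direct-form-I
# initial conditions, so a constant passes exactly and a ramp is preserved
# away from the edges.

# one causal pass, started from steady state at x[1]
.butter_pass <- function(x, b, a) {
  as.numeric(signal::filter(b, a, x,
                            init = rep(x[1], length(a) - 1L),
                            init.x = rep(x[1], length(b) - 1L)))
}

# zero-phase (forward-backward) pass over one channel
.filtfilt_channel <- function(x, b, a, padlen) {
  n <- length(x)
  padlen <- min(n - 1L, padlen)
  pre <- 2 * x[1] - x[seq(padlen + 1L, 2L)]
  post <- 2 * x[n] - x[seq(n - 1L, n - padlen)]
  y <- .butter_pass(c(pre, x, post), b, a)
  y <- rev(.butter_pass(rev(y), b, a))
  y[(padlen + 1L):(padlen + n)]
}

#' Zero-phase Butterworth low-pass filter
#'
#' Applies a two-way (forward-backward, hence zero-phase) Butterworth low-pass
#' filter to every finger channel of a trial. The defaults — order 4, 4 Hz
#' cutoff — are the standard preprocessing for 170 Hz finger-force recordings;
#' because the filter runs twice, the effective magnitude response is the
#' square of the single-pass Butterworth response and the DC gain is exactly 1.
#'
#' @param trial A [force_trial()].
#' @param cutoff_hz Cutoff frequency in Hz; must be below the Nyquist
#'   frequency.
#' @param order Filter order of a single pass.
#' @return The trial with filtered force channels.
#' @examples
#' tr <- simulate_ramp_trial(trial_spec(seed = 1))
#' filt <- lowpass_filter(tr)
#' @export
lowpass_filter <- function(trial, cutoff_hz = 4, order = 4L) {
  stopifnot(inherits(trial, "force_trial"))
  fs <- trial$sample_rate_hz
  if (cutoff_hz <= 0 || cutoff_hz >= fs / 2)
    stop("cutoff_hz must lie in (0, Nyquist) = (0, ", fs / 2, ") Hz")
  n <- nrow(trial$forces_n)
  min_n <- 3L * (2L * order + 1L)
  if (n < min_n)
    stop("trial too short to filter: ", n, " samples, need at least ", min_n)
  bf <- signal::butter(order, cutoff_hz / (fs / 2), type = "low")
  padlen <- as.integer(ceiling(3 * fs / cutoff_hz))
  trial$forces_n <- apply(trial$forces_n, 2L, .filtfilt_channel,
                          b = bf$b, a = bf$a, padlen = padlen)
  colnames(trial$forces_n) <- FINGERS
  attr(trial, "filtered") <- TRUE
  trial
}

#' Analytic two-pass Butterworth magnitude response
#'
#' Magnitude gain of the zero-phase (two-way) digital Butterworth low-pass at
#' a given frequency, accounting for the bilinear-transform frequency warping
#' used in the filter design. Useful as an independent check of
#' [lowpass_filter()].
#'
#' @param freq_hz Frequency at which to evaluate the gain (Hz).
#' @param cutoff_hz,order Filter design parameters as in [lowpass_filter()].
#' @param sample_rate_hz Sampling rate (Hz).
#' @return Gain in (0, 1]; the single-pass power response, i.e. the two-pass
#'   amplitude response.
#' @export
butterworth_gain <- function(freq_hz, cutoff_hz = 4, order = 4L,
                             sample_rate_hz = 170) {
  w <- tan(pi * freq_hz / sample_rate_hz) / tan(pi * cutoff_hz / sample_rate_hz)
  1 / (1 + w^(2 * order))
}
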