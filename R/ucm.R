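# Single-trial uncontrolled-manifold decomposition.
#
# Task variable: total force F_TOT = sum of the four finger forces. The
# Jacobian of the task is [1 1 1 1]; fluctuations inside its null space leave
# the total force unchanged ("good" variance), fluctuations along [1 1 1 1]
# perturb it ("bad" variance). The synergy index delta-v contrasts the two on
# a per-dimension basis and is bounded in [-4, 4/3].

#' Jacobian of the total-force task
#'
#' @return The 1x4 matrix `[1 1 1 1]` mapping changes in the four finger
#'   forces to the change in total force.
#' @export
total_force_jacobian <- function() matrix(1, nrow = 1, ncol = 4)

#' Orthonormal basis of the total-force null space
#'
#' The three solutions e_i of `[1 1 1 1] e = 0` used for the UCM projection,
#' as rows of a 3x4 matrix, in the conventional order
#' `(-1/2, 5/6, -1/6, -1/6)`, `(-1/2, -1/6, 5/6, -1/6)`,
#' `(-1/2, -1/6, -1/6, 5/6)`. The vectors are unit-norm and mutually
#' orthogonal.
#'
#' @return 3x4 numeric matrix whose rows are the basis vectors.
#' @export
null_space_basis <- function() {
  rbind(c(-1/2,  5/6, -1/6, -1/6),
        c(-1/2, -1/6,  5/6, -1/6),
        c(-1/2, -1/6, -1/6,  5/6))
}

#' Remove each finger's linear trend
#'
#' Subtracts from every finger channel its own least-squares line over time,
#' yielding the fluctuation matrix `df` analysed by the UCM decomposition.
#'
#' @param trial A (filtered) [force_trial()] with at least 3 samples.
#' @return A list of class `detrended_trial` with elements `df` (samples x 4,
#'   Newtons), `time_s`, and — after [project_ucm()] — `f_par` and `f_perp`.
#' @export
detrend_linear <- function(trial) {
  stopifnot(inherits(trial, "force_trial"))
  n <- length(trial$time_s)
  if (n < 3L) stop("detrending needs at least 3 samples")
  if (max(trial$time_s) - min(trial$time_s) <= 0)
    stop("degenerate time vector")
  X <- cbind(1, trial$time_s)
  fit <- stats::lm.fit(X, trial$forces_n)
  df <- trial$forces_n - X %*% fit$coefficients
  dimnames(df) <- list(NULL, FINGERS)
  structure(list(df = df, trend = X %*% fit$coefficients,
                 time_s = trial$time_s, meta = trial$meta),
            class = "detrended_trial")
}

#' Project detrended forces onto the task null space
#'
#' Splits `df` into `f_par`, the component lying in the null space of
#' `[1 1 1 1]` (every row sums to zero: it does not change the total force),
#' and the orthogonal remainder `f_perp` (every row has four equal entries:
#' pure common-mode change of the total force), with
#' `f_par(t) = sum_i (e_i . df(t)) e_i` over the three basis vectors.
#'
#' @param detrended A `detrended_trial` from [detrend_linear()].
#' @param basis Basis matrix as returned by [null_space_basis()].
#' @return The `detrended_trial` with `f_par` and `f_perp` filled in.
#' @export
project_ucm <- function(detrended, basis = null_space_basis()) {
  stopifnot(inherits(detrended, "detrended_trial"))
  basis <- as.matrix(basis)
  if (!all(dim(basis) == c(3L, 4L)))
    stop("basis must be a 3x4 matrix of null-space vectors")
  coords <- detrended$df %*% t(basis)       # samples x 3
  detrended$f_par <- coords %*% basis
  detrended$f_perp <- detrended$df - detrended$f_par
  detrended
}

#' Good/bad variance decomposition of a projected trial
#'
#' With N samples, the good (task-irrelevant) variance is
#' `v_good = sum_t |f_par(t)|^2 / (3 N)` — normalized by the three null-space
#' dimensions — and the bad (task-relevant) variance is
#' `v_bad = sum_t |f_perp(t)|^2 / N`. Both are in Newtons squared; the sums
#' divide by N exactly (no N-1 correction).
#'
#' @param projected A `detrended_trial` with `f_par`/`f_perp` from
#'   [project_ucm()].
#' @return A list of class `variance_decomposition` with `v_good`, `v_bad`,
#'   `delta_v`, `n_samples`, and the intermediate sums `f_par_sq_sum`,
#'   `f_perp_sq_sum`.
#' @export
variance_decomposition <- function(projected) {
  stopifnot(inherits(projected, "detrended_trial"))
  if (is.null(projected$f_par))
    stop("run project_ucm() before variance_decomposition()")
  n <- nrow(projected$df)
  if (n == 0L) stop("empty trial")
  par_sq <- sum(projected$f_par^2)
  perp_sq <- sum(projected$f_perp^2)
  v_good <- par_sq / (3 * n)
  v_bad <- perp_sq / n
  structure(list(v_good = v_good, v_bad = v_bad,
                 delta_v = if (par_sq == 0 && perp_sq == 0) NA_real_
                           else synergy_index(v_good, v_bad),
                 n_samples = n,
                 f_par_sq_sum = par_sq, f_perp_sq_sum = perp_sq),
            class = "variance_decomposition")
}

#' @export
print.variance_decomposition <- function(x, ...) {
  cat(sprintf("v_good = %.4g N^2  v_bad = %.4g N^2  delta_v = %.4g  (N = %d)\n",
              x$v_good, x$v_bad, x$delta_v, x$n_samples))
  invisible(x)
}

#' Synergy index delta-v
#'
#' The dimension-normalized contrast of good and bad variance,
#' `delta_v = (v_good - v_bad) / ((3 v_good + v_bad) / 4)`, bounded in
#' `[-4, 4/3]`: `4/3` when all variance is task-irrelevant (`v_bad = 0`),
#' `-4` when all variance perturbs the total force (`v_good = 0`), and 0 when
#' the per-dimension variances are equal. Positive values indicate
#' force-stabilizing covariation between the fingers.
#'
#' @param v_good Good variance (N^2 per dimension per sample), or a
#'   `variance_decomposition` object.
#' @param v_bad Bad variance (N^2 per sample); ignored when `v_good` is a
#'   `variance_decomposition`.
#' @return delta-v (dimensionless).
#' @export
synergy_index <- function(v_good, v_bad) {
  if (inherits(v_good, "variance_decomposition")) {
    v_bad <- v_good$v_bad
    v_good <- v_good$v_good
  }
  if (v_good < 0 || v_bad < 0) stop("variances must be nonnegative")
  if (v_good == 0 && v_bad == 0)
    stop("delta_v is undefined when v_good = v_bad = 0")
  (v_good - v_bad) / ((3 * v_good + v_bad) / 4)
}

#' Fisher-style transform of delta-v
#'
#' Maps the bounded synergy index from `(-4, 4/3)` onto the real line,
#' `z = log((4 + delta_v) / (4/3 - delta_v)) / 2`, as sometimes used before
#' parametric statistics. The analysis pipeline uses raw delta-v by default.
#'
#' @param delta_v Synergy index values in `(-4, 4/3)`.
#' @return Transformed values.
#' @export
delta_v_fisher <- function(delta_v) {
  if (any(delta_v <= -4 | delta_v >= 4/3, na.rm = TRUE))
    stop("delta_v must lie strictly inside (-4, 4/3)")
  0.5 * log((4 + delta_v) / (4/3 - delta_v))
}

#' Single-trial UCM analysis
#'
#' The core fitting function: filter (optional) -> per-finger linear detrend
#' -> null-space projection -> good/bad variance -> synergy index, together
#' with the per-trial performance measures (straight-line deviation, finger
#' sharing, peak total force).
#'
#' @param trial A raw ramp-task [force_trial()].
#' @param filter Apply [lowpass_filter()] first? Default `TRUE`.
#' @param cutoff_hz,order Filter settings.
#' @param trim_s Seconds to drop from each end after filtering (default 0:
#'   trials are analysed in full).
#' @param sharing_floor_n Total-force floor for [finger_sharing()].
#' @return An object of class `ucm_fit`; see [coef.ucm_fit()],
#'   [summary.ucm_fit()], [residuals.ucm_fit()].
#' @examples
#' fit <- ucm(simulate_ramp_trial(trial_spec(seed = 7)))
#' coef(fit)
#' @export
ucm <- function(trial, filter = TRUE, cutoff_hz = 4, order = 4L, trim_s = 0,
                sharing_floor_n = 0.5) {
  stopifnot(inherits(trial, "force_trial"))
  cl <- match.call()
  tr <- if (filter) lowpass_filter(trial, cutoff_hz, order) else trial
  if (trim_s > 0) {
    keep <- tr$time_s >= (tr$time_s[1] + trim_s) &
      tr$time_s <= (tr$time_s[length(tr$time_s)] - trim_s)
    if (sum(keep) < 3L) stop("trim_s leaves fewer than 3 samples")
    tr <- force_trial(tr$time_s[keep], tr$forces_n[keep, , drop = FALSE],
                      tr$sample_rate_hz, tr$meta)
  }
  det <- project_ucm(detrend_linear(tr))
  v <- variance_decomposition(det)
  measures <- list(
    straight_line_dev_n = straight_line_deviation(tr),
    sharing_pct = finger_sharing(tr, floor_n = sharing_floor_n),
    peak_total_n = peak_total_force(tr))
  structure(list(decomposition = v, measures = measures, detrended = det,
                 trial = tr, call = cl),
            class = "ucm_fit")
}

#' @export
print.ucm_fit <- function(x, ...) {
  cat("Single-trial UCM analysis\n")
  m <- x$trial$meta
  if (!is.null(m$subject))
    cat(sprintf("  subject %s, trial %s\n", m$subject,
                if (is.null(m$trial)) "?" else m$trial))
  print(x$decomposition)
  cat(sprintf("  straight-line deviation: %.4g N, peak total: %.4g N\n",
              x$measures$straight_line_dev_n, x$measures$peak_total_n))
  cat("  sharing (%):", paste(sprintf("%s %.1f", FINGERS,
                                      x$measures$sharing_pct),
                              collapse = ", "), "\n")
  invisible(x)
}

#' Extract UCM quantities from a fit
#'
#' @param object A `ucm_fit`.
#' @param ... Unused.
#' @return Named vector `v_good`, `v_bad`, `delta_v`.
#' @export
coef.ucm_fit <- function(object, ...) {
  v <- object$decomposition
  c(v_good = v$v_good, v_bad = v$v_bad, delta_v = v$delta_v)
}

#' @export
residuals.ucm_fit <- function(object, ...) object$detrended$df

#' @export
fitted.ucm_fit <- function(object, ...) object$detrended$trend

#' @export
summary.ucm_fit <- function(object, ...) {
  v <- object$decomposition
  out <- data.frame(
    v_good_n2 = v$v_good, v_bad_n2 = v$v_bad, delta_v = v$delta_v,
    n_samples = v$n_samples,
    straight_line_dev_n = object$measures$straight_line_dev_n,
    peak_total_n = object$measures$peak_total_n,
    t(object$measures$sharing_pct))
  names(out)[7:10] <- paste0("sharing_pct_", FINGERS)
  class(out) <- c("summary.ucm_fit", "data.frame")
  out
}

#' @export
plot.ucm_fit <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(op))
  plot(x$trial)
  graphics::matplot(x$detrended$time_s,
                    cbind(rowSums(x$detrended$f_par^2),
                          rowSums(x$detrended$f_perp^2)),
                    type = "l", lty = 1, col = c("#009E73", "#D55E00"),
                    xlab = "time (s)", ylab = expression("squared fluctuation (N"^2*")"))
  graphics::legend("topleft", bty = "n", lty = 1,
                   col = c("#009E73", "#D55E00"),
                   legend = c(expression("|f"[par]*"|"^2),
                              expression("|f"[perp]*"|"^2)))
  invisible(x)
}

#' Analyse a batch of ramp trials into a results table
#'
#' Runs [ucm()] on every trial and collects one row per trial with the trial
#' metadata, the variance decomposition, the synergy index and the
#' performance measures — the long-format table consumed by the statistics
#' stage.
#'
#' @param trials List of [force_trial()] objects.
#' @param mvc Optional named vector of MVC values (N) keyed by subject id,
#'   copied into the `mvc_n` column.
#' @param ... Passed to [ucm()].
#' @return A `data.frame` with columns `subject, group, age_years, hand,
#'   paretic, task, trial, v_good_n2, v_bad_n2, delta_v,
#'   straight_line_dev_n, sharing_pct_index..little, peak_total_n, mvc_n`.
#' @export
analyze_trials <- function(trials, mvc = NULL, ...) {
  stopifnot(length(trials) > 0L)
  rows <- lapply(trials, function(tr) {
    m <- tr$meta
    fit <- tryCatch(ucm(tr, ...), error = function(e)
      stop("trial ", if (is.null(m$trial)) "?" else m$trial,
           " (subject ", if (is.null(m$subject)) "?" else m$subject, "): ",
           conditionMessage(e), call. = FALSE))
    s <- summary(fit)
    data.frame(
      subject = if (is.null(m$subject)) NA_character_ else as.character(m$subject),
      group = if (is.null(m$group)) NA_character_ else as.character(m$group),
      age_years = if (is.null(m$age_years)) NA_real_ else as.numeric(m$age_years),
      hand = if (is.null(m$hand)) NA_character_ else as.character(m$hand),
      paretic = if (is.null(m$paretic)) NA else as.logical(m$paretic),
      task = if (is.null(m$task)) NA_character_ else as.character(m$task),
      trial = if (is.null(m$trial)) NA_integer_ else as.integer(m$trial),
      s, row.names = NULL)
  })
  out <- do.call(rbind, rows)
  if (!is.null(mvc)) out$mvc_n <- unname(mvc[out$subject])
  else out$mvc_n <- NA_real_
  class(out) <- c("ucm_results", "data.frame")
  out
}

#' Aggregate per-trial results to subject level
#'
#' Averages the per-trial outcomes over trials within subject, hand and task
#' (one point per subject/hand/task), carrying the metadata columns along —
#' the aggregation level used by the model-selection stage.
#'
#' @param results A table from [analyze_trials()].
#' @param by Grouping columns.
#' @return Aggregated `data.frame`.
#' @export
summarize_subjects <- function(results,
                               by = c("subject", "hand", "task")) {
  stopifnot(is.data.frame(results))
  by <- intersect(by, names(results))
  num <- c("v_good_n2", "v_bad_n2", "delta_v", "straight_line_dev_n",
           paste0("sharing_pct_", FINGERS), "peak_total_n", "mvc_n")
  num <- intersect(num, names(results))
  agg <- stats::aggregate(results[num], results[by],
                          function(x) mean(x, na.rm = TRUE))
  meta <- c("group", "age_years", "paretic")
  meta <- intersect(meta, names(results))
  first <- stats::aggregate(results[meta], results[by], function(x) x[1])
  merge(first, agg, by = by)
}
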