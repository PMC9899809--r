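#' @keywords internal
"_PACKAGE"

FINGERS <- c("index", "middle", "ring", "little")

#' Construct a four-finger force trial
#'
#' A `force_trial` is the atom of the pipeline: one trial's uniformly sampled
#' four-finger force matrix (index, middle, ring, little; Newtons) together
#' with its sampling rate and subject/task metadata.
#'
#' @param time_s Numeric vector of sample times in seconds; strictly
#'   increasing and uniformly spaced (within 1e-6 s).
#' @param forces_n Numeric matrix with one row per sample and exactly four
#'   columns (index, middle, ring, little), in Newtons.
#' @param sample_rate_hz Sampling rate in Hz. Defaults to the rate implied by
#'   `time_s`.
#' @param meta Named list of metadata; recognised fields are `subject`,
#'   `group` (one of `"control"`, `"CP"`, `"TBI"`), `age_years`, `hand`,
#'   `paretic` (logical), `task` and `trial`.
#' @return An object of class `force_trial`.
#' @examples
#' t <- seq(0, 1, by = 1 / 170)
#' f <- matrix(1, length(t), 4)
#' tr <- force_trial(t, f)
#' total_force(tr)[1]
#' @export
force_trial <- function(time_s, forces_n, sample_rate_hz = NULL, meta = list()) {
  time_s <- as.numeric(time_s)
  forces_n <- as.matrix(forces_n)
  if (ncol(forces_n) != 4L)
    stop("forces_n must have exactly 4 finger channels, got ", ncol(forces_n))
  if (nrow(forces_n) != length(time_s))
    stop("time_s and forces_n disagree on the number of samples")
  if (length(time_s) < 2L)
    stop("a trial needs at least 2 samples")
  dt <- diff(time_s)
  if (any(dt <= 0))
    stop("time_s must be strictly increasing")
  if (max(dt) - min(dt) > 1e-6)
    stop("time_s must be uniformly spaced within 1e-6 s")
  if (!all(is.finite(forces_n)))
    stop("forces_n contains non-finite values",
         if (!is.null(meta$trial)) paste0(" (trial ", meta$trial, ")") else "")
  if (is.null(sample_rate_hz)) sample_rate_hz <- 1 / mean(dt)
  colnames(forces_n) <- FINGERS
  structure(
    list(time_s = time_s, forces_n = forces_n,
         sample_rate_hz = as.numeric(sample_rate_hz), meta = meta),
    class = "force_trial")
}

#' @export
print.force_trial <- function(x, ...) {
  n <- nrow(x$forces_n)
  cat(sprintf("<force_trial> %d samples @ %.6g Hz (%.3g s)\n",
              n, x$sample_rate_hz, x$time_s[n] - x$time_s[1]))
  tot <- rowSums(x$forces_n)
  cat(sprintf("  total force: %.3g to %.3g N\n", min(tot), max(tot)))
  m <- x$meta
  if (length(m)) {
    keys <- intersect(c("subject", "group", "age_years", "hand", "paretic",
                        "task", "trial"), names(m))
    if (length(keys))
      cat("  meta:", paste(sprintf("%s=%s", keys, unlist(m[keys])),
                           collapse = ", "), "\n")
  }
  invisible(x)
}

#' Per-sample total (four-finger) force
#'
#' @param trial A [force_trial()].
#' @return Numeric vector of the per-sample sum of the four finger forces (N).
#' @export
total_force <- function(trial) {
  stopifnot(inherits(trial, "force_trial"))
  rowSums(trial$forces_n)
}

#' @export
plot.force_trial <- function(x, ...) {
  tot <- total_force(x)
  graphics::matplot(x$time_s, cbind(x$forces_n, tot), type = "l",
                    lty = c(rep(1, 4), 1), lwd = c(rep(1, 4), 2),
                    col = c("#E69F00", "#56B4E9", "#009E73", "#CC79A7", "black"),
                    xlab = "time (s)", ylab = "force (N)", ...)
  graphics::legend("topleft", bty = "n", lwd = c(rep(1, 4), 2),
                   col = c("#E69F00", "#56B4E9", "#009E73", "#CC79A7", "black"),
                   legend = c(FINGERS, "total"))
  invisible(x)
}

#' Write a trial to CSV
#'
#' Columns `time_s, f_index_n, f_middle_n, f_ring_n, f_little_n` with a header
#' row; metadata is stored in leading `#`-comment lines so that a written file
#' round-trips through [read_trial_csv()].
#'
#' @param trial A [force_trial()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trial_csv <- function(trial, path) {
  stopifnot(inherits(trial, "force_trial"))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  m <- trial$meta
  for (k in names(m))
    writeLines(sprintf("# %s: %s", k, as.character(m[[k]])), con)
  writeLines(sprintf("# sample_rate_hz: %.10g", trial$sample_rate_hz), con)
  df <- data.frame(time_s = trial$time_s,
                   f_index_n = trial$forces_n[, 1],
                   f_middle_n = trial$forces_n[, 2],
                   f_ring_n = trial$forces_n[, 3],
                   f_little_n = trial$forces_n[, 4])
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read a trial from CSV
#'
#' @param path Path to a CSV written by [write_trial_csv()] (or any CSV with
#'   columns `time_s, f_index_n, f_middle_n, f_ring_n, f_little_n`).
#' @return A [force_trial()].
#' @export
read_trial_csv <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  hdr <- grep("^#", lines, value = TRUE)
  meta <- list()
  srate <- NULL
  for (h in hdr) {
    kv <- sub("^#\\s*", "", h)
    key <- sub(":.*$", "", kv)
    val <- trimws(sub("^[^:]*:", "", kv))
    if (key == "sample_rate_hz") srate <- as.numeric(val)
    else meta[[key]] <- utils::type.convert(val, as.is = TRUE)
  }
  df <- utils::read.csv(text = lines[!grepl("^#", lines)])
  need <- c("time_s", "f_index_n", "f_middle_n", "f_ring_n", "f_little_n")
  if (!all(need %in% names(df)))
    stop("malformed trial CSV ", path, ": missing column(s) ",
         paste(setdiff(need, names(df)), collapse = ", "))
  if (anyNA(df[need]))
    stop("malformed trial CSV ", path, ": NA/NaN force values",
         if (!is.null(meta$trial)) paste0(" (trial ", meta$trial, ")") else "")
  force_trial(df$time_s, as.matrix(df[, need[-1]]),
              sample_rate_hz = srate, meta = meta)
}
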