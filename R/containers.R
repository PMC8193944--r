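#' Sampled membrane-current trace
#'
#' Container for a voltage-clamp current recording. Synaptic events are
#' stored as positive magnitudes regardless of recorded polarity; inward
#' currents are sign-flipped at ingest (see [read_trace_csv()]).
#'
#' @param samples Numeric vector of current samples (pA).
#' @param sample_rate_hz Sampling rate (Hz).
#' @param holding_potential_mv Holding potential metadata (mV).
#' @param cell_id Identifier.
#' @return An object of class \code{current_trace}.
#' @export
current_trace <- function(samples, sample_rate_hz,
                          holding_potential_mv = -60, cell_id = "cell") {
  chk_num(sample_rate_hz, "sample_rate_hz", positive = TRUE)
  if (!is.numeric(samples) || length(samples) == 0 || any(!is.finite(samples)))
    stop_invalid("'samples' must be a non-empty finite numeric vector")
  structure(list(samples = as.numeric(samples),
                 sample_rate_hz = sample_rate_hz,
                 holding_potential_mv = holding_potential_mv,
                 cell_id = cell_id),
            class = "current_trace")
}

#' @export
print.current_trace <- function(x, ...) {
  cat(sprintf("<current_trace> %s: %d samples @ %g Hz (%.3f s), Vh = %g mV\n",
              x$cell_id, length(x$samples), x$sample_rate_hz,
              length(x$samples) / x$sample_rate_hz, x$holding_potential_mv))
  invisible(x)
}

#' @export
plot.current_trace <- function(x, ...) {
  t <- (seq_along(x$samples) - 1) / x$sample_rate_hz
  graphics::plot(t, x$samples, type = "l", xlab = "time (s)",
                 ylab = "current (pA)", main = x$cell_id, ...)
  invisible(x)
}

#' Duration of a trace in seconds
#' @param x A \code{current_trace}.
#' @export
trace_duration <- function(x) length(x$samples) / x$sample_rate_hz

#' Train of synaptic events
#'
#' @param times_s Event times (s), strictly increasing, within
#'   \code{[0, duration_s]}.
#' @param amplitudes_pa Event peak amplitudes (pA, positive).
#' @param duration_s Observation duration (s).
#' @param cell_id Identifier.
#' @return An object of class \code{event_train}.
#' @export
event_train <- function(times_s, amplitudes_pa, duration_s, cell_id = "cell") {
  chk_num(duration_s, "duration_s", positive = TRUE)
  if (length(times_s) != length(amplitudes_pa))
    stop_invalid("'times_s' and 'amplitudes_pa' must have equal length")
  if (length(times_s)) {
    if (is.unsorted(times_s, strictly = TRUE))
      stop_invalid("event times must be strictly increasing")
    if (any(times_s < 0) || any(times_s > duration_s))
      stop_invalid("event times must lie in [0, duration_s]")
    if (any(amplitudes_pa <= 0))
      stop_invalid("event amplitudes must be positive")
  }
  structure(list(times_s = as.numeric(times_s),
                 amplitudes_pa = as.numeric(amplitudes_pa),
                 duration_s = duration_s, cell_id = cell_id),
            class = "event_train")
}

#' @export
print.event_train <- function(x, ...) {
  cat(sprintf("<event_train> %s: %d events over %.3f s (%.3g Hz)\n",
              x$cell_id, length(x$times_s), x$duration_s,
              length(x$times_s) / x$duration_s))
  invisible(x)
}

#' Set of evoked (stimulus-locked) trials
#'
#' Per-stimulus response amplitudes with failure flags. \code{n_stim} (N) is
#' the number of trials, \code{n_failures} (N0) the number flagged as
#' failures; these drive the method-of-failures estimate of quantal content.
#'
#' @param amplitudes_pa Per-trial response amplitude (pA).
#' @param stim_times_s Stimulus times (s); defaults to 15-s intervals.
#' @param failure_flags Logical vector (may be NA before classification).
#' @param true_k Optional ground-truth quanta count per trial (from the
#'   generator).
#' @param cell_id Identifier.
#' @return An object of class \code{evoked_trials}.
#' @export
evoked_trials <- function(amplitudes_pa, stim_times_s = NULL,
                          failure_flags = NULL, true_k = NULL,
                          cell_id = "cell") {
  n <- length(amplitudes_pa)
  if (n < 1) stop_invalid("at least one trial required")
  if (is.null(stim_times_s)) stim_times_s <- (seq_len(n) - 1) * 15
  if (is.null(failure_flags)) failure_flags <- rep(NA, n)
  if (length(stim_times_s) != n || length(failure_flags) != n)
    stop_invalid("per-trial fields must have equal length")
  if (!is.null(true_k) && length(true_k) != n)
    stop_invalid("'true_k' must have one entry per trial")
  structure(list(amplitudes_pa = as.numeric(amplitudes_pa),
                 stim_times_s = as.numeric(stim_times_s),
                 failure_flags = as.logical(failure_flags),
                 true_k = true_k, cell_id = cell_id),
            class = "evoked_trials")
}

#' Number of trials and of failures
#' @param trials An \code{evoked_trials} object with failure flags set.
#' @return Named integer vector \code{c(n_stim, n_failures)}.
#' @export
trial_counts <- function(trials) {
  stopifnot(inherits(trials, "evoked_trials"))
  flags <- trials$failure_flags
  if (anyNA(flags))
    stop_invalid("failure flags not set; run classify_failures() first")
  c(n_stim = length(flags), n_failures = sum(flags))
}

#' @export
print.evoked_trials <- function(x, ...) {
  nf <- if (anyNA(x$failure_flags)) "unclassified" else
    sprintf("%d failures", sum(x$failure_flags))
  cat(sprintf("<evoked_trials> %s: %d trials, %s\n",
              x$cell_id, length(x$amplitudes_pa), nf))
  invisible(x)
}

#' Fura-2 ratio trace
#'
#' @param time_s Sample times (s).
#' @param ratio 340/380 fluorescence ratio samples.
#' @param calib A [calibration_constants()] object.
#' @param cell_id Identifier.
#' @return An object of class \code{fura_trace}.
#' @export
fura_trace <- function(time_s, ratio, calib = calibration_constants(),
                       cell_id = "cell") {
  if (length(time_s) != length(ratio) || length(ratio) == 0)
    stop_invalid("'time_s' and 'ratio' must be non-empty and equal length")
  stopifnot(inherits(calib, "calibration_constants"))
  structure(list(time_s = as.numeric(time_s), ratio = as.numeric(ratio),
                 calib = calib, cell_id = cell_id),
            class = "fura_trace")
}

#' @export
print.fura_trace <- function(x, ...) {
  cat(sprintf("<fura_trace> %s: %d samples over %.1f s, ratio range [%.3f, %.3f]\n",
              x$cell_id, length(x$ratio), max(x$time_s) - min(x$time_s),
              min(x$ratio), max(x$ratio)))
  invisible(x)
}

#' Wheel-running actogram
#'
#' Day-by-bin matrix of wheel revolutions together with the light schedule.
#' Bins are left-closed \code{[t, t + bin_min)} minutes from midnight and
#' days are 0-based in analyses.
#'
#' @param counts Integer matrix, one row per day, \code{1440 / bin_min}
#'   columns.
#' @param bin_min Bin width (minutes).
#' @param lights_on_min,lights_off_min Light schedule (minutes from midnight).
#' @param animal_id,genotype_label,age_label Metadata.
#' @return An object of class \code{actogram}.
#' @export
actogram <- function(counts, bin_min = 10, lights_on_min = 360,
                     lights_off_min = 1080, animal_id = "animal",
                     genotype_label = "", age_label = "") {
  counts <- as.matrix(counts)
  if (1440 %% bin_min != 0) stop_invalid("'bin_min' must divide 1440")
  if (ncol(counts) != 1440 / bin_min)
    stop_invalid("'counts' must have 1440/bin_min columns, got ", ncol(counts))
  if (any(counts < 0) || any(counts != round(counts)))
    stop_invalid("'counts' must be non-negative integers")
  structure(list(counts = counts, bin_min = bin_min,
                 lights_on_min = lights_on_min,
                 lights_off_min = lights_off_min, animal_id = animal_id,
                 genotype_label = genotype_label, age_label = age_label),
            class = "actogram")
}

#' @export
print.actogram <- function(x, ...) {
  cat(sprintf(
    "<actogram> %s%s: %d days x %d bins (%g min), LD lights on %02d:%02d off %02d:%02d\n",
    x$animal_id,
    if (nzchar(x$genotype_label)) paste0(" (", x$age_label, " ", x$genotype_label, ")") else "",
    nrow(x$counts), ncol(x$counts), x$bin_min,
    x$lights_on_min %/% 60, x$lights_on_min %% 60,
    x$lights_off_min %/% 60, x$lights_off_min %% 60))
  cat(sprintf("  mean daily revolutions: %.0f\n", mean(rowSums(x$counts))))
  invisible(x)
}
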