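#' Detect spontaneous synaptic events in a current trace
#'
#' Threshold detector for positive-going synaptic events: the trace is
#' smoothed with a ~1-ms boxcar, a candidate onset is a crossing of the
#' rising-slope threshold, the peak is located within a short post-onset
#' window, and the event is accepted when peak minus the median of the
#' preceding baseline window exceeds the amplitude threshold. Accepted events
#' are separated by at least the refractory interval.
#'
#' The detector is deliberately simple; its contract is recall/precision
#' against simulated ground truth, not algorithmic identity with any
#' particular acquisition software.
#'
#' @param trace A [current_trace()]; events positive-going.
#' @param params A [detection_params()] object.
#' @return An [event_train()]; times are onset (slope-crossing) times.
#' @examples
#' sim <- simulate_spontaneous(spontaneous_params(duration_s = 10, seed = 1))
#' ev <- detect_events(sim$trace)
#' @export
detect_events <- function(trace, params = detection_params()) {
  stopifnot(inherits(trace, "current_trace"),
            inherits(params, "detection_params"))
  fs <- trace$sample_rate_hz
  x <- trace$samples
  n <- length(x)
  bl_n <- max(2L, round(params$baseline_window_ms / 1000 * fs))
  if (n <= bl_n)
    stop_invalid("trace shorter than the baseline window")
  k <- max(1L, round(0.001 * fs))                  # ~1 ms smoothing
  s <- as.numeric(stats::filter(x, rep(1 / k, k), sides = 2))
  s[is.na(s)] <- x[is.na(s)]
  d <- max(1L, round(0.0005 * fs))                 # slope span ~0.5 ms
  slope <- c((s[(1 + d):n] - s[1:(n - d)]) / (d / fs * 1000), rep(0, d))
  cand <- slope >= params$deriv_threshold_pa_per_ms
  onsets <- which(cand & !c(FALSE, cand[-n]))      # rising edges of runs
  refr_n <- round(params$refractory_ms / 1000 * fs)
  peak_n <- max(refr_n, round(0.010 * fs))         # peak search window
  times <- amps <- numeric(0)
  last_peak <- -Inf  # refractory runs from the accepted peak, so a noise
                     # crossing shortly before an onset cannot double-count it
  for (i in onsets) {
    if (i - last_peak < refr_n) next
    win <- i:min(i + peak_n, n)
    peak <- max(s[win])
    b0 <- max(1L, i - bl_n)
    baseline <- stats::median(s[b0:i])
    a <- peak - baseline
    if (a >= params$amp_threshold_pa) {
      times <- c(times, (i - 1) / fs)
      amps <- c(amps, a)
      last_peak <- i + which.max(s[win]) - 1L
    }
  }
  event_train(times, amps, duration_s = n / fs, cell_id = trace$cell_id)
}

#' Frequency and amplitude statistics of an event train
#'
#' @param train An [event_train()].
#' @return A list with \code{frequency_hz} (count/duration),
#'   \code{mean_amp_pa}, \code{sem_amp_pa}, \code{n_events}, and
#'   \code{amplitude_defined} (FALSE for an empty train, whose amplitude
#'   summaries are NA).
#' @examples
#' ev <- event_train(c(1, 2, 3), c(40, 50, 60), duration_s = 60)
#' event_statistics(ev)  # 0.05 Hz, 50 +/- 5.77 pA
#' @export
event_statistics <- function(train) {
  stopifnot(inherits(train, "event_train"))
  if (train$duration_s <= 0) stop_invalid("duration must be positive")
  n <- length(train$times_s)
  if (n == 0)
    return(list(frequency_hz = 0, mean_amp_pa = NA_real_,
                sem_amp_pa = NA_real_, n_events = 0L,
                amplitude_defined = FALSE))
  a <- train$amplitudes_pa
  list(frequency_hz = n / train$duration_s,
       mean_amp_pa = mean(a),
       sem_amp_pa = if (n > 1) stats::sd(a) / sqrt(n) else NA_real_,
       n_events = n, amplitude_defined = TRUE)
}

#' Empirical CDF of inter-event intervals
#'
#' Successive differences of the event times with cumulative probabilities
#' k/n, as used for cumulative-probability plots of inter-event intervals.
#'
#' @param train An [event_train()] with at least two events.
#' @return An object of class \code{iei_cdf}: a list with sorted
#'   \code{interval_s}, \code{cum_prob} (k/n), and \code{fun}, the
#'   [stats::ecdf()] step function.
#' @export
iei_cdf <- function(train) {
  stopifnot(inherits(train, "event_train"))
  if (length(train$times_s) < 2)
    stop_invalid("at least two events required for inter-event intervals")
  iei <- diff(train$times_s)
  s <- sort(iei)
  structure(list(interval_s = s,
                 cum_prob = seq_along(s) / length(s),
                 fun = stats::ecdf(iei)),
            class = "iei_cdf")
}

#' @export
print.iei_cdf <- function(x, ...) {
  cat(sprintf("<iei_cdf> %d intervals, median %.3g s\n",
              length(x$interval_s), stats::median(x$interval_s)))
  invisible(x)
}

#' @export
plot.iei_cdf <- function(x, ...) {
  graphics::plot(x$interval_s, x$cum_prob, type = "s",
                 xlab = "inter-event interval (s)",
                 ylab = "cumulative probability", ylim = c(0, 1), ...)
  invisible(x)
}

#' Normalized fold change across paired cells
#'
#' Per-cell ratio drug/control averaged across cells (mean of ratios, not
#' ratio of means), matching a paired design in which each cell is its own
#' control. Cells with a zero control value are excluded with a warning.
#'
#' @param pairs A data frame with columns \code{control_value} and
#'   \code{drug_value} (one row per cell); a \code{cell_id} column is carried
#'   through if present.
#' @return A list with \code{mean_ratio}, \code{sem_ratio}, \code{n}, and the
#'   per-cell \code{ratios}.
#' @examples
#' normalized_fold_change(data.frame(control_value = c(2, 4),
#'                                   drug_value = c(1, 1)))
#' @export
normalized_fold_change <- function(pairs) {
  if (!is.data.frame(pairs) ||
      !all(c("control_value", "drug_value") %in% names(pairs)))
    stop_invalid("'pairs' needs columns control_value and drug_value")
  if (anyNA(pairs$control_value) || anyNA(pairs$drug_value))
    stop_invalid("paired design requires both values for every cell")
  zero <- pairs$control_value == 0
  if (any(zero)) {
    warning(sum(zero), " cell(s) with zero control value excluded")
    pairs <- pairs[!zero, , drop = FALSE]
  }
  if (nrow(pairs) == 0) stop_invalid("no usable pairs")
  r <- pairs$drug_value / pairs$control_value
  list(mean_ratio = mean(r),
       sem_ratio = if (length(r) > 1) stats::sd(r) / sqrt(length(r)) else NA_real_,
       n = length(r), ratios = r)
}
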