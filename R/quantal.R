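#' Peak evoked-response amplitude within a fixed window
#'
#' Measures the evoked response as the peak baseline-subtracted current over
#' \code{window_ms} from the time the response begins. Response onset is the
#' first post-stimulus crossing of \code{onset_threshold_pa} above the
#' pre-stimulus baseline median, searched over at most \code{latency_ms};
#' if no crossing occurs the trial measures 0 pA.
#'
#' @param trace A [current_trace()] (events positive-going).
#' @param stim_time_s Stimulus time (s), inside the trace.
#' @param window_ms Measurement window from response onset (ms).
#' @param latency_ms Maximum onset latency searched after the stimulus (ms).
#' @param onset_threshold_pa Onset threshold above baseline (pA); by default
#'   3 times a robust noise estimate (MAD) of the pre-stimulus baseline.
#' @param baseline_ms Pre-stimulus window defining the baseline median (ms).
#' @return Peak amplitude (pA, baseline-subtracted), 0 if no onset found.
#' @export
measure_evoked_amplitude <- function(trace, stim_time_s, window_ms = 20,
                                     latency_ms = 20,
                                     onset_threshold_pa = NULL,
                                     baseline_ms = 20) {
  stopifnot(inherits(trace, "current_trace"))
  fs <- trace$sample_rate_hz
  n <- length(trace$samples)
  i_stim <- floor(stim_time_s * fs) + 1
  if (stim_time_s < 0 || i_stim > n)
    stop_invalid("stimulus time outside the trace")
  b0 <- max(1L, i_stim - round(baseline_ms / 1000 * fs))
  base_win <- trace$samples[b0:i_stim]
  baseline <- stats::median(base_win)
  if (is.null(onset_threshold_pa)) {
    noise <- stats::mad(base_win)
    onset_threshold_pa <- max(3 * noise, .Machine$double.eps)
  }
  i_lat <- min(n, i_stim + round(latency_ms / 1000 * fs))
  rel <- trace$samples[i_stim:i_lat] - baseline
  cross <- which(rel >= onset_threshold_pa)
  if (!length(cross)) return(0)
  i_on <- i_stim + cross[1] - 1
  i_end <- min(n, i_on + round(window_ms / 1000 * fs))
  max(trace$samples[i_on:i_end] - baseline)
}

#' Classify evoked trials into failures and responses
#'
#' A trial is flagged as a failure when its measured amplitude is below
#' \code{k} times the measurement noise SD; N and N0 are recomputed from the
#' flags. With k = 3 the per-trial false-failure rate for a true response of
#' at least one quantum is kept negligible while pure-noise trials are
#' flagged with probability ~99.9%.
#'
#' @param trials An [evoked_trials()] object (raw amplitudes).
#' @param noise_sd_pa Measurement noise SD (pA), > 0.
#' @param k Failure criterion in noise SDs (default 3).
#' @return The trial set with \code{failure_flags} set; see [trial_counts()].
#' @examples
#' tr <- evoked_trials(c(0, 0, 50, 60))
#' trial_counts(classify_failures(tr, noise_sd_pa = 2))  # N = 4, N0 = 2
#' @export
classify_failures <- function(trials, noise_sd_pa, k = 3) {
  stopifnot(inherits(trials, "evoked_trials"))
  chk_num(noise_sd_pa, "noise_sd_pa", positive = TRUE)
  chk_num(k, "k", positive = TRUE)
  trials$failure_flags <- trials$amplitudes_pa < k * noise_sd_pa
  trials
}

#' Quantal content by the method of failures
#'
#' Under the Poisson release model the probability that a stimulus releases
#' no quanta is \eqn{e^{-m}}, so the quantal content is estimated from the
#' observed failure fraction as \eqn{\hat m = \ln(N/N_0)}, where N is the
#' total number of stimuli and N0 the number of failures. The standard error
#' follows by the delta method: \eqn{\sqrt{(N - N_0)/(N N_0)}}.
#'
#' When no failures are observed the estimate is undefined; the result then
#' carries status \code{"no-failures"} with \code{m = NA} and the lower bound
#' \eqn{\ln N} instead of a silent number.
#'
#' @param n_stim Total number of stimuli N (or an [evoked_trials()] object
#'   with failure flags set, in which case \code{n_failures} is ignored).
#' @param n_failures Number of failures N0.
#' @return An object of class \code{quantal_estimate} with fields \code{m},
#'   \code{se_m}, \code{n_stim}, \code{n_failures}, \code{status}
#'   (\code{"ok"} or \code{"no-failures"}) and, for the no-failure case,
#'   \code{m_lower}.
#' @examples
#' quantal_content(100, 37)   # m = ln(100/37) = 0.994
#' quantal_content(100, 8)    # m = 2.526
#' @export
quantal_content <- function(n_stim, n_failures) {
  if (inherits(n_stim, "evoked_trials")) {
    cnt <- trial_counts(n_stim)
    n_failures <- cnt[["n_failures"]]
    n_stim <- cnt[["n_stim"]]
  }
  chk_num(n_stim, "n_stim", positive = TRUE)
  chk_num(n_failures, "n_failures", nonneg = TRUE)
  if (n_failures > n_stim) stop_invalid("n_failures cannot exceed n_stim")
  if (n_failures == 0) {
    out <- list(m = NA_real_, se_m = NA_real_, m_lower = log(n_stim),
                n_stim = n_stim, n_failures = 0, status = "no-failures")
  } else {
    out <- list(m = log(n_stim / n_failures),
                se_m = sqrt((n_stim - n_failures) / (n_stim * n_failures)),
                n_stim = n_stim, n_failures = n_failures, status = "ok")
  }
  structure(out, class = "quantal_estimate")
}

#' @export
print.quantal_estimate <- function(x, ...) {
  if (x$status == "no-failures") {
    cat(sprintf(
      "<quantal_estimate> no failures in %d stimuli: m undefined (m > %.3f)\n",
      x$n_stim, x$m_lower))
  } else {
    cat(sprintf("<quantal_estimate> m = %.3f (SE %.3f), N = %d, N0 = %d\n",
                x$m, x$se_m, as.integer(x$n_stim), as.integer(x$n_failures)))
  }
  invisible(x)
}

#' @export
coef.quantal_estimate <- function(object, ...) c(m = object$m)

#' Mean evoked amplitude excluding failures
#'
#' Mean and SEM of the response amplitude over non-failure trials only, the
#' convention used when averaging evoked currents.
#'
#' @param trials An [evoked_trials()] object with failure flags set.
#' @return A list with \code{mean_pa}, \code{sem_pa}, \code{n_responses}, and
#'   \code{defined} (FALSE when every trial is a failure).
#' @export
mean_amplitude_excluding_failures <- function(trials) {
  stopifnot(inherits(trials, "evoked_trials"))
  if (anyNA(trials$failure_flags))
    stop_invalid("failure flags not set; run classify_failures() first")
  a <- trials$amplitudes_pa[!trials$failure_flags]
  if (!length(a))
    return(list(mean_pa = NA_real_, sem_pa = NA_real_, n_responses = 0L,
                defined = FALSE))
  list(mean_pa = mean(a),
       sem_pa = if (length(a) > 1) stats::sd(a) / sqrt(length(a)) else NA_real_,
       n_responses = length(a), defined = TRUE)
}

#' Monte-Carlo calibration of the failures estimator
#'
#' For each true quantal content in \code{m_grid}, simulates \code{reps}
#' evoked trial sets of \code{n_stim} stimuli, runs the full
#' simulate -> classify -> estimate chain, and reports bias, RMSE and the
#' frequency of no-failure outcomes (for which the estimate is undefined and
#' excluded from bias/RMSE).
#'
#' @param m_grid True quantal contents (> 0).
#' @param n_stim Stimuli per simulated set.
#' @param reps Replicates per grid point.
#' @param seed Integer seed.
#' @param q_pa,q_cv,noise_sd_pa Quantal size and noise settings passed to the
#'   generator.
#' @return A data frame with columns \code{m_true}, \code{bias}, \code{rmse},
#'   \code{p_no_failure}, \code{reps_used}.
#' @export
estimator_calibration <- function(m_grid, n_stim = 100, reps = 500, seed = 1L,
                                  q_pa = 50, q_cv = 0.3, noise_sd_pa = 3) {
  chk_num(m_grid, "m_grid", positive = TRUE, len = length(m_grid))
  set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max, length(m_grid) * reps)
  dim(sub_seeds) <- c(length(m_grid), reps)
  res <- lapply(seq_along(m_grid), function(gi) {
    m <- m_grid[gi]
    est <- vapply(seq_len(reps), function(r) {
      p <- quantal_params(m_true = m, q_pa = q_pa, q_cv = q_cv,
                          n_stim = n_stim, noise_sd_pa = noise_sd_pa,
                          seed = sub_seeds[gi, r])
      tr <- classify_failures(simulate_evoked(p), noise_sd_pa = noise_sd_pa)
      quantal_content(tr)$m
    }, numeric(1))
    ok <- !is.na(est)
    data.frame(m_true = m,
               bias = mean(est[ok]) - m,
               rmse = sqrt(mean((est[ok] - m)^2)),
               p_no_failure = mean(!ok),
               reps_used = sum(ok))
  })
  do.call(rbind, res)
}
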