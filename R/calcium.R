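#' Convert a fura-2 ratio to free-calcium concentration
#'
#' Standard ratiometric equation
#' \deqn{[Ca^{2+}] = K_d \, \beta \, (R - R_{min}) / (R_{max} - R),}
#' strictly increasing in R on \eqn{(R_{min}, R_{max})}.
#'
#' @param ratio 340/380 ratio values.
#' @param calib A [calibration_constants()] object.
#' @param clip If TRUE, ratios outside \eqn{[R_{min}, R_{max}]} are clamped
#'   to the boundary (giving 0 or Inf) with a warning instead of an error.
#' @return Concentrations (nM).
#' @examples
#' cal <- calibration_constants()
#' ratio_to_concentration(cal$r_min, cal)  # 0 nM
#' @export
ratio_to_concentration <- function(ratio, calib = calibration_constants(),
                                   clip = FALSE) {
  stopifnot(inherits(calib, "calibration_constants"))
  out_of_range <- ratio < calib$r_min | ratio > calib$r_max
  if (any(out_of_range)) {
    if (!clip)
      stop_invalid("ratio outside [r_min, r_max]; use clip = TRUE to clamp")
    warning(sum(out_of_range), " ratio value(s) clamped to [r_min, r_max]")
    ratio <- pmin(pmax(ratio, calib$r_min), calib$r_max)
  }
  calib$kd_nm * calib$beta * (ratio - calib$r_min) / (calib$r_max - ratio)
}

#' Convert free-calcium concentration to a fura-2 ratio
#'
#' Inverse of [ratio_to_concentration()]; finite concentrations always map
#' strictly below \eqn{R_{max}}.
#'
#' @param conc_nm Concentrations (nM, non-negative).
#' @param calib A [calibration_constants()] object.
#' @return Ratio values.
#' @export
concentration_to_ratio <- function(conc_nm, calib = calibration_constants()) {
  stopifnot(inherits(calib, "calibration_constants"))
  if (any(conc_nm < 0)) stop_invalid("concentration must be non-negative")
  u <- conc_nm / (calib$kd_nm * calib$beta)
  (calib$r_min + calib$r_max * u) / (1 + u)
}

#' Per-stimulus calcium-transient amplitudes
#'
#' For each stimulus, the transient amplitude is the peak concentration in a
#' post-stimulus search window minus the median concentration of a
#' pre-stimulus baseline window. Search windows are truncated at the next
#' stimulus (with a warning) so overlapping transients are not double
#' counted.
#'
#' @param trace A [fura_trace()].
#' @param stim_times_s Stimulus times (s), inside the trace.
#' @param search_s Post-stimulus peak-search window (s).
#' @param baseline_s Pre-stimulus baseline window (s).
#' @param clip Passed to [ratio_to_concentration()].
#' @return Numeric vector of transient amplitudes (nM), one per stimulus.
#' @export
transient_amplitudes <- function(trace, stim_times_s, search_s = 5,
                                 baseline_s = 5, clip = FALSE) {
  stopifnot(inherits(trace, "fura_trace"))
  t <- trace$time_s
  if (any(stim_times_s < min(t)) || any(stim_times_s > max(t)))
    stop_invalid("stimulus outside the trace")
  stim <- sort(stim_times_s)
  conc <- ratio_to_concentration(trace$ratio, trace$calib, clip = clip)
  if (length(stim) > 1 && any(diff(stim) < search_s))
    warning("peak-search windows overlap the next stimulus; truncated")
  vapply(seq_along(stim), function(i) {
    s <- stim[i]
    end <- min(s + search_s,
               if (i < length(stim)) stim[i + 1] else Inf)
    base <- conc[t >= s - baseline_s & t < s]
    if (!length(base)) stop_invalid("no baseline samples before stimulus")
    peak <- conc[t >= s & t <= end]
    max(peak) - stats::median(base)
  }, numeric(1))
}

#' Summarize drug inhibition of calcium transients
#'
#' Means and SEMs of control and drug transient amplitudes, percent
#' inhibition of the means, and (for a paired design with n >= 2) a paired
#' t-test on the per-cell amplitudes.
#'
#' @param control_deltas,drug_deltas Transient amplitudes (nM) per cell or
#'   per trial; equal length when \code{paired = TRUE}.
#' @param paired Paired design (default TRUE).
#' @return An object of class \code{inhibition_summary}: means, SEMs, n,
#'   \code{pct_inhibition}, and \code{t_test} (a [paired_t()] result or NULL).
#' @examples
#' inhibition_summary(c(238, 250), c(65, 66))
#' @export
inhibition_summary <- function(control_deltas, drug_deltas, paired = TRUE) {
  if (paired && length(control_deltas) != length(drug_deltas))
    stop_invalid("paired design requires equal-length amplitude lists")
  mc <- mean(control_deltas); md <- mean(drug_deltas)
  sem <- function(x) if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else NA_real_
  tt <- if (paired && length(control_deltas) >= 2)
    paired_t(control_deltas, drug_deltas) else NULL
  structure(list(mean_control = mc, sem_control = sem(control_deltas),
                 mean_drug = md, sem_drug = sem(drug_deltas),
                 n_control = length(control_deltas),
                 n_drug = length(drug_deltas),
                 pct_inhibition = percent_inhibition(mc, md),
                 paired = paired, t_test = tt),
            class = "inhibition_summary")
}

#' @export
print.inhibition_summary <- function(x, ...) {
  cat(sprintf("control: %.4g +/- %.3g nM (n = %d)\n",
              x$mean_control, x$sem_control, x$n_control))
  cat(sprintf("drug:    %.4g +/- %.3g nM (n = %d)\n",
              x$mean_drug, x$sem_drug, x$n_drug))
  cat(sprintf("inhibition of means: %.1f%%\n", x$pct_inhibition))
  if (!is.null(x$t_test))
    cat(sprintf("paired t(%d) = %.3g, p = %.3g\n",
                x$t_test$df, x$t_test$t, x$t_test$p))
  invisible(x)
}
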