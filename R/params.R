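#' @keywords internal
stop_invalid <- function(...) {
  stop(structure(class = c("synphys_invalid_parameter", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

chk_num <- function(x, name, positive = FALSE, nonneg = FALSE, len = 1L) {
  if (!is.numeric(x) || length(x) != len || anyNA(x) || any(!is.finite(x)))
    stop_invalid("'", name, "' must be a finite numeric of length ", len)
  if (positive && any(x <= 0)) stop_invalid("'", name, "' must be > 0")
  if (nonneg && any(x < 0)) stop_invalid("'", name, "' must be >= 0")
  x
}

#' Parameters for simulating spontaneous synaptic current traces
#'
#' Defines a homogeneous Poisson train of inhibitory postsynaptic currents
#' (IPSCs) riding on Gaussian recording noise. Amplitudes are lognormal;
#' each event contributes a difference-of-exponentials waveform normalized
#' to unit peak, so the amplitude parameter is the peak current in pA.
#'
#' @param rate_hz Mean event rate (events/s) of the Poisson process.
#' @param amp_mean_pa Mean event peak amplitude (pA, stored positive).
#' @param amp_cv Coefficient of variation of amplitudes (must be < 1).
#' @param tau_rise_ms,tau_decay_ms Rise and decay time constants (ms);
#'   decay must exceed rise.
#' @param noise_sd_pa Standard deviation of additive Gaussian noise (pA).
#' @param duration_s Trace duration (s).
#' @param sample_rate_hz Sampling rate (Hz).
#' @param seed Integer seed; all randomness in the simulation flows from it.
#' @return An object of class \code{spontaneous_params}.
#' @seealso [simulate_spontaneous()]
#' @export
spontaneous_params <- function(rate_hz = 1.05, amp_mean_pa = 50, amp_cv = 0.3,
                               tau_rise_ms = 1, tau_decay_ms = 25,
                               noise_sd_pa = 3, duration_s = 60,
                               sample_rate_hz = 10000, seed = 1L) {
  chk_num(rate_hz, "rate_hz", nonneg = TRUE)
  chk_num(amp_mean_pa, "amp_mean_pa", positive = TRUE)
  chk_num(amp_cv, "amp_cv", positive = TRUE)
  if (amp_cv >= 1) stop_invalid("'amp_cv' must be < 1")
  chk_num(tau_rise_ms, "tau_rise_ms", positive = TRUE)
  chk_num(tau_decay_ms, "tau_decay_ms", positive = TRUE)
  if (tau_decay_ms <= tau_rise_ms)
    stop_invalid("'tau_decay_ms' must exceed 'tau_rise_ms'")
  chk_num(noise_sd_pa, "noise_sd_pa", nonneg = TRUE)
  chk_num(duration_s, "duration_s", positive = TRUE)
  chk_num(sample_rate_hz, "sample_rate_hz", positive = TRUE)
  structure(list(rate_hz = rate_hz, amp_mean_pa = amp_mean_pa, amp_cv = amp_cv,
                 tau_rise_ms = tau_rise_ms, tau_decay_ms = tau_decay_ms,
                 noise_sd_pa = noise_sd_pa, duration_s = duration_s,
                 sample_rate_hz = sample_rate_hz, seed = as.integer(seed)),
            class = "spontaneous_params")
}

#' Parameters for simulating evoked (stimulus-locked) trial sets
#'
#' Each stimulus releases k ~ Poisson(m) quanta; the response amplitude is the
#' sum of k quantal sizes drawn from a normal distribution truncated at zero,
#' plus Gaussian measurement noise.
#'
#' @param m_true Mean quantal content (quanta per stimulus).
#' @param q_pa Mean quantal size (pA).
#' @param q_cv Coefficient of variation of the quantal size.
#' @param n_stim Number of stimuli (trials).
#' @param noise_sd_pa Measurement noise SD (pA).
#' @param seed Integer seed.
#' @return An object of class \code{quantal_params}.
#' @seealso [simulate_evoked()], [quantal_content()]
#' @export
quantal_params <- function(m_true = 2.46, q_pa = 50, q_cv = 0.3,
                           n_stim = 75, noise_sd_pa = 3, seed = 1L) {
  chk_num(m_true, "m_true", nonneg = TRUE)
  chk_num(q_pa, "q_pa", positive = TRUE)
  chk_num(q_cv, "q_cv", nonneg = TRUE)
  chk_num(n_stim, "n_stim", positive = TRUE)
  if (n_stim < 1 || n_stim != round(n_stim))
    stop_invalid("'n_stim' must be a positive integer")
  chk_num(noise_sd_pa, "noise_sd_pa", nonneg = TRUE)
  structure(list(m_true = m_true, q_pa = q_pa, q_cv = q_cv,
                 n_stim = as.integer(n_stim), noise_sd_pa = noise_sd_pa,
                 seed = as.integer(seed)),
            class = "quantal_params")
}

#' Parameters for simulating wheel-running actograms
#'
#' A nocturnal animal entrained to a light/dark cycle starts running once per
#' circadian day. The daily onset is \code{lights_off - psi_true_min} plus
#' Gaussian day-to-day jitter, rounded to the recording bin grid (the actogram
#' cannot represent sub-bin timing, so ground truth is exact at the data's
#' resolution). Activity then fills a contiguous block of
#' \code{active_hours}, wrapping within the circadian day, with Poisson bin
#' counts summing to \code{daily_revs} in expectation.
#'
#' @param n_days Number of recorded days.
#' @param bin_min Bin width in minutes; must divide 1440.
#' @param lights_on_min,lights_off_min Clock times of lights-on/off
#'   (minutes from midnight).
#' @param psi_true_min True phase angle of entrainment (min); positive means
#'   onset before lights-off, negative after.
#' @param onset_jitter_sd_min Day-to-day SD of the onset time (min).
#' @param daily_revs Expected total wheel revolutions per 24 h.
#' @param active_hours Length of the nightly active block (h); the default 10
#'   keeps the block inside the dark phase for onsets up to about an hour
#'   after lights-off.
#' @param seed Integer seed.
#' @return An object of class \code{actogram_params}.
#' @seealso [simulate_actogram()]
#' @export
actogram_params <- function(n_days = 30, bin_min = 10, lights_on_min = 360,
                            lights_off_min = 1080, psi_true_min = -5,
                            onset_jitter_sd_min = 20, daily_revs = 15000,
                            active_hours = 10, seed = 1L) {
  chk_num(n_days, "n_days", positive = TRUE)
  chk_num(bin_min, "bin_min", positive = TRUE)
  if (1440 %% bin_min != 0)
    stop_invalid("'bin_min' must divide 1440 minutes")
  chk_num(lights_on_min, "lights_on_min", nonneg = TRUE)
  chk_num(lights_off_min, "lights_off_min", nonneg = TRUE)
  chk_num(psi_true_min, "psi_true_min")
  chk_num(onset_jitter_sd_min, "onset_jitter_sd_min", nonneg = TRUE)
  chk_num(daily_revs, "daily_revs", nonneg = TRUE)
  chk_num(active_hours, "active_hours", positive = TRUE)
  if (active_hours >= 24) stop_invalid("'active_hours' must be < 24")
  structure(list(n_days = as.integer(n_days), bin_min = bin_min,
                 lights_on_min = lights_on_min, lights_off_min = lights_off_min,
                 psi_true_min = psi_true_min,
                 onset_jitter_sd_min = onset_jitter_sd_min,
                 daily_revs = daily_revs, active_hours = active_hours,
                 seed = as.integer(seed)),
            class = "actogram_params")
}

#' Parameters for simulating fura-2 ratio traces
#'
#' A baseline free-calcium concentration with per-stimulus transients that
#' jump by \code{delta_nm} and decay exponentially. The concentration trace is
#' mapped to a 340/380 fluorescence ratio through the ratiometric calibration
#' equation and Gaussian ratio noise is added.
#'
#' @param baseline_nm Baseline free calcium (nM).
#' @param delta_nm Transient peak amplitude above baseline (nM).
#' @param decay_s Exponential decay time constant of the transient (s).
#' @param stim_times_s Stimulus times (s), strictly within the trace.
#' @param calib A [calibration_constants()] object.
#' @param noise_sd_ratio SD of Gaussian noise added to the ratio.
#' @param duration_s Trace duration (s).
#' @param sample_rate_hz Sampling rate (Hz).
#' @param seed Integer seed.
#' @return An object of class \code{fura_sim_params}.
#' @seealso [simulate_fura()], [ratio_to_concentration()]
#' @export
fura_sim_params <- function(baseline_nm = 100, delta_nm = 238, decay_s = 3,
                            stim_times_s = c(15, 40), calib = calibration_constants(),
                            noise_sd_ratio = 0.01, duration_s = 60,
                            sample_rate_hz = 10, seed = 1L) {
  chk_num(baseline_nm, "baseline_nm", nonneg = TRUE)
  chk_num(delta_nm, "delta_nm", nonneg = TRUE)
  chk_num(decay_s, "decay_s", positive = TRUE)
  chk_num(duration_s, "duration_s", positive = TRUE)
  chk_num(sample_rate_hz, "sample_rate_hz", positive = TRUE)
  chk_num(noise_sd_ratio, "noise_sd_ratio", nonneg = TRUE)
  chk_num(stim_times_s, "stim_times_s", len = length(stim_times_s))
  if (any(stim_times_s < 0) || any(stim_times_s >= duration_s))
    stop_invalid("'stim_times_s' must lie within [0, duration_s)")
  stopifnot(inherits(calib, "calibration_constants"))
  structure(list(baseline_nm = baseline_nm, delta_nm = delta_nm,
                 decay_s = decay_s, stim_times_s = sort(stim_times_s),
                 calib = calib, noise_sd_ratio = noise_sd_ratio,
                 duration_s = duration_s, sample_rate_hz = sample_rate_hz,
                 seed = as.integer(seed)),
            class = "fura_sim_params")
}

#' Multiplicative drug-effect preset
#'
#' Encodes a drug condition as multipliers applied to generator parameters
#' before simulation: spontaneous event rate, event amplitude, quantal
#' content, and calcium-transient amplitude. The identity effect (all 1) is
#' the control condition.
#'
#' @param rate_mult,amp_mult,m_mult,delta_ca_mult Non-negative multipliers.
#' @return An object of class \code{drug_effect}.
#' @export
drug_effect <- function(rate_mult = 1, amp_mult = 1, m_mult = 1,
                        delta_ca_mult = 1) {
  for (v in c("rate_mult", "amp_mult", "m_mult", "delta_ca_mult"))
    chk_num(get(v), v, nonneg = TRUE)
  structure(list(rate_mult = rate_mult, amp_mult = amp_mult, m_mult = m_mult,
                 delta_ca_mult = delta_ca_mult),
            class = "drug_effect")
}

#' Event-detection parameters
#'
#' Tuning constants for the threshold detector in [detect_events()]. The
#' derivative threshold gates on the rising slope of the smoothed trace; the
#' amplitude threshold gates on peak minus local pre-event baseline.
#'
#' @param amp_threshold_pa Minimum accepted peak-minus-baseline amplitude (pA).
#' @param deriv_threshold_pa_per_ms Minimum rising slope (pA/ms).
#' @param refractory_ms Minimum separation between detected events (ms).
#' @param baseline_window_ms Length of the pre-event window whose median is
#'   the local baseline (ms).
#' @return An object of class \code{detection_params}.
#' @export
detection_params <- function(amp_threshold_pa = 15,
                             deriv_threshold_pa_per_ms = 8,
                             refractory_ms = 10, baseline_window_ms = 10) {
  for (v in c("amp_threshold_pa", "deriv_threshold_pa_per_ms",
              "refractory_ms", "baseline_window_ms"))
    chk_num(get(v), v, positive = TRUE)
  structure(list(amp_threshold_pa = amp_threshold_pa,
                 deriv_threshold_pa_per_ms = deriv_threshold_pa_per_ms,
                 refractory_ms = refractory_ms,
                 baseline_window_ms = baseline_window_ms),
            class = "detection_params")
}

#' Fura-2 ratiometric calibration constants
#'
#' Constants of the standard ratiometric equation
#' \deqn{[Ca^{2+}] = K_d \beta (R - R_{min}) / (R_{max} - R).}
#' The defaults are placeholders typical of in-cell fura-2 calibrations and
#' are configurable; analyses built on conversions use round-trips, never the
#' defaults' absolute truth.
#'
#' @param r_min,r_max Ratio at zero and saturating calcium (r_max > r_min > 0).
#' @param kd_nm Effective dissociation constant (nM).
#' @param beta Ratio of 380-nm fluorescence of free to bound dye.
#' @return An object of class \code{calibration_constants}.
#' @export
calibration_constants <- function(r_min = 0.3, r_max = 6, kd_nm = 224,
                                  beta = 5) {
  chk_num(r_min, "r_min", positive = TRUE)
  chk_num(r_max, "r_max", positive = TRUE)
  if (r_max <= r_min) stop_invalid("'r_max' must exceed 'r_min'")
  chk_num(kd_nm, "kd_nm", positive = TRUE)
  chk_num(beta, "beta", positive = TRUE)
  structure(list(r_min = r_min, r_max = r_max, kd_nm = kd_nm, beta = beta),
            class = "calibration_constants")
}

#' Generator presets for the study conditions
#'
#' Returns the full set of generator parameters and drug-effect multipliers
#' for one of the named experimental conditions, read from the YAML preset
#' file shipped with the package. Synaptic presets (\code{young_control},
#' \code{young_ami}, \code{aged_control}, \code{aged_ami}) carry spontaneous,
#' evoked and calcium parameters; circadian presets
#' (\code{young_wt}, \code{young_vgat}, \code{aged_wt}, \code{aged_vgat})
#' carry actogram parameters.
#'
#' @param name Preset name; see Details. With no argument, the list of
#'   available preset names is returned.
#' @param seed Integer seed inserted into every parameter object.
#' @return A list with (depending on the preset) elements
#'   \code{spontaneous}, \code{quantal}, \code{fura}, \code{effect} or
#'   \code{actogram}.
#' @export
synth_preset <- function(name, seed = 1L) {
  path <- system.file("extdata", "presets.yaml", package = "synphys")
  presets <- yaml::read_yaml(path)
  if (missing(name)) return(names(presets))
  if (!name %in% names(presets))
    stop_invalid("unknown preset '", name, "'; available: ",
                 paste(names(presets), collapse = ", "))
  p <- presets[[name]]
  out <- list()
  if (!is.null(p$spontaneous))
    out$spontaneous <- do.call(spontaneous_params, c(p$spontaneous, seed = seed))
  if (!is.null(p$quantal))
    out$quantal <- do.call(quantal_params, c(p$quantal, seed = seed))
  if (!is.null(p$fura))
    out$fura <- do.call(fura_sim_params, c(p$fura, seed = seed))
  if (!is.null(p$actogram))
    out$actogram <- do.call(actogram_params, c(p$actogram, seed = seed))
  out$effect <- if (!is.null(p$effect)) do.call(drug_effect, p$effect) else drug_effect()
  out
}
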