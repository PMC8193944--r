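#' Difference-of-exponentials synaptic current kernel
#'
#' Unit-peak waveform \eqn{k(t) = c (e^{-t/\tau_d} - e^{-t/\tau_r})} with the
#' normalizing constant chosen so the peak equals 1; an event of amplitude A
#' therefore peaks at exactly A pA, making ground-truth amplitudes directly
#' comparable to detector output.
#'
#' @param t_ms Times since event onset (ms); values < 0 give 0.
#' @param tau_rise_ms,tau_decay_ms Rise/decay time constants (ms).
#' @return Kernel values, unit peak.
#' @export
psc_kernel <- function(t_ms, tau_rise_ms, tau_decay_ms) {
  if (tau_decay_ms <= tau_rise_ms)
    stop_invalid("'tau_decay_ms' must exceed 'tau_rise_ms'")
  t_peak <- tau_rise_ms * tau_decay_ms / (tau_decay_ms - tau_rise_ms) *
    log(tau_decay_ms / tau_rise_ms)
  peak <- exp(-t_peak / tau_decay_ms) - exp(-t_peak / tau_rise_ms)
  out <- ifelse(t_ms < 0, 0,
                (exp(-t_ms / tau_decay_ms) - exp(-t_ms / tau_rise_ms)) / peak)
  out
}

# lognormal meanlog/sdlog from arithmetic mean and CV
lnorm_pars <- function(mean, cv) {
  sdlog2 <- log(1 + cv^2)
  c(meanlog = log(mean) - sdlog2 / 2, sdlog = sqrt(sdlog2))
}

#' Simulate a spontaneous synaptic current trace with ground truth
#'
#' Generates a homogeneous Poisson event train at
#' \code{rate_hz * effect$rate_mult}, gives each event a lognormal amplitude
#' with mean \code{amp_mean_pa * effect$amp_mult} and CV \code{amp_cv},
#' superimposes unit-peak difference-of-exponentials waveforms on Gaussian
#' noise, and returns both the trace and the exact event list.
#'
#' @param params A [spontaneous_params()] object.
#' @param effect A [drug_effect()] object; identity by default.
#' @param cell_id Identifier copied onto the outputs.
#' @return A list with elements \code{trace} (a [current_trace()]) and
#'   \code{truth} (an [event_train()] of exact times and amplitudes).
#' @examples
#' sim <- simulate_spontaneous(spontaneous_params(duration_s = 5, seed = 7))
#' length(sim$truth$times_s)
#' @export
simulate_spontaneous <- function(params, effect = drug_effect(),
                                 cell_id = "sim") {
  stopifnot(inherits(params, "spontaneous_params"),
            inherits(effect, "drug_effect"))
  set.seed(params$seed)
  rate <- params$rate_hz * effect$rate_mult
  amp_mean <- params$amp_mean_pa * effect$amp_mult
  n_samp <- round(params$duration_s * params$sample_rate_hz)
  n_ev <- stats::rpois(1, rate * params$duration_s)
  times <- sort(stats::runif(n_ev, 0, params$duration_s))
  if (n_ev > 1) # enforce strict ordering for the ground-truth contract
    times <- times + seq(0, by = 1e-9, length.out = n_ev)
  if (n_ev > 0 && amp_mean > 0) {
    lp <- lnorm_pars(amp_mean, params$amp_cv)
    amps <- stats::rlnorm(n_ev, lp["meanlog"], lp["sdlog"])
  } else amps <- numeric(0)
  x <- stats::rnorm(n_samp, 0, params$noise_sd_pa)
  if (n_ev > 0) {
    # kernel support: until decay to <0.1% of peak
    sup_ms <- params$tau_decay_ms * log(1000)
    sup_n <- ceiling(sup_ms / 1000 * params$sample_rate_hz)
    k_t <- (0:sup_n) / params$sample_rate_hz * 1000
    kern <- psc_kernel(k_t, params$tau_rise_ms, params$tau_decay_ms)
    for (i in seq_len(n_ev)) {
      i0 <- floor(times[i] * params$sample_rate_hz) + 1
      idx <- i0:min(i0 + sup_n, n_samp)
      x[idx] <- x[idx] + amps[i] * kern[seq_along(idx)]
    }
  }
  keep <- times < params$duration_s  # guard against runif() hitting the edge
  list(trace = current_trace(x, params$sample_rate_hz, cell_id = cell_id),
       truth = event_train(times[keep], amps[keep], params$duration_s,
                           cell_id = cell_id))
}

# truncated-at-zero normal draws (rejection; fine for cv < ~1)
rtnorm0 <- function(n, mean, sd) {
  if (n == 0) return(numeric(0))
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < 0)
  while (length(bad)) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] < 0]
  }
  x
}

#' Simulate an evoked trial set under the Poisson release model
#'
#' Per stimulus, the quanta count is \code{k ~ Poisson(m_true * effect$m_mult)};
#' the response amplitude is the sum of k quantal sizes drawn from a normal
#' distribution truncated at zero (mean \code{q_pa}, CV \code{q_cv}) plus
#' Gaussian measurement noise. A trial is a true failure iff k = 0; the
#' ground-truth counts are stored on the result.
#'
#' @param params A [quantal_params()] object.
#' @param effect A [drug_effect()] object.
#' @param cell_id Identifier.
#' @return An [evoked_trials()] object with \code{true_k} set and failure
#'   flags unclassified (use [classify_failures()]).
#' @examples
#' tr <- simulate_evoked(quantal_params(m_true = 1, n_stim = 20, seed = 2))
#' table(tr$true_k)
#' @export
simulate_evoked <- function(params, effect = drug_effect(), cell_id = "sim") {
  stopifnot(inherits(params, "quantal_params"), inherits(effect, "drug_effect"))
  set.seed(params$seed)
  m_eff <- params$m_true * effect$m_mult
  k <- stats::rpois(params$n_stim, m_eff)
  q_sd <- params$q_pa * params$q_cv
  amp_true <- vapply(k, function(ki)
    sum(rtnorm0(ki, params$q_pa, q_sd)), numeric(1))
  amp <- amp_true + stats::rnorm(params$n_stim, 0, params$noise_sd_pa)
  evoked_trials(amplitudes_pa = amp, true_k = k, cell_id = cell_id)
}

#' Simulate a wheel-running actogram with known onsets
#'
#' The daily onset is \code{lights_off_min - psi_true_min} plus Gaussian
#' jitter, rounded to the nearest bin boundary (ground truth is exact at the
#' recording resolution; see the package vignette). Activity then occupies a
#' contiguous block of \code{active_hours} starting at the onset, wrapping
#' circularly within the circadian day, with independent Poisson bin counts
#' whose expectations sum to \code{daily_revs}.
#'
#' @param params An [actogram_params()] object.
#' @param animal_id,genotype_label,age_label Metadata copied to the actogram.
#' @return A list with elements \code{actogram} (an [actogram()]) and
#'   \code{onsets_min} (numeric vector of true onset minutes-from-midnight,
#'   one per day).
#' @examples
#' sim <- simulate_actogram(actogram_params(n_days = 5, seed = 3))
#' sim$onsets_min
#' @export
simulate_actogram <- function(params, animal_id = "sim", genotype_label = "",
                              age_label = "") {
  stopifnot(inherits(params, "actogram_params"))
  set.seed(params$seed)
  nb <- 1440 / params$bin_min
  onset_raw <- params$lights_off_min - params$psi_true_min +
    stats::rnorm(params$n_days, 0, params$onset_jitter_sd_min)
  onsets <- round(onset_raw / params$bin_min) * params$bin_min
  onsets <- onsets %% 1440
  active_bins <- round(params$active_hours * 60 / params$bin_min)
  lambda <- params$daily_revs / active_bins
  counts <- matrix(0L, params$n_days, nb)
  for (d in seq_len(params$n_days)) {
    start_bin <- onsets[d] / params$bin_min       # 0-based
    idx <- (start_bin + seq_len(active_bins) - 1) %% nb + 1
    counts[d, idx] <- stats::rpois(active_bins, lambda)
  }
  list(actogram = actogram(counts, params$bin_min, params$lights_on_min,
                           params$lights_off_min, animal_id = animal_id,
                           genotype_label = genotype_label,
                           age_label = age_label),
       onsets_min = onsets)
}

#' Simulate a fura-2 ratio trace with known transient amplitudes
#'
#' Builds a free-calcium concentration trace (baseline plus per-stimulus
#' instantaneous-rise, exponential-decay transients of amplitude
#' \code{delta_nm * effect$delta_ca_mult}), converts it to a 340/380 ratio by
#' inverting the ratiometric calibration equation, and adds Gaussian ratio
#' noise.
#'
#' @param params A [fura_sim_params()] object.
#' @param effect A [drug_effect()] object.
#' @param cell_id Identifier.
#' @return A list with elements \code{trace} (a [fura_trace()]) and
#'   \code{delta_nm} (true transient amplitudes, one per stimulus).
#' @export
simulate_fura <- function(params, effect = drug_effect(), cell_id = "sim") {
  stopifnot(inherits(params, "fura_sim_params"), inherits(effect, "drug_effect"))
  set.seed(params$seed)
  t <- seq(0, params$duration_s, by = 1 / params$sample_rate_hz)
  t <- t[t < params$duration_s]
  conc <- rep(params$baseline_nm, length(t))
  delta <- rep(params$delta_nm * effect$delta_ca_mult,
               length(params$stim_times_s))
  for (i in seq_along(params$stim_times_s)) {
    s <- params$stim_times_s[i]
    after <- t >= s
    conc[after] <- conc[after] + delta[i] * exp(-(t[after] - s) / params$decay_s)
  }
  ratio <- concentration_to_ratio(conc, params$calib)
  ratio <- ratio + stats::rnorm(length(ratio), 0, params$noise_sd_ratio)
  list(trace = fura_trace(t, ratio, params$calib, cell_id = cell_id),
       delta_nm = delta)
}
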