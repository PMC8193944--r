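# Generator presets for the study conditions.
#
# Synaptic presets (young/aged x control/AMI): spontaneous IPSC rate and
# amplitude, quantal content, and calcium-transient amplitude are the
# published group means; the AMI condition is expressed as the published
# normalized fold changes applied multiplicatively. Amplitude CV, kinetics
# and noise are representative values not printed in the source tables (see
# the package vignette).
#
# Circadian presets (age x genotype): phase angle and daily revolutions are
# the published group means; the onset jitter SD is derived from the
# published mean day-to-day onset variability v via sigma = v * sqrt(pi)/2
# (for iid normal onsets, E|successive difference| = 2*sigma/sqrt(pi)).

young_control:
  spontaneous: {rate_hz: 1.05, amp_mean_pa: 50.06, amp_cv: 0.3,
                tau_rise_ms: 1, tau_decay_ms: 25, noise_sd_pa: 3,
                duration_s: 60, sample_rate_hz: 10000}
  quantal: {m_true: 2.46, q_pa: 50, q_cv: 0.3, n_stim: 75, noise_sd_pa: 3}
  fura: {baseline_nm: 100, delta_nm: 238, decay_s: 3, noise_sd_ratio: 0.01,
         duration_s: 60, sample_rate_hz: 10}
young_ami:
  spontaneous: {rate_hz: 1.05, amp_mean_pa: 50.06, amp_cv: 0.3,
                tau_rise_ms: 1, tau_decay_ms: 25, noise_sd_pa: 3,
                duration_s: 60, sample_rate_hz: 10000}
  quantal: {m_true: 2.46, q_pa: 50, q_cv: 0.3, n_stim: 75, noise_sd_pa: 3}
  fura: {baseline_nm: 100, delta_nm: 238, decay_s: 3, noise_sd_ratio: 0.01,
         duration_s: 60, sample_rate_hz: 10}
  effect: {rate_mult: 0.24, amp_mult: 0.65, m_mult: 0.24,
           delta_ca_mult: 0.2752}
aged_control:
  spontaneous: {rate_hz: 0.92, amp_mean_pa: 53.75, amp_cv: 0.3,
                tau_rise_ms: 1, tau_decay_ms: 25, noise_sd_pa: 3,
                duration_s: 60, sample_rate_hz: 10000}
  quantal: {m_true: 1.61, q_pa: 50, q_cv: 0.3, n_stim: 75, noise_sd_pa: 3}
  fura: {baseline_nm: 100, delta_nm: 238, decay_s: 3, noise_sd_ratio: 0.01,
         duration_s: 60, sample_rate_hz: 10}
aged_ami:
  spontaneous: {rate_hz: 0.92, amp_mean_pa: 53.75, amp_cv: 0.3,
                tau_rise_ms: 1, tau_decay_ms: 25, noise_sd_pa: 3,
                duration_s: 60, sample_rate_hz: 10000}
  quantal: {m_true: 1.61, q_pa: 50, q_cv: 0.3, n_stim: 75, noise_sd_pa: 3}
  fura: {baseline_nm: 100, delta_nm: 238, decay_s: 3, noise_sd_ratio: 0.01,
         duration_s: 60, sample_rate_hz: 10}
  effect: {rate_mult: 0.35, amp_mult: 0.78, m_mult: 0.15,
           delta_ca_mult: 0.2752}

young_wt:
  actogram: {n_days: 30, bin_min: 10, lights_on_min: 360, lights_off_min: 1080,
             psi_true_min: -7.70, onset_jitter_sd_min: 16.29,
             daily_revs: 14695, active_hours: 10}
young_vgat:
  actogram: {n_days: 30, bin_min: 10, lights_on_min: 360, lights_off_min: 1080,
             psi_true_min: -4.97, onset_jitter_sd_min: 21.56,
             daily_revs: 15410, active_hours: 10}
aged_wt:
  actogram: {n_days: 30, bin_min: 10, lights_on_min: 360, lights_off_min: 1080,
             psi_true_min: -28.76, onset_jitter_sd_min: 48.64,
             daily_revs: 5358, active_hours: 8}
aged_vgat:
  actogram: {n_days: 30, bin_min: 10, lights_on_min: 360, lights_off_min: 1080,
             psi_true_min: -30.93, onset_jitter_sd_min: 54.25,
             daily_revs: 1655, active_hours: 8}
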