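# Greedy matching of detected event times to ground truth within a
# tolerance; returns true/false positive and false negative counts.
match_events <- function(truth_times, detected_times, tol_s = 0.010) {
  used <- rep(FALSE, length(detected_times))
  tp <- 0L
  for (t in truth_times) {
    j <- which(!used & abs(detected_times - t) <= tol_s)
    if (length(j)) {
      used[j[1]] <- TRUE
      tp <- tp + 1L
    }
  }
  c(tp = tp, fp = length(detected_times) - tp,
    fn = length(truth_times) - tp)
}

f1_score <- function(m) {
  unname(2 * m["tp"] / (2 * m["tp"] + m["fp"] + m["fn"]))
}

# A noiseless trace holding one kernel-shaped event of given amplitude.
one_event_trace <- function(amp_pa, onset_s, duration_s = 1,
                            fs = 10000, tau_rise = 1, tau_decay = 25) {
  n <- round(duration_s * fs)
  x <- numeric(n)
  i0 <- round(onset_s * fs) + 1
  t_ms <- (0:(n - i0)) / fs * 1000
  x[i0:n] <- amp_pa * psc_kernel(t_ms, tau_rise, tau_decay)
  current_trace(x, fs)
}

# Published 2x2 wheel-running summaries as constructors (used by several
# test files without touching extdata).
fig_daily_activity <- function() group_summary_2x2(
  age = c("young", "young", "aged", "aged"),
  genotype = c("WT", "VGAT", "WT", "VGAT"),
  mean = c(14695, 15410, 5358, 1655),
  sem = c(2387, 1740, 1744, 382.7), n = c(6, 6, 10, 10),
  measure = "daily_activity")

fig_phase_angle <- function() group_summary_2x2(
  age = c("young", "young", "aged", "aged"),
  genotype = c("WT", "VGAT", "WT", "VGAT"),
  mean = c(-7.70, -4.97, -28.76, -30.93),
  sem = c(2.63, 0.97, 3.94, 3.57), n = c(6, 6, 10, 10),
  measure = "phase_angle")

fig_onset_variability <- function() group_summary_2x2(
  age = c("young", "young", "aged", "aged"),
  genotype = c("WT", "VGAT", "WT", "VGAT"),
  mean = c(18.38, 24.33, 54.88, 61.21),
  sem = c(5.03, 5.84, 5.70, 6.49), n = c(6, 6, 10, 10),
  measure = "onset_variability")
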