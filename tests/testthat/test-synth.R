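test_that("generators are deterministic under a fixed seed", {
  p <- spontaneous_params(duration_s = 2, sample_rate_hz = 2000, seed = 42)
  s1 <- simulate_spontaneous(p)
  s2 <- simulate_spontaneous(p)
  expect_identical(s1$trace$samples, s2$trace$samples)
  expect_identical(s1$truth$times_s, s2$truth$times_s)

  q <- quantal_params(m_true = 1.5, n_stim = 200, seed = 7)
  expect_identical(simulate_evoked(q)$amplitudes_pa,
                   simulate_evoked(q)$amplitudes_pa)

  a <- actogram_params(n_days = 5, seed = 9)
  expect_identical(simulate_actogram(a)$actogram$counts,
                   simulate_actogram(a)$actogram$counts)

  f <- fura_sim_params(duration_s = 20, stim_times_s = 5, seed = 3)
  expect_identical(simulate_fura(f)$trace$ratio, simulate_fura(f)$trace$ratio)
})

test_that("zero-rate spontaneous simulation is pure noise with empty truth", {
  p <- spontaneous_params(rate_hz = 0, noise_sd_pa = 2, duration_s = 1,
                          sample_rate_hz = 1000, seed = 1)
  sim <- simulate_spontaneous(p)
  expect_length(sim$truth$times_s, 0)
  expect_lt(max(abs(sim$trace$samples)), 10)  # noise only, no 50-pA events
})

test_that("spontaneous event counts follow the Poisson mean", {
  # rate 1 Hz x 600 s; low sampling rate since only counts are examined
  counts <- vapply(1:200, function(s) {
    p <- spontaneous_params(rate_hz = 1, duration_s = 600,
                            sample_rate_hz = 200, noise_sd_pa = 1, seed = s)
    length(simulate_spontaneous(p)$truth$times_s)
  }, numeric(1))
  se <- sqrt(600 / 200)  # SD of the mean of 200 Poisson(600) counts
  expect_lt(abs(mean(counts) - 600), 3 * se)
  # variance consistent with Poisson as well (loose factor-2 band)
  expect_gt(var(counts), 600 / 2)
  expect_lt(var(counts), 600 * 2)
})

test_that("drug-effect multipliers scale rate and amplitude before generation", {
  p <- spontaneous_params(rate_hz = 2, amp_mean_pa = 50, duration_s = 200,
                          sample_rate_hz = 500, seed = 11)
  eff <- drug_effect(rate_mult = 0.25, amp_mult = 0.5)
  sim <- simulate_spontaneous(p, eff)
  expect_lt(abs(length(sim$truth$times_s) / 200 - 0.5), 3 * sqrt(0.5 / 200))
  expect_lt(abs(mean(sim$truth$amplitudes_pa) - 25), 3 * 25 * 0.3 /
              sqrt(length(sim$truth$times_s)))
})

test_that("evoked failures follow the Poisson law exp(-m)", {
  for (m in c(0.25, 0.5, 1, 2.5)) {
    p <- quantal_params(m_true = m, n_stim = 10000, seed = round(1000 * m))
    k <- simulate_evoked(p)$true_k
    p0 <- exp(-m)
    se <- sqrt(p0 * (1 - p0) / 10000)
    expect_lt(abs(mean(k == 0) - p0), 3 * se)
  }
})

test_that("degenerate evoked cases: m = 0 all failures; preset m gives the expected failure count", {
  p <- quantal_params(m_true = 0, n_stim = 100, noise_sd_pa = 0, seed = 2)
  tr <- simulate_evoked(p)
  expect_true(all(tr$true_k == 0))
  expect_true(all(abs(tr$amplitudes_pa) < 1e-12))

  # m = 2.46 with 100 stimuli: expected failures 100*exp(-2.46) = 8.54
  fails <- vapply(1:300, function(s) {
    sum(simulate_evoked(quantal_params(m_true = 2.46, n_stim = 100,
                                       seed = s))$true_k == 0)
  }, numeric(1))
  expect_lt(abs(mean(fails) - 100 * exp(-2.46)),
            3 * sd(fails) / sqrt(300))
})

test_that("actogram onsets sit on the bin grid at the configured phase angle", {
  p <- actogram_params(n_days = 20, psi_true_min = 0,
                       onset_jitter_sd_min = 0, seed = 5)
  sim <- simulate_actogram(p)
  expect_true(all(sim$onsets_min == 1080))  # lights-off exactly
  # no activity outside the active window when jitter = 0
  active_bins <- round(10 * 60 / 10)
  first_bin <- 1080 / 10 + 1
  idx <- (first_bin - 1 + seq_len(active_bins) - 1) %% 144 + 1
  outside <- sim$actogram$counts[, -idx, drop = FALSE]
  expect_true(all(outside == 0))
})

test_that("actogram daily totals conserve daily_revs within Poisson error", {
  p <- actogram_params(n_days = 30, daily_revs = 15000, seed = 21)
  sim <- simulate_actogram(p)
  totals <- rowSums(sim$actogram$counts)
  expect_lt(abs(mean(totals) - 15000), 3 * sqrt(15000 / 30))
  p2 <- actogram_params(n_days = 30, daily_revs = 1655, active_hours = 8,
                        psi_true_min = -30.93, onset_jitter_sd_min = 54.25,
                        seed = 22)
  totals2 <- rowSums(simulate_actogram(p2)$actogram$counts)
  expect_lt(abs(mean(totals2) - 1655), 3 * sqrt(1655 / 30))
})

test_that("successive-onset differences match the folded-normal expectation", {
  # E|X - Y| = 2*sigma/sqrt(pi) for iid normal onsets, mildly inflated by
  # rounding onto the 10-min bin grid
  diffs <- unlist(lapply(1:60, function(s) {
    sim <- simulate_actogram(actogram_params(n_days = 30, psi_true_min = -30,
                                             onset_jitter_sd_min = 20,
                                             seed = s))
    abs(diff(sim$onsets_min))
  }))
  expected <- 2 * 20 / sqrt(pi)
  expect_lt(abs(mean(diffs) - expected), 0.10 * expected)
})

test_that("fura simulation round-trips through the calibration", {
  p <- fura_sim_params(baseline_nm = 100, delta_nm = 0, noise_sd_ratio = 0,
                       stim_times_s = 10, duration_s = 20, seed = 1)
  sim <- simulate_fura(p)
  conc <- ratio_to_concentration(sim$trace$ratio, p$calib)
  expect_equal(conc, rep(100, length(conc)), tolerance = 1e-9)

  p2 <- fura_sim_params(baseline_nm = 100, delta_nm = 238,
                        stim_times_s = c(15, 40), seed = 5)
  sim2 <- simulate_fura(p2)
  d <- transient_amplitudes(sim2$trace, p2$stim_times_s)
  # noise_sd_ratio 0.01 maps to a few nM around these ratios
  expect_true(all(abs(d - 238) < 15))
})

test_that("parameter validation rejects invalid inputs", {
  expect_error(spontaneous_params(duration_s = -1), class = "synphys_invalid_parameter")
  expect_error(spontaneous_params(sample_rate_hz = 0), class = "synphys_invalid_parameter")
  expect_error(spontaneous_params(amp_cv = 1.2), class = "synphys_invalid_parameter")
  expect_error(actogram_params(bin_min = 7), class = "synphys_invalid_parameter")
  expect_error(quantal_params(m_true = -1), class = "synphys_invalid_parameter")
  expect_error(fura_sim_params(stim_times_s = 100, duration_s = 60),
               class = "synphys_invalid_parameter")
  expect_error(calibration_constants(r_min = 2, r_max = 1),
               class = "synphys_invalid_parameter")
})

test_that("presets ship the published condition means", {
  yc <- synth_preset("young_control")
  expect_equal(yc$spontaneous$rate_hz, 1.05)
  expect_equal(yc$quantal$m_true, 2.46)
  expect_equal(yc$fura$delta_nm, 238)
  ya <- synth_preset("young_ami")
  expect_equal(ya$effect$rate_mult, 0.24)
  expect_equal(ya$effect$m_mult, 0.24)
  av <- synth_preset("aged_vgat")
  expect_equal(av$actogram$psi_true_min, -30.93)
  expect_equal(av$actogram$daily_revs, 1655)
  expect_error(synth_preset("nonesuch"), class = "synphys_invalid_parameter")
})
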