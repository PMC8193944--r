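test_that("detector achieves F1 >= 0.95 at amplitude/noise >= 10 and rate <= 2 Hz", {
  for (case in list(c(rate = 1, seed = 11), c(rate = 2, seed = 12))) {
    p <- spontaneous_params(rate_hz = case["rate"], amp_mean_pa = 50,
                            noise_sd_pa = 5, duration_s = 60,
                            seed = case["seed"])
    sim <- simulate_spontaneous(p)
    det <- detect_events(sim$trace)
    m <- match_events(sim$truth$times_s, det$times_s)
    expect_gte(f1_score(m), 0.95)
    # detected amplitudes track truth on matched events
    expect_lt(abs(mean(det$amplitudes_pa) - mean(sim$truth$amplitudes_pa)), 5)
  }
})

test_that("pure-noise traces yield (near) zero detections", {
  set.seed(99)
  tr <- current_trace(rnorm(60 * 10000, 0, 2), 10000)
  det <- detect_events(tr, detection_params(amp_threshold_pa = 15))
  expect_lte(length(det$times_s), 1)
})

test_that("a noiseless kernel event is measured at its true amplitude", {
  tr <- one_event_trace(50, onset_s = 0.3)
  det <- detect_events(tr)
  expect_length(det$times_s, 1)
  expect_lt(abs(det$amplitudes_pa - 50), 1)
  expect_lt(abs(det$times_s - 0.3), 0.005)
})

test_that("detection is robust to a baseline offset (median subtraction)", {
  tr <- one_event_trace(50, onset_s = 0.3)
  tr$samples <- tr$samples + 40  # constant holding-current offset
  det <- detect_events(tr)
  expect_length(det$times_s, 1)
  expect_lt(abs(det$amplitudes_pa - 50), 1)
})

test_that("event_statistics computes frequency and amplitude summaries", {
  ev <- event_train(c(1, 2, 3), c(40, 50, 60), duration_s = 60)
  st <- event_statistics(ev)
  expect_equal(st$frequency_hz, 0.05)
  expect_equal(st$mean_amp_pa, 50)
  expect_equal(st$sem_amp_pa, sd(c(40, 50, 60)) / sqrt(3), tolerance = 1e-12)
  # 63 events in 60 s -> 1.05 Hz
  ev2 <- event_train(seq(0.5, 59.5, length.out = 63), rep(50, 63), 60)
  expect_equal(event_statistics(ev2)$frequency_hz, 1.05)
  # empty train: zero frequency, undefined amplitude, flagged
  st0 <- event_statistics(event_train(numeric(0), numeric(0), 60))
  expect_equal(st0$frequency_hz, 0)
  expect_false(st0$amplitude_defined)
  expect_true(is.na(st0$mean_amp_pa))
})

test_that("detected frequency is consistent with the generating rate", {
  ratios <- vapply(1:3, function(s) {
    p <- spontaneous_params(rate_hz = 1, amp_mean_pa = 50, noise_sd_pa = 5,
                            duration_s = 100, sample_rate_hz = 5000, seed = s)
    sim <- simulate_spontaneous(p)
    event_statistics(detect_events(sim$trace))$frequency_hz
  }, numeric(1))
  expect_lt(abs(mean(ratios) - 1), 0.1)
})

test_that("iei_cdf is a valid CDF and matches the exponential law", {
  ev <- event_train(c(0.5, 1.5, 2.5, 3.5), rep(50, 4), 5)
  cdf <- iei_cdf(ev)
  expect_equal(cdf$interval_s, c(1, 1, 1))
  expect_equal(max(cdf$cum_prob), 1)
  expect_true(all(diff(cdf$cum_prob) >= 0))
  expect_error(iei_cdf(event_train(1, 50, 5)), class = "synphys_invalid_parameter")

  # Poisson train intervals are exponential(lambda)
  p <- spontaneous_params(rate_hz = 2, duration_s = 500, sample_rate_hz = 200,
                          noise_sd_pa = 1, seed = 8)
  iei <- diff(simulate_spontaneous(p)$truth$times_s)
  ks <- suppressWarnings(stats::ks.test(iei, stats::pexp, rate = 2))
  expect_gt(ks$p.value, 0.001)
})

test_that("normalized fold change is the mean of per-cell ratios", {
  r <- normalized_fold_change(data.frame(control_value = c(2, 4),
                                         drug_value = c(1, 1)))
  expect_equal(r$mean_ratio, 0.375)
  expect_equal(r$sem_ratio, 0.125)
  # identity and scale invariance
  same <- normalized_fold_change(data.frame(control_value = c(3, 5, 7),
                                            drug_value = c(3, 5, 7)))
  expect_equal(same$mean_ratio, 1)
  expect_equal(same$sem_ratio, 0)
  base <- data.frame(control_value = c(1, 2, 5), drug_value = c(0.5, 1, 1))
  expect_equal(normalized_fold_change(base)$mean_ratio,
               normalized_fold_change(transform(base,
                 control_value = control_value * 13,
                 drug_value = drug_value * 13))$mean_ratio)
  # zero controls excluded with a warning
  expect_warning(
    rz <- normalized_fold_change(data.frame(control_value = c(0, 2),
                                            drug_value = c(1, 1))),
    "zero control")
  expect_equal(rz$n, 1)
})

test_that("fold-change recovery from simulated paired cells", {
  ratios <- vapply(1:8, function(cell) {
    pc <- spontaneous_params(rate_hz = 1.05, duration_s = 120,
                             sample_rate_hz = 200, noise_sd_pa = 1,
                             seed = 100 + cell)
    pd <- pc
    pd$seed <- 200 + cell
    nc <- length(simulate_spontaneous(pc)$truth$times_s)
    nd <- length(simulate_spontaneous(pd, drug_effect(rate_mult = 0.24))$truth$times_s)
    nd / nc
  }, numeric(1))
  r <- normalized_fold_change(data.frame(control_value = 1, drug_value = ratios))
  expect_lt(abs(r$mean_ratio - 0.24), max(3 * r$sem_ratio, 0.03))
})
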