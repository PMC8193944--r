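make_act <- function(days, ...) actogram(days, ...)

test_that("10%-of-peak onset rule on constructed days", {
  x <- integer(144)
  x[110] <- 30    # bin starting 18:10 (minute 1090), first to reach 10% of peak
  x[115] <- 200   # the day's peak
  x[40] <- 15     # sub-threshold activity after lights-on
  act <- make_act(rbind(x))
  expect_equal(detect_daily_onset(act, 1), 1090)
  # relative threshold: scaling the day leaves the onset unchanged
  act7 <- make_act(rbind(7L * x))
  expect_equal(detect_daily_onset(act7, 1), 1090)
  # constant nonzero activity: degenerate onset at the lights-on bin
  const <- make_act(rbind(rep(10L, 144)))
  expect_equal(detect_daily_onset(const, 1), 360)
  # all-zero or sub-floor days are missing, never a zero-minute onset
  expect_true(is.na(detect_daily_onset(make_act(rbind(integer(144))), 1)))
  low <- integer(144); low[100] <- 30
  expect_true(is.na(detect_daily_onset(make_act(rbind(low)), 1,
                                       min_daily_revs = 50)))
  expect_error(detect_daily_onset(act, 5), class = "synphys_invalid_parameter")
})

test_that("record-scope peak option uses the whole record's maximum", {
  d1 <- integer(144); d1[112] <- 1000
  d2 <- integer(144); d2[115] <- 60; d2[110] <- 90
  act <- make_act(rbind(d1, d2))
  # per-day: day 2 threshold 9 -> first bin 110 (minute 1090)
  expect_equal(detect_daily_onset(act, 2, peak_scope = "day"), 1090)
  # per-record: threshold 100 -> no day-2 bin qualifies
  expect_true(is.na(detect_daily_onset(act, 2, peak_scope = "record")))
})

test_that("detected onsets equal simulated truth on the bin grid", {
  sim <- simulate_actogram(actogram_params(n_days = 30, psi_true_min = -30,
                                           onset_jitter_sd_min = 5, seed = 44))
  det <- activity_onsets(sim$actogram)
  expect_gte(mean(abs(det - sim$onsets_min) <= 10), 0.95)
})

test_that("phase angle sign convention and regression evaluation", {
  expect_equal(entrainment_phase(rep(1080, 10), 1080), 0)
  expect_equal(entrainment_phase(rep(1100, 10), 1080), -20)
  # trending onsets: line evaluated at the window midpoint
  on <- 1080 + 10 * (0:3)
  on[2] <- NA  # missing day keeps true spacing
  expect_equal(entrainment_phase(on, 1080), -(10 * 1.5))
  expect_error(entrainment_phase(c(1080, 1080, NA, NA), 1080),
               class = "synphys_invalid_parameter")
})

test_that("phase-angle recovery across conditions", {
  for (case in list(c(psi = -30, sd = 20), c(psi = -5, sd = 5),
                    c(psi = 0, sd = 20), c(psi = 10, sd = 5))) {
    psis <- vapply(1:100, function(a) {
      p <- actogram_params(n_days = 30, psi_true_min = case["psi"],
                           onset_jitter_sd_min = case["sd"],
                           seed = 7000 + 100 * case["psi"] + a)
      sim <- simulate_actogram(p)
      entrainment_phase(activity_onsets(sim$actogram),
                        sim$actogram$lights_off_min)
    }, numeric(1))
    se <- sd(psis) / sqrt(length(psis))
    expect_lt(abs(mean(psis) - case["psi"]), 3 * se)
  }
})

test_that("onset variability: arithmetic, invariances, missing days", {
  expect_equal(onset_variability(c(1080, 1110, 1090)), 25)
  expect_equal(onset_variability(rep(1080, 10)), 0)
  x <- c(1080, 1095, 1070, 1100, 1085)
  expect_equal(onset_variability(x + 37), onset_variability(x))
  # linear scaling of deviations scales the variability linearly
  expect_equal(onset_variability(1080 + 3 * (x - 1080)),
               3 * onset_variability(x))
  # pairs spanning a missing day are excluded
  expect_equal(onset_variability(c(1080, NA, 1120, 1140)), 20)
  expect_error(onset_variability(c(1080, NA, 1120, NA)),
               class = "synphys_invalid_parameter")
})

test_that("total activity and its ratio across age presets", {
  m <- matrix(0L, 30, 144); m[, 80] <- 15000L
  expect_equal(total_activity(make_act(m)), 15000)
  expect_equal(total_activity(make_act(matrix(0L, 5, 144))), 0)
  young <- simulate_actogram(synth_preset("young_vgat", seed = 1)$actogram)
  aged <- simulate_actogram(synth_preset("aged_vgat", seed = 2)$actogram)
  ratio <- total_activity(young$actogram) / total_activity(aged$actogram)
  expect_gt(ratio, 7)  # "up to 8-fold" difference between age groups
  expect_lt(ratio, 11)
})

test_that("double-plotted display matrix has the conventional structure", {
  sim <- simulate_actogram(actogram_params(n_days = 3, seed = 6))
  m <- actogram_matrix(sim$actogram)
  expect_equal(dim(m), c(2, 288))
  expect_equal(m[1, 145:288], m[2, 1:144])  # right half = next day's left half
  # original counts recoverable from the left halves plus the last right half
  rec <- rbind(m[, 1:144], m[nrow(m), 145:288])
  expect_equal(unname(rec), unname(sim$actogram$counts))
  expect_equal(nrow(attr(m, "dark_spans")), 2)
})

test_that("entrainment summary ties the metrics together", {
  sim <- simulate_actogram(actogram_params(n_days = 30, psi_true_min = -30,
                                           onset_jitter_sd_min = 20,
                                           seed = 12))
  es <- entrainment_summary(sim$actogram)
  expect_equal(es$psi_min,
               entrainment_phase(activity_onsets(sim$actogram), 1080))
  expect_equal(es$onset_variability_min,
               onset_variability(activity_onsets(sim$actogram)))
  expect_equal(es$total_daily_activity, total_activity(sim$actogram))
  expect_equal(es$n_days_used, 30)
})
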