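test_that("simulation is deterministic under seed and distinct across seeds", {
  a <- simulate_concentrations(subject_sim_spec(seed = 21, baseline_s = 20,
                                                task_s = 10))
  b <- simulate_concentrations(subject_sim_spec(seed = 21, baseline_s = 20,
                                                task_s = 10))
  c <- simulate_concentrations(subject_sim_spec(seed = 22, baseline_s = 20,
                                                task_s = 10))
  expect_identical(a$series$channels, b$series$channels)
  expect_false(identical(a$series$channels$F7$hbo2,
                         c$series$channels$F7$hbo2))
})

test_that("a silent specification yields identically zero concentrations", {
  s <- subject_sim_spec(seed = 1, baseline_s = 20, task_s = 10,
                        fatigue_hbo2_shift = 0, fatigue_hb_shift = 0,
                        fatigue_mayer_gain = 1,
                        mayer_amp = 0, resp_amp = 0, cardiac_amp = 0,
                        drift_slope = 0, noise_sd = 0)
  sim <- simulate_concentrations(s)
  expect_equal(sim$series$channels$F7$hbo2, rep(0, 5000))
  g <- generate_subject_recording(s)
  expect_equal(g$recording$channels$F7$i_l1, rep(1, 5000))
  expect_equal(g$recording$channels$F8$i_l2, rep(1, 5000))
})

test_that("post-pre block means recover the fatigue shifts", {
  s <- subject_sim_spec(seed = 33)
  sim <- simulate_concentrations(s)
  fs <- s$rate_hz
  pre <- 1:(s$baseline_s * fs)
  post <- (s$baseline_s + s$task_s) * fs + pre
  n <- length(pre)
  for (site in c("F7", "F8")) {
    dm_hbo2 <- mean(sim$series$channels[[site]]$hbo2[post]) -
      mean(sim$series$channels[[site]]$hbo2[pre])
    # drift contributes slope * (720 s) to the block-mean difference
    drift <- s$drift_slope * (s$baseline_s + s$task_s)
    expect_lt(abs(dm_hbo2 - drift - s$fatigue_hbo2_shift),
              3 * s$noise_sd / sqrt(n) + 0.002)
    dm_hb <- mean(sim$series$channels[[site]]$hb[post]) -
      mean(sim$series$channels[[site]]$hb[pre])
    expect_lt(abs(dm_hb - drift - s$fatigue_hb_shift),
              3 * s$noise_sd / sqrt(n) + 0.002)
  }
})

test_that("default recordings have the protocol geometry end to end", {
  g <- generate_subject_recording(subject_sim_spec(seed = 12))
  expect_length(g$recording$channels$F7$i_l1, 84000)
  expect_true(all(g$recording$channels$F7$i_l1 > 0))
  fm <- process_recording(g$recording, subject_id = "S12")
  expect_equal(nrow(fm), 22)
  expect_equal(as.integer(table(fm$label)), c(11, 11))
})

test_that("simulated spectra peak at the specified physiological bands", {
  s <- subject_sim_spec(seed = 41, noise_sd = 5e-4)
  sim <- simulate_concentrations(s)
  x <- sim$series$channels$F7$hbo2[1:12000]  # pre baseline only
  sp <- stats::spec.pgram(stats::ts(x, frequency = 100), plot = FALSE,
                          taper = 0, detrend = TRUE)
  for (f0 in c(s$mayer_freq_hz, s$resp_freq_hz, s$cardiac_freq_hz)) {
    near <- abs(sp$freq - f0) <= 0.02
    far <- sp$freq > 0.05 & abs(sp$freq - f0) > 0.05 &
      pmin(abs(sp$freq - s$mayer_freq_hz),
           abs(sp$freq - s$resp_freq_hz),
           abs(sp$freq - s$cardiac_freq_hz)) > 0.05
    expect_gt(max(sp$spec[near]), 10 * stats::median(sp$spec[far]))
  }
})

test_that("the pipeline filter attenuates the cardiac band by half or more", {
  s <- subject_sim_spec(seed = 51, noise_sd = 0, mayer_amp = 0,
                        resp_amp = 0, drift_slope = 0,
                        fatigue_hbo2_shift = 0, fatigue_hb_shift = 0,
                        fatigue_mayer_gain = 1,
                        baseline_s = 60, task_s = 30)
  sim <- simulate_concentrations(s)
  filt <- bandpass(sim$series)
  mid <- 4000:8000
  amp_in <- (max(sim$series$channels$F7$hbo2[mid]) -
               min(sim$series$channels$F7$hbo2[mid])) / 2
  amp_out <- (max(filt$channels$F7$hbo2[mid]) -
                min(filt$channels$F7$hbo2[mid])) / 2
  expect_lt(amp_out, 0.5 * amp_in)
})

test_that("cohorts are reproducible, distinct, and scale with effect size", {
  coh <- generate_cohort(3, base_seed = 77, baseline_s = 20, task_s = 10)
  coh2 <- generate_cohort(3, base_seed = 77, baseline_s = 20, task_s = 10)
  expect_identical(lapply(coh, function(s) s$recording$channels),
                   lapply(coh2, function(s) s$recording$channels))
  expect_false(identical(coh[[1]]$recording$channels$F7$i_l1,
                         coh[[2]]$recording$channels$F7$i_l1))
  expect_equal(vapply(coh, function(s) s$spec$subject_id, character(1)),
               c("S01", "S02", "S03"))
  # zero effect multiplier removes the class signature entirely
  null <- generate_cohort(1, base_seed = 5, effect_range = 0,
                          baseline_s = 20, task_s = 10)
  expect_equal(null[[1]]$spec$fatigue_hbo2_shift, 0)
  expect_equal(null[[1]]$spec$fatigue_mayer_gain, 1)
})
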