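test_that("equal baseline and task intensities give zero change", {
  d <- delta_concentrations(1.3, 1.3, 0.7, 0.7)
  expect_equal(d$delta_hbo2, 0)
  expect_equal(d$delta_hb, 0)
})

test_that("10% attenuation at both wavelengths matches the hand-worked values", {
  # frozen from an independent substitution of the two-wavelength
  # optical-density equations with log10 and the default coefficients
  d <- delta_concentrations(1, 0.9, 1, 0.9)
  expect_equal(d$delta_hbo2, 0.01555928, tolerance = 1e-6)
  expect_equal(d$delta_hb, 0.00513619, tolerance = 1e-6)
})

test_that("attenuation only at 660 nm is attributed mainly to Hb", {
  # at 660 nm Hb absorbs far more strongly than HbO2, so a drop seen only
  # there must be explained by more Hb (and compensating less HbO2)
  d <- delta_concentrations(1, 0.9, 1, 1)
  expect_gt(d$delta_hb, 0)
  expect_lt(d$delta_hbo2, 0)
})

test_that("forward model is the exact inverse of the concentration solver", {
  expect_equal(forward_intensities(0, 0, 2, 3),
               list(i_t_l1 = 2, i_t_l2 = 3))
  it <- forward_intensities(0.01555928, 0.00513619, 1, 1)
  expect_equal(it$i_t_l1, 0.9, tolerance = 1e-6)
  expect_equal(it$i_t_l2, 0.9, tolerance = 1e-6)

  set.seed(42)
  for (i in 1:1000) {
    dh <- runif(1, -0.05, 0.05)
    db <- runif(1, -0.05, 0.05)
    ib <- runif(2, 0.5, 2)
    it <- forward_intensities(dh, db, ib[1], ib[2])
    back <- delta_concentrations(ib[1], it$i_t_l1, ib[2], it$i_t_l2)
    expect_lt(abs(back$delta_hbo2 - dh), 1e-10)
    expect_lt(abs(back$delta_hb - db), 1e-10)
  }
})

test_that("concentration change is linear in the log intensity ratio", {
  d1 <- delta_concentrations(1, 0.95, 1, 0.97)
  d2 <- delta_concentrations(1, 0.95^2, 1, 0.97^2)  # doubled log-ratios
  expect_equal(d2$delta_hbo2, 2 * d1$delta_hbo2, tolerance = 1e-12)
  expect_equal(d2$delta_hb, 2 * d1$delta_hb, tolerance = 1e-12)
})

test_that("constant recordings convert to identically zero series", {
  ser <- intensity_to_chromophores(flat_recording())
  for (site in c("F7", "F8")) {
    expect_equal(ser$channels[[site]]$hbo2, rep(0, 25000))
    expect_equal(ser$channels[[site]]$hb, rep(0, 25000))
    expect_equal(ser$channels[[site]]$hbt, rep(0, 25000))
  }
})

test_that("identical channels produce identical chromophore series", {
  g <- generate_subject_recording(subject_sim_spec(seed = 5, baseline_s = 30,
                                                   task_s = 10))
  rec <- g$recording
  rec$channels$F8 <- rec$channels$F7
  ser <- intensity_to_chromophores(rec)
  expect_identical(ser$channels$F7, ser$channels$F8)
})

test_that("total haemoglobin equals the sum of the chromophores everywhere", {
  g <- generate_subject_recording(subject_sim_spec(seed = 9, baseline_s = 40,
                                                   task_s = 20))
  ser <- intensity_to_chromophores(g$recording)
  for (site in c("F7", "F8"))
    expect_true(all(abs(ser$channels[[site]]$hbt -
                          ser$channels[[site]]$hbo2 -
                          ser$channels[[site]]$hb) < 1e-12))
})

test_that("a forward-generated recording is inverted exactly", {
  # concentration series that are zero over the reference interval, so the
  # estimated baseline intensity equals the true one
  fs <- 100
  n <- 40 * fs
  t <- (seq_len(n) - 1) / fs
  ramp <- pmax(0, (t - 15) / 25) * 0.02
  wob <- 0.005 * sin(2 * pi * 0.25 * t) * (t > 12)
  it <- forward_intensities(ramp + wob, -0.5 * ramp, 1.2, 0.8)
  rec <- fnirs_recording(
    list(F7 = list(i_l1 = it$i_t_l1, i_l2 = it$i_t_l2),
         F8 = list(i_l1 = it$i_t_l1, i_l2 = it$i_t_l2)),
    sampling_rate_hz = fs,
    periods = data.frame(start_s = c(0, 20), end_s = c(20, 40),
                         role = c("baseline_pre", "baseline_post")))
  ser <- intensity_to_chromophores(rec)
  expect_lt(max(abs(ser$channels$F7$hbo2 - (ramp + wob))), 1e-10)
  expect_lt(max(abs(ser$channels$F7$hb - (-0.5 * ramp))), 1e-10)
})

test_that("default-generator recordings are recovered up to the reference mean", {
  g <- generate_subject_recording(subject_sim_spec(seed = 11))
  ser <- intensity_to_chromophores(g$recording)
  ref <- 1:1000  # the reference interval at the default policy
  for (site in c("F7", "F8")) {
    rec_hbo2 <- ser$channels[[site]]$hbo2
    tru_hbo2 <- g$truth$channels[[site]]$hbo2
    expect_lt(max(abs((rec_hbo2 - mean(rec_hbo2[ref])) -
                        (tru_hbo2 - mean(tru_hbo2[ref])))), 1e-9)
  }
})

test_that("invalid inputs are rejected with informative errors", {
  expect_error(delta_concentrations(1, 0, 1, 1), "index 1")
  expect_error(delta_concentrations(1, c(1, -2), 1, 1), "index 2")
  expect_error(optical_constants(epsilon_hb_l1 = -1), "extinction")
  expect_error(optical_constants(lambda1_nm = 900), "lambda1")
  expect_error(
    intensity_to_chromophores(flat_recording(),
                              reference_policy(k_s = 1000)),
    "outside")
})
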