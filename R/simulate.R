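#' Per-subject synthetic fNIRS simulation specification
#'
#' Describes one simulated participant: two labelled resting baselines
#' (120 s each by default) flanking an unlabelled task block (600 s),
#' sampled at 100 Hz. The haemodynamic model per channel is a sum of a
#' class-dependent concentration shift (0 in the pre-task baseline, the
#' fatigue shift in the post-task baseline), three physiological
#' oscillations with per-channel random phases (Mayer/vasomotor ~0.1 Hz,
#' respiratory ~0.3 Hz, cardiac ~1.2 Hz), a linear drift, and white sensor
#' noise. The deoxygenated series uses its own shift, half the oscillation
#' amplitudes, and independent phases.
#'
#' The fatigue signature has two components, both in the direction reported
#' for cognitive fatigue: a sustained concentration shift (oxygenated
#' haemoglobin down, deoxygenated up) and an increase of the vasomotor
#' (Mayer-wave) oscillation amplitude by the factor `fatigue_mayer_gain`
#' during the fatigued baseline. The amplitude component matters because a
#' sustained shift is near-DC: the pipeline's 0.01 Hz high-pass reduces it
#' to a decaying transient, whereas the 0.1 Hz vasomotor band passes the
#' filter unchanged.
#'
#' All concentration quantities are mM/DPF; `noise_sd = 0.002` was
#' calibrated once so the default effect size is comfortably recoverable by
#' the full pipeline, then frozen.
#'
#' @param seed Integer seed for phases and noise.
#' @param baseline_s,task_s,rate_hz Protocol geometry.
#' @param fatigue_hbo2_shift,fatigue_hb_shift Class-dependent shifts
#'   applied during the post-task baseline, mM/DPF.
#' @param fatigue_mayer_gain Multiplier on the vasomotor oscillation
#'   amplitude during the post-task baseline (1 = no amplitude effect).
#' @param mayer_amp,mayer_freq_hz Vasomotor (Mayer wave) oscillation.
#' @param resp_amp,resp_freq_hz Respiratory oscillation.
#' @param cardiac_amp,cardiac_freq_hz Cardiac oscillation.
#' @param drift_slope Linear drift, mM/DPF per second.
#' @param noise_sd White noise standard deviation, mM/DPF.
#' @param i_b_l1,i_b_l2 Reference intensities used by the forward optical
#'   model.
#' @param subject_id Identifier.
#' @return Object of class `subject_sim_spec`.
#' @export
subject_sim_spec <- function(seed = 1, baseline_s = 120, task_s = 600,
                             rate_hz = 100,
                             fatigue_hbo2_shift = -0.02,
                             fatigue_hb_shift = 0.01,
                             fatigue_mayer_gain = 1.5,
                             mayer_amp = 0.005, mayer_freq_hz = 0.1,
                             resp_amp = 0.003, resp_freq_hz = 0.3,
                             cardiac_amp = 0.002, cardiac_freq_hz = 1.2,
                             drift_slope = 1e-5, noise_sd = 0.002,
                             i_b_l1 = 1.0, i_b_l2 = 1.0,
                             subject_id = "S01") {
  fields <- as.list(environment())
  if (baseline_s <= 0 || task_s < 0 || rate_hz <= 0)
    stop("durations and rate must be positive")
  if (any(c(mayer_amp, resp_amp, cardiac_amp) < 0) || noise_sd < 0)
    stop("amplitudes must be >= 0")
  if (any(c(mayer_freq_hz, resp_freq_hz, cardiac_freq_hz) >= rate_hz / 2))
    stop("frequencies must be below Nyquist")
  if (fatigue_mayer_gain < 0) stop("fatigue_mayer_gain must be >= 0")
  structure(fields, class = "subject_sim_spec")
}

#' Simulate ground-truth chromophore series for one subject
#'
#' @param spec A [subject_sim_spec()].
#' @return A list: `series` (a `chromophore_series` with channels F7/F8),
#'   `periods` (baseline_pre / task / baseline_post boundaries) and
#'   `labels` (0 for the pre period, 1 for the post period).
#' @export
simulate_concentrations <- function(spec) {
  stopifnot(inherits(spec, "subject_sim_spec"))
  fs <- spec$rate_hz
  total_s <- 2 * spec$baseline_s + spec$task_s
  n <- as.integer(round(total_s * fs))
  t <- (seq_len(n) - 1) / fs
  periods <- data.frame(
    start_s = c(0, spec$baseline_s, spec$baseline_s + spec$task_s),
    end_s = c(spec$baseline_s, spec$baseline_s + spec$task_s, total_s),
    role = c("baseline_pre", "task", "baseline_post"),
    stringsAsFactors = FALSE)
  in_post <- t >= periods$start_s[3]
  set.seed(spec$seed)
  mayer_env <- 1 + (spec$fatigue_mayer_gain - 1) * in_post
  osc <- function(amp_scale) {
    amps <- c(spec$mayer_amp, spec$resp_amp, spec$cardiac_amp) * amp_scale
    freqs <- c(spec$mayer_freq_hz, spec$resp_freq_hz, spec$cardiac_freq_hz)
    phases <- stats::runif(3, 0, 2 * pi)
    env <- list(mayer_env, 1, 1)
    out <- numeric(n)
    for (j in 1:3) out <- out + env[[j]] * amps[j] *
      sin(2 * pi * freqs[j] * t + phases[j])
    out
  }
  channels <- lapply(c(F7 = "F7", F8 = "F8"), function(site) {
    hbo2 <- ifelse(in_post, spec$fatigue_hbo2_shift, 0) + osc(1) +
      spec$drift_slope * t + stats::rnorm(n, 0, spec$noise_sd)
    hb <- ifelse(in_post, spec$fatigue_hb_shift, 0) + osc(0.5) +
      spec$drift_slope * t + stats::rnorm(n, 0, spec$noise_sd)
    list(hbo2 = hbo2, hb = hb, hbt = hbo2 + hb)
  })
  series <- structure(list(sampling_rate_hz = fs, channels = channels,
                           periods = periods),
                      class = "chromophore_series")
  list(series = series, periods = periods, labels = c(0L, 1L))
}

#' Generate a raw intensity recording for one simulated subject
#'
#' Pushes the simulated ground-truth concentration series through the
#' forward optical model ([forward_intensities()]) to obtain strictly
#' positive dual-wavelength intensities, packaged as an
#' [fnirs_recording()]. Running the recording back through
#' [intensity_to_chromophores()] recovers the simulated series exactly up
#' to a per-channel constant fixed by the reference-interval convention.
#'
#' @param spec A [subject_sim_spec()].
#' @param constants An [optical_constants()] object.
#' @return A list: `recording` (an `fnirs_recording`), `truth` (the
#'   simulated `chromophore_series`) and `spec`.
#' @export
generate_subject_recording <- function(spec,
                                       constants = optical_constants()) {
  sim <- simulate_concentrations(spec)
  channels <- lapply(sim$series$channels, function(ch) {
    it <- forward_intensities(ch$hbo2, ch$hb, spec$i_b_l1, spec$i_b_l2,
                              constants)
    if (any(it$i_t_l1 <= 0) || any(it$i_t_l2 <= 0))
      stop("simulated excursions drove intensity to zero; reduce amplitudes")
    list(i_l1 = it$i_t_l1, i_l2 = it$i_t_l2)
  })
  rec <- fnirs_recording(channels, sampling_rate_hz = spec$rate_hz,
                         periods = sim$periods)
  list(recording = rec, truth = sim$series, spec = spec)
}

#' Generate a cohort of simulated subjects
#'
#' Each subject gets an independently derived seed and an effect-size
#' multiplier drawn uniformly from `effect_range` (a length-2 range, or a
#' single value for a homogeneous cohort); the multiplier scales both
#' fatigue shifts and the vasomotor amplitude excess
#' (`fatigue_mayer_gain - 1`), emulating inter-subject variability in the
#' fatigue response. `effect_range = c(0, 0)` produces a null cohort whose
#' pipeline accuracy is chance level.
#'
#' @param n_subjects Number of subjects.
#' @param base_seed Integer master seed.
#' @param effect_range Numeric length 1 or 2; multiplier(s) for the
#'   fatigue shifts.
#' @param ... Further arguments passed to [subject_sim_spec()].
#' @return List of per-subject lists as returned by
#'   [generate_subject_recording()], with `multiplier` added.
#' @export
generate_cohort <- function(n_subjects = 10, base_seed = 1,
                            effect_range = c(1, 1), ...) {
  if (n_subjects < 1) stop("n_subjects must be >= 1")
  if (length(effect_range) == 1) effect_range <- rep(effect_range, 2)
  set.seed(derive_seed(base_seed, 555))
  mult <- stats::runif(n_subjects, effect_range[1], effect_range[2])
  lapply(seq_len(n_subjects), function(i) {
    spec <- subject_sim_spec(
      seed = derive_seed(base_seed, i),
      subject_id = sprintf("S%02d", i), ...)
    spec$fatigue_hbo2_shift <- spec$fatigue_hbo2_shift * mult[i]
    spec$fatigue_hb_shift <- spec$fatigue_hb_shift * mult[i]
    spec$fatigue_mayer_gain <- 1 + (spec$fatigue_mayer_gain - 1) * mult[i]
    out <- generate_subject_recording(spec)
    out$multiplier <- mult[i]
    out
  })
}
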