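#' Band-pass filter specification
#'
#' Second-order Butterworth band-pass (0.01-1 Hz by default), applied
#' forward-backward (zero phase) to each chromophore series. The pass band
#' keeps the slow haemodynamic content of fNIRS while rejecting instrumental
#' drift below 0.01 Hz and cardiac/electrical components above 1 Hz.
#'
#' @param low_cut_hz,high_cut_hz Cut-off frequencies in Hz.
#' @param order Butterworth design order per band edge.
#' @param zero_phase Apply forward-backward filtering (`TRUE`, default)?
#' @return An object of class `filter_spec`.
#' @export
filter_spec <- function(low_cut_hz = 0.01, high_cut_hz = 1.0, order = 2,
                        zero_phase = TRUE) {
  if (!is.finite(low_cut_hz) || !is.finite(high_cut_hz) ||
      low_cut_hz <= 0 || high_cut_hz <= low_cut_hz)
    stop("need 0 < low_cut_hz < high_cut_hz")
  if (order < 1) stop("order must be >= 1")
  structure(list(low_cut_hz = low_cut_hz, high_cut_hz = high_cut_hz,
                 order = as.integer(order), zero_phase = isTRUE(zero_phase)),
            class = "filter_spec")
}

butter_coefs <- function(spec, fs) {
  nyq <- fs / 2
  if (spec$high_cut_hz >= nyq)
    stop(sprintf("high_cut_hz (%g) must be below the Nyquist frequency (%g)",
                 spec$high_cut_hz, nyq))
  signal::butter(spec$order,
                 c(spec$low_cut_hz, spec$high_cut_hz) / nyq, type = "pass")
}

#' Analytic magnitude response of the band-pass filter
#'
#' Evaluates |H(f)| of the designed digital Butterworth band-pass at the
#' given frequencies; with `zero_phase = TRUE` the forward-backward
#' application squares the single-pass magnitude.
#'
#' @param spec A [filter_spec()].
#' @param freq_hz Frequencies at which to evaluate, Hz.
#' @param fs Sampling rate, Hz.
#' @return Numeric vector of magnitudes.
#' @export
filter_response <- function(spec, freq_hz, fs = 100) {
  bf <- butter_coefs(spec, fs)
  vapply(freq_hz, function(f) {
    z <- exp(-1i * 2 * pi * f / fs)
    h <- sum(bf$b * z^(seq_along(bf$b) - 1)) /
      sum(bf$a * z^(seq_along(bf$a) - 1))
    if (spec$zero_phase) abs(h)^2 else abs(h)
  }, numeric(1))
}

#' Band-pass filter a chromophore series
#'
#' Filters each of the six series (two channels x HbO2/Hb/Hbt) identically.
#' Filtering is linear, so the total-haemoglobin identity
#' `hbt = hbo2 + hb` is preserved.
#'
#' @param series A `chromophore_series` (see
#'   [intensity_to_chromophores()]).
#' @param spec A [filter_spec()].
#' @return The filtered `chromophore_series` (same length).
#' @export
bandpass <- function(series, spec = filter_spec()) {
  stopifnot(inherits(series, "chromophore_series"))
  fs <- series$sampling_rate_hz
  bf <- butter_coefs(spec, fs)
  n <- length(series$channels[[1]]$hbo2)
  if (n <= 3 * 2 * spec$order)
    stop("series too short for stable filtering")
  apply1 <- function(x) {
    if (spec$zero_phase) signal::filtfilt(bf, x)
    else as.numeric(signal::filter(bf, x))
  }
  series$channels <- lapply(series$channels, function(ch) {
    out <- list(hbo2 = apply1(ch$hbo2), hb = apply1(ch$hb))
    # by linearity this equals the filtered hbt; summing keeps the
    # additive total-haemoglobin identity exact
    out$hbt <- out$hbo2 + out$hb
    out
  })
  series
}

#' Windowing specification
#'
#' Baseline periods are cut into consecutive non-overlapping windows
#' (10 s by default), anchored at the period start; a trailing partial
#' window is dropped, and then the last complete window of each baseline
#' period is discarded to keep task-contaminated samples out.
#'
#' @param window_s Window length in seconds.
#' @param overlap Fractional overlap between windows; fixed at 0.
#' @param discard_last_per_period Drop the final complete window of each
#'   period (default `TRUE`)?
#' @return An object of class `windowing_spec`.
#' @export
windowing_spec <- function(window_s = 10, overlap = 0,
                           discard_last_per_period = TRUE) {
  if (!is.finite(window_s) || window_s <= 0) stop("window_s must be > 0")
  if (!identical(overlap, 0) && !isTRUE(all.equal(overlap, 0)))
    stop("only non-overlapping windows are supported (overlap = 0)")
  structure(list(window_s = window_s, overlap = 0,
                 discard_last_per_period = isTRUE(discard_last_per_period)),
            class = "windowing_spec")
}

#' Segment baseline periods into labelled windows
#'
#' Cuts the pre-task and post-task baseline periods of a chromophore series
#' into fixed-length windows and labels them: windows from `baseline_pre`
#' are labelled 0 (absence of cognitive fatigue), windows from
#' `baseline_post` are labelled 1 (cognitive fatigue). Task-period samples
#' never enter any window. With the defaults (10 s windows, discard-last)
#' two exact 120 s baselines yield 22 windows, 11 per class.
#'
#' @param series A `chromophore_series` whose period table contains
#'   `baseline_pre` and `baseline_post`.
#' @param spec A [windowing_spec()].
#' @param subject_id Identifier copied onto every window.
#' @return A list of `labeled_window` objects; each holds the six series
#'   (names `<site>_<chromophore>`), `label` (0/1), `subject_id`,
#'   `window_index` and `sampling_rate_hz`.
#' @export
segment_and_label <- function(series, spec = windowing_spec(),
                              subject_id = "S") {
  stopifnot(inherits(series, "chromophore_series"))
  fs <- series$sampling_rate_hz
  wlen <- as.integer(round(spec$window_s * fs))
  roles <- c(baseline_pre = 0L, baseline_post = 1L)
  for (r in names(roles))
    if (!r %in% series$periods$role)
      stop(sprintf("series has no %s period", r))
  chrom_names <- c(hbo2 = "HbO2", hb = "Hb", hbt = "Hbt")
  windows <- list()
  idx <- 0L
  for (r in names(roles)) {
    p <- series$periods[series$periods$role == r, , drop = FALSE]
    dur <- p$end_s - p$start_s
    n_complete <- floor(dur / spec$window_s)
    n_win <- if (spec$discard_last_per_period) max(0L, n_complete - 1L)
    else n_complete
    if (dur < 2 * spec$window_s) {
      warning(sprintf(
        "%s period (%.1f s) shorter than two windows: no windows produced",
        r, dur))
      next
    }
    start0 <- floor(p$start_s * fs)
    for (w in seq_len(n_win)) {
      i0 <- start0 + (w - 1L) * wlen + 1L
      sl <- list()
      for (site in names(series$channels))
        for (ch in names(chrom_names))
          sl[[paste0(site, "_", chrom_names[[ch]])]] <-
        series$channels[[site]][[ch]][i0:(i0 + wlen - 1L)]
      idx <- idx + 1L
      windows[[idx]] <- structure(
        list(series = sl, label = roles[[r]], subject_id = subject_id,
             window_index = idx, sampling_rate_hz = fs),
        class = "labeled_window")
    }
  }
  windows
}
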