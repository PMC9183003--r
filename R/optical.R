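#' Optical constants for the modified Beer-Lambert law
#'
#' Bundles the wavelength-specific extinction coefficients of deoxygenated
#' (Hb) and oxygenated (HbO2) haemoglobin, the emitter-detector separation
#' and the differential path-length factor (DPF) used to convert optical
#' density changes into chromophore concentration changes. Defaults are the
#' Matcher et al. coefficients for a 660 nm / 860 nm emitter pair and a 2 cm
#' separation. The DPF is factored out of the conversion (DPF = 1), so all
#' concentration changes carry units of mM/DPF.
#'
#' @param epsilon_hb_l1 Extinction coefficient of Hb at `lambda1_nm`,
#'   mM^-1 cm^-1.
#' @param epsilon_hbo2_l1 Extinction coefficient of HbO2 at `lambda1_nm`.
#' @param epsilon_hb_l2 Extinction coefficient of Hb at `lambda2_nm`.
#' @param epsilon_hbo2_l2 Extinction coefficient of HbO2 at `lambda2_nm`.
#' @param emitter_detector_distance_cm Source-detector separation in cm.
#' @param dpf Differential path-length factor (dimensionless; 1 = factored
#'   out).
#' @param lambda1_nm,lambda2_nm Emitter wavelengths in nm; `lambda1_nm`
#'   must be the shorter (red) wavelength.
#' @return An object of class `optical_constants`.
#' @examples
#' oc <- optical_constants()
#' oc$epsilon_hb_l1
#' @export
optical_constants <- function(epsilon_hb_l1 = 3.4408,
                              epsilon_hbo2_l1 = 0.3346,
                              epsilon_hb_l2 = 0.7977,
                              epsilon_hbo2_l2 = 1.2071,
                              emitter_detector_distance_cm = 2.0,
                              dpf = 1.0,
                              lambda1_nm = 660,
                              lambda2_nm = 860) {
  eps <- c(epsilon_hb_l1, epsilon_hbo2_l1, epsilon_hb_l2, epsilon_hbo2_l2)
  if (any(!is.finite(eps)) || any(eps <= 0))
    stop("all extinction coefficients must be finite and > 0")
  if (!is.finite(emitter_detector_distance_cm) ||
      emitter_detector_distance_cm <= 0)
    stop("emitter_detector_distance_cm must be > 0")
  if (!is.finite(dpf) || dpf <= 0) stop("dpf must be > 0")
  if (!(lambda1_nm < lambda2_nm))
    stop("lambda1_nm must be smaller than lambda2_nm")
  det <- epsilon_hbo2_l1 * epsilon_hb_l2 - epsilon_hbo2_l2 * epsilon_hb_l1
  if (abs(det) < .Machine$double.eps)
    stop("degenerate constants: extinction coefficient matrix is singular")
  structure(
    list(epsilon_hb_l1 = epsilon_hb_l1, epsilon_hbo2_l1 = epsilon_hbo2_l1,
         epsilon_hb_l2 = epsilon_hb_l2, epsilon_hbo2_l2 = epsilon_hbo2_l2,
         emitter_detector_distance_cm = emitter_detector_distance_cm,
         dpf = dpf, lambda1_nm = lambda1_nm, lambda2_nm = lambda2_nm),
    class = "optical_constants")
}

#' Chromophore concentration changes from paired intensity measurements
#'
#' Applies the modified Beer-Lambert law at two wavelengths. With optical
#' density change `OD_l = log10(I_b / I_t)` at each wavelength, the pair of
#' linear equations `OD_l = (eps_HbO2_l * dHbO2 + eps_Hb_l * dHb) * d * DPF`
#' is solved for the oxygenated and deoxygenated haemoglobin changes.
#' The logarithm is base 10 (the optical-density convention).
#'
#' Arguments are recycled; `i_t_l1` / `i_t_l2` may be whole series while the
#' baselines are scalars.
#'
#' @param i_b_l1,i_t_l1 Baseline and task light intensity at the first
#'   wavelength (arbitrary positive units).
#' @param i_b_l2,i_t_l2 Same at the second wavelength.
#' @param constants An [optical_constants()] object.
#' @return A list with numeric vectors `delta_hbo2` and `delta_hb`, in
#'   mM/DPF.
#' @examples
#' delta_concentrations(1, 0.9, 1, 0.9)
#' @export
delta_concentrations <- function(i_b_l1, i_t_l1, i_b_l2, i_t_l2,
                                 constants = optical_constants()) {
  ints <- list(i_b_l1, i_t_l1, i_b_l2, i_t_l2)
  for (v in ints) {
    if (any(!is.finite(v)) || any(v <= 0)) {
      bad <- which(!is.finite(v) | v <= 0)[1]
      stop(sprintf("intensities must be finite and > 0 (first offender at index %d)",
                   bad))
    }
  }
  od1 <- log10(i_b_l1 / i_t_l1)
  od2 <- log10(i_b_l2 / i_t_l2)
  d <- constants$emitter_detector_distance_cm * constants$dpf
  det <- constants$epsilon_hbo2_l1 * constants$epsilon_hb_l2 -
    constants$epsilon_hbo2_l2 * constants$epsilon_hb_l1
  list(
    delta_hbo2 = (od1 * constants$epsilon_hb_l2 -
                    od2 * constants$epsilon_hb_l1) / (d * det),
    delta_hb   = (od2 * constants$epsilon_hbo2_l1 -
                    od1 * constants$epsilon_hbo2_l2) / (d * det))
}

#' Forward model: intensities implied by known concentration changes
#'
#' Exact inverse of [delta_concentrations()]: given chromophore change
#' series and baseline intensities, returns the task intensities
#' `I_t = I_b * 10^(-OD)` with
#' `OD_l = (eps_HbO2_l * dHbO2 + eps_Hb_l * dHb) * d * DPF`.
#' Used by the synthetic generator to emit raw recordings whose ground-truth
#' concentration series is known.
#'
#' @param delta_hbo2,delta_hb Concentration change series, mM/DPF.
#' @param i_b_l1,i_b_l2 Baseline intensities at each wavelength (> 0).
#' @param constants An [optical_constants()] object.
#' @return List with numeric vectors `i_t_l1`, `i_t_l2`.
#' @export
forward_intensities <- function(delta_hbo2, delta_hb, i_b_l1 = 1, i_b_l2 = 1,
                                constants = optical_constants()) {
  if (any(c(i_b_l1, i_b_l2) <= 0)) stop("baseline intensities must be > 0")
  if (length(delta_hbo2) != length(delta_hb))
    stop("delta_hbo2 and delta_hb must have equal length")
  d <- constants$emitter_detector_distance_cm * constants$dpf
  od1 <- (constants$epsilon_hbo2_l1 * delta_hbo2 +
            constants$epsilon_hb_l1 * delta_hb) * d
  od2 <- (constants$epsilon_hbo2_l2 * delta_hbo2 +
            constants$epsilon_hb_l2 * delta_hb) * d
  list(i_t_l1 = i_b_l1 * 10^(-od1), i_t_l2 = i_b_l2 * 10^(-od2))
}

#' Reference-interval policy for the baseline intensity
#'
#' The baseline intensity I_b of each channel/wavelength is the mean
#' intensity over a reference interval inside the pre-task baseline period.
#' `first_k_seconds` (default, k = 10) uses the first `k_s` seconds of the
#' pre-task baseline; `whole_pre_baseline` uses the entire period.
#'
#' @param mode `"first_k_seconds"` or `"whole_pre_baseline"`.
#' @param k_s Reference duration in seconds (only for `first_k_seconds`).
#' @return An object of class `reference_policy`.
#' @export
reference_policy <- function(mode = c("first_k_seconds", "whole_pre_baseline"),
                             k_s = 10) {
  mode <- match.arg(mode)
  if (mode == "first_k_seconds" && (!is.finite(k_s) || k_s <= 0))
    stop("k_s must be > 0")
  structure(list(mode = mode, k_s = k_s), class = "reference_policy")
}

#' Convert a raw intensity recording into chromophore series
#'
#' For each channel, the baseline intensity at each wavelength is the mean
#' over the reference interval ([reference_policy()]); every sample is then
#' converted with [delta_concentrations()], and the total haemoglobin change
#' is appended as `delta_hbt = delta_hbo2 + delta_hb`. Samples where the
#' momentary intensity exceeds the reference are allowed (they contribute
#' negative optical density); nothing is clipped.
#'
#' @param rec An [fnirs_recording()].
#' @param policy A [reference_policy()].
#' @param constants An [optical_constants()] object.
#' @return A `chromophore_series` object: per channel the numeric series
#'   `hbo2`, `hb`, `hbt` (mM/DPF) plus the sampling rate and the period
#'   table copied from `rec`.
#' @export
intensity_to_chromophores <- function(rec, policy = reference_policy(),
                                      constants = optical_constants()) {
  stopifnot(inherits(rec, "fnirs_recording"))
  fs <- rec$sampling_rate_hz
  pre <- rec$periods[rec$periods$role == "baseline_pre", , drop = FALSE]
  if (nrow(pre) != 1)
    stop("recording must contain exactly one baseline_pre period")
  i0 <- floor(pre$start_s * fs) + 1L
  i1 <- if (policy$mode == "first_k_seconds") {
    i0 + as.integer(round(policy$k_s * fs)) - 1L
  } else {
    floor(pre$end_s * fs)
  }
  n <- length(rec$channels[[1]]$i_l1)
  if (i1 > n || i1 < i0)
    stop("reference interval falls outside the recording")
  channels <- lapply(rec$channels, function(ch) {
    ib1 <- mean(ch$i_l1[i0:i1])
    ib2 <- mean(ch$i_l2[i0:i1])
    d <- delta_concentrations(ib1, ch$i_l1, ib2, ch$i_l2, constants)
    list(hbo2 = d$delta_hbo2, hb = d$delta_hb,
         hbt = d$delta_hbo2 + d$delta_hb)
  })
  structure(list(sampling_rate_hz = fs, channels = channels,
                 periods = rec$periods),
            class = "chromophore_series")
}

#' @export
print.chromophore_series <- function(x, ...) {
  n <- length(x$channels[[1]]$hbo2)
  cat(sprintf("<chromophore_series> %d samples @ %g Hz (%.1f s), channels: %s\n",
              n, x$sampling_rate_hz, n / x$sampling_rate_hz,
              paste(names(x$channels), collapse = ", ")))
  invisible(x)
}

#' Export chromophore series as a CSV table
#'
#' Columns: `time_s`, then `<site>_HbO2`, `<site>_Hb`, `<site>_Hbt` for each
#' channel.
#'
#' @param series A `chromophore_series`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_chromophores_csv <- function(series, path) {
  n <- length(series$channels[[1]]$hbo2)
  out <- data.frame(time_s = (seq_len(n) - 1) / series$sampling_rate_hz)
  for (site in names(series$channels)) {
    ch <- series$channels[[site]]
    out[[paste0(site, "_HbO2")]] <- ch$hbo2
    out[[paste0(site, "_Hb")]] <- ch$hb
    out[[paste0(site, "_Hbt")]] <- ch$hbt
  }
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
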