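#' The 26-feature definition set
#'
#' Ordered list of the 26 per-series features: 8 statistical (maximum,
#' minimum, polarity, mean, variance, standard deviation, kurtosis,
#' skewness), 8 temporal (mean of differences, total energy, area under the
#' curve, absolute energy, peak-to-peak distance, Shannon entropy, slope of
#' linear regression, zero-crossing count), 6 spectral (fundamental
#' frequency, maximum frequency, power bandwidth, spectral distance, median
#' frequency, spectral entropy) and 4 fNIRS-specific ones (root mean
#' square, naive slope, maximum variation, minimum variation).
#'
#' Numerical conventions are pinned for reproducibility: variance/standard
#' deviation and skewness/kurtosis (Fisher excess) use the population
#' (biased) estimators; the spectrum is the magnitude of the real-input DFT
#' of the unmodified window (no detrending or tapering); temporal entropy
#' uses 10 equal-width bins over the window range and is reported in bits.
#'
#' @param entropy_bins Number of histogram bins for the temporal Shannon
#'   entropy.
#' @param prominence_fraction Fraction of the strongest non-DC spectral
#'   magnitude a local maximum must exceed to count as the fundamental
#'   frequency peak.
#' @return Object of class `feature_definitions` with the ordered feature
#'   names in `$names`.
#' @export
feature_definitions <- function(entropy_bins = 10,
                                prominence_fraction = 0.2) {
  structure(list(
    names = c("maximum", "minimum", "polarity", "mean", "variance",
              "std", "kurtosis", "skewness",
              "mean_diff", "total_energy", "auc", "abs_energy",
              "peak_to_peak", "entropy", "slope", "zero_cross",
              "fundamental_freq", "max_freq", "power_bandwidth",
              "spectral_distance", "median_freq", "spectral_entropy",
              "rms", "naive_slope", "max_variation", "min_variation"),
    entropy_bins = as.integer(entropy_bins),
    prominence_fraction = prominence_fraction),
    class = "feature_definitions")
}

shannon_entropy_bits <- function(x, bins) {
  rng <- range(x)
  if (rng[1] == rng[2]) return(0)
  counts <- tabulate(pmin(bins, 1L + floor((x - rng[1]) / diff(rng) * bins)),
                     nbins = bins)
  p <- counts / sum(counts)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Extract the 26 features from one window series
#'
#' @param x Numeric vector (one chromophore series of one window).
#' @param rate Sampling rate in Hz.
#' @param defs A [feature_definitions()] object.
#' @return Named numeric vector of length 26, in the fixed feature order.
#'   All values are finite; the polarity feature returns 0 (with a warning)
#'   when the window minimum is exactly zero.
#' @export
extract_feature_vector <- function(x, rate, defs = feature_definitions()) {
  n <- length(x)
  if (any(!is.finite(x))) stop("window contains non-finite samples")
  if (n < 2 * rate)
    stop("window too short: need at least two 1-second blocks")
  t <- (seq_len(n) - 1) / rate
  mx <- max(x); mn <- min(x); mu <- mean(x)
  pvar <- mean((x - mu)^2)          # population variance
  psd <- sqrt(pvar)
  polarity <- if (mn == 0) {
    warning("degenerate polarity: window minimum is zero; returning 0")
    0
  } else mx / mn
  if (psd > 0) {
    kurt <- e1071::kurtosis(x, type = 1)    # population Fisher excess
    skew <- e1071::skewness(x, type = 1)
  } else {
    kurt <- 0; skew <- 0
  }

  dx <- diff(x)
  duration <- n / rate
  abs_energy <- sum(x^2)
  total_energy <- abs_energy / duration
  auc <- pracma::trapz(t, x)
  entropy <- shannon_entropy_bits(x, defs$entropy_bins)
  vt <- mean((t - mean(t))^2)
  slope <- mean((t - mean(t)) * (x - mu)) / vt
  zero_cross <- sum(x[-n] * x[-1] < 0)

  # one-sided magnitude spectrum of the raw window; df = rate/n
  sp <- stats::fft(x)[1:(n %/% 2 + 1)]
  m <- Mod(sp)
  freqs <- (seq_along(m) - 1) * rate / n
  pw <- m^2
  tot <- sum(pw)
  if (tot > 0) {
    cumP <- cumsum(pw) / tot
    max_freq <- freqs[which(cumP >= 0.95)[1]]
    median_freq <- freqs[which(cumP >= 0.5)[1]]
    power_bandwidth <- freqs[which(cumP >= 0.975)[1]] -
      freqs[which(cumP >= 0.025)[1]]
  } else {
    max_freq <- median_freq <- power_bandwidth <- 0
  }
  nb <- length(m)
  fundamental_freq <- 0
  if (nb > 2) {
    gmax <- max(m[-1])
    if (gmax > 0) {
      thr <- defs$prominence_fraction * gmax
      for (i in 2:(nb - 1)) {
        if (m[i] > m[i - 1] && m[i] > m[i + 1] && m[i] > thr) {
          fundamental_freq <- freqs[i]
          break
        }
      }
    }
  }
  cm <- cumsum(m)
  bi <- seq_along(cm)
  beta <- mean((bi - mean(bi)) * (cm - mean(cm))) / mean((bi - mean(bi))^2)
  fit <- mean(cm) + beta * (bi - mean(bi))
  spectral_distance <- sum(cm - fit)
  pnd <- pw[-1]
  spectral_entropy <- if (sum(pnd) > 0) {
    p <- pnd / sum(pnd)
    p <- p[p > 0]
    -sum(p * log2(p))
  } else 0

  nb1 <- floor(n / rate)                      # 1-second block means
  b <- vapply(seq_len(nb1), function(i)
    mean(x[((i - 1) * rate + 1):(i * rate)]), numeric(1))
  db <- diff(b)

  out <- c(mx, mn, polarity, mu, pvar, psd, kurt, skew,
           mean(dx), total_energy, auc, abs_energy,
           mx - mn, entropy, slope, zero_cross,
           fundamental_freq, max_freq, power_bandwidth,
           spectral_distance, median_freq, spectral_entropy,
           sqrt(mean(x^2)), x[n] - x[1], max(db), min(db))
  names(out) <- defs$names
  out
}

#' Assemble the windows-by-features matrix
#'
#' One row per labelled window; 26 features for each of the six series
#' (channel-major, chromophore order HbO2, Hb, Hbt), named
#' `<site>_<chromophore>_<feature>`; 156 columns at the defaults, plus the
#' binary `label` column copied from the windows.
#'
#' @param windows List of `labeled_window` objects (see
#'   [segment_and_label()]).
#' @param defs A [feature_definitions()] object.
#' @return A data frame of class `fnirs_features` whose last column is
#'   `label`; the feature-name order is stored in
#'   `attr(, "feature_names")`.
#' @export
build_feature_matrix <- function(windows, defs = feature_definitions()) {
  if (length(windows) == 0) stop("empty window list")
  rates <- vapply(windows, function(w) w$sampling_rate_hz, numeric(1))
  if (length(unique(rates)) != 1)
    stop("windows have inconsistent sampling rates")
  lens <- unlist(lapply(windows, function(w)
    vapply(w$series, length, integer(1))))
  if (length(unique(lens)) != 1)
    stop("windows have inconsistent series lengths")
  series_names <- names(windows[[1]]$series)
  rows <- lapply(windows, function(w) {
    v <- unlist(lapply(series_names, function(s)
      extract_feature_vector(w$series[[s]], w$sampling_rate_hz, defs)))
    names(v) <- as.vector(outer(defs$names, series_names,
                                function(f, s) paste(s, f, sep = "_")))
    v
  })
  mat <- do.call(rbind, rows)
  if (any(!is.finite(mat))) stop("non-finite feature values produced")
  out <- as.data.frame(mat)
  out$label <- vapply(windows, function(w) w$label, integer(1))
  out$subject_id <- vapply(windows, function(w) w$subject_id, character(1))
  attr(out, "feature_names") <- setdiff(names(out),
                                        c("label", "subject_id"))
  class(out) <- c("fnirs_features", "data.frame")
  out
}

#' @export
print.fnirs_features <- function(x, ...) {
  cat(sprintf("<fnirs_features> %d windows x %d features (+label), labels: %s\n",
              nrow(x), length(attr(x, "feature_names")),
              paste(sprintf("%d x %d", table(x$label),
                            as.integer(names(table(x$label)))),
                    collapse = ", ")))
  invisible(x)
}

#' Write a feature matrix to CSV (features, then a final `label` column)
#'
#' @param fm An `fnirs_features` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(fm, path) {
  cols <- c(attr(fm, "feature_names"), "label")
  utils::write.csv(fm[, cols], path, row.names = FALSE)
  invisible(path)
}
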