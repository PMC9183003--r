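# Small in-code fixtures shared across test files.

# a recording with flat unit intensities and standard periods
flat_recording <- function(duration_s = 250, fs = 100,
                           periods = data.frame(
                             start_s = c(0, 120, 130),
                             end_s = c(120, 130, 250),
                             role = c("baseline_pre", "task",
                                      "baseline_post"))) {
  n <- duration_s * fs
  ch <- list(i_l1 = rep(1, n), i_l2 = rep(1, n))
  fnirs_recording(list(F7 = ch, F8 = ch), sampling_rate_hz = fs,
                  periods = periods)
}

# chromophore series with given per-channel hbo2/hb and standard periods
make_series <- function(hbo2, hb, fs = 100, periods = NULL) {
  n <- length(hbo2)
  if (is.null(periods)) {
    dur <- n / fs
    periods <- data.frame(start_s = 0, end_s = dur, role = "baseline_pre")
  }
  ch <- list(hbo2 = hbo2, hb = hb, hbt = hbo2 + hb)
  structure(list(sampling_rate_hz = fs,
                 channels = list(F7 = ch, F8 = ch), periods = periods),
            class = "chromophore_series")
}

# series with two baselines of given durations and zero task gap
two_baseline_series <- function(pre_s, post_s, fs = 100, task_s = 30,
                                signal = function(t) 0 * t) {
  total <- pre_s + task_s + post_s
  t <- (seq_len(total * fs) - 1) / fs
  x <- signal(t)
  make_series(x, x, fs = fs, periods = data.frame(
    start_s = c(0, pre_s, pre_s + task_s),
    end_s = c(pre_s, pre_s + task_s, total),
    role = c("baseline_pre", "task", "baseline_post")))
}

# feature matrix with planted structure: `signal_cols` separate the classes
planted_feature_matrix <- function(n_per_class = 11, p = 156,
                                   signal_cols = integer(0),
                                   gap = 5, seed = 1) {
  set.seed(seed)
  n <- 2 * n_per_class
  X <- matrix(rnorm(n * p), n, p)
  y <- rep(c(0L, 1L), each = n_per_class)
  for (j in signal_cols) X[y == 1, j] <- X[y == 1, j] + gap
  colnames(X) <- sprintf("feat_%03d", seq_len(p))
  fm <- as.data.frame(X)
  fm$label <- y
  fm$subject_id <- "T"
  attr(fm, "feature_names") <- colnames(X)
  class(fm) <- c("fnirs_features", "data.frame")
  fm
}

table3_accuracies <- c(54.55, 90.91, 86.36, 72.73, 90.91,
                       59.09, 72.73, 54.55, 59.09, 68.18)
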