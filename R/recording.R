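#' Two-channel dual-wavelength fNIRS intensity recording
#'
#' Container for the raw optical intensities of a two-channel fNIRS
#' acquisition: per channel (sites F7 and F8 of the 10-20 system by
#' default) one intensity series per emitter wavelength, plus the sampling
#' rate and a table of annotated periods. Period intervals are half-open
#' `[start_s, end_s)` in seconds from recording start.
#'
#' @param channels Named list of channels, each a list with numeric vectors
#'   `i_l1` (shorter wavelength) and `i_l2` of equal length. Names are the
#'   site labels.
#' @param sampling_rate_hz Sampling frequency in Hz.
#' @param periods Data frame with columns `start_s`, `end_s`, `role`;
#'   `role` is one of `"baseline_pre"`, `"task"`, `"baseline_post"`.
#' @param resolution_bits ADC resolution, carried as metadata only.
#' @return An object of class `fnirs_recording`.
#' @export
fnirs_recording <- function(channels, sampling_rate_hz = 100,
                            periods = empty_periods(),
                            resolution_bits = 16) {
  if (length(channels) < 1 || is.null(names(channels)) ||
      any(names(channels) == ""))
    stop("channels must be a non-empty named list")
  lens <- unlist(lapply(channels, function(ch) c(length(ch$i_l1),
                                                 length(ch$i_l2))))
  if (length(unique(lens)) != 1)
    stop("all channel series must have the same length")
  for (site in names(channels)) {
    for (w in c("i_l1", "i_l2")) {
      v <- channels[[site]][[w]]
      if (is.null(v)) stop(sprintf("channel %s is missing series %s", site, w))
      if (any(!is.finite(v) | v <= 0)) {
        bad <- which(!is.finite(v) | v <= 0)[1]
        stop(sprintf("channel %s/%s: intensity must be > 0 (sample %d)",
                     site, w, bad))
      }
    }
  }
  if (!is.finite(sampling_rate_hz) || sampling_rate_hz <= 0)
    stop("sampling_rate_hz must be > 0")
  periods <- validate_periods(periods, lens[1] / sampling_rate_hz)
  structure(list(sampling_rate_hz = sampling_rate_hz, channels = channels,
                 periods = periods, resolution_bits = resolution_bits),
            class = "fnirs_recording")
}

#' @rdname fnirs_recording
#' @export
empty_periods <- function() {
  data.frame(start_s = numeric(0), end_s = numeric(0),
             role = character(0), stringsAsFactors = FALSE)
}

validate_periods <- function(periods, duration_s) {
  req <- c("start_s", "end_s", "role")
  if (!all(req %in% names(periods)))
    stop("periods must have columns start_s, end_s, role")
  ok_roles <- c("baseline_pre", "task", "baseline_post")
  if (nrow(periods) == 0) return(periods[, req, drop = FALSE])
  if (!all(periods$role %in% ok_roles))
    stop(sprintf("unknown period role(s): %s",
                 paste(setdiff(periods$role, ok_roles), collapse = ", ")))
  if (any(periods$end_s <= periods$start_s))
    stop("periods must satisfy start_s < end_s")
  if (any(periods$start_s < 0) ||
      any(periods$end_s > duration_s + 1e-9))
    stop("periods must lie within the recording duration")
  p <- periods[order(periods$start_s), , drop = FALSE]
  if (nrow(p) > 1 && any(p$start_s[-1] < p$end_s[-nrow(p)] - 1e-9))
    stop("periods must not overlap")
  for (r in c("baseline_pre", "baseline_post"))
    if (sum(periods$role == r) > 1)
      stop(sprintf("at most one %s period is allowed", r))
  rownames(p) <- NULL
  p[, req, drop = FALSE]
}

#' @export
print.fnirs_recording <- function(x, ...) {
  n <- length(x$channels[[1]]$i_l1)
  cat(sprintf("<fnirs_recording> %d samples @ %g Hz (%.1f s)\n",
              n, x$sampling_rate_hz, n / x$sampling_rate_hz))
  cat(sprintf("  channels: %s\n", paste(names(x$channels), collapse = ", ")))
  if (nrow(x$periods))
    cat(sprintf("  periods: %s\n",
                paste(sprintf("%s [%g, %g)", x$periods$role,
                              x$periods$start_s, x$periods$end_s),
                      collapse = "; ")))
  invisible(x)
}

#' Write an fNIRS recording to disk
#'
#' The text dialect mirrors OpenSignals conventions: the file starts with a
#' `#`-prefixed JSON metadata header (device tag, sampling rate, resolution,
#' column map, period table), followed by tab-separated columns
#' `time_s` then `<site>_<lambda1>` / `<site>_<lambda2>` per channel.
#' Values are written with 17 significant digits so a read/write round trip
#' is value-identical.
#'
#' @param rec An [fnirs_recording()].
#' @param path Output file path.
#' @param dialect Recording format; only `"opensignals_txt"` is supported.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, dialect = "opensignals_txt") {
  stopifnot(inherits(rec, "fnirs_recording"))
  dialect <- match.arg(dialect, "opensignals_txt")
  lam <- c(660, 860)
  cols <- unlist(lapply(names(rec$channels),
                        function(s) paste0(s, "_", lam)))
  header <- list(
    device = "fnirsfatigue-synthetic",
    format = "opensignals_txt",
    sampling_rate_hz = rec$sampling_rate_hz,
    resolution_bits = rec$resolution_bits,
    columns = c("time_s", cols),
    periods = rec$periods)
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste0("# ", jsonlite::toJSON(header, auto_unbox = TRUE,
                                           digits = NA)), con)
  writeLines("# EndOfHeader", con)
  n <- length(rec$channels[[1]]$i_l1)
  mat <- cbind((seq_len(n) - 1) / rec$sampling_rate_hz)
  for (ch in rec$channels) mat <- cbind(mat, ch$i_l1, ch$i_l2)
  lines <- do.call(paste, c(lapply(seq_len(ncol(mat)), function(j)
    sprintf("%.17g", mat[, j])), sep = "\t"))
  writeLines(c(paste(c("time_s", cols), collapse = "\t"), lines), con)
  invisible(path)
}

#' Read an fNIRS recording from disk
#'
#' Counterpart of [write_recording()]; see there for the dialect.
#' Malformed headers raise a format error naming the missing field, and any
#' non-positive intensity raises a validation error with the sample index.
#'
#' @param path File path.
#' @param dialect Recording format; only `"opensignals_txt"` is supported.
#' @return An [fnirs_recording()].
#' @export
read_recording <- function(path, dialect = "opensignals_txt") {
  dialect <- match.arg(dialect, "opensignals_txt")
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  first <- readLines(path, n = 1L)
  if (!startsWith(first, "# "))
    stop("format error: missing '#'-prefixed JSON metadata header")
  header <- tryCatch(jsonlite::fromJSON(sub("^# ", "", first)),
                     error = function(e)
                       stop("format error: header is not valid JSON"))
  for (field in c("sampling_rate_hz", "columns"))
    if (is.null(header[[field]]))
      stop(sprintf("format error: header omits required field '%s'", field))
  dat <- utils::read.table(path, header = TRUE, sep = "\t",
                           comment.char = "#", check.names = FALSE)
  cols <- header$columns
  if (!identical(names(dat), as.character(cols)))
    stop("format error: data columns do not match header 'columns' map")
  sites <- unique(sub("_[0-9]+$", "", cols[-1]))
  channels <- lapply(sites, function(s) {
    sc <- grep(paste0("^", s, "_"), cols, value = TRUE)
    lamn <- sort(as.numeric(sub("^.*_", "", sc)))
    list(i_l1 = dat[[paste0(s, "_", lamn[1])]],
         i_l2 = dat[[paste0(s, "_", lamn[2])]])
  })
  names(channels) <- sites
  periods <- if (!is.null(header$periods) && length(header$periods)) {
    as.data.frame(header$periods, stringsAsFactors = FALSE)
  } else {
    empty_periods()
  }
  fnirs_recording(channels, sampling_rate_hz = header$sampling_rate_hz,
                  periods = periods,
                  resolution_bits = if (is.null(header$resolution_bits)) 16
                  else header$resolution_bits)
}
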