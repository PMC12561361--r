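# Neural feature extraction: ESA, SBP, LFP band powers, LMP, threshold
# crossings, cMUA, and binning onto the 20 Hz kinematic grid.

#' Continuous neural feature stream
#'
#' Lightweight container for a (possibly multichannel) feature stream at an
#' intermediate rate, carrying the sampling rate and trial-clock origin so
#' [bin_and_lag()] can place bins correctly.
#'
#' @param data channels x samples numeric matrix (a vector is one channel).
#' @param fs sampling rate in Hz.
#' @param kind feature label (e.g. `"ESA"`).
#' @param t0_s trial-clock time of the first sample.
#' @return object of class `neural_stream`.
#' @export
neural_stream <- function(data, fs, kind = "stream", t0_s = 0) {
  if (is.null(dim(data))) data <- matrix(data, nrow = 1L)
  structure(list(data = data, fs = fs, kind = kind, t0_s = t0_s),
            class = "neural_stream")
}

#' @export
print.neural_stream <- function(x, ...) {
  cat(sprintf("Neural stream [%s]: %d channels x %d samples at %g Hz\n",
              x$kind, nrow(x$data), ncol(x$data), x$fs))
  invisible(x)
}

check_raw <- function(raw, min_s = 0.1) {
  if (!inherits(raw, "raw_recording")) stop("expected a 'raw_recording'")
  if (ncol(raw$data) / raw$fs < min_s)
    stop(sprintf("recording shorter than the %d ms filter warm-up", round(min_s * 1000)))
}

filt_channels <- function(data, flt, causal = FALSE) {
  t(apply(data, 1L, function(ch) {
    if (causal) as.numeric(signal::filter(flt, ch))
    else as.numeric(signal::filtfilt(flt, ch))
  }))
}

decimate_channels <- function(data, factor) {
  data[, seq(1L, ncol(data), by = factor), drop = FALSE]
}

#' Entire spiking activity (ESA)
#'
#' First-order Butterworth high-pass at 300 Hz, rectification (absolute
#' value), first-order Butterworth low-pass at 12 Hz, then down-sampling to
#' 1 kHz. Filtering is zero-phase (forward-backward) by default for offline
#' analysis; set `causal = TRUE` for a real-time-compatible variant.
#'
#' @param raw a [raw_recording()] at 30 kHz.
#' @param causal use causal single-pass filtering instead of zero-phase.
#' @return a [neural_stream()] at 1 kHz.
#' @export
extract_esa <- function(raw, causal = FALSE) {
  check_raw(raw)
  nyq <- raw$fs / 2
  hp <- signal::butter(1, 300 / nyq, type = "high")
  lp <- signal::butter(1, 12 / nyq, type = "low")
  x <- filt_channels(raw$data, hp, causal)
  x <- abs(x)
  x <- filt_channels(x, lp, causal)
  neural_stream(decimate_channels(x, raw$fs / 1000), 1000, "ESA", raw$t0_s)
}

#' Spiking-band power (SBP)
#'
#' Second-order Butterworth band-pass 300-1000 Hz, rectification, then
#' down-sampling to 2 kHz.
#'
#' @inheritParams extract_esa
#' @return a [neural_stream()] at 2 kHz.
#' @export
extract_sbp <- function(raw, causal = FALSE) {
  check_raw(raw)
  nyq <- raw$fs / 2
  bp <- signal::butter(2, c(300, 1000) / nyq, type = "pass")
  x <- abs(filt_channels(raw$data, bp, causal))
  neural_stream(decimate_channels(x, raw$fs / 2000), 2000, "SBP", raw$t0_s)
}

#' Local field potential (LFP) stream
#'
#' Low-pass below 500 Hz, down-sample to 2 kHz, clip excursions beyond
#' +/- 3 SD of the mean (sporadic outlier control), then a third-order
#' Butterworth low-pass (500 Hz, matching the anti-alias intent).
#'
#' @inheritParams extract_esa
#' @return a [neural_stream()] at 2 kHz.
#' @export
extract_lfp <- function(raw, causal = FALSE) {
  check_raw(raw)
  lp1 <- signal::butter(3, 500 / (raw$fs / 2), type = "low")
  x <- filt_channels(raw$data, lp1, causal)
  x <- decimate_channels(x, raw$fs / 2000)
  x <- t(apply(x, 1L, function(ch) {
    m <- mean(ch); s <- stats::sd(ch)
    pmin(pmax(ch, m - 3 * s), m + 3 * s)
  }))
  lp2 <- signal::butter(3, 500 / 1000, type = "low")
  x <- filt_channels(x, lp2, causal)
  neural_stream(x, 2000, "LFP", raw$t0_s)
}

#' LFP band-power streams
#'
#' Band-pass filters the [extract_lfp()] stream in the five canonical bands
#' (1-4, 3-10, 12-23, 27-38, 50-300 Hz) and squares the result, giving
#' instantaneous band power; [bin_and_lag()] then averages it into the mean
#' power per bin.
#'
#' @inheritParams extract_esa
#' @return named list of [neural_stream()] objects at 2 kHz, one per band.
#' @export
extract_lfp_bands <- function(raw, causal = FALSE) {
  lfp <- extract_lfp(raw, causal)
  bands <- list(`1-4` = c(1, 4), `3-10` = c(3, 10), `12-23` = c(12, 23),
                `27-38` = c(27, 38), `50-300` = c(50, 300))
  nyq <- lfp$fs / 2
  out <- lapply(names(bands), function(nm) {
    bp <- signal::butter(3, bands[[nm]] / nyq, type = "pass")
    p <- filt_channels(lfp$data, bp, causal)^2
    neural_stream(p, lfp$fs, paste0("LFP_", nm), lfp$t0_s)
  })
  names(out) <- names(bands)
  out
}

#' Local motor potential (LMP)
#'
#' Moving average of the LFP in non-overlapping 50 ms windows.
#'
#' @param lfp a [neural_stream()] from [extract_lfp()].
#' @param window_ms window length in milliseconds (default 50).
#' @return a [neural_stream()] at `1000 / window_ms` Hz.
#' @export
extract_lmp <- function(lfp, window_ms = 50) {
  win <- round(lfp$fs * window_ms / 1000)
  n_win <- ncol(lfp$data) %/% win
  idx <- rep(seq_len(n_win), each = win)
  out <- t(apply(lfp$data[, seq_len(n_win * win), drop = FALSE], 1L,
                 function(ch) tapply(ch, idx, mean)))
  neural_stream(matrix(out, nrow = nrow(lfp$data)), 1000 / window_ms,
                "LMP", lfp$t0_s)
}

#' Threshold-crossing multiunit events
#'
#' Band-pass 250-5000 Hz, then detect negative-going crossings of
#' `-k x rms` per channel (rms over the whole segment) with a 1 ms lockout.
#'
#' @inheritParams extract_esa
#' @param k threshold multiplier, conventionally 4.5 or 6.25.
#' @return list of class `threshold_events`: `times` (list of event times in
#'   trial-clock seconds per channel), `stream` (1 kHz count
#'   [neural_stream()] for binning with `aggregate = "sum"`), `k`.
#' @export
threshold_crossings <- function(raw, k = 4.5) {
  check_raw(raw)
  nyq <- raw$fs / 2
  bp <- signal::butter(3, c(250, 5000) / nyq, type = "pass")
  x <- filt_channels(raw$data, bp)
  lock <- round(raw$fs / 1000)  # 1 ms
  times <- lapply(seq_len(nrow(x)), function(ch) {
    sig <- x[ch, ]
    thr <- -k * sqrt(mean(sig^2))
    cross <- which(sig[-1L] < thr & sig[-length(sig)] >= thr) + 1L
    if (length(cross) > 1L) {
      keep <- cross[1L]
      for (s in cross[-1L]) if (s - keep[length(keep)] >= lock) keep <- c(keep, s)
      cross <- keep
    }
    raw$t0_s + (cross - 1L) / raw$fs
  })
  # 1 kHz count stream
  n_ms <- ceiling(ncol(raw$data) / raw$fs * 1000)
  counts <- t(vapply(times, function(tt) {
    tabulate(floor((tt - raw$t0_s) * 1000) + 1L, nbins = n_ms)
  }, numeric(n_ms)))
  structure(list(times = times,
                 stream = neural_stream(counts, 1000, "TC", raw$t0_s),
                 k = k),
            class = "threshold_events")
}

#' Continuous multiunit activity (cMUA)
#'
#' Third-order Butterworth band-pass 300-6000 Hz, squaring, third-order
#' Butterworth low-pass at 100 Hz, clipping of negative values, square
#' root, then down-sampling to 1 kHz.
#'
#' @inheritParams extract_esa
#' @return a [neural_stream()] at 1 kHz.
#' @export
extract_cmua <- function(raw, causal = FALSE) {
  check_raw(raw)
  nyq <- raw$fs / 2
  bp <- signal::butter(3, c(300, 6000) / nyq, type = "pass")
  x <- filt_channels(raw$data, bp, causal)^2
  lp <- signal::butter(3, 100 / nyq, type = "low")
  x <- sqrt(pmax(filt_channels(x, lp, causal), 0))
  neural_stream(decimate_channels(x, raw$fs / 1000), 1000, "CMUA", raw$t0_s)
}

#' Bin a feature stream onto the kinematic grid with a temporal lag
#'
#' For kinematic sample `t` (on a `step_ms` grid starting at 0) the feature
#' bin aggregates the stream over the 200 ms window ending `lag_ms` before
#' `t`: `[t - lag_ms - bin_ms, t - lag_ms)`. A stream event therefore shows
#' up in kinematic bins `lag_ms` to `lag_ms + bin_ms` later, matching a
#' neural signal that leads the kinematics it encodes. The stream must
#' start at least `lag_ms + bin_ms` before the first kinematic sample.
#'
#' @param stream a [neural_stream()] (its `t0_s` locates it on the trial
#'   clock, where kinematic sample 1 sits at time 0).
#' @param n_bins number of kinematic samples to produce.
#' @param bin_ms,step_ms,lag_ms bin width, grid step, and temporal lag in
#'   milliseconds (defaults 200, 50, 300).
#' @param aggregate `"mean"` for continuous features, `"sum"` for event
#'   counts.
#' @return object of class `feature_matrix`: `values` (channels x bins)
#'   plus `kind`, `bin_ms`, `step_ms`, `lag_ms`.
#' @export
bin_and_lag <- function(stream, n_bins, bin_ms = 200, step_ms = 50,
                        lag_ms = 300, aggregate = c("mean", "sum")) {
  aggregate <- match.arg(aggregate)
  if (!inherits(stream, "neural_stream")) stop("expected a 'neural_stream'")
  fs <- stream$fs
  n_ch <- nrow(stream$data)
  vals <- matrix(NA_real_, n_ch, n_bins)
  for (b in seq_len(n_bins)) {
    t_kin <- (b - 1L) * step_ms / 1000
    w0 <- t_kin - (lag_ms + bin_ms) / 1000
    w1 <- t_kin - lag_ms / 1000
    i0 <- round((w0 - stream$t0_s) * fs) + 1L
    i1 <- round((w1 - stream$t0_s) * fs)
    if (i0 < 1L)
      stop("insufficient pre-trial padding in stream for the requested lag")
    if (i1 > ncol(stream$data))
      stop("stream does not cover the trial duration")
    seg <- stream$data[, i0:i1, drop = FALSE]
    vals[, b] <- if (aggregate == "mean") rowMeans(seg) else rowSums(seg)
  }
  feature_matrix(vals, kind = stream$kind, bin_ms = bin_ms,
                 step_ms = step_ms, lag_ms = lag_ms)
}

#' Channels x bins feature matrix
#'
#' @param values channels x bins numeric matrix (no NA).
#' @param kind feature family label.
#' @param bin_ms,step_ms,lag_ms binning metadata in milliseconds.
#' @param channel_ids optional labels.
#' @return object of class `feature_matrix`.
#' @export
feature_matrix <- function(values, kind = "feature", bin_ms = 200,
                           step_ms = 50, lag_ms = 300, channel_ids = NULL) {
  values <- as.matrix(values)
  if (anyNA(values)) stop("feature matrix contains NA")
  if (is.null(channel_ids)) channel_ids <- sprintf("ch%03d", seq_len(nrow(values)))
  structure(list(values = values, kind = kind, bin_ms = bin_ms,
                 step_ms = step_ms, lag_ms = lag_ms,
                 channel_ids = channel_ids),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("Feature matrix [%s]: %d channels x %d bins (bin %g ms, step %g ms, lag %g ms)\n",
              x$kind, nrow(x$values), ncol(x$values), x$bin_ms, x$step_ms, x$lag_ms))
  invisible(x)
}

# bins x channels matrix view used by the decoders
timebins <- function(x) {
  if (inherits(x, "feature_matrix")) t(x$values) else as.matrix(x)
}

#' Z-score features by channel with frozen training statistics
#'
#' Normalizes each channel to zero mean / unit SD. Statistics are computed
#' from `features` unless `stats` (from a training set) is supplied, so test
#' data can be normalized with training-fold statistics. Zero-variance
#' channels map to zeros.
#'
#' @param features a [feature_matrix()] (or channels x bins matrix).
#' @param stats optional list with `mean` and `sd` per channel.
#' @return normalized object of the same class, with attribute `stats`.
#' @export
zscore_channels <- function(features, stats = NULL) {
  fm <- inherits(features, "feature_matrix")
  vals <- if (fm) features$values else as.matrix(features)
  if (is.null(stats))
    stats <- list(mean = rowMeans(vals), sd = apply(vals, 1L, stats::sd))
  s <- ifelse(is.finite(stats$sd) & stats$sd > 0, stats$sd, Inf)
  out <- (vals - stats$mean) / s
  if (fm) {
    features$values <- out
    attr(features, "stats") <- stats
    features
  } else {
    attr(out, "stats") <- stats
    out
  }
}

#' Gaussian noise augmentation of features
#'
#' Adds zero-mean Gaussian noise whose per-channel SD equals `scale` times
#' that channel's feature SD, the standard augmentation against decoder
#' overfitting (scales 0.2-1.0).
#'
#' @param features a [feature_matrix()] (or channels x bins matrix).
#' @param scale noise scale relative to channel SD (0 returns the input).
#' @param seed integer seed for reproducibility.
#' @return augmented object of the same class.
#' @export
augment_noise <- function(features, scale, seed = 1L) {
  if (scale == 0) return(features)
  fm <- inherits(features, "feature_matrix")
  vals <- if (fm) features$values else as.matrix(features)
  ch_sd <- apply(vals, 1L, stats::sd)
  noise <- with_seed(derive_seed(seed, "augment"),
                     matrix(stats::rnorm(length(vals)), nrow(vals), ncol(vals)))
  out <- vals + noise * (scale * ch_sd)
  if (fm) { features$values <- out; features } else out
}
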