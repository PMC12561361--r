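# Synthetic study data: glyph corpora, simulated feature sessions, and raw
# 30 kHz recordings with ground-truth spikes.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  force(code)
}

#' Packaged corpus of 26 block-capital letter glyphs
#'
#' Deterministic, code-defined stroke templates for A-Z on the unit square
#' (x rightward, y upward). Each letter has 1-4 pen-down strokes; pen lifts
#' are inserted automatically between disconnected strokes, so total segment
#' counts vary across the corpus. Used as the stand-in character set for the
#' recognition and simulation experiments.
#'
#' @return object of class `glyph_corpus`: list with `templates` (named list
#'   of [stroke_template()]).
#' @export
letter_corpus <- function() {
  S <- function(...) list(...)  # list of stroke polylines
  P <- function(...) matrix(c(...), ncol = 2L, byrow = TRUE)
  strokes <- list(
    A = S(P(0, 0, 0.5, 1, 1, 0), P(0.2, 0.4, 0.8, 0.4)),
    B = S(P(0, 0, 0, 1),
          P(0, 1, 0.8, 0.9, 0.9, 0.75, 0.8, 0.55, 0, 0.5,
            0.85, 0.4, 0.95, 0.25, 0.8, 0.05, 0, 0)),
    C = S(P(0.9, 0.85, 0.6, 1, 0.2, 0.9, 0, 0.5, 0.2, 0.1, 0.6, 0, 0.9, 0.15)),
    D = S(P(0, 0, 0, 1), P(0, 1, 0.7, 0.9, 1, 0.5, 0.7, 0.1, 0, 0)),
    E = S(P(1, 1, 0, 1, 0, 0, 1, 0), P(0, 0.5, 0.7, 0.5)),
    F = S(P(0, 1, 0, 0), P(0, 1, 0.9, 1), P(0, 0.5, 0.7, 0.5)),
    G = S(P(0.9, 0.85, 0.5, 1, 0.1, 0.85, 0, 0.5, 0.1, 0.15, 0.5, 0,
            0.9, 0.1, 0.9, 0.4, 0.55, 0.4)),
    H = S(P(0, 1, 0, 0), P(1, 1, 1, 0), P(0, 0.5, 1, 0.5)),
    I = S(P(0.5, 1, 0.5, 0)),
    J = S(P(0.7, 1, 0.7, 0.2, 0.5, 0, 0.3, 0.05, 0.15, 0.25)),
    K = S(P(0, 1, 0, 0), P(0.9, 1, 0.05, 0.5), P(0.05, 0.5, 0.9, 0)),
    L = S(P(0, 1, 0, 0, 0.9, 0)),
    M = S(P(0, 0, 0, 1, 0.5, 0.4, 1, 1, 1, 0)),
    N = S(P(0, 0, 0, 1, 1, 0, 1, 1)),
    O = S(P(0.5, 1, 0.15, 0.85, 0, 0.5, 0.15, 0.15, 0.5, 0,
            0.85, 0.15, 1, 0.5, 0.85, 0.85, 0.5, 1)),
    P = S(P(0, 0, 0, 1, 0.8, 0.9, 0.95, 0.7, 0.8, 0.5, 0, 0.5)),
    Q = S(P(0.5, 1, 0.15, 0.85, 0, 0.5, 0.15, 0.15, 0.5, 0,
            0.85, 0.15, 1, 0.5, 0.85, 0.85, 0.5, 1),
          P(0.6, 0.3, 0.95, 0.02)),
    R = S(P(0, 0, 0, 1, 0.8, 0.9, 0.95, 0.7, 0.8, 0.5, 0, 0.5),
          P(0, 0.5, 0.9, 0)),
    S = S(P(0.9, 0.85, 0.5, 1, 0.1, 0.85, 0.1, 0.6, 0.9, 0.4,
            0.9, 0.15, 0.5, 0, 0.1, 0.15)),
    T = S(P(0, 1, 1, 1), P(0.5, 1, 0.5, 0)),
    U = S(P(0, 1, 0, 0.2, 0.2, 0, 0.8, 0, 1, 0.2, 1, 1)),
    V = S(P(0, 1, 0.5, 0, 1, 1)),
    W = S(P(0, 1, 0.25, 0, 0.5, 0.6, 0.75, 0, 1, 1)),
    X = S(P(0, 1, 1, 0), P(1, 1, 0, 0)),
    Y = S(P(0, 1, 0.5, 0.5, 1, 1), P(0.5, 0.5, 0.5, 0)),
    Z = S(P(0, 1, 1, 1, 0, 0, 1, 0))
  )
  templates <- lapply(names(strokes), function(id)
    glyph_from_strokes(id, strokes[[id]]))
  names(templates) <- names(strokes)
  structure(list(templates = templates), class = "glyph_corpus")
}

#' @export
print.glyph_corpus <- function(x, ...) {
  segs <- vapply(x$templates, function(tp) length(tp$segments), integer(1L))
  cat(sprintf("Glyph corpus: %d templates, %d-%d segments each\n",
              length(x$templates), min(segs), max(segs)))
  invisible(x)
}

#' Random connected multi-stroke glyph
#'
#' Generates a reproducible random glyph inside the unit square with the
#' requested number of pen-down strokes (2-4 waypoints each) joined by
#' straight pen lifts. Used to scale template libraries and to emulate the
#' unseen characters added in multi-day sessions.
#'
#' @param seed integer seed; the same seed always yields the same glyph, and
#'   the id encodes the seed so large collections have collision-free ids.
#' @param n_strokes number of pen-down strokes (>= 1).
#' @return a [stroke_template()] with id `"rg<seed>"`.
#' @export
random_glyph <- function(seed, n_strokes = 2L) {
  n_strokes <- as.integer(n_strokes)
  if (n_strokes < 1L) stop("'n_strokes' must be >= 1")
  with_seed(derive_seed(seed, "glyph"), {
    strokes <- lapply(seq_len(n_strokes), function(k) {
      npts <- sample(2:4, 1L)
      pts <- matrix(stats::runif(2L * npts), ncol = 2L)
      # spread waypoints so strokes have usable arclength
      while (segment_arclength(pts) < 0.3) {
        pts <- matrix(stats::runif(2L * npts), ncol = 2L)
      }
      pts
    })
    glyph_from_strokes(sprintf("rg%d", as.integer(seed)), strokes)
  })
}

#' Fixed linear encoder from velocity to simulated neural channels
#'
#' Weights are drawn once (standard normal scaled by `1/sqrt(2)`) from the
#' given seed and then held fixed for a whole experiment, emulating a stable
#' linear velocity encoding across trials and days.
#'
#' @param n_channels number of simulated channels (default 96, two Utah
#'   arrays' worth of usable channels).
#' @param seed integer seed for the weight draw.
#' @param bias per-channel offset (default 0).
#' @return list with `W` (`n_channels` x 2), `b`, `n_channels`, `seed`.
#' @export
make_linear_encoder <- function(n_channels = 96L, seed = 1L, bias = 0) {
  W <- with_seed(derive_seed(seed, "encoder"),
                 matrix(stats::rnorm(n_channels * 2L) / sqrt(2), n_channels, 2L))
  list(W = W, b = rep(bias, length.out = n_channels),
       n_channels = as.integer(n_channels), seed = as.integer(seed))
}

#' Simulate a recording session of feature trials
#'
#' For every template and repetition: synthesize the prompted kinematics,
#' optionally resample the timeline (the subject's misaligned "actual"
#' velocity), pass the actual velocity through the fixed linear encoder,
#' apply per-day gain/offset drift, and add Gaussian observation noise with
#' per-channel SD equal to `noise_sd` times that channel's signal SD.
#'
#' @param corpus a `glyph_corpus` (or list of templates).
#' @param encoder encoder from [make_linear_encoder()]; created from `seed`
#'   when `NULL`.
#' @param repetitions repetitions per character (default 3, as in a typical
#'   session).
#' @param misalign apply per-trial timeline resampling (default `TRUE`).
#' @param day day index; each day has its own multiplicative channel gain
#'   (lognormal, sdlog 0.1) and additive offset (normal, 0.1 x channel SD).
#'   Day 1 is drift-free.
#' @param noise_sd observation noise scale relative to per-channel signal SD
#'   (default 1: channel-level SNR of one, typical of single-trial
#'   intracortical features).
#' @param seed master seed; all per-trial randomness is derived from it.
#' @return list of class `session` with `trials` (each holding `id`, `rep`,
#'   `day`, `label` ([kinematic_series()], the prompt), `v_actual` (bins x 2
#'   executed velocity), `features` (bins x channels)), plus the `encoder`
#'   and the arguments as fields.
#' @export
simulate_session <- function(corpus, encoder = NULL, repetitions = 3L,
                             misalign = TRUE, day = 1L, noise_sd = 1,
                             seed = 1L) {
  templates <- if (inherits(corpus, "glyph_corpus")) corpus$templates else corpus
  if (is.null(encoder)) encoder <- make_linear_encoder(seed = seed)
  trials <- list()
  for (tp in templates) {
    lab <- synthesize_kinematics(tp)
    P <- cbind(lab$x, lab$y)
    for (r in seq_len(repetitions)) {
      if (misalign) {
        rs <- resample_timeline(P, origin = lab$origin, fs = lab$fs,
                                seed = derive_seed(seed, "warp", tp$id, r, day))
        v_act <- rs$V
      } else {
        v_act <- velocity_matrix(lab)
      }
      s <- linear_encode(v_act, encoder)
      trials[[length(trials) + 1L]] <-
        list(id = tp$id, rep = r, day = as.integer(day),
             label = lab, v_actual = v_act, features = s)
    }
  }
  # day drift: fixed per (encoder seed, day); day 1 is the reference day
  ch_sd <- apply(do.call(rbind, lapply(trials, `[[`, "features")), 2L, stats::sd)
  drift <- with_seed(derive_seed(encoder$seed, "drift", day), {
    if (day > 1L)
      list(gain = exp(stats::rnorm(encoder$n_channels, 0, 0.1)),
           offset = stats::rnorm(encoder$n_channels, 0, 0.1) * ch_sd)
    else list(gain = rep(1, encoder$n_channels),
              offset = rep(0, encoder$n_channels))
  })
  for (k in seq_along(trials)) {
    f <- sweep(sweep(trials[[k]]$features, 2L, drift$gain, "*"),
               2L, drift$offset, "+")
    if (noise_sd > 0) {
      noise <- with_seed(derive_seed(seed, "noise", k, day),
                         matrix(stats::rnorm(length(f)), nrow(f), ncol(f)))
      f <- f + noise * rep(drift$gain * ch_sd * noise_sd, each = nrow(f))
    }
    trials[[k]]$features <- f
  }
  structure(list(trials = trials, encoder = encoder, day = as.integer(day),
                 misalign = misalign, noise_sd = noise_sd,
                 repetitions = as.integer(repetitions), seed = seed),
            class = "session")
}

#' @export
print.session <- function(x, ...) {
  ids <- unique(vapply(x$trials, `[[`, character(1L), "id"))
  cat(sprintf(
    "Simulated session (day %d): %d trials, %d characters x %d reps, %d channels, %s\n",
    x$day, length(x$trials), length(ids), x$repetitions,
    x$encoder$n_channels,
    if (x$misalign) "misaligned" else "aligned"))
  invisible(x)
}

#' Velocity-tuning specification for raw-recording simulation
#'
#' @param n_channels number of electrodes.
#' @param baseline_hz baseline firing rate.
#' @param depth_hz modulation depth in Hz per unit of projected velocity.
#' @param noise_sd_uv background-noise SD in microvolts.
#' @param snr spike peak amplitude expressed in multiples of the
#'   background-noise SD.
#' @param seed seed for the per-channel preferred directions.
#' @return list of tuning parameters (class `tuning_spec`).
#' @export
tuning_spec <- function(n_channels = 4L, baseline_hz = 20, depth_hz = 50,
                        noise_sd_uv = 10, snr = 5, seed = 1L) {
  ang <- with_seed(derive_seed(seed, "tuning"),
                   stats::runif(n_channels, 0, 2 * pi))
  structure(list(n_channels = as.integer(n_channels),
                 baseline_hz = baseline_hz, depth_hz = depth_hz,
                 noise_sd_uv = noise_sd_uv, snr = snr,
                 pd = cbind(cos(ang), sin(ang)), seed = seed),
            class = "tuning_spec")
}

# 1/f ("pink") noise via FFT spectrum shaping, unit SD.
pink_noise <- function(n) {
  w <- stats::rnorm(n)
  spec <- stats::fft(w)
  f <- c(1, seq_len(n - 1L))
  f <- pmin(f, n - f + 1)  # symmetric frequency index
  spec <- spec / sqrt(f)
  x <- Re(stats::fft(spec, inverse = TRUE)) / n
  (x - mean(x)) / stats::sd(x)
}

spike_waveform <- function(fs) {
  # 1.2 ms biphasic extracellular waveform, unit (negative) peak
  t <- seq(0, 1.2e-3, by = 1 / fs)
  w <- -exp(-((t - 3e-4) / 1.2e-4)^2) + 0.45 * exp(-((t - 6.5e-4) / 2.2e-4)^2)
  w / max(abs(w))
}

#' Simulate a raw 30 kHz recording with ground-truth spikes
#'
#' Each channel fires an inhomogeneous point process whose rate is
#' `baseline + depth * (velocity . preferred_direction)` (clipped at zero),
#' with a 2 ms refractory period. Spike waveforms (peak `snr` times the
#' noise SD) are added to a pink-plus-white background. The rate follows the
#' kinematics with a lead of `lead_s` so that binning with the standard
#' 200 ms / 300 ms lag settings aligns features with the kinematic grid.
#'
#' @param kinematics a [kinematic_series()] giving the velocity drive.
#' @param tuning a [tuning_spec()].
#' @param seed integer seed.
#' @param fs sampling rate (default 30000 Hz).
#' @param lead_s neural lead over the kinematic series in seconds
#'   (default 0.4 = lag 300 ms + half the 200 ms bin).
#' @param pad_s quiet padding appended before and after the trial (default
#'   0.6 s), needed by the binning lag.
#' @return object of class `raw_recording`: `data` (channels x samples,
#'   microvolts), `fs`, `channel_ids`, `spike_times` (list, seconds,
#'   relative to recording start), `t0_s` (kinematic time of the first raw
#'   sample, negative).
#' @export
simulate_raw_recording <- function(kinematics, tuning = tuning_spec(),
                                   seed = 1L, fs = 30000, lead_s = 0.4,
                                   pad_s = 0.6) {
  v <- velocity_matrix(kinematics)
  n_kin <- nrow(v)
  dur <- n_kin / kinematics$fs
  t0 <- -pad_s
  n <- round((dur + 2 * pad_s) * fs)
  t <- t0 + (seq_len(n) - 1L) / fs
  wf <- spike_waveform(fs)
  amp <- tuning$snr * tuning$noise_sd_uv
  data <- matrix(0, tuning$n_channels, n)
  spike_times <- vector("list", tuning$n_channels)
  # velocity each raw sample sees, shifted so neural activity leads kinematics
  kin_idx <- floor((t + lead_s) * kinematics$fs) + 1L
  inside <- kin_idx >= 1L & kin_idx <= n_kin
  refr <- round(2e-3 * fs)
  for (ch in seq_len(tuning$n_channels)) {
    proj <- rep(0, n)
    proj[inside] <- v[kin_idx[inside], , drop = FALSE] %*% tuning$pd[ch, ]
    rate <- pmax(0, tuning$baseline_hz + tuning$depth_hz * proj)
    ch_seed <- derive_seed(seed, "rawrec", ch)
    spikes <- with_seed(ch_seed, which(stats::runif(n) < rate / fs))
    if (length(spikes) > 1L) {  # refractory lockout
      keep <- spikes[1L]
      for (s in spikes[-1L]) if (s - keep[length(keep)] >= refr) keep <- c(keep, s)
      spikes <- keep
    }
    sig <- with_seed(ch_seed + 1L,
                     tuning$noise_sd_uv *
                       (sqrt(0.5) * stats::rnorm(n) + sqrt(0.5) * pink_noise(n)))
    for (s in spikes) {
      idx <- s:min(n, s + length(wf) - 1L)
      sig[idx] <- sig[idx] + amp * wf[seq_along(idx)]
    }
    data[ch, ] <- sig
    spike_times[[ch]] <- (spikes - 1L) / fs
  }
  raw_recording(data, fs = fs, spike_times = spike_times, t0_s = t0)
}

#' Raw multichannel recording container
#'
#' @param data channels x samples numeric matrix (microvolts).
#' @param fs sampling rate in Hz (30 kHz for raw acquisitions).
#' @param channel_ids optional channel labels.
#' @param spike_times optional list of ground-truth spike times (s).
#' @param t0_s time of the first sample on the trial clock (default 0).
#' @return object of class `raw_recording`.
#' @export
raw_recording <- function(data, fs = 30000, channel_ids = NULL,
                          spike_times = NULL, t0_s = 0) {
  data <- as.matrix(data)
  if (anyNA(data) || any(!is.finite(data))) stop("raw data must be finite")
  if (is.null(channel_ids)) channel_ids <- sprintf("ch%03d", seq_len(nrow(data)))
  structure(list(data = data, fs = fs, channel_ids = channel_ids,
                 spike_times = spike_times, t0_s = t0_s),
            class = "raw_recording")
}

#' @export
print.raw_recording <- function(x, ...) {
  cat(sprintf("Raw recording: %d channels x %d samples at %g Hz (%.2f s)\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs))
  invisible(x)
}
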