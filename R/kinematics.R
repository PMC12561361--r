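# Video-guided handwriting kinematics: stroke templates in, 20 Hz
# velocity/position series out.

#' Stroke/pen-lift glyph template
#'
#' A glyph is an ordered list of polyline segments, each labelled `"stroke"`
#' (visible writing) or `"pen_lift"` (straight transition between strokes).
#' Consecutive segments must connect: each segment starts where the previous
#' one ends, so the whole glyph is one continuous path.
#'
#' @param id character label (e.g. `"A"`).
#' @param segments list of segments, each a list with `points` (k x 2
#'   numeric matrix, k >= 2) and `label` (`"stroke"` or `"pen_lift"`).
#' @return object of class `stroke_template`.
#' @seealso [glyph_from_strokes()] which inserts pen lifts automatically.
#' @export
stroke_template <- function(id, segments) {
  if (length(segments) < 1L) stop("a template needs at least one segment")
  segments <- lapply(segments, function(s) {
    pts <- as.matrix(s$points)
    if (nrow(pts) < 2L || ncol(pts) != 2L)
      stop("each segment polyline needs >= 2 two-dimensional points")
    if (!s$label %in% c("stroke", "pen_lift"))
      stop("segment label must be 'stroke' or 'pen_lift'")
    list(points = unname(pts), label = s$label)
  })
  for (k in seq_along(segments)[-1L]) {
    a <- segments[[k - 1L]]$points
    b <- segments[[k]]$points
    if (max(abs(a[nrow(a), ] - b[1L, ])) > 1e-6)
      stop(sprintf("template '%s': segment %d does not start where segment %d ends",
                   id, k, k - 1L))
  }
  structure(list(id = as.character(id), segments = segments),
            class = "stroke_template")
}

#' Build a connected template from strokes only
#'
#' Inserts a straight pen-lift segment between consecutive strokes whose
#' endpoints do not touch, mirroring how inter-stroke movements are
#' presented as direct lines in the writing animation.
#'
#' @param id character label.
#' @param strokes list of k x 2 matrices, one polyline per stroke, in
#'   writing order.
#' @return a [stroke_template()].
#' @export
glyph_from_strokes <- function(id, strokes) {
  segs <- list()
  prev_end <- NULL
  for (pts in strokes) {
    pts <- as.matrix(pts)
    if (!is.null(prev_end) && max(abs(prev_end - pts[1L, ])) > 1e-9)
      segs[[length(segs) + 1L]] <-
        list(points = rbind(prev_end, pts[1L, ]), label = "pen_lift")
    segs[[length(segs) + 1L]] <- list(points = pts, label = "stroke")
    prev_end <- pts[nrow(pts), ]
  }
  stroke_template(id, segs)
}

segment_arclength <- function(points) {
  d <- diff(points)
  sum(sqrt(rowSums(d^2)))
}

template_arclength <- function(template) {
  sum(vapply(template$segments, function(s) segment_arclength(s$points),
             numeric(1L)))
}

template_points <- function(template) {
  do.call(rbind, lapply(template$segments, function(s) s$points))
}

#' @export
print.stroke_template <- function(x, ...) {
  n_stroke <- sum(vapply(x$segments, function(s) s$label == "stroke", logical(1L)))
  cat(sprintf("Stroke template '%s': %d segments (%d strokes), arclength %.3f\n",
              x$id, length(x$segments), n_stroke, template_arclength(x)))
  invisible(x)
}

#' @export
plot.stroke_template <- function(x, ...) {
  pts <- template_points(x)
  graphics::plot(pts[, 1L], pts[, 2L], type = "n", asp = 1,
                 xlab = "x", ylab = "y", main = x$id, ...)
  for (s in x$segments)
    graphics::lines(s$points[, 1L], s$points[, 2L],
                    lty = if (s$label == "stroke") 1L else 2L,
                    col = if (s$label == "stroke") "black" else "grey50")
  invisible(x)
}

#' Per-segment durations proportional to arclength
#'
#' Splits a total writing duration across segments so each segment's
#' duration is proportional to its polyline arclength - i.e. constant speed
#' across the glyph, as in the guiding animation.
#'
#' @param template a [stroke_template()].
#' @param total_T total writing duration in seconds, > 0.
#' @return numeric vector of durations summing to `total_T`.
#' @export
segment_durations <- function(template, total_T) {
  if (total_T <= 0) stop("'total_T' must be > 0")
  len <- vapply(template$segments, function(s) segment_arclength(s$points),
                numeric(1L))
  if (any(len <= 0)) stop("zero-length segment in template")
  total_T * len / sum(len)
}

#' Triangular (bang-bang) velocity profile for one segment axis
#'
#' Samples the profile \eqn{v(t) = at} for \eqn{0 \le t < T/2} and
#' \eqn{v(t) = aT - at} for \eqn{T/2 \le t \le T}, with the scaling factor
#' solved so the continuous profile integrates to the requested axis
#' displacement: \eqn{a = 4\,\mathrm{displacement}/T^2} (peak
#' \eqn{2\,\mathrm{displacement}/T} at \eqn{t = T/2}).
#'
#' @param displacement axis displacement covered by the segment.
#' @param T segment duration in seconds, > 0.
#' @param fs sampling rate in Hz (default 20).
#' @return numeric vector of sampled velocities at `t = k/fs`,
#'   `k = 0 .. ceiling(T*fs) - 1`.
#' @export
triangular_profile <- function(displacement, T, fs = 20) {
  if (T <= 0 || fs <= 0) stop("'T' and 'fs' must be > 0")
  n <- ceiling(T * fs)
  if (n < 2L) stop("segment too short: fewer than 2 samples at this rate")
  t <- (seq_len(n) - 1L) / fs
  a <- 4 * displacement / T^2
  ifelse(t < T / 2, a * t, a * T - a * t)
}

# Straight-line pieces of a template: every consecutive point pair of every
# segment polyline, each shaped by its own triangular profile at synthesis.
template_edges <- function(template) {
  do.call(rbind, lapply(template$segments, function(s) {
    p <- s$points
    data.frame(x0 = p[-nrow(p), 1L], y0 = p[-nrow(p), 2L],
               x1 = p[-1L, 1L], y1 = p[-1L, 2L])
  }))
}

# Piecewise-triangular velocity sampled on the global grid t = k/fs.  Each
# straight-line piece (polyline edge) carries its own bell profile, with
# duration proportional to its length (constant writing speed overall).
sample_segment_profiles <- function(template, total_T, fs) {
  edges <- template_edges(template)
  len <- sqrt((edges$x1 - edges$x0)^2 + (edges$y1 - edges$y0)^2)
  if (any(len <= 0)) stop("zero-length straight piece in template")
  durations <- total_T * len / sum(len)
  starts <- cumsum(c(0, durations))
  n <- ceiling(total_T * fs)
  t <- (seq_len(n) - 1L) / fs
  seg_idx <- pmin(findInterval(t, starts, rightmost.closed = TRUE),
                  length(durations))
  v <- matrix(0, n, 2L)
  for (k in seq_len(nrow(edges))) {
    disp <- c(edges$x1[k] - edges$x0[k], edges$y1[k] - edges$y0[k])
    Tk <- durations[k]
    a <- 4 * disp / Tk^2
    sel <- seg_idx == k
    tau <- t[sel] - starts[k]
    for (ax in 1:2)
      v[sel, ax] <- ifelse(tau < Tk / 2, a[ax] * tau, a[ax] * Tk - a[ax] * tau)
  }
  v
}

moving_average_replicate <- function(x, window) {
  if (window <= 1L) return(x)
  half <- (window - 1L) %/% 2L
  n <- length(x)
  xp <- c(rep(x[1L], half), x, rep(x[n], window - 1L - half))
  stats::filter(xp, rep(1 / window, window), sides = 1L)[window:(n + window - 1L)]
}

#' Synthesize 20 Hz handwriting kinematics from a glyph template
#'
#' Concatenates per-segment triangular velocity profiles (durations
#' proportional to segment arclength), applies centred moving-average
#' smoothing (edge samples replicated), and integrates to positions. With
#' the default duration policy the total writing time grows linearly with
#' glyph arclength between 4 and 8 s, matching typical guided-writing
#' pacing.
#'
#' @param template a [stroke_template()].
#' @param total_T total duration in seconds; when `NULL` (default) it is set
#'   from the glyph arclength (4 s at arclength <= 1, 8 s at arclength >=
#'   5, linear in between).
#' @param fs sampling rate in Hz (default 20).
#' @param smooth centred moving-average window in samples (default 5;
#'   use 1 to disable).
#' @return a [kinematic_series()] whose origin is the template start point.
#' @export
synthesize_kinematics <- function(template, total_T = NULL, fs = 20, smooth = 5) {
  if (is.null(total_T)) {
    L <- template_arclength(template)
    total_T <- min(8, max(4, 4 + (L - 1) * (8 - 4) / (5 - 1)))
  }
  if (total_T < 0.5) stop("total duration below 0.5 s")
  v <- sample_segment_profiles(template, total_T, fs)
  if (smooth > 1L)
    v <- apply(v, 2L, moving_average_replicate, window = as.integer(smooth))
  kinematic_series(v, fs = fs, origin = template$segments[[1L]]$points[1L, ])
}

#' 20 Hz kinematic series (velocity + integrated position)
#'
#' @param v n x 2 matrix of velocities (units/s), columns x and y.
#' @param fs sampling rate in Hz.
#' @param origin start position, length-2 numeric.
#' @return object of class `kinematic_series` with fields `vx`, `vy`, `x`,
#'   `y`, `fs`, `origin`.
#' @export
kinematic_series <- function(v, fs = 20, origin = c(0, 0)) {
  v <- as.matrix(v)
  if (ncol(v) != 2L) stop("'v' must have two columns (vx, vy)")
  p <- integrate_velocity(v, origin = origin, fs = fs)
  structure(list(vx = v[, 1L], vy = v[, 2L], x = p[, 1L], y = p[, 2L],
                 fs = fs, origin = origin),
            class = "kinematic_series")
}

#' @export
print.kinematic_series <- function(x, ...) {
  cat(sprintf("Kinematic series: %d samples at %g Hz (%.2f s), start (%.2f, %.2f)\n",
              length(x$vx), x$fs, length(x$vx) / x$fs,
              x$origin[1L], x$origin[2L]))
  invisible(x)
}

#' @export
plot.kinematic_series <- function(x, what = c("trajectory", "velocity"), ...) {
  what <- match.arg(what)
  if (what == "trajectory") {
    graphics::plot(x$x, x$y, type = "l", asp = 1, xlab = "x", ylab = "y", ...)
    graphics::points(x$origin[1L], x$origin[2L], pch = 16, col = "darkgreen")
  } else {
    t <- (seq_along(x$vx) - 1L) / x$fs
    graphics::matplot(t, cbind(x$vx, x$vy), type = "l", lty = 1L,
                      xlab = "time (s)", ylab = "velocity", ...)
  }
  invisible(x)
}

#' Velocity matrix of a kinematic series
#'
#' @param series a [kinematic_series()].
#' @return n x 2 matrix with columns vx, vy.
#' @export
velocity_matrix <- function(series) {
  cbind(series$vx, series$vy)
}

#' Integrate velocity into position
#'
#' Cumulative sum times the sample period, starting from `origin`:
#' `p[k] = origin + sum(v[1:k]) / fs`.
#'
#' @param v n x d velocity matrix (or vector) in units/s, or a
#'   [kinematic_series()].
#' @param origin start position (length d).
#' @param fs sampling rate in Hz.
#' @return n x d position matrix.
#' @export
integrate_velocity <- function(v, origin = NULL, fs = 20) {
  if (inherits(v, "kinematic_series")) {
    if (is.null(origin)) origin <- v$origin
    fs <- v$fs
    v <- velocity_matrix(v)
  }
  v <- as.matrix(v)
  if (is.null(origin)) origin <- rep(0, ncol(v))
  p <- apply(v, 2L, cumsum) / fs
  p <- matrix(p, nrow = nrow(v))
  sweep(p, 2L, origin, "+")
}

#' Differentiate position into velocity
#'
#' Inverse of [integrate_velocity()] under the same convention:
#' `v[k] = (p[k] - p[k-1]) * fs` with `p[0] = origin`.
#'
#' @param p n x d position matrix.
#' @param origin position preceding the first sample (defaults to `p[1, ]`,
#'   making the first velocity zero).
#' @param fs sampling rate in Hz.
#' @return n x d velocity matrix.
#' @export
differentiate_position <- function(p, origin = NULL, fs = 20) {
  p <- as.matrix(p)
  if (is.null(origin)) origin <- p[1L, ]
  rbind(p[1L, ] - origin, diff(p)) * fs
}
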