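# Sagittal-plane spinal geometry.  A traced spinal curve (C7 down to S1,
# with the T12 landmark identified along it) is resampled to equidistant
# points and summarised by signed inter-segment turn angles; pelvic tilt is
# the angle of the PSIS->ASIS line to the horizontal.
#
# Coordinate convention: x = anterior-posterior (anterior positive),
# y = vertical (up positive).  Sign convention for turn angles: positive =
# flexion (curve convex posteriorly); mirroring the curve about a vertical
# axis flips every sign.

#' Construct a sagittal spinal curve
#'
#' An ordered polyline of sagittal-plane points running head-to-sacrum from
#' the C7 landmark (first point) to the S1 landmark (last point), with the
#' index of the point closest to the T12 landmark identified.
#'
#' @param x,y Numeric coordinate vectors (anterior-posterior, vertical), in
#'   any consistent length unit; `y` must be strictly decreasing.
#' @param t12_index Index of the vertex closest to T12; must be strictly
#'   between the first and last point.
#' @return An object of class `"spinal_curve"`.
#' @export
spinal_curve <- function(x, y, t12_index = NULL) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y))
  if (length(x) < 3L) stop("a spinal curve needs >= 3 points", call. = FALSE)
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stop("curve coordinates must be finite", call. = FALSE)
  }
  if (any(diff(y) >= 0)) {
    stop("vertical coordinate must be strictly decreasing (C7 first, S1 last)",
         call. = FALSE)
  }
  if (!is.null(t12_index)) {
    t12_index <- as.integer(t12_index)
    if (t12_index <= 1L || t12_index >= length(x)) {
      stop("t12_index must lie strictly between C7 and S1", call. = FALSE)
    }
  }
  structure(list(x = as.numeric(x), y = as.numeric(y),
                 t12_index = t12_index),
            class = "spinal_curve")
}

#' @export
print.spinal_curve <- function(x, ...) {
  cat("Spinal curve: ", length(x$x), " points, vertical span ",
      round(x$y[1] - x$y[length(x$y)], 2), sep = "")
  if (!is.null(x$t12_index)) cat(", T12 at point ", x$t12_index, sep = "")
  cat("\n")
  invisible(x)
}

# cumulative arc length along a polyline
arc_lengths <- function(x, y) {
  c(0, cumsum(sqrt(diff(x)^2 + diff(y)^2)))
}

# interpolate a polyline at arc-length positions s
interp_at <- function(x, y, s_nodes, s) {
  list(x = stats::approx(s_nodes, x, xout = s, rule = 2)$y,
       y = stats::approx(s_nodes, y, xout = s, rule = 2)$y)
}

#' Resample a curve to equidistant points
#'
#' Places `n_points` points at equal arc-length spacing along the
#' piecewise-linear input curve, preserving the first and last points.
#'
#' @param curve A [spinal_curve()].
#' @param n_points Number of output points, at least 3.
#' @return A [spinal_curve()] with `n_points` points.  The T12 index, if
#'   set on the input, is mapped to the resampled vertex nearest to the
#'   original T12 arc-length position.
#' @export
resample_equidistant <- function(curve, n_points) {
  stopifnot(inherits(curve, "spinal_curve"))
  n_points <- as.integer(n_points)
  if (is.na(n_points) || n_points < 3L) {
    stop("n_points must be >= 3", call. = FALSE)
  }
  s <- arc_lengths(curve$x, curve$y)
  total <- s[length(s)]
  if (total <= 0) stop("degenerate zero-length curve", call. = FALSE)
  grid <- seq(0, total, length.out = n_points)
  pts <- interp_at(curve$x, curve$y, s, grid)
  t12 <- NULL
  if (!is.null(curve$t12_index)) {
    t12 <- which.min(abs(grid - s[curve$t12_index]))
    t12 <- min(max(t12, 2L), n_points - 1L)
  }
  spinal_curve(pts$x, pts$y, t12_index = t12)
}

# signed turn angles (degrees) at the interior vertices of a polyline;
# positive where the curve turns toward posterior convexity (flexion)
turn_angles <- function(x, y) {
  dx <- diff(x); dy <- diff(y)
  n <- length(dx)
  a <- numeric(n - 1L)
  for (i in seq_len(n - 1L)) {
    cross <- dx[i] * dy[i + 1L] - dy[i] * dx[i + 1L]
    dot <- dx[i] * dx[i + 1L] + dy[i] * dy[i + 1L]
    a[i] <- atan2(cross, dot) * 180 / pi
  }
  a
}

#' Regional curvature angles from a spinal curve
#'
#' Resamples the curve to 20 equidistant points constrained so that T12
#' falls exactly on a resampled vertex — 13 equidistant points span C7 to
#' T12 and 8 span T12 to S1, sharing the T12 vertex — giving 19 segments
#' and 18 interior turn angles.  The thoracic curvature is the sum of the
#' first 12 turn angles (C7 span, including the angle at the T12 vertex)
#' and the lumbar curvature the sum of the remaining 6.  Positive sums
#' indicate flexion (posterior convexity), negative extension.
#'
#' @param curve A [spinal_curve()] with `t12_index` set.
#' @return A list of class `"regional_angles"` with elements `angles`
#'   (the 18 signed turn angles, degrees), `thoracic_sum` and `lumbar_sum`
#'   (degrees).
#' @export
regional_curvature <- function(curve) {
  stopifnot(inherits(curve, "spinal_curve"))
  if (is.null(curve$t12_index)) {
    stop("regional_curvature() needs a curve with t12_index set",
         call. = FALSE)
  }
  i <- curve$t12_index
  n <- length(curve$x)
  s <- arc_lengths(curve$x, curve$y)
  if (s[i] <= 0 || s[n] - s[i] <= 0) {
    stop("T12 coincides with C7 or S1; regional split undefined",
         call. = FALSE)
  }
  # piecewise-equidistant resampling with T12 pinned on the shared vertex
  upper <- interp_at(curve$x, curve$y, s, seq(0, s[i], length.out = 13L))
  lower <- interp_at(curve$x, curve$y, s, seq(s[i], s[n], length.out = 8L))
  px <- c(upper$x, lower$x[-1L])
  py <- c(upper$y, lower$y[-1L])
  ang <- turn_angles(px, py)
  stopifnot(length(ang) == 18L)
  structure(
    list(angles = ang,
         thoracic_sum = sum(ang[1:12]),
         lumbar_sum = sum(ang[13:18])),
    class = "regional_angles"
  )
}

#' @export
print.regional_angles <- function(x, ...) {
  cat(sprintf("Regional curvature: thoracic %+.2f deg, lumbar %+.2f deg\n",
              x$thoracic_sum, x$lumbar_sum))
  invisible(x)
}

#' Sagittal pelvic tilt angle
#'
#' The signed angle between the PSIS-to-ASIS line and the horizontal,
#' positive for anterior tilt (ASIS below PSIS), in `(-90, 90]` degrees.
#'
#' @param asis,psis Length-2 numeric vectors `(x, y)`: the anterior and
#'   posterior superior iliac spine points in the sagittal plane (anterior
#'   positive `x`, up positive `y`).
#' @return Angle in degrees.
#' @examples
#' pelvic_angle(asis = c(1, -1), psis = c(0, 0))  # 45 (anterior tilt)
#' @export
pelvic_angle <- function(asis, psis) {
  stopifnot(is.numeric(asis), is.numeric(psis),
            length(asis) == 2L, length(psis) == 2L,
            all(is.finite(asis)), all(is.finite(psis)))
  d <- asis - psis
  if (all(d == 0)) stop("ASIS and PSIS coincide", call. = FALSE)
  if (abs(d[1]) < 1e-12 * max(1, abs(d[2]))) {
    stop("ASIS and PSIS are vertically aligned; tilt direction undefined",
         call. = FALSE)
  }
  # angle of the line to the horizontal; anterior (downward ASIS) positive
  atan(-d[2] / abs(d[1])) * 180 / pi
}

#' Read sagittal marker/trace data
#'
#' Parses delimited text with columns `frame,label,x,y` (coordinates in
#' millimetres).  Recognised labels: `C7`, `T12`, `S1` (vertebral
#' landmarks), `ASIS`, `PSIS` (pelvis), and `SW` for the spinal-wheel trace
#' points in head-to-sacrum order.
#'
#' @param path File path.
#' @param frame Frame number to extract (default: first frame present).
#' @return A list with elements `curve` (a [spinal_curve()] built from the
#'   C7, SW..., S1 points, with `t12_index` at the trace point closest to
#'   the T12 marker) and `pelvis` (list with `asis`, `psis` points, or
#'   `NULL` if absent).
#' @export
read_marker_curve <- function(path, frame = NULL) {
  df <- utils::read.csv(path, check.names = FALSE)
  need <- c("frame", "label", "x", "y")
  if (!all(need %in% names(df))) {
    stop("marker file needs columns frame,label,x,y", call. = FALSE)
  }
  if (is.null(frame)) frame <- df$frame[1]
  df <- df[df$frame == frame, ]
  pick <- function(lab) {
    r <- df[df$label == lab, , drop = FALSE]
    if (nrow(r) == 0L) return(NULL)
    c(r$x[1], r$y[1])
  }
  c7 <- pick("C7"); s1 <- pick("S1"); t12 <- pick("T12")
  if (is.null(c7) || is.null(s1) || is.null(t12)) {
    stop("marker file must contain C7, T12 and S1 labels", call. = FALSE)
  }
  sw <- df[df$label == "SW", , drop = FALSE]
  px <- c(c7[1], sw$x, s1[1])
  py <- c(c7[2], sw$y, s1[2])
  d2 <- (px - t12[1])^2 + (py - t12[2])^2
  curve <- spinal_curve(px, py, t12_index = which.min(d2))
  pelvis <- NULL
  asis <- pick("ASIS"); psis <- pick("PSIS")
  if (!is.null(asis) && !is.null(psis)) {
    pelvis <- list(asis = asis, psis = psis)
  }
  list(curve = curve, pelvis = pelvis)
}
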