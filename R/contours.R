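# Contour geometry: smoothing, resampling, rasterization.
#
# All coordinates are 0-based (x = column, y = row, y down); integer
# coordinates sit at pixel centres, so pixel [r, c] of an R matrix
# (1-based) has centre (c - 1, r - 1).

#' Signed polygon area (shoelace)
#'
#' Positive sign corresponds to the package's canonical vertex order
#' (counter-clockwise in the y-down image frame as drawn on screen).
#'
#' @param pts n x 2 matrix of (x, y) vertices, closed implicitly.
#' @return signed area in px^2.
#' @export
polygonArea <- function(pts) {
  x <- pts[, 1]; y <- pts[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

# enforce canonical (positive-shoelace) vertex order
ensureCanonicalOrder <- function(pts) {
  if (polygonArea(pts) < 0) pts[rev(seq_len(nrow(pts))), , drop = FALSE]
  else pts
}

# fold an angle in degrees into (-90, 90]
foldAngle <- function(a) {
  a <- a %% 180
  ifelse(a > 90, a - 180, a)
}

#' Smooth a closed contour by periodic cubic spline interpolation
#'
#' Manual ROI delineations are jagged; the boundary is smoothed by fitting an
#' interpolating periodic cubic spline through the vertices (parameterized by
#' cumulative chord length) and resampling it at `nOut` points at uniform
#' parameter spacing. With zero smoothing the curve passes through every
#' input vertex.
#'
#' @param points n x 2 matrix of (x, y) contour vertices, n >= 4 distinct,
#'   closed implicitly (do not repeat the first point).
#' @param nOut number of output points; defaults to 4x the input count.
#' @return nOut x 2 matrix tracing the smoothed closed contour.
#' @examples
#' th <- seq(0, 2 * pi, length.out = 17)[-17]
#' circ <- cbind(100 + 50 * cos(th), 100 + 50 * sin(th))
#' sm <- smoothContour(circ, 200)
#' @export
smoothContour <- function(points, nOut = 4L * nrow(points)) {
  points <- as.matrix(points)
  if (nrow(points) >= 2 && all(points[1, ] == points[nrow(points), ]))
    points <- points[-nrow(points), , drop = FALSE]
  if (nrow(unique(points)) < 4L)
    stop("smoothContour: need at least 4 distinct points")
  if (abs(polygonArea(points)) < sqrt(.Machine$double.eps))
    stop("smoothContour: degenerate (zero-area) contour")
  if (nOut < 3L) stop("smoothContour: nOut must be >= 3")
  closed <- rbind(points, points[1, ])
  seg <- sqrt(rowSums(diff(closed)^2))
  if (any(seg == 0)) {
    keep <- c(TRUE, seg[-length(seg)] > 0)
    points <- points[keep, , drop = FALSE]
    closed <- rbind(points, points[1, ])
    seg <- sqrt(rowSums(diff(closed)^2))
  }
  tknot <- c(0, cumsum(seg))
  L <- tknot[length(tknot)]
  tout <- seq(0, L, length.out = nOut + 1L)[-(nOut + 1L)]
  sx <- spline(tknot, closed[, 1], method = "periodic", xout = tout)$y
  sy <- spline(tknot, closed[, 2], method = "periodic", xout = tout)$y
  cbind(x = sx, y = sy)
}

#' Resample a closed polyline at uniform arc length
#'
#' @param pts n x 2 closed polyline (first point not repeated).
#' @param n number of output points.
#' @return n x 2 matrix; point 1 coincides with input point 1.
#' @export
resampleArc <- function(pts, n = 256L) {
  closed <- rbind(pts, pts[1, ])
  seg <- sqrt(rowSums(diff(closed)^2))
  s <- c(0, cumsum(seg))
  L <- s[length(s)]
  sout <- seq(0, L, length.out = n + 1L)[-(n + 1L)]
  cbind(x = approx(s, closed[, 1], xout = sout)$y,
        y = approx(s, closed[, 2], xout = sout)$y)
}

# polyline length of a closed contour
contourPerimeter <- function(pts) {
  closed <- rbind(pts, pts[1, ])
  sum(sqrt(rowSums(diff(closed)^2)))
}

#' Rasterize a closed contour into a binary mask
#'
#' A pixel belongs to the region iff its centre lies inside the polygon under
#' the even-odd rule (scanline crossing test, half-open so results are
#' deterministic on edges). Contours extending beyond the frame are clipped
#' with a warning.
#'
#' @param contour n x 2 matrix of (x, y) vertices in 0-based coordinates.
#' @param shape integer (H, W) of the target frame.
#' @return logical H x W matrix.
#' @export
rasterizeRegion <- function(contour, shape) {
  H <- as.integer(shape[1]); W <- as.integer(shape[2])
  mask <- matrix(FALSE, H, W)
  P <- as.matrix(contour)
  if (nrow(P) < 3L) stop("rasterizeRegion: contour needs >= 3 points")
  if (any(P[, 1] < 0 | P[, 1] > W - 1 | P[, 2] < 0 | P[, 2] > H - 1))
    warning("rasterizeRegion: contour extends beyond the frame; clipped")
  x1 <- P[, 1]; y1 <- P[, 2]
  x2 <- c(x1[-1], x1[1]); y2 <- c(y1[-1], y1[1])
  rlo <- max(0L, floor(min(y1))); rhi <- min(H - 1L, ceiling(max(y1)))
  if (rlo > rhi) return(mask)
  for (y in rlo:rhi) {
    up <- (y1 <= y & y2 > y) | (y2 <= y & y1 > y)
    if (!any(up)) next
    xs <- x1[up] + (y - y1[up]) / (y2[up] - y1[up]) * (x2[up] - x1[up])
    xs <- sort(xs)
    for (i in seq(1L, length(xs) - 1L, by = 2L)) {
      c0 <- max(0L, ceiling(xs[i]))
      c1 <- min(W - 1L, ceiling(xs[i + 1L]) - 1L)
      if (c0 <= c1) mask[y + 1L, (c0:c1) + 1L] <- TRUE
    }
  }
  mask
}
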