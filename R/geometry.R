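#' Polygon area of an outline
#'
#' Shoelace area of the closed polygon, in square micrometres. Invariant to
#' rotation, translation and cyclic shift of the vertex order.
#'
#' @param outline An [outline()].
#' @return Positive area (um^2).
#' @export
polygon_area <- function(outline) {
  abs(signed_area(unclass(outline)))
}

#' Perimeter of an outline
#'
#' @param outline An [outline()].
#' @return Perimeter length (um).
#' @export
perimeter <- function(outline) {
  xy <- unclass(outline)
  j <- c(2:nrow(xy), 1)
  sum(sqrt((xy[j, 1] - xy[, 1])^2 + (xy[j, 2] - xy[, 2])^2))
}

#' Resample an outline to equal arc-length spacing
#'
#' Places `n_points` vertices equally spaced in arc length along the closed
#' polygon, starting at the first vertex. Manual tracing produces wildly
#' uneven vertex density; fixed-density resampling removes that nuisance
#' before any measurement or Fourier analysis.
#'
#' @param outline An [outline()].
#' @param n_points Number of vertices (>= 8).
#' @return A resampled `outline` with the same label.
#' @export
resample <- function(outline, n_points = 300L) {
  stopifnot(n_points >= 8)
  xy <- unclass(outline)
  n <- nrow(xy)
  closed <- rbind(xy, xy[1, ])
  seg <- sqrt(diff(closed[, 1])^2 + diff(closed[, 2])^2)
  s <- c(0, cumsum(seg))
  total <- s[n + 1]
  if (total <= 0) stop("cannot resample a zero-perimeter outline", call. = FALSE)
  at <- seq(0, total, length.out = n_points + 1)[-(n_points + 1)]
  newx <- stats::approx(s, closed[, 1], xout = at, ties = "ordered")$y
  newy <- stats::approx(s, closed[, 2], xout = at, ties = "ordered")$y
  outline(newx, newy, label = attr(outline, "label"),
          border = attr(outline, "border"), validate = FALSE)
}

#' Convex hull of an outline
#'
#' Smallest convex polygon containing the outline; the "rubber band" whose
#' area enters the solidity descriptor. Vertices are a subset of the input
#' vertices, in counter-clockwise order.
#'
#' @param outline An [outline()].
#' @return An `outline` holding the hull.
#' @export
convex_hull <- function(outline) {
  xy <- unclass(outline)
  idx <- grDevices::chull(xy[, 1], xy[, 2])
  if (length(idx) < 3) {
    stop("degenerate outline: convex hull is not two-dimensional", call. = FALSE)
  }
  outline(xy[idx, 1], xy[idx, 2], label = attr(outline, "label"),
          validate = FALSE)
}

#' Principal-axis extents of an outline
#'
#' Aligns the outline to the principal axis of its vertex covariance (after
#' equal arc-length resampling, so vertex density cannot bias the axis) and
#' returns the coordinate extents along and across that axis. `width /
#' length` is the aspect-ratio descriptor: 1 for an isotropic shape,
#' approaching 0 for elongate cells. The maximum-Feret-chord alternative is
#' available via `method = "feret"` (a 2 x 1 rectangle then no longer gives
#' AR exactly 0.5, which is why covariance alignment is the default).
#'
#' @param outline An [outline()].
#' @param n_points Resampling density used for the covariance axis.
#' @param method `"covariance"` (default) or `"feret"`.
#' @return A list with `length`, `width` (length >= width), `angle` of the
#'   major axis in radians, and `isotropic` (TRUE when the eigenvalue tie
#'   made the angle conventionally 0).
#' @export
principal_extents <- function(outline, n_points = 360L,
                              method = c("covariance", "feret")) {
  method <- match.arg(method)
  xy <- unclass(resample(outline, n_points))
  xy <- sweep(xy, 2, colMeans(xy))
  if (method == "feret") {
    # maximum chord defines the length axis
    d2 <- as.matrix(stats::dist(xy))^2
    ij <- which(d2 == max(d2), arr.ind = TRUE)[1, ]
    v <- xy[ij[2], ] - xy[ij[1], ]
    ang <- atan2(v[2], v[1])
    iso <- FALSE
  } else {
    cv <- stats::cov(xy)
    eg <- eigen(cv, symmetric = TRUE)
    iso <- eg$values[1] / max(eg$values[2], .Machine$double.xmin) < 1 + 1e-9
    ang <- if (iso) 0 else atan2(eg$vectors[2, 1], eg$vectors[1, 1])
  }
  al <- rotate_xy(xy, -ang)
  len <- diff(range(al[, 1]))
  wid <- diff(range(al[, 2]))
  if (wid > len) {           # covariance axis can land on the minor side only
    tmp <- len; len <- wid; wid <- tmp   # for near-ties; keep length >= width
    ang <- ang + pi / 2
  }
  list(length = len, width = wid, angle = ang %% pi, isotropic = iso)
}
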