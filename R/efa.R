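#' Elliptic Fourier analysis of a closed outline
#'
#' Decomposes a closed outline into a sum of harmonic ellipses using the
#' classical closed-form coefficients over the polyline arc-length
#' parameterization: for harmonic `n`,
#' `a_n, b_n` describe the x(t) projection and `c_n, d_n` the y(t)
#' projection. Before the transform the outline is aligned along its longest
#' radius by default: the vertex farthest from the centroid is rotated onto
#' the positive x-axis (`align = "covariance"` uses the principal axis
#' instead; `"none"` skips alignment).
#'
#' @param outline An [outline()], ideally resampled to equal arc spacing.
#' @param n_harmonics Number of harmonics (1 to `floor(n_points / 2) - 1`).
#' @param align Pre-alignment rule; see Details.
#' @return An object of class `efa`: list with `coef` (n_harmonics x 4
#'   matrix, columns `a`, `b`, `c`, `d`), offsets `A0`, `C0`, flag
#'   `normalized`, and the source perimeter `T`.
#' @export
efa_forward <- function(outline, n_harmonics = 20L,
                        align = c("longest_radius", "covariance", "none")) {
  align <- match.arg(align)
  xy <- unclass(outline)
  m <- nrow(xy)
  if (n_harmonics < 1 || n_harmonics > floor(m / 2) - 1) {
    stop("n_harmonics must be in [1, floor(n_points/2) - 1] = [1, ",
         floor(m / 2) - 1, "]", call. = FALSE)
  }
  ctr <- colMeans(xy)
  cxy <- sweep(xy, 2, ctr)
  if (align == "longest_radius") {
    r2 <- rowSums(cxy^2)
    v <- cxy[which.max(r2), ]
    ang <- atan2(v[2], v[1])
    cxy <- rotate_xy(cxy, -ang)
  } else if (align == "covariance") {
    eg <- eigen(stats::cov(cxy), symmetric = TRUE)
    ang <- atan2(eg$vectors[2, 1], eg$vectors[1, 1])
    cxy <- rotate_xy(cxy, -ang)
  }
  # segment p joins vertex p-1 -> p, with segment 1 closing from vertex m
  dx <- cxy[, 1] - cxy[c(m, 1:(m - 1)), 1]
  dy <- cxy[, 2] - cxy[c(m, 1:(m - 1)), 2]
  dt <- sqrt(dx^2 + dy^2)
  if (any(dt == 0)) stop("outline has zero-length segments", call. = FALSE)
  t1 <- cumsum(dt)
  t0 <- c(0, t1[-m])
  Tt <- t1[m]
  n <- seq_len(n_harmonics)
  w <- 2 * pi * outer(t1, n) / Tt        # m x N phase at segment ends
  w0 <- 2 * pi * outer(t0, n) / Tt
  konst <- Tt / (2 * n^2 * pi^2)
  dcos <- cos(w) - cos(w0)
  dsin <- sin(w) - sin(w0)
  a <- konst * colSums(dx / dt * dcos)
  b <- konst * colSums(dx / dt * dsin)
  cc <- konst * colSums(dy / dt * dcos)
  d <- konst * colSums(dy / dt * dsin)
  structure(list(coef = cbind(a = a, b = b, c = cc, d = d),
                 A0 = ctr[1], C0 = ctr[2], normalized = FALSE, T = Tt),
            class = "efa")
}

# rotate row-vector coordinates by ang radians (counter-clockwise)
rotate_xy <- function(xy, ang) {
  xy %*% cbind(c(cos(ang), -sin(ang)), c(sin(ang), cos(ang)))
}

#' @export
print.efa <- function(x, ...) {
  cat(sprintf("<efa> %d harmonics%s\n", nrow(x$coef),
              if (x$normalized) ", normalized" else ""))
  invisible(x)
}

#' Normalize elliptic Fourier coefficients by the first harmonic
#'
#' Removes size, rotation and starting-point dependence using the first
#' harmonic ellipse: the starting point is rotated to the end of the first
#' semi-major axis, the coefficient frame is rotated onto that axis, and all
#' coefficients are divided by its magnitude, leaving `a_1 = 1`,
#' `b_1 = c_1 = 0` up to numerical tolerance. The half-period ambiguity of
#' the construction (which end of the major axis starts the ellipse) is
#' resolved by a deterministic lexicographic rule on the coefficient vector,
#' so two copies of one outline differing by rotation and start vertex
#' normalize identically. Reflection is *not* quotiented away: mirroring an
#' outline changes its normalized coefficients.
#'
#' @param x An unnormalized `efa` object.
#' @return A normalized `efa` object (offsets reset to 0).
#' @export
efa_normalize <- function(x) {
  stopifnot(inherits(x, "efa"))
  if (x$normalized) return(x)
  cf <- x$coef
  a1 <- cf[1, 1]; b1 <- cf[1, 2]; c1 <- cf[1, 3]; d1 <- cf[1, 4]
  if (a1^2 + b1^2 + c1^2 + d1^2 < 1e-20) {
    stop("degenerate first harmonic: cannot normalize", call. = FALSE)
  }
  theta <- 0.5 * atan2(2 * (a1 * b1 + c1 * d1),
                       a1^2 + c1^2 - b1^2 - d1^2)
  cand <- lapply(c(theta, theta + pi), function(th) normalize_at(cf, th))
  # deterministic tie-break between the two major-axis starting points:
  # take the candidate whose first coefficient differing beyond numerical
  # noise is the larger one
  d <- as.vector(t(cand[[1]])) - as.vector(t(cand[[2]]))
  i <- which(abs(d) > 1e-9)[1]
  cf2 <- if (is.na(i) || d[i] > 0) cand[[1]] else cand[[2]]
  structure(list(coef = cf2, A0 = 0, C0 = 0, normalized = TRUE, T = x$T),
            class = "efa")
}

normalize_at <- function(cf, theta) {
  n <- seq_len(nrow(cf))
  cn <- cos(n * theta); sn <- sin(n * theta)
  # start-point shift: [a b; c d] %*% [cos -sin; sin cos] per harmonic
  a <- cf[, 1] * cn + cf[, 2] * sn
  b <- -cf[, 1] * sn + cf[, 2] * cn
  cc <- cf[, 3] * cn + cf[, 4] * sn
  d <- -cf[, 3] * sn + cf[, 4] * cn
  psi <- atan2(cc[1], a[1])
  E <- sqrt(a[1]^2 + cc[1]^2)
  cp <- cos(psi); sp <- sin(psi)
  # frame rotation: [cos sin; -sin cos] %*% [a b; c d], then scale by 1/E
  cbind(a = (cp * a + sp * cc) / E, b = (cp * b + sp * d) / E,
        c = (-sp * a + cp * cc) / E, d = (-sp * b + cp * d) / E)
}

#' Per-harmonic power spectrum
#'
#' Power of harmonic `n` is `(a_n^2 + b_n^2 + c_n^2 + d_n^2) / 2`; the
#' cumulative fraction guides how many harmonics suffice to describe an
#' outline.
#'
#' @param x An `efa` object.
#' @return A tibble: `harmonic`, `power`, `cumulative` (fraction of total).
#' @export
harmonic_power <- function(x) {
  stopifnot(inherits(x, "efa"))
  p <- rowSums(x$coef^2) / 2
  tibble::tibble(harmonic = seq_along(p), power = p,
                 cumulative = cumsum(p) / sum(p))
}

#' Smallest harmonic count reaching a cumulative power threshold
#'
#' @param x An `efa` object fitted at high harmonic count (e.g. 50).
#' @param threshold Cumulative power fraction in (0, 1); default 0.999.
#' @return Integer harmonic count.
#' @export
select_harmonics <- function(x, threshold = 0.999) {
  if (!is.numeric(threshold) || threshold <= 0 || threshold >= 1) {
    stop("threshold must be in (0, 1)", call. = FALSE)
  }
  hp <- harmonic_power(x)
  which(hp$cumulative > threshold)[1]
}

#' Inverse elliptic Fourier synthesis
#'
#' Reconstructs an outline from its coefficients. With one harmonic the
#' result is an ellipse; the reconstruction converges to the source outline
#' as the harmonic count grows.
#'
#' @param x An `efa` object.
#' @param n_points Number of reconstruction vertices.
#' @return An [outline()].
#' @export
efa_inverse <- function(x, n_points = 300L) {
  stopifnot(inherits(x, "efa"))
  tt <- seq(0, 1, length.out = n_points + 1)[-(n_points + 1)]
  n <- seq_len(nrow(x$coef))
  cosm <- cos(2 * pi * outer(tt, n))
  sinm <- sin(2 * pi * outer(tt, n))
  px <- x$A0 + cosm %*% x$coef[, 1] + sinm %*% x$coef[, 2]
  py <- x$C0 + cosm %*% x$coef[, 3] + sinm %*% x$coef[, 4]
  outline(as.vector(px), as.vector(py), label = "efa reconstruction",
          validate = FALSE)
}

#' Reconstruction error of a truncated harmonic series
#'
#' Mean nearest-vertex distance from the N-harmonic reconstruction to the
#' source outline, after centring both, expressed as a fraction of the
#' source's mean centroid radius. The transform is run unaligned so source
#' and reconstruction share a frame (the error itself is
#' rotation-equivariant, so alignment would not change it).
#'
#' @param outline Source [outline()] (resampled).
#' @param n_harmonics Harmonic count of the reconstruction.
#' @return Relative error (dimensionless).
#' @export
efa_reconstruction_error <- function(outline, n_harmonics) {
  src <- unclass(outline)
  src <- sweep(src, 2, colMeans(src))
  cf <- efa_forward(outline, n_harmonics, align = "none")
  rec <- unclass(efa_inverse(cf, nrow(src)))
  rec <- sweep(rec, 2, colMeans(rec))
  d2 <- outer(rowSums(rec^2), rowSums(src^2), "+") - 2 * rec %*% t(src)
  nearest <- sqrt(pmax(apply(d2, 1, min), 0))
  mean(nearest) / mean(sqrt(rowSums(src^2)))
}

#' Tidy elliptic Fourier coefficients
#'
#' @param x An `efa` object.
#' @param ... Unused.
#' @return A tibble: `harmonic`, `a`, `b`, `c`, `d`, `normalized`.
#' @export
tidy.efa <- function(x, ...) {
  tibble::tibble(harmonic = seq_len(nrow(x$coef)),
                 a = x$coef[, 1], b = x$coef[, 2],
                 c = x$coef[, 3], d = x$coef[, 4],
                 normalized = x$normalized)
}
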