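#' Read a binary segmentation mask
#'
#' Accepts PNG or TIFF with exactly two distinct pixel values; the greater
#' value is foreground unless `invert = TRUE`. Multi-channel images are
#' collapsed by their first channel.
#'
#' @param path Image file (`.png`, `.tif`, `.tiff`).
#' @param invert Treat the smaller pixel value as foreground.
#' @return Logical matrix, `TRUE` = foreground, rows = image rows.
#' @export
read_mask <- function(path, invert = FALSE) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported mask format: .", ext, " (use PNG or TIFF)", call. = FALSE))
  if (length(dim(img)) == 3) img <- img[, , 1]
  as_binary_mask(img, invert = invert)
}

# validate the two-valued constraint and return a logical matrix
as_binary_mask <- function(img, invert = FALSE) {
  if (is.logical(img)) return(if (invert) !img else img)
  vals <- sort(unique(as.vector(img)))
  if (length(vals) > 2) {
    stop("mask is not two-valued; found pixel values: ",
         paste(utils::head(signif(vals, 6), 8), collapse = ", "),
         if (length(vals) > 8) ", ..." else "", call. = FALSE)
  }
  fg <- vals[length(vals)]
  m <- img == fg
  if (length(vals) == 1) m[] <- FALSE   # uniform image: treat as empty
  if (invert) m <- !m
  m
}

#' Trace cell outlines from a binary mask
#'
#' Labels 4-connected foreground components and traces each component's
#' outer boundary along pixel *edges* (the crack contour), so a k x k pixel
#' square yields polygon area exactly k^2 px^2 - the unbiased convention for
#' small objects. Coordinates are scaled to micrometres; components touching
#' the image border are kept but flagged (and excluded by downstream
#' summaries by default); components below `min_area` pixels are dropped as
#' speckle.
#'
#' @param mask Logical/two-valued matrix, or a PNG/TIFF path.
#' @param scale Micrometres per pixel (> 0).
#' @param min_area Minimum component size in px^2 (default 50, suppresses
#'   segmentation speckle).
#' @param invert Passed to [read_mask()] when `mask` is a path.
#' @return A list of [outline()] objects (possibly empty), labels
#'   `"cell_<k>"` with `" [border]"` components flagged via the `border`
#'   attribute.
#' @export
trace_outlines <- function(mask, scale = 1, min_area = 50, invert = FALSE) {
  stopifnot(is.numeric(scale), length(scale) == 1, scale > 0, min_area >= 0)
  if (is.character(mask)) mask <- read_mask(mask, invert = invert)
  mask <- as_binary_mask(mask)
  if (!any(mask)) return(list())
  lab <- EBImage::bwlabel(mask * 1L)
  lab <- matrix(as.integer(lab), nrow = nrow(mask))
  nlab <- max(lab)
  counts <- tabulate(lab[lab > 0L], nbins = nlab)
  out <- list()
  for (k in seq_len(nlab)) {
    if (counts[k] < min_area) next
    comp <- lab == k
    pix <- which(comp, arr.ind = TRUE)
    border <- any(pix[, 1] == 1L | pix[, 1] == nrow(mask) |
                  pix[, 2] == 1L | pix[, 2] == ncol(mask))
    xy <- crack_contour(comp)
    # flip to y-up image coordinates, then scale to micrometres
    xy[, 2] <- nrow(mask) - xy[, 2]
    out[[length(out) + 1L]] <- outline(
      xy[, 1] * scale, xy[, 2] * scale,
      label = sprintf("cell_%d", length(out) + 1L),
      border = border, validate = FALSE)
  }
  out
}

# Outer crack contour of one pixel component.
# comp: logical matrix with the component's pixels TRUE. Returns lattice
# vertices (x = column units, y = row units, y increasing downwards) of the
# largest boundary loop, collinear runs collapsed. Every exposed pixel side
# is emitted as a directed edge (clockwise per pixel cell in screen
# coordinates); shared sides cancel, so chaining the survivors yields closed
# loops. At pinch corners (diagonally self-touching component, two outgoing
# edges) the clockwise turn - towards the component interior - is taken, so
# the trace stays on the local pixel and the outer loop never splits.
crack_contour <- function(comp) {
  nr <- nrow(comp); nc <- ncol(comp)
  pad <- matrix(FALSE, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- comp
  up <- pad[1:nr, 2:(nc + 1L)]
  dn <- pad[3:(nr + 2L), 2:(nc + 1L)]
  lf <- pad[2:(nr + 1L), 1:nc]
  rt <- pad[2:(nr + 1L), 3:(nc + 2L)]
  fx <- integer(0); fy <- integer(0); tx <- integer(0); ty <- integer(0)
  add <- function(which_pix, dfx, dfy, dtx, dty) {
    if (!nrow(which_pix)) return()
    r <- which_pix[, 1]; cc <- which_pix[, 2]
    fx <<- c(fx, cc + dfx); fy <<- c(fy, r + dfy)
    tx <<- c(tx, cc + dtx); ty <<- c(ty, r + dty)
  }
  add(which(comp & !up, arr.ind = TRUE), -1L, -1L, 0L, -1L)  # top: L -> R
  add(which(comp & !rt, arr.ind = TRUE), 0L, -1L, 0L, 0L)    # right: T -> B
  add(which(comp & !dn, arr.ind = TRUE), 0L, 0L, -1L, 0L)    # bottom: R -> L
  add(which(comp & !lf, arr.ind = TRUE), -1L, 0L, -1L, -1L)  # left: B -> T
  m <- length(fx)
  W <- nc + 2L
  by_from <- split(seq_len(m), fy * W + fx)
  used <- logical(m)
  loops <- list()
  for (s in seq_len(m)) {
    if (used[s]) next
    px <- integer(0); py <- integer(0)
    cur <- s
    repeat {
      used[cur] <- TRUE
      px <- c(px, fx[cur]); py <- c(py, fy[cur])
      cand <- by_from[[as.character(ty[cur] * W + tx[cur])]]
      if (length(cand) > 1L) {
        # pinch: rank by turn preference cw > straight > ccw
        dx <- tx[cur] - fx[cur]; dy <- ty[cur] - fy[cur]
        cw_x <- -dy; cw_y <- dx
        pick <- cand[tx[cand] - fx[cand] == cw_x & ty[cand] - fy[cand] == cw_y]
        nxt <- if (length(pick)) pick[1] else cand[1]
      } else nxt <- cand[1]
      if (nxt == s) break          # loop closed on its starting edge
      if (used[nxt]) break         # defensive; cannot happen on valid input
      cur <- nxt
    }
    loops[[length(loops) + 1L]] <- cbind(x = px, y = py)
  }
  # keep the loop with the largest absolute area (outer boundary; holes drop)
  areas <- vapply(loops, function(L) abs(signed_area(L)), numeric(1))
  xy <- loops[[which.max(areas)]]
  # collapse collinear runs of unit steps
  n <- nrow(xy)
  prv <- xy[c(n, 1:(n - 1)), , drop = FALSE]
  nxt <- xy[c(2:n, 1), , drop = FALSE]
  turn <- (xy[, 1] - prv[, 1]) * (nxt[, 2] - xy[, 2]) -
          (xy[, 2] - prv[, 2]) * (nxt[, 1] - xy[, 1])
  xy[turn != 0, , drop = FALSE]
}
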