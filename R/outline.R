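#' Construct a cell or leaf outline
#'
#' An outline is an ordered, closed, simple polygon in micrometres: the traced
#' anticlinal wall of one pavement cell, or one leaf margin. On construction
#' the vertex sequence is canonicalized: consecutive duplicate vertices are
#' dropped, the implicit closing vertex (first == last) is removed, and the
#' orientation is corrected to counter-clockwise (positive signed area).
#' Self-crossing polygons are rejected.
#'
#' @param x,y Numeric vertex coordinates in micrometres, or `x` may be a
#'   two-column matrix / data frame with columns `x` and `y`.
#' @param label Free-text identifier (species, cell id, leaf side).
#' @param border Logical; `TRUE` flags a mask component that touched the
#'   image border (downstream summaries exclude these by default).
#' @param validate Logical; run the simplicity (segment-crossing) scan.
#' @return An object of class `outline`: an n x 2 numeric matrix with
#'   attributes `label` and `border`.
#' @examples
#' sq <- outline(c(0, 1, 1, 0), c(0, 0, 1, 1), label = "unit square")
#' polygon_area(sq)
#' @export
outline <- function(x, y = NULL, label = "", border = FALSE, validate = TRUE) {
  if (is.null(y)) {
    xy <- if (is.matrix(x)) x else as.matrix(as.data.frame(x)[, c("x", "y")])
  } else {
    xy <- cbind(x, y)
  }
  storage.mode(xy) <- "double"
  if (anyNA(xy) || any(!is.finite(xy))) {
    stop("outline vertices must be finite and non-missing", call. = FALSE)
  }
  # drop explicit closure and consecutive duplicates
  n <- nrow(xy)
  if (n >= 2 && all(xy[1, ] == xy[n, ])) xy <- xy[-n, , drop = FALSE]
  keep <- c(TRUE, rowSums(abs(diff(xy))) > 0)
  xy <- xy[keep, , drop = FALSE]
  if (nrow(xy) < 3) {
    stop("an outline needs at least 3 distinct vertices", call. = FALSE)
  }
  sa <- signed_area(xy)
  if (abs(sa) < .Machine$double.eps * max(abs(xy), 1)^2) {
    stop("degenerate outline: zero area (collinear vertices?)", call. = FALSE)
  }
  if (sa < 0) xy <- xy[rev(seq_len(nrow(xy))), , drop = FALSE]
  if (validate && !is_simple_polygon(xy)) {
    stop("outline is self-intersecting", call. = FALSE)
  }
  structure(xy, class = "outline", label = as.character(label),
            border = isTRUE(border), dimnames = list(NULL, c("x", "y")))
}

#' @export
print.outline <- function(x, ...) {
  cat(sprintf("<outline> %d vertices, area %.4g, label: %s%s\n",
              nrow(x), polygon_area(x), attr(x, "label"),
              if (isTRUE(attr(x, "border"))) " [border]" else ""))
  invisible(x)
}

#' Coerce an outline to a tibble of vertices
#'
#' @param x An `outline`.
#' @param ... Unused.
#' @return A tibble with columns `vertex_index`, `x_um`, `y_um`.
#' @export
as_tibble.outline <- function(x, ...) {
  tibble::tibble(vertex_index = seq_len(nrow(x)),
                 x_um = x[, 1], y_um = x[, 2])
}

# signed area by the shoelace formula; > 0 for CCW vertex order
signed_area <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  j <- c(2:nrow(xy), 1)
  sum(x * y[j] - x[j] * y) / 2
}

# Proper segment-crossing scan (O(n^2), vectorized). Edges sharing a vertex
# (adjacent, or a pinch point from crack tracing) do not count as crossings;
# collinear overlap of non-adjacent edges does.
is_simple_polygon <- function(xy) {
  n <- nrow(xy)
  j <- c(2:n, 1)
  p1x <- xy[, 1]; p1y <- xy[, 2]
  p2x <- xy[j, 1]; p2y <- xy[j, 2]
  a <- rep.int(1:(n - 1), (n - 1):1)
  b <- sequence((n - 1):1, from = 2:n)
  adj <- (b - a == 1) | (a == 1 & b == n)
  a <- a[!adj]; b <- b[!adj]
  if (!length(a)) return(TRUE)
  # bounding-box prefilter: only overlapping segment boxes can cross
  lox <- pmin(p1x, p2x); hix <- pmax(p1x, p2x)
  loy <- pmin(p1y, p2y); hiy <- pmax(p1y, p2y)
  keep <- lox[a] <= hix[b] & lox[b] <= hix[a] &
          loy[a] <= hiy[b] & loy[b] <= hiy[a]
  a <- a[keep]; b <- b[keep]
  if (!length(a)) return(TRUE)
  cross <- function(ox, oy, ax, ay, bx, by) {
    (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
  }
  d1 <- cross(p1x[a], p1y[a], p2x[a], p2y[a], p1x[b], p1y[b])
  d2 <- cross(p1x[a], p1y[a], p2x[a], p2y[a], p2x[b], p2y[b])
  d3 <- cross(p1x[b], p1y[b], p2x[b], p2y[b], p1x[a], p1y[a])
  d4 <- cross(p1x[b], p1y[b], p2x[b], p2y[b], p2x[a], p2y[a])
  proper <- (d1 * d2 < 0) & (d3 * d4 < 0)
  if (any(proper)) return(FALSE)
  # collinear candidates: all four cross products ~ 0 and projections overlap
  tol <- 1e-12 * max(abs(xy), 1)^2
  col4 <- abs(d1) < tol & abs(d2) < tol & abs(d3) < tol & abs(d4) < tol
  if (any(col4)) {
    ia <- a[col4]; ib <- b[col4]
    lo_a <- pmin(p1x[ia], p2x[ia]); hi_a <- pmax(p1x[ia], p2x[ia])
    lo_b <- pmin(p1x[ib], p2x[ib]); hi_b <- pmax(p1x[ib], p2x[ib])
    lo_ay <- pmin(p1y[ia], p2y[ia]); hi_ay <- pmax(p1y[ia], p2y[ia])
    lo_by <- pmin(p1y[ib], p2y[ib]); hi_by <- pmax(p1y[ib], p2y[ib])
    overl <- (hi_a > lo_b & hi_b > lo_a) | (hi_ay > lo_by & hi_by > lo_ay)
    if (any(overl)) return(FALSE)
  }
  TRUE
}

#' Read traced outlines from a long-format CSV
#'
#' Expected columns: `species`, `cell_id`, `side`, `vertex_index`, `x_um`,
#' `y_um`, one row per vertex; leaf outlines use `cell_id = "leaf"`.
#'
#' @param path CSV file path, or a data frame already in that layout.
#' @return A tibble with one row per outline: `species`, `cell_id`, `side`
#'   and a list-column `outline` of `outline` objects.
#' @export
read_outlines <- function(path) {
  df <- if (is.data.frame(path)) {
    tibble::as_tibble(path)
  } else {
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  }
  need <- c("species", "cell_id", "side", "vertex_index", "x_um", "y_um")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("outline table is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  df |>
    dplyr::arrange(.data$species, .data$cell_id, .data$side,
                   .data$vertex_index) |>
    dplyr::group_by(.data$species, .data$cell_id, .data$side) |>
    dplyr::summarise(outline = list(outline(
      .data$x_um, .data$y_um,
      label = paste(.data$species[1], .data$cell_id[1], .data$side[1]))),
      .groups = "drop")
}

#' Write outlines to the long-format CSV schema
#'
#' @param outlines Tibble as returned by [read_outlines()] (list-column
#'   `outline` plus `species`, `cell_id`, `side`).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_outlines <- function(outlines, path) {
  long <- outlines |>
    dplyr::mutate(.vtx = purrr::map(.data$outline, as_tibble.outline)) |>
    dplyr::select(-"outline") |>
    tidyr::unnest(".vtx")
  readr::write_csv(long, path, progress = FALSE)
  invisible(path)
}
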