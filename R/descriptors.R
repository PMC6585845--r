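#' Shape descriptors of a single outline
#'
#' The four traditional descriptors used throughout the pipeline:
#'
#' * **area** `A` - polygon area (um^2 for cells, mm^2 for leaves);
#' * **aspect ratio** `AR = width / length` after principal-axis alignment,
#'   in (0, 1]: 1 isotropic, small values elongate;
#' * **circularity** `C = P^2 / (4 pi A)`, >= 1, equal to 1 only for a
#'   circle; grows with both elongation and margin undulation;
#' * **solidity** `S = A / A_hull`, in (0, 1]: 1 convex, low values
#'   undulate (or strongly curved) margins.
#'
#' @param outline An [outline()].
#' @name shape-descriptors
NULL

#' @rdname shape-descriptors
#' @export
solidity <- function(outline) {
  polygon_area(outline) / polygon_area(convex_hull(outline))
}

#' @rdname shape-descriptors
#' @param ... Passed to [principal_extents()] (e.g. `method = "feret"`).
#' @export
aspect_ratio <- function(outline, ...) {
  ext <- principal_extents(outline, ...)
  ext$width / ext$length
}

#' @rdname shape-descriptors
#' @export
circularity <- function(outline) {
  perimeter(outline)^2 / (4 * pi * polygon_area(outline))
}

#' Measure one outline
#'
#' Resamples the outline to equal arc-length spacing (fixed vertex density
#' removes the nuisance variation of hand tracing) and computes all shape
#' descriptors from the resampled polygon.
#'
#' @param outline An [outline()].
#' @param n_points Resampling density (default 300).
#' @return A one-row tibble: `area`, `perimeter`, `solidity`,
#'   `aspect_ratio`, `circularity`, `border`.
#' @export
measure <- function(outline, n_points = 300L) {
  o <- resample(outline, n_points)
  ext <- principal_extents(o)
  a <- polygon_area(o)
  p <- perimeter(o)
  tibble::tibble(
    area = a,
    perimeter = p,
    solidity = a / polygon_area(convex_hull(o)),
    aspect_ratio = ext$width / ext$length,
    circularity = p^2 / (4 * pi * a),
    border = isTRUE(attr(outline, "border"))
  )
}

#' Measure a table of outlines
#'
#' Batch version of [measure()] over the list-column layout of
#' [read_outlines()]. An outline whose measurement fails is dropped with a
#' warning naming it; the batch continues.
#'
#' @param outlines Tibble with columns `species`, `cell_id`, `side` and
#'   list-column `outline`.
#' @param n_points Resampling density.
#' @return A tibble with one row per successfully measured outline.
#' @export
measure_outlines <- function(outlines, n_points = 300L) {
  res <- purrr::pmap(outlines[c("species", "cell_id", "side", "outline")],
    function(species, cell_id, side, outline) {
      m <- tryCatch(measure(outline, n_points), error = function(e) {
        warning(sprintf("skipping %s/%s/%s: %s", species, cell_id, side,
                        conditionMessage(e)), call. = FALSE)
        NULL
      })
      if (is.null(m)) return(NULL)
      dplyr::bind_cols(tibble::tibble(species = species, cell_id = cell_id,
                                      side = side), m)
    })
  dplyr::bind_rows(res)
}

#' Quartile classification of a descriptor
#'
#' Assigns each value to one of four classes split at the dataset quartiles
#' (type-7 linear-interpolation quantiles at 0.25/0.5/0.75). Intervals are
#' right-closed, so boundary ties fall in the lower class; class 1 covers
#' the minimum. Used to colour the solidity and aspect-ratio distributions
#' in the morphospace figures.
#'
#' @param values Numeric vector, length >= 4.
#' @return An integer vector of classes 1-4 with attribute `breakpoints`
#'   (the three quartiles). All-equal input yields class 1 throughout, with
#'   a degeneracy warning.
#' @export
quartile_classify <- function(values) {
  if (length(values) < 4) {
    stop("quartile classification needs at least 4 values", call. = FALSE)
  }
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  if (q[1] == q[3]) {
    warning("degenerate quartiles: values are (nearly) all equal", call. = FALSE)
  }
  cls <- 1L + (values > q[1]) + (values > q[2]) + (values > q[3])
  attr(cls, "breakpoints") <- q
  cls
}
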