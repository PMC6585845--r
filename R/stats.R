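#' PCA of the shape-descriptor table
#'
#' Principal component analysis of the four traditional descriptors
#' (`aspect_ratio`, `area`, `circularity`, `solidity`) over all cells. Each
#' descriptor is standardized to unit variance by default, since area
#' (um^2) and the dimensionless ratios live on incommensurate scales; the
#' unstandardized covariance PCA is available with `standardize = FALSE`.
#'
#' @param metrics Data frame with the four descriptor columns (extra
#'   columns are carried into the scores output).
#' @param standardize Scale each descriptor to unit variance.
#' @return An object of class `pavecell_pca`: list with `loadings`
#'   (descriptor x component tibble), `scores` (cell x component tibble,
#'   carrying any id columns), `variance_explained` (fraction per
#'   component), and the underlying `prcomp` fit.
#' @export
pca_descriptors <- function(metrics, standardize = TRUE) {
  vars <- c("aspect_ratio", "area", "circularity", "solidity")
  miss <- setdiff(vars, names(metrics))
  if (length(miss)) {
    stop("metrics table lacks descriptor columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (nrow(metrics) < 3) stop("need at least 3 rows for PCA", call. = FALSE)
  X <- as.matrix(metrics[vars])
  sds <- apply(X, 2, stats::sd)
  if (standardize && any(sds == 0)) {
    stop("cannot standardize constant descriptor column(s): ",
         paste(vars[sds == 0], collapse = ", "), call. = FALSE)
  }
  fit <- stats::prcomp(X, center = TRUE, scale. = standardize)
  ve <- fit$sdev^2 / sum(fit$sdev^2)
  ids <- metrics[setdiff(names(metrics), vars)]
  structure(list(
    loadings = dplyr::bind_cols(
      tibble::tibble(descriptor = vars),
      tibble::as_tibble(unclass(fit$rotation))),
    scores = dplyr::bind_cols(tibble::as_tibble(ids),
                              tibble::as_tibble(unclass(fit$x))),
    variance_explained = ve,
    standardized = standardize,
    fit = fit), class = "pavecell_pca")
}

#' @export
print.pavecell_pca <- function(x, ...) {
  cat(sprintf("<pavecell_pca> %d cells; PC1+PC2 explain %.1f%% of variance\n",
              nrow(x$scores), 100 * sum(x$variance_explained[1:2])))
  invisible(x)
}

#' @rdname pca_descriptors
#' @param x A `pavecell_pca` object.
#' @param ... Unused.
#' @export
tidy.pavecell_pca <- function(x, ...) {
  tidyr::pivot_longer(x$loadings, -"descriptor",
                      names_to = "component", values_to = "loading")
}

#' @rdname pca_descriptors
#' @export
glance.pavecell_pca <- function(x, ...) {
  tibble::tibble(
    n = nrow(x$scores),
    standardized = x$standardized,
    pc1_var = x$variance_explained[1],
    pc2_var = x$variance_explained[2],
    pc12_var = sum(x$variance_explained[1:2]))
}

#' Spearman rank correlation with the t-approximation p-value
#'
#' Spearman's rho on average ranks (ties shared), with the two-sided
#' p-value from `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` degrees
#' of freedom. Perfect correlations (|rho| = 1) get p = 0.
#'
#' @param x,y Equal-length numeric vectors, n >= 5.
#' @return An object of class `pavecell_cor` (also a one-row tibble):
#'   `rho`, `n`, `statistic` (t), `p_value`.
#' @export
spearman <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 5 || length(y) != n) {
    stop("spearman needs two equal-length vectors with n >= 5", call. = FALSE)
  }
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    stop("rho undefined: zero variance in ranks", call. = FALSE)
  }
  rho <- stats::cor(rx, ry)
  if (abs(rho) >= 1 - 1e-15) {
    tstat <- sign(rho) * Inf
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  out <- tibble::tibble(rho = rho, n = n, statistic = tstat, p_value = p)
  class(out) <- c("pavecell_cor", class(out))
  out
}

#' @export
tidy.pavecell_cor <- function(x, ...) tibble::as_tibble(unclass(x))

#' Aggregate cell and leaf measurements per species and leaf side
#'
#' Computes per-species, per-side means and standard deviations of each
#' descriptor, joins the single leaf measurement per species, and the
#' adaxial-abaxial solidity difference where both sides were measured.
#' When a species supplies more than `cells_per_side` cells on a side, a
#' seeded random subsample caps it (the study design measured 30 cells per
#' side). Border-flagged cells are excluded by default.
#'
#' @param cells Cell metrics table (from [measure_outlines()]); columns
#'   `species`, `side` plus descriptors.
#' @param leaves Leaf metrics table; one row per species (column `species`
#'   plus descriptors; `area` is interpreted in mm^2).
#' @param meta Species metadata: `species`, `clade`.
#' @param cells_per_side Sampling cap (default 30).
#' @param seed Seed for the subsampling (default 20181003).
#' @param drop_border Exclude border-flagged cells.
#' @return A tibble, one row per species: clade, per-side `n`, `mean_*`,
#'   `sd_*` for each descriptor, `leaf_ar`, `leaf_area_mm2`, and
#'   `solidity_diff` (adaxial minus abaxial mean solidity; `NA` unless both
#'   sides present).
#' @export
summarize_species <- function(cells, leaves = NULL, meta = NULL,
                              cells_per_side = 30L, seed = 20181003L,
                              drop_border = TRUE) {
  if (!is.null(meta)) {
    missing_sp <- setdiff(unique(cells$species), meta$species)
    if (length(missing_sp)) {
      stop("species missing from metadata: ",
           paste(missing_sp, collapse = ", "), call. = FALSE)
    }
  }
  if (drop_border && "border" %in% names(cells)) {
    cells <- dplyr::filter(cells, !.data$border)
  }
  cells <- dplyr::arrange(cells, .data$species, .data$side, .data$cell_id)
  sampled <- withr::with_seed(seed,
    cells |>
      dplyr::group_by(.data$species, .data$side) |>
      dplyr::slice_sample(n = cells_per_side) |>
      dplyr::ungroup())
  per_side <- sampled |>
    dplyr::group_by(.data$species, .data$side) |>
    dplyr::summarise(
      n = dplyr::n(),
      dplyr::across(c("area", "perimeter", "solidity", "aspect_ratio",
                      "circularity"),
                    list(mean = mean, sd = stats::sd)),
      .groups = "drop")
  wide <- tidyr::pivot_wider(
    per_side, id_cols = "species", names_from = "side",
    values_from = -c("species", "side"), names_glue = "{side}_{.value}")
  if ("adaxial_solidity_mean" %in% names(wide) &&
      "abaxial_solidity_mean" %in% names(wide)) {
    wide$solidity_diff <- wide$adaxial_solidity_mean - wide$abaxial_solidity_mean
  } else {
    wide$solidity_diff <- NA_real_
  }
  if (!is.null(leaves)) {
    leaf_tbl <- leaves |>
      dplyr::group_by(.data$species) |>
      dplyr::slice(1) |>
      dplyr::ungroup() |>
      dplyr::transmute(.data$species, leaf_ar = .data$aspect_ratio,
                       leaf_area_mm2 = .data$area)
    wide <- dplyr::left_join(wide, leaf_tbl, by = "species")
  }
  if (!is.null(meta)) {
    wide <- dplyr::left_join(wide, dplyr::distinct(meta[c("species", "clade")]),
                             by = "species")
  }
  dplyr::relocate(wide, "species", dplyr::any_of("clade"))
}

#' Pooled species means across leaf sides
#'
#' Mean of the per-side means for each descriptor, regardless of side (a
#' species with one side measured keeps that side's mean).
#'
#' @param summaries Output of [summarize_species()].
#' @return Tibble: `species`, (`clade`,) `mean_solidity`,
#'   `mean_aspect_ratio`, `mean_area`, plus `leaf_ar` when present.
#' @export
pool_sides <- function(summaries) {
  pick <- function(metric) {
    cols <- intersect(paste0(c("adaxial_", "abaxial_"), metric, "_mean"),
                      names(summaries))
    rowMeans(as.matrix(summaries[cols]), na.rm = TRUE)
  }
  out <- tibble::tibble(
    species = summaries$species,
    mean_solidity = pick("solidity"),
    mean_aspect_ratio = pick("aspect_ratio"),
    mean_area = pick("area"))
  if ("clade" %in% names(summaries)) out$clade <- summaries$clade
  if ("leaf_ar" %in% names(summaries)) out$leaf_ar <- summaries$leaf_ar
  out
}

#' Adaxial-abaxial solidity difference
#'
#' For every species measured on both leaf sides, the difference between
#' mean adaxial and mean abaxial solidity; positive values mean the abaxial
#' surface is the more undulate one.
#'
#' @param summaries Output of [summarize_species()].
#' @return A list: `per_species` tibble (`species`, `solidity_diff`,
#'   `abaxial_lower` flag), `n_both_sides`, `n_abaxial_lower`,
#'   `frac_abaxial_lower`, and `n_excluded` (species lacking a side).
#' @export
side_difference <- function(summaries) {
  d <- summaries[!is.na(summaries$solidity_diff),
                 c("species", "solidity_diff")]
  d$abaxial_lower <- d$solidity_diff > 0
  list(per_species = tibble::as_tibble(d),
       n_both_sides = nrow(d),
       n_abaxial_lower = sum(d$abaxial_lower),
       frac_abaxial_lower = mean(d$abaxial_lower),
       n_excluded = nrow(summaries) - nrow(d))
}

#' Correlation between leaf and cell aspect ratio across species
#'
#' Spearman correlation of species-level leaf aspect ratio against the
#' side-pooled mean cell aspect ratio, optionally within a clade subset
#' (e.g. ferns + gymnosperms + monocots vs eudicots + early-diverging
#' angiosperms).
#'
#' @param summaries Output of [summarize_species()] (with leaf metrics).
#' @param clades Character vector of clades to keep; `NULL` = all.
#' @return A `pavecell_cor` row (see [spearman()]).
#' @export
leaf_cell_correlation <- function(summaries, clades = NULL) {
  pooled <- pool_sides(summaries)
  if (!is.null(clades)) {
    if (!"clade" %in% names(pooled)) {
      stop("summaries carry no clade column", call. = FALSE)
    }
    pooled <- pooled[pooled$clade %in% clades, ]
  }
  pooled <- pooled[stats::complete.cases(pooled$leaf_ar,
                                         pooled$mean_aspect_ratio), ]
  if (nrow(pooled) < 5) {
    stop("fewer than 5 species with both leaf and cell aspect ratio",
         call. = FALSE)
  }
  spearman(pooled$leaf_ar, pooled$mean_aspect_ratio)
}

#' Dataset-level descriptor summaries over species means
#'
#' Median and range of the side-pooled species means - the scale on which
#' the headline dataset statistics are reported. Set `level = "cells"` for
#' the all-cells variant.
#'
#' @param summaries Output of [summarize_species()].
#' @param cells Cell metrics table, required for `level = "cells"`.
#' @param level `"species"` (default) or `"cells"`.
#' @return Tibble: `metric`, `median`, `min`, `max`, `n`.
#' @export
dataset_summary <- function(summaries = NULL, cells = NULL,
                            level = c("species", "cells")) {
  level <- match.arg(level)
  if (level == "species") {
    pooled <- pool_sides(summaries)
    vals <- list(solidity = pooled$mean_solidity,
                 aspect_ratio = pooled$mean_aspect_ratio)
  } else {
    vals <- list(solidity = cells$solidity, aspect_ratio = cells$aspect_ratio)
  }
  purrr::imap(vals, function(v, nm) {
    v <- v[!is.na(v)]
    tibble::tibble(metric = nm, median = stats::median(v),
                   min = min(v), max = max(v), n = length(v))
  }) |> dplyr::bind_rows()
}
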