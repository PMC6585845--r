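#' Generate a synthetic lobed pavement-cell outline
#'
#' Radial-perturbation model of a lobed cell: an ellipse with semi-axes
#' `a >= b` whose radius is modulated by `k` sinusoidal lobes of relative
#' amplitude `amp`,
#' `(x, y) = ((1 + amp sin(k t + phase)) a cos t, (1 + amp sin(k t + phase)) b sin t)`,
#' plus optional multiplicative radial jitter per vertex. `amp = 0` gives
#' an exact ellipse. This spans the solidity range seen in real epidermides
#' while keeping the ground truth analytic; it does not emulate true
#' jigsaw interdigitation of neighbouring cells.
#'
#' If the drawn polygon self-intersects (extreme amplitude + jitter), it is
#' regenerated at 80% amplitude up to 3 times before failing.
#'
#' @param a,b Semi-axes in micrometres (`a >= b > 0`).
#' @param k Lobe count (integer >= 0).
#' @param amp Lobe amplitude in `[0, 0.4]` (fraction of local radius).
#' @param phase Lobe phase in radians.
#' @param jitter_sd Radial jitter standard deviation (fraction of local
#'   radius; default 0).
#' @param n_points Number of vertices.
#' @param seed Integer seed (used only when `jitter_sd > 0`).
#' @param label Outline label.
#' @return An [outline()].
#' @export
make_lobed_cell <- function(a = 1, b = 1, k = 0L, amp = 0, phase = 0,
                            jitter_sd = 0, n_points = 300L, seed = 1L,
                            label = "synthetic cell") {
  stopifnot(a >= b, b > 0, k >= 0, amp >= 0, amp <= 0.4, jitter_sd >= 0)
  gen <- function(amp_now, try_seed) {
    th <- seq(0, 2 * pi, length.out = n_points + 1)[-(n_points + 1)]
    r <- 1 + amp_now * sin(k * th + phase)
    if (jitter_sd > 0) {
      r <- r * withr::with_seed(try_seed,
                                exp(stats::rnorm(n_points, 0, jitter_sd)))
    }
    tryCatch(outline(a * r * cos(th), b * r * sin(th), label = label),
             error = function(e) NULL)
  }
  amp_now <- amp
  for (try in 0:3) {
    o <- gen(amp_now, seed + try)
    if (!is.null(o)) return(o)
    amp_now <- amp_now * 0.8
  }
  stop(sprintf("could not generate a simple lobed outline (amp = %g, k = %d)",
               amp, k), call. = FALSE)
}

#' Generate a superellipse leaf outline
#'
#' `|x / (L/2)|^p + |y / (W/2)|^p = 1`, sampled densely; `p = 2` is an
#' ellipse, larger exponents approach a rectangle (broader leaf at equal
#' bounding box). Leaf aspect ratio is `width / length`.
#'
#' @param length,width Leaf length and width in mm (`width <= length`).
#' @param exponent Superellipse exponent (> 0, default 2).
#' @param n_points Number of vertices.
#' @param label Outline label.
#' @return An [outline()] (coordinates in mm).
#' @export
make_leaf <- function(length = 10, width = 5, exponent = 2, n_points = 400L,
                      label = "synthetic leaf") {
  stopifnot(length > 0, width > 0, width <= length, exponent > 0)
  th <- seq(0, 2 * pi, length.out = n_points + 1)[-(n_points + 1)]
  x <- (length / 2) * sign(cos(th)) * abs(cos(th))^(2 / exponent)
  y <- (width / 2) * sign(sin(th)) * abs(sin(th))^(2 / exponent)
  outline(x, y, label = label, validate = FALSE)
}

#' Rasterize an outline to a binary mask
#'
#' Fills the polygon on a pixel grid (pixel centre in polygon = foreground,
#' even-odd rule), for round-trip testing of mask tracing.
#'
#' @param outline An [outline()] with coordinates in micrometres.
#' @param microns_per_pixel Pixel size (> 0).
#' @param bounds Optional `c(xmin, xmax, ymin, ymax)` raster window in
#'   micrometres; an outline exceeding explicit bounds is an error. Default:
#'   bounding box plus a 2-pixel margin.
#' @return Logical matrix (rows = image rows, top row = greatest y).
#' @export
rasterize <- function(outline, microns_per_pixel = 1, bounds = NULL) {
  stopifnot(microns_per_pixel > 0)
  xy <- unclass(outline)
  if (is.null(bounds)) {
    m <- 2 * microns_per_pixel
    bounds <- c(min(xy[, 1]) - m, max(xy[, 1]) + m,
                min(xy[, 2]) - m, max(xy[, 2]) + m)
  } else if (min(xy[, 1]) < bounds[1] || max(xy[, 1]) > bounds[2] ||
             min(xy[, 2]) < bounds[3] || max(xy[, 2]) > bounds[4]) {
    stop("outline exceeds the raster bounds", call. = FALSE)
  }
  nx <- max(1L, ceiling((bounds[2] - bounds[1]) / microns_per_pixel))
  ny <- max(1L, ceiling((bounds[4] - bounds[3]) / microns_per_pixel))
  cx <- bounds[1] + (seq_len(nx) - 0.5) * microns_per_pixel
  cy <- bounds[3] + (seq_len(ny) - 0.5) * microns_per_pixel
  centres <- cbind(rep(cx, each = ny), rep(rev(cy), times = nx))
  poly <- rbind(xy, xy[1, ])
  inside <- mgcv::in.out(poly, centres)
  matrix(inside, nrow = ny, ncol = nx)
}

# --- amplitude -> solidity calibration ------------------------------------

calib_cache <- new.env(parent = emptyenv())

# Noise-free solidity of the lobed-cell model on a grid of amplitudes for a
# given lobe count; strictly decreasing in amp, so invertible by monotone
# interpolation. Solidity is affine-invariant, so the curve does not depend
# on the ellipse aspect ratio. Cached per lobe count.
amp_solidity_curve <- function(k, n_points = 300L) {
  key <- sprintf("k%d", k)
  if (!is.null(calib_cache[[key]])) return(calib_cache[[key]])
  amps <- seq(0, 0.4, by = 0.02)
  sol <- vapply(amps, function(am) {
    o <- make_lobed_cell(a = 1, b = 1, k = k, amp = am, n_points = n_points)
    solidity(o)
  }, numeric(1))
  # guard: keep the strictly decreasing prefix (flat tails would break inversion)
  keep <- c(TRUE, diff(sol) < 0)
  curve <- list(amp = amps[keep], solidity = sol[keep])
  calib_cache[[key]] <- curve
  curve
}

# invert target solidity to lobe amplitude for a lobe count
solidity_to_amp <- function(target, k) {
  cv <- amp_solidity_curve(k)
  if (target > max(cv$solidity) + 1e-9 || target < min(cv$solidity) - 1e-9) {
    return(NA_real_)
  }
  stats::approx(cv$solidity, cv$amp, xout = min(max(target, min(cv$solidity)),
                                                max(cv$solidity)))$y
}

#' Default clade specification for the synthetic dataset
#'
#' Reads the versioned clade specification shipped with the package
#' (`inst/extdata/default_clades.csv`): three clades of 30 species each
#' whose species-level solidity and aspect-ratio targets follow Beta
#' distributions. The clade means reproduce the qualitative ordering seen
#' in real epidermides - ferns most undulate, monocots least; monocots most
#' elongate - and are synthetic choices, not estimates from any real
#' dataset. Leaf-cell aspect-ratio coupling is on for monocots and ferns
#' and off for eudicots.
#'
#' @param path Optional path to an alternative specification CSV.
#' @return A tibble with one row per clade: `clade`, `n_species`,
#'   `solidity_mean`, `solidity_sd`, `ar_mean`, `ar_sd`, `amp_noise_sd`,
#'   `jitter_sd`, `abaxial_amp_offset`, `leaf_link`.
#' @export
default_clade_spec <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "default_clades.csv", package = "pavecell")
  }
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

# Beta shape parameters from mean and sd on (0, 1)
beta_shapes <- function(mean, sd) {
  v <- sd^2
  vmax <- mean * (1 - mean)
  if (v >= vmax) stop("Beta sd too large for mean ", mean, call. = FALSE)
  nu <- vmax / v - 1
  c(shape1 = mean * nu, shape2 = (1 - mean) * nu)
}

#' Generate a clade-structured synthetic species dataset
#'
#' Emulates the study's sampling design: per species, `cells_per_side`
#' cell outlines on each leaf side plus one leaf outline. Species-level
#' target solidity and aspect ratio are drawn from each clade's Beta
#' distributions; the lobe amplitude that realizes the solidity target is
#' found by inverting a precomputed amplitude-to-solidity calibration curve
#' for the species' (lobe count, aspect ratio) stratum. Cell-level
#' variation enters through radial jitter and per-cell amplitude noise;
#' abaxial cells receive an additional amplitude offset (more undulation on
#' the lower surface). Leaf aspect ratio follows the cell target
#' (log-normal noise) in clades with `leaf_link`, and an independent Beta
#' draw otherwise.
#'
#' @param clades Clade specification tibble ([default_clade_spec()]).
#' @param cells_per_side Cells per species per side (default 30).
#' @param sides Character vector of leaf sides to generate.
#' @param n_points Vertices per cell outline.
#' @param seed Integer seed; the dataset is fully reproducible from
#'   (specification, seed).
#' @return A list of tibbles: `outlines` (long vertex format), `leaves`
#'   (long vertex format, mm), `metadata` (`species`, `clade`),
#'   `ground_truth` (`species`, `clade`, `target_solidity`, `target_ar`,
#'   `amp`, `k`, `leaf_ar`, `seed`).
#' @export
make_dataset <- function(clades = default_clade_spec(), cells_per_side = 30L,
                         sides = c("adaxial", "abaxial"), n_points = 300L,
                         seed = 1L) {
  stopifnot(nrow(clades) >= 1)
  withr::with_seed(seed, {
    species_rows <- list()
    outline_rows <- list()
    leaf_rows <- list()
    sp_idx <- 0L
    for (ci in seq_len(nrow(clades))) {
      cl <- clades[ci, ]
      bs <- beta_shapes(cl$solidity_mean, cl$solidity_sd)
      ba <- beta_shapes(cl$ar_mean, cl$ar_sd)
      for (si in seq_len(cl$n_species)) {
        sp_idx <- sp_idx + 1L
        sp <- sprintf("%s_sp%02d", cl$clade, si)
        target_ar <- min(max(stats::rbeta(1, ba[1], ba[2]), 0.05), 1)
        # draw the solidity target, then pick a lobe count able to realize
        # it (deep undulation needs more lobes at bounded amplitude);
        # redraw targets the radial-lobe model cannot reach at all
        kk <- 5:12
        target_s <- NA_real_
        for (draw in 1:50) {
          cand <- stats::rbeta(1, bs[1], bs[2])
          feas <- kk[vapply(kk, function(k) {
            cv <- amp_solidity_curve(k)
            cand >= min(cv$solidity) && cand <= max(cv$solidity)
          }, logical(1))]
          if (length(feas)) {
            target_s <- cand
            k <- if (length(feas) == 1) feas else sample(feas, 1)
            break
          }
        }
        if (is.na(target_s)) {
          stop(sprintf(
            "species %s: clade solidity distribution lies below the attainable range (min %.3f at k = %d)",
            sp, min(amp_solidity_curve(max(kk))$solidity), max(kk)),
            call. = FALSE)
        }
        amp <- solidity_to_amp(target_s, k)
        # cell size: log-normal area around 1500 um^2
        mean_r <- sqrt(1500 / (pi * target_ar)) / 2
        leaf_ar <- if (isTRUE(cl$leaf_link)) {
          min(max(target_ar * exp(stats::rnorm(1, 0, 0.3)), 0.02), 1)
        } else {
          stats::rbeta(1, ba[1], ba[2])
        }
        species_rows[[sp_idx]] <- tibble::tibble(
          species = sp, clade = cl$clade, target_solidity = target_s,
          target_ar = target_ar, amp = amp, k = k, leaf_ar = leaf_ar,
          seed = seed)
        for (side in sides) {
          amp_side <- amp + if (side == "abaxial") cl$abaxial_amp_offset else 0
          for (cj in seq_len(cells_per_side)) {
            amp_cell <- min(max(amp_side + stats::rnorm(1, 0, cl$amp_noise_sd),
                                0), 0.4)
            size <- mean_r * exp(stats::rnorm(1, 0, 0.15))
            o <- make_lobed_cell(
              a = size * 2, b = size * 2 * target_ar, k = k, amp = amp_cell,
              phase = stats::runif(1, 0, 2 * pi), jitter_sd = cl$jitter_sd,
              n_points = n_points,
              seed = sample.int(.Machine$integer.max, 1),
              label = sp)
            outline_rows[[length(outline_rows) + 1L]] <- dplyr::bind_cols(
              tibble::tibble(species = sp, cell_id = sprintf("cell_%02d", cj),
                             side = side),
              as_tibble.outline(o))
          }
        }
        leaf_len <- 10 * exp(stats::rnorm(1, 0, 0.2))
        leaf <- make_leaf(length = leaf_len, width = leaf_len * leaf_ar,
                          exponent = stats::runif(1, 1.8, 3), label = sp)
        leaf_rows[[sp_idx]] <- dplyr::bind_cols(
          tibble::tibble(species = sp, cell_id = "leaf", side = "leaf"),
          as_tibble.outline(leaf))
      }
    }
    gt <- dplyr::bind_rows(species_rows)
    list(outlines = dplyr::bind_rows(outline_rows),
         leaves = dplyr::bind_rows(leaf_rows),
         metadata = gt[c("species", "clade")],
         ground_truth = gt)
  })
}

#' Generate a random ultrametric phylogeny
#'
#' Yule (pure-birth) tree scaled to unit height. With `clades` given (a
#' `species -> clade` assignment, e.g. from [make_dataset()] metadata), one
#' Yule subtree is grown per clade and the subtrees are attached to a
#' backbone, so clade-structured traits are phylogenetically clustered.
#'
#' @param n_tips Number of tips (ignored when `clades` is given).
#' @param seed Integer seed.
#' @param clades Optional named character vector or two-column data frame
#'   (`species`, `clade`).
#' @return A `phylo` object with unit root-to-tip height.
#' @export
make_tree <- function(n_tips = 50L, seed = 1L, clades = NULL) {
  rescale_height <- function(tr, h) {
    tr$edge.length <- tr$edge.length / max(ape::node.depth.edgelength(tr)) * h
    tr
  }
  withr::with_seed(seed, {
    if (is.null(clades)) {
      stopifnot(n_tips >= 2)
      if (n_tips == 2) {
        return(read_phylogeny("(t1:1,t2:1);"))
      }
      return(rescale_height(ape::rphylo(n_tips, birth = 1, death = 0), 1))
    }
    if (is.data.frame(clades)) {
      clades <- stats::setNames(clades$clade, clades$species)
    }
    groups <- split(names(clades), clades)
    m <- length(groups)
    subs <- lapply(groups, function(sp) {
      if (length(sp) == 1) return(list(nwk = sp, height = 0))
      st <- rescale_height(ape::rphylo(length(sp), birth = 1, death = 0), 0.5)
      st$tip.label <- sample(sp)
      list(nwk = gsub(";", "", ape::write.tree(st)), height = 0.5)
    })
    if (m == 1) {
      one <- groups[[1]]
      st <- rescale_height(ape::rphylo(length(one), birth = 1, death = 0), 1)
      st$tip.label <- sample(one)
      return(st)
    }
    # pectinate backbone: node j at depth d[j]; every tip ends at depth 1
    d <- seq(0, 0.4, length.out = m - 1)
    stem <- function(j) 1 - subs[[j]]$height - d[min(j, m - 1)]
    nwk <- sprintf("(%s:%g,%s:%g)", subs[[m - 1]]$nwk, stem(m - 1),
                   subs[[m]]$nwk, 1 - subs[[m]]$height - d[m - 1])
    if (m > 2) {
      for (j in (m - 2):1) {
        nwk <- sprintf("(%s:%g,%s:%g)", subs[[j]]$nwk,
                       1 - subs[[j]]$height - d[j], nwk, d[j + 1] - d[j])
      }
    }
    read_phylogeny(paste0(nwk, ";"))
  })
}
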