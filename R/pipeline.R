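#' Pipeline configuration
#'
#' Assembles and validates the configuration driving the pipeline stages.
#' All randomness in a run flows from the single `seed` through fixed,
#' named substreams (simulation, cell subsampling, permutations), so one
#' knob reproduces a whole run. A configuration can also be read from a
#' YAML file via `config_file`.
#'
#' @param outdir Output directory (created if absent).
#' @param seed Master seed.
#' @param cells_per_side Cells sampled per species and side.
#' @param n_points Resampling density for measurement and EFA.
#' @param n_harmonics EFA harmonic count (default 20).
#' @param standardize Standardize descriptors before PCA.
#' @param n_perm Moran permutation count.
#' @param alpha Hotspot significance level.
#' @param scale Micrometres per pixel for mask extraction.
#' @param min_area Speckle threshold for mask extraction (px^2).
#' @param linked_clades Clade subset expected to couple leaf and cell
#'   aspect ratio (correlation is reported for this subset, its complement,
#'   and all species).
#' @param clade_spec_path Optional path to a clade specification CSV for
#'   the simulate stage.
#' @param config_file Optional YAML file whose keys override the defaults
#'   above (flat key-value).
#' @return A named list of class `pavecell_config`.
#' @export
pipeline_config <- function(outdir, seed = 1L, cells_per_side = 30L,
                            n_points = 300L, n_harmonics = 20L,
                            standardize = TRUE, n_perm = 999L, alpha = 0.05,
                            scale = 1, min_area = 50,
                            linked_clades = c("fern", "monocot"),
                            clade_spec_path = NULL, config_file = NULL) {
  cfg <- list(outdir = outdir, seed = as.integer(seed),
              cells_per_side = as.integer(cells_per_side),
              n_points = as.integer(n_points),
              n_harmonics = as.integer(n_harmonics),
              standardize = isTRUE(standardize), n_perm = as.integer(n_perm),
              alpha = alpha, scale = scale, min_area = min_area,
              linked_clades = linked_clades,
              clade_spec_path = clade_spec_path)
  if (!is.null(config_file)) {
    over <- yaml::read_yaml(config_file)
    for (k in names(over)) cfg[[k]] <- over[[k]]
  }
  stopifnot(cfg$cells_per_side >= 1, cfg$n_harmonics >= 1,
            cfg$n_perm >= 99, cfg$alpha > 0, cfg$alpha < 1, cfg$scale > 0)
  class(cfg) <- "pavecell_config"
  cfg
}

# named substreams derived from the master seed
substream <- function(cfg, name) {
  offs <- c(simulate = 0L, sample = 101L, moran = 202L)
  cfg$seed + offs[[name]]
}

stage_path <- function(cfg, file) file.path(cfg$outdir, file)

read_stage <- function(cfg, file) {
  p <- stage_path(cfg, file)
  if (!file.exists(p)) {
    stop("missing pipeline input '", file,
         "' - run the upstream stage first (looked in ", cfg$outdir, ")",
         call. = FALSE)
  }
  readr::read_csv(p, show_col_types = FALSE, progress = FALSE)
}

write_stage <- function(cfg, df, file) {
  if (!dir.exists(cfg$outdir)) dir.create(cfg$outdir, recursive = TRUE)
  readr::write_csv(df, stage_path(cfg, file), progress = FALSE)
  invisible(stage_path(cfg, file))
}

#' Pipeline stages
#'
#' Each stage reads its upstream CSV artifacts from `config$outdir`, writes
#' its own, and returns the main result invisibly; stages are individually
#' re-runnable and deterministic given the configuration.
#'
#' * `pipeline_simulate()` - synthetic dataset + clade-mapped tree
#'   (`outlines.csv`, `leaves.csv`, `metadata.csv`, `ground_truth.csv`,
#'   `tree.nwk`);
#' * `pipeline_extract()` - mask directory -> `outlines.csv` (files named
#'   `<species>__<side>*.png/tif`, one or more cells per mask);
#' * `pipeline_measure()` - descriptors per cell and leaf
#'   (`cell_metrics.csv` with quartile classes, `leaf_metrics.csv`);
#' * `pipeline_efa()` - normalized Fourier coefficients
#'   (`efa_coefficients.csv`);
#' * `pipeline_summarize()` - species summaries + dataset medians
#'   (`species_summaries.csv`, `dataset_summary.csv`);
#' * `pipeline_pca()` - loadings, scores, variance fractions;
#' * `pipeline_correlate()` - leaf-cell correlations by clade subset +
#'   adaxial-abaxial report (`correlations.csv`, `side_difference.csv`);
#' * `pipeline_physignal()` - local Moran results per trait
#'   (`moran_<trait>.csv`, `moran_global.csv`);
#' * `run_pipeline()` - all of the above in order, plus `manifest.yaml`
#'   (configuration echo, package version, output file hashes).
#'
#' @param config A [pipeline_config()].
#' @param mask_dir Directory of binary masks (extract stage).
#' @name pipeline
NULL

#' @rdname pipeline
#' @export
pipeline_simulate <- function(config) {
  spec <- default_clade_spec(config$clade_spec_path)
  ds <- make_dataset(spec, cells_per_side = config$cells_per_side,
                     seed = substream(config, "simulate"))
  write_stage(config, ds$outlines, "outlines.csv")
  write_stage(config, ds$leaves, "leaves.csv")
  write_stage(config, ds$metadata, "metadata.csv")
  write_stage(config, ds$ground_truth, "ground_truth.csv")
  tree <- make_tree(seed = substream(config, "simulate"),
                    clades = ds$metadata)
  ape::write.tree(tree, stage_path(config, "tree.nwk"))
  invisible(ds)
}

#' @rdname pipeline
#' @export
pipeline_extract <- function(config, mask_dir) {
  files <- list.files(mask_dir, pattern = "\\.(png|tif|tiff)$",
                      ignore.case = TRUE, full.names = TRUE)
  if (!length(files)) stop("no mask images in ", mask_dir, call. = FALSE)
  rows <- purrr::map(files, function(f) {
    parts <- strsplit(sub("\\.[^.]+$", "", basename(f)), "__")[[1]]
    species <- parts[1]
    side <- if (length(parts) >= 2) parts[2] else "adaxial"
    cells <- trace_outlines(f, scale = config$scale,
                            min_area = config$min_area)
    purrr::imap(cells, function(o, i) dplyr::bind_cols(
      tibble::tibble(species = species,
                     cell_id = sprintf("%s_cell_%02d", basename(f), i),
                     side = side),
      as_tibble.outline(o)))
  })
  long <- dplyr::bind_rows(purrr::flatten(rows))
  write_stage(config, long, "outlines.csv")
  invisible(long)
}

#' @rdname pipeline
#' @export
pipeline_measure <- function(config) {
  cells <- read_outlines(read_stage(config, "outlines.csv")) |>
    measure_outlines(n_points = config$n_points)
  cells$quartile_solidity <- quartile_classify(cells$solidity)
  cells$quartile_aspect_ratio <- quartile_classify(cells$aspect_ratio)
  write_stage(config, cells, "cell_metrics.csv")
  leaf_path <- stage_path(config, "leaves.csv")
  if (file.exists(leaf_path)) {
    leaves <- read_outlines(read_stage(config, "leaves.csv")) |>
      measure_outlines(n_points = config$n_points)
    write_stage(config, leaves, "leaf_metrics.csv")
  }
  invisible(cells)
}

#' @rdname pipeline
#' @export
pipeline_efa <- function(config) {
  outl <- read_outlines(read_stage(config, "outlines.csv"))
  coef_rows <- purrr::pmap(outl, function(species, cell_id, side, outline) {
    cf <- efa_normalize(efa_forward(resample(outline, config$n_points),
                                    n_harmonics = config$n_harmonics))
    dplyr::bind_cols(tibble::tibble(species = species, cell_id = cell_id,
                                    side = side), tidy(cf))
  })
  out <- dplyr::bind_rows(coef_rows)
  write_stage(config, out, "efa_coefficients.csv")
  invisible(out)
}

#' @rdname pipeline
#' @export
pipeline_summarize <- function(config) {
  cells <- read_stage(config, "cell_metrics.csv")
  leaves <- tryCatch(read_stage(config, "leaf_metrics.csv"),
                     error = function(e) NULL)
  meta <- tryCatch(read_stage(config, "metadata.csv"),
                   error = function(e) NULL)
  summ <- summarize_species(cells, leaves, meta,
                            cells_per_side = config$cells_per_side,
                            seed = substream(config, "sample"))
  write_stage(config, summ, "species_summaries.csv")
  write_stage(config, dataset_summary(summ), "dataset_summary.csv")
  invisible(summ)
}

#' @rdname pipeline
#' @export
pipeline_pca <- function(config) {
  cells <- read_stage(config, "cell_metrics.csv")
  fit <- pca_descriptors(cells, standardize = config$standardize)
  write_stage(config, fit$loadings, "pca_loadings.csv")
  write_stage(config, fit$scores, "pca_scores.csv")
  write_stage(config, tibble::tibble(
    component = paste0("PC", seq_along(fit$variance_explained)),
    variance_explained = fit$variance_explained), "pca_variance.csv")
  invisible(fit)
}

#' @rdname pipeline
#' @export
pipeline_correlate <- function(config) {
  summ <- read_stage(config, "species_summaries.csv")
  subsets <- list(all = NULL, linked = config$linked_clades)
  if ("clade" %in% names(summ)) {
    subsets$other <- setdiff(unique(summ$clade), config$linked_clades)
  }
  cors <- purrr::imap(subsets, function(cl, nm) {
    res <- tryCatch(leaf_cell_correlation(summ, clades = cl),
                    error = function(e) NULL)
    if (is.null(res)) return(NULL)
    dplyr::bind_cols(tibble::tibble(subset = nm), tibble::as_tibble(res))
  }) |> dplyr::bind_rows()
  write_stage(config, cors, "correlations.csv")
  sd_res <- side_difference(summ)
  write_stage(config, sd_res$per_species, "side_difference.csv")
  write_stage(config, tibble::tibble(
    n_both_sides = sd_res$n_both_sides,
    n_abaxial_lower = sd_res$n_abaxial_lower,
    frac_abaxial_lower = sd_res$frac_abaxial_lower,
    n_excluded = sd_res$n_excluded), "side_difference_summary.csv")
  invisible(list(correlations = cors, side_difference = sd_res))
}

#' @rdname pipeline
#' @export
pipeline_physignal <- function(config) {
  tree_path <- stage_path(config, "tree.nwk")
  if (!file.exists(tree_path)) {
    stop("missing tree.nwk in ", config$outdir,
         " - supply a Newick tree or run pipeline_simulate()", call. = FALSE)
  }
  tree <- read_phylogeny(tree_path, file = TRUE)
  summ <- read_stage(config, "species_summaries.csv")
  pooled <- pool_sides(summ)
  keep <- intersect(tree$tip.label, pooled$species)
  if (length(keep) < 5) {
    stop("fewer than 5 tree tips with trait data", call. = FALSE)
  }
  tree <- ape::keep.tip(tree, keep)
  W <- proximity_matrix(tree)
  traits <- list(solidity = "mean_solidity", aspect_ratio = "mean_aspect_ratio")
  glances <- purrr::imap(traits, function(col, nm) {
    tv <- stats::setNames(pooled[[col]], pooled$species)[keep]
    res <- local_moran(tv, W, n_perm = config$n_perm,
                       seed = substream(config, "moran"),
                       alpha = config$alpha)
    write_stage(config, tidy(res), paste0("moran_", nm, ".csv"))
    dplyr::bind_cols(tibble::tibble(trait = nm), glance(res))
  })
  out <- dplyr::bind_rows(glances)
  write_stage(config, out, "moran_global.csv")
  invisible(out)
}

#' @rdname pipeline
#' @export
run_pipeline <- function(config) {
  pipeline_simulate(config)
  pipeline_measure(config)
  pipeline_efa(config)
  pipeline_summarize(config)
  pipeline_pca(config)
  pipeline_correlate(config)
  pipeline_physignal(config)
  outputs <- list.files(config$outdir, pattern = "\\.(csv|nwk)$")
  manifest <- list(
    package_version = as.character(utils::packageVersion("pavecell")),
    config = unclass(config)[setdiff(names(config), "outdir")],
    outputs = as.list(stats::setNames(
      unname(tools::md5sum(file.path(config$outdir, outputs))), outputs)))
  yaml::write_yaml(manifest, stage_path(config, "manifest.yaml"))
  invisible(manifest)
}
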