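test_that("spearman matches hand computation and the brute-force oracle", {
  expect_equal(spearman(1:10, 1:10)$rho, 1)
  expect_equal(spearman(1:10, 10:1)$rho, -1)

  # hand-ranked worked example: rho = 0.8, t on 3 df
  res <- spearman(c(1, 2, 3, 4, 5), c(1, 3, 2, 5, 4))
  expect_equal(res$rho, 0.8)
  expect_equal(res$p_value, 2 * pt(-0.8 * sqrt(3 / 0.36), df = 3))
  expect_equal(res$p_value, 0.104, tolerance = 5e-3)

  # rank-then-Pearson oracle on tie-free data
  set.seed(5)
  for (i in 1:10) {
    x <- rnorm(20); y <- rnorm(20)
    expect_equal(spearman(x, y)$rho, cor(rank(x), rank(y)), tolerance = 1e-12)
  }

  # cross-check rho against the reference implementation, with ties
  xt <- c(1, 2, 2, 3, 5, 5, 7, 8)
  yt <- c(2, 1, 4, 4, 5, 7, 6, 8)
  expect_equal(spearman(xt, yt)$rho,
               unname(cor.test(xt, yt, method = "spearman",
                               exact = FALSE)$estimate),
               tolerance = 1e-12)
  expect_error(spearman(1:4, 1:4), "n >= 5")
  expect_error(spearman(rep(1, 6), 1:6), "zero variance")
})

test_that("p-value decreases in |rho| at fixed n", {
  set.seed(8)
  res <- dplyr::bind_rows(lapply(1:30, function(i) {
    tibble::as_tibble(spearman(rnorm(12), rnorm(12)))
  }))
  ord <- order(abs(res$rho), decreasing = TRUE)
  expect_true(all(diff(res$p_value[ord]) >= -1e-12))
})

test_that("descriptor PCA separates AR and solidity as independent axes", {
  set.seed(77)
  n <- 300
  amp <- runif(n, 0, 0.3)
  ar <- runif(n, 0.3, 0.95)
  rows <- lapply(seq_len(n), function(i) {
    measure(make_lobed_cell(a = 1, b = ar[i], k = 8, amp = amp[i],
                            n_points = 150), n_points = 150)
  })
  tbl <- dplyr::bind_rows(rows)
  fit <- pca_descriptors(tbl)
  expect_gt(sum(fit$variance_explained[1:2]), 0.9)
  # AR and S loading vectors near-perpendicular in the PC1-PC2 plane
  L <- as.matrix(fit$loadings[, c("PC1", "PC2")])
  rownames(L) <- fit$loadings$descriptor
  v1 <- L["aspect_ratio", ] / sqrt(sum(L["aspect_ratio", ]^2))
  v2 <- L["solidity", ] / sqrt(sum(L["solidity", ]^2))
  expect_lt(abs(sum(v1 * v2)), 0.3)
  # variance fractions: valid simplex, loadings orthonormal
  expect_equal(sum(fit$variance_explained), 1, tolerance = 1e-12)
  expect_true(all(diff(fit$variance_explained) <= 1e-12))
  R <- as.matrix(fit$loadings[, -1])
  expect_equal(crossprod(R), diag(4), tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("PCA edge cases: single varying column, replication invariance", {
  base <- tibble::tibble(aspect_ratio = runif(20), area = 1, circularity = 1,
                         solidity = 1)
  fit <- pca_descriptors(base, standardize = FALSE)
  expect_equal(fit$variance_explained[1], 1)
  expect_error(pca_descriptors(base, standardize = TRUE), "constant")

  set.seed(2)
  tbl <- tibble::tibble(aspect_ratio = runif(15), area = rnorm(15, 10),
                        circularity = runif(15, 1, 2), solidity = runif(15))
  f1 <- pca_descriptors(tbl)
  f2 <- pca_descriptors(dplyr::bind_rows(tbl, tbl))
  expect_equal(f2$variance_explained, f1$variance_explained, tolerance = 1e-9)
})

test_that("species summaries aggregate, subsample reproducibly and validate", {
  one <- measure(make_lobed_cell(a = 1.2, b = 1, k = 6, amp = 0.15))
  cells <- dplyr::bind_cols(
    tidyr::expand_grid(species = c("spA", "spB"), side = c("adaxial", "abaxial"),
                       cell_id = sprintf("c%02d", 1:30)),
    one[rep(1, 120), ])
  meta <- tibble::tibble(species = c("spA", "spB"), clade = "fern")
  summ <- summarize_species(cells, meta = meta)
  expect_equal(summ$adaxial_solidity_sd, c(0, 0))
  expect_equal(summ$adaxial_solidity_mean, rep(one$solidity, 2))
  expect_equal(summ$solidity_diff, c(0, 0))

  # 45 supplied -> exactly 30 used, reproducibly
  set.seed(1)
  cells45 <- dplyr::bind_cols(
    tidyr::expand_grid(species = "spA", side = "adaxial",
                       cell_id = sprintf("c%02d", 1:45)),
    one[rep(1, 45), ])
  cells45$solidity <- runif(45)
  s1 <- summarize_species(cells45, seed = 99)
  s2 <- summarize_species(cells45, seed = 99)
  expect_equal(s1$adaxial_n, 30)
  expect_equal(s1$adaxial_solidity_mean, s2$adaxial_solidity_mean)

  # row order must not matter
  s3 <- summarize_species(cells45[sample(45), ], seed = 99)
  expect_equal(s1$adaxial_solidity_mean, s3$adaxial_solidity_mean)

  expect_error(summarize_species(cells, meta = meta[1, ]),
               "missing from metadata: spB")
})

test_that("side difference flags abaxial-lower-solidity species", {
  summ <- tibble::tibble(
    species = c("a", "b", "c"),
    solidity_diff = c(0.1, -0.02, NA))
  res <- side_difference(summ)
  expect_equal(res$n_both_sides, 2)
  expect_equal(res$n_abaxial_lower, 1)
  expect_equal(res$n_excluded, 1)
  expect_equal(res$per_species$solidity_diff[1], 0.1)
})

test_that("leaf-cell correlation recovers coupling and its absence", {
  set.seed(13)
  n <- 60
  cell_ar <- runif(n, 0.2, 0.9)
  linked <- tibble::tibble(
    species = sprintf("s%02d", 1:n), clade = "monocot",
    adaxial_aspect_ratio_mean = cell_ar,
    adaxial_solidity_mean = 0.8, adaxial_area_mean = 1000,
    leaf_ar = pmin(pmax(cell_ar * exp(rnorm(n, 0, 0.25)), 0.02), 1),
    solidity_diff = NA_real_)
  res <- leaf_cell_correlation(linked)
  expect_gt(res$rho, 0.5)
  expect_lt(res$p_value, 1e-4)

  # perfect rank agreement
  perf <- linked
  perf$leaf_ar <- cell_ar
  expect_equal(leaf_cell_correlation(perf)$rho, 1)

  # independent null: |rho| small, p rarely significant
  set.seed(29)
  hits <- 0; rhos <- numeric(20)
  for (i in 1:20) {
    nul <- linked
    nul$leaf_ar <- runif(n, 0.05, 0.95)
    r <- leaf_cell_correlation(nul)
    rhos[i] <- r$rho
    hits <- hits + (r$p_value < 0.05)
  }
  expect_lt(mean(abs(rhos)), 0.2)
  expect_lte(hits / 20, 0.15)

  expect_error(leaf_cell_correlation(linked, clades = "fern"))
})

test_that("dataset summary reports medians over species means", {
  summ <- tibble::tibble(
    species = c("a", "b", "c", "d"),
    adaxial_solidity_mean = c(0.9, 0.8, 0.7, 0.6),
    abaxial_solidity_mean = c(0.8, 0.7, 0.6, 0.5),
    adaxial_aspect_ratio_mean = c(0.5, 0.6, 0.7, 0.8),
    abaxial_aspect_ratio_mean = c(0.5, 0.6, 0.7, 0.8),
    adaxial_area_mean = 1, abaxial_area_mean = 1,
    solidity_diff = 0.1)
  ds <- dataset_summary(summ)
  sol <- ds[ds$metric == "solidity", ]
  expect_equal(sol$median, median(c(0.85, 0.75, 0.65, 0.55)))
  expect_equal(sol$min, 0.55)
  expect_equal(sol$n, 4)
})
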