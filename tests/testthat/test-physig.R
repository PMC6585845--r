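test_that("newick ingestion validates and preserves structure", {
  tr <- read_phylogeny("((A:1,B:1):1,C:2);")
  expect_equal(ape::Ntip(tr), 3)
  d <- ape::cophenetic.phylo(tr)
  expect_equal(d["A", "B"], 2)
  expect_equal(d["A", "C"], 4)

  expect_error(read_phylogeny("((A:1,A:1):1,C:2);"), "duplicate tip")
  expect_error(read_phylogeny("((A:1,B:1):1,C);"), "branch length")
  tr0 <- suppressMessages(read_phylogeny("((A:1,B:1):1,C);", strict = FALSE))
  expect_equal(sum(tr0$edge.length == 0), 1)

  # write -> read round trip
  tmp <- withr::local_tempfile(fileext = ".nwk")
  ape::write.tree(tr, tmp)
  tr2 <- read_phylogeny(tmp, file = TRUE)
  expect_equal(sort(tr2$tip.label), sort(tr$tip.label))
  expect_equal(ape::cophenetic.phylo(tr2)[rownames(d), colnames(d)], d)
})

test_that("proximity weights are reciprocal patristic distances", {
  tr <- read_phylogeny("((A:1,B:1):1,C:2);")
  W <- proximity_matrix(tr, row_normalize = FALSE)
  expect_equal(W["A", "B"], 0.5)
  expect_equal(W["A", "C"], 0.25)
  expect_equal(diag(W), c(A = 0, B = 0, C = 0))

  Wn <- proximity_matrix(tr)
  expect_equal(unname(Wn["A", ]), c(0, 2 / 3, 1 / 3))
  expect_equal(unname(rowSums(Wn)), rep(1, 3), tolerance = 1e-12)

  # star tree: uniform off-diagonal rows
  star <- read_phylogeny("(A:1,B:1,C:1,D:1);")
  Ws <- proximity_matrix(star)
  expect_equal(unname(Ws["A", -1]), rep(1 / 3, 3), tolerance = 1e-12)

  expect_error(proximity_matrix(read_phylogeny("((A:0,B:0):1,C:2);")),
               "zero patristic")
})

test_that("local Moran detects forced two-clade structure", {
  tr <- read_phylogeny(paste0(
    "(((A:0.2,B:0.2):0.2,(C:0.2,D:0.2):0.2):1.0,",
    "((E:0.2,F:0.2):0.2,(G:0.2,H:0.2):0.2):1.0);"))
  W <- proximity_matrix(tr)
  x <- setNames(c(1, 1.02, 0.98, 1.01, 2, 2.01, 1.97, 2.02), tr$tip.label)
  res <- local_moran(x, W, n_perm = 999, seed = 3)
  expect_true(all(res$local_i > 0))
  expect_gte(sum(res$p_raw < 0.05), 6)
  expect_true(all(res$hotspot == (res$p_raw < 0.05 & res$local_i > 0)))
  g <- attr(res, "global")
  expect_gt(g$I, 0)
  expect_lte(g$p_value, 0.05)

  # reproducibility and the row-normalized mean identity
  res2 <- local_moran(x, W, n_perm = 999, seed = 3)
  expect_equal(res$p_raw, res2$p_raw)
  expect_equal(mean(res$local_i), g$I, tolerance = 1e-12)
})

test_that("input validation: too few tips, zero variance, missing tips", {
  tr <- make_tree(6, seed = 2)
  W <- proximity_matrix(tr)
  x <- setNames(rnorm(6), tr$tip.label)
  expect_error(local_moran(x[1:4], proximity_matrix(make_tree(4, seed = 1))),
               "at least 5")
  expect_error(local_moran(setNames(rep(1, 6), tr$tip.label), W),
               "zero variance")
  expect_error(local_moran(x[1:5], W), "missing for tips")
  expect_error(local_moran(x, W, n_perm = 10), "at least 99")
})

test_that("local Moran p-values agree with the exhaustive oracle on 6 tips", {
  tr <- make_tree(6, seed = 4)
  W <- proximity_matrix(tr)
  x <- setNames(c(0.1, 0.3, 0.2, 0.9, 1.0, 0.8), tr$tip.label)
  res <- local_moran(x, W, n_perm = 999, seed = 10)

  # oracle: enumerate all 5! conditional permutations exactly
  z <- x - mean(x)
  m2 <- sum(z^2) / 6
  perms <- as.matrix(expand.grid(rep(list(1:5), 5)))
  perms <- perms[apply(perms, 1, function(p) length(unique(p)) == 5), ]
  for (i in 1:6) {
    zi <- z[-i]
    wi <- W[i, -i]
    I_obs <- z[i] / m2 * sum(wi * zi)
    I_all <- apply(perms, 1, function(p) z[i] / m2 * sum(wi * zi[p]))
    p_exact <- (1 + sum(I_all >= I_obs - 1e-9)) / (1 + nrow(perms))
    expect_equal(res$local_i[i], unname(I_obs), tolerance = 1e-12)
    expect_lt(abs(res$p_raw[i] - p_exact), 0.08)
  }
})

test_that("global Moran is calibrated against its null expectation", {
  tr <- make_tree(50, seed = 11)
  W <- proximity_matrix(tr)
  Is <- vapply(1:200, function(s) {
    x <- withr::with_seed(4000 + s, rnorm(50))
    names(x) <- tr$tip.label
    z <- x - mean(x)
    (50 / sum(W)) * sum(z * (W %*% z)) / sum(z^2)
  }, numeric(1))
  expect_lt(abs(mean(Is) - (-1 / 49)), 0.02)

  # anti-correlated arrangement on a cherry chain: I below expectation
  star <- read_phylogeny("((A:1,B:1):1,(C:1,D:1):1,(E:1,F:1):1);")
  Wd <- proximity_matrix(star)
  alt <- setNames(c(1, -1, 1, -1, 1, -1), star$tip.label)
  g <- global_moran(alt, Wd, n_perm = 199, seed = 1)
  expect_lt(g$I, g$expectation)
})

test_that("Brownian simulation matches closed-form moments", {
  star <- read_phylogeny("(A:2,B:2,C:2,D:2,E:2,F:2,G:2,H:2);")
  vals <- vapply(1:2000, function(s) simulate_brownian(star, sigma2 = 0.5,
                                                       seed = s)[1],
                 numeric(1))
  expect_equal(var(vals), 0.5 * 2, tolerance = 0.15)
  expect_equal(mean(vals), 0, tolerance = 0.1)

  # sister tips with tiny terminal branches are near-identical
  sis <- read_phylogeny("((A:0.001,B:0.001):1,C:1.001);")
  ab <- vapply(1:500, function(s) {
    x <- simulate_brownian(sis, 1, seed = s)
    x["A"] - x["B"]
  }, numeric(1))
  expect_lt(sd(ab), 0.1)

  expect_equal(simulate_brownian(star, 1, seed = 7),
               simulate_brownian(star, 1, seed = 7))
})

test_that("permutation p-values are never zero and BH column is adjusted", {
  tr <- make_tree(10, seed = 6)
  W <- proximity_matrix(tr)
  x <- simulate_brownian(tr, 1, seed = 2)
  res <- local_moran(x, W, n_perm = 99, seed = 5)
  expect_true(all(res$p_raw > 0))
  expect_true(all(res$p_raw <= 1))
  expect_equal(res$p_bh, p.adjust(res$p_raw, "BH"))
  expect_true(all(res$p_bh >= res$p_raw - 1e-12))
})
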