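test_that("forward transform matches an FFT oracle on equal-arc outlines", {
  # for equally spaced points the closed-form sums must agree with a plain
  # DFT of the coordinate series
  ell <- resample(ellipse_outline(a = 2, b = 1, n = 1024), 1024)
  xy <- unclass(ell)
  fx <- stats::fft(xy[, 1]) / 1024
  fy <- stats::fft(xy[, 2]) / 1024
  oracle <- vapply(1:10, function(n) 2 * (Mod(fx[n + 1])^2 + Mod(fy[n + 1])^2),
                   numeric(1))
  hp <- harmonic_power(efa_forward(ell, 10, align = "none"))
  expect_equal(hp$power / sum(hp$power), oracle / sum(oracle),
               tolerance = 1e-6)
})

test_that("harmonic-1 dominance on ellipses follows the oracle values", {
  # arc-length traversal of a 2:1 ellipse carries ~0.58% of power above
  # harmonic 1 (FFT-verified); a mild ellipse is first-harmonic pure to
  # better than 99.9%
  cf <- efa_forward(resample(ellipse_outline(2, 1, 512), 256), 20)
  hp <- harmonic_power(cf)
  expect_equal(hp$cumulative[1], 0.99425, tolerance = 1e-3)
  expect_lt(max(hp$power[-1] / sum(hp$power)), 0.006)

  mild <- efa_forward(resample(ellipse_outline(1.15, 1, 512), 256), 20)
  expect_gt(harmonic_power(mild)$cumulative[1], 0.999)
  expect_equal(select_harmonics(mild), 1L)

  circ <- harmonic_power(efa_forward(circle_outline(n = 256), 20))
  expect_gt(circ$cumulative[1], 0.999)
})

test_that("a k-lobed outline concentrates power at harmonics k-1 and k+1", {
  for (k in c(6, 8)) {
    lob <- resample(make_lobed_cell(a = 1, b = 1, k = k, amp = 0.2,
                                    n_points = 512), 512)
    hp <- harmonic_power(efa_forward(lob, 40, align = "none"))
    higher <- hp[hp$harmonic >= 2, ]
    peak <- higher$harmonic[which.max(higher$power)]
    expect_true(peak %in% c(k - 1, k + 1))
  }
})

test_that("select_harmonics validates thresholds and handles a square", {
  sq <- efa_forward(resample(unit_square(), 256), 50)
  expect_lte(select_harmonics(sq), 10)
  expect_error(select_harmonics(sq, threshold = 1.2), "in \\(0, 1\\)")
  ell <- efa_forward(resample(ellipse_outline(2, 1, 512), 256), 50)
  expect_error(efa_forward(resample(unit_square(), 16), 8), "n_harmonics")
})

test_that("normalization is invariant to rotation, start point and scale", {
  lob <- make_lobed_cell(a = 1.6, b = 1, k = 7, amp = 0.15, phase = 0.4,
                         n_points = 256)
  n1 <- efa_normalize(efa_forward(lob, 12))
  moved <- cycle_outline(rotate_outline(lob, pi / 2), 31)
  n2 <- efa_normalize(efa_forward(moved, 12))
  expect_equal(n1$coef, n2$coef, tolerance = 1e-6)

  xy <- unclass(lob) * 3
  n3 <- efa_normalize(efa_forward(outline(xy[, 1], xy[, 2]), 12))
  expect_equal(n1$coef, n3$coef, tolerance = 1e-6)

  expect_equal(unname(abs(n1$coef[1, "a"])), 1, tolerance = 1e-9)
  expect_equal(unname(n1$coef[1, "b"]), 0, tolerance = 1e-9)
  expect_equal(unname(n1$coef[1, "c"]), 0, tolerance = 1e-9)
})

test_that("mirroring an asymmetric outline changes normalized coefficients", {
  # asymmetric: two lobe systems at incommensurate phases
  th <- seq(0, 2 * pi, length.out = 257)[-257]
  r <- 1 + 0.15 * sin(5 * th + 0.7) + 0.08 * sin(3 * th)
  o <- outline(1.4 * r * cos(th), r * sin(th))
  xy <- unclass(o)
  mir <- outline(-xy[, 1], xy[, 2])
  nm <- efa_normalize(efa_forward(o, 12))
  nmir <- efa_normalize(efa_forward(mir, 12))
  expect_gt(max(abs(nm$coef - nmir$coef)), 1e-3)
})

test_that("inverse synthesis converges and N=1 yields an ellipse", {
  lob <- resample(make_lobed_cell(a = 1, b = 1, k = 6, amp = 0.2,
                                  n_points = 500), 500)
  errs <- vapply(c(1, 5, 10, 20), function(N) efa_reconstruction_error(lob, N),
                 numeric(1))
  expect_true(all(diff(errs) <= 1e-12))
  expect_lt(errs[4], 0.01)            # < 1% of mean radius at N = 20

  # truncation error scales as sqrt(residual power fraction): the ellipse
  # keeps a third-harmonic residual from its arc-length parameterization
  for (ab in c(1.15, 2)) {
    ell <- resample(ellipse_outline(ab, 1, 512), 256)
    resid <- 1 - harmonic_power(efa_forward(ell, 30, align = "none"))$cumulative[2]
    err <- efa_reconstruction_error(ell, 2)
    expect_lt(err, 2 * sqrt(resid))
    expect_gt(err, 0.2 * sqrt(resid))
  }

  one <- efa_inverse(efa_forward(lob, 1), 256)
  expect_equal(solidity(one), 1, tolerance = 1e-3)
})

test_that("inverse and forward are Parseval-consistent", {
  lob <- resample(make_lobed_cell(a = 1.3, b = 1, k = 8, amp = 0.2,
                                  n_points = 512), 512)
  cf <- efa_forward(lob, 20, align = "none")
  rec <- efa_inverse(cf, 512)

  # exact identity: the DFT of the reconstruction sampled at its synthesis
  # parameter recovers every coefficient
  xy <- unclass(rec)
  fx <- stats::fft(xy[, 1]) / 512
  fy <- stats::fft(xy[, 2]) / 512
  for (n in 1:20) {
    expect_equal(2 * Re(fx[n + 1]), unname(cf$coef[n, "a"]), tolerance = 1e-10)
    expect_equal(-2 * Im(fx[n + 1]), unname(cf$coef[n, "b"]), tolerance = 1e-10)
    expect_equal(2 * Re(fy[n + 1]), unname(cf$coef[n, "c"]), tolerance = 1e-10)
    expect_equal(-2 * Im(fy[n + 1]), unname(cf$coef[n, "d"]), tolerance = 1e-10)
  }

  # re-transforming the reconstruction re-parameterizes by chord length, so
  # total power matches only approximately (sub-percent on smooth outlines)
  cf2 <- efa_forward(rec, 20, align = "none")
  expect_equal(sum(harmonic_power(cf)$power), sum(harmonic_power(cf2)$power),
               tolerance = 0.01)
})

test_that("coefficient distances track aspect ratio, not undulation", {
  # the known blind spot of normalized EFA for margin undulation: on a
  # factorial amp x AR grid, pairwise coefficient distance rank-correlates
  # strongly with AR differences and weakly with solidity differences
  grid <- expand.grid(amp = seq(0, 0.3, length.out = 5),
                      ar = seq(0.3, 0.9, length.out = 5))
  cells <- Map(function(am, ar) make_lobed_cell(a = 1, b = ar, k = 8, amp = am),
               grid$amp, grid$ar)
  cfv <- vapply(cells, function(o)
    as.vector(efa_normalize(efa_forward(resample(o, 300), 20))$coef),
    numeric(80))
  S <- vapply(cells, solidity, numeric(1))
  AR <- vapply(cells, aspect_ratio, numeric(1))
  D <- as.vector(dist(t(cfv)))
  r_s <- cor(D, as.vector(dist(S)), method = "spearman")
  r_ar <- cor(D, as.vector(dist(AR)), method = "spearman")
  expect_gt(r_ar, r_s + 0.3)
})
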