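#' Read and validate a rooted Newick phylogeny
#'
#' Thin wrapper over [ape::read.tree()] that enforces the invariants the
#' signal tests rely on: unique tip labels and branch lengths present.
#' Zero-length branches are allowed but reported via a message.
#'
#' @param text Newick string, or a file path when `file = TRUE`.
#' @param file Treat `text` as a path.
#' @param strict Error on missing branch lengths (otherwise they become 0).
#' @return An [ape::read.tree()] `phylo` object.
#' @export
read_phylogeny <- function(text, file = FALSE, strict = TRUE) {
  tr <- if (file) ape::read.tree(text) else ape::read.tree(text = text)
  if (is.null(tr)) stop("could not parse Newick input", call. = FALSE)
  if (anyDuplicated(tr$tip.label)) {
    stop("duplicate tip labels: ",
         paste(unique(tr$tip.label[duplicated(tr$tip.label)]), collapse = ", "),
         call. = FALSE)
  }
  if (is.null(tr$edge.length)) {
    if (strict) stop("tree has no branch lengths", call. = FALSE)
    tr$edge.length <- rep(0, nrow(tr$edge))
  }
  if (anyNA(tr$edge.length)) {
    if (strict) stop("tree has missing branch lengths", call. = FALSE)
    tr$edge.length[is.na(tr$edge.length)] <- 0
  }
  if (any(tr$edge.length == 0)) {
    message("note: tree contains zero-length branches")
  }
  tr
}

#' Phylogenetic proximity weights from patristic distances
#'
#' Builds the spatial-style weight matrix used by the Moran statistics:
#' `w_ij = 1 / d_ij` for the patristic (sum-of-branch-lengths) distance
#' `d_ij`, zero diagonal, optionally row-normalized so each row sums to 1.
#'
#' @param tree A `phylo` object with branch lengths.
#' @param method Currently `"inverse_patristic"`.
#' @param row_normalize Normalize each row to sum 1 (default).
#' @return A matrix with attributes `row_normalized` and `method`; row and
#'   column names are the tip labels.
#' @export
proximity_matrix <- function(tree, method = "inverse_patristic",
                             row_normalize = TRUE) {
  method <- match.arg(method, "inverse_patristic")
  d <- ape::cophenetic.phylo(tree)
  off <- d[upper.tri(d)]
  if (any(off == 0)) {
    idx <- which(d == 0 & upper.tri(d), arr.ind = TRUE)[1, ]
    stop(sprintf("tips at zero patristic distance: %s and %s",
                 rownames(d)[idx[1]], colnames(d)[idx[2]]), call. = FALSE)
  }
  w <- 1 / d
  diag(w) <- 0
  if (row_normalize) w <- w / rowSums(w)
  attr(w, "row_normalized") <- row_normalize
  attr(w, "method") <- method
  w
}

# align a named trait vector with the weight matrix's tip order
align_trait <- function(trait, W) {
  tips <- rownames(W)
  if (is.null(names(trait))) {
    if (length(trait) != nrow(W)) {
      stop("unnamed trait vector must match the weight matrix dimension",
           call. = FALSE)
    }
    return(stats::setNames(as.numeric(trait), tips))
  }
  miss <- setdiff(tips, names(trait))
  if (length(miss)) {
    stop("trait values missing for tips: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  trait[tips]
}

#' Local Moran's I across the tips of a phylogeny
#'
#' Per-tip autocorrelation statistic
#' `I_i = (z_i / m_2) * sum_j w_ij z_j` with `z_i = x_i - mean(x)` and
#' `m_2 = sum(z^2) / n`, detecting local hotspots where a tip and its
#' phylogenetic neighbourhood share similar trait values. Significance is
#' assessed by conditional permutation: tip i's value is held fixed while
#' the remaining values are shuffled across the other tips. The default
#' test is one-sided for positive autocorrelation (hotspots), mirroring the
#' hotspot use of the statistic; p-values are
#' `(1 + #[perm >= obs]) / (1 + n_perm)` and therefore never 0. Raw and
#' Benjamini-Hochberg-adjusted p-values are both reported.
#'
#' @param trait Named numeric vector (tip label -> value), or unnamed in
#'   the weight-matrix tip order.
#' @param W Proximity matrix from [proximity_matrix()].
#' @param n_perm Number of permutations (>= 99; default 999).
#' @param seed Integer seed; results are reproducible given it.
#' @param alpha Hotspot significance level (default 0.05).
#' @param alternative `"greater"` (hotspots; default) or `"two.sided"`.
#' @return An object of class `pavecell_moran`: tibble with `tip`,
#'   `local_i`, `p_raw`, `p_bh`, `hotspot` (`p_raw < alpha` and
#'   `local_i > 0`), `hotspot_bh`; attributes hold the matching
#'   [global_moran()] results, `n_perm`, `seed`, `alpha`.
#' @export
local_moran <- function(trait, W, n_perm = 999L, seed = 1L, alpha = 0.05,
                        alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  x <- align_trait(trait, W)
  n <- length(x)
  if (n < 5) stop("local Moran's I needs at least 5 tips", call. = FALSE)
  if (n_perm < 99) stop("use at least 99 permutations", call. = FALSE)
  z <- x - mean(x)
  if (all(z == 0)) stop("trait has zero variance", call. = FALSE)
  m2 <- sum(z^2) / n
  lag <- as.vector(W %*% z)
  I_obs <- z / m2 * lag
  p <- numeric(n)
  withr::with_seed(seed, {
    for (i in seq_len(n)) {
      zi <- z[-i]
      wi <- W[i, -i]
      # n_perm conditional permutations of the other tips' values
      idx <- vapply(seq_len(n_perm), function(k) sample.int(n - 1L),
                    integer(n - 1L))
      lag_perm <- as.vector(wi %*% matrix(zi[idx], nrow = n - 1L))
      I_perm <- z[i] / m2 * lag_perm
      # tie-tolerant counting: on ultrametric trees permuted lags often tie
      # with the observed value exactly, and fp noise must not break ties
      tol <- 1e-9 * max(1, abs(I_obs[i]))
      p[i] <- if (alternative == "greater") {
        (1 + sum(I_perm >= I_obs[i] - tol)) / (1 + n_perm)
      } else {
        (1 + sum(abs(I_perm) >= abs(I_obs[i]) - tol)) / (1 + n_perm)
      }
    }
  })
  res <- tibble::tibble(
    tip = names(x), local_i = unname(I_obs), p_raw = p,
    p_bh = stats::p.adjust(p, method = "BH"),
    hotspot = p < alpha & I_obs > 0,
    hotspot_bh = stats::p.adjust(p, method = "BH") < alpha & I_obs > 0)
  class(res) <- c("pavecell_moran", class(res))
  attr(res, "global") <- global_moran(x, W, n_perm = n_perm, seed = seed,
                                      alternative = alternative)
  attr(res, "n_perm") <- n_perm
  attr(res, "seed") <- seed
  attr(res, "alpha") <- alpha
  attr(res, "method") <- attr(W, "method")
  res
}

#' Global Moran's I on a phylogeny
#'
#' The cross-product statistic
#' `I = (n / S0) * sum_ij w_ij z_i z_j / sum_i z_i^2` with
#' `S0 = sum_ij w_ij`; its expectation under exchangeability is
#' `E[I] = -1 / (n - 1)`. Significance by total randomization of the trait
#' across tips.
#'
#' @inheritParams local_moran
#' @return A list: `I`, `expectation`, `p_value`, `n`, `n_perm`, `seed`.
#' @export
global_moran <- function(trait, W, n_perm = 999L, seed = 1L,
                         alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  x <- align_trait(trait, W)
  n <- length(x)
  z <- x - mean(x)
  if (all(z == 0)) stop("trait has zero variance", call. = FALSE)
  s0 <- sum(W)
  stat <- function(zz) (n / s0) * sum(zz * (W %*% zz)) / sum(zz^2)
  I_obs <- stat(z)
  I_perm <- withr::with_seed(seed,
    vapply(seq_len(n_perm), function(k) stat(z[sample.int(n)]), numeric(1)))
  tol <- 1e-9 * max(1, abs(I_obs))
  p <- if (alternative == "greater") {
    (1 + sum(I_perm >= I_obs - tol)) / (1 + n_perm)
  } else {
    e <- -1 / (n - 1)
    (1 + sum(abs(I_perm - e) >= abs(I_obs - e) - tol)) / (1 + n_perm)
  }
  list(I = I_obs, expectation = -1 / (n - 1), p_value = p, n = n,
       n_perm = n_perm, seed = seed)
}

#' @export
print.pavecell_moran <- function(x, ...) {
  g <- attr(x, "global")
  cat(sprintf(
    "<pavecell_moran> %d tips; global I = %.4f (E[I] = %.4f, p = %.4g); %d hotspot tip(s) at alpha = %g\n",
    nrow(x), g$I, g$expectation, g$p_value, sum(x$hotspot), attr(x, "alpha")))
  invisible(x)
}

#' @rdname local_moran
#' @param x A `pavecell_moran` object.
#' @param ... Unused.
#' @export
tidy.pavecell_moran <- function(x, ...) {
  tibble::as_tibble(unclass(x)[c("tip", "local_i", "p_raw", "p_bh",
                                 "hotspot", "hotspot_bh")])
}

#' @rdname local_moran
#' @export
glance.pavecell_moran <- function(x, ...) {
  g <- attr(x, "global")
  tibble::tibble(n = g$n, global_i = g$I, expectation = g$expectation,
                 p_value = g$p_value, n_hotspot = sum(x$hotspot),
                 frac_hotspot = mean(x$hotspot), n_perm = g$n_perm)
}

#' Simulate a Brownian-motion trait on a tree
#'
#' Root-to-tip accumulation of independent normal increments with variance
#' `sigma2 * branch length`; the standard positive control for
#' phylogenetic-signal tests.
#'
#' @param tree A `phylo` object.
#' @param sigma2 Increment variance per unit branch length (> 0).
#' @param seed Integer seed.
#' @param root Root state (default 0).
#' @return Named numeric vector of tip trait values.
#' @export
simulate_brownian <- function(tree, sigma2 = 1, seed = 1L, root = 0) {
  stopifnot(sigma2 > 0)
  withr::with_seed(seed,
    ape::rTraitCont(tree, model = "BM", sigma = sqrt(sigma2),
                    root.value = root))
}
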