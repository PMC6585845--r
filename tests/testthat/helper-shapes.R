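# shared shape constructors and small utilities for the tests

circle_outline <- function(r = 1, n = 256, cx = 0, cy = 0) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  outline(cx + r * cos(th), cy + r * sin(th))
}

ellipse_outline <- function(a = 2, b = 1, n = 256) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  outline(a * cos(th), b * sin(th))
}

# five unit squares arranged as a plus sign; area 5, hull area 7 (octagon)
plus_outline <- function() {
  outline(c(1, 2, 2, 3, 3, 2, 2, 1, 1, 0, 0, 1),
          c(0, 0, 1, 1, 2, 2, 3, 3, 2, 2, 1, 1))
}

unit_square <- function() outline(c(0, 1, 1, 0), c(0, 0, 1, 1))

rect_2x1 <- function() outline(c(0, 2, 2, 0), c(0, 0, 1, 1))

rotate_outline <- function(o, ang) {
  xy <- unclass(o) %*% cbind(c(cos(ang), -sin(ang)), c(sin(ang), cos(ang)))
  outline(xy[, 1], xy[, 2], label = attr(o, "label"))
}

cycle_outline <- function(o, k) {
  xy <- unclass(o)
  n <- nrow(xy)
  idx <- c((k + 1):n, 1:k)
  outline(xy[idx, 1], xy[idx, 2])
}

# tiny clade specification for fast pipeline tests
small_clade_spec <- function(n_species = 4) {
  tibble::tibble(
    clade = c("fern", "monocot", "eudicot"),
    n_species = n_species,
    solidity_mean = c(0.68, 0.88, 0.78), solidity_sd = c(0.06, 0.04, 0.06),
    ar_mean = c(0.60, 0.35, 0.65), ar_sd = 0.08,
    amp_noise_sd = 0.02, jitter_sd = 0.01,
    abaxial_amp_offset = 0.05, leaf_link = c(TRUE, TRUE, FALSE))
}
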