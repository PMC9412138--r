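# Independent oracles and fixture builders shared across the suite.

# Keep test output quiet; warnings still surface through testthat.
options(conchmetrics.log_level = "error")

# Heron's-formula per-face area summation: an implementation-independent
# check of the cross-product surface area.
heron_area <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  total <- 0
  for (i in seq_len(nrow(f))) {
    a <- sqrt(sum((v[f[i, 1], ] - v[f[i, 2], ])^2))
    b <- sqrt(sum((v[f[i, 2], ] - v[f[i, 3], ])^2))
    c <- sqrt(sum((v[f[i, 3], ] - v[f[i, 1], ])^2))
    s <- (a + b + c) / 2
    total <- total + sqrt(max(0, s * (s - a) * (s - b) * (s - c)))
  }
  total
}

# Brute-force sphere stamping: the defining computation of the influence
# volume, used as the oracle for the EDT-based implementation.
brute_dilation_volume <- function(occ, r) {
  dims <- dim(occ)
  off <- as.matrix(expand.grid(
    x = -floor(r):floor(r), y = -floor(r):floor(r), z = -floor(r):floor(r)
  ))
  off <- off[rowSums(off^2) <= r^2 + 1e-9, , drop = FALSE]
  idx <- which(occ, arr.ind = TRUE)
  out <- array(FALSE, dims)
  for (i in seq_len(nrow(idx))) {
    pts <- sweep(off, 2, idx[i, ], "+")
    keep <- pts[, 1] >= 1 & pts[, 1] <= dims[1] &
      pts[, 2] >= 1 & pts[, 2] <= dims[2] &
      pts[, 3] >= 1 & pts[, 3] <= dims[3]
    out[pts[keep, , drop = FALSE]] <- TRUE
  }
  sum(out)
}

# Two-pass product-moment correlation with the textbook t-transform p-value:
# the oracle for pearson_matrix().
brute_pearson <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]
  y <- y[ok]
  n <- length(x)
  mx <- mean(x)
  my <- mean(y)
  r <- sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
  t_stat <- r * sqrt((n - 2) / (1 - r^2))
  p <- 2 * stats::pt(-abs(t_stat), df = n - 2)
  list(r = r, p = p, n = n)
}

# Small ribbed/smooth pair at test resolution (coil minimums).
test_pair <- function(rib_amplitude = 0.5, seed = 3, ...) {
  generate_pair(
    coil_params(steps_per_whorl = 64L, sections = 32L, ...),
    ornament_params(rib_amplitude = rib_amplitude, seed = seed)
  )
}

# Random closed mesh with fixed topology: an icosphere with seeded radial
# noise (stays star-shaped, watertight, non-symmetric).
random_bumpy_mesh <- function(seed, radius = 2, subdivisions = 2,
                              noise = 0.15) {
  m <- make_primitive("icosphere", radius = radius,
                      subdivisions = subdivisions)
  set.seed(seed)
  scale <- 1 + noise * (stats::runif(nrow(m$vertices)) - 0.5)
  m$vertices <- m$vertices * scale
  m$name <- paste0("bumpy_", seed)
  m
}

oi_of_pair <- function(pair) {
  ornamentation_index(surface_area(pair$ornamented),
                      surface_area(pair$smooth))
}

two_cubes_mesh <- function() {
  c1 <- make_primitive("cube")
  c2 <- translate_mesh(make_primitive("cube"), c(3, 0, 0))
  triangle_mesh(rbind(c1$vertices, c2$vertices),
                rbind(c1$faces, c2$faces + nrow(c1$vertices)),
                name = "two_cubes")
}
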