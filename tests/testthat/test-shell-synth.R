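# Parametric conch generator and ornament displacement field.

test_that("parameter constructors validate their domains", {
  expect_error(coil_params(whorl_expansion = 1), "exceed 1")
  expect_error(coil_params(umbilical_ratio = 1), "\\[0, 1\\)")
  expect_error(coil_params(n_whorls = 0), "positive")
  expect_error(coil_params(steps_per_whorl = 32), ">= 64")
  expect_error(ornament_params(rib_amplitude = -1), ">= 0")
})

test_that("generated conches are watertight and planispiral", {
  coil <- coil_params(steps_per_whorl = 64L, sections = 32L)
  smooth <- generate_conch(coil)
  d <- validate_mesh(smooth)
  expect_true(d$is_watertight)
  expect_identical(d$n_components, 1L)
  expect_gt(enclosed_volume(smooth), 0)

  # translation = 0: reflection through the coiling plane maps the vertex
  # set onto itself
  v <- smooth$vertices
  refl <- v
  refl[, 3] <- -refl[, 3]
  key <- function(m) sort(paste(round(m[, 1], 9), round(m[, 2], 9),
                                round(m[, 3], 9)))
  expect_identical(key(refl), key(v))

  # helicospiral version is not symmetric but still watertight
  heli <- generate_conch(coil_params(steps_per_whorl = 64L, sections = 32L,
                                     translation = 0.3))
  expect_true(validate_mesh(heli)$is_watertight)
  expect_false(identical(key(heli$vertices),
                         key(local({h <- heli$vertices; h[, 3] <- -h[, 3]; h}))))
})

test_that("a quarter-whorl near-circular tube approximates a torus segment", {
  # expansion ~ 1 and circular aperture: area ~ quarter torus + end caps
  a <- 1                      # tube radius
  coil <- coil_params(
    whorl_expansion = 1.0001, umbilical_ratio = 0.6,
    aperture_width = a, aperture_height = a,
    n_whorls = 0.25, steps_per_whorl = 512L, sections = 128L
  )
  m <- generate_conch(coil)
  R <- a * 1.6 / 0.4          # centre radius from the umbilical ratio
  analytic <- 2 * pi * a * (pi / 2) * R + 2 * pi * a^2  # tube + two caps
  expect_lt(abs(surface_area(m) - analytic) / analytic, 0.02)
})

test_that("surface area converges as the sweep is refined", {
  base <- coil_params(steps_per_whorl = 128L, sections = 48L)
  fine <- coil_params(steps_per_whorl = 256L, sections = 48L)
  a1 <- surface_area(generate_conch(base))
  a2 <- surface_area(generate_conch(fine))
  expect_lt(abs(a2 - a1) / a1, 0.005)
})

test_that("ornament displacement is identity at zero amplitude and grows area", {
  coil <- coil_params(steps_per_whorl = 64L, sections = 32L)
  smooth <- generate_conch(coil)
  same <- apply_ornament(smooth, ornament_params())
  expect_identical(same$vertices, smooth$vertices)

  a_half <- surface_area(apply_ornament(
    smooth, ornament_params(rib_amplitude = 0.5, seed = 9)))
  a_one <- surface_area(apply_ornament(
    smooth, ornament_params(rib_amplitude = 1.0, seed = 9)))
  expect_gt(a_half, surface_area(smooth))
  expect_gt(a_one, a_half)

  # meshes without parametrization metadata are refused
  expect_error(apply_ornament(make_primitive("cube"),
                              ornament_params(rib_amplitude = 1)),
               "parametrization")
})

test_that("identical parameters and seed reproduce bitwise-identical pairs", {
  orn <- ornament_params(rib_amplitude = 0.6, node_amplitude = 0.4,
                         node_density = 10, seed = 42)
  coil <- coil_params(steps_per_whorl = 64L, sections = 32L)
  p1 <- generate_pair(coil, orn)
  p2 <- generate_pair(coil, orn)
  expect_identical(p1$ornamented$vertices, p2$ornamented$vertices)
  expect_identical(p1$smooth$vertices, p2$smooth$vertices)
  # a different seed moves the nodes
  p3 <- generate_pair(coil, ornament_params(rib_amplitude = 0.6,
                                            node_amplitude = 0.4,
                                            node_density = 10, seed = 43))
  expect_false(identical(p1$ornamented$vertices, p3$ornamented$vertices))
  # the generator does not disturb the caller's RNG stream
  set.seed(123)
  before <- runif(1)
  generate_pair(coil, orn)
  set.seed(123)
  expect_identical(before, runif(1))
})

test_that("pairs share topology and OI rises strictly with rib amplitude", {
  amplitudes <- c(0, 0.2, 0.4, 0.8, 1.6)
  ois <- vapply(amplitudes, function(a) oi_of_pair(test_pair(a)), numeric(1))
  expect_identical(ois[1], 0)
  expect_true(all(diff(ois) > 0))
  expect_equal(cor(ois, amplitudes, method = "spearman"), 1)

  pair <- test_pair(0.8)
  expect_identical(pair$ornamented$faces, pair$smooth$faces)
  expect_gte(surface_area(pair$ornamented), surface_area(pair$smooth))
  expect_gt(pair$true_amplitude_summary, 0)
})

test_that("all ornament families add area, including spiral ridges and nodes", {
  coil <- coil_params(steps_per_whorl = 64L, sections = 32L)
  smooth <- generate_conch(coil)
  a0 <- surface_area(smooth)
  spiral <- apply_ornament(smooth, ornament_params(spiral_amplitude = 0.5))
  nodes <- apply_ornament(smooth, ornament_params(node_amplitude = 0.8,
                                                  node_density = 12,
                                                  seed = 2))
  expect_gt(surface_area(spiral), a0)
  expect_gt(surface_area(nodes), a0)
  expect_true(validate_mesh(spiral)$is_watertight)
  expect_true(validate_mesh(nodes)$is_watertight)
})

test_that("doubled whorl width moves rugosity far more than OI", {
  # the shape-sensitivity contrast: widening the whorl leaves the silhouette
  # on the coiling plane nearly unchanged and inflates rugosity, while OI,
  # which compares like-for-like surfaces, moves much less
  mk <- function(w) generate_pair(
    coil_params(steps_per_whorl = 96L, sections = 48L, aperture_width = w),
    ornament_params(rib_amplitude = 0.3, seed = 7)
  )
  p1 <- mk(3)
  p2 <- mk(6)
  sp1 <- projected_area(p1$ornamented, c(0, 0, 1), 0.05)
  sp2 <- projected_area(p2$ornamented, c(0, 0, 1), 0.05)
  expect_lt(abs(sp2 / sp1 - 1), 0.05)  # silhouette ~constant

  rug1 <- rugosity(p1$ornamented, c(0, 0, 1), 0.05)
  rug2 <- rugosity(p2$ornamented, c(0, 0, 1), 0.05)
  oi1 <- oi_of_pair(p1)
  oi2 <- oi_of_pair(p2)
  rug_change <- abs(rug2 - rug1) / rug1
  oi_change <- abs(oi2 - oi1) / oi1
  expect_gt(rug_change, 0.25)          # rugosity is strongly shape-driven
  expect_lt(oi_change, rug_change)     # OI is the less shape-sensitive index
})

test_that("primitives deliver their advertised closed forms", {
  expect_identical(nrow(make_primitive("icosphere",
                                       subdivisions = 4)$faces), 5120L)
  expect_true(validate_mesh(make_primitive("icosphere",
                                           subdivisions = 2))$is_watertight)
  patch <- make_primitive("flat_patch")
  expect_equal(surface_area(patch), 1)
  expect_false(validate_mesh(patch)$is_watertight)
  tube <- make_primitive("line_tube", length = 10, radius = 0.1)
  expect_true(validate_mesh(tube)$is_watertight)
  # inscribed 24-gon cross-section: volume deficit 1 - sinc(2*pi/24) ~ 1.1%
  expect_equal(enclosed_volume(tube), pi * 0.1^2 * 10, tolerance = 0.02)
})
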