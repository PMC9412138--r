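# Surface area, volume, silhouette, rugosity, OI, symmetry plane.

test_that("surface area and volume match closed forms and the Heron oracle", {
  cube <- make_primitive("cube")
  expect_equal(surface_area(cube), 6)
  expect_equal(enclosed_volume(cube), 1)

  box <- make_primitive("box", size = c(1, 2, 3))
  expect_equal(surface_area(box), 22)
  expect_equal(enclosed_volume(box), 6)

  ico <- make_primitive("icosphere", radius = 1, subdivisions = 4)
  expect_lt(abs(surface_area(ico) - 4 * pi) / (4 * pi), 0.002)
  expect_lt(surface_area(ico), 4 * pi)  # inscribed polyhedron is below
  expect_lt(abs(enclosed_volume(ico) - 4 * pi / 3) / (4 * pi / 3), 0.003)

  # area converges with subdivision
  errs <- vapply(2:4, function(s) {
    abs(surface_area(make_primitive("icosphere", subdivisions = s)) - 4 * pi)
  }, numeric(1))
  expect_true(all(diff(errs) < 0))

  # independent per-face summation oracle on arbitrary meshes
  for (seed in 1:3) {
    m <- random_bumpy_mesh(seed)
    expect_equal(surface_area(m), heron_area(m), tolerance = 1e-10)
  }
})

test_that("volume is orientation-insensitive and refuses open meshes", {
  cube <- make_primitive("cube")
  inward <- cube
  inward$faces <- inward$faces[, c(1, 3, 2)]
  expect_equal(enclosed_volume(inward), 1)
  expect_error(enclosed_volume(make_primitive("flat_patch")),
               "not watertight")
})

test_that("S/V behaves dimensionally: 3/r for spheres, 1/k under scaling", {
  expect_equal(sv_ratio(make_primitive("cube")), 6)
  ico <- make_primitive("icosphere", radius = 2, subdivisions = 3)
  expect_lt(abs(sv_ratio(ico) - 3 / 2) / (3 / 2), 0.005)
  m <- random_bumpy_mesh(4)
  expect_equal(sv_ratio(scale_mesh(m, 3)), sv_ratio(m) / 3,
               tolerance = 1e-12)
})

test_that("projected silhouette area matches analytic shapes", {
  patch <- make_primitive("flat_patch")
  expect_equal(projected_area(patch, c(0, 0, 1), 0.05), 1,
               tolerance = 1e-9)

  hemi <- make_primitive("hemisphere", radius = 10)
  expect_lt(abs(projected_area(hemi, c(0, 0, 1), 0.05) - 100 * pi) /
              (100 * pi), 0.01)

  # closed sphere: front and back project onto the same disk, counted once
  ball <- make_primitive("icosphere", radius = 10, subdivisions = 4)
  for (normal in list(c(0, 0, 1), c(1, 1, 1))) {
    expect_lt(abs(projected_area(ball, normal, 0.05) - 100 * pi) /
                (100 * pi), 0.01)
  }
  expect_error(projected_area(patch, c(0, 0, 0)), "non-zero")
})

test_that("rugosity is 1 for a flat patch, 2 for a hemisphere, 4 for a sphere", {
  patch <- make_primitive("flat_patch")
  expect_equal(rugosity(patch, c(0, 0, 1), 0.05), 1, tolerance = 1e-9)

  hemi <- make_primitive("hemisphere", radius = 10)
  expect_lt(abs(rugosity(hemi, c(0, 0, 1), 0.05) - 2) / 2, 0.01)

  ball <- make_primitive("icosphere", radius = 10, subdivisions = 4)
  expect_lt(abs(rugosity(ball, c(0, 0, 1), 0.05) - 4) / 4, 0.01)

  # any non-flat deformation with the same silhouette raises rugosity
  bent <- make_primitive("flat_patch", nx = 16, ny = 16)
  bent$vertices[, 3] <- 0.2 * sin(4 * pi * bent$vertices[, 1])
  expect_gt(rugosity(bent, c(0, 0, 1), 0.02), 1)

  # edge-on projection is rejected as degenerate
  expect_error(rugosity(patch, c(1, 0, 0), 0.05), "degenerate")
})

test_that("ornamentation index follows its defining formula", {
  expect_equal(ornamentation_index(1, 1), 0)
  expect_equal(ornamentation_index(2, 1), 1)
  expect_equal(ornamentation_index(1.6181, 1), 0.6181, tolerance = 1e-12)
  # slightly negative OI passes through (polished-shell case)
  expect_equal(ornamentation_index(0.9997, 1), -3e-4, tolerance = 1e-9)
  expect_warning(ornamentation_index(0.5, 1), "reference")
  expect_error(ornamentation_index(1, 0), "positive")
  expect_error(ornamentation_index(1, -2), "positive")
})

test_that("oi_from_meshes populates the record and is scale-invariant", {
  cube <- make_primitive("cube")
  rec <- oi_from_meshes(cube, cube, plane_normal = NULL)
  expect_equal(rec$OI, 0)
  expect_equal(rec$S, 6)
  expect_equal(rec$V, 1)
  expect_equal(rec$sv_ratio, 6)

  pair <- test_pair(rib_amplitude = 0)
  rec0 <- oi_from_meshes(pair$ornamented, pair$smooth, plane_normal = NULL)
  expect_lt(abs(rec0$OI), 1e-6)

  pair2 <- test_pair(rib_amplitude = 0.7)
  oi1 <- oi_from_meshes(pair2$ornamented, pair2$smooth,
                        plane_normal = NULL)$OI
  oi2 <- oi_from_meshes(scale_mesh(pair2$ornamented, 2),
                        scale_mesh(pair2$smooth, 2),
                        plane_normal = NULL)$OI
  expect_equal(oi1, oi2, tolerance = 1e-12)
})

test_that("symmetry-plane estimation recovers known planes", {
  patch <- make_primitive("flat_patch")
  expect_equal(estimate_symmetry_plane(patch), c(0, 0, 1))

  rot <- patch
  rot$vertices <- patch$vertices %*%
    t(matrix(c(1, 0, 0, 0, 0, -1, 0, 1, 0), 3, byrow = TRUE))
  expect_equal(abs(estimate_symmetry_plane(rot)), c(0, 1, 0),
               tolerance = 1e-9)

  # planispiral conch: the estimate recovers the coiling axis within 5 deg
  smooth <- generate_conch(coil_params(steps_per_whorl = 64L,
                                       sections = 32L))
  n <- estimate_symmetry_plane(smooth)
  angle <- acos(min(1, abs(sum(n * c(0, 0, 1))))) * 180 / pi
  expect_lt(angle, 5)

  # isotropic meshes are refused with advice
  expect_error(estimate_symmetry_plane(make_primitive("icosphere")),
               "supply the projection normal")
})
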