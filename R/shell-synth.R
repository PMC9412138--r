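# Parametric generator of matched ornamented/smooth conch pairs, plus the
# analytic primitives used as fixtures with closed-form area and volume.
#
# The smooth conch is a logarithmic-spiral sweep of an elliptical aperture
# (the classic coiling-morphospace construction: whorl expansion rate,
# umbilical ratio, axial translation).  Ornament is added afterwards as a
# non-negative displacement field along the cross-section outward normal, so
# ornamented and smooth meshes share vertex count and face topology exactly
# and the smooth mesh plays the role of the manually built reference model.

#' Coiling parameters for a synthetic conch
#'
#' @param whorl_expansion Per-revolution growth factor of the aperture
#'   (> 1).  2 doubles the aperture every whorl, a typical evolute ammonite.
#' @param umbilical_ratio Raup-style umbilical ratio in `[0, 1)`: the inner
#'   whorl margin sits at `umbilical_ratio` times the outer margin's distance
#'   from the coiling axis.  The default 0.55 keeps successive whorls from
#'   overlapping so the swept tube is embedded.
#' @param translation Axial drift per revolution as a fraction of the
#'   aperture centre radius; 0 gives a planispiral (bilaterally symmetric)
#'   shell, > 0 a helicospiral gastropod-like one.
#' @param aperture_width Axial ellipse semi-axis at the final whorl (mm).
#' @param aperture_height Radial ellipse semi-axis at the final whorl (mm).
#' @param n_whorls Number of revolutions swept (> 0).
#' @param steps_per_whorl Sweep discretization (integer >= 64).
#' @param sections Aperture-ellipse discretization (integer >= 32).
#' @return A `coil_params` list.
#' @export
coil_params <- function(whorl_expansion = 2, umbilical_ratio = 0.55,
                        translation = 0, aperture_width = 3,
                        aperture_height = 4, n_whorls = 2,
                        steps_per_whorl = 256L, sections = 64L) {
  if (whorl_expansion <= 1) stop("`whorl_expansion` must exceed 1", call. = FALSE)
  if (umbilical_ratio < 0 || umbilical_ratio >= 1) {
    stop("`umbilical_ratio` must lie in [0, 1)", call. = FALSE)
  }
  if (n_whorls <= 0) stop("`n_whorls` must be positive", call. = FALSE)
  if (aperture_width <= 0 || aperture_height <= 0) {
    stop("aperture semi-axes must be positive", call. = FALSE)
  }
  steps_per_whorl <- as.integer(steps_per_whorl)
  sections <- as.integer(sections)
  if (steps_per_whorl < 64L) stop("`steps_per_whorl` must be >= 64", call. = FALSE)
  if (sections < 32L) stop("`sections` must be >= 32", call. = FALSE)
  structure(
    list(
      whorl_expansion = whorl_expansion,
      umbilical_ratio = umbilical_ratio,
      translation = translation,
      aperture_width = aperture_width,
      aperture_height = aperture_height,
      n_whorls = n_whorls,
      steps_per_whorl = steps_per_whorl,
      sections = sections
    ),
    class = "coil_params"
  )
}

#' Ornament parameters for a synthetic conch
#'
#' Describes the displacement field superimposed on the smooth conch:
#' transverse ribs (ridges crossing the whorl, repeating along the spiral),
#' spiral ridges (running along the growth direction, repeating around the
#' aperture) and tubercle-like nodes (Gaussian bumps at seeded pseudo-random
#' positions).  All amplitudes are in mm and the field is rectified to be
#' non-negative, so ornament only ever adds material outward and the
#' ornamented area is never below the smooth area.
#'
#' @param rib_amplitude,rib_frequency Rib height (mm) and ribs per whorl.
#' @param spiral_amplitude,spiral_count Spiral-ridge height (mm) and number
#'   of ridges around the aperture.
#' @param node_amplitude,node_density,node_width Node height (mm), nodes per
#'   whorl, and Gaussian width of each node (mm).
#' @param seed Integer seed for the jittered node placement; required so
#'   every fixture is exactly reproducible.
#' @return An `ornament_params` list.
#' @export
ornament_params <- function(rib_amplitude = 0, rib_frequency = 12,
                            spiral_amplitude = 0, spiral_count = 8,
                            node_amplitude = 0, node_density = 8,
                            node_width = 1, seed = 1L) {
  amps <- c(rib_amplitude, spiral_amplitude, node_amplitude)
  if (any(amps < 0)) stop("ornament amplitudes must be >= 0", call. = FALSE)
  if (node_width <= 0) stop("`node_width` must be positive", call. = FALSE)
  structure(
    list(
      rib_amplitude = rib_amplitude,
      rib_frequency = rib_frequency,
      spiral_amplitude = spiral_amplitude,
      spiral_count = spiral_count,
      node_amplitude = node_amplitude,
      node_density = node_density,
      node_width = node_width,
      seed = as.integer(seed)
    ),
    class = "ornament_params"
  )
}

# Growth factor of the aperture at spiral angle theta, normalised so the
# final whorl has factor 1.
coil_growth <- function(coil, theta) {
  theta_max <- 2 * pi * coil$n_whorls
  coil$whorl_expansion^((theta - theta_max) / (2 * pi))
}

# Radial distance of the aperture centre from the coiling axis.
coil_center_radius <- function(coil, theta) {
  h <- coil$aperture_height * coil_growth(coil, theta)
  u <- coil$umbilical_ratio
  h * (1 + u) / (1 - u)
}

#' Generate a smooth synthetic conch
#'
#' Sweeps the aperture ellipse along a logarithmic spiral about the z axis
#' and caps both ends, producing a watertight tube.  With
#' `translation = 0` the construction is planispiral: the vertex set is
#' symmetric under reflection through the coiling plane `z = 0`, and the
#' coiling axis is `(0, 0, 1)`.  The (theta, phi) sweep parametrization and
#' the per-vertex cross-section outward normals are attached as metadata so
#' [apply_ornament()] can displace vertices without estimating normals from
#' the discrete mesh.
#'
#' @param coil A [coil_params()] object.
#' @param name Mesh identifier.
#' @return A watertight [triangle_mesh()] with a `parametrization` attribute.
#' @export
generate_conch <- function(coil, name = "conch") {
  stopifnot(inherits(coil, "coil_params"))
  theta_max <- 2 * pi * coil$n_whorls
  n_rings <- as.integer(round(coil$n_whorls * coil$steps_per_whorl)) + 1L
  n_phi <- coil$sections
  theta <- seq(0, theta_max, length.out = n_rings)
  phi <- 2 * pi * (seq_len(n_phi) - 1L) / n_phi

  g <- coil_growth(coil, theta)
  h <- coil$aperture_height * g          # radial semi-axis per ring
  w <- coil$aperture_width * g           # axial semi-axis per ring
  cr <- coil_center_radius(coil, theta)  # centre distance from axis
  cz <- coil$translation * cr - coil$translation * cr[n_rings]  # axial drift

  th_g <- rep(theta, each = n_phi)
  ph_g <- rep(phi, times = n_rings)
  h_g <- rep(h, each = n_phi)
  w_g <- rep(w, each = n_phi)
  cr_g <- rep(cr, each = n_phi)
  cz_g <- rep(cz, each = n_phi)

  r_rad <- cr_g + h_g * cos(ph_g)
  x <- r_rad * cos(th_g)
  y <- r_rad * sin(th_g)
  z <- cz_g + w_g * sin(ph_g)
  verts <- cbind(x, y, z)

  # cross-section outward normal: for ellipse point (h cos phi, w sin phi)
  # the outward normal is proportional to (w cos phi, h sin phi)
  nr_loc <- w_g * cos(ph_g)
  nz_loc <- h_g * sin(ph_g)
  nlen <- sqrt(nr_loc^2 + nz_loc^2)
  normal_dir <- cbind(
    (nr_loc / nlen) * cos(th_g),
    (nr_loc / nlen) * sin(th_g),
    nz_loc / nlen
  )

  # tube faces
  i <- rep(seq_len(n_rings - 1L), each = n_phi)
  j <- rep(seq_len(n_phi), times = n_rings - 1L)
  jn <- j %% n_phi + 1L
  v00 <- (i - 1L) * n_phi + j
  v01 <- (i - 1L) * n_phi + jn
  v10 <- i * n_phi + j
  v11 <- i * n_phi + jn
  faces <- rbind(
    cbind(v00, v10, v11),
    cbind(v00, v11, v01)
  )

  # end caps: fans around the aperture centres
  n_tube <- n_rings * n_phi
  c0 <- n_tube + 1L
  c1 <- n_tube + 2L
  verts <- rbind(
    verts,
    c(cr[1] * cos(theta[1]), cr[1] * sin(theta[1]), cz[1]),
    c(cr[n_rings] * cos(theta[n_rings]), cr[n_rings] * sin(theta[n_rings]),
      cz[n_rings])
  )
  normal_dir <- rbind(normal_dir, c(0, 0, 0), c(0, 0, 0))
  ring0 <- seq_len(n_phi)
  ring1 <- (n_rings - 1L) * n_phi + seq_len(n_phi)
  cap0 <- cbind(c0, ring0, c(ring0[-1], ring0[1]))
  cap1 <- cbind(c1, c(ring1[-1], ring1[1]), ring1)
  faces <- rbind(faces, cap0, cap1)

  mesh <- triangle_mesh(verts, faces, name = name)

  # fix global orientation so the signed volume is positive (outward faces)
  v <- mesh$vertices
  f <- mesh$faces
  p1 <- v[f[, 1], , drop = FALSE]
  p2 <- v[f[, 2], , drop = FALSE]
  p3 <- v[f[, 3], , drop = FALSE]
  det6 <- p1[, 1] * (p2[, 2] * p3[, 3] - p2[, 3] * p3[, 2]) -
    p1[, 2] * (p2[, 1] * p3[, 3] - p2[, 3] * p3[, 1]) +
    p1[, 3] * (p2[, 1] * p3[, 2] - p2[, 2] * p3[, 1])
  if (sum(det6) < 0) mesh <- flip_faces(mesh)

  attr(mesh, "parametrization") <- list(
    theta = c(th_g, theta[1], theta[n_rings]),
    phi = c(ph_g, NA_real_, NA_real_),
    normal_dir = normal_dir,
    is_cap_center = c(rep(FALSE, n_tube), TRUE, TRUE),
    coil = coil
  )
  mesh
}

#' Displace a smooth conch by an ornament field
#'
#' Each tube vertex is pushed outward along its cross-section normal by
#' `f(theta, phi) =
#'   rib_amplitude * max(0, sin(rib_frequency * theta))^2 +
#'   spiral_amplitude * max(0, sin(spiral_count * phi))^2 +
#'   sum of Gaussian node bumps`,
#' a non-negative field, so the ornamented mesh shares the face topology of
#' the smooth input and never loses area relative to it.  Node positions are
#' a jittered lattice over the sweep, drawn from the seed in
#' `ornament$seed`; the same seed and parameters always reproduce the exact
#' same mesh.
#'
#' @param smooth A mesh produced by [generate_conch()] (its sweep
#'   parametrization metadata is required).
#' @param ornament An [ornament_params()] object.
#' @return The ornamented [triangle_mesh()]; the attribute
#'   `max_displacement` records the largest displacement applied (mm).
#' @export
apply_ornament <- function(smooth, ornament) {
  stopifnot(is_triangle_mesh(smooth), inherits(ornament, "ornament_params"))
  par <- attr(smooth, "parametrization")
  if (is.null(par)) {
    stop("mesh lacks sweep parametrization metadata; ",
         "ornament can only be applied to generate_conch() output",
         call. = FALSE)
  }
  theta <- par$theta
  phi <- par$phi
  coil <- par$coil
  f <- numeric(length(theta))

  if (ornament$rib_amplitude > 0) {
    f <- f + ornament$rib_amplitude *
      pmax(0, sin(ornament$rib_frequency * theta))^2
  }
  if (ornament$spiral_amplitude > 0) {
    f <- f + ornament$spiral_amplitude *
      pmax(0, sin(ornament$spiral_count * phi))^2
  }
  if (ornament$node_amplitude > 0) {
    n_nodes <- max(1L, as.integer(round(ornament$node_density * coil$n_whorls)))
    theta_max <- 2 * pi * coil$n_whorls
    jit <- with_local_seed(ornament$seed, {
      list(t = stats::runif(n_nodes, -0.45, 0.45),
           p = stats::runif(n_nodes, 0, 2 * pi))
    })
    node_theta <- theta_max * (seq_len(n_nodes) - 0.5 + jit$t) / n_nodes
    node_phi <- jit$p
    sigma <- ornament$node_width
    for (k in seq_len(n_nodes)) {
      # arc-length distances on the sweep surface near the node
      c_k <- coil_center_radius(coil, node_theta[k])
      rho_k <- sqrt(coil$aperture_height * coil$aperture_width) *
        coil_growth(coil, node_theta[k])
      dth <- (theta - node_theta[k]) * c_k
      dph_ang <- abs(phi - node_phi[k])
      dph_ang <- pmin(dph_ang, 2 * pi - dph_ang)
      dph <- dph_ang * rho_k
      d2 <- dth^2 + dph^2
      f <- f + ornament$node_amplitude * exp(-d2 / (2 * sigma^2))
    }
  }

  f[par$is_cap_center | is.na(phi)] <- 0
  out <- smooth
  out$vertices <- smooth$vertices + f * par$normal_dir
  out$name <- paste0(smooth$name, "_ornamented")
  attr(out, "parametrization") <- par
  attr(out, "max_displacement") <- max(f)
  out
}

#' Generate a matched ornamented/smooth conch pair
#'
#' The synthetic stand-in for a scanned specimen and its manually modelled
#' smooth reference: both meshes share conch geometry, vertex count and face
#' topology, differing only by the outward ornament displacement.
#'
#' @inheritParams generate_conch
#' @inheritParams apply_ornament
#' @return A `shell_pair`: list with `ornamented`, `smooth`, `coil`,
#'   `ornament` and `true_amplitude_summary` (max normal displacement, mm).
#' @examples
#' pair <- generate_pair(coil_params(steps_per_whorl = 64, sections = 32),
#'                       ornament_params(rib_amplitude = 0.5))
#' ornamentation_index(surface_area(pair$ornamented),
#'                     surface_area(pair$smooth))
#' @export
generate_pair <- function(coil = coil_params(),
                          ornament = ornament_params(), name = "conch") {
  smooth <- generate_conch(coil, name = name)
  ornamented <- apply_ornament(smooth, ornament)
  structure(
    list(
      ornamented = ornamented,
      smooth = smooth,
      coil = coil,
      ornament = ornament,
      true_amplitude_summary = attr(ornamented, "max_displacement")
    ),
    class = "shell_pair"
  )
}

#' @export
print.shell_pair <- function(x, ...) {
  cat(sprintf(
    "<shell_pair '%s': %d vertices, %d faces, max ornament displacement %.3g mm>\n",
    x$smooth$name, nrow(x$smooth$vertices), nrow(x$smooth$faces),
    x$true_amplitude_summary
  ))
  invisible(x)
}

# -- analytic primitives ------------------------------------------------------

#' Canonical primitive meshes with known closed-form geometry
#'
#' Deterministic fixtures for oracle tests and examples:
#' \describe{
#'   \item{`cube`}{axis-aligned cube of edge `size` with one corner at the
#'     origin; area `6 size^2`, volume `size^3`.}
#'   \item{`box`}{axis-aligned box with edges `size` (length-3).}
#'   \item{`icosphere`}{subdivided icosahedron projected to radius `radius`;
#'     `20 * 4^subdivisions` faces, watertight.}
#'   \item{`hemisphere`}{open upper half-sphere (UV grid), area converging to
#'     `2 pi radius^2`, silhouette along +z a disk of area `pi radius^2`.}
#'   \item{`flat_patch`}{planar rectangle in the xy-plane, not watertight.}
#'   \item{`line_tube`}{thin capped cylinder along z.}
#' }
#'
#' @param kind One of `"cube"`, `"box"`, `"icosphere"`, `"hemisphere"`,
#'   `"flat_patch"`, `"line_tube"`.
#' @param size Edge length (cube, scalar) or edge lengths (box, length-3) or
#'   side lengths (flat_patch, length-2 recycled).
#' @param radius Radius in mm (icosphere, hemisphere, line_tube).
#' @param subdivisions Icosphere subdivision level (0-7).
#' @param n_lat,n_lon Hemisphere grid resolution.
#' @param length Cylinder length (line_tube).
#' @param n_theta,n_seg Cylinder discretization.
#' @param nx,ny Flat-patch grid cells.
#' @return A [triangle_mesh()].
#' @export
make_primitive <- function(kind = c("cube", "box", "icosphere", "hemisphere",
                                    "flat_patch", "line_tube"),
                           size = 1, radius = 1, subdivisions = 4L,
                           n_lat = 48L, n_lon = 96L, length = 10,
                           n_theta = 24L, n_seg = 50L, nx = 4L, ny = 4L) {
  kind <- match.arg(kind)
  switch(kind,
    cube = primitive_box(rep(size[1], 3), "cube"),
    box = primitive_box(rep_len(size, 3), "box"),
    icosphere = primitive_icosphere(radius, subdivisions),
    hemisphere = primitive_hemisphere(radius, n_lat, n_lon),
    flat_patch = primitive_flat_patch(rep_len(size, 2), nx, ny),
    line_tube = primitive_line_tube(length, radius, n_theta, n_seg)
  )
}

primitive_box <- function(s, name) {
  if (any(s <= 0)) stop("box dimensions must be positive", call. = FALSE)
  v <- as.matrix(expand.grid(x = c(0, s[1]), y = c(0, s[2]), z = c(0, s[3])))
  dimnames(v) <- NULL
  # 12 triangles with outward orientation (vertex order from expand.grid:
  # x fastest, then y, then z; 1-based corners)
  f <- rbind(
    c(1, 3, 4), c(1, 4, 2),   # z = 0 (down)
    c(5, 6, 8), c(5, 8, 7),   # z = s3 (up)
    c(1, 2, 6), c(1, 6, 5),   # y = 0
    c(3, 7, 8), c(3, 8, 4),   # y = s2
    c(1, 5, 7), c(1, 7, 3),   # x = 0
    c(2, 4, 8), c(2, 8, 6)    # x = s1
  )
  triangle_mesh(v, f, name = name)
}

primitive_icosphere <- function(radius, subdivisions) {
  subdivisions <- as.integer(subdivisions)
  if (subdivisions < 0L || subdivisions > 7L) {
    stop("`subdivisions` must be between 0 and 7", call. = FALSE)
  }
  if (radius <= 0) stop("`radius` must be positive", call. = FALSE)
  t <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, t, 0), c(1, t, 0), c(-1, -t, 0), c(1, -t, 0),
    c(0, -1, t), c(0, 1, t), c(0, -1, -t), c(0, 1, -t),
    c(t, 0, -1), c(t, 0, 1), c(-t, 0, -1), c(-t, 0, 1)
  )
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2)
  )
  for (s in seq_len(subdivisions)) {
    edges <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
    ekey <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
    ukey <- unique(ekey)
    mid_of <- match(ekey, ukey) + nrow(v)
    ue <- edges[!duplicated(ekey), , drop = FALSE]
    mids <- (v[ue[, 1], , drop = FALSE] + v[ue[, 2], , drop = FALSE]) / 2
    v <- rbind(v, mids)
    m12 <- mid_of[seq_len(nrow(f))]
    m23 <- mid_of[nrow(f) + seq_len(nrow(f))]
    m31 <- mid_of[2 * nrow(f) + seq_len(nrow(f))]
    f <- rbind(
      cbind(f[, 1], m12, m31),
      cbind(f[, 2], m23, m12),
      cbind(f[, 3], m31, m23),
      cbind(m12, m23, m31)
    )
  }
  v <- v / sqrt(rowSums(v^2)) * radius
  triangle_mesh(v, f, name = sprintf("icosphere_r%g_s%d", radius, subdivisions))
}

primitive_hemisphere <- function(radius, n_lat, n_lon) {
  if (radius <= 0) stop("`radius` must be positive", call. = FALSE)
  n_lat <- as.integer(n_lat)
  n_lon <- as.integer(n_lon)
  lat <- seq(0, pi / 2, length.out = n_lat + 1L)[-1]  # skip the pole row
  lon <- 2 * pi * (seq_len(n_lon) - 1L) / n_lon
  v <- rbind(
    c(0, 0, radius),  # pole
    cbind(
      radius * sin(rep(lat, each = n_lon)) * cos(rep(lon, times = n_lat)),
      radius * sin(rep(lat, each = n_lon)) * sin(rep(lon, times = n_lat)),
      radius * cos(rep(lat, each = n_lon))
    )
  )
  ring <- function(i) 1L + (i - 1L) * n_lon + seq_len(n_lon)
  j <- seq_len(n_lon)
  jn <- j %% n_lon + 1L
  f <- cbind(1L, ring(1)[j], ring(1)[jn])  # pole fan
  for (i in seq_len(n_lat - 1L)) {
    a <- ring(i)
    b <- ring(i + 1L)
    f <- rbind(f, cbind(a[j], b[j], b[jn]), cbind(a[j], b[jn], a[jn]))
  }
  triangle_mesh(v, f, name = sprintf("hemisphere_r%g", radius))
}

primitive_flat_patch <- function(s, nx, ny) {
  nx <- as.integer(nx)
  ny <- as.integer(ny)
  xs <- seq(0, s[1], length.out = nx + 1L)
  ys <- seq(0, s[2], length.out = ny + 1L)
  v <- as.matrix(expand.grid(x = xs, y = ys))
  v <- cbind(v, 0)
  dimnames(v) <- NULL
  id <- function(i, j) (j - 1L) * (nx + 1L) + i
  i <- rep(seq_len(nx), times = ny)
  j <- rep(seq_len(ny), each = nx)
  f <- rbind(
    cbind(id(i, j), id(i + 1L, j), id(i + 1L, j + 1L)),
    cbind(id(i, j), id(i + 1L, j + 1L), id(i, j + 1L))
  )
  triangle_mesh(v, f, name = "flat_patch")
}

primitive_line_tube <- function(length, radius, n_theta, n_seg) {
  if (length <= 0 || radius <= 0) {
    stop("tube dimensions must be positive", call. = FALSE)
  }
  n_theta <- as.integer(n_theta)
  n_seg <- as.integer(n_seg)
  z <- seq(0, length, length.out = n_seg + 1L)
  th <- 2 * pi * (seq_len(n_theta) - 1L) / n_theta
  v <- cbind(
    radius * cos(rep(th, times = n_seg + 1L)),
    radius * sin(rep(th, times = n_seg + 1L)),
    rep(z, each = n_theta)
  )
  n_side <- (n_seg + 1L) * n_theta
  v <- rbind(v, c(0, 0, 0), c(0, 0, length))
  c_lo <- n_side + 1L
  c_hi <- n_side + 2L
  j <- seq_len(n_theta)
  jn <- j %% n_theta + 1L
  f <- NULL
  for (i in seq_len(n_seg)) {
    a <- (i - 1L) * n_theta
    b <- i * n_theta
    f <- rbind(f, cbind(a + j, b + j, b + jn), cbind(a + j, b + jn, a + jn))
  }
  f <- rbind(
    f,
    cbind(c_lo, j, jn),                                        # bottom cap
    cbind(c_hi, n_seg * n_theta + jn, n_seg * n_theta + j)     # top cap
  )
  triangle_mesh(v, f, name = "line_tube")
}
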