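# The metric suite: surface area S, enclosed volume V, projected silhouette
# area Sp, S/V ratio, rugosity S/Sp, and the ornamentation index
# OI = S/S' - 1 where S' is the surface area of a smooth reference model of
# the same conch geometry.  Areas are mm^2, volumes mm^3, OI and rugosity are
# dimensionless, S/V is mm^-1.

#' Total surface area of a mesh
#'
#' Sum of triangle areas (half cross-product magnitudes), in mm^2.
#'
#' @param mesh A [triangle_mesh()].
#' @return Surface area (mm^2).
#' @examples
#' surface_area(make_primitive("cube")) # 6
#' @export
surface_area <- function(mesh) {
  stopifnot(is_triangle_mesh(mesh))
  if (nrow(mesh$faces) == 0L) stop("mesh has no faces", call. = FALSE)
  sum(face_areas(mesh))
}

#' Enclosed volume of a watertight mesh
#'
#' Divergence-theorem (signed tetrahedron) volume, returned as an absolute
#' value so it is insensitive to global face orientation.  Open meshes are
#' refused rather than silently capped: the S/V ratio is undefined for open
#' unilateral models.
#'
#' @inheritParams surface_area
#' @return Enclosed volume (mm^3).
#' @examples
#' enclosed_volume(make_primitive("cube")) # 1
#' @export
enclosed_volume <- function(mesh) {
  stopifnot(is_triangle_mesh(mesh))
  diag <- validate_mesh(mesh)
  if (!diag$is_watertight) {
    stop("enclosed volume is undefined: mesh '", mesh$name,
         "' is not watertight (open boundary or inconsistent orientation)",
         call. = FALSE)
  }
  v <- mesh$vertices
  f <- mesh$faces
  p1 <- v[f[, 1], , drop = FALSE]
  p2 <- v[f[, 2], , drop = FALSE]
  p3 <- v[f[, 3], , drop = FALSE]
  det6 <- p1[, 1] * (p2[, 2] * p3[, 3] - p2[, 3] * p3[, 2]) -
    p1[, 2] * (p2[, 1] * p3[, 3] - p2[, 3] * p3[, 1]) +
    p1[, 3] * (p2[, 1] * p3[, 2] - p2[, 2] * p3[, 1])
  abs(sum(det6)) / 6
}

#' Surface-to-volume ratio
#'
#' `S/V` in mm^-1.  Scale-dependent: isometric growth by factor `k` divides
#' it by `k`, which is exactly why the ornamentation index was introduced as
#' a size-free alternative.
#'
#' @inheritParams enclosed_volume
#' @export
sv_ratio <- function(mesh) {
  surface_area(mesh) / enclosed_volume(mesh)
}

# Orthonormal in-plane basis (u, v) for a projection plane with normal n.
projection_basis <- function(normal) {
  n <- unit_vector(normal, "`plane_normal`")
  e <- diag(3)[, which.min(abs(n))]
  u <- c(
    n[2] * e[3] - n[3] * e[2],
    n[3] * e[1] - n[1] * e[3],
    n[1] * e[2] - n[2] * e[1]
  )
  u <- u / sqrt(sum(u^2))
  v <- c(
    n[2] * u[3] - n[3] * u[2],
    n[3] * u[1] - n[1] * u[3],
    n[1] * u[2] - n[2] * u[1]
  )
  list(n = n, u = u, v = v)
}

#' Projected silhouette area
#'
#' Area of the silhouette of the mesh on the plane orthogonal to
#' `plane_normal`: projected triangles are rasterized at pixel size
#' `resolution` and covered pixels are counted once, so overlapping front and
#' back faces are not double-counted.  Rasterization (rather than exact
#' polygon union) is used because scanned meshes routinely self-overlap in
#' projection.
#'
#' @inheritParams surface_area
#' @param plane_normal Normal of the projection plane (any non-zero
#'   3-vector).
#' @param resolution Pixel edge length in mm (default 0.05).
#' @return Silhouette area (mm^2).
#' @examples
#' projected_area(make_primitive("flat_patch"), c(0, 0, 1)) # 1
#' @export
projected_area <- function(mesh, plane_normal = c(0, 0, 1),
                           resolution = 0.05) {
  stopifnot(is_triangle_mesh(mesh))
  if (!is.numeric(resolution) || length(resolution) != 1L || resolution <= 0) {
    stop("`resolution` must be a positive pixel size in mm", call. = FALSE)
  }
  basis <- projection_basis(plane_normal)
  p2 <- cbind(mesh$vertices %*% basis$u, mesh$vertices %*% basis$v)
  lo <- c(min(p2[, 1]), min(p2[, 2])) - resolution
  hi <- c(max(p2[, 1]), max(p2[, 2])) + resolution
  dims <- pmax(1L, as.integer(ceiling((hi - lo) / resolution)))
  covered <- rasterize_tris_cpp(p2, mesh$faces, lo, resolution, dims)
  covered * resolution^2
}

#' Rugosity (roughness per unit footprint)
#'
#' Surface area divided by projected silhouette area, `S / Sp`.  A flat patch
#' viewed face-on gives 1.  Note the closed-surface convention: for a closed
#' mesh the full two-sided surface area is divided by a one-sided silhouette,
#' so a sphere gives 4 and closed shells give values >= 2.  The convention
#' used for the shells this package targets is the unilateral half-model
#' (one side of a planispiral shell cut along its symmetry plane) projected
#' onto that symmetry plane, which yields the familiar >= 1 range.
#'
#' @inheritParams projected_area
#' @return Dimensionless rugosity.
#' @export
rugosity <- function(mesh, plane_normal = c(0, 0, 1), resolution = 0.05) {
  sp <- projected_area(mesh, plane_normal, resolution)
  if (sp < resolution^2 * 1.5) {
    stop("degenerate projection: silhouette area is below the pixel size ",
         "(plane viewed edge-on?)", call. = FALSE)
  }
  surface_area(mesh) / sp
}

#' Ornamentation index
#'
#' `OI = S / S' - 1`: the fractional extra surface area of an ornamented
#' shell relative to a smooth model of identical conch geometry.
#' Dimensionless (multiply by 100 to report percent) and, unlike `S/V` and
#' rugosity, unaffected by size and conch shape.  Slightly negative values
#' occur for real smooth references (a polished shell can measure below its
#' virtual model); values below -0.05 trigger a logged warning suggesting a
#' mismatched reference.
#'
#' @param S Surface area of the ornamented model (mm^2).
#' @param S_ref Surface area S' of the smooth reference model (mm^2).
#' @return Dimensionless fraction.
#' @examples
#' ornamentation_index(2, 1) # 1 (i.e. 100%)
#' @export
ornamentation_index <- function(S, S_ref) {
  if (!is.numeric(S_ref) || any(S_ref <= 0)) {
    stop("`S_ref` must be positive", call. = FALSE)
  }
  oi <- S / S_ref - 1
  if (any(oi < -0.05)) {
    cm_warn("OI below -5%: the smooth reference may not match the specimen")
  }
  oi
}

#' Metrics for an ornamented mesh against its smooth reference
#'
#' Computes the full per-specimen metric record: S, S', OI, and (where their
#' preconditions hold) V, S/V, Sp and rugosity.  The caller asserts that both
#' meshes represent the same specimen side and trim (for planispiral shells,
#' the same unilateral aperture-opened convention).
#'
#' @param mesh Ornamented specimen mesh.
#' @param reference Smooth reference mesh of the same conch geometry.
#' @param specimen_id Identifier for the output row; defaults to the mesh
#'   name.
#' @param plane_normal Projection normal for Sp/rugosity: a 3-vector,
#'   `"auto"` to use [estimate_symmetry_plane()], or `NULL` to skip the
#'   silhouette metrics.
#' @param resolution Silhouette pixel size (mm).
#' @return A one-row tibble (see [metrics_record()]).
#' @examples
#' pair <- generate_pair(coil_params(steps_per_whorl = 64, sections = 32),
#'                       ornament_params(rib_amplitude = 0.5, seed = 1))
#' oi_from_meshes(pair$ornamented, pair$smooth, plane_normal = c(0, 0, 1))
#' @export
oi_from_meshes <- function(mesh, reference, specimen_id = mesh$name,
                           plane_normal = NULL, resolution = 0.05) {
  stopifnot(is_triangle_mesh(mesh), is_triangle_mesh(reference))
  compute_all_metrics(mesh,
    reference = reference, specimen_id = specimen_id,
    plane_normal = plane_normal, resolution = resolution
  )
}

#' Estimate the symmetry plane of a planispiral shell
#'
#' Returns the unit normal of the plane of least spread: the principal
#' direction of smallest variance of the area-weighted face centroids.  For a
#' planispiral shell this is the coiling axis, i.e. the normal of the plane
#' of symmetry that rugosity projects onto.  Deterministic up to sign; the
#' sign is fixed toward the positive-z hemisphere (then +y, then +x for
#' normals orthogonal to z).
#'
#' @inheritParams surface_area
#' @param tol Relative eigenvalue-separation tolerance below which the
#'   principal directions are declared degenerate.
#' @return Unit 3-vector.
#' @export
estimate_symmetry_plane <- function(mesh, tol = 1e-9) {
  stopifnot(is_triangle_mesh(mesh))
  v <- mesh$vertices
  f <- mesh$faces
  cent <- (v[f[, 1], , drop = FALSE] + v[f[, 2], , drop = FALSE] +
             v[f[, 3], , drop = FALSE]) / 3
  w <- face_areas(mesh)
  wsum <- sum(w)
  if (wsum <= 0) stop("mesh has zero total area", call. = FALSE)
  mu <- colSums(cent * w) / wsum
  d <- sweep(cent, 2, mu)
  cov <- crossprod(d * w, d) / wsum
  eig <- eigen(cov, symmetric = TRUE)
  vals <- eig$values  # decreasing
  scale <- max(vals[1], .Machine$double.eps)
  if ((vals[2] - vals[3]) / scale < tol) {
    stop("principal directions are degenerate (isotropic mesh); ",
         "supply the projection normal explicitly", call. = FALSE)
  }
  n <- eig$vectors[, 3]
  # sign convention: positive-z hemisphere, ties broken toward +y then +x
  # (components below 1e-12 count as zero so roundoff cannot flip the sign)
  s <- 0
  for (comp in c(n[3], n[2], n[1])) {
    if (abs(comp) > 1e-12) {
      s <- sign(comp)
      break
    }
  }
  if (s < 0) n <- -n
  n
}
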