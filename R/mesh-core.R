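# Triangle-mesh data model and geometric transforms.
#
# A triangle_mesh is the unit of currency of the package: the scanned
# specimen, its smooth reference model, and every synthetic fixture are all
# stored as a plain vertex matrix plus a face-index matrix.  Coordinates are
# in millimetres throughout; there is no unit-conversion layer.

#' Construct a triangle mesh
#'
#' Creates the basic mesh container used throughout the package: an `n x 3`
#' numeric matrix of vertex coordinates (millimetres) and an `m x 3` integer
#' matrix of 1-based vertex indices, one row per triangle.
#'
#' @param vertices Numeric matrix (or coercible) with 3 columns, one vertex
#'   per row, coordinates in mm.
#' @param faces Integer matrix with 3 columns of 1-based vertex indices.
#' @param name Identifier carried through metric tables.
#' @return An object of class `triangle_mesh`.
#' @examples
#' v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
#' triangle_mesh(v, rbind(c(1, 2, 3)), name = "tri")
#' @export
triangle_mesh <- function(vertices, faces, name = "mesh") {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  if (ncol(vertices) != 3L) {
    stop("`vertices` must have 3 columns", call. = FALSE)
  }
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(faces) != 3L) {
    stop("`faces` must have 3 columns (triangles only)", call. = FALSE)
  }
  if (nrow(faces) == 0L) {
    stop("mesh has no faces", call. = FALSE)
  }
  if (anyNA(vertices) || anyNA(faces)) {
    stop("mesh contains missing values", call. = FALSE)
  }
  if (min(faces) < 1L || max(faces) > nrow(vertices)) {
    stop("face indices out of range [1, n_vertices]", call. = FALSE)
  }
  dimnames(vertices) <- NULL
  dimnames(faces) <- NULL
  structure(
    list(vertices = vertices, faces = faces, name = as.character(name)[1]),
    class = "triangle_mesh"
  )
}

#' @export
print.triangle_mesh <- function(x, ...) {
  bb <- mesh_bbox(x)
  cat(sprintf(
    "<triangle_mesh '%s': %d vertices, %d faces, bbox [%s] - [%s] mm>\n",
    x$name, nrow(x$vertices), nrow(x$faces),
    paste(signif(bb[1, ], 4), collapse = ", "),
    paste(signif(bb[2, ], 4), collapse = ", ")
  ))
  invisible(x)
}

#' @rdname triangle_mesh
#' @param x Object to test.
#' @export
is_triangle_mesh <- function(x) inherits(x, "triangle_mesh")

mesh_bbox <- function(mesh) {
  rbind(
    min = apply(mesh$vertices, 2, min),
    max = apply(mesh$vertices, 2, max)
  )
}

# Per-face areas via half cross-product magnitude.
face_areas <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  b <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cx <- a[, 2] * b[, 3] - a[, 3] * b[, 2]
  cy <- a[, 3] * b[, 1] - a[, 1] * b[, 3]
  cz <- a[, 1] * b[, 2] - a[, 2] * b[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

# Directed half-edge table: one row per face edge, columns from/to.
half_edges <- function(faces) {
  rbind(
    faces[, c(1, 2), drop = FALSE],
    faces[, c(2, 3), drop = FALSE],
    faces[, c(3, 1), drop = FALSE]
  )
}

#' Diagnose mesh quality
#'
#' Reports watertightness, manifoldness, connected components, degenerate
#' faces and the bounding box without mutating the mesh.  The manifoldness
#' definition used is *edge-manifold*: every undirected edge is shared by at
#' most two faces.  A mesh is watertight when every undirected edge is shared
#' by exactly two faces with opposite orientation and no directed edge is
#' repeated; under this definition watertight implies edge-manifold and a
#' signed enclosed volume is well-defined.
#'
#' @param mesh A [triangle_mesh()].
#' @param area_tol Faces with area below this (mm^2) count as degenerate.
#' @return A `mesh_diagnostics` object (also a plain list) with fields
#'   `is_watertight`, `is_manifold`, `n_components`, `n_degenerate_faces`,
#'   `bbox`, `n_vertices`, `n_faces`.
#' @examples
#' validate_mesh(make_primitive("cube"))
#' @export
validate_mesh <- function(mesh, area_tol = 1e-12) {
  stopifnot(is_triangle_mesh(mesh))
  he <- half_edges(mesh$faces)
  dir_key <- paste(he[, 1], he[, 2])
  undir_key <- paste(pmin(he[, 1], he[, 2]), pmax(he[, 1], he[, 2]))
  dir_counts <- table(dir_key)
  undir_counts <- table(undir_key)
  is_manifold <- all(undir_counts <= 2L)
  is_watertight <- all(undir_counts == 2L) && all(dir_counts == 1L)

  used <- sort(unique(as.vector(mesh$faces)))
  g <- igraph::graph_from_edgelist(
    cbind(match(he[, 1], used), match(he[, 2], used)),
    directed = FALSE
  )
  n_components <- igraph::count_components(g)
  if (n_components > 1L) {
    cm_warn("mesh '", mesh$name, "' has ", n_components,
            " connected components; metrics operate on the union")
  }

  n_degenerate <- sum(face_areas(mesh) < area_tol)
  structure(
    list(
      is_watertight = is_watertight,
      is_manifold = is_manifold,
      n_components = as.integer(n_components),
      n_degenerate_faces = as.integer(n_degenerate),
      bbox = mesh_bbox(mesh),
      n_vertices = nrow(mesh$vertices),
      n_faces = nrow(mesh$faces)
    ),
    class = "mesh_diagnostics"
  )
}

#' @export
print.mesh_diagnostics <- function(x, ...) {
  cat("<mesh_diagnostics>\n")
  cat("  watertight:      ", x$is_watertight, "\n")
  cat("  edge-manifold:   ", x$is_manifold, "\n")
  cat("  components:      ", x$n_components, "\n")
  cat("  degenerate faces:", x$n_degenerate_faces, "\n")
  cat("  vertices/faces:  ", x$n_vertices, "/", x$n_faces, "\n")
  invisible(x)
}

#' @method tidy mesh_diagnostics
#' @export
tidy.mesh_diagnostics <- function(x, ...) {
  tibble::tibble(
    is_watertight = x$is_watertight,
    is_manifold = x$is_manifold,
    n_components = x$n_components,
    n_degenerate_faces = x$n_degenerate_faces,
    n_vertices = x$n_vertices,
    n_faces = x$n_faces
  )
}

#' Drop degenerate faces
#'
#' Scanned meshes routinely contain sliver triangles; these are removed (with
#' a logged count) rather than treated as an error.  Vertices are left in
#' place so indices stay stable.
#'
#' @inheritParams validate_mesh
#' @return The cleaned `triangle_mesh`.
#' @export
clean_mesh <- function(mesh, area_tol = 1e-12) {
  stopifnot(is_triangle_mesh(mesh))
  keep <- face_areas(mesh) >= area_tol
  if (!all(keep)) {
    cm_info("dropped ", sum(!keep), " degenerate face(s) from '", mesh$name, "'")
    if (!any(keep)) stop("all faces are degenerate", call. = FALSE)
    mesh$faces <- mesh$faces[keep, , drop = FALSE]
  }
  mesh
}

#' Uniformly scale a mesh
#'
#' Multiplies all vertex coordinates by `factor` about the coordinate origin,
#' so areas scale by `factor^2` and volumes by `factor^3`.  Callers needing
#' centroid-anchored scaling should [translate_mesh()] first.
#'
#' @inheritParams validate_mesh
#' @param factor Positive scale factor.
#' @return The scaled `triangle_mesh`.
#' @examples
#' surface_area(scale_mesh(make_primitive("cube"), 2)) # 24
#' @export
scale_mesh <- function(mesh, factor) {
  stopifnot(is_triangle_mesh(mesh))
  if (!is.numeric(factor) || length(factor) != 1L || !is.finite(factor) ||
      factor <= 0) {
    stop("`factor` must be a positive scalar", call. = FALSE)
  }
  mesh$vertices <- mesh$vertices * factor
  mesh
}

#' Anisotropically stretch a mesh along an axis
#'
#' Applies the affine map `p + (factor - 1) * (p . a) a` for unit axis `a`:
#' coordinates along the axis are multiplied by `factor`, directions
#' orthogonal to it are unchanged.
#'
#' @inheritParams scale_mesh
#' @param axis Direction to stretch along (any non-zero 3-vector; normalised
#'   internally).
#' @examples
#' stretched <- stretch_mesh(make_primitive("cube"), c(0, 0, 1), 2)
#' surface_area(stretched) # 10
#' @export
stretch_mesh <- function(mesh, axis, factor) {
  stopifnot(is_triangle_mesh(mesh))
  a <- unit_vector(axis, "`axis`")
  if (!is.numeric(factor) || length(factor) != 1L || !is.finite(factor) ||
      factor <= 0) {
    stop("`factor` must be a positive scalar", call. = FALSE)
  }
  proj <- mesh$vertices %*% a
  mesh$vertices <- mesh$vertices + (factor - 1) * (proj %*% t(a))
  mesh
}

#' Translate a mesh
#'
#' @inheritParams validate_mesh
#' @param offset Numeric 3-vector added to every vertex (mm).
#' @export
translate_mesh <- function(mesh, offset) {
  stopifnot(is_triangle_mesh(mesh))
  offset <- as.numeric(offset)
  if (length(offset) != 3L || any(!is.finite(offset))) {
    stop("`offset` must be a finite 3-vector", call. = FALSE)
  }
  mesh$vertices <- sweep(mesh$vertices, 2, offset, "+")
  mesh
}

# Reverse face winding (flips the outward direction of every triangle).
flip_faces <- function(mesh) {
  mesh$faces <- mesh$faces[, c(1, 3, 2), drop = FALSE]
  mesh
}
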