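# Readers and writers for the mesh formats specimen scans ship in:
# Wavefront OBJ (the primary exchange format for scanned shells), STL
# (ASCII and binary little-endian) and PLY (ASCII and binary little-endian).
# Only geometry is kept: normals and texture coordinates are ignored on read
# and omitted on write.  Text output uses 9 significant digits.

#' Read a triangle mesh from file
#'
#' Supports Wavefront OBJ, PLY (ASCII and binary little-endian) and STL
#' (ASCII and binary).  Polygonal faces with more than three vertices are
#' fan-triangulated.  STL files, which store no shared vertices, are welded
#' on exact coordinate equality so that closedness can be diagnosed.
#' Coordinates are preserved exactly as stored and assumed to be in
#' millimetres.
#'
#' @param path Path to the mesh file.
#' @param format One of `"auto"` (from the file extension), `"obj"`, `"ply"`,
#'   `"stl"`.
#' @param name Mesh identifier; defaults to the file name without extension.
#' @return A [triangle_mesh()].
#' @export
read_mesh <- function(path, format = c("auto", "obj", "ply", "stl"),
                      name = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop("cannot read mesh: no such file '", path, "'", call. = FALSE)
  }
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext,
      obj = "obj", ply = "ply", stl = "stl",
      stop("cannot infer mesh format from extension '.", ext,
           "'; pass `format` explicitly", call. = FALSE)
    )
  }
  if (is.null(name)) {
    name <- tools::file_path_sans_ext(basename(path))
  }
  mesh <- switch(format,
    obj = read_obj(path),
    ply = read_ply(path),
    stl = read_stl(path)
  )
  if (nrow(mesh$faces) == 0L) {
    stop("mesh in '", path, "' has no faces", call. = FALSE)
  }
  mesh$name <- name
  mesh
}

#' Write a triangle mesh to file
#'
#' Writes OBJ, ASCII PLY or ASCII STL depending on `format` (or the file
#' extension for `"auto"`).  Text coordinates carry 9 significant digits.
#'
#' @inheritParams read_mesh
#' @param mesh A [triangle_mesh()].
#' @param digits Significant digits for text coordinate output.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, format = c("auto", "obj", "ply", "stl"),
                       digits = 9) {
  stopifnot(is_triangle_mesh(mesh))
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext,
      obj = "obj", ply = "ply", stl = "stl",
      stop("cannot infer mesh format from extension '.", ext, "'",
           call. = FALSE)
    )
  }
  switch(format,
    obj = write_obj(mesh, path, digits),
    ply = write_ply_ascii(mesh, path, digits),
    stl = write_stl_ascii(mesh, path, digits)
  )
  invisible(path)
}

fmt_num <- function(x, digits) formatC(x, digits = digits, format = "g")

# -- OBJ ----------------------------------------------------------------------

read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  vlines <- lines[startsWith(lines, "v ")]
  flines <- lines[startsWith(lines, "f ")]
  if (length(vlines) == 0L) {
    stop("OBJ file '", path, "' contains no vertices", call. = FALSE)
  }
  vtok <- strsplit(sub("^v\\s+", "", vlines), "\\s+")
  verts <- t(vapply(vtok, function(t) as.numeric(t[1:3]), numeric(3)))
  if (anyNA(verts)) {
    stop("malformed vertex line in OBJ file '", path, "'", call. = FALSE)
  }
  nv <- nrow(verts)
  ftok <- strsplit(sub("^f\\s+", "", flines), "\\s+")
  tris <- lapply(ftok, function(tok) {
    idx <- suppressWarnings(as.integer(sub("/.*$", "", tok)))
    if (anyNA(idx) || length(idx) < 3L) {
      stop("malformed face line in OBJ file '", path, "'", call. = FALSE)
    }
    idx <- ifelse(idx < 0L, nv + idx + 1L, idx)  # negative = relative indices
    k <- length(idx)
    cbind(idx[1], idx[2:(k - 1)], idx[3:k])      # fan triangulation
  })
  faces <- do.call(rbind, tris)
  if (is.null(faces)) {
    stop("OBJ file '", path, "' contains no faces", call. = FALSE)
  }
  triangle_mesh(verts, faces)
}

write_obj <- function(mesh, path, digits) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf("# conchmetrics OBJ export: %s", mesh$name), con)
  v <- mesh$vertices
  writeLines(paste("v", fmt_num(v[, 1], digits), fmt_num(v[, 2], digits),
                   fmt_num(v[, 3], digits)), con)
  f <- mesh$faces
  writeLines(paste("f", f[, 1], f[, 2], f[, 3]), con)
}

# -- STL ----------------------------------------------------------------------

# STL stores bare triangle soup; weld exactly equal coordinates so that
# watertightness of a closed solid survives the round trip.
weld_vertices <- function(tri_coords) {
  key <- paste(
    formatC(tri_coords[, 1], digits = 17, format = "g"),
    formatC(tri_coords[, 2], digits = 17, format = "g"),
    formatC(tri_coords[, 3], digits = 17, format = "g")
  )
  idx <- match(key, unique(key))
  verts <- tri_coords[!duplicated(key), , drop = FALSE]
  faces <- matrix(idx, ncol = 3, byrow = TRUE)
  list(vertices = verts, faces = faces)
}

read_stl <- function(path) {
  head_raw <- readBin(path, "raw", n = 512L)
  is_ascii <- length(head_raw) >= 5L &&
    identical(rawToChar(head_raw[1:5]), "solid") &&
    # binary files may also start with "solid": require a facet keyword
    grepl("facet", rawToChar(head_raw[head_raw != as.raw(0)]), fixed = TRUE)
  coords <- if (is_ascii) read_stl_ascii(path) else read_stl_binary(path)
  w <- weld_vertices(coords)
  triangle_mesh(w$vertices, w$faces)
}

read_stl_ascii <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  vlines <- lines[startsWith(lines, "vertex")]
  if (length(vlines) == 0L || length(vlines) %% 3L != 0L) {
    stop("malformed ASCII STL file '", path, "'", call. = FALSE)
  }
  tok <- strsplit(sub("^vertex\\s+", "", vlines), "\\s+")
  coords <- t(vapply(tok, function(t) as.numeric(t[1:3]), numeric(3)))
  if (anyNA(coords)) stop("malformed ASCII STL file '", path, "'", call. = FALSE)
  coords
}

read_stl_binary <- function(path) {
  size <- file.info(path)$size
  con <- file(path, open = "rb")
  on.exit(close(con))
  readBin(con, "raw", n = 80L)
  n <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
  if (is.na(n) || n <= 0L || 84 + 50 * n > size) {
    stop("malformed binary STL file '", path, "'", call. = FALSE)
  }
  body <- readBin(con, "raw", n = 50L * n)
  rec <- matrix(body, nrow = 50L)
  vert_bytes <- as.raw(rec[13:48, , drop = FALSE])  # skip 12 normal bytes
  coords <- readBin(vert_bytes, "double", n = 9L * n, size = 4L,
                    endian = "little")
  matrix(coords, ncol = 3, byrow = TRUE)
}

write_stl_ascii <- function(mesh, path, digits) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  b <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  nrm <- cbind(
    a[, 2] * b[, 3] - a[, 3] * b[, 2],
    a[, 3] * b[, 1] - a[, 1] * b[, 3],
    a[, 1] * b[, 2] - a[, 2] * b[, 1]
  )
  len <- sqrt(rowSums(nrm^2))
  len[len == 0] <- 1
  nrm <- nrm / len
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste("solid", mesh$name), con)
  for (i in seq_len(nrow(f))) {
    writeLines(c(
      paste("facet normal", fmt_num(nrm[i, 1], digits),
            fmt_num(nrm[i, 2], digits), fmt_num(nrm[i, 3], digits)),
      "  outer loop",
      paste("    vertex", fmt_num(v[f[i, 1], 1], digits),
            fmt_num(v[f[i, 1], 2], digits), fmt_num(v[f[i, 1], 3], digits)),
      paste("    vertex", fmt_num(v[f[i, 2], 1], digits),
            fmt_num(v[f[i, 2], 2], digits), fmt_num(v[f[i, 2], 3], digits)),
      paste("    vertex", fmt_num(v[f[i, 3], 1], digits),
            fmt_num(v[f[i, 3], 2], digits), fmt_num(v[f[i, 3], 3], digits)),
      "  endloop",
      "endfacet"
    ), con)
  }
  writeLines(paste("endsolid", mesh$name), con)
}

# -- PLY ----------------------------------------------------------------------

.ply_sizes <- c(
  char = 1L, uchar = 1L, int8 = 1L, uint8 = 1L,
  short = 2L, ushort = 2L, int16 = 2L, uint16 = 2L,
  int = 4L, uint = 4L, int32 = 4L, uint32 = 4L,
  float = 4L, float32 = 4L, double = 8L, float64 = 8L
)
.ply_is_float <- function(type) type %in% c("float", "float32", "double", "float64")

read_ply <- function(path) {
  con <- file(path, open = "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L)
  if (!identical(trimws(magic), "ply")) {
    stop("'", path, "' is not a PLY file", call. = FALSE)
  }
  fmt <- NULL
  elements <- list()
  cur <- NULL
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) stop("truncated PLY header", call. = FALSE)
    tok <- strsplit(trimws(line), "\\s+")[[1]]
    if (length(tok) == 0L || tok[1] == "comment") next
    if (tok[1] == "format") {
      fmt <- tok[2]
    } else if (tok[1] == "element") {
      if (!is.null(cur)) elements[[cur$name]] <- cur
      cur <- list(name = tok[2], count = as.integer(tok[3]), props = list())
    } else if (tok[1] == "property") {
      if (tok[2] == "list") {
        cur$props[[length(cur$props) + 1L]] <-
          list(name = tok[5], list = TRUE, count_type = tok[3], type = tok[4])
      } else {
        cur$props[[length(cur$props) + 1L]] <-
          list(name = tok[3], list = FALSE, type = tok[2])
      }
    } else if (tok[1] == "end_header") {
      if (!is.null(cur)) elements[[cur$name]] <- cur
      break
    }
  }
  if (is.null(elements$vertex) || is.null(elements$face)) {
    stop("PLY file '", path, "' lacks vertex or face elements", call. = FALSE)
  }
  if (identical(fmt, "ascii")) {
    read_ply_ascii_body(con, elements)
  } else if (identical(fmt, "binary_little_endian")) {
    read_ply_binary_body(con, elements, endian = "little")
  } else if (identical(fmt, "binary_big_endian")) {
    read_ply_binary_body(con, elements, endian = "big")
  } else {
    stop("unsupported PLY format '", fmt, "'", call. = FALSE)
  }
}

read_ply_ascii_body <- function(con, elements) {
  verts <- NULL
  faces <- NULL
  for (el in elements) {
    lines <- readLines(con, n = el$count)
    toks <- strsplit(trimws(lines), "\\s+")
    if (el$name == "vertex") {
      names_ <- vapply(el$props, `[[`, "", "name")
      ix <- match(c("x", "y", "z"), names_)
      if (anyNA(ix)) stop("PLY vertex element lacks x/y/z", call. = FALSE)
      verts <- t(vapply(toks, function(t) as.numeric(t[ix]), numeric(3)))
    } else if (el$name == "face") {
      tris <- lapply(toks, function(t) {
        k <- as.integer(t[1])
        idx <- as.integer(t[2:(1 + k)]) + 1L
        cbind(idx[1], idx[2:(k - 1)], idx[3:k])
      })
      faces <- do.call(rbind, tris)
    }
  }
  triangle_mesh(verts, faces)
}

read_ply_binary_body <- function(con, elements, endian) {
  read_scalar <- function(type, n = 1L) {
    sz <- .ply_sizes[[type]]
    if (.ply_is_float(type)) {
      readBin(con, "double", n = n, size = sz, endian = endian)
    } else {
      readBin(con, "integer", n = n, size = sz, endian = endian,
              signed = !(sz < 4 && grepl("^u", type)))
    }
  }
  verts <- NULL
  faces <- NULL
  for (el in elements) {
    simple <- all(!vapply(el$props, `[[`, TRUE, "list"))
    if (el$name == "vertex" && simple) {
      types <- vapply(el$props, `[[`, "", "type")
      names_ <- vapply(el$props, `[[`, "", "name")
      if (length(unique(types)) == 1L) {
        vals <- read_scalar(types[1], n = el$count * length(types))
        m <- matrix(vals, ncol = length(types), byrow = TRUE)
      } else {
        m <- matrix(0, nrow = el$count, ncol = length(types))
        for (i in seq_len(el$count)) {
          for (j in seq_along(types)) m[i, j] <- read_scalar(types[j])
        }
      }
      ix <- match(c("x", "y", "z"), names_)
      if (anyNA(ix)) stop("PLY vertex element lacks x/y/z", call. = FALSE)
      verts <- m[, ix, drop = FALSE]
    } else if (el$name == "face") {
      lp <- el$props[[1]]
      if (!lp$list) stop("PLY face element is not a list property", call. = FALSE)
      tris <- vector("list", el$count)
      for (i in seq_len(el$count)) {
        k <- read_scalar(lp$count_type)
        idx <- read_scalar(lp$type, n = k) + 1L
        tris[[i]] <- cbind(idx[1], idx[2:(k - 1)], idx[3:k])
      }
      faces <- do.call(rbind, tris)
    } else {
      # skip unknown fixed-width elements
      for (i in seq_len(el$count)) {
        for (p in el$props) {
          if (p$list) {
            k <- read_scalar(p$count_type)
            read_scalar(p$type, n = k)
          } else {
            read_scalar(p$type)
          }
        }
      }
    }
  }
  triangle_mesh(verts, faces)
}

write_ply_ascii <- function(mesh, path, digits) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  v <- mesh$vertices
  f <- mesh$faces
  writeLines(c(
    "ply",
    "format ascii 1.0",
    paste("comment conchmetrics export:", mesh$name),
    paste("element vertex", nrow(v)),
    "property double x",
    "property double y",
    "property double z",
    paste("element face", nrow(f)),
    "property list uchar int vertex_indices",
    "end_header"
  ), con)
  writeLines(paste(fmt_num(v[, 1], digits), fmt_num(v[, 2], digits),
                   fmt_num(v[, 3], digits)), con)
  writeLines(paste(3, f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L), con)
}
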