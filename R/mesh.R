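#' Construct a triangle surface mesh
#'
#' Lightweight container for a body-surface mesh in the table frame.
#' Units are millimetres by contract (STL itself is unitless); a bounding-box
#' heuristic warns when the scale looks wrong for a human torso.
#'
#' @param vertices Numeric n x 3 matrix of vertex coordinates (mm).
#' @param faces Integer m x 3 matrix of 1-based vertex indices, counterclockwise
#'   when seen from outside (outward normals).
#' @param provenance Free-text description of where the mesh came from.
#' @return An object of class `surface_mesh`.
#' @export
surface_mesh <- function(vertices, faces, provenance = "constructed") {
  vertices <- as.matrix(vertices)
  faces <- matrix(as.integer(as.matrix(faces)), ncol = 3)
  if (ncol(vertices) != 3) stop("`vertices` must be an n x 3 matrix")
  if (ncol(faces) != 3) stop("`faces` must be an m x 3 matrix")
  if (nrow(faces) == 0 || nrow(vertices) == 0) stop("mesh is empty")
  if (any(!is.finite(vertices))) stop("non-finite vertex coordinates")
  if (min(faces) < 1 || max(faces) > nrow(vertices)) {
    stop("face indices out of range")
  }
  storage.mode(vertices) <- "double"
  dimnames(vertices) <- NULL
  dimnames(faces) <- NULL
  structure(list(vertices = vertices, faces = faces, provenance = provenance),
            class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  bb <- apply(x$vertices, 2, range)
  cat(sprintf("<surface_mesh> %d vertices, %d faces (%s)\n",
              nrow(x$vertices), nrow(x$faces), x$provenance))
  cat(sprintf("  bbox x [%.1f, %.1f]  y [%.1f, %.1f]  z [%.1f, %.1f] mm\n",
              bb[1, 1], bb[2, 1], bb[1, 2], bb[2, 2], bb[1, 3], bb[2, 3]))
  invisible(x)
}

# m x 3 matrices of the three corner positions of each face
face_corners <- function(mesh) {
  list(a = mesh$vertices[mesh$faces[, 1], , drop = FALSE],
       b = mesh$vertices[mesh$faces[, 2], , drop = FALSE],
       c = mesh$vertices[mesh$faces[, 3], , drop = FALSE])
}

cross3 <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

#' Per-face areas of a mesh
#' @param mesh A [surface_mesh()].
#' @return Numeric vector of triangle areas in mm^2.
#' @export
face_areas <- function(mesh) {
  co <- face_corners(mesh)
  cr <- cross3(co$b - co$a, co$c - co$a)
  0.5 * sqrt(rowSums(cr^2))
}

face_centroids <- function(mesh) {
  co <- face_corners(mesh)
  (co$a + co$b + co$c) / 3
}

face_normals <- function(mesh) {
  co <- face_corners(mesh)
  cr <- cross3(co$b - co$a, co$c - co$a)
  len <- sqrt(rowSums(cr^2))
  len[len == 0] <- 1
  cr / len
}

#' Translate a mesh
#' @param mesh A [surface_mesh()].
#' @param offset Length-3 numeric translation in mm.
#' @return The translated mesh.
#' @export
translate_mesh <- function(mesh, offset) {
  stopifnot(length(offset) == 3)
  mesh$vertices <- sweep(mesh$vertices, 2, as.numeric(offset), "+")
  mesh
}

# Merge vertices closer than `tol` and drop degenerate faces.
merge_mesh_vertices <- function(vertices, faces, tol = 1e-6) {
  key <- paste(round(vertices[, 1] / tol), round(vertices[, 2] / tol),
               round(vertices[, 3] / tol))
  first <- !duplicated(key)
  map <- match(key, key[first])
  vertices <- vertices[first, , drop = FALSE]
  faces <- matrix(map[faces], ncol = 3)
  degen <- faces[, 1] == faces[, 2] | faces[, 2] == faces[, 3] |
    faces[, 1] == faces[, 3]
  faces <- faces[!degen, , drop = FALSE]
  list(vertices = vertices, faces = faces)
}

warn_if_odd_scale <- function(vertices) {
  bb <- apply(vertices, 2, range)
  diag_mm <- sqrt(sum((bb[2, ] - bb[1, ])^2))
  if (diag_mm < 100 || diag_mm > 3000) {
    warning(sprintf(paste0("bounding-box diagonal is %.3g mm; coordinates are ",
                           "expected in millimetres for a body surface"), diag_mm))
  }
  invisible(NULL)
}

#' Read an STL file
#'
#' Reads ASCII or binary (little-endian) stereolithography files. Duplicate
#' vertices are merged within 1e-6 mm so that shared triangle edges become
#' topologically connected; zero-area faces are dropped.
#'
#' @param path Path to an `.stl` file.
#' @param provenance Provenance string stored on the mesh; defaults to the
#'   file name.
#' @return A [surface_mesh()].
#' @export
read_stl <- function(path, provenance = basename(path)) {
  if (!file.exists(path)) stop("file not found: ", path)
  size <- file.info(path)$size
  if (is.na(size) || size < 15) stop("not a readable STL file: ", path)

  con <- file(path, "rb")
  on.exit(close(con))
  head_raw <- readBin(con, "raw", n = min(size, 512))
  is_ascii <- identical(rawToChar(head_raw[1:5]), "solid") &&
    grepl("facet", rawToChar(head_raw), fixed = TRUE)

  if (is_ascii) {
    tri <- parse_stl_ascii(path)
  } else {
    tri <- parse_stl_binary(con, size)
  }
  if (nrow(tri) == 0 || nrow(tri) %% 3 != 0) {
    stop("not a readable STL file (no complete facets): ", path)
  }
  m <- merge_mesh_vertices(tri, matrix(seq_len(nrow(tri)), ncol = 3, byrow = TRUE))
  if (nrow(m$faces) == 0) stop("STL file contains only degenerate facets: ", path)
  warn_if_odd_scale(m$vertices)
  surface_mesh(m$vertices, m$faces, provenance = provenance)
}

parse_stl_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vlines <- grep("^\\s*vertex\\s", lines, value = TRUE)
  if (length(vlines) == 0 || length(vlines) %% 3 != 0) {
    stop("not a readable ASCII STL file (vertex count not a multiple of 3): ", path)
  }
  nums <- strsplit(trimws(vlines), "\\s+")
  coords <- vapply(nums, function(x) as.numeric(x[2:4]), numeric(3))
  if (any(!is.finite(coords))) stop("malformed vertex line in ASCII STL: ", path)
  t(coords)
}

parse_stl_binary <- function(con, size) {
  seek(con, 80)
  n_tri <- readBin(con, "integer", n = 1, size = 4, endian = "little")
  expected <- 84 + n_tri * 50
  if (n_tri <= 0 || size < expected) {
    stop("truncated or malformed binary STL (declared ", n_tri, " facets)")
  }
  raw <- readBin(con, "raw", n = n_tri * 50)
  # each record: 12 floats (48 bytes) + uint16 attribute
  idx <- rep(seq_len(n_tri) - 1L, each = 48L) * 50L + rep(1:48, n_tri)
  floats <- readBin(raw[idx], "numeric", n = n_tri * 12, size = 4,
                    endian = "little")
  rec <- matrix(floats, ncol = 12, byrow = TRUE)
  # columns 4:12 are the three vertices; 1:3 is the stored normal (ignored)
  verts <- rbind(rec[, 4:6, drop = FALSE], rec[, 7:9, drop = FALSE],
                 rec[, 10:12, drop = FALSE])
  ord <- as.vector(t(matrix(seq_len(3 * n_tri), ncol = 3)))
  verts[ord, , drop = FALSE]
}

#' Write an STL file
#'
#' @param mesh A [surface_mesh()].
#' @param path Output path.
#' @param dialect `"binary"` (default, compact) or `"ascii"`.
#' @return Invisibly, `path`.
#' @export
write_stl <- function(mesh, path, dialect = c("binary", "ascii")) {
  stopifnot(inherits(mesh, "surface_mesh"))
  dialect <- match.arg(dialect)
  if (nrow(mesh$faces) == 0) stop("refusing to write an empty mesh")
  co <- face_corners(mesh)
  n <- face_normals(mesh)
  m <- nrow(mesh$faces)
  if (dialect == "ascii") {
    fmt <- paste0(
      " facet normal %.9g %.9g %.9g\n  outer loop\n",
      "   vertex %.9g %.9g %.9g\n   vertex %.9g %.9g %.9g\n",
      "   vertex %.9g %.9g %.9g\n  endloop\n endfacet")
    body <- sprintf(fmt, n[, 1], n[, 2], n[, 3],
                    co$a[, 1], co$a[, 2], co$a[, 3],
                    co$b[, 1], co$b[, 2], co$b[, 3],
                    co$c[, 1], co$c[, 2], co$c[, 3])
    writeLines(c("solid beamskin", body, "endsolid beamskin"), path)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(charToRaw(formatC("beamskin binary STL", width = -80)), con)
    writeBin(as.integer(m), con, size = 4, endian = "little")
    rec <- cbind(n, co$a, co$b, co$c)  # m x 12
    for (i in seq_len(m)) {
      writeBin(as.numeric(rec[i, ]), con, size = 4, endian = "little")
      writeBin(as.integer(0), con, size = 2, endian = "little")
    }
  }
  invisible(path)
}

# undirected edge keys for an m x 3 face matrix
edge_keys <- function(faces) {
  e <- rbind(faces[, c(1, 2)], faces[, c(2, 3)], faces[, c(3, 1)])
  paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
}

mesh_components <- function(mesh) {
  g <- igraph::graph_from_edgelist(
    rbind(mesh$faces[, c(1, 2)], mesh$faces[, c(2, 3)]), directed = FALSE)
  memb <- igraph::components(g)$membership
  memb[mesh$faces[, 1]]  # component id per face
}

#' Reduce a hollow shell to its outer surface
#'
#' Hollowed body meshes carry a second, inner skin shell. The engine needs
#' only the outer surface, so this keeps the connected component with the
#' largest axis-aligned bounding-box volume (robust against dense inner
#' shells that may have more faces or area). Ties pick the component
#' containing the lowest-indexed face, with a warning.
#'
#' @param mesh A [surface_mesh()].
#' @return A [surface_mesh()] with a single connected component.
#' @export
extract_outer_surface <- function(mesh) {
  stopifnot(inherits(mesh, "surface_mesh"))
  comp <- mesh_components(mesh)
  ids <- unique(comp)
  if (length(ids) == 1) return(mesh)
  vol <- vapply(ids, function(k) {
    vs <- unique(as.vector(mesh$faces[comp == k, ]))
    bb <- apply(mesh$vertices[vs, , drop = FALSE], 2, range)
    prod(pmax(bb[2, ] - bb[1, ], 0))
  }, numeric(1))
  best <- ids[vol >= max(vol) - 1e-9]
  if (length(best) > 1) {
    warning("bounding-box volume tie between components; keeping the first-indexed one")
    best <- best[which.min(vapply(best, function(k) min(which(comp == k)), numeric(1)))]
  }
  keep <- comp == best[1]
  faces <- mesh$faces[keep, , drop = FALSE]
  used <- sort(unique(as.vector(faces)))
  remap <- match(faces, used)
  surface_mesh(mesh$vertices[used, , drop = FALSE],
               matrix(remap, ncol = 3),
               provenance = paste0(mesh$provenance, " (outer surface)"))
}

#' Validate a mesh and report its basic properties
#'
#' @param mesh A [surface_mesh()].
#' @param strict If `TRUE`, a non-watertight mesh is an error rather than a
#'   reported flag. Ray and clipping operations tolerate open meshes, so the
#'   default is permissive.
#' @return A list (JSON-serialisable) with `watertight`, `n_components`,
#'   `n_vertices`, `n_faces`, `bbox_min`, `bbox_max`, `area_mm2`.
#' @export
validate_mesh <- function(mesh, strict = FALSE) {
  stopifnot(inherits(mesh, "surface_mesh"))
  keys <- edge_keys(mesh$faces)
  watertight <- all(table(keys) == 2)
  if (strict && !watertight) stop("mesh is not watertight")
  bb <- apply(mesh$vertices, 2, range)
  list(watertight = watertight,
       n_components = length(unique(mesh_components(mesh))),
       n_vertices = nrow(mesh$vertices),
       n_faces = nrow(mesh$faces),
       bbox_min = bb[1, ],
       bbox_max = bb[2, ],
       area_mm2 = sum(face_areas(mesh)))
}
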