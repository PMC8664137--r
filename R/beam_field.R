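#' Perpendicular-plane beam area at the skin entrance
#'
#' Area of the beam cross-section in the plane perpendicular to the central
#' axis at the skin entrance point. The collimator tracks the field of view
#' at a reference plane `fov_ref_offset_mm` beyond the SID, so by similar
#' triangles
#' `Ap = (fov_side * SSD / (SID + fov_ref_offset))^2`.
#'
#' @param cfg A [carm_config()].
#' @param sid_mm Source-to-image-receptor distance.
#' @param ssd_mm Source-to-surface distance.
#' @return Area in mm^2.
#' @examples
#' compute_ap(carm_config(), sid_mm = 976, ssd_mm = 593) # ~10748
#' @export
compute_ap <- function(cfg, sid_mm, ssd_mm) {
  stopifnot(inherits(cfg, "carm_config"))
  ref <- sid_mm + cfg$fov_ref_offset_mm
  if (!is.finite(sid_mm) || !is.finite(ssd_mm) || ssd_mm <= 0 || sid_mm <= 0) {
    stop("`sid_mm` and `ssd_mm` must be positive")
  }
  if (ssd_mm > ref) stop("`ssd_mm` must not exceed the FOV reference distance")
  (cfg$fov_side_mm * ssd_mm / ref)^2
}

#' Beam pyramid for a view
#'
#' The collimated beam as a square pyramid: apex at the X-ray focus, four
#' lateral planes through the edges of the FOV square at the reference plane
#' (`SID + fov_ref_offset_mm` along the axis). The in-plane `u` axis is the
#' projection of the patient z axis (detector rows stay aligned with the
#' table), `v = d x u`.
#'
#' @param ang An [angulation()].
#' @param cfg A [carm_config()].
#' @param sid_mm SID for the view.
#' @return An object of class `beam_pyramid` with the apex, frame,
#'   reference distance, FOV side, and the four inward-oriented lateral
#'   plane normals.
#' @export
beam_pyramid <- function(ang, cfg, sid_mm) {
  stopifnot(sid_mm > 0)
  fr <- beam_frame(ang)
  apex <- -cfg$source_to_isocenter_mm * fr$d
  ref <- sid_mm + cfg$fov_ref_offset_mm
  half <- cfg$fov_side_mm / 2
  nrm <- function(x) x / sqrt(sum(x^2))
  planes <- rbind(
    nrm(half * fr$d - ref * fr$u),   # inward normal of the +u face
    nrm(half * fr$d + ref * fr$u),
    nrm(half * fr$d - ref * fr$v),
    nrm(half * fr$d + ref * fr$v)
  )
  structure(list(apex = apex, frame = fr, ref_distance_mm = ref,
                 fov_side_mm = cfg$fov_side_mm, lateral_planes = planes),
            class = "beam_pyramid")
}

#' Test points against a beam pyramid
#'
#' @param pyramid A [beam_pyramid()].
#' @param points n x 3 matrix of points (mm).
#' @return Logical vector: inside all four lateral half-spaces and in front
#'   of the apex.
#' @export
pyramid_contains <- function(pyramid, points) {
  points <- matrix(points, ncol = 3)
  rel <- sweep(points, 2, pyramid$apex)
  t <- as.vector(rel %*% pyramid$frame$d)
  u <- as.vector(rel %*% pyramid$frame$u)
  v <- as.vector(rel %*% pyramid$frame$v)
  half <- pyramid$fov_side_mm / 2
  lim <- half * t / pyramid$ref_distance_mm
  t > 0 & abs(u) <= lim & abs(v) <= lim
}

#' Refine a mesh to a maximum edge length
#'
#' Repeated longest-edge bisection of every face with an edge longer than
#' `max_edge_mm`. Bisection handles long thin triangles (e.g. prism strips)
#' without exploding the face count, and is adaptive, which can leave
#' T-junctions on unsplit neighbours; midpoints lie exactly on the shared
#' edge so the surface and its total area are unchanged. A parent map links
#' each refined face back to its face in the input mesh.
#'
#' @param mesh A [surface_mesh()].
#' @param max_edge_mm Target maximum edge length.
#' @return A list with `mesh` (refined) and `parent` (integer vector, length
#'   = refined face count, of input-mesh face ids).
#' @export
refine_mesh <- function(mesh, max_edge_mm) {
  stopifnot(inherits(mesh, "surface_mesh"), max_edge_mm > 0)
  V <- mesh$vertices
  F <- mesh$faces
  parent <- seq_len(nrow(F))
  repeat {
    len <- cbind(
      sqrt(rowSums((V[F[, 1], , drop = FALSE] - V[F[, 2], , drop = FALSE])^2)),
      sqrt(rowSums((V[F[, 2], , drop = FALSE] - V[F[, 3], , drop = FALSE])^2)),
      sqrt(rowSums((V[F[, 3], , drop = FALSE] - V[F[, 1], , drop = FALSE])^2)))
    longest <- max.col(len, ties.method = "first")
    split <- which(len[cbind(seq_len(nrow(F)), longest)] >
                     max_edge_mm * (1 + 1e-12))
    if (length(split) == 0) break
    fs <- F[split, , drop = FALSE]
    le <- longest[split]
    # rotate so the longest edge is (v1, v2)
    rot2 <- le == 2
    rot3 <- le == 3
    fs[rot2, ] <- fs[rot2, c(2, 3, 1), drop = FALSE]
    fs[rot3, ] <- fs[rot3, c(3, 1, 2), drop = FALSE]
    # unique midpoints keyed by the sorted vertex index pair
    pr <- cbind(pmin(fs[, 1], fs[, 2]), pmax(fs[, 1], fs[, 2]))
    key <- paste(pr[, 1], pr[, 2])
    first <- !duplicated(key)
    mid <- nrow(V) + match(key, key[first])
    V <- rbind(V, (V[pr[first, 1], , drop = FALSE] +
                     V[pr[first, 2], , drop = FALSE]) / 2)
    newF <- rbind(cbind(fs[, 1], mid, fs[, 3]),
                  cbind(mid, fs[, 2], fs[, 3]))
    newP <- rep(parent[split], 2)
    keep <- setdiff(seq_len(nrow(F)), split)
    F <- rbind(F[keep, , drop = FALSE], newF)
    parent <- c(parent[keep], newP)
  }
  list(mesh = surface_mesh(V, F, provenance = paste0(mesh$provenance, " (refined)")),
       parent = parent)
}

#' Beam field on the skin: entrance-surface face classification
#'
#' Implements the surface Boolean intersection between the beam pyramid and
#' the body surface, restricted to the entrance side. A refined-mesh face
#' belongs to the skin patch when (a) it lies (at least partly) inside all
#' four lateral half-spaces of the pyramid and (b) its centroid is the first
#' intersection of the ray from the apex through it (visibility: the
#' beam-exit skin on the far side of the body is occluded and excluded).
#' Faces straddling the field rim are clipped exactly against the pyramid
#' planes and enter with the clipped fraction of their area as weight, so
#' the patch area As is the exact area of the visible beam-surface
#' intersection, independent of how the triangulation happens to align with
#' the field edges.
#'
#' @param refined_mesh A [surface_mesh()] in the view's panned frame,
#'   typically from [refine_mesh()].
#' @param pyramid A [beam_pyramid()] for the view.
#' @param view Optional view label stored on the patch.
#' @return An object of class `skin_patch`: `view`, `member_faces` (refined
#'   face ids), `member_weights` (in-field area fraction per member face),
#'   `area_mm2`, `mesh_token` (provenance check for overlap computations).
#' @export
classify_skin_faces <- function(refined_mesh, pyramid, view = NULL) {
  stopifnot(inherits(refined_mesh, "surface_mesh"),
            inherits(pyramid, "beam_pyramid"))
  cen <- face_centroids(refined_mesh)
  vin <- pyramid_contains(pyramid, refined_mesh$vertices)
  n_in <- vin[refined_mesh$faces[, 1]] + vin[refined_mesh$faces[, 2]] +
    vin[refined_mesh$faces[, 3]]
  # rim faces straddle the field boundary; slivers can straddle with every
  # vertex outside, caught by the centroid test
  rim <- which(n_in %in% 1:2 | (n_in == 0 & pyramid_contains(pyramid, cen)))
  weights <- rep(1, nrow(refined_mesh$faces))
  if (length(rim) > 0) {
    weights[rim] <- vapply(rim, function(f) {
      pyramid_area_fraction(refined_mesh$vertices[refined_mesh$faces[f, ], ,
                                                  drop = FALSE], pyramid)
    }, numeric(1))
  }
  cand <- c(which(n_in == 3), rim[weights[rim] > 0])
  member <- integer(0)
  if (length(cand) > 0) {
    dirs <- sweep(cen[cand, , drop = FALSE], 2, pyramid$apex)
    dirs <- dirs / sqrt(rowSums(dirs^2))
    hits <- ray_first_hits(refined_mesh, pyramid$apex, dirs, pyramid$frame)
    member <- cand[!is.na(hits$face) & hits$face == cand]
  }
  member <- sort(member)
  areas <- face_areas(refined_mesh)
  area <- sum(areas[member] * weights[member])
  if (length(member) == 0) {
    warning("beam does not intersect the surface: empty skin patch")
  }
  structure(list(view = view %||% "view", member_faces = member,
                 member_weights = weights[member],
                 area_mm2 = area,
                 mesh_token = mesh_token(refined_mesh)),
            class = "skin_patch")
}

# exact fraction of a triangle's area inside the pyramid's four lateral
# half-spaces (Sutherland-Hodgman clip in 3D; planes pass through the apex)
pyramid_area_fraction <- function(tri, pyramid) {
  poly <- sweep(tri, 2, pyramid$apex)
  full <- polygon_area3(poly)
  if (full <= 0) return(0)
  for (k in 1:4) {
    n <- pyramid$lateral_planes[k, ]
    d <- as.vector(poly %*% n)
    if (all(d >= 0)) next
    if (all(d < 0)) return(0)
    m <- nrow(poly)
    keep <- vector("list", m)
    for (i in seq_len(m)) {
      j <- if (i == m) 1L else i + 1L
      if (d[i] >= 0) {
        keep[[i]] <- poly[i, , drop = FALSE]
        if (d[j] < 0) {
          w <- d[i] / (d[i] - d[j])
          keep[[i]] <- rbind(keep[[i]], poly[i, ] + w * (poly[j, ] - poly[i, ]))
        }
      } else if (d[j] >= 0) {
        w <- d[i] / (d[i] - d[j])
        keep[[i]] <- matrix(poly[i, ] + w * (poly[j, ] - poly[i, ]), 1)
      }
    }
    poly <- do.call(rbind, keep)
    if (is.null(poly) || nrow(poly) < 3) return(0)
  }
  polygon_area3(poly) / full
}

# area of a planar polygon given by its 3D vertices (fan decomposition)
polygon_area3 <- function(p) {
  if (nrow(p) < 3) return(0)
  acc <- c(0, 0, 0)
  for (i in 2:(nrow(p) - 1)) {
    e1 <- p[i, ] - p[1, ]
    e2 <- p[i + 1, ] - p[1, ]
    acc <- acc + c(e1[2] * e2[3] - e1[3] * e2[2],
                   e1[3] * e2[1] - e1[1] * e2[3],
                   e1[1] * e2[2] - e1[2] * e2[1])
  }
  0.5 * sqrt(sum(acc^2))
}

mesh_token <- function(mesh) {
  c(nrow(mesh$vertices), nrow(mesh$faces), round(sum(face_areas(mesh)), 6))
}

#' @export
print.skin_patch <- function(x, ...) {
  cat(sprintf("<skin_patch> %s: %d faces, As = %.0f mm^2\n",
              x$view, length(x$member_faces), x$area_mm2))
  invisible(x)
}

#' Monte-Carlo ray oracle for the on-skin beam area
#'
#' Independent estimate of As by stratified ray sampling over the FOV square
#' at the pyramid's reference plane. Each of the `g x g` jittered rays that
#' hits the surface contributes its exact flat-plane area element mapped to
#' the skin: `da_ref * cos(phi) * (t / r_ref)^2 / cos(theta_inc)`, where
#' `phi` is the ray's angle to the axis, `t` the hit distance, `r_ref` the
#' distance from apex to the ray's reference-plane point, and `theta_inc`
#' the incidence angle at the surface. The standard error is estimated from
#' the per-ray variance (conservative under stratification).
#'
#' @param mesh Surface mesh in the view's panned frame.
#' @param pyramid A [beam_pyramid()].
#' @param n_rays Requested ray count (rounded down to a square).
#' @param seed Integer seed for the jitter.
#' @return A list: `area_mm2`, `se_mm2`, `n_rays`, `n_hits`.
#' @export
as_oracle_mc <- function(mesh, pyramid, n_rays = 1e4, seed = 1L) {
  stopifnot(n_rays >= 1e4)
  g <- floor(sqrt(n_rays))
  restore <- .Random.seed_exists()
  on.exit(restore(), add = TRUE)
  set.seed(seed)

  half <- pyramid$fov_side_mm / 2
  step <- pyramid$fov_side_mm / g
  centers <- -half + step * (seq_len(g) - 0.5)
  au <- rep(centers, g) + stats::runif(g * g, -step / 2, step / 2)
  av <- rep(centers, each = g) + stats::runif(g * g, -step / 2, step / 2)

  fr <- pyramid$frame
  ref <- pyramid$ref_distance_mm
  pts <- outer(au, fr$u) + outer(av, fr$v) + outer(rep(ref, g * g), fr$d)
  rlen <- sqrt(rowSums(pts^2))
  dirs <- pts / rlen
  cos_phi <- ref / rlen

  hits <- ray_first_hits(mesh, pyramid$apex, dirs, fr)
  da <- step^2
  contrib <- rep(0, g * g)
  ok <- !is.na(hits$t) & hits$cos_inc > 1e-6
  contrib[ok] <- da * cos_phi[ok] * (hits$t[ok] / rlen[ok])^2 / hits$cos_inc[ok]
  list(area_mm2 = sum(contrib),
       se_mm2 = stats::sd(contrib) * sqrt(g * g),
       n_rays = g * g,
       n_hits = sum(ok))
}

#' Pairwise on-skin overlap matrix
#'
#' Overlap between the skin patches of two views is the summed area of the
#' refined-mesh faces that belong to both patches, each shared face counted
#' at the smaller of its two in-field weights. Computing overlaps through
#' shared face membership (rather than pairwise mesh Booleans) makes the
#' matrix symmetric and bounded by `min(As_i, As_j)` by construction.
#'
#' @param patches List of [classify_skin_faces()] results, all referencing
#'   the same refined phantom-frame mesh.
#' @param refined_mesh The shared refined [surface_mesh()].
#' @return An object of class `overlap_matrix`: named square matrix of
#'   overlap areas (mm^2) with `NA` on the diagonal.
#' @export
overlap_matrix <- function(patches, refined_mesh) {
  stopifnot(length(patches) >= 2)
  tok <- mesh_token(refined_mesh)
  for (p in patches) {
    if (!inherits(p, "skin_patch")) stop("`patches` must be skin_patch objects")
    if (!isTRUE(all.equal(p$mesh_token, tok))) {
      stop("patch '", p$view, "' references a different refined mesh")
    }
  }
  areas <- face_areas(refined_mesh)
  n <- length(patches)
  nm <- vapply(patches, function(p) p$view, character(1))
  m <- matrix(NA_real_, n, n, dimnames = list(nm, nm))
  for (i in seq_len(n - 1)) {
    for (j in seq((i + 1), n)) {
      pi_ <- patches[[i]]; pj <- patches[[j]]
      ki <- match(pj$member_faces, pi_$member_faces)
      shared <- which(!is.na(ki))
      w <- pmin(pj$member_weights[shared], pi_$member_weights[ki[shared]])
      m[i, j] <- m[j, i] <- sum(areas[pj$member_faces[shared]] * w)
    }
  }
  structure(m, class = c("overlap_matrix", "matrix"))
}

#' Fit the FOV reference-plane offset from printed geometry triplets
#'
#' Given reported (SID, SSD, Ap) triplets, finds the offset `c` that best
#' explains them under the projection model
#' `Ap = (fov_side * SSD / (SID + c))^2`, by least squares on Ap. Used to
#' justify the default `fov_ref_offset_mm` in [carm_config()] from the
#' reference study's tables.
#'
#' @param sid_mm,ssd_mm,ap_mm2 Numeric vectors of equal length.
#' @param fov_side_mm FOV side (default 175).
#' @param interval Search interval for the offset.
#' @return The fitted offset in mm.
#' @export
fit_fov_offset <- function(sid_mm, ssd_mm, ap_mm2, fov_side_mm = 175,
                           interval = c(-100, 200)) {
  stopifnot(length(sid_mm) == length(ssd_mm), length(sid_mm) == length(ap_mm2),
            length(sid_mm) >= 3)
  sse <- function(c0) {
    pred <- (fov_side_mm * ssd_mm / (sid_mm + c0))^2
    sum((ap_mm2 - pred)^2)
  }
  stats::optimize(sse, interval = interval)$minimum
}

#' Export a skin patch as a sub-mesh
#'
#' @param patch A `skin_patch`.
#' @param refined_mesh The refined mesh the patch references.
#' @return A [surface_mesh()] of the member faces only (for STL export).
#' @export
patch_submesh <- function(patch, refined_mesh) {
  if (length(patch$member_faces) == 0) stop("empty patch")
  faces <- refined_mesh$faces[patch$member_faces, , drop = FALSE]
  used <- sort(unique(as.vector(faces)))
  surface_mesh(refined_mesh$vertices[used, , drop = FALSE],
               matrix(match(faces, used), ncol = 3),
               provenance = paste0("skin patch ", patch$view))
}
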