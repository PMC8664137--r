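#' Solve table panning for a view
#'
#' Finds the lateral (LD) and cranio-caudal (CCD) table translation that puts
#' the heart center on the central beam axis at the given angulation, at fixed
#' table height. Positive LD is a left-lateral shift, positive CCD cranial.
#' The solve is closed-form: the axis is intersected with the horizontal plane
#' through the heart, and the heart is shifted in x/z onto that point.
#'
#' @param heart_center Length-3 heart-center coordinate (mm) in the table
#'   frame at its PA-centred position (x = 0, z = 0 after initial alignment).
#' @param ang An [angulation()].
#' @param cfg A [carm_config()].
#' @return A tibble row with `ld_mm`, `ccd_mm`, `total_mm`.
#' @examples
#' solve_panning(c(0, 46, 0), angulation(-10, -30), carm_config())
#' @export
solve_panning <- function(heart_center, ang, cfg) {
  stopifnot(length(heart_center) == 3)
  ax <- beam_axis(ang, cfg)
  d <- ax$direction
  s <- ax$source_point
  if (abs(d[2]) <= 1e-6) {
    stop("near-horizontal beam: panning at fixed table height cannot reach the axis")
  }
  t <- (heart_center[2] - s[2]) / d[2]
  ld <- s[1] + t * d[1] - heart_center[1]
  ccd <- s[3] + t * d[3] - heart_center[3]
  tibble::tibble(ld_mm = ld, ccd_mm = ccd, total_mm = total_panning(ld, ccd))
}

#' Total panning magnitude
#'
#' @param ld_mm,ccd_mm Signed lateral and cranio-caudal displacements (mm).
#' @return `sqrt(ld^2 + ccd^2)` in mm.
#' @examples
#' total_panning(-8, -28) # 29.1
#' @export
total_panning <- function(ld_mm, ccd_mm) {
  sqrt(ld_mm^2 + ccd_mm^2)
}

# axial and transverse detector-frame coordinates of mesh vertices
detector_coords <- function(vertices, ang, cfg) {
  fr <- beam_frame(ang)
  s <- -cfg$source_to_isocenter_mm * fr$d
  rel <- sweep(vertices, 2, s)
  list(t = as.vector(rel %*% fr$d),
       u = as.vector(rel %*% fr$u),
       v = as.vector(rel %*% fr$v),
       frame = fr, source = s)
}

#' Solve the source-to-image-receptor distance (SID)
#'
#' The SID is set so the image receptor cover clears the body surface by the
#' configured clearance: SID = cover gap + clearance + Dmax, where Dmax is the
#' largest axial depth (along the beam axis) of any surface point inside the
#' detector footprint. The footprint is the detector housing square projected
#' along the axis by default; restricting it prevents anatomy far outside the
#' beam (e.g. shoulders at steep angles) from inflating the SID.
#'
#' @param mesh A [surface_mesh()] of the body, already panned for the view
#'   (or pass `panning` to shift it here).
#' @param ang An [angulation()].
#' @param cfg A [carm_config()].
#' @param panning Optional length-2 `(ld, ccd)` translation applied to the
#'   mesh before the solve.
#' @param footprint `"housing"` (default), `"fov"`, or `"full"` (whole body).
#' @return SID in mm.
#' @export
solve_sid <- function(mesh, ang, cfg, panning = c(0, 0),
                      footprint = c("housing", "fov", "full")) {
  stopifnot(inherits(mesh, "surface_mesh"))
  footprint <- match.arg(footprint)
  # the depth scan runs over vertices, so coarse meshes (e.g. a 12-face slab)
  # are densified first to sample the surface inside the footprint
  sample_edge <- cfg$detector_housing_side_mm / 8
  if (max(edge_lengths(mesh)) > sample_edge) {
    mesh <- refine_mesh(mesh, sample_edge)$mesh
  }
  verts <- sweep(mesh$vertices, 2, c(panning[1], 0, panning[2]), "+")
  dc <- detector_coords(verts, ang, cfg)
  half <- switch(footprint,
                 housing = cfg$detector_housing_side_mm / 2,
                 fov = cfg$fov_side_mm / 2,
                 full = Inf)
  inside <- abs(dc$u) <= half & abs(dc$v) <= half & dc$t > 0
  if (!any(inside)) {
    stop("no surface point inside the detector footprint: clearance undefined")
  }
  d_max <- max(dc$t[inside])
  sid <- cfg$cover_to_fpd_mm + cfg$clearance_mm + d_max
  if (sid < cfg$source_to_isocenter_mm) {
    warning("SID below the source-to-isocenter distance: detector plane inside the isocenter")
  }
  sid
}

# first hits of rays from `source` (unit `dirs`) against a mesh
ray_first_hits <- function(mesh, source, dirs, frame) {
  .cpp_ray_first_hits(mesh$vertices, mesh$faces, as.numeric(source),
                      frame$d, frame$u, frame$v,
                      matrix(dirs, ncol = 3), 1e-6)
}

#' Source-to-surface distance (SSD) along the central axis
#'
#' Distance from the X-ray focus to the first intersection of the central
#' beam ray with the skin surface. Grazing back-face hits within the ray
#' tolerance are resolved to the nearest hit.
#'
#' @inheritParams solve_sid
#' @return SSD in mm.
#' @examples
#' ph <- make_slab()
#' compute_ssd(ph$mesh, angulation(0, 0), carm_config()) # 590 for the default slab
#' @export
compute_ssd <- function(mesh, ang, cfg, panning = c(0, 0)) {
  stopifnot(inherits(mesh, "surface_mesh"))
  m <- translate_mesh(mesh, c(panning[1], 0, panning[2]))
  fr <- beam_frame(ang)
  s <- -cfg$source_to_isocenter_mm * fr$d
  hit <- ray_first_hits(m, s, fr$d, fr)
  if (is.na(hit$t[1])) {
    stop("central beam axis does not intersect the mesh: SSD undefined")
  }
  hit$t[1]
}
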