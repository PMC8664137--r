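#' Synthetic torso parameters
#'
#' Parameters of the deterministic synthetic supine-torso surface used in
#' place of scanned anthropomorphic phantoms. The torso is a superelliptic
#' cylinder (convex anterior chest, flat-ish dorsal side) with rounded
#' cranio-caudal caps and a cranial shoulder taper, resting dorsal-side-down
#' on the pad. The embedded heart is placed left of the midline at one third
#' of the chest depth from the frontal skin surface, halfway along the torso
#' by default.
#'
#' @param width_mm Lateral (x) extent of the chest.
#' @param thickness_mm Anterior-posterior (y) extent of the chest.
#' @param length_mm Cranio-caudal (z) extent.
#' @param superellipse_exponent Exponent of the superelliptic cross-section;
#'   2 is an ellipse, larger is boxier.
#' @param shoulder_taper_fraction Relative width reduction reached at the
#'   cranial cap (shoulders narrower than the chest).
#' @param heart_left_offset_mm Heart-center distance left of the midline.
#' @param heart_depth_fraction Heart-center depth from the frontal skin
#'   surface as a fraction of `thickness_mm`.
#' @param heart_z_fraction Heart-center position along the torso (0 caudal,
#'   1 cranial).
#' @param heart_diameter_mm Heart sphere diameter (visualization only; the
#'   positioning solver uses the center point).
#' @param mesh_resolution_mm Target edge length of the generated surface.
#' @param noise_mm Amplitude of optional random surface perturbation along
#'   vertex normals; 0 (default) keeps the shape fully analytic.
#' @param seed Integer seed used only when `noise_mm > 0`.
#' @return A list of class `torso_params`.
#' @export
torso_params <- function(width_mm = 340, thickness_mm = 233, length_mm = 600,
                         superellipse_exponent = 2.5,
                         shoulder_taper_fraction = 0.15,
                         heart_left_offset_mm = 30,
                         heart_depth_fraction = 1 / 3,
                         heart_z_fraction = 0.5,
                         heart_diameter_mm = 100,
                         mesh_resolution_mm = 5,
                         noise_mm = 0, seed = 1L) {
  if (thickness_mm >= width_mm) stop("`thickness_mm` must be less than `width_mm`")
  if (heart_diameter_mm <= 2 || heart_diameter_mm >= thickness_mm + 100) {
    stop("`heart_diameter_mm` out of plausible range")
  }
  if (mesh_resolution_mm <= 0) stop("`mesh_resolution_mm` must be positive")
  if (mesh_resolution_mm > thickness_mm / 4) {
    stop("mesh resolution coarser than the torso features; use a finer `mesh_resolution_mm`")
  }
  if (heart_depth_fraction <= 0 || heart_depth_fraction >= 1) {
    stop("`heart_depth_fraction` must be in (0, 1)")
  }
  structure(as.list(environment()), class = "torso_params")
}

# y level of the pad surface the phantom rests on
pad_plane_y <- function(cfg) {
  -(cfg$table_top_below_isocenter_mm - cfg$pad_thickness_mm)
}

new_placed_phantom <- function(mesh, heart_center) {
  structure(list(mesh = mesh, heart_center = as.numeric(heart_center)),
            class = "placed_phantom")
}

#' @export
print.placed_phantom <- function(x, ...) {
  cat("<placed_phantom>\n  heart center:",
      sprintf("(%.1f, %.1f, %.1f) mm\n", x$heart_center[1], x$heart_center[2],
              x$heart_center[3]))
  print(x$mesh)
  invisible(x)
}

#' Rectangular slab phantom
#'
#' An axis-aligned box resting on the pad, used as an analytic test fixture:
#' the dorsal face sits on the pad plane and the anterior face at
#' `pad_plane + thickness`.
#'
#' @param width_mm,length_mm,thickness_mm Box dimensions (x, z, y).
#' @param cfg A [carm_config()]; sets the pad plane height.
#' @param heart_center Optional heart-center override; defaults to mid-depth
#'   on the midline.
#' @return A `placed_phantom`.
#' @export
make_slab <- function(width_mm = 340, length_mm = 600, thickness_mm = 233,
                      cfg = carm_config(), heart_center = NULL) {
  stopifnot(width_mm > 0, length_mm > 0, thickness_mm > 0)
  y0 <- pad_plane_y(cfg)
  v <- as.matrix(expand.grid(x = c(-1, 1) * width_mm / 2,
                             y = c(y0, y0 + thickness_mm),
                             z = c(-1, 1) * length_mm / 2))
  dimnames(v) <- NULL
  # 12 triangles, outward orientation
  f <- rbind(
    c(1, 3, 7), c(1, 7, 5),   # y = y0 (dorsal, normal -y)
    c(2, 8, 4), c(2, 6, 8),   # y = y0 + t (anterior, +y)
    c(1, 5, 6), c(1, 6, 2),   # x = -w/2 ... check below
    c(3, 4, 8), c(3, 8, 7),
    c(1, 2, 4), c(1, 4, 3),   # z = -L/2
    c(5, 7, 8), c(5, 8, 6)    # z = +L/2
  )
  mesh <- surface_mesh(v, f, provenance = "slab phantom")
  mesh <- orient_outward(mesh)
  if (is.null(heart_center)) heart_center <- c(0, y0 + thickness_mm / 2, 0)
  new_placed_phantom(mesh, heart_center)
}

#' Cylinder phantom
#'
#' A circular cylinder with its axis along z, resting tangent on the pad.
#'
#' @param radius_mm,length_mm Cylinder dimensions.
#' @param cfg A [carm_config()].
#' @param n_theta Angular facet count.
#' @return A `placed_phantom`.
#' @export
make_cylinder <- function(radius_mm = 100, length_mm = 600,
                          cfg = carm_config(), n_theta = 96) {
  stopifnot(radius_mm > 0, length_mm > 0, n_theta >= 8)
  yc <- pad_plane_y(cfg) + radius_mm
  th <- seq(0, 2 * pi, length.out = n_theta + 1)[-(n_theta + 1)]
  ring <- cbind(radius_mm * cos(th), yc + radius_mm * sin(th))
  # segment along z at roughly the angular spacing for near-isotropic faces
  n_z <- max(1L, as.integer(round(length_mm / (2 * pi * radius_mm / n_theta))))
  zs <- seq(-length_mm / 2, length_mm / 2, length.out = n_z + 1)
  v <- do.call(rbind, lapply(zs, function(z) cbind(ring, z)))
  v <- rbind(v, c(0, yc, zs[1]), c(0, yc, zs[n_z + 1]))
  n <- n_theta
  i <- seq_len(n); j <- c(seq_len(n)[-1], 1)
  side <- do.call(rbind, lapply(seq_len(n_z), function(k) {
    a <- (k - 1L) * n; b <- k * n
    rbind(cbind(a + i, a + j, b + j), cbind(a + i, b + j, b + i))
  }))
  ip0 <- (n_z + 1L) * n + 1L
  ip1 <- ip0 + 1L
  cap0 <- cbind(ip0, j, i)
  cap1 <- cbind(ip1, n_z * n + i, n_z * n + j)
  mesh <- surface_mesh(v, rbind(side, cap0, cap1), provenance = "cylinder phantom")
  mesh <- orient_outward(mesh)
  new_placed_phantom(mesh, c(0, yc, 0))
}

# taper multiplier applied to the half-width as a function of axial fraction
shoulder_scale <- function(zf, taper_fraction, region = 0.25) {
  s <- pmin(pmax((zf - (1 - region)) / region, 0), 1)
  1 - taper_fraction * (3 * s^2 - 2 * s^3)
}

#' Synthetic supine torso phantom
#'
#' Generates the analytic torso surface described in [torso_params()], placed
#' in the table frame with its dorsal plane on the pad, and the heart center
#' per the placement rule (left offset, fractional depth from the frontal
#' skin surface, fractional position along the torso). Deterministic for
#' fixed parameters.
#'
#' @param params A [torso_params()].
#' @param cfg A [carm_config()].
#' @return A `placed_phantom` with a watertight mesh.
#' @examples
#' ph <- make_torso(torso_params(mesh_resolution_mm = 15), carm_config())
#' ph$heart_center
#' @export
make_torso <- function(params = torso_params(), cfg = carm_config()) {
  stopifnot(inherits(params, "torso_params"))
  p <- params
  y0 <- pad_plane_y(cfg)
  t2 <- p$thickness_mm / 2
  w2 <- p$width_mm / 2
  yc <- y0 + t2
  L <- p$length_mm
  res <- p$mesh_resolution_mm

  per <- 2 * pi * sqrt((w2^2 + t2^2) / 2)
  n_th <- max(16L, as.integer(round(per / res)))
  n_z <- max(8L, as.integer(round(L / res)))

  cap_len <- t2  # rounded cap length at each end
  zf <- seq(0, 1, length.out = n_z + 1)
  z <- zf * L - L / 2

  ex <- 2 / p$superellipse_exponent
  th <- seq(0, 2 * pi, length.out = n_th + 1)[-(n_th + 1)]
  ux <- sign(cos(th)) * abs(cos(th))^ex
  uy <- sign(sin(th)) * abs(sin(th))^ex

  # cross-section scale: rounded caps at both ends
  zl <- zf * L
  s_cap <- rep(1, length(zl))
  low <- zl < cap_len
  s_cap[low] <- sqrt(pmax(1 - ((cap_len - zl[low]) / cap_len)^2, 0))
  high <- zl > L - cap_len
  s_cap[high] <- sqrt(pmax(1 - ((zl[high] - (L - cap_len)) / cap_len)^2, 0))
  s_w <- shoulder_scale(zf, p$shoulder_taper_fraction)

  interior <- s_cap > 1e-8
  ring_z <- z[interior]
  ring_sc <- s_cap[interior]
  ring_sw <- s_w[interior]
  n_ring <- length(ring_z)
  if (n_ring < 3) stop("mesh resolution too coarse for the torso length")

  verts <- do.call(rbind, lapply(seq_len(n_ring), function(k) {
    cbind(w2 * ring_sw[k] * ring_sc[k] * ux,
          yc + t2 * ring_sc[k] * uy,
          ring_z[k])
  }))
  pole0 <- c(0, yc, -L / 2)
  pole1 <- c(0, yc, L / 2)
  verts <- rbind(verts, pole0, pole1)
  ip0 <- nrow(verts) - 1L
  ip1 <- nrow(verts)

  i <- seq_len(n_th); j <- c(seq_len(n_th)[-1], 1L)
  strips <- do.call(rbind, lapply(seq_len(n_ring - 1), function(k) {
    a <- (k - 1L) * n_th
    b <- k * n_th
    rbind(cbind(a + i, a + j, b + j), cbind(a + i, b + j, b + i))
  }))
  fan0 <- cbind(ip0, j, i)                      # caudal cap
  a <- (n_ring - 1L) * n_th
  fan1 <- cbind(ip1, a + i, a + j)              # cranial cap
  mesh <- surface_mesh(verts, rbind(strips, fan0, fan1),
                       provenance = "synthetic torso phantom")
  mesh <- orient_outward(mesh)

  if (p$noise_mm > 0) {
    old <- .Random.seed_exists()
    set.seed(p$seed)
    nrm <- vertex_normals(mesh)
    mesh$vertices <- mesh$vertices +
      nrm * stats::runif(nrow(mesh$vertices), -p$noise_mm, p$noise_mm)
    on.exit(old(), add = TRUE)
  }

  y_front <- y0 + p$thickness_mm
  heart <- c(p$heart_left_offset_mm,
             y_front - p$heart_depth_fraction * p$thickness_mm,
             (p$heart_z_fraction - 0.5) * L)
  new_placed_phantom(mesh, heart)
}

.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    saved <- get(".Random.seed", envir = globalenv())
    function() assign(".Random.seed", saved, envir = globalenv())
  } else {
    function() invisible(NULL)
  }
}

vertex_normals <- function(mesh) {
  fn <- face_normals(mesh)
  out <- matrix(0, nrow(mesh$vertices), 3)
  for (k in 1:3) {
    for (c in 1:3) {
      acc <- tapply(fn[, c], mesh$faces[, k], sum)
      out[as.integer(names(acc)), c] <- out[as.integer(names(acc)), c] + acc
    }
  }
  len <- sqrt(rowSums(out^2)); len[len == 0] <- 1
  out / len
}

# Flip faces so normals point away from the mesh interior. Works for the
# star-shaped phantom surfaces generated here (centroid visibility test).
orient_outward <- function(mesh) {
  inner <- colMeans(mesh$vertices)
  cen <- face_centroids(mesh)
  nrm <- face_normals(mesh)
  flip <- rowSums(nrm * sweep(cen, 2, inner)) < 0
  mesh$faces[flip, ] <- mesh$faces[flip, c(1, 3, 2), drop = FALSE]
  mesh
}

#' Preset phantoms
#'
#' Named phantom presets: `male` and `female` synthetic torsos (differing in
#' chest width/thickness and heart placement: left offset 30 mm at 1/3 of a
#' 233-mm chest depth vs 20 mm at 1/3 of a 198-mm depth), plus `slab` and
#' `cylinder` analytic fixtures.
#'
#' @param preset One of `"male"`, `"female"`, `"slab"`, `"cylinder"`.
#' @param cfg A [carm_config()].
#' @param mesh_resolution_mm Surface resolution for the torso presets.
#' @return A `placed_phantom`.
#' @export
preset_phantom <- function(preset = c("male", "female", "slab", "cylinder"),
                           cfg = carm_config(), mesh_resolution_mm = 5) {
  preset <- match.arg(preset)
  switch(preset,
    male = make_torso(torso_params(width_mm = 340, thickness_mm = 233,
                                   heart_left_offset_mm = 30,
                                   mesh_resolution_mm = mesh_resolution_mm),
                      cfg),
    female = make_torso(torso_params(width_mm = 320, thickness_mm = 198,
                                     heart_left_offset_mm = 20,
                                     mesh_resolution_mm = mesh_resolution_mm),
                        cfg),
    slab = make_slab(cfg = cfg),
    cylinder = make_cylinder(cfg = cfg)
  )
}

#' Heart sphere visualization mesh
#'
#' The 10-cm heart sphere as a triangle mesh around a phantom's heart center,
#' for export alongside the body surface. The positioning solver itself uses
#' only the center point.
#'
#' @param phantom A `placed_phantom`.
#' @param diameter_mm Sphere diameter.
#' @param n Icosphere subdivision level.
#' @return A [surface_mesh()].
#' @export
heart_sphere <- function(phantom, diameter_mm = 100, n = 3) {
  s <- icosphere(n)
  s$vertices <- s$vertices * (diameter_mm / 2)
  translate_mesh(s, phantom$heart_center)
}

# unit icosphere by midpoint subdivision of an icosahedron
icosphere <- function(subdiv = 3) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  mesh <- surface_mesh(v, f, provenance = "icosphere")
  for (k in seq_len(subdiv)) {
    r <- subdivide_all(mesh)
    r$vertices <- r$vertices / sqrt(rowSums(r$vertices^2))
    mesh <- r
  }
  orient_outward(mesh)
}

# one uniform 4-to-1 midpoint split of every face (keeps triangle quality)
subdivide_all <- function(mesh) {
  V <- mesh$vertices
  F <- mesh$faces
  pr <- rbind(cbind(F[, 1], F[, 2]), cbind(F[, 2], F[, 3]),
              cbind(F[, 3], F[, 1]))
  pr <- cbind(pmin(pr[, 1], pr[, 2]), pmax(pr[, 1], pr[, 2]))
  key <- paste(pr[, 1], pr[, 2])
  first <- !duplicated(key)
  mid <- nrow(V) + match(key, key[first])
  V <- rbind(V, (V[pr[first, 1], , drop = FALSE] +
                   V[pr[first, 2], , drop = FALSE]) / 2)
  m <- nrow(F)
  mab <- mid[seq_len(m)]
  mbc <- mid[m + seq_len(m)]
  mca <- mid[2 * m + seq_len(m)]
  surface_mesh(V, rbind(cbind(F[, 1], mab, mca),
                        cbind(mab, F[, 2], mbc),
                        cbind(mca, mbc, F[, 3]),
                        cbind(mab, mbc, mca)),
               provenance = mesh$provenance)
}

edge_lengths <- function(mesh) {
  co <- face_corners(mesh)
  c(sqrt(rowSums((co$a - co$b)^2)),
    sqrt(rowSums((co$b - co$c)^2)),
    sqrt(rowSums((co$c - co$a)^2)))
}
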