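test_that("perpendicular-plane area follows the projection model", {
  cfg <- default_cfg
  # at the reference plane the beam is exactly the FOV square
  expect_equal(compute_ap(cfg, sid_mm = 975, ssd_mm = 1000), 175^2)
  # reference-geometry consistency: printed PA row within 0.2%
  expect_equal(compute_ap(cfg, 976, 593), 10738, tolerance = 0.002)
  # inverse-square scaling
  expect_equal(compute_ap(cfg, 976, 593 / 2), compute_ap(cfg, 976, 593) / 4)
  expect_error(compute_ap(cfg, 976, -1), "positive")
  expect_error(compute_ap(cfg, 976, 1200), "reference")
})

test_that("beam pyramid contains the axis and excludes far-off points", {
  for (ang in list(angulation(0, 0), angulation(45, 30), angulation(-30, -30))) {
    pyr <- beam_pyramid(ang, default_cfg, sid_mm = 1000)
    d <- beam_direction(ang)
    axis_pts <- t(vapply(c(100, 400, 800), function(t) pyr$apex + t * d,
                         numeric(3)))
    expect_true(all(pyramid_contains(pyr, axis_pts)))
    # apex is on no positive side of a lateral plane
    expect_true(all(abs(pyr$lateral_planes %*% (pyr$apex - pyr$apex)) < 1e-12))
    # a point 2 FOV sides off-axis at the reference distance is outside
    off <- pyr$apex + pyr$ref_distance_mm * d +
      2 * pyr$fov_side_mm * pyr$frame$u
    expect_false(pyramid_contains(pyr, matrix(off, 1)))
    # corner ray half-angle
    corner <- pyr$apex + pyr$ref_distance_mm * d +
      (pyr$fov_side_mm / 2) * (pyr$frame$u + pyr$frame$v)
    cd <- corner - pyr$apex
    half_angle <- acos(sum(cd * d) / sqrt(sum(cd^2)))
    expect_equal(half_angle, atan(87.5 * sqrt(2) / pyr$ref_distance_mm),
                 tolerance = 1e-9)
  }
})

test_that("refinement conserves area and respects the edge bound", {
  m <- cube_mesh(100)
  r <- refine_mesh(m, 2)
  expect_lt(max(beamskin:::edge_lengths(r$mesh)), 2 + 1e-9)
  expect_equal(sum(face_areas(r$mesh)), 60000, tolerance = 1e-9)
  expect_equal(length(r$parent), nrow(r$mesh$faces))
  expect_setequal(unique(r$parent), seq_len(nrow(m$faces)))
  # parent map: areas grouped by parent reproduce the original faces
  by_parent <- tapply(face_areas(r$mesh), r$parent, sum)
  expect_equal(as.numeric(by_parent), face_areas(m), tolerance = 1e-9)
  # an already-fine mesh is untouched
  fine <- refine_mesh(r$mesh, 5)
  expect_identical(nrow(fine$mesh$faces), nrow(r$mesh$faces))
})

test_that("a flat entrance perpendicular to the axis reproduces Ap", {
  slab <- make_slab()
  ang <- angulation(0, 0)
  sid <- solve_sid(slab$mesh, ang, default_cfg)
  ssd <- compute_ssd(slab$mesh, ang, default_cfg)
  ap <- compute_ap(default_cfg, sid, ssd)
  pyr <- beam_pyramid(ang, default_cfg, sid)
  patch <- classify_skin_faces(refine_mesh(slab$mesh, 4)$mesh, pyr)
  expect_equal(patch$area_mm2, ap, tolerance = 0.01)
})

test_that("a 30-degree oblique plane enlarges the on-skin field by 1/cos", {
  m <- tilted_plane(30)
  ang <- angulation(0, 0)
  ssd <- compute_ssd(m, ang, default_cfg)
  sid <- 976
  ap <- compute_ap(default_cfg, sid, ssd)
  pyr <- beam_pyramid(ang, default_cfg, sid)
  patch <- classify_skin_faces(refine_mesh(m, 4)$mesh, pyr)
  expect_equal(patch$area_mm2 / ap, 1 / cos(30 * pi / 180), tolerance = 0.01)
})

test_that("visibility keeps the entrance cap and drops the beam-exit skin", {
  sph <- sphere_mesh(100, subdiv = 4)
  ang <- angulation(0, 0)
  pyr <- beam_pyramid(ang, default_cfg, 940)
  patch <- classify_skin_faces(sph, pyr)
  expect_gt(length(patch$member_faces), 0)
  cen <- beamskin:::face_centroids(sph)[patch$member_faces, , drop = FALSE]
  # all member centroids are on the source side of the sphere
  expect_lt(max(cen[, 2]), 0)
})

test_that("clipped area converges with refinement and matches the ray oracle", {
  m <- tilted_plane(30, half_mm = 150)
  ang <- angulation(0, 0)
  pyr <- beam_pyramid(ang, default_cfg, 976)
  a4 <- classify_skin_faces(refine_mesh(m, 4)$mesh, pyr)$area_mm2
  a1 <- classify_skin_faces(refine_mesh(m, 1)$mesh, pyr)$area_mm2
  expect_lt(abs(a4 - a1) / a1, 0.02)
  mc <- as_oracle_mc(m, pyr, n_rays = 4e4, seed = 5)
  expect_lt(abs(a1 - mc$area_mm2), 3 * mc$se_mm2 + 0.01 * a1)
})

test_that("the Monte-Carlo oracle is exact on a perpendicular slab and seeded", {
  slab <- make_slab()
  ang <- angulation(0, 0)
  sid <- solve_sid(slab$mesh, ang, default_cfg)
  ssd <- compute_ssd(slab$mesh, ang, default_cfg)
  pyr <- beam_pyramid(ang, default_cfg, sid)
  mc <- as_oracle_mc(slab$mesh, pyr, n_rays = 1e4, seed = 3)
  expect_equal(mc$area_mm2, compute_ap(default_cfg, sid, ssd), tolerance = 1e-9)
  expect_equal(mc$n_hits, mc$n_rays)
  mc2 <- as_oracle_mc(slab$mesh, pyr, n_rays = 1e4, seed = 3)
  expect_identical(mc$area_mm2, mc2$area_mm2)
  # beam entirely missing the surface
  far <- cube_mesh(40, c(600, 0, 0))
  mc0 <- as_oracle_mc(far, pyr, n_rays = 1e4, seed = 3)
  expect_equal(mc0$area_mm2, 0)
  expect_error(as_oracle_mc(slab$mesh, pyr, n_rays = 100), "n_rays")
})

test_that("overlap areas come from shared face membership", {
  ph <- make_cylinder(radius_mm = 100, length_mm = 400)
  refined <- refine_mesh(ph$mesh, 4)$mesh
  pyr_a <- beam_pyramid(angulation(0, 0), default_cfg, 940)
  pyr_b <- beam_pyramid(angulation(-10, -30), default_cfg, 1000)
  pa <- classify_skin_faces(refined, pyr_a, "A")
  pb <- classify_skin_faces(refined, pyr_b, "B")
  pa2 <- pa; pa2$view <- "A clone"
  m <- overlap_matrix(list(pa, pa2, pb), refined)
  expect_true(is.na(m[1, 1]) && is.na(m[2, 2]))
  expect_equal(m[1, 2], pa$area_mm2)              # identical sets
  expect_equal(unclass(m)[lower.tri(m)], t(unclass(m))[lower.tri(m)])
  expect_lte(m[1, 3], min(pa$area_mm2, pb$area_mm2))
  # nested sets overlap by the smaller area
  sub <- pa
  half <- seq_len(floor(length(pa$member_faces) / 2))
  sub$member_faces <- pa$member_faces[half]
  sub$member_weights <- pa$member_weights[half]
  sub$area_mm2 <- sum(face_areas(refined)[sub$member_faces] * sub$member_weights)
  sub$view <- "A half"
  m2 <- overlap_matrix(list(pa, sub), refined)
  expect_equal(m2[1, 2], sub$area_mm2)
  # disjoint patches
  pc <- pa; pc$view <- "C"
  pc$member_faces <- setdiff(seq_len(nrow(refined$faces)), pa$member_faces)[1:5]
  pc$member_weights <- rep(1, 5)
  pc$area_mm2 <- sum(face_areas(refined)[pc$member_faces])
  expect_equal(overlap_matrix(list(pa, pc), refined)[1, 2], 0)
  # provenance mismatch
  other <- refine_mesh(ph$mesh, 5)$mesh
  expect_error(overlap_matrix(list(pa, pb), other), "different refined mesh")
})

test_that("the FOV reference offset is recoverable from consistent triplets", {
  cfg <- carm_config(fov_ref_offset_mm = 25)
  sid <- c(950, 1000, 1050, 1100, 980, 1020)
  ssd <- c(590, 575, 560, 550, 585, 570)
  ap <- mapply(function(s1, s2) compute_ap(cfg, s1, s2), sid, ssd)
  expect_equal(fit_fov_offset(sid, ssd, ap), 25, tolerance = 1e-3)
})

test_that("patch sub-mesh export preserves the patch area", {
  ph <- make_cylinder(radius_mm = 100, length_mm = 400)
  refined <- refine_mesh(ph$mesh, 5)$mesh
  pyr <- beam_pyramid(angulation(0, 0), default_cfg, 940)
  p <- classify_skin_faces(refined, pyr, "PA")
  sub <- patch_submesh(p, refined)
  expect_equal(sum(face_areas(sub)),
               sum(face_areas(refined)[p$member_faces]), tolerance = 1e-9)
  # member faces carry the whole patch area through their weights
  expect_gte(sum(face_areas(sub)) + 1e-9, p$area_mm2)
})
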