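test_that("panning solve reproduces the closed-form line intersection", {
  # PA with a centred heart needs no panning
  pan <- solve_panning(c(0, 46, 0), angulation(0, 0), default_cfg)
  expect_equal(c(pan$ld_mm, pan$ccd_mm, pan$total_mm), c(0, 0, 0))
  # steep caudal right-oblique view
  pan <- solve_panning(c(0, 46, 0), angulation(-10, -30), default_cfg)
  expect_equal(round(pan$ld_mm, 1), -8.1)
  expect_equal(round(pan$ccd_mm, 0), -27)
  # mirror views give mirrored lateral displacement
  for (a in c(10, 30, 45)) {
    l <- solve_panning(c(0, 46, 0), angulation(a, 0), default_cfg)
    r <- solve_panning(c(0, 46, 0), angulation(-a, 0), default_cfg)
    expect_equal(l$ld_mm, -r$ld_mm, tolerance = 1e-12)
    expect_equal(l$ccd_mm, r$ccd_mm, tolerance = 1e-12)
  }
})

test_that("panned heart lands on the central axis (random property sweep)", {
  set.seed(2024)
  n_bad <- 0
  for (k in 1:1000) {
    ang <- angulation(stats::runif(1, -120, 120), stats::runif(1, -60, 60))
    d <- beam_direction(ang)
    if (abs(d[2]) <= 1e-6) next
    heart <- c(0, stats::runif(1, -80, 100), 0)
    pan <- solve_panning(heart, ang, default_cfg)
    shifted <- heart + c(pan$ld_mm, 0, pan$ccd_mm)
    s <- -default_cfg$source_to_isocenter_mm * d
    rel <- shifted - s
    resid <- sqrt(sum((rel - sum(rel * d) * d)^2))
    if (resid >= 1e-6) n_bad <- n_bad + 1
    expect_equal(pan$total_mm, sqrt(pan$ld_mm^2 + pan$ccd_mm^2),
                 tolerance = 1e-9)
  }
  expect_equal(n_bad, 0)
})

test_that("near-horizontal beams are rejected by the panning solver", {
  expect_error(solve_panning(c(0, 46, 0), angulation(90, 0), default_cfg),
               "horizontal")
})

test_that("total panning is the Euclidean magnitude", {
  expect_equal(round(total_panning(-8, -28)), 29)
  expect_equal(total_panning(0, 0), 0)
  expect_equal(total_panning(3, 4), 5)
})

test_that("SID follows the clearance rule on analytic phantoms", {
  slab <- make_slab(thickness_mm = 233)
  # anterior face at +123: Dmax = 700 + 123, SID = Dmax + 100 + 50
  expect_equal(solve_sid(slab$mesh, angulation(0, 0), default_cfg), 973)
  cfg0 <- carm_config(clearance_mm = 1e-9)
  expect_equal(solve_sid(slab$mesh, angulation(0, 0), cfg0), 873,
               tolerance = 1e-6)
  cyl <- make_cylinder(radius_mm = 100)
  expect_equal(solve_sid(cyl$mesh, angulation(0, 0), default_cfg), 940,
               tolerance = 0.5)
})

test_that("SID is monotone in clearance and in phantom thickness", {
  sids_cl <- vapply(c(50, 100, 150), function(cl) {
    solve_sid(make_slab()$mesh, angulation(-30, 30),
              carm_config(clearance_mm = cl))
  }, numeric(1))
  expect_true(all(diff(sids_cl) > 0))
  sids_t <- vapply(c(180, 233, 280), function(t) {
    solve_sid(make_slab(thickness_mm = t)$mesh, angulation(0, 0), default_cfg)
  }, numeric(1))
  expect_true(all(diff(sids_t) > 0))
})

test_that("footprint restriction caps the depth scan near the beam", {
  # a tall spike far outside the footprint must not inflate the SID
  slab <- make_slab(thickness_mm = 150)
  spike <- cube_mesh(40, center = c(160, 60, 0))  # above the slab, off-axis
  both <- surface_mesh(rbind(slab$mesh$vertices, spike$vertices),
                       rbind(slab$mesh$faces, spike$faces + nrow(slab$mesh$vertices)))
  sid_housing <- solve_sid(both, angulation(0, 0), default_cfg, footprint = "housing")
  sid_full <- solve_sid(both, angulation(0, 0), default_cfg, footprint = "full")
  expect_equal(sid_housing, solve_sid(slab$mesh, angulation(0, 0), default_cfg))
  expect_gt(sid_full, sid_housing)
  expect_error(solve_sid(cube_mesh(40, c(500, 0, 0)), angulation(0, 0),
                         default_cfg), "footprint")
})

test_that("SSD is the first intersection along the central axis", {
  expect_equal(compute_ssd(make_slab()$mesh, angulation(0, 0), default_cfg), 590)
  expect_equal(compute_ssd(sphere_mesh(100), angulation(0, 0), default_cfg),
               600, tolerance = 0.2)
  expect_error(compute_ssd(cube_mesh(40, c(500, 0, 0)), angulation(0, 0),
                           default_cfg), "SSD")
})

test_that("entrance comes before exit: SSD below the footprint depth max", {
  for (view in list(angulation(0, 0), angulation(-30, 30), angulation(45, -30))) {
    ph <- make_cylinder(radius_mm = 110)
    sid <- solve_sid(ph$mesh, view, default_cfg)
    ssd <- compute_ssd(ph$mesh, view, default_cfg)
    d_max <- sid - default_cfg$cover_to_fpd_mm - default_cfg$clearance_mm
    expect_lt(ssd, d_max)
  }
})
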