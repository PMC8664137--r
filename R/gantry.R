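#' Gantry angulation
#'
#' A primary/secondary C-arm gantry angulation. Primary rotation is in the
#' axial plane: positive angles are LAO (left anterior oblique), negative RAO.
#' Secondary angulation tilts the beam along the patient axis: positive is
#' cranial (CRA), negative caudal (CAU).
#'
#' @param primary_deg Signed primary angle in degrees (+ = LAO, - = RAO).
#' @param secondary_deg Signed secondary angle in degrees (+ = CRA, - = CAU).
#' @param name Optional label such as `"LAO 45/CRA 30"`; autogenerated when
#'   omitted.
#' @return An object of class `angulation`.
#' @examples
#' angulation(45, 30)
#' angulation(-30, 0, name = "RAO 30")
#' @export
angulation <- function(primary_deg, secondary_deg, name = NULL) {
  stopifnot(is.numeric(primary_deg), length(primary_deg) == 1, is.finite(primary_deg),
            is.numeric(secondary_deg), length(secondary_deg) == 1, is.finite(secondary_deg))
  if (abs(primary_deg) > 120) {
    stop("`primary_deg` must be within +/-120 degrees, got ", primary_deg)
  }
  if (abs(secondary_deg) > 60) {
    stop("`secondary_deg` must be within +/-60 degrees, got ", secondary_deg)
  }
  if (is.null(name)) {
    p <- if (primary_deg == 0) "PA 0" else
      sprintf("%s %g", if (primary_deg > 0) "LAO" else "RAO", abs(primary_deg))
    s <- if (secondary_deg == 0) "" else
      sprintf("/%s %g", if (secondary_deg > 0) "CRA" else "CAU", abs(secondary_deg))
    name <- paste0(p, s)
  }
  structure(
    list(primary_deg = primary_deg, secondary_deg = secondary_deg, name = name),
    class = "angulation"
  )
}

#' @export
print.angulation <- function(x, ...) {
  cat(sprintf("<angulation> %s (primary %+g deg, secondary %+g deg)\n",
              x$name, x$primary_deg, x$secondary_deg))
  invisible(x)
}

#' C-arm machine configuration
#'
#' Fixed geometry of the modelled cardiovascular angiography system. Defaults
#' describe a system with a 700-mm source-to-isocenter distance, a
#' 200 x 200 mm flat-panel detector housing with a 175 x 175 mm field of view,
#' a 50-mm image-receptor cover-to-detector gap, the tabletop 150 mm below the
#' isocenter with a 40-mm pad, a 100-mm cover-to-skin clearance rule, and the
#' patient entrance reference point (PERP) 150 mm from the isocenter toward
#' the tube.
#'
#' @param source_to_isocenter_mm X-ray focus to isocenter distance.
#' @param cover_to_fpd_mm Image receptor cover to detector plane distance.
#' @param fov_side_mm Side of the square field of view at the detector.
#' @param detector_housing_side_mm Side of the square detector housing; the
#'   clearance rule applies within its projected footprint.
#' @param table_top_below_isocenter_mm Tabletop height below the isocenter.
#' @param pad_thickness_mm Mattress pad thickness on the tabletop.
#' @param clearance_mm Required separation between the image receptor cover
#'   and the body surface.
#' @param fov_ref_offset_mm Distance beyond the SID at which the nominal FOV
#'   square is defined (the collimator tracks the FOV at this reference
#'   plane). See [fit_fov_offset()] for how the default is justified.
#' @param focal_spot_diameter_mm Focal spot size; recorded only, the source is
#'   modelled as a point.
#' @param perp_below_isocenter_mm PERP distance from the isocenter toward the
#'   tube.
#' @return An object of class `carm_config`.
#' @examples
#' cfg <- carm_config()
#' spd(cfg)
#' @export
carm_config <- function(source_to_isocenter_mm = 700,
                        cover_to_fpd_mm = 50,
                        fov_side_mm = 175,
                        detector_housing_side_mm = 200,
                        table_top_below_isocenter_mm = 150,
                        pad_thickness_mm = 40,
                        clearance_mm = 100,
                        fov_ref_offset_mm = 25,
                        focal_spot_diameter_mm = 1.2,
                        perp_below_isocenter_mm = 150) {
  lens <- c(source_to_isocenter_mm, cover_to_fpd_mm, fov_side_mm,
            detector_housing_side_mm, table_top_below_isocenter_mm,
            pad_thickness_mm, clearance_mm, focal_spot_diameter_mm,
            perp_below_isocenter_mm)
  if (any(!is.finite(lens)) || any(lens <= 0)) {
    stop("all length parameters must be positive finite numbers")
  }
  if (!is.finite(fov_ref_offset_mm)) stop("`fov_ref_offset_mm` must be finite")
  if (fov_side_mm > detector_housing_side_mm) {
    stop("`fov_side_mm` cannot exceed `detector_housing_side_mm`")
  }
  if (source_to_isocenter_mm <= perp_below_isocenter_mm) {
    stop("PERP would lie behind the source: need source_to_isocenter_mm > perp_below_isocenter_mm")
  }
  structure(
    list(source_to_isocenter_mm = source_to_isocenter_mm,
         cover_to_fpd_mm = cover_to_fpd_mm,
         fov_side_mm = fov_side_mm,
         detector_housing_side_mm = detector_housing_side_mm,
         table_top_below_isocenter_mm = table_top_below_isocenter_mm,
         pad_thickness_mm = pad_thickness_mm,
         clearance_mm = clearance_mm,
         fov_ref_offset_mm = fov_ref_offset_mm,
         focal_spot_diameter_mm = focal_spot_diameter_mm,
         perp_below_isocenter_mm = perp_below_isocenter_mm),
    class = "carm_config"
  )
}

#' @export
print.carm_config <- function(x, ...) {
  cat("<carm_config>\n")
  for (nm in names(x)) cat(sprintf("  %-30s %g\n", nm, x[[nm]]))
  cat(sprintf("  %-30s %g\n", "spd_mm (derived)", spd(x)))
  invisible(x)
}

#' Source-to-PERP distance
#'
#' Distance from the X-ray focus to the patient entrance reference point
#' (PERP) along the central beam axis. The PERP sits
#' `perp_below_isocenter_mm` from the isocenter toward the tube, so
#' SPD = source-to-isocenter distance - PERP offset (550 mm for defaults).
#'
#' @param cfg A [carm_config()].
#' @return SPD in millimetres.
#' @examples
#' spd(carm_config()) # 550
#' @export
spd <- function(cfg) {
  stopifnot(inherits(cfg, "carm_config"))
  out <- cfg$source_to_isocenter_mm - cfg$perp_below_isocenter_mm
  if (out <= 0) stop("configuration error: SPD is not positive")
  out
}

#' Central beam direction for an angulation
#'
#' Unit vector from the X-ray focus toward the detector, in the table frame
#' (origin at the isocenter, +x patient left, +y anterior, +z cranial). The
#' parametrization is spherical: primary angle about the cranio-caudal axis,
#' secondary angle as elevation, i.e.
#' `d = (sin a cos b, cos a cos b, sin b)` with `a` primary and `b` secondary
#' in degrees. The sign convention (LAO/CRA positive) makes left-lateral and
#' cranial pannings come out positive downstream.
#'
#' @param ang An [angulation()].
#' @return Numeric length-3 unit vector.
#' @examples
#' beam_direction(angulation(0, 0))   # (0, 1, 0): PA, beam travels anteriorly
#' beam_direction(angulation(90, 0))  # (1, 0, 0): left lateral
#' @export
beam_direction <- function(ang) {
  stopifnot(inherits(ang, "angulation"))
  a <- ang$primary_deg * pi / 180
  b <- ang$secondary_deg * pi / 180
  d <- c(sin(a) * cos(b), cos(a) * cos(b), sin(b))
  d / sqrt(sum(d^2))
}

#' Central beam axis for an angulation
#'
#' The central axis always passes through the isocenter (the origin); the
#' focus sits `source_to_isocenter_mm` behind it along the beam direction.
#'
#' @inheritParams beam_direction
#' @param cfg A [carm_config()].
#' @return A list with `source_point` (3-vector, mm) and `direction`
#'   (unit 3-vector, source toward detector), class `beam_axis`.
#' @examples
#' beam_axis(angulation(0, 0), carm_config())$source_point # (0, -700, 0)
#' @export
beam_axis <- function(ang, cfg) {
  stopifnot(inherits(cfg, "carm_config"))
  d <- beam_direction(ang)
  structure(
    list(source_point = -cfg$source_to_isocenter_mm * d, direction = d),
    class = "beam_axis"
  )
}

# Orthonormal detector frame (d, u, v) for a beam axis: u is the in-plane
# horizontal axis (global z projected onto the plane normal to d, so detector
# rows stay z-aligned), v = d x u.
beam_frame <- function(ang) {
  d <- beam_direction(ang)
  zhat <- c(0, 0, 1)
  u <- zhat - sum(zhat * d) * d
  nu <- sqrt(sum(u^2))
  if (nu < 1e-9) stop("beam axis parallel to the patient axis: detector frame undefined")
  u <- u / nu
  v <- c(d[2] * u[3] - d[3] * u[2],
         d[3] * u[1] - d[1] * u[3],
         d[1] * u[2] - d[2] * u[1])
  list(d = d, u = u, v = v)
}

#' Standard 10-view coronary intervention protocol
#'
#' The ten typical gantry angulations used in percutaneous coronary
#' intervention studies, in protocol order, as a tibble ready for
#' [run_study()]. Packaged as `extdata/views_pci10.csv`.
#'
#' @return A tibble with columns `name`, `primary_deg`, `secondary_deg`.
#' @examples
#' pci_views()
#' @export
pci_views <- function() {
  path <- system.file("extdata", "views_pci10.csv", package = "beamskin",
                      mustWork = TRUE)
  read_views(path)
}

#' Read a views table
#'
#' @param path CSV file with header `name,primary_deg,secondary_deg`.
#' @return A tibble with one row per view.
#' @export
read_views <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("name", "primary_deg", "secondary_deg")
  if (!all(need %in% names(df))) {
    stop("views file must have columns: ", paste(need, collapse = ", "))
  }
  # validate every row through the angulation constructor
  purrr::pwalk(df[need], function(name, primary_deg, secondary_deg) {
    angulation(primary_deg, secondary_deg, name)
  })
  tibble::as_tibble(df[need])
}
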