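#' Dosimetry inputs
#'
#' Container for the measured dose indices and correction factors used by the
#' entrance-surface air-kerma conversions: incident air kerma at the patient
#' entrance reference point (`ka_i_gy`), kerma-area product (`pka_gy_mm2`),
#' backscatter factor `B`, and the examination table (and pad) attenuation
#' factor `k_ta`. `B` and `k_ta` are user-supplied: they depend on beam
#' quality and equipment and are not modelled here.
#'
#' @param ka_i_gy Incident air kerma at PERP, Gy (optional).
#' @param pka_gy_mm2 Kerma-area product, Gy*mm^2 (optional). Use
#'   `pka_gy_cm2 * 100` to convert from Gy*cm^2.
#' @param backscatter_b Backscatter factor (typically 1 to 1.6).
#' @param table_factor_kta Table/pad attenuation factor (typically 0.5 to 1).
#' @return A list of class `dosimetry_inputs`.
#' @export
dosimetry_inputs <- function(ka_i_gy = NULL, pka_gy_mm2 = NULL,
                             backscatter_b = 1, table_factor_kta = 1) {
  for (v in list(ka_i_gy, pka_gy_mm2, backscatter_b, table_factor_kta)) {
    if (!is.null(v) && (!is.numeric(v) || v <= 0)) {
      stop("dosimetry inputs must be positive numbers")
    }
  }
  if (backscatter_b < 1 || backscatter_b > 1.6) {
    warning("backscatter factor outside the typical [1, 1.6] range")
  }
  if (table_factor_kta < 0.5 || table_factor_kta > 1) {
    warning("table attenuation factor outside the typical [0.5, 1] range")
  }
  structure(list(ka_i_gy = ka_i_gy, pka_gy_mm2 = pka_gy_mm2,
                 backscatter_b = backscatter_b,
                 table_factor_kta = table_factor_kta),
            class = "dosimetry_inputs")
}

#' Inverse-square distance correction factor
#'
#' The factor `(SPD / SSD)^2` that maps incident air kerma reported at the
#' patient entrance reference point to the actual skin entrance distance.
#'
#' @param spd_mm Source-to-PERP distance.
#' @param ssd_mm Source-to-surface distance.
#' @return Dimensionless factor.
#' @examples
#' distance_correction_factor(550, 599) # ~0.84: PERP closer than the skin
#' @export
distance_correction_factor <- function(spd_mm, ssd_mm) {
  if (any(spd_mm <= 0) || any(ssd_mm <= 0)) {
    stop("`spd_mm` and `ssd_mm` must be positive")
  }
  (spd_mm / ssd_mm)^2
}

#' Entrance-surface air kerma from incident air kerma
#'
#' `Ka_e = Ka_i * B * k_ta * (SPD / SSD)^2`.
#'
#' @param inputs A [dosimetry_inputs()] with `ka_i_gy` set.
#' @param spd_mm Source-to-PERP distance (see [spd()]).
#' @param ssd_mm Source-to-surface distance for the view.
#' @return Entrance-surface air kerma in Gy.
#' @export
ka_e_from_incident <- function(inputs, spd_mm, ssd_mm) {
  stopifnot(inherits(inputs, "dosimetry_inputs"))
  if (is.null(inputs$ka_i_gy)) stop("`ka_i_gy` is required for the SSD-based correction")
  inputs$ka_i_gy * inputs$backscatter_b * inputs$table_factor_kta *
    distance_correction_factor(spd_mm, ssd_mm)
}

#' Entrance-surface air kerma from the kerma-area product
#'
#' `Ka_e = (P_KA / Ap) * B * k_ta`, with Ap the beam area in the plane
#' perpendicular to the axis at the skin entrance (see [compute_ap()]).
#' Note the caveat: the equipment's P_KA calibration plane is assumed
#' consistent with the entrance-plane Ap used here.
#'
#' @param inputs A [dosimetry_inputs()] with `pka_gy_mm2` set.
#' @param ap_mm2 Perpendicular-plane beam area at the entrance.
#' @return Entrance-surface air kerma in Gy.
#' @export
ka_e_from_pka <- function(inputs, ap_mm2) {
  stopifnot(inherits(inputs, "dosimetry_inputs"))
  if (is.null(inputs$pka_gy_mm2)) stop("`pka_gy_mm2` is required for the area-based correction")
  if (ap_mm2 <= 0) stop("`ap_mm2` must be positive")
  (inputs$pka_gy_mm2 / ap_mm2) * inputs$backscatter_b * inputs$table_factor_kta
}
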