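#' Run the full per-view geometry study
#'
#' Executes the whole pipeline for each view in protocol order: solve the
#' table panning that centres the heart on the beam axis, translate the
#' body, solve the SID under the clearance rule, compute the SSD along the
#' central axis, the perpendicular-plane beam area Ap, and the on-skin beam
#' area As by entrance-visibility mesh clipping; then assemble the pairwise
#' As overlap matrix across views. The body is first aligned so the heart
#' sits on the PA axis (x = z = 0), mirroring initial patient centring.
#'
#' @param phantom A `placed_phantom`, or a [surface_mesh()] (then supply
#'   `heart_center`).
#' @param views A tibble of views (see [pci_views()] / [read_views()]), or a
#'   list of [angulation()] objects.
#' @param cfg A [carm_config()].
#' @param heart_center Heart center, required when `phantom` is a bare mesh.
#' @param refine_max_edge_mm Sub-face resolution for the As computation; the
#'   mesh is refined once and shared by all views so overlaps are computed on
#'   common faces.
#' @param footprint Clearance footprint rule for [solve_sid()].
#' @return A tibble of class `beamskin_study`, one row per view with columns
#'   `name`, `primary_deg`, `secondary_deg`, `ld_mm`, `ccd_mm`,
#'   `total_panning_mm`, `sid_mm`, `ssd_mm`, `ap_mm2`, `as_mm2`,
#'   `ratio_as_ap`, `error`. The overlap matrix, patches, refined mesh and
#'   configuration are attached as attributes (`overlaps`, `patches`,
#'   `refined_mesh`, `config`).
#' @examples
#' \donttest{
#' study <- run_study(preset_phantom("male", mesh_resolution_mm = 12),
#'                    pci_views(), refine_max_edge_mm = 6)
#' glance(study)
#' }
#' @export
run_study <- function(phantom, views, cfg = carm_config(), heart_center = NULL,
                      refine_max_edge_mm = 2.5,
                      footprint = c("housing", "fov", "full")) {
  footprint <- match.arg(footprint)
  if (inherits(phantom, "placed_phantom")) {
    mesh <- phantom$mesh
    heart <- phantom$heart_center
  } else if (inherits(phantom, "surface_mesh")) {
    if (is.null(heart_center)) stop("supply `heart_center` with a bare mesh")
    mesh <- phantom
    heart <- as.numeric(heart_center)
  } else {
    stop("`phantom` must be a placed_phantom or surface_mesh")
  }
  views <- as_view_table(views)
  if (anyDuplicated(views$name)) stop("duplicate view names in the protocol")

  # initial alignment: heart on the PA axis
  shift <- c(-heart[1], 0, -heart[3])
  mesh <- translate_mesh(mesh, shift)
  heart <- heart + shift

  ref <- refine_mesh(mesh, refine_max_edge_mm)
  refined <- ref$mesh

  patches <- vector("list", nrow(views))
  rows <- purrr::pmap(views, function(name, primary_deg, secondary_deg) {
    ang <- angulation(primary_deg, secondary_deg, name)
    out <- tibble::tibble(name = name, primary_deg = primary_deg,
                          secondary_deg = secondary_deg,
                          ld_mm = NA_real_, ccd_mm = NA_real_,
                          total_panning_mm = NA_real_, sid_mm = NA_real_,
                          ssd_mm = NA_real_, ap_mm2 = NA_real_,
                          as_mm2 = NA_real_, ratio_as_ap = NA_real_,
                          error = NA_character_)
    tryCatch({
      pan <- solve_panning(heart, ang, cfg)
      panned <- translate_mesh(refined, c(pan$ld_mm, 0, pan$ccd_mm))
      sid <- solve_sid(panned, ang, cfg, footprint = footprint)
      ssd <- compute_ssd(panned, ang, cfg)
      ap <- compute_ap(cfg, sid, ssd)
      pyr <- beam_pyramid(ang, cfg, sid)
      patch <- classify_skin_faces(panned, pyr, view = name)
      out$ld_mm <- pan$ld_mm; out$ccd_mm <- pan$ccd_mm
      out$total_panning_mm <- pan$total_mm
      out$sid_mm <- sid; out$ssd_mm <- ssd; out$ap_mm2 <- ap
      out$as_mm2 <- patch$area_mm2
      out$ratio_as_ap <- patch$area_mm2 / ap
      attr(out, "patch") <- patch
      out
    }, error = function(e) {
      out$error <- conditionMessage(e)
      out
    })
  })
  patches <- purrr::map(rows, ~ attr(.x, "patch"))
  tbl <- dplyr::bind_rows(purrr::map(rows, function(r) {
    attr(r, "patch") <- NULL
    r
  }))

  ok <- !purrr::map_lgl(patches, is.null)
  overlaps <- NULL
  if (sum(ok) >= 2) overlaps <- overlap_matrix(patches[ok], refined)

  structure(tbl,
            class = c("beamskin_study", class(tbl)),
            overlaps = overlaps,
            patches = patches,
            refined_mesh = refined,
            config = cfg)
}

as_view_table <- function(views) {
  if (is.data.frame(views)) {
    need <- c("name", "primary_deg", "secondary_deg")
    stopifnot(all(need %in% names(views)))
    return(tibble::as_tibble(views[need]))
  }
  if (inherits(views, "angulation")) views <- list(views)
  dplyr::bind_rows(purrr::map(views, function(a) {
    stopifnot(inherits(a, "angulation"))
    tibble::tibble(name = a$name, primary_deg = a$primary_deg,
                   secondary_deg = a$secondary_deg)
  }))
}

#' Column mean and sample standard deviation
#'
#' @param values Numeric vector, `n >= 2`.
#' @return A tibble with `mean`, `sd` (sample, n-1 denominator), `n`.
#' @export
summarize_column <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 2) stop("need at least two values for mean +/- SD")
  tibble::tibble(mean = mean(values), sd = stats::sd(values),
                 n = length(values))
}

#' Overlap-matrix statistics
#'
#' Statistics over all `n(n-1)/2` unordered view pairs, zeros included
#' (that convention reproduces the reference study's published mean:
#' sum / 45 pairs for a 10-view protocol).
#'
#' @param m An [overlap_matrix()] or symmetric numeric matrix with an
#'   ignorable diagonal.
#' @return A tibble: `count_nonzero`, `n_pairs`, `sum_mm2`, `mean_mm2`,
#'   `sd_mm2`.
#' @export
overlap_stats <- function(m) {
  m <- unclass(m)
  stopifnot(is.matrix(m), nrow(m) == ncol(m), nrow(m) >= 2)
  off <- row(m) != col(m)
  if (!isTRUE(all.equal(m[off & upper.tri(m)], t(m)[off & upper.tri(m)]))) {
    stop("overlap matrix is not symmetric")
  }
  vals <- m[lower.tri(m)]
  if (any(is.na(vals))) stop("missing off-diagonal overlap values")
  tibble::tibble(count_nonzero = sum(vals > 0),
                 n_pairs = length(vals),
                 sum_mm2 = sum(vals),
                 mean_mm2 = mean(vals),
                 sd_mm2 = stats::sd(vals))
}

#' Pearson correlation with a Fisher-z confidence interval
#'
#' Sample Pearson product-moment correlation with the standard
#' Fisher z-transform interval (SE `1/sqrt(n - 3)`), via [stats::cor.test()].
#'
#' @param x,y Numeric vectors, `n >= 4`, finite, nonconstant.
#' @param level Confidence level (default 0.95).
#' @return A tibble: `r`, `ci_low`, `ci_high`, `n`, `p_value`.
#' @examples
#' pearson_ci(1:10, c(2 * (1:10) + rnorm(10)))
#' @export
pearson_ci <- function(x, y, level = 0.95) {
  stopifnot(length(x) == length(y))
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 4) stop("need at least four complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined for a constant vector")
  }
  ct <- stats::cor.test(x, y, method = "pearson", conf.level = level)
  tibble::tibble(r = unname(ct$estimate),
                 ci_low = ct$conf.int[1], ci_high = ct$conf.int[2],
                 n = length(x), p_value = ct$p.value)
}

#' @export
glance.beamskin_study <- function(x, ...) {
  ok <- is.na(x$error)
  num <- x[ok, c("total_panning_mm", "sid_mm", "ssd_mm", "ap_mm2", "as_mm2",
                 "ratio_as_ap")]
  out <- tibble::tibble(n_views = nrow(x), n_failed = sum(!ok))
  for (col in names(num)) {
    s <- summarize_column(num[[col]])
    out[[paste0(col, "_mean")]] <- s$mean
    out[[paste0(col, "_sd")]] <- s$sd
  }
  ov <- attr(x, "overlaps")
  if (!is.null(ov)) {
    os <- overlap_stats(ov)
    out$overlap_count_nonzero <- os$count_nonzero
    out$overlap_n_pairs <- os$n_pairs
    out$overlap_sum_mm2 <- os$sum_mm2
    out$overlap_mean_mm2 <- os$mean_mm2
    out$overlap_sd_mm2 <- os$sd_mm2
  }
  out
}

#' @export
tidy.beamskin_study <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' Broom-style generics
#'
#' `tidy()` returns the per-view table of a study; `glance()` a one-row
#' summary (column means/SDs and overlap statistics).
#' @param x Object to summarise.
#' @param ... Unused.
#' @name beamskin-broom
#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @rdname beamskin-broom
#' @export
glance <- function(x, ...) UseMethod("glance")

#' Round a study table the way clinical reports print it
#'
#' Lengths to whole millimetres, areas to whole mm^2, the As/Ap ratio to two
#' decimals.
#'
#' @param study A `beamskin_study` (or compatible tibble).
#' @return A tibble with rounded columns.
#' @export
format_study <- function(study) {
  tidy(study) |>
    dplyr::mutate(dplyr::across(dplyr::any_of(
      c("ld_mm", "ccd_mm", "total_panning_mm", "sid_mm", "ssd_mm",
        "ap_mm2", "as_mm2")), round),
      dplyr::across(dplyr::any_of("ratio_as_ap"), ~ round(.x, 2)))
}

#' Write / read a per-view study table
#'
#' Full-precision CSV round-trip: numeric columns are written with 17
#' significant digits, enough to reproduce every double bit-exactly, so
#' summaries recomputed after re-reading match the originals identically.
#'
#' @param study A `beamskin_study` or tibble.
#' @param path Output CSV path.
#' @return `read_per_view()` returns a tibble.
#' @export
write_per_view <- function(study, path) {
  df <- tidy(study)
  df[] <- lapply(df, function(x) {
    if (is.double(x)) sprintf("%.17g", x) else x
  })
  readr::write_csv(df, path, na = "NA")
  invisible(path)
}

#' @rdname write_per_view
#' @export
read_per_view <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}

#' Write an overlap matrix as CSV
#'
#' Lower triangle populated, `NA` diagonal, mirroring how overlap tables are
#' reported.
#'
#' @param m An [overlap_matrix()].
#' @param path Output CSV path.
#' @export
write_overlaps <- function(m, path) {
  stopifnot(inherits(m, "overlap_matrix"))
  out <- unclass(m)
  out[upper.tri(out)] <- NA
  df <- data.frame(name = rownames(out), out, check.names = FALSE)
  readr::write_csv(df, path, na = "")
  invisible(path)
}

#' Reference study tables
#'
#' Published per-view geometry and overlap tables from the reference
#' anthropomorphic-phantom study (male and female CIRS phantoms on a
#' clinical C-arm), transcribed as packaged CSV fixtures. These are external
#' study data used for cross-checks and statistics, never outputs of this
#' engine.
#'
#' @param phantom `"male"` or `"female"`.
#' @return `reference_geometry()`: a tibble with the per-view columns
#'   (`name`, `table_height_cm`, `ld_mm`, `ccd_mm`, `total_panning_mm`,
#'   `sid_mm`, `ssd_mm`, `ap_mm2`, `as_mm2`, `ratio_as_ap`).
#'   `reference_overlap()`: an [overlap_matrix()].
#' @export
reference_geometry <- function(phantom = c("male", "female")) {
  phantom <- match.arg(phantom)
  path <- system.file("extdata", paste0("ref_geometry_", phantom, ".csv"),
                      package = "beamskin", mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE)
}

#' @rdname reference_geometry
#' @export
reference_overlap <- function(phantom = c("male", "female")) {
  phantom <- match.arg(phantom)
  path <- system.file("extdata", paste0("ref_overlap_", phantom, ".csv"),
                      package = "beamskin", mustWork = TRUE)
  df <- utils::read.csv(path, check.names = FALSE)
  nm <- df$name
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- nm
  storage.mode(m) <- "double"
  # lower triangle is populated; mirror it and blank the diagonal
  m[upper.tri(m)] <- t(m)[upper.tri(m)]
  diag(m) <- NA_real_
  structure(m, class = c("overlap_matrix", "matrix"))
}

#' Plot per-view beam areas
#'
#' Bar chart of Ap and As per view in protocol order.
#'
#' @param object A `beamskin_study`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.beamskin_study <- function(object, ...) {
  df <- tidy(object) |>
    dplyr::mutate(name = factor(.data$name, levels = .data$name)) |>
    tidyr::pivot_longer(c("ap_mm2", "as_mm2"), names_to = "quantity",
                        values_to = "area_mm2") |>
    dplyr::mutate(quantity = dplyr::recode(.data$quantity,
                                           ap_mm2 = "Ap (perpendicular plane)",
                                           as_mm2 = "As (on skin)"))
  ggplot2::ggplot(df, ggplot2::aes(.data$name, .data$area_mm2,
                                   fill = .data$quantity)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "area (mm²)", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot an overlap matrix
#'
#' Heatmap of pairwise on-skin beam-field overlaps.
#'
#' @param object An [overlap_matrix()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.overlap_matrix <- function(object, ...) {
  m <- unclass(object)
  df <- as.data.frame(as.table(m), stringsAsFactors = FALSE)
  names(df) <- c("view_a", "view_b", "overlap_mm2")
  df$view_a <- factor(df$view_a, levels = rownames(m))
  df$view_b <- factor(df$view_b, levels = rev(rownames(m)))
  ggplot2::ggplot(df, ggplot2::aes(.data$view_a, .data$view_b,
                                   fill = .data$overlap_mm2)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(na.value = "grey90") +
    ggplot2::labs(x = NULL, y = NULL, fill = "overlap (mm²)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
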