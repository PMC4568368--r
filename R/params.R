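#' Ground-truth tissue parameters for the synthetic dermis
#'
#' Defines one simulated animal's dermis: the numerical density of
#' fibroblasts, volume fractions of collagen bundles and hair follicles,
#' vessel length density and diameter distribution, the simulated block
#' extent, and the seed. These are the quantities the stereological
#' estimators are supposed to recover, so a `tissue_params` object doubles
#' as the recovery oracle's truth. Defaults are on the scale of the
#' untreated (control) dermis of a diabetic-rat excisional wound study.
#'
#' Internally the constructor calibrates the Boolean-model grain
#' intensities so that the *realized* phase fractions — after applying the
#' phase precedence vessel > hair > collagen used everywhere in the
#' package — equal the requested `vv_*` values in expectation. Parameter
#' sets whose implied total solid fraction reaches 1 are rejected.
#'
#' @param nv_fibroblast fibroblast numerical density, cells per mm^3.
#' @param vv_collagen,vv_hair volume fractions in `[0, 1)`.
#' @param lv_vessel vessel length density, mm of centerline per mm^3.
#' @param vessel_diameter_mean,vessel_diameter_sd vessel diameter
#'   distribution, um (normal truncated at 0).
#' @param extent simulated block extent `(x, y, z)` in um.
#' @param seed integer seed; identical parameters give identical volumes.
#' @param collagen_grain_radius,hair_grain_radius Boolean-model sphere
#'   radii, um. Collagen bundles are modelled as 12 um spheres, hair
#'   follicles as 25 um spheres; only the resulting volume fractions (not
#'   grain shapes) enter the estimators.
#' @param vessel_length_range range of individual vessel segment lengths,
#'   um (uniform). Only total length density and diameter matter to the
#'   estimators.
#' @return an object of class `tissue_params`.
#' @examples
#' tissue_params(seed = 7)
#' @export
tissue_params <- function(nv_fibroblast = 284.5e3,
                          vv_collagen = 0.474,
                          vv_hair = 0.026,
                          lv_vessel = 17.2,
                          vessel_diameter_mean = 11.7,
                          vessel_diameter_sd = 3.1,
                          extent = c(500, 500, 500),
                          seed = 1L,
                          collagen_grain_radius = 12,
                          hair_grain_radius = 25,
                          vessel_length_range = c(50, 200)) {
  stopifnot(
    length(extent) == 3, all(extent > 0),
    nv_fibroblast >= 0, lv_vessel >= 0,
    vv_collagen >= 0, vv_collagen < 1, vv_hair >= 0, vv_hair < 1,
    vessel_diameter_mean >= 0, vessel_diameter_sd >= 0,
    collagen_grain_radius > 0, hair_grain_radius > 0,
    length(vessel_length_range) == 2, all(vessel_length_range > 0),
    diff(vessel_length_range) >= 0
  )
  p <- structure(
    list(
      nv_fibroblast = nv_fibroblast,
      vv_collagen = vv_collagen,
      vv_hair = vv_hair,
      lv_vessel = lv_vessel,
      vessel_diameter_mean = vessel_diameter_mean,
      vessel_diameter_sd = vessel_diameter_sd,
      extent = as.numeric(extent),
      seed = as.integer(seed),
      collagen_grain_radius = collagen_grain_radius,
      hair_grain_radius = hair_grain_radius,
      vessel_length_range = as.numeric(vessel_length_range)
    ),
    class = "tissue_params"
  )
  p$calibration <- calibrate_phases(p)   # errors if infeasible
  p
}

# Solve the grain/segment intensities behind the requested phase fractions.
# Boolean-model vacancy: P(point not covered) = exp(-lambda * E[grain vol]),
# and independent phases compose multiplicatively, so precedence
# (vessel > hair > collagen) is compensated exactly in expectation.
calibrate_phases <- function(p) {
  mean_len <- mean(p$vessel_length_range)
  mu_r <- p$vessel_diameter_mean / 2
  sd_r <- p$vessel_diameter_sd / 2
  if (p$lv_vessel > 0 && mu_r > 0) {
    e_r2 <- truncnorm_moment(2, mu_r, sd_r)
    e_r3 <- truncnorm_moment(3, mu_r, sd_r)
    lambda_len_um <- p$lv_vessel / 1e6            # mm/mm^3 -> um/um^3
    lambda_seg <- lambda_len_um / mean_len        # segments per um^3
    e_vol_capsule <- pi * e_r2 * mean_len + 4 / 3 * pi * e_r3
    p_vessel <- 1 - exp(-lambda_seg * e_vol_capsule)
  } else {
    lambda_seg <- 0
    p_vessel <- 0
  }

  p_hair_set <- p$vv_hair / (1 - p_vessel)
  p_col_set <- p$vv_collagen / ((1 - p_vessel) * (1 - p_hair_set))
  total <- p$vv_collagen + p$vv_hair + p_vessel
  if (!is.finite(p_col_set) || p_hair_set >= 1 || p_col_set >= 1 || total >= 1) {
    abort(sprintf(
      "infeasible tissue parameters: implied total solid fraction %.3f reaches 1",
      total
    ))
  }
  vol_hair <- 4 / 3 * pi * p$hair_grain_radius^3
  vol_col <- 4 / 3 * pi * p$collagen_grain_radius^3
  list(
    lambda_segments = lambda_seg,                       # per um^3
    lambda_hair = -log1p(-p_hair_set) / vol_hair,       # per um^3
    lambda_collagen = -log1p(-p_col_set) / vol_col,     # per um^3
    expected_fraction = c(
      vessel = p_vessel, hair = p$vv_hair, collagen = p$vv_collagen
    )
  )
}

#' @export
print.tissue_params <- function(x, ...) {
  cat("<tissue_params>\n")
  cat(sprintf("  Nv fibroblast : %.1f x10^3 / mm^3\n", x$nv_fibroblast / 1e3))
  cat(sprintf("  Vv collagen   : %.1f %%\n", 100 * x$vv_collagen))
  cat(sprintf("  Vv hair       : %.1f %%\n", 100 * x$vv_hair))
  cat(sprintf("  Lv vessel     : %.1f mm/mm^3\n", x$lv_vessel))
  cat(sprintf("  vessel diam   : %.1f (%.1f) um\n",
              x$vessel_diameter_mean, x$vessel_diameter_sd))
  cat(sprintf("  extent        : %s um, seed %d\n",
              paste(x$extent, collapse = " x "), x$seed))
  invisible(x)
}

#' Optical dissector geometry
#'
#' The dissector probes a thick section of `section_thickness` um; the top
#' and bottom guard zones ("areas of safety") are excluded, leaving a
#' counting height `h = section_thickness - guard_top - guard_bottom`.
#' Defaults follow standard practice for 15 um sections with 5 um guards,
#' giving h = 5 um. The lateral counting frame is an unbiased (Gundersen)
#' frame: left and bottom edges include, right and top edges exclude.
#'
#' @param section_thickness physical section thickness, um.
#' @param guard_top,guard_bottom guard-zone thicknesses, um.
#' @param frame_width,frame_height counting-frame sides, um.
#' @return an object of class `dissector_spec`.
#' @export
dissector_spec <- function(section_thickness = 15, guard_top = 5,
                           guard_bottom = 5, frame_width = 200,
                           frame_height = 200) {
  stopifnot(
    section_thickness > 0, guard_top >= 0, guard_bottom >= 0,
    frame_width > 0, frame_height > 0
  )
  if (guard_top + guard_bottom >= section_thickness) {
    abort("guard zones leave no dissector height: guard_top + guard_bottom must be < section_thickness")
  }
  structure(
    list(
      section_thickness = section_thickness,
      guard_top = guard_top,
      guard_bottom = guard_bottom,
      frame_width = frame_width,
      frame_height = frame_height,
      height = section_thickness - guard_top - guard_bottom
    ),
    class = "dissector_spec"
  )
}

#' @export
print.dissector_spec <- function(x, ...) {
  cat(sprintf(
    "<dissector_spec> section %g um, guards %g/%g um (h = %g um), frame %g x %g um\n",
    x$section_thickness, x$guard_top, x$guard_bottom, x$height,
    x$frame_width, x$frame_height
  ))
  invisible(x)
}

#' Point grid for area and volume-fraction counting
#'
#' A square point grid with spacing in mm; the area associated with each
#' point (`a/p`, the area surrounded by every four crosses) is
#' `spacing^2`. When `offset` is `NULL` a fresh uniform random offset in
#' `[0, spacing)^2` is drawn each time the grid is thrown (systematic
#' uniform random sampling); a fixed offset makes throws reproducible.
#'
#' @param spacing grid spacing, mm.
#' @param offset `NULL` (SUR mode) or a length-2 offset in mm.
#' @param rotation grid rotation in radians (about the grid origin).
#' @return an object of class `point_grid`.
#' @examples
#' g <- point_grid(spacing = 1)
#' g$area_per_point  # 1 mm^2
#' @export
point_grid <- function(spacing, offset = NULL, rotation = 0) {
  stopifnot(is.numeric(spacing), length(spacing) == 1, spacing > 0)
  if (!is.null(offset)) {
    stopifnot(length(offset) == 2, all(offset >= 0), all(offset < spacing))
  }
  structure(
    list(
      spacing = spacing,
      area_per_point = spacing^2,
      offset = offset,
      rotation = rotation
    ),
    class = "point_grid"
  )
}

grid_offset <- function(grid) {
  grid$offset %||% runif(2, 0, grid$spacing)
}
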