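#' Point-grid (Cavalieri-type) area estimate
#'
#' Estimates a planar area from a point-grid count:
#' `Area = sum(P) * a/p`, where `sum(P)` is the number of grid points
#' falling on the structure and `a/p` is the area associated with each
#' grid point (the area surrounded by every four crosses).
#'
#' @param total_points non-negative point count(s) (`sum(P)`); vectorized.
#' @param grid a [point_grid()] supplying `a/p` in mm^2.
#' @return estimated area(s), mm^2.
#' @examples
#' estimate_area(25, point_grid(spacing = 2))  # 25 * 4 = 100 mm^2
#' @export
estimate_area <- function(total_points, grid) {
  stopifnot(inherits(grid, "point_grid"))
  if (any(total_points < 0)) abort("point counts must be non-negative")
  total_points * grid$area_per_point
}

#' Count systematic-uniform-random grid points falling on a binary mask
#'
#' Throws a point grid (spacing in mm) over a binary mask with the given
#' physical scale and counts points landing on `TRUE` pixels. The mask is
#' indexed row-major with the origin at the top-left pixel corner.
#'
#' @param mask logical (or 0/1) matrix; rows are y, columns are x.
#' @param mm_per_pixel physical pixel size, mm.
#' @param grid a [point_grid()]; a fresh SUR offset is drawn when the
#'   grid carries none.
#' @param offset optional fixed offset (mm, length 2) overriding the grid's.
#' @return integer count of grid points on the mask.
#' @export
count_points_on_mask <- function(mask, mm_per_pixel, grid, offset = NULL) {
  stopifnot(is.matrix(mask), mm_per_pixel > 0, inherits(grid, "point_grid"))
  mask <- mask > 0
  off <- offset %||% grid_offset(grid)
  width_mm <- ncol(mask) * mm_per_pixel
  height_mm <- nrow(mask) * mm_per_pixel
  xs <- seq(off[1], width_mm - 1e-12, by = grid$spacing)
  ys <- seq(off[2], height_mm - 1e-12, by = grid$spacing)
  if (!length(xs) || !length(ys)) return(0L)
  cx <- pmin(floor(rep(xs, times = length(ys)) / mm_per_pixel) + 1, ncol(mask))
  cy <- pmin(floor(rep(ys, each = length(xs)) / mm_per_pixel) + 1, nrow(mask))
  sum(mask[cbind(cy, cx)])
}

#' Wound area from a binary mask
#'
#' Computes the wound area either by overlaying the point grid (the
#' stereological route, the default) or by direct pixel counting.
#'
#' @inheritParams count_points_on_mask
#' @param method `"grid"` (point counting, default) or `"pixel"`.
#' @return area in mm^2.
#' @export
area_from_mask <- function(mask, mm_per_pixel, method = c("grid", "pixel"),
                           grid = point_grid(1), offset = NULL) {
  method <- match.arg(method)
  if (method == "pixel") return(sum(mask > 0) * mm_per_pixel^2)
  estimate_area(count_points_on_mask(mask, mm_per_pixel, grid, offset), grid)
}

check_fields <- function(fields) {
  stopifnot(is.data.frame(fields))
  if (!nrow(fields)) abort("field-count table is empty")
  invisible(fields)
}

#' Volume density by point counting
#'
#' `Vv(phase/dermis) = P(phase) / P(dermis)` pooled as a ratio of sums
#' across fields (not a mean of per-field ratios), the standard
#' stereological pooling within one animal.
#'
#' @param fields field-count tibble (see [render_field_counts()] or
#'   [read_field_counts()]).
#' @param phase `"collagen"`, `"vessel"` or `"hair"`.
#' @return volume fraction in `[0, 1]`.
#' @examples
#' f <- tibble::tibble(p_collagen = 25L, p_vessel = 0L, p_hair = 0L,
#'                     p_dermis = 100L)
#' estimate_volume_density(f, "collagen")  # 0.25
#' @export
estimate_volume_density <- function(fields,
                                    phase = c("collagen", "vessel", "hair")) {
  check_fields(fields)
  phase <- match.arg(phase)
  denom <- sum(fields$p_dermis)
  if (denom <= 0) {
    abort("volume density undefined: zero reference (dermis) point count")
  }
  sum(fields[[paste0("p_", phase)]]) / denom
}

#' Numerical density by the optical dissector
#'
#' `Nv = sum(Q) / (sum(A) * h)`: nuclei coming into focus within the
#' dissector height `h`, per total frame area, per height — i.e. counts
#' divided by the total dissector volume probed. All fields must share
#' one dissector height.
#'
#' @inheritParams estimate_volume_density
#' @return numerical density in cells per mm^3 (divide by 1e3 for the
#'   conventional 10^3/mm^3 reporting unit).
#' @examples
#' f <- tibble::tibble(q_minus = 50L, frame_area_mm2 = 0.1, height_mm = 0.005)
#' estimate_numerical_density(f)  # 1e5 cells/mm^3
#' @export
estimate_numerical_density <- function(fields) {
  check_fields(fields)
  h <- unique(fields$height_mm)
  if (length(h) != 1) abort("mixed dissector heights across fields")
  if (h <= 0) abort("dissector height must be positive")
  total_area <- sum(fields$frame_area_mm2)
  if (total_area <= 0) abort("total frame area must be positive")
  sum(fields$q_minus) / (total_area * h)
}

#' Vessel length density from profile counts
#'
#' `Lv = 2 * Q_A` with `Q_A = sum(transects) / sum(frame area)`: valid for
#' isotropic uniform random sections, where the expected number of
#' transects of an isotropic curve process with a plane is half its length
#' density per unit area.
#'
#' @inheritParams estimate_volume_density
#' @return length density, mm per mm^3.
#' @export
estimate_length_density <- function(fields) {
  check_fields(fields)
  total_area <- sum(fields$frame_area_mm2)
  if (total_area <= 0) abort("total frame area must be positive")
  2 * sum(fields$vessel_transects) / total_area
}

#' Mean vessel diameter from profile minor axes
#'
#' Arithmetic mean of the pooled per-profile diameters. Profiles are
#' measured as the minor axis of the elliptical transect, which for a
#' cylindrical vessel equals the true diameter at any sectioning angle.
#'
#' @inheritParams estimate_volume_density
#' @return mean diameter, um.
#' @export
estimate_mean_diameter <- function(fields) {
  check_fields(fields)
  d <- unlist(fields$diameters_um, use.names = FALSE)
  if (!length(d)) abort("mean diameter undefined: no vessel profiles measured")
  mean(d)
}

#' Per-animal stereological summary
#'
#' Pools all fields of each animal (ratio-of-sums) and returns one row per
#' animal with every estimator in its reporting unit. The animal — never
#' the field — is the statistical unit for downstream group comparison.
#'
#' @param fields field-count tibble containing `animal_id` and `group`.
#' @return tibble with one row per animal: `nv_fibroblast` (10^3 cells
#'   per mm^3), `vv_collagen_pct`, `vv_vessel_pct`, `vv_hair_pct` (%),
#'   `lv_vessel` (mm/mm^3), `vessel_diameter_um` (um; `NA` when no
#'   profile was measured) and `n_fields`.
#' @export
summarize_animals <- function(fields) {
  check_fields(fields)
  stopifnot(all(c("animal_id", "group") %in% names(fields)))
  fields |>
    dplyr::group_by(.data$animal_id, .data$group) |>
    dplyr::group_modify(function(f, key) {
      d <- unlist(f$diameters_um, use.names = FALSE)
      tibble::tibble(
        n_fields = nrow(f),
        nv_fibroblast = estimate_numerical_density(f) / 1e3,
        vv_collagen_pct = 100 * estimate_volume_density(f, "collagen"),
        vv_vessel_pct = 100 * estimate_volume_density(f, "vessel"),
        vv_hair_pct = 100 * estimate_volume_density(f, "hair"),
        lv_vessel = estimate_length_density(f),
        vessel_diameter_um = if (length(d)) mean(d) else NA_real_
      )
    }) |>
    dplyr::ungroup()
}
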