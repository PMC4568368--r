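#' Simulate a synthetic dermis volume with known ground truth
#'
#' Generates one animal's simulated dermis block from [tissue_params()]:
#' fibroblast nuclei as a homogeneous Poisson point process, collagen
#' bundles and hair follicles as Boolean models of spheres, and vessels as
#' isotropically oriented random segments (capsules) whose expected
#' centerline length per unit volume equals `lv_vessel`. Grains and
#' segments are generated in a guard band extending beyond the block
#' ("plus-sampling") so interior phase fractions are free of boundary
#' depletion. The realization is deterministic given `params$seed`.
#'
#' @param params a [tissue_params()] object.
#' @return an object of class `stereo_volume`: geometry lists
#'   (`fibroblast_centers`, `collagen_grains`, `hair_grains`,
#'   `vessel_segments`), the block `extent` (um) and the generating
#'   `params`.
#' @examples
#' vol <- simulate_volume(tissue_params(extent = c(200, 200, 200), seed = 1))
#' nrow(vol$fibroblast_centers)
#' @export
simulate_volume <- function(params) {
  stopifnot(inherits(params, "tissue_params"))
  cal <- params$calibration
  ext <- params$extent

  with_seed(params$seed, {
    # fibroblast nuclei: points, no guard needed (fields are interior)
    vol_um3 <- prod(ext)
    n_fib <- rpois(1, params$nv_fibroblast / UM3_PER_MM3 * vol_um3)
    fib <- cbind(
      runif(n_fib, 0, ext[1]), runif(n_fib, 0, ext[2]), runif(n_fib, 0, ext[3])
    )

    collagen <- sample_grains(ext, cal$lambda_collagen, params$collagen_grain_radius)
    hair <- sample_grains(ext, cal$lambda_hair, params$hair_grain_radius)
    vessels <- sample_vessels(ext, params)

    structure(
      list(
        fibroblast_centers = fib,
        collagen_grains = collagen,
        hair_grains = hair,
        vessel_segments = vessels,
        extent = ext,
        params = params
      ),
      class = "stereo_volume"
    )
  })
}

# Poisson sphere grains in the block dilated by one radius (plus-sampling).
sample_grains <- function(ext, lambda, radius) {
  lo <- -radius
  hi <- ext + radius
  n <- rpois(1, lambda * prod(hi - lo))
  list(
    centers = cbind(runif(n, lo, hi[1]), runif(n, lo, hi[2]), runif(n, lo, hi[3])),
    radius = radius
  )
}

# Isotropic Poisson segment (capsule) process; centers in the block dilated
# by max half-length + a radius allowance so clipped length density is
# unbiased inside the block.
sample_vessels <- function(ext, params) {
  lambda_seg <- params$calibration$lambda_segments
  guard <- params$vessel_length_range[2] / 2 +
    params$vessel_diameter_mean / 2 + 4 * params$vessel_diameter_sd / 2
  lo <- -guard
  hi <- ext + guard
  n <- rpois(1, lambda_seg * prod(hi - lo))
  if (n == 0) {
    return(list(p0 = matrix(numeric(0), 0, 3), p1 = matrix(numeric(0), 0, 3),
                radius = numeric(0)))
  }
  centers <- cbind(runif(n, lo, hi[1]), runif(n, lo, hi[2]), runif(n, lo, hi[3]))
  u <- random_directions(n)
  len <- runif(n, params$vessel_length_range[1], params$vessel_length_range[2])
  radius <- rnorm_pos(n, params$vessel_diameter_mean / 2,
                      params$vessel_diameter_sd / 2)
  list(
    p0 = centers - u * len / 2,
    p1 = centers + u * len / 2,
    radius = radius
  )
}

#' @export
print.stereo_volume <- function(x, ...) {
  cat(sprintf(
    "<stereo_volume> %s um: %d fibroblasts, %d collagen grains, %d hair grains, %d vessel segments\n",
    paste(x$extent, collapse = " x "), nrow(x$fibroblast_centers),
    nrow(x$collagen_grains$centers), nrow(x$hair_grains$centers),
    nrow(x$vessel_segments$p0)
  ))
  invisible(x)
}

#' Query which tissue phase occupies given 3D points
#'
#' Evaluates the volume's indicator function at arbitrary 3D positions,
#' applying the fixed phase precedence vessel > hair > collagen > ground,
#' so the phases partition the dermis as mutually exclusive fractions.
#'
#' @param volume a `stereo_volume`.
#' @param points numeric matrix `n x 3` of positions in um.
#' @return character vector of `"vessel"`, `"hair"`, `"collagen"`,
#'   `"ground"`.
#' @export
query_phase <- function(volume, points) {
  stopifnot(inherits(volume, "stereo_volume"), ncol(points) == 3)
  n <- nrow(points)
  phase <- rep("ground", n)

  seg <- volume$vessel_segments
  in_vessel <- logical(n)
  if (length(seg$radius)) {
    alive <- seq_len(n)
    for (i in seq_along(seg$radius)) {
      if (!length(alive)) break
      d <- dist_to_segment(points[alive, , drop = FALSE], seg$p0[i, ], seg$p1[i, ])
      newly <- d <= seg$radius[i]
      in_vessel[alive[newly]] <- TRUE
      alive <- alive[!newly]
    }
  }
  phase[in_vessel] <- "vessel"

  rest <- which(!in_vessel)
  if (length(rest)) {
    hh <- points_in_spheres(points[rest, , drop = FALSE],
                            volume$hair_grains$centers,
                            volume$hair_grains$radius)
    phase[rest[hh]] <- "hair"
    rest <- rest[!hh]
  }
  if (length(rest)) {
    cc <- points_in_spheres(points[rest, , drop = FALSE],
                            volume$collagen_grains$centers,
                            volume$collagen_grains$radius)
    phase[rest[cc]] <- "collagen"
  }
  phase
}

#' Serialize synthetic volume geometry to and from JSON
#'
#' Geometry lists (not voxels) are stored, so files remain small and
#' round-trips are lossless to double precision.
#'
#' @param volume a `stereo_volume`.
#' @param path file path to write to / read from.
#' @return `volume_to_json()` returns `path` invisibly;
#'   `volume_from_json()` returns a `stereo_volume`.
#' @export
volume_to_json <- function(volume, path) {
  stopifnot(inherits(volume, "stereo_volume"))
  p <- volume$params
  obj <- list(
    params = p[c(
      "nv_fibroblast", "vv_collagen", "vv_hair", "lv_vessel",
      "vessel_diameter_mean", "vessel_diameter_sd", "extent", "seed",
      "collagen_grain_radius", "hair_grain_radius", "vessel_length_range"
    )],
    fibroblast_centers = volume$fibroblast_centers,
    collagen_centers = volume$collagen_grains$centers,
    collagen_radius = volume$collagen_grains$radius,
    hair_centers = volume$hair_grains$centers,
    hair_radius = volume$hair_grains$radius,
    vessel_p0 = volume$vessel_segments$p0,
    vessel_p1 = volume$vessel_segments$p1,
    vessel_radius = volume$vessel_segments$radius
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname volume_to_json
#' @export
volume_from_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  params <- do.call(tissue_params, obj$params)
  as_mat <- function(x) {
    if (is.null(x) || !length(x)) matrix(numeric(0), 0, 3) else as.matrix(x)
  }
  structure(
    list(
      fibroblast_centers = as_mat(obj$fibroblast_centers),
      collagen_grains = list(centers = as_mat(obj$collagen_centers),
                             radius = obj$collagen_radius),
      hair_grains = list(centers = as_mat(obj$hair_centers),
                         radius = obj$hair_radius),
      vessel_segments = list(p0 = as_mat(obj$vessel_p0),
                             p1 = as_mat(obj$vessel_p1),
                             radius = obj$vessel_radius %||% numeric(0)),
      extent = params$extent,
      params = params
    ),
    class = "stereo_volume"
  )
}

#' Cut an isotropic uniform random section stack through a volume
#'
#' Draws a section orientation (uniform on the sphere in IUR mode, the
#' z-axis otherwise) and places `n_sections` parallel slabs of thickness
#' `section_thickness` at systematic uniform random positions along the
#' section normal, centred on the block. Sections are disjoint and ordered.
#'
#' @param volume a `stereo_volume`.
#' @param section_thickness slab thickness, um (e.g. 5 for thin Vv
#'   sections, 15 for dissector sections).
#' @param n_sections number of slabs.
#' @param iur logical; draw the orientation isotropically (default) or
#'   section perpendicular to z.
#' @param seed optional integer seed for orientation and positions.
#' @return an object of class `section_stack`.
#' @export
section_stack <- function(volume, section_thickness = 15, n_sections = 5,
                          iur = TRUE, seed = NULL) {
  stopifnot(inherits(volume, "stereo_volume"), section_thickness > 0,
            n_sections >= 1)
  r_in <- min(volume$extent) / 2
  zmax <- 0.6 * r_in
  spacing <- 2 * zmax / n_sections
  if (spacing <= section_thickness) {
    abort("sections would overlap: reduce n_sections or section_thickness")
  }
  with_seed(seed, {
    normal <- if (iur) as.vector(random_directions(1)) else c(0, 0, 1)
    start <- runif(1, 0, spacing)
    z0 <- -zmax + start + spacing * (seq_len(n_sections) - 1)
    structure(
      list(
        volume = volume,
        basis = plane_basis(normal),
        z0 = z0,                       # slab centres along the normal,
        thickness = section_thickness, # relative to the block centre
        iur = iur
      ),
      class = "section_stack"
    )
  })
}

#' @export
print.section_stack <- function(x, ...) {
  cat(sprintf(
    "<section_stack> %d %s sections, %g um thick, normal (%.2f, %.2f, %.2f)\n",
    length(x$z0), if (x$iur) "IUR" else "axial", x$thickness,
    x$basis["n", 1], x$basis["n", 2], x$basis["n", 3]
  ))
  invisible(x)
}
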