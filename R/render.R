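#' Render microscopist field counts from a synthetic section stack
#'
#' Produces, for each sampled microscopic field, exactly the raw numbers a
#' microscopist would record: point-grid counts per phase against the
#' dermis reference, optical-dissector counts of fibroblast nuclei inside
#' the unbiased counting frame and dissector height, and vessel profile
#' transects (with their minor-axis diameters) on the central focal plane.
#'
#' Fields are placed uniformly at random within each section, constrained
#' so the whole frame-by-thickness prism lies inside the simulated block
#' for any section orientation. The counting frame follows the unbiased
#' (Gundersen) rule: left/bottom edges include, right/top edges exclude.
#'
#' @param stack a [section_stack()].
#' @param grid a [point_grid()] (spacing in mm) thrown over each frame
#'   with a fresh systematic-uniform-random offset.
#' @param frame a [dissector_spec()]; its `section_thickness` must equal
#'   the stack's.
#' @param n_fields number of fields, spread round-robin across sections.
#' @param animal_id,group labels attached to every row.
#' @param seed optional integer seed for field placement and grid offsets.
#' @param field_centers optional `n_fields x 2` matrix of in-plane field
#'   centres (um, relative to the block centre, rotated coordinates) for
#'   deterministic placement; mainly for constructed test cases.
#' @return a tibble with one row per field: `animal_id`, `group`, `field`,
#'   `p_collagen`, `p_vessel`, `p_hair`, `p_dermis`, `q_minus`,
#'   `frame_area_mm2`, `height_mm`, `vessel_transects` and the list-column
#'   `diameters_um`.
#' @export
render_field_counts <- function(stack, grid = point_grid(0.02),
                                frame = dissector_spec(), n_fields = 30,
                                animal_id = "animal1", group = NA_character_,
                                seed = NULL, field_centers = NULL) {
  stopifnot(inherits(stack, "section_stack"), inherits(grid, "point_grid"),
            inherits(frame, "dissector_spec"), n_fields >= 1)
  if (!isTRUE(all.equal(frame$section_thickness, stack$thickness))) {
    abort("frame section_thickness must match the section stack thickness")
  }
  vol <- stack$volume
  ext <- vol$extent
  centre <- ext / 2
  basis <- stack$basis
  fw <- frame$frame_width
  fh <- frame$frame_height
  tt <- frame$section_thickness
  half_diag <- sqrt((fw / 2)^2 + (fh / 2)^2 + (tt / 2)^2)
  max_r <- min(ext) / 2 - half_diag
  if (max_r <= 0) {
    abort("counting frame does not fit inside the volume for arbitrary orientations")
  }

  with_seed(seed, {
    # assign fields to sections that leave room for the frame prism
    ok_sections <- which(abs(stack$z0) < max_r - 1e-9)
    if (!length(ok_sections)) abort("no section leaves room for the counting frame")
    sec_of_field <- rep_len(ok_sections, n_fields)

    if (is.null(field_centers)) {
      rho_max <- sqrt(pmax(max_r^2 - stack$z0[sec_of_field]^2, 0))
      rr <- rho_max * sqrt(runif(n_fields))
      th <- runif(n_fields, 0, 2 * pi)
      field_centers <- cbind(rr * cos(th), rr * sin(th))
    } else {
      field_centers <- as.matrix(field_centers)
      stopifnot(nrow(field_centers) == n_fields, ncol(field_centers) == 2)
    }

    # rotated coordinates (u, v, w) of everything, relative to block centre
    rot <- function(p) sweep(p, 2, centre) %*% t(basis)
    fib_rot <- if (nrow(vol$fibroblast_centers)) rot(vol$fibroblast_centers) else
      matrix(numeric(0), 0, 3)
    seg <- vol$vessel_segments
    n_seg <- length(seg$radius)
    seg0 <- if (n_seg) rot(seg$p0) else matrix(numeric(0), 0, 3)
    seg1 <- if (n_seg) rot(seg$p1) else matrix(numeric(0), 0, 3)

    spacing_um <- grid$spacing * UM_PER_MM
    z_lo <- stack$z0 - tt / 2 + frame$guard_bottom
    z_hi <- stack$z0 + tt / 2 - frame$guard_top

    grid_pts <- vector("list", n_fields)
    res <- vector("list", n_fields)
    for (f in seq_len(n_fields)) {
      s <- sec_of_field[f]
      u_ll <- field_centers[f, 1] - fw / 2
      v_ll <- field_centers[f, 2] - fh / 2
      z0 <- stack$z0[s]

      off <- grid_offset(grid) * UM_PER_MM
      us <- seq(u_ll + off[1], u_ll + fw - 1e-9, by = spacing_um)
      vs <- seq(v_ll + off[2], v_ll + fh - 1e-9, by = spacing_um)
      gp <- cbind(rep(us, times = length(vs)), rep(vs, each = length(us)))
      grid_pts[[f]] <- cbind(gp, z0)

      # optical dissector: nuclei inside the unbiased frame and height
      q <- 0L
      if (nrow(fib_rot)) {
        q <- sum(
          fib_rot[, 1] >= u_ll & fib_rot[, 1] < u_ll + fw &
          fib_rot[, 2] >= v_ll & fib_rot[, 2] < v_ll + fh &
          fib_rot[, 3] >= z_lo[s] & fib_rot[, 3] < z_hi[s]
        )
      }

      # vessel transects: centerline crossings of the central focal plane
      diam <- numeric(0)
      if (n_seg) {
        w0 <- seg0[, 3] - z0
        w1 <- seg1[, 3] - z0
        crossing <- which(w0 * w1 < 0)
        if (length(crossing)) {
          tpar <- w0[crossing] / (w0[crossing] - w1[crossing])
          uu <- seg0[crossing, 1] + tpar * (seg1[crossing, 1] - seg0[crossing, 1])
          vv <- seg0[crossing, 2] + tpar * (seg1[crossing, 2] - seg0[crossing, 2])
          in_frame <- uu >= u_ll & uu < u_ll + fw & vv >= v_ll & vv < v_ll + fh
          # minor axis of the plane-cylinder ellipse equals the true
          # diameter, whatever the sectioning angle
          diam <- 2 * seg$radius[crossing][in_frame]
        }
      }

      res[[f]] <- list(q_minus = as.integer(q), vessel_transects = length(diam),
                       diameters_um = diam)
    }

    # one batched phase query for all grid points (fast path)
    all_pts <- do.call(rbind, grid_pts)
    world <- all_pts %*% basis + matrix(centre, nrow(all_pts), 3, byrow = TRUE)
    phase <- query_phase(vol, world)
    field_of_pt <- rep(seq_len(n_fields), vapply(grid_pts, nrow, 0L))

    counts <- function(ph) {
      tab <- tabulate(field_of_pt[phase == ph], nbins = n_fields)
      as.integer(tab)
    }

    tibble::tibble(
      animal_id = animal_id,
      group = group,
      field = seq_len(n_fields),
      p_collagen = counts("collagen"),
      p_vessel = counts("vessel"),
      p_hair = counts("hair"),
      p_dermis = as.integer(tabulate(field_of_pt, nbins = n_fields)),
      q_minus = vapply(res, `[[`, 0L, "q_minus"),
      frame_area_mm2 = fw * fh / UM2_PER_MM2,
      height_mm = frame$height / UM_PER_MM,
      vessel_transects = vapply(res, `[[`, 0L, "vessel_transects"),
      diameters_um = lapply(res, `[[`, "diameters_um")
    )
  })
}

#' Simulate one animal end to end: blocks, IUR sections, field counts
#'
#' Emulates the standard histological workflow: the animal's skin sample
#' is cut into `n_blocks` systematically sampled tissue blocks, each
#' block is sectioned with its own isotropic uniform random orientation,
#' and `n_fields` microscopic fields are spread evenly over the blocks.
#' Multiple independently oriented blocks per animal are what make the
#' orientation-dependent length-density estimator precise at the animal
#' level; probing a single block would leave transect counts dominated by
#' one orientation and one vessel realization. All seeds derive from
#' `params$seed`, so one integer reproduces the whole animal.
#'
#' @inheritParams render_field_counts
#' @param params a [tissue_params()] object; each block is an independent
#'   realization of the same ground truth.
#' @param n_blocks number of tissue blocks (default 9, as in systematic
#'   random sampling of nine ~1 mm^2 pieces).
#' @param n_sections IUR sections cut per block.
#' @return a field-count tibble (see [render_field_counts()]) with a
#'   `block` column.
#' @export
simulate_animal <- function(params, n_fields = 30, grid = point_grid(0.02),
                            frame = dissector_spec(), n_blocks = 9,
                            n_sections = 5,
                            animal_id = paste0("animal", params$seed),
                            group = NA_character_) {
  stopifnot(n_blocks >= 1)
  per_block <- diff(round(seq(0, n_fields, length.out = n_blocks + 1)))
  purrr::map(seq_len(n_blocks), function(b) {
    if (per_block[b] == 0) return(NULL)
    bp <- params
    bp$seed <- derive_seed(params$seed, 7000 + b)
    vol <- simulate_volume(bp)
    stack <- section_stack(vol, section_thickness = frame$section_thickness,
                           n_sections = n_sections,
                           seed = derive_seed(params$seed, 101 + b))
    render_field_counts(stack, grid = grid, frame = frame,
                        n_fields = per_block[b],
                        animal_id = animal_id, group = group,
                        seed = derive_seed(params$seed, 202 + b)) |>
      dplyr::mutate(block = b, .after = "group")
  }) |> purrr::list_rbind()
}

#' Simulate a multi-group cohort of synthetic animals
#'
#' Draws per-animal ground-truth densities from group-level mean/SD
#' specifications (normal, truncated to feasible ranges), simulates each
#' animal with [simulate_animal()], and returns the pooled field counts.
#' With the default `groups = default_group_tissue()` the cohort emulates
#' a four-arm diabetic wound study (control, vehicle gel, two treated
#' arms of a herbal gel) with n = 12 animals per arm.
#'
#' @param groups a tibble with columns `group`, `nv_mean`, `nv_sd`
#'   (cells/mm^3), `vv_collagen_mean`, `vv_collagen_sd`, `vv_hair_mean`,
#'   `vv_hair_sd` (fractions), `lv_mean`, `lv_sd` (mm/mm^3), `diam_mean`,
#'   `diam_sd` (um). See [default_group_tissue()].
#' @param n_animals animals per group.
#' @param extent block extent per animal, um.
#' @param seed integer master seed.
#' @inheritParams simulate_animal
#' @return list with `fields` (pooled field-count tibble) and `truth`
#'   (per-animal tibble of the drawn ground-truth densities).
#' @export
simulate_cohort <- function(groups = default_group_tissue(), n_animals = 12,
                            n_fields = 30, grid = point_grid(0.02),
                            frame = dissector_spec(), n_blocks = 9,
                            extent = c(500, 500, 500), seed = 1) {
  stopifnot(is.data.frame(groups), n_animals >= 1)
  draws <- with_seed(seed, {
    purrr::pmap(groups, function(group, nv_mean, nv_sd, vv_collagen_mean,
                                 vv_collagen_sd, vv_hair_mean, vv_hair_sd,
                                 lv_mean, lv_sd, diam_mean, diam_sd, ...) {
      tibble::tibble(
        group = group,
        animal = seq_len(n_animals),
        nv_fibroblast = rnorm_pos(n_animals, nv_mean, nv_sd),
        vv_collagen = pmin(pmax(rnorm(n_animals, vv_collagen_mean,
                                      vv_collagen_sd), 0.01), 0.9),
        vv_hair = pmin(pmax(rnorm(n_animals, vv_hair_mean, vv_hair_sd),
                            0.001), 0.2),
        lv_vessel = rnorm_pos(n_animals, lv_mean, lv_sd),
        vessel_diameter_mean = rnorm_pos(n_animals, diam_mean, diam_sd)
      )
    }) |> purrr::list_rbind()
  })
  draws$animal_id <- sprintf("%s_%02d", draws$group, draws$animal)
  draws$seed <- derive_seed(seed, seq_len(nrow(draws)))

  fields <- purrr::pmap(draws, function(group, animal, nv_fibroblast,
                                        vv_collagen, vv_hair, lv_vessel,
                                        vessel_diameter_mean, animal_id,
                                        seed, ...) {
    params <- tissue_params(
      nv_fibroblast = nv_fibroblast, vv_collagen = vv_collagen,
      vv_hair = vv_hair, lv_vessel = lv_vessel,
      vessel_diameter_mean = vessel_diameter_mean,
      vessel_diameter_sd = 0.25 * vessel_diameter_mean,
      extent = extent, seed = seed
    )
    simulate_animal(params, n_fields = n_fields, grid = grid, frame = frame,
                    n_blocks = n_blocks, animal_id = animal_id, group = group)
  }) |> purrr::list_rbind()

  list(fields = fields, truth = draws)
}
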