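# Shared fixture builders: all synthetic, generated in code at test time.

with_seed <- stereowound:::with_seed

make_fields <- function(p_collagen = 25L, p_vessel = 5L, p_hair = 2L,
                        p_dermis = 100L, q_minus = 10L,
                        frame_area_mm2 = 0.04, height_mm = 0.005,
                        vessel_transects = 2L,
                        diameters = list(c(10, 12)),
                        n = 1, animal_id = "a1", group = "g1") {
  tibble::tibble(
    animal_id = animal_id, group = group, field = seq_len(n),
    p_collagen = rep_len(p_collagen, n), p_vessel = rep_len(p_vessel, n),
    p_hair = rep_len(p_hair, n), p_dermis = rep_len(p_dermis, n),
    q_minus = rep_len(q_minus, n),
    frame_area_mm2 = rep_len(frame_area_mm2, n),
    height_mm = rep_len(height_mm, n),
    vessel_transects = rep_len(vessel_transects, n),
    diameters_um = rep_len(diameters, n)
  )
}

# A volume with hand-placed geometry (for constructed counting cases).
make_volume <- function(fibroblasts = matrix(numeric(0), 0, 3),
                        extent = c(500, 500, 500),
                        vessel_p0 = matrix(numeric(0), 0, 3),
                        vessel_p1 = matrix(numeric(0), 0, 3),
                        vessel_radius = numeric(0)) {
  params <- tissue_params(nv_fibroblast = 0, vv_collagen = 0, vv_hair = 0,
                          lv_vessel = 0, extent = extent, seed = 1)
  structure(
    list(
      fibroblast_centers = fibroblasts,
      collagen_grains = list(centers = matrix(numeric(0), 0, 3), radius = 12),
      hair_grains = list(centers = matrix(numeric(0), 0, 3), radius = 25),
      vessel_segments = list(p0 = vessel_p0, p1 = vessel_p1,
                             radius = vessel_radius),
      extent = extent,
      params = params
    ),
    class = "stereo_volume"
  )
}

# An axial section stack with a slab centred exactly at the block midplane.
make_axial_stack <- function(volume, thickness = 15) {
  structure(
    list(volume = volume,
         basis = stereowound:::plane_basis(c(0, 0, 1)),
         z0 = 0, thickness = thickness, iur = FALSE),
    class = "section_stack"
  )
}

empty_params <- function(extent = c(400, 400, 400), seed = 1) {
  tissue_params(nv_fibroblast = 0, vv_collagen = 0, vv_hair = 0,
                lv_vessel = 0, extent = extent, seed = seed)
}
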