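test_that("structure-free volumes yield zero structure counts, live reference", {
  f <- simulate_animal(empty_params(seed = 3), n_fields = 6, n_blocks = 2,
                       grid = point_grid(0.03),
                       frame = dissector_spec(frame_width = 150,
                                              frame_height = 150))
  expect_true(all(f$p_collagen == 0 & f$p_vessel == 0 & f$p_hair == 0))
  expect_true(all(f$q_minus == 0 & f$vessel_transects == 0))
  expect_true(all(f$p_dermis > 0))
})

test_that("a nucleus mid-dissector inside the frame counts exactly once", {
  vol <- make_volume(fibroblasts = rbind(c(250, 250, 250)))
  stack <- make_axial_stack(vol)
  f <- render_field_counts(stack, n_fields = 1,
                           field_centers = matrix(0, 1, 2), seed = 1)
  expect_equal(f$q_minus, 1L)
})

test_that("guard zones and unbiased frame edges include/exclude correctly", {
  # w = +/-4 um is inside the 5 um guard zones (dissector spans [-2.5, 2.5))
  vol <- make_volume(fibroblasts = rbind(c(250, 250, 254), c(250, 250, 246)))
  f <- render_field_counts(make_axial_stack(vol), n_fields = 1,
                           field_centers = matrix(0, 1, 2), seed = 1)
  expect_equal(f$q_minus, 0L)

  # left/bottom edges include, right/top edges exclude (frame x in [150, 350))
  vol2 <- make_volume(fibroblasts = rbind(c(150, 250, 250), c(350, 250, 250)))
  f2 <- render_field_counts(make_axial_stack(vol2), n_fields = 1,
                            field_centers = matrix(0, 1, 2), seed = 1)
  expect_equal(f2$q_minus, 1L)
})

test_that("a vessel crossing the focal plane in-frame is one transect", {
  vol <- make_volume(
    vessel_p0 = rbind(c(250, 250, 200)), vessel_p1 = rbind(c(250, 250, 300)),
    vessel_radius = 6
  )
  f <- render_field_counts(make_axial_stack(vol), n_fields = 1,
                           field_centers = matrix(0, 1, 2), seed = 1)
  expect_equal(f$vessel_transects, 1L)
  expect_equal(f$diameters_um[[1]], 12)

  # a segment parallel to the plane never transects it
  vol2 <- make_volume(
    vessel_p0 = rbind(c(200, 250, 260)), vessel_p1 = rbind(c(300, 250, 260)),
    vessel_radius = 6
  )
  f2 <- render_field_counts(make_axial_stack(vol2), n_fields = 1,
                            field_centers = matrix(0, 1, 2), seed = 1)
  expect_equal(f2$vessel_transects, 0L)
})

test_that("oversized frames are rejected and stacks must match thickness", {
  p <- empty_params(extent = c(300, 300, 300))
  vol <- simulate_volume(p)
  st <- section_stack(vol, 15, 3, seed = 2)
  expect_error(
    render_field_counts(st, frame = dissector_spec(frame_width = 450,
                                                   frame_height = 450),
                        n_fields = 2, seed = 1),
    "does not fit"
  )
  expect_error(
    render_field_counts(st, frame = dissector_spec(section_thickness = 10,
                                                   guard_top = 2,
                                                   guard_bottom = 2),
                        n_fields = 2, seed = 1),
    "thickness"
  )
})

test_that("dissector recovers a known numerical density at moderate effort", {
  est <- vapply(1:6, function(s) {
    p <- tissue_params(nv_fibroblast = 300e3, vv_collagen = 0.3,
                       vv_hair = 0.01, lv_vessel = 10, seed = 600 + s)
    f <- simulate_animal(p, n_fields = 36, n_blocks = 4,
                         grid = point_grid(0.05), group = "g")
    estimate_numerical_density(f)
  }, 0)
  expect_equal(mean(est) / 300e3, 1, tolerance = 0.1)
})

test_that("wound series generator honors its invariants", {
  prof <- wound_profile("treated", decay_rate = 0.25, noise_sd = 0)
  s <- simulate_wound_series(prof, n_animals = 3, seed = 4)
  expect_setequal(unique(s$day), seq(0, 15, 3))
  expect_true(all(s$area_mm2 >= 0))
  expect_identical(s, simulate_wound_series(prof, n_animals = 3, seed = 4))

  # noise-free exponential decay matches the closed form
  a0 <- setNames(s$area_mm2[s$day == 0], s$animal_id[s$day == 0])
  expect_equal(s$area_mm2, unname(a0[s$animal_id]) * exp(-0.25 * s$day))
})

test_that("negative simulated areas are clipped to zero and flagged", {
  prof <- wound_profile("t", initial_mean = 5, initial_sd = 0,
                        decay_rate = 0.5, noise_sd = 30)
  s <- simulate_wound_series(prof, n_animals = 8, seed = 2)
  expect_true(any(s$clipped))
  expect_true(all(s$area_mm2[s$clipped] == 0))
})
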