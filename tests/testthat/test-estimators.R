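test_that("point-grid area is count times area-per-point", {
  expect_equal(estimate_area(25, point_grid(spacing = 2)), 100)
  expect_equal(estimate_area(0, point_grid(spacing = 2)), 0)
  expect_equal(estimate_area(c(1, 10), point_grid(spacing = 0.5)),
               c(0.25, 2.5))
  expect_error(estimate_area(-1, point_grid(1)), "non-negative")
})

test_that("volume density is a ratio of sums, not a mean of ratios", {
  f <- make_fields(p_collagen = 25L, p_dermis = 100L)
  expect_equal(estimate_volume_density(f, "collagen"), 0.25)

  sat <- make_fields(p_collagen = 60L, p_vessel = 0L, p_hair = 0L,
                     p_dermis = 60L, n = 3)
  expect_equal(estimate_volume_density(sat, "collagen"), 1)

  # unequal field sizes: pooled counts, not averaged per-field fractions
  uneq <- dplyr::bind_rows(
    make_fields(p_collagen = 10L, p_dermis = 20L),
    make_fields(p_collagen = 0L, p_dermis = 80L)
  )
  expect_equal(estimate_volume_density(uneq, "collagen"), 0.1)

  zero <- make_fields(p_dermis = 0L, p_collagen = 0L, p_vessel = 0L,
                      p_hair = 0L)
  expect_error(estimate_volume_density(zero, "collagen"), "undefined")
})

test_that("optical dissector divides counts by probed volume", {
  f <- make_fields(q_minus = 50L, frame_area_mm2 = 0.1, height_mm = 0.005)
  expect_equal(estimate_numerical_density(f), 1e5)  # 100 x10^3 / mm^3

  f0 <- make_fields(q_minus = 0L)
  expect_equal(estimate_numerical_density(f0), 0)

  mixed <- dplyr::bind_rows(make_fields(height_mm = 0.005),
                            make_fields(height_mm = 0.010))
  expect_error(estimate_numerical_density(mixed), "mixed dissector heights")
})

test_that("length density doubles the transect areal density", {
  # Q_A = 43 / 5 mm^2 = 8.6 per mm^2 -> Lv = 17.2 mm/mm^3
  f <- make_fields(vessel_transects = 43L, frame_area_mm2 = 5)
  expect_equal(estimate_length_density(f), 17.2)
  expect_equal(estimate_length_density(make_fields(vessel_transects = 0L)), 0)
  expect_error(estimate_length_density(make_fields(frame_area_mm2 = 0)),
               "frame area")
})

test_that("mean diameter pools profile minor axes", {
  f <- make_fields(diameters = list(c(10, 12, 14)))
  expect_equal(estimate_mean_diameter(f), 12)
  expect_equal(estimate_mean_diameter(make_fields(diameters = list(11.7))),
               11.7)
  expect_error(estimate_mean_diameter(make_fields(diameters = list(numeric(0)))),
               "no vessel profiles")
})

test_that("estimates are invariant under field replication", {
  set.seed(11)
  f <- make_fields(
    p_collagen = as.integer(rpois(6, 30)), p_vessel = as.integer(rpois(6, 2)),
    p_hair = as.integer(rpois(6, 1)), p_dermis = 80L,
    q_minus = as.integer(rpois(6, 8)), vessel_transects = as.integer(rpois(6, 1)),
    diameters = lapply(1:6, function(i) runif(2, 8, 20)), n = 6
  )
  f3 <- dplyr::bind_rows(f, f, f)
  for (fun in list(function(x) estimate_volume_density(x, "collagen"),
                   estimate_numerical_density, estimate_length_density,
                   estimate_mean_diameter)) {
    expect_equal(fun(f3), fun(f))
  }
})

test_that("per-animal summary reports all-zero structures with valid reference", {
  f <- make_fields(p_collagen = 0L, p_vessel = 0L, p_hair = 0L,
                   p_dermis = 100L, q_minus = 0L, vessel_transects = 0L,
                   diameters = list(numeric(0)), n = 4)
  s <- summarize_animals(f)
  expect_equal(nrow(s), 1)
  expect_equal(s$nv_fibroblast, 0)
  expect_equal(s$vv_collagen_pct, 0)
  expect_equal(s$lv_vessel, 0)
  expect_true(is.na(s$vessel_diameter_um))
})

test_that("per-animal summary converts the dissector density to 10^3/mm^3", {
  f <- make_fields(q_minus = 50L, frame_area_mm2 = 0.1, height_mm = 0.005)
  s <- summarize_animals(f)
  expect_equal(s$nv_fibroblast, 100)  # 1e5 cells/mm^3
})

test_that("point-count Vv converges to a dense-grid voxel oracle", {
  p <- tissue_params(nv_fibroblast = 0, vv_hair = 0, lv_vessel = 0,
                     vv_collagen = 0.474, extent = c(300, 300, 300), seed = 42)
  vol <- simulate_volume(p)
  # same in-block square region, fine (1 um, the voxel oracle) vs coarse
  # (3 um) sampling on three parallel planes
  diffs <- vapply(c(100, 150, 200), function(z) {
    fine <- seq(50.5, 249.5, by = 1)
    coarse <- seq(51, 249, by = 3)
    g_fine <- as.matrix(expand.grid(fine, fine))
    g_coarse <- as.matrix(expand.grid(coarse, coarse))
    f_fr <- mean(query_phase(vol, cbind(g_fine, z)) == "collagen")
    c_fr <- mean(query_phase(vol, cbind(g_coarse, z)) == "collagen")
    c_fr - f_fr
  }, 0)
  expect_lt(abs(mean(diffs)), 0.005)
})

test_that("minor-axis diameters are angle independent for cylinders", {
  p <- tissue_params(nv_fibroblast = 0, vv_collagen = 0, vv_hair = 0,
                     lv_vessel = 60, vessel_diameter_mean = 20,
                     vessel_diameter_sd = 0, seed = 5)
  f <- simulate_animal(p, n_fields = 40, n_blocks = 6, group = "g")
  d <- unlist(f$diameters_um)
  expect_gt(length(d), 20)
  expect_equal(mean(d), 20, tolerance = 1e-12)
})
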