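test_that("identical parameters reproduce identical volumes", {
  p <- tissue_params(extent = c(250, 250, 250), seed = 77)
  v1 <- simulate_volume(p)
  v2 <- simulate_volume(p)
  expect_identical(v1$fibroblast_centers, v2$fibroblast_centers)
  expect_identical(v1$collagen_grains, v2$collagen_grains)
  expect_identical(v1$vessel_segments, v2$vessel_segments)
})

test_that("zero intensities give empty processes", {
  v <- simulate_volume(empty_params())
  expect_equal(nrow(v$fibroblast_centers), 0)
  expect_equal(nrow(v$collagen_grains$centers), 0)
  expect_equal(length(v$vessel_segments$radius), 0)
})

test_that("parameter sets implying a solid fraction of one are rejected", {
  expect_error(tissue_params(vv_collagen = 0.97, vv_hair = 0.04),
               "solid fraction")
})

test_that("Boolean collagen model realizes the requested volume fraction", {
  # Monte-Carlo volume-fraction oracle: uniform random points in the block
  fr <- vapply(1:25, function(s) {
    p <- tissue_params(nv_fibroblast = 0, lv_vessel = 0, vv_hair = 0,
                       vv_collagen = 0.474, extent = c(300, 300, 300),
                       seed = 1000 + s)
    vol <- simulate_volume(p)
    pts <- with_seed(s, matrix(runif(3000 * 3, 0, 300), ncol = 3))
    mean(query_phase(vol, pts) == "collagen")
  }, 0)
  expect_lt(abs(mean(fr) - 0.474), 0.012)
})

test_that("phase precedence keeps realized fractions on target with overlap", {
  fr <- vapply(1:20, function(s) {
    p <- tissue_params(extent = c(300, 300, 300), seed = 3000 + s)
    vol <- simulate_volume(p)
    pts <- with_seed(s, matrix(runif(3000 * 3, 0, 300), ncol = 3))
    ph <- query_phase(vol, pts)
    c(mean(ph == "collagen"), mean(ph == "hair"))
  }, numeric(2))
  expect_lt(abs(mean(fr[1, ]) - 0.474), 0.015)
  expect_lt(abs(mean(fr[2, ]) - 0.026), 0.006)
})

test_that("segment process realizes the requested length density", {
  # oracle: exact clipping of each segment to the block
  clip_len <- function(seg, ext) {
    tot <- 0
    for (i in seq_along(seg$radius)) {
      p0 <- seg$p0[i, ]; d <- seg$p1[i, ] - p0
      t0 <- 0; t1 <- 1
      for (k in 1:3) {
        if (d[k] != 0) {
          ta <- -p0[k] / d[k]; tb <- (ext[k] - p0[k]) / d[k]
          t0 <- max(t0, min(ta, tb)); t1 <- min(t1, max(ta, tb))
        } else if (p0[k] < 0 || p0[k] > ext[k]) {
          t0 <- 1; t1 <- 0
        }
      }
      if (t1 > t0) tot <- tot + (t1 - t0) * sqrt(sum(d^2))
    }
    tot
  }
  lv <- vapply(1:200, function(s) {
    p <- tissue_params(nv_fibroblast = 0, vv_collagen = 0, vv_hair = 0,
                       lv_vessel = 20, extent = c(500, 500, 500),
                       seed = 5000 + s)
    v <- simulate_volume(p)
    clip_len(v$vessel_segments, p$extent) / prod(p$extent) * 1e6
  }, 0)
  se <- sd(lv) / sqrt(length(lv))
  expect_lt(abs(mean(lv) - 20), 3 * se + 1e-9)
})

test_that("volume geometry survives a JSON round trip", {
  p <- tissue_params(extent = c(150, 150, 150), seed = 12)
  v <- simulate_volume(p)
  path <- withr::local_tempfile(fileext = ".json")
  volume_to_json(v, path)
  v2 <- volume_from_json(path)
  expect_equal(v2$fibroblast_centers, v$fibroblast_centers)
  expect_equal(v2$collagen_grains$centers, v$collagen_grains$centers)
  expect_equal(v2$vessel_segments$p0, v$vessel_segments$p0)
  expect_equal(v2$vessel_segments$radius, v$vessel_segments$radius)
  expect_equal(v2$params$vv_collagen, p$vv_collagen)
})

test_that("rendered counts are internally consistent and seed deterministic", {
  p <- tissue_params(extent = c(400, 400, 400), seed = 31)
  vol <- simulate_volume(p)
  st <- section_stack(vol, 15, 4, seed = 8)
  f1 <- render_field_counts(st, grid = point_grid(0.03),
                            frame = dissector_spec(frame_width = 150,
                                                   frame_height = 150),
                            n_fields = 12, seed = 9)
  f2 <- render_field_counts(st, grid = point_grid(0.03),
                            frame = dissector_spec(frame_width = 150,
                                                   frame_height = 150),
                            n_fields = 12, seed = 9)
  expect_identical(f1, f2)
  expect_true(all(f1$p_collagen + f1$p_vessel + f1$p_hair <= f1$p_dermis))
  expect_true(all(f1$p_dermis > 0))
})
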