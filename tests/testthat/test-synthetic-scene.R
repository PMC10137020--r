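test_that("scene generation is deterministic and validates its config", {
  cfg <- tiny_scene_config()
  expect_identical(generate_scene(cfg), generate_scene(cfg))
  expect_error(scene_config(field_size_px = c(0, 128)), "field_size_px")
  expect_error(scene_config(n_planes = 0), "n_planes")
  expect_error(scene_config(background_sd = 0), "background_sd")
  expect_error(scene_config(fragmentation_prob = 1.5), "fragmentation_prob")
})

test_that("stationary limit: zero rates give identical truth at every timepoint", {
  cfg <- tiny_scene_config(migration_rate_px_per_step = 0,
                           growth_rate_per_step = 0, fragmentation_prob = 0)
  sc <- generate_scene(cfg)
  t0 <- sc$clusters_truth[sc$clusters_truth$timepoint == 0, -1]
  rownames(t0) <- NULL
  for (h in unique(sc$clusters_truth$timepoint)) {
    tt <- sc$clusters_truth[sc$clusters_truth$timepoint == h, -1]
    rownames(tt) <- NULL
    expect_identical(tt, t0)
  }
})

test_that("migration makes mean truth distance to center strictly increase", {
  sc <- generate_scene(tiny_scene_config(migration_rate_px_per_step = 5,
                                         n_timepoints = 5,
                                         n_clusters_initial = 8, seed = 1))
  md <- truth_mean_distance(sc)
  expect_length(md, 5)
  expect_true(all(diff(md) > 0))
})

test_that("truth bookkeeping: centroids in field, vessels valid polylines", {
  sc <- generate_scene(tiny_scene_config(seed = 7))
  tr <- sc$clusters_truth
  expect_true(all(tr$x_px >= 0 & tr$x_px <= 127))
  expect_true(all(tr$y_px >= 0 & tr$y_px <= 127))
  expect_true(all(tr$area_px2 > 0))
  for (v in sc$vessels_truth) {
    expect_gte(nrow(v$points), 2)
    seg_sum <- sum(sqrt(rowSums(diff(v$points)^2))) * sc$config$pixel_size_mm
    expect_equal(v$length_mm, seg_sum, tolerance = 1e-12)
  }
  expect_true(all(sc$in_focus_plane_map >= 0 &
                    sc$in_focus_plane_map < sc$config$n_planes))
})

test_that("rendering: shape, determinism, and error handling", {
  sc <- generate_scene(tiny_scene_config(n_planes = 4))
  st <- render_zstack(sc, 1, "tumor")
  expect_s3_class(st, "ImageStack")
  expect_equal(dim(st$pixels), c(128, 128, 4))
  expect_true(all(st$pixels == round(st$pixels)))
  expect_true(all(st$pixels >= 0 & st$pixels <= 65535))
  expect_identical(st$pixels, render_zstack(sc, 1, "tumor")$pixels)
  expect_error(render_zstack(sc, 1, "nirvana"), "unknown channel")
  expect_error(render_zstack(sc, 99, "tumor"), "out of range")
})

test_that("pixel values scale linearly with exposure time", {
  mk <- function(expo) generate_scene(tiny_scene_config(
    background_mean = 1000, background_sd = 100, cluster_intensity = 2000,
    exposure_times_ms = expo, n_planes = 3, seed = 5))
  a <- render_zstack(mk(20), 1, "tumor")$pixels
  b <- render_zstack(mk(40), 1, "tumor")$pixels
  # identical noise stream, doubled exposure: exact 2x up to output rounding
  expect_lte(max(abs(b - 2 * a)), 1)
})

test_that("zero defocus renders all planes identically up to the noise draw", {
  cfg <- tiny_scene_config(defocus_sigma_per_plane = 0, background_sd = 1,
                           background_mean = 500, n_planes = 3)
  st <- render_zstack(generate_scene(cfg), 1, "tumor")
  # signal part identical across planes; noise sd 1 bounds the difference
  expect_lt(max(abs(st$pixels[, , 1] - st$pixels[, , 3])), 10)
})

test_that("raising cluster intensity never decreases a tumor pixel", {
  lo <- render_zstack(generate_scene(tiny_scene_config(cluster_intensity = 2000)),
                      1, "tumor")$pixels
  hi <- render_zstack(generate_scene(tiny_scene_config(cluster_intensity = 3000)),
                      1, "tumor")$pixels
  expect_true(all(hi >= lo))
})

test_that("thresholding the in-focus render recovers a known disk area", {
  # single cluster, noise sd = 1% of intensity
  cfg <- tiny_scene_config(n_clusters_initial = 1, cluster_intensity = 3000,
                           background_mean = 500, background_sd = 30,
                           mean_cluster_area_px2 = 500, seed = 2)
  sc <- generate_scene(cfg)
  truth <- sc$clusters_truth$area_px2[sc$clusters_truth$timepoint == 0]
  img <- render_infocus(sc, 1, "tumor")$pixels[, , 1]
  bg <- estimate_background(img)
  m <- morphological_clean(threshold_mask(img, bg, 2), "auto", 50)
  cl <- detect_clusters(m, 50, cfg$pixel_size_mm)
  expect_equal(nrow(cl), 1)
  expect_lt(abs(cl$area_px2 - truth) / truth, 0.05)
})

test_that("truth tables round-trip and the vessel CSV feeds the importer", {
  sc <- generate_scene(tiny_scene_config(vessel_count = 3, seed = 9))
  dir <- withr::local_tempdir()
  write_truth_tables(sc, dir)
  cl <- read.csv(file.path(dir, "clusters.csv"))
  expect_equal(cl$x_px, sc$clusters_truth$x_px, tolerance = 1e-12)
  expect_equal(cl$area_px2, sc$clusters_truth$area_px2)
  traces <- read_vessel_traces(file.path(dir, "vessels.csv"))
  expect_length(traces, 3)
  got <- sum(vapply(traces, function(t)
    sum(sqrt(rowSums(diff(t$points)^2))), numeric(1))) * sc$config$pixel_size_mm
  truth <- sum(vapply(sc$vessels_truth, `[[`, numeric(1), "length_mm"))
  expect_equal(got, truth, tolerance = 1e-9)
})

test_that("a vessel-free scene writes a header-only vessel CSV", {
  sc <- generate_scene(tiny_scene_config(vessel_count = 0L))
  dir <- withr::local_tempdir()
  write_truth_tables(sc, dir)
  v <- read.csv(file.path(dir, "vessels.csv"))
  expect_equal(nrow(v), 0)
  expect_named(v, c("trace_id", "point_index", "x_px", "y_px"))
})

test_that("scratch artifacts are rendered and then removed by cleanup", {
  cfg <- tiny_scene_config(n_artifacts = 2L, background_sd = 50,
                           background_mean = 500, seed = 4)
  sc <- generate_scene(cfg)
  img <- render_infocus(sc, 1, "tumor")$pixels[, , 1]
  bg <- estimate_background(img)
  raw <- threshold_mask(img, bg, 2)
  cleaned <- morphological_clean(raw, "auto", 50)
  cl <- detect_clusters(cleaned, 50, cfg$pixel_size_mm)
  truth_n <- sum(sc$clusters_truth$timepoint == 0)
  expect_equal(nrow(cl), truth_n)          # scratches do not survive
  expect_gt(sum(raw$pixels), sum(cleaned$pixels))
})
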