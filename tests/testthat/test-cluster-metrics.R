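# Build a cluster table directly (pixel size in mm attached as on detection).
fake_clusters <- function(x, y, area_px2, pixel_size_mm = 1) {
  a_mm <- area_px2 * pixel_size_mm^2
  df <- data.frame(cluster_id = seq_along(x), area_px2 = area_px2,
                   area_mm2 = a_mm, centroid_x_px = x, centroid_y_px = y,
                   diameter_mm = 2 * sqrt(a_mm / pi))
  attr(df, "pixel_size_mm") <- pixel_size_mm
  df
}

test_that("center of mass is the area-weighted centroid", {
  one <- fake_clusters(3, 4, 100)
  expect_equal(unname(center_of_mass(one)), c(3, 4))
  two <- fake_clusters(c(0, 10), c(0, 0), c(50, 50))
  expect_equal(unname(center_of_mass(two)), c(5, 0))
  wt <- fake_clusters(c(0, 8), c(0, 0), c(30, 10))
  expect_equal(unname(center_of_mass(wt)), c(2, 0))
  expect_equal(unname(center_of_mass(wt, "unweighted")), c(4, 0))
  expect_error(center_of_mass(fake_clusters(numeric(0), numeric(0), numeric(0))),
               "0 clusters")
})

test_that("distances and area moments follow their definitions", {
  one <- fake_clusters(5, 5, 200)
  a1 <- annotate_distances_and_moments(one, center_of_mass(one))
  expect_equal(a1$distance_to_com_mm, 0)
  expect_equal(a1$area_moment_mm3, 0)
  expect_equal(a1$percent_area, 100)

  # two equal clusters 10 mm apart: each 5 mm from the COM, moment 5a each
  a <- 2.5
  two <- fake_clusters(c(0, 10), c(0, 0), rep(a, 2))
  a2 <- annotate_distances_and_moments(two, center_of_mass(two))
  expect_equal(a2$distance_to_com_mm, c(5, 5))
  expect_equal(a2$area_moment_mm3, rep(5 * a, 2))

  # moments recompute independently from the table to 1e-12 relative
  set.seed(5)
  many <- fake_clusters(runif(20, 0, 100), runif(20, 0, 100),
                        runif(20, 60, 400), pixel_size_mm = 0.0051)
  am <- annotate_distances_and_moments(many, center_of_mass(many),
                                       origin_mm = c(0.1, 0.2))
  expect_equal(am$area_moment_mm3, am$distance_to_com_mm * am$area_mm2,
               tolerance = 1e-12)
  expect_equal(am$distance_to_origin_mm,
               sqrt((many$centroid_x_px * 0.0051 - 0.1)^2 +
                      (many$centroid_y_px * 0.0051 - 0.2)^2),
               tolerance = 1e-12)
  expect_equal(sum(am$percent_area), 100, tolerance = 1e-9)
})

test_that("translation invariance and calibration covariance hold", {
  set.seed(6)
  base <- fake_clusters(runif(8, 20, 80), runif(8, 20, 80), runif(8, 60, 300))
  shifted <- base
  shifted$centroid_x_px <- base$centroid_x_px + 13.7
  shifted$centroid_y_px <- base$centroid_y_px - 4.2
  attr(shifted, "pixel_size_mm") <- 1
  a0 <- annotate_distances_and_moments(base, center_of_mass(base))
  a1 <- annotate_distances_and_moments(shifted, center_of_mass(shifted))
  expect_equal(a1$distance_to_com_mm, a0$distance_to_com_mm)
  expect_equal(a1$area_moment_mm3, a0$area_moment_mm3)

  # doubling the calibration: distances x2, areas x4, moments x8
  big <- fake_clusters(base$centroid_x_px, base$centroid_y_px, base$area_px2,
                       pixel_size_mm = 2)
  a2 <- annotate_distances_and_moments(big, center_of_mass(big))
  expect_equal(a2$distance_to_com_mm, 2 * a0$distance_to_com_mm)
  expect_equal(big$area_mm2, 4 * base$area_mm2)
  expect_equal(big$diameter_mm, 2 * base$diameter_mm)
  expect_equal(a2$area_moment_mm3, 8 * a0$area_moment_mm3)
})

test_that("timepoint summaries: hand-checked values and degenerate counts", {
  cl <- fake_clusters(c(0, 4), c(0, 0), c(1, 3))
  cl <- annotate_distances_and_moments(cl, center_of_mass(cl))
  s <- summarize_timepoint(cl, 24)
  expect_equal(s$n_clusters, 2)
  expect_equal(s$total_area_mm2, 4)
  expect_equal(s$mean_area_mm2, 2)
  expect_equal(s$sem_area_mm2, 1) # sd = sqrt(2), / sqrt(2)

  one <- annotate_distances_and_moments(fake_clusters(1, 1, 5),
                                        center_of_mass(fake_clusters(1, 1, 5)))
  s1 <- summarize_timepoint(one, 0)
  expect_true(is.na(s1$sem_area_mm2)) # SEM undefined for n < 2
  expect_equal(one$percent_area, 100)

  s0 <- summarize_timepoint(fake_clusters(numeric(0), numeric(0), numeric(0)), 0)
  expect_equal(s0$n_clusters, 0)
  expect_equal(s0$total_area_mm2, 0)
  expect_true(is.na(s0$mean_area_mm2))
})

test_that("longitudinal table sorts, differences, and rejects duplicates", {
  mk <- function(h, area) {
    cl <- annotate_distances_and_moments(
      fake_clusters(c(0, 4), c(0, 0), c(area, area)),
      center_of_mass(fake_clusters(c(0, 4), c(0, 0), c(area, area))))
    summarize_timepoint(cl, h)
  }
  tab <- longitudinal_table(list(mk(48, 3), mk(0, 1), mk(24, 2)))
  expect_equal(tab$timepoint_hours, c(0, 24, 48))
  expect_equal(tab$d_total_area_mm2, c(NA, 2, 2))
  expect_error(longitudinal_table(list(mk(0, 1), mk(0, 2))), "duplicate")
  one <- longitudinal_table(list(mk(5, 1)))
  expect_equal(nrow(one), 1)
  expect_true(is.na(one$d_total_area_mm2))
})

test_that("stationary scene yields identical summaries at every timepoint", {
  cfg <- tiny_scene_config(migration_rate_px_per_step = 0,
                           growth_rate_per_step = 0, fragmentation_prob = 0,
                           background_sd = 1, background_mean = 500)
  sc <- generate_scene(cfg)
  summaries <- lapply(1:3, function(t) {
    img <- render_infocus(sc, t, "tumor")$pixels[, , 1]
    m <- morphological_clean(threshold_mask(img, estimate_background(img), 2),
                             "auto", 50)
    cl <- detect_clusters(m, 50, cfg$pixel_size_mm)
    cl <- annotate_distances_and_moments(cl, center_of_mass(cl))
    summarize_timepoint(cl, 0)
  })
  # truth is frozen; only the noise draw (and hence the auto-chosen opening
  # count and a handful of boundary pixels) differs between renders
  expect_equal(summaries[[2]], summaries[[1]], tolerance = 0.02)
  expect_equal(summaries[[3]], summaries[[1]], tolerance = 0.02)
  expect_equal(summaries[[2]]$n_clusters, summaries[[1]]$n_clusters)
})
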