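px_mm <- 0.01

test_that("traced density is length over ROI area, with exact clipping", {
  roi <- roi_rect(0, 0, 200, 200, px_mm) # 4 mm^2
  tr <- list(list(trace_id = 1, points = cbind(x = c(0, 200), y = c(100, 100))))
  r <- trace_length(tr, roi, px_mm)
  expect_equal(r$total_length_mm, 2)
  expect_equal(r$density_per_mm, 0.5)
  expect_equal(r$method, "traced")

  expect_equal(trace_length(list(), roi, px_mm)$density_per_mm, 0)

  # trace crossing one edge perpendicularly: exactly half its length counts
  half <- list(list(trace_id = 1, points = cbind(x = c(100, 300), y = c(50, 50))))
  r2 <- trace_length(half, roi, px_mm)
  expect_equal(r2$total_length_mm, 1)

  # additive over disjoint trace sets
  both <- trace_length(c(tr, half), roi, px_mm)
  expect_equal(both$total_length_mm,
               r$total_length_mm + r2$total_length_mm)
})

test_that("density scale law: halving the ROI area doubles the density", {
  inner <- roi_rect(50, 0, 100, 200, px_mm) # half the area, contains the trace
  tr <- list(list(trace_id = 1, points = cbind(x = c(60, 140), y = c(100, 100))))
  d_full <- trace_length(tr, roi_rect(0, 0, 200, 200, px_mm), px_mm)$density_per_mm
  d_half <- trace_length(tr, inner, px_mm)$density_per_mm
  expect_equal(d_half, 2 * d_full)
})

test_that("circular ROI clipping matches the chord geometry", {
  roi <- roi_circle(100, 100, 50, px_mm)
  tr <- list(list(trace_id = 1, points = cbind(x = c(0, 200), y = c(100, 100))))
  r <- trace_length(tr, roi, px_mm)
  expect_equal(r$total_length_mm, 100 * px_mm) # diameter chord
  expect_equal(r$roi_area_mm2, pi * 0.5^2)
})

test_that("skeleton length recovers bars, rings, and empty masks", {
  m <- matrix(FALSE, 60, 120); m[30:34, 10:110] <- TRUE # 101 px, 5 thick
  r <- skeleton_length(binary_mask(m), roi_rect(0, 0, 119, 59, px_mm), px_mm)
  expect_equal(r$method, "skeletonized")
  expect_lt(abs(r$total_length_mm - 1) / 1, 0.03)

  xy <- expand.grid(y = 1:100, x = 1:100)
  d <- sqrt((xy$x - 50.5)^2 + (xy$y - 50.5)^2)
  ann <- matrix(d >= 27.5 & d <= 32.5, 100, 100)
  r2 <- skeleton_length(binary_mask(ann), roi_rect(0, 0, 99, 99, px_mm), px_mm)
  expect_lt(abs(r2$total_length_mm - 2 * pi * 30 * px_mm) / (2 * pi * 30 * px_mm),
            0.05)

  r3 <- skeleton_length(binary_mask(matrix(FALSE, 40, 40)),
                        roi_rect(0, 0, 39, 39, px_mm), px_mm)
  expect_equal(r3$total_length_mm, 0)
  expect_equal(r3$density_per_mm, 0)
})

test_that("skeleton length recovers synthetic vessel truth within 5%", {
  cfg <- tiny_scene_config(vessel_count = 3, background_sd = 50,
                           background_mean = 500, seed = 13)
  sc <- generate_scene(cfg)
  img <- render_infocus(sc, 1, "lymphatic")$pixels[, , 1]
  vm <- morphological_clean(threshold_mask(img, estimate_background(img), 2),
                            "auto", 50)
  roi <- roi_rect(0, 0, 127, 127, cfg$pixel_size_mm)
  got <- skeleton_length(vm, roi, cfg$pixel_size_mm)$total_length_mm
  truth <- sum(vapply(sc$vessels_truth, `[[`, numeric(1), "length_mm"))
  expect_lt(abs(got - truth) / truth, 0.05)
})

test_that("overlap fractions follow set arithmetic and swap symmetrically", {
  full <- binary_mask(matrix(TRUE, 10, 10))
  expect_equal(channel_overlap(full, full, 1)$tumor_on_lymph_fraction, 1)
  expect_equal(channel_overlap(full, full, 1)$lymph_on_tumor_fraction, 1)

  a <- matrix(FALSE, 10, 10); a[1:5, 1:5] <- TRUE
  b <- matrix(FALSE, 10, 10); b[6:10, 6:10] <- TRUE
  dis <- channel_overlap(binary_mask(a), binary_mask(b), 1)
  expect_equal(dis$tumor_on_lymph_fraction, 0)
  expect_equal(dis$overlap_area_mm2, 0)

  tum <- matrix(FALSE, 20, 20); tum[1:10, 1:5] <- TRUE  # 50 px
  lym <- matrix(FALSE, 20, 20); lym[1:10, 1:20] <- TRUE # 200 px
  ov <- channel_overlap(binary_mask(tum), binary_mask(lym), 1)
  expect_equal(ov$tumor_on_lymph_fraction, 1)
  expect_equal(ov$lymph_on_tumor_fraction, 0.25)
  sw <- channel_overlap(binary_mask(lym), binary_mask(tum), 1)
  expect_equal(sw$tumor_on_lymph_fraction, ov$lymph_on_tumor_fraction)
  expect_equal(sw$lymph_on_tumor_fraction, ov$tumor_on_lymph_fraction)

  empty <- binary_mask(matrix(FALSE, 10, 10))
  expect_true(is.na(channel_overlap(empty, full, 1)$tumor_on_lymph_fraction))
  expect_error(channel_overlap(full, binary_mask(matrix(TRUE, 5, 5)), 1),
               "shapes differ")
})
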