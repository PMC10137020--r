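test_that("background statistics are exact sample statistics", {
  img <- matrix(7, 20, 20)
  bg <- estimate_background(img, matrix(TRUE, 20, 20))
  expect_equal(bg$mean, 7)
  expect_equal(bg$sd, 0)

  img2 <- matrix(c(rep(10, 100), rep(20, 100), rep(0, 200)), 20, 20)
  region <- matrix(c(rep(TRUE, 200), rep(FALSE, 200)), 20, 20)
  bg2 <- estimate_background(img2, region)
  expect_equal(bg2$mean, 15)
  expect_equal(bg2$sd, sd(c(rep(10, 100), rep(20, 100))))

  expect_error(estimate_background(matrix(1, 5, 5), matrix(TRUE, 5, 5)),
               "at least 100")
})

test_that("corner-patch default samples 4 corners, large-sample stats converge", {
  set.seed(99)
  img <- matrix(rnorm(1000 * 1000, 100, 10), 1000, 1000)
  bg <- estimate_background(img)
  expect_equal(bg$n_pixels, 4 * 50 * 50)
  bg_all <- estimate_background(img, matrix(TRUE, 1000, 1000))
  expect_lt(abs(bg_all$mean - 100), 0.05)
  expect_lt(abs(bg_all$sd - 10), 0.05)
})

test_that("threshold is strict and background-relative", {
  img <- matrix(c(121, 120, 119, 200), 2, 2)
  m <- threshold_mask(img, list(mean = 100, sd = 10), k = 2)
  expect_identical(as.vector(m$pixels), c(TRUE, FALSE, FALSE, TRUE))
  expect_equal(m$provenance$threshold, 120)
  m0 <- threshold_mask(img, list(mean = 120, sd = 10), k = 0)
  expect_identical(as.vector(m0$pixels), c(TRUE, FALSE, FALSE, TRUE))
})

test_that("k=2 foreground fraction on pure Gaussian background is the upper tail", {
  set.seed(12)
  img <- matrix(rnorm(1024^2, 500, 40), 1024, 1024)
  m <- threshold_mask(img, list(mean = 500, sd = 40), k = 2)
  expect_lt(abs(mean(m$pixels) - pnorm(2, lower.tail = FALSE)), 0.002)
})

test_that("identical masks from real-valued and exactly-affine 8-bit paths", {
  # 16-bit values that are multiples of 257 convert to 0..255 without rounding,
  # so the background-relative threshold rule gives the same mask on both.
  set.seed(21)
  img <- matrix(sample(0:255, 128^2, TRUE) * 257L, 128, 128)
  img[40:60, 40:60] <- 255L * 257L
  region <- matrix(FALSE, 128, 128); region[1:16, 1:16] <- TRUE
  img8 <- convert_to_8bit(img, 0, 65535)
  m16 <- threshold_mask(img, estimate_background(img, region), 2)
  m8 <- threshold_mask(img8, estimate_background(img8, region), 2)
  expect_identical(m16$pixels, m8$pixels)
})

test_that("binary opening cleans specks, preserves solids, and is anti-extensive", {
  speck <- matrix(FALSE, 32, 32)
  speck[cbind(c(3, 10, 20, 28), c(5, 15, 7, 30))] <- TRUE
  out <- morphological_clean(binary_mask(speck), "auto", 50)
  expect_equal(sum(out$pixels), 0)
  expect_equal(out$provenance$morphology_iterations, 1)

  sq <- matrix(FALSE, 32, 32); sq[6:25, 6:25] <- TRUE
  op1 <- morphological_clean(binary_mask(sq), 1, 50)
  expect_identical(op1$pixels, brute_open(sq, 1)) # vs independent brute force
  expect_gte(sum(op1$pixels), 400 * 0.96)
  expect_true(all(sq[op1$pixels])) # anti-extensive: subset of input

  ident <- morphological_clean(binary_mask(sq), 0, 50)
  expect_identical(ident$pixels, sq)
  expect_error(morphological_clean(binary_mask(sq), -1, 50), "nonnegative")
})

test_that("strict area filter keeps only components above the bound", {
  m <- matrix(FALSE, 40, 60)
  m[2:8, 2:8] <- TRUE          # 49
  m[12:21, 12:16] <- TRUE      # 50
  m[2:18, 30:32] <- TRUE       # 51
  m[25:32, 40:47] <- TRUE      # 64
  cl <- detect_clusters(binary_mask(m), 50, 1)
  expect_equal(nrow(cl), 2)
  expect_equal(sort(cl$area_px2), c(51, 64))
  expect_equal(cl$area_px2, c(64, 51)) # ordered by descending area
  # raising the bound never increases the count
  ns <- vapply(c(0, 49, 50, 51, 64), function(a)
    nrow(detect_clusters(binary_mask(m), a, 1)), numeric(1))
  expect_true(all(diff(ns) <= 0))
})

test_that("equivalent diameter follows the circular formula", {
  # one disk of area ~78.54 px^2 at 1 mm/px has diameter ~10 mm
  m <- matrix(FALSE, 30, 30)
  xy <- expand.grid(r = 1:30, c = 1:30)
  m[as.matrix(xy[(xy$r - 15)^2 + (xy$c - 15)^2 <= 5^2, ])] <- TRUE
  cl <- detect_clusters(binary_mask(m), 50, 1)
  expect_equal(cl$diameter_mm, 2 * sqrt(cl$area_mm2 / pi))
  expect_lt(abs(cl$diameter_mm - 10), 0.25) # digitized disk of radius 5
})

test_that("labeling is 8-connected and areas partition the foreground", {
  m <- matrix(FALSE, 6, 6)
  m[cbind(c(1, 2, 3), c(1, 2, 3))] <- TRUE # pure diagonal chain
  expect_equal(max(label_components(m)), 1)
  expect_equal(max(label_components_bruteforce(m)), 1)

  set.seed(31)
  m2 <- matrix(runif(64^2) < 0.25, 64, 64)
  cl <- detect_clusters(binary_mask(m2), 0, 1)
  lab <- attr(cl, "label_matrix")
  expect_equal(sum(cl$area_px2), sum(lab > 0))
  expect_equal(sum(lab > 0), sum(m2))
})

test_that("main labeling agrees exactly with the brute-force flood-fill oracle", {
  set.seed(7)
  for (i in 1:25) {
    m <- matrix(runif(96^2) < 0.1, 96, 96)
    a <- label_components(m)
    b <- label_components_bruteforce(m)
    expect_equal(max(a), max(b))
    expect_equal(label_areas(a), label_areas(b))
    # same partition: labels correspond one-to-one
    expect_true(all(tapply(b[m], a[m], function(v) length(unique(v))) == 1))
  }
})
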