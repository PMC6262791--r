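test_that("roundness matches the fitted-ellipse shape descriptor", {
  # a rasterized circle has roundness 1.0
  circle <- make_ellipse_mask(40, 40, 0, pixel_size = 1)
  expect_lt(abs(roundness(circle) - 1.0), 0.02)

  # exact ellipses: roundness = minor/major (+/- 0.02 discretization)
  expect_lt(abs(roundness(make_ellipse_mask(40, 20, 0, pixel_size = 1)) - 0.5), 0.02)
  expect_lt(abs(roundness(make_ellipse_mask(60, 12, 35, pixel_size = 1)) - 0.2), 0.02)

  # degenerate (collinear) region
  line <- matrix(FALSE, 30, 30); line[5:25, 10] <- TRUE
  expect_error(roundness(region_mask(line)), "degenerate|collinear")
})

test_that("roundness of rasterized ellipses converges with resolution", {
  coarse <- abs(roundness(make_ellipse_mask(40, 16, 25, pixel_size = 1)) - 0.4)
  fine <- abs(roundness(make_ellipse_mask(40, 16, 25, pixel_size = 0.25)) - 0.4)
  expect_lte(fine, max(coarse, 0.005))
})

test_that("elongation angle recovers planted orientations, folded axially", {
  expect_equal(elongation_angle(make_ellipse_mask(40, 10, 0, pixel_size = 0.5)),
               0, tolerance = 1)
  expect_equal(elongation_angle(make_ellipse_mask(40, 10, 30, pixel_size = 0.5)),
               30, tolerance = 1)
  # 120 degrees folds to -60 (axial data)
  expect_equal(elongation_angle(make_ellipse_mask(40, 10, 120, pixel_size = 0.5)),
               -60, tolerance = 1)
  # angle is measured against the supplied AP axis
  m <- make_ellipse_mask(40, 10, 30, pixel_size = 0.5)
  rotated_ap <- region_mask(m$mask, m$pixel_size, ap_axis = c(0, 1))
  expect_equal(elongation_angle(rotated_ap), 30 - 90, tolerance = 1)
  # near-circular regions are flagged
  expect_warning(elongation_angle(make_ellipse_mask(30, 30, 0, pixel_size = 0.5)),
                 "unstable")
})

test_that("shape measurements are invariant under translation and 180-deg rotation", {
  m <- make_ellipse_mask(36, 14, 40, pixel_size = 0.5, shape = c(120, 120),
                         center = c(25, 25))
  shifted <- make_ellipse_mask(36, 14, 40, pixel_size = 0.5, shape = c(120, 120),
                               center = c(32, 29))
  expect_equal(roundness(shifted), roundness(m), tolerance = 0.01)
  expect_equal(elongation_angle(shifted), elongation_angle(m), tolerance = 0.5)
  # a 180-degree rotation of the mask array maps the ellipse onto itself
  flipped <- region_mask(m$mask[nrow(m$mask):1, ncol(m$mask):1],
                         m$pixel_size, m$ap_axis)
  expect_equal(roundness(flipped), roundness(m), tolerance = 1e-9)
  expect_equal(axial_dist(elongation_angle(flipped), elongation_angle(m)), 0,
               tolerance = 0.5)
})

test_that("fissure opening angle is the interior ray angle in degrees", {
  expect_equal(fissure_angle(c(0, 0), c(1, 0), c(0, 1)), 90)
  expect_equal(fissure_angle(c(0, 0), c(1, 0), c(-1, 0)), 180)
  # inverse construction at the wild-type mean opening scale
  expect_equal(fissure_angle(c(0, 0), c(1, 0), c(cos(19 * pi / 180), sin(19 * pi / 180))),
               19, tolerance = 1e-9)
  expect_error(fissure_angle(c(0, 0), c(0, 0), c(1, 1)), "vertex")
})

test_that("AP extent and reporter midpoint fractions are plain interval ratios", {
  expect_equal(ap_extent_fraction(c(0, 120), c(0, 120))$fraction, 1.0)
  expect_equal(ap_extent_fraction(c(10, 40), c(0, 120))$fraction, 0.25)
  expect_equal(ap_extent_fraction(c(15, 15), c(0, 120))$fraction, 0)
  expect_error(ap_extent_fraction(c(40, 10), c(0, 120)), "inverted")

  expect_equal(reporter_midpoint_fraction(200, 200, 200), 1.0)
  expect_equal(reporter_midpoint_fraction(40, 60, 200), 0.25)
  expect_equal(reporter_midpoint_fraction(0, 0, 200), 0)
  expect_error(reporter_midpoint_fraction(-1, 10, 100), ">= 0")
})

test_that("quarter intensity ratio follows the profile-quarters procedure", {
  # uniform image -> exactly 1
  img <- matrix(180, 60, 120)
  expect_equal(quarter_intensity_ratio(img, c(9, 1, 44, 120)), 1)

  # anterior quarter at 200, posterior at 100 -> 2
  img2 <- matrix(0, 60, 100)
  img2[, 1:25] <- 200; img2[, 76:100] <- 100
  expect_equal(quarter_intensity_ratio(img2, c(9, 1, 44, 100)), 2)

  # linear AP gradient 0..99 over 100 rows: mean(0..24)/mean(75..99) = 12/87
  img3 <- matrix(rep(0:99, each = 60), 60, 100)
  expect_equal(quarter_intensity_ratio(img3, c(9, 1, 44, 100)), 12 / 87)

  # invariant under uniform intensity scaling
  expect_equal(quarter_intensity_ratio(img3 * 2.5, c(9, 1, 44, 100)), 12 / 87)

  # remainder rows are assigned to the middle: outer quarters are floor(n/4)
  img4 <- matrix(rep(c(rep(10, 2), rep(0, 6), rep(5, 2)), each = 50), 50, 10)
  expect_equal(quarter_intensity_ratio(img4, c(1, 1, 44, 10), rect_width_px = 44),
               2)

  expect_error(quarter_intensity_ratio(img, c(30, 1, 44, 120)), "outside")
  expect_error(quarter_intensity_ratio(img, c(9, 1, 40, 120)), "differs")
  zero <- matrix(0, 60, 100); zero[, 1:25] <- 7
  expect_warning(r <- quarter_intensity_ratio(zero, c(9, 1, 44, 100)), "undefined")
  expect_true(is.nan(r))
})

test_that("label volumes use voxel count times dx^2*dz and conserve totals", {
  a <- array(0L, c(20, 10, 5))
  a[1:10, 1:10, 1:2] <- 1L          # cup-like: 200 voxels... (10*10*2)
  a[11:20, 1:5, 1] <- 2L            # stalk-like: 50 voxels
  lv <- label_volumes(a, spacing = c(1, 2))
  expect_equal(lv$volume_um3[lv$label == 1L], 200 * 1 * 2)
  expect_equal(lv$relative_volume[lv$label == 2L], 50 / 250)

  # single 1000-voxel label at dx=1, dz=2 -> 2000 um^3
  b <- array(1L, c(10, 10, 10))
  expect_equal(label_volumes(b, c(1, 2))$volume_um3, 2000)

  # planted synthetic labels match the generator truth exactly
  lvx <- make_labeled_volume(list(list(label = 3L, voxels = cbind(1:7, 2, 2)),
                                  list(label = 9L, voxels = cbind(8:9, 5, 3))),
                             shape = c(12, 8, 4), spacing = c(0.692, 2.1))
  got <- label_volumes(lvx$labels, lvx$spacing)
  expect_equal(got$volume_um3, lvx$truth$volume_um3)

  # conservation: labeled + background = whole grid volume
  set.seed(3)
  r <- array(sample(0:3, 600, replace = TRUE), c(10, 12, 5))
  lr <- label_volumes(r, spacing = c(0.7, 2.1))
  background <- sum(r == 0) * 0.7^2 * 2.1
  expect_equal(sum(lr$volume_um3) + background, prod(dim(r)) * 0.7^2 * 2.1)

  expect_equal(nrow(label_volumes(array(0L, c(4, 4, 2)), c(1, 1))), 0L)
})
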