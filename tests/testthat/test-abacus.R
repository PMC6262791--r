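test_that("Hi-Lo rescaling anchors background at 0 and ceiling just below saturation", {
  g <- voxel_grid(array(c(10, 50, 130, 200), c(4, 1, 1)), dx = 1, dz = 2)
  out <- rescale_hi_lo(g, background = 10, ceiling = 130)
  # hand linear map: (50-10) * 254/120 = 84.67 -> 84 under floor rounding
  expect_equal(as.vector(out$data), c(0, 84, 254, 254))

  # uniform grid at background level -> all zeros
  u <- voxel_grid(array(37, c(5, 4, 3)), dx = 1, dz = 1)
  expect_true(all(rescale_hi_lo(u, 37, 200)$data == 0))

  # full-range identity-ish map: max input goes to 254, not 255
  f <- voxel_grid(array(c(0, 255), c(2, 1, 1)), dx = 1, dz = 1)
  expect_equal(as.vector(rescale_hi_lo(f, 0, 255)$data), c(0, 254))

  expect_error(rescale_hi_lo(g, 130, 130), "background")
  expect_error(rescale_hi_lo(g, 0, 300), "bit-depth")
})

test_that("anisotropic smoothing has the right per-axis widths and conserves intensity", {
  # delta impulse: output second moments match (sxy^2, sxy^2, sz^2)
  n <- 41; nz <- 21
  a <- array(0, c(n, n, nz)); a[21, 21, 11] <- 255
  g <- voxel_grid(a, dx = 0.7, dz = 2.1)
  sm <- smooth_anisotropic(g, sigma_xy = 3)$data  # sigma_z = 3 * 0.7/2.1 = 1 voxel
  w <- sm / sum(sm)
  m2 <- function(axis) {
    idx <- slice.index(w, axis)
    ctr <- sum(w * idx)
    sum(w * (idx - ctr)^2)
  }
  expect_equal(m2(1), 9, tolerance = 0.01)
  expect_equal(m2(2), 9, tolerance = 0.01)
  expect_equal(m2(3), 1, tolerance = 0.01)
  # total intensity conserved (interior-dominated image)
  expect_equal(sum(sm), 255, tolerance = 0.001 * 255)

  # constant image is a fixed point of the normalized filter
  u <- voxel_grid(array(123, c(12, 10, 8)), dx = 0.692, dz = 2.1)
  expect_equal(smooth_anisotropic(u, 2)$data, u$data, tolerance = 1e-12)

  # micrometre sigma input converts through dx
  g2 <- voxel_grid(a, dx = 0.5, dz = 2.1)
  s_vox <- smooth_anisotropic(g2, sigma_xy = 3)$data
  s_um <- smooth_anisotropic(g2, sigma_xy = 1.5, units = "um")$data
  expect_equal(s_vox, s_um, tolerance = 1e-12)
})

test_that("a noiseless planted blob is found once, near its true center", {
  nf <- nucleus_field(x = 6.92, y = 8.304, z = 8.4, sigma = 2, amplitude = 200)
  v <- make_nuclei_volume(nf, shape = c(30, 30, 12), spacing = c(0.692, 2.1))
  cs <- find_nuclei(v$green, abacus_params(sigma_xy = 2, L = 12, h = 20))
  expect_equal(nrow(cs), 1L)
  expect_lt(abs(cs$x - 6.92), 0.692)
  expect_lt(abs(cs$y - 8.304), 0.692)
  expect_lt(abs(cs$z - 8.4), 2.1)
  expect_gte(cs$peak, 12)
})

test_that("two blobs merge below the saddle depth and split above it", {
  # two equal blobs 3 sigma apart; measure the actual saddle depth of the
  # smoothed, thresholded stack by scanning the line between the peaks
  sep <- 6; sg <- 2
  nf <- nucleus_field(x = c(10, 10 + sep), y = 10, z = 6, sigma = sg, amplitude = 200)
  v <- make_nuclei_volume(nf, shape = c(40, 26, 7), spacing = c(1, 2))
  L <- 12
  sm <- smooth_anisotropic(v$green, 1.5)$data
  sm[sm < L] <- 0
  prof <- sm[, 11, 4]                       # line through both centers
  i1 <- 11; i2 <- 11 + sep                  # voxel indices of the two peaks
  peaks <- range(sm[c(i1, i2), 11, 4])
  saddle <- min(prof[i1:i2])
  depth <- peaks[1] - saddle                # dynamic of the weaker maximum
  expect_gt(depth, 5)                       # fixture sanity: a real saddle

  p_split <- abacus_params(sigma_xy = 1.5, L = L, h = max(depth * 0.5, 1))
  p_merge <- abacus_params(sigma_xy = 1.5, L = L, h = depth * 1.5)
  expect_equal(nrow(find_nuclei(v$green, p_split)), 2L)
  expect_equal(nrow(find_nuclei(v$green, p_merge)), 1L)
})

test_that("degenerate stacks yield empty results, not errors", {
  flat <- voxel_grid(array(5, c(10, 10, 4)), dx = 1, dz = 2)
  # everything below L
  expect_equal(nrow(find_nuclei(flat, abacus_params(1, L = 50, h = 5))), 0L)
  # h at/above the dynamic range
  nf <- nucleus_field(x = 5, y = 5, z = 4, sigma = 1.5, amplitude = 100)
  v <- make_nuclei_volume(nf, shape = c(12, 12, 5), spacing = c(1, 2))
  expect_warning(cs <- find_nuclei(v$green, abacus_params(1, L = 5, h = 255)),
                 "dynamic range")
  expect_equal(nrow(cs), 0L)
})

test_that("ROI counting uses nearest-voxel membership and checks congruence", {
  nf <- sample_nucleus_field(10, shape = c(60, 60, 20), spacing = c(1, 2),
                             sigma = 1.5, min_sep = 10, margin = 5, seed = 42)
  v <- make_nuclei_volume(nf, shape = c(60, 60, 20), spacing = c(1, 2))
  cs <- find_nuclei(v$green, abacus_params(sigma_xy = 1.5, L = 12, h = 20))
  expect_equal(nrow(cs), 10L)

  whole <- array(TRUE, c(60, 60, 20))
  expect_equal(count_in_roi(cs, whole), 10L)
  expect_equal(count_in_roi(cs, array(FALSE, c(60, 60, 20))), 0L)

  # ROI = left half of the volume: count must equal the planted truth there
  roi <- array(FALSE, c(60, 60, 20))
  roi[1:30, , ] <- TRUE
  expected <- sum(nf$x <= 29 * 1)          # planted centers in the half-space
  expect_equal(count_in_roi(cs, roi), expected)

  expect_error(count_in_roi(cs, array(TRUE, c(10, 10, 4))), "does not match")
})

test_that("counts are monotone non-increasing in h and in L", {
  nf <- sample_nucleus_field(15, shape = c(80, 80, 20), spacing = c(1, 2),
                             sigma = 1.5, min_sep = 8, margin = 4, seed = 7)
  v <- make_nuclei_volume(nf, shape = c(80, 80, 20), spacing = c(1, 2),
                          noise_sd = 4, seed = 7)
  counts_h <- vapply(c(5, 15, 30, 60, 90), function(h)
    nrow(suppressWarnings(find_nuclei(v$green, abacus_params(1.5, L = 10, h = h)))),
    numeric(1))
  expect_true(all(diff(counts_h) <= 0))
  counts_L <- vapply(c(0, 10, 30, 60, 100), function(L)
    nrow(find_nuclei(v$green, abacus_params(1.5, L = L, h = 10))), numeric(1))
  expect_true(all(diff(counts_L) <= 0))
})

test_that("extended maxima match the level-set oracle on small random grids", {
  # a quick cross-check per connectivity; the full 200-grid sweep lives in
  # the acceptance suite
  for (conn in c(6L, 26L)) {
    for (seed in 1:10) {
      f <- random_grid(seed + 100 * (conn == 26L))
      h <- sample(1:6, 1)
      got <- extended_maxima(f, h, connectivity = conn)
      want <- oracle_extended_maxima(f, h, conn)
      expect_identical(got$mask, want$mask,
                       label = sprintf("mask (seed %d conn %d)", seed, conn))
      expect_true(same_partition(got$labels, want$labels),
                  label = sprintf("partition (seed %d conn %d)", seed, conn))
    }
  }
})

test_that("grayscale reconstruction matches the threshold-decomposition oracle", {
  for (seed in 1:8) {
    f <- random_grid(seed + 500)
    h <- sample(1:8, 1)
    rec <- grey_reconstruct(f - h, f, connectivity = 26)
    expect_equal(rec, oracle_reconstruct(f, h, 26))
  }
})

test_that("doubling dz on a z-halved grid of the same scene preserves counts", {
  nf <- sample_nucleus_field(12, shape = c(70, 70, 48), spacing = c(1, 1.05),
                             sigma = 2, min_sep = 12, margin = 6, seed = 3)
  fine <- make_nuclei_volume(nf, shape = c(70, 70, 48), spacing = c(1, 1.05))
  coarse <- make_nuclei_volume(nf, shape = c(70, 70, 24), spacing = c(1, 2.1))
  p <- abacus_params(sigma_xy = 2, L = 12, h = 25)
  expect_equal(nrow(find_nuclei(fine$green, p)), 12L)
  expect_equal(nrow(find_nuclei(coarse$green, p)), 12L)
})
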