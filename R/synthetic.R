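# Synthetic ground-truth generators. Every input the quantification pipeline
# consumes can be produced here with known truth: nucleus fields rendered as
# Gaussian intensity blobs on anisotropic voxel grids, elongated cell
# outlines at controlled orientations, piecewise-linear 3D trajectories
# sampled at fixed time steps, and multi-label tissue volumes.

#' Specify a field of synthetic nuclei
#'
#' @param x,y,z nucleus centers, micrometres (0-based pixel-center frame).
#' @param sigma isotropic intensity spread of each nucleus, micrometres
#'   (recycled).
#' @param amplitude peak gray value of each nucleus (recycled).
#' @param channel `"green"` or `"red"` per nucleus (recycled).
#' @return data frame with one row per nucleus.
#' @export
nucleus_field <- function(x, y, z, sigma = 2, amplitude = 200, channel = "green") {
  if (length(x) == 0L)
    return(data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                      sigma = numeric(0), amplitude = numeric(0),
                      channel = character(0), stringsAsFactors = FALSE))
  df <- data.frame(x = x, y = y, z = z, sigma = sigma,
                   amplitude = amplitude, channel = channel,
                   stringsAsFactors = FALSE)
  if (any(df$sigma <= 0)) stop("`sigma` must be > 0")
  if (any(df$amplitude <= 0)) stop("`amplitude` must be > 0")
  if (!all(df$channel %in% c("green", "red")))
    stop("`channel` must be \"green\" or \"red\"")
  df
}

#' Sample well-separated random nucleus positions
#'
#' Rejection-samples centers with a minimum pairwise distance (default
#' `6 * sigma`, at which Gaussian blobs do not interact) and a margin from
#' the volume borders, emulating a dispersed nuclear field.
#'
#' @param n number of nuclei.
#' @param shape voxel counts `c(nx, ny, nz)`.
#' @param spacing `c(dx, dz)` micrometres.
#' @param sigma blob spread, micrometres.
#' @param amplitude peak gray value (scalar or length-n).
#' @param channel channel label(s), recycled.
#' @param min_sep minimum pairwise center distance, micrometres.
#' @param margin distance kept from every border, micrometres.
#' @param seed RNG seed.
#' @return a [nucleus_field()] data frame.
#' @export
sample_nucleus_field <- function(n, shape, spacing = c(0.692, 2.1), sigma = 2,
                                 amplitude = 200, channel = "green",
                                 min_sep = 6 * sigma, margin = 4 * sigma,
                                 seed = NULL) {
  ext <- c((shape[1] - 1) * spacing[1], (shape[2] - 1) * spacing[1],
           (shape[3] - 1) * spacing[2])
  if (any(ext <= 2 * margin)) stop("volume too small for the requested margin")
  with_seed(seed, {
    pts <- matrix(NA_real_, n, 3)
    placed <- 0L
    attempts <- 0L
    while (placed < n) {
      attempts <- attempts + 1L
      if (attempts > 2000L * n)
        stop("could not place nuclei at the requested separation; lower `n` or `min_sep`")
      p <- margin + stats::runif(3) * (ext - 2 * margin)
      if (placed == 0L ||
          min(sqrt(colSums((t(pts[seq_len(placed), , drop = FALSE]) - p)^2))) > min_sep) {
        placed <- placed + 1L
        pts[placed, ] <- p
      }
    }
    nucleus_field(pts[, 1], pts[, 2], pts[, 3], sigma = sigma,
                  amplitude = amplitude, channel = channel)
  })
}

#' Render a synthetic nucleus volume
#'
#' Renders each nucleus as an isotropic (in physical units) 3D Gaussian
#' intensity blob sampled on the anisotropic voxel grid, adds zero-mean
#' Gaussian noise, rounds to integer gray values and clips to the 8-bit
#' range. Channels are rendered independently with no bleed-through.
#' Identical inputs and seed yield bit-identical volumes.
#'
#' @param nuclei a [nucleus_field()] data frame.
#' @param shape voxel counts `c(nx, ny, nz)`.
#' @param spacing `c(dx, dz)` micrometres (default the study's confocal
#'   geometry, 0.692 and 2.1).
#' @param noise_sd additive Gaussian noise s.d., gray-value units.
#' @param seed RNG seed for the noise.
#' @return named list of [voxel_grid()]s, one per channel present (in
#'   `green`, `red` order); the `nuclei` table, `spacing`, `noise_sd` and
#'   `seed` are attached as attribute `truth`.
#' @examples
#' nf <- nucleus_field(x = 10, y = 10, z = 10, sigma = 2, amplitude = 200)
#' v <- make_nuclei_volume(nf, shape = c(32, 32, 12), spacing = c(1, 2), noise_sd = 0)
#' max(v$green$data)
#' @export
make_nuclei_volume <- function(nuclei, shape, spacing = c(0.692, 2.1),
                               noise_sd = 0, seed = NULL) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 1L)) stop("`shape` must be 3 positive voxel counts")
  dx <- spacing[1]; dz <- spacing[2]
  ext <- c((shape[1] - 1) * dx, (shape[2] - 1) * dx, (shape[3] - 1) * dz)
  if (nrow(nuclei)) {
    out_of_bounds <- which(nuclei$x < 0 | nuclei$x > ext[1] |
                           nuclei$y < 0 | nuclei$y > ext[2] |
                           nuclei$z < 0 | nuclei$z > ext[3])
    if (length(out_of_bounds))
      stop(sprintf("nucleus %s outside the volume bounds",
                   paste(out_of_bounds, collapse = ", ")))
  }
  xs <- (seq_len(shape[1]) - 1) * dx
  ys <- (seq_len(shape[2]) - 1) * dx
  zs <- (seq_len(shape[3]) - 1) * dz
  channels <- intersect(c("green", "red"), unique(nuclei$channel))
  if (!length(channels)) channels <- "green"
  grids <- with_seed(seed, {
    out <- list()
    for (ch in channels) {
      a <- array(0, shape)
      sel <- which(nuclei$channel == ch)
      for (i in sel) {
        s <- nuclei$sigma[i]
        # render within +/- 4 sigma to keep cost proportional to blob size
        ix <- which(abs(xs - nuclei$x[i]) <= 4 * s)
        iy <- which(abs(ys - nuclei$y[i]) <= 4 * s)
        iz <- which(abs(zs - nuclei$z[i]) <= 4 * s)
        if (!length(ix) || !length(iy) || !length(iz)) next
        gx <- exp(-(xs[ix] - nuclei$x[i])^2 / (2 * s^2))
        gy <- exp(-(ys[iy] - nuclei$y[i])^2 / (2 * s^2))
        gz <- exp(-(zs[iz] - nuclei$z[i])^2 / (2 * s^2))
        blob <- nuclei$amplitude[i] * (gx %o% gy %o% gz)
        a[ix, iy, iz] <- a[ix, iy, iz] + blob
      }
      if (noise_sd > 0)
        a <- a + stats::rnorm(length(a), sd = noise_sd)
      a <- round(a)
      a[a < 0] <- 0
      a[a > 255] <- 255
      out[[ch]] <- voxel_grid(a, dx = dx, dz = dz, bit_depth = 8L)
    }
    out
  })
  attr(grids, "truth") <- list(nuclei = nuclei, spacing = spacing,
                               noise_sd = noise_sd, seed = seed)
  grids
}

#' Rasterize a rotated filled ellipse as a 2D cell mask
#'
#' Fixture for the shape measurements: a filled ellipse of known axes and
#' orientation. The recorded truth is roundness `minor/major` and the
#' orientation folded into the axial range `[-90, 90)` degrees. Angles are
#' measured from the anterior-posterior axis (`ap_axis`, default the image
#' x direction), positive rotating towards the image +y direction.
#'
#' @param major,minor full axis lengths, micrometres (`major >= minor > 0`).
#' @param angle_deg orientation of the major axis vs the AP axis, degrees.
#' @param pixel_size micrometres per pixel.
#' @param shape pixel counts `c(nx, ny)`; default is sized to fit the
#'   ellipse with a 2-pixel border.
#' @param center ellipse center in micrometres; default the image center.
#' @return a [region_mask()] with attributes `roundness_true` and
#'   `angle_true`.
#' @examples
#' m <- make_ellipse_mask(major = 40, minor = 20, angle_deg = 30, pixel_size = 0.5)
#' attr(m, "roundness_true")
#' @export
make_ellipse_mask <- function(major, minor, angle_deg, pixel_size = 1,
                              shape = NULL, center = NULL) {
  if (!(major >= minor && minor > 0)) stop("need major >= minor > 0")
  if (is.null(shape)) {
    npx <- ceiling(major / pixel_size) + 5L
    shape <- c(npx, npx)
  }
  shape <- as.integer(shape)
  if (is.null(center))
    center <- c((shape[1] - 1) / 2, (shape[2] - 1) / 2) * pixel_size
  xs <- (seq_len(shape[1]) - 1) * pixel_size - center[1]
  ys <- (seq_len(shape[2]) - 1) * pixel_size - center[2]
  A <- angle_deg * pi / 180
  X <- matrix(xs, shape[1], shape[2])
  Y <- matrix(ys, shape[1], shape[2], byrow = TRUE)
  u <- cos(A) * X + sin(A) * Y
  v <- -sin(A) * X + cos(A) * Y
  inside <- (u / (major / 2))^2 + (v / (minor / 2))^2 <= 1
  if (any(inside[1, ]) || any(inside[shape[1], ]) ||
      any(inside[, 1]) || any(inside[, shape[2]]))
    stop("ellipse is clipped by the image border; enlarge `shape`")
  if (!any(inside)) stop("ellipse rasterized to an empty mask; decrease `pixel_size`")
  m <- region_mask(inside, pixel_size = pixel_size)
  attr(m, "roundness_true") <- minor / major
  attr(m, "angle_true") <- fold_axial(angle_deg)
  m
}

#' Sample a trajectory along a waypoint polyline
#'
#' Samples `n_samples` points at near-constant speed along the polyline
#' through `waypoints`, timestamps them at multiples of `dt`, and adds
#' isotropic Gaussian positional jitter. Whole sampling intervals are
#' allocated to segments (proportionally to their length), so every
#' waypoint is itself a sample and the noiseless sampled path length
#' equals the polyline length exactly; this requires
#' `n_samples > number of segments`. The polyline length and net
#' displacement are recorded as truth.
#'
#' @param waypoints numeric matrix, one 3D point (micrometres) per row,
#'   at least 2 rows.
#' @param dt sampling interval, minutes (default 2.75, the study's
#'   z-stack interval).
#' @param n_samples number of samples along the path (>= 2 and greater
#'   than the number of polyline segments).
#' @param noise_sd positional jitter s.d. per coordinate, micrometres.
#' @param seed RNG seed.
#' @param track_id identifier stored with the trajectory.
#' @return a [trajectory()] with attribute `truth` (list with
#'   `path_length`, `net_displacement`, `waypoints`, `noise_sd`, `seed`).
#' @export
make_trajectory <- function(waypoints, dt = 2.75, n_samples = 11L,
                            noise_sd = 0, seed = NULL, track_id = "synthetic") {
  waypoints <- as.matrix(waypoints)
  if (ncol(waypoints) != 3L || nrow(waypoints) < 2L)
    stop("`waypoints` must be an n x 3 matrix with n >= 2")
  if (n_samples < 2L) stop("`n_samples` must be >= 2")
  if (dt <= 0) stop("`dt` must be > 0")
  seg <- diff(waypoints)
  seg_len <- sqrt(rowSums(seg^2))
  if (any(seg_len == 0)) stop("consecutive waypoints coincide")
  total <- sum(seg_len)
  n_seg <- length(seg_len)
  steps <- n_samples - 1L
  if (steps < n_seg)
    stop("`n_samples` must exceed the number of polyline segments")
  # largest-remainder allocation of sampling intervals to segments
  q <- steps * seg_len / total
  n_i <- pmax(floor(q), 1)
  while (sum(n_i) > steps) {
    i <- which.max(ifelse(n_i > 1, n_i - q, -Inf))
    n_i[i] <- n_i[i] - 1
  }
  while (sum(n_i) < steps) {
    i <- which.max(q - n_i)
    n_i[i] <- n_i[i] + 1
  }
  pts <- waypoints[1, , drop = FALSE]
  for (i in seq_len(n_seg)) {
    f <- seq_len(n_i[i]) / n_i[i]
    pts <- rbind(pts, sweep(outer(f, seg[i, ]), 2, waypoints[i, ], "+"))
  }
  pts <- with_seed(seed, {
    if (noise_sd > 0) pts + matrix(stats::rnorm(length(pts), sd = noise_sd),
                                   nrow(pts), 3) else pts
  })
  tr <- trajectory(track_id = track_id, t = (seq_len(n_samples) - 1) * dt,
                   x = pts[, 1], y = pts[, 2], z = pts[, 3])
  attr(tr, "truth") <- list(
    path_length = total,
    net_displacement = sqrt(sum((waypoints[nrow(waypoints), ] - waypoints[1, ])^2)),
    waypoints = waypoints, dt = dt, noise_sd = noise_sd, seed = seed)
  tr
}

#' Build a labeled tissue volume with known per-label volumes
#'
#' @param regions list of `list(label = <positive integer>, voxels = <m x 3
#'   integer matrix of voxel indices>)`; voxel sets must be disjoint.
#' @param shape voxel counts `c(nx, ny, nz)`.
#' @param spacing `c(dx, dz)` micrometres.
#' @return list with `labels` (integer 3D array) and `truth` (data frame
#'   `label`, `n_voxels`, `volume_um3` where volume = count * dx^2 * dz).
#' @export
make_labeled_volume <- function(regions, shape, spacing = c(0.692, 2.1)) {
  shape <- as.integer(shape)
  arr <- array(0L, shape)
  truth <- data.frame(label = integer(0), n_voxels = integer(0),
                      volume_um3 = numeric(0))
  for (rg in regions) {
    if (rg$label <= 0) stop("labels must be positive integers")
    vox <- as.matrix(rg$voxels)
    if (any(vox < 1) || any(vox[, 1] > shape[1]) || any(vox[, 2] > shape[2]) ||
        any(vox[, 3] > shape[3]))
      stop("voxel indices outside the volume")
    if (any(arr[vox] != 0L))
      stop(sprintf("label %d overlaps a previously placed label", rg$label))
    arr[vox] <- as.integer(rg$label)
    truth <- rbind(truth, data.frame(
      label = as.integer(rg$label), n_voxels = nrow(vox),
      volume_um3 = nrow(vox) * spacing[1]^2 * spacing[2]))
  }
  list(labels = arr, spacing = spacing, truth = truth)
}
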