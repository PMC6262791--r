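#' Parameters of the 3D nucleus counting algorithm
#'
#' Bundles the tunables of the counting pipeline: in-plane smoothing scale,
#' background threshold, minimum maxima height, and voxel connectivity. The
#' z smoothing scale is never set directly -- it is derived from the grid it
#' is applied to as `sigma_z = sigma_xy * (dx / dz)` (voxel units), i.e. the
#' smoothing is isotropic in physical space.
#'
#' There are no universal defaults for `sigma_xy`, `L` and `h`: in the
#' original workflow they are tuned per dataset by overlaying detected
#' centroids on intensity isosurfaces and adjusting until they match. This
#' package treats them as required configuration.
#'
#' @param sigma_xy in-plane Gaussian standard deviation; xy-voxel units by
#'   default (`sigma_units = "um"` accepts micrometres and converts using
#'   the grid's `dx` at apply time).
#' @param L gray-value threshold; voxels of the smoothed stack below `L` are
#'   set to zero to eliminate background noise.
#' @param h minimum height (dynamic) a regional maximum must have, gray
#'   value units.
#' @param connectivity voxel neighborhood for maxima and component labeling:
#'   6, 18 or 26 (default 26, the full 3D neighborhood, which merges
#'   diagonal plateaus and avoids double counting).
#' @param sigma_units `"voxel"` (default) or `"um"`.
#' @return an object of class `abacus_params`.
#' @examples
#' abacus_params(sigma_xy = 3, L = 12, h = 8)
#' @export
abacus_params <- function(sigma_xy, L, h, connectivity = 26L,
                          sigma_units = c("voxel", "um")) {
  sigma_units <- match.arg(sigma_units)
  if (!is.numeric(sigma_xy) || length(sigma_xy) != 1L || sigma_xy <= 0)
    stop("`sigma_xy` must be a positive scalar")
  if (!is.numeric(L) || length(L) != 1L || L < 0)
    stop("`L` must be a nonnegative gray value")
  if (!is.numeric(h) || length(h) != 1L || h <= 0)
    stop("`h` must be a positive gray value")
  connectivity <- as.integer(connectivity)
  if (!connectivity %in% c(6L, 18L, 26L))
    stop("`connectivity` must be 6, 18 or 26")
  structure(list(sigma_xy = sigma_xy, L = L, h = h,
                 connectivity = connectivity, sigma_units = sigma_units),
            class = "abacus_params")
}

#' @export
print.abacus_params <- function(x, ...) {
  cat(sprintf("<abacus_params> sigma_xy = %g %s, L = %g, h = %g, connectivity = %d\n",
              x$sigma_xy, x$sigma_units, x$L, x$h, x$connectivity))
  invisible(x)
}

#' Hi-Lo linear rescaling of a stack
#'
#' Preprocessing step mirroring the Hi-Lo lookup-table adjustment: a linear
#' map that sends the background gray level to 0 and the chosen ceiling to
#' one below the bit-depth maximum (254 for 8-bit -- the brightest pixels
#' end up just below saturation), with clipping at both ends and floor
#' rounding to integer gray values.
#'
#' @param grid a [voxel_grid()].
#' @param background gray value mapped to 0.
#' @param ceiling gray value mapped to `2^bit_depth - 2`; must exceed
#'   `background` and not exceed the bit-depth maximum.
#' @return a rescaled `voxel_grid` of the same shape and spacing.
#' @examples
#' g <- voxel_grid(array(c(10, 50, 130, 200), c(4, 1, 1)), dx = 1, dz = 2)
#' rescale_hi_lo(g, background = 10, ceiling = 130)$data
#' @export
rescale_hi_lo <- function(grid, background, ceiling) {
  stopifnot_voxel_grid(grid)
  vmax <- 2^grid$bit_depth - 1
  if (background >= ceiling) stop("`background` must be < `ceiling`")
  if (ceiling > vmax) stop("`ceiling` exceeds the bit-depth maximum")
  out <- floor((grid$data - background) * (vmax - 1) / (ceiling - background))
  out[out < 0] <- 0
  out[out > vmax - 1] <- vmax - 1
  g <- grid
  g$data <- out
  g
}

# normalized 1D Gaussian kernel truncated at 4 sigma
gauss_kernel <- function(sigma) {
  r <- max(1L, as.integer(ceiling(4 * sigma)))
  k <- stats::dnorm(seq(-r, r), sd = sigma)
  k / sum(k)
}

# n x n convolution matrix with symmetric ("reflect": d c b a | a b c d)
# boundary handling; rows sum to 1 so constants are fixed points
conv_matrix_reflect <- function(n, k) {
  r <- (length(k) - 1L) %/% 2L
  M <- matrix(0, n, n)
  for (o in seq(-r, r)) {
    j <- seq_len(n) + o
    while (any(j < 1L | j > n)) j <- ifelse(j < 1L, 1L - j, ifelse(j > n, 2L * n + 1L - j, j))
    ij <- cbind(seq_len(n), j)
    M[ij] <- M[ij] + k[o + r + 1L]
  }
  M
}

filter_axis <- function(a, axis, sigma) {
  d <- dim(a)
  k <- gauss_kernel(sigma)
  M <- conv_matrix_reflect(d[axis], k)
  perm <- c(axis, setdiff(1:3, axis))
  ap <- aperm(a, perm)
  res <- M %*% matrix(ap, d[axis])
  res <- array(res, d[perm])
  aperm(res, order(perm))
}

#' Anisotropic 3D Gaussian smoothing
#'
#' Low-pass filters a z-stack with a separable 3D Gaussian whose standard
#' deviation in z is derived from the in-plane one via
#' `sigma_z = sigma_xy * (dx / dz)` (voxel units): because z-sections are
#' `dz/dx`-fold coarser than in-plane pixels, this makes the smoothing
#' isotropic in physical space. Boundary handling is symmetric reflection;
#' the kernel is normalized, so total intensity is conserved for
#' interior-dominated images and constant images are unchanged.
#'
#' @param grid a [voxel_grid()].
#' @param sigma_xy in-plane standard deviation (`units`).
#' @param units `"voxel"` (xy-voxel units, default) or `"um"`.
#' @return the smoothed `voxel_grid` (gray values no longer integer).
#' @export
smooth_anisotropic <- function(grid, sigma_xy, units = c("voxel", "um")) {
  stopifnot_voxel_grid(grid)
  units <- match.arg(units)
  if (!is.numeric(sigma_xy) || length(sigma_xy) != 1L || sigma_xy <= 0)
    stop("`sigma_xy` must be a positive scalar")
  s_xy <- if (units == "um") sigma_xy / grid$dx else sigma_xy
  s_z <- s_xy * grid$dx / grid$dz
  a <- filter_axis(grid$data, 1L, s_xy)
  a <- filter_axis(a, 2L, s_xy)
  a <- filter_axis(a, 3L, s_z)
  g <- grid
  g$data <- a
  g
}

empty_centroid_set <- function(grid) {
  structure(data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                       peak = numeric(0)),
            class = c("centroid_set", "data.frame"),
            grid_dim = dim(grid$data), dx = grid$dx, dz = grid$dz)
}

#' Detect nuclei in a 3D stack
#'
#' The core counting pipeline: anisotropic Gaussian smoothing
#' ([smooth_anisotropic()]), zeroing of voxels below the noise threshold
#' `L`, extended-maxima detection at minimum height `h`
#' ([extended_maxima()]), connected-component labeling at the configured
#' connectivity, and centroid extraction. Each maxima region yields one
#' nucleus; the centroid is the unweighted mean of the region's voxel
#' positions converted to micrometres, and the region's peak gray value
#' (of the smoothed, thresholded stack) is reported alongside.
#'
#' A stack that is entirely below `L` yields an empty result (no error);
#' `h` at or above the post-threshold dynamic range yields an empty result
#' with a warning.
#'
#' @param grid a [voxel_grid()], already rescaled (see [rescale_hi_lo()]).
#' @param params an [abacus_params()].
#' @return a `centroid_set`: data frame with columns `x`, `y`, `z`
#'   (micrometres, 0-based pixel-center coordinates) and `peak`, carrying
#'   the source grid geometry as attributes.
#' @export
find_nuclei <- function(grid, params) {
  stopifnot_voxel_grid(grid)
  if (!inherits(params, "abacus_params")) stop("`params` must be abacus_params")
  sm <- smooth_anisotropic(grid, params$sigma_xy, units = params$sigma_units)
  g <- sm$data
  g[g < params$L] <- 0
  if (all(g == 0)) return(empty_centroid_set(grid))
  if (params$h >= max(g) - min(g)) {
    warning("`h` is at or above the dynamic range of the thresholded stack; no maxima")
    return(empty_centroid_set(grid))
  }
  em <- extended_maxima(g, params$h, params$connectivity, floor = 0)
  if (em$n == 0L) return(empty_centroid_set(grid))
  idx <- which(em$mask)
  lab <- em$labels[idx]
  co <- arrayInd(idx, dim(g))
  x_um <- tapply((co[, 1] - 1) * grid$dx, lab, mean)
  y_um <- tapply((co[, 2] - 1) * grid$dx, lab, mean)
  z_um <- tapply((co[, 3] - 1) * grid$dz, lab, mean)
  peak <- tapply(g[idx], lab, max)
  ord <- order(as.integer(names(x_um)))
  structure(data.frame(x = as.numeric(x_um[ord]), y = as.numeric(y_um[ord]),
                       z = as.numeric(z_um[ord]), peak = as.numeric(peak[ord])),
            class = c("centroid_set", "data.frame"),
            grid_dim = dim(grid$data), dx = grid$dx, dz = grid$dz)
}

#' @export
print.centroid_set <- function(x, ...) {
  cat(sprintf("<centroid_set> %d nuclei on a %s grid\n", nrow(x),
              paste(attr(x, "grid_dim"), collapse = "x")))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat(sprintf("  ... %d more\n", nrow(x) - 10))
  invisible(x)
}

#' Count detected nuclei inside a region of interest
#'
#' A centroid is counted when its nearest voxel lies inside the ROI mask.
#'
#' @param centroids a `centroid_set` from [find_nuclei()].
#' @param roi logical 3D array congruent with the source grid (or a
#'   `voxel_grid` whose nonzero voxels define the ROI).
#' @return integer count.
#' @export
count_in_roi <- function(centroids, roi) {
  if (!inherits(centroids, "centroid_set")) stop("`centroids` must be a centroid_set")
  if (is_voxel_grid(roi)) roi <- roi$data > 0
  gd <- attr(centroids, "grid_dim")
  if (!identical(dim(roi), gd))
    stop(sprintf("ROI shape %s does not match source grid %s",
                 paste(dim(roi), collapse = "x"), paste(gd, collapse = "x")))
  if (nrow(centroids) == 0L) return(0L)
  dx <- attr(centroids, "dx"); dz <- attr(centroids, "dz")
  i <- pmin(pmax(round(centroids$x / dx) + 1, 1), gd[1])
  j <- pmin(pmax(round(centroids$y / dx) + 1, 1), gd[2])
  k <- pmin(pmax(round(centroids$z / dz) + 1, 1), gd[3])
  sum(roi[cbind(i, j, k)])
}

#' Write a centroid set to CSV
#' @param centroids a `centroid_set`.
#' @param path output CSV (`x_um,y_um,z_um,peak`).
#' @return `path`, invisibly.
#' @export
write_centroids <- function(centroids, path) {
  df <- as.data.frame(centroids)
  names(df) <- c("x_um", "y_um", "z_um", "peak")
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
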