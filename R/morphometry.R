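#' 2D region mask with pixel size and embryo axis
#'
#' A binary outline of one cell or region of interest, as drawn on a
#' captured 2D view. Carries the physical pixel size and the direction of
#' the embryo's anterior-posterior (AP) axis in image coordinates, against
#' which elongation angles are measured.
#'
#' @param mask logical matrix indexed `[x, y]` (x right, y down in the
#'   captured image); must contain at least one `TRUE` pixel.
#' @param pixel_size micrometres per pixel.
#' @param ap_axis 2D vector giving the anterior-to-posterior direction in
#'   image coordinates; normalized internally. Default `c(1, 0)`.
#' @return an object of class `region_mask`.
#' @export
region_mask <- function(mask, pixel_size = 1, ap_axis = c(1, 0)) {
  if (!is.matrix(mask) || !is.logical(mask)) stop("`mask` must be a logical matrix")
  if (!any(mask)) stop("`mask` is empty")
  if (pixel_size <= 0) stop("`pixel_size` must be > 0")
  nrm <- sqrt(sum(ap_axis^2))
  if (length(ap_axis) != 2L || nrm == 0) stop("`ap_axis` must be a nonzero 2D vector")
  structure(list(mask = mask, pixel_size = pixel_size, ap_axis = ap_axis / nrm),
            class = "region_mask")
}

#' @export
print.region_mask <- function(x, ...) {
  cat(sprintf("<region_mask> %d x %d px, %d foreground px, pixel %g um, AP axis (%.2f, %.2f)\n",
              nrow(x$mask), ncol(x$mask), sum(x$mask), x$pixel_size,
              x$ap_axis[1], x$ap_axis[2]))
  invisible(x)
}

# moment-based ellipse fit of a binary region: centroid, axis diameters and
# major-axis orientation from second-order central moments (the fit behind
# the ImageJ shape descriptors). Works in pixel units.
fit_ellipse_moments <- function(region) {
  idx <- which(region$mask, arr.ind = TRUE)
  if (nrow(idx) < 5L) stop("region too small for a moment fit (< 5 px)")
  xs <- idx[, 1] - 1; ys <- idx[, 2] - 1
  cxx <- mean((xs - mean(xs))^2)
  cyy <- mean((ys - mean(ys))^2)
  cxy <- mean((xs - mean(xs)) * (ys - mean(ys)))
  C <- matrix(c(cxx, cxy, cxy, cyy), 2)
  ev <- eigen(C, symmetric = TRUE)
  if (ev$values[1] <= 0 || ev$values[2] <= 1e-9 * ev$values[1])
    stop("degenerate (collinear) region; no ellipse fit")
  # a solid ellipse with semi-axes a >= b has second moments a^2/4, b^2/4
  major <- 4 * sqrt(ev$values[1])
  minor <- 4 * sqrt(max(ev$values[2], 0))
  theta <- 0.5 * atan2(2 * cxy, cxx - cyy) * 180 / pi
  list(centroid = c(mean(xs), mean(ys)), major = major, minor = minor,
       theta_deg = theta, area_px = nrow(idx))
}

#' Roundness shape descriptor of a 2D region
#'
#' The ImageJ/Fiji shape descriptor `4 * Area / (pi * major_axis^2)`, with
#' the major axis taken from a moment-based ellipse fit of the binary
#' region. A perfect circle has roundness 1.0; an extremely elongated
#' outline approaches 0. Values marginally above 1 from discretization are
#' clipped to 1.
#'
#' @param region a [region_mask()] with at least 5 foreground pixels.
#' @return roundness in (0, 1].
#' @examples
#' roundness(make_ellipse_mask(40, 20, 0, pixel_size = 0.5))
#' @export
roundness <- function(region) {
  if (!inherits(region, "region_mask")) stop("`region` must be a region_mask")
  fit <- fit_ellipse_moments(region)
  min(4 * fit$area_px / (pi * fit$major^2), 1)
}

#' Elongation angle of a cell vs the anterior-posterior axis
#'
#' The axial angle between the fitted-ellipse major axis of the cell
#' outline and the embryo's AP axis, folded into `[-90, 90)` degrees
#' (orientations are axial: 120 degrees is the same axis as -60). Positive
#' angles rotate from the AP axis towards the image +y direction.
#'
#' A near-circular region has no stable long axis; when roundness exceeds
#' 0.95 the angle is still returned but flagged with a warning and the
#' attribute `unstable`.
#'
#' @param region a [region_mask()].
#' @return angle in degrees in `[-90, 90)`.
#' @export
elongation_angle <- function(region) {
  if (!inherits(region, "region_mask")) stop("`region` must be a region_mask")
  fit <- fit_ellipse_moments(region)
  ang <- fold_axial(fit$theta_deg - atan2(region$ap_axis[2], region$ap_axis[1]) * 180 / pi)
  rnd <- min(4 * fit$area_px / (pi * fit$major^2), 1)
  if (rnd >= 0.95) {
    warning("region is near-circular (roundness >= 0.95); elongation axis is unstable")
    attr(ang, "unstable") <- TRUE
  }
  ang
}

#' Optic fissure opening angle
#'
#' Interior angle between two rays sharing a vertex, in degrees -- the
#' measurement taken on a lateral view with the vertex at the lens center
#' and the rays projected along the fissure margins. The three points are
#' supplied (clicked) by the user; no automatic lens detection is done.
#'
#' @param vertex,ray_point_1,ray_point_2 2D points (image or physical
#'   coordinates; only directions matter).
#' @return angle in degrees, in (0, 180].
#' @examples
#' fissure_angle(c(0, 0), c(1, 0), c(0, 1))  # 90
#' @export
fissure_angle <- function(vertex, ray_point_1, ray_point_2) {
  u <- ray_point_1 - vertex
  v <- ray_point_2 - vertex
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) stop("ray point coincides with the vertex")
  acos(pmin(pmax(sum(u * v) / (nu * nv), -1), 1)) * 180 / pi
}

#' Anterior-posterior extent fraction
#'
#' Fraction of the optic vesicle's AP length occupied by an expression
#' domain: `|expression interval| / |vesicle interval|`.
#'
#' @param expression_interval `c(start, end)` along the AP axis (same units
#'   as the vesicle interval); `start <= end`.
#' @param vesicle_interval `c(start, end)` of the vesicle; positive length.
#' @return list with `expression_extent`, `vesicle_length`, `fraction`.
#' @export
ap_extent_fraction <- function(expression_interval, vesicle_interval) {
  if (expression_interval[2] < expression_interval[1] ||
      vesicle_interval[2] < vesicle_interval[1])
    stop("inverted interval")
  vl <- diff(vesicle_interval)
  if (vl <= 0) stop("vesicle length must be > 0")
  ex <- diff(expression_interval)
  list(expression_extent = ex, vesicle_length = vl, fraction = ex / vl)
}

#' Reporter-extent midpoint as a fraction of vesicle length
#'
#' The AP extent of reporter expression is measured along the medial and
#' lateral edges of the vesicle; their midpoint is reported as a ratio of
#' the whole vesicle length.
#'
#' @param medial_extent,lateral_extent AP extents, micrometres (>= 0).
#' @param vesicle_length vesicle AP length, micrometres (> 0).
#' @return the midpoint fraction `((medial + lateral)/2) / vesicle_length`.
#' @export
reporter_midpoint_fraction <- function(medial_extent, lateral_extent, vesicle_length) {
  if (medial_extent < 0 || lateral_extent < 0) stop("extents must be >= 0")
  if (vesicle_length <= 0) stop("`vesicle_length` must be > 0")
  ((medial_extent + lateral_extent) / 2) / vesicle_length
}

#' Anterior/posterior quarter fluorescence intensity ratio
#'
#' Reproduces the rectangular-ROI profile measurement: a vertical rectangle
#' (default width 44 px) spanning the AP length of a vertically oriented
#' vesicle; the per-row mean intensity profile is computed across the
#' rectangle width, the profile is split into four quarters
#' (`floor(n/4)` rows in each outer quarter, remainder rows assigned to the
#' middle), and the anterior quarter's mean is divided by the posterior
#' quarter's mean. A value of 1 means equal fluorescence in the quarters.
#'
#' @param img numeric matrix indexed `[x, y]`; rows of the profile run
#'   along y (anterior = small y).
#' @param rect `c(x0, y0, width, height)` in pixels, 1-based, axis-aligned;
#'   must lie inside the image, `height >= 4`.
#' @param rect_width_px expected rectangle width; a mismatch with
#'   `rect[3]` is an error (guards against mis-specified ROIs). Default 44.
#' @return the anterior/posterior ratio; `NaN` with a warning when the
#'   posterior quarter's mean is 0.
#' @export
quarter_intensity_ratio <- function(img, rect, rect_width_px = 44L) {
  if (!is.matrix(img)) stop("`img` must be a matrix")
  x0 <- rect[1]; y0 <- rect[2]; w <- rect[3]; hh <- rect[4]
  if (x0 < 1 || y0 < 1 || x0 + w - 1 > nrow(img) || y0 + hh - 1 > ncol(img))
    stop("rectangle extends outside the image")
  if (hh < 4) stop("rectangle must span at least 4 rows")
  if (!is.null(rect_width_px) && w != rect_width_px)
    stop(sprintf("rectangle width %d differs from the configured %d px", w, rect_width_px))
  sub <- img[x0:(x0 + w - 1), y0:(y0 + hh - 1), drop = FALSE]
  profile <- colMeans(sub)            # per-row mean across the rect width
  q <- floor(length(profile) / 4)
  anterior <- mean(profile[seq_len(q)])
  posterior <- mean(profile[seq(length(profile) - q + 1, length(profile))])
  if (posterior == 0) {
    warning("posterior-quarter mean is 0; ratio undefined")
    return(NaN)
  }
  anterior / posterior
}

#' Volumes of labeled tissue regions
#'
#' Volume per label (voxel count times `dx^2 * dz`) of a labeled
#' segmentation volume, with each label's relative share of the total
#' labeled volume -- e.g. stalk volume as a proportion of cup + stalk.
#'
#' @param labeled integer 3D array; 0 = background.
#' @param spacing `c(dx, dz)` micrometres.
#' @return data frame `label`, `n_voxels`, `volume_um3`, `relative_volume`
#'   (empty when no nonzero labels).
#' @examples
#' a <- array(0L, c(10, 10, 5)); a[1:5, , ] <- 1L; a[6:10, 1:2, ] <- 2L
#' label_volumes(a, spacing = c(1, 2))
#' @export
label_volumes <- function(labeled, spacing) {
  if (!is.array(labeled) || length(dim(labeled)) != 3L)
    stop("`labeled` must be a 3D array")
  if (any(labeled < 0)) stop("labels must be nonnegative (0 = background)")
  dx <- spacing[1]; dz <- spacing[2]
  labs <- sort(unique(as.vector(labeled)))
  labs <- labs[labs > 0]
  if (!length(labs))
    return(data.frame(label = integer(0), n_voxels = integer(0),
                      volume_um3 = numeric(0), relative_volume = numeric(0)))
  counts <- vapply(labs, function(l) sum(labeled == l), numeric(1))
  vols <- counts * dx^2 * dz
  data.frame(label = as.integer(labs), n_voxels = as.integer(counts),
             volume_um3 = vols, relative_volume = vols / sum(vols))
}
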