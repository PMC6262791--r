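#' Photoconversion fate-map fraction: marked (green) nuclei in an ROI
#'
#' Quantifies a photoconversion fate map: the proportion of unconverted
#' (green) nuclei among all nuclei inside a region of interest. In the
#' photoconvertible-fluorophore scheme, converted nuclei fluoresce red and
#' unconverted nuclei green, so by default the total is assembled as
#' `n_green + n_red` counted independently per channel with
#' [find_nuclei()], minus double positives: a green centroid within
#' `match_radius` of a red centroid (a partially converted nucleus visible
#' in both channels) is counted once. Alternatively, supply a dedicated
#' all-nuclei counterstain channel as `total` and the total is counted
#' from it directly.
#'
#' @param green [voxel_grid()] of the unconverted (green) channel.
#' @param red [voxel_grid()] of the converted (red) channel; required
#'   unless `total` is given.
#' @param roi logical 3D array (or binary `voxel_grid`) congruent with the
#'   channels.
#' @param params_green [abacus_params()] for the green channel.
#' @param params_red parameters for the red channel (default: same).
#' @param total optional all-nuclei channel [voxel_grid()]; when given,
#'   `n_total` is counted from it (with `params_total`) instead of
#'   `n_green + n_red`.
#' @param params_total parameters for the `total` channel (default: same
#'   as green).
#' @param match_radius double-positive matching radius, micrometres
#'   (about one nuclear radius; default 3).
#' @return list of class `fatemap_result`: `n_green`, `n_red`,
#'   `n_double_positive`, `n_total`, `fraction`, and `undefined` (TRUE,
#'   with `fraction = NA`, when no nuclei are found at all).
#' @export
marked_fraction <- function(green, red = NULL, roi, params_green,
                            params_red = params_green,
                            total = NULL, params_total = params_green,
                            match_radius = 3) {
  stopifnot_voxel_grid(green)
  if (is.null(red) && is.null(total))
    stop("supply `red` (two-channel scheme) or `total` (counterstain channel)")
  if (is_voxel_grid(roi)) roi <- roi$data > 0
  check_congruent(green, roi)

  cg <- find_nuclei(green, params_green)
  n_green <- count_in_roi(cg, roi)

  n_red <- NA_integer_
  n_dp <- 0L
  if (!is.null(total)) {
    stopifnot_voxel_grid(total)
    check_congruent(total, roi)
    ct <- find_nuclei(total, params_total)
    n_total <- count_in_roi(ct, roi)
  } else {
    stopifnot_voxel_grid(red)
    check_congruent(red, roi)
    cr <- find_nuclei(red, params_red)
    n_red <- count_in_roi(cr, roi)
    n_dp <- n_double_positive(cg, cr, roi, match_radius)
    n_total <- n_green + n_red - n_dp
  }

  res <- list(n_green = as.integer(n_green), n_red = n_red,
              n_double_positive = as.integer(n_dp),
              n_total = as.integer(n_total),
              fraction = if (n_total > 0) n_green / n_total else NA_real_,
              undefined = n_total == 0L)
  if (res$undefined)
    warning("no nuclei detected in the ROI; fraction undefined")
  class(res) <- "fatemap_result"
  res
}

#' @export
print.fatemap_result <- function(x, ...) {
  cat(sprintf("<fatemap_result> green %d / total %d = %s\n",
              x$n_green, x$n_total,
              if (x$undefined) "undefined" else sprintf("%.3f", x$fraction)))
  invisible(x)
}

# greedy one-to-one matching of green centroids to red centroids within
# `radius` um, restricted to the ROI
n_double_positive <- function(green_cs, red_cs, roi, radius) {
  ing <- centroids_in_roi(green_cs, roi)
  inr <- centroids_in_roi(red_cs, roi)
  if (!nrow(ing) || !nrow(inr)) return(0L)
  d <- sqrt(outer(ing$x, inr$x, "-")^2 + outer(ing$y, inr$y, "-")^2 +
            outer(ing$z, inr$z, "-")^2)
  n <- 0L
  repeat {
    m <- which.min(d)
    if (!length(m) || d[m] > radius) break
    n <- n + 1L
    i <- (m - 1) %% nrow(d) + 1
    j <- (m - 1) %/% nrow(d) + 1
    d[i, ] <- Inf
    d[, j] <- Inf
  }
  n
}

centroids_in_roi <- function(cs, roi) {
  if (nrow(cs) == 0L) return(cs)
  gd <- attr(cs, "grid_dim"); dx <- attr(cs, "dx"); dz <- attr(cs, "dz")
  i <- pmin(pmax(round(cs$x / dx) + 1, 1), gd[1])
  j <- pmin(pmax(round(cs$y / dx) + 1, 1), gd[2])
  k <- pmin(pmax(round(cs$z / dz) + 1, 1), gd[3])
  cs[roi[cbind(i, j, k)], , drop = FALSE]
}
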