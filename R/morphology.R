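# Grayscale/binary 3D morphology primitives underlying the nucleus detector.
# All functions operate on plain 3D arrays indexed [x, y, z] and treat the
# outside of the image as -Inf (dilation) / FALSE (labeling), i.e. nothing
# propagates in from the border.

conn_offsets <- function(connectivity) {
  if (!connectivity %in% c(6L, 18L, 26L))
    stop("`connectivity` must be 6, 18 or 26")
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
  keep <- switch(as.character(connectivity),
                 "6"  = rowSums(abs(g)) == 1,
                 "18" = rowSums(abs(g)) <= 2,
                 "26" = rep(TRUE, nrow(g)))
  g[keep, , drop = FALSE]
}

# shift so that out[i] = a[i - o], replicating the clamped edge value.
# For a max filter whose support includes the center this is equivalent to
# -Inf padding (the duplicated edge value is already a candidate via self).
shift_clamp <- function(a, o) {
  d <- dim(a)
  i1 <- pmin(pmax(seq_len(d[1]) - o[1], 1L), d[1])
  i2 <- pmin(pmax(seq_len(d[2]) - o[2], 1L), d[2])
  i3 <- pmin(pmax(seq_len(d[3]) - o[3], 1L), d[3])
  a[i1, i2, i3, drop = FALSE]
}

# 3x3(x3) grayscale dilation at the given connectivity
dilate3 <- function(a, connectivity = 26) {
  d <- dim(a)
  if (connectivity == 26L) {
    # separable: the 26-neighborhood SE is a 3x3x3 box
    for (ax in 1:3) {
      up <- integer(3); up[ax] <- 1L
      dn <- integer(3); dn[ax] <- -1L
      a <- pmax(a, shift_clamp(a, up), shift_clamp(a, dn))
    }
    return(a)
  }
  offs <- conn_offsets(connectivity)
  out <- a
  for (r in seq_len(nrow(offs))) out <- pmax(out, shift_clamp(a, offs[r, ]))
  out
}

# neighborhood maximum EXCLUDING the center voxel, -Inf outside the image
neigh_max <- function(a, offsets) {
  d <- dim(a)
  pd <- d + 2L
  ap <- array(-Inf, pd)
  ap[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- a
  out <- array(-Inf, d)
  for (r in seq_len(nrow(offsets))) {
    o <- offsets[r, ]
    sl <- ap[(2:(d[1] + 1)) + o[1], (2:(d[2] + 1)) + o[2], (2:(d[3] + 1)) + o[3],
             drop = FALSE]
    out <- pmax(out, sl)
  }
  out
}

#' Grayscale geodesic reconstruction by dilation
#'
#' Iterates `marker <- min(dilate(marker), mask)` to a fixed point: the
#' largest image below `mask` reachable from `marker` by downhill-limited
#' growth. This is the engine of the h-maxima (extended maxima) transform
#' used by the nucleus detector.
#'
#' @param marker,mask 3D arrays of identical shape with `marker <= mask`
#'   everywhere.
#' @param connectivity 6, 18 or 26 (voxel neighborhood).
#' @param max_iter safety cap on geodesic propagation sweeps.
#' @return the reconstructed 3D array.
#' @export
grey_reconstruct <- function(marker, mask, connectivity = 26, max_iter = 100000L) {
  if (!identical(dim(marker), dim(mask)))
    stop("marker and mask must have identical shape")
  if (any(marker > mask)) stop("marker must be <= mask everywhere")
  rec <- marker
  for (it in seq_len(max_iter)) {
    nxt <- pmin(dilate3(rec, connectivity), mask)
    if (all(nxt == rec)) return(nxt)
    rec <- nxt
  }
  warning("grey_reconstruct: no convergence after max_iter sweeps")
  rec
}

#' Label connected components of a 3D binary mask
#'
#' @param mask logical 3D array.
#' @param connectivity 6, 18 or 26.
#' @return integer 3D array; 0 = background, components numbered from 1 in
#'   first-encounter (column-major) order.
#' @export
label_components <- function(mask, connectivity = 26) {
  if (!is.array(mask) || length(dim(mask)) != 3L)
    stop("`mask` must be a logical 3D array")
  d <- dim(mask)
  pd <- d + 2L
  mp <- array(FALSE, pd)
  mp[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- mask
  offs <- conn_offsets(connectivity)
  loff <- offs[, 1] + offs[, 2] * pd[1] + offs[, 3] * pd[1] * pd[2]
  mpv <- as.vector(mp)
  labp <- integer(length(mpv))
  seeds <- which(mpv)
  nlab <- 0L
  for (s in seeds) {
    if (labp[s] != 0L) next
    nlab <- nlab + 1L
    labp[s] <- nlab
    frontier <- s
    while (length(frontier)) {
      nb <- as.vector(outer(frontier, loff, "+"))
      nb <- unique(nb[mpv[nb] & labp[nb] == 0L])
      if (length(nb)) labp[nb] <- nlab
      frontier <- nb
    }
  }
  array(labp, pd)[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1), drop = FALSE]
}

#' Regional maxima of a 3D image
#'
#' A regional maximum is a connected plateau (voxels of equal value) all of
#' whose outside neighbors are strictly lower. Plateaus at or below `floor`
#' are treated as background and never reported.
#'
#' @param x 3D array.
#' @param connectivity 6, 18 or 26.
#' @param floor background level; use `-Inf` (default) for the pure
#'   morphological definition.
#' @return list with `mask` (logical array), `labels` (integer array, one
#'   label per maximum region) and `n` (number of regions).
#' @export
regional_maxima <- function(x, connectivity = 26, floor = -Inf) {
  offs <- conn_offsets(connectivity)
  nm <- neigh_max(x, offs)
  cand <- (x >= nm) & (x > floor)
  d <- dim(x)
  if (!any(cand))
    return(list(mask = array(FALSE, d), labels = array(0L, d), n = 0L))
  lab <- label_components(cand, connectivity)
  # a candidate plateau is not a maximum if it continues, at equal value,
  # into a voxel that itself has a strictly higher neighbor
  pd <- d + 2L
  xp <- array(-Inf, pd); xp[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- x
  cp <- array(FALSE, pd); cp[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- cand
  rejected <- integer(0)
  core1 <- 2:(d[1] + 1); core2 <- 2:(d[2] + 1); core3 <- 2:(d[3] + 1)
  for (r in seq_len(nrow(offs))) {
    o <- offs[r, ]
    nv <- xp[core1 + o[1], core2 + o[2], core3 + o[3], drop = FALSE]
    nc <- cp[core1 + o[1], core2 + o[2], core3 + o[3], drop = FALSE]
    bad <- cand & !nc & (nv == x)
    if (any(bad)) rejected <- c(rejected, unique(lab[bad]))
  }
  if (length(rejected)) {
    keepmask <- cand & !(lab %in% unique(rejected))
    lab <- label_components(keepmask, connectivity)
    cand <- keepmask
  }
  list(mask = cand, labels = lab, n = max(lab))
}

#' Extended maxima (h-maxima) of a 3D image
#'
#' Regional maxima that survive suppression of all maxima whose dynamic
#' (height above the highest saddle linking them to higher terrain) is less
#' than `h`: the h-maxima transform `R(x - h, x)` followed by
#' [regional_maxima()]. Maxima separated by saddles shallower than `h`
#' merge into a single region.
#'
#' @param x 3D array.
#' @param h minimum height (gray value), > 0.
#' @param connectivity 6, 18 or 26.
#' @param floor background level. When finite, the marker is clipped at
#'   `floor` from below (the reconstruction is unchanged above the floor)
#'   and plateaus at or below `floor` are treated as suppressed background.
#' @return as [regional_maxima()].
#' @export
extended_maxima <- function(x, h, connectivity = 26, floor = -Inf) {
  if (!is.numeric(h) || length(h) != 1L || h <= 0) stop("`h` must be > 0")
  marker <- x - h
  if (is.finite(floor)) marker <- pmax(marker, floor)
  rec <- grey_reconstruct(marker, x, connectivity)
  regional_maxima(rec, connectivity, floor = floor)
}
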