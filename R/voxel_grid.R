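#' 3D image grid with physical voxel spacing
#'
#' The central image container of the package: a 3D scalar array together
#' with its physical voxel spacing. Confocal stacks are anisotropic --
#' in-plane pixels are square with side `dx` (micrometres) while optical
#' sections are `dz` apart, typically several-fold coarser.
#'
#' In memory the array is indexed `data[x, y, z]`; physical coordinates use
#' 0-based pixel centers, so voxel `(i, j, k)` sits at
#' `((i-1)*dx, (j-1)*dx, (k-1)*dz)` micrometres. On disk (TIFF) planes are
#' stored row-major `[y, x]` in z-major order; [read_stack()] and
#' [write_stack()] perform the transposition.
#'
#' @param data numeric 3D array of gray values.
#' @param dx in-plane pixel size, micrometres (isotropic in x and y).
#' @param dz z-step between planes, micrometres.
#' @param bit_depth 8 or 16; gray values must lie in `[0, 2^bit_depth - 1]`.
#'
#' @return an object of class `voxel_grid`: a list with elements `data`,
#'   `dx`, `dz`, `bit_depth`.
#' @examples
#' g <- voxel_grid(array(0, c(8, 8, 4)), dx = 0.692, dz = 2.1)
#' dim(g$data)
#' @export
voxel_grid <- function(data, dx, dz, bit_depth = 8L) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array")
  if (any(dim(data) < 1L)) stop("all array dimensions must be >= 1")
  if (!is.numeric(dx) || length(dx) != 1L || dx <= 0) stop("`dx` must be a positive scalar")
  if (!is.numeric(dz) || length(dz) != 1L || dz <= 0) stop("`dz` must be a positive scalar")
  bit_depth <- as.integer(bit_depth)
  if (!bit_depth %in% c(8L, 16L)) stop("`bit_depth` must be 8 or 16")
  vmax <- 2^bit_depth - 1
  rng <- range(data)
  if (rng[1] < 0 || rng[2] > vmax)
    stop(sprintf("gray values must lie in [0, %d] for %d-bit data", vmax, bit_depth))
  structure(list(data = data, dx = dx, dz = dz, bit_depth = bit_depth),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<voxel_grid> %d x %d x %d voxels, dx = %g um, dz = %g um, %d-bit\n",
              d[1], d[2], d[3], x$dx, x$dz, x$bit_depth))
  cat(sprintf("  physical extent %.1f x %.1f x %.1f um, gray range [%g, %g]\n",
              d[1] * x$dx, d[2] * x$dx, d[3] * x$dz,
              min(x$data), max(x$data)))
  invisible(x)
}

is_voxel_grid <- function(x) inherits(x, "voxel_grid")

stopifnot_voxel_grid <- function(x, arg = deparse(substitute(x))) {
  if (!is_voxel_grid(x)) stop(sprintf("`%s` must be a voxel_grid", arg))
  invisible(x)
}

#' Check that two grids (or a grid and a mask) are congruent
#'
#' Congruent means same voxel dimensions and same spacing, so that voxel
#' indices refer to the same physical locations.
#'
#' @param a,b `voxel_grid` objects, or a `voxel_grid` and a plain array
#'   (e.g. an ROI mask) for which only dimensions are compared.
#' @return `TRUE` invisibly, or an error.
#' @export
check_congruent <- function(a, b) {
  dim_a <- if (is_voxel_grid(a)) dim(a$data) else dim(a)
  dim_b <- if (is_voxel_grid(b)) dim(b$data) else dim(b)
  if (!identical(dim_a, dim_b))
    stop(sprintf("shape mismatch: %s vs %s",
                 paste(dim_a, collapse = "x"), paste(dim_b, collapse = "x")))
  if (is_voxel_grid(a) && is_voxel_grid(b) &&
      (a$dx != b$dx || a$dz != b$dz))
    stop("voxel spacing mismatch between grids")
  invisible(TRUE)
}

#' Read a 3D TIFF stack as a voxel grid
#'
#' Reads a multi-page grayscale TIFF (z-major plane order, rows = y) into a
#' [voxel_grid()]. Gray values are returned on the original integer scale
#' (0..255 for 8-bit input).
#'
#' @param path TIFF file.
#' @param dx,dz voxel spacing in micrometres (not stored in the files this
#'   package targets; supplied by the caller or a config).
#' @param bit_depth bit depth of the stored data (default 8).
#' @return a `voxel_grid`.
#' @export
read_stack <- function(path, dx, dz, bit_depth = 8L) {
  planes <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(planes)) planes <- list(planes)
  vmax <- 2^as.integer(bit_depth) - 1
  arr <- vapply(planes, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1]  # drop extra channels if present
    t(p) * vmax                              # [y, x] -> [x, y], rescale to gray
  }, matrix(0, ncol(planes[[1]]), nrow(planes[[1]])))
  voxel_grid(round(arr), dx = dx, dz = dz, bit_depth = bit_depth)
}

#' Write a voxel grid to a 3D TIFF stack
#'
#' Planes are written z-major, row-major `[y, x]`, at the grid's bit depth.
#'
#' @param grid a `voxel_grid`.
#' @param path output TIFF file.
#' @return `path`, invisibly.
#' @export
write_stack <- function(grid, path) {
  stopifnot_voxel_grid(grid)
  vmax <- 2^grid$bit_depth - 1
  planes <- lapply(seq_len(dim(grid$data)[3]),
                   function(k) t(grid$data[, , k]) / vmax)
  tiff::writeTIFF(planes, path, bits.per.sample = grid$bit_depth)
  invisible(path)
}

#' Write a 2D mask or slice as TIFF
#' @param x logical or numeric matrix indexed `[x, y]`; logical masks are
#'   written as 0/255.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_mask <- function(x, path) {
  m <- if (is.logical(x)) ifelse(x, 1, 0) else x / max(x, 1)
  tiff::writeTIFF(t(m), path, bits.per.sample = 8)
  invisible(path)
}

# restore RNG state after seeded generation so generators do not perturb
# the caller's random stream
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    genv <- globalenv()
    if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      old <- get(".Random.seed", envir = genv)
      on.exit(assign(".Random.seed", old, envir = genv), add = TRUE)
    } else {
      on.exit(suppressWarnings(rm(".Random.seed", envir = genv)), add = TRUE)
    }
    set.seed(seed)
  }
  force(code)
}

# fold an angle in degrees into [-90, 90): axial data (a cell's long axis
# has no head or tail, so 120 deg and -60 deg are the same orientation)
fold_axial <- function(deg) ((deg + 90) %% 180) - 90
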