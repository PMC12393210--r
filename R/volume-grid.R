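#' Isotropic 3D volume grid
#'
#' The basic container of the pipeline: a scalar (real or complex) value per
#' voxel on an isotropic 3D grid, together with the voxel size and the
#' physical position of the grid. The field of view is `shape * voxel_size`
#' on every axis. Physical coordinates are in mm with the origin at the
#' magnet isocenter; voxel `(i, j, k)` (1-based) is centered at
#' `(i - 1 - N/2) * voxel_size + origin` on the first axis (so for even `N`
#' the voxel with index `N/2 + 1` sits at the origin, matching the DFT
#' center convention used by the gridding reconstruction).
#'
#' @param values numeric or complex 3D array (all axes the same length).
#' @param voxel_size isotropic voxel edge length in mm.
#' @param origin length-3 numeric, mm offset of the grid center from the
#'   isocenter.
#' @return an object of class `volume_grid` with fields `values`, `shape`,
#'   `voxel_size`, `fov`, `origin`.
#' @export
volume_grid <- function(values, voxel_size, origin = c(0, 0, 0)) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3D array")
  d <- dim(values)
  if (length(unique(d)) != 1L)
    stop("grid must be isotropic: all three axes must have the same length")
  if (!is.numeric(voxel_size) || length(voxel_size) != 1L || voxel_size <= 0)
    stop("`voxel_size` must be a positive scalar (mm)")
  origin <- as.numeric(origin)
  if (length(origin) != 3L) stop("`origin` must have length 3")
  structure(
    list(values = values, shape = d, voxel_size = as.numeric(voxel_size),
         fov = d * voxel_size, origin = origin),
    class = "volume_grid")
}

#' @export
print.volume_grid <- function(x, ...) {
  cat(sprintf("<volume_grid %dx%dx%d, voxel %.4g mm, FOV %.4g mm, %s>\n",
              x$shape[1], x$shape[2], x$shape[3], x$voxel_size, x$fov[1],
              if (is.complex(x$values)) "complex" else "real"))
  invisible(x)
}

#' Axis coordinates of a volume grid
#'
#' @param grid a [volume_grid].
#' @param axis 1, 2 or 3.
#' @return numeric vector of voxel-center positions (mm) along the axis.
#' @export
grid_axis <- function(grid, axis) {
  n <- grid$shape[axis]
  (seq_len(n) - 1 - n / 2) * grid$voxel_size + grid$origin[axis]
}

#' Voxel-center coordinate arrays
#'
#' Returns an `n_voxels x 3` matrix of the physical coordinates (mm) of all
#' voxel centers in column-major (R array) order.
#' @param grid a [volume_grid].
#' @export
grid_coords <- function(grid) {
  ax <- lapply(1:3, grid_axis, grid = grid)
  n <- grid$shape
  cbind(rep(ax[[1]], times = n[2] * n[3]),
        rep(rep(ax[[2]], each = n[1]), times = n[3]),
        rep(ax[[3]], each = n[1] * n[2]))
}

#' Construct an empty grid covering a field of view
#'
#' @param n voxels per axis.
#' @param fov field of view in mm (scalar).
#' @param origin mm offset of the grid center.
#' @export
empty_grid <- function(n, fov, origin = c(0, 0, 0)) {
  volume_grid(array(0, dim = c(n, n, n)), voxel_size = fov / n,
              origin = origin)
}

same_grid <- function(a, b, tol = 1e-9) {
  all(a$shape == b$shape) &&
    abs(a$voxel_size - b$voxel_size) < tol &&
    all(abs(a$origin - b$origin) < tol)
}

stopifnot_same_grid <- function(a, b, what = "volumes") {
  if (!same_grid(a, b))
    stop(sprintf("%s are not defined on the same grid", what))
  invisible(TRUE)
}

with_values <- function(grid, values) {
  g <- grid
  if (is.null(dim(values))) dim(values) <- grid$shape
  g$values <- values
  g
}

#' Trilinear resampling onto a target grid
#'
#' Resamples `image` onto the voxel centers of `target` by trilinear
#' interpolation. Both grids must cover the same field of view (the paper's
#' volumes all share the (400 mm)^3 FOV; resampling is only used to bring
#' volumes of different matrix size onto a common grid). Trilinear
#' interpolation reproduces affine functions exactly. Sample points outside
#' the source voxel-center hull are clamped to the edge value.
#'
#' @param image a [volume_grid] to resample.
#' @param target a [volume_grid] providing the output geometry.
#' @return a [volume_grid] with the geometry of `target`.
#' @export
resample_to <- function(image, target) {
  if (any(abs(image$fov - target$fov) > 1e-6))
    stop("resample_to: source and target FOV differ")
  if (same_grid(image, target)) return(with_values(target, image$values))
  n <- image$shape
  # continuous (1-based) source index of each target voxel center, per axis
  idx <- lapply(1:3, function(a) {
    x <- grid_axis(target, a)
    i <- (x - image$origin[a]) / image$voxel_size + n[a] / 2 + 1
    pmin(pmax(i, 1), n[a])   # clamp to the voxel-center hull
  })
  nt <- target$shape
  ix <- rep(idx[[1]], times = nt[2] * nt[3])
  iy <- rep(rep(idx[[2]], each = nt[1]), times = nt[3])
  iz <- rep(idx[[3]], each = nt[1] * nt[2])
  v <- trilinear_gather(image$values, ix, iy, iz)
  with_values(target, array(v, dim = nt))
}

# gather with trilinear weights at continuous 1-based indices
trilinear_gather <- function(arr, ix, iy, iz) {
  n <- dim(arr)
  x0 <- pmin(pmax(floor(ix), 1), n[1] - 1); fx <- ix - x0
  y0 <- pmin(pmax(floor(iy), 1), n[2] - 1); fy <- iy - y0
  z0 <- pmin(pmax(floor(iz), 1), n[3] - 1); fz <- iz - z0
  # handle n == 1 axes (degenerate) by zero fraction
  if (n[1] == 1) { x0[] <- 1; fx[] <- 0 }
  if (n[2] == 1) { y0[] <- 1; fy[] <- 0 }
  if (n[3] == 1) { z0[] <- 1; fz[] <- 0 }
  lin <- function(i, j, k) ((k - 1) * n[2] + (j - 1)) * n[1] + i
  out <- arr[lin(x0, y0, z0)] * (1 - fx) * (1 - fy) * (1 - fz)
  out <- out + arr[lin(x0 + 1, y0, z0)] * fx * (1 - fy) * (1 - fz)
  out <- out + arr[lin(x0, y0 + 1, z0)] * (1 - fx) * fy * (1 - fz)
  out <- out + arr[lin(x0 + 1, y0 + 1, z0)] * fx * fy * (1 - fz)
  out <- out + arr[lin(x0, y0, z0 + 1)] * (1 - fx) * (1 - fy) * fz
  out <- out + arr[lin(x0 + 1, y0, z0 + 1)] * fx * (1 - fy) * fz
  out <- out + arr[lin(x0, y0 + 1, z0 + 1)] * (1 - fx) * fy * fz
  out <- out + arr[lin(x0 + 1, y0 + 1, z0 + 1)] * fx * fy * fz
  out
}
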