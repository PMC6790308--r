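#' Volume grids and statistical maps
#'
#' A `volume_grid` is the raster all maps in the package live on: voxel
#' dimensions, voxel size in mm, a voxel-to-MNI affine (RAS+, NIfTI sform
#' semantics, 0-based voxel indices; a voxel's coordinate is its centre) and a
#' logical brain mask. A `stat_map` is a scalar raster (t, z, beta or
#' arbitrary amplitude) on such a grid.
#'
#' @name grid
NULL

#' Construct a volume grid
#'
#' @param dim Integer vector of length 3, voxels per axis.
#' @param voxel_size_mm Numeric vector of length 3 (or scalar), mm per voxel.
#' @param origin_mm MNI coordinate (mm) of the centre of voxel (0,0,0).
#' @param mask Logical array of dimension `dim`, or `NULL` for the default
#'   ellipsoidal brain mask (semi-axes 1.1 times the half-extent of the box).
#' @return An object of class `volume_grid`.
#' @export
volume_grid <- function(dim = c(53L, 63L, 52L),
                        voxel_size_mm = c(3, 3, 3),
                        origin_mm = c(-78, -112, -50),
                        mask = NULL) {
  dim <- as.integer(dim)
  stopifnot(length(dim) == 3L, all(dim > 0L))
  if (length(voxel_size_mm) == 1L) voxel_size_mm <- rep(voxel_size_mm, 3L)
  stopifnot(length(voxel_size_mm) == 3L, all(voxel_size_mm > 0))
  affine <- diag(4)
  affine[1:3, 1:3] <- diag(voxel_size_mm)
  affine[1:3, 4] <- origin_mm
  if (is.null(mask)) {
    mask <- default_ellipsoid_mask(dim, voxel_size_mm, origin_mm)
  }
  stopifnot(is.logical(mask), identical(dim(mask), as.integer(dim)))
  structure(
    list(dim = dim, voxel_size_mm = as.numeric(voxel_size_mm),
         affine = affine, mask = mask),
    class = "volume_grid"
  )
}

# ellipsoid centred on the box, semi-axes inflated 10% so peripheral
# structures (cerebellum, frontal pole) stay in-mask
default_ellipsoid_mask <- function(dim, vox, origin, inflate = 1.1) {
  ext <- (dim - 1) * vox
  centre <- origin + ext / 2
  semi <- pmax(ext / 2 * inflate, vox)
  co <- voxel_coords(dim, vox, origin)
  r2 <- ((co[, 1] - centre[1]) / semi[1])^2 +
    ((co[, 2] - centre[2]) / semi[2])^2 +
    ((co[, 3] - centre[3]) / semi[3])^2
  array(r2 <= 1, dim = dim)
}

# n_voxels x 3 matrix of voxel-centre MNI coordinates in array order
voxel_coords <- function(dim, vox, origin) {
  i <- seq_len(dim[1]) - 1L
  j <- seq_len(dim[2]) - 1L
  k <- seq_len(dim[3]) - 1L
  cbind(
    rep(origin[1] + i * vox[1], times = dim[2] * dim[3]),
    rep(rep(origin[2] + j * vox[2], each = dim[1]), times = dim[3]),
    rep(origin[3] + k * vox[3], each = dim[1] * dim[2])
  )
}

#' MNI coordinates of every voxel centre
#'
#' @param grid A `volume_grid`.
#' @return A matrix with one row per voxel (array order) and columns x, y, z.
#' @export
grid_coordinates <- function(grid) {
  stopifnot(inherits(grid, "volume_grid"))
  co <- voxel_coords(grid$dim, grid$voxel_size_mm, grid$affine[1:3, 4])
  colnames(co) <- c("x", "y", "z")
  co
}

#' The demonstration grid used by the synthetic pipeline
#'
#' A coarse 20 x 20 x 20 raster at 8 mm spacing whose box covers the MNI
#' locations of every shipped network template node, so whole-pipeline
#' simulations stay small enough to iterate on at a desk while keeping
#' template coordinates in real MNI millimetres.
#'
#' @return A `volume_grid`.
#' @export
demo_grid <- function() {
  volume_grid(dim = c(20L, 20L, 20L), voxel_size_mm = c(8, 8, 8),
              origin_mm = c(-76, -98, -46))
}

#' @export
print.volume_grid <- function(x, ...) {
  cat(sprintf("<volume_grid> %d x %d x %d voxels at %.3g x %.3g x %.3g mm, %d in mask\n",
              x$dim[1], x$dim[2], x$dim[3],
              x$voxel_size_mm[1], x$voxel_size_mm[2], x$voxel_size_mm[3],
              sum(x$mask)))
  invisible(x)
}

#' Construct a statistical map
#'
#' @param grid A `volume_grid`.
#' @param values Numeric array of the grid's dimension, or a vector of length
#'   `prod(grid$dim)`. Non-finite values are only allowed outside the mask.
#' @param kind One of `"t"`, `"z"`, `"beta"`, `"amplitude"`.
#' @return An object of class `stat_map`.
#' @export
stat_map <- function(grid, values, kind = c("amplitude", "t", "z", "beta")) {
  kind <- match.arg(kind)
  stopifnot(inherits(grid, "volume_grid"))
  values <- array(as.numeric(values), dim = grid$dim)
  if (any(!is.finite(values[grid$mask])))
    stop("stat_map: non-finite values inside the brain mask")
  structure(list(grid = grid, values = values, kind = kind),
            class = "stat_map")
}

#' @export
print.stat_map <- function(x, ...) {
  v <- x$values[x$grid$mask]
  cat(sprintf("<stat_map kind=%s> range [%.4g, %.4g] over %d in-mask voxels\n",
              x$kind, min(v), max(v), length(v)))
  invisible(x)
}

#' Convert MNI mm coordinates to voxel indices
#'
#' Inverts the grid affine and rounds to the nearest voxel centre. Voxel
#' indices are returned 1-based (R array convention); the affine itself uses
#' the NIfTI 0-based convention internally.
#'
#' @param grid A `volume_grid`.
#' @param xyz_mm Numeric length-3 coordinate, or an n x 3 matrix.
#' @return Integer voxel indices (1-based), same shape as the input.
#' @export
mni_to_voxel <- function(grid, xyz_mm) {
  stopifnot(inherits(grid, "volume_grid"))
  xyz <- if (is.matrix(xyz_mm)) xyz_mm else matrix(xyz_mm, nrow = 1)
  stopifnot(ncol(xyz) == 3L)
  inv <- solve(grid$affine)
  v0 <- t(inv %*% rbind(t(xyz), 1))[, 1:3, drop = FALSE]  # 0-based, fractional
  idx <- round(v0) + 1L
  bad <- idx < 1L | idx > matrix(grid$dim, nrow(idx), 3, byrow = TRUE)
  if (any(bad)) {
    row <- which(rowSums(bad) > 0)[1]
    stop(sprintf("coordinate (%g, %g, %g) mm lies outside the grid bounding box",
                 xyz[row, 1], xyz[row, 2], xyz[row, 3]))
  }
  out <- matrix(as.integer(idx), ncol = 3)
  if (!is.matrix(xyz_mm)) out <- drop(out)
  out
}

#' Convert voxel indices to MNI mm coordinates
#'
#' @param grid A `volume_grid`.
#' @param voxel Integer length-3 index (1-based), or an n x 3 matrix.
#' @return Numeric MNI coordinates, same shape as the input.
#' @export
voxel_to_mni <- function(grid, voxel) {
  stopifnot(inherits(grid, "volume_grid"))
  v <- if (is.matrix(voxel)) voxel else matrix(voxel, nrow = 1)
  stopifnot(ncol(v) == 3L)
  out <- t(grid$affine %*% rbind(t(v) - 1, 1))[, 1:3, drop = FALSE]
  colnames(out) <- c("x", "y", "z")
  if (!is.matrix(voxel)) out <- drop(out)
  out
}

#' Write a map to NIfTI-1
#'
#' The affine is stored in the sform (and qform) and data are written as
#' float64 so a read round-trip is exact.
#'
#' @param map A `stat_map`.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_nifti_map <- function(map, path) {
  stopifnot(inherits(map, "stat_map"))
  img <- RNifti::asNifti(map$values)
  img <- RNifti::`sform<-`(img, structure(map$grid$affine, code = 4L))
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

#' Read a NIfTI volume as a stat_map
#'
#' @param path A `.nii`/`.nii.gz` file.
#' @param kind Map kind to tag the result with.
#' @param mask Optional logical mask; default: all finite voxels.
#' @return A `stat_map` on a grid rebuilt from the file's sform.
#' @export
read_nifti_map <- function(path, kind = "amplitude", mask = NULL) {
  img <- RNifti::readNifti(path)
  aff <- RNifti::xform(img)
  vox <- sqrt(colSums(aff[1:3, 1:3]^2))
  values <- array(as.numeric(img), dim = dim(img)[1:3])
  if (is.null(mask)) mask <- array(is.finite(values), dim = dim(values))
  grid <- volume_grid(dim = dim(values), voxel_size_mm = vox,
                      origin_mm = aff[1:3, 4], mask = mask)
  grid$affine <- unclass(matrix(aff, 4, 4))
  stat_map(grid, values, kind = kind)
}

#' Gaussian smoothing of a map
#'
#' Separable Gaussian convolution with mask-aware renormalization: the map is
#' convolved as `smooth(values * mask) / smooth(mask)`, so constants are
#' preserved up to the mask edge. The kernel standard deviation per axis is
#' `fwhm_mm / (sqrt(8 log 2) * voxel_size_mm)` voxels.
#'
#' @param map A `stat_map`.
#' @param fwhm_mm Full width at half maximum in mm; 0 returns the input.
#' @return A smoothed `stat_map` on the same grid.
#' @export
gaussian_smooth <- function(map, fwhm_mm) {
  stopifnot(inherits(map, "stat_map"))
  if (fwhm_mm < 0) stop("fwhm_mm must be non-negative")
  if (fwhm_mm == 0) return(map)
  sigma_vox <- fwhm_mm / (sqrt(8 * log(2)) * map$grid$voxel_size_mm)
  m <- map$grid$mask
  num <- map$values
  num[!m] <- 0
  den <- array(as.numeric(m), dim = map$grid$dim)
  for (axis in 1:3) {
    k <- gauss_kernel_1d(sigma_vox[axis])
    if (length(k) > 1L) {
      num <- convolve_axis(num, k, axis)
      den <- convolve_axis(den, k, axis)
    }
  }
  out <- array(0, dim = map$grid$dim)
  out[m] <- num[m] / den[m]
  stat_map(map$grid, out, kind = map$kind)
}

gauss_kernel_1d <- function(sigma) {
  if (sigma <= 0) return(1)
  r <- max(1L, ceiling(4 * sigma))
  x <- (-r):r
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# zero-padded 1-D convolution along `axis` of a 3-D array
convolve_axis <- function(arr, kernel, axis) {
  d <- dim(arr)
  perm <- switch(axis, `1` = 1:3, `2` = c(2, 1, 3), `3` = c(3, 1, 2))
  a <- aperm(arr, perm)
  dp <- dim(a)
  n <- dp[1]
  m <- matrix(a, nrow = n)
  r <- (length(kernel) - 1L) / 2L
  pad <- matrix(0, nrow = r, ncol = ncol(m))
  mp <- rbind(pad, m, pad)
  out <- matrix(0, nrow = n, ncol = ncol(m))
  for (t in seq_along(kernel)) {
    out <- out + kernel[t] * mp[seq_len(n) + (t - 1L), , drop = FALSE]
  }
  # kernel index t corresponds to offset t-1-r; the loop above slides the
  # padded matrix so row i accumulates sum_k kernel[k] * m[i + k - 1 - r]
  b <- array(out, dim = dp)
  aperm(b, order(perm))
}

#' Local maxima of a statistical map
#'
#' Returns in-mask voxels strictly above `threshold` that are greater than or
#' equal to all of their 26-connected neighbours, then greedily suppresses
#' peaks closer than `min_separation_mm` to a stronger peak (descending-value
#' order).
#'
#' @param map A `stat_map`.
#' @param threshold Minimum value (exclusive).
#' @param min_separation_mm Minimum Euclidean distance between reported peaks.
#' @param source Provenance tag stored on the peak set.
#' @return A `peak_set`: data frame with columns `x`, `y`, `z` (MNI mm),
#'   `value`, `rank`, plus attribute `source`.
#' @export
local_maxima <- function(map, threshold, min_separation_mm = 8,
                         source = "map") {
  stopifnot(inherits(map, "stat_map"), is.finite(threshold))
  v <- map$values
  m <- map$grid$mask
  v[!m] <- -Inf
  d <- dim(v)
  cand <- v > threshold
  if (any(cand)) {
    shifts <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
    shifts <- shifts[!(shifts$dx == 0 & shifts$dy == 0 & shifts$dz == 0), ]
    is_max <- cand
    for (s in seq_len(nrow(shifts))) {
      nb <- shift_array(v, c(shifts$dx[s], shifts$dy[s], shifts$dz[s]), -Inf)
      is_max <- is_max & (v >= nb)
    }
  } else {
    is_max <- cand
  }
  idx <- which(is_max, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(empty_peak_set(source))
  vals <- v[is_max]
  ord <- order(vals, decreasing = TRUE)
  idx <- idx[ord, , drop = FALSE]
  vals <- vals[ord]
  xyz <- voxel_to_mni(map$grid, idx)
  if (!is.matrix(xyz)) xyz <- matrix(xyz, nrow = 1)
  keep <- integer(0)
  for (i in seq_along(vals)) {
    if (length(keep) == 0L) {
      keep <- i
    } else {
      dmin <- min(sqrt(rowSums(
        (xyz[keep, , drop = FALSE] -
           matrix(xyz[i, ], length(keep), 3, byrow = TRUE))^2)))
      if (dmin >= min_separation_mm) keep <- c(keep, i)
    }
  }
  peak_set(xyz[keep, , drop = FALSE], vals[keep], source = source)
}

# shift array contents by integer offset, filling vacated cells
shift_array <- function(arr, offset, fill) {
  d <- dim(arr)
  out <- array(fill, dim = d)
  src <- dst <- vector("list", 3)
  for (a in 1:3) {
    o <- offset[a]
    if (o >= 0) {
      dst[[a]] <- seq_len(d[a] - o) + o
      src[[a]] <- seq_len(d[a] - o)
    } else {
      dst[[a]] <- seq_len(d[a] + o)
      src[[a]] <- seq_len(d[a] + o) - o
    }
    if (length(dst[[a]]) == 0L) return(out)
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- arr[src[[1]], src[[2]], src[[3]]]
  out
}

#' Construct a peak set
#'
#' @param xyz_mm n x 3 matrix of MNI coordinates.
#' @param values Peak values, one per row; rows must arrive or will be sorted
#'   in descending value order (rank 1 = global maximum).
#' @param source Provenance tag (component id or contrast name).
#' @return A `peak_set` data frame.
#' @export
peak_set <- function(xyz_mm, values, source = "map") {
  xyz_mm <- matrix(xyz_mm, ncol = 3)
  ord <- order(values, decreasing = TRUE)
  df <- data.frame(x = xyz_mm[ord, 1], y = xyz_mm[ord, 2], z = xyz_mm[ord, 3],
                   value = values[ord], rank = seq_along(ord))
  attr(df, "source") <- source
  class(df) <- c("peak_set", "data.frame")
  df
}

empty_peak_set <- function(source = "map") {
  df <- data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                   value = numeric(0), rank = integer(0))
  attr(df, "source") <- source
  class(df) <- c("peak_set", "data.frame")
  df
}

#' Write a peak set to TSV
#'
#' Columns: source, rank, x, y, z, value.
#'
#' @param peaks A `peak_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peaks_tsv <- function(peaks, path) {
  df <- data.frame(source = attr(peaks, "source") %||% "map",
                   rank = peaks$rank, x = peaks$x, y = peaks$y, z = peaks$z,
                   value = peaks$value)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
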