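# Independent oracles used to derive expected values.

# nearest-voxel search by exhaustive scan over all voxel centres
oracle_nearest_voxel <- function(grid, xyz) {
  co <- grid_coordinates(grid)
  d2 <- (co[, 1] - xyz[1])^2 + (co[, 2] - xyz[2])^2 + (co[, 3] - xyz[3])^2
  i <- which.min(d2)
  d <- grid$dim
  k <- (i - 1) %/% (d[1] * d[2])
  j <- ((i - 1) %% (d[1] * d[2])) %/% d[1]
  ii <- (i - 1) %% d[1]
  as.integer(c(ii, j, k) + 1L)
}

# brute-force peak finder: per-candidate 3x3x3 neighbourhood scan followed by
# the same greedy distance suppression, written independently of the
# shift-array implementation under test
oracle_local_maxima <- function(map, threshold, min_sep) {
  v <- map$values
  v[!map$grid$mask] <- -Inf
  d <- dim(v)
  cand <- which(v > threshold, arr.ind = TRUE)
  keep <- logical(nrow(cand))
  for (r in seq_len(nrow(cand))) {
    i <- cand[r, 1]; j <- cand[r, 2]; k <- cand[r, 3]
    nb <- v[max(1, i - 1):min(d[1], i + 1),
            max(1, j - 1):min(d[2], j + 1),
            max(1, k - 1):min(d[3], k + 1)]
    keep[r] <- v[i, j, k] >= max(nb)
  }
  cand <- cand[keep, , drop = FALSE]
  if (nrow(cand) == 0L) {
    return(data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                      value = numeric(0)))
  }
  vals <- v[cand]
  ord <- order(vals, decreasing = TRUE)
  cand <- cand[ord, , drop = FALSE]
  vals <- vals[ord]
  xyz <- voxel_to_mni(map$grid, cand)
  if (!is.matrix(xyz)) xyz <- matrix(xyz, nrow = 1)
  sel <- integer(0)
  for (i in seq_along(vals)) {
    ok <- TRUE
    for (s in sel) {
      if (sqrt(sum((xyz[i, ] - xyz[s, ])^2)) < min_sep) { ok <- FALSE; break }
    }
    if (ok) sel <- c(sel, i)
  }
  data.frame(x = xyz[sel, 1], y = xyz[sel, 2], z = xyz[sel, 3],
             value = vals[sel])
}

# small all-mask grid for fast unit tests
tiny_grid <- function(dim = c(12, 12, 12), vox = 3) {
  volume_grid(dim = dim, voxel_size_mm = rep(vox, 3),
              origin_mm = -vox * (dim - 1) / 2,
              mask = array(TRUE, dim = dim))
}

# random smooth map on a grid (seeded by caller)
random_smooth_map <- function(grid, fwhm = 9) {
  m <- stat_map(grid, array(stats::rnorm(prod(grid$dim)), dim = grid$dim))
  gaussian_smooth(m, fwhm)
}

# linear index of a voxel among in-mask voxels (for glm_fit beta lookup)
mask_index <- function(grid, voxel) {
  lin <- (voxel[3] - 1) * grid$dim[1] * grid$dim[2] +
    (voxel[2] - 1) * grid$dim[1] + voxel[1]
  match(lin, which(as.vector(grid$mask)))
}
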