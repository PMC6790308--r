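#' Multiple-comparison thresholding of t maps
#'
#' Two families are supported. `FWE_voxel` controls the family-wise error
#' over in-mask voxels by Bonferroni on one-sided voxel p-values (a
#' conservative, assumption-light stand-in for random-field theory).
#' `FDR_cluster` forms clusters at an uncorrected voxel threshold
#' (26-connectivity) and applies Benjamini-Hochberg over cluster-extent
#' p-values taken from a permutation null supplied by the caller.
#'
#' @param family `"FWE_voxel"` or `"FDR_cluster"`.
#' @param alpha Corrected significance level (default 0.05).
#' @param cluster_forming_p Uncorrected voxel p forming clusters
#'   (default 0.001, `FDR_cluster` only).
#' @param min_cluster_voxels Optional minimum cluster extent k.
#' @return An object of class `threshold_spec`.
#' @export
threshold_spec <- function(family = c("FWE_voxel", "FDR_cluster"),
                           alpha = 0.05, cluster_forming_p = 0.001,
                           min_cluster_voxels = 0L) {
  family <- match.arg(family)
  stopifnot(alpha > 0, alpha < 1, cluster_forming_p > 0,
            cluster_forming_p < 1)
  structure(list(family = family, alpha = alpha,
                 cluster_forming_p = cluster_forming_p,
                 min_cluster_voxels = as.integer(min_cluster_voxels)),
            class = "threshold_spec")
}

#' Apply a significance threshold to a t map
#'
#' @param map A `stat_map` of kind `"t"`.
#' @param spec A `threshold_spec`.
#' @param dof Degrees of freedom of the t statistic (defaults to the map's
#'   `dof` attribute).
#' @param null_maps For `FDR_cluster`: list of null t maps (same grid) from
#'   which the null cluster-extent distribution is pooled, e.g. from
#'   [perm_null_tmaps()] or sign-flipped paired differences.
#' @return List with `map` (thresholded `stat_map`; subthreshold voxels set
#'   to 0) and `clusters` (data frame: cluster id, size in voxels, peak
#'   value, peak MNI x/y/z).
#' @export
apply_threshold <- function(map, spec, dof = attr(map, "dof"),
                            null_maps = NULL) {
  stopifnot(inherits(map, "stat_map"), map$kind == "t",
            inherits(spec, "threshold_spec"))
  if (is.null(dof) || dof <= 0) stop("positive dof required")
  nvox <- sum(map$grid$mask)
  if (spec$family == "FWE_voxel") {
    tcut <- stats::qt(1 - spec$alpha / nvox, df = dof)
    supra <- map$values > tcut & map$grid$mask
  } else {
    tform <- stats::qt(1 - spec$cluster_forming_p, df = dof)
    supra <- map$values > tform & map$grid$mask
    if (any(supra)) {
      if (is.null(null_maps))
        stop("FDR_cluster thresholding needs null_maps for the cluster-size null")
      lab <- label_clusters(supra)
      sizes <- tabulate(lab[supra])
      null_sizes <- unlist(lapply(null_maps, function(nm) {
        ns <- nm$values > tform & nm$grid$mask
        if (!any(ns)) return(integer(0))
        nl <- label_clusters(ns)
        tabulate(nl[ns])
      }))
      nnull <- length(null_sizes)
      pvals <- vapply(sizes, function(k)
        (1 + sum(null_sizes >= k)) / (1 + nnull), numeric(1))
      keep_ids <- which(pvals <= bh_cutoff(pvals, spec$alpha) &
                          sizes >= spec$min_cluster_voxels)
      supra <- supra & array(lab %in% keep_ids, dim = dim(lab))
    }
  }
  vals <- map$values
  vals[!supra] <- 0
  out <- stat_map(map$grid, vals, kind = "t")
  attr(out, "dof") <- dof
  list(map = out, clusters = cluster_table(out, supra))
}

# largest p passing Benjamini-Hochberg at level alpha; -Inf if none
bh_cutoff <- function(pvals, alpha) {
  if (length(pvals) == 0) return(-Inf)
  ps <- sort(pvals)
  ok <- ps <= alpha * seq_along(ps) / length(ps)
  if (!any(ok)) return(-Inf)
  ps[max(which(ok))]
}

# 26-connected component labels of a logical array, by iterated min-label
# propagation (converges in O(cluster diameter) sweeps)
label_clusters <- function(supra) {
  d <- dim(supra)
  lab <- array(0, dim = d)
  lab[supra] <- seq_len(sum(supra))
  shifts <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  shifts <- shifts[rowSums(abs(shifts)) > 0, , drop = FALSE]
  big <- prod(d) + 1
  repeat {
    lab0 <- lab
    work <- lab
    work[!supra] <- big
    for (s in seq_len(nrow(shifts))) {
      nb <- shift_array(work, shifts[s, ], big)
      lab[supra] <- pmin(lab[supra], nb[supra])
    }
    if (identical(lab, lab0)) break
  }
  # compact labels to 1..n_clusters
  ids <- sort(unique(lab[supra]))
  lab[supra] <- match(lab[supra], ids)
  lab
}

# summary table of surviving clusters
cluster_table <- function(map, supra) {
  if (!any(supra)) {
    return(data.frame(cluster = integer(0), size = integer(0),
                      peak = numeric(0), x = numeric(0), y = numeric(0),
                      z = numeric(0)))
  }
  lab <- label_clusters(supra)
  ids <- sort(unique(lab[supra]))
  rows <- lapply(ids, function(id) {
    idx <- which(lab == id, arr.ind = TRUE)
    v <- map$values[lab == id]
    pk <- which.max(v)
    xyz <- voxel_to_mni(map$grid, idx[pk, ])
    data.frame(cluster = id, size = nrow(idx), peak = max(v),
               x = xyz[1], y = xyz[2], z = xyz[3])
  })
  out <- do.call(rbind, rows)
  out[order(-out$size), , drop = FALSE]
}

#' Null t maps by residual permutation
#'
#' Builds the permutation null for cluster-extent inference: the GLM
#' residuals (which obey the null of no condition effect) are permuted in
#' time with a common permutation across voxels and refitted against the
#' design, yielding one null t map per permutation.
#'
#' @param fit A `glm_fit`.
#' @param contrast Named contrast vector.
#' @param n_perm Number of permutations (default 500).
#' @param seed Integer seed.
#' @return List of `stat_map`s of kind `"t"`.
#' @export
perm_null_tmaps <- function(fit, contrast = c(SG = 1, TL = -1),
                            n_perm = 500, seed = 1L) {
  cv <- contrast_vector(fit, contrast)
  X <- fit$design$X
  qrX <- qr(X)
  varc <- drop(t(cv) %*% fit$xtx_inv %*% cv)
  R <- t(fit$residuals)                       # time x voxels
  n <- nrow(R)
  grid <- fit$grid
  midx <- which(as.vector(grid$mask))
  with_seed(seed, {
    lapply(seq_len(n_perm), function(p) {
      Rp <- R[sample.int(n), , drop = FALSE]
      beta <- qr.coef(qrX, Rp)
      res <- qr.resid(qrX, Rp)
      s2 <- colSums(res^2) / fit$dof
      t <- drop(crossprod(beta, cv)) / sqrt(s2 * varc)
      t[!is.finite(t)] <- 0
      vals <- numeric(prod(grid$dim))
      vals[midx] <- t
      out <- stat_map(grid, vals, kind = "t")
      attr(out, "dof") <- fit$dof
      out
    })
  })
}
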