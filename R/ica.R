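#' Spatial ICA of resting-state runs
#'
#' The decomposition is spatial: voxels are the realisations, each component
#' is a spatial map independent of the others over voxels, and its single
#' time course is the corresponding mixing column. Whitening reduces the
#' temporal dimension by PCA; unmixing uses extended Infomax
#' (natural-gradient entropy maximisation with a kurtosis-switching
#' nonlinearity).
#'
#' @name ica
NULL

#' ICA configuration
#'
#' @param n_components Number of components (default 55, mirroring the
#'   clinical protocol; it is validated against the temporal rank of the data
#'   and desk-scale simulations typically use 15-25).
#' @param learning_rate Initial natural-gradient step (default 0.1).
#' @param max_iter Maximum iterations (default 500).
#' @param tol Convergence tolerance on the relative weight update
#'   (default 1e-7).
#' @param extended Use the kurtosis-switching (extended) nonlinearity,
#'   robust to sub-Gaussian sources (default `TRUE`).
#' @param seed Integer seed for the weight initialisation.
#' @return An object of class `ica_config`.
#' @export
ica_config <- function(n_components = 55L, learning_rate = 0.1,
                       max_iter = 500L, tol = 1e-7, extended = TRUE,
                       seed = 1L) {
  stopifnot(n_components >= 1, learning_rate > 0, max_iter >= 1, tol > 0)
  structure(list(n_components = as.integer(n_components),
                 learning_rate = learning_rate,
                 max_iter = as.integer(max_iter), tol = tol,
                 extended = isTRUE(extended), seed = as.integer(seed)),
            class = "ica_config")
}

#' PCA whitening of a BOLD run (temporal reduction)
#'
#' Centres each time point over voxels, then projects the time x voxel data
#' onto the top `n_components` temporal eigenvectors, scaled so the reduced
#' spatial series are mutually uncorrelated with unit variance over voxels.
#'
#' @param run A `bold_run`.
#' @param n_components Number of retained components; must not exceed the
#'   rank of the centred data.
#' @return List with `Y` (components x voxels, white), `whitener`
#'   (components x time), `dewhitener` (time x components, back-projection),
#'   `mean` (per-timepoint mean), `explained_variance` (fraction),
#'   `eigenvalues`.
#' @export
pca_whiten <- function(run, n_components) {
  stopifnot(inherits(run, "bold_run"))
  X <- run_matrix(run)                        # voxels x time
  V <- nrow(X)
  mu <- colMeans(X)
  Xc <- t(sweep(X, 2, mu))                    # time x voxels, centred
  C <- tcrossprod(Xc) / V                     # time x time covariance
  eg <- eigen(C, symmetric = TRUE)
  pos <- eg$values > max(eg$values) * 1e-10
  rank <- sum(pos)
  if (n_components > rank)
    stop(sprintf("n_components = %d exceeds the temporal rank %d of the data",
                 n_components, rank))
  idx <- seq_len(n_components)
  U <- eg$vectors[, idx, drop = FALSE]
  d <- eg$values[idx]
  whitener <- diag(1 / sqrt(d), n_components) %*% t(U)
  dewhitener <- U %*% diag(sqrt(d), n_components)
  list(Y = whitener %*% Xc, whitener = whitener, dewhitener = dewhitener,
       mean = mu, explained_variance = sum(d) / sum(eg$values[pos]),
       eigenvalues = eg$values)
}

#' Extended Infomax unmixing
#'
#' Natural-gradient ascent of the Infomax objective on whitened data. With
#' `extended = TRUE` the per-source nonlinearity switches sign with the
#' estimated kurtosis (Lee-Girolami-Sejnowski rule `I - K tanh(u) u' - u u'`);
#' otherwise the logistic rule `I + (1 - 2 g(u)) u'` is used. The learning
#' rate is annealed when an update overshoots. Rows of the result are scaled
#' so recovered sources have unit variance.
#'
#' @param Y Whitened data, components x observations (spatial orientation:
#'   observations are voxels).
#' @param config An `ica_config`.
#' @return List with `W` (unmixing matrix), `iterations`, `final_change`,
#'   `converged`, `kurtosis_signs`.
#' @export
infomax_unmix <- function(Y, config = ica_config(n_components = nrow(Y))) {
  K <- nrow(Y)
  V <- ncol(Y)
  lr <- config$learning_rate
  with_seed(config$seed, {
    W0 <- matrix(stats::rnorm(K * K), K, K)
    W <- qr.Q(qr(W0))                        # random orthonormal start
  })
  I <- diag(K)
  change <- Inf
  iter <- 0L
  signs <- rep(1, K)
  while (iter < config$max_iter && change > config$tol) {
    iter <- iter + 1L
    u <- W %*% Y
    if (config$extended) {
      if (iter %% 5L == 1L) {
        m2 <- rowMeans(u^2)
        m4 <- rowMeans(u^4)
        signs <- sign(m4 / m2^2 - 3)
        signs[signs == 0] <- 1
      }
      G <- (I - (signs * tanh(u)) %*% t(u) / V - u %*% t(u) / V) %*% W
    } else {
      gu <- 1 / (1 + exp(-u))
      G <- (I + (1 - 2 * gu) %*% t(u) / V) %*% W
    }
    Wn <- W + lr * G
    change <- sqrt(sum((lr * G)^2) / sum(W^2))
    if (!is.finite(change) || change > 1) {   # overshoot: anneal and restart step
      lr <- lr / 2
      change <- Inf
      next
    }
    W <- Wn
  }
  converged <- change <= config$tol
  if (!converged)
    warning(sprintf("Infomax did not converge in %d iterations (change %.2e)",
                    iter, change))
  # unit-variance sources
  u <- W %*% Y
  sds <- sqrt(rowMeans(u^2) - rowMeans(u)^2)
  W <- W / sds
  u <- u / sds
  kurt <- rowMeans(u^4) - 3  # excess kurtosis; near 0 flags Gaussian sources
  list(W = W, iterations = iter, final_change = change,
       converged = converged, kurtosis_signs = signs,
       source_kurtosis = kurt)
}

#' Spatial ICA decomposition of a resting-state run
#'
#' Whitens to `n_components`, runs extended Infomax, z-scores each spatial
#' map over in-mask voxels and fixes each component's sign so its spatial
#' skewness is non-negative (activation positive, making a z = 2 threshold
#' meaningful). Components are ordered by explained variance of their
#' back-projection.
#'
#' @param run A preprocessed `bold_run` (initial volumes discarded,
#'   optionally smoothed).
#' @param config An `ica_config`.
#' @return An object of class `ica_decomposition`: `spatial_maps` (list of
#'   `stat_map`s of kind `"z"`), `time_courses` (volumes x components),
#'   `diagnostics`, `config`.
#' @export
decompose_rest <- function(run, config = ica_config()) {
  wh <- pca_whiten(run, config$n_components)
  um <- infomax_unmix(wh$Y, config)
  S <- um$W %*% wh$Y                           # components x voxels
  A <- wh$dewhitener %*% solve(um$W)           # time x components mixing
  # order by mixing-column energy (variance explained by each component)
  energy <- colSums(A^2) * rowMeans(S^2)
  ord <- order(energy, decreasing = TRUE)
  S <- S[ord, , drop = FALSE]
  A <- A[, ord, drop = FALSE]
  grid <- run$grid
  midx <- as.vector(grid$mask)
  maps <- vector("list", nrow(S))
  for (k in seq_len(nrow(S))) {
    s <- S[k, ]
    s <- (s - mean(s)) / stats::sd(s)
    sk <- mean(s^3)
    if (sk < 0) {
      s <- -s
      A[, k] <- -A[, k]
    }
    vals <- numeric(prod(grid$dim))
    vals[midx] <- s
    maps[[k]] <- stat_map(grid, vals, kind = "z")
  }
  structure(list(spatial_maps = maps, time_courses = A,
                 diagnostics = list(iterations = um$iterations,
                                    final_change = um$final_change,
                                    converged = um$converged,
                                    kurtosis_signs = um$kurtosis_signs,
                                    source_kurtosis = um$source_kurtosis[ord],
                                    explained_variance = wh$explained_variance),
                 config = config),
            class = "ica_decomposition")
}

#' @export
print.ica_decomposition <- function(x, ...) {
  cat(sprintf("<ica_decomposition> %d components, %d volumes, %s in %d iterations\n",
              length(x$spatial_maps), nrow(x$time_courses),
              if (x$diagnostics$converged) "converged" else "NOT converged",
              x$diagnostics$iterations))
  invisible(x)
}

#' Threshold a component z map
#'
#' Values less than or equal to `z` are set to 0; the mask is unchanged.
#'
#' @param map A `stat_map` of kind `"z"`.
#' @param z Threshold (default 2).
#' @return A thresholded `stat_map`.
#' @export
threshold_component <- function(map, z = 2.0) {
  stopifnot(inherits(map, "stat_map"), !is.na(z))  # -Inf allowed: identity
  vals <- map$values
  vals[vals <= z] <- 0
  stat_map(map$grid, vals, kind = map$kind)
}

#' Match decomposition components to ground-truth maps
#'
#' Greedy one-to-one assignment of components to templates by descending
#' in-mask Pearson spatial correlation (absolute value; component sign is a
#' convention). The greedy assignment is a feasible one, so the correlations
#' it reports are lower bounds on the best assignment's.
#'
#' @param decomp An `ica_decomposition`.
#' @param truth_maps Named list of `stat_map`s (planted templates).
#' @return Data frame: template, component index, spatial correlation.
#' @export
match_components <- function(decomp, truth_maps) {
  midx <- as.vector(decomp$spatial_maps[[1]]$grid$mask)
  Tm <- vapply(truth_maps, function(m) as.vector(m$values)[midx],
               numeric(sum(midx)))
  Cm <- vapply(decomp$spatial_maps, function(m) as.vector(m$values)[midx],
               numeric(sum(midx)))
  colnames(Cm) <- seq_along(decomp$spatial_maps)
  R <- abs(stats::cor(Tm, Cm))
  out <- data.frame(template = character(0), component = integer(0),
                    correlation = numeric(0))
  while (nrow(R) > 0 && ncol(R) > 0 && any(is.finite(R))) {
    best <- which(R == max(R), arr.ind = TRUE)[1, ]
    out <- rbind(out, data.frame(template = rownames(R)[best[1]],
                                 component = as.integer(colnames(R)[best[2]]),
                                 correlation = R[best[1], best[2]]))
    R <- R[-best[1], -best[2], drop = FALSE]
  }
  out[order(out$template), , drop = FALSE]
}

#' Save a decomposition to disk
#'
#' One 4D NIfTI of z maps, a TSV of time courses and a JSON of diagnostics.
#'
#' @param decomp An `ica_decomposition`.
#' @param prefix Output path prefix.
#' @return `prefix`, invisibly.
#' @export
write_decomposition <- function(decomp, prefix) {
  grid <- decomp$spatial_maps[[1]]$grid
  arr <- array(0, dim = c(grid$dim, length(decomp$spatial_maps)))
  for (k in seq_along(decomp$spatial_maps))
    arr[, , , k] <- decomp$spatial_maps[[k]]$values
  img <- RNifti::asNifti(arr)
  img <- RNifti::`sform<-`(img, structure(grid$affine, code = 4L))
  RNifti::writeNifti(img, paste0(prefix, "_zmaps.nii.gz"),
                     datatype = "double")
  utils::write.table(decomp$time_courses,
                     paste0(prefix, "_timecourses.tsv"),
                     sep = "\t", row.names = FALSE,
                     col.names = paste0("IC", seq_len(ncol(decomp$time_courses))))
  jsonlite::write_json(decomp$diagnostics, paste0(prefix, "_diagnostics.json"),
                       auto_unbox = TRUE)
  invisible(prefix)
}
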