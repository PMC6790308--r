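#' Canonical haemodynamic response function
#'
#' The double-gamma model: a gamma density peaking at 6 s minus an undershoot
#' gamma peaking at 16 s scaled by 1/6 (dispersions 1), evaluated over 32 s
#' and sampled every `tr_s` seconds, then normalised to a peak of 1.
#'
#' @param tr_s Sampling interval, s.
#' @return Numeric kernel of length `floor(32 / tr_s) + 1`.
#' @export
canonical_hrf <- function(tr_s) {
  stopifnot(tr_s > 0)
  t <- seq(0, 32, by = tr_s)
  h <- stats::dgamma(t, shape = 6, rate = 1) -
    stats::dgamma(t, shape = 16, rate = 1) / 6
  h / max(h)
}

#' Discard initial volumes of a run
#'
#' Drops the first `n` volumes (longitudinal-magnetisation stabilisation),
#' trimming the condition track and any ground-truth regressor consistently.
#' Block-design onsets must be shifted separately with
#' [shift_block_design()].
#'
#' @param run A `bold_run`.
#' @param n Number of volumes to drop (default 3).
#' @return A shortened `bold_run`.
#' @export
discard_initial_volumes <- function(run, n = 3L) {
  stopifnot(inherits(run, "bold_run"))
  n <- as.integer(n)
  if (n < 0 || n >= run$n_volumes)
    stop(sprintf("cannot discard %d of %d volumes", n, run$n_volumes))
  if (n == 0L) return(run)
  keep <- (n + 1L):run$n_volumes
  gt <- run$ground_truth
  if (!is.null(gt$time_courses)) gt$time_courses <- gt$time_courses[keep, , drop = FALSE]
  if (!is.null(gt$regressor)) gt$regressor <- gt$regressor[keep]
  bold_run(run$grid, run$data[, , , keep, drop = FALSE], tr_s = run$tr_s,
           condition_track = run$condition_track[keep],
           ground_truth = gt, seed = run$seed)
}

#' Shift block-design onsets
#'
#' Subtracts `shift_s` seconds from every onset (e.g. after discarding
#' initial volumes); epochs that now start before time zero are clipped at
#' acquisition start when regressors are built.
#'
#' @param design A `block_design`.
#' @param shift_s Seconds to subtract from each onset.
#' @return A shifted `block_design`.
#' @export
shift_block_design <- function(design, shift_s) {
  design$onsets <- lapply(design$onsets, function(o) o - shift_s)
  design$total_s <- design$total_s - shift_s
  design
}

#' Build a task design matrix
#'
#' Columns: the SG and TL boxcars convolved with the canonical HRF and
#' sampled at volume times, discrete-cosine drift regressors for every
#' frequency below `1 / highpass_cutoff_s` Hz, and an intercept. No
#' global-signal column is included.
#'
#' @param design A `block_design` (onsets already shifted to the analysed
#'   run's clock).
#' @param n_timepoints Number of volumes in the analysed run.
#' @param tr_s Repetition time, s.
#' @param highpass_cutoff_s High-pass cutoff period, s (default 128; the
#'   number of drift columns is `floor(2 * n * tr / cutoff)`).
#' @param hrf_dt Sampling interval of the fine HRF grid used for the
#'   convolution (default 0.1 s).
#' @return An object of class `design_matrix`: list with `X` (time x
#'   regressors), `columns`, `tr_s`.
#' @export
build_design <- function(design, n_timepoints, tr_s = 2.28,
                         highpass_cutoff_s = 128, hrf_dt = 0.1) {
  stopifnot(inherits(design, "block_design"), n_timepoints > 1)
  hrf <- canonical_hrf(hrf_dt)
  task_cols <- lapply(design$conditions, function(cond)
    convolved_regressor(design, cond, n_timepoints, tr_s, hrf = hrf))
  names(task_cols) <- design$conditions
  X <- do.call(cbind, task_cols)
  dct <- dct_drift_basis(n_timepoints, tr_s, highpass_cutoff_s)
  X <- cbind(X, dct, intercept = 1)
  colnames(X) <- c(design$conditions,
                   if (ncol(dct) > 0) paste0("dct", seq_len(ncol(dct))),
                   "intercept")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("design matrix is rank deficient; collinear columns: ",
         paste(dropped, collapse = ", "))
  }
  structure(list(X = X, columns = colnames(X), tr_s = tr_s),
            class = "design_matrix")
}

# DCT-II drift columns with frequencies below 1/cutoff Hz (constant excluded)
dct_drift_basis <- function(n, tr_s, cutoff_s) {
  total_s <- n * tr_s
  K <- floor(2 * total_s / cutoff_s)
  if (K < 1) return(matrix(numeric(0), nrow = n, ncol = 0))
  t <- seq_len(n) - 1
  sapply(seq_len(K), function(k)
    sqrt(2 / n) * cos(pi * (2 * t + 1) * k / (2 * n)))
}

#' Fit a voxel-wise GLM
#'
#' Ordinary least squares of every in-mask voxel time course on the design.
#'
#' @param run A `bold_run` (after initial-volume discard).
#' @param design A `design_matrix` with as many rows as the run has volumes.
#' @return An object of class `glm_fit`: in-mask beta matrix (voxels x
#'   regressors), residual variance, residuals, degrees of freedom, the
#'   design and grid.
#' @export
fit_glm <- function(run, design) {
  stopifnot(inherits(run, "bold_run"), inherits(design, "design_matrix"))
  X <- design$X
  if (nrow(X) != run$n_volumes)
    stop(sprintf("design has %d rows but run has %d volumes",
                 nrow(X), run$n_volumes))
  Y <- t(run_matrix(run))                      # time x voxels
  qrX <- qr(X)
  beta <- qr.coef(qrX, Y)                      # regressors x voxels
  resid <- qr.resid(qrX, Y)
  dof <- nrow(X) - qrX$rank
  sigma2 <- colSums(resid^2) / dof
  structure(list(beta = t(beta), sigma2 = sigma2, residuals = t(resid),
                 dof = dof, xtx_inv = chol2inv(qr.R(qrX)),
                 design = design, grid = run$grid),
            class = "glm_fit")
}

#' @export
print.glm_fit <- function(x, ...) {
  cat(sprintf("<glm_fit> %d voxels, %d regressors, dof %d\n",
              nrow(x$beta), ncol(x$beta), x$dof))
  invisible(x)
}

# resolve a named contrast vector against the design columns
contrast_vector <- function(fit, contrast) {
  cols <- fit$design$columns
  unknown <- setdiff(names(contrast), cols)
  if (length(unknown) > 0)
    stop("unknown regressor(s) in contrast: ", paste(unknown, collapse = ", "))
  cv <- numeric(length(cols))
  names(cv) <- cols
  cv[names(contrast)] <- contrast
  cv
}

#' t-contrast map of a GLM fit
#'
#' `t = c'beta / sqrt(sigma2 * c'(X'X)^-1 c)` per voxel. Voxels with zero
#' residual variance (t undefined) are removed from the output mask.
#'
#' @param fit A `glm_fit`.
#' @param contrast Named numeric vector of contrast weights over design
#'   columns, default `c(SG = 1, TL = -1)`.
#' @return A `stat_map` of kind `"t"` with attributes `dof`.
#' @export
t_contrast <- function(fit, contrast = c(SG = 1, TL = -1)) {
  cv <- contrast_vector(fit, contrast)
  eff <- drop(fit$beta %*% cv)
  varc <- drop(t(cv) %*% fit$xtx_inv %*% cv)
  se <- sqrt(fit$sigma2 * varc)
  t <- eff / se
  # numerically-zero residual variance (relative to the fitted scale) means
  # the t statistic is undefined, not huge
  zero_tol <- (1e-10 * max(1e-300, max(abs(fit$beta))))^2
  defined <- is.finite(t) & fit$sigma2 > zero_tol
  grid <- fit$grid
  vals <- numeric(prod(grid$dim))
  midx <- which(as.vector(grid$mask))
  vals[midx] <- ifelse(defined, t, 0)
  newmask <- array(FALSE, dim = grid$dim)
  newmask[midx[defined]] <- TRUE
  grid$mask <- newmask
  out <- stat_map(grid, vals, kind = "t")
  attr(out, "dof") <- fit$dof
  out
}

#' Fixed-effects pooling of session contrasts
#'
#' Pools the same contrast over several sessions of one subject: the pooled
#' effect is the mean of per-session effects and its variance the sum of
#' per-session variances divided by the squared session count; degrees of
#' freedom add.
#'
#' @param fits List of `glm_fit` objects on a common grid.
#' @param contrast Named contrast vector (as in [t_contrast()]).
#' @return A `stat_map` of kind `"t"` with attribute `dof`.
#' @export
t_contrast_pooled <- function(fits, contrast = c(SG = 1, TL = -1)) {
  stopifnot(length(fits) >= 1)
  S <- length(fits)
  effs <- vars <- NULL
  dof <- 0
  for (f in fits) {
    cv <- contrast_vector(f, contrast)
    eff <- drop(f$beta %*% cv)
    varc <- drop(t(cv) %*% f$xtx_inv %*% cv)
    effs <- if (is.null(effs)) eff else effs + eff
    vars <- if (is.null(vars)) f$sigma2 * varc else vars + f$sigma2 * varc
    dof <- dof + f$dof
  }
  t <- (effs / S) / sqrt(vars / S^2)
  grid <- fits[[1]]$grid
  defined <- is.finite(t)
  vals <- numeric(prod(grid$dim))
  midx <- which(as.vector(grid$mask))
  vals[midx] <- ifelse(defined, t, 0)
  newmask <- array(FALSE, dim = grid$dim)
  newmask[midx[defined]] <- TRUE
  grid$mask <- newmask
  out <- stat_map(grid, vals, kind = "t")
  attr(out, "dof") <- dof
  out
}
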