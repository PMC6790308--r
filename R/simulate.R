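#' Synthetic BOLD runs
#'
#' Generators for resting-state and block-task 4D BOLD series directly in
#' template space, with ground truth attached for recovery testing. All
#' generators are pure functions of their arguments including `seed`: the
#' global RNG state is saved and restored, and identical seeds give
#' bit-identical output.
#'
#' @name simulate
NULL

# evaluate expr under a local RNG seeded with `seed`, restoring global state
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Construct a BOLD run object
#'
#' @param grid A `volume_grid`.
#' @param data 4D numeric array, `c(grid$dim, n_volumes)`.
#' @param tr_s Repetition time in seconds (default 2.28).
#' @param condition_track Optional character vector, one label per volume
#'   (`"SG"`, `"TL"` or `"rest"`).
#' @param ground_truth Optional list (planted maps and time courses).
#' @param seed Integer seed the run was generated with, or `NA`.
#' @return An object of class `bold_run`.
#' @export
bold_run <- function(grid, data, tr_s = 2.28, condition_track = NULL,
                     ground_truth = NULL, seed = NA_integer_) {
  stopifnot(inherits(grid, "volume_grid"), tr_s > 0,
            length(dim(data)) == 4L,
            identical(dim(data)[1:3], as.integer(grid$dim)))
  n <- dim(data)[4]
  if (!is.null(condition_track)) stopifnot(length(condition_track) == n)
  structure(list(grid = grid, data = data, tr_s = tr_s,
                 n_volumes = n, condition_track = condition_track,
                 ground_truth = ground_truth, seed = seed),
            class = "bold_run")
}

#' @export
print.bold_run <- function(x, ...) {
  cat(sprintf("<bold_run> %d volumes, TR %.3g s, grid %d x %d x %d\n",
              x$n_volumes, x$tr_s, x$grid$dim[1], x$grid$dim[2], x$grid$dim[3]))
  invisible(x)
}

# in-mask voxels x time matrix view of a run
run_matrix <- function(run) {
  m <- matrix(run$data, nrow = prod(run$grid$dim), ncol = run$n_volumes)
  m[as.vector(run$grid$mask), , drop = FALSE]
}

# rebuild a 4D array from an in-mask voxels x time matrix
embed_matrix <- function(grid, vmat) {
  full <- matrix(0, nrow = prod(grid$dim), ncol = ncol(vmat))
  full[as.vector(grid$mask), ] <- vmat
  array(full, dim = c(grid$dim, ncol(vmat)))
}

#' Band-limited non-Gaussian time course
#'
#' Laplacian innovations band-passed by hard truncation of the FFT to
#' `band_hz`, standardised to zero mean and unit variance. The heavy-tailed
#' innovations keep the excess kurtosis of the filtered series non-zero,
#' which spatio-temporal decompositions rely on.
#'
#' @param n Number of samples.
#' @param tr_s Sampling interval in seconds.
#' @param band_hz Length-2 pass band (Hz), inside `(0, 1/(2 tr_s))`.
#' @return Numeric vector of length `n`. Call inside a seeded context.
#' @export
band_limited_series <- function(n, tr_s, band_hz = c(0.01, 0.1)) {
  nyquist <- 1 / (2 * tr_s)
  if (band_hz[1] <= 0 || band_hz[2] > nyquist || band_hz[1] >= band_hz[2])
    stop(sprintf("band (%g, %g) Hz must lie inside (0, Nyquist = %.4g) Hz",
                 band_hz[1], band_hz[2], nyquist))
  u <- stats::runif(n) - 0.5
  innov <- -sign(u) * log(1 - 2 * abs(u))  # standard Laplace
  f <- c(0, seq_len(n - 1)) / (n * tr_s)
  f <- pmin(f, 1 / tr_s - f)  # two-sided frequency axis
  keep <- f >= band_hz[1] & f <= band_hz[2]
  x <- Re(stats::fft(stats::fft(innov) * keep, inverse = TRUE)) / n
  (x - mean(x)) / stats::sd(x)
}

#' Simulate a resting-state BOLD run
#'
#' Data are `sum_k map_k (x) s_k(t) + noise`: each planted network's spatial
#' map modulated by an independent band-limited non-Gaussian time course of
#' unit variance, plus white Gaussian voxel noise. Spatial maps (sparse
#' Gaussian blobs) carry the non-Gaussian spatial structure that spatial ICA
#' needs for identifiability.
#'
#' @param templates List of `network_template` objects.
#' @param grid A `volume_grid` (default [demo_grid()]).
#' @param n_volumes Number of volumes (default 270).
#' @param tr_s Repetition time, s (default 2.28).
#' @param band_hz Pass band of the spontaneous fluctuations, Hz
#'   (default 0.01-0.1).
#' @param noise_sd Standard deviation of the additive white noise
#'   (default 1).
#' @param seed Integer seed.
#' @return A `bold_run` with `ground_truth$maps` (named `stat_map`s) and
#'   `ground_truth$time_courses` (volumes x networks matrix).
#' @export
simulate_rest_run <- function(templates, grid = demo_grid(),
                              n_volumes = 270, tr_s = 2.28,
                              band_hz = c(0.01, 0.1), noise_sd = 1,
                              seed = 1L) {
  stopifnot(noise_sd >= 0, n_volumes >= 2)
  maps <- lapply(templates, render_network_map, grid = grid)
  names(maps) <- vapply(templates, function(t) t$name, character(1))
  mask <- as.vector(grid$mask)
  map_mat <- vapply(maps, function(m) as.vector(m$values)[mask],
                    numeric(sum(mask)))
  with_seed(seed, {
    tc <- vapply(seq_along(templates), function(k)
      band_limited_series(n_volumes, tr_s, band_hz), numeric(n_volumes))
    vmat <- map_mat %*% t(tc)
    if (noise_sd > 0)
      vmat <- vmat + matrix(stats::rnorm(length(vmat), sd = noise_sd),
                            nrow = nrow(vmat))
    colnames(tc) <- names(maps)
    bold_run(grid, embed_matrix(grid, vmat), tr_s = tr_s,
             condition_track = rep("rest", n_volumes),
             ground_truth = list(maps = maps, time_courses = tc),
             seed = as.integer(seed))
  })
}

#' Block design for the two-condition language task
#'
#' Alternating sentence-generation (SG) and tone-listening (TL) epochs of
#' `epoch_s` seconds tiling the run from time zero; a remainder shorter than
#' one epoch is left as unmodelled baseline.
#'
#' @param n_volumes Number of volumes.
#' @param tr_s Repetition time, s.
#' @param epoch_s Epoch length, s (default 16).
#' @param order Condition order within a cycle (default SG then TL).
#' @return An object of class `block_design` with per-condition onset times
#'   (s), `epoch_s`, `n_epochs` and the total run duration.
#' @export
block_design <- function(n_volumes, tr_s = 2.28, epoch_s = 16,
                         order = c("SG", "TL")) {
  stopifnot(epoch_s > 0, n_volumes > 0)
  total_s <- n_volumes * tr_s
  n_epochs <- floor(total_s / epoch_s)
  if (n_epochs < length(order))
    stop("design longer than run: not even one epoch per condition fits")
  starts <- (seq_len(n_epochs) - 1) * epoch_s
  cond <- rep_len(order, n_epochs)
  onsets <- split(starts, factor(cond, levels = unique(order)))
  structure(list(epoch_s = epoch_s, n_epochs = n_epochs,
                 conditions = unique(order), onsets = onsets,
                 total_s = total_s),
            class = "block_design")
}

#' @export
print.block_design <- function(x, ...) {
  cat(sprintf("<block_design> %d epochs of %g s (%s), run %.2f s\n",
              x$n_epochs, x$epoch_s, paste(x$conditions, collapse = "/"),
              x$total_s))
  invisible(x)
}

# condition label of each volume (volume i acquired at (i-1)*tr)
design_track <- function(design, n_volumes, tr_s) {
  t <- (seq_len(n_volumes) - 1) * tr_s
  lab <- rep("rest", n_volumes)
  for (cond in names(design$onsets)) {
    for (on in design$onsets[[cond]]) {
      lab[t >= on & t < on + design$epoch_s] <- cond
    }
  }
  lab
}

# unit-amplitude condition boxcar sampled at volume times, convolved with the
# HRF kernel on a fine grid (dt = 0.1 s) for onset accuracy
convolved_regressor <- function(design, condition, n_volumes, tr_s,
                                hrf = canonical_hrf(0.1)) {
  dt <- 0.1
  tmax <- n_volumes * tr_s + 32
  tfine <- seq(0, tmax, by = dt)
  box <- numeric(length(tfine))
  for (on in design$onsets[[condition]]) {
    box[tfine >= on & tfine < on + design$epoch_s] <- 1
  }
  conv <- stats::convolve(box, rev(hrf), type = "open")[seq_along(tfine)] * dt
  stats::approx(tfine, conv, xout = (seq_len(n_volumes) - 1) * tr_s,
                rule = 2)$y
}

#' Simulate a block-task BOLD run
#'
#' Data are `effect_size * map_active (x) (SG boxcar * HRF) + drift + noise`,
#' where `*` is convolution with the canonical double-gamma haemodynamic
#' response. The drift is a seeded random cubic polynomial per run (shared
#' across voxels), slow enough to be removed by the 128-s high-pass.
#'
#' @param active_template `network_template` activated during SG epochs.
#' @param design A `block_design`; must fit inside the run.
#' @param grid A `volume_grid` (default [demo_grid()]).
#' @param n_volumes,tr_s Acquisition length and repetition time.
#' @param effect_size BOLD amplitude of the activation (default 1).
#' @param noise_sd White-noise standard deviation (default 1).
#' @param drift_amplitude Peak-to-peak scale of the polynomial drift
#'   (default 1).
#' @param seed Integer seed.
#' @return A `bold_run` with `condition_track` filled and
#'   `ground_truth$maps$active`, `ground_truth$regressor` recorded.
#' @export
simulate_task_run <- function(active_template, design, grid = demo_grid(),
                              n_volumes = 270, tr_s = 2.28,
                              effect_size = 1, noise_sd = 1,
                              drift_amplitude = 1, seed = 1L) {
  stopifnot(inherits(design, "block_design"), effect_size >= 0,
            noise_sd >= 0)
  if (design$n_epochs * design$epoch_s > n_volumes * tr_s + 1e-9)
    stop("design longer than run")
  amap <- render_network_map(active_template, grid)
  mask <- as.vector(grid$mask)
  mvec <- as.vector(amap$values)[mask]
  reg <- convolved_regressor(design, design$conditions[1], n_volumes, tr_s)
  with_seed(seed, {
    tt <- seq(-1, 1, length.out = n_volumes)
    coefs <- stats::rnorm(4)
    drift <- drift_amplitude *
      (coefs[1] + coefs[2] * tt + coefs[3] * tt^2 + coefs[4] * tt^3)
    vmat <- effect_size * (mvec %*% t(reg)) +
      matrix(drift, nrow = length(mvec), ncol = n_volumes, byrow = TRUE)
    if (noise_sd > 0)
      vmat <- vmat + matrix(stats::rnorm(length(vmat), sd = noise_sd),
                            nrow = nrow(vmat))
    bold_run(grid, embed_matrix(grid, vmat), tr_s = tr_s,
             condition_track = design_track(design, n_volumes, tr_s),
             ground_truth = list(maps = list(active = amap),
                                 regressor = reg, design = design,
                                 effect_size = effect_size),
             seed = as.integer(seed))
  })
}

#' Temporal band-pass filter of a BOLD run
#'
#' Hard FFT truncation of every voxel time course to `band_hz`, the standard
#' resting-state preprocessing step that restricts the data to the band of
#' spontaneous network fluctuations before decomposition.
#'
#' @param run A `bold_run`.
#' @param band_hz Length-2 pass band, Hz (default 0.01-0.1).
#' @return A filtered `bold_run` (condition track and ground truth carried
#'   over unchanged).
#' @export
bandpass_bold_run <- function(run, band_hz = c(0.01, 0.1)) {
  stopifnot(inherits(run, "bold_run"))
  nyquist <- 1 / (2 * run$tr_s)
  if (band_hz[1] <= 0 || band_hz[2] > nyquist || band_hz[1] >= band_hz[2])
    stop(sprintf("band (%g, %g) Hz must lie inside (0, Nyquist = %.4g) Hz",
                 band_hz[1], band_hz[2], nyquist))
  X <- run_matrix(run)
  n <- ncol(X)
  f <- c(0, seq_len(n - 1)) / (n * run$tr_s)
  f <- pmin(f, 1 / run$tr_s - f)
  keep <- f >= band_hz[1] & f <= band_hz[2]
  Xf <- t(stats::mvfft(t(X)))
  Xf[, !keep] <- 0
  Xf <- Re(t(stats::mvfft(t(Xf), inverse = TRUE))) / n
  bold_run(run$grid, embed_matrix(run$grid, Xf), tr_s = run$tr_s,
           condition_track = run$condition_track,
           ground_truth = run$ground_truth, seed = run$seed)
}

#' Write a BOLD run to NIfTI with a JSON sidecar
#'
#' @param run A `bold_run`.
#' @param path Output `.nii`/`.nii.gz` path; the sidecar replaces the
#'   extension with `.json` and records TR, seed and the condition track.
#' @return `path`, invisibly.
#' @export
write_bold_run <- function(run, path) {
  img <- RNifti::asNifti(run$data)
  img <- RNifti::`sform<-`(img, structure(run$grid$affine, code = 4L))
  RNifti::writeNifti(img, path, datatype = "double")
  side <- sub("\\.nii(\\.gz)?$", ".json", path)
  jsonlite::write_json(
    list(tr_s = run$tr_s, n_volumes = run$n_volumes, seed = run$seed,
         condition_track = run$condition_track),
    side, auto_unbox = TRUE, null = "null")
  invisible(path)
}
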