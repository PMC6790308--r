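#' Concordance of fMRI peaks with intraoperative stimulation
#'
#' During awake craniotomy, electrocortical stimulation (ECS) sites where
#' language was transiently disturbed (aphasia, speech arrest, paraphasia)
#' are the gold standard for eloquent cortex. A site counts as detected by a
#' modality when that modality shows a peak (of activity for the task
#' contrast, of component for the resting-state language network) within
#' 10 mm of the stimulation site.
#'
#' @name concordance
NULL

#' Is a stimulation site detected by a peak set?
#'
#' Coordinate mode: detection iff the Euclidean distance from some peak to
#' the site is at most `radius_mm`. Label mode (no coordinates available):
#' detection iff some peak lies inside the named atlas region's spheres.
#'
#' @param peaks A `peak_set`.
#' @param site List with either `xyz` (MNI mm) or `region` (atlas region
#'   name).
#' @param radius_mm Detection radius (default 10).
#' @param atlas A `roi_atlas`; required in label mode.
#' @return Logical.
#' @export
site_detected <- function(peaks, site, radius_mm = 10, atlas = NULL) {
  if (!is.null(site$xyz)) {
    if (nrow(peaks) == 0) return(FALSE)
    d <- sqrt((peaks$x - site$xyz[1])^2 + (peaks$y - site$xyz[2])^2 +
                (peaks$z - site$xyz[3])^2)
    return(any(d <= radius_mm))
  }
  if (!is.null(site$region)) {
    if (is.null(atlas)) stop("label-mode detection needs an atlas")
    return(peaks_in_region(peaks, atlas, site$region)$laterality != "No")
  }
  stop("unresolvable site: needs xyz coordinates or a region label")
}

#' Load the stimulation-outcome fixture
#'
#' One row per cortical-mapping-positive stimulation site (patients can
#' contribute several sites). `rest_only = TRUE` transcribes the source
#' table's bold-face convention: an eloquent site identified by the
#' resting-state language network but missed by the task contrast. Detection
#' flags follow from that convention: the rest modality detected every CM
#' site, the task modality every non-bold site.
#'
#' @param path CSV path; defaults to the shipped fixture.
#' @return Data frame of concordance records with columns patient,
#'   site_description, region, hemisphere, rest_only, task_detected,
#'   rest_detected.
#' @export
load_concordance_sites <- function(path = lang_fixture("table7_sites.csv")) {
  df <- utils::read.csv(path)
  stopifnot(identical(names(df), c("patient", "site_description", "region",
                                   "hemisphere", "rest_only")),
            is.logical(df$rest_only))
  df$task_detected <- !df$rest_only
  df$rest_detected <- TRUE
  df
}

#' Load the per-region network detection fixture
#'
#' Task and rest language-network involvement per patient and region, in the
#' Left/Right/Bi/No vocabulary.
#'
#' @param path CSV path; defaults to the shipped fixture.
#' @return Data frame (patient, modality, MTG, ANG, TP, IFG, SMA_preSMA,
#'   dACC, AIFO).
#' @export
load_network_table <- function(path = lang_fixture("table7_networks.csv")) {
  df <- utils::read.csv(path)
  vocab <- c("Left", "Right", "Bi", "No")
  for (col in c("MTG", "ANG", "TP", "IFG", "SMA_preSMA", "dACC", "AIFO"))
    stopifnot(all(df[[col]] %in% vocab))
  df
}

#' Per-modality sensitivity against cortical mapping
#'
#' Each CM-positive stimulation site is one unit; sensitivity is
#' `100 * detected sites / all sites`, reported to one decimal.
#'
#' @param records Concordance records (see [load_concordance_sites()]);
#'   must contain at least one site.
#' @param modality `"task"` or `"rest"`.
#' @return List: `modality`, `n_cm_positive`, `n_detected`, `sensitivity`.
#' @export
sensitivity <- function(records, modality = c("task", "rest")) {
  modality <- match.arg(modality)
  if (nrow(records) == 0) stop("no CM-positive sites in records")
  det <- records[[paste0(modality, "_detected")]]
  n <- nrow(records)
  list(modality = modality, n_cm_positive = n, n_detected = sum(det),
       sensitivity = round(100 * sum(det) / n, 1))
}

#' Second-order paired comparison of task and rest maps
#'
#' Voxel-wise paired t test between per-subject task contrast maps and
#' resting-state language-network maps (both unthresholded), in both
#' directions. The task > rest direction is thresholded voxel-wise
#' (family-wise, Bonferroni); the rest > task direction cluster-wise (FDR
#' over cluster extents at a voxel-forming p < .001, null cluster sizes from
#' sign-flipping the paired differences).
#'
#' @param task_maps,rest_maps Equal-length lists (>= 2) of `stat_map`s on a
#'   common grid, paired by subject.
#' @param fwe_alpha Voxel-level FWE level for task > rest (default 0.05).
#' @param fdr_alpha Cluster-level FDR level for rest > task (default 0.05).
#' @param cluster_forming_p Voxel p forming clusters (default 0.001).
#' @param n_perm Sign-flip permutations for the cluster null (default 500).
#' @param seed Integer seed for the permutations.
#' @return List with elements `task_gt_rest` and `rest_gt_task`, each a list
#'   of `t` (unthresholded `stat_map`), `thresholded` and `clusters`.
#' @export
paired_second_order <- function(task_maps, rest_maps, fwe_alpha = 0.05,
                                fdr_alpha = 0.05, cluster_forming_p = 0.001,
                                n_perm = 500, seed = 1L) {
  n <- length(task_maps)
  if (n != length(rest_maps)) stop("task and rest map lists differ in length")
  stopifnot(n >= 2)
  grid <- task_maps[[1]]$grid
  midx <- as.vector(grid$mask)
  D <- vapply(seq_len(n), function(i)
    (as.vector(task_maps[[i]]$values) - as.vector(rest_maps[[i]]$values))[midx],
    numeric(sum(midx)))                        # voxels x subjects
  dof <- n - 1L
  tmap_from <- function(Dm) {
    mu <- rowMeans(Dm)
    sdm <- sqrt(apply(Dm, 1, stats::var) / n)
    t <- mu / sdm
    t[!is.finite(t)] <- 0
    vals <- numeric(prod(grid$dim))
    vals[midx] <- t
    out <- stat_map(grid, vals, kind = "t")
    attr(out, "dof") <- dof
    out
  }
  t_task <- tmap_from(D)
  t_rest <- tmap_from(-D)
  fwe <- apply_threshold(t_task, threshold_spec("FWE_voxel", alpha = fwe_alpha),
                         dof = dof)
  null_maps <- with_seed(seed, lapply(seq_len(n_perm), function(p) {
    signs <- sample(c(-1, 1), n, replace = TRUE)
    tmap_from(sweep(D, 2, signs, `*`))
  }))
  fdr <- apply_threshold(t_rest,
                         threshold_spec("FDR_cluster", alpha = fdr_alpha,
                                        cluster_forming_p = cluster_forming_p),
                         dof = dof, null_maps = null_maps)
  list(task_gt_rest = list(t = t_task, thresholded = fwe$map,
                           clusters = fwe$clusters),
       rest_gt_task = list(t = t_rest, thresholded = fdr$map,
                           clusters = fdr$clusters))
}
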