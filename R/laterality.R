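#' Hemispheric lateralization index
#'
#' Mass-based LI of a statistical map: suprathreshold values are summed over
#' voxels with MNI `x < -midline_exclusion_mm` (left mass L) and
#' `x > +midline_exclusion_mm` (right mass R), and
#' `LI = 100 (R - L) / (R + L)`.
#'
#' Sign convention: positive LI means RIGHT-hemisphere dominance, matching
#' the clinical laterality table this package ships (and the Edinburgh
#' handedness scale), which is the OPPOSITE of the common LI-toolbox
#' convention where positive means left.
#'
#' @param map A `stat_map`.
#' @param threshold Only values above this contribute (default 0; use the
#'   map's z = 2 or FWE t cutoff depending on modality).
#' @param midline_exclusion_mm Half-width of the excluded midline strip, mm
#'   (default 5).
#' @return An object of class `laterality_result`: `li` (-100..100, `NA`
#'   when no suprathreshold mass), `left_mass`, `right_mass`, `threshold`,
#'   `midline_exclusion_mm`.
#' @export
laterality_index <- function(map, threshold = 0, midline_exclusion_mm = 5) {
  stopifnot(inherits(map, "stat_map"))
  co <- grid_coordinates(map$grid)
  v <- as.vector(map$values)
  m <- as.vector(map$grid$mask)
  supra <- m & v > threshold
  left <- sum(v[supra & co[, 1] < -midline_exclusion_mm])
  right <- sum(v[supra & co[, 1] > midline_exclusion_mm])
  li <- if (left + right > 0) 100 * (right - left) / (right + left) else NA_real_
  structure(list(li = li, left_mass = left, right_mass = right,
                 threshold = threshold,
                 midline_exclusion_mm = midline_exclusion_mm),
            class = "laterality_result")
}

#' @export
print.laterality_result <- function(x, ...) {
  cat(sprintf("<laterality_result> LI = %s (L mass %.4g, R mass %.4g; + = right dominant)\n",
              if (is.na(x$li)) "undefined" else sprintf("%.1f", x$li),
              x$left_mass, x$right_mass))
  invisible(x)
}

#' Classify hemispheric dominance from an LI
#'
#' Default sign-only criterion: right iff LI > 0, left iff LI < 0. With
#' `bilateral_band` set (e.g. 10), `|LI| < band` is called bilateral.
#'
#' @param result A `laterality_result`, or a bare LI value.
#' @param bilateral_band Optional half-width of the bilateral band.
#' @return `"left"`, `"right"` or `"bilateral"`.
#' @export
classify_dominance <- function(result, bilateral_band = NULL) {
  li <- if (inherits(result, "laterality_result")) result$li else result
  if (is.na(li)) stop("LI undefined: no suprathreshold mass")
  if (!is.null(bilateral_band) && abs(li) < bilateral_band) return("bilateral")
  if (li > 0) "right" else if (li < 0) "left"
  else if (is.null(bilateral_band)) "bilateral" else "left"
}

#' Load the laterality-index table fixture
#'
#' Per-patient Edinburgh handedness score and the task (TIA) and rest LIs,
#' all on the -100 (left) to +100 (right) scale.
#'
#' @param path CSV path; defaults to the shipped fixture.
#' @return Data frame with columns patient, edinburgh, tia, rest.
#' @export
load_laterality_table <- function(path = lang_fixture("table2_laterality.csv")) {
  df <- utils::read.csv(path)
  stopifnot(identical(names(df), c("patient", "edinburgh", "tia", "rest")),
            all(abs(df$edinburgh) <= 100), all(abs(df$tia) <= 100),
            all(abs(df$rest) <= 100))
  df
}

#' Summary of the left-handed subgroup
#'
#' Left-handers are patients with Edinburgh score < 0. The Edinburgh mean is
#' reported on the -1..+1 scale (score / 100), the convention of the source
#' series' text; counts of right-hemisphere dominance use the sign-only
#' criterion (LI > 0).
#'
#' @param table Laterality table from [load_laterality_table()].
#' @return List: `n_left_handed`, `mean_edinburgh` (on -1..1),
#'   `sd_edinburgh`, `n_right_dominant_rest`, `n_right_dominant_task`.
#' @export
left_hander_summary <- function(table = load_laterality_table()) {
  lh <- table[table$edinburgh < 0, , drop = FALSE]
  list(n_left_handed = nrow(lh),
       mean_edinburgh = mean(lh$edinburgh) / 100,
       sd_edinburgh = stats::sd(lh$edinburgh) / 100,
       n_right_dominant_rest = sum(lh$rest > 0),
       n_right_dominant_task = sum(lh$tia > 0))
}
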