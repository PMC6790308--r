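#' Rule-based identification of resting-state networks
#'
#' ICA components are classified into LANG / VAN / SN / DAN / lFPC by
#' anatomical peak criteria: a network rule names required regions (all must
#' contain a peak, in either hemisphere) and exclusion regions (a peak there
#' that outranks every required-region peak vetoes the rule). The language
#' network requires MTG, IFG and ANG peaks; the angular-gyrus versus
#' supramarginal/TPJ opposition separates it from the ventral attention
#' network, and DLPFC/orbitofrontal dominance marks the fronto-parietal
#' control network. The deterministic rule engine replaces the two-rater
#' consensus of clinical practice; `report = TRUE` in
#' [classify_component()] returns the per-rule evidence for human audit.
#'
#' @name network_id
NULL

#' Load an ROI atlas and classification rules
#'
#' @param path YAML file with `regions` and `rules`; defaults to the shipped
#'   atlas.
#' @return List with `regions` (named list of sphere data frames: centre,
#'   radius, hemisphere) and `rules` (list of network rules), class
#'   `roi_atlas`.
#' @export
load_atlas <- function(path = system.file("extdata", "language_atlas.yaml",
                                          package = "langmapr")) {
  raw <- yaml::read_yaml(path)
  regions <- lapply(raw$regions, function(sph) {
    df <- do.call(rbind, lapply(sph, function(s)
      data.frame(x = s$centre[1], y = s$centre[2], z = s$centre[3],
                 radius = s$radius, hemisphere = s$hemisphere)))
    stopifnot(all(df$radius > 0))
    stopifnot(all(df$x[df$hemisphere == "L"] < 0),
              all(df$x[df$hemisphere == "R"] > 0))
    df
  })
  rules <- lapply(raw$rules, function(r) {
    stopifnot(length(intersect(r$required, r$exclusion)) == 0)
    list(network = r$network, required = as.character(r$required),
         exclusion = as.character(r$exclusion %||% character(0)))
  })
  missing <- setdiff(unique(unlist(lapply(rules, function(r)
    c(r$required, r$exclusion)))), names(regions))
  if (length(missing) > 0)
    stop("rules reference unknown regions: ", paste(missing, collapse = ", "))
  structure(list(regions = regions, rules = rules), class = "roi_atlas")
}

#' Peaks falling inside an atlas region
#'
#' A peak matches when it lies within any of the region's spheres. The
#' hemisphere summary uses the Left/Right/Bi/No vocabulary of the clinical
#' detection tables.
#'
#' @param peaks A `peak_set`.
#' @param atlas A `roi_atlas`.
#' @param region Region name.
#' @return List with `peaks` (matching subset, with a `hemisphere` column)
#'   and `laterality` (`"Left"`, `"Right"`, `"Bi"` or `"No"`).
#' @export
peaks_in_region <- function(peaks, atlas, region) {
  if (!region %in% names(atlas$regions))
    stop("unknown region: ", region)
  sph <- atlas$regions[[region]]
  if (nrow(peaks) == 0) {
    return(list(peaks = cbind(peaks, hemisphere = character(0)),
                laterality = "No"))
  }
  hem <- rep(NA_character_, nrow(peaks))
  for (s in seq_len(nrow(sph))) {
    d <- sqrt((peaks$x - sph$x[s])^2 + (peaks$y - sph$y[s])^2 +
                (peaks$z - sph$z[s])^2)
    hit <- d <= sph$radius[s] & is.na(hem)
    hem[hit] <- sph$hemisphere[s]
  }
  matched <- peaks[!is.na(hem), , drop = FALSE]
  matched$hemisphere <- hem[!is.na(hem)]
  sides <- unique(matched$hemisphere)
  lat <- if (nrow(matched) == 0) "No"
  else if (all(sides == "M")) "Bi"
  else if (all(sides %in% c("L", "M"))) "Left"
  else if (all(sides %in% c("R", "M"))) "Right"
  else "Bi"
  list(peaks = matched, laterality = lat)
}

#' Classify one component's peaks into a network
#'
#' Evaluates every rule: the score is the fraction of required regions
#' containing a peak; a rule is fully satisfied when the score is 1 and no
#' exclusion region holds a peak outranking the best required-region peak.
#' Among fully satisfied rules the highest score wins, ties broken by summed
#' matched-peak z then by the fixed rule order (LANG, VAN, SN, DAN, lFPC).
#'
#' @param peaks A `peak_set` (from a z-thresholded component).
#' @param atlas A `roi_atlas`.
#' @param report Also return the per-rule evidence table.
#' @return List with `network` (name or `"unclassified"`), `score`,
#'   `matched_regions`, `summed_z`; with `report = TRUE` also `evidence`.
#' @export
classify_component <- function(peaks, atlas, report = FALSE) {
  evals <- lapply(atlas$rules, function(rule) {
    hits <- lapply(rule$required, function(rg) peaks_in_region(peaks, atlas, rg))
    names(hits) <- rule$required
    hit_ok <- vapply(hits, function(h) nrow(h$peaks) > 0, logical(1))
    score <- mean(hit_ok)
    best_req <- suppressWarnings(max(vapply(hits, function(h)
      if (nrow(h$peaks) > 0) max(h$peaks$value) else -Inf, numeric(1))))
    vetoed <- FALSE
    for (rg in rule$exclusion) {
      ex <- peaks_in_region(peaks, atlas, rg)
      if (nrow(ex$peaks) > 0 && max(ex$peaks$value) >= best_req) vetoed <- TRUE
    }
    summed_z <- sum(vapply(hits, function(h) sum(h$peaks$value), numeric(1)))
    list(network = rule$network, score = score,
         satisfied = all(hit_ok) && !vetoed, vetoed = vetoed,
         matched = rule$required[hit_ok], summed_z = summed_z)
  })
  sat <- Filter(function(e) e$satisfied, evals)
  if (length(sat) == 0) {
    out <- list(network = "unclassified", score = 0,
                matched_regions = character(0), summed_z = 0)
  } else {
    scores <- vapply(sat, `[[`, numeric(1), "score")
    zs <- vapply(sat, `[[`, numeric(1), "summed_z")
    best <- order(-scores, -zs)[1]              # stable: earlier rule wins ties
    out <- list(network = sat[[best]]$network, score = sat[[best]]$score,
                matched_regions = sat[[best]]$matched,
                summed_z = sat[[best]]$summed_z)
  }
  if (report) {
    out$evidence <- do.call(rbind, lapply(evals, function(e)
      data.frame(network = e$network, score = e$score,
                 satisfied = e$satisfied, vetoed = e$vetoed,
                 summed_z = e$summed_z,
                 matched = paste(e$matched, collapse = "+"))))
  }
  out
}

#' Select the language component of a decomposition
#'
#' Thresholds each component at `z_threshold` (the visual-inspection
#' threshold), identifies peaks at the stricter `peak_z` (peak
#' identification uses further thresholding at higher z, which suppresses
#' spurious noise maxima), classifies them, and returns the LANG-labelled
#' component with the highest score (ties: higher summed matched z, then
#' lower component index).
#'
#' @param decomp An `ica_decomposition`.
#' @param atlas A `roi_atlas`.
#' @param z_threshold Component map threshold (default 2).
#' @param peak_z Peak-identification threshold (default 3).
#' @param min_separation_mm Peak separation (default 8).
#' @return List with `component` (index), `label` (classification result)
#'   and `peaks`; or `NULL` when no component is labelled LANG.
#' @export
select_language_component <- function(decomp, atlas = load_atlas(),
                                      z_threshold = 2, peak_z = 3,
                                      min_separation_mm = 8) {
  best <- NULL
  for (k in seq_along(decomp$spatial_maps)) {
    thr <- threshold_component(decomp$spatial_maps[[k]], z = z_threshold)
    pk <- local_maxima(thr, threshold = max(z_threshold, peak_z),
                       min_separation_mm = min_separation_mm,
                       source = sprintf("IC%d", k))
    lab <- classify_component(pk, atlas)
    if (lab$network != "LANG") next
    if (is.null(best) || lab$score > best$label$score ||
        (lab$score == best$label$score && lab$summed_z > best$label$summed_z)) {
      best <- list(component = k, label = lab, peaks = pk)
    }
  }
  best
}

#' Region-detection row for a peak set
#'
#' Summarises which atlas regions a peak set hits, in the Left/Right/Bi/No
#' vocabulary of the clinical detection tables (columns MTG, ANG, TP, IFG,
#' SMA/pre-SMA, dACC, AIFO).
#'
#' @param peaks A `peak_set`.
#' @param atlas A `roi_atlas`.
#' @param regions Regions to report (default the seven table columns).
#' @return Named character vector of lateralities.
#' @export
region_detection_row <- function(peaks, atlas,
                                 regions = c("MTG", "ANG", "TP", "IFG",
                                             "SMA_preSMA", "dACC", "AIFO")) {
  vapply(regions, function(rg) peaks_in_region(peaks, atlas, rg)$laterality,
         character(1))
}
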