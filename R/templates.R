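#' Network templates for the synthetic BOLD generator
#'
#' A `network_template` spatialises a resting-state network as a sum of
#' isotropic Gaussian blobs at MNI coordinates. The shipped defaults (LANG,
#' VAN, SN, DAN, lFPC, DMN, VIS) live in
#' `inst/extdata/network_templates.yaml`; LANG and SN node coordinates follow
#' the published group peak tables, the others are conventional locations
#' documented in the config file.
#'
#' @param name Network name.
#' @param nodes A list of nodes, each a list with `xyz` (MNI mm), `amplitude`
#'   (>= 0, finite) and `sigma` (mm, > 0).
#' @return An object of class `network_template`.
#' @export
network_template <- function(name, nodes) {
  stopifnot(length(nodes) >= 1L)
  for (nd in nodes) {
    stopifnot(length(nd$xyz) == 3L, all(is.finite(unlist(nd$xyz))),
              is.finite(nd$amplitude), nd$amplitude >= 0, nd$sigma > 0)
  }
  structure(list(name = name, nodes = nodes), class = "network_template")
}

#' @export
print.network_template <- function(x, ...) {
  cat(sprintf("<network_template %s> %d node(s)\n", x$name, length(x$nodes)))
  invisible(x)
}

#' Load the shipped network templates
#'
#' @param path YAML file of templates; defaults to the shipped config.
#' @return Named list of `network_template` objects.
#' @export
default_templates <- function(path = system.file("extdata",
                                                 "network_templates.yaml",
                                                 package = "langmapr")) {
  raw <- yaml::read_yaml(path)
  out <- lapply(names(raw), function(nm) {
    nodes <- lapply(raw[[nm]], function(nd)
      list(xyz = as.numeric(nd$xyz), amplitude = as.numeric(nd$amplitude),
           sigma = as.numeric(nd$sigma)))
    network_template(nm, nodes)
  })
  names(out) <- names(raw)
  out
}

#' Templates used by the default resting-state simulation
#'
#' The six networks planted in the default simulation: the language network
#' plus the five networks it must be discriminated from or alongside (VAN,
#' SN, DAN, lFPC, DMN).
#'
#' @return Named list of six `network_template` objects.
#' @export
default_rest_templates <- function() {
  default_templates()[c("LANG", "VAN", "SN", "DAN", "lFPC", "DMN")]
}

#' The source-recovery validation grid
#'
#' A 20 x 20 x 20 raster at the study resolution of 3 mm (a 60-mm cube
#' centred on the origin) with the default ellipsoidal mask. At this
#' kernel-to-voxel ratio spatial smoothing meaningfully suppresses voxel
#' noise, which is what makes quantitative source recovery measurable at a
#' desk; the grid is abstract (not anatomically registered).
#'
#' @return A `volume_grid`.
#' @export
validation_grid <- function() {
  volume_grid(dim = c(20L, 20L, 20L), voxel_size_mm = c(3, 3, 3),
              origin_mm = c(-28.5, -28.5, -28.5))
}

#' Six tiling templates for source-recovery validation
#'
#' Six three-node templates (sigma 6 mm, amplitude 1) whose nodes occupy the
#' 18 points of a 3 x 3 x 2 lattice spanning the validation grid, each point
#' used once and each template's nodes mutually spread, so pairwise spatial
#' correlations stay low. The narrow nodes keep each map's spatial excess
#' kurtosis high (around 11), which is the property spatial ICA
#' identifiability rests on: wider nodes on this small a box blur into
#' near-Gaussian marginals that no ICA can separate. Purely synthetic
#' sources named N1-N6.
#'
#' @param sigma Node width, mm (default 6).
#' @param amplitude Node peak amplitude (default 1).
#' @return Named list of six `network_template` objects.
#' @export
validation_templates <- function(sigma = 6, amplitude = 1) {
  assign_nodes <- list(
    N1 = list(c(-18, -18, -12), c(18, 0, -12), c(0, 18, 12)),
    N2 = list(c(0, -18, -12), c(-18, 18, -12), c(18, 18, 12)),
    N3 = list(c(18, -18, -12), c(-18, 0, -12), c(0, 0, 12)),
    N4 = list(c(0, 0, -12), c(-18, 18, 12), c(18, -18, 12)),
    N5 = list(c(0, 18, -12), c(-18, -18, 12), c(18, 0, 12)),
    N6 = list(c(18, 18, -12), c(0, -18, 12), c(-18, 0, 12))
  )
  out <- lapply(names(assign_nodes), function(nm)
    network_template(nm, lapply(assign_nodes[[nm]], function(xyz)
      list(xyz = xyz, amplitude = amplitude, sigma = sigma))))
  names(out) <- names(assign_nodes)
  out
}

#' Render a network template onto a grid
#'
#' The map is the sum over nodes of `amplitude * exp(-d^2 / (2 sigma^2))`
#' where `d` is the distance from the voxel centre to the node.
#'
#' @param template A `network_template`.
#' @param grid A `volume_grid`; every node must lie inside the grid box.
#' @return A `stat_map` of kind `"amplitude"` (zero outside the mask).
#' @export
render_network_map <- function(template, grid) {
  stopifnot(inherits(template, "network_template"),
            inherits(grid, "volume_grid"))
  co <- grid_coordinates(grid)
  vals <- numeric(nrow(co))
  for (nd in template$nodes) {
    mni_to_voxel(grid, nd$xyz)  # errors if the node is outside the box
    if (nd$amplitude == 0) next
    d2 <- (co[, 1] - nd$xyz[1])^2 + (co[, 2] - nd$xyz[2])^2 +
      (co[, 3] - nd$xyz[3])^2
    vals <- vals + nd$amplitude * exp(-d2 / (2 * nd$sigma^2))
  }
  vals[!grid$mask] <- 0
  stat_map(grid, vals, kind = "amplitude")
}
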