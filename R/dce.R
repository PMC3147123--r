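## Dynamic contrast-enhanced analysis: difference images, ROI extraction,
## enhancement linearity and kinetics.

#' Enhancement difference image
#'
#' Node-wise `mua(post) - mua(pre)` of two reconstructions (or ground-truth
#' maps) on the same mesh.
#'
#' @param post,pre `optical_map`s on the same mesh.
#' @param label optional label (contrast name or frame time).
#' @return an `enhancement_map` with `values` (delta-mua per node) and the
#'   shared mesh.
#' @export
difference_map <- function(post, pre, label = NULL) {
  if (nrow(post$mesh$nodes) != nrow(pre$mesh$nodes) ||
      !isTRUE(all.equal(post$mesh$nodes, pre$mesh$nodes, tolerance = 1e-12)))
    stopf("post and pre maps are not on the same mesh")
  structure(list(values = post$mua - pre$mua, mesh = post$mesh,
                 label = label),
            class = "enhancement_map")
}

#' @export
print.enhancement_map <- function(x, ...) {
  cat(sprintf("enhancement_map%s: %d nodes, range [%.3g, %.3g] mm^-1\n",
              if (is.null(x$label)) "" else paste0(" (", x$label, ")"),
              length(x$values), min(x$values), max(x$values)))
  invisible(x)
}

#' Full-width-half-maximum region of interest
#'
#' Thresholds the enhancement map at half of its peak above the background
#' level (the node median, robust to the inclusion's own nodes) and keeps
#' only the element-adjacency connected component containing the maximum.
#'
#' @param map an `enhancement_map`.
#' @return integer vector of ROI node indices.
#' @export
roi_fwhm <- function(map) {
  v <- map$values
  bg <- median(v)
  if (max(v) <= bg + .Machine$double.eps^0.5 * max(1, abs(bg)))
    stopf("no inclusion resolved: map maximum does not exceed background")
  thr <- bg + 0.5 * (max(v) - bg)
  cand <- which(v >= thr)
  if (length(cand) == 1) return(cand)
  ed <- element_edges(map$mesh$elements)
  keep <- ed[, 1] %in% cand & ed[, 2] %in% cand
  g <- igraph::graph_from_edgelist(
    matrix(match(ed[keep, ], cand), ncol = 2), directed = FALSE)
  g <- igraph::add_vertices(g, max(0, length(cand) - igraph::vcount(g)))
  comp <- igraph::components(g)$membership
  cand[comp == comp[match(which.max(v), cand)]]
}

#' Region of interest from the structural prior
#'
#' @param mesh a `dot_mesh` with region labels.
#' @param region_id region id (0 = background is allowed).
#' @return integer vector of node indices with that label.
#' @export
roi_from_prior <- function(mesh, region_id) {
  if (!region_id %in% mesh$region_labels)
    stopf("unknown region id %s (labels present: %s)", region_id,
          paste(sort(unique(mesh$region_labels)), collapse = ", "))
  which(mesh$region_labels == region_id)
}

#' Area-weighted mean enhancement over a region of interest
#'
#' Node weights are one third of the incident element areas, making the
#' mean stable under mesh refinement.
#'
#' @param map an `enhancement_map`.
#' @param roi integer vector of node indices.
#' @return mean delta-mua (mm^-1).
#' @export
mean_enhancement <- function(map, roi) {
  if (length(roi) == 0) stopf("empty ROI")
  w <- node_weights(map$mesh)[roi]
  sum(w * map$values[roi]) / sum(w)
}

#' Linearity of enhancement versus contrast
#'
#' Ordinary least-squares line through (contrast, enhancement) and the
#' deviation vector `|data - fit| / max(data)`.
#'
#' @param contrast_levels x values (>= 3 points).
#' @param mean_enhancements y values (same length).
#' @return list with `slope`, `intercept`, `fitted`, `deviations`,
#'   `r_squared`.
#' @export
linearity_analysis <- function(contrast_levels, mean_enhancements) {
  if (length(contrast_levels) != length(mean_enhancements))
    stopf("x and y lengths differ")
  if (length(contrast_levels) < 3)
    stopf("linearity analysis needs at least 3 points")
  fit <- lm(mean_enhancements ~ contrast_levels)
  fitted <- unname(fitted(fit))
  dev <- abs(mean_enhancements - fitted) / max(mean_enhancements)
  ss_res <- sum((mean_enhancements - fitted)^2)
  ss_tot <- sum((mean_enhancements - mean(mean_enhancements))^2)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       fitted = fitted, deviations = dev,
       r_squared = 1 - ss_res / ss_tot)
}

#' Enhancement kinetics curve over a time series
#'
#' Area-weighted mean ROI enhancement per frame, plus the max-normalised
#' curve.  If the curve maximum is not positive the normalised curve is
#' flagged and omitted while the raw curve is still returned.
#'
#' @param frame_maps list of `enhancement_map`s (one per frame).
#' @param roi integer node indices.
#' @param times frame times in seconds (strictly increasing, same length).
#' @return a `kinetics_curve` with `times`, `values`, `normalized` and
#'   `normalization_failed`.
#' @export
kinetics_curve <- function(frame_maps, roi, times) {
  if (length(frame_maps) != length(times))
    stopf("frame_maps and times lengths differ")
  if (any(diff(times) <= 0)) stopf("times must be strictly increasing")
  values <- vapply(frame_maps, mean_enhancement, numeric(1), roi = roi)
  mx <- max(values)
  failed <- !(mx > 0)
  if (failed) warning("curve maximum is not positive; normalization skipped")
  structure(list(times = times, values = values,
                 normalized = if (failed) NULL else values / mx,
                 normalization_failed = failed),
            class = "kinetics_curve")
}

#' @export
print.kinetics_curve <- function(x, ...) {
  cat(sprintf("kinetics_curve: %d frames over %.0f s, peak %.4g mm^-1 at %.0f s\n",
              length(x$times), diff(range(x$times)),
              max(x$values), x$times[which.max(x$values)]))
  invisible(x)
}
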