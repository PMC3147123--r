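## Plain-text interchange: measurement frames and maps as CSV, meshes as
## node/element text files, layouts and configs as JSON, masks as PNG.
## All indices in files are 1-based.

#' Write / read a measurement frame as CSV
#'
#' Columns: `source_index`, `detector_index`, `amplitude`, `phase`
#' (radians, positive lag).
#'
#' @param frame a `dot_frame`.
#' @param path CSV file path.
#' @return `write_frame_csv` returns `path` invisibly; `read_frame_csv`
#'   returns a `dot_frame` (complex flux rebuilt from amplitude and phase).
#' @export
write_frame_csv <- function(frame, path) {
  df <- data.frame(
    source_index = rep(seq_len(frame$Ns), each = frame$Nd),
    detector_index = rep(seq_len(frame$Nd), times = frame$Ns),
    amplitude = as.vector(t(frame$amplitude)),
    phase = as.vector(t(frame$phase)))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_frame_csv
#' @param path CSV file path.
#' @export
read_frame_csv <- function(path) {
  df <- read.csv(path)
  Ns <- max(df$source_index); Nd <- max(df$detector_index)
  amp <- matrix(0, Ns, Nd); ph <- matrix(0, Ns, Nd)
  amp[cbind(df$source_index, df$detector_index)] <- df$amplitude
  ph[cbind(df$source_index, df$detector_index)] <- df$phase
  new_frame(amp * exp(-1i * ph))
}

#' Write a nodal map (or enhancement image) as CSV
#'
#' Columns: `node`, `x`, `y`, then the value columns (`mua`, `musp` for an
#' `optical_map`; `delta_mua` for an `enhancement_map`).
#'
#' @param map an `optical_map` or `enhancement_map`.
#' @param path CSV file path.
#' @export
write_map_csv <- function(map, path) {
  mesh <- map$mesh
  df <- data.frame(node = seq_len(nrow(mesh$nodes)),
                   x = mesh$nodes[, 1], y = mesh$nodes[, 2])
  if (inherits(map, "optical_map")) {
    df$mua <- map$mua; df$musp <- map$musp
  } else {
    df$delta_mua <- map$values
  }
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write / read a mesh as plain node and element files
#'
#' `<prefix>.node`: `index x y region`; `<prefix>.ele`:
#' `index n1 n2 n3` (1-based).
#'
#' @param mesh a `dot_mesh`.
#' @param prefix file path prefix.
#' @export
write_mesh <- function(mesh, prefix) {
  nd <- data.frame(index = seq_len(nrow(mesh$nodes)),
                   x = mesh$nodes[, 1], y = mesh$nodes[, 2],
                   region = mesh$region_labels)
  el <- data.frame(index = seq_len(nrow(mesh$elements)),
                   n1 = mesh$elements[, 1], n2 = mesh$elements[, 2],
                   n3 = mesh$elements[, 3])
  write.table(nd, paste0(prefix, ".node"), row.names = FALSE, quote = FALSE)
  write.table(el, paste0(prefix, ".ele"), row.names = FALSE, quote = FALSE)
  invisible(prefix)
}

#' @rdname write_mesh
#' @export
read_mesh <- function(prefix) {
  nd <- read.table(paste0(prefix, ".node"), header = TRUE)
  el <- read.table(paste0(prefix, ".ele"), header = TRUE)
  tri <- as.matrix(el[, c("n1", "n2", "n3")])
  dimnames(tri) <- NULL
  nodes <- as.matrix(nd[, c("x", "y")])
  new_mesh(nodes, tri, trace_boundary_loop(tri), as.integer(nd$region))
}

#' Write an optode layout as JSON
#' @param layout an `optode_layout`.
#' @param path JSON file path.
#' @export
write_layout_json <- function(layout, path) {
  jsonlite::write_json(list(
    center = layout$center, Ns = layout$Ns, Nd = layout$Nd,
    source_nodes = layout$source_nodes,
    detector_nodes = layout$detector_nodes,
    source_positions = unname(layout$source_positions),
    detector_positions = unname(layout$detector_positions),
    source_angles_deg = layout$source_angles * 180 / pi,
    detector_angles_deg = layout$detector_angles * 180 / pi),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a binary mask as an 8-bit PNG
#' @param mask logical matrix (image convention).
#' @param path PNG file path.
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(mask * 1, path)
  invisible(path)
}

#' Render a nodal map to a graphics device
#'
#' Draws the mesh elements filled by interpolated node values; intended for
#' quick-look figures of reconstructions and difference images.
#'
#' @param map an `optical_map` (absorption shown) or `enhancement_map`.
#' @param file optional PNG path; when given the plot is written there.
#' @param zlim optional colour scale limits (shared scales across panels).
#' @param main plot title.
#' @export
plot_map <- function(map, file = NULL, zlim = NULL, main = NULL) {
  v <- if (inherits(map, "optical_map")) map$mua else map$values
  mesh <- map$mesh
  if (!is.null(file)) {
    grDevices::png(file, width = 600, height = 600)
    on.exit(grDevices::dev.off())
  }
  zlim <- zlim %||% range(v)
  pal <- grDevices::hcl.colors(64, "viridis")
  tri_val <- rowMeans(matrix(v[mesh$elements], ncol = 3))
  col_idx <- pmin(64, pmax(1, 1 + floor(63 * (tri_val - zlim[1]) /
                                          max(zlim[2] - zlim[1], 1e-30))))
  graphics::plot(NA, xlim = range(mesh$nodes[, 1]),
                 ylim = range(mesh$nodes[, 2]), asp = 1,
                 xlab = "x (mm)", ylab = "y (mm)",
                 main = main %||% map$label %||% "")
  for (e in seq_len(nrow(mesh$elements))) {
    p <- mesh$nodes[mesh$elements[e, ], ]
    graphics::polygon(p[, 1], p[, 2], col = pal[col_idx[e]], border = NA)
  }
  invisible(map)
}
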