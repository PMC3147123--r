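## Fan-beam optode layout: 16 rays from a centre point at 22.5 degree
## increments; alternate boundary intersections become 8 sources and 8
## detectors, each snapped to the nearest boundary node.

new_optode_layout <- function(source_nodes, detector_nodes, mesh, center,
                              source_angles, detector_angles) {
  structure(list(
    source_nodes = source_nodes, detector_nodes = detector_nodes,
    source_positions = mesh$nodes[source_nodes, , drop = FALSE],
    detector_positions = mesh$nodes[detector_nodes, , drop = FALSE],
    source_angles = source_angles, detector_angles = detector_angles,
    center = center, Ns = length(source_nodes), Nd = length(detector_nodes)),
    class = "optode_layout")
}

#' @export
print.optode_layout <- function(x, ...) {
  cat(sprintf("optode_layout: %d sources, %d detectors, centre (%.1f, %.1f)\n",
              x$Ns, x$Nd, x$center[1], x$center[2]))
  invisible(x)
}

#' Map a fan-beam source/detector layout onto a mesh boundary
#'
#' Casts 16 rays from `center` at 22.5 degree increments, intersects each
#' with the mesh boundary, and snaps the intersections to the nearest
#' boundary nodes.  Rays at 0, 45, 90, ... degrees become sources; rays at
#' 22.5, 67.5, ... degrees become detectors.
#'
#' @param mesh a `dot_mesh`.
#' @param center interior point (mm) from which the rays emanate.
#' @return an `optode_layout` with `Ns = Nd = 8`.
#' @export
map_optodes <- function(mesh, center = c(0, 0)) {
  loop <- mesh$boundary_edges[, 1]
  poly <- mesh$nodes[loop, , drop = FALSE]
  if (!points_in_polygon(poly, matrix(center, ncol = 2)))
    stopf("center is not inside the mesh boundary")
  angles <- (0:15) * 22.5 * pi / 180
  nodes <- integer(16)
  for (m in 1:16) {
    dir <- c(cos(angles[m]), sin(angles[m]))
    hit <- ray_polygon_hit(center, dir, poly)
    if (is.null(hit))
      stopf("ray at %.1f degrees does not intersect the boundary",
            angles[m] * 180 / pi)
    d2 <- (mesh$nodes[loop, 1] - hit[1])^2 + (mesh$nodes[loop, 2] - hit[2])^2
    nodes[m] <- loop[which.min(d2)]
  }
  src <- seq(1, 16, by = 2)   # 0, 45, 90, ... degrees
  det <- seq(2, 16, by = 2)   # 22.5, 67.5, ... degrees
  new_optode_layout(nodes[src], nodes[det], mesh, center,
                    angles[src], angles[det])
}

## First intersection of ray origin + t*dir (t > 0) with closed polygon.
ray_polygon_hit <- function(origin, dir, poly) {
  a <- poly
  b <- rbind(poly[-1, , drop = FALSE], poly[1, , drop = FALSE])
  ex <- b[, 1] - a[, 1]; ey <- b[, 2] - a[, 2]
  den <- dir[1] * (-ey) - dir[2] * (-ex)
  wx <- a[, 1] - origin[1]; wy <- a[, 2] - origin[2]
  t <- (wx * (-ey) + wy * ex) / den
  u <- (dir[1] * wy - dir[2] * wx) / den
  ok <- is.finite(t) & t > 1e-9 & u >= -1e-9 & u <= 1 + 1e-9
  if (!any(ok)) return(NULL)
  tmin <- min(t[ok])
  origin + tmin * dir
}
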