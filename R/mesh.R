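## Triangular FEM meshes.  A `dot_mesh` is a list with
##   nodes          N x 2 matrix (mm)
##   elements       M x 3 matrix of node indices, counter-clockwise
##   boundary_edges K x 2 ordered node pairs forming one closed CCW loop
##                  (domain on the left, outward normal to the right)
##   region_labels  integer per node, 0 = background
## Indices are 1-based throughout.

new_mesh <- function(nodes, elements, boundary_edges, region_labels) {
  structure(list(nodes = nodes, elements = elements,
                 boundary_edges = boundary_edges,
                 region_labels = region_labels),
            class = "dot_mesh")
}

#' @export
print.dot_mesh <- function(x, ...) {
  cat(sprintf(
    "dot_mesh: %d nodes, %d elements, %d boundary edges, %d region(s)\n",
    nrow(x$nodes), nrow(x$elements), nrow(x$boundary_edges),
    length(unique(x$region_labels))))
  invisible(x)
}

## Signed areas of all elements.
element_areas <- function(mesh) {
  nd <- mesh$nodes; tri <- mesh$elements
  x1 <- nd[tri[, 1], 1]; y1 <- nd[tri[, 1], 2]
  x2 <- nd[tri[, 2], 1]; y2 <- nd[tri[, 2], 2]
  x3 <- nd[tri[, 3], 1]; y3 <- nd[tri[, 3], 2]
  0.5 * ((x2 - x1) * (y3 - y1) - (x3 - x1) * (y2 - y1))
}

#' Total mesh area
#' @param mesh a `dot_mesh`.
#' @return sum of element areas (mm^2).
#' @export
mesh_area <- function(mesh) sum(element_areas(mesh))

#' Area weights per node
#'
#' One third of the total area of the elements incident to each node; used
#' for mesh-refinement-stable region averages.
#'
#' @param mesh a `dot_mesh`.
#' @return numeric vector of length `nrow(mesh$nodes)`.
#' @export
node_weights <- function(mesh) {
  ar <- element_areas(mesh)
  w <- numeric(nrow(mesh$nodes))
  for (k in 1:3) {
    s <- rowsum(ar / 3, mesh$elements[, k])
    w[as.integer(rownames(s))] <- w[as.integer(rownames(s))] + s[, 1]
  }
  w
}

## Edges of each element as a 3M x 2 matrix in element-local CCW order.
element_edges <- function(elements) {
  rbind(elements[, c(1, 2)], elements[, c(2, 3)], elements[, c(3, 1)])
}

## Directed boundary edges (appear in exactly one element), ordered into a
## closed loop.  Returns K x 2 matrix; errors if the boundary is not a single
## closed loop.
trace_boundary_loop <- function(elements) {
  ed <- element_edges(elements)
  key <- paste(pmin(ed[, 1], ed[, 2]), pmax(ed[, 1], ed[, 2]))
  cnt <- table(key)
  bnd <- ed[key %in% names(cnt)[cnt == 1], , drop = FALSE]
  if (nrow(bnd) < 3) stopf("degenerate boundary")
  nxt <- integer(max(bnd))
  nxt[bnd[, 1]] <- bnd[, 2]
  start <- min(bnd[, 1])
  loop <- integer(nrow(bnd))
  cur <- start
  for (i in seq_len(nrow(bnd))) {
    loop[i] <- cur
    cur <- nxt[cur]
    if (cur == 0L) stopf("boundary is not a closed loop")
  }
  if (cur != start) stopf("boundary is not a single closed loop")
  cbind(loop, c(loop[-1], loop[1]))
}

#' Outward unit normals of the boundary edges
#' @param mesh a `dot_mesh`.
#' @return K x 2 matrix of unit normals, one per row of `boundary_edges`.
#' @export
boundary_normals <- function(mesh) {
  be <- mesh$boundary_edges
  d <- mesh$nodes[be[, 2], , drop = FALSE] - mesh$nodes[be[, 1], , drop = FALSE]
  n <- cbind(d[, 2], -d[, 1])          # right of travel = outward for CCW loop
  n / sqrt(rowSums(n^2))
}

## Outward unit normal at a boundary node: mean of its two edge normals.
node_outward_normal <- function(mesh, node) {
  be <- mesh$boundary_edges
  nrm <- boundary_normals(mesh)
  sel <- which(be[, 1] == node | be[, 2] == node)
  if (length(sel) == 0) stopf("node %d is not on the boundary", node)
  v <- colMeans(nrm[sel, , drop = FALSE])
  v / sqrt(sum(v^2))
}

#' Build a triangular mesh of a polygonal domain
#'
#' All supplied polygon vertices become mesh nodes (long boundary segments
#' are subdivided); the interior is filled with a hexagonal point lattice of
#' spacing `target_edge_mm` and triangulated by Delaunay triangulation, then
#' clipped to the polygon.
#'
#' @param boundary_polygon simple CCW polygon (n x 2 matrix, mm).
#' @param target_edge_mm desired typical edge length in mm (> 0).
#' @return a `dot_mesh`.
#' @export
build_mesh <- function(boundary_polygon, target_edge_mm) {
  poly <- as.matrix(boundary_polygon)
  if (!is.numeric(target_edge_mm) || target_edge_mm <= 0)
    stopf("target_edge_mm must be > 0")
  if (nrow(poly) < 3) stopf("polygon needs at least 3 vertices")
  if (polygon_self_intersects(poly)) stopf("polygon is self-intersecting")
  if (polygon_area(poly) < 0) poly <- poly[rev(seq_len(nrow(poly))), ]
  h <- target_edge_mm

  ## boundary nodes: polygon vertices plus subdivisions of long segments
  bpts <- NULL
  n <- nrow(poly)
  for (i in seq_len(n)) {
    a <- poly[i, ]; b <- poly[if (i == n) 1 else i + 1, ]
    bpts <- rbind(bpts, a)
    L <- sqrt(sum((b - a)^2))
    nseg <- ceiling(L / (1.4 * h))
    if (nseg > 1) {
      t <- seq_len(nseg - 1) / nseg
      bpts <- rbind(bpts, cbind(a[1] + t * (b[1] - a[1]),
                                a[2] + t * (b[2] - a[2])))
    }
  }

  ## interior lattice
  rng_x <- range(poly[, 1]); rng_y <- range(poly[, 2])
  xs <- seq(rng_x[1] - h, rng_x[2] + h, by = h)
  ys <- seq(rng_y[1] - h, rng_y[2] + h, by = h * sqrt(3) / 2)
  gx <- rep(xs, times = length(ys)) +
    rep(ifelse(seq_along(ys) %% 2 == 0, h / 2, 0), each = length(xs))
  gy <- rep(ys, each = length(xs))
  keep <- points_in_polygon(poly, cbind(gx, gy))
  gx <- gx[keep]; gy <- gy[keep]
  if (length(gx)) {
    far <- dist_to_polygon(cbind(gx, gy), poly) > 0.72 * h
    gx <- gx[far]; gy <- gy[far]
  }

  pts <- rbind(bpts, cbind(gx, gy))
  dup <- duplicated(round(pts / (0.05 * h)))
  pts <- pts[!dup, , drop = FALSE]

  junk <- utils::capture.output(suppressMessages(
    dd <- deldir::deldir(pts[, 1], pts[, 2], suppressMsge = TRUE)))
  tl <- deldir::triang.list(dd)
  tri <- t(vapply(tl, function(t) t$ptNum, integer(3)))

  ## orient CCW, clip to polygon by centroid test
  x <- pts[, 1]; y <- pts[, 2]
  ar <- 0.5 * ((x[tri[, 2]] - x[tri[, 1]]) * (y[tri[, 3]] - y[tri[, 1]]) -
               (x[tri[, 3]] - x[tri[, 1]]) * (y[tri[, 2]] - y[tri[, 1]]))
  flip <- ar < 0
  tri[flip, ] <- tri[flip, c(1, 3, 2)]
  cx <- (x[tri[, 1]] + x[tri[, 2]] + x[tri[, 3]]) / 3
  cy <- (y[tri[, 1]] + y[tri[, 2]] + y[tri[, 3]]) / 3
  tri <- tri[points_in_polygon(poly, cbind(cx, cy)), , drop = FALSE]

  ## drop unused nodes, reindex
  used <- sort(unique(as.vector(tri)))
  remap <- integer(nrow(pts)); remap[used] <- seq_along(used)
  tri <- matrix(remap[tri], ncol = 3)
  nodes <- pts[used, , drop = FALSE]
  colnames(nodes) <- c("x", "y")

  mesh <- new_mesh(nodes, tri, trace_boundary_loop(tri),
                   integer(nrow(nodes)))
  ar <- element_areas(mesh)
  if (any(ar <= 0))
    stopf("element %d has non-positive area", which(ar <= 0)[1])
  mesh
}

#' Label the mesh nodes inside a polygonal region
#'
#' Nodes strictly inside `region_polygon` receive the next free region id
#' (ids are contiguous integers starting at 0 = background).
#'
#' @param mesh a `dot_mesh`.
#' @param region_polygon simple polygon (mm) lying inside the domain.
#' @return the mesh with updated `region_labels`.
#' @export
label_region <- function(mesh, region_polygon) {
  inside <- points_in_polygon(as.matrix(region_polygon), mesh$nodes)
  if (!any(inside))
    stopf("region polygon encloses no mesh nodes")
  mesh$region_labels[inside] <- max(mesh$region_labels) + 1L
  mesh
}

#' Polygon approximating a disk
#' @param center disk centre `c(x, y)` in mm.
#' @param diameter disk diameter in mm.
#' @param n number of polygon vertices.
#' @return n x 2 CCW polygon matrix.
#' @export
disk_polygon <- function(center, diameter, n = 64) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(center[1] + diameter / 2 * cos(th),
        center[2] + diameter / 2 * sin(th))
}

#' Structured polar disk mesh with 16-fold symmetry
#'
#' Builds a disk mesh from concentric rings (ring k carries 16 k nodes), so
#' every multiple of 22.5 degrees is an exact boundary node at every
#' refinement level.  Used for validation against rotationally symmetric
#' reference solutions and for grid-convergence checks where the optode
#' positions must not move with refinement.
#'
#' @param radius disk radius (mm).
#' @param n_rings number of rings; typical edge length is `radius/n_rings`.
#' @param mirror_symmetric triangulate the upper half plane and reflect it,
#'   making the mesh exactly symmetric across the x axis (at the cost of
#'   exact rotational symmetry); used for mirror-image validation checks.
#' @return a `dot_mesh`.
#' @export
polar_disk_mesh <- function(radius, n_rings, mirror_symmetric = FALSE) {
  stopifnot(n_rings >= 1)
  nodes <- matrix(c(0, 0), 1, 2)
  ring_start <- integer(n_rings + 1)   # index of first node of each ring
  ring_start[1] <- 1                   # ring 0 = centre node
  for (k in seq_len(n_rings)) {
    nk <- 16L * k
    th <- 2 * pi * (seq_len(nk) - 1) / nk
    r <- radius * k / n_rings
    ring_start[k + 1] <- nrow(nodes) + 1L
    nodes <- rbind(nodes, cbind(r * cos(th), r * sin(th)))
  }
  ring_idx <- function(k) {            # node indices of ring k (k >= 1)
    ring_start[k + 1] - 1L + seq_len(16L * k)
  }
  if (mirror_symmetric) {
    ## reflection map: ring k node j (0-based) -> node (16k - j) mod 16k
    refl <- seq_len(nrow(nodes))
    for (k in seq_len(n_rings)) {
      idx <- ring_idx(k); nk <- 16L * k
      j <- seq_len(nk) - 1L
      refl[idx] <- idx[((nk - j) %% nk) + 1L]
    }
    ## centre fan, upper half (0 .. 180 degrees)
    r1 <- ring_idx(1)
    tri <- cbind(1L, r1[1:8], r1[2:9])
    if (n_rings >= 2) for (k in 2:n_rings) {
      inner <- ring_idx(k - 1); outer <- ring_idx(k)
      ni <- 8L * (k - 1); no <- 8L * k      # half-ring segment counts
      ai <- pi * (0:ni) / ni; ao <- pi * (0:no) / no
      i <- 1L; j <- 1L
      while (i <= ni || j <= no) {
        if (j <= no && (i > ni || ao[j + 1] <= ai[i + 1] + 1e-9)) {
          tri <- rbind(tri, c(outer[j], outer[j + 1],
                              inner[min(i, ni + 1)]))
          j <- j + 1L
        } else {
          tri <- rbind(tri, c(inner[i], outer[min(j, no + 1)],
                              inner[i + 1]))
          i <- i + 1L
        }
      }
    }
    ## reflect the upper half (orientation swapped)
    tri <- rbind(tri, cbind(refl[tri[, 1]], refl[tri[, 3]], refl[tri[, 2]]))
  } else {
    tri <- NULL
    ## centre fan
    r1 <- ring_idx(1)
    tri <- cbind(1L, r1, c(r1[-1], r1[1]))
    ## sew consecutive rings by advancing the pointer with the smaller angle
    for (k in 2:max(2, n_rings)) {
      if (k > n_rings) break
      inner <- ring_idx(k - 1); outer <- ring_idx(k)
      ni <- length(inner); no <- length(outer)
      ai <- 2 * pi * (0:ni) / ni         # closing wrap angle appended
      ao <- 2 * pi * (0:no) / no
      i <- 1L; j <- 1L
      while (i <= ni || j <= no) {
        ## tolerance so floating-point ties at sector boundaries resolve the
        ## same way in every sector (keeps the mesh exactly 16-fold symmetric)
        if (j <= no && (i > ni || ao[j + 1] <= ai[i + 1] + 1e-9)) {
          ## advance outer: triangle (outer j, outer j+1, inner i)
          tri <- rbind(tri, c(outer[j], outer[if (j == no) 1 else j + 1],
                              inner[if (i > ni) 1 else i]))
          j <- j + 1L
        } else {
          ## advance inner: triangle (inner i, outer j, inner i+1)
          tri <- rbind(tri, c(inner[i], outer[if (j > no) 1 else j],
                              inner[if (i == ni) 1 else i + 1]))
          i <- i + 1L
        }
      }
    }
  }
  colnames(nodes) <- c("x", "y")
  mesh <- new_mesh(nodes, tri, trace_boundary_loop(tri), integer(nrow(nodes)))
  ar <- element_areas(mesh)
  flip <- ar < 0
  mesh$elements[flip, ] <- mesh$elements[flip, c(1, 3, 2)]
  mesh$boundary_edges <- trace_boundary_loop(mesh$elements)
  mesh
}

## Locate the element containing point p; returns list(element, weights)
## with barycentric weights, or NULL if outside the mesh.
find_element <- function(mesh, p) {
  nd <- mesh$nodes; tri <- mesh$elements
  x1 <- nd[tri[, 1], 1]; y1 <- nd[tri[, 1], 2]
  x2 <- nd[tri[, 2], 1]; y2 <- nd[tri[, 2], 2]
  x3 <- nd[tri[, 3], 1]; y3 <- nd[tri[, 3], 2]
  den <- (y2 - y3) * (x1 - x3) + (x3 - x2) * (y1 - y3)
  l1 <- ((y2 - y3) * (p[1] - x3) + (x3 - x2) * (p[2] - y3)) / den
  l2 <- ((y3 - y1) * (p[1] - x3) + (x1 - x3) * (p[2] - y3)) / den
  l3 <- 1 - l1 - l2
  tol <- -1e-9
  e <- which(l1 >= tol & l2 >= tol & l3 >= tol)
  if (length(e) == 0) return(NULL)
  e <- e[1]
  w <- unname(c(l1[e], l2[e], l3[e]))
  w <- pmax(w, 0); w <- w / sum(w)
  list(element = e, weights = w)
}
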