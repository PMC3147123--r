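## Frequency-domain diffusion forward model on linear triangles.
##
## PDE:   div(D grad Phi) - (mua + i w / c_n) Phi = -q0
## Robin: Phi + 2 A D dPhi/dn = 0  on the boundary,
## flux:  phi = Phi / (2A) at the detector node.
##
## Phase convention: e^{+i w t} time dependence, so the measured phase is
## reported as a positive lag, phase = -Arg(phi).

#' Nodal optical property map
#'
#' @param mesh a `dot_mesh`.
#' @param mua absorption coefficient (mm^-1), scalar or per node.
#' @param musp reduced scattering coefficient (mm^-1), scalar or per node.
#' @return an `optical_map` holding `mua`, `musp` and the mesh; the diffusion
#'   coefficient `D = 1/(3 (mua + musp))` is always derived, never stored.
#' @export
optical_map <- function(mesh, mua, musp) {
  N <- nrow(mesh$nodes)
  mua <- rep_len(as.numeric(mua), N)
  musp <- rep_len(as.numeric(musp), N)
  if (any(!is.finite(mua)) || any(mua <= 0)) stopf("mua must be positive")
  if (any(!is.finite(musp)) || any(musp <= 0)) stopf("musp must be positive")
  structure(list(mua = mua, musp = musp, mesh = mesh), class = "optical_map")
}

#' Diffusion coefficient of an optical map
#' @param map an `optical_map`.
#' @return per-node `D = 1/(3 (mua + musp))` in mm.
#' @export
diffusion_coef <- function(map) 1 / (3 * (map$mua + map$musp))

#' Boundary mismatch parameter from the refractive index contrast
#'
#' Effective-reflection approximation `R_eff(n)` (Groenhuis-type cubic in
#' 1/n) with `A = (1 + R_eff) / (1 - R_eff)`.
#'
#' @param n_rel interior/exterior refractive index ratio.
#' @return the boundary mismatch parameter A (>= 1 for n_rel >= 1).
#' @export
mismatch_A <- function(n_rel) {
  if (n_rel == 1) return(1)
  r_eff <- -1.440 / n_rel^2 + 0.710 / n_rel + 0.668 + 0.0636 * n_rel
  (1 + r_eff) / (1 - r_eff)
}

#' Forward model configuration
#'
#' @param modulation_freq source modulation frequency in Hz (default 100 MHz).
#' @param n_interior,n_exterior refractive indices (defaults 1.4 / 1.0).
#' @param A boundary mismatch parameter; derived from the index ratio when
#'   `NULL`.
#' @param c0 vacuum light speed in mm/s.
#' @return a `forward_config` list with `omega` (rad/s), `cn` (mm/s) and `A`.
#' @export
forward_config <- function(modulation_freq = 100e6, n_interior = 1.4,
                           n_exterior = 1.0, A = NULL, c0 = 2.998e11) {
  A <- A %||% mismatch_A(n_interior / n_exterior)
  structure(list(modulation_freq = modulation_freq,
                 omega = 2 * pi * modulation_freq,
                 n_interior = n_interior, n_exterior = n_exterior,
                 A = A, c0 = c0, cn = c0 / n_interior),
            class = "forward_config")
}

## Per-element geometry used by assembly and the Jacobian: shape-function
## gradients b, c (rows = elements), areas, and node indices.
element_geometry <- function(mesh) {
  nd <- mesh$nodes; tri <- mesh$elements
  x <- matrix(nd[tri, 1], ncol = 3); y <- matrix(nd[tri, 2], ncol = 3)
  b <- cbind(y[, 2] - y[, 3], y[, 3] - y[, 1], y[, 1] - y[, 2])
  cc <- cbind(x[, 3] - x[, 2], x[, 1] - x[, 3], x[, 2] - x[, 1])
  ar <- 0.5 * (b[, 1] * cc[, 2] - b[, 2] * cc[, 1])
  list(tri = tri, b = b, cc = cc, area = ar)
}

## Exact integrals of products of three linear shape functions:
## T[m, a, b] = (1/Area) * int psi_m psi_a psi_b dA.
.tri3 <- local({
  T <- array(1 / 60, c(3, 3, 3))
  for (m in 1:3) for (a in 1:3) for (b in 1:3) {
    eq <- (m == a) + (a == b) + (m == b)
    T[m, a, b] <- if (eq == 3) 1 / 10 else if (eq == 1) 1 / 30 else 1 / 60
  }
  T
})

#' Assemble the complex FEM system for the diffusion equation
#'
#' Builds the N x N complex symmetric system: D-weighted stiffness plus
#' `(mua + i omega / c_n)`-weighted mass plus a `1/(2A)` boundary mass on
#' the boundary edges.  The system is returned as its real and imaginary
#' sparse parts with a memoised block-LU factorisation.
#'
#' @param mesh a `dot_mesh`.
#' @param map an `optical_map` on the same mesh.
#' @param cfg a `forward_config`.
#' @return a `dot_system` list (`Ar`, `Ai`, `N`, `cfg`).
#' @export
assemble_system <- function(mesh, map, cfg = forward_config()) {
  geo <- element_geometry(mesh)
  bad <- which(abs(geo$area) < 1e-12)
  if (length(bad)) stopf("element %d has zero area", bad[1])
  if (any(geo$area < 0)) stopf("element %d has negative area",
                               which(geo$area < 0)[1])
  N <- nrow(mesh$nodes)
  D <- diffusion_coef(map)
  Dbar <- rowMeans(matrix(D[geo$tri], ncol = 3))
  muae <- matrix(map$mua[geo$tri], ncol = 3)
  oc <- cfg$omega / cfg$cn

  nE <- nrow(geo$tri)
  ii <- jj <- integer(9 * nE)
  vr <- vi <- numeric(9 * nE)
  k <- 0L
  for (a in 1:3) for (b in 1:3) {
    sl <- (k * nE + 1):((k + 1) * nE)
    stiff <- Dbar * (geo$b[, a] * geo$b[, b] + geo$cc[, a] * geo$cc[, b]) /
      (4 * geo$area)
    mass_mua <- geo$area * as.vector(muae %*% .tri3[, a, b])
    mass_w <- geo$area * (if (a == b) 1 / 6 else 1 / 12) * oc
    ii[sl] <- geo$tri[, a]; jj[sl] <- geo$tri[, b]
    vr[sl] <- stiff + mass_mua
    vi[sl] <- mass_w
    k <- k + 1L
  }
  Ar <- Matrix::sparseMatrix(i = ii, j = jj, x = vr, dims = c(N, N))
  Ai <- Matrix::sparseMatrix(i = ii, j = jj, x = vi, dims = c(N, N))

  be <- mesh$boundary_edges
  len <- sqrt(rowSums((mesh$nodes[be[, 1], , drop = FALSE] -
                       mesh$nodes[be[, 2], , drop = FALSE])^2))
  Ar <- Ar + Matrix::sparseMatrix(
    i = c(be[, 1], be[, 2], be[, 1], be[, 2]),
    j = c(be[, 1], be[, 2], be[, 2], be[, 1]),
    x = c(len / 3, len / 3, len / 6, len / 6) / (2 * cfg$A),
    dims = c(N, N))

  structure(list(Ar = Ar, Ai = Ai, N = N, cfg = cfg,
                 cache = new.env(parent = emptyenv())),
            class = "dot_system")
}

## Memoised sparse LU of the 2N x 2N real block form of the complex system.
system_factor <- function(system) {
  if (is.null(system$cache$lu)) {
    A <- rbind(cbind(system$Ar, -system$Ai), cbind(system$Ai, system$Ar))
    system$cache$lu <- Matrix::lu(methods::as(A, "CsparseMatrix"))
  }
  system$cache$lu
}

#' Solve the assembled system for one or more sources
#'
#' Uses a sparse LU factorisation of the real block form of the complex
#' system; the factorisation is cached on the system and reused across the
#' sources of a frame.
#'
#' @param system a `dot_system` from [assemble_system()].
#' @param source complex source vector of length N, or an N x k matrix.
#' @return complex fluence: vector (one source) or N x k matrix.
#' @export
solve_fluence <- function(system, source) {
  one <- is.null(dim(source))
  B <- if (one) matrix(source, ncol = 1) else source
  if (nrow(B) != system$N) stopf("source length %d != %d nodes",
                                 nrow(B), system$N)
  lu <- system_factor(system)
  X <- as.matrix(Matrix::solve(lu, rbind(Re(B), Im(B))))
  out <- X[seq_len(system$N), , drop = FALSE] +
    1i * X[system$N + seq_len(system$N), , drop = FALSE]
  if (any(!is.finite(out))) stopf("singular forward system")
  if (one) out[, 1] else out
}

#' Place a point source one transport length inside the boundary
#'
#' The unit point source for an optode is positioned `1/musp_local` inside
#' the boundary along the inward normal and distributed onto the nodes of
#' the enclosing element with barycentric weights (which sum to one).
#'
#' @param mesh a `dot_mesh`.
#' @param optode_pos boundary position of the optode (mm); snapped to the
#'   nearest boundary node for the normal direction.
#' @param musp_local reduced scattering at the optode (mm^-1).
#' @return complex source vector of length N with attribute `point`.
#' @export
place_source <- function(mesh, optode_pos, musp_local) {
  bn <- unique(as.vector(mesh$boundary_edges))
  d2 <- (mesh$nodes[bn, 1] - optode_pos[1])^2 +
    (mesh$nodes[bn, 2] - optode_pos[2])^2
  node <- bn[which.min(d2)]
  nrm <- node_outward_normal(mesh, node)
  p <- mesh$nodes[node, ] - nrm / musp_local
  fe <- find_element(mesh, p)
  if (is.null(fe))
    stopf("interior source point falls outside the mesh (domain too thin)")
  q <- complex(length.out = nrow(mesh$nodes))
  q[mesh$elements[fe$element, ]] <- fe$weights
  attr(q, "point") <- p
  q
}

#' Boundary flux at the detectors
#'
#' Under the Robin condition the measurable photon flux is
#' `phi = Phi / (2A)` at the detector node.
#'
#' @param field complex fluence vector (one source).
#' @param layout an `optode_layout`.
#' @param cfg a `forward_config`.
#' @return complex flux, one value per detector.
#' @export
boundary_flux <- function(field, layout, cfg = forward_config()) {
  dn <- layout$detector_nodes
  if (any(dn < 1) || any(dn > length(field)))
    stopf("detector index out of range")
  field[dn] / (2 * cfg$A)
}

new_frame <- function(flux, frame_time = 0) {
  amp <- Mod(flux)
  ph <- -Arg(flux)
  ## unwrap along detector index within each source
  ph <- t(apply(ph, 1, function(p) signal::unwrap(p)))
  structure(list(flux = flux, amplitude = amp, phase = ph,
                 Ns = nrow(flux), Nd = ncol(flux), frame_time = frame_time),
            class = "dot_frame")
}

#' @export
print.dot_frame <- function(x, ...) {
  cat(sprintf(
    "dot_frame: %d x %d source-detector pairs (%d amplitude + %d phase), t = %g s\n",
    x$Ns, x$Nd, x$Ns * x$Nd, x$Ns * x$Nd, x$frame_time))
  invisible(x)
}

#' Simulate one noise-free measurement frame
#'
#' Assembles and factors the system once, solves the fluence for all
#' sources, and evaluates the boundary flux at all detectors: an 8 x 8
#' layout yields 64 amplitude and 64 phase data.
#'
#' @param mesh a `dot_mesh`.
#' @param map an `optical_map` on the mesh.
#' @param layout an `optode_layout` on the mesh.
#' @param cfg a `forward_config`.
#' @param frame_time time stamp in seconds stored on the frame.
#' @return a `dot_frame` with complex `flux` (Ns x Nd), `amplitude` and
#'   positive-lag `phase` (unwrapped along the detector index per source).
#' @export
forward_measurements <- function(mesh, map, layout, cfg = forward_config(),
                                 frame_time = 0) {
  system <- assemble_system(mesh, map, cfg)
  Q <- vapply(seq_len(layout$Ns), function(i) {
    place_source(mesh, layout$source_positions[i, ], map$musp[layout$source_nodes[i]])
  }, complex(nrow(mesh$nodes)))
  Phi <- solve_fluence(system, Q)
  flux <- t(Phi[layout$detector_nodes, , drop = FALSE]) / (2 * cfg$A)
  new_frame(flux, frame_time)
}

## Stack a frame into the data vector used by the inversion:
## log-amplitude rows (source-major) then, optionally, phase rows.
stack_data <- function(frame, data_type = c("amplitude", "both")) {
  data_type <- match.arg(data_type)
  la <- as.vector(t(log(frame$amplitude)))   # source-major: (s1,d1..dNd), ...
  if (data_type == "amplitude") la else c(la, as.vector(t(frame$phase)))
}

## Residual measured - predicted in stacked data space; phase residuals are
## computed as wrapped differences so unwrapping conventions cannot leak in.
stack_residual <- function(measured, predicted,
                           data_type = c("amplitude", "both")) {
  data_type <- match.arg(data_type)
  r <- as.vector(t(log(measured$amplitude) - log(predicted$amplitude)))
  if (data_type == "both") {
    dph <- wrap_to_pi(as.vector(t(measured$phase - predicted$phase)))
    r <- c(r, dph)
  }
  r
}
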