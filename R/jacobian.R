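## Adjoint-method Jacobian.
##
## For a measurement phi_ij = c_j' K^{-1} q_i (c_j = detector functional,
## q_i = source vector) and a parameter p entering the system matrix K,
##   d phi_ij / d p = - Psi_j' (dK/dp) Phi_i,
## with Phi_i the forward field and Psi_j = K^{-1} c_j the adjoint field
## (K is complex symmetric, so one factorisation serves both).
##
## Unknowns are nodal mua (and optionally nodal musp).  mua enters the mass
## term directly and the stiffness term through D = 1/(3(mua+musp)) with
## dD/dmua = dD/dmusp = -3 D^2.  Rows are in log-amplitude / phase space:
## d log phi = (d phi)/phi; log-amplitude row = Re, phase row = -Im (phase
## is reported as positive lag -Arg phi).

#' Jacobian of the measurements with respect to nodal optical properties
#'
#' Computes the sensitivity matrix by the adjoint method, reusing one sparse
#' factorisation for the forward fields of all sources and the adjoint
#' fields of all detectors.
#'
#' @param mesh a `dot_mesh`.
#' @param map an `optical_map` (linearisation point).
#' @param layout an `optode_layout`.
#' @param cfg a `forward_config`.
#' @param unknowns `"mua"` (N columns) or `"both"` (mua then musp, 2N).
#' @param data_type `"amplitude"` (64 log-amplitude rows) or `"both"`
#'   (64 log-amplitude + 64 phase rows); rows are source-major.
#' @return list with `J` (rows x cols), the predicted `frame`, and the
#'   forward/adjoint fields.
#' @export
jacobian_adjoint <- function(mesh, map, layout, cfg = forward_config(),
                             unknowns = c("mua", "both"),
                             data_type = c("amplitude", "both")) {
  unknowns <- match.arg(unknowns)
  data_type <- match.arg(data_type)
  N <- nrow(mesh$nodes)
  geo <- element_geometry(mesh)
  system <- assemble_system(mesh, map, cfg)

  Q <- vapply(seq_len(layout$Ns), function(i) {
    place_source(mesh, layout$source_positions[i, ],
                 map$musp[layout$source_nodes[i]])
  }, complex(N))
  C <- matrix(0 + 0i, N, layout$Nd)
  for (j in seq_len(layout$Nd)) C[layout$detector_nodes[j], j] <- 1 / (2 * cfg$A)
  X <- solve_fluence(system, cbind(Q, C))
  Phi <- X[, seq_len(layout$Ns), drop = FALSE]
  Psi <- X[, layout$Ns + seq_len(layout$Nd), drop = FALSE]
  flux <- t(Phi[layout$detector_nodes, , drop = FALSE]) / (2 * cfg$A)
  frame <- new_frame(flux)

  D <- diffusion_coef(map)
  dD <- -3 * D^2                       # d D / d mua = d D / d musp
  tri <- geo$tri
  nE <- nrow(tri)
  ## unit-D stiffness entries per element (9 vectors) and area
  G <- vector("list", 9L)
  k <- 0L
  for (a in 1:3) for (b in 1:3) {
    k <- k + 1L
    G[[k]] <- (geo$b[, a] * geo$b[, b] + geo$cc[, a] * geo$cc[, b]) /
      (4 * geo$area)
  }

  npairs <- layout$Ns * layout$Nd
  ncols <- if (unknowns == "both") 2L * N else N
  dlog <- matrix(0 + 0i, npairs, ncols)  # complex d log phi / d p

  grp <- as.vector(tri)                  # length 3 nE, node index per slot
  for (i in seq_len(layout$Ns)) {
    Pe <- matrix(Phi[tri, i], ncol = 3)
    for (j in seq_len(layout$Nd)) {
      Qe <- matrix(Psi[tri, j], ncol = 3)
      ## pairwise products P_a Q_b, 9 complex vectors over elements
      PQ <- vector("list", 9L)
      k <- 0L
      for (a in 1:3) for (b in 1:3) { k <- k + 1L; PQ[[k]] <- Pe[, a] * Qe[, b] }
      ## stiffness bilinear form with unit D
      S <- PQ[[1]] * G[[1]]
      for (k in 2:9) S <- S + PQ[[k]] * G[[k]]
      ## mass contributions per element node slot m
      slot <- matrix(0 + 0i, nE, 3)
      for (m in 1:3) {
        acc <- 0 + 0i
        k <- 0L
        for (a in 1:3) for (b in 1:3) {
          k <- k + 1L
          acc <- acc + .tri3[m, a, b] * PQ[[k]]
        }
        slot[, m] <- geo$area * acc
      }
      stiff_slot <- matrix(S / 3, nE, 3)   # dDbar/dD_m = 1/3 per node
      row <- (i - 1L) * layout$Nd + j
      ## d phi = -(mass + stiffness * dD) summed over incident elements
      mua_col <- rowsum_complex(as.vector(slot) +
                                  as.vector(stiff_slot) * dD[grp], grp, N)
      dlog[row, seq_len(N)] <- -mua_col / flux[i, j]
      if (unknowns == "both") {
        musp_col <- rowsum_complex(as.vector(stiff_slot) * dD[grp], grp, N)
        dlog[row, N + seq_len(N)] <- -musp_col / flux[i, j]
      }
    }
  }

  J <- Re(dlog)
  if (data_type == "both") J <- rbind(J, -Im(dlog))
  list(J = J, frame = frame, Phi = Phi, Psi = Psi)
}

## Sum complex values by integer group, returning a dense length-N vector.
rowsum_complex <- function(x, grp, N) {
  re <- rowsum(Re(x), grp)
  im <- rowsum(Im(x), grp)
  out <- complex(length.out = N)
  idx <- as.integer(rownames(re))
  out[idx] <- re[, 1] + 1i * im[, 1]
  out
}
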