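## Independent oracles.

## Modified Bessel K0 for complex argument via its integral representation
## K0(z) = int_0^inf exp(-z cosh t) dt  (Re z > 0); independent of the FEM.
k0_complex <- function(z) {
  vapply(z, function(zz) {
    fr <- integrate(function(t) Re(exp(-zz * cosh(t))), 0, 20,
                    rel.tol = 1e-10)$value
    fi <- integrate(function(t) Im(exp(-zz * cosh(t))), 0, 20,
                    rel.tol = 1e-10)$value
    complex(real = fr, imaginary = fi)
  }, complex(1))
}

## Central finite-difference Jacobian column for nodal mua or musp.
fd_column <- function(mesh, map, layout, cfg, node, what = "mua",
                      h = 1e-6, data_type = "both") {
  m1 <- map; m2 <- map
  m1[[what]][node] <- m1[[what]][node] - h
  m2[[what]][node] <- m2[[what]][node] + h
  f1 <- forward_measurements(mesh, m1, layout, cfg)
  f2 <- forward_measurements(mesh, m2, layout, cfg)
  la <- as.vector(t(log(f2$amplitude) - log(f1$amplitude)))
  out <- la
  if (data_type == "both")
    out <- c(la, as.vector(t(f2$phase - f1$phase)))
  out / (2 * h)
}
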