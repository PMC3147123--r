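test_that("the assembled system is complex symmetric and real at zero frequency", {
  cc <- fix_coarse()
  map <- optical_map(cc$mesh, 0.01, 0.6)
  sys <- assemble_system(cc$mesh, map, cc$cfg)
  expect_equal(max(abs(sys$Ar - Matrix::t(sys$Ar))), 0)
  expect_equal(max(abs(sys$Ai - Matrix::t(sys$Ai))), 0)
  sys0 <- assemble_system(cc$mesh, map, forward_config(modulation_freq = 0))
  expect_equal(max(abs(sys0$Ai)), 0)
})

test_that("the unit right triangle reproduces the closed-form stiffness matrix", {
  ## single element (0,0), (1,0), (0,1); D = 1 via mua + musp = 1/3.
  mesh <- dcedot:::new_mesh(
    nodes = rbind(c(0, 0), c(1, 0), c(0, 1)),
    elements = matrix(c(1, 2, 3), 1),
    boundary_edges = rbind(c(1, 2), c(2, 3), c(3, 1)),
    region_labels = integer(3))
  ## suppress mass and boundary terms: tiny mua, zero frequency, huge A
  map <- optical_map(mesh, 1e-12, 1 / 3 - 1e-12)
  sys <- assemble_system(mesh, map,
                         forward_config(modulation_freq = 0, A = 1e14))
  K <- as.matrix(sys$Ar)
  K_ref <- rbind(c(1, -0.5, -0.5), c(-0.5, 0.5, 0), c(-0.5, 0, 0.5))
  expect_equal(K, K_ref, tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("the absorption mass term is linear and independent of the stiffness block", {
  cc <- fix_coarse()
  cfg <- cc$cfg
  ## hold D fixed (mua + musp constant) while changing mua
  s1 <- assemble_system(cc$mesh, optical_map(cc$mesh, 0.010, 0.600), cfg)
  s2 <- assemble_system(cc$mesh, optical_map(cc$mesh, 0.020, 0.590), cfg)
  s3 <- assemble_system(cc$mesh, optical_map(cc$mesh, 0.030, 0.580), cfg)
  expect_equal(max(abs(s1$Ai - s2$Ai)), 0)          # frequency mass unchanged
  d12 <- s2$Ar - s1$Ar
  d23 <- s3$Ar - s2$Ar
  expect_lt(max(abs(d12 - d23)), 1e-12)             # equal mua increments
})

test_that("point sources sit one transport length inside the boundary with barycentric weights", {
  cc <- fix_circle()
  musp <- 0.6
  q <- place_source(cc$mesh, cc$layout$source_positions[1, ], musp)
  p <- attr(q, "point")
  node <- cc$layout$source_nodes[1]
  depth <- sqrt(sum((cc$mesh$nodes[node, ] - p)^2))
  expect_equal(depth, 1 / musp, tolerance = 1e-9)
  w <- Re(q[q != 0])
  expect_equal(sum(w), 1, tolerance = 1e-12)
  expect_true(all(w >= 0 & w <= 1))
})

test_that("barycentric weights collapse to a single node at an element vertex", {
  cc <- fix_coarse()
  k <- 11
  fe <- dcedot:::find_element(cc$mesh, cc$mesh$nodes[k, ])
  tri <- cc$mesh$elements[fe$element, ]
  expect_equal(fe$weights[tri == k], 1, tolerance = 1e-9)
})

test_that("the fluence solve is linear in the source", {
  cc <- fix_coarse()
  sys <- assemble_system(cc$mesh, optical_map(cc$mesh, 0.01, 0.6), cc$cfg)
  q <- place_source(cc$mesh, cc$layout$source_positions[1, ], 0.6)
  f1 <- solve_fluence(sys, q)
  f2 <- solve_fluence(sys, 2 * q)
  expect_equal(f2, 2 * f1, tolerance = 1e-12)
})

test_that("fluence decays monotonically with distance in a homogeneous disk", {
  pp <- fix_polar()
  sys <- assemble_system(pp$mesh, pp$map, pp$cfg)
  q <- place_source(pp$mesh, pp$layout$source_positions[1, ], 0.6)
  phi <- solve_fluence(sys, q)
  src <- attr(q, "point")
  ## sample along the diameter through the source
  on_axis <- which(abs(pp$mesh$nodes[, 2]) < 1e-9 & pp$mesh$nodes[, 1] < 20)
  r <- sqrt((pp$mesh$nodes[on_axis, 1] - src[1])^2 +
            (pp$mesh$nodes[on_axis, 2] - src[2])^2)
  o <- order(r)
  expect_true(all(diff(Mod(phi[on_axis][o])) < 0))
})

test_that("FEM fluence matches the 2-D infinite-medium K0 solution at mid-radius", {
  mesh <- polar_disk_mesh(36, 24)
  cfg <- forward_config()
  mua <- 0.01; musp <- 1.0
  map <- optical_map(mesh, mua, musp)
  sys <- assemble_system(mesh, map, cfg)
  ## interior point source at the centre node
  q <- complex(length.out = nrow(mesh$nodes)); q[1] <- 1
  phi <- solve_fluence(sys, q)
  D <- 1 / (3 * (mua + musp))
  kwave <- sqrt((mua + 1i * cfg$omega / cfg$cn) / D)
  r <- sqrt(rowSums(mesh$nodes^2))
  sel <- which(r > 0.45 * 36 & r < 0.55 * 36)
  ref <- k0_complex(kwave * r[sel]) / (2 * pi * D)
  expect_lt(max(abs(Mod(phi[sel]) / Mod(ref) - 1)), 0.05)
  expect_lt(max(abs(Arg(phi[sel]) - Arg(ref))) * 180 / pi, 2)
})

test_that("boundary flux follows phi = Phi / (2A)", {
  cc <- fix_coarse()
  field <- complex(real = rep(0.5, nrow(cc$mesh$nodes)))
  cfg1 <- forward_config(A = 1)
  expect_equal(unname(boundary_flux(field, cc$layout, cfg1)[1]), 0.25 + 0i)
  expect_equal(boundary_flux(0 * field, cc$layout, cfg1),
               rep(0 + 0i, 8), ignore_attr = TRUE)
  cfg2 <- forward_config(A = 2)
  expect_equal(boundary_flux(field, cc$layout, cfg2),
               boundary_flux(field, cc$layout, cfg1) / 2)
  bad_lay <- cc$layout; bad_lay$detector_nodes[1] <- 10 * nrow(cc$mesh$nodes)
  expect_error(boundary_flux(field, bad_lay, cfg1), "out of range")
})

test_that("a frame holds 64 amplitude and 64 phase data for the 8x8 layout", {
  fr <- fix_polar()$frame
  expect_equal(dim(fr$amplitude), c(8, 8))
  expect_equal(dim(fr$phase), c(8, 8))
  expect_equal(length(fr$amplitude) + length(fr$phase), 128)
  expect_true(all(fr$amplitude > 0))
})

test_that("the symmetric system is reciprocal: adjoint identity and optode swap", {
  cc <- fix_circle()
  map <- optical_map(cc$mesh, 0.01, 0.6)
  sys <- assemble_system(cc$mesh, map, cc$cfg)
  q1 <- place_source(cc$mesh, cc$layout$source_positions[1, ], 0.6)
  n2 <- cc$layout$detector_nodes[4]
  e2 <- complex(length.out = sys$N); e2[n2] <- 1
  ## algebraic adjoint reciprocity of the symmetric system: u' K^-1 v = v' K^-1 u
  a <- sum(e2 * solve_fluence(sys, q1))
  b <- sum(q1 * solve_fluence(sys, e2))
  expect_lt(Mod(a - b) / Mod(a), 1e-8)
  ## physically swapping the optode roles agrees at interpolation level
  fr <- forward_measurements(cc$mesh, map, cc$layout, cc$cfg)
  sw <- cc$layout
  sw$source_nodes[1] <- cc$layout$detector_nodes[4]
  sw$source_positions[1, ] <- cc$layout$detector_positions[4, ]
  sw$detector_nodes[4] <- cc$layout$source_nodes[1]
  sw$detector_positions[4, ] <- cc$layout$source_positions[1, ]
  fr_sw <- forward_measurements(cc$mesh, map, sw, cc$cfg)
  expect_lt(Mod(fr_sw$flux[1, 4] - fr$flux[1, 4]) / Mod(fr$flux[1, 4]), 0.05)
})

test_that("measurements on a symmetric disk depend only on source-detector separation", {
  fr <- fix_polar()$frame
  a <- fr$amplitude
  ph <- fr$phase
  ## rotation-equivalent pairs (45 degree shifts) agree to solver precision
  for (shift in c(1, 3)) {
    idx <- c((1 + shift):8, 1:shift)
    expect_lt(max(abs(a[idx, idx] - a) / a), 1e-6)
    expect_lt(max(abs(ph[idx, idx] - ph)), 1e-6)
  }
  ## mirror-equivalent separations agree at discretisation level
  sep <- outer(fix_polar()$layout$source_angles,
               fix_polar()$layout$detector_angles,
               function(x, y) pmin(abs(x - y) %% (2 * pi),
                                   2 * pi - abs(x - y) %% (2 * pi)))
  for (s in unique(round(as.vector(sep), 9))) {
    idx <- which(abs(sep - s) < 1e-9)
    expect_lt(diff(range(a[idx])) / mean(a[idx]), 0.01)
  }
})

test_that("phase lag is positive and grows with source-detector separation", {
  fr <- fix_polar()$frame
  expect_true(all(fr$phase > 0))
  lay <- fix_polar()$layout
  for (i in 1:8) {
    d <- sqrt(rowSums((lay$detector_positions -
                         matrix(lay$source_positions[i, ], 8, 2,
                                byrow = TRUE))^2))
    expect_gt(fr$phase[i, which.max(d)], fr$phase[i, which.min(d)])
  }
})

test_that("halving the edge length changes the log-amplitude by less than 1 %", {
  cfg <- forward_config()
  m1 <- polar_disk_mesh(25, 12); l1 <- map_optodes(m1)
  m2 <- polar_disk_mesh(25, 24); l2 <- map_optodes(m2)
  f1 <- forward_measurements(m1, optical_map(m1, 0.01, 0.6), l1, cfg)
  f2 <- forward_measurements(m2, optical_map(m2, 0.01, 0.6), l2, cfg)
  expect_lt(max(abs(log(f1$amplitude) - log(f2$amplitude))), 0.01)
})
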