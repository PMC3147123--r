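test_that("the contrast series carries the printed ground-truth absorption values", {
  bs <- fix_b_series()
  s <- bs$series
  expect_named(s, c("B0", "B2", "B4", "B6", "B8"))
  ## OBC 1: homogeneous background
  expect_equal(s[["B0"]]$mua, rep(0.01, nrow(bs$mesh$nodes)))
  ## OBC 4: inclusion nodes at 0.04
  idx <- attr(s[["B4"]], "inclusion_nodes")
  expect_true(length(idx) > 0)
  expect_equal(unique(s[["B4"]]$mua[idx]), 0.04)
  ## min/max by construction for every map
  for (nm in names(s)) {
    expect_equal(min(s[[nm]]$mua), 0.01)
    expect_equal(max(s[[nm]]$mua), attr(s[[nm]], "obc") * 0.01)
    expect_equal(unique(s[[nm]]$musp), 0.6)
  }
})

test_that("phantom specifications validate their geometry and contrasts", {
  poly <- make_shape("circle", scale = 25)$polygon
  expect_error(phantom_spec(poly, c(24, 0)), "inside")
  expect_error(phantom_spec(poly, c(8, 0), contrast_levels = c(0.5, 2)),
               ">= 1")
  expect_error(phantom_spec(poly, c(8, 0), contrast_levels = c(4, 2)),
               "ascending")
  expect_error(phantom_spec(poly, c(8, 0), inclusion_diameter = -1), "> 0")
})

test_that("a too-coarse mesh for the inclusion is reported with a density hint", {
  poly <- make_shape("circle", scale = 25)$polygon
  mesh <- build_mesh(poly, 8)
  spec <- phantom_spec(poly, c(8, 0), inclusion_diameter = 2)
  expect_error(make_phantom_series(spec, mesh), "refine the mesh")
})

test_that("the calibration phantom is exactly homogeneous at the printed values", {
  mesh <- fix_coarse()$mesh
  map <- make_calibration_phantom(mesh)
  expect_equal(sd(map$mua), 0)
  expect_equal(unique(map$mua), 0.006)
  expect_equal(unique(map$musp), 1.0)
})

test_that("identity corruption reproduces the forward data exactly", {
  bs <- fix_b_series()
  sim <- simulate_measurements(bs$series[["B0"]], bs$layout,
                               coupling = coupling_factors(rep(1, 8),
                                                           rep(1, 8)),
                               noise = noise_model(0, 0, seed = 1),
                               cfg = bs$cfg)
  expect_equal(sim$flux, bs$frames[["B0"]]$flux)
})

test_that("a single source gain doubles its measurements and keeps phases", {
  bs <- fix_b_series()
  coup <- coupling_factors(s = c(2, rep(1, 7)), d = rep(1, 8))
  sim <- simulate_measurements(bs$series[["B0"]], bs$layout,
                               coupling = coup, cfg = bs$cfg)
  ref <- bs$frames[["B0"]]
  expect_equal(sim$amplitude[1, ], 2 * ref$amplitude[1, ], tolerance = 1e-14)
  expect_equal(sim$amplitude[-1, ], ref$amplitude[-1, ], tolerance = 1e-14)
  expect_equal(sim$phase, ref$phase, tolerance = 1e-14)
  expect_error(coupling_factors(s = c(-1, rep(1, 7)), d = rep(1, 8)),
               "positive")
})

test_that("noisy frames are bit-reproducible under a fixed seed", {
  bs <- fix_b_series()
  nm <- noise_model(0.02, 0.002, seed = 11)
  a <- simulate_measurements(bs$series[["B0"]], bs$layout, noise = nm,
                             cfg = bs$cfg)
  b <- simulate_measurements(bs$series[["B0"]], bs$layout, noise = nm,
                             cfg = bs$cfg)
  expect_identical(a$flux, b$flux)
  nm2 <- nm; nm2$seed <- 12L
  c2 <- simulate_measurements(bs$series[["B0"]], bs$layout, noise = nm2,
                              cfg = bs$cfg)
  expect_false(identical(a$flux, c2$flux))
  ## the caller's RNG stream is untouched
  set.seed(99); before <- rnorm(1)
  set.seed(99)
  invisible(simulate_measurements(bs$series[["B0"]], bs$layout, noise = nm,
                                  cfg = bs$cfg))
  expect_identical(rnorm(1), before)
})

test_that("empirical amplitude noise matches the nominal coefficient of variation", {
  ## corrupt one fixed frame many times and pool the per-pair CVs
  bs <- fix_b_series()
  base <- bs$frames[["B0"]]
  n_rep <- 1000
  cv <- 0.01
  amps <- matrix(0, n_rep, 64)
  for (r in seq_len(n_rep)) {
    pert <- dcedot:::with_rng_seed(20000 + r, rnorm(64, 0, cv))
    amps[r, ] <- as.vector(base$amplitude) * (1 + pert)
  }
  emp <- mean(apply(amps, 2, sd) / colMeans(amps))
  expect_lt(abs(emp - cv) / cv, 0.10)
})

test_that("the ICG series is baseline before injection and peaks as designed", {
  bs <- fix_b_series()
  prof <- kinetic_profile()
  series <- make_icg_series(bs$spec, prof, bs$mesh)
  expect_length(series, 32)
  delta <- attr(series, "truth_delta")
  ## frames before the injection frame are exactly baseline
  for (k in 1:6) expect_identical(series[[k]]$mua, bs$series[["B0"]]$mua)
  expect_true(all(delta[1:6] == 0))
  ## the sampled peak reaches the design peak up to frame discretisation
  expect_lte(max(delta), prof$peak_delta_mua)
  half_step <- kinetic_delta(prof, (prof$injection_frame - 1 +
                                      prof$rise_time / prof$frame_interval +
                                      0.5) * prof$frame_interval)
  expect_gte(max(delta), half_step)
  ## background carries the scaled-down copy
  k_peak <- which.max(delta)
  idx <- attr(series, "inclusion_nodes")
  bg <- setdiff(seq_along(series[[k_peak]]$mua), idx)
  expect_equal(unique(series[[k_peak]]$mua[bg] - 0.01),
               0.1 * delta[k_peak], tolerance = 1e-12)
})

test_that("the gamma-variate tail decays below 5 % of peak for short decay times", {
  prof <- kinetic_profile(decay_time = 30, rise_time = 24)
  t_end <- prof$n_frames * prof$frame_interval
  expect_lt(kinetic_delta(prof, t_end) / prof$peak_delta_mua, 0.05)
  expect_error(kinetic_profile(injection_frame = 40), "n_frames")
  expect_error(kinetic_profile(peak_delta_mua = -1), ">= 0")
})
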