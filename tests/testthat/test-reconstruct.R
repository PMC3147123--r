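test_that("homogeneous noise-free data reconstruct to a flat map for every method", {
  bs <- fix_b_series()
  ctrl <- list(homog = bs$hom, max_iter = 6)
  for (m in 1:4) {
    mesh <- if (m == 4) bs$mesh_lab else bs$mesh
    rec <- reconstruct(bs$calibrated[["B0"]], mesh, bs$layout, m, bs$cfg,
                       control = ctrl)
    expect_lt(sd(rec$map$mua) / mean(rec$map$mua), 0.05,
              label = sprintf("method %d flatness", m))
  }
})

test_that("the structural prior recovers the highest-contrast inclusion absorption", {
  bs <- fix_b_series()
  rec <- reconstruct(bs$calibrated[["B8"]], bs$mesh_lab, bs$layout, 4,
                     bs$cfg, control = list(homog = bs$hom))
  roi <- roi_from_prior(bs$mesh_lab, 1)
  mu <- mean_mua(rec, bs$mesh_lab, roi)
  expect_lt(abs(mu - 0.08) / 0.08, 0.10)
})

test_that("explicit coupling unknowns recover an injected gain ratio", {
  bs <- fix_b_series()
  coup <- coupling_factors(s = c(1.3, rep(1, 7)), d = rep(1, 8))
  fr <- simulate_measurements(bs$series[["B8"]], bs$layout,
                              coupling = coup, cfg = bs$cfg)
  fr0 <- simulate_measurements(bs$series[["B0"]], bs$layout,
                               coupling = coup, cfg = bs$cfg)
  calib <- calibrate(fr, bs$homo, bs$homo)
  hom <- fit_homogeneous(calibrate(fr0, bs$homo, bs$homo), bs$mesh,
                         bs$layout, bs$cfg)
  rec <- reconstruct(calib, bs$mesh, bs$layout, 3, bs$cfg,
                     control = list(homog = hom))
  s <- rec$coupling$s
  expect_lt(abs(s[1] / s[2] - 1.3) / 1.3, 0.05)
  ## on coupling-free data the gains stay near unity and the augmented
  ## solution reproduces the plain ROI recovery
  calib_cf <- bs$calibrated[["B8"]]
  rec3 <- reconstruct(calib_cf, bs$mesh, bs$layout, 3, bs$cfg,
                      control = list(homog = bs$hom, max_iter = 10))
  rec2 <- reconstruct(calib_cf, bs$mesh, bs$layout, 2, bs$cfg,
                      control = list(homog = bs$hom, max_iter = 10))
  expect_true(all(abs(log(rec3$coupling$s)) < 0.1))
  expect_true(all(abs(log(rec3$coupling$d)) < 0.1))
  idx <- attr(bs$series[["B8"]], "inclusion_nodes")
  expect_lt(abs(mean(rec3$map$mua[idx]) - mean(rec2$map$mua[idx])) /
              mean(rec2$map$mua[idx]), 0.05)
})

test_that("modelling the couplings suppresses optode hypersensitivity", {
  bs <- fix_b_series()
  set.seed(1)
  coup <- coupling_factors(s = exp(rnorm(8, 0, 0.1)),
                           d = exp(rnorm(8, 0, 0.1)))
  calib <- calibrate(simulate_measurements(bs$series[["B8"]], bs$layout,
                                           coupling = coup, cfg = bs$cfg),
                     bs$homo, bs$homo)
  hom <- fit_homogeneous(
    calibrate(simulate_measurements(bs$series[["B0"]], bs$layout,
                                    coupling = coup, cfg = bs$cfg),
              bs$homo, bs$homo),
    bs$mesh, bs$layout, bs$cfg)
  on <- unique(c(bs$layout$source_nodes, bs$layout$detector_nodes))
  art <- numeric(2)
  for (m in 2:3) {
    rec <- reconstruct(calib, bs$mesh, bs$layout, m, bs$cfg,
                       control = list(homog = hom))
    art[m - 1] <- sum((rec$map$mua[on] - median(rec$map$mua))^2)
  }
  expect_lt(art[2], art[1])   # method 3 artifact energy strictly lower
})

test_that("zero-sum gain patterns are absorbed by the coupling unknowns", {
  bs <- fix_b_series()
  ## a gauge-compatible corruption: log gains sum to zero per block
  ls <- c(0.2, -0.1, 0.05, -0.15, 0.1, -0.05, 0.03, -0.08)
  ls <- ls - mean(ls)
  ld <- rev(ls)
  coup <- coupling_factors(exp(ls), exp(ld))
  corrupted <- calibrate(
    simulate_measurements(bs$series[["B8"]], bs$layout, coupling = coup,
                          cfg = bs$cfg), bs$homo, bs$homo)
  ctrl <- list(homog = bs$hom, max_iter = 12)
  r_clean <- reconstruct(bs$calibrated[["B8"]], bs$mesh, bs$layout, 3,
                         bs$cfg, control = ctrl)
  r_corr <- reconstruct(corrupted, bs$mesh, bs$layout, 3, bs$cfg,
                        control = ctrl)
  ## the image is essentially unchanged: the gains soak up the corruption
  expect_lt(max(abs(r_corr$map$mua - r_clean$map$mua)) /
              max(r_clean$map$mua), 0.05)
  expect_equal(log(r_corr$coupling$s) - log(r_clean$coupling$s), ls,
               tolerance = 0.02, ignore_attr = TRUE)
  ## gauge: recovered log gains always sum to zero per block
  expect_equal(sum(log(r_corr$coupling$s)), 0, tolerance = 1e-12)
  expect_equal(sum(log(r_corr$coupling$d)), 0, tolerance = 1e-12)
})

test_that("invalid method ids and a prior-free mesh are rejected", {
  bs <- fix_b_series()
  expect_error(reconstruct(bs$calibrated[["B0"]], bs$mesh, bs$layout, 7,
                           bs$cfg), "method_id")
  expect_error(reconstruct(bs$calibrated[["B0"]], bs$mesh, bs$layout, 4,
                           bs$cfg, control = list(homog = bs$hom)),
               "region labels")
})
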