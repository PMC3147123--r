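## Synthetic enhancement map on a mesh from a function of position.
field_map <- function(mesh, f) {
  structure(list(values = f(mesh$nodes[, 1], mesh$nodes[, 2]), mesh = mesh,
                 label = NULL), class = "enhancement_map")
}

test_that("difference maps are zero for identical inputs and antisymmetric", {
  bs <- fix_b_series()
  m0 <- bs$series[["B0"]]; m8 <- bs$series[["B8"]]
  expect_true(all(difference_map(m0, m0)$values == 0))
  d1 <- difference_map(m8, m0)
  d2 <- difference_map(m0, m8)
  expect_equal(d1$values, -d2$values)
  other <- optical_map(fix_polar()$mesh, 0.01, 0.6)
  expect_error(difference_map(m0, other), "same mesh")
})

test_that("FWHM ROI selects the half-maximum component containing the peak", {
  mesh <- fix_circle()$mesh
  ## compact blob: 1 at the centre of the inclusion, 0 outside 10 mm
  blob <- function(cx, cy, peak = 1) function(x, y) {
    r2 <- (x - cx)^2 + (y - cy)^2
    ifelse(r2 < 100, peak * exp(-r2 / 18), 0)
  }
  m1 <- field_map(mesh, blob(8, 0))
  roi <- roi_fwhm(m1)
  expect_setequal(unname(roi),
                  unname(which(m1$values >= 0.5 * max(m1$values))))
  ## two disjoint blobs: only the higher one's component is kept
  m2 <- field_map(mesh, function(x, y)
    blob(8, 0, 1)(x, y) + blob(-12, 0, 0.6)(x, y))
  roi2 <- roi_fwhm(m2)
  expect_true(all(mesh$nodes[roi2, 1] > 0))
  expect_equal(max(m2$values[roi2]), max(m2$values))
  ## flat maps cannot contain an inclusion
  expect_error(roi_fwhm(field_map(mesh, function(x, y) rep(1, length(x)))),
               "no inclusion")
})

test_that("prior-based ROIs are the labelled node sets", {
  bs <- fix_b_series()
  roi <- roi_from_prior(bs$mesh_lab, 1)
  expect_equal(length(roi), sum(bs$mesh_lab$region_labels == 1))
  roi0 <- roi_from_prior(bs$mesh_lab, 0)
  expect_equal(sort(c(roi, roi0)), seq_len(nrow(bs$mesh_lab$nodes)))
  expect_error(roi_from_prior(bs$mesh_lab, 3), "unknown region")
})

test_that("mean enhancement is the area-weighted nodal average", {
  mesh <- fix_coarse()$mesh
  m <- field_map(mesh, function(x, y) 0.02 * x + 0.001)
  roi <- which(mesh$nodes[, 1] > 0)
  w <- node_weights(mesh)
  brute <- sum(w[roi] * m$values[roi]) / sum(w[roi])
  expect_equal(mean_enhancement(m, roi), brute, tolerance = 1e-14)
  ## a constant is returned exactly, and a zero map averages to zero
  expect_equal(mean_enhancement(field_map(mesh, function(x, y)
    rep(0.42, length(x))), roi), 0.42)
  expect_equal(mean_enhancement(field_map(mesh, function(x, y)
    numeric(length(x))), seq_len(nrow(mesh$nodes))), 0)
  expect_error(mean_enhancement(m, integer(0)), "empty")
})

test_that("linearity analysis reproduces closed-form least squares", {
  ## perfectly linear data fit with zero deviation
  la <- linearity_analysis(c(1, 2, 4, 6, 8), 0.01 * c(0, 1, 3, 5, 7))
  expect_equal(la$deviations, rep(0, 5), tolerance = 1e-12)
  expect_equal(la$slope, 0.01, tolerance = 1e-12)
  ## frozen closed-form case: (1,1), (2,2), (3,4)
  lb <- linearity_analysis(1:3, c(1, 2, 4))
  expect_equal(lb$slope, 1.5, tolerance = 1e-12)
  expect_equal(lb$intercept, -2 / 3, tolerance = 1e-12)
  expect_equal(lb$deviations, c(1 / 24, 1 / 12, 1 / 24), tolerance = 1e-12)
  ## adding a constant leaves the slope unchanged
  lc <- linearity_analysis(1:3, c(1, 2, 4) + 10)
  expect_equal(lc$slope, lb$slope, tolerance = 1e-12)
  expect_error(linearity_analysis(1:2, 1:2), "3 points")
})

test_that("kinetics curves normalise to unit maximum and flag flat series", {
  mesh <- fix_coarse()$mesh
  vals <- c(0, 0, 0.4, 1.0, 0.7, 0.3)
  maps <- lapply(vals, function(v) field_map(mesh, function(x, y)
    rep(v * 0.03, length(x))))
  roi <- seq_len(nrow(mesh$nodes))
  kc <- kinetics_curve(maps, roi, times = 16 * seq_along(vals))
  expect_equal(max(kc$normalized), 1)
  expect_equal(kc$values, vals * 0.03, tolerance = 1e-12)
  ## idempotence: normalising an already normalised curve changes nothing
  maps_n <- lapply(kc$normalized, function(v) field_map(mesh, function(x, y)
    rep(v, length(x))))
  kc2 <- kinetics_curve(maps_n, roi, kc$times)
  expect_equal(kc2$normalized, kc$normalized, tolerance = 1e-12)
  ## all-zero curves are flagged but still returned
  zero_maps <- lapply(1:3, function(i) field_map(mesh, function(x, y)
    numeric(length(x))))
  expect_warning(kz <- kinetics_curve(zero_maps, roi, times = 1:3),
                 "normalization")
  expect_true(kz$normalization_failed)
  expect_equal(kz$values, rep(0, 3))
  expect_error(kinetics_curve(maps, roi, times = rev(16 * seq_along(vals))),
               "increasing")
})
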