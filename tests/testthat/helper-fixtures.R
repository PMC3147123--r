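## Shared fixtures, built once per test run and cached.

.fix_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fix_cache[[name]])) .fix_cache[[name]] <- builder()
  .fix_cache[[name]]
}

fwd_cfg <- function() forward_config()

## Unstructured circle mesh at moderate resolution with layout.
fix_circle <- function() fixture("circle", function() {
  poly <- make_shape("circle", scale = 25)$polygon
  mesh <- build_mesh(poly, 2.8)
  list(poly = poly, mesh = mesh, layout = map_optodes(mesh),
       cfg = fwd_cfg())
})

## Coarse circle mesh for cheap checks.
fix_coarse <- function() fixture("coarse", function() {
  poly <- make_shape("circle", scale = 25)$polygon
  mesh <- build_mesh(poly, 4.5)
  list(poly = poly, mesh = mesh, layout = map_optodes(mesh),
       cfg = fwd_cfg())
})

## Structured symmetric polar mesh with layout and a homogeneous frame.
fix_polar <- function() fixture("polar", function() {
  mesh <- polar_disk_mesh(25, 10)
  layout <- map_optodes(mesh)
  cfg <- fwd_cfg()
  map <- optical_map(mesh, 0.01, 0.6)
  list(mesh = mesh, layout = layout, cfg = cfg, map = map,
       frame = forward_measurements(mesh, map, layout, cfg))
})

## Same-mesh noise-free contrast-series pipeline on the circle phantom:
## B-series maps, simulated + calibrated frames, homogeneous fit, labelled
## mesh.  This is the exact-recovery configuration (data generated on the
## reconstruction mesh) used by the parameter-recovery checks.
fix_b_series <- function() fixture("b_series", function() {
  cc <- fix_circle()
  spec <- phantom_spec(cc$poly, inclusion_center = c(8, 0))
  mesh_lab <- label_region(cc$mesh, disk_polygon(c(8, 0), 10))
  series <- make_phantom_series(spec, cc$mesh)
  homo <- forward_measurements(cc$mesh, make_calibration_phantom(cc$mesh),
                               cc$layout, cc$cfg)
  frames <- lapply(series, forward_measurements, mesh = cc$mesh,
                   layout = cc$layout, cfg = cc$cfg)
  calibrated <- lapply(frames, calibrate, homo_measured = homo,
                       homo_forward = homo)
  hom <- fit_homogeneous(calibrated[["B0"]], cc$mesh, cc$layout, cc$cfg)
  list(spec = spec, mesh = cc$mesh, mesh_lab = mesh_lab,
       layout = cc$layout, cfg = cc$cfg, series = series, homo = homo,
       frames = frames, calibrated = calibrated, hom = hom)
})

## Mean mua of a reconstruction over a node set (area-weighted).
mean_mua <- function(recon, mesh, roi) {
  em <- structure(list(values = recon$map$mua, mesh = mesh),
                  class = "enhancement_map")
  mean_enhancement(em, roi)
}
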