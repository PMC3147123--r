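## Synthetic phantoms: contrast series, calibration phantom, corrupted
## measurement frames and an ICG-like bolus time series, all with exact
## ground truth attached.

#' Specification of a contrast phantom
#'
#' @param boundary_polygon simple CCW polygon of the phantom outline (mm).
#' @param inclusion_center centre of the cylindrical inclusion (mm).
#' @param inclusion_diameter inclusion diameter in mm (default 10, the inner
#'   diameter of a thin-walled NMR tube).
#' @param background_mua,background_musp homogeneous background optical
#'   properties (defaults 0.01 and 0.6 mm^-1).
#' @param contrast_levels ascending object-to-background contrasts (OBC);
#'   default `c(1, 2, 4, 6, 8)` giving the B0...B8 series with inclusion
#'   mua 0.01, 0.02, 0.04, 0.06, 0.08 mm^-1.
#' @return a `phantom_spec`.
#' @export
phantom_spec <- function(boundary_polygon, inclusion_center,
                         inclusion_diameter = 10,
                         background_mua = 0.01, background_musp = 0.6,
                         contrast_levels = c(1, 2, 4, 6, 8)) {
  poly <- as.matrix(boundary_polygon)
  if (inclusion_diameter <= 0) stopf("inclusion diameter must be > 0")
  if (any(contrast_levels < 1)) stopf("contrast levels must all be >= 1")
  if (is.unsorted(contrast_levels, strictly = FALSE))
    stopf("contrast levels must be sorted ascending")
  inside <- points_in_polygon(poly, matrix(inclusion_center, ncol = 2))
  margin <- dist_to_polygon(matrix(inclusion_center, ncol = 2), poly)
  if (!inside || margin <= inclusion_diameter / 2)
    stopf("inclusion does not lie strictly inside the boundary polygon")
  structure(list(boundary_polygon = poly,
                 inclusion_center = as.numeric(inclusion_center),
                 inclusion_diameter = inclusion_diameter,
                 background_mua = background_mua,
                 background_musp = background_musp,
                 contrast_levels = contrast_levels),
            class = "phantom_spec")
}

#' Measurement noise model
#'
#' Multiplicative Gaussian noise on amplitude and additive Gaussian noise
#' on phase, the conventional frequency-domain instrument model.
#'
#' @param amplitude_cv relative standard deviation of the amplitude noise
#'   (default 0.01 = 1 %).
#' @param phase_sd standard deviation of the phase noise in radians
#'   (default 0.1 degree).
#' @param seed RNG seed; the same seed reproduces bit-identical frames.
#' @return a `noise_model`.
#' @export
noise_model <- function(amplitude_cv = 0.01, phase_sd = 0.1 * pi / 180,
                        seed = 1L) {
  if (amplitude_cv < 0 || phase_sd < 0) stopf("noise levels must be >= 0")
  structure(list(amplitude_cv = amplitude_cv, phase_sd = phase_sd,
                 seed = as.integer(seed)), class = "noise_model")
}

#' Source/detector coupling factors
#'
#' Per-optode multiplicative gains modelling fibre-tissue contact
#' variability; the measured flux for pair (i, j) is `s_i d_j` times the
#' modelled flux.
#'
#' @param s,d positive gain per source / per detector.
#' @return a `coupling_factors`.
#' @export
coupling_factors <- function(s, d) {
  if (any(s <= 0) || any(d <= 0))
    stopf("coupling factors must be positive (physically meaningless gain)")
  structure(list(s = as.numeric(s), d = as.numeric(d)),
            class = "coupling_factors")
}

#' ICG bolus kinetic profile
#'
#' Gamma-variate enhancement curve: zero before the injection, then
#' `(tau/rise_time)^alpha exp(alpha (1 - tau/rise_time))` scaled to
#' `peak_delta_mua`, with `alpha = rise_time / decay_time` so the tail
#' decays as `exp(-tau / decay_time)`.
#'
#' @param n_frames number of measurement frames (default 32).
#' @param frame_interval seconds between frames (default 16).
#' @param injection_frame frame during which the bolus is injected
#'   (default 7); frames before it are exactly baseline.
#' @param peak_delta_mua peak absorption enhancement in mm^-1.
#' @param rise_time,decay_time curve shape parameters in seconds.
#' @return a `kinetic_profile`.
#' @export
kinetic_profile <- function(n_frames = 32, frame_interval = 16,
                            injection_frame = 7, peak_delta_mua = 0.03,
                            rise_time = 48, decay_time = 120) {
  if (injection_frame >= n_frames) stopf("injection_frame must be < n_frames")
  if (peak_delta_mua < 0) stopf("peak_delta_mua must be >= 0")
  structure(list(n_frames = as.integer(n_frames),
                 frame_interval = frame_interval,
                 injection_frame = as.integer(injection_frame),
                 peak_delta_mua = peak_delta_mua,
                 rise_time = rise_time, decay_time = decay_time),
            class = "kinetic_profile")
}

#' Evaluate the gamma-variate enhancement curve
#' @param profile a `kinetic_profile`.
#' @param t times in seconds (frame k is acquired at `k * frame_interval`;
#'   the bolus arrives at `(injection_frame - 1) * frame_interval`).
#' @return enhancement delta-mua at each time (mm^-1).
#' @export
kinetic_delta <- function(profile, t) {
  t0 <- (profile$injection_frame - 1) * profile$frame_interval
  tau <- pmax(t - t0, 0)
  alpha <- profile$rise_time / profile$decay_time
  v <- ifelse(tau > 0,
              (tau / profile$rise_time)^alpha *
                exp(alpha * (1 - tau / profile$rise_time)),
              0)
  profile$peak_delta_mua * v
}

## Nodes inside the phantom's inclusion; errors if the mesh is too coarse.
inclusion_nodes <- function(spec, mesh) {
  d <- sqrt((mesh$nodes[, 1] - spec$inclusion_center[1])^2 +
            (mesh$nodes[, 2] - spec$inclusion_center[2])^2)
  idx <- which(d <= spec$inclusion_diameter / 2)
  if (length(idx) == 0)
    stopf(paste0("no mesh node inside the inclusion; refine the mesh ",
                 "(target edge <= %.1f mm)"), spec$inclusion_diameter / 3)
  idx
}

#' Generate the contrast (B-) series of optical maps
#'
#' One map per contrast level: background nodes carry the background
#' properties, inclusion nodes carry `mua = OBC * background_mua`;
#' scattering is spatially constant.
#'
#' @param spec a `phantom_spec`.
#' @param mesh a `dot_mesh` covering the phantom.
#' @return list of `optical_map`s (named `B0` for OBC 1, otherwise
#'   `B<OBC>`: B2, B4, ...); each carries attributes `obc` and
#'   `inclusion_nodes`.
#' @export
make_phantom_series <- function(spec, mesh) {
  idx <- inclusion_nodes(spec, mesh)
  maps <- lapply(spec$contrast_levels, function(obc) {
    mua <- rep(spec$background_mua, nrow(mesh$nodes))
    mua[idx] <- obc * spec$background_mua
    m <- optical_map(mesh, mua, spec$background_musp)
    attr(m, "obc") <- obc
    attr(m, "inclusion_nodes") <- idx
    m
  })
  names(maps) <- paste0("B", ifelse(spec$contrast_levels == 1, 0,
                                    spec$contrast_levels))
  maps
}

#' Homogeneous calibration phantom map
#'
#' Spatially constant map with the solid epoxy calibration phantom
#' properties, `mua = 0.006 mm^-1`, `musp = 1.0 mm^-1`.
#'
#' @param mesh circular calibration `dot_mesh`.
#' @param mua,musp calibration phantom optical properties.
#' @return an `optical_map`.
#' @export
make_calibration_phantom <- function(mesh, mua = 0.006, musp = 1.0) {
  optical_map(mesh, mua, musp)
}

#' Simulate a (possibly corrupted) measurement frame
#'
#' Runs the forward model and applies multiplicative coupling factors and
#' instrument noise: `amplitude(i,j) = s_i d_j |phi_ij| (1 + noise)`, phase
#' gets additive Gaussian noise.  Deterministic given the noise seed; the
#' caller's RNG state is untouched.
#'
#' @param map an `optical_map`.
#' @param layout an `optode_layout` on the same mesh.
#' @param noise a `noise_model`, or `NULL` for noise-free data.
#' @param coupling a `coupling_factors`, or `NULL` for unity gains.
#' @param cfg a `forward_config`.
#' @param frame_time frame time stamp (s).
#' @return a `dot_frame`.
#' @export
simulate_measurements <- function(map, layout, noise = NULL, coupling = NULL,
                                  cfg = forward_config(), frame_time = 0) {
  frame <- forward_measurements(map$mesh, map, layout, cfg, frame_time)
  flux <- frame$flux
  if (!is.null(coupling)) {
    if (any(coupling$s <= 0) || any(coupling$d <= 0))
      stopf("coupling factors must be positive")
    flux <- flux * outer(coupling$s, coupling$d)
  }
  if (!is.null(noise) && (noise$amplitude_cv > 0 || noise$phase_sd > 0)) {
    n <- length(flux)
    pert <- with_rng_seed(noise$seed, {
      list(a = rnorm(n, 0, noise$amplitude_cv), p = rnorm(n, 0, noise$phase_sd))
    })
    ## positive phase lag is -Arg(flux): adding lag rotates by exp(-i p)
    flux <- flux * (1 + pert$a) * exp(-1i * pert$p)
  }
  new_frame(flux, frame_time)
}

#' Generate the ICG uptake time series of optical maps
#'
#' Frames before the injection equal the baseline map exactly; afterwards
#' the inclusion follows the gamma-variate enhancement of `profile` and the
#' background receives a scaled-down copy (default 10 %).
#'
#' @param spec a `phantom_spec` (its first contrast level is the baseline).
#' @param profile a `kinetic_profile`.
#' @param mesh a `dot_mesh`.
#' @param background_fraction fraction of the inclusion enhancement applied
#'   to the background nodes.
#' @return list of `optical_map`s with attributes `times` (s),
#'   `truth_delta` (inclusion enhancement per frame) and `inclusion_nodes`
#'   on the list.
#' @export
make_icg_series <- function(spec, profile, mesh, background_fraction = 0.1) {
  idx <- inclusion_nodes(spec, mesh)
  times <- seq_len(profile$n_frames) * profile$frame_interval
  delta <- kinetic_delta(profile, times)
  maps <- lapply(seq_len(profile$n_frames), function(k) {
    mua <- rep(spec$background_mua + background_fraction * delta[k],
               nrow(mesh$nodes))
    mua[idx] <- spec$background_mua + delta[k]
    m <- optical_map(mesh, mua, spec$background_musp)
    attr(m, "time") <- times[k]
    m
  })
  attr(maps, "times") <- times
  attr(maps, "truth_delta") <- delta
  attr(maps, "inclusion_nodes") <- idx
  maps
}
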