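## End-to-end studies: the contrast-series (B-series) method comparison and
## the ICG time-series experiment, both driven by one configuration object.

#' Configuration for the phantom and DCE studies
#'
#' All arguments have defaults matching the study conditions: eight
#' arbitrarily shaped phantoms at 25 mm nominal radius, 10 mm inclusions,
#' background `mua = 0.01`, `musp = 0.6` mm^-1, contrast series OBC
#' 1/2/4/6/8, calibration phantom `mua = 0.006`, `musp = 1.0` mm^-1, and a
#' 32-frame ICG series with injection during frame 7 at 16 s resolution.
#'
#' @param shapes shape ids to run (see [shape_ids()]).
#' @param contrast_levels object-to-background contrasts.
#' @param methods analysis methods (subset of 1:4).
#' @param seeds replicate seeds for noisy runs.
#' @param noise a `noise_model` or `NULL` (noise-free); its seed field is
#'   re-derived per shape/replicate/frame.
#' @param coupling a `coupling_factors` applied to the object frames (not
#'   the calibration scan), or `NULL` for unity gains.
#' @param scale nominal phantom radius (mm).
#' @param pixel_mm mask pixel size (mm).
#' @param recon_edge reconstruction mesh target edge (mm).
#' @param data_refine data-generation mesh refinement factor (the forward
#'   data are produced on a mesh this much finer, avoiding the inverse
#'   crime); `same_mesh = TRUE` forces identical meshes for exact-recovery
#'   checks.
#' @param same_mesh logical, see `data_refine`.
#' @param inclusion_frac radial position of the inclusion centre as a
#'   fraction of the boundary distance along `inclusion_angle`.
#' @param inclusion_angle direction of the inclusion offset (radians).
#' @param inclusion_diameter inclusion diameter (mm).
#' @param background_mua,background_musp background optical properties.
#' @param cal_mua,cal_musp calibration phantom optical properties.
#' @param profile `kinetic_profile` for the ICG study.
#' @param dce_shape,dce_edge,dce_methods ICG study geometry and methods.
#' @param background_fraction background fraction of the ICG enhancement.
#' @param cfg `forward_config`.
#' @param control reconstruction control list (see [reconstruct()]).
#' @param seed master seed from which all per-frame noise seeds derive.
#' @param out_dir optional output directory (CSV tables are written there).
#' @param render write PNG renderings of the maps (requires `out_dir`).
#' @return an `experiment_config` list.
#' @export
experiment_config <- function(shapes = shape_ids(),
                              contrast_levels = c(1, 2, 4, 6, 8),
                              methods = 1:4, seeds = 1L, noise = NULL,
                              coupling = NULL, scale = 25, pixel_mm = 0.5,
                              recon_edge = 3, data_refine = 1.5,
                              same_mesh = FALSE, inclusion_frac = 0.45,
                              inclusion_angle = 0, inclusion_diameter = 10,
                              background_mua = 0.01, background_musp = 0.6,
                              cal_mua = 0.006, cal_musp = 1.0,
                              profile = kinetic_profile(),
                              dce_shape = "circle", dce_edge = 2.2,
                              dce_methods = c(2, 4),
                              background_fraction = 0.1,
                              cfg = forward_config(), control = list(),
                              seed = 1L, out_dir = NULL, render = FALSE) {
  cfgs <- as.list(environment())
  structure(cfgs, class = "experiment_config")
}

## Deterministic per-frame noise seed (< 2^31).
derive_seed <- function(base, shape_i, rep_i, frame_i) {
  ((base * 1009L + shape_i * 101L + rep_i * 17L + frame_i) %% 2147483629L) + 1L
}

## Build meshes, layouts and phantom spec for one shape.
phantom_geometry <- function(config, shape_id, target_edge = NULL) {
  edge <- target_edge %||% config$recon_edge
  sh <- make_shape(shape_id, scale = config$scale, pixel_mm = config$pixel_mm)
  mask <- mask_from_image(sh$mask * 255)
  poly <- extract_boundary(mask, keep_every = 5, pixel_mm = config$pixel_mm)
  recon_mesh <- build_mesh(poly, edge)
  data_mesh <- if (config$same_mesh) recon_mesh
               else build_mesh(poly, edge / config$data_refine)
  dir <- c(cos(config$inclusion_angle), sin(config$inclusion_angle))
  hit <- ray_polygon_hit(c(0, 0), dir, poly)
  center <- config$inclusion_frac * hit
  spec <- phantom_spec(poly, center,
                       inclusion_diameter = config$inclusion_diameter,
                       background_mua = config$background_mua,
                       background_musp = config$background_musp,
                       contrast_levels = config$contrast_levels)
  recon_mesh <- label_region(recon_mesh,
                             disk_polygon(center, config$inclusion_diameter))
  list(spec = spec, polygon = poly,
       recon_mesh = recon_mesh, data_mesh = data_mesh,
       recon_layout = map_optodes(recon_mesh),
       data_layout = map_optodes(data_mesh))
}

## Calibration chain: simulated measurement of the homogeneous calibration
## phantom (data-resolution circular mesh) and its forward model at
## reconstruction resolution.
calibration_pair <- function(config, target_edge = NULL) {
  edge <- target_edge %||% config$recon_edge
  poly <- make_shape("circle", scale = config$scale,
                     pixel_mm = config$pixel_mm)$polygon
  recon_mesh <- build_mesh(poly, edge)
  data_mesh <- if (config$same_mesh) recon_mesh
               else build_mesh(poly, edge / config$data_refine)
  recon_layout <- map_optodes(recon_mesh)
  data_layout <- map_optodes(data_mesh)
  homo_measured <- forward_measurements(
    data_mesh, make_calibration_phantom(data_mesh, config$cal_mua,
                                        config$cal_musp),
    data_layout, config$cfg)
  homo_forward <- forward_measurements(
    recon_mesh, make_calibration_phantom(recon_mesh, config$cal_mua,
                                         config$cal_musp),
    recon_layout, config$cfg)
  list(homo_measured = homo_measured, homo_forward = homo_forward)
}

#' Run the contrast-series phantom study
#'
#' For every shape x replicate x method: simulates the B-series on the
#' data-generation mesh (optionally noise- and coupling-corrupted),
#' calibrates against the homogeneous phantom chain, reconstructs every
#' contrast, forms enhancement images against the B0 baseline
#' reconstruction, extracts the ROI (FWHM of the top-contrast enhancement
#' map for methods 1-3, the structural prior region for method 4) and fits
#' the enhancement-versus-contrast line.
#'
#' @param config an [experiment_config()].
#' @return list with `enhancement` (long data frame: shape, seed, method,
#'   contrast, mean and true enhancement, fit and deviation), `linearity`
#'   (per-cell slope/intercept/max deviation/R^2), `failures`, `config`,
#'   and `maps` (per cell, the reconstructed maps) unless `out_dir` is set
#'   in which case tables are also written as CSV.
#' @export
run_phantom_study <- function(config = experiment_config()) {
  cal <- calibration_pair(config)
  enh <- NULL; lin <- NULL; failures <- character(0)
  maps <- list()
  for (si in seq_along(config$shapes)) {
    shape <- config$shapes[si]
    geo <- tryCatch(phantom_geometry(config, shape), error = function(e) e)
    if (inherits(geo, "error")) {
      failures <- c(failures, sprintf("%s: geometry: %s", shape,
                                      conditionMessage(geo)))
      next
    }
    truth_maps <- make_phantom_series(geo$spec, geo$data_mesh)
    truth_delta <- (config$contrast_levels - 1) * config$background_mua
    for (ri in seq_along(config$seeds)) {
      rep_seed <- config$seeds[ri]
      frames <- lapply(seq_along(truth_maps), function(ci) {
        nm <- config$noise
        if (!is.null(nm))
          nm$seed <- derive_seed(config$seed + rep_seed, si, ri, ci)
        simulate_measurements(truth_maps[[ci]], geo$data_layout, noise = nm,
                              coupling = config$coupling, cfg = config$cfg)
      })
      calibrated <- lapply(frames, calibrate, homo_measured = cal$homo_measured,
                           homo_forward = cal$homo_forward)
      hom <- tryCatch(
        fit_homogeneous(calibrated[[1]], geo$recon_mesh, geo$recon_layout,
                        config$cfg),
        error = function(e) e)
      if (inherits(hom, "error")) {
        failures <- c(failures, sprintf("%s seed %d: homogeneous fit: %s",
                                        shape, rep_seed,
                                        conditionMessage(hom)))
        next
      }
      for (method in config$methods) {
        cell <- tryCatch({
          ctrl <- config$control; ctrl$homog <- hom
          recons <- lapply(calibrated, reconstruct, mesh = geo$recon_mesh,
                           layout = geo$recon_layout, method_id = method,
                           cfg = config$cfg, control = ctrl)
          dce <- lapply(seq_along(recons), function(ci)
            difference_map(recons[[ci]]$map, recons[[1]]$map,
                           label = names(truth_maps)[ci]))
          roi <- if (method == 4) roi_from_prior(geo$recon_mesh, 1)
                 else roi_fwhm(dce[[length(dce)]])
          means <- vapply(dce, mean_enhancement, numeric(1), roi = roi)
          fit <- if (length(means) >= 3)
            linearity_analysis(config$contrast_levels, means) else NULL
          list(recons = recons, dce = dce, roi = roi, means = means,
               fit = fit)
        }, error = function(e) e)
        if (inherits(cell, "error")) {
          failures <- c(failures, sprintf("%s seed %d method %d: %s", shape,
                                          rep_seed, method,
                                          conditionMessage(cell)))
          next
        }
        enh <- rbind(enh, data.frame(
          shape = shape, seed = rep_seed, method = method,
          contrast = config$contrast_levels,
          label = names(truth_maps),
          mean_enhancement = cell$means,
          true_enhancement = truth_delta,
          fitted = if (is.null(cell$fit)) NA_real_ else cell$fit$fitted,
          deviation = if (is.null(cell$fit)) NA_real_
                      else cell$fit$deviations))
        lin <- rbind(lin, data.frame(
          shape = shape, seed = rep_seed, method = method,
          slope = if (is.null(cell$fit)) NA_real_ else cell$fit$slope,
          intercept = if (is.null(cell$fit)) NA_real_ else cell$fit$intercept,
          max_deviation = if (is.null(cell$fit)) NA_real_
                          else max(cell$fit$deviations),
          r_squared = if (is.null(cell$fit)) NA_real_ else cell$fit$r_squared))
        maps[[sprintf("%s_seed%d_m%d", shape, rep_seed, method)]] <-
          list(recons = cell$recons, dce = cell$dce, roi = cell$roi)
      }
    }
  }
  if (is.null(enh)) stopf("all study cells failed:\n%s",
                          paste(failures, collapse = "\n"))
  out <- list(enhancement = enh, linearity = lin, failures = failures,
              config = config, maps = maps)
  if (!is.null(config$out_dir)) write_study_outputs(out, config)
  out
}

#' Run the ICG dynamic contrast-enhanced study
#'
#' Generates the 32-frame ICG series on the data-generation mesh,
#' reconstructs every frame with the configured methods, forms enhancement
#' maps against the pre-injection baseline reconstruction and extracts raw
#' and normalised kinetics curves.
#'
#' @param config an [experiment_config()].
#' @return list with `curves` (long data frame: method, frame, time, value,
#'   normalized), `truth` (generator curve), `kinetics` (per-method
#'   `kinetics_curve` objects), `peak_maps`, `config`.
#' @export
run_dce_study <- function(config = experiment_config()) {
  geo <- phantom_geometry(config, config$dce_shape,
                          target_edge = config$dce_edge)
  cal <- calibration_pair(config, target_edge = config$dce_edge)
  series <- make_icg_series(geo$spec, config$profile, geo$data_mesh,
                            background_fraction = config$background_fraction)
  times <- attr(series, "times")
  truth <- attr(series, "truth_delta")
  frames <- lapply(seq_along(series), function(k) {
    nm <- config$noise
    if (!is.null(nm)) nm$seed <- derive_seed(config$seed, 99L, 1L, k)
    simulate_measurements(series[[k]], geo$data_layout, noise = nm,
                          coupling = config$coupling, cfg = config$cfg,
                          frame_time = times[k])
  })
  calibrated <- lapply(frames, calibrate, homo_measured = cal$homo_measured,
                       homo_forward = cal$homo_forward)
  hom <- fit_homogeneous(calibrated[[1]], geo$recon_mesh, geo$recon_layout,
                         config$cfg)
  curves <- NULL; kin <- list(); peak_maps <- list()
  for (method in config$dce_methods) {
    ctrl <- config$control; ctrl$homog <- hom
    recons <- lapply(calibrated, reconstruct, mesh = geo$recon_mesh,
                     layout = geo$recon_layout, method_id = method,
                     cfg = config$cfg, control = ctrl)
    dce <- lapply(seq_along(recons), function(k)
      difference_map(recons[[k]]$map, recons[[1]]$map,
                     label = sprintf("t=%gs", times[k])))
    peak_k <- which.max(vapply(dce, function(m) max(m$values), numeric(1)))
    roi <- if (method == 4) roi_from_prior(geo$recon_mesh, 1)
           else roi_fwhm(dce[[peak_k]])
    kc <- kinetics_curve(dce, roi, times)
    kin[[as.character(method)]] <- kc
    peak_maps[[as.character(method)]] <- dce[[peak_k]]
    curves <- rbind(curves, data.frame(
      method = method, frame = seq_along(times), time = times,
      value = kc$values,
      normalized = if (kc$normalization_failed) NA_real_ else kc$normalized))
  }
  out <- list(curves = curves,
              truth = data.frame(frame = seq_along(times), time = times,
                                 delta_mua = truth,
                                 normalized = if (max(truth) > 0)
                                   truth / max(truth) else NA_real_),
              kinetics = kin, peak_maps = peak_maps, config = config,
              inclusion_nodes = attr(series, "inclusion_nodes"))
  if (!is.null(config$out_dir)) write_dce_outputs(out, config)
  out
}

write_study_outputs <- function(results, config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(results$enhancement,
            file.path(config$out_dir, "enhancement.csv"), row.names = FALSE)
  write.csv(results$linearity,
            file.path(config$out_dir, "linearity.csv"), row.names = FALSE)
  write_config_json(config, file.path(config$out_dir, "config.json"))
  if (length(results$failures))
    writeLines(results$failures, file.path(config$out_dir, "failures.log"))
  for (nm in names(results$maps)) {
    cellmap <- results$maps[[nm]]
    for (ci in seq_along(cellmap$recons)) {
      write_map_csv(cellmap$recons[[ci]]$map,
                    file.path(config$out_dir,
                              sprintf("map_%s_c%d.csv", nm, ci)))
      write_map_csv(cellmap$dce[[ci]],
                    file.path(config$out_dir,
                              sprintf("dce_%s_c%d.csv", nm, ci)))
      if (isTRUE(config$render)) {
        plot_map(cellmap$dce[[ci]],
                 file.path(config$out_dir, sprintf("dce_%s_c%d.png", nm, ci)))
      }
    }
  }
  invisible(config$out_dir)
}

write_dce_outputs <- function(results, config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(results$curves, file.path(config$out_dir, "kinetics.csv"),
            row.names = FALSE)
  write.csv(results$truth, file.path(config$out_dir, "kinetics_truth.csv"),
            row.names = FALSE)
  write_config_json(config, file.path(config$out_dir, "config.json"))
  for (m in names(results$peak_maps)) {
    write_map_csv(results$peak_maps[[m]],
                  file.path(config$out_dir, sprintf("dce_peak_m%s.csv", m)))
    if (isTRUE(config$render))
      plot_map(results$peak_maps[[m]],
               file.path(config$out_dir, sprintf("dce_peak_m%s.png", m)))
  }
  invisible(config$out_dir)
}

## Serialise a config (dropping non-scalar closures/objects to summaries).
write_config_json <- function(config, path) {
  ser <- lapply(unclass(config), function(x) {
    if (inherits(x, "forward_config")) unclass(x)
    else if (inherits(x, "kinetic_profile")) unclass(x)
    else if (inherits(x, "noise_model")) unclass(x)
    else if (inherits(x, "coupling_factors")) unclass(x)
    else x
  })
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Load study result tables back from an output directory
#'
#' Reads the CSV tables and configuration written by [run_phantom_study()]
#' / [run_dce_study()], so reports can be regenerated without recomputing.
#'
#' @param dir study output directory.
#' @return list with any of `enhancement`, `linearity`, `curves`, `truth`,
#'   `failures` and the deserialised `config`.
#' @export
load_study_results <- function(dir) {
  out <- list()
  rd <- function(f) {
    p <- file.path(dir, f)
    if (file.exists(p)) read.csv(p) else NULL
  }
  out$enhancement <- rd("enhancement.csv")
  out$linearity <- rd("linearity.csv")
  out$curves <- rd("kinetics.csv")
  out$truth <- rd("kinetics_truth.csv")
  flog <- file.path(dir, "failures.log")
  out$failures <- if (file.exists(flog)) readLines(flog) else character(0)
  cfgp <- file.path(dir, "config.json")
  if (file.exists(cfgp)) out$config <- jsonlite::fromJSON(cfgp)
  out
}

#' Write a markdown summary report of study results
#'
#' Summarises the linearity table (per-method maximum deviation from the
#' linear fit) and, when present, the kinetics recovery, together with the
#' configuration hash and seeds, so a run can be audited from its outputs
#' alone.
#'
#' @param results output of [run_phantom_study()] and/or [run_dce_study()];
#'   a list with any of `enhancement`, `linearity`, `curves`, `truth`,
#'   `config`.
#' @param path output markdown file.
#' @return `path` invisibly.
#' @export
write_report <- function(results, path) {
  has_lin <- !is.null(results$linearity) && nrow(results$linearity) > 0
  has_cur <- !is.null(results$curves) && nrow(results$curves) > 0
  if (!has_lin && !has_cur) stopf("no completed results to report")
  cfg_file <- tempfile(fileext = ".json")
  write_config_json(results$config, cfg_file)
  cfg_hash <- unname(tools::md5sum(cfg_file))
  unlink(cfg_file)
  lines <- c("# DCE-DOT study report", "",
             sprintf("- config md5: `%s`", cfg_hash),
             sprintf("- master seed: %s", results$config$seed),
             sprintf("- replicate seeds: %s",
                     paste(results$config$seeds, collapse = ", ")), "")
  if (has_lin) {
    lines <- c(lines, "## Enhancement linearity", "",
               "| method | mean max deviation | mean R^2 |",
               "|---|---|---|")
    for (m in sort(unique(results$linearity$method))) {
      sub <- results$linearity[results$linearity$method == m, ]
      lines <- c(lines, sprintf("| %d | %.4f | %.4f |", m,
                                mean(sub$max_deviation), mean(sub$r_squared)))
    }
    lines <- c(lines, "")
  }
  if (has_cur) {
    lines <- c(lines, "## ICG kinetics recovery", "",
               "| method | peak delta-mua | peak frame | max norm. error vs truth |",
               "|---|---|---|---|")
    tn <- results$truth$normalized
    for (m in sort(unique(results$curves$method))) {
      sub <- results$curves[results$curves$method == m, ]
      err <- max(abs(sub$normalized - tn))
      lines <- c(lines, sprintf("| %d | %.4g | %d | %.3f |", m,
                                max(sub$value), sub$frame[which.max(sub$value)],
                                err))
    }
    lines <- c(lines, "")
  }
  if (length(results$failures))
    lines <- c(lines, "## Failures", "", paste0("- ", results$failures), "")
  writeLines(lines, path)
  invisible(path)
}
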