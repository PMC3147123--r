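#!/usr/bin/env Rscript
## ICG uptake study: 32 measurement frames at 16 s resolution with a bolus
## injected during frame 7.  Every frame is reconstructed with the
## amplitude-only method (2) and the structural-prior method (4); the raw
## and max-normalised enhancement kinetics in the inclusion ROI are written
## together with the generator's ground-truth curve.
##
##   Rscript analysis/02_icg_study.R [--seed 1] [--out results/icg_study]

suppressMessages({library(optparse); library(dcedot)})
opt <- parse_args(OptionParser(option_list = list(
  make_option("--seed", type = "integer", default = 1L),
  make_option("--out", type = "character", default = "results/icg_study")
)))

config <- experiment_config(
  dce_shape = "circle", dce_edge = 2.1, dce_methods = c(2, 4),
  noise = noise_model(amplitude_cv = 0.01, phase_sd = 0.1 * pi / 180),
  seed = opt$seed, out_dir = opt$out)

t0 <- Sys.time()
res <- run_dce_study(config)
message(sprintf("reconstructed %d frames x %d methods in %.1f min",
                max(res$curves$frame), length(unique(res$curves$method)),
                as.numeric(Sys.time() - t0, units = "mins")))

tn <- res$truth$normalized
for (m in names(res$kinetics)) {
  kc <- res$kinetics[[m]]
  message(sprintf(
    "method %s: peak delta-mua %.4g mm^-1 at frame %d; max |normalized - truth| = %.3f",
    m, max(kc$values), which.max(kc$values),
    max(abs(kc$normalized - tn))))
}
message("curves written under ", opt$out)
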