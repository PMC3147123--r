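#!/usr/bin/env Rscript
## Contrast-series method comparison on the eight arbitrarily shaped
## phantoms.
##
## For every shape, the B-series (object-to-background contrast 1, 2, 4, 6,
## 8; background mua 0.01 mm^-1, musp 0.6 mm^-1; 10 mm inclusion) is
## simulated with 1 % amplitude noise on a mesh ~1.5x finer than the
## reconstruction mesh, calibrated against the homogeneous phantom chain,
## and reconstructed with all four analysis methods.  Outputs: per-cell
## reconstructions and enhancement maps (CSV), the enhancement-vs-contrast
## table and the per-method linearity summary.
##
##   Rscript analysis/01_phantom_study.R [--seed 1] [--out results/phantom_study]

suppressMessages({library(optparse); library(dcedot)})
opt <- parse_args(OptionParser(option_list = list(
  make_option("--seed", type = "integer", default = 1L),
  make_option("--out", type = "character", default = "results/phantom_study"),
  make_option("--shapes", type = "character",
              default = paste(shape_ids(), collapse = ",")),
  make_option("--n_seeds", type = "integer", default = 1L)
)))

config <- experiment_config(
  shapes = strsplit(opt$shapes, ",")[[1]],
  seeds = seq_len(opt$n_seeds),
  noise = noise_model(amplitude_cv = 0.01, phase_sd = 0.1 * pi / 180),
  methods = 1:4, recon_edge = 3, data_refine = 1.5,
  seed = opt$seed, out_dir = opt$out)

t0 <- Sys.time()
res <- run_phantom_study(config)
message(sprintf("completed %d cells in %.1f min (%d failures)",
                nrow(res$linearity), as.numeric(Sys.time() - t0, units = "mins"),
                length(res$failures)))

## headline: per-method maximum deviation from the linear fit (Fig.-5 metric)
agg <- aggregate(max_deviation ~ method, res$linearity, mean)
for (i in seq_len(nrow(agg)))
  message(sprintf("method %d: mean max |data - fit| / max(data) = %.4f",
                  agg$method[i], agg$max_deviation[i]))
message("the structural-prior method (4) should show the smallest deviation")
message("tables written under ", opt$out)
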