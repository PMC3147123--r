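#!/usr/bin/env Rscript
## Regenerates the markdown summary report from the saved study tables
## (no recomputation).
##
##   Rscript analysis/03_report.R [--phantom results/phantom_study]
##                                [--icg results/icg_study]
##                                [--out results/report.md]

suppressMessages({library(optparse); library(dcedot)})
opt <- parse_args(OptionParser(option_list = list(
  make_option("--phantom", type = "character", default = "results/phantom_study"),
  make_option("--icg", type = "character", default = "results/icg_study"),
  make_option("--out", type = "character", default = "results/report.md")
)))

res <- list()
if (dir.exists(opt$phantom)) res <- load_study_results(opt$phantom)
if (dir.exists(opt$icg)) {
  icg <- load_study_results(opt$icg)
  res$curves <- icg$curves
  res$truth <- icg$truth
  if (is.null(res$config)) res$config <- icg$config
}
write_report(res, opt$out)
message("report written to ", opt$out)
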