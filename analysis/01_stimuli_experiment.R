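#!/usr/bin/env Rscript
# Stimuli-comparison experiment: solve mid-flexion, mid-extension and rigid
# paralysis on the control joint section, summarise the five stimulus fields
# (Von Mises, max/min principal stress, pore pressure, fluid velocity) over
# the eight anatomical probe regions, and write the regime comparison.
#
# Usage: Rscript analysis/01_stimuli_experiment.R [--seed N] [--out DIR]

library(jointmorph)

args <- commandArgs(trailingOnly = TRUE)
get_opt <- function(flag, default) {
  i <- which(args == flag)
  if (length(i) == 1 && i < length(args)) args[i + 1] else default
}
seed <- as.integer(get_opt("--seed", "1"))
out <- get_opt("--out", "results/stimuli")

cfg <- default_config(seed = seed)
dir.create(out, recursive = TRUE, showWarnings = FALSE)
write_config(cfg, file.path(out, "config.yaml"))

t0 <- Sys.time()
res <- run_stimuli_experiment(cfg, out_dir = out, write_vtk_fields = TRUE)
cat("stimuli experiment finished in",
    format(round(difftime(Sys.time(), t0, units = "secs"), 1)), "\n")
print(res$mesh)
print(res$report)
cat("outputs:\n"); writeLines(paste(" ", res$outputs))
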