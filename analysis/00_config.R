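# Shared configuration for the analysis scripts. Each numbered script can
# be run standalone from the repository root:
#   Rscript analysis/01_simulate.R
# The simulation seed makes every script deterministic; scripts that need
# the generated study re-derive it from this config.

library(sdrmap)

cfg <- sim_config(seed = 1L)

res_dir <- "results"
sim_dir <- file.path(res_dir, "simulated")
dir.create(sim_dir, showWarnings = FALSE, recursive = TRUE)

study <- simulate_pedigree_genotypes(cfg)
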