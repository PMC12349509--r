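#!/usr/bin/env Rscript
# Generate the default synthetic conserved-germplasm collection (190 selfing
# accessions, 588 potential deleterious sites plus decoy SNPs) and write its
# input files. The VCF and other regenerable inputs go under scratch/; every
# later script reads from there.

library(germburden)

cfg <- sim_config(seed = 20260101)
sim <- generate_dataset(cfg)
dir <- "scratch/simdata"
write_sim_output(sim, dir, fodder = 5)

cat("simulated", length(sim$vs$samples), "accessions x",
    nrow(sim$vs$sites), "SNPs (", sim$truth$L, "deleterious )\n")
cat("covariates: acquisition age", paste(range(sim$metadata$y_acq),
                                         collapse = "-"),
    "years; regeneration cycles", paste(range(sim$metadata$r_cycles),
                                        collapse = "-"),
    "; years since last regeneration",
    paste(range(sim$metadata$y_last), collapse = "-"), "\n")
cat("true burden means: total", round(mean(sim$truth$b_tot), 4), "\n")
cat("inputs written to", dir, "(20 fodder records appended for the filter)\n")
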