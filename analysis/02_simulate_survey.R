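#!/usr/bin/env Rscript

## Generates one synthetic 24-lake survey under the default study
## conditions (9 never-stocked and 15 stocked demes, area-scaled drift,
## purifying selection on the deleterious SNP class, stocking as mass- and
## area-scaled admixture pulses) and writes it as VCF + CSV/TSV under
## results/synthetic_survey/.

suppressMessages(library(stockload))

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args)) as.integer(args[[1]]) else 1L

cfg <- simulation_config(seed = seed)
ds <- simulate_dataset(cfg)
write_dataset(ds, "results/synthetic_survey")

cat(sprintf("simulated %d individuals x %d SNPs across %d lakes (seed %d)\n",
            nrow(ds$genotypes$dosage), ncol(ds$genotypes$dosage),
            nrow(ds$lakes), seed))
cat(sprintf("classes: %s\n",
            paste(names(table(ds$manifest$classes)),
                  table(ds$manifest$classes), collapse = ", ")))
cat(sprintf("stocking pulses: %d (into %d lakes from %d sources)\n",
            nrow(ds$schedule), length(unique(ds$schedule$sink)),
            length(unique(ds$schedule$source))))
cat("wrote results/synthetic_survey/\n")
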