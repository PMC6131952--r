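#!/usr/bin/env Rscript
# Generate the synthetic monitoring study that drives the whole analysis:
# 19 sequencing runs of mock-community positive controls, repeat stool
# samples from three specimens, negative controls, and a sequential
# dilution series with qPCR on run 18. Writes the study to results/study/.

suppressPackageStartupMessages(library(ampvar))

seed <- 1
study <- simulate_study(seed = seed)
write_synthetic_study(study, "results/study")

md <- study$metadata
cat("Simulated study (seed", seed, "):\n")
print(table(md$sample_type))
cat(sprintf("  dilution libraries on run18: %d (%d levels x %d replicates)\n",
            sum(!is.na(md$dilution_factor)),
            length(unique(na.omit(md$dilution_factor))),
            sum(md$dilution_factor == 1, na.rm = TRUE)))
cat(sprintf("  feature table: %d SVs x %d samples, %s reads\n",
            nrow(study$counts$counts), ncol(study$counts$counts),
            format(sum(study$counts$counts), big.mark = ",")))
cat("Wrote counts.tsv, metadata.tsv, qpcr.tsv, standards.tsv, truth.json",
    "to results/study/\n")
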