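#!/usr/bin/env Rscript
# Quality control: contaminant scoring against the negative controls,
# removal at score > 0.1, automatic read-depth threshold selection (at
# most 2 negatives may survive), sample filtering and rarefaction.
# Reads results/study/, writes results/qc/.

suppressPackageStartupMessages(library(ampvar))

table <- read_feature_table("results/study/counts.tsv")
metadata <- read_metadata("results/study/metadata.tsv")

qc <- qc_pipeline(table, metadata, threshold = 0.1,
                  max_negatives_retained = 2, rarefy_seed = 1)

dir.create("results/qc", showWarnings = FALSE, recursive = TRUE)
write.table(qc$scores, "results/qc/contaminant_scores.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write_feature_table(qc$table, "results/qc/counts_filtered.tsv")
write_metadata(qc$metadata, "results/qc/metadata_filtered.tsv")
write_feature_table(qc$rarefied, "results/qc/counts_rarefied.tsv")
write.table(qc$report$depth_report, "results/qc/depth_report.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

st <- qc$report$stages
cat(sprintf("Contaminant filter (score > 0.1): %d -> %d SVs (%d removed)\n",
            st$input$n_sv, st$contaminant_filtered$n_sv,
            st$input$n_sv - st$contaminant_filtered$n_sv))
cat(sprintf("Depth threshold selected: %d reads\n", qc$depth_threshold))
print(qc$report$depth_report)
cat(sprintf("Samples retained: %d of %d\n",
            st$depth_filtered$n_samples, st$input$n_samples))
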