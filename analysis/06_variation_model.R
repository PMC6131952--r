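#!/usr/bin/env Rscript
# Predicting variation from biomass and abundance: assemble the per-taxon,
# per-dilution-level CV dataset and fit
# log10(CV) ~ log10(copies/uL) + log10(mean relative abundance),
# then tabulate predicted CVs over a biomass x abundance grid.
# Reads results/qc/ and results/study/, writes results/model/.

suppressPackageStartupMessages(library(ampvar))

table <- read_feature_table("results/qc/counts_filtered.tsv")
metadata <- read_metadata("results/qc/metadata_filtered.tsv")
relabund <- relative_abundance(table)
qpcr <- read_qpcr("results/study/qpcr.tsv")

ds <- build_cv_dataset(relabund, metadata, qpcr, taxon_rank = "genus")
cat(sprintf("CV dataset: %d taxon x dilution-level rows (%d genera, %d levels)\n",
            nrow(ds), length(unique(ds$taxon)),
            length(unique(ds$dilution_factor))))

dir.create("results/model", showWarnings = FALSE, recursive = TRUE)
write.table(ds, "results/model/cv_dataset.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

rho_c <- cor(log10(ds$cv), log10(ds$copies_per_ul), method = "spearman")
rho_m <- cor(log10(ds$cv), log10(ds$mean_ra), method = "spearman")
cat(sprintf("Spearman rho of CV with copies/uL: %.2f; with mean RA: %.2f\n",
            rho_c, rho_m))

model <- fit_variation_model(ds)
print(model)
co <- model$coefficients
co$term <- rownames(co)
write.table(co[, c("term", "estimate", "std_error", "t_value", "p_value")],
            "results/model/model_summary.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

grid <- prediction_grid(model)
write.table(round(grid, 2), "results/model/prediction_grid.tsv",
            sep = "\t", quote = FALSE, col.names = NA)
cat("Predicted CV (%) for copies/uL (rows) x mean RA % (columns):\n")
print(round(grid, 2))
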