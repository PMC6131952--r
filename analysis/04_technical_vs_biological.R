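#!/usr/bin/env Rscript
# Can biological variation be distinguished from technical variation?
# Bray-Curtis distances and PCoA over QC-filtered mock + stool libraries,
# PERMANOVA by sample type and sequencing run, and stratification of
# stool distances into intra-run / inter-run / between-specimen sets.
# Reads results/qc/, writes results/distance/.

suppressPackageStartupMessages(library(ampvar))

table <- read_feature_table("results/qc/counts_filtered.tsv")
metadata <- read_metadata("results/qc/metadata_filtered.tsv")
relabund <- relative_abundance(table)

core <- metadata$sample_type != "negative" &
  (is.na(metadata$dilution_factor) | metadata$dilution_factor == 1)
rel <- subset_table(relabund, samples = metadata$sample_id[core])
md <- metadata[core, , drop = FALSE]
cat(sprintf("QC-filtered undiluted libraries: %d (%d mock, %d stool)\n",
            nrow(md), sum(md$sample_type == "mock"),
            sum(md$sample_type == "stool")))

dir.create("results/distance", showWarnings = FALSE, recursive = TRUE)
dm <- pairwise_distances(rel, "bray_curtis")
write.table(dm, "results/distance/bray_curtis.tsv", sep = "\t",
            quote = FALSE, col.names = NA)

ord <- pcoa(dm, 2)
coords <- data.frame(sample_id = rownames(ord$coordinates),
                     ord$coordinates,
                     sample_type = md$sample_type, run_id = md$run_id)
write.table(coords, "results/distance/pcoa.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat(sprintf("PCoA axes 1-2 explain %.1f%% and %.1f%% of variation\n",
            100 * ord$proportion_explained[1],
            100 * ord$proportion_explained[2]))

set.seed(1)
perm <- permanova(dm, md, c("sample_type", "run_id"), 999)
for (f in names(perm))
  cat(sprintf("PERMANOVA %s: R2 = %.3f, pseudo-F = %.1f, p = %.3g\n",
              f, perm[[f]]$r_squared, perm[[f]]$pseudo_f,
              perm[[f]]$p_value))

stool <- md$sample_type == "stool"
dg <- distance_groups(
  pairwise_distances(subset_table(rel, samples = md$sample_id[stool]),
                     "bray_curtis"),
  md[stool, , drop = FALSE])
write.table(dg$summary, "results/distance/distance_groups.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("Stool pairwise Bray-Curtis distances:\n")
print(dg$summary)
wt <- wilcox.test(dg$sets$biological, dg$sets$inter_run)
cat(sprintf("Biological vs inter-run rank-sum p = %.3g\n", wt$p.value))
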