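#!/usr/bin/env Rscript
# Intra- and inter-assay variability of the undiluted mock controls:
# per-genus CV within each run and pooled across runs, one-way ICC by
# run, Levey-Jennings flags, and the CV-abundance association.
# Reads results/qc/, writes results/variability/.

suppressPackageStartupMessages(library(ampvar))

table <- read_feature_table("results/qc/counts_filtered.tsv")
metadata <- read_metadata("results/qc/metadata_filtered.tsv")
relabund <- relative_abundance(table)

mock <- metadata$sample_type == "mock" &
  (is.na(metadata$dilution_factor) | metadata$dilution_factor == 1)
rel <- subset_table(relabund, samples = metadata$sample_id[mock])
md <- metadata[mock, , drop = FALSE]
cat(sprintf("Undiluted mock libraries: %d across %d runs\n",
            nrow(md), length(unique(md$run_id))))

dir.create("results/variability", showWarnings = FALSE, recursive = TRUE)
for (rk in c("family", "genus")) {
  intra <- suppressWarnings(cv_table(rel, md, "run", rk))
  inter <- cv_table(rel, md, "none", rk)
  icc <- icc_oneway(rel, md, "run_id", rk)
  write.table(intra, sprintf("results/variability/cv_intra_%s.tsv", rk),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(inter, sprintf("results/variability/cv_inter_%s.tsv", rk),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(icc$per_taxon, sprintf("results/variability/icc_%s.tsv", rk),
              sep = "\t", quote = FALSE, row.names = FALSE)

  mi <- mean_intra_cv(intra)
  cmp <- merge(mi, inter[, c("taxon", "cv", "mean")], by = "taxon")
  big <- cmp[cmp$mean > 0.01 & !is.na(cmp$cv), ]
  assoc <- cv_abundance_association(inter)
  cat(sprintf(
    "[%s] taxa > 1%%: mean intra-assay CV %.1f-%.1f%%, inter-assay CV %.1f-%.1f%%\n",
    rk, min(big$mean_intra_cv), max(big$mean_intra_cv), min(big$cv),
    max(big$cv)))
  cat(sprintf("[%s] inter > mean intra for %.0f%% of taxa > 1%%; mean ICC = %.3f\n",
              rk, 100 * mean(big$cv > big$mean_intra_cv), icc$mean_icc))
  cat(sprintf("[%s] CV vs abundance: Spearman rho = %.2f (p = %.2g)\n",
              rk, assoc$rho, assoc$p))
}

lj <- levey_jennings(rel, md, "genus", k_sd = 2)
write.table(lj, "results/variability/levey_jennings_genus.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("Levey-Jennings: %d of %d taxon-sample points beyond 2 SD\n",
            sum(lj$flagged), nrow(lj)))
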