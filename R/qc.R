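#' Contaminant scores from negative controls
#'
#' For each SV i, the contaminant score is the fraction of its total reads
#' that fall in negative-control samples:
#' `S_i = sum_j c_ij / sum(c_i)` with j ranging over negative controls.
#' The score is 0 for SVs never seen in a negative control and 1 for SVs
#' seen only there; intermediate values measure how likely the SV is to be
#' reagent-derived.
#'
#' @param table a [feature_table()].
#' @param metadata sample metadata (see [read_metadata()]).
#' @return data.frame per SV: `sv_id`, `negative_count`, `total_count`,
#'   `score`, `zero_total` (flag for SVs with no reads at all, scored 0).
#' @export
contaminant_scores <- function(table, metadata) {
  metadata <- match_metadata(table, metadata)
  neg <- metadata$sample_type == "negative"
  if (!any(neg))
    warning("no negative-control samples: all contaminant scores are 0")
  total <- rowSums(table$counts)
  negct <- rowSums(table$counts[, neg, drop = FALSE])
  score <- ifelse(total > 0, negct / total, 0)
  data.frame(sv_id = sv_ids(table), negative_count = negct,
             total_count = total, score = score, zero_total = total == 0,
             row.names = NULL)
}

#' Remove contaminant SVs by score threshold
#'
#' Removes SVs whose contaminant score strictly exceeds `threshold`
#' ("exceeded" read literally: a score exactly at the threshold is kept).
#' Zero-total SVs are dropped as bookkeeping rows. Samples are untouched.
#'
#' @param table a [feature_table()].
#' @param scores output of [contaminant_scores()].
#' @param threshold score cutoff in `[0, 1]` (default 0.1).
#' @return the filtered `feature_table`.
#' @export
remove_contaminants <- function(table, scores, threshold = 0.1) {
  stopifnot(threshold >= 0, threshold <= 1)
  keep <- scores$sv_id[scores$score <= threshold & !scores$zero_total]
  subset_table(table, svs = intersect(sv_ids(table), keep))
}

#' Select a read-depth threshold that excludes negative controls
#'
#' Operationalizes choosing a depth cutoff "above which only a handful of
#' negative controls remain": returns the smallest per-sample total among
#' non-negative samples such that at most `max_negatives_retained` negative
#' controls reach it. A manual override short-circuits the rule.
#'
#' @param depths named vector of post-filter per-sample read totals.
#' @param metadata sample metadata covering those samples.
#' @param max_negatives_retained maximum acceptable surviving negatives
#'   (default 2).
#' @param manual_override if given, returned as-is.
#' @return integer depth threshold.
#' @export
select_depth_threshold <- function(depths, metadata,
                                   max_negatives_retained = 2,
                                   manual_override = NULL) {
  if (!is.null(manual_override)) return(as.integer(manual_override))
  metadata <- metadata[match(names(depths), metadata$sample_id), ,
                       drop = FALSE]
  neg <- metadata$sample_type == "negative"
  if (all(neg)) stop("no non-negative samples")
  cand <- sort(unique(depths[!neg]))
  negd <- depths[neg]
  for (d in cand) {
    if (sum(negd >= d) <= max_negatives_retained) return(as.integer(d))
  }
  stop(sprintf(
    "no sample depth satisfies the constraint; minimum achievable negative count is %d",
    sum(negd >= max(cand))))
}

#' Filter samples by total read depth
#'
#' @param table a [feature_table()].
#' @param metadata sample metadata.
#' @param threshold minimum total reads per sample (>= 1).
#' @return list with the filtered `table` and `metadata`, and a `report`
#'   data.frame of retained/dropped counts per sample type.
#' @export
filter_samples_by_depth <- function(table, metadata, threshold) {
  stopifnot(threshold >= 1)
  metadata <- match_metadata(table, metadata)
  totals <- colSums(table$counts)
  keep <- totals >= threshold
  if (!any(keep)) stop("depth threshold drops every sample")
  report <- do.call(rbind, lapply(c("mock", "stool", "negative"),
    function(tp) {
      sel <- metadata$sample_type == tp
      data.frame(sample_type = tp, n_input = sum(sel),
                 n_retained = sum(sel & keep), n_dropped = sum(sel & !keep))
    }))
  list(table = subset_table(table, samples = sample_ids(table)[keep]),
       metadata = metadata[keep, , drop = FALSE],
       report = report)
}

#' Rarefy a feature table
#'
#' Subsamples each sample to `depth` reads without replacement
#' (multivariate hypergeometric). Samples below `depth` are dropped (and
#' reported via an attribute), never resampled upward.
#'
#' @param table a [feature_table()].
#' @param depth target depth (>= 1).
#' @param seed optional integer seed for the single rarefaction draw.
#' @return a rarefied `feature_table`; attribute `dropped` lists the ids of
#'   samples below depth.
#' @export
rarefy <- function(table, depth, seed = NULL) {
  stopifnot(depth >= 1)
  if (!is.null(seed)) set.seed(seed)
  totals <- colSums(table$counts)
  keep <- totals >= depth
  m <- t(table$counts[, keep, drop = FALSE])
  # vegan heuristically warns on small integer tables; the draw is valid
  rr <- withCallingHandlers(
    vegan::rrarefy(m, depth),
    warning = function(w) {
      if (grepl("observed counts", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  out <- feature_table(t(rr), table$taxonomy)
  attr(out, "dropped") <- sample_ids(table)[!keep]
  out
}

#' Convert counts to relative abundances
#'
#' @param table a [feature_table()] (or any nonnegative matrix-backed
#'   table).
#' @return a `feature_table`-shaped object whose columns sum to 1.
#' @export
relative_abundance <- function(table) {
  totals <- colSums(table$counts)
  if (any(totals == 0))
    stop("zero-total sample(s): ",
         paste(sample_ids(table)[totals == 0], collapse = ", "))
  out <- table
  out$counts <- sweep(table$counts, 2L, totals, "/")
  out
}

RANK_INDEX <- c(kingdom = 1L, phylum = 2L, class = 3L, order = 4L,
                family = 5L, genus = 6L, species = 7L)

#' Collapse a feature table to a taxonomic rank
#'
#' Sums rows sharing the lineage prefix through the requested rank.
#' `rank = "sv"` is the identity. Rows unassigned at the rank collapse to
#' `"unclassified_<deepest assigned parent>"`, so reads are conserved at
#' every rank.
#'
#' @param table a [feature_table()] (counts or proportions).
#' @param rank one of `"family"`, `"genus"`, `"species"`, `"sv"` (any of
#'   the seven ranks is accepted).
#' @return a collapsed `feature_table`; row names are lineage prefixes
#'   (ranks joined by `;`).
#' @export
collapse_rank <- function(table, rank = c("genus", "family", "species",
                                          "sv", "kingdom", "phylum",
                                          "class", "order")) {
  rank <- match.arg(rank)
  if (rank == "sv") return(table)
  k <- RANK_INDEX[[rank]]
  parts <- split_lineages(table$taxonomy)
  labels <- apply(parts, 1L, function(p) {
    if (all(p[seq_len(k)] != "")) return(paste(p[seq_len(k)],
                                               collapse = ";"))
    assigned <- which(p != "")
    parent <- if (length(assigned)) p[max(assigned[assigned <= k])] else
      "Root"
    paste0("unclassified_", parent)
  })
  agg <- rowsum(table$counts, group = labels)
  new_feature_table(agg, stats::setNames(rownames(agg), rownames(agg)))
}

#' Run the fixed-order quality-control pipeline
#'
#' Score -> remove contaminant SVs -> select depth threshold -> filter
#' samples -> rarefy (for alpha diversity) and relative abundance (for
#' everything else), with per-stage accounting.
#'
#' @param table a [feature_table()].
#' @param metadata sample metadata.
#' @param threshold contaminant-score cutoff (default 0.1).
#' @param max_negatives_retained for [select_depth_threshold()] (default 2).
#' @param depth_override manual depth threshold (skips automatic
#'   selection).
#' @param rarefy_seed seed for the rarefaction draw.
#' @return list: `scores`, `depth_threshold`, `table` and `metadata`
#'   (post-QC counts), `rarefied`, `relabund`, and `report` (per-stage SV /
#'   sample / read accounting).
#' @export
qc_pipeline <- function(table, metadata, threshold = 0.1,
                        max_negatives_retained = 2, depth_override = NULL,
                        rarefy_seed = 1) {
  metadata <- match_metadata(table, metadata)
  stages <- list(input = list(n_sv = nrow(table$counts),
                              n_samples = ncol(table$counts),
                              n_reads = sum(table$counts)))
  scores <- contaminant_scores(table, metadata)
  filt <- remove_contaminants(table, scores, threshold)
  stages$contaminant_filtered <- list(n_sv = nrow(filt$counts),
                                      n_samples = ncol(filt$counts),
                                      n_reads = sum(filt$counts))
  depth <- select_depth_threshold(colSums(filt$counts), metadata,
                                  max_negatives_retained, depth_override)
  ds <- filter_samples_by_depth(filt, metadata, depth)
  stages$depth_filtered <- list(n_sv = nrow(ds$table$counts),
                                n_samples = ncol(ds$table$counts),
                                n_reads = sum(ds$table$counts))
  rar <- rarefy(ds$table, depth, seed = rarefy_seed)
  list(scores = scores, depth_threshold = depth, table = ds$table,
       metadata = ds$metadata, rarefied = rar,
       relabund = relative_abundance(ds$table),
       report = list(stages = stages, depth_report = ds$report,
                     threshold = threshold))
}
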