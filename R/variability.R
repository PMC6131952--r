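#' Per-taxon coefficient-of-variation table
#'
#' Computes, per taxon and stratum, the mean and sample SD (n-1
#' denominator) of relative abundances and the coefficient of variation
#' `CV = 100 * SD / mean` (percent). Stratifying by run gives intra-assay
#' variability (one stratum per sequencing run); `stratify_by = "none"`
#' pools every sample into one stratum, the inter-assay variability of the
#' material. Negative controls are always excluded. Taxa absent from a
#' stratum (mean 0) have `cv = NA` — undefined, not zero.
#'
#' @param relabund relative-abundance [feature_table()] (columns sum to 1).
#' @param metadata sample metadata.
#' @param stratify_by `"run"` or `"none"`.
#' @param taxon_rank rank to collapse to before computing (see
#'   [collapse_rank()]).
#' @return data.frame: `taxon`, `stratum`, `mean`, `sd`, `cv`, `n_samples`,
#'   `n_detected`. Strata with fewer than 2 samples are skipped with a
#'   warning.
#' @export
cv_table <- function(relabund, metadata, stratify_by = c("run", "none"),
                     taxon_rank = "genus") {
  stratify_by <- match.arg(stratify_by)
  metadata <- match_metadata(relabund, metadata)
  keep <- metadata$sample_type != "negative"
  tab <- collapse_rank(subset_table(relabund,
                                    samples = sample_ids(relabund)[keep]),
                       taxon_rank)
  metadata <- metadata[keep, , drop = FALSE]
  strata <- if (stratify_by == "run") split(seq_len(ncol(tab$counts)),
                                            metadata$run_id) else
    list(pooled = seq_len(ncol(tab$counts)))
  rows <- lapply(names(strata), function(s) {
    idx <- strata[[s]]
    if (length(idx) < 2L) {
      warning("stratum '", s, "' has fewer than 2 samples; skipped")
      return(NULL)
    }
    m <- tab$counts[, idx, drop = FALSE]
    mu <- rowMeans(m)
    sd_ <- apply(m, 1L, stats::sd)
    data.frame(taxon = rownames(m), stratum = s, mean = mu, sd = sd_,
               cv = ifelse(mu > 0, 100 * sd_ / mu, NA_real_),
               n_samples = length(idx), n_detected = rowSums(m > 0),
               row.names = NULL)
  })
  do.call(rbind, rows)
}

#' Mean intra-assay CV per taxon
#'
#' The unweighted mean of per-run CVs for each taxon, dropping strata
#' where the taxon was undetected.
#'
#' @param vtable a run-stratified [cv_table()] result.
#' @return data.frame: `taxon`, `mean_intra_cv`, `n_strata`.
#' @export
mean_intra_cv <- function(vtable) {
  sp <- split(vtable$cv, vtable$taxon)
  data.frame(taxon = names(sp),
             mean_intra_cv = vapply(sp, function(x) mean(x, na.rm = TRUE),
                                    numeric(1)),
             n_strata = vapply(sp, function(x) sum(!is.na(x)), numeric(1)),
             row.names = NULL)
}

# one-way random-effects single-measure ICC from ANOVA mean squares,
# tolerating unbalanced (and singleton) groups
icc1 <- function(values, groups) {
  groups <- as.factor(groups)
  n_j <- tabulate(groups)
  J <- nlevels(groups)
  N <- length(values)
  if (J < 2L) stop("need at least 2 groups")
  if (N - J < 1L) stop("need at least 1 within-group degree of freedom")
  grand <- mean(values)
  gm <- tapply(values, groups, mean)
  ssb <- sum(n_j * (gm - grand)^2)
  ssw <- sum((values - gm[groups])^2)
  msb <- ssb / (J - 1)
  msw <- ssw / (N - J)
  n0 <- (N - sum(n_j^2) / N) / (J - 1)
  icc <- if (msb == 0 && msw == 0) NA_real_ else
    (msb - msw) / (msb + (n0 - 1) * msw)
  list(icc = icc, msb = msb, msw = msw, n0 = n0, n_groups = J, n = N)
}

#' One-way intraclass correlation per taxon
#'
#' Reproducibility of relative abundances across groups (typically
#' sequencing runs): the one-way random-effects, single-measure,
#' absolute-agreement ICC computed per taxon from ANOVA mean squares,
#' `ICC = (MSB - MSW) / (MSB + (n0 - 1) MSW)` with the unbalanced-design
#' mean group size `n0 = (N - sum(n_j^2)/N) / (J - 1)`. The per-rank
#' summary is the unweighted mean over taxa with a defined ICC.
#'
#' @param relabund relative-abundance [feature_table()].
#' @param metadata sample metadata.
#' @param group_by metadata column defining groups (default `"run_id"`).
#' @param taxon_rank rank to collapse to.
#' @return list with `per_taxon` (data.frame: taxon, icc, msb, msw, n0)
#'   and `mean_icc`.
#' @export
icc_oneway <- function(relabund, metadata, group_by = "run_id",
                       taxon_rank = "genus") {
  metadata <- match_metadata(relabund, metadata)
  keep <- metadata$sample_type != "negative"
  tab <- collapse_rank(subset_table(relabund,
                                    samples = sample_ids(relabund)[keep]),
                       taxon_rank)
  groups <- metadata[[group_by]][keep]
  if (length(unique(groups)) < 2L) stop("need at least 2 groups")
  per <- do.call(rbind, lapply(rownames(tab$counts), function(tx) {
    r <- icc1(tab$counts[tx, ], groups)
    data.frame(taxon = tx, icc = r$icc, msb = r$msb, msw = r$msw,
               n0 = r$n0, row.names = NULL)
  }))
  list(per_taxon = per, mean_icc = mean(per$icc, na.rm = TRUE))
}

#' Levey-Jennings control flags
#'
#' Clinical-lab style control charting: per taxon, the mean and SD over
#' all (non-negative) samples define control limits; samples further than
#' `k_sd` SDs from the mean are flagged. A taxon with zero SD produces no
#' flags.
#'
#' @param relabund relative-abundance [feature_table()].
#' @param metadata sample metadata (used to order samples by run and to
#'   drop negatives).
#' @param taxon_rank rank to collapse to.
#' @param k_sd control-limit width in SDs (default 2).
#' @return data.frame: `taxon`, `sample_id`, `run_id`, `value`, `zscore`,
#'   `flagged`, in run order.
#' @export
levey_jennings <- function(relabund, metadata, taxon_rank = "genus",
                           k_sd = 2) {
  metadata <- match_metadata(relabund, metadata)
  keep <- metadata$sample_type != "negative"
  if (sum(keep) < 3L) stop("need at least 3 samples")
  ord <- order(metadata$run_id[keep])
  tab <- collapse_rank(subset_table(relabund,
                                    samples = sample_ids(relabund)[keep][ord]),
                       taxon_rank)
  md <- metadata[keep, , drop = FALSE][ord, , drop = FALSE]
  rows <- lapply(rownames(tab$counts), function(tx) {
    x <- tab$counts[tx, ]
    mu <- mean(x); s <- stats::sd(x)
    z <- if (s > 0) (x - mu) / s else rep(0, length(x))
    data.frame(taxon = tx, sample_id = md$sample_id, run_id = md$run_id,
               value = unname(x), zscore = unname(z),
               flagged = s > 0 & abs(x - mu) > k_sd * s,
               row.names = NULL)
  })
  do.call(rbind, rows)
}

#' Shannon diversity per sample
#'
#' `H = -sum(p log p)` over nonzero proportions; computed on rarefied
#' counts so depths are comparable.
#'
#' @param table a [feature_table()] of (rarefied) counts.
#' @param base logarithm base (default natural).
#' @return named numeric vector, one value per sample.
#' @export
shannon <- function(table, base = exp(1)) {
  totals <- colSums(table$counts)
  if (any(totals == 0))
    stop("zero-total sample(s): ",
         paste(sample_ids(table)[totals == 0], collapse = ", "))
  vegan::diversity(t(table$counts), index = "shannon", base = base)
}

#' Association between CV and mean relative abundance
#'
#' Spearman rank correlation (average ranks on ties) between per-taxon
#' mean relative abundance and CV; rarer taxa are expected to be noisier
#' (negative rho).
#'
#' @param vtable a [cv_table()] result (rows with undefined CV are
#'   dropped).
#' @return list: `rho`, `p`, `n`, `tied` (TRUE when CV is constant, in
#'   which case rho is reported as 0 with `p = NA`).
#' @export
cv_abundance_association <- function(vtable) {
  ok <- !is.na(vtable$cv)
  x <- vtable$mean[ok]; y <- vtable$cv[ok]
  if (length(x) < 3L) stop("need at least 3 taxa with defined CV")
  if (stats::sd(y) == 0 || stats::sd(x) == 0)
    return(list(rho = 0, p = NA_real_, n = length(x), tied = TRUE))
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value, n = length(x),
       tied = FALSE)
}
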