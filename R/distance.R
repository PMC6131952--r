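#' Pairwise ecological distances
#'
#' Distances between sample columns of a relative-abundance table:
#' * `bray_curtis`: `sum |x - y| / sum (x + y)` (via \pkg{vegan});
#' * `jaccard`: `1 - |A intersect B| / |A union B|` on presence/absence
#'   (detection = value > 0);
#' * `jensen_shannon`: square root of the Jensen-Shannon divergence with
#'   base-2 logarithms, a metric with range `[0, 1]`.
#'
#' @param relabund relative-abundance [feature_table()] (columns sum to 1;
#'   Jaccard also accepts raw counts).
#' @param metric one of `"bray_curtis"`, `"jaccard"`, `"jensen_shannon"`.
#' @return symmetric distance matrix with sample ids as dimnames and a
#'   `metric` attribute.
#' @export
pairwise_distances <- function(relabund,
                               metric = c("bray_curtis", "jaccard",
                                          "jensen_shannon")) {
  metric <- match.arg(metric)
  x <- t(relabund$counts)
  if (nrow(x) < 2L) stop("need at least 2 samples")
  d <- switch(metric,
    bray_curtis = as.matrix(vegan::vegdist(x, method = "bray")),
    jaccard = as.matrix(vegan::vegdist(x > 0, method = "jaccard",
                                       binary = TRUE)),
    jensen_shannon = js_distance(x))
  dimnames(d) <- list(rownames(x), rownames(x))
  attr(d, "metric") <- metric
  d
}

# sqrt Jensen-Shannon divergence, base-2 logs; rows of x are distributions
js_distance <- function(x) {
  x <- x / rowSums(x)
  n <- nrow(x)
  h <- function(p) { p <- p[p > 0]; -sum(p * log2(p)) }
  hs <- apply(x, 1L, h)
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    m <- (x[i, ] + x[j, ]) / 2
    jsd <- h(m) - (hs[i] + hs[j]) / 2
    d[i, j] <- d[j, i] <- sqrt(max(jsd, 0))
  }
  d
}

#' Principal coordinates analysis
#'
#' Classical metric scaling: Gower double-centering of `-D^2 / 2`,
#' eigendecomposition, coordinates from the positive eigenvalues sorted
#' descending. The proportion of variation explained divides by the sum of
#' positive eigenvalues; negative eigenvalues are reported, not corrected.
#'
#' @param dm distance matrix from [pairwise_distances()].
#' @param n_axes number of axes to return.
#' @return list: `coordinates` (samples x axes), `eigenvalues` (all),
#'   `proportion_explained` (for the returned axes).
#' @export
pcoa <- function(dm, n_axes = 2) {
  n <- nrow(dm)
  res <- stats::cmdscale(stats::as.dist(dm), k = min(n_axes, n - 1L),
                         eig = TRUE)
  eig <- res$eig
  pos <- eig[eig > 1e-12]
  if (!length(pos)) stop("no positive eigenvalues: degenerate distances")
  coords <- as.matrix(res$points)
  k <- ncol(coords)
  colnames(coords) <- paste0("PCo", seq_len(k))
  list(coordinates = coords, eigenvalues = eig,
       proportion_explained = eig[seq_len(k)] / sum(pos))
}

#' Permutational multivariate analysis of variance
#'
#' One-way PERMANOVA on a distance matrix: with squared distances `d^2`,
#' `SS_total = sum_{i<j} d^2 / N` and
#' `SS_within = sum_g sum_{i<j in g} d^2 / n_g`; `R^2 = 1 - SSW/SST` and
#' `pseudo-F = (SSB/(a-1)) / (SSW/(N-a))`. Significance comes from
#' shuffling the group labels; `p = (1 + #{F_perm >= F_obs}) / (1 + P)`,
#' so p is never exactly 0. With `n_permutations = "exhaustive"` all
#' distinct label arrangements other than the observed one are enumerated.
#' Several factors are tested marginally, one PERMANOVA each.
#'
#' @param dm distance matrix.
#' @param metadata sample metadata (rows matched to `dm` by `sample_id`).
#' @param factor metadata column name(s) to test.
#' @param n_permutations number of label permutations (>= 99), or
#'   `"exhaustive"`.
#' @return for a single factor, a list (`factor`, `r_squared`, `pseudo_f`,
#'   `p_value`, `n_permutations`, `degenerate`); for several, a named list
#'   of such lists.
#' @export
permanova <- function(dm, metadata, factor = "sample_type",
                      n_permutations = 999) {
  if (length(factor) > 1L) {
    out <- lapply(factor, function(f) permanova(dm, metadata, f,
                                                n_permutations))
    names(out) <- factor
    return(out)
  }
  md <- metadata[match(rownames(dm), metadata$sample_id), , drop = FALSE]
  labels <- as.character(md[[factor]])
  if (length(unique(labels)) < 2L) stop("factor needs >= 2 groups")
  D2 <- dm^2
  N <- nrow(D2)
  a <- length(unique(labels))
  sst <- sum(D2[upper.tri(D2)]) / N
  ssw_of <- function(lab) {
    s <- 0
    for (g in unique(lab)) {
      idx <- which(lab == g)
      if (length(idx) > 1L)
        s <- s + sum(D2[idx, idx]) / (2 * length(idx))
    }
    s
  }
  ssw <- ssw_of(labels)
  ssb <- sst - ssw
  r2 <- 1 - ssw / sst
  degenerate <- ssw == 0
  f_of <- function(ssw_) if (ssw_ == 0) Inf else
    (sst - ssw_) / (a - 1) / (ssw_ / (N - a))
  f_obs <- f_of(ssw)

  if (identical(n_permutations, "exhaustive")) {
    perms <- multiset_permutations(labels)
    # drop the observed arrangement itself
    obs_key <- paste(labels, collapse = "\r")
    keys <- vapply(perms, paste, character(1), collapse = "\r")
    perms <- perms[keys != obs_key]
    fstats <- vapply(perms, function(lab) f_of(ssw_of(lab)), numeric(1))
    P <- length(perms)
  } else {
    stopifnot(n_permutations >= 99)
    fstats <- vapply(seq_len(n_permutations), function(i)
      f_of(ssw_of(sample(labels))), numeric(1))
    P <- n_permutations
  }
  p <- (1 + sum(fstats >= f_obs)) / (1 + P)
  list(factor = factor, r_squared = r2, pseudo_f = f_obs, p_value = p,
       n_permutations = P, degenerate = degenerate)
}

# all distinct permutations of a label multiset (guarded by a size cap)
multiset_permutations <- function(labels, cap = 20000L) {
  out <- list()
  rec <- function(remaining, acc) {
    if (length(out) > cap) stop("too many arrangements to enumerate")
    if (!length(remaining)) {
      out[[length(out) + 1L]] <<- acc
      return(invisible())
    }
    for (u in unique(remaining)) {
      i <- match(u, remaining)
      rec(remaining[-i], c(acc, u))
    }
  }
  rec(labels, character(0))
  out
}

#' Partition pairwise distances into technical and biological sets
#'
#' For samples with a specimen id, splits all pairwise distances into
#' intra-run/same-specimen (technical, within one run),
#' inter-run/same-specimen (technical, across runs) and
#' different-specimen (biological) sets.
#'
#' @param dm distance matrix.
#' @param metadata sample metadata with `run_id` and `specimen_id`.
#' @return list: `sets` (named list of numeric distance vectors) and
#'   `summary` (data.frame: group, n, mean, median). Empty partitions are
#'   kept with `n = 0`.
#' @export
distance_groups <- function(dm, metadata) {
  md <- metadata[match(rownames(dm), metadata$sample_id), , drop = FALSE]
  has <- !is.na(md$specimen_id)
  idx <- which(has)
  sets <- list(intra_run = numeric(0), inter_run = numeric(0),
               biological = numeric(0))
  if (length(idx) >= 2L) {
    for (ii in seq_along(idx)[-length(idx)]) {
      for (jj in (ii + 1L):length(idx)) {
        i <- idx[ii]; j <- idx[jj]
        g <- if (md$specimen_id[i] != md$specimen_id[j]) "biological"
        else if (md$run_id[i] == md$run_id[j]) "intra_run"
        else "inter_run"
        sets[[g]] <- c(sets[[g]], dm[i, j])
      }
    }
  }
  summary <- do.call(rbind, lapply(names(sets), function(g)
    data.frame(group = g, n = length(sets[[g]]),
               mean = if (length(sets[[g]])) mean(sets[[g]]) else NA_real_,
               median = if (length(sets[[g]])) stats::median(sets[[g]])
               else NA_real_)))
  list(sets = sets, summary = summary)
}
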