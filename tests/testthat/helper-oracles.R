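# Independent brute-force implementations used as oracles. These are kept
# deliberately naive (double loops, textbook formulas) and must never call
# into the package's own code paths.

oracle_contaminant_scores <- function(counts, negative_samples) {
  scores <- numeric(nrow(counts))
  for (i in seq_len(nrow(counts))) {
    neg <- 0; tot <- 0
    for (j in seq_len(ncol(counts))) {
      tot <- tot + counts[i, j]
      if (colnames(counts)[j] %in% negative_samples)
        neg <- neg + counts[i, j]
    }
    scores[i] <- if (tot > 0) neg / tot else 0
  }
  scores
}

oracle_cv <- function(x) {
  n <- length(x)
  m <- sum(x) / n
  s <- sqrt(sum((x - m)^2) / (n - 1))
  100 * s / m
}

oracle_icc1 <- function(values, groups) {
  groups <- as.character(groups)
  gs <- unique(groups)
  J <- length(gs); N <- length(values)
  grand <- mean(values)
  ssb <- 0; ssw <- 0; sumn2 <- 0
  for (g in gs) {
    v <- values[groups == g]
    ssb <- ssb + length(v) * (mean(v) - grand)^2
    ssw <- ssw + sum((v - mean(v))^2)
    sumn2 <- sumn2 + length(v)^2
  }
  msb <- ssb / (J - 1)
  msw <- ssw / (N - J)
  n0 <- (N - sumn2 / N) / (J - 1)
  (msb - msw) / (msb + (n0 - 1) * msw)
}

oracle_bray <- function(x, y) sum(abs(x - y)) / sum(x + y)

oracle_jaccard <- function(x, y) {
  a <- x > 0; b <- y > 0
  1 - sum(a & b) / sum(a | b)
}

oracle_js <- function(x, y) {
  x <- x / sum(x); y <- y / sum(y)
  m <- (x + y) / 2
  kl <- function(p, q) {
    s <- 0
    for (i in seq_along(p)) if (p[i] > 0) s <- s + p[i] * log2(p[i] / q[i])
    s
  }
  sqrt(max(0, kl(x, m) / 2 + kl(y, m) / 2))
}

oracle_permanova_r2 <- function(dm, labels) {
  n <- nrow(dm)
  sst <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) sst <- sst + dm[i, j]^2
  sst <- sst / n
  ssw <- 0
  for (g in unique(labels)) {
    idx <- which(labels == g)
    if (length(idx) < 2) next
    s <- 0
    for (a in seq_along(idx)[-length(idx)])
      for (b in (a + 1):length(idx)) s <- s + dm[idx[a], idx[b]]^2
    ssw <- ssw + s / length(idx)
  }
  1 - ssw / sst
}

oracle_ols <- function(X, y) as.vector(solve(t(X) %*% X, t(X) %*% y))

oracle_spearman <- function(x, y) stats::cor(rank(x), rank(y))

# random feature table with a negative-control block
random_table <- function(n_sv, n_samp, n_neg, lambda = 5) {
  counts <- matrix(stats::rpois(n_sv * n_samp, lambda), n_sv, n_samp,
                   dimnames = list(paste0("sv", seq_len(n_sv)),
                                   paste0("s", seq_len(n_samp))))
  md <- data.frame(
    sample_id = colnames(counts),
    run_id = paste0("run", rep_len(1:3, n_samp)),
    sample_type = c(rep("mock", n_samp - n_neg), rep("negative", n_neg)),
    specimen_id = NA_character_, dilution_factor = NA_real_)
  list(table = feature_table(counts), metadata = md)
}
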