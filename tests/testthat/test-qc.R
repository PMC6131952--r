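test_that("contaminant scores implement the negative-fraction formula", {
  counts <- matrix(c(5, 40, 3, 2), nrow = 1,
                   dimnames = list("sv1", c("a", "b", "n1", "n2")))
  md <- data.frame(sample_id = c("a", "b", "n1", "n2"),
                   run_id = "run1",
                   sample_type = c("mock", "mock", "negative", "negative"))
  sc <- contaminant_scores(feature_table(counts), md)
  expect_equal(sc$score, 5 / 50)  # (3 + 2) / 50

  counts2 <- rbind(only_neg = c(0, 0, 4, 6), never_neg = c(9, 1, 0, 0),
                   empty = c(0, 0, 0, 0))
  colnames(counts2) <- c("a", "b", "n1", "n2")
  sc2 <- contaminant_scores(feature_table(counts2), md)
  expect_equal(sc2$score, c(1, 0, 0))
  expect_equal(sc2$zero_total, c(FALSE, FALSE, TRUE))
})

test_that("contaminant scores equal a brute-force double loop", {
  set.seed(11)
  for (i in 1:10) {
    n_sv <- sample(5:50, 1); n_samp <- sample(4:50, 1)
    n_neg <- sample(1:(n_samp - 2), 1)
    rt <- random_table(n_sv, n_samp, n_neg)
    sc <- contaminant_scores(rt$table, rt$metadata)
    neg_ids <- rt$metadata$sample_id[rt$metadata$sample_type == "negative"]
    expect_equal(sc$score,
                 oracle_contaminant_scores(rt$table$counts, neg_ids),
                 tolerance = 1e-12)
  }
})

test_that("contaminant removal uses a strict threshold and is idempotent", {
  # svA hits the threshold exactly (kept), svB just exceeds it (removed)
  counts <- rbind(svA = c(9, 1), svB = c(89, 11))
  colnames(counts) <- c("s", "n")
  md <- data.frame(sample_id = c("s", "n"), run_id = "r",
                   sample_type = c("mock", "negative"))
  tab <- feature_table(counts)
  sc <- contaminant_scores(tab, md)
  expect_equal(sc$score, c(0.1, 0.11))
  kept <- remove_contaminants(tab, sc, 0.1)
  expect_equal(rownames(kept$counts), "svA")

  expect_equal(rownames(remove_contaminants(tab, sc, 1)$counts),
               c("svA", "svB"))
  expect_equal(nrow(remove_contaminants(tab, sc, 0)$counts), 0L)

  twice <- remove_contaminants(kept, sc, 0.1)
  expect_identical(twice$counts, kept$counts)
})

test_that("depth threshold selection obeys the negatives-retained rule", {
  depths <- c(n1 = 100, n2 = 200, s1 = 150, s2 = 300, s3 = 5000)
  md <- data.frame(sample_id = names(depths), run_id = "r",
                   sample_type = c("negative", "negative", "mock", "mock",
                                   "mock"))
  expect_equal(select_depth_threshold(depths, md, 0), 300L)
  expect_equal(select_depth_threshold(depths, md, 2), 150L)
  expect_equal(select_depth_threshold(depths, md, 0,
                                      manual_override = 10942), 10942L)

  deep <- c(n1 = 9000, s1 = 150)
  md2 <- data.frame(sample_id = names(deep), run_id = "r",
                    sample_type = c("negative", "mock"))
  expect_error(select_depth_threshold(deep, md2, 0),
               "minimum achievable negative count is 1")
})

test_that("depth filtering reports per-type accounting", {
  tt <- tiny_table()
  same <- filter_samples_by_depth(tt$table, tt$metadata, 1)
  expect_identical(same$table$counts, tt$table$counts)
  rep <- same$report
  expect_equal(sum(rep$n_retained) + sum(rep$n_dropped), 4)

  hi <- filter_samples_by_depth(tt$table, tt$metadata, 50)
  expect_equal(hi$report$n_retained[hi$report$sample_type == "negative"], 0)
  expect_false("neg1" %in% colnames(hi$table$counts))
  expect_error(filter_samples_by_depth(tt$table, tt$metadata, 1e6),
               "every sample")
})

test_that("rarefaction subsamples without replacement to the exact depth", {
  counts <- matrix(c(10, 30, 60), ncol = 1,
                   dimnames = list(c("a", "b", "c"), "s1"))
  tab <- feature_table(counts)
  expect_equal(rarefy(tab, 100, seed = 1)$counts, counts)

  r10 <- rarefy(tab, 10, seed = 1)
  expect_equal(sum(r10$counts), 10)
  expect_true(all(r10$counts <= counts))

  set.seed(3)
  means <- rowMeans(replicate(1000, rarefy(tab, 10)$counts[, 1]))
  # hypergeometric mean/variance oracle
  v <- 10 * (c(10, 30, 60) / 100) * (1 - c(10, 30, 60) / 100) * 90 / 99
  expect_true(all(abs(means - c(1, 3, 6)) < 3 * sqrt(v / 1000)))

  # samples below depth are dropped, not upsampled
  two <- feature_table(cbind(counts, s2 = c(2, 2, 1)))
  r <- rarefy(two, 10, seed = 1)
  expect_equal(colnames(r$counts), "s1")
  expect_equal(attr(r, "dropped"), "s2")
})

test_that("relative abundance normalizes columns and flags empty samples", {
  tab <- feature_table(matrix(c(2, 3, 5), ncol = 1,
                              dimnames = list(letters[1:3], "s1")))
  expect_equal(unname(relative_abundance(tab)$counts[, 1]),
               c(0.2, 0.3, 0.5))
  one <- feature_table(matrix(7, dimnames = list("a", "s1")))
  expect_equal(unname(relative_abundance(one)$counts[, 1]), 1)
  scaled <- tab; scaled$counts <- tab$counts * 100
  expect_equal(relative_abundance(scaled)$counts,
               relative_abundance(tab)$counts)
  bad <- feature_table(matrix(c(1, 0), ncol = 2,
                              dimnames = list("a", c("s1", "s2"))))
  expect_error(relative_abundance(bad), "s2")
})

test_that("rank collapsing sums lineage prefixes and conserves reads", {
  tt <- tiny_table()
  gen <- collapse_rank(tt$table, "genus")
  expect_equal(unname(gen$counts["Bacteria;P1;C1;O1;F1;G1", ]),
               unname(colSums(tt$table$counts[c("svA", "svB"), ])))
  expect_identical(collapse_rank(tt$table, "sv"), tt$table)
  for (rk in c("family", "genus", "species"))
    expect_equal(sum(collapse_rank(tt$table, rk)$counts),
                 sum(tt$table$counts))

  # unassigned at the rank collapses under its deepest assigned parent
  part <- feature_table(
    matrix(c(4, 6), ncol = 1, dimnames = list(c("x", "y"), "s1")),
    c(x = "Bacteria;P1;C1;O1;F1;;", y = "Bacteria;P1;C1;O1;F1;G1;G1_s"))
  gn <- collapse_rank(part, "genus")
  expect_true("unclassified_F1" %in% rownames(gn$counts))
  expect_equal(sum(gn$counts), 10)
})

test_that("score filtering removes nearly all contaminant reads from mocks", {
  contam <- contaminant_taxa()$taxon_id
  removed_frac <- vapply(1:20, function(s) {
    st <- simulate_study(design = small_design(), seed = s)
    sc <- contaminant_scores(st$counts, st$metadata)
    filt <- remove_contaminants(st$counts, sc, 0.1)
    md <- st$metadata
    mock <- md$sample_id[md$sample_type == "mock"]
    pre <- st$counts$counts[rownames(st$counts$counts) %in% contam, mock,
                            drop = FALSE]
    post <- filt$counts[rownames(filt$counts) %in% contam, mock,
                        drop = FALSE]
    if (sum(pre) == 0) return(1)
    1 - sum(post) / sum(pre)
  }, numeric(1))
  expect_true(mean(removed_frac) >= 0.95)
})

test_that("the qc pipeline runs the stages in fixed order with accounting", {
  st <- simulate_study(design = small_design(), seed = 7)
  qc <- qc_pipeline(st$counts, st$metadata)
  stages <- qc$report$stages
  expect_true(stages$input$n_sv >= stages$contaminant_filtered$n_sv)
  expect_true(stages$input$n_samples >= stages$depth_filtered$n_samples)
  expect_equal(colSums(qc$rarefied$counts),
               setNames(rep(qc$depth_threshold,
                            ncol(qc$rarefied$counts)),
                        colnames(qc$rarefied$counts)))
  expect_equal(unname(colSums(qc$relabund$counts)),
               rep(1, ncol(qc$relabund$counts)))
})
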