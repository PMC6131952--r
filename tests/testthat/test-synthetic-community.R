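test_that("run composition perturbation preserves simplex structure", {
  spec <- mock_community_spec()
  quiet <- noise_model(run_effect_sd = 0)
  expect_identical(sample_run_composition(spec, quiet), spec$proportions)

  spec4 <- mock_community_spec(
    data.frame(taxon_id = paste0("t", 1:4),
               lineage = rep("Bacteria;;;;;;", 4)))
  set.seed(42)
  p <- sample_run_composition(spec4, noise_model(run_effect_sd = 0.5))
  expect_equal(sum(p), 1, tolerance = 1e-12)
  expect_true(all(p > 0))
})

test_that("run composition mean matches a brute-force resampling estimate", {
  spec4 <- mock_community_spec(
    data.frame(taxon_id = paste0("t", 1:4),
               lineage = rep("Bacteria;;;;;;", 4)),
    proportions = c(0.4, 0.3, 0.2, 0.1))
  nm <- noise_model(run_effect_sd = 0.2)
  n <- 2000
  set.seed(7)
  draws <- replicate(n, sample_run_composition(spec4, nm))
  set.seed(1234)
  oracle <- replicate(n, {
    q <- spec4$proportions * exp(rnorm(4, 0, 0.2))
    q / sum(q)
  })
  se <- sqrt(apply(draws, 1, var) / n + apply(oracle, 1, var) / n)
  expect_true(all(abs(rowMeans(draws) - rowMeans(oracle)) < 3 * se))
})

test_that("contamination mixing follows the constant-load two-source model", {
  nm <- noise_model(contaminant_load = 100)
  p <- c(a = 0.6, b = 0.4)
  pure <- mix_contamination(p, 0, nm)
  expect_equal(unname(pure[names(nm$contaminant_profile)]),
               unname(nm$contaminant_profile))
  expect_equal(sum(pure), 1)
  expect_equal(unname(pure[c("a", "b")]), c(0, 0))

  none <- mix_contamination(p, 100, noise_model(contaminant_load = 0))
  expect_equal(unname(none[c("a", "b")]), c(0.6, 0.4))

  half <- mix_contamination(p, 100, nm)  # w = 100/(100+100) = 0.5
  expect_equal(unname(half[c("a", "b")]), c(0.3, 0.2))
  expect_equal(sum(half), 1)
})

test_that("read counts are multinomial draws conserving depth", {
  expect_equal(unname(draw_counts(c(1, 0), 50)), c(50, 0))
  set.seed(1)
  for (i in 1:20) expect_equal(sum(draw_counts(c(0.2, 0.3, 0.5), 137)), 137)
  expect_error(draw_counts(c(0.5, 0.4), 10), "sum to 1")

  set.seed(2)
  draws <- replicate(2000, draw_counts(c(0.3, 0.7), 100))
  se <- sqrt(100 * c(0.3, 0.7) * c(0.7, 0.3) / 2000)
  expect_true(all(abs(rowMeans(draws) - c(30, 70)) < 3 * se))
})

test_that("dilution series has the expected layout and noise-free limits", {
  des <- default_study_design()
  st <- simulate_dilution_series(design = des, seed = 1)
  md <- st$metadata
  expect_equal(sum(!is.na(md$dilution_factor)), 110)  # 11 levels x 10 reps

  nf <- noise_model(overdilution_bias = 1, qpcr_cv = 0)
  st0 <- simulate_dilution_series(noise = nf, design = des, seed = 2)
  md0 <- st0$metadata[!is.na(st0$metadata$dilution_factor), ]
  qp <- st0$qpcr[match(md0$sample_id, st0$qpcr$sample_id), ]
  spec <- mock_community_spec()
  expect_equal(qp$copies_per_ul,
               spec$stock_copies_per_ul / md0$dilution_factor,
               tolerance = 1e-12)
})

test_that("contaminant reads take over as the series is diluted", {
  contam <- contaminant_taxa()$taxon_id
  frac_at <- function(st, fac) {
    md <- st$metadata
    ids <- md$sample_id[!is.na(md$dilution_factor) &
                          md$dilution_factor == fac]
    m <- st$counts$counts[, ids, drop = FALSE]
    sum(m[rownames(m) %in% contam, ]) / sum(m)
  }
  diffs <- vapply(1:20, function(s) {
    st <- simulate_dilution_series(seed = s)
    frac_at(st, 1000) - frac_at(st, 1)
  }, numeric(1))
  expect_true(all(diffs > 0))
})

test_that("contaminant read share decreases with input biomass", {
  nm <- noise_model()
  set.seed(5)
  grid <- c(0, 10, 100, 1000, 1e5)
  share <- vapply(grid, function(cp) {
    mean(replicate(100, {
      mixed <- mix_contamination(c(a = 0.5, b = 0.5), cp, nm)
      cnt <- draw_counts(mixed, 2000)
      sum(cnt[names(nm$contaminant_profile)]) / sum(cnt)
    }))
  }, numeric(1))
  expect_true(all(diff(share) < 0))
})

test_that("full study reproduces the design layout and is deterministic", {
  st <- simulate_study(seed = 3)
  tt <- table(st$metadata$sample_type)
  expect_equal(as.integer(tt[c("mock", "stool", "negative")]),
               c(218L, 29L, 222L))
  expect_equal(nrow(st$metadata), 469L)
  expect_true(all(st$metadata$sample_id %in% colnames(st$counts$counts)))
  expect_equal(sort(names(st$truth$copies_per_ul)),
               sort(st$metadata$sample_id))

  st2 <- simulate_study(seed = 3)
  expect_identical(st$counts$counts, st2$counts$counts)
  expect_identical(st$qpcr, st2$qpcr)
  st3 <- simulate_study(seed = 4)
  expect_false(identical(st$counts$counts, st3$counts$counts))

  # every latent composition is a valid probability vector
  sums <- colSums(st$truth$composition)
  expect_true(all(abs(sums - 1) < 1e-9))
  expect_true(all(st$truth$composition >= 0))
})

test_that("a design without negatives yields zero contaminant scores", {
  des <- small_design()
  des$runs$n_negative <- 0
  st <- simulate_study(design = des, seed = 1)
  expect_false(any(st$metadata$sample_type == "negative"))
  expect_warning(sc <- contaminant_scores(st$counts, st$metadata),
                 "no negative-control samples")
  expect_true(all(sc$score == 0))
})

test_that("biological variation exceeds inter-run exceeds intra-run distance", {
  for (s in 1:3) {
    st <- simulate_study(design = small_design(), seed = s)
    md <- st$metadata
    stool <- md$sample_type == "stool"
    rel <- relative_abundance(
      subset_table(st$counts, samples = md$sample_id[stool]))
    dg <- distance_groups(pairwise_distances(rel, "bray_curtis"),
                          md[stool, ])
    med <- setNames(dg$summary$median, dg$summary$group)
    expect_gt(med["biological"], med["inter_run"])
    expect_gt(med["inter_run"], med["intra_run"])
  }
})
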