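perfect_standards <- function() {
  copies <- 10^(2:7)
  data.frame(copies_per_reaction = c(0, copies),
             ct = c(NA, 40 - 3.3219 * log10(copies)))
}

test_that("standard curve fitting inverts the perfect-efficiency curve", {
  curve <- fit_standard_curve(perfect_standards())
  expect_equal(curve$slope, -3.3219, tolerance = 1e-10)
  expect_equal(curve$intercept, 40, tolerance = 1e-10)
  expect_equal(curve$r_squared, 1, tolerance = 1e-12)
  expect_equal(curve$efficiency, 1, tolerance = 1e-4)
  expect_false(0 %in% curve$standards_used)

  two <- data.frame(copies_per_reaction = c(100, 1000), ct = c(33, 30))
  expect_error(fit_standard_curve(two), "at least 3")
  rising <- data.frame(copies_per_reaction = 10^(2:4), ct = c(20, 25, 30))
  expect_error(fit_standard_curve(rising), "slope")
})

test_that("noisy standard curves recover the true slope", {
  copies <- rep(10^(2:7), each = 3)
  set.seed(121)
  slopes <- replicate(100, {
    df <- data.frame(copies_per_reaction = copies,
                     ct = 40 - 3.3219 * log10(copies) + rnorm(length(copies),
                                                              0, 0.1))
    fit_standard_curve(df)$slope
  })
  expect_true(all(abs(slopes + 3.3219) < 0.15))
})

test_that("quantification inverts Ct to copies through the curve", {
  curve <- fit_standard_curve(perfect_standards())
  q <- quantify(data.frame(sample_id = "s1", ct = 30.0343), curve)
  expect_equal(q$copies_per_reaction, 1000, tolerance = 1e-4)
  expect_equal(q$copies_per_ul, 200, tolerance = 1e-4)

  at_intercept <- quantify(data.frame(sample_id = "s1", ct = 40), curve)
  expect_equal(at_intercept$copies_per_ul, 0.2, tolerance = 1e-10)

  # round trip on exact copies
  true_cp <- c(5, 320, 1e4, 2.5e6)
  ct <- curve$intercept + curve$slope * log10(true_cp)
  rt <- quantify(data.frame(sample_id = paste0("s", seq_along(ct)),
                            ct = ct), curve)
  expect_equal(rt$copies_per_reaction, true_cp, tolerance = 1e-6)

  # replicate wells average; all-undetermined flags zero copies
  wells <- data.frame(sample_id = c("a", "a", "a", "b", "b"),
                      ct = c(30, 31, NA, NA, NA))
  qa <- quantify(wells, curve)
  expect_equal(qa$mean_ct[qa$sample_id == "a"], 30.5)
  expect_true(qa$undetermined[qa$sample_id == "b"])
  expect_equal(qa$copies_per_ul[qa$sample_id == "b"], 0)
})

test_that("expected copies follow the naive and sequential calibrations", {
  cal <- expected_copies(1e5, c(1, 80), c(1e5, 1100))
  expect_equal(cal$naive_expected[2], 1250)

  cal2 <- expected_copies(1e5, c(1, 10, 20), c(1e5, 9000, 4200))
  expect_equal(cal2$sequential_expected, c(1e5, 1e4, 4500))

  # naive expectation is log-linear in the factor with slope -1
  f <- c(1, 10, 20, 50, 100, 1000)
  cal3 <- expected_copies(5e4, f, 5e4 / f * 0.9)
  fit <- lm(log10(cal3$naive_expected) ~ log10(f))
  expect_equal(unname(coef(fit)[2]), -1, tolerance = 1e-12)
  expect_true(attr(cal3, "log10_correlation") > 0.999)
})

test_that("cv dataset rows follow the inclusion filters", {
  # three taxa x two levels, three replicates each, everything detectable
  m <- cbind(s1 = c(0.6, 0.3, 0.1), s2 = c(0.5, 0.2, 0.3),
             s3 = c(0.4, 0.25, 0.35), s4 = c(0.2, 0.5, 0.3),
             s5 = c(0.3, 0.45, 0.25), s6 = c(0.25, 0.4, 0.35))
  rownames(m) <- c("tA", "tB", "tC")
  md <- data.frame(sample_id = colnames(m), run_id = "r18",
                   sample_type = "mock", specimen_id = NA_character_,
                   dilution_factor = rep(c(1, 100), each = 3))
  qp <- data.frame(sample_id = colnames(m),
                   copies_per_ul = rep(c(5000, 50), each = 3))
  ds <- build_cv_dataset(ra_table(m), md, qp, taxon_rank = "sv",
                         min_detected = 3)
  expect_equal(nrow(ds), 6L)
  expect_equal(sort(unique(ds$copies_per_ul)), c(50, 5000))

  # a taxon absent at one level loses only that row
  m2 <- m; m2["tA", 4:6] <- 0; m2 <- sweep(m2, 2, colSums(m2), "/")
  ds2 <- build_cv_dataset(ra_table(m2), md, qp, taxon_rank = "sv",
                          min_detected = 3)
  expect_equal(nrow(ds2), 5L)
  expect_false(any(ds2$taxon == "tA" & ds2$dilution_factor == 100))
})

test_that("the default dilution design yields on the order of 126 rows", {
  # scores drawn from the whole study so contaminant SVs are removed
  # before the dilution-run replicates are summarized per level
  st <- simulate_study(seed = 9)
  qc <- qc_pipeline(st$counts, st$metadata)
  ds <- build_cv_dataset(qc$relabund, qc$metadata, st$qpcr)
  expect_gte(nrow(ds), 100)
  expect_lte(nrow(ds), 132)
})

test_that("the variation model interpolates noise-free log-log data", {
  set.seed(131)
  n <- 40
  copies <- 10^runif(n, 0.5, 4)
  ra <- 10^runif(n, -1, 1.7)  # percent
  cv <- 10^(1.4 - 0.28 * log10(copies) - 0.55 * log10(ra))
  ds <- data.frame(taxon = paste0("t", 1:n), dilution_factor = 1,
                   mean_ra = ra / 100, cv = cv, sd = cv * ra / 1e4,
                   copies_per_ul = copies, n_detected = 10,
                   n_replicates = 10)
  fit <- fit_variation_model(ds)
  expect_equal(fit$coefficients$estimate, c(1.4, -0.28, -0.55),
               tolerance = 1e-8)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)

  # coefficients equal the normal-equations oracle
  X <- cbind(1, log10(copies), log10(ra))
  expect_equal(fit$coefficients$estimate, oracle_ols(X, log10(cv)),
               tolerance = 1e-8)

  flat <- ds; flat$cv <- 25
  ffit <- fit_variation_model(flat)
  expect_equal(ffit$coefficients$estimate[2:3], c(0, 0))
  expect_equal(ffit$r_squared, 0)

  expect_error(fit_variation_model(ds[1:3, ]), "at least 4")
})

test_that("prediction back-transforms the fitted model", {
  mk_model <- function(b) structure(
    list(coefficients = data.frame(estimate = b,
                                   row.names = c("intercept",
                                                 "log10_copies_per_ul",
                                                 "log10_mean_ra")),
         ra_unit = "percent", response = "cv"),
    class = "variation_model")
  expect_equal(predict_variation(mk_model(c(0, 0, 0)), 123, 45), 1)
  expect_equal(predict_variation(mk_model(c(1, -1, 0)), 10, 5), 1)
  m <- mk_model(c(1.43238, -0.2816, -0.54936))
  expect_equal(predict_variation(m, 10, 1), 10^1.15078, tolerance = 1e-6)
  expect_error(predict_variation(m, -1, 1), "positive")

  grid <- prediction_grid(m)
  expect_equal(dim(grid), c(3L, 5L))
  expect_equal(grid["10", "5"], predict_variation(m, 10, 5))
  # negative biomass slope: predictions fall as copies rise
  for (j in seq_len(ncol(grid))) expect_true(all(diff(grid[, j]) < 0))
})
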