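#' Noise model for synthetic amplicon studies
#'
#' Collects the stochastic components layered onto a mock community's true
#' composition on the way to an observed feature table:
#' a multiplicative log-normal run batch effect, Dirichlet replicate noise
#' within a run, a finite-template bottleneck tied to input biomass,
#' constant-load reagent contamination, log-normal qPCR measurement error
#' and a systematic per-step over-dilution bias.
#'
#' @param run_effect_sd SD of the per-taxon log-proportion perturbation
#'   shared by all samples of a run (0 disables the batch effect).
#' @param replicate_concentration Dirichlet concentration scale for
#'   within-run replicate noise; replicate compositions are drawn
#'   `Dirichlet(replicate_concentration * run_composition)`. Larger is
#'   tighter.
#' @param specimen_effect_sd SD of the log-proportion perturbation between
#'   stool specimens (biological variation).
#' @param contaminant_profile probability vector over contaminant-only SVs.
#' @param contaminant_load effective contaminant concentration (16S
#'   copies/uL equivalents); the contaminant share of a sample is
#'   `contaminant_load / (contaminant_load + copies_per_ul)`.
#' @param qpcr_cv SD of the log-normal error on qPCR-measured copies.
#' @param overdilution_bias multiplier >= 1 applied once per sequential
#'   dilution step: each prepared dilution is slightly more dilute than its
#'   nominal factor because it is made from the previous (already
#'   over-diluted) tube.
#' @param template_volume_ul template volume per PCR reaction (uL). The
#'   number of template molecules entering a reaction is
#'   `copies_per_ul * template_volume_ul`; compositions are resampled
#'   multinomially at that size, which is the mechanism by which replicate
#'   variance grows as biomass falls.
#' @param ct_sd per-well SD of simulated qPCR Ct values.
#' @return an object of class `noise_model`.
#' @export
noise_model <- function(run_effect_sd = 0.2,
                        replicate_concentration = 1000,
                        specimen_effect_sd = 0.8,
                        contaminant_profile = default_contaminant_profile(),
                        contaminant_load = 10,
                        qpcr_cv = 0.1,
                        overdilution_bias = 1.05,
                        template_volume_ul = 5,
                        ct_sd = 0.1) {
  stopifnot(run_effect_sd >= 0, specimen_effect_sd >= 0, qpcr_cv >= 0,
            replicate_concentration > 0, contaminant_load >= 0,
            overdilution_bias >= 1, template_volume_ul > 0, ct_sd >= 0)
  if (abs(sum(contaminant_profile) - 1) > 1e-9)
    stop("contaminant_profile must sum to 1")
  if (is.null(names(contaminant_profile)))
    stop("contaminant_profile must be named by SV id")
  structure(list(run_effect_sd = run_effect_sd,
                 replicate_concentration = replicate_concentration,
                 specimen_effect_sd = specimen_effect_sd,
                 contaminant_profile = contaminant_profile,
                 contaminant_load = contaminant_load,
                 qpcr_cv = qpcr_cv,
                 overdilution_bias = overdilution_bias,
                 template_volume_ul = template_volume_ul,
                 ct_sd = ct_sd),
            class = "noise_model")
}

#' Study design for synthetic amplicon studies
#'
#' @param runs data.frame with columns `run_id`, `n_mock`, `n_stool`,
#'   `n_negative`: per-run library counts for undiluted mock controls,
#'   repeat stool samples and negative controls.
#' @param dilution_levels dilution factors (1 = stock), strictly
#'   increasing; the default spans stock to a thousandfold dilution
#'   (1, 10, 20, 30, 40, 50, 60, 80, 100, 500, 1000).
#' @param replicates_per_level libraries per dilution level.
#' @param dilution_run run id that hosts the dilution series (`NULL` for
#'   no dilution series).
#' @param n_specimens number of distinct stool specimens, cycled across
#'   stool libraries.
#' @param depth_meanlog,depth_sdlog log-normal parameters for per-sample
#'   read totals of mock/stool/dilution libraries (truncated at 1).
#' @param negative_depth_meanlog,negative_depth_sdlog the same for
#'   negative controls, which receive far fewer reads.
#' @param stool_copies_per_ul 16S copies/uL of stool DNA extracts
#'   (high-biomass samples).
#' @return an object of class `study_design`.
#' @export
study_design <- function(runs,
                         dilution_levels = c(1, 10, 20, 30, 40, 50, 60, 80,
                                             100, 500, 1000),
                         replicates_per_level = 10,
                         dilution_run = "run18",
                         n_specimens = 3,
                         depth_meanlog = log(4e4), depth_sdlog = 0.5,
                         negative_depth_meanlog = log(1500),
                         negative_depth_sdlog = 0.8,
                         stool_copies_per_ul = 1e5) {
  stopifnot(is.data.frame(runs),
            all(c("run_id", "n_mock", "n_stool", "n_negative") %in%
                  names(runs)),
            all(runs$n_mock >= 0), all(runs$n_stool >= 0),
            all(runs$n_negative >= 0))
  if (length(dilution_levels)) {
    stopifnot(all(dilution_levels >= 1),
              all(diff(dilution_levels) > 0))
  }
  stopifnot(replicates_per_level >= 1, n_specimens >= 1)
  structure(list(runs = runs, dilution_levels = dilution_levels,
                 replicates_per_level = replicates_per_level,
                 dilution_run = dilution_run, n_specimens = n_specimens,
                 depth_meanlog = depth_meanlog, depth_sdlog = depth_sdlog,
                 negative_depth_meanlog = negative_depth_meanlog,
                 negative_depth_sdlog = negative_depth_sdlog,
                 stool_copies_per_ul = stool_copies_per_ul),
            class = "study_design")
}

#' Default study design: 19 runs, 469 libraries
#'
#' Mirrors a multi-year monitoring layout: 108 undiluted mock libraries
#' spread over 18 runs plus a dilution run of 110 libraries (11 levels x 10
#' replicates, including 10 undiluted), 29 stool libraries from 3 specimens
#' across 3 runs, and 222 negative controls — 469 libraries in total.
#'
#' @param ... overrides passed to [study_design()].
#' @return a `study_design`.
#' @export
default_study_design <- function(...) {
  runs <- data.frame(
    run_id = sprintf("run%02d", 1:19),
    n_mock = c(5, 7, 21, 9, 4, 3, 3, 2, 2, 3, 11, 3, 4, 1, 4, 10, 14, 0, 2),
    n_stool = c(0, 0, 0, 0, 0, 8, 0, 0, 0, 15, 0, 0, 0, 0, 6, 0, 0, 0, 0),
    n_negative = c(5, 7, 12, 1, 3, 7, 5, 6, 7, 11, 38, 10, 33, 10, 1, 27,
                   13, 24, 2)
  )
  study_design(runs = runs, dilution_run = "run18", ...)
}

# ---- elementary generator operations ---------------------------------------

#' Draw a run-level composition
#'
#' Perturbs the true proportions multiplicatively by
#' `exp(Normal(0, run_effect_sd))` per taxon and renormalizes; all samples
#' of a run share the resulting composition, producing run-level
#' clustering. Uses the current RNG state.
#'
#' @param spec a [mock_community_spec()].
#' @param noise a [noise_model()].
#' @return probability vector named by taxon id.
#' @export
sample_run_composition <- function(spec, noise) {
  perturb_composition(spec$proportions, noise$run_effect_sd)
}

perturb_composition <- function(p, sd) {
  if (sd == 0) return(p)
  q <- p * exp(stats::rnorm(length(p), 0, sd))
  q / sum(q)
}

#' Mix reagent contamination into a sample composition
#'
#' A constant-load two-source model: the contaminant share is
#' `w = L / (L + c)` for contaminant load `L` and sample biomass `c`
#' (copies/uL), so contamination is negligible at high biomass and takes
#' over as biomass approaches zero (a negative control, `c = 0`, is pure
#' contaminant).
#'
#' @param sample_proportions probability vector over community SVs.
#' @param sample_copies_per_ul nonnegative sample biomass.
#' @param noise a [noise_model()].
#' @return probability vector over community SVs followed by contaminant
#'   SVs.
#' @export
mix_contamination <- function(sample_proportions, sample_copies_per_ul,
                              noise) {
  stopifnot(sample_copies_per_ul >= 0)
  L <- noise$contaminant_load
  w <- if (L == 0 && sample_copies_per_ul == 0) 0 else
    L / (L + sample_copies_per_ul)
  c((1 - w) * sample_proportions, w * noise$contaminant_profile)
}

#' Draw sequencing read counts
#'
#' Multinomial sampling of `depth` reads from a composition.
#'
#' @param proportions probability vector (must sum to 1).
#' @param depth number of reads (>= 1).
#' @return integer count vector, same names, summing to `depth`.
#' @export
draw_counts <- function(proportions, depth) {
  if (abs(sum(proportions) - 1) > 1e-9)
    stop("proportions must sum to 1")
  stopifnot(depth >= 1)
  stats::setNames(stats::rmultinom(1L, depth, proportions)[, 1L],
                  names(proportions))
}

# Dirichlet draw via normalized gammas; zero alphas give exact zeros.
rdirichlet1 <- function(alpha) {
  x <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(x) == 0) x[which.max(alpha)] <- 1
  stats::setNames(x / sum(x), names(alpha))
}

# Finite-template bottleneck: resample a composition as the multinomial
# fraction of the template molecules actually pipetted into the reaction.
# Above the cap the resampling noise is negligible and skipped.
template_bottleneck <- function(p, copies_per_ul, template_volume_ul,
                                cap = 1e6) {
  n <- round(copies_per_ul * template_volume_ul)
  if (n >= cap) return(p)
  if (n < 1) n <- 1
  stats::setNames(stats::rmultinom(1L, n, p)[, 1L] / n, names(p))
}

rdepth <- function(n, meanlog, sdlog) {
  pmax(1, round(stats::rlnorm(n, meanlog, sdlog)))
}

# Simulated qPCR: measured copies carry log-normal error; the Ct is read
# back through a fixed reference curve (100% efficiency, intercept 38).
sim_qpcr_curve <- function() list(slope = -1 / log10(2), intercept = 38)

measure_qpcr <- function(true_copies_per_ul, noise) {
  measured <- true_copies_per_ul * stats::rlnorm(1L, 0, noise$qpcr_cv)
  curve <- sim_qpcr_curve()
  ct <- if (measured * noise$template_volume_ul < 1) NA_real_ else
    curve$intercept +
      curve$slope * log10(measured * noise$template_volume_ul) +
      stats::rnorm(1L, 0, noise$ct_sd)
  list(copies_per_ul = measured, ct = ct)
}

#' Simulate a qPCR standard dilution plate
#'
#' Standards at 0 and 10^2..10^7 copies per reaction, in triplicate wells,
#' with Gaussian Ct noise; zero-copy wells are reported undetermined (NA).
#'
#' @param noise a [noise_model()].
#' @param copies_per_reaction standard concentrations.
#' @param n_wells replicate wells per standard.
#' @return data.frame with `copies_per_reaction` and `ct`.
#' @export
simulate_qpcr_standards <- function(noise = noise_model(),
                                    copies_per_reaction = c(0, 10^(2:7)),
                                    n_wells = 3) {
  curve <- sim_qpcr_curve()
  rows <- lapply(copies_per_reaction, function(cp) {
    ct <- if (cp == 0) rep(NA_real_, n_wells) else
      curve$intercept + curve$slope * log10(cp) +
        stats::rnorm(n_wells, 0, noise$ct_sd)
    data.frame(copies_per_reaction = cp, ct = ct)
  })
  do.call(rbind, rows)
}

# ---- study assembly --------------------------------------------------------

# Pool of gut genera used to label the synthetic stool community.
stool_taxon_pool <- function() {
  data.frame(
    genus = c("Roseburia", "Blautia", "Dorea", "Ruminococcus", "Alistipes",
              "Parabacteroides", "Coprococcus", "Dialister", "Sutterella",
              "Oscillibacter", "Anaerostipes", "Odoribacter",
              "Butyricicoccus", "Collinsella", "Phascolarctobacterium"),
    family = c("Lachnospiraceae", "Lachnospiraceae", "Lachnospiraceae",
               "Ruminococcaceae", "Rikenellaceae", "Porphyromonadaceae",
               "Lachnospiraceae", "Veillonellaceae", "Sutterellaceae",
               "Oscillospiraceae", "Lachnospiraceae", "Odoribacteraceae",
               "Clostridiaceae", "Coriobacteriaceae", "Acidaminococcaceae"),
    order = c("Clostridiales", "Clostridiales", "Clostridiales",
              "Clostridiales", "Bacteroidales", "Bacteroidales",
              "Clostridiales", "Veillonellales", "Burkholderiales",
              "Clostridiales", "Clostridiales", "Bacteroidales",
              "Clostridiales", "Coriobacteriales", "Acidaminococcales"),
    class = c("Clostridia", "Clostridia", "Clostridia", "Clostridia",
              "Bacteroidia", "Bacteroidia", "Clostridia", "Negativicutes",
              "Betaproteobacteria", "Clostridia", "Clostridia",
              "Bacteroidia", "Clostridia", "Coriobacteriia",
              "Negativicutes"),
    phylum = c("Firmicutes", "Firmicutes", "Firmicutes", "Firmicutes",
               "Bacteroidetes", "Bacteroidetes", "Firmicutes", "Firmicutes",
               "Proteobacteria", "Firmicutes", "Firmicutes",
               "Bacteroidetes", "Firmicutes", "Actinobacteria",
               "Firmicutes")
  )
}

stool_taxa <- function(n = 60) {
  pool <- stool_taxon_pool()
  i <- rep_len(seq_len(nrow(pool)), n)
  sp <- stats::ave(seq_len(n), i, FUN = seq_along)
  data.frame(
    taxon_id = sprintf("SV_%s_st%02d", pool$genus[i], sp),
    lineage = lineage7(pool$phylum[i], pool$class[i], pool$order[i],
                       pool$family[i], pool$genus[i], sprintf("sp%02d", sp))
  )
}

#' Simulate a complete synthetic sequencing study
#'
#' Generates, per run: undiluted mock-community libraries (shared run
#' composition, Dirichlet replicate noise), repeat stool libraries from
#' latent specimen compositions, contaminant-only negative controls, and —
#' on the designated run — a sequential dilution series with qPCR
#' measurements. All latent values are recorded in `truth`.
#'
#' @param spec a [mock_community_spec()].
#' @param design a [study_design()].
#' @param noise a [noise_model()].
#' @param seed integer seed; the whole study is a deterministic function of
#'   (spec, design, noise, seed).
#' @return an object of class `synthetic_study`: list with `counts`
#'   (a [feature_table()]), `metadata` (data.frame), `qpcr`
#'   (sample_id / ct / copies_per_ul), `standards` (a simulated standard
#'   plate) and `truth` (per-sample latent composition matrix, true
#'   copies/uL and contaminant mixture weight).
#' @export
simulate_study <- function(spec = mock_community_spec(),
                           design = default_study_design(),
                           noise = noise_model(), seed = 1) {
  set.seed(seed)
  ctaxa <- contaminant_taxa()
  ctaxa <- ctaxa[ctaxa$taxon_id %in% names(noise$contaminant_profile), ,
                 drop = FALSE]
  n_stool_total <- sum(design$runs$n_stool)
  staxa <- if (n_stool_total > 0) stool_taxa() else
    stool_taxa()[0, , drop = FALSE]

  universe <- rbind(spec$taxa,
                    staxa,
                    data.frame(taxon_id = names(noise$contaminant_profile),
                               lineage = ctaxa$lineage[
                                 match(names(noise$contaminant_profile),
                                       ctaxa$taxon_id)]))
  zero <- stats::setNames(numeric(nrow(universe)), universe$taxon_id)

  # latent stool specimen compositions: a heavy-tailed base community
  # perturbed per specimen by the biological effect
  if (n_stool_total > 0) {
    base <- stats::rlnorm(nrow(staxa), 0, 2)
    base <- stats::setNames(base / sum(base), staxa$taxon_id)
    specimens <- lapply(seq_len(design$n_specimens), function(i)
      perturb_composition(base, noise$specimen_effect_sd))
    names(specimens) <- sprintf("specimen%02d", seq_along(specimens))
  } else specimens <- list()

  samples <- list()   # each: list(counts, meta, qpcr, comp, copies, w)
  add_sample <- function(id, run, type, specimen, dilution, comp, copies,
                         depth) {
    mixed <- mix_contamination(comp, copies, noise)
    w <- if (noise$contaminant_load == 0 && copies == 0) 0 else
      noise$contaminant_load / (noise$contaminant_load + copies)
    cnt <- draw_counts(mixed, depth)
    full <- zero; full[names(cnt)] <- cnt
    fullcomp <- zero; fullcomp[names(mixed)] <- mixed
    q <- measure_qpcr(copies, noise)
    samples[[id]] <<- list(
      counts = full,
      meta = data.frame(sample_id = id, run_id = run, sample_type = type,
                        specimen_id = specimen %||% NA_character_,
                        dilution_factor = dilution %||% NA_real_),
      qpcr = data.frame(sample_id = id, ct = q$ct,
                        copies_per_ul = q$copies_per_ul),
      comp = fullcomp, copies = copies, w = w)
  }

  for (r in seq_len(nrow(design$runs))) {
    run <- design$runs$run_id[r]
    run_comp <- sample_run_composition(spec, noise)
    # run-level batch effect applies to stool compositions as well
    run_specimens <- lapply(specimens, perturb_composition,
                            sd = noise$run_effect_sd)

    n_mock <- design$runs$n_mock[r]
    if (n_mock > 0) {
      depths <- rdepth(n_mock, design$depth_meanlog, design$depth_sdlog)
      for (i in seq_len(n_mock)) {
        comp <- rdirichlet1(noise$replicate_concentration * run_comp)
        comp <- template_bottleneck(comp, spec$stock_copies_per_ul,
                                    noise$template_volume_ul)
        add_sample(sprintf("%s_M%02d", run, i), run, "mock", NULL, NULL,
                   comp, spec$stock_copies_per_ul, depths[i])
      }
    }

    n_stool <- design$runs$n_stool[r]
    if (n_stool > 0) {
      depths <- rdepth(n_stool, design$depth_meanlog, design$depth_sdlog)
      for (i in seq_len(n_stool)) {
        sp_i <- ((i - 1L) %% design$n_specimens) + 1L
        comp <- rdirichlet1(noise$replicate_concentration *
                              run_specimens[[sp_i]])
        comp <- template_bottleneck(comp, design$stool_copies_per_ul,
                                    noise$template_volume_ul)
        add_sample(sprintf("%s_S%02d", run, i), run, "stool",
                   names(run_specimens)[sp_i], NULL, comp,
                   design$stool_copies_per_ul, depths[i])
      }
    }

    if (identical(run, design$dilution_run) &&
        length(design$dilution_levels)) {
      dil <- sim_dilution_samples(spec, design, noise, run, run_comp)
      for (s in dil) samples[[s$meta$sample_id]] <- s
    }

    n_neg <- design$runs$n_negative[r]
    if (n_neg > 0) {
      depths <- rdepth(n_neg, design$negative_depth_meanlog,
                       design$negative_depth_sdlog)
      for (i in seq_len(n_neg)) {
        comp <- stats::setNames(numeric(nrow(spec$taxa)), spec$taxa$taxon_id)
        add_sample(sprintf("%s_N%02d", run, i), run, "negative", NULL,
                   NULL, comp, 0, depths[i])
      }
    }
  }

  assemble_study(samples, universe, seed,
                 simulate_qpcr_standards(noise))
}

# dilution-series samples for one run sharing a run composition
sim_dilution_samples <- function(spec, design, noise, run, run_comp) {
  out <- list()
  levels <- design$dilution_levels
  for (k in seq_along(levels)) {
    d <- levels[k]
    true_copies <- spec$stock_copies_per_ul /
      (d * noise$overdilution_bias^(k - 1L))
    depths <- rdepth(design$replicates_per_level, design$depth_meanlog,
                     design$depth_sdlog)
    for (i in seq_len(design$replicates_per_level)) {
      id <- sprintf("%s_D%04d_r%02d", run, d, i)
      comp <- rdirichlet1(noise$replicate_concentration * run_comp)
      comp <- template_bottleneck(comp, true_copies,
                                  noise$template_volume_ul)
      mixed <- mix_contamination(comp, true_copies, noise)
      cnt <- draw_counts(mixed, depths[i])
      q <- measure_qpcr(true_copies, noise)
      out[[id]] <- list(
        counts = cnt,
        meta = data.frame(sample_id = id, run_id = run,
                          sample_type = "mock", specimen_id = NA_character_,
                          dilution_factor = d),
        qpcr = data.frame(sample_id = id, ct = q$ct,
                          copies_per_ul = q$copies_per_ul),
        comp = mixed, copies = true_copies,
        w = noise$contaminant_load / (noise$contaminant_load + true_copies))
    }
  }
  out
}

#' Simulate a dilution series only
#'
#' The prospective dilution experiment on a single run: every level of
#' `design$dilution_levels` sequenced with `design$replicates_per_level`
#' replicates, plus that run's negative controls if the design requests
#' them.
#'
#' @inheritParams simulate_study
#' @return a `synthetic_study` containing only the dilution run.
#' @export
simulate_dilution_series <- function(spec = mock_community_spec(),
                                     design = default_study_design(),
                                     noise = noise_model(), seed = 1) {
  if (!length(design$dilution_levels))
    stop("design has no dilution levels")
  run <- design$dilution_run %||% "run18"
  design2 <- design
  keep <- design$runs$run_id == run
  design2$runs <- design$runs[keep, , drop = FALSE]
  if (!nrow(design2$runs))
    design2$runs <- data.frame(run_id = run, n_mock = 0, n_stool = 0,
                               n_negative = 0)
  design2$runs$n_mock <- 0
  design2$runs$n_stool <- 0
  simulate_study(spec, design2, noise, seed)
}

assemble_study <- function(samples, universe, seed, standards) {
  ids <- names(samples)
  pad <- function(field) {
    vapply(samples, function(s) {
      v <- stats::setNames(numeric(nrow(universe)), universe$taxon_id)
      v[names(s[[field]])] <- s[[field]]
      v
    }, numeric(nrow(universe)))
  }
  counts <- pad("counts")
  comp <- pad("comp")
  metadata <- do.call(rbind, lapply(samples, `[[`, "meta"))
  rownames(metadata) <- NULL
  qpcr <- do.call(rbind, lapply(samples, `[[`, "qpcr"))
  rownames(qpcr) <- NULL
  # drop SVs never observed anywhere (e.g. stool taxa in a mock-only study)
  keep <- rowSums(counts) > 0
  if (!any(keep)) keep[1L] <- TRUE
  tab <- feature_table(counts[keep, , drop = FALSE],
                       stats::setNames(universe$lineage,
                                       universe$taxon_id)[keep])
  structure(list(
    counts = tab,
    metadata = metadata,
    qpcr = qpcr,
    standards = standards,
    truth = list(composition = comp,
                 copies_per_ul = vapply(samples, `[[`, numeric(1), "copies"),
                 contaminant_weight = vapply(samples, `[[`, numeric(1), "w")),
    seed = seed), class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  tt <- table(x$metadata$sample_type)
  cat(sprintf(
    "synthetic_study: %d samples (%s), %d SVs, seed %d\n",
    nrow(x$metadata),
    paste(sprintf("%s %d", names(tt), tt), collapse = ", "),
    nrow(x$counts$counts), x$seed))
  invisible(x)
}

#' Write a synthetic study to disk
#'
#' Emits `counts.tsv` (feature table), `metadata.tsv`, `qpcr.tsv`,
#' `standards.tsv` and `truth.json`.
#'
#' @param study a `synthetic_study`.
#' @param dir output directory (created if needed).
#' @param format feature-table format, `"tsv"` or `"biom"`.
#' @return `dir`, invisibly.
#' @export
write_synthetic_study <- function(study, dir, format = "tsv") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ext <- if (format == "biom") "biom" else "tsv"
  write_feature_table(study$counts, file.path(dir, paste0("counts.", ext)),
                      format)
  write_metadata(study$metadata, file.path(dir, "metadata.tsv"))
  utils::write.table(study$qpcr, file.path(dir, "qpcr.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "")
  utils::write.table(study$standards, file.path(dir, "standards.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "Undetermined")
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(
      list(seed = study$seed,
           copies_per_ul = as.list(study$truth$copies_per_ul),
           contaminant_weight = as.list(study$truth$contaminant_weight),
           composition = apply(study$truth$composition, 2L, as.list)),
      file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
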