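#' Read a qPCR plate TSV
#'
#' Expected columns: `sample_id`, optionally `well`, and `ct`; the text
#' `Undetermined` (any case) or an empty field is read as NA.
#'
#' @param path file path.
#' @return data.frame with `sample_id` and numeric `ct` (plus any extra
#'   columns).
#' @export
read_qpcr <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          colClasses = "character")
  if (!all(c("sample_id", "ct") %in% names(df)))
    stop("qPCR table needs 'sample_id' and 'ct' columns")
  ct <- df$ct
  ct[tolower(ct) %in% c("undetermined", "")] <- NA
  df$ct <- as.numeric(ct)
  if ("copies_per_ul" %in% names(df))
    df$copies_per_ul <- as.numeric(df$copies_per_ul)
  df
}

#' Run the full study-level analysis pipeline
#'
#' Orchestrates the complete workflow on one study: quality control
#' (contaminant scoring and removal, depth thresholding, rarefaction,
#' relative abundance), per-rank variability (CV tables, ICC,
#' Levey-Jennings flags, CV-abundance association), community distances
#' (Bray-Curtis PCoA, PERMANOVA by sample type and run, distance-group
#' stratification) and — when the study includes a dilution series with
#' qPCR — the biomass analyses (dilution calibration, CV dataset,
#' variation model, prediction grid). Sections that cannot run are marked
#' skipped with a reason rather than failing the report.
#'
#' @param study a `synthetic_study`, or a list with elements `counts`
#'   (a [feature_table()]), `metadata`, and optionally `qpcr`.
#' @param threshold contaminant-score cutoff (default 0.1).
#' @param max_negatives_retained for [select_depth_threshold()] (default
#'   2).
#' @param depth_override manual rarefaction depth.
#' @param taxon_ranks ranks for the variability section.
#' @param n_permutations PERMANOVA permutations (default 999).
#' @param seed seed for rarefaction and permutation draws.
#' @return a `study_report` list: `seeds`, `qc`, `variability`, `icc`,
#'   `distance`, `biomass`; skipped sections are
#'   `list(skipped = TRUE, reason = ...)`.
#' @export
run_pipeline <- function(study, threshold = 0.1,
                         max_negatives_retained = 2, depth_override = NULL,
                         taxon_ranks = c("family", "genus"),
                         n_permutations = 999, seed = 1) {
  stopifnot(inherits(study$counts, "feature_table"))
  report <- list(seeds = list(pipeline = seed,
                              study = study$seed %||% NA))

  qc <- qc_pipeline(study$counts, study$metadata, threshold,
                    max_negatives_retained, depth_override,
                    rarefy_seed = seed)
  report$qc <- qc$report
  report$qc$depth_threshold <- qc$depth_threshold

  md <- qc$metadata
  undil <- is.na(md$dilution_factor) | md$dilution_factor == 1
  core <- md$sample_type != "negative" & undil
  relab_core <- subset_table(qc$relabund, samples = md$sample_id[core])
  md_core <- md[core, , drop = FALSE]

  report$variability <- lapply(stats::setNames(taxon_ranks, taxon_ranks),
    function(rk) {
      intra <- cv_table(relab_core, md_core, "run", rk)
      inter <- cv_table(relab_core, md_core, "none", rk)
      list(intra = intra, inter = inter, mean_intra = mean_intra_cv(intra),
           association = tryCatch(cv_abundance_association(inter),
                                  error = function(e) NULL),
           levey_jennings = levey_jennings(relab_core, md_core, rk))
    })
  report$icc <- lapply(stats::setNames(taxon_ranks, taxon_ranks),
    function(rk) tryCatch(icc_oneway(relab_core, md_core, "run_id", rk),
                          error = function(e)
                            list(skipped = TRUE,
                                 reason = conditionMessage(e))))

  set.seed(seed)
  dm <- pairwise_distances(relab_core, "bray_curtis")
  ord <- pcoa(dm)
  perm <- if (length(unique(md_core$sample_type)) >= 2L)
    permanova(dm, md_core, c("sample_type", "run_id"), n_permutations)
  else list(skipped = TRUE, reason = "single sample type")
  dgroups <- if (any(!is.na(md_core$specimen_id)))
    distance_groups(dm, md_core)
  else list(skipped = TRUE, reason = "no specimen ids")
  report$distance <- list(pcoa = ord, permanova = perm,
                          groups = dgroups,
                          mean_bray_curtis = mean(dm[upper.tri(dm)]))

  dil <- !is.na(md$dilution_factor)
  if (!is.null(study$qpcr) && any(dil)) {
    mdd <- md[dil, , drop = FALSE]
    qp <- study$qpcr
    levels_ <- sort(unique(mdd$dilution_factor))
    measured <- vapply(levels_, function(d) {
      ids <- mdd$sample_id[mdd$dilution_factor == d]
      mean(qp$copies_per_ul[qp$sample_id %in% ids], na.rm = TRUE)
    }, numeric(1))
    calib <- if (levels_[1L] == 1)
      expected_copies(measured[1L], levels_, measured)
    else list(skipped = TRUE, reason = "no stock (factor 1) level")
    ds <- tryCatch(build_cv_dataset(qc$relabund, md, qp),
                   error = function(e) NULL)
    model <- if (!is.null(ds) && nrow(ds) >= 4L)
      tryCatch(fit_variation_model(ds), error = function(e) NULL)
    else NULL
    shannon_by_level <- vapply(levels_, function(d) {
      ids <- intersect(mdd$sample_id[mdd$dilution_factor == d],
                       sample_ids(qc$rarefied))
      if (!length(ids)) return(NA_real_)
      mean(shannon(subset_table(qc$rarefied, samples = ids)))
    }, numeric(1))
    report$biomass <- list(
      calibration = calib,
      shannon = data.frame(dilution_factor = levels_,
                           mean_shannon = shannon_by_level),
      cv_dataset = ds,
      model = model %||% list(skipped = TRUE,
                              reason = "variation model could not be fit"),
      prediction_grid = if (!is.null(model)) prediction_grid(model) else
        NULL)
  } else {
    report$biomass <- list(skipped = TRUE,
                           reason = "no qPCR data or no dilution series")
  }
  class(report) <- "study_report"
  report
}

#' @export
print.study_report <- function(x, ...) {
  cat("study_report\n")
  st <- x$qc$stages
  cat(sprintf("  QC: %d -> %d SVs, %d -> %d samples (depth >= %d)\n",
              st$input$n_sv, st$contaminant_filtered$n_sv,
              st$input$n_samples, st$depth_filtered$n_samples,
              x$qc$depth_threshold))
  if (!isTRUE(x$biomass$skipped))
    cat("  biomass section: present\n")
  else cat(sprintf("  biomass section: skipped (%s)\n", x$biomass$reason))
  invisible(x)
}

#' Write the main report tables to a directory
#'
#' Emits TSV tables for the variability and distance sections, a JSON
#' summary, and the prediction grid when present.
#'
#' @param report a [run_pipeline()] result.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, name)
    utils::write.table(df, file.path(dir, name), sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "")
  for (rk in names(report$variability)) {
    wt(report$variability[[rk]]$intra, sprintf("cv_intra_%s.tsv", rk))
    wt(report$variability[[rk]]$inter, sprintf("cv_inter_%s.tsv", rk))
  }
  wt(report$distance$groups$summary %||%
       data.frame(note = "no specimen ids"), "distance_groups.tsv")
  if (!isTRUE(report$biomass$skipped)) {
    wt(report$biomass$calibration, "dilution_calibration.tsv")
    if (!is.null(report$biomass$cv_dataset))
      wt(report$biomass$cv_dataset, "cv_dataset.tsv")
    if (!is.null(report$biomass$prediction_grid))
      utils::write.table(report$biomass$prediction_grid,
                         file.path(dir, "prediction_grid.tsv"),
                         sep = "\t", quote = FALSE, col.names = NA)
  }
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    summ <- list(
      seeds = report$seeds,
      qc = report$qc$stages,
      depth_threshold = report$qc$depth_threshold,
      mean_icc = lapply(report$icc, function(r)
        if (!is.null(r$mean_icc)) r$mean_icc else NA),
      permanova = if (!isTRUE(report$distance$permanova$skipped))
        lapply(report$distance$permanova, function(p)
          p[c("r_squared", "pseudo_f", "p_value")]) else NULL,
      model = if (!isTRUE(report$biomass$skipped) &&
                  !isTRUE(report$biomass$model$skipped))
        list(coefficients = report$biomass$model$coefficients$estimate,
             r_squared = report$biomass$model$r_squared) else NULL)
    jsonlite::write_json(summ, file.path(dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
  }
  invisible(dir)
}
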