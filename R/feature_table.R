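#' Construct a feature table
#'
#' A feature table holds integer read counts for amplicon sequence variants
#' (SVs, rows) across samples (columns), together with a 7-rank
#' semicolon-delimited taxonomic lineage per SV
#' (`Kingdom;Phylum;Class;Order;Family;Genus;Species`; trailing ranks may be
#' empty when unassigned).
#'
#' @param counts numeric matrix of nonnegative integer counts, rows = SVs
#'   (rownames are SV ids), columns = samples (colnames are sample ids).
#' @param taxonomy character vector of lineages, one per SV, named by SV id
#'   (or in row order). `NULL` leaves all lineages unassigned.
#' @return an object of class `feature_table` with elements `counts` and
#'   `taxonomy`.
#' @export
feature_table <- function(counts, taxonomy = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || anyDuplicated(rownames(counts)))
    stop("counts must have unique SV row names")
  if (is.null(colnames(counts)) || anyDuplicated(colnames(counts)))
    stop("counts must have unique sample column names")
  if (any(counts < 0)) stop("counts must be nonnegative")
  if (any(abs(counts - round(counts)) > 1e-8))
    stop("counts must be integers")
  storage.mode(counts) <- "double"
  counts <- round(counts)
  if (is.null(taxonomy)) {
    taxonomy <- stats::setNames(rep("", nrow(counts)), rownames(counts))
  } else {
    if (is.null(names(taxonomy))) names(taxonomy) <- rownames(counts)
    if (!all(rownames(counts) %in% names(taxonomy)))
      stop("taxonomy must cover every SV id")
    taxonomy <- taxonomy[rownames(counts)]
  }
  structure(list(counts = counts, taxonomy = taxonomy),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("feature_table: %d SVs x %d samples, %s total reads\n",
              nrow(x$counts), ncol(x$counts),
              format(sum(x$counts), big.mark = ",")))
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$counts)

sample_ids <- function(table) colnames(table$counts)
sv_ids <- function(table) rownames(table$counts)

# internal constructor without the integer-count validation, for derived
# tables (proportions, collapsed ranks, subsets)
new_feature_table <- function(counts, taxonomy) {
  structure(list(counts = counts, taxonomy = taxonomy),
            class = "feature_table")
}

#' Subset a feature table by SV and/or sample ids
#'
#' @param table a [feature_table()].
#' @param svs,samples character vectors of ids to keep (default: all).
#' @return a `feature_table`.
#' @export
subset_table <- function(table, svs = sv_ids(table),
                         samples = sample_ids(table)) {
  new_feature_table(table$counts[svs, samples, drop = FALSE],
                    table$taxonomy[svs])
}

# ---- tabular I/O ------------------------------------------------------------

#' Read / write feature tables
#'
#' The TSV dialect is tab-separated with the SV id in the first column
#' (header `sv_id`), sample counts in the middle columns, and the lineage in
#' a final `taxonomy` column. BIOM files are handled through the
#' \pkg{biomformat} package.
#'
#' @param path file path.
#' @param format `"tsv"` or `"biom"`.
#' @return `read_feature_table` returns a [feature_table()];
#'   `write_feature_table` returns `path` invisibly.
#' @export
read_feature_table <- function(path, format = c("tsv", "biom")) {
  format <- match.arg(format)
  if (format == "biom") {
    if (!requireNamespace("biomformat", quietly = TRUE))
      stop("the biomformat package is required for BIOM input")
    b <- biomformat::read_biom(path)
    counts <- as.matrix(biomformat::biom_data(b))
    obs <- biomformat::observation_metadata(b)
    tax <- if (is.null(obs)) NULL else
      apply(as.matrix(obs), 1L, paste, collapse = ";")
    return(feature_table(counts, tax))
  }
  df <- utils::read.delim(path, check.names = FALSE,
                          colClasses = "character")
  if (names(df)[1L] != "sv_id" || names(df)[ncol(df)] != "taxonomy")
    stop("malformed header: expected first column 'sv_id' and last column 'taxonomy'")
  if (anyDuplicated(df$sv_id))
    stop("duplicate SV id: ", df$sv_id[duplicated(df$sv_id)][1L])
  samp_cols <- setdiff(names(df), c("sv_id", "taxonomy"))
  counts <- as.matrix(df[samp_cols])
  suppressWarnings(storage.mode(counts) <- "double")
  if (anyNA(counts) || any(counts != round(counts)))
    stop("non-integer count encountered in ", path)
  rownames(counts) <- df$sv_id
  feature_table(counts, stats::setNames(df$taxonomy, df$sv_id))
}

#' @rdname read_feature_table
#' @param table a [feature_table()].
#' @export
write_feature_table <- function(table, path, format = c("tsv", "biom")) {
  format <- match.arg(format)
  if (format == "biom") {
    if (!requireNamespace("biomformat", quietly = TRUE))
      stop("the biomformat package is required for BIOM output")
    ranks <- c("Kingdom", "Phylum", "Class", "Order", "Family", "Genus",
               "Species")
    tax <- split_lineages(table$taxonomy)
    colnames(tax) <- ranks
    b <- biomformat::make_biom(table$counts,
                               observation_metadata = as.data.frame(tax))
    biomformat::write_biom(b, path)
    return(invisible(path))
  }
  df <- data.frame(sv_id = sv_ids(table), table$counts,
                   taxonomy = unname(table$taxonomy),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Split semicolon lineages into an n x 7 character matrix, padding with "".
split_lineages <- function(lineages) {
  parts <- strsplit(lineages, ";", fixed = TRUE)
  out <- t(vapply(parts, function(p) {
    p <- trimws(p)
    length(p) <- 7L
    p[is.na(p)] <- ""
    p
  }, character(7L)))
  rownames(out) <- names(lineages)
  out
}

#' Read / write sample metadata
#'
#' Metadata TSV columns: `sample_id`, `run_id`, `sample_type`
#' (mock / stool / negative), `specimen_id` (empty when not applicable) and
#' `dilution_factor` (>= 1; empty when the sample is not part of a dilution
#' series).
#'
#' @param path file path.
#' @return a data.frame, one row per sample.
#' @export
read_metadata <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          colClasses = "character")
  required <- c("sample_id", "run_id", "sample_type")
  if (!all(required %in% names(df)))
    stop("metadata is missing column(s): ",
         paste(setdiff(required, names(df)), collapse = ", "))
  if (!all(df$sample_type %in% c("mock", "stool", "negative")))
    stop("sample_type must be one of mock, stool, negative")
  if (!"specimen_id" %in% names(df)) df$specimen_id <- NA_character_
  df$specimen_id[df$specimen_id == ""] <- NA_character_
  if (!"dilution_factor" %in% names(df)) df$dilution_factor <- NA
  df$dilution_factor <- suppressWarnings(as.numeric(df$dilution_factor))
  df
}

#' @rdname read_metadata
#' @param metadata a metadata data.frame.
#' @export
write_metadata <- function(metadata, path) {
  utils::write.table(metadata, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

# Align metadata to a table's samples, erroring on mismatch.
match_metadata <- function(table, metadata) {
  ids <- sample_ids(table)
  missing <- setdiff(ids, metadata$sample_id)
  if (length(missing))
    stop("metadata missing for sample(s): ",
         paste(utils::head(missing, 5L), collapse = ", "))
  metadata[match(ids, metadata$sample_id), , drop = FALSE]
}
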