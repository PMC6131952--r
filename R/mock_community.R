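#' Define a mock bacterial community
#'
#' A mock community is a defined mixture of bacterial strains used as a
#' positive sequencing control. The specification carries the strain
#' lineages, their true proportions in the stock, and the absolute 16S rRNA
#' gene copy concentration of the undiluted stock.
#'
#' @param taxa data.frame with columns `taxon_id` and `lineage` (7-rank
#'   semicolon-delimited). Defaults to a synthetic 33-strain community
#'   spanning 12 genera, [default_mock_taxa()].
#' @param proportions probability vector over the taxa (sums to 1). Default
#'   uniform: the community membership is defined, but equal cell input is
#'   assumed in the absence of a measured composition.
#' @param stock_copies_per_ul 16S copies per microliter of undiluted stock.
#'   The default (7520) places an 80-fold dilution at 94 copies/uL, the
#'   neighbourhood where contamination begins to dominate amplification.
#' @return an object of class `mock_community_spec`.
#' @export
mock_community_spec <- function(taxa = default_mock_taxa(),
                                proportions = NULL,
                                stock_copies_per_ul = 7520) {
  stopifnot(is.data.frame(taxa), all(c("taxon_id", "lineage") %in% names(taxa)))
  if (nrow(taxa) < 2L) stop("a mock community needs at least 2 taxa")
  if (anyDuplicated(taxa$taxon_id)) stop("taxon ids must be unique")
  if (is.null(proportions))
    proportions <- rep(1 / nrow(taxa), nrow(taxa))
  if (length(proportions) != nrow(taxa))
    stop("proportions must match the number of taxa")
  if (any(proportions < 0)) stop("proportions must be nonnegative")
  if (abs(sum(proportions) - 1) > 1e-12)
    stop("proportions must sum to 1")
  if (stock_copies_per_ul <= 0) stop("stock_copies_per_ul must be positive")
  structure(list(taxa = taxa,
                 proportions = stats::setNames(proportions, taxa$taxon_id),
                 stock_copies_per_ul = stock_copies_per_ul),
            class = "mock_community_spec")
}

#' @export
print.mock_community_spec <- function(x, ...) {
  cat(sprintf("mock_community_spec: %d strains, stock %.3g 16S copies/uL\n",
              nrow(x$taxa), x$stock_copies_per_ul))
  invisible(x)
}

lineage7 <- function(phylum, class, order, family, genus, species) {
  paste("Bacteria", phylum, class, order, family, genus,
        paste0(genus, "_", species), sep = ";")
}

#' Default synthetic 33-strain mock community membership
#'
#' Thirty-three strains across 12 genera and 12 families, covering the
#' major gut-associated phyla. The membership (and all names) is synthetic;
#' it mirrors the scale of whole-cell mock controls used for run-to-run
#' monitoring, where a few dozen strains collapse to roughly a dozen genera.
#'
#' @return data.frame with `taxon_id` and `lineage` columns (33 rows).
#' @export
default_mock_taxa <- function() {
  g <- list(
    list("Bacteroidetes", "Bacteroidia", "Bacteroidales", "Bacteroidaceae",
         "Bacteroides", c("fragilis", "vulgatus", "thetaiotaomicron", "ovatus")),
    list("Bacteroidetes", "Bacteroidia", "Bacteroidales", "Prevotellaceae",
         "Prevotella", c("copri", "melaninogenica", "bivia")),
    list("Firmicutes", "Bacilli", "Lactobacillales", "Lactobacillaceae",
         "Lactobacillus", c("acidophilus", "rhamnosus", "plantarum", "casei")),
    list("Firmicutes", "Bacilli", "Lactobacillales", "Streptococcaceae",
         "Streptococcus", c("mutans", "agalactiae", "salivarius")),
    list("Firmicutes", "Bacilli", "Bacillales", "Staphylococcaceae",
         "Staphylococcus", c("aureus", "epidermidis", "hominis")),
    list("Firmicutes", "Bacilli", "Lactobacillales", "Enterococcaceae",
         "Enterococcus", c("faecalis", "faecium")),
    list("Firmicutes", "Clostridia", "Clostridiales", "Clostridiaceae",
         "Clostridium", c("perfringens", "butyricum", "sporogenes")),
    list("Firmicutes", "Clostridia", "Clostridiales", "Ruminococcaceae",
         "Faecalibacterium", c("prausnitzii", "duncaniae")),
    list("Firmicutes", "Negativicutes", "Veillonellales", "Veillonellaceae",
         "Veillonella", c("parvula", "dispar", "atypica")),
    list("Actinobacteria", "Actinobacteria", "Bifidobacteriales",
         "Bifidobacteriaceae", "Bifidobacterium",
         c("longum", "adolescentis", "bifidum")),
    list("Proteobacteria", "Gammaproteobacteria", "Enterobacterales",
         "Enterobacteriaceae", "Escherichia", c("coli", "fergusonii")),
    list("Verrucomicrobia", "Verrucomicrobiae", "Verrucomicrobiales",
         "Akkermansiaceae", "Akkermansia", c("muciniphila"))
  )
  rows <- do.call(rbind, lapply(g, function(x) {
    data.frame(taxon_id = paste0("SV_", x[[5]], "_", x[[6]]),
               lineage = lineage7(x[[1]], x[[2]], x[[3]], x[[4]], x[[5]],
                                  x[[6]]))
  }))
  rownames(rows) <- NULL
  rows
}

#' Default reagent contaminant profile
#'
#' Five contaminant-only SVs from genera classically reported in extraction
#' and amplification reagents ("kitome"): Pseudomonas, Moraxella, Ralstonia,
#' Sphingomonas and Bradyrhizobium.
#'
#' @return named probability vector; names are contaminant SV ids. The
#'   lineages are retrievable with [contaminant_taxa()].
#' @export
default_contaminant_profile <- function() {
  p <- c(0.40, 0.25, 0.15, 0.12, 0.08)
  names(p) <- contaminant_taxa()$taxon_id
  p
}

#' @rdname default_contaminant_profile
#' @export
contaminant_taxa <- function() {
  data.frame(
    taxon_id = c("SV_Pseudomonas_contam", "SV_Moraxella_contam",
                 "SV_Ralstonia_contam", "SV_Sphingomonas_contam",
                 "SV_Bradyrhizobium_contam"),
    lineage = c(
      lineage7("Proteobacteria", "Gammaproteobacteria", "Pseudomonadales",
               "Pseudomonadaceae", "Pseudomonas", "sp"),
      lineage7("Proteobacteria", "Gammaproteobacteria", "Pseudomonadales",
               "Moraxellaceae", "Moraxella", "sp"),
      lineage7("Proteobacteria", "Betaproteobacteria", "Burkholderiales",
               "Burkholderiaceae", "Ralstonia", "sp"),
      lineage7("Proteobacteria", "Alphaproteobacteria", "Sphingomonadales",
               "Sphingomonadaceae", "Sphingomonas", "sp"),
      lineage7("Proteobacteria", "Alphaproteobacteria", "Rhizobiales",
               "Bradyrhizobiaceae", "Bradyrhizobium", "sp")
    )
  )
}
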