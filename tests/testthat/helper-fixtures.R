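# Small study configurations used across tests to keep runtimes down.

small_design <- function(dilution = FALSE) {
  runs <- data.frame(
    run_id = sprintf("run%02d", 1:4),
    n_mock = c(4, 4, 4, 4),
    n_stool = c(6, 6, 0, 0),
    n_negative = c(3, 3, 3, 3))
  study_design(runs = runs,
               dilution_levels = if (dilution)
                 c(1, 10, 20, 30, 40, 50, 60, 80, 100, 500, 1000)
               else numeric(0),
               dilution_run = if (dilution) "run04" else NULL)
}

# tiny hand-checkable feature table: 3 SVs x 4 samples (one negative)
tiny_table <- function() {
  counts <- matrix(c(10, 30, 60,
                     20, 30, 50,
                      5,  5, 90,
                      8,  1,  1),
                   nrow = 3,
                   dimnames = list(c("svA", "svB", "svC"),
                                   c("s1", "s2", "s3", "neg1")))
  md <- data.frame(sample_id = colnames(counts),
                   run_id = c("run1", "run1", "run2", "run1"),
                   sample_type = c("mock", "mock", "mock", "negative"),
                   specimen_id = NA_character_,
                   dilution_factor = NA_real_)
  list(table = feature_table(counts,
                             c(svA = "Bacteria;P1;C1;O1;F1;G1;G1_s1",
                               svB = "Bacteria;P1;C1;O1;F1;G1;G1_s2",
                               svC = "Bacteria;P2;C2;O2;F2;G2;G2_s1")),
       metadata = md)
}

# relative-abundance table from a plain numeric matrix
ra_table <- function(m) {
  if (is.null(rownames(m))) rownames(m) <- paste0("t", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- paste0("s", seq_len(ncol(m)))
  tab <- feature_table(matrix(1L, nrow(m), ncol(m), dimnames = dimnames(m)))
  tab$counts <- m
  tab
}
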