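#' Packaged CgrA direct-regulon table
#'
#' The published direct-regulon table for the CRP-family regulator CgrA of
#' *Rhodospirillum centenum*: genes with both CgrA-dependent expression and
#' an upstream ChIP-seq binding peak. 46 rows covering 45 unique loci (one
#' locus is listed under two functional categories); `distance` is the
#' signed summit-to-start-codon distance (bp, `NA` for operon followers,
#' positive when the summit lies inside the gene), `operon_role` is
#' `single` / `first_in_operon` / `in_operon`, `log2fc` is the deletion
#' strain versus wild type, `site_seq` is the predicted binding sequence
#' under the peak, and `cyst_regulated` / `cog` are study metadata.
#'
#' @param path Path to a table in the same format; defaults to the packaged
#'   fixture.
#' @return A tibble with columns `peak_id`, `locus_id`, `cyst_regulated`,
#'   `gene_name`, `strand`, `distance`, `operon_role`, `product`, `log2fc`,
#'   `site_seq`, `cog`.
#' @export
load_table1 <- function(path = system.file("extdata", "table1_regulon.tsv",
                                           package = "regulonmapr")) {
  if (!nzchar(path) || !file.exists(path)) stop("fixture not found: ", path)
  tb <- utils::read.delim(path, sep = "\t", na.strings = "NA",
                          colClasses = "character",
                          stringsAsFactors = FALSE)
  tb <- tibble::as_tibble(tb)
  if ("distance" %in% names(tb)) tb$distance <- as.integer(tb$distance)
  if ("log2fc" %in% names(tb)) tb$log2fc <- as.numeric(tb$log2fc)
  need <- c("peak_id", "locus_id", "strand", "distance", "operon_role",
            "log2fc", "site_seq")
  miss <- setdiff(need, names(tb))
  if (length(miss) > 0) stop("malformed regulon table, missing column(s): ",
                             paste(miss, collapse = ", "))
  if (!all(tb$operon_role %in% c("single", "first_in_operon", "in_operon"))) {
    stop("malformed regulon table: unknown operon_role value")
  }
  tb
}

#' Recompute direct-regulon bookkeeping from a regulon table
#'
#' Derives from the table rows, rather than reading any published count:
#' the number of unique directly regulated loci; loci with a peak directly
#' upstream (rows bearing a distance, role `single` or `first_in_operon`);
#' the singular vs first-in-operon split; the activated (log2fc < 0 in the
#' deletion strain) vs repressed split among those; divergent pairs (a peak
#' shared by two distance-bearing rows of opposite gene strand); and how
#' many distinct predicted binding sequences match the strict palindromic
#' dyad (TGTGA-N6-TCACA) by an actual dyad scan.
#'
#' @param table A tibble from [load_table1()], or a path to one.
#' @return A one-row tibble of counts.
#' @export
#' @examples
#' replay_table1()
replay_table1 <- function(table = load_table1()) {
  if (is.character(table)) table <- load_table1(table)
  tb <- table[!duplicated(table$locus_id), ]
  up <- tb[!is.na(tb$distance) &
             tb$operon_role %in% c("single", "first_in_operon"), ]
  divergent <- vapply(split(up$strand, up$peak_id), function(s) {
    length(s) >= 2 && length(unique(s)) == 2
  }, logical(1))
  strict <- dyad_spec("TGTGA", "TCACA", 6L)
  seqs <- unique(stats::na.omit(table$site_seq))
  n_dyad <- sum(vapply(seqs, function(s) nrow(scan_dyad(strict, s)) > 0,
                       logical(1)))
  tibble::tibble(
    n_rows = nrow(table),
    n_unique_loci = nrow(tb),
    n_upstream_peak_genes = nrow(up),
    n_single = sum(up$operon_role == "single"),
    n_first_in_operon = sum(up$operon_role == "first_in_operon"),
    n_activated = sum(up$log2fc < 0),
    n_repressed = sum(up$log2fc > 0),
    n_divergent_pairs = sum(divergent),
    n_strict_dyad_sequences = n_dyad)
}
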