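#' Signed distance from a peak summit to a gene's start codon
#'
#' Measured along the gene's strand: for `+` genes `summit - start`, for
#' `-` genes `end - summit` (both in 1-based coordinates after converting
#' the 0-based summit). Negative values put the summit upstream of the
#' start codon; a summit exactly on the start codon gives 0.
#'
#' @param summit 0-based summit position(s).
#' @param start,end 1-based inclusive gene coordinates.
#' @param strand `"+"` or `"-"` (recycled).
#' @return Signed integer distance(s) in bp.
#' @export
#' @examples
#' summit_to_start_distance(909, 1000, 1400, "+")   # -90, upstream
#' summit_to_start_distance(1963, 1500, 2000, "-")  # +36, inside the gene
summit_to_start_distance <- function(summit, start, end, strand) {
  s1 <- summit + 1L
  n <- max(length(s1), length(start), length(end), length(strand))
  s1 <- rep_len(s1, n); start <- rep_len(start, n)
  end <- rep_len(end, n); strand <- rep_len(strand, n)
  ifelse(strand == "+", s1 - start, end - s1)
}

summit_in_gene <- function(summit, ann) {
  s1 <- summit + 1L
  which(ann$start <= s1 & ann$end >= s1)
}

#' Classify the genomic context of peaks
#'
#' Each peak summit falls into exactly one of five categories:
#' \describe{
#'   \item{rna_locus}{summit inside an rRNA/tRNA gene;}
#'   \item{intergenic_divergent}{summit between a divergently transcribed
#'     gene pair (a `-` gene then a `+` gene, start codons facing the gap)
#'     with *both* starts within the promoter window;}
#'   \item{intergenic_upstream}{summit in an intergenic region within the
#'     window upstream of at least one gene start;}
#'   \item{intragenic_upstream}{summit inside a gene but within the window
#'     of a downstream gene's start;}
#'   \item{intragenic}{everything else.}
#' }
#'
#' @param peaks Peaks tibble (needs `peak_id`, `summit`).
#' @param ann A [genome_annotation()].
#' @param window Promoter window around the start codon, bp
#'   (default `c(-1000, 50)`).
#' @return Tibble: `peak_id`, `summit`, `category`, `is_intergenic`
#'   (summit covered by no gene), and list-column `candidates`
#'   (tibbles `locus_id`, `distance` of genes whose start lies within the
#'   window, nearest first).
#' @export
classify_peaks <- function(peaks, ann, window = c(-1000, 50)) {
  if (nrow(peaks) == 0) {
    return(tibble::tibble(peak_id = character(), summit = integer(),
                          category = character(), is_intergenic = logical(),
                          candidates = list()))
  }
  purrr::map_dfr(seq_len(nrow(peaks)), function(i) {
    s0 <- peaks$summit[i]
    d <- summit_to_start_distance(s0, ann$start, ann$end, ann$strand)
    inside <- summit_in_gene(s0, ann)
    in_window <- which(d >= window[1] & d <= window[2])
    cand <- tibble::tibble(locus_id = ann$locus_id[in_window],
                           strand = ann$strand[in_window],
                           distance = d[in_window])
    cand <- dplyr::arrange(cand, abs(.data$distance))
    is_intergenic <- length(inside) == 0
    category <- if (length(inside) > 0 &&
                      any(ann$kind[inside] %in% c("rRNA", "tRNA"))) {
      "rna_locus"
    } else if (is_intergenic && nrow(cand) >= 2 &&
                 dplyr::n_distinct(cand$strand) == 2) {
      "intergenic_divergent"
    } else if (is_intergenic && nrow(cand) >= 1) {
      "intergenic_upstream"
    } else if (!is_intergenic && nrow(cand) >= 1 &&
                 any(!cand$locus_id %in% ann$locus_id[inside])) {
      "intragenic_upstream"
    } else {
      "intragenic"
    }
    if (category == "intergenic_divergent") {
      # one candidate per strand: the nearer start on each side
      cand <- dplyr::slice_head(dplyr::group_by(cand, .data$strand), n = 1)
      cand <- dplyr::arrange(dplyr::ungroup(cand), abs(.data$distance))
    }
    tibble::tibble(peak_id = peaks$peak_id[i], summit = s0,
                   category = category, is_intergenic = is_intergenic,
                   candidates = list(cand))
  })
}

#' Infer operons from gene spacing and expression similarity
#'
#' Genes belong to one operon when they are adjacent, on the same strand,
#' separated by fewer than `max_gap` bp, and expressed to a similar extent
#' (|difference in log2 expression| at most `max_expr_delta` between
#' neighbours). Maximal such runs of two or more genes are reported;
#' singletons are not operons.
#'
#' @param ann A [genome_annotation()].
#' @param expression Tibble `locus_id`/`level` (e.g. mean RPKM) or a named
#'   numeric vector; levels are offset by 0.5 before taking logs.
#' @param max_gap Gap threshold, bp (gaps must be strictly smaller).
#' @param max_expr_delta Expression-similarity threshold, log2 units.
#' @return Tibble `operon_id`, `locus_id`, `position_in_operon` (1 = first
#'   gene in transcription order), `role` (`first_in_operon`/`in_operon`).
#' @export
infer_operons <- function(ann, expression, max_gap = 50,
                          max_expr_delta = 1) {
  if (is.data.frame(expression)) {
    expr <- stats::setNames(expression$level, expression$locus_id)
  } else {
    expr <- expression
  }
  if (!all(ann$locus_id %in% names(expr))) {
    stop("expression levels missing for some genes")
  }
  lev <- log2(expr[ann$locus_id] + 0.5)
  n <- nrow(ann)
  if (n < 2) {
    return(tibble::tibble(operon_id = character(), locus_id = character(),
                          position_in_operon = integer(), role = character()))
  }
  gap <- ann$start[-1] - ann$end[-n] - 1L
  link <- ann$strand[-1] == ann$strand[-n] &
    gap < max_gap &
    abs(lev[-1] - lev[-n]) <= max_expr_delta
  run_id <- cumsum(c(1L, !link))
  runs <- split(seq_len(n), run_id)
  runs <- runs[lengths(runs) >= 2]
  if (length(runs) == 0) {
    return(tibble::tibble(operon_id = character(), locus_id = character(),
                          position_in_operon = integer(), role = character()))
  }
  purrr::imap_dfr(unname(runs), function(idx, i) {
    if (ann$strand[idx[1]] == "-") idx <- rev(idx)  # transcription order
    tibble::tibble(
      operon_id = sprintf("op_%03d", i),
      locus_id = ann$locus_id[idx],
      position_in_operon = seq_along(idx),
      role = c("first_in_operon", rep("in_operon", length(idx) - 1L)))
  })
}

operon_roles <- function(locus_ids, operons) {
  role <- rep("single", length(locus_ids))
  i <- match(locus_ids, operons$locus_id)
  hit <- !is.na(i)
  role[hit] <- operons$role[i[hit]]
  role
}

#' Assign direct / indirect regulation to DEGs
#'
#' The core cross-referencing step: a DEG whose operon role is `single` or
#' `first_in_operon` and which has a peak summit at a signed distance
#' within the promoter window of its start codon is *direct*; a DEG inside
#' an operon whose first gene is direct is *direct_via_operon*; every other
#' DEG is *indirect*. A divergent peak can make both flanking DEGs direct.
#' When motif hits are supplied, each direct record carries the best hit
#' found in its peak (dyad hits preferred, then lowest p-value).
#'
#' @param peaks_ctx Output of [classify_peaks()].
#' @param degs A `deg_results` tibble (only rows with `mode != "none"` are
#'   assigned).
#' @param operons Output of [infer_operons()].
#' @param ann A [genome_annotation()].
#' @param window Promoter window, bp.
#' @param motif_hits Optional tibble `peak_id`, `matched`, `p`, `kind`
#'   (`"dyad"` or `"pwm"`).
#' @return A tibble of class `regulon`: `locus_id`, `peak_id`, `distance`,
#'   `operon_role`, `log2fc`, `mode`, `matched_site`, `regulation`.
#' @export
assign_regulation <- function(peaks_ctx, degs, operons, ann,
                              window = c(-1000, 50), motif_hits = NULL) {
  deg <- degs[degs$mode != "none", ]
  missing <- setdiff(deg$locus_id, ann$locus_id)
  if (length(missing) > 0) {
    stop("DEG loci absent from the annotation: ",
         paste(missing, collapse = ", "))
  }
  best_site <- function(pid) {
    if (is.null(motif_hits)) return(NA_character_)
    h <- motif_hits[motif_hits$peak_id == pid, ]
    if (nrow(h) == 0) return(NA_character_)
    h <- dplyr::arrange(h, .data$kind != "dyad", .data$p)
    h$matched[1]
  }
  role <- operon_roles(deg$locus_id, operons)
  gi <- match(deg$locus_id, ann$locus_id)

  rows <- purrr::map_dfr(seq_len(nrow(deg)), function(k) {
    g <- ann[gi[k], ]
    d <- summit_to_start_distance(peaks_ctx$summit, g$start, g$end, g$strand)
    ok <- which(d >= window[1] & d <= window[2])
    if (length(ok) > 0 && role[k] %in% c("single", "first_in_operon")) {
      j <- ok[which.min(abs(d[ok]))]
      tibble::tibble(locus_id = deg$locus_id[k],
                     peak_id = peaks_ctx$peak_id[j], distance = d[j],
                     operon_role = role[k], log2fc = deg$log2fc[k],
                     mode = deg$mode[k],
                     matched_site = best_site(peaks_ctx$peak_id[j]),
                     regulation = "direct")
    } else {
      tibble::tibble(locus_id = deg$locus_id[k], peak_id = NA_character_,
                     distance = NA_real_, operon_role = role[k],
                     log2fc = deg$log2fc[k], mode = deg$mode[k],
                     matched_site = NA_character_, regulation = "indirect")
    }
  })
  # operon expansion: followers of a direct first gene become direct_via_operon
  if (nrow(operons) > 0 && nrow(rows) > 0) {
    direct_first <- rows$locus_id[rows$regulation == "direct" &
                                    rows$operon_role == "first_in_operon"]
    direct_ops <- unique(operons$operon_id[
      operons$locus_id %in% direct_first & operons$role == "first_in_operon"])
    followers <- operons$locus_id[operons$operon_id %in% direct_ops &
                                    operons$role == "in_operon"]
    via <- rows$regulation == "indirect" & rows$locus_id %in% followers
    if (any(via)) {
      first_of <- function(lid) {
        op <- operons$operon_id[match(lid, operons$locus_id)]
        first <- operons$locus_id[operons$operon_id == op &
                                    operons$role == "first_in_operon"]
        rows$peak_id[match(first, rows$locus_id)]
      }
      rows$regulation[via] <- "direct_via_operon"
      rows$peak_id[via] <- vapply(rows$locus_id[via], first_of, character(1))
      rows$matched_site[via] <- vapply(rows$peak_id[via], best_site,
                                       character(1))
    }
  }
  class(rows) <- c("regulon", class(tibble::tibble()))
  attr(rows, "window") <- window
  rows
}

#' @export
print.regulon <- function(x, ...) {
  cat(sprintf("# regulon: %d DEGs -> %d direct, %d direct_via_operon, %d indirect\n",
              nrow(x), sum(x$regulation == "direct"),
              sum(x$regulation == "direct_via_operon"),
              sum(x$regulation == "indirect")))
  NextMethod()
}

#' @rdname assign_regulation
#' @param x A `regulon` tibble.
#' @param ... Unused.
#' @export
tidy.regulon <- function(x, ...) tibble::as_tibble(x)

#' @rdname assign_regulation
#' @export
glance.regulon <- function(x, ...) {
  tibble::tibble(
    n_deg = nrow(x),
    n_direct = sum(x$regulation == "direct"),
    n_direct_via_operon = sum(x$regulation == "direct_via_operon"),
    n_indirect = sum(x$regulation == "indirect"),
    n_direct_activated = sum(x$regulation != "indirect" & x$mode == "activated"),
    n_direct_repressed = sum(x$regulation != "indirect" & x$mode == "repressed"),
    n_distinct_peaks = dplyr::n_distinct(x$peak_id[!is.na(x$peak_id)])
  )
}

divergent_pair_count <- function(records, ann) {
  direct <- records[records$regulation == "direct" & !is.na(records$peak_id), ]
  if (nrow(direct) == 0) return(0L)
  direct$strand <- ann$strand[match(direct$locus_id, ann$locus_id)]
  by_peak <- split(direct$strand, direct$peak_id)
  sum(vapply(by_peak, function(s) length(s) >= 2 &&
               dplyr::n_distinct(s) == 2, logical(1)))
}

#' Summarize a regulon
#'
#' Counts direct / operon-expanded / indirect targets, the activated vs
#' repressed split among direct targets, distinct bound regions and
#' divergent pairs, the peak-context histogram, the enrichment of peaks in
#' intergenic sequence against the genome's intergenic fraction (exact
#' one-sided binomial test), and a Mann-Whitney comparison (normal
#' approximation) of summit heights between intergenic and intragenic
#' peaks.
#'
#' @param records A `regulon` tibble from [assign_regulation()].
#' @param peaks_ctx Output of [classify_peaks()]; needs a `height` column
#'   joined from the peaks for the height comparison (optional).
#' @param ann A [genome_annotation()].
#' @return A list of class `regulon_summary`.
#' @export
summarize_regulon <- function(records, peaks_ctx, ann) {
  g <- glance.regulon(records)
  categories <- c("intergenic_upstream", "intergenic_divergent",
                  "intragenic_upstream", "intragenic", "rna_locus")
  cat_counts <- table(factor(peaks_ctx$category, levels = categories))
  n_peaks <- nrow(peaks_ctx)
  x <- sum(peaks_ctx$is_intergenic)
  p0 <- intergenic_fraction(ann)
  enr <- if (n_peaks > 0 && p0 > 0 && p0 < 1) {
    stats::binom.test(x, n_peaks, p0, alternative = "greater")$p.value
  } else {
    NA_real_
  }
  height_p <- NA_real_
  if ("height" %in% names(peaks_ctx)) {
    hi <- peaks_ctx$height[peaks_ctx$is_intergenic]
    ho <- peaks_ctx$height[!peaks_ctx$is_intergenic]
    if (length(hi) > 0 && length(ho) > 0) {
      height_p <- stats::wilcox.test(hi, ho, exact = FALSE,
                                     correct = FALSE)$p.value
      if (is.nan(height_p)) height_p <- 1  # all values tied
    }
  }
  structure(list(
    counts = g,
    n_divergent_pairs = divergent_pair_count(records, ann),
    category_counts = tibble::tibble(category = categories,
                                     n = as.integer(cat_counts)),
    n_peaks = n_peaks,
    n_intergenic_peaks = x,
    intergenic_peak_fraction = if (n_peaks > 0) x / n_peaks else NA_real_,
    genome_intergenic_fraction = p0,
    intergenic_enrichment_p = enr,
    height_mannwhitney_p = height_p),
    class = "regulon_summary")
}

#' @export
print.regulon_summary <- function(x, ...) {
  cat("# regulon summary\n")
  print(x$counts)
  cat(sprintf("divergent pairs: %d\n", x$n_divergent_pairs))
  cat(sprintf("peaks: %d (%d intergenic, %.0f%% vs %.0f%% of genome, enrichment p = %.3g)\n",
              x$n_peaks, x$n_intergenic_peaks,
              100 * x$intergenic_peak_fraction,
              100 * x$genome_intergenic_fraction,
              x$intergenic_enrichment_p))
  print(x$category_counts)
  invisible(x)
}

#' @rdname summarize_regulon
#' @param x A `regulon_summary`.
#' @param ... Unused.
#' @export
glance.regulon_summary <- function(x, ...) {
  dplyr::bind_cols(
    x$counts,
    tibble::tibble(
      n_divergent_pairs = x$n_divergent_pairs,
      n_peaks = x$n_peaks,
      intergenic_peak_fraction = x$intergenic_peak_fraction,
      genome_intergenic_fraction = x$genome_intergenic_fraction,
      intergenic_enrichment_p = x$intergenic_enrichment_p,
      height_mannwhitney_p = x$height_mannwhitney_p))
}

#' Three-set Venn region cardinalities
#'
#' @param set_a,set_b,set_c Character vectors of locus identifiers.
#' @return A tibble with the 7 region sizes: `a_only`, `b_only`, `c_only`,
#'   `ab`, `ac`, `bc`, `abc`.
#' @export
venn_counts <- function(set_a, set_b, set_c) {
  a <- unique(set_a); b <- unique(set_b); c_ <- unique(set_c)
  u <- unique(c(a, b, c_))
  ina <- u %in% a; inb <- u %in% b; inc <- u %in% c_
  tibble::tibble(
    a_only = sum(ina & !inb & !inc),
    b_only = sum(!ina & inb & !inc),
    c_only = sum(!ina & !inb & inc),
    ab = sum(ina & inb & !inc),
    ac = sum(ina & !inb & inc),
    bc = sum(!ina & inb & inc),
    abc = sum(ina & inb & inc))
}
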