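#' Infer sample conditions from column names
#'
#' Samples named `wt_*` are wild type, `mut_*` are the deletion strain.
#'
#' @param counts A counts tibble (`locus_id`, `length_bp`, sample columns).
#' @return Tibble with columns `sample`, `condition`.
#' @export
sample_conditions <- function(counts) {
  s <- setdiff(names(counts), c("locus_id", "length_bp"))
  cond <- dplyr::case_when(startsWith(s, "wt") ~ "wt",
                           startsWith(s, "mut") ~ "mutant",
                           TRUE ~ NA_character_)
  if (anyNA(cond)) {
    stop("cannot infer condition for sample(s): ",
         paste(s[is.na(cond)], collapse = ", "),
         "; pass `conditions` explicitly")
  }
  tibble::tibble(sample = s, condition = cond)
}

count_matrix <- function(counts) {
  s <- setdiff(names(counts), c("locus_id", "length_bp"))
  m <- as.matrix(counts[, s])
  rownames(m) <- counts$locus_id
  storage.mode(m) <- "double"
  m
}

#' Median-of-ratios size factors
#'
#' The geometric normalization estimator: each sample's factor is the
#' median, over genes with all-positive counts, of that sample's count
#' divided by the gene's geometric mean across samples. Factors are
#' rescaled to have geometric mean 1, so a sample with twice the depth of
#' another gets twice its factor.
#'
#' @param counts A counts tibble (`locus_id`, `length_bp`, sample columns).
#' @return Named numeric vector of positive per-sample factors.
#' @export
#' @examples
#' cm <- tibble::tibble(locus_id = paste0("g", 1:3), length_bp = 1000,
#'                      a = c(10, 20, 30), b = c(20, 40, 60))
#' size_factors(cm)  # ratio b/a = 2
size_factors <- function(counts) {
  m <- count_matrix(counts)
  pos <- rowSums(m > 0) == ncol(m)
  if (!any(pos)) {
    stop("no gene has positive counts in every sample; ",
         "filter all-zero genes before normalization")
  }
  lg <- log(m[pos, , drop = FALSE])
  geo <- rowMeans(lg)
  f <- apply(exp(lg - geo), 2, stats::median)
  f <- f / exp(mean(log(f)))
  f
}

#' Reads per kilobase per million mapped reads
#'
#' `rpkm = count * 1e9 / (gene length * sample total)`.
#'
#' @param counts A counts tibble (`locus_id`, `length_bp`, sample columns).
#' @return Tibble `locus_id` plus one RPKM column per sample.
#' @export
rpkm <- function(counts) {
  if (any(counts$length_bp <= 0)) stop("gene lengths must be positive")
  m <- count_matrix(counts)
  tot <- colSums(m)
  if (any(tot == 0)) {
    stop("sample(s) with zero total counts: ",
         paste(colnames(m)[tot == 0], collapse = ", "))
  }
  r <- sweep(m * 1e9 / counts$length_bp, 2, tot, "/")
  dplyr::bind_cols(tibble::tibble(locus_id = counts$locus_id),
                   tibble::as_tibble(r))
}

#' Negative-binomial Wald test for differential expression
#'
#' Tests each gene for a difference between mutant and wild-type normalized
#' means. Genes whose mean normalized count is below `min_count` in both
#' conditions are not tested (`p = 1`, `log2fc = 0`). For tested genes the
#' per-gene dispersion is estimated by the method of moments within each
#' condition (floored at `dispersion_floor`), the log2 fold change is
#' `log2(mutant mean / wt mean)` of normalized counts (a pseudocount of 0.5
#' normalized units is applied when either mean is zero), and the Wald
#' statistic `log2fc / SE(log2fc)` is referred to a standard normal.
#'
#' @param counts A counts tibble (`locus_id`, `length_bp`, sample columns).
#' @param conditions Tibble `sample`/`condition` (`"wt"`/`"mutant"`);
#'   inferred from sample names by default.
#' @param min_count Minimum mean normalized count for a gene to be tested.
#' @param dispersion_floor Lower bound on the moment dispersion estimate.
#' @return Tibble with columns `locus_id`, `mean_wt`, `mean_mut`, `log2fc`,
#'   `se`, `stat`, `p`, `tested`.
#' @export
test_differential <- function(counts, conditions = sample_conditions(counts),
                              min_count = 10, dispersion_floor = 0.01) {
  m <- count_matrix(counts)
  cond <- conditions$condition[match(colnames(m), conditions$sample)]
  if (anyNA(cond)) stop("conditions missing for some samples")
  for (cc in c("wt", "mutant")) {
    if (sum(cond == cc) < 2) stop("need >= 2 replicates in condition ", cc)
  }
  f <- size_factors(counts)
  norm <- sweep(m, 2, f, "/")
  wt <- norm[, cond == "wt", drop = FALSE]
  mut <- norm[, cond == "mutant", drop = FALSE]
  n_wt <- ncol(wt); n_mut <- ncol(mut)
  m_wt <- rowMeans(wt); m_mut <- rowMeans(mut)
  v_wt <- apply(wt, 1, stats::var); v_mut <- apply(mut, 1, stats::var)

  tested <- m_wt >= min_count | m_mut >= min_count
  alpha_of <- function(mu, v) ifelse(mu > 0, (v - mu) / mu^2, NA_real_)
  a1 <- alpha_of(m_wt, v_wt); a2 <- alpha_of(m_mut, v_mut)
  alpha <- pmax(apply(cbind(a1, a2), 1, max, na.rm = TRUE), dispersion_floor)

  pc <- ifelse(m_wt == 0 | m_mut == 0, 0.5, 0)
  log2fc <- log2((m_mut + pc) / (m_wt + pc))
  vlog <- function(mu, n) (1 / pmax(mu, 0.5) + alpha) / n
  se <- sqrt(vlog(m_wt, n_wt) + vlog(m_mut, n_mut)) / log(2)
  stat <- log2fc / se
  p <- 2 * stats::pnorm(-abs(stat))

  out <- tibble::tibble(
    locus_id = counts$locus_id,
    mean_wt = unname(m_wt), mean_mut = unname(m_mut),
    log2fc = unname(ifelse(tested, log2fc, 0)),
    se = unname(ifelse(tested, se, NA_real_)),
    stat = unname(ifelse(tested, stat, NA_real_)),
    p = unname(ifelse(tested, p, 1)),
    tested = unname(tested)
  )
  out
}

#' Call differentially expressed genes
#'
#' Applies Benjamini-Hochberg correction over the tested genes and labels
#' each gene's regulation mode. A gene is a DEG when `|log2fc| >=
#' lfc_threshold` and `q < q_threshold` (the default 1.32 corresponds to a
#' 2.5-fold change). The sign convention follows the deletion-strain
#' contrast: `activated` means expression is *lower* without the factor
#' (`log2fc < 0`), `repressed` means higher (`log2fc > 0`).
#'
#' @param records Output of [test_differential()].
#' @param lfc_threshold Minimum absolute log2 fold change.
#' @param q_threshold BH-adjusted p-value cutoff.
#' @return The input tibble with columns `q` and `mode`
#'   (`activated`/`repressed`/`none`), of class `deg_results`.
#' @export
call_degs <- function(records, lfc_threshold = 1.32, q_threshold = 0.05) {
  stopifnot(all(records$p >= 0 & records$p <= 1))
  q <- rep(NA_real_, nrow(records))
  q[records$tested] <- stats::p.adjust(records$p[records$tested], method = "BH")
  q[!records$tested] <- 1
  deg <- abs(records$log2fc) >= lfc_threshold & q < q_threshold
  mode <- dplyr::case_when(deg & records$log2fc < 0 ~ "activated",
                           deg & records$log2fc > 0 ~ "repressed",
                           TRUE ~ "none")
  out <- dplyr::mutate(records, q = q, mode = mode)
  class(out) <- c("deg_results", class(tibble::tibble()))
  attr(out, "lfc_threshold") <- lfc_threshold
  attr(out, "q_threshold") <- q_threshold
  out
}

#' @export
print.deg_results <- function(x, ...) {
  cat(sprintf("# deg_results: %d genes, %d tested, %d DEGs (%d activated, %d repressed)\n",
              nrow(x), sum(x$tested), sum(x$mode != "none"),
              sum(x$mode == "activated"), sum(x$mode == "repressed")))
  NextMethod()
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname call_degs
#' @param x A `deg_results` object.
#' @param ... Unused.
#' @export
tidy.deg_results <- function(x, ...) {
  tibble::as_tibble(x)[, c("locus_id", "log2fc", "p", "q", "mode")]
}

#' @rdname call_degs
#' @export
glance.deg_results <- function(x, ...) {
  tibble::tibble(
    n_genes = nrow(x), n_tested = sum(x$tested),
    n_deg = sum(x$mode != "none"),
    n_activated = sum(x$mode == "activated"),
    n_repressed = sum(x$mode == "repressed"),
    lfc_threshold = attr(x, "lfc_threshold"),
    q_threshold = attr(x, "q_threshold")
  )
}

#' Read / write DEG reports and counts
#'
#' The counts TSV has a header row of sample names after `locus_id` and
#' `length_bp`; the DEG report carries `locus_id`, `log2fc`, `p`, `q`,
#' `mode`.
#'
#' @param path File path.
#' @return `read_counts()` returns a counts tibble; `write_deg_report()`
#'   returns `path` invisibly.
#' @export
read_counts <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' @rdname read_counts
#' @param degs A `deg_results` tibble.
#' @export
write_deg_report <- function(degs, path) {
  readr::write_tsv(tidy.deg_results(degs), path)
  invisible(path)
}
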