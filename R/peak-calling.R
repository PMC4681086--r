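#' @keywords internal
#' Upper-tail Poisson p-value, P(X >= count | lambda)
poisson_tail_p <- function(count, lambda) {
  stats::ppois(count - 1, lambda, lower.tail = FALSE)
}

# Sliding-window sums of a per-base track at the caller's tiling.
window_sums <- function(track, starts0, width) {
  cs <- c(0, cumsum(track))
  cs[starts0 + width + 1L] - cs[starts0 + 1L]
}

# Centred window mean per bp, clipped at the genome ends.
centred_mean <- function(track, centres0, half) {
  cs <- c(0, cumsum(track))
  L <- length(track)
  lo <- pmax(centres0 - half, 0L)
  hi <- pmin(centres0 + half, L)
  (cs[hi + 1L] - cs[lo + 1L]) / (hi - lo)
}

merge_windows_to_peaks <- function(sig_starts, width, ip, p_window, expected_bg) {
  if (length(sig_starts) == 0) {
    return(tibble::tibble(peak_id = character(), start = integer(),
                          end = integer(), summit = integer(),
                          height = numeric(), p = numeric(),
                          fold_enrichment = numeric()))
  }
  ir <- IRanges::reduce(IRanges::IRanges(sig_starts + 1L, sig_starts + width))
  win <- IRanges::IRanges(sig_starts + 1L, sig_starts + width)
  hits <- IRanges::findOverlaps(win, ir)
  purrr::map_dfr(seq_along(ir), function(i) {
    s1 <- BiocGenerics::start(ir)[i]; e1 <- BiocGenerics::end(ir)[i]
    seg <- ip[s1:e1]
    summit0 <- s1 - 1L + which.max(seg) - 1L  # leftmost maximum
    idx <- S4Vectors::queryHits(hits)[S4Vectors::subjectHits(hits) == i]
    bg <- max(mean(expected_bg[idx]), 1e-9)
    tibble::tibble(
      peak_id = NA_character_, start = s1 - 1L, end = e1,
      summit = summit0, height = max(seg), p = min(p_window[idx]),
      fold_enrichment = max(seg) / bg)
  })
}

#' Call peaks with a local Poisson background
#'
#' A MACS-style caller: the input track is scaled to the IP depth, and for
#' each 300 bp window (75 bp step) the local background rate is the maximum
#' of the genome-wide mean and the 1 kb / 5 kb / 10 kb input means centred
#' on the window. Window coverage sums are converted to fragment counts
#' (divided by `fragment_size`), and a window is significant when the
#' upper-tail Poisson probability of its IP count is at most `p_cutoff`.
#' Overlapping significant windows are merged; the summit is the leftmost
#' per-base IP maximum of the merged region.
#'
#' @param ip,input Per-base coverage vectors of equal length.
#' @param p_cutoff Poisson p-value cutoff (default 1e-5).
#' @param window Window width in bp.
#' @param step Window step in bp.
#' @param fragment_size Fragment length used to convert coverage to counts.
#' @return A tibble of peaks: `peak_id`, `start`, `end` (0-based half-open),
#'   `summit` (0-based), `height`, `p_poisson`, `fold_enrichment`.
#' @export
call_peaks_poisson <- function(ip, input, p_cutoff = 1e-5, window = 300L,
                               step = 75L, fragment_size = 150L) {
  if (length(ip) != length(input)) stop("ip and input track lengths differ")
  if (sum(input) <= 0) stop("input track has no signal")
  L <- length(ip)
  r <- sum(ip) / sum(input)
  starts0 <- seq.int(0L, L - window, by = step)
  centres0 <- starts0 + window %/% 2L
  ip_count <- window_sums(ip, starts0, window) / fragment_size
  bg_global <- r * mean(input)
  bg_local <- pmax(bg_global,
                   r * centred_mean(input, centres0, 500L),
                   r * centred_mean(input, centres0, 2500L),
                   r * centred_mean(input, centres0, 5000L))
  lambda <- bg_local * window / fragment_size
  p_window <- poisson_tail_p(ceiling(ip_count), lambda)
  sig <- which(p_window <= p_cutoff)
  pk <- merge_windows_to_peaks(starts0[sig], window, ip,
                               p_window[sig], bg_local[sig])
  pk <- dplyr::rename(pk, p_poisson = "p")
  pk$peak_id <- sprintf("peak_%03d", seq_len(nrow(pk)))
  pk
}

# GC fraction of tiling windows from the genome sequence
window_gc <- function(sequence, starts0, width) {
  gc <- as.integer(strsplit(sequence, "", fixed = TRUE)[[1]] %in% c("G", "C"))
  window_sums(gc, starts0, width) / width
}

#' Call peaks with a GC-stratified negative-binomial background
#'
#' A MOSAiCS-style caller: tiling windows are stratified into `gc_bins`
#' quantile bins of GC content, and within each bin a negative-binomial
#' background is fitted to the depth-scaled input window counts by the
#' method of moments (degenerating to Poisson when the variance does not
#' exceed the mean). A window is significant when the upper-tail NB
#' probability of its IP count under its bin's background is at most
#' `p_cutoff`; merging and summit selection are as in
#' [call_peaks_poisson()]. Bins with fewer than 20 windows are merged with
#' the nearest bin (with a warning).
#'
#' @inheritParams call_peaks_poisson
#' @param sequence Genome nucleotide string (for window GC content).
#' @param gc_bins Number of GC strata.
#' @return A tibble of peaks with `p_nb` in place of `p_poisson`.
#' @export
call_peaks_nb_gc <- function(ip, input, sequence, p_cutoff = 1e-5,
                             gc_bins = 10L, window = 300L, step = 75L,
                             fragment_size = 150L) {
  if (length(ip) != length(input)) stop("ip and input track lengths differ")
  if (nchar(sequence) != length(ip)) stop("sequence length != track length")
  L <- length(ip)
  r <- sum(ip) / sum(input)
  starts0 <- seq.int(0L, L - window, by = step)
  ip_count <- window_sums(ip, starts0, window) / fragment_size
  in_count <- r * window_sums(input, starts0, window) / fragment_size
  gc <- window_gc(sequence, starts0, window)

  br <- unique(stats::quantile(gc, probs = seq(0, 1, length.out = gc_bins + 1)))
  bin <- if (length(br) > 2) {
    cut(gc, breaks = br, include.lowest = TRUE, labels = FALSE)
  } else {
    rep(1L, length(gc))
  }
  # merge sparse bins into their nearest neighbour
  repeat {
    tab <- table(bin)
    small <- names(tab)[tab < 20]
    if (length(small) == 0 || length(tab) == 1) break
    b <- as.integer(small[1])
    others <- as.integer(setdiff(names(tab), small[1]))
    nb <- others[which.min(abs(others - b))]
    warning("GC bin ", b, " has < 20 windows; merged with bin ", nb)
    bin[bin == b] <- nb
  }

  p_window <- rep(1, length(starts0))
  bg_mean <- rep(mean(in_count), length(starts0))
  for (b in unique(bin)) {
    idx <- which(bin == b)
    m <- mean(in_count[idx]); v <- stats::var(in_count[idx])
    bg_mean[idx] <- m
    if (is.na(v) || v <= m) {
      p_window[idx] <- poisson_tail_p(ceiling(ip_count[idx]), m)
    } else {
      size <- m^2 / (v - m)
      p_window[idx] <- stats::pnbinom(ceiling(ip_count[idx]) - 1, mu = m,
                                      size = size, lower.tail = FALSE)
    }
  }
  sig <- which(p_window <= p_cutoff)
  pk <- merge_windows_to_peaks(starts0[sig], window, ip, p_window[sig],
                               bg_mean[sig] / window * fragment_size)
  pk <- dplyr::rename(pk, p_nb = "p")
  pk$peak_id <- sprintf("nbpeak_%03d", seq_len(nrow(pk)))
  pk
}

#' Intersect two peak calls
#'
#' Retains peaks from `a` that overlap (by at least 1 bp) any peak in `b`,
#' mirroring the "called by both callers" rule. The retained peaks keep
#' caller A's interval, summit and p-value and gain the best (smallest)
#' overlapping p-value from caller B.
#'
#' @param a Peaks from [call_peaks_poisson()].
#' @param b Peaks from [call_peaks_nb_gc()].
#' @return A tibble like `a` with an added `p_nb` column, sorted by `start`.
#' @export
consensus_peaks <- function(a, b) {
  if (nrow(a) == 0 || nrow(b) == 0) {
    out <- a[0, ]
    out$p_nb <- numeric(0)
    return(out)
  }
  ia <- IRanges::IRanges(a$start + 1L, a$end)
  ib <- IRanges::IRanges(b$start + 1L, b$end)
  hits <- IRanges::findOverlaps(ia, ib)
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  keep <- sort(unique(qh))
  p_nb <- vapply(keep, function(i) {
    pb <- b$p_nb[sh[qh == i]]
    if (is.null(pb)) NA_real_ else min(pb)
  }, numeric(1))
  out <- a[keep, ]
  out$p_nb <- p_nb
  out <- dplyr::arrange(out, .data$start)
  out
}

#' Write and read peaks in narrowPeak format
#'
#' narrowPeak columns: chrom, start, end, name, score
#' (`round(-10 * log10(p))`, capped), strand ".", signalValue
#' (fold enrichment), pValue (-log10), qValue (-1), peak (summit - start).
#'
#' @param peaks A peaks tibble.
#' @param path File path.
#' @param seqname Sequence name.
#' @return `path` invisibly; `read_narrowpeak()` returns a peaks tibble.
#' @export
write_narrowpeak <- function(peaks, path, seqname = "chr") {
  p <- if ("p_poisson" %in% names(peaks)) peaks$p_poisson else peaks$p_nb
  lp <- -log10(pmax(p, 1e-300))
  df <- data.frame(
    chrom = seqname, start = peaks$start, end = peaks$end,
    name = peaks$peak_id, score = pmin(1000L, as.integer(round(10 * lp))),
    strand = ".", signalValue = round(peaks$fold_enrichment, 4),
    pValue = round(lp, 4), qValue = -1, peak = peaks$summit - peaks$start)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_narrowpeak
#' @export
read_narrowpeak <- function(path) {
  df <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE,
                          col.names = c("chrom", "start", "end", "name",
                                        "score", "strand", "signalValue",
                                        "pValue", "qValue", "peak"))
  tibble::tibble(
    peak_id = df$name, start = df$start, end = df$end,
    summit = df$start + df$peak, height = NA_real_,
    p_poisson = 10^(-df$pValue), fold_enrichment = df$signalValue)
}
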