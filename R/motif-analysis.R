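BASES <- c("A", "C", "G", "T")

#' Reverse complement of a nucleotide string
#' @param x Nucleotide string (ACGT).
#' @return Reverse complement string.
#' @export
revcomp <- function(x) {
  comp <- chartr("ACGTacgt", "TGCAtgca", x)
  vapply(strsplit(comp, "", fixed = TRUE), function(ch) {
    paste(rev(ch), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

seq_to_idx <- function(seq) {
  idx <- match(strsplit(toupper(seq), "", fixed = TRUE)[[1]], BASES)
  if (anyNA(idx)) stop("sequence contains non-ACGT characters")
  idx
}

#' Build a position weight matrix from aligned sites
#'
#' Column probabilities are `(count + pseudocount) / (n + 4 * pseudocount)`.
#' The background defaults to uniform; pass the genome mononucleotide
#' frequencies for a composition-aware model (recommended on high-GC
#' genomes, where a uniform background overstates AT-rich matches).
#'
#' @param sites Character vector of >= 2 equal-length ACGT sequences,
#'   pre-aligned.
#' @param pseudocount Added to every base count per column.
#' @param background Optional probability 4-vector (A, C, G, T order).
#' @return A list of class `pwm` with elements `mat` (4 x width probability
#'   matrix, rows A/C/G/T), `background`, `pseudocount`.
#' @export
build_pwm <- function(sites, pseudocount = 0.5, background = NULL) {
  if (length(sites) < 2) stop("need at least 2 sites")
  w <- unique(nchar(sites))
  if (length(w) != 1) stop("sites must have equal length")
  mat <- matrix(0, nrow = 4, ncol = w, dimnames = list(BASES, NULL))
  for (s in sites) {
    idx <- seq_to_idx(s)
    for (j in seq_len(w)) mat[idx[j], j] <- mat[idx[j], j] + 1
  }
  mat <- sweep(mat + pseudocount, 2, length(sites) + 4 * pseudocount, "/")
  if (is.null(background)) background <- rep(0.25, 4)
  if (abs(sum(background) - 1) > 1e-6) stop("background must sum to 1")
  structure(list(mat = mat, background = stats::setNames(background, BASES),
                 pseudocount = pseudocount),
            class = "pwm")
}

#' Background base frequencies of a sequence
#' @param sequence Nucleotide string.
#' @return Probability 4-vector in A, C, G, T order.
#' @export
base_frequencies <- function(sequence) {
  tab <- table(factor(strsplit(toupper(sequence), "", fixed = TRUE)[[1]],
                      levels = BASES))
  as.vector(tab / sum(tab))
}

pwm_int_scores <- function(pwm, resolution) {
  lo <- log2(pwm$mat / pwm$background)
  lo[!is.finite(lo)] <- -100  # impossible base under pseudocount 0
  round(lo / resolution)
}

#' Exact p-value calibration of a PWM
#'
#' Computes, by column-wise convolution over the background distribution,
#' the exact null distribution of the log-odds score discretized at
#' `resolution` bits. The returned table maps each achievable score to
#' `P(S >= score)` for a background-random sequence of the motif's width.
#'
#' @param pwm A [build_pwm()] object.
#' @param resolution Score discretization, bits.
#' @return A list of class `pwm_pvalues`: `table` (tibble `score`, `p`,
#'   sorted by score), `min_int`, `p_tail`, `resolution`.
#' @export
pwm_pvalue_table <- function(pwm, resolution = 0.001) {
  ints <- pwm_int_scores(pwm, resolution)
  bg <- pwm$background
  # distribution over integer score sums
  dist <- c(1)
  offset <- 0L  # integer score of dist[1]
  for (j in seq_len(ncol(ints))) {
    col <- ints[, j]
    lo <- offset + min(col)
    hi <- offset + length(dist) - 1L + max(col)
    new <- numeric(hi - lo + 1L)
    for (k in 1:4) {
      sh <- offset + col[k] - lo
      idx <- seq_along(dist) + sh
      new[idx] <- new[idx] + dist * bg[k]
    }
    dist <- new
    offset <- lo
  }
  p_tail <- rev(cumsum(rev(dist)))
  p_tail <- pmin(p_tail, 1)
  scores <- (offset + seq_along(dist) - 1L) * resolution
  keep <- dist > 0
  structure(list(
    table = tibble::tibble(score = scores[keep], p = p_tail[keep]),
    min_int = offset, p_tail = p_tail, resolution = resolution),
    class = "pwm_pvalues")
}

pwm_lookup_p <- function(tab, int_score) {
  i <- int_score - tab$min_int + 1L
  i <- pmin(pmax(i, 1L), length(tab$p_tail))
  out <- tab$p_tail[i]
  out[int_score > tab$min_int + length(tab$p_tail) - 1L] <- 0
  out[int_score < tab$min_int] <- 1
  out
}

rc_pwm <- function(pwm) {
  mat <- pwm$mat[4:1, ncol(pwm$mat):1, drop = FALSE]
  rownames(mat) <- BASES
  bg <- pwm$background[4:1]
  names(bg) <- BASES
  structure(list(mat = mat, background = bg, pseudocount = pwm$pseudocount),
            class = "pwm")
}

scan_one_strand <- function(ints, idx) {
  w <- ncol(ints)
  n <- length(idx) - w + 1L
  if (n < 1) return(integer(0))
  sc <- integer(n)
  for (j in seq_len(w)) {
    sc <- sc + unname(ints[, j])[idx[seq_len(n) + j - 1L]]
  }
  sc
}

#' Scan a sequence with a PWM
#'
#' Scores every position on both strands against the exact null
#' distribution and reports positions whose per-position p-value is at most
#' `p_threshold`. Minus-strand hits are reported at the forward coordinate
#' of their leftmost matched base, with `matched` given as read on the
#' minus strand.
#'
#' @param pwm A [build_pwm()] object.
#' @param seq Nucleotide string, length >= motif width.
#' @param p_threshold Per-position p-value cutoff.
#' @param pvalues Optional precomputed [pwm_pvalue_table()] (computed if
#'   missing; the minus strand reuses the same calibration when the
#'   background is strand-symmetric, and is recalibrated otherwise).
#' @return Tibble of hits: `position` (0-based), `strand`, `matched`,
#'   `score` (bits), `p`.
#' @export
scan_pwm <- function(pwm, seq, p_threshold = 0.01, pvalues = NULL) {
  w <- ncol(pwm$mat)
  if (nchar(seq) < w) stop("sequence shorter than motif width")
  if (is.null(pvalues)) pvalues <- pwm_pvalue_table(pwm)
  res <- pvalues$resolution
  idx <- seq_to_idx(seq)
  hits <- list()
  sym <- isTRUE(all.equal(unname(pwm$background),
                          unname(pwm$background[4:1])))
  for (str in c("+", "-")) {
    m <- if (str == "+") pwm else rc_pwm(pwm)
    tab <- if (str == "+" || sym) pvalues else pwm_pvalue_table(m, res)
    sc <- scan_one_strand(pwm_int_scores(m, res), idx)
    p <- pwm_lookup_p(tab, sc)
    sel <- which(p <= p_threshold)
    if (length(sel) > 0) {
      matched <- substring(seq, sel, sel + w - 1L)
      if (str == "-") matched <- vapply(matched, revcomp, character(1))
      hits[[str]] <- tibble::tibble(
        position = sel - 1L, strand = str, matched = unname(matched),
        score = sc[sel] * res, p = p[sel])
    }
  }
  out <- dplyr::bind_rows(hits)
  if (nrow(out) == 0) {
    out <- tibble::tibble(position = integer(), strand = character(),
                          matched = character(), score = numeric(),
                          p = numeric())
  }
  dplyr::arrange(out, .data$position, .data$strand)
}

#' Spaced-dyad motif specification
#'
#' Two conserved half-sites separated by an unconstrained spacer, e.g. the
#' CRP-family palindrome TGTGA-N6-TCACA (16 bp) or its relaxed cores
#' GTG-N8-CAC and GTG-N10-CAC.
#'
#' @param left,right Half-site words over ACGT.
#' @param spacers Integer vector of allowed spacer lengths.
#' @return A list of class `dyad_spec` with a `widths` field
#'   (`nchar(left) + spacer + nchar(right)` per spacer).
#' @export
dyad_spec <- function(left = "TGTGA", right = "TCACA", spacers = 6L) {
  left <- toupper(left); right <- toupper(right)
  if (!grepl("^[ACGT]+$", left) || !grepl("^[ACGT]+$", right)) {
    stop("half-sites must be ACGT words")
  }
  spacers <- as.integer(spacers)
  if (any(spacers < 0)) stop("spacers must be >= 0")
  structure(list(left = left, right = right, spacers = spacers,
                 widths = nchar(left) + spacers + nchar(right)),
            class = "dyad_spec")
}

dyad_find <- function(pattern_left, pattern_right, s, seq) {
  pat <- paste0("(?=", pattern_left, "[ACGT]{", s, "}", pattern_right, ")")
  m <- gregexpr(pat, seq, perl = TRUE)[[1]]
  if (m[1] == -1) integer(0) else as.integer(m)
}

#' Scan a sequence for a spaced dyad
#'
#' Exact-match search for `left . N^s . right` for every allowed spacer
#' `s`, on both strands; overlapping hits are all reported. For a
#' palindromic dyad (one whose reverse complement has the same half-sites)
#' every forward hit has a mirror minus-strand hit over the same interval.
#'
#' @param spec A [dyad_spec()].
#' @param seq Nucleotide string.
#' @return Tibble of hits: `position` (0-based, leftmost matched base on
#'   the forward strand), `strand`, `matched` (as read on the hit strand),
#'   `spacer`, `width`.
#' @export
scan_dyad <- function(spec, seq) {
  seq <- toupper(seq)
  hits <- list()
  for (s in spec$spacers) {
    w <- nchar(spec$left) + s + nchar(spec$right)
    fwd <- dyad_find(spec$left, spec$right, s, seq)
    if (length(fwd) > 0) {
      hits[[length(hits) + 1L]] <- tibble::tibble(
        position = fwd - 1L, strand = "+",
        matched = substring(seq, fwd, fwd + w - 1L), spacer = s, width = w)
    }
    rev_ <- dyad_find(revcomp(spec$right), revcomp(spec$left), s, seq)
    if (length(rev_) > 0) {
      hits[[length(hits) + 1L]] <- tibble::tibble(
        position = rev_ - 1L, strand = "-",
        matched = vapply(substring(seq, rev_, rev_ + w - 1L), revcomp,
                         character(1), USE.NAMES = FALSE),
        spacer = s, width = w)
    }
  }
  out <- dplyr::bind_rows(hits)
  if (length(hits) == 0) {
    out <- tibble::tibble(position = integer(), strand = character(),
                          matched = character(), spacer = integer(),
                          width = integer())
  }
  dplyr::arrange(out, .data$position, .data$strand)
}

IUPAC2 <- c(AC = "M", AG = "R", AT = "W", CG = "S", CT = "Y", GT = "K")

#' Consensus string and information content of aligned sites
#'
#' Per column, the majority base is reported, or the two-base IUPAC
#' ambiguity code when the top two base frequencies are within 0.10 of each
#' other. Information content is `2 + sum(f * log2(f))` bits per column
#' (0 log 0 taken as 0), so a fully conserved column carries 2 bits.
#'
#' @param sites Character vector of equal-length aligned ACGT sequences.
#' @return A list with `consensus` (string, same length as the sites) and
#'   `information` (numeric bits per column).
#' @export
consensus_from_sites <- function(sites) {
  w <- unique(nchar(sites))
  if (length(w) != 1) stop("sites must have equal length")
  mat <- vapply(sites, seq_to_idx, integer(w))
  if (w == 1) mat <- matrix(mat, nrow = 1)
  cons <- character(w); ic <- numeric(w)
  for (j in seq_len(w)) {
    f <- tabulate(mat[j, ], nbins = 4) / length(sites)
    ord <- order(f, decreasing = TRUE)
    if (f[ord[2]] > 0 && f[ord[1]] - f[ord[2]] <= 0.10) {
      pair <- paste(sort(BASES[ord[1:2]]), collapse = "")
      cons[j] <- IUPAC2[[pair]]
    } else {
      cons[j] <- BASES[ord[1]]
    }
    fz <- f[f > 0]
    ic[j] <- 2 + sum(fz * log2(fz))
  }
  list(consensus = paste(cons, collapse = ""), information = ic)
}

#' Export / import a PWM in MEME minimal text format
#'
#' @param pwm A [build_pwm()] object.
#' @param path File path.
#' @param name Motif name.
#' @return `path` invisibly; `read_meme_pwm()` returns a `pwm`.
#' @export
write_meme_pwm <- function(pwm, path, name = "motif") {
  w <- ncol(pwm$mat)
  lines <- c(
    "MEME version 4", "",
    "ALPHABET= ACGT", "",
    sprintf("Background letter frequencies"),
    sprintf("A %.5f C %.5f G %.5f T %.5f", pwm$background[1],
            pwm$background[2], pwm$background[3], pwm$background[4]), "",
    sprintf("MOTIF %s", name),
    sprintf("letter-probability matrix: alength= 4 w= %d", w),
    apply(t(pwm$mat), 1, function(r) sprintf(" %.6f %.6f %.6f %.6f",
                                             r[1], r[2], r[3], r[4])))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_meme_pwm
#' @export
read_meme_pwm <- function(path) {
  lines <- readLines(path)
  bg <- rep(0.25, 4)
  bgl <- grep("^A [0-9.]+ C", lines)
  if (length(bgl) > 0) {
    v <- as.numeric(strsplit(trimws(lines[bgl[1]]), "\\s+")[[1]][c(2, 4, 6, 8)])
    if (!anyNA(v)) bg <- v
  }
  hdr <- grep("letter-probability matrix", lines)
  if (length(hdr) == 0) stop("no letter-probability matrix in ", path)
  w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", lines[hdr[1]]))
  rows <- lines[(hdr[1] + 1):(hdr[1] + w)]
  mat <- vapply(rows, function(l) {
    as.numeric(strsplit(trimws(l), "\\s+")[[1]])
  }, numeric(4))
  dimnames(mat) <- list(BASES, NULL)
  mat <- sweep(mat, 2, colSums(mat), "/")
  structure(list(mat = mat, background = stats::setNames(bg, BASES),
                 pseudocount = NA_real_), class = "pwm")
}
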