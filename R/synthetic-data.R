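#' Simulation configuration
#'
#' Bundles every tunable of the paired ChIP-seq/RNA-seq simulator. Defaults
#' describe a dense, high-GC bacterial replicon: 200 kb carrying 150 genes
#' (~90% of bases intragenic), 70.5% GC, 60% of genes inside operons whose
#' internal gaps are below 50 bp, 20 planted palindromic dyad binding sites
#' (TGTGA-N6-TCACA) with 8-fold IP enrichment over a Poisson background,
#' and negative-binomial counts for three replicates per condition with
#' planted |log2 fold changes| of 2 on target genes.
#'
#' @param seed Integer seed; all three generators derive their randomness
#'   from it (offsets +1 and +2 for coverage and counts).
#' @param genome_length Replicon length in bp.
#' @param n_genes Number of genes to place.
#' @param gc_content Genome GC fraction.
#' @param intragenic_fraction Target fraction of bases inside genes.
#' @param operon_fraction Fraction of genes placed inside multi-gene operons.
#' @param operon_gap Upper bound (exclusive) on intra-operon gaps, bp.
#' @param n_sites Number of binding sites planted upstream of transcription
#'   units.
#' @param site_left,site_right,site_spacer Dyad half-sites and spacer length
#'   of the planted motif.
#' @param intragenic_site_fraction Fraction of sites planted mid-gene
#'   instead of in promoters (exercises context classification).
#' @param enrichment Expected IP/background coverage ratio at a site summit.
#' @param background_depth Mean fragment starts per bp in the input track.
#' @param fragment_size Sequenced fragment length, bp.
#' @param n_replicates Replicates per condition (>= 2).
#' @param direct_fraction Fraction of site-adjacent transcription units
#'   given a planted expression change.
#' @param lfc_direct Planted |log2 fold change| (mutant vs wild type).
#' @param plant_followers Logical; also plant the fold change on the
#'   downstream genes of a targeted operon (exercises operon expansion,
#'   at the cost of a larger differentially expressed fraction).
#' @param prob_activated Probability a planted target is activated by the
#'   factor (negative log2FC in the deletion strain).
#' @param n_indirect Number of planted differentially expressed genes with
#'   no binding site.
#' @param nb_dispersion Negative-binomial dispersion of counts.
#' @param base_mean Median expected normalized count for a 1 kb gene.
#'
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       genome_length = 200000L,
                       n_genes = 150L,
                       gc_content = 0.705,
                       intragenic_fraction = 0.9,
                       operon_fraction = 0.6,
                       operon_gap = 50L,
                       n_sites = 20L,
                       site_left = "TGTGA",
                       site_right = "TCACA",
                       site_spacer = 6L,
                       intragenic_site_fraction = 0,
                       enrichment = 8,
                       background_depth = 0.5,
                       fragment_size = 150L,
                       n_replicates = 3L,
                       direct_fraction = 1,
                       lfc_direct = 2,
                       plant_followers = FALSE,
                       prob_activated = 0.75,
                       n_indirect = 10L,
                       nb_dispersion = 0.05,
                       base_mean = 150) {
  cfg <- list(
    seed = as.integer(seed), genome_length = as.integer(genome_length),
    n_genes = as.integer(n_genes), gc_content = gc_content,
    intragenic_fraction = intragenic_fraction,
    operon_fraction = operon_fraction, operon_gap = as.integer(operon_gap),
    n_sites = as.integer(n_sites), site_left = site_left,
    site_right = site_right, site_spacer = as.integer(site_spacer),
    intragenic_site_fraction = intragenic_site_fraction,
    enrichment = enrichment, background_depth = background_depth,
    fragment_size = as.integer(fragment_size),
    n_replicates = as.integer(n_replicates),
    direct_fraction = direct_fraction, lfc_direct = lfc_direct,
    plant_followers = isTRUE(plant_followers),
    prob_activated = prob_activated, n_indirect = as.integer(n_indirect),
    nb_dispersion = nb_dispersion, base_mean = base_mean
  )
  fr <- c(cfg$gc_content, cfg$intragenic_fraction, cfg$operon_fraction,
          cfg$intragenic_site_fraction, cfg$direct_fraction,
          cfg$prob_activated)
  if (any(fr < 0 | fr > 1)) stop("fractions must lie in [0, 1]")
  if (cfg$enrichment <= 1) stop("enrichment must exceed 1")
  if (cfg$n_replicates < 2) stop("at least 2 replicates per condition")
  class(cfg) <- "sim_config"
  cfg
}

random_dna <- function(n, gc) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

#' Generate a synthetic annotated genome with planted binding sites
#'
#' Places genes as transcription units (singletons and same-strand operons
#' with gaps below `operon_gap`; units separated by at least 200 bp), draws
#' an i.i.d. nucleotide sequence at the configured GC content, writes the
#' dyad site sequence into the genome at each planted position, and returns
#' the ground truth needed to score every downstream stage.
#'
#' Sites are planted in the intergenic gap upstream of a unit's first gene,
#' at a signed summit-to-start distance within the promoter window, so the
#' unit's first gene is a *direct* target. Every gene of a targeted unit
#' receives the planted fold change (operons are co-transcribed); followers
#' are recorded as `operon_targets`. `n_indirect` further genes, chosen so
#' that no planted site falls in their promoter window, are `indirect_targets`.
#'
#' @param cfg A [sim_config()].
#' @return A list with elements `annotation` (a [genome_annotation()] with
#'   sequence attached) and `truth`, a list with tibbles `sites` (`site_id`,
#'   `position` = 0-based summit, `strand`, `sequence`, `target`),
#'   `direct_targets` (`locus_id`, `lfc`, `site_id`), `operon_targets`,
#'   `indirect_targets`, and `operons` (tibble `operon_id`, `locus_id`,
#'   `position_in_operon`).
#' @export
generate_genome <- function(cfg = sim_config()) {
  set.seed(cfg$seed)
  L <- cfg$genome_length
  n <- cfg$n_genes

  # transcription units: operons of 2-4 genes until the operonic quota is met
  n_op_genes <- round(cfg$operon_fraction * n)
  op_sizes <- integer(0)
  while (sum(op_sizes) < n_op_genes) {
    op_sizes <- c(op_sizes, sample(2:4, 1))
  }
  if (length(op_sizes) > 0) {
    op_sizes[length(op_sizes)] <-
      op_sizes[length(op_sizes)] - (sum(op_sizes) - n_op_genes)
    op_sizes <- op_sizes[op_sizes >= 2]
  }
  unit_sizes <- sample(c(op_sizes, rep(1L, n - sum(op_sizes))))
  n_units <- length(unit_sizes)

  # gene lengths scaled to hit the intragenic target exactly
  target_gene_bp <- round(cfg$intragenic_fraction * L)
  raw <- stats::rgamma(n, shape = 4, rate = 1)
  lens <- pmax(150L, as.integer(round(raw / sum(raw) * target_gene_bp)))
  lens[1] <- lens[1] + (target_gene_bp - sum(lens))
  intra_gaps <- sample(5:min(35L, cfg$operon_gap - 1L),
                       sum(pmax(unit_sizes - 1L, 0L)), replace = TRUE)
  remaining <- L - sum(lens) - sum(intra_gaps)
  min_gap <- 200L
  if (remaining < min_gap * (n_units + 1L)) {
    stop("infeasible packing: ", remaining, " intergenic bp for ",
         n_units + 1L, " inter-unit gaps of >= ", min_gap, " bp")
  }
  extra <- as.vector(stats::rmultinom(1, remaining - min_gap * (n_units + 1L),
                                      rep(1, n_units + 1L)))
  unit_gaps <- min_gap + extra

  strands <- sample(c("+", "-"), n_units, replace = TRUE)
  gi <- 0L
  kk <- 0L
  pos <- 0L  # 0-based cursor
  rows <- vector("list", n)
  unit_first <- integer(n_units)   # row index of first (promoter-side) gene
  unit_strand <- character(n_units)
  unit_of_gene <- integer(n)
  operons <- list()
  for (u in seq_len(n_units)) {
    pos <- pos + unit_gaps[u]
    members <- integer(unit_sizes[u])
    for (j in seq_len(unit_sizes[u])) {
      gi <- gi + 1L
      if (j > 1) {
        kk <- kk + 1L
        pos <- pos + intra_gaps[kk]
      }
      start1 <- pos + 1L
      end1 <- pos + lens[gi]
      rows[[gi]] <- tibble::tibble(
        locus_id = sprintf("SYN_%04d", gi), start = start1, end = end1,
        strand = strands[u], kind = "protein_coding", name = NA_character_)
      pos <- end1
      members[j] <- gi
      unit_of_gene[gi] <- u
    }
    # first gene in transcription order: leftmost for +, rightmost for -
    unit_first[u] <- if (strands[u] == "+") members[1] else members[length(members)]
    unit_strand[u] <- strands[u]
    if (unit_sizes[u] > 1) {
      ord <- if (strands[u] == "+") members else rev(members)
      operons[[length(operons) + 1L]] <- sprintf("SYN_%04d", ord)
    }
  }
  genes <- dplyr::bind_rows(rows)
  seq_chars <- strsplit(random_dna(L, cfg$gc_content), "", fixed = TRUE)[[1]]

  # plant sites upstream of distinct transcription units
  site_w <- nchar(cfg$site_left) + cfg$site_spacer + nchar(cfg$site_right)
  n_intra_sites <- round(cfg$intragenic_site_fraction * cfg$n_sites)
  n_prom_sites <- cfg$n_sites - n_intra_sites
  if (n_prom_sites > n_units) stop("more sites requested than transcription units")
  site_units <- sample(n_units, n_prom_sites)
  sites <- vector("list", cfg$n_sites)
  for (k in seq_along(site_units)) {
    u <- site_units[k]
    g <- genes[unit_first[u], ]
    # promoter-side gap: preceding gap for '+', following gap for '-'
    gap <- if (g$strand == "+") unit_gaps[u] else unit_gaps[u + 1L]
    # available upstream room: stay inside the adjacent intergenic gap
    room <- min(400L, gap - site_w - 10L)
    d <- -sample(60:max(61L, room), 1)  # summit-to-start distance, upstream
    if (g$strand == "+") {
      centre0 <- (g$start - 1L) + d      # 0-based summit
    } else {
      centre0 <- (g$end - 1L) - d
    }
    s0 <- centre0 - (site_w - 1L) %/% 2L
    site_seq <- paste0(cfg$site_left,
                       random_dna(cfg$site_spacer, cfg$gc_content),
                       cfg$site_right)
    if (g$strand == "-") site_seq <- revcomp(site_seq)
    seq_chars[(s0 + 1L):(s0 + site_w)] <- strsplit(site_seq, "")[[1]]
    sites[[k]] <- tibble::tibble(
      site_id = sprintf("site_%02d", k), position = centre0,
      strand = g$strand, sequence = site_seq, target = g$locus_id)
  }
  if (n_intra_sites > 0) {
    big <- which(genes$end - genes$start > 600)
    mid_genes <- sample(big, n_intra_sites)
    for (k in seq_len(n_intra_sites)) {
      g <- genes[mid_genes[k], ]
      centre0 <- as.integer((g$start + g$end) / 2)
      s0 <- centre0 - (site_w - 1L) %/% 2L
      site_seq <- paste0(cfg$site_left,
                         random_dna(cfg$site_spacer, cfg$gc_content),
                         cfg$site_right)
      seq_chars[(s0 + 1L):(s0 + site_w)] <- strsplit(site_seq, "")[[1]]
      sites[[n_prom_sites + k]] <- tibble::tibble(
        site_id = sprintf("site_%02d", n_prom_sites + k), position = centre0,
        strand = "+", sequence = site_seq, target = NA_character_)
    }
  }
  sites <- if (cfg$n_sites == 0) {
    tibble::tibble(site_id = character(), position = integer(),
                   strand = character(), sequence = character(),
                   target = character())
  } else {
    dplyr::bind_rows(sites)
  }

  # planted expression effects
  targeted_units <- site_units[
    seq_len(round(cfg$direct_fraction * length(site_units)))]
  direct <- list(); op_followers <- list()
  for (u in targeted_units) {
    sgn <- if (stats::runif(1) < cfg$prob_activated) -1 else 1
    lfc <- sgn * cfg$lfc_direct
    first_id <- genes$locus_id[unit_first[u]]
    sid <- sites$site_id[match(first_id, sites$target)]
    direct[[length(direct) + 1L]] <-
      tibble::tibble(locus_id = first_id, lfc = lfc, site_id = sid)
    others <- genes$locus_id[which(unit_of_gene == u)]
    others <- setdiff(others, first_id)
    if (cfg$plant_followers && length(others) > 0) {
      op_followers[[length(op_followers) + 1L]] <-
        tibble::tibble(locus_id = others, lfc = lfc)
    }
  }
  direct <- dplyr::bind_rows(direct)
  op_followers <- dplyr::bind_rows(op_followers)

  # indirect targets: genes of untargeted units with no site in the window
  window <- c(-1000L, 50L)
  in_window_of_site <- function(g) {
    d <- if (g$strand == "+") sites$position + 1L - g$start
         else g$end - (sites$position + 1L)
    any(d >= window[1] & d <= window[2])
  }
  pool <- setdiff(seq_len(n), which(unit_of_gene %in% site_units))
  pool <- pool[!vapply(pool, function(i) in_window_of_site(genes[i, ]), logical(1))]
  ind_idx <- sample(pool, min(cfg$n_indirect, length(pool)))
  indirect <- tibble::tibble(
    locus_id = genes$locus_id[ind_idx],
    lfc = ifelse(stats::runif(length(ind_idx)) < cfg$prob_activated, -1, 1) *
      cfg$lfc_direct)

  op_tbl <- if (length(operons) == 0) {
    tibble::tibble(operon_id = character(), locus_id = character(),
                   position_in_operon = integer())
  } else {
    purrr::imap_dfr(operons, function(ids, i) {
      tibble::tibble(operon_id = sprintf("op_%03d", i), locus_id = ids,
                     position_in_operon = seq_along(ids))
    })
  }

  ann <- genome_annotation(genes, genome_length = L,
                           sequence = paste(seq_chars, collapse = ""))
  list(annotation = ann,
       truth = list(sites = sites, direct_targets = direct,
                    operon_targets = op_tbl_filter(op_followers),
                    indirect_targets = indirect, operons = op_tbl))
}

op_tbl_filter <- function(x) {
  if (is.null(x) || nrow(x) == 0) {
    tibble::tibble(locus_id = character(), lfc = numeric())
  } else x
}

#' Simulate IP and input coverage tracks
#'
#' The input track draws Poisson fragment starts at `background_depth` per
#' bp and accumulates per-base coverage over `fragment_size` bases; the IP
#' track adds, at each planted site, extra fragments whose starts are
#' uniform over the `fragment_size` positions covering the summit, so the
#' expected summit height is about `enrichment` times the background
#' coverage.
#'
#' @param ann A [genome_annotation()] (only the length is used).
#' @param truth Truth list from [generate_genome()]; its `sites` tibble
#'   gives the planted summit positions.
#' @param cfg The [sim_config()] used to generate the genome.
#' @return A list with numeric per-base vectors `ip` and `input`.
#' @export
simulate_coverage <- function(ann, truth, cfg = sim_config()) {
  set.seed(cfg$seed + 1L)
  L <- genome_length(ann)
  frag <- cfg$fragment_size
  cover <- function(starts) {
    cs <- cumsum(starts)
    cs - c(rep(0, frag), cs[seq_len(L - frag)])
  }
  input <- cover(stats::rpois(L, cfg$background_depth))
  ip_starts <- stats::rpois(L, cfg$background_depth)
  for (i in seq_len(nrow(truth$sites))) {
    c1 <- truth$sites$position[i] + 1L  # 1-based summit
    n_extra <- stats::rpois(1, (cfg$enrichment - 1) * cfg$background_depth * frag)
    st <- sample(max(1L, c1 - frag + 1L):c1, n_extra, replace = TRUE)
    tab <- tabulate(st, nbins = L)
    ip_starts <- ip_starts + tab
  }
  list(ip = cover(ip_starts), input = input)
}

#' Simulate a gene-by-sample count matrix
#'
#' Counts are negative-binomial with mean proportional to gene length times
#' a lognormal expression level, times a per-sample library-size factor
#' drawn uniformly within +/-30%; mutant-condition means are multiplied by
#' `2^lfc` for planted target genes. Targeted genes have their expression
#' level floored so they pass the minimum-count filter; operon members share
#' one expression level (up to 1.5-fold jitter) so operons are co-expressed.
#'
#' @param ann A [genome_annotation()].
#' @param truth Truth list from [generate_genome()].
#' @param cfg The [sim_config()].
#' @param expr_levels Optional named per-gene expression multipliers
#'   (overrides the lognormal draw; a 0 silences a gene entirely).
#' @return A tibble with columns `locus_id`, `length_bp`, then one column
#'   per sample (`wt_1 ... wt_R, mut_1 ... mut_R`).
#' @export
simulate_counts <- function(ann, truth, cfg = sim_config(), expr_levels = NULL) {
  set.seed(cfg$seed + 2L)
  n <- nrow(ann)
  lens <- ann$end - ann$start + 1L
  expr <- stats::rlnorm(n, meanlog = 0, sdlog = 1)
  names(expr) <- ann$locus_id
  # co-express operon members around the operon's own level
  if (nrow(truth$operons) > 0) {
    for (op in split(truth$operons$locus_id, truth$operons$operon_id)) {
      base <- stats::rlnorm(1, 0, 1)
      expr[op] <- base * stats::runif(length(op), 1 / 1.5, 1.5)
    }
  }
  planted <- unique(c(truth$direct_targets$locus_id,
                      truth$operon_targets$locus_id,
                      truth$indirect_targets$locus_id))
  # keep planted targets comfortably above the count filter
  expr[planted] <- pmax(expr[planted], 0.5)
  if (!is.null(expr_levels)) expr[names(expr_levels)] <- expr_levels
  mu <- cfg$base_mean * (lens / 1000) * expr[ann$locus_id]

  lfc <- stats::setNames(rep(0, n), ann$locus_id)
  all_t <- dplyr::bind_rows(truth$direct_targets[, c("locus_id", "lfc")],
                            truth$operon_targets, truth$indirect_targets)
  lfc[all_t$locus_id] <- all_t$lfc
  R <- cfg$n_replicates
  sf <- stats::runif(2 * R, 0.7, 1.3)
  samples <- c(sprintf("wt_%d", seq_len(R)), sprintf("mut_%d", seq_len(R)))
  out <- tibble::tibble(locus_id = ann$locus_id, length_bp = lens)
  for (j in seq_len(2 * R)) {
    m <- if (j <= R) mu else mu * 2^lfc
    out[[samples[j]]] <- stats::rnbinom(n, mu = m * sf[j],
                                        size = 1 / cfg$nb_dispersion)
    out[[samples[j]]][m == 0] <- 0L
  }
  out
}

#' Write simulated inputs to disk
#'
#' Writes the genome FASTA, GFF3 annotation, IP/input bedGraph tracks,
#' counts TSV and truth tables under one directory.
#'
#' @param sim List with `annotation` and `truth` from [generate_genome()].
#' @param tracks List with `ip`/`input` from [simulate_coverage()].
#' @param counts Counts tibble from [simulate_counts()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of written paths, invisibly.
#' @export
write_simulation <- function(sim, tracks, counts, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    genome = file.path(dir, "genome.fasta"),
    annotation = file.path(dir, "annotation.gff3"),
    ip = file.path(dir, "ip.bedgraph"),
    input = file.path(dir, "input.bedgraph"),
    counts = file.path(dir, "counts.tsv"),
    sites = file.path(dir, "truth_sites.tsv"),
    targets = file.path(dir, "truth_targets.tsv"),
    operons = file.path(dir, "truth_operons.tsv")
  )
  write_genome_fasta(genome_sequence(sim$annotation), paths["genome"])
  write_gff(sim$annotation, paths["annotation"])
  write_bedgraph(tracks$ip, paths["ip"])
  write_bedgraph(tracks$input, paths["input"])
  readr::write_tsv(counts, paths["counts"])
  readr::write_tsv(sim$truth$sites, paths["sites"])
  targets <- dplyr::bind_rows(
    dplyr::mutate(sim$truth$direct_targets, class = "direct"),
    dplyr::mutate(sim$truth$operon_targets, class = "operon"),
    dplyr::mutate(sim$truth$indirect_targets, class = "indirect"))
  readr::write_tsv(targets, paths["targets"])
  readr::write_tsv(sim$truth$operons, paths["operons"])
  invisible(paths)
}

#' Write a per-base coverage vector as bedGraph
#' @param track Numeric per-base coverage vector.
#' @param path Output path.
#' @param seqname Sequence name.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path, seqname = "chr") {
  r <- rle(track)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  gr <- GenomicRanges::GRanges(seqname, IRanges::IRanges(starts, ends),
                               score = r$values)
  GenomeInfoDb::seqlengths(gr) <- stats::setNames(length(track), seqname)
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Read a bedGraph file into a per-base coverage vector
#' @param path Path to a bedGraph file.
#' @param genome_length Replicon length (positions past the last record are 0).
#' @return Numeric vector of length `genome_length`.
#' @export
read_bedgraph <- function(path, genome_length) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  out <- numeric(genome_length)
  s <- BiocGenerics::start(gr); e <- BiocGenerics::end(gr)
  for (i in seq_along(gr)) out[s[i]:e[i]] <- gr$score[i]
  out
}
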