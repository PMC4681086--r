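#' Default pipeline configuration
#'
#' All thresholds of the analysis in one list: peak p-value cutoff 1e-5,
#' motif p-value 0.01, DEG thresholds log2FC 1.32 / BH q 0.05, promoter
#' window -1000..+50 bp, operon gap < 50 bp, operon expression similarity
#' 1 log2 unit, plus the simulation block.
#'
#' @param seed Master seed; the simulation block inherits it.
#' @param ... Overrides for any field (`peak_p_cutoff`, `motif_p`,
#'   `lfc_threshold`, `q_threshold`, `window`, `operon_gap`,
#'   `operon_expr_delta`, `sim` or any [sim_config()] argument).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, ...) {
  dots <- list(...)
  cfg <- list(
    seed = as.integer(seed),
    peak_p_cutoff = 1e-5,
    motif_p = 0.01,
    lfc_threshold = 1.32,
    q_threshold = 0.05,
    window = c(-1000, 50),
    operon_gap = 50,
    operon_expr_delta = 1,
    sim = NULL
  )
  sim_args <- intersect(names(dots), names(formals(sim_config)))
  for (nm in setdiff(names(dots), c(sim_args, "sim"))) cfg[[nm]] <- dots[[nm]]
  if (!is.null(dots$sim)) {
    cfg$sim <- dots$sim
  } else {
    cfg$sim <- do.call(sim_config, c(list(seed = cfg$seed), dots[sim_args]))
  }
  if (cfg$window[1] >= cfg$window[2]) stop("window lower bound must be below upper")
  if (any(c(cfg$peak_p_cutoff, cfg$motif_p, cfg$lfc_threshold,
            cfg$q_threshold) <= 0)) stop("thresholds must be positive")
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys map to [pipeline_config()] fields; a `sim:` block maps to
#' [sim_config()] arguments.
#'
#' @param path Path to a YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  y <- yaml::read_yaml(path)
  sim <- y$sim
  y$sim <- NULL
  args <- c(y, sim)
  do.call(pipeline_config, args)
}

peak_sequences <- function(peaks, sequence, flank = 100L) {
  L <- nchar(sequence)
  lo <- pmax(peaks$summit + 1L - flank, 1L)
  hi <- pmin(peaks$summit + 1L + flank, L)
  stats::setNames(substring(sequence, lo, hi), peaks$peak_id)
}

#' Motif analysis over peak sequences
#'
#' Scans the sequence around each summit for the strict dyad and the
#' relaxed GTG-N8-CAC / GTG-N10-CAC variants; if at least two strict-dyad
#' sites are found, builds a PWM from them (background = genome
#' composition) and re-scans all peaks at `p_threshold`.
#'
#' @param peaks Consensus peaks tibble.
#' @param sequence Genome nucleotide string.
#' @param p_threshold PWM per-position p-value cutoff.
#' @param flank Half-width of sequence taken around each summit, bp.
#' @return A list: `hits` (tibble `peak_id`, `position`, `strand`,
#'   `matched`, `score`, `p`, `kind`), `pwm` (or `NULL`), `consensus` (or
#'   `NULL`).
#' @export
motif_report <- function(peaks, sequence, p_threshold = 0.01, flank = 100L) {
  specs <- list(
    strict = dyad_spec("TGTGA", "TCACA", 6L),
    relaxed8 = dyad_spec("GTG", "CAC", 8L),
    relaxed10 = dyad_spec("GTG", "CAC", 10L))
  seqs <- peak_sequences(peaks, sequence, flank)
  dyad_hits <- purrr::imap_dfr(seqs, function(s, pid) {
    purrr::imap_dfr(specs, function(sp, nm) {
      h <- scan_dyad(sp, s)
      if (nrow(h) == 0) return(NULL)
      tibble::tibble(peak_id = pid, position = h$position,
                     strand = h$strand, matched = h$matched,
                     score = NA_real_, p = NA_real_,
                     kind = "dyad", variant = nm)
    })
  })
  pwm <- NULL; consensus <- NULL; pwm_hits <- NULL
  strict_sites <- unique(dyad_hits$matched[dyad_hits$variant == "strict" &
                                             dyad_hits$strand == "+"])
  if (length(strict_sites) >= 2) {
    bg <- base_frequencies(sequence)
    pwm <- build_pwm(strict_sites, background = bg)
    consensus <- consensus_from_sites(strict_sites)
    tab <- pwm_pvalue_table(pwm)
    pwm_hits <- purrr::imap_dfr(seqs, function(s, pid) {
      h <- scan_pwm(pwm, s, p_threshold = p_threshold, pvalues = tab)
      if (nrow(h) == 0) return(NULL)
      tibble::tibble(peak_id = pid, position = h$position, strand = h$strand,
                     matched = h$matched, score = h$score, p = h$p,
                     kind = "pwm", variant = "pwm")
    })
  }
  hits <- dplyr::bind_rows(dyad_hits, pwm_hits)
  list(hits = hits, pwm = pwm, consensus = consensus)
}

#' Run the full simulate-and-analyze pipeline
#'
#' Stages, in order: simulate genome/coverage/counts (or read them from
#' `input_dir`), call peaks with both background models and intersect,
#' test differential expression and call DEGs, scan motifs over consensus
#' peaks, infer operons from wild-type RPKM, classify peak contexts, assign
#' direct/indirect regulation, and summarize. Every stage output is written
#' under `out_dir` together with a run manifest recording the seed and all
#' thresholds. A fixed seed makes the whole run byte-reproducible.
#'
#' @param cfg A [pipeline_config()].
#' @param out_dir Output directory.
#' @param input_dir Optional directory of pre-existing inputs in
#'   [write_simulation()] layout (a missing file is an error naming it);
#'   the default simulates fresh inputs.
#' @return A list (invisibly): `summary`, `regulon`, `degs`, `peaks`,
#'   `peaks_ctx`, `motifs`, `truth` (when simulated), `paths`.
#' @export
run_pipeline <- function(cfg = pipeline_config(), out_dir = tempfile("run_"),
                         input_dir = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  truth <- NULL
  if (is.null(input_dir)) {
    sim <- stage("simulate", generate_genome(cfg$sim))
    ann <- sim$annotation
    truth <- sim$truth
    tracks <- stage("simulate", simulate_coverage(ann, truth, cfg$sim))
    counts <- stage("simulate", simulate_counts(ann, truth, cfg$sim))
    stage("simulate", write_simulation(sim, tracks, counts, out_dir))
  } else {
    need <- c(genome = "genome.fasta", annotation = "annotation.gff3",
              ip = "ip.bedgraph", input = "input.bedgraph",
              counts = "counts.tsv")
    paths <- file.path(input_dir, need)
    missing <- paths[!file.exists(paths)]
    if (length(missing) > 0) {
      stop("missing input file(s): ", paste(missing, collapse = ", "))
    }
    ann <- stage("read", read_gff(paths[2],
                                  sequence = read_genome_fasta(paths[1])))
    L <- genome_length(ann)
    tracks <- stage("read", list(ip = read_bedgraph(paths[3], L),
                                 input = read_bedgraph(paths[4], L)))
    counts <- stage("read", read_counts(paths[5]))
  }

  frag <- cfg$sim$fragment_size
  pk_a <- stage("peaks", call_peaks_poisson(
    tracks$ip, tracks$input, p_cutoff = cfg$peak_p_cutoff,
    fragment_size = frag))
  pk_b <- stage("peaks", call_peaks_nb_gc(
    tracks$ip, tracks$input, genome_sequence(ann),
    p_cutoff = cfg$peak_p_cutoff, fragment_size = frag))
  peaks <- stage("peaks", consensus_peaks(pk_a, pk_b))
  write_narrowpeak(pk_a, file.path(out_dir, "peaks_poisson.narrowPeak"))
  if (nrow(pk_b) > 0) {
    write_narrowpeak(pk_b, file.path(out_dir, "peaks_nb.narrowPeak"))
  }
  write_narrowpeak(peaks, file.path(out_dir, "peaks_consensus.narrowPeak"))

  degs <- stage("deg", call_degs(test_differential(counts),
                                 lfc_threshold = cfg$lfc_threshold,
                                 q_threshold = cfg$q_threshold))
  write_deg_report(degs, file.path(out_dir, "deg.tsv"))

  motifs <- stage("motifs", motif_report(peaks, genome_sequence(ann),
                                         p_threshold = cfg$motif_p))
  if (nrow(motifs$hits) > 0) {
    readr::write_tsv(motifs$hits, file.path(out_dir, "motif_hits.tsv"))
  }
  if (!is.null(motifs$pwm)) {
    write_meme_pwm(motifs$pwm, file.path(out_dir, "motif_pwm.meme"))
  }

  conds <- sample_conditions(counts)
  rp <- rpkm(counts)
  wt_cols <- conds$sample[conds$condition == "wt"]
  expr <- tibble::tibble(locus_id = rp$locus_id,
                         level = rowMeans(as.matrix(rp[, wt_cols])))
  operons <- stage("integrate", infer_operons(
    ann, expr, max_gap = cfg$operon_gap,
    max_expr_delta = cfg$operon_expr_delta))
  peaks_ctx <- stage("integrate", classify_peaks(peaks, ann,
                                                 window = cfg$window))
  peaks_ctx$height <- peaks$height[match(peaks_ctx$peak_id, peaks$peak_id)]
  regulon <- stage("integrate", assign_regulation(
    peaks_ctx, degs, operons, ann, window = cfg$window,
    motif_hits = if (nrow(motifs$hits) > 0) motifs$hits else NULL))
  readr::write_tsv(tibble::as_tibble(regulon),
                   file.path(out_dir, "regulon.tsv"))

  summary <- stage("summarize", summarize_regulon(regulon, peaks_ctx, ann))
  jsonlite::write_json(
    c(as.list(glance.regulon_summary(summary)),
      list(category_counts = summary$category_counts)),
    file.path(out_dir, "summary.json"), auto_unbox = TRUE, digits = NA)
  manifest <- list(
    package = "regulonmapr",
    version = as.character(utils::packageVersion("regulonmapr")),
    seed = cfg$seed,
    thresholds = cfg[c("peak_p_cutoff", "motif_p", "lfc_threshold",
                       "q_threshold", "window", "operon_gap",
                       "operon_expr_delta")],
    outputs = list.files(out_dir))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(summary = summary, regulon = regulon, degs = degs,
                 peaks = peaks, peaks_ctx = peaks_ctx, motifs = motifs,
                 operons = operons, annotation = ann, truth = truth,
                 paths = out_dir))
}
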