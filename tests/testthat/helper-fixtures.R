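# Shared fixtures, computed lazily and cached for the whole test run.
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# default study conditions: 200 kb, 150 genes, 20 planted sites, enrichment 8
default_cfg <- function() sim_config(seed = 1)

default_sim <- function() cached("sim", generate_genome(default_cfg()))

default_tracks <- function() {
  cached("tracks", {
    s <- default_sim()
    simulate_coverage(s$annotation, s$truth, default_cfg())
  })
}

default_consensus <- function() {
  cached("consensus", {
    s <- default_sim()
    tr <- default_tracks()
    a <- call_peaks_poisson(tr$ip, tr$input)
    b <- call_peaks_nb_gc(tr$ip, tr$input, genome_sequence(s$annotation))
    consensus_peaks(a, b)
  })
}

# the default-seed pipeline run shared by the integration checks
default_run <- function() {
  cached("run", run_pipeline(pipeline_config(seed = 1),
                             out_dir = file.path(tempdir(), "regulonmapr_run")))
}

# singleton-target configuration for expression recovery: 150 genes, exactly
# 20 planted fold changes, no operons (needs a longer replicon to pack)
deg_recovery_cfg <- function() {
  sim_config(seed = 1, genome_length = 350000, n_genes = 150, n_sites = 20,
             n_indirect = 0, operon_fraction = 0, lfc_direct = 2)
}

# small hand-built annotation: two + genes and one - gene on 10 kb
toy_annotation <- function() {
  genome_annotation(
    data.frame(locus_id = c("gA", "gB", "gC"),
               start = c(1001, 3001, 6001),
               end = c(2000, 4000, 7000),
               strand = c("+", "+", "-")),
    genome_length = 10000)
}

# brute-force per-base intergenic scan (oracle for interval arithmetic)
brute_intergenic <- function(ann) {
  L <- genome_length(ann)
  covered <- logical(L)
  for (i in seq_len(nrow(ann))) covered[ann$start[i]:ann$end[i]] <- TRUE
  r <- rle(!covered)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  tibble::tibble(start = starts[r$values] - 1L, end = ends[r$values])
}

random_dna_test <- function(n, gc) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# brute-force BH step-up (oracle for multiple-testing correction)
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  adj <- p[o] * m / seq_len(m)
  q[o] <- rev(cummin(rev(adj)))
  pmin(q, 1)
}
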