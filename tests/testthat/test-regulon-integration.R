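test_that("summit-to-start distances follow the strand-aware sign convention", {
  # + gene starting at 1000, summit at base 910 (1-based): 90 bp upstream
  expect_equal(summit_to_start_distance(909, 1000, 1400, "+"), -90)
  # - gene ending at 2000, summit at base 1964: 36 bp past the start codon
  expect_equal(summit_to_start_distance(1963, 1500, 2000, "-"), 36)
  # summit exactly on the start codon
  expect_equal(summit_to_start_distance(999, 1000, 1400, "+"), 0)
  expect_equal(summit_to_start_distance(1999, 1500, 2000, "-"), 0)
  # vectorized over summits with a scalar gene
  expect_equal(summit_to_start_distance(c(909, 999), 1000, 1400, "+"),
               c(-90, 0))
})

divergent_ann <- function() {
  # <-gA ... gap ... gB->  with both starts near the gap, plus a far gene
  genome_annotation(
    data.frame(locus_id = c("gA", "gB", "gC", "rA"),
               start = c(1001, 3501, 9001, 11001),
               end = c(3000, 5500, 10000, 11500),
               strand = c("-", "+", "+", "+"),
               kind = c("protein_coding", "protein_coding",
                        "protein_coding", "rRNA")),
    genome_length = 20000)
}

test_that("peak contexts are classified into the five categories", {
  ann <- divergent_ann()
  peaks <- tibble::tibble(
    peak_id = c("p_div", "p_up", "p_mid", "p_rna", "p_far"),
    summit = c(3250L,    8600L,  4200L,   11200L,  17000L))
  ctx <- classify_peaks(peaks, ann)
  expect_equal(ctx$category[ctx$peak_id == "p_div"], "intergenic_divergent")
  expect_equal(ctx$category[ctx$peak_id == "p_up"], "intergenic_upstream")
  # p_mid is inside gB with gC's start 4.8 kb away: purely intragenic
  expect_equal(ctx$category[ctx$peak_id == "p_mid"], "intragenic")
  expect_equal(ctx$category[ctx$peak_id == "p_rna"], "rna_locus")
  expect_equal(ctx$category[ctx$peak_id == "p_far"], "intragenic")

  # divergent context carries exactly 2 candidates on opposite strands
  cand <- ctx$candidates[ctx$peak_id == "p_div"][[1]]
  expect_equal(nrow(cand), 2)
  expect_setequal(cand$strand, c("+", "-"))
  expect_true(all(cand$distance >= -1000 & cand$distance <= 50))

  # categories are exhaustive: one per peak
  expect_equal(nrow(ctx), nrow(peaks))
  expect_true(all(ctx$category %in% c(
    "intergenic_upstream", "intergenic_divergent", "intragenic_upstream",
    "intragenic", "rna_locus")))
})

test_that("an intragenic summit upstream of a downstream gene is flagged", {
  ann <- genome_annotation(
    data.frame(locus_id = c("gA", "gB"), start = c(1001, 3101),
               end = c(3000, 4000), strand = "+"), 10000)
  ctx <- classify_peaks(tibble::tibble(peak_id = "p", summit = 2500L), ann)
  expect_equal(ctx$category, "intragenic_upstream")
  expect_false(ctx$is_intergenic)
})

test_that("operon inference applies the gap, strand and expression rules", {
  mk_ann <- function(gap, strands = c("+", "+")) {
    genome_annotation(
      data.frame(locus_id = c("g1", "g2"), start = c(1001, 2000 + gap + 1),
                 end = c(2000, 3000 + gap), strand = strands), 10000)
  }
  expr_eq <- tibble::tibble(locus_id = c("g1", "g2"), level = c(100, 100))

  op <- infer_operons(mk_ann(30), expr_eq)
  expect_equal(nrow(op), 2)
  expect_equal(op$role, c("first_in_operon", "in_operon"))

  # boundary: gaps of 50+ bp break the operon ("fewer than 50")
  expect_equal(nrow(infer_operons(mk_ann(60), expr_eq)), 0)
  expect_equal(nrow(infer_operons(mk_ann(50), expr_eq)), 0)
  expect_equal(nrow(infer_operons(mk_ann(49), expr_eq)), 2)

  # opposite strands never join
  expect_equal(nrow(infer_operons(mk_ann(30, c("+", "-")), expr_eq)), 0)

  # dissimilar expression (> 1 log2 unit) breaks the operon
  expr_diff <- tibble::tibble(locus_id = c("g1", "g2"), level = c(100, 450))
  expect_equal(nrow(infer_operons(mk_ann(30), expr_diff)), 0)

  # on the minus strand the first gene is the rightmost one
  ann_m <- mk_ann(30, c("-", "-"))
  op_m <- infer_operons(ann_m, expr_eq)
  expect_equal(op_m$locus_id[op_m$role == "first_in_operon"], "g2")
})

test_that("operon inference recovers the planted operons", {
  sim <- default_sim()
  cm <- simulate_counts(sim$annotation, sim$truth, default_cfg())
  rp <- rpkm(cm)
  expr <- tibble::tibble(locus_id = rp$locus_id,
                         level = rowMeans(as.matrix(rp[, c("wt_1", "wt_2", "wt_3")])))
  inferred <- infer_operons(sim$annotation, expr)
  truth_pairs <- function(ops) {
    unlist(lapply(split(ops$locus_id, ops$operon_id), function(g) {
      if (length(g) < 2) return(character(0))
      paste(g[-length(g)], g[-1], sep = "|")
    }), use.names = FALSE)
  }
  tp <- truth_pairs(sim$truth$operons)
  ip <- truth_pairs(inferred)
  expect_gte(mean(tp %in% ip), 0.8)  # most adjacent truth pairs recovered
})

test_that("regulation assignment handles no-peak and divergent-peak cases", {
  ann <- divergent_ann()
  degs <- tibble::tibble(
    locus_id = c("gA", "gB", "gC"),
    log2fc = c(-2, -2, 2), p = 1e-6, q = 1e-5, tested = TRUE,
    mode = c("activated", "activated", "repressed"))
  ops <- infer_operons(ann, tibble::tibble(locus_id = ann$locus_id, level = 10))

  # no peaks at all: every DEG indirect
  ctx0 <- classify_peaks(tibble::tibble(peak_id = character(),
                                        summit = integer()), ann)
  r0 <- assign_regulation(ctx0, degs, ops, ann)
  expect_true(all(r0$regulation == "indirect"))

  # one divergent peak makes both flanking DEGs direct, sharing one peak_id
  ctx1 <- classify_peaks(tibble::tibble(peak_id = "p_div", summit = 3250L), ann)
  r1 <- assign_regulation(ctx1, degs, ops, ann)
  direct <- r1[r1$regulation == "direct", ]
  expect_setequal(direct$locus_id, c("gA", "gB"))
  expect_equal(unique(direct$peak_id), "p_div")
  expect_equal(r1$regulation[r1$locus_id == "gC"], "indirect")
  expect_equal(sum(r1$regulation != "indirect") + sum(r1$regulation == "indirect"),
               nrow(degs))

  # locus mismatch is an error naming the offender
  degs_bad <- dplyr::mutate(degs, locus_id = c("gA", "gB", "missing"))
  expect_error(assign_regulation(ctx1, degs_bad, ops, ann), "missing")
})

test_that("operon followers of a direct first gene become direct_via_operon", {
  ann <- genome_annotation(
    data.frame(locus_id = c("g1", "g2", "g3"),
               start = c(2001, 3031, 4061), end = c(3000, 4030, 5060),
               strand = "+"), 10000)
  ops <- infer_operons(ann, tibble::tibble(locus_id = ann$locus_id, level = 10))
  expect_equal(nrow(ops), 3)
  degs <- tibble::tibble(
    locus_id = c("g1", "g2", "g3"), log2fc = -2, p = 1e-6, q = 1e-5,
    tested = TRUE, mode = "activated")
  ctx <- classify_peaks(tibble::tibble(peak_id = "p1", summit = 1900L), ann)
  r <- assign_regulation(ctx, degs, ops, ann)
  expect_equal(r$regulation[r$locus_id == "g1"], "direct")
  expect_equal(r$regulation[r$locus_id == "g2"], "direct_via_operon")
  expect_equal(r$regulation[r$locus_id == "g3"], "direct_via_operon")
  expect_equal(unique(r$peak_id), "p1")
})

test_that("shrinking the promoter window never adds direct genes", {
  run <- default_run()
  wide <- assign_regulation(run$peaks_ctx, run$degs, run$operons,
                            run$annotation, window = c(-1000, 50))
  narrow <- assign_regulation(run$peaks_ctx, run$degs, run$operons,
                              run$annotation, window = c(-300, 50))
  n_direct <- function(r) sum(r$regulation != "indirect")
  expect_lte(n_direct(narrow), n_direct(wide))
  # and the regulation field partitions the DEGs
  expect_equal(sum(table(wide$regulation)), sum(run$degs$mode != "none"))
})

test_that("regulon summary statistics match closed forms", {
  # 20 peaks, all intergenic, on a genome that is 50% intergenic
  ann <- genome_annotation(
    data.frame(locus_id = "g1", start = 1, end = 10000, strand = "+"), 20000)
  ctx <- tibble::tibble(
    peak_id = sprintf("p%02d", 1:20), summit = 10100L + (1:20) * 400L,
    category = "intergenic_upstream", is_intergenic = TRUE,
    candidates = list(tibble::tibble()), height = 100)
  rec <- structure(
    tibble::tibble(locus_id = character(), peak_id = character(),
                   distance = numeric(), operon_role = character(),
                   log2fc = numeric(), mode = character(),
                   matched_site = character(), regulation = character()),
    class = c("regulon", class(tibble::tibble())))
  s <- summarize_regulon(rec, ctx, ann)
  expect_equal(s$intergenic_enrichment_p, 2^-20, tolerance = 1e-12)
  expect_equal(s$intergenic_peak_fraction, 1)
  expect_equal(s$genome_intergenic_fraction, 0.5)

  # identical height lists: Mann-Whitney is uninformative (p ~ 1)
  ctx2 <- ctx
  ctx2$is_intergenic[1:10] <- FALSE
  ctx2$category[1:10] <- "intragenic"
  s2 <- summarize_regulon(rec, ctx2, ann)
  expect_gt(s2$height_mannwhitney_p, 0.99)
})

test_that("Venn region counts agree with set-algebra enumeration", {
  expect_equal(
    venn_counts(c("a1", "a2"), c("b1"), c("c1", "c2", "c3")),
    tibble::tibble(a_only = 2L, b_only = 1L, c_only = 3L, ab = 0L, ac = 0L,
                   bc = 0L, abc = 0L))
  same <- c("x", "y", "z")
  v <- venn_counts(same, same, same)
  expect_equal(v$abc, 3L)
  expect_equal(sum(unlist(v[, 1:6])), 0L)

  set.seed(5)
  for (rep in 1:5) {
    u <- sprintf("g%02d", 1:30)
    a <- sample(u, 12); b <- sample(u, 9); c_ <- sample(u, 15)
    v <- venn_counts(a, b, c_)
    oracle <- table(factor(paste0(
      as.integer(u %in% a), as.integer(u %in% b), as.integer(u %in% c_)),
      levels = c("100", "010", "001", "110", "101", "011", "111")))
    expect_equal(unname(unlist(v)), as.vector(oracle))
    expect_equal(sum(unlist(v)), length(unique(c(a, b, c_))))
  }
})
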