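mk_counts <- function(mat, lengths = 1000L) {
  if (is.null(colnames(mat))) {
    half <- ncol(mat) / 2
    colnames(mat) <- c(sprintf("wt_%d", seq_len(half)),
                       sprintf("mut_%d", seq_len(half)))
  }
  tibble::tibble(locus_id = sprintf("g%03d", seq_len(nrow(mat))),
                 length_bp = lengths) |>
    dplyr::bind_cols(tibble::as_tibble(mat))
}

test_that("size factors follow the median-of-ratios closed forms", {
  a <- c(10, 50, 100, 200, 1000)
  cm <- mk_counts(cbind(wt_1 = a, wt_2 = a))
  expect_equal(unname(size_factors(cm)), c(1, 1))

  cm2 <- mk_counts(cbind(wt_1 = a, wt_2 = 2 * a))
  f <- size_factors(cm2)
  expect_equal(unname(f[2] / f[1]), 2)
  expect_equal(exp(mean(log(f))), 1)  # rescaled to geometric mean 1

  # permutation invariance over genes
  perm <- sample(nrow(cm2))
  expect_equal(size_factors(cm2[perm, ]), size_factors(cm2))

  cm3 <- mk_counts(cbind(wt_1 = c(0, 5), wt_2 = c(5, 0)))
  expect_error(size_factors(cm3), "filter")
})

test_that("rpkm follows its defining formula", {
  cm <- mk_counts(matrix(c(100, rep(0, 3)), ncol = 2,
                         dimnames = list(NULL, c("wt_1", "wt_2"))))
  cm$length_bp <- c(1000L, 2000L)
  cm$wt_1 <- c(100, 999900)  # total 1e6
  cm$wt_2 <- c(100, 999900)
  r <- rpkm(cm)
  expect_equal(r$wt_1[1], 100)          # 100 reads, 1 kb gene, 1e6 total
  cm$length_bp[1] <- 2000L
  expect_equal(rpkm(cm)$wt_1[1], 50)    # doubling length halves RPKM
  cm$wt_1[1] <- 0
  expect_equal(rpkm(cm)$wt_1[1], 0)
})

test_that("the NB Wald test recovers hand-computable fold changes", {
  cm <- mk_counts(cbind(wt_1 = 100, wt_2 = 100, wt_3 = 100,
                        mut_1 = 100, mut_2 = 100, mut_3 = 100))
  td <- test_differential(cm)
  expect_equal(td$log2fc, 0)

  # several stable genes keep the size factors at 1
  stable <- matrix(rep(c(500, 300, 700, 450, 900), 6), ncol = 6)
  cm2 <- mk_counts(rbind(c(800, 820, 790, 100, 95, 110), stable))
  names(cm2)[3:8] <- c("wt_1", "wt_2", "wt_3", "mut_1", "mut_2", "mut_3")
  td2 <- test_differential(cm2)
  oracle <- log2(mean(c(100, 95, 110)) / mean(c(800, 820, 790)))
  expect_lt(abs(td2$log2fc[1] - oracle), 0.1)
  expect_lt(abs(td2$log2fc[1] - (-3.0)), 0.1)

  # low-count genes are not tested
  cm3 <- mk_counts(cbind(wt_1 = c(2, 100, 50), wt_2 = c(3, 100, 50),
                         wt_3 = c(1, 100, 50), mut_1 = c(2, 100, 50),
                         mut_2 = c(4, 100, 50), mut_3 = c(2, 100, 50)))
  td3 <- test_differential(cm3)
  expect_false(td3$tested[1])
  expect_equal(td3$p[1], 1)
  expect_equal(td3$log2fc[1], 0)

  expect_error(
    test_differential(mk_counts(cbind(wt_1 = 10, mut_1 = 10, mut_2 = 10))),
    "replicates")
})

test_that("the Wald p-values are calibrated under the null", {
  set.seed(1)
  n <- 2000
  mu <- stats::rlnorm(n, log(200), 1)
  mat <- vapply(1:6, function(j) stats::rnbinom(n, mu = mu, size = 1 / 0.05),
                numeric(n))
  colnames(mat) <- c("wt_1", "wt_2", "wt_3", "mut_1", "mut_2", "mut_3")
  td <- test_differential(mk_counts(mat))
  frac <- mean(td$p[td$tested] < 0.05)
  expect_gte(frac, 0.03)
  expect_lte(frac, 0.08)
})

test_that("BH adjustment matches the step-up oracle and hand example", {
  rec <- tibble::tibble(locus_id = c("a", "b", "c"),
                        log2fc = c(2, -2, 2), p = c(0.01, 0.02, 0.04),
                        tested = TRUE)
  out <- call_degs(rec)
  expect_equal(out$q, c(0.03, 0.03, 0.04))

  set.seed(11)
  for (rep in 1:5) {
    m <- sample(5:50, 1)
    p <- stats::runif(m)^sample(1:3, 1)
    rec2 <- tibble::tibble(locus_id = sprintf("g%02d", 1:m), log2fc = 0,
                           p = p, tested = TRUE)
    q <- call_degs(rec2)$q
    expect_equal(q, brute_bh(p))
    expect_true(all(q >= p - 1e-12))
    expect_true(all(diff(q[order(p)]) >= -1e-12))  # monotone in sorted p
  }
})

test_that("DEG thresholds are strict and modes partition the genes", {
  rec <- tibble::tibble(
    locus_id = c("under", "over_dn", "over_up", "null"),
    log2fc = c(-1.31, -1.5, 1.32, 0.1),
    p = c(1e-6, 1e-6, 1e-6, 0.8), tested = TRUE)
  out <- call_degs(rec)
  expect_equal(out$mode, c("none", "activated", "repressed", "none"))
  expect_true(all(table(out$mode)[c("activated", "none", "repressed")] ==
                    c(1, 2, 1)))
  # a 1.32 log2 threshold is the 2.5-fold-change criterion
  expect_equal(round(2^1.32, 1), 2.5)
})

test_that("planted fold changes are recovered with high recall and low FDR", {
  cfg <- deg_recovery_cfg()
  sim <- generate_genome(cfg)
  cm <- simulate_counts(sim$annotation, sim$truth, cfg)
  degs <- call_degs(test_differential(cm))
  planted <- sim$truth$direct_targets$locus_id
  called <- degs$locus_id[degs$mode != "none"]
  expect_gte(mean(planted %in% called), 0.9)
  expect_lte(mean(!called %in% planted), 0.10)
  # sign convention: planted negative log2FC means the factor activates
  dn <- sim$truth$direct_targets$locus_id[sim$truth$direct_targets$lfc < 0]
  modes <- degs$mode[match(dn, degs$locus_id)]
  expect_true(all(modes %in% c("activated", "none")))
})

test_that("tidy and glance summarize DEG results", {
  cfg <- deg_recovery_cfg()
  sim <- generate_genome(cfg)
  cm <- simulate_counts(sim$annotation, sim$truth, cfg)
  degs <- call_degs(test_differential(cm))
  td <- generics::tidy(degs)
  expect_named(td, c("locus_id", "log2fc", "p", "q", "mode"))
  g <- generics::glance(degs)
  expect_equal(g$n_deg, g$n_activated + g$n_repressed)
  expect_equal(g$n_genes, nrow(cm))
})
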