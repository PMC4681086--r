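test_that("PWM construction matches hand counts", {
  p0 <- build_pwm(c("ACGT", "ACGT"), pseudocount = 0)
  expect_true(all(apply(p0$mat, 2, max) == 1))  # unit vectors
  expect_equal(diag(p0$mat[c("A", "C", "G", "T"), ]), rep(1, 4),
               ignore_attr = TRUE)

  p1 <- build_pwm(c("ACGT", "TGCA"), pseudocount = 0)
  expect_true(all(colSums(p1$mat == 0.5) == 2))  # two bases at 0.5 per column

  p2 <- build_pwm(c("AAAA", "AAAC", "GGTT"), pseudocount = 0.5)
  expect_equal(colSums(p2$mat), rep(1, 4), tolerance = 1e-9)
  expect_equal(unname(p2$mat["A", 1]), (2 + 0.5) / (3 + 2))

  expect_error(build_pwm(c("ACGT", "ACG")), "equal length")
  expect_error(build_pwm(c("ACGN", "ACGT")), "non-ACGT")
  expect_error(build_pwm("ACGT"), "at least 2")
})

test_that("the exact score distribution matches brute-force enumeration", {
  set.seed(21)
  # width-1 PWM: four-point distribution
  p1 <- build_pwm(c("A", "A", "C"), pseudocount = 0.5)
  tab1 <- pwm_pvalue_table(p1)
  expect_equal(nrow(tab1$table), length(unique(round(
    log2(p1$mat / 0.25) / tab1$resolution))))

  # width-5 PWM vs exhaustive enumeration over all 4^5 words
  sites <- c("ACGTA", "ACGTT", "ACGCA", "TCGTA")
  bg <- c(0.2, 0.3, 0.3, 0.2)
  pwm <- build_pwm(sites, pseudocount = 0.5, background = bg)
  res <- 0.001
  tab <- pwm_pvalue_table(pwm, resolution = res)
  ints <- round(log2(pwm$mat / bg) / res)
  words <- expand.grid(rep(list(1:4), 5))
  word_scores <- apply(words, 1, function(w) sum(ints[cbind(w, 1:5)]))
  word_probs <- apply(words, 1, function(w) prod(bg[w]))
  for (s in sample(unique(word_scores), 20)) {
    oracle <- sum(word_probs[word_scores >= s])
    got <- regulonmapr:::pwm_lookup_p(tab, s)
    expect_equal(got, oracle, tolerance = 1e-9)
  }
  # p is monotone non-increasing in score
  expect_true(all(diff(tab$table$p) <= 1e-12))
})

test_that("PWM scanning is strand-symmetric and self-recovering", {
  sites <- c("TGTGACCTAG", "TGTGACCTAG", "TGTGACCTAG", "TGTGATCTAG")
  pwm <- build_pwm(sites, pseudocount = 0.1)
  tab <- pwm_pvalue_table(pwm)
  # a sharp PWM finds its own site at the minimal achievable p
  hits <- scan_pwm(pwm, "TGTGACCTAG", p_threshold = 0.01, pvalues = tab)
  fw <- hits[hits$strand == "+", ]
  expect_equal(fw$position, 0L)
  expect_equal(fw$p, min(tab$table$p))

  set.seed(31)
  for (rep in 1:3) {
    seq <- random_dna_test(200, 0.5)
    h_f <- scan_pwm(pwm, seq, p_threshold = 0.05, pvalues = tab)
    h_r <- scan_pwm(pwm, revcomp(seq), p_threshold = 0.05, pvalues = tab)
    # mirror image: position -> len - width - position, strand flipped
    mirrored <- tibble::tibble(
      position = 200L - 10L - h_r$position,
      strand = ifelse(h_r$strand == "+", "-", "+"),
      matched = h_r$matched, score = h_r$score, p = h_r$p)
    mirrored <- dplyr::arrange(mirrored, position, strand)
    expect_equal(mirrored$position, h_f$position)
    expect_equal(mirrored$strand, h_f$strand)
    expect_equal(mirrored$score, h_f$score)
  }

  expect_equal(nrow(scan_pwm(pwm, "TGTGACCTAGTT", p_threshold = 0)), 0)
})

test_that("dyad scanning finds the published worked example", {
  seq25 <- "TGTGAAGCAGTTCACA"  # a bound promoter site, 16 bp
  strict <- dyad_spec("TGTGA", "TCACA", 6L)
  h <- scan_dyad(strict, seq25)
  expect_equal(sort(unique(h$strand)), c("+", "-"))
  expect_true(all(h$position == 0))  # palindrome: both strands, same interval
  expect_equal(unique(h$width), 16L)

  relaxed <- dyad_spec("GTG", "CAC", 8L)
  h8 <- scan_dyad(relaxed, seq25)
  expect_true(any(h8$position == 1 & h8$strand == "+"))

  expect_equal(nrow(scan_dyad(dyad_spec("GTG", "CAC", integer(0)), seq25)), 0)
})

test_that("palindromic dyads produce paired-strand hits on random sequence", {
  set.seed(41)
  strict <- dyad_spec("TGTGA", "TCACA", 6L)
  for (rep in 1:5) {
    seq <- paste0(random_dna_test(300, 0.7), "TGTGA", random_dna_test(6, 0.7),
                  "TCACA", random_dna_test(300, 0.7))
    h <- scan_dyad(strict, seq)
    fw <- h[h$strand == "+", ]
    rv <- h[h$strand == "-", ]
    expect_equal(fw$position, rv$position)  # same intervals on both strands
    expect_gte(nrow(fw), 1)
  }
})

test_that("overlapping dyad hits are all reported", {
  # one left half-site pairing with two right half-sites at both spacings
  h <- scan_dyad(dyad_spec("GTG", "CAC", c(2L, 5L)), "GTGATCACCAC")
  fw <- h[h$strand == "+", ]
  expect_equal(nrow(fw), 2)
  expect_true(all(fw$position == 0))
  expect_setequal(fw$spacer, c(2L, 5L))
})

test_that("consensus and information content follow the entropy formula", {
  cons <- consensus_from_sites(c("ACGT", "ACGT", "ACGT"))
  expect_equal(cons$consensus, "ACGT")
  expect_equal(cons$information, rep(2, 4))

  # a 50/50 column carries 1 bit and an ambiguity code
  cons2 <- consensus_from_sites(c("AAAA", "CAAA"))
  expect_equal(cons2$information[1], 1)
  expect_equal(substr(cons2$consensus, 1, 1), "M")  # A/C
  expect_equal(nchar(cons2$consensus), 4)
})

test_that("MEME minimal format round-trips a PWM", {
  pwm <- build_pwm(c("TGTGAAGCAGTTCACA", "TGTGACCTAGTTCACA"),
                   background = c(0.15, 0.35, 0.35, 0.15))
  path <- withr::local_tempfile(fileext = ".meme")
  write_meme_pwm(pwm, path)
  back <- read_meme_pwm(path)
  expect_equal(back$mat, pwm$mat, tolerance = 1e-5)
  expect_equal(unname(back$background), c(0.15, 0.35, 0.35, 0.15),
               tolerance = 1e-5)
})
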