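test_that("donor and acceptor window extraction obeys the fixed geometry", {
  # + strand: exon1 1..50, intron 51..150, exon2 151..250
  set.seed(41)
  chromSeq <- randomSeq(400)
  g <- Biostrings::DNAStringSet(c(chr1 = chromSeq))
  ex <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(c(1, 151), c(50, 250)), strand = "+")
  ex$gene_id <- "g1"; ex$transcript_id <- "t1"; ex$exon_rank <- 1:2
  ex$five_prime_status <- "non-SL"
  donor <- extractSpliceSites(ex, g, "donor")
  acc <- extractSpliceSites(ex, g, "acceptor")
  expect_equal(unname(as.character(donor)), substr(chromSeq, 48, 56))
  expect_equal(unname(as.character(acc)), substr(chromSeq, 131, 153))
  expect_equal(Biostrings::width(donor), 9L)
  expect_equal(Biostrings::width(acc), 23L)
})

test_that("minus-strand extraction equals reverse-complement brute force", {
  set.seed(42)
  for (rep in 1:5) {
    chromSeq <- randomSeq(500)
    g <- Biostrings::DNAStringSet(c(chr1 = chromSeq))
    # - strand gene: exon1 (rank 1) at 301..400, exon2 at 101..200,
    # intron genomic 201..300; transcription right-to-left
    ex <- GenomicRanges::GRanges("chr1",
      IRanges::IRanges(c(301, 101), c(400, 200)), strand = "-")
    ex$gene_id <- "g1"; ex$transcript_id <- "t1"; ex$exon_rank <- 1:2
    ex$five_prime_status <- "non-SL"
    rc <- function(s) as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(s)))
    donor <- extractSpliceSites(ex, g, "donor")
    acc <- extractSpliceSites(ex, g, "acceptor")
    # donor: exon1 last 3 transcribed (genomic 301..303) + intron first 6
    # (genomic 295..300) -> genomic window 295..303 reverse-complemented
    expect_equal(unname(as.character(donor)),
                 rc(substr(chromSeq, 295, 303)))
    # acceptor: intron last 20 (genomic 201..220) + exon2 first 3
    # (genomic 198..200) -> genomic window 198..220 reverse-complemented
    expect_equal(unname(as.character(acc)),
                 rc(substr(chromSeq, 198, 220)))
  }
})

test_that("intronless transcripts and edge windows yield no sites", {
  g <- Biostrings::DNAStringSet(c(chr1 = randomSeq(100)))
  ex <- GenomicRanges::GRanges("chr1", IRanges::IRanges(10, 90),
                               strand = "+")
  ex$gene_id <- "g1"; ex$transcript_id <- "t1"; ex$exon_rank <- 1L
  ex$five_prime_status <- "non-SL"
  expect_equal(length(extractSpliceSites(ex, g, "donor")), 0L)
  # intron so close to the edge that the acceptor window is cut off
  ex2 <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(c(1, 15), c(4, 90)), strand = "+")
  ex2$gene_id <- "g2"; ex2$transcript_id <- "t2"; ex2$exon_rank <- 1:2
  ex2$five_prime_status <- "non-SL"
  expect_equal(length(extractSpliceSites(ex2, g, "acceptor")), 0L)
})

test_that("PWM training normalizes columns with pseudocounts", {
  m0 <- trainPwm("ACGTACGTA", pseudocount = 0)
  expect_equal(m0@dist$pwm[1, ], c(A = 1, C = 0, G = 0, T = 0))
  set.seed(43)
  sites <- vapply(1:30, function(i) randomSeq(9), "")
  m <- trainPwm(sites, pseudocount = 0.25)
  expect_true(all(abs(rowSums(m@dist$pwm) - 1) < 1e-12))
  # huge pseudocount -> uniform columns
  mInf <- trainPwm(sites, pseudocount = 1e9)
  expect_true(all(abs(mInf@dist$pwm - 0.25) < 1e-6))
  expect_error(trainPwm(c("ACGT", "ACGTA")), "same width")
})

test_that("MEM with single-position constraints reproduces PWM scores", {
  set.seed(44)
  sites <- vapply(1:50, function(i) randomSeq(9), "")
  pwm <- trainPwm(sites, pseudocount = 0.25)
  mem <- trainMem(sites, constraints = "single", pseudocount = 0.25)
  probe <- vapply(1:40, function(i) randomSeq(9), "")
  expect_lt(max(abs(scoreSpliceSites(pwm, probe) -
                      scoreSpliceSites(mem, probe))), 1e-6)
  # same equivalence for the factorized (wide-window) representation
  sites23 <- vapply(1:50, function(i) randomSeq(23), "")
  pwm23 <- trainPwm(sites23, pseudocount = 0.25)
  mem23 <- trainMem(sites23, constraints = "single", pseudocount = 0.25)
  probe23 <- vapply(1:20, function(i) randomSeq(23), "")
  expect_lt(max(abs(scoreSpliceSites(pwm23, probe23) -
                      scoreSpliceSites(mem23, probe23))), 1e-6)
})

test_that("MEM pairwise fit matches empirical constraint marginals", {
  set.seed(45)
  # correlated positions so pairwise structure actually matters
  sites <- vapply(1:80, function(i) {
    a <- sample(BASES, 1)
    b <- if (runif(1) < 0.8) a else sample(BASES, 1)
    paste0(a, b, randomSeq(3), a)
  }, "")
  mem <- trainMem(sites, constraints = "pairs", tol = 1e-8,
                  pseudocount = 0.25)
  q <- mem@dist$table
  expect_equal(sum(q), 1, tolerance = 1e-9)
  km <- outronscan:::.kmerMatrix(sites)
  for (i in 1:5) {
    emp <- outronscan:::.empMarginal(km, c(i, min(i + 1, 5)), 0.25)
    if (i < 5) {
      cur <- apply(q, c(i, i + 1), sum)
      expect_lt(max(abs(cur - emp)), 1e-7)
    }
  }
})

test_that("small-space MEM agrees with a direct constrained max-entropy solve", {
  set.seed(46)
  sites <- vapply(1:40, function(i) randomSeq(3), "")
  mem <- trainMem(sites, constraints = "pairs", tol = 1e-10,
                  pseudocount = 0.25)
  km <- outronscan:::.kmerMatrix(sites)
  e12 <- outronscan:::.empMarginal(km, c(1, 2), 0.25)
  e23 <- outronscan:::.empMarginal(km, c(2, 3), 0.25)
  # independent oracle: maximize entropy over the 64-simplex under the
  # two pair constraints via constrained optimization on logits
  obj <- function(theta) {
    p <- exp(theta) / sum(exp(theta))
    q <- array(p, dim = c(4, 4, 4))
    pen <- sum((apply(q, c(1, 2), sum) - e12)^2) +
      sum((apply(q, c(2, 3), sum) - e23)^2)
    sum(p * log(p + 1e-300)) + 1e5 * pen
  }
  opt <- stats::optim(rep(0, 64), obj, method = "BFGS",
                      control = list(maxit = 2000, reltol = 1e-14))
  oracle <- exp(opt$par) / sum(exp(opt$par))
  expect_lt(max(abs(as.vector(mem@dist$table) - oracle)), 5e-3)
})

test_that("log-odds scoring matches closed forms", {
  set.seed(47)
  sites <- vapply(1:30, function(i) randomSeq(9), "")
  m <- trainPwm(sites)
  # signal == background -> all scores zero
  expect_lt(max(abs(scoreSpliceSites(m, sites[1:5], background = m))),
            1e-12)
  # P_signal = 0.5 against uniform 9-mer background: log2(0.5 * 4^9) = 17
  one <- trainPwm("AAAAAAAAA", pseudocount = 0)
  half <- one
  half@dist$pwm[1, ] <- c(0.5, 0.5, 0, 0)
  expect_equal(scoreSpliceSites(half, "AAAAAAAAA"), 17)
  # uniform training -> scores ~ 0 against uniform background
  uni <- trainPwm(c("ACGT", "CGTA", "GTAC", "TACG"), pseudocount = 1e9)
  expect_lt(max(abs(scoreSpliceSites(uni, c("AAAA", "GGGG")))), 1e-6)
})

test_that("scores are invariant to training-site order", {
  set.seed(48)
  sites <- vapply(1:40, function(i) randomSeq(9), "")
  probe <- vapply(1:10, function(i) randomSeq(9), "")
  m1 <- trainMem(sites); m2 <- trainMem(rev(sites))
  expect_equal(scoreSpliceSites(m1, probe), scoreSpliceSites(m2, probe),
               tolerance = 1e-9)
})

test_that("planted strong-vs-weak donor sets rank correctly", {
  set.seed(49)
  strong <- vapply(1:100, function(i)
    paste0(randomSeq(3), "GTAAGT"), "")
  weak <- vapply(1:100, function(i)
    paste0(randomSeq(3), "GT", randomSeq(4)), "")
  model <- trainMem(c(strong, weak))
  expect_gt(mean(scoreSpliceSites(model, strong)),
            mean(scoreSpliceSites(model, weak)))
  cmp <- compareStrength(weak, strong, model, alternative = "less")
  expect_lt(cmp$p.value, 1e-6)
})

test_that("identical groups give a two-sided p near 1", {
  set.seed(50)
  sites <- vapply(1:30, function(i) randomSeq(9), "")
  m <- trainPwm(sites)
  cmp <- compareStrength(sites, sites, m)
  expect_gt(cmp$p.value, 0.95)
  expect_error(compareStrength(sites[1], sites, m), "at least 2")
})

test_that("batch comparisons share one BH correction", {
  set.seed(51)
  a <- vapply(1:20, function(i) paste0(randomSeq(3), "GTAAGT"), "")
  b <- vapply(1:20, function(i) paste0(randomSeq(3), "GT",
                                       randomSeq(4)), "")
  m <- trainMem(c(a, b))
  out <- compareStrengthBatch(list(
    ds = list(a = a, b = b, signal = m),
    null = list(a = b, b = b, signal = m)))
  expect_equal(nrow(out), 2L)
  expect_true(all(out$fdr >= out$p.value - 1e-12))
})
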