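SL16 <- "ATTCTATTTGAATAAG"

test_that("reads partition into SL (trimmed) and capped (untrimmed)", {
  set.seed(20)
  genomic <- randomSeq(34)
  reads <- Biostrings::DNAStringSet(c(
    slRead = paste0(SL16, genomic),
    capRead = randomSeq(50)))
  out <- classifyReads(reads, SL16)
  expect_equal(as.character(out$sl), c(slRead = genomic))
  expect_equal(length(out$capped), 1L)
  expect_equal(Biostrings::width(out$capped), 50L)
  expect_equal(length(out$sl) + length(out$capped), length(reads))
})

test_that("shorter SL suffix matching trims only the matched bases", {
  genomic <- "ACGGTTACGGTTACGGTTAC"
  read <- Biostrings::DNAStringSet(c(r = paste0(substr(SL16, 9, 16),
                                                genomic)))
  out <- classifyReads(read, SL16, minPrefixMatch = 8L)
  expect_equal(unname(as.character(out$sl)), genomic)
})

test_that("classification recovers simulated labels perfectly at zero error", {
  cfg <- smallConfig(seed = 71L, decoyClusters = 0L)
  sim <- simulateGenome(cfg)
  tg <- simulateTags(sim, depth = 40)
  out <- classifyReads(tg$reads, cfg@slSequence)
  predSL <- names(tg$reads) %in% names(out$sl)
  expect_identical(predSL, tg$truth$category == "SL")
})

test_that("empty reads are skipped with a warning", {
  reads <- Biostrings::DNAStringSet(c(a = "", b = randomSeq(30)))
  expect_warning(out <- classifyReads(reads, SL16), "empty")
  expect_equal(length(out$sl) + length(out$capped), 1L)
})

test_that("exact 5'-end mapping reports the 5'-most base per strand", {
  set.seed(21)
  g <- Biostrings::DNAStringSet(c(chr1 = randomSeq(5000)))
  fwd <- Biostrings::subseq(g[[1]], 1001, 1050)
  rcv <- Biostrings::reverseComplement(
    Biostrings::subseq(g[[1]], 2001, 2050))
  reads <- Biostrings::DNAStringSet(c(f = as.character(fwd),
                                      r = as.character(rcv)))
  m <- mapFivePrime(reads, g, "capped")
  aln <- m$alignments
  expect_equal(m$unmapped + m$multimapped, 0L)
  plus <- aln[as.character(GenomicRanges::strand(aln)) == "+"]
  minus <- aln[as.character(GenomicRanges::strand(aln)) == "-"]
  expect_equal(GenomicRanges::start(plus), 1001L)
  # 5'-most base of a minus-strand read is the higher coordinate
  expect_equal(GenomicRanges::start(minus), 2050L)
})

test_that("multi-mapping reads are dropped and counted", {
  unit <- randomSeq(40)
  g <- Biostrings::DNAStringSet(c(chr1 = paste0(unit, randomSeq(200),
                                                unit)))
  reads <- Biostrings::DNAStringSet(c(r1 = unit))
  m <- mapFivePrime(reads, g, "SL")
  expect_equal(length(m$alignments), 0L)
  expect_equal(m$multimapped, 1L)
  m2 <- mapFivePrime(reads, g, "SL", requiredUnique = FALSE)
  expect_equal(length(m2$alignments), 1L)
})

test_that("mapping positions equal brute-force string search", {
  set.seed(22)
  g <- Biostrings::DNAStringSet(c(c1 = randomSeq(3000),
                                  c2 = randomSeq(3000)))
  starts <- sample(100:2900, 10)
  chroms <- sample(names(g), 10, replace = TRUE)
  strands <- sample(c("+", "-"), 10, replace = TRUE)
  gr <- GenomicRanges::GRanges(chroms, IRanges::IRanges(starts,
                                                        starts + 39),
                               strand = strands)
  reads <- extractRegions(g, gr)
  names(reads) <- sprintf("r%d", 1:10)
  m <- mapFivePrime(reads, g, "capped")
  aln <- m$alignments
  expPos <- ifelse(strands == "-", starts + 39L, starts)
  key <- sort(paste(chroms, expPos, strands))
  got <- sort(paste(as.character(GenomicRanges::seqnames(aln)),
                    GenomicRanges::start(aln),
                    as.character(GenomicRanges::strand(aln))))
  expect_equal(got, unique(key))
})

mkAln <- function(pos, count, strand = "+", category = "SL") {
  gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(pos, pos),
                               strand = strand)
  gr$category <- category; gr$count <- count
  gr
}

test_that("tag clustering follows single-linkage chaining", {
  a <- mkAln(c(100L, 103L), c(5L, 2L))
  cl <- clusterTags(a, maxGap = 50L)
  expect_equal(length(cl), 1L)
  expect_equal(cl$mode_pos, 100L)
  expect_equal(cl$total_tags, 7L)
  b <- mkAln(c(100L, 200L), c(1L, 1L))
  expect_equal(length(clusterTags(b, maxGap = 50L)), 2L)
  expect_equal(length(clusterTags(b, maxGap = 100L)), 1L)
})

test_that("mode tie-break is 5'-most on the cluster's strand", {
  tiePlus <- clusterTags(mkAln(c(10L, 14L), c(5L, 5L)), maxGap = 50L)
  expect_equal(tiePlus$mode_pos, 10L)
  tieMinus <- clusterTags(mkAln(c(10L, 14L), c(5L, 5L), strand = "-"),
                          maxGap = 50L)
  expect_equal(tieMinus$mode_pos, 14L)
})

test_that("clustering matches the brute-force chaining oracle and is order-invariant", {
  set.seed(23)
  for (rep in 1:20) {
    pos <- sort(sample(1:2000, sample(5:40, 1)))
    maxGap <- sample(c(5L, 20L, 50L), 1)
    perm <- sample(seq_along(pos))
    a <- mkAln(pos[perm], rep(1L, length(pos)))
    cl <- clusterTags(a, maxGap = maxGap)
    oracle <- chainOracle(pos, maxGap)
    expect_equal(length(cl), length(oracle))
    expect_equal(sort(GenomicRanges::start(cl)),
                 unname(sort(vapply(oracle, min, numeric(1)))))
    expect_equal(sort(GenomicRanges::end(cl)),
                 unname(sort(vapply(oracle, max, numeric(1)))))
  }
})

test_that("TAS calling keeps only AG-context positions", {
  # genome with AG before position 103 but GG before position 203
  s <- paste(rep("C", 300), collapse = "")
  substr(s, 101, 102) <- "AG"
  substr(s, 201, 202) <- "GG"
  g <- Biostrings::DNAStringSet(c(chr1 = s))
  cl <- clusterTags(c(mkAln(103L, 10L), mkAln(203L, 4L)), maxGap = 10L)
  out <- callTas(cl, g)
  expect_equal(length(out$tas), 1L)
  expect_equal(GenomicRanges::start(out$tas), 103L)
  expect_equal(out$tas$tag_count, 10L)
  expect_equal(out$dropped_clusters, 1L)
})

test_that("minus-strand TAS calling checks the CT context downstream", {
  s <- paste(rep("A", 300), collapse = "")
  substr(s, 151, 152) <- "CT"   # AG on the minus strand, 5' of pos 150
  g <- Biostrings::DNAStringSet(c(chr1 = s))
  cl <- clusterTags(mkAln(150L, 6L, strand = "-"), maxGap = 10L)
  out <- callTas(cl, g)
  expect_equal(GenomicRanges::start(out$tas), 150L)
})

test_that("TSS calling requires open-chromatin overlap", {
  cl <- clusterTags(c(mkAln(100L, 10L, category = "capped"),
                      mkAln(500L, 99L, category = "capped")),
                    maxGap = 10L)
  peaks <- GenomicRanges::GRanges("chr1", IRanges::IRanges(80, 120))
  out <- callTss(cl, peaks)
  expect_equal(length(out$tss), 1L)
  expect_equal(GenomicRanges::start(out$tss), 100L)
  expect_equal(out$rejected, 1L)
})

test_that("per-gene TSS is the mode of the highest-count supported cluster", {
  cl <- clusterTags(c(mkAln(100L, 10L, category = "capped"),
                      mkAln(180L, 30L, category = "capped")),
                    maxGap = 10L)
  peaks <- GenomicRanges::GRanges("chr1", IRanges::IRanges(50, 300))
  genes <- GenomicRanges::GRanges("chr1", IRanges::IRanges(90, 400),
                                  strand = "+")
  genes$gene_id <- "gA"
  out <- callTss(cl, peaks, genes)
  expect_equal(length(out$tss), 1L)
  expect_equal(GenomicRanges::start(out$tss), 180L)
  expect_equal(out$tss$gene_id, "gA")
})
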