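mkGenes <- function(starts, ends, strands, ids = NULL) {
  gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(starts, ends),
                               strand = strands)
  gr$gene_id <- if (is.null(ids)) sprintf("g%d", seq_along(gr)) else ids
  gr
}

mkSites <- function(pos, strands, counts = NULL) {
  gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(pos, pos),
                               strand = strands)
  if (!is.null(counts)) gr$tag_count <- counts
  gr
}

test_that("gene bodies extend to cover assigned novel transcripts", {
  genes <- mkGenes(1000, 2000, "+")
  novel <- GenomicRanges::GRanges("chr1", IRanges::IRanges(700, 1100),
                                  strand = "+")
  out <- redefineGeneBodies(genes, novel)
  expect_equal(GenomicRanges::start(out$genes), 700L)
  expect_equal(GenomicRanges::end(out$genes), 2000L)
  expect_equal(out$dropped, 0L)
  # no novel transcripts -> identity
  same <- redefineGeneBodies(genes, GenomicRanges::GRanges())
  expect_identical(as.data.frame(same$genes), as.data.frame(genes))
})

test_that("novel transcripts follow the larger-overlap rule; orphans drop", {
  genes <- mkGenes(c(1000, 3000), c(2000, 4000), c("+", "+"))
  novel <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(c(1900, 6000), c(3500, 6400)), strand = "+")
  out <- redefineGeneBodies(genes, novel)
  # overlap with g2 (3000..3500 = 501 bp) beats g1 (1900..2000 = 101 bp)
  expect_equal(GenomicRanges::start(out$genes), c(1000L, 1900L))
  expect_equal(out$dropped, 1L)
  expect_equal(length(out$genes), length(genes))  # count unchanged
  # opposite strand never captures
  novelMinus <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(1900, 3500), strand = "-")
  out2 <- redefineGeneBodies(genes, novelMinus)
  expect_equal(out2$dropped, 1L)
})

test_that("operon detection honors the zero-gap boundary exactly", {
  # two abutting same-strand genes, downstream 5' end at a TAS
  genes <- mkGenes(c(100, 301), c(300, 500), c("+", "+"))
  tas <- mkSites(301, "+")
  expect_equal(detectOperons(genes, tas), c(TRUE, TRUE))
  # 1-bp gap breaks the operon
  genes1 <- mkGenes(c(100, 302), c(300, 500), c("+", "+"))
  expect_equal(detectOperons(genes1, mkSites(302, "+")), c(FALSE, FALSE))
  # no TAS at the downstream 5' end breaks it too
  expect_equal(detectOperons(genes, mkSites(999, "+")), c(FALSE, FALSE))
  # minus-strand operon: transcription-first is the rightmost gene
  genesM <- mkGenes(c(100, 301), c(300, 500), c("-", "-"))
  tasM <- mkSites(300, "-")   # 5' end of the left (downstream) gene
  expect_equal(detectOperons(genesM, tasM), c(TRUE, TRUE))
})

test_that("operon flags equal the brute-force run scanner on random layouts", {
  set.seed(31)
  for (rep in 1:60) {
    lay <- randomLayout(sample(4:15, 1))
    tasKey <- paste(as.character(GenomicRanges::seqnames(lay$tas)),
                    GenomicRanges::start(lay$tas),
                    as.character(GenomicRanges::strand(lay$tas)))
    expect_equal(detectOperons(lay$genes, lay$tas),
                 operonOracle(lay$genes, tasKey))
  }
})

test_that("status classification distinguishes primary/secondary sources", {
  genes <- mkGenes(c(100, 400, 700), c(300, 600, 900), rep("+", 3))
  prim <- mkSites(150, "+")
  sec <- mkSites(450, "+")
  st <- classifyGeneStatus(genes, prim, sec)
  expect_equal(st, c("trans_spliced", "ambiguous", "non_trans_spliced"))
  # statuses partition the gene set
  expect_equal(length(st), length(genes))
})

test_that("major TAS selection maximizes tags with 5'-most tie-break", {
  s <- mkSites(c(10, 20, 30), rep("+", 3), counts = c(100L, 20L, 5L))
  expect_equal(GenomicRanges::start(selectMajorTas(s)), 10L)
  one <- mkSites(42, "+", counts = 7L)
  expect_equal(GenomicRanges::start(selectMajorTas(one)), 42L)
  tie <- mkSites(c(10, 30), c("+", "+"), counts = c(50L, 50L))
  expect_equal(GenomicRanges::start(selectMajorTas(tie)), 10L)
  tieM <- mkSites(c(10, 30), c("-", "-"), counts = c(50L, 50L))
  expect_equal(GenomicRanges::start(selectMajorTas(tieM)), 30L)
  expect_error(selectMajorTas(mkSites(integer(0), character(0))))
})

mkExons <- function(bounds, strand = "+", status = "non-SL") {
  gr <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(vapply(bounds, `[[`, numeric(1), 1),
                     vapply(bounds, `[[`, numeric(1), 2)),
    strand = strand)
  # bounds are given in transcription order
  gr$gene_id <- "g1"; gr$transcript_id <- "g1.t1"
  gr$exon_rank <- seq_along(bounds)
  gr$five_prime_status <- status
  gr
}

test_that("TAS location categories follow the transcript structure", {
  # + strand: exon1 100-200, intron 201-300, exon2 301-400, CDS at 320
  ex <- mkExons(list(c(100, 200), c(301, 400)))
  expect_equal(locateTas(301, ex, 320), "AS_1")
  expect_equal(locateTas(150, ex, 320), "5UTR_first_exon")
  expect_equal(locateTas(350, ex, 320), "internal_exon")
  expect_equal(locateTas(250, ex, 320), "other")       # intronic, not AS
  expect_equal(locateTas(310, ex, 320), "5UTR_nd")     # exon2 5' UTR
  # ND transcript (SL-type 5' end)
  exND <- mkExons(list(c(100, 200), c(301, 400)), status = "SL")
  expect_equal(locateTas(301, exND, 320), "AS_nd")
  expect_equal(locateTas(150, exND, 320), "5UTR_nd")
  # minus strand: exon1 is rightmost; acceptor 1 = end of left exon
  exM <- mkExons(list(c(301, 400), c(100, 200)), strand = "-")
  expect_equal(locateTas(200, exM, 180), "AS_1")
  expect_equal(locateTas(350, exM, 180), "5UTR_first_exon")
  expect_equal(locateTas(NA_integer_, GenomicRanges::GRanges(), NA),
               "other")
})

test_that("location categories are fully recovered on simulated genes", {
  cfg <- smallConfig(seed = 87L, operonFraction = 0)
  sim <- simulateGenome(cfg)
  genes <- geneRanges(sim)
  cdsStart <- ifelse(as.character(GenomicRanges::strand(cdsRanges(sim)))
                     == "-", GenomicRanges::end(cdsRanges(sim)),
                     GenomicRanges::start(cdsRanges(sim)))
  names(cdsStart) <- cdsRanges(sim)$gene_id
  tas <- trueTas(sim)[trueTas(sim)$is_major]
  for (i in seq_along(tas)) {
    gid <- tas$gene_id[i]
    cls <- genes$gene_class[genes$gene_id == gid]
    ex <- exonRanges(sim)[exonRanges(sim)$gene_id == gid]
    loc <- locateTas(GenomicRanges::start(tas)[i], ex, cdsStart[[gid]])
    expected <- if (cls == "TS_1stAS") "AS_1" else "5UTR_first_exon"
    expect_equal(loc, expected)
  }
})

test_that("first-AS binomial test matches its closed forms", {
  # all majors at AS_1 with p0 < 1 -> p = p0^n
  locs <- rep("AS_1", 5)
  nAcc <- c(2L, 2L, 4L, 4L, 4L)        # p0 = 5/16 per site
  out <- firstAsTest(locs, nAcc)
  expect_equal(out$p0, 5 / 16)
  expect_equal(out$p.value, (5 / 16)^5, tolerance = 1e-12)
  # k = 0 -> p = 1
  out0 <- firstAsTest(rep("AS_2", 4), nAcc)
  expect_equal(out0$p.value, 1)
  # (k=8, n=10, p0=0.3) vs pmf summation
  locs2 <- c(rep("AS_1", 8), rep("AS_2", 2))
  nAcc2 <- rep(10L, 3)                 # per_site p0 = 3/30 = 0.1
  outP <- firstAsTest(locs2, nAcc2, background = "per_gene")
  expect_equal(outP$p0, 0.1)
  oracle <- sum(dbinom(8:10, 10, 0.1))
  expect_equal(outP$p.value, oracle, tolerance = 1e-12)
  expect_error(firstAsTest(rep("5UTR_first_exon", 3), nAcc), "no major")
})

test_that("trans-splicing ratio arithmetic and High/Low split", {
  expect_equal(transSplicingRatio(10, 30), 0.75)
  expect_equal(transSplicingRatio(0, 5), 1.0)
  expect_error(transSplicingRatio(0, 0), "undefined")
  expect_equal(splitHighLow(c(0.75, 0.5, 0.2), 0.5),
               c("TS_High", "TS_High", "TS_Low"))  # boundary inclusive
  labs <- splitHighLow(runif(20), 0.3)
  expect_equal(sum(labs == "TS_High") + sum(labs == "TS_Low"), 20L)
})

test_that("end-to-end gene classification matches planted truth", {
  cfg <- smallConfig(seed = 53L, tagDepthPerGene = 150)
  sim <- simulateGenome(cfg)
  peaks <- simulateAtac(sim)
  tg <- simulateTags(sim, peaks = peaks)
  cls <- classifyReads(tg$reads, cfg@slSequence)
  aln <- c(mapFivePrime(cls$sl, genomeSeq(sim), "SL")$alignments,
           mapFivePrime(cls$capped, genomeSeq(sim), "capped")$alignments)
  clusters <- clusterTags(aln)
  tas <- callTas(clusters[clusters$category == "SL"], genomeSeq(sim))$tas
  tss <- callTss(clusters[clusters$category == "capped"], peaks,
                 geneRanges(sim))$tss
  tab <- classifyGenes(geneRanges(sim), exonRanges(sim), cdsRanges(sim),
                       tas, tss)
  truthTS <- geneRanges(sim)$gene_class %in%
    c("TS_1stAS", "TS_5UTR", "operon_internal")
  expect_equal(tab$status == "trans_spliced", truthTS)
  expect_equal(tab$operonic, !is.na(geneRanges(sim)$operon_id))
  grp <- tab$group[geneRanges(sim)$gene_class == "TS_1stAS"]
  expect_true(mean(grp == "TS-1stAS") > 0.9)
  # ratios estimate truth within binomial noise for measured genes
  ok <- !is.na(tab$ts_ratio)
  rho <- geneRanges(sim)$ts_ratio[ok]
  expect_lt(mean(abs(tab$ts_ratio[ok] - rho)), 0.15)
})
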