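# shared fixture builders; everything is generated in code at test time

BASES <- c("A", "C", "G", "T")

randomSeq <- function(n) paste(sample(BASES, n, replace = TRUE),
                               collapse = "")

# a small simulation most tests can share (built once per test run)
smallConfig <- function(seed = 42L, ...) {
  args <- utils::modifyList(
    list(seed = seed, nGenes = 30L, nChromosomes = 2L,
         chromLength = 50000L, tagDepthPerGene = 80),
    list(...))
  do.call(simConfig, args)
}

# a sharp PWM for motif tests: near-indicator of the given word
wordPwm <- function(word, id = "toy", conc = 0.94) {
  ch <- match(strsplit(word, "")[[1]], BASES)
  m <- matrix((1 - conc) / 3, nrow = length(ch), ncol = 4)
  m[cbind(seq_along(ch), ch)] <- conc
  motifPWM(id, m)
}

randomPwm <- function(w, id = "rand") {
  m <- matrix(stats::rgamma(4 * w, 1) + 0.05, ncol = 4)
  motifPWM(id, m / rowSums(m))
}

# brute-force single-linkage chaining oracle for tag clustering
chainOracle <- function(pos, maxGap) {
  o <- order(pos); p <- pos[o]
  grp <- cumsum(c(1L, as.integer(diff(p) > maxGap)))
  split(p, grp)
}

# brute-force operon scanner: genomic-order runs, gap <= 0, non-first
# (transcription order) 5' ends at a TAS
operonOracle <- function(genes, tasKey) {
  n <- length(genes)
  flags <- logical(n)
  ord <- order(as.character(GenomicRanges::seqnames(genes)),
               GenomicRanges::start(genes))
  i <- 1
  while (i <= n) {
    j <- i
    while (j < n) {
      a <- ord[j]; b <- ord[j + 1]
      sameChrom <- as.character(GenomicRanges::seqnames(genes))[a] ==
        as.character(GenomicRanges::seqnames(genes))[b]
      sameStrand <- as.character(GenomicRanges::strand(genes))[a] ==
        as.character(GenomicRanges::strand(genes))[b]
      gap <- GenomicRanges::start(genes)[b] -
        GenomicRanges::end(genes)[a] - 1L
      if (sameChrom && sameStrand && gap <= 0L) j <- j + 1 else break
    }
    if (j > i) {
      members <- ord[i:j]
      st <- as.character(GenomicRanges::strand(genes))[members[1]]
      firstMember <- if (st == "-") members[length(members)]
        else members[1]
      rest <- setdiff(members, firstMember)
      fp <- ifelse(as.character(GenomicRanges::strand(genes))[rest] == "-",
                   GenomicRanges::end(genes)[rest],
                   GenomicRanges::start(genes)[rest])
      key <- paste(as.character(GenomicRanges::seqnames(genes))[rest], fp,
                   as.character(GenomicRanges::strand(genes))[rest])
      if (all(key %in% tasKey)) flags[members] <- TRUE
    }
    i <- j + 1
  }
  flags
}

# random non-overlapping gene layout on one chromosome, with some
# deliberately abutting pairs; returns list(genes, tas)
randomLayout <- function(nGenes = 12L) {
  starts <- integer(0); ends <- integer(0); strands <- character(0)
  cursor <- 1L
  for (i in seq_len(nGenes)) {
    gap <- sample(c(0L, 0L, 1L, sample(2:300, 1L)), 1L)
    len <- sample(100:400, 1L)
    s <- cursor + gap
    starts <- c(starts, s); ends <- c(ends, s + len - 1L)
    strands <- c(strands, sample(c("+", "-"), 1L))
    cursor <- s + len
  }
  genes <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(starts, ends), strand = strands)
  genes$gene_id <- sprintf("g%02d", seq_len(nGenes))
  # give a random subset of genes a TAS at their 5' end
  fp <- ifelse(strands == "-", ends, starts)
  withTas <- sample(nGenes, size = sample(0:nGenes, 1L))
  tas <- GenomicRanges::GRanges(rep("chr1", length(withTas)),
    IRanges::IRanges(fp[withTas], fp[withTas]),
    strand = strands[withTas])
  list(genes = genes, tas = tas)
}
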