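# 5'-end coordinate of a stranded range (start on "+", end on "-")
.fivePrimeEnd <- function(gr) {
  ifelse(as.character(strand(gr)) == "-", end(gr), start(gr))
}

#' Redefine gene bodies from known models plus novel transcripts
#'
#' Each novel transcript is assigned to the known gene it overlaps on the
#' same strand (ties on overlap width go to the 5'-most gene); the gene
#' body becomes the union span of the known body and its assigned
#' transcripts. Novel transcripts overlapping no known gene are dropped
#' and counted; the gene count never changes.
#'
#' @param genes GRanges of known gene bodies with a \code{gene_id} column.
#' @param novel GRanges of novel transcript spans.
#' @return A list with \code{genes} (updated GRanges) and \code{dropped}
#'   (number of unassignable novel transcripts).
#' @export
redefineGeneBodies <- function(genes, novel) {
  if (length(novel) == 0L) return(list(genes = genes, dropped = 0L))
  hits <- GenomicRanges::findOverlaps(novel, genes, ignore.strand = FALSE)
  dropped <- length(novel) - length(unique(S4Vectors::queryHits(hits)))
  if (length(hits)) {
    ovw <- width(IRanges::pintersect(
      granges(novel)[S4Vectors::queryHits(hits)],
      granges(genes)[S4Vectors::subjectHits(hits)]))
    d <- data.frame(q = S4Vectors::queryHits(hits),
                    s = S4Vectors::subjectHits(hits), w = ovw)
    d$fp <- .fivePrimeEnd(genes)[d$s]
    neg <- as.character(strand(genes))[d$s] == "-"
    # larger overlap wins; tie -> 5'-most gene on its own strand
    d$fpKey <- ifelse(neg, -d$fp, d$fp)
    d <- d[order(d$q, -d$w, d$fpKey), ]
    d <- d[!duplicated(d$q), ]
    newStart <- start(genes); newEnd <- end(genes)
    for (i in seq_len(nrow(d))) {
      s <- d$s[i]; q <- d$q[i]
      newStart[s] <- min(newStart[s], start(novel)[q])
      newEnd[s] <- max(newEnd[s], end(novel)[q])
    }
    out <- genes
    IRanges::ranges(out) <- IRanges(newStart, newEnd)
  } else out <- genes
  list(genes = out, dropped = dropped)
}

#' Detect operons
#'
#' Operonic genes are maximal same-strand runs of two or more genes with
#' no intergenic distance (gap <= 0 bp, i.e. abutting or overlapping)
#' where the 5' end of every gene except the transcription-first one
#' coincides exactly with a trans-splice acceptor site. All members of a
#' qualifying run are flagged.
#'
#' @param genes GRanges of gene bodies with \code{gene_id}.
#' @param tas Width-1 GRanges of trans-splice acceptor sites.
#' @return Logical vector parallel to \code{genes}.
#' @export
detectOperons <- function(genes, tas) {
  n <- length(genes)
  flags <- logical(n)
  if (n < 2L) return(flags)
  tasKey <- paste(as.character(seqnames(tas)), start(tas),
                  as.character(strand(tas)))
  ord <- order(as.character(seqnames(genes)), start(genes))
  chrom <- as.character(seqnames(genes))[ord]
  st <- as.character(strand(genes))[ord]
  gs <- start(genes)[ord]; ge <- end(genes)[ord]
  # chain genomically-consecutive same-strand genes with gap <= 0
  runId <- cumsum(c(1L, as.integer(
    chrom[-1] != chrom[-length(ord)] |
      st[-1] != st[-length(ord)] |
      (gs[-1] - ge[-length(ord)] - 1L) > 0L)))
  for (r in unique(runId)) {
    idx <- which(runId == r)
    if (length(idx) < 2L) next
    members <- ord[idx]
    # transcription-first gene: leftmost on "+", rightmost on "-"
    firstMember <- if (st[idx[1]] == "-") members[length(members)]
      else members[1]
    rest <- setdiff(members, firstMember)
    fp <- .fivePrimeEnd(genes[rest])
    key <- paste(as.character(seqnames(genes))[rest], fp,
                 as.character(strand(genes))[rest])
    if (all(key %in% tasKey)) flags[members] <- TRUE
  }
  flags
}

# per-gene assignment of width-1 sites lying on the gene body (same strand)
.sitesOnGenes <- function(sites, genes) {
  GenomicRanges::findOverlaps(sites, genes, ignore.strand = FALSE)
}

#' Classify genes by trans-splicing status
#'
#' A gene is \code{trans_spliced} if at least one primary trans-splice
#' acceptor site lies on its body (same strand), \code{ambiguous} if only
#' secondary-source sites do, and \code{non_trans_spliced} if neither
#' source contributes a site.
#'
#' @param genes GRanges of gene bodies with \code{gene_id}.
#' @param tasPrimary Width-1 GRanges of primary (tag-based) acceptor
#'   sites.
#' @param tasSecondary Width-1 GRanges of secondary (annotation-based)
#'   sites; may be empty.
#' @return Character vector of statuses parallel to \code{genes}.
#' @export
classifyGeneStatus <- function(genes, tasPrimary,
                               tasSecondary = GRanges()) {
  hasPrim <- IRanges::overlapsAny(genes, tasPrimary, ignore.strand = FALSE)
  hasSec <- if (length(tasSecondary))
    IRanges::overlapsAny(genes, tasSecondary, ignore.strand = FALSE)
  else rep(FALSE, length(genes))
  ifelse(hasPrim, "trans_spliced",
         ifelse(hasSec, "ambiguous", "non_trans_spliced"))
}

#' Select the major trans-splice acceptor site of one gene
#'
#' The most tag-supported site; ties are broken 5'-most on the gene's
#' strand.
#'
#' @param tas Width-1 GRanges of one gene's acceptor sites with a
#'   \code{tag_count} column.
#' @return Single-row GRanges of the major site.
#' @export
selectMajorTas <- function(tas) {
  if (length(tas) == 0L)
    stop("selectMajorTas: empty site set")
  best <- which(tas$tag_count == max(tas$tag_count))
  if (length(best) > 1L) {
    fp <- if (as.character(strand(tas))[1] == "-")
      best[which.max(start(tas)[best])]
    else best[which.min(start(tas)[best])]
    best <- fp
  }
  tas[best]
}

# transcription-ordered cis acceptor positions of a transcript's exon set:
# acceptor k = first base of exon (k+1)
.cisAcceptors <- function(exons) {
  o <- order(exons$exon_rank)
  ex <- exons[o]
  if (length(ex) < 2L) return(integer(0))
  .fivePrimeEnd(ex[-1L])
}

#' Locate a major TAS on its gene's transcript structure
#'
#' Assigns the location category of a major trans-splice acceptor site:
#' \code{AS_k} when it coincides exactly with the k-th cis-splice acceptor
#' site, \code{5UTR_first_exon} when it lies in the first exon upstream of
#' the start codon, \code{5UTR_nd} for 5'-UTR positions on transcripts
#' whose own 5' end is not a confirmed TSS (or beyond the first exon),
#' \code{internal_exon} for exonic positions downstream of the start
#' codon, and \code{other} otherwise. Evaluated against the transcript
#' whose \code{five_prime_status} is \code{"non-SL"} when one exists.
#'
#' @param tasPos Genomic coordinate of the major TAS.
#' @param exons GRanges of one transcript's exons with \code{exon_rank}
#'   and \code{five_prime_status}.
#' @param cdsStart Genomic coordinate of the start codon's first base
#'   (\code{NA} when unknown).
#' @return Location category string.
#' @export
locateTas <- function(tasPos, exons, cdsStart = NA_integer_) {
  if (length(exons) == 0L) return("other")
  strandG <- as.character(strand(exons))[1]
  nd <- !identical(exons$five_prime_status[1], "non-SL")
  acc <- .cisAcceptors(exons)
  k <- match(tasPos, acc)
  if (!is.na(k)) return(if (nd) "AS_nd" else paste0("AS_", k))
  inExon <- which(start(exons) <= tasPos & end(exons) >= tasPos)
  if (length(inExon)) {
    rank <- exons$exon_rank[inExon[1]]
    upstreamOfCds <- if (is.na(cdsStart)) NA else if (strandG == "-")
      tasPos > cdsStart else tasPos < cdsStart
    if (isTRUE(upstreamOfCds)) {
      if (rank == 1L) return(if (nd) "5UTR_nd" else "5UTR_first_exon")
      return("5UTR_nd")
    }
    if (is.na(upstreamOfCds)) return("5UTR_nd")
    return("internal_exon")
  }
  "other"
}

#' Binomial test for first-acceptor-site preference
#'
#' Tests whether major trans-splice acceptor sites fall at the first
#' cis-splice acceptor site more often than expected. k = genes whose
#' major TAS is at acceptor 1; n = genes whose major TAS is at any cis
#' acceptor; the background proportion p0 is the fraction of all cis
#' acceptor sites that are first acceptor sites (\code{"per_site"}), or
#' the mean over genes of 1 / (number of acceptor sites)
#' (\code{"per_gene"}).
#'
#' @param locations Character vector of location categories (one per
#'   trans-spliced gene), e.g. from \code{\link{locateTas}}.
#' @param nAcceptorsPerGene Integer vector: number of cis acceptor sites
#'   of each spliced gene in the background set.
#' @param background Background-proportion definition.
#' @return A list with \code{k}, \code{n}, \code{p0} and \code{p.value}
#'   (upper-tail binomial).
#' @export
firstAsTest <- function(locations, nAcceptorsPerGene,
                        background = c("per_site", "per_gene")) {
  background <- match.arg(background)
  atAS <- grepl("^AS_[0-9]+$", locations)
  n <- sum(atAS)
  if (n == 0L) stop("firstAsTest: no major TAS at any cis acceptor site")
  k <- sum(locations == "AS_1")
  nAcc <- nAcceptorsPerGene[nAcceptorsPerGene > 0]
  p0 <- if (background == "per_site") length(nAcc) / sum(nAcc)
    else mean(1 / nAcc)
  list(k = k, n = n, p0 = p0, p.value = binomUpperTail(k, n, p0))
}

#' Trans-splicing ratio of one gene
#'
#' Fraction of a gene's 5'-end tags that are SL-derived:
#' \code{tas / (tas + tss)}, so that a higher ratio means more
#' trans-splicing.
#'
#' @param tssCount Tag count at the gene's representative TSS.
#' @param tasCount Tag count at the gene's major trans-splice acceptor
#'   site.
#' @return Ratio in [0, 1].
#' @export
transSplicingRatio <- function(tssCount, tasCount) {
  if (tssCount + tasCount <= 0)
    stop("transSplicingRatio: undefined when both tag counts are zero")
  tasCount / (tasCount + tssCount)
}

#' Split genes into TS-High and TS-Low by trans-splicing ratio
#'
#' Boundary-inclusive: a ratio equal to the threshold is TS_High.
#'
#' @param ratios Numeric ratios in [0, 1]; NAs propagate.
#' @param threshold Split point, default 0.5.
#' @return Character vector of \code{"TS_High"} / \code{"TS_Low"} labels.
#' @export
splitHighLow <- function(ratios, threshold = 0.5) {
  ifelse(is.na(ratios), NA_character_,
         ifelse(ratios >= threshold, "TS_High", "TS_Low"))
}

#' Full per-gene trans-splicing classification
#'
#' Combines the classification operations into the per-gene table of the
#' pipeline: status, operon flag, major TAS, location category, gene
#' group, trans-splicing ratio and TS-High/TS-Low class.
#'
#' @param genes GRanges of gene bodies with \code{gene_id}.
#' @param exons GRanges of exons with \code{gene_id},
#'   \code{transcript_id}, \code{exon_rank}, \code{five_prime_status}.
#' @param cds GRanges of CDS with \code{gene_id} (start codon positions).
#' @param tas Width-1 GRanges of called acceptor sites with
#'   \code{tag_count}.
#' @param tss Width-1 GRanges of called TSSs with \code{gene_id} and
#'   \code{tag_count}.
#' @param tasSecondary Optional secondary acceptor-site GRanges.
#' @param ratioThreshold TS-High/TS-Low split point.
#' @return A data.frame with one row per gene: \code{gene_id},
#'   \code{status}, \code{operonic}, \code{major_tas}, \code{location},
#'   \code{group}, \code{ts_ratio}, \code{ts_class}.
#' @export
classifyGenes <- function(genes, exons, cds, tas, tss,
                          tasSecondary = GRanges(),
                          ratioThreshold = 0.5) {
  status <- classifyGeneStatus(genes, tas, tasSecondary)
  operonic <- detectOperons(genes, tas)
  hits <- .sitesOnGenes(tas, genes)
  tasByGene <- split(S4Vectors::queryHits(hits),
                     genes$gene_id[S4Vectors::subjectHits(hits)])
  tssCount <- stats::setNames(rep(NA_real_, length(genes)),
                              genes$gene_id)
  if (length(tss) && !is.null(tss$gene_id)) {
    tssCount[tss$gene_id] <- tss$tag_count
  }
  cdsStartByGene <- stats::setNames(.fivePrimeEnd(cds), cds$gene_id)

  out <- data.frame(gene_id = genes$gene_id, status = status,
                    operonic = operonic,
                    major_tas = NA_integer_, location = NA_character_,
                    group = "none", ts_ratio = NA_real_,
                    ts_class = NA_character_,
                    stringsAsFactors = FALSE)
  for (i in seq_along(genes)) {
    gidv <- genes$gene_id[i]
    if (status[i] != "trans_spliced") next
    gt <- tas[tasByGene[[gidv]]]
    major <- selectMajorTas(gt)
    out$major_tas[i] <- start(major)
    ex <- exons[exons$gene_id == gidv]
    # prefer the transcript whose 5' end is a confirmed TSS
    txs <- split(seq_along(ex), ex$transcript_id)
    pickTx <- names(txs)[1]
    for (tx in names(txs))
      if (identical(ex$five_prime_status[txs[[tx]][1]], "non-SL")) {
        pickTx <- tx; break
      }
    exTx <- ex[txs[[pickTx]]]
    out$location[i] <- locateTas(start(major), exTx,
                                 cdsStartByGene[gidv])
    out$group[i] <- if (out$location[i] == "AS_1") "TS-1stAS"
      else if (out$location[i] == "5UTR_first_exon") "TS-5UTR"
      else "other"
    # ratio uses the gene's full SL tag mass: minor acceptor sites carry
    # genuine SL tags, so major-only counting would underestimate it
    tssC <- tssCount[[gidv]]
    if (!is.na(tssC))
      out$ts_ratio[i] <- transSplicingRatio(tssC, sum(gt$tag_count))
  }
  out$ts_class <- splitHighLow(out$ts_ratio, ratioThreshold)
  out
}
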