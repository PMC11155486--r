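#' Classify 5'-tag reads by spliced-leader prefix
#'
#' A read is SL-derived iff its first \code{minPrefixMatch} bases exactly
#' match the 3'-terminal \code{minPrefixMatch} bases of the SL sequence
#' (shorter matches support truncated leaders). SL reads are returned with
#' the matched prefix removed; every other read is a capped read, returned
#' untrimmed. Empty reads are skipped with a warning.
#'
#' @param reads A named \link[Biostrings]{DNAStringSet}.
#' @param slSequence The SL 5'-exon sequence (16 nt in the tunicate
#'   system).
#' @param minPrefixMatch Number of SL-suffix bases that must match;
#'   default the full leader.
#' @return A list with elements \code{sl} (trimmed SL reads) and
#'   \code{capped}, both named DNAStringSets partitioning the input.
#' @export
classifyReads <- function(reads, slSequence,
                          minPrefixMatch = nchar(slSequence)) {
  stopifnot(minPrefixMatch >= 1L, minPrefixMatch <= nchar(slSequence))
  empty <- Biostrings::width(reads) == 0L
  if (any(empty)) {
    warning(sum(empty), " empty read(s) skipped")
    reads <- reads[!empty]
  }
  slSuffix <- substr(slSequence, nchar(slSequence) - minPrefixMatch + 1L,
                     nchar(slSequence))
  longEnough <- Biostrings::width(reads) > minPrefixMatch
  prefix <- rep(NA_character_, length(reads))
  prefix[longEnough] <- as.character(
    Biostrings::subseq(reads[longEnough], 1L, minPrefixMatch))
  isSL <- !is.na(prefix) & prefix == slSuffix
  sl <- reads[isSL]
  if (length(sl))
    sl <- Biostrings::subseq(sl, minPrefixMatch + 1L)
  list(sl = sl, capped = reads[!isSL])
}

# all exact genome hits of a set of equal-width sequences; returns a list
# (per sequence) of data.frames chrom/pos/strand where pos is the genomic
# coordinate of the RNA 5'-most base
.exactHits <- function(seqs, genome) {
  w <- unique(Biostrings::width(seqs))
  stopifnot(length(w) == 1L)
  pd <- Biostrings::PDict(seqs)
  pdrc <- Biostrings::PDict(Biostrings::reverseComplement(seqs))
  hits <- rep(list(NULL), length(seqs))
  addHits <- function(i, chrom, pos, strand) {
    hits[[i]] <<- rbind(hits[[i]],
                        data.frame(chrom = chrom, pos = pos,
                                   strand = strand,
                                   stringsAsFactors = FALSE))
  }
  for (chrom in names(genome)) {
    mp <- Biostrings::matchPDict(pd, genome[[chrom]])
    for (i in which(lengths(mp) > 0))
      addHits(i, chrom, BiocGenerics::start(mp[[i]]), "+")
    mm <- Biostrings::matchPDict(pdrc, genome[[chrom]])
    for (i in which(lengths(mm) > 0))
      addHits(i, chrom, BiocGenerics::end(mm[[i]]), "-")
  }
  hits
}

#' Map read 5' ends to the genome by exact match
#'
#' Exact substring search of each read against both strands of the genome.
#' A read maps iff it occurs exactly once genome-wide (with
#' \code{requiredUnique}); multi-mapping and unmapped reads are counted and
#' dropped. The reported position is the genomic coordinate of the RNA
#' 5'-most base (range start on "+", range end on "-").
#'
#' @param reads A DNAStringSet of (SL-trimmed or capped) reads.
#' @param genome Named DNAStringSet.
#' @param category Tag category label, \code{"SL"} or \code{"capped"}.
#' @param requiredUnique Drop reads with more than one exact hit.
#' @return A list with \code{alignments} (width-1 GRanges with columns
#'   \code{category} and \code{count}, one row per distinct 5'-end
#'   position), \code{multimapped} and \code{unmapped} read counts.
#' @export
mapFivePrime <- function(reads, genome, category = "SL",
                         requiredUnique = TRUE) {
  if (length(reads) == 0L)
    return(list(alignments = GRanges(), multimapped = 0L, unmapped = 0L))
  seqChar <- as.character(reads)
  multimapped <- 0L; unmapped <- 0L
  rows <- list()
  for (w in unique(nchar(seqChar))) {
    inGroup <- nchar(seqChar) == w
    uniqSeq <- unique(seqChar[inGroup])
    nPerSeq <- table(factor(seqChar[inGroup], levels = uniqSeq))
    hits <- .exactHits(Biostrings::DNAStringSet(uniqSeq), genome)
    for (i in seq_along(uniqSeq)) {
      h <- hits[[i]]
      nReads <- as.integer(nPerSeq[[i]])
      if (is.null(h)) { unmapped <- unmapped + nReads; next }
      if (nrow(h) > 1L) {
        if (requiredUnique) { multimapped <- multimapped + nReads; next }
        h <- h[1L, , drop = FALSE]
      }
      rows[[length(rows) + 1L]] <-
        cbind(h, count = nReads, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(list(alignments = GRanges(), multimapped = multimapped,
                unmapped = unmapped))
  df <- do.call(rbind, rows)
  # aggregate tags landing on the same 5'-end position
  key <- paste(df$chrom, df$pos, df$strand)
  agg <- rowsum(df$count, key)
  first <- !duplicated(key)
  df2 <- df[first, , drop = FALSE]
  df2$count <- as.integer(agg[match(paste(df2$chrom, df2$pos, df2$strand),
                                    rownames(agg)), 1])
  gr <- GRanges(factor(df2$chrom, levels = names(genome)),
                IRanges(df2$pos, df2$pos), strand = df2$strand)
  mcols(gr) <- DataFrame(category = category, count = df2$count)
  list(alignments = sort(gr),
       multimapped = multimapped, unmapped = unmapped)
}

#' Cluster tag 5'-end positions
#'
#' Single-linkage chaining per chromosome, strand and category:
#' consecutive tag positions at most \code{maxGap} bp apart join one
#' cluster. The cluster mode is the position with the highest tag count;
#' ties are broken 5'-most on the cluster's own strand.
#'
#' @param alignments Width-1 GRanges with \code{category} and \code{count}
#'   columns as returned by \code{\link{mapFivePrime}}.
#' @param maxGap Maximum chaining gap in bp (default 50, the scale over
#'   which minor acceptor sites scatter around major ones).
#' @return A GRanges of clusters with columns \code{category},
#'   \code{total_tags}, \code{mode_pos}, \code{positions} and
#'   \code{counts} (IntegerLists).
#' @export
clusterTags <- function(alignments, maxGap = 50L) {
  if (length(alignments) == 0L) return(GRanges())
  key <- paste(as.character(seqnames(alignments)),
               as.character(strand(alignments)),
               alignments$category)
  out <- list()
  for (k in unique(key)) {
    a <- alignments[key == k]
    o <- order(start(a))
    pos <- start(a)[o]; cnt <- a$count[o]
    grp <- cumsum(c(1L, as.integer(diff(pos) > maxGap)))
    for (g in unique(grp)) {
      p <- pos[grp == g]; ct <- cnt[grp == g]
      best <- which(ct == max(ct))
      mode <- if (as.character(strand(a))[1] == "-")
        max(p[best]) else min(p[best])
      gr <- GRanges(factor(as.character(seqnames(a))[1],
                           levels = GenomeInfoDb::seqlevels(alignments)),
                    IRanges(min(p), max(p)), strand = strand(a)[1])
      mcols(gr) <- DataFrame(
        category = a$category[1], total_tags = sum(ct), mode_pos = mode,
        positions = IRanges::IntegerList(list(p)),
        counts = IRanges::IntegerList(list(ct)))
      out[[length(out) + 1L]] <- gr
    }
  }
  sort(do.call(c, out), ignore.strand = TRUE)
}

# strand-aware AG-context check at width-1 positions
.hasUpstreamAG <- function(genome, chrom, pos, strand) {
  mapply(function(ch, p, st) {
    L <- Biostrings::width(genome)[match(ch, names(genome))]
    if (st == "+") {
      if (p < 3L) return(FALSE)
      as.character(Biostrings::subseq(genome[[ch]], p - 2L, p - 1L)) == "AG"
    } else {
      if (p > L - 2L) return(FALSE)
      as.character(Biostrings::subseq(genome[[ch]], p + 1L, p + 2L)) == "CT"
    }
  }, chrom, pos, strand, USE.NAMES = FALSE)
}

#' Call trans-splice acceptor sites from SL tag clusters
#'
#' Within each SL cluster, every tag position whose immediate 5' genomic
#' dinucleotide (strand-aware) is AG becomes a trans-splice acceptor site
#' carrying that position's tag count; AG-incompatible positions are
#' discarded. Clusters with no AG-compatible position are dropped and
#' counted.
#'
#' @param clusters GRanges of SL-category clusters from
#'   \code{\link{clusterTags}}.
#' @param genome Named DNAStringSet.
#' @return A list with \code{tas} (width-1 GRanges, columns
#'   \code{tag_count}, \code{cluster_id}), \code{dropped_positions} and
#'   \code{dropped_clusters} counts.
#' @export
callTas <- function(clusters, genome) {
  droppedPos <- 0L; droppedClust <- 0L
  rows <- list()
  for (i in seq_along(clusters)) {
    cl <- clusters[i]
    stopifnot(cl$category == "SL")
    p <- cl$positions[[1]]; ct <- cl$counts[[1]]
    chrom <- as.character(seqnames(cl))
    st <- as.character(strand(cl))
    ok <- .hasUpstreamAG(genome, rep(chrom, length(p)), p,
                         rep(st, length(p)))
    droppedPos <- droppedPos + sum(!ok)
    if (!any(ok)) { droppedClust <- droppedClust + 1L; next }
    gr <- GRanges(factor(chrom, levels = names(genome)),
                  IRanges(p[ok], p[ok]), strand = st)
    mcols(gr) <- DataFrame(tag_count = ct[ok], cluster_id = i)
    rows[[length(rows) + 1L]] <- gr
  }
  tas <- if (length(rows)) sort(do.call(c, rows), ignore.strand = TRUE)
    else GRanges()
  # AG invariant asserted on output
  if (length(tas))
    stopifnot(all(.hasUpstreamAG(genome,
                                 as.character(seqnames(tas)), start(tas),
                                 as.character(strand(tas)))))
  list(tas = tas, dropped_positions = droppedPos,
       dropped_clusters = droppedClust)
}

#' Call TSSs from capped tag clusters with open-chromatin support
#'
#' A capped cluster yields a TSS only if its interval overlaps at least
#' one ATAC peak by at least 1 bp; clusters without peak support are
#' rejected as artifacts. When gene models are supplied, clusters are
#' assigned to genes (overlap of the cluster mode with the gene body, same
#' strand) and the representative TSS per gene is the mode of its
#' highest-count supported cluster.
#'
#' @param clusters GRanges of capped-category clusters.
#' @param peaks GRanges of open-chromatin peaks.
#' @param genes Optional GRanges of gene bodies with a \code{gene_id}
#'   column.
#' @return A list with \code{tss} (width-1 GRanges, columns
#'   \code{tag_count}, and \code{gene_id} when genes were supplied) and
#'   \code{rejected} (count of clusters without peak support).
#' @export
callTss <- function(clusters, peaks, genes = NULL) {
  if (length(clusters) == 0L)
    return(list(tss = GRanges(), rejected = 0L))
  stopifnot(all(clusters$category == "capped"))
  ov <- IRanges::overlapsAny(clusters, peaks, ignore.strand = TRUE)
  rejected <- sum(!ov)
  kept <- clusters[ov]
  if (length(kept) == 0L)
    return(list(tss = GRanges(), rejected = rejected))
  modes <- GRanges(seqnames(kept), IRanges(kept$mode_pos, kept$mode_pos),
                   strand = strand(kept))
  mcols(modes) <- DataFrame(tag_count = kept$total_tags)
  if (is.null(genes))
    return(list(tss = sort(modes, ignore.strand = TRUE),
                rejected = rejected))
  hit <- GenomicRanges::findOverlaps(modes, genes, ignore.strand = FALSE)
  if (!length(hit))
    return(list(tss = GRanges(), rejected = rejected))
  df <- data.frame(cluster = S4Vectors::queryHits(hit),
                   gene = S4Vectors::subjectHits(hit))
  df$count <- modes$tag_count[df$cluster]
  # highest-count supported cluster per gene
  df <- df[order(df$gene, -df$count, start(modes)[df$cluster]), ]
  df <- df[!duplicated(df$gene), ]
  tss <- modes[df$cluster]
  mcols(tss)$gene_id <- genes$gene_id[df$gene]
  list(tss = sort(tss, ignore.strand = TRUE), rejected = rejected)
}
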