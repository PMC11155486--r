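#' Nucleotide content of a sequence
#'
#' Fraction of bases belonging to a nucleotide set. Sets are written in
#' RNA terms on the coding strand, so U counts T ("GU" content is the
#' G + T fraction of the transcribed-strand DNA).
#'
#' @param seq A single sequence (character or DNAString).
#' @param bases Character vector of bases, e.g. \code{c("G", "U")}.
#' @return Fraction in [0, 1].
#' @export
regionContent <- function(seq, bases) {
  s <- toupper(as.character(seq))
  if (nchar(s) == 0L) stop("regionContent: empty sequence")
  bases <- toupper(bases)
  bases[bases == "U"] <- "T"
  ch <- strsplit(s, "")[[1]]
  mean(ch %in% bases)
}

#' Strand-aware regions around anchor points
#'
#' Extracts transcribed-strand sequence windows around width-1 anchor
#' sites (TSSs or first acceptor sites): \code{upstream} bases 5' of the
#' anchor and \code{downstream} bases from the anchor on (the anchor base
#' is the first downstream base). Anchors too close to a contig edge are
#' dropped.
#'
#' @param anchors Width-1 GRanges of anchor positions.
#' @param genome Named DNAStringSet.
#' @param upstream,downstream Span in bp on each side of the anchor.
#' @return A DNAStringSet (named by \code{anchors$gene_id} when present);
#'   position \code{upstream + 1} of every sequence is the anchor base.
#' @export
anchorRegions <- function(anchors, genome, upstream = 0L,
                          downstream = 240L) {
  if (!length(anchors)) return(Biostrings::DNAStringSet())
  lens <- stats::setNames(Biostrings::width(genome), names(genome))
  st <- as.character(strand(anchors))
  pos <- start(anchors)
  gs <- ifelse(st == "-", pos - downstream + 1L, pos - upstream)
  ge <- ifelse(st == "-", pos + upstream, pos + downstream - 1L)
  ok <- gs >= 1L & ge <= lens[as.character(seqnames(anchors))]
  gr <- GRanges(seqnames(anchors)[ok], IRanges(gs[ok], ge[ok]),
                strand = st[ok])
  seqs <- extractRegions(genome, gr)
  if (!is.null(anchors$gene_id)) names(seqs) <- anchors$gene_id[ok]
  seqs
}

#' Sliding-window nucleotide content profiles
#'
#' Tiles 30-bp (by default) windows along each sequence and computes the
#' content of a nucleotide set per window. Sequences shorter than a
#' window's end simply drop out of that window's sample (partial windows
#' are excluded).
#'
#' @param seqs DNAStringSet of anchored regions (position 1 = anchor,
#'   or use \code{offset0} to report coordinates relative to an anchor
#'   placed inside the sequence).
#' @param bases Nucleotide set (U counts T).
#' @param window Window width in bp.
#' @param step Step between window starts in bp.
#' @param offset0 Offset (bp) of sequence position 1 relative to the
#'   anchor; e.g. \code{-100} for windows starting 100 bp upstream.
#' @return A list with \code{offsets} (window start offsets from the
#'   anchor) and \code{values} (genes x windows matrix, NA where the
#'   sequence does not cover the window).
#' @export
profileContent <- function(seqs, bases, window = 30L, step = 10L,
                           offset0 = 0L) {
  maxLen <- if (length(seqs)) max(Biostrings::width(seqs)) else 0L
  if (maxLen < window)
    return(list(offsets = integer(0),
                values = matrix(numeric(0), nrow = length(seqs))))
  starts <- seq(1L, maxLen - window + 1L, by = step)
  bases <- toupper(bases); bases[bases == "U"] <- "T"
  chs <- strsplit(as.character(seqs), "")
  vals <- matrix(NA_real_, nrow = length(seqs), ncol = length(starts))
  for (i in seq_along(chs)) {
    inSet <- chs[[i]] %in% bases
    cs <- cumsum(inSet)
    ok <- starts + window - 1L <= length(inSet)
    e <- starts[ok] + window - 1L
    vals[i, ok] <- (cs[e] - c(0, cs)[starts[ok]]) / window
  }
  rownames(vals) <- names(seqs)
  list(offsets = starts - 1L + offset0, values = vals)
}

#' Per-window content enrichment test
#'
#' For each window, tests with a one-sided (greater) Mann-Whitney U test
#' whether the content is higher in target (trans-spliced) genes than in
#' control (non-trans-spliced) genes; p-values are BH-adjusted across the
#' windows of one content spec. Fold enrichment is the ratio of group
#' centers (means by default).
#'
#' @param target,control Profile lists from \code{\link{profileContent}}
#'   computed on the same window grid.
#' @param minPerGroup Windows with fewer covering genes in either group
#'   are marked untested.
#' @param center \code{"mean"} or \code{"median"} for fold enrichment.
#' @param alternative Test direction; default \code{"greater"}.
#' @return data.frame with one row per window: \code{offset},
#'   \code{n_target}, \code{n_control}, \code{fold_enrichment},
#'   \code{p.value}, \code{fdr}, \code{tested}.
#' @export
testContentWindows <- function(target, control, minPerGroup = 2L,
                               center = c("mean", "median"),
                               alternative = "greater") {
  center <- match.arg(center)
  stopifnot(identical(target$offsets, control$offsets))
  cfun <- if (center == "mean") mean else stats::median
  nW <- length(target$offsets)
  out <- data.frame(offset = target$offsets,
                    n_target = NA_integer_, n_control = NA_integer_,
                    fold_enrichment = NA_real_, p.value = NA_real_,
                    fdr = NA_real_, tested = FALSE)
  for (j in seq_len(nW)) {
    tv <- target$values[, j]; tv <- tv[!is.na(tv)]
    cv <- control$values[, j]; cv <- cv[!is.na(cv)]
    out$n_target[j] <- length(tv); out$n_control[j] <- length(cv)
    if (length(tv) < minPerGroup || length(cv) < minPerGroup) next
    out$tested[j] <- TRUE
    out$fold_enrichment[j] <- cfun(tv) / cfun(cv)
    out$p.value[j] <- mannWhitneyU(tv, cv,
                                   alternative = alternative)$p.value
  }
  out$fdr[out$tested] <- bhAdjust(out$p.value[out$tested])
  out
}

#' Whole-region content comparison across several nucleotide specs
#'
#' Compares whole-region content (e.g. of the first exon + intron) of
#' target vs control genes for each content spec with a two-sided
#' Mann-Whitney U test, BH-adjusting across the specs in the batch (four
#' single-nucleotide or six dinucleotide specs).
#'
#' @param targetSeqs,controlSeqs DNAStringSets of whole regions.
#' @param specs List of nucleotide sets, e.g.
#'   \code{list(U = "U", GU = c("G","U"))}.
#' @return data.frame with \code{spec}, \code{mean_target},
#'   \code{mean_control}, \code{p.value}, \code{fdr}.
#' @export
compareRegionContent <- function(targetSeqs, controlSeqs, specs) {
  rows <- lapply(names(specs), function(nm) {
    b <- specs[[nm]]
    tv <- vapply(as.character(targetSeqs), regionContent, numeric(1),
                 bases = b, USE.NAMES = FALSE)
    cv <- vapply(as.character(controlSeqs), regionContent, numeric(1),
                 bases = b, USE.NAMES = FALSE)
    data.frame(spec = nm, mean_target = mean(tv),
               mean_control = mean(cv),
               p.value = mannWhitneyU(tv, cv, "two.sided")$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- bhAdjust(out$p.value)
  out
}
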