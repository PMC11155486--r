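# per-position log-odds of a PWM against its background, plus the
# integer-discretized score system used for the exact null distribution
.pwmScoreSystem <- function(pwm, granularity = 2000L) {
  lo <- log(pwm@matrix) - log(matrix(pwm@background, nrow(pwm@matrix),
                                     4, byrow = TRUE))
  if (any(!is.finite(lo)))
    stop("PWM has zero entries; train or load it with pseudocounts")
  rng <- sum(apply(lo, 1, max) - apply(lo, 1, min))
  eps <- if (rng > 0) rng / granularity else 1
  ilo <- round(lo / eps)
  ilo <- ilo - apply(ilo, 1, min)          # shift each column to min 0
  list(lo = lo, ilo = ilo, eps = eps)
}

# exact null distribution of the integer score under the background
# model, by dynamic programming (convolution over positions); returns
# P(S >= s) for s = 0..max
.pwmNullUpperTail <- function(pwm, sys) {
  w <- nrow(pwm@matrix)
  maxS <- sum(apply(sys$ilo, 1, max))
  p <- c(1, numeric(maxS))                  # P(S = s) after 0 positions
  for (i in seq_len(w)) {
    np <- numeric(maxS + 1L)
    for (b in 1:4) {
      s <- sys$ilo[i, b]
      if (pwm@background[b] > 0)
        np[(s + 1L):(maxS + 1L)] <- np[(s + 1L):(maxS + 1L)] +
          p[1:(maxS + 1L - s)] * pwm@background[b]
    }
    p <- np
  }
  rev(cumsum(rev(p)))                       # upper tail over integer scores
}

#' Scan sequences with a PWM (FIMO-style)
#'
#' At each offset the window is scored as the sum of per-position
#' log-likelihood ratios against the background model. The score p-value
#' is the exact probability, under the background model, of an equal or
#' higher score, computed from the integer-discretized null score
#' distribution by dynamic programming. A hit is any offset with p-value
#' at or below \code{pThreshold}.
#'
#' @param pwm A \linkS4class{MotifPWM} (no zero entries).
#' @param seqs Named character vector or DNAStringSet.
#' @param pThreshold Score p-value threshold for calling hits
#'   (default 1e-4).
#' @return data.frame of hits: \code{seq_id}, \code{offset} (1-based
#'   start), \code{score} (log-likelihood ratio, natural log units),
#'   \code{p.value}.
#' @export
scanMotif <- function(pwm, seqs, pThreshold = 1e-4) {
  w <- motifWidth(pwm)
  seqs <- as.character(seqs)
  if (is.null(names(seqs)))
    names(seqs) <- sprintf("seq_%d", seq_along(seqs))
  sys <- .pwmScoreSystem(pwm)
  tail <- .pwmNullUpperTail(pwm, sys)
  rows <- list()
  for (si in seq_along(seqs)) {
    ch <- match(strsplit(seqs[[si]], "")[[1]], DNA_BASES4)
    L <- length(ch)
    if (L < w) next
    nOff <- L - w + 1L
    # windowed sums as w shifted vector adds (vectorized over offsets)
    iscore <- integer(nOff); score <- numeric(nOff)
    for (i in seq_len(w)) {
      bi <- ch[i:(nOff + i - 1L)]
      iscore <- iscore + sys$ilo[cbind(i, bi)]
      score <- score + sys$lo[cbind(i, bi)]
    }
    pv <- tail[iscore + 1L]
    hit <- which(!is.na(pv) & pv <= pThreshold)
    if (length(hit))
      rows[[length(rows) + 1L]] <- data.frame(
        seq_id = names(seqs)[si], offset = hit, score = score[hit],
        p.value = pv[hit], stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(seq_id = character(0), offset = integer(0),
                      score = numeric(0), p.value = numeric(0)))
  do.call(rbind, rows)
}

#' Exact null upper tail of PWM scores
#'
#' Exposes the dynamic-programming null distribution for verification:
#' the probability under the background model that a random window scores
#' at least each integer-discretized score.
#'
#' @param pwm A \linkS4class{MotifPWM}.
#' @return A list with \code{upper_tail} (vector over integer scores
#'   0..max), \code{eps} (discretization unit) and \code{ilo} (the
#'   integer score matrix).
#' @export
pwmNullDistribution <- function(pwm) {
  sys <- .pwmScoreSystem(pwm)
  list(upper_tail = .pwmNullUpperTail(pwm, sys), eps = sys$eps,
       ilo = sys$ilo)
}

#' Sample background sequences from intergenic space
#'
#' Draws fixed-length sequences uniformly from the intergenic intervals
#' of a genome (positions where the whole window fits in one interval).
#'
#' @param genome Named DNAStringSet.
#' @param genes GRanges of gene bodies to exclude.
#' @param n Number of sequences (3000 in the published protocol).
#' @param length Sequence length in bp.
#' @param seed RNG seed.
#' @return A DNAStringSet of \code{n} sequences.
#' @export
sampleBackground <- function(genome, genes, n, length, seed = 1L) {
  set.seed(seed)
  if (n == 0L) return(Biostrings::DNAStringSet())
  lens <- Biostrings::width(genome)
  all <- GRanges(names(genome), IRanges(1L, lens))
  inter <- if (base::length(genes))
    GenomicRanges::setdiff(all, GenomicRanges::reduce(granges(genes),
                           ignore.strand = TRUE), ignore.strand = TRUE)
  else all
  inter <- inter[width(inter) >= length]
  nStarts <- width(inter) - length + 1L
  if (sum(as.numeric(width(inter))) < n * length)
    stop("sampleBackground: intergenic space (", sum(width(inter)),
         " bp) is smaller than n * length = ", n * length, " bp")
  iv <- sample.int(base::length(inter), n, replace = TRUE,
                   prob = nStarts)
  off <- vapply(iv, function(i) sample.int(nStarts[i], 1L), integer(1))
  gr <- GRanges(seqnames(inter)[iv],
                IRanges(start(inter)[iv] + off - 1L, width = length))
  extractRegions(genome, gr)
}

# per-sequence presence/absence of >=1 hit starting in each window
.hitPresence <- function(hits, seqNames, offsets, window) {
  pres <- matrix(FALSE, nrow = length(seqNames), ncol = length(offsets),
                 dimnames = list(seqNames, NULL))
  if (!nrow(hits)) return(pres)
  for (j in seq_along(offsets)) {
    lo <- offsets[j] + 1L; hi <- offsets[j] + window
    inWin <- hits$offset >= lo & hits$offset <= hi
    pres[unique(hits$seq_id[inWin]), j] <- TRUE
  }
  pres
}

#' Stage-1 local motif enrichment: binomial test against background
#'
#' Per 30-bp window, counts the target sequences with at least one motif
#' hit starting in the window (k of n) and the fraction of background
#' sequences with a hit in the same window (p), and computes the
#' upper-tail binomial p-value. BH correction is applied across windows;
#' windows with FDR < \code{fdrCut} are candidates of locally enriched
#' regions.
#'
#' @param targetSeqs,backgroundSeqs Named DNAStringSets (anchored,
#'   equal-grid regions).
#' @param pwm A \linkS4class{MotifPWM}.
#' @param window,step Window geometry in bp.
#' @param pThreshold Hit-calling score p-value threshold.
#' @param fdrCut Candidate-window FDR cutoff.
#' @return data.frame per window: \code{offset}, \code{n}, \code{k},
#'   \code{p_bg}, \code{p.value}, \code{fdr}, \code{candidate}.
#' @export
motifStage1 <- function(targetSeqs, backgroundSeqs, pwm, window = 30L,
                        step = 10L, pThreshold = 1e-4, fdrCut = 0.05) {
  stopifnot(length(targetSeqs) > 0L, length(backgroundSeqs) > 0L)
  span <- min(max(Biostrings::width(targetSeqs)),
              max(Biostrings::width(backgroundSeqs)))
  offsets <- seq(0L, span - window, by = step)
  if (is.null(names(targetSeqs)))
    names(targetSeqs) <- sprintf("t%d", seq_along(targetSeqs))
  if (is.null(names(backgroundSeqs)))
    names(backgroundSeqs) <- sprintf("b%d", seq_along(backgroundSeqs))
  ht <- scanMotif(pwm, targetSeqs, pThreshold)
  hb <- scanMotif(pwm, backgroundSeqs, pThreshold)
  pt <- .hitPresence(ht, names(targetSeqs), offsets, window)
  pb <- .hitPresence(hb, names(backgroundSeqs), offsets, window)
  n <- length(targetSeqs)
  out <- data.frame(offset = offsets, n = n, k = colSums(pt),
                    p_bg = colMeans(pb))
  out$p.value <- vapply(seq_len(nrow(out)), function(j) {
    if (out$p_bg[j] == 0 && out$k[j] > 0) 0
    else binomUpperTail(out$k[j], n, out$p_bg[j])
  }, numeric(1))
  out$fdr <- bhAdjust(out$p.value)
  out$candidate <- out$fdr < fdrCut
  out
}

#' Stage-2 local motif enrichment: Fisher test against control genes
#'
#' For each stage-1 candidate window, builds the 2x2 table of
#' motif-carrying target vs control sequences and computes the one-sided
#' (enrichment) Fisher exact p-value; BH correction across the candidate
#' windows. A motif is locally enriched iff at least one window survives
#' at FDR < \code{fdrCut}.
#'
#' @param targetSeqs,controlSeqs Named DNAStringSets.
#' @param pwm A \linkS4class{MotifPWM}.
#' @param candidateOffsets Window start offsets from stage 1.
#' @param window Window width in bp.
#' @param pThreshold Hit-calling threshold.
#' @param fdrCut Significance cutoff.
#' @return A list with \code{table} (data.frame per candidate window:
#'   \code{offset}, \code{N}, \code{C}, \code{R}, \code{x},
#'   \code{log2_fe}, \code{p.value}, \code{fdr}) and \code{enriched}
#'   (logical).
#' @export
motifStage2 <- function(targetSeqs, controlSeqs, pwm, candidateOffsets,
                        window = 30L, pThreshold = 1e-4, fdrCut = 0.05) {
  if (!length(candidateOffsets))
    return(list(table = data.frame(), enriched = FALSE))
  if (is.null(names(targetSeqs)))
    names(targetSeqs) <- sprintf("t%d", seq_along(targetSeqs))
  if (is.null(names(controlSeqs)))
    names(controlSeqs) <- sprintf("c%d", seq_along(controlSeqs))
  ht <- scanMotif(pwm, targetSeqs, pThreshold)
  hc <- scanMotif(pwm, controlSeqs, pThreshold)
  pt <- .hitPresence(ht, names(targetSeqs), candidateOffsets, window)
  pc <- .hitPresence(hc, names(controlSeqs), candidateOffsets, window)
  R <- length(targetSeqs)
  N <- R + length(controlSeqs)
  out <- data.frame(offset = candidateOffsets,
                    N = N, C = colSums(pt) + colSums(pc), R = R,
                    x = colSums(pt))
  out$log2_fe <- log2((out$x / out$R) /
                        ((out$C - out$x) / (out$N - out$R)))
  out$p.value <- vapply(seq_len(nrow(out)), function(j)
    fisherOneSided(out$N[j], out$C[j], out$R[j], out$x[j]), numeric(1))
  out$fdr <- bhAdjust(out$p.value)
  list(table = out, enriched = any(out$fdr < fdrCut))
}

# best ungapped alignment of two PWMs: max over offsets of the mean
# per-column Pearson correlation (overlap of at least minOverlap columns)
.pwmSimilarity <- function(a, b, minOverlap = 4L) {
  ma <- a@matrix; mb <- b@matrix
  wa <- nrow(ma); wb <- nrow(mb)
  best <- -Inf; bestOff <- 0L; bestLen <- 0L
  for (off in seq(-(wb - minOverlap), wa - minOverlap)) {
    ia <- max(1L, 1L + off):min(wa, wb + off)
    ib <- ia - off
    if (length(ia) < minOverlap) next
    cc <- vapply(seq_along(ia), function(k) {
      va <- ma[ia[k], ]; vb <- mb[ib[k], ]
      if (stats::sd(va) == 0 || stats::sd(vb) == 0) return(1)
      stats::cor(va, vb)
    }, numeric(1))
    m <- mean(cc)
    # ties (e.g. periodic motifs) resolved toward the longer overlap
    if (m > best + 1e-12 ||
        (abs(m - best) <= 1e-12 && length(ia) > bestLen)) {
      best <- m; bestOff <- off; bestLen <- length(ia)
    }
  }
  list(sim = best, offset = bestOff)
}

#' Merge redundant motifs
#'
#' Pairwise similarity is the best ungapped-offset mean per-column
#' Pearson correlation; motifs are single-linkage clustered at the given
#' threshold and each cluster is collapsed to one representative by
#' position-wise averaging after aligning every member to the cluster's
#' lexicographically first motif at its best offset. The procedure is
#' invariant to the input order.
#'
#' @param pwms List of \linkS4class{MotifPWM}.
#' @param threshold Similarity threshold for merging (default 0.8).
#' @return Named list of nonredundant \linkS4class{MotifPWM}s; merged
#'   representatives carry the ids of their members joined by "+".
#' @export
mergeMotifs <- function(pwms, threshold = 0.8) {
  n <- length(pwms)
  if (n <= 1L) return(pwms)
  ids <- vapply(pwms, motifId, character(1))
  ord <- order(ids)
  pwms <- pwms[ord]; ids <- ids[ord]
  sim <- matrix(1, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    sim[i, j] <- sim[j, i] <- .pwmSimilarity(pwms[[i]], pwms[[j]])$sim
  # single-linkage clusters above threshold
  cl <- stats::cutree(stats::hclust(stats::as.dist(1 - sim),
                                    method = "single"),
                      h = 1 - threshold)
  out <- list()
  for (g in sort(unique(cl))) {
    members <- which(cl == g)
    if (length(members) == 1L) {
      out[[ids[members]]] <- pwms[[members]]
      next
    }
    ref <- members[1L]                       # lexicographically first id
    refM <- pwms[[ref]]@matrix
    stack <- matrix(0, nrow(refM), 4)
    cnt <- matrix(0, nrow(refM), 4)
    for (m in members) {
      al <- .pwmSimilarity(pwms[[ref]], pwms[[m]])
      mm <- pwms[[m]]@matrix
      ia <- max(1L, 1L + al$offset):min(nrow(refM), nrow(mm) + al$offset)
      ib <- ia - al$offset
      stack[ia, ] <- stack[ia, ] + mm[ib, ]
      cnt[ia, ] <- cnt[ia, ] + 1
    }
    avg <- stack / pmax(cnt, 1)
    keep <- rowSums(cnt) > 0
    avg <- avg[keep, , drop = FALSE]
    avg <- avg / rowSums(avg)
    newId <- paste(ids[members], collapse = "+")
    out[[newId]] <- motifPWM(newId, avg, pwms[[ref]]@background)
  }
  out[order(names(out))]
}

#' Per-motif, per-window log2 fold-enrichment matrix with clustering
#'
#' Collects stage-2 fold enrichments
#' \code{FE = (x/R) / ((C-x)/(N-R))} into a motifs x windows matrix of
#' log2 values and orders motifs by complete-linkage clustering on the
#' Euclidean distances between their log2(FE) window vectors (missing
#' values are excluded pairwise from the distances).
#'
#' @param stage2List Named list (per motif) of \code{\link{motifStage2}}
#'   results computed on a common window grid.
#' @param offsets The common window-offset grid.
#' @return A list with \code{log2_fe} (matrix), \code{order} (row order
#'   from clustering) and \code{hclust} (the tree, or NULL for < 2
#'   motifs).
#' @export
foldEnrichmentMatrix <- function(stage2List, offsets) {
  m <- matrix(NA_real_, nrow = length(stage2List),
              ncol = length(offsets),
              dimnames = list(names(stage2List), offsets))
  for (nm in names(stage2List)) {
    tb <- stage2List[[nm]]$table
    if (!is.null(tb) && nrow(tb)) {
      v <- tb$log2_fe
      v[!is.finite(v)] <- NA_real_
      m[nm, match(tb$offset, offsets)] <- v
    }
  }
  if (nrow(m) < 2L)
    return(list(log2_fe = m, order = seq_len(nrow(m)), hclust = NULL))
  d <- stats::dist(m)                       # Euclidean, NA pairwise-dropped
  d[is.na(d)] <- max(d, na.rm = TRUE) + 1
  hc <- stats::hclust(d, method = "complete")
  list(log2_fe = m, order = hc$order, hclust = hc)
}
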