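#' Splice-site strength model
#'
#' A trained sequence model over fixed-width splice-site windows: 9-bp
#' donor windows (-3..+6 around the exon|intron boundary) or 23-bp
#' acceptor windows (-20..+3 around the intron|exon boundary). The signal
#' distribution is either a position weight matrix (independent columns),
#' a full maximum-entropy k-mer table fitted by iterative proportional
#' fitting, or a factorized adjacent-pair (first-order Markov) model for
#' windows too wide to enumerate. Scores are log2 odds against a
#' background model (uniform by default).
#'
#' @slot siteType \code{"donor"}, \code{"acceptor"} or \code{"custom"}.
#' @slot modelKind \code{"PWM"} or \code{"MEM"}.
#' @slot width Window width in nt.
#' @slot dist Internal distribution representation (list with a
#'   \code{kind} element: \code{"pwm"}, \code{"table"} or
#'   \code{"markov"}).
#' @slot pseudocount Smoothing pseudocount used in training.
#' @export
setClass("SpliceSiteModel",
  representation(siteType = "character", modelKind = "character",
                 width = "integer", dist = "list",
                 pseudocount = "numeric"))

setMethod("show", "SpliceSiteModel", function(object) {
  cat("SpliceSiteModel:", object@modelKind, object@siteType,
      "width", object@width,
      sprintf("(%s representation)\n", object@dist$kind))
})

.siteTypeFromWidth <- function(w) {
  if (w == 9L) "donor" else if (w == 23L) "acceptor" else "custom"
}

# n x w integer matrix of base codes 1..4 from sequences
.kmerMatrix <- function(sites) {
  sites <- as.character(sites)
  w <- unique(nchar(sites))
  if (length(w) != 1L)
    stop("sites must all have the same width")
  m <- matrix(match(unlist(strsplit(sites, "")), DNA_BASES4),
              ncol = w, byrow = TRUE)
  if (anyNA(m)) stop("sites contain non-ACGT characters")
  m
}

#' Extract first (or k-th) donor / acceptor site windows
#'
#' Computes intron boundaries from transcript exon chains and extracts the
#' fixed splice-site windows: donor = last 3 exonic + first 6 intronic
#' bases (9 nt); acceptor = last 20 intronic + first 3 exonic bases
#' (23 nt). Extraction is strand-aware (windows are reported on the
#' transcribed strand); windows crossing a contig edge are dropped.
#'
#' @param exons GRanges of exons with \code{transcript_id} and
#'   \code{exon_rank} (transcription order).
#' @param genome Named DNAStringSet.
#' @param siteType \code{"donor"} or \code{"acceptor"}.
#' @param intronIndex Which intron (1 = first intron).
#' @return A DNAStringSet named by transcript id.
#' @export
extractSpliceSites <- function(exons, genome,
                               siteType = c("donor", "acceptor"),
                               intronIndex = 1L) {
  siteType <- match.arg(siteType)
  out <- list()
  lens <- stats::setNames(Biostrings::width(genome), names(genome))
  for (tx in unique(exons$transcript_id)) {
    ex <- exons[exons$transcript_id == tx]
    ex <- ex[order(ex$exon_rank)]
    if (length(ex) < intronIndex + 1L) next
    strandG <- as.character(strand(ex))[1]
    chrom <- as.character(seqnames(ex))[1]
    up <- ex[intronIndex]; down <- ex[intronIndex + 1L]
    if (strandG == "+") {
      s <- end(up) + 1L; e <- start(down) - 1L
      dr <- c(s - 3L, s + 5L); ar <- c(e - 19L, e + 3L)
    } else {
      s <- end(down) + 1L; e <- start(up) - 1L
      dr <- c(e - 5L, e + 3L); ar <- c(s - 3L, s + 19L)
    }
    rng <- if (siteType == "donor") dr else ar
    if (rng[1] < 1L || rng[2] > lens[[chrom]]) next
    gr <- GRanges(chrom, IRanges(rng[1], rng[2]), strand = strandG)
    out[[tx]] <- as.character(extractRegions(genome, gr))
  }
  if (!length(out)) return(Biostrings::DNAStringSet())
  res <- Biostrings::DNAStringSet(unlist(out))
  res
}

#' Train a position weight matrix splice-site model
#'
#' Column probabilities are \code{(count + pseudocount) /
#' (n + 4 * pseudocount)}.
#'
#' @param sites Character vector or DNAStringSet of equal-width site
#'   sequences.
#' @param pseudocount Additive smoothing per base.
#' @return A \linkS4class{SpliceSiteModel} of kind PWM.
#' @export
trainPwm <- function(sites, pseudocount = 0.25) {
  km <- .kmerMatrix(sites)
  n <- nrow(km); w <- ncol(km)
  m <- t(vapply(seq_len(w), function(j)
    (tabulate(km[, j], nbins = 4L) + pseudocount) / (n + 4 * pseudocount),
    numeric(4)))
  colnames(m) <- DNA_BASES4
  new("SpliceSiteModel", siteType = .siteTypeFromWidth(w),
      modelKind = "PWM", width = as.integer(w),
      dist = list(kind = "pwm", pwm = m), pseudocount = pseudocount)
}

# empirical marginal over a position set, with pseudocount smoothing
.empMarginal <- function(km, cset, pseudocount) {
  n <- nrow(km)
  if (length(cset) == 1L) {
    (tabulate(km[, cset], nbins = 4L) + pseudocount) /
      (n + 4 * pseudocount)
  } else {
    idx <- km[, cset[1]] + 4L * (km[, cset[2]] - 1L)
    matrix((tabulate(idx, nbins = 16L) + pseudocount) /
             (n + 16 * pseudocount), nrow = 4)
  }
}

#' Train a maximum-entropy splice-site model
#'
#' Fits the maximum-entropy distribution over the k-mer space subject to
#' empirical marginal constraints, by iterative proportional fitting:
#' each sweep rescales the current distribution so one constrained
#' marginal matches its empirical value, until all residuals fall below
#' \code{tol}. With single-position constraints only, the fit is the
#' product of position marginals (PWM-equivalent). For windows wider than
#' \code{maxEnumWidth} (the 23-nt acceptor window; 4^23 k-mers cannot be
#' enumerated) the model is factorized over adjacent-pair constraint
#' blocks and scored as a first-order Markov chain.
#'
#' @param sites Site sequences (equal width).
#' @param constraints \code{"pairs"} (adjacent-pair marginals, which
#'   imply the single-position marginals) or \code{"single"}
#'   (single-position marginals only; PWM-equivalent).
#' @param tol Convergence tolerance on marginal residuals.
#' @param maxIter Iteration cap; exceeding it is an error reporting the
#'   largest residual.
#' @param pseudocount Additive smoothing applied to constraint marginals.
#' @param maxEnumWidth Widest window fitted on the full k-mer table.
#' @return A \linkS4class{SpliceSiteModel} of kind MEM.
#' @export
trainMem <- function(sites, constraints = c("pairs", "single"),
                     tol = 1e-6, maxIter = 500L, pseudocount = 0.25,
                     maxEnumWidth = 10L) {
  constraints <- match.arg(constraints)
  km <- .kmerMatrix(sites)
  w <- ncol(km)
  if (w > maxEnumWidth) {
    # factorized adjacent-pair (first-order Markov) representation
    p1 <- .empMarginal(km, 1L, pseudocount)
    trans <- lapply(seq_len(w - 1L), function(i) {
      pij <- .empMarginal(km, c(i, i + 1L), pseudocount)
      if (constraints == "single") {
        pj <- .empMarginal(km, i + 1L, pseudocount)
        matrix(rep(pj, each = 4), nrow = 4)   # independence
      } else {
        sweep(pij, 1, rowSums(pij), "/")
      }
    })
    dist <- list(kind = "markov", p1 = p1, trans = trans)
    return(new("SpliceSiteModel", siteType = .siteTypeFromWidth(w),
               modelKind = "MEM", width = as.integer(w), dist = dist,
               pseudocount = pseudocount))
  }
  # adjacent-pair constraints imply the single-position marginals (the
  # smoothed pair tables are mutually consistent), so the two kinds are
  # never mixed: mixing separately-smoothed singles and pairs would give
  # an inconsistent constraint set and IPF could not converge
  csets <- if (constraints == "pairs")
    lapply(seq_len(w - 1L), function(i) c(i, i + 1L))
  else lapply(seq_len(w), function(i) i)
  emp <- lapply(csets, function(cs) .empMarginal(km, cs, pseudocount))
  q <- array(1 / 4^w, dim = rep(4L, w))
  for (iter in seq_len(maxIter)) {
    for (ci in seq_along(csets)) {
      cs <- csets[[ci]]
      cur <- apply(q, cs, sum)
      ratio <- emp[[ci]] / cur
      if (length(cs) == 1L) {
        q <- q * as.vector(ratio)[slice.index(q, cs)]
      } else {
        ii <- slice.index(q, cs[1]); jj <- slice.index(q, cs[2])
        q <- q * ratio[cbind(as.vector(ii), as.vector(jj))]
      }
    }
    resid <- max(vapply(seq_along(csets), function(ci)
      max(abs(apply(q, csets[[ci]], sum) - emp[[ci]])), numeric(1)))
    if (resid < tol) {
      dist <- list(kind = "table", table = q)
      return(new("SpliceSiteModel", siteType = .siteTypeFromWidth(w),
                 modelKind = "MEM", width = as.integer(w), dist = dist,
                 pseudocount = pseudocount))
    }
  }
  stop(sprintf(
    "trainMem: not converged after %d iterations (max residual %.3g)",
    maxIter, resid))
}

#' Probability of k-mers under a splice-site model
#'
#' @param model A \linkS4class{SpliceSiteModel}.
#' @param kmers Character vector or DNAStringSet of sequences matching
#'   the model width.
#' @return Numeric probability vector.
#' @export
siteProbability <- function(model, kmers) {
  km <- .kmerMatrix(kmers)
  if (ncol(km) != model@width)
    stop("k-mer width ", ncol(km), " does not match model width ",
         model@width)
  d <- model@dist
  switch(d$kind,
    pwm = apply(km, 1, function(x)
      prod(d$pwm[cbind(seq_along(x), x)])),
    table = d$table[km],
    markov = apply(km, 1, function(x) {
      p <- d$p1[x[1]]
      for (i in seq_len(length(x) - 1L))
        p <- p * d$trans[[i]][x[i], x[i + 1L]]
      p
    }),
    stop("unknown distribution kind"))
}

#' Score splice sites as log2 odds
#'
#' \code{log2(P_signal(kmer) / P_background(kmer))}; the higher the
#' score, the stronger the splice site. Background defaults to the
#' uniform distribution over the window.
#'
#' @param signal Signal \linkS4class{SpliceSiteModel}.
#' @param kmers Sequences to score.
#' @param background Optional background model (e.g. trained on decoy
#'   sites); NULL means uniform.
#' @return Numeric vector of scores in log2 units.
#' @export
scoreSpliceSites <- function(signal, kmers, background = NULL) {
  ps <- siteProbability(signal, kmers)
  pb <- if (is.null(background)) rep(0.25^signal@width, length(ps))
    else siteProbability(background, kmers)
  if (any(pb <= 0))
    stop("scoreSpliceSites: zero background probability (use pseudocounts)")
  log2(ps / pb)
}

#' Compare splice-site strength between two gene groups
#'
#' Scores both site sets under one model and compares the score
#' distributions with the Mann-Whitney U test.
#'
#' @param sitesA,sitesB Site sequences of the two groups.
#' @param signal Signal model used for scoring.
#' @param background Optional background model.
#' @param alternative Test direction (see \code{\link{mannWhitneyU}}).
#' @return A list with \code{scoresA}, \code{scoresB}, \code{U},
#'   \code{p.value}.
#' @export
compareStrength <- function(sitesA, sitesB, signal, background = NULL,
                            alternative = "two.sided") {
  sa <- scoreSpliceSites(signal, sitesA, background)
  sb <- scoreSpliceSites(signal, sitesB, background)
  if (length(sa) < 2L || length(sb) < 2L)
    stop("compareStrength: need at least 2 scores per group")
  mw <- mannWhitneyU(sa, sb, alternative = alternative)
  list(scoresA = sa, scoresB = sb, U = mw$U, p.value = mw$p.value)
}

#' Batch strength comparisons with FDR adjustment
#'
#' Runs \code{\link{compareStrength}} for each named pair (e.g. first
#' donor sites and first acceptor sites) and adjusts the batch of
#' p-values with Benjamini-Hochberg, mirroring how donor and acceptor
#' comparisons are corrected together.
#'
#' @param pairs Named list; each element a list with \code{a}, \code{b}
#'   (site sets) and \code{signal} (model), optional \code{background},
#'   \code{alternative}.
#' @return data.frame with columns \code{comparison}, \code{U},
#'   \code{p.value}, \code{fdr}.
#' @export
compareStrengthBatch <- function(pairs) {
  res <- lapply(pairs, function(p)
    compareStrength(p$a, p$b, p$signal, p$background,
                    if (is.null(p$alternative)) "two.sided"
                    else p$alternative))
  p <- vapply(res, `[[`, numeric(1), "p.value")
  data.frame(comparison = names(pairs),
             U = vapply(res, `[[`, numeric(1), "U"),
             p.value = p, fdr = bhAdjust(p),
             stringsAsFactors = FALSE, row.names = NULL)
}
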