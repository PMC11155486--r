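#' Simulation configuration for the synthetic trans-splicing genome
#'
#' Holds every knob of the toy-genome generator: genome geometry, gene
#' counts, the operon and trans-spliced gene fractions, the Beta
#' distribution of per-gene trans-splicing ratios, the 16-nt spliced-leader
#' sequence, tag depth, minor-site scatter, the planted GU/AU dinucleotide
#' bias of outrons, and planted motif occurrences.
#'
#' @slot seed Integer master seed; the whole genome build is a
#'   deterministic function of it.
#' @slot nChromosomes,chromLength Genome geometry (bp).
#' @slot nGenes Number of genes to place.
#' @slot operonFraction Fraction of genes that are operonic members.
#' @slot tsGeneFraction Fraction of non-operon-internal genes that are
#'   trans-spliced.
#' @slot ts5utrFraction Among trans-spliced genes, fraction whose major TAS
#'   falls in the 5' UTR of the first exon (the rest sit at the first
#'   cis-splice acceptor site).
#' @slot tsRatioShape Beta(alpha, beta) parameters of the per-gene true
#'   trans-splicing ratio.
#' @slot slSequence The 16-nt 5' exon of the SL RNA added to trans-spliced
#'   mRNAs.
#' @slot tagDepthPerGene Mean Poisson tag count per gene.
#' @slot tasJitter Spacing scale (bp) of minor TAS around the major site.
#' @slot minorTasMax,minorTasDecay Maximum number of minor TAS per gene and
#'   the geometric decay of their expected tag shares.
#' @slot guAuBias Multiplicative weight (>= 1) applied to G and T when
#'   sampling outron bases of trans-spliced genes; 1 disables the planted
#'   bias.
#' @slot plantedMotifs List of planted-motif descriptors, each a list with
#'   elements \code{pwm} (a \linkS4class{MotifPWM}), \code{region}
#'   (\code{"tss"} or \code{"first_as"}), \code{rate}
#'   (occurrences per trans-spliced gene) and optional \code{offsetRange}.
#' @slot readLength Read length in nt, SL prefix included when present.
#' @slot errorRate Per-base substitution error rate of simulated reads.
#' @slot outronMedian,outronSdLog Log-normal outron length parameters
#'   (median bp, sdlog); draws are truncated below at 240 bp so that every
#'   outron fully contains the planted-bias core.
#' @slot exon2Length Length of the exon downstream of the first intron.
#' @slot intergenicRange Uniform range (bp) of intergenic gaps.
#' @slot peakHalfWidth ATAC peak half-width around each true TSS.
#' @slot decoyPeaks Number of intergenic decoy ATAC peaks.
#' @slot decoyClusters,decoyClusterDepth Number and tag depth of artifact
#'   capped-tag clusters planted outside any ATAC peak.
#' @slot weakTsDonors If TRUE, first donor sites of trans-spliced genes are
#'   degenerate (random beyond the invariant GT) while non-trans-spliced
#'   genes carry the consensus GTAAGT donor.
#' @export
setClass("SimConfig",
  representation(
    seed = "integer", nChromosomes = "integer", chromLength = "integer",
    nGenes = "integer", operonFraction = "numeric",
    tsGeneFraction = "numeric", ts5utrFraction = "numeric",
    tsRatioShape = "numeric", slSequence = "character",
    tagDepthPerGene = "numeric", tasJitter = "numeric",
    minorTasMax = "integer", minorTasDecay = "numeric",
    guAuBias = "numeric", plantedMotifs = "list",
    readLength = "integer", errorRate = "numeric",
    outronMedian = "numeric", outronSdLog = "numeric",
    exon2Length = "integer", intergenicRange = "numeric",
    peakHalfWidth = "integer", decoyPeaks = "integer",
    decoyClusters = "integer", decoyClusterDepth = "integer",
    weakTsDonors = "logical"),
  validity = function(object) {
    msg <- character()
    if (nchar(object@slSequence) != 16L)
      msg <- c(msg, "slSequence must be exactly 16 nt")
    fr <- c(object@operonFraction, object@tsGeneFraction,
            object@ts5utrFraction, object@errorRate)
    if (any(fr < 0 | fr > 1))
      msg <- c(msg, "fractions and errorRate must lie in [0, 1]")
    if (object@nChromosomes < 1L || object@chromLength < 1000L)
      msg <- c(msg, "need >= 1 chromosome of >= 1000 bp")
    if (object@nGenes < 0L) msg <- c(msg, "nGenes must be >= 0")
    if (any(object@tsRatioShape <= 0) || length(object@tsRatioShape) != 2L)
      msg <- c(msg, "tsRatioShape must be two positive Beta parameters")
    if (object@guAuBias < 1) msg <- c(msg, "guAuBias must be >= 1")
    if (object@readLength <= nchar(object@slSequence) + 10L)
      msg <- c(msg, "readLength too short for an informative genomic part")
    if (length(msg)) msg else TRUE
  })

#' Build a simulation configuration
#'
#' All arguments default to the study conditions of the packaged synthetic
#' benchmark: a 2 x 150 kb genome carrying 200 genes, 20% of them operonic,
#' 60% of free-standing genes trans-spliced with Beta(2,2) trans-splicing
#' ratios, log-normal outrons with median 458 bp, minor acceptor sites
#' scattered within 50 bp of the major site, and a 1.5-fold G/U sampling
#' bias in outrons.
#'
#' @param seed Integer master seed.
#' @param nChromosomes,chromLength,nGenes Genome geometry and gene count.
#' @param operonFraction,tsGeneFraction,ts5utrFraction Composition
#'   fractions (see \linkS4class{SimConfig}).
#' @param tsRatioShape Beta parameters of true trans-splicing ratios.
#' @param slSequence 16-nt SL 5' exon (synthetic default, AU-rich like the
#'   natural leader).
#' @param tagDepthPerGene Mean tag count per gene.
#' @param tasJitter,minorTasMax,minorTasDecay Minor-TAS scatter.
#' @param guAuBias Outron G/U sampling weight.
#' @param plantedMotifs Planted motif descriptors (see
#'   \linkS4class{SimConfig}).
#' @param readLength,errorRate Read simulation parameters.
#' @param outronMedian,outronSdLog,exon2Length,intergenicRange Gene
#'   geometry.
#' @param peakHalfWidth,decoyPeaks ATAC peak geometry.
#' @param decoyClusters,decoyClusterDepth Artifact capped-tag clusters.
#' @param weakTsDonors Plant weak first donors in trans-spliced genes.
#' @return A validated \linkS4class{SimConfig}.
#' @export
simConfig <- function(seed = 1L,
                      nChromosomes = 2L, chromLength = 150000L,
                      nGenes = 200L,
                      operonFraction = 0.2, tsGeneFraction = 0.6,
                      ts5utrFraction = 0.5,
                      tsRatioShape = c(2, 2),
                      slSequence = "ATTCTATTTGAATAAG",
                      tagDepthPerGene = 200,
                      tasJitter = 8, minorTasMax = 3L,
                      minorTasDecay = 0.45,
                      guAuBias = 1.5,
                      plantedMotifs = list(),
                      readLength = 50L, errorRate = 0,
                      outronMedian = 458, outronSdLog = 0.4,
                      exon2Length = 300L,
                      intergenicRange = c(320, 700),
                      peakHalfWidth = 150L, decoyPeaks = 10L,
                      decoyClusters = 5L, decoyClusterDepth = 20L,
                      weakTsDonors = TRUE) {
  new("SimConfig",
      seed = as.integer(seed), nChromosomes = as.integer(nChromosomes),
      chromLength = as.integer(chromLength), nGenes = as.integer(nGenes),
      operonFraction = operonFraction, tsGeneFraction = tsGeneFraction,
      ts5utrFraction = ts5utrFraction, tsRatioShape = as.numeric(tsRatioShape),
      slSequence = toupper(slSequence),
      tagDepthPerGene = tagDepthPerGene, tasJitter = tasJitter,
      minorTasMax = as.integer(minorTasMax), minorTasDecay = minorTasDecay,
      guAuBias = guAuBias, plantedMotifs = plantedMotifs,
      readLength = as.integer(readLength), errorRate = errorRate,
      outronMedian = outronMedian, outronSdLog = outronSdLog,
      exon2Length = as.integer(exon2Length),
      intergenicRange = as.numeric(intergenicRange),
      peakHalfWidth = as.integer(peakHalfWidth),
      decoyPeaks = as.integer(decoyPeaks),
      decoyClusters = as.integer(decoyClusters),
      decoyClusterDepth = as.integer(decoyClusterDepth),
      weakTsDonors = weakTsDonors)
}

#' Synthetic genome with planted trans-splicing ground truth
#'
#' Container returned by \code{\link{simulateGenome}}: the genome sequence,
#' the gene/transcript annotation, and the full planted truth (TAS
#' positions and tag shares, TSSs, operon membership, true trans-splicing
#' ratios, planted motif occurrences and the planted-bias window core).
#'
#' @slot config The \linkS4class{SimConfig} used.
#' @slot genome Named DNAStringSet of chromosomes.
#' @slot genes GRanges of gene bodies with per-gene truth columns
#'   (\code{gene_id}, \code{class}, \code{operon_id}, \code{operon_first},
#'   \code{ts_ratio}, \code{tss}, \code{outron_len}).
#' @slot exons GRanges of exons (\code{gene_id}, \code{transcript_id},
#'   \code{exon_rank} in transcription order, \code{five_prime_status}).
#' @slot cds GRanges of coding regions.
#' @slot tas GRanges of true trans-splice acceptor sites (width 1;
#'   \code{gene_id}, \code{share}, \code{is_major}).
#' @slot tss GRanges of true TSSs (width 1; \code{gene_id}).
#' @slot motifHits GRanges of planted motif occurrences
#'   (\code{motif_id}, \code{gene_id}).
#' @slot enriched List describing the planted-bias core: every
#'   trans-spliced outron is G/U-biased over its first \code{coreLen} bp
#'   downstream of the TSS.
#' @export
setClass("SLSimulation",
  representation(config = "SimConfig", genome = "DNAStringSet",
                 genes = "GRanges", exons = "GRanges", cds = "GRanges",
                 tas = "GRanges", tss = "GRanges", motifHits = "GRanges",
                 enriched = "list"))

setMethod("show", "SLSimulation", function(object) {
  g <- object@genes
  cat("SLSimulation:", length(object@genome), "chromosome(s),",
      length(g), "genes\n")
  if (length(g))
    print(table(gene_class = g$gene_class))
  cat(length(object@tas), "true TAS,", length(object@tss), "true TSS,",
      length(object@motifHits), "planted motif occurrence(s)\n")
})

#' @rdname SLSimulation-accessors
#' @name SLSimulation-accessors
#' @title Accessors for SLSimulation ground truth
#' @param sim An \linkS4class{SLSimulation}.
#' @return The corresponding slot: genome sequence, gene/exon/CDS ranges,
#'   true TAS/TSS sites, true ratios, or planted motif occurrences.
#' @export
genomeSeq <- function(sim) sim@genome

#' @rdname SLSimulation-accessors
#' @export
geneRanges <- function(sim) sim@genes

#' @rdname SLSimulation-accessors
#' @export
exonRanges <- function(sim) sim@exons

#' @rdname SLSimulation-accessors
#' @export
cdsRanges <- function(sim) sim@cds

#' @rdname SLSimulation-accessors
#' @export
trueTas <- function(sim) sim@tas

#' @rdname SLSimulation-accessors
#' @export
trueTss <- function(sim) sim@tss

#' @rdname SLSimulation-accessors
#' @export
plantedMotifHits <- function(sim) sim@motifHits

#' @rdname SLSimulation-accessors
#' @export
trueRatios <- function(sim) {
  r <- sim@genes$ts_ratio
  names(r) <- sim@genes$gene_id
  r
}

#' Load a simulation configuration from YAML
#'
#' Reads a YAML mapping whose keys are \code{\link{simConfig}} argument
#' names; unknown keys are an error.
#'
#' @param path Path to a YAML file.
#' @return A validated \linkS4class{SimConfig}.
#' @export
simConfigFromYaml <- function(path) {
  args <- yaml::read_yaml(path)
  known <- names(formals(simConfig))
  bad <- setdiff(names(args), known)
  if (length(bad))
    stop("simConfigFromYaml: unknown config key(s): ",
         paste(bad, collapse = ", "))
  do.call(simConfig, args)
}

# draw one outron length (bp), truncated log-normal
.drawOutron <- function(cfg) {
  repeat {
    x <- round(stats::rlnorm(1, meanlog = log(cfg@outronMedian),
                             sdlog = cfg@outronSdLog))
    if (x >= 240 && x <= 2000) return(x)
  }
}

# per-gene local plan in transcribed coordinates (1 = TSS / 5' end)
.planGene <- function(cfg, geneClass) {
  e2 <- cfg@exon2Length
  if (geneClass == "operon_internal") {
    # body starts at its TAS; keep a short 5' UTR exon + intron + exon
    e1 <- 80L; i1 <- 160L
    return(list(e1 = e1, i1 = i1, e2 = e2, len = e1 + i1 + e2,
                tasLocal = 1L, minors = integer(0),
                outronLen = 0L))
  }
  out <- .drawOutron(cfg)
  e1 <- as.integer(round(out * stats::runif(1, 0.25, 0.45)))
  e1 <- max(60L, e1)
  i1 <- as.integer(out - e1)
  len <- e1 + i1 + e2
  sp <- max(6L, as.integer(round(cfg@tasJitter)))
  if (geneClass == "TS_1stAS") {
    tas <- e1 + i1 + 1L
    lo <- e1 + 13L             # keep clear of the 6-bp donor window
  } else if (geneClass == "TS_5UTR") {
    tas <- as.integer(round(stats::runif(1, 40, e1 - 10)))
    lo <- 20L
  } else {
    return(list(e1 = e1, i1 = i1, e2 = e2, len = len,
                tasLocal = NA_integer_, minors = integer(0),
                outronLen = e1 + i1))
  }
  nm <- sample(0:cfg@minorTasMax, 1L)
  minors <- tas - sp * seq_len(nm)
  minors <- minors[minors >= lo & minors <= tas - 6L & tas - minors <= 50L]
  list(e1 = e1, i1 = i1, e2 = e2, len = len, tasLocal = tas,
       minors = as.integer(minors), outronLen = e1 + i1)
}

# build the transcribed-strand base vector for one gene
.buildGeneSeq <- function(cfg, plan, geneClass, motifSlots, tsRatio = 0) {
  len <- plan$len
  s <- sample(DNA_BASES4, len, replace = TRUE)
  isTS <- geneClass %in% c("TS_1stAS", "TS_5UTR")
  # planted G/U bias over the outron, stopping short of the 23-nt
  # acceptor window so the acceptor-strength comparison stays neutral
  biasLen <- max(0L, plan$outronLen - 23L)
  if (isTS && cfg@guAuBias > 1 && biasLen > 0) {
    w <- c(A = 1, C = 1, G = cfg@guAuBias, T = cfg@guAuBias)
    s[seq_len(biasLen)] <-
      sample(DNA_BASES4, biasLen, replace = TRUE, prob = w / sum(w))
  }
  # intron boundaries: donor GT..., acceptor polypyrimidine + AG;
  # donor degeneracy tracks the gene's true trans-splicing ratio, so
  # high-ratio genes carry the weaker first donor sites
  intronStart <- plan$e1 + 1L
  intronEnd <- plan$e1 + plan$i1
  donor <- if (isTS && cfg@weakTsDonors && stats::runif(1) < tsRatio)
    c("G", "T", sample(DNA_BASES4, 4, replace = TRUE))
  else c("G", "T", "A", "A", "G", "T")
  s[intronStart:(intronStart + 5L)] <- donor
  s[(intronEnd - 9L):intronEnd] <- c("T", "T", "T", "T", "T", "T", "T",
                                     "T", "A", "G")
  # planted AG context at major + minor TAS
  for (p in c(plan$tasLocal, plan$minors)) {
    if (!is.na(p) && p >= 3L) s[c(p - 2L, p - 1L)] <- c("A", "G")
  }
  # planted motifs
  hits <- list()
  if (isTS && length(motifSlots)) {
    for (ms in motifSlots) {
      pwm <- ms$pwm
      w <- motifWidth(pwm)
      rng <- if (!is.null(ms$offsetRange)) ms$offsetRange else c(31L, 60L)
      if (stats::runif(1) < ms$rate) {
        if (identical(ms$region, "first_as") && !is.na(plan$tasLocal)) {
          off <- plan$tasLocal - sample(seq(rng[1], rng[2]), 1L) - w
        } else {
          off <- sample(seq(rng[1], rng[2]), 1L)
        }
        if (off >= 1L && off + w - 1L <= plan$outronLen &&
            (is.na(plan$tasLocal) ||
             off + w - 1L < plan$tasLocal - 3L ||
             off > plan$tasLocal)) {
          s[off:(off + w - 1L)] <- .samplePwmSeq(pwm)
          hits[[length(hits) + 1L]] <- list(id = motifId(pwm), start = off,
                                            width = w)
        }
      }
    }
  }
  list(seq = s, motifHits = hits)
}

#' Generate the synthetic genome with ground truth
#'
#' Builds a toy multi-gene genome: i.i.d. uniform background sequence;
#' genes placed without overlap except operons (consecutive same-strand
#' genes with zero intergenic gap whose non-first members start at a
#' trans-splice acceptor site); each trans-spliced gene carries an outron
#' (G/U-biased when configured) upstream of its major TAS, with minor
#' acceptor sites scattered within 50 bp at geometrically decaying tag
#' shares; every true TAS has the AG dinucleotide immediately 5' of it.
#' The build is a deterministic function of \code{config@seed}.
#'
#' @param config A \linkS4class{SimConfig}.
#' @return An \linkS4class{SLSimulation}.
#' @export
simulateGenome <- function(config) {
  methods::validObject(config)
  set.seed(config@seed)
  cfg <- config
  nchr <- cfg@nChromosomes
  chromNames <- sprintf("chr%d", seq_len(nchr))

  if (cfg@nGenes == 0L) {
    genome <- Biostrings::DNAStringSet(vapply(seq_len(nchr), function(i)
      paste(sample(DNA_BASES4, cfg@chromLength, replace = TRUE),
            collapse = ""), character(1)))
    names(genome) <- chromNames
    e <- GRanges()
    return(new("SLSimulation", config = cfg, genome = genome,
               genes = e, exons = e, cds = e, tas = e, tss = e,
               motifHits = e, enriched = list(coreLen = 240L)))
  }

  # --- plan gene classes and operon structure -------------------------
  nOperonic <- round(cfg@operonFraction * cfg@nGenes)
  units <- list()     # each unit: one singleton or one operon run
  placed <- 0L
  while (placed < nOperonic - 1L) {
    k <- sample(2:3, 1L)
    k <- min(k, cfg@nGenes - placed)
    if (k < 2L) break
    units[[length(units) + 1L]] <- list(type = "operon", k = k)
    placed <- placed + k
  }
  nSingle <- cfg@nGenes - placed
  for (i in seq_len(nSingle))
    units[[length(units) + 1L]] <- list(type = "single", k = 1L)
  units <- units[sample.int(length(units))]

  geneRows <- list()   # accumulating per-gene records
  gid <- 0L
  chromCursor <- rep(1L, nchr)
  curChrom <- 1L
  chromBases <- lapply(seq_len(nchr), function(i)
    sample(DNA_BASES4, cfg@chromLength, replace = TRUE))

  for (u in units) {
    strandU <- sample(c("+", "-"), 1L)
    plans <- list()
    classes <- character(u$k)
    for (j in seq_len(u$k)) {
      if (u$type == "operon" && j > 1L) {
        classes[j] <- "operon_internal"
      } else if (stats::runif(1) < cfg@tsGeneFraction) {
        classes[j] <- if (stats::runif(1) < cfg@ts5utrFraction)
          "TS_5UTR" else "TS_1stAS"
      } else classes[j] <- "nonTS"
      plans[[j]] <- .planGene(cfg, classes[j])
    }
    unitLen <- sum(vapply(plans, `[[`, integer(1), "len"))
    gap <- as.integer(round(stats::runif(1, cfg@intergenicRange[1],
                                         cfg@intergenicRange[2])))
    while (chromCursor[curChrom] + gap + unitLen > cfg@chromLength) {
      curChrom <- curChrom + 1L
      if (curChrom > nchr)
        stop("simulateGenome: genes cannot fit in the configured genome; ",
             "increase chromLength or nChromosomes or reduce nGenes")
    }
    startPos <- chromCursor[curChrom] + gap
    # genomic order: transcription order for "+", reversed for "-"
    orderIdx <- if (strandU == "+") seq_len(u$k) else rev(seq_len(u$k))
    cursor <- startPos
    coords <- vector("list", u$k)
    for (j in orderIdx) {
      coords[[j]] <- c(cursor, cursor + plans[[j]]$len - 1L)
      cursor <- cursor + plans[[j]]$len
    }
    chromCursor[curChrom] <- cursor
    opId <- if (u$type == "operon")
      sprintf("operon_%03d", gid + 1L) else NA_character_
    for (j in seq_len(u$k)) {
      gid <- gid + 1L
      geneRows[[gid]] <- list(
        gene_id = sprintf("gene_%04d", gid),
        chrom = curChrom, start = coords[[j]][1], end = coords[[j]][2],
        strand = strandU, gene_class = classes[j],
        operon_id = opId, operon_first = (u$type == "operon" && j == 1L),
        plan = plans[[j]])
    }
  }

  # --- realize sequences and truth features ---------------------------
  tasRows <- list(); tssRows <- list(); motifRows <- list()
  exonRows <- list(); cdsRows <- list()
  ratios <- numeric(length(geneRows))
  for (i in seq_along(geneRows)) {
    g <- geneRows[[i]]
    plan <- g$plan
    isTS <- g$gene_class %in% c("TS_1stAS", "TS_5UTR", "operon_internal")
    rho <- if (g$gene_class == "operon_internal") 1
      else if (isTS) stats::rbeta(1, cfg@tsRatioShape[1],
                                  cfg@tsRatioShape[2])
      else 0
    ratios[i] <- rho
    built <- .buildGeneSeq(cfg, plan, g$gene_class, cfg@plantedMotifs,
                           tsRatio = rho)
    seqLocal <- built$seq
    # place into chromosome
    if (g$strand == "+") {
      chromBases[[g$chrom]][g$start:g$end] <- seqLocal
    } else {
      chromBases[[g$chrom]][g$start:g$end] <- .revcompChars(seqLocal)
    }
    toGenomic <- function(local) {
      if (g$strand == "+") g$start + local - 1L else g$end - local + 1L
    }
    if (isTS) {
      locs <- c(plan$tasLocal, plan$minors)
      shares <- cfg@minorTasDecay^(seq_along(locs) - 1L)
      shares <- shares / sum(shares)
      for (k in seq_along(locs)) {
        tasRows[[length(tasRows) + 1L]] <- list(
          chrom = g$chrom, pos = toGenomic(locs[k]), strand = g$strand,
          gene_id = g$gene_id, share = shares[k], is_major = (k == 1L))
      }
    }
    if (g$gene_class != "operon_internal") {
      tssRows[[length(tssRows) + 1L]] <- list(
        chrom = g$chrom, pos = toGenomic(1L), strand = g$strand,
        gene_id = g$gene_id)
    }
    for (h in built$motifHits) {
      gpos <- sort(c(toGenomic(h$start), toGenomic(h$start + h$width - 1L)))
      motifRows[[length(motifRows) + 1L]] <- list(
        chrom = g$chrom, start = gpos[1], end = gpos[2],
        strand = g$strand, motif_id = h$id, gene_id = g$gene_id)
    }
    # exon structure (transcription order ranks)
    exLoc <- list(c(1L, plan$e1),
                  c(plan$e1 + plan$i1 + 1L, plan$len))
    txId <- paste0(g$gene_id, ".t1")
    fps <- if (g$gene_class == "operon_internal") "SL" else "non-SL"
    for (r in seq_along(exLoc)) {
      gpos <- sort(c(toGenomic(exLoc[[r]][1]), toGenomic(exLoc[[r]][2])))
      exonRows[[length(exonRows) + 1L]] <- list(
        chrom = g$chrom, start = gpos[1], end = gpos[2],
        strand = g$strand, gene_id = g$gene_id, transcript_id = txId,
        exon_rank = r, five_prime_status = fps)
    }
    cdsLoc <- c(plan$e1 + plan$i1 + 10L, plan$len - 3L)
    gpos <- sort(c(toGenomic(cdsLoc[1]), toGenomic(cdsLoc[2])))
    cdsRows[[length(cdsRows) + 1L]] <- list(
      chrom = g$chrom, start = gpos[1], end = gpos[2], strand = g$strand,
      gene_id = g$gene_id, transcript_id = txId)
  }

  # --- universal AG planting immediately 5' of every true TAS ---------
  for (t in tasRows) {
    if (t$strand == "+") {
      chromBases[[t$chrom]][c(t$pos - 2L, t$pos - 1L)] <- c("A", "G")
    } else {
      chromBases[[t$chrom]][c(t$pos + 1L, t$pos + 2L)] <- c("C", "T")
    }
  }

  genome <- Biostrings::DNAStringSet(vapply(chromBases, paste,
                                            character(1), collapse = ""))
  names(genome) <- chromNames

  df <- function(rows) do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  gdf <- df(lapply(geneRows, function(g) g[names(g) != "plan"]))
  gdf$ts_ratio <- ratios
  gdf$outron_len <- vapply(geneRows, function(g) g$plan$outronLen,
                           integer(1))
  genes <- GRanges(factor(chromNames[gdf$chrom], levels = chromNames),
                   IRanges(gdf$start, gdf$end), strand = gdf$strand)
  mcols(genes) <- gdf[, c("gene_id", "gene_class", "operon_id",
                          "operon_first", "ts_ratio", "outron_len")]
  names(genes) <- genes$gene_id

  mkPointGr <- function(rows, extra) {
    if (!length(rows)) return(GRanges())
    d <- df(rows)
    gr <- GRanges(factor(chromNames[d$chrom], levels = chromNames),
                  IRanges(d$pos, d$pos), strand = d$strand)
    mcols(gr) <- d[, extra, drop = FALSE]
    gr
  }
  tas <- mkPointGr(tasRows, c("gene_id", "share", "is_major"))
  tss <- mkPointGr(tssRows, "gene_id")
  motifs <- if (length(motifRows)) {
    d <- df(motifRows)
    gr <- GRanges(factor(chromNames[d$chrom], levels = chromNames),
                  IRanges(d$start, d$end), strand = d$strand)
    mcols(gr) <- d[, c("motif_id", "gene_id")]
    gr
  } else GRanges()
  edf <- df(exonRows)
  exons <- GRanges(factor(chromNames[edf$chrom], levels = chromNames),
                   IRanges(edf$start, edf$end), strand = edf$strand)
  mcols(exons) <- edf[, c("gene_id", "transcript_id", "exon_rank",
                          "five_prime_status")]
  cdf <- df(cdsRows)
  cds <- GRanges(factor(chromNames[cdf$chrom], levels = chromNames),
                 IRanges(cdf$start, cdf$end), strand = cdf$strand)
  mcols(cds) <- cdf[, c("gene_id", "transcript_id")]

  new("SLSimulation", config = cfg, genome = genome, genes = genes,
      exons = exons, cds = cds, tas = tas, tss = tss, motifHits = motifs,
      enriched = list(coreLen = 240L))
}

#' Export the simulated annotation as GFF3-ready GRanges
#'
#' @param sim An \linkS4class{SLSimulation}.
#' @return A GRanges with \code{type}, \code{ID} and \code{Parent} columns
#'   suitable for \code{\link{writeGff3}}.
#' @export
simAnnotation <- function(sim) {
  genes <- sim@genes; exons <- sim@exons; cds <- sim@cds
  gg <- granges(genes)
  mcols(gg) <- DataFrame(type = "gene", ID = genes$gene_id)
  txIds <- unique(exons$transcript_id)
  txGene <- sub("\\.t1$", "", txIds)
  txSpan <- unlist(range(split(granges(exons), exons$transcript_id)))
  txSpan <- txSpan[txIds]
  mcols(txSpan) <- DataFrame(type = "mRNA", ID = txIds)
  tx <- txSpan
  ee <- granges(exons)
  mcols(ee) <- DataFrame(type = "exon",
                         ID = paste0(exons$transcript_id, ".exon",
                                     exons$exon_rank))
  cc <- granges(cds)
  mcols(cc) <- DataFrame(type = "CDS",
                         ID = paste0(cds$transcript_id, ".cds"))
  mcols(cc)$phase <- 0L
  out <- c(gg, tx, ee, cc)
  par <- c(rep(NA_character_, length(gg)), txGene,
           exons$transcript_id, cds$transcript_id)
  mcols(out)$Parent <- IRanges::CharacterList(
    lapply(par, function(x) if (is.na(x)) character(0) else x))
  mcols(out)$gene_id <- c(genes$gene_id, txGene, exons$gene_id,
                          cds$gene_id)
  mcols(out)$five_prime_status <- c(
    rep(NA_character_, length(gg) + length(tx)),
    exons$five_prime_status, rep(NA_character_, length(cc)))
  mcols(out)$exon_rank <- c(rep(NA_integer_, length(gg) + length(tx)),
                            exons$exon_rank, rep(NA_integer_, length(cc)))
  out
}

#' Simulate ATAC-like open-chromatin peaks
#'
#' Emits one peak spanning each true TSS plus a configurable number of
#' intergenic decoy peaks that contain no TSS.
#'
#' @param sim An \linkS4class{SLSimulation}.
#' @param nDecoy Number of decoy peaks; defaults to the config value.
#' @param seed RNG seed (defaults to \code{config@seed + 1}).
#' @return A GRanges of peaks with a logical \code{decoy} column.
#' @export
simulateAtac <- function(sim, nDecoy = sim@config@decoyPeaks,
                         seed = sim@config@seed + 1L) {
  set.seed(seed)
  hw <- sim@config@peakHalfWidth
  tss <- sim@tss
  lens <- Biostrings::width(sim@genome)
  if (length(tss)) {
    st <- pmax(1L, start(tss) - hw)
    en <- pmin(lens[match(as.character(seqnames(tss)), names(sim@genome))],
               start(tss) + hw)
    peaks <- GRanges(seqnames(tss), IRanges(st, en), strand = "*")
    mcols(peaks) <- DataFrame(decoy = FALSE)
  } else peaks <- GRanges()
  if (nDecoy > 0) {
    inter <- intergenicRegions(sim)
    inter <- inter[width(inter) >= 2L * hw + 1L]
    decoys <- GRanges()
    tries <- 0L
    while (length(decoys) < nDecoy && tries < 200L * nDecoy) {
      tries <- tries + 1L
      i <- sample.int(length(inter), 1L)
      c0 <- sample(seq(start(inter)[i] + hw, end(inter)[i] - hw), 1L)
      cand <- GRanges(seqnames(inter)[i], IRanges(c0 - hw, c0 + hw))
      if (length(peaks) &&
          length(IRanges::findOverlaps(cand, peaks)) > 0) next
      if (length(decoys) &&
          length(IRanges::findOverlaps(cand, decoys)) > 0) next
      decoys <- c(decoys, cand)
    }
    if (length(decoys)) {
      mcols(decoys) <- DataFrame(decoy = TRUE)
      peaks <- c(peaks, decoys)
    }
  }
  sort(peaks, ignore.strand = TRUE)
}

#' Intergenic regions of a simulated genome
#'
#' @param sim An \linkS4class{SLSimulation}.
#' @return Strandless GRanges of the genome minus all gene bodies.
#' @export
intergenicRegions <- function(sim) {
  lens <- Biostrings::width(sim@genome)
  all <- GRanges(names(sim@genome), IRanges(1L, lens))
  if (!length(sim@genes)) return(all)
  bodies <- GenomicRanges::reduce(granges(sim@genes), ignore.strand = TRUE)
  GenomicRanges::setdiff(all, bodies, ignore.strand = TRUE)
}

# substitute bases at random with rate err
.addErrors <- function(seqs, err) {
  if (err <= 0) return(seqs)
  vapply(seqs, function(s) {
    ch <- strsplit(s, "")[[1]]
    hit <- which(stats::runif(length(ch)) < err)
    for (i in hit)
      ch[i] <- sample(setdiff(DNA_BASES4, ch[i]), 1L)
    paste(ch, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Simulate 5'-end tag reads
#'
#' Per gene, a Poisson number of tags is drawn; each tag is SL-derived with
#' the gene's true trans-splicing ratio. SL reads are the 16-nt SL sequence
#' followed by genome sequence starting at a true TAS (chosen by the
#' planted tag shares); capped reads start at the true TSS. A configurable
#' number of artifact capped-tag clusters is planted outside any ATAC peak.
#'
#' @param sim An \linkS4class{SLSimulation}.
#' @param depth Mean tag count per gene (default from config).
#' @param peaks Optional ATAC peak GRanges used to keep artifact clusters
#'   peak-free.
#' @param seed RNG seed (defaults to \code{config@seed + 2}).
#' @return A list with \code{reads} (named DNAStringSet) and \code{truth}
#'   (one row per read: \code{read_id}, \code{gene_id}, \code{category},
#'   \code{chrom}, \code{pos} of the expected 5'-end mapping, \code{strand}).
#' @export
simulateTags <- function(sim, depth = sim@config@tagDepthPerGene,
                         peaks = NULL, seed = sim@config@seed + 2L) {
  set.seed(seed)
  cfg <- sim@config
  sl <- cfg@slSequence
  gl <- cfg@readLength - nchar(sl)   # genomic part of an SL read
  genes <- sim@genes
  tasByGene <- split(sim@tas, sim@tas$gene_id)
  tssPos <- stats::setNames(start(sim@tss), sim@tss$gene_id)
  tssChrom <- stats::setNames(as.character(seqnames(sim@tss)),
                              sim@tss$gene_id)
  lens <- Biostrings::width(sim@genome)
  names(lens) <- names(sim@genome)

  grabDown <- function(chrom, pos, strand, n) {
    # n bases downstream (transcription direction) starting at pos
    if (strand == "+") {
      e <- min(pos + n - 1L, lens[[chrom]])
      as.character(Biostrings::subseq(sim@genome[[chrom]], pos, e))
    } else {
      s <- max(1L, pos - n + 1L)
      as.character(Biostrings::reverseComplement(
        Biostrings::subseq(sim@genome[[chrom]], s, pos)))
    }
  }

  # per-gene blocks built vectorized: each distinct 5'-end position has
  # one template sequence, replicated per sampled tag
  seqsL <- list(); truthL <- list()
  for (i in seq_along(genes)) {
    g <- genes[i]
    gidv <- g$gene_id
    n <- stats::rpois(1, depth)
    if (n == 0L) next
    rho <- g$ts_ratio
    hasTss <- gidv %in% names(tssPos)
    nSL <- if (!hasTss) n else stats::rbinom(1, n, rho)
    nCap <- n - nSL
    chrom <- as.character(seqnames(g))
    strand <- as.character(strand(g))
    pos <- integer(0); cat <- character(0); sq <- character(0)
    if (nSL > 0L) {
      sites <- tasByGene[[gidv]]
      tmpl <- vapply(start(sites), function(p)
        paste0(sl, grabDown(chrom, p, strand, gl)), character(1))
      pick <- sample.int(length(sites), nSL, replace = TRUE,
                         prob = sites$share)
      pos <- c(pos, start(sites)[pick])
      cat <- c(cat, rep("SL", nSL))
      sq <- c(sq, tmpl[pick])
    }
    if (nCap > 0L && hasTss) {
      p <- tssPos[[gidv]]
      rs <- grabDown(chrom, p, strand, cfg@readLength)
      pos <- c(pos, rep(p, nCap))
      cat <- c(cat, rep("capped", nCap))
      sq <- c(sq, rep(rs, nCap))
    }
    if (!length(sq)) next
    seqsL[[length(seqsL) + 1L]] <- sq
    truthL[[length(truthL) + 1L]] <- data.frame(
      gene_id = gidv, category = cat, chrom = chrom, pos = pos,
      strand = strand, stringsAsFactors = FALSE)
  }

  # artifact capped clusters outside any peak
  if (cfg@decoyClusters > 0L) {
    inter <- intergenicRegions(sim)
    if (!is.null(peaks) && length(peaks))
      inter <- GenomicRanges::setdiff(inter, peaks + 10L,
                                      ignore.strand = TRUE)
    inter <- inter[width(inter) >= cfg@readLength + 20L]
    nDec <- min(cfg@decoyClusters, length(inter))
    pickI <- sample.int(length(inter), nDec)
    for (i in pickI) {
      p <- sample(seq(start(inter)[i] + 5L,
                      end(inter)[i] - cfg@readLength - 5L), 1L)
      chrom <- as.character(seqnames(inter)[i])
      rs <- grabDown(chrom, p, "+", cfg@readLength)
      nd <- cfg@decoyClusterDepth
      seqsL[[length(seqsL) + 1L]] <- rep(rs, nd)
      truthL[[length(truthL) + 1L]] <- data.frame(
        gene_id = "decoy", category = "decoy_capped", chrom = chrom,
        pos = p, strand = "+", stringsAsFactors = FALSE)[rep(1L, nd), ]
    }
  }

  reads <- .addErrors(unlist(seqsL), cfg@errorRate)
  ids <- sprintf("read_%07d", seq_along(reads))
  truth <- do.call(rbind, truthL)
  rownames(truth) <- NULL
  truth <- cbind(read_id = ids, truth, stringsAsFactors = FALSE)
  reads <- Biostrings::DNAStringSet(reads)
  names(reads) <- ids
  list(reads = reads, truth = truth)
}
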