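# tiny polynomial rolling hash of a string, for provenance headers
.configHash <- function(x) {
  h <- 0
  for (b in utf8ToInt(x)) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

.provHeader <- function(config, extra = character()) {
  c(tool = paste0("outronscan ",
                  as.character(utils::packageVersion("outronscan"))),
    seed = as.character(config@seed),
    config_hash = .configHash(paste(deparse(config), collapse = "")),
    extra)
}

#' Run the full synthetic trans-splicing analysis pipeline
#'
#' Executes the stages in dependency order on a simulated genome:
#' simulate (genome, annotation, ATAC peaks, 5'-tag reads), tagcall
#' (classify by SL prefix, exact-match 5'-end mapping, clustering, TAS and
#' TSS calling), geneclass (operons, trans-spliced status, major TAS
#' location, trans-splicing ratio), strength (first donor/acceptor site
#' score comparison), content (windowed nucleotide-content enrichment)
#' and motif (two-stage local motif enrichment). Every output TSV carries
#' a header with the tool version, config hash and seed; counts at each
#' filtering step are collected in the returned \code{log}.
#'
#' @param config A \linkS4class{SimConfig}.
#' @param outDir Output directory (created if needed); NULL to skip all
#'   file output.
#' @param stages Character vector of stages to run; later stages require
#'   earlier ones in this call.
#' @param maxGap Tag clustering gap (bp).
#' @param ratioThreshold TS-High/TS-Low split point.
#' @param window,step Enrichment window geometry (bp).
#' @param span Anchored-region span downstream of the TSS (bp).
#' @param backgroundN Number of intergenic background sequences for the
#'   stage-1 motif test.
#' @param motifs Optional named list of \linkS4class{MotifPWM}s to test;
#'   defaults to the PWMs planted in the config.
#' @param minPrefixMatch SL-prefix bases required for SL classification.
#' @return Invisible list with the intermediate and final objects:
#'   \code{sim}, \code{peaks}, \code{tags}, \code{tas}, \code{tss},
#'   \code{classification}, \code{strength}, \code{content},
#'   \code{motif}, \code{log}.
#' @export
runPipeline <- function(config, outDir = NULL,
                        stages = c("simulate", "tagcall", "geneclass",
                                   "strength", "content", "motif"),
                        maxGap = 50L, ratioThreshold = 0.5,
                        window = 30L, step = 10L, span = 240L,
                        backgroundN = 500L, motifs = NULL,
                        minPrefixMatch = nchar(config@slSequence)) {
  t0 <- Sys.time()
  log <- list()
  res <- list()
  hdr <- .provHeader(config)
  if (!is.null(outDir) && !dir.exists(outDir))
    dir.create(outDir, recursive = TRUE)
  out <- function(f) file.path(outDir, f)
  stage <- function(s) s %in% stages

  if (!stage("simulate"))
    stop("runPipeline: the 'simulate' stage is required as data source")
  message("[simulate] building genome (seed ", config@seed, ")")
  sim <- simulateGenome(config)
  peaks <- simulateAtac(sim)
  tags <- simulateTags(sim, peaks = peaks)
  res$sim <- sim; res$peaks <- peaks; res$tags <- tags
  log$n_genes <- length(sim@genes)
  log$n_reads <- length(tags$reads)
  if (!is.null(outDir)) {
    writeGenomeFasta(sim@genome, out("genome.fa"))
    writeGff3(simAnnotation(sim), out("annotation.gff3"))
    writeBed(peaks, out("peaks.bed"))
    writeTagFastq(tags$reads, out("reads.fastq"))
    writeTsv(tags$truth, out("read_truth.tsv"), hdr)
  }
  if (!stage("tagcall")) return(invisible(c(res, list(log = log))))

  message("[tagcall] classifying ", length(tags$reads), " reads")
  cls <- classifyReads(tags$reads, config@slSequence, minPrefixMatch)
  log$n_sl_reads <- length(cls$sl)
  log$n_capped_reads <- length(cls$capped)
  mapSL <- mapFivePrime(cls$sl, sim@genome, "SL")
  mapCap <- mapFivePrime(cls$capped, sim@genome, "capped")
  log$multimapped <- mapSL$multimapped + mapCap$multimapped
  log$unmapped <- mapSL$unmapped + mapCap$unmapped
  aln <- c(mapSL$alignments, mapCap$alignments)
  clusters <- clusterTags(aln, maxGap = maxGap)
  slClusters <- clusters[clusters$category == "SL"]
  capClusters <- clusters[clusters$category == "capped"]
  log$n_sl_clusters <- length(slClusters)
  log$n_capped_clusters <- length(capClusters)
  tasCall <- callTas(slClusters, sim@genome)
  tssCall <- callTss(capClusters, peaks, genes = sim@genes)
  log$tas_dropped_positions <- tasCall$dropped_positions
  log$tss_clusters_rejected <- tssCall$rejected
  res$tas <- tasCall$tas; res$tss <- tssCall$tss
  if (!is.null(outDir)) {
    writeBed(res$tas, out("tas.bed"))
    writeBed(res$tss, out("tss.bed"))
  }
  if (!stage("geneclass")) return(invisible(c(res, list(log = log))))

  message("[geneclass] classifying ", length(sim@genes), " genes")
  classification <- classifyGenes(sim@genes, sim@exons, sim@cds,
                                  res$tas, res$tss,
                                  ratioThreshold = ratioThreshold)
  res$classification <- classification
  log$genes_per_class <- table(classification$status)
  if (!is.null(outDir))
    writeTsv(classification, out("gene_classification.tsv"), hdr)

  ts1 <- classification$gene_id[classification$group == "TS-1stAS"]
  nonTS <- classification$gene_id[
    classification$status == "non_trans_spliced"]
  exonsOf <- function(ids) sim@exons[sim@exons$gene_id %in% ids]

  if (stage("strength")) {
    message("[strength] comparing splice-site scores")
    donorTS <- extractSpliceSites(exonsOf(ts1), sim@genome, "donor")
    donorNon <- extractSpliceSites(exonsOf(nonTS), sim@genome, "donor")
    accTS <- extractSpliceSites(exonsOf(ts1), sim@genome, "acceptor")
    accNon <- extractSpliceSites(exonsOf(nonTS), sim@genome, "acceptor")
    if (length(donorNon) >= 2 && length(donorTS) >= 2) {
      # train on the pooled sites of both groups: a model trained on one
      # group alone scores its own training set higher (finite-sample
      # overfit) and would bias the comparison
      donorModel <- trainMem(c(donorTS, donorNon))
      accModel <- trainMem(c(accTS, accNon))
      res$strength <- compareStrengthBatch(list(
        first_donor = list(a = donorTS, b = donorNon,
                           signal = donorModel),
        first_acceptor = list(a = accTS, b = accNon,
                              signal = accModel)))
      hi <- classification$gene_id[classification$group == "TS-1stAS" &
                                   !is.na(classification$ts_class) &
                                   classification$ts_class == "TS_High"]
      lo <- classification$gene_id[classification$group == "TS-1stAS" &
                                   !is.na(classification$ts_class) &
                                   classification$ts_class == "TS_Low"]
      dHi <- extractSpliceSites(exonsOf(hi), sim@genome, "donor")
      dLo <- extractSpliceSites(exonsOf(lo), sim@genome, "donor")
      if (length(dHi) >= 2 && length(dLo) >= 2) {
        hl <- compareStrength(dHi, dLo, donorModel)
        res$strength <- rbind(res$strength, data.frame(
          comparison = "donor_high_vs_low", U = hl$U,
          p.value = hl$p.value, fdr = hl$p.value))
      }
      if (!is.null(outDir))
        writeTsv(res$strength, out("splice_strength.tsv"), hdr)
    } else message("[strength] skipped: too few spliced genes per group")
  }

  tsAll <- classification$gene_id[
    classification$status == "trans_spliced" &
      classification$group %in% c("TS-1stAS", "TS-5UTR")]
  tssTs <- res$tss[!is.na(match(res$tss$gene_id, tsAll))]
  tssNon <- res$tss[!is.na(match(res$tss$gene_id, nonTS))]
  targetRegions <- anchorRegions(tssTs, sim@genome, downstream = span)
  controlRegions <- anchorRegions(tssNon, sim@genome, downstream = span)

  if (stage("content")) {
    message("[content] windowed nucleotide-content tests")
    specs <- list(U = "U", G = "G", A = "A", C = "C",
                  GU = c("G", "U"), AU = c("A", "U"))
    if (length(targetRegions) >= 2 && length(controlRegions) >= 2) {
      tabs <- lapply(names(specs), function(nm) {
        tw <- testContentWindows(
          profileContent(targetRegions, specs[[nm]], window, step),
          profileContent(controlRegions, specs[[nm]], window, step))
        cbind(spec = nm, anchor = "tss", tw)
      })
      res$content <- do.call(rbind, tabs)
      if (!is.null(outDir))
        writeTsv(res$content, out("content_enrichment.tsv"), hdr)
    } else message("[content] skipped: too few genes with called TSS")
  }

  if (stage("motif")) {
    if (is.null(motifs) && length(config@plantedMotifs))
      motifs <- stats::setNames(
        lapply(config@plantedMotifs, `[[`, "pwm"),
        vapply(config@plantedMotifs, function(m) motifId(m$pwm),
               character(1)))
    if (length(motifs) && length(targetRegions) >= 2 &&
        length(controlRegions) >= 2) {
      message("[motif] two-stage local enrichment, ",
              length(motifs), " motif(s)")
      bg <- sampleBackground(sim@genome, sim@genes, backgroundN, span,
                             seed = config@seed + 3L)
      s2 <- list(); s1 <- list()
      for (nm in names(motifs)) {
        s1[[nm]] <- motifStage1(targetRegions, bg, motifs[[nm]],
                                window, step)
        s2[[nm]] <- motifStage2(targetRegions, controlRegions,
                                motifs[[nm]],
                                s1[[nm]]$offset[s1[[nm]]$candidate],
                                window)
      }
      res$motif <- list(stage1 = s1, stage2 = s2,
                        enriched = vapply(s2, `[[`, logical(1),
                                          "enriched"))
      if (!is.null(outDir)) {
        tb <- do.call(rbind, lapply(names(s2), function(nm)
          if (nrow(s2[[nm]]$table))
            cbind(motif = nm, s2[[nm]]$table) else NULL))
        if (!is.null(tb))
          writeTsv(tb, out("motif_enrichment.tsv"), hdr)
      }
    } else message("[motif] skipped: no motifs to test")
  }

  log$elapsed_sec <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  message(sprintf("pipeline finished in %.1f s", log$elapsed_sec))
  invisible(c(res, list(log = log)))
}

#' Evaluate pipeline calls against planted truth
#'
#' Compares called sites and gene classes with the simulation ground
#' truth: exact-coordinate recovery of true major TAS, recovery of true
#' TSSs, rejection of artifact clusters, and per-gene trans-splicing
#' ratio errors in binomial standard-error units.
#'
#' @param sim The \linkS4class{SLSimulation} that generated the data.
#' @param res Result list from \code{\link{runPipeline}} (needs
#'   \code{tas}, \code{tss}, \code{classification}, \code{log}).
#' @param depth Tag depth used (for the ratio SE).
#' @return A list of summary numbers (rates in [0, 1]).
#' @export
evaluateAgainstTruth <- function(sim, res, depth = sim@config@tagDepthPerGene) {
  trueMajor <- sim@tas[sim@tas$is_major]
  calledKey <- paste(as.character(seqnames(res$tas)), start(res$tas),
                     as.character(strand(res$tas)))
  majorKey <- paste(as.character(seqnames(trueMajor)), start(trueMajor),
                    as.character(strand(trueMajor)))
  tasRecovery <- mean(majorKey %in% calledKey)

  tssKey <- paste(as.character(seqnames(res$tss)), start(res$tss),
                  as.character(strand(res$tss)))
  trueTssKey <- paste(as.character(seqnames(sim@tss)), start(sim@tss),
                      as.character(strand(sim@tss)))
  tssRecovery <- mean(trueTssKey %in% tssKey)

  cl <- res$classification
  truthClass <- sim@genes$gene_class
  predTS <- cl$status == "trans_spliced"
  trueTS <- truthClass %in% c("TS_1stAS", "TS_5UTR", "operon_internal")
  statusAccuracy <- mean(predTS == trueTS)

  grpPred <- cl$group[match(sim@genes$gene_id, cl$gene_id)]
  grpTrue <- ifelse(truthClass == "TS_1stAS", "TS-1stAS",
                    ifelse(truthClass == "TS_5UTR", "TS-5UTR", NA))
  groupAccuracy <- mean(grpPred[!is.na(grpTrue)] ==
                          grpTrue[!is.na(grpTrue)])

  rho <- sim@genes$ts_ratio
  est <- cl$ts_ratio[match(sim@genes$gene_id, cl$gene_id)]
  ok <- !is.na(est) & sim@genes$gene_class %in% c("TS_1stAS", "TS_5UTR")
  se <- sqrt(pmax(rho[ok] * (1 - rho[ok]), 1e-12) / depth)
  ratioWithin3SE <- if (any(ok))
    mean(abs(est[ok] - rho[ok]) <= pmax(3 * se, 3 / depth)) else NA

  list(tas_major_recovery = tasRecovery,
       tss_recovery = tssRecovery,
       status_accuracy = statusAccuracy,
       group_accuracy = groupAccuracy,
       ratio_within_3se = ratioWithin3SE,
       n_ratio_genes = sum(ok),
       decoy_clusters_rejected = res$log$tss_clusters_rejected)
}
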