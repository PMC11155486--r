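#' @import methods
#' @import BiocGenerics
#' @import S4Vectors
#' @import IRanges
#' @import GenomicRanges
#' @import Biostrings
#' @importFrom GenomeInfoDb seqlevels
#' @importFrom rtracklayer import export
#' @importFrom yaml read_yaml
NULL

DNA_BASES4 <- c("A", "C", "G", "T")

#' Position weight matrix for motif scanning
#'
#' A probability matrix over A/C/G/T per motif position plus the background
#' base distribution it is scored against, as parsed from MEME minimal
#' format. Rows are positions, columns are A, C, G, T.
#'
#' @slot id Motif identifier.
#' @slot matrix Numeric matrix, width x 4; each row sums to 1.
#' @slot background Numeric length-4 base distribution, sums to 1.
#' @export
setClass("MotifPWM",
  representation(id = "character", matrix = "matrix",
                 background = "numeric"),
  validity = function(object) {
    m <- object@matrix
    msg <- character()
    if (ncol(m) != 4L) msg <- c(msg, "matrix must have 4 columns (A,C,G,T)")
    if (any(m < 0)) msg <- c(msg, "matrix entries must be >= 0")
    if (nrow(m) > 0 && any(abs(rowSums(m) - 1) > 1e-9))
      msg <- c(msg, "matrix rows must each sum to 1")
    if (length(object@background) != 4L ||
        abs(sum(object@background) - 1) > 1e-9)
      msg <- c(msg, "background must be 4 probabilities summing to 1")
    if (length(msg)) msg else TRUE
  })

#' Construct a MotifPWM
#'
#' @param id Motif identifier.
#' @param matrix Width x 4 probability matrix (columns A, C, G, T).
#' @param background Length-4 background distribution; default uniform.
#' @return A \linkS4class{MotifPWM}.
#' @export
motifPWM <- function(id, matrix, background = rep(0.25, 4)) {
  m <- as.matrix(matrix)
  colnames(m) <- DNA_BASES4
  new("MotifPWM", id = as.character(id), matrix = m,
      background = as.numeric(background))
}

#' @describeIn motifPWM Motif width (number of positions).
#' @param x A MotifPWM.
#' @export
motifWidth <- function(x) nrow(x@matrix)

#' @describeIn motifPWM Motif identifier.
#' @export
motifId <- function(x) x@id

setMethod("show", "MotifPWM", function(object) {
  cat("MotifPWM", object@id, "width", nrow(object@matrix), "\n")
  cat("consensus:", paste(DNA_BASES4[apply(object@matrix, 1, which.max)],
                          collapse = ""), "\n")
})

#' Read a genome FASTA file
#'
#' @param path Path to an (uncompressed or gzipped) FASTA file.
#' @return A \link[Biostrings]{DNAStringSet}, one element per sequence.
#' @export
readGenomeFasta <- function(path) {
  Biostrings::readDNAStringSet(path, format = "fasta")
}

#' Write a genome FASTA file
#'
#' @param seqs A DNAStringSet (or named character vector).
#' @param path Output path.
#' @export
writeGenomeFasta <- function(seqs, path) {
  if (!methods::is(seqs, "DNAStringSet"))
    seqs <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, path, format = "fasta")
  invisible(path)
}

#' Read 5'-tag reads from FASTQ
#'
#' @param path Path to a FASTQ file.
#' @return A named \link[Biostrings]{DNAStringSet} (qualities are not used
#'   by the exact-match pipeline and are dropped).
#' @export
readTagFastq <- function(path) {
  Biostrings::readDNAStringSet(path, format = "fastq")
}

#' Write reads to FASTQ (constant quality)
#'
#' @param seqs Named DNAStringSet of reads.
#' @param path Output path.
#' @export
writeTagFastq <- function(seqs, path) {
  if (!methods::is(seqs, "DNAStringSet"))
    seqs <- Biostrings::DNAStringSet(seqs)
  q <- Biostrings::BStringSet(vapply(width(seqs), function(w)
    paste(rep("I", w), collapse = ""), character(1)))
  x <- Biostrings::QualityScaledDNAStringSet(
    seqs, Biostrings::PhredQuality(q))
  Biostrings::writeQualityScaledXStringSet(x, path)
  invisible(path)
}

#' Read gene annotation from GFF3
#'
#' Imports a GFF3 file as a GRanges (1-based closed coordinates, the
#' native convention of both GFF3 and GRanges).
#'
#' @param path Path to a GFF3 file.
#' @return A \link[GenomicRanges]{GRanges} with the GFF3 attribute columns.
#' @export
readGff3 <- function(path) {
  rtracklayer::import(path, format = "gff3")
}

#' Write gene annotation to GFF3
#'
#' @param gr A GRanges with at least \code{type} and \code{ID} metadata.
#' @param path Output path.
#' @export
writeGff3 <- function(gr, path) {
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read intervals from BED
#'
#' BED files are 0-based half-open on disk; the returned GRanges is 1-based
#' closed (rtracklayer performs the shift).
#'
#' @param path Path to a BED file.
#' @return A GRanges.
#' @export
readBed <- function(path) {
  rtracklayer::import(path, format = "bed")
}

#' Write intervals to BED
#'
#' @param gr A GRanges.
#' @param path Output path.
#' @export
writeBed <- function(gr, path) {
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' Read motifs in MEME minimal format
#'
#' Parses the MEME minimal motif format: an optional background frequency
#' block and one or more \code{MOTIF} blocks each followed by a
#' \code{letter-probability matrix} section. Rows are renormalized to sum
#' exactly to 1 to absorb rounding in the file.
#'
#' @param path Path to a MEME minimal format file.
#' @return A list of \linkS4class{MotifPWM} objects, named by motif id.
#' @export
readMeme <- function(path) {
  lines <- readLines(path)
  bg <- rep(0.25, 4)
  bgLine <- grep("^Background letter frequencies", lines)
  if (length(bgLine)) {
    toks <- strsplit(trimws(lines[bgLine[1] + 1]), "\\s+")[[1]]
    freq <- as.numeric(toks[seq(2, length(toks), by = 2)])
    names(freq) <- toks[seq(1, length(toks), by = 2)]
    bg <- as.numeric(freq[DNA_BASES4])
    bg <- bg / sum(bg)
  }
  motifStarts <- grep("^MOTIF", lines)
  if (!length(motifStarts)) stop("readMeme: no MOTIF blocks in ", path)
  out <- list()
  for (s in motifStarts) {
    id <- strsplit(trimws(lines[s]), "\\s+")[[1]][2]
    hdr <- grep("^letter-probability matrix", lines[s:length(lines)])[1]
    if (is.na(hdr))
      stop("readMeme: MOTIF at line ", s, " lacks a letter-probability matrix")
    hdr <- s + hdr - 1
    w <- suppressWarnings(as.integer(
      sub(".*w\\s*=\\s*([0-9]+).*", "\\1", lines[hdr])))
    rows <- list()
    i <- hdr + 1
    while (i <= length(lines)) {
      tl <- trimws(lines[i])
      if (tl == "" || grepl("^(MOTIF|URL)", tl)) break
      vals <- suppressWarnings(as.numeric(strsplit(tl, "\\s+")[[1]]))
      if (length(vals) != 4 || anyNA(vals))
        stop("readMeme: malformed matrix row at line ", i)
      rows[[length(rows) + 1L]] <- vals
      i <- i + 1
    }
    m <- do.call(rbind, rows)
    if (!is.na(w) && nrow(m) != w)
      stop("readMeme: motif ", id, " declares w=", w, " but has ",
           nrow(m), " rows")
    m <- m / rowSums(m)
    out[[id]] <- motifPWM(id, m, bg)
  }
  out
}

#' Write motifs in MEME minimal format
#'
#' @param pwms A list of \linkS4class{MotifPWM}.
#' @param path Output path.
#' @export
writeMeme <- function(pwms, path) {
  if (methods::is(pwms, "MotifPWM")) pwms <- list(pwms)
  bg <- pwms[[1]]@background
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "strands: + -", "",
               "Background letter frequencies",
               paste(sprintf("%s %.6f", DNA_BASES4, bg), collapse = " "),
               ""), con)
  for (p in pwms) {
    writeLines(sprintf("MOTIF %s", p@id), con)
    writeLines(sprintf(
      "letter-probability matrix: alength= 4 w= %d nsites= 20 E= 0",
      nrow(p@matrix)), con)
    apply(p@matrix, 1, function(r)
      writeLines(paste(sprintf("%.6f", r), collapse = " "), con))
    writeLines("", con)
  }
  invisible(path)
}

#' Write a data frame as TSV with a provenance header
#'
#' @param df A data.frame.
#' @param path Output path.
#' @param header Optional named character vector written as leading
#'   \code{# key: value} comment lines.
#' @export
writeTsv <- function(df, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header))
    writeLines(sprintf("# %s: %s", names(header), unname(header)), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by \code{writeTsv}
#'
#' @param path Path to a TSV file; leading \code{#} lines are skipped.
#' @return A data.frame.
#' @export
readTsv <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}
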