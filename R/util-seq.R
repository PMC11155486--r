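#' Strand-aware sequence extraction
#'
#' Extracts the transcribed-strand sequence for each range: ranges on the
#' minus strand are reverse-complemented, so position 1 of every returned
#' sequence is the 5'-most transcribed base. Ranges must lie inside their
#' chromosome.
#'
#' @param genome A named \link[Biostrings]{DNAStringSet}.
#' @param gr A \link[GenomicRanges]{GRanges}; strand "*" is treated as "+".
#' @return A DNAStringSet parallel to \code{gr}.
#' @export
extractRegions <- function(genome, gr) {
  chrom <- as.character(seqnames(gr))
  bad <- !(chrom %in% names(genome))
  if (any(bad))
    stop("extractRegions: unknown chromosome(s): ",
         paste(unique(chrom[bad]), collapse = ", "))
  lens <- Biostrings::width(genome)[match(chrom, names(genome))]
  if (any(start(gr) < 1L) || any(end(gr) > lens))
    stop("extractRegions: range outside chromosome bounds")
  out <- Biostrings::DNAStringSet(vapply(seq_along(gr), function(i) {
    as.character(Biostrings::subseq(genome[[chrom[i]]],
                                    start(gr)[i], end(gr)[i]))
  }, character(1)))
  neg <- as.character(strand(gr)) == "-"
  if (any(neg))
    out[neg] <- Biostrings::reverseComplement(out[neg])
  names(out) <- if (!is.null(names(gr))) names(gr) else NULL
  out
}

# reverse-complement a plain character vector of single bases
.revcompChars <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  rev(unname(comp[x]))
}

# sample one sequence (character vector) from a PWM's column distributions
.samplePwmSeq <- function(pwm) {
  m <- pwm@matrix
  vapply(seq_len(nrow(m)), function(i)
    sample(DNA_BASES4, 1L, prob = m[i, ]), character(1))
}
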