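#' GC content of intervals over a genome
#'
#' Computes (G + C) / (A + C + G + T) per interval, case-insensitive;
#' ambiguous bases (N) count in neither numerator nor denominator.
#'
#' @param intervals Interval tibble.
#' @param genome A [Biostrings::DNAStringSet] named by chromosome.
#' @return Numeric vector of GC fractions, one per interval row.
#' @export
gc_content <- function(intervals, genome) {
  intervals <- tibble::as_tibble(intervals)
  out <- numeric(nrow(intervals))
  for (chr in unique(intervals$chrom)) {
    idx <- which(intervals$chrom == chr)
    if (!chr %in% names(genome)) stop("chromosome not in genome: ", chr)
    seq <- genome[[chr]]
    if (any(intervals$end[idx] > length(seq))) {
      stop("interval beyond end of ", chr)
    }
    v <- Biostrings::Views(seq, start = intervals$start[idx] + 1,
                           end = intervals$end[idx])
    counts <- Biostrings::letterFrequency(v, letters = c("A", "C", "G", "T"))
    denom <- rowSums(counts)
    if (any(denom == 0)) {
      stop("GC content undefined: interval(s) with no unambiguous bases at row(s) ",
           paste(utils::head(idx[denom == 0], 5), collapse = ", "))
    }
    out[idx] <- (counts[, "C"] + counts[, "G"]) / denom
  }
  out
}

#' Write a genome to FASTA
#' @param genome A named [Biostrings::DNAStringSet].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path)
  invisible(path)
}

#' Read a genome from FASTA
#' @param path FASTA path.
#' @return A named [Biostrings::DNAStringSet].
#' @export
read_genome_fasta <- function(path) {
  genome <- Biostrings::readDNAStringSet(path)
  names(genome) <- sub("\\s.*$", "", names(genome))
  genome
}

#' Chromosome sizes of a genome
#' @param genome A named [Biostrings::DNAStringSet].
#' @return Named numeric vector of lengths.
#' @export
genome_sizes <- function(genome) {
  stats::setNames(as.numeric(Biostrings::width(genome)), names(genome))
}
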