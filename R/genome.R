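#' Genome reference wrapper
#'
#' Wraps a set of chromosome sequences behind a 0-based half-open interval
#' accessor. All coordinates in this package are 0-based half-open; requests
#' beyond chromosome bounds are rejected rather than clipped.
#'
#' @param x A [Biostrings::DNAStringSet], a named character vector of
#'   sequences, or the path to a FASTA file.
#' @return An object of class `genome_ref`.
#' @export
genome_ref <- function(x) {
  if (is.character(x) && length(x) == 1L && file.exists(x)) {
    x <- Biostrings::readDNAStringSet(x)
    # FASTA description lines may carry comments after the identifier
    names(x) <- sub("\\s.*$", "", names(x))
  } else if (is.character(x)) {
    x <- Biostrings::DNAStringSet(x)
  }
  stopifnot(methods::is(x, "DNAStringSet"))
  if (is.null(names(x)) || anyDuplicated(names(x)))
    stop("genome sequences must have unique names")
  structure(list(seqs = x), class = "genome_ref")
}

#' @export
print.genome_ref <- function(x, ...) {
  cat("<genome_ref> ", length(x$seqs), " sequence(s), ",
      sum(as.numeric(Biostrings::width(x$seqs))), " bases\n", sep = "")
  invisible(x)
}

#' Chromosome lengths of a genome reference
#' @param genome A `genome_ref`.
#' @return Named integer vector of chromosome lengths.
#' @export
seq_lengths <- function(genome) {
  stopifnot(inherits(genome, "genome_ref"))
  stats::setNames(Biostrings::width(genome$seqs), names(genome$seqs))
}

#' Extract genome sequence for 0-based half-open intervals
#'
#' @param genome A `genome_ref`.
#' @param chrom Chromosome name(s), recycled against `start`/`end`.
#' @param start,end 0-based half-open interval bounds.
#' @return Uppercase character vector of sequences, one per interval.
#' @export
genome_seq <- function(genome, chrom, start, end) {
  stopifnot(inherits(genome, "genome_ref"))
  n <- max(length(chrom), length(start), length(end))
  chrom <- rep_len(chrom, n); start <- rep_len(start, n); end <- rep_len(end, n)
  lens <- seq_lengths(genome)
  if (!all(chrom %in% names(lens)))
    stop("unknown chromosome: ", paste(setdiff(chrom, names(lens)), collapse = ", "))
  if (any(start < 0) || any(end > lens[chrom]) || any(start > end))
    stop("interval outside chromosome bounds")
  out <- character(n)
  for (cn in unique(chrom)) {
    idx <- which(chrom == cn & end > start)
    if (!length(idx)) next
    v <- Biostrings::extractAt(genome$seqs[[cn]],
                               IRanges::IRanges(start[idx] + 1L, end[idx]))
    out[idx] <- toupper(as.character(v))
  }
  out
}

#' Write a genome reference to FASTA
#' @param genome A `genome_ref`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  stopifnot(inherits(genome, "genome_ref"))
  Biostrings::writeXStringSet(genome$seqs, path)
  invisible(path)
}
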