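# Shared fixtures, built in code.

# deterministic toy genome: one or more random-sequence chromosomes
toy_genome <- function(lens = c(chr1 = 5000L), seed = 99L) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  genome_ref(vapply(lens, function(L)
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""),
    ""))
}

# annotation row helper
tx_row <- function(transcript_id, gene_id, starts, ends,
                   chrom = "chr1", strand = "+") {
  data.frame(transcript_id = transcript_id, gene_id = gene_id,
             chrom = chrom, strand = strand,
             exon_starts = paste(starts, collapse = ","),
             exon_ends = paste(ends, collapse = ","),
             stringsAsFactors = FALSE)
}

# a 3-exon gene with inclusion + skip transcripts (classic cassette layout)
cassette_annotation <- function(strand = "+") {
  rbind(tx_row("t1", "g1", c(100, 300, 500), c(200, 400, 600),
               strand = strand),
        tx_row("t2", "g1", c(100, 500), c(200, 600), strand = strand))
}

# write a SAM file from record rows; refs = named lengths
write_test_sam <- function(path, records, refs) {
  header <- c("@HD\tVN:1.6\tSO:unknown",
              sprintf("@SQ\tSN:%s\tLN:%d", names(refs), refs))
  writeLines(c(header, records), path)
  path
}

sam_rec <- function(qname, flag, rname, pos1, cigar, nm = 0L,
                    rnext = "*", pnext = 0L, tlen = 0L, seq = "*") {
  sprintf("%s\t%d\t%s\t%d\t255\t%s\t%s\t%d\t%d\t%s\t*\tNM:i:%d",
          qname, flag, rname, pos1, cigar, rnext, pnext, tlen, seq, nm)
}
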