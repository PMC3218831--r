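#' @importFrom stats setNames median qnorm dbinom pchisq
#' @importFrom utils read.delim write.table
#' @importFrom methods is
NULL

# ---------------------------------------------------------------------------
# Transcript annotation table
#
# The package's internal annotation exchange format is one row per transcript:
#   transcript_id, gene_id, chrom, strand, exon_starts, exon_ends
# with exon coordinates 0-based half-open, comma-joined, sorted.
# ---------------------------------------------------------------------------

.parse_int_list <- function(x) {
  lapply(strsplit(as.character(x), ","), function(v) as.integer(v[nzchar(v)]))
}

.join_int_list <- function(x) vapply(x, paste, "", collapse = ",")

#' Validate and normalize a transcript annotation table
#'
#' @param df A data.frame with columns `transcript_id`, `gene_id`, `chrom`,
#'   `strand`, `exon_starts`, `exon_ends` (0-based half-open, comma-joined).
#' @return The normalized data.frame, classed `transcript_annotation`.
#' @export
as_annotation <- function(df) {
  need <- c("transcript_id", "gene_id", "chrom", "strand",
            "exon_starts", "exon_ends")
  if (!all(need %in% names(df)))
    stop("annotation table must have columns: ", paste(need, collapse = ", "))
  df <- as.data.frame(df)[need]
  starts <- .parse_int_list(df$exon_starts)
  ends <- .parse_int_list(df$exon_ends)
  for (i in seq_len(nrow(df))) {
    s <- starts[[i]]; e <- ends[[i]]
    if (!length(s) || length(s) != length(e))
      stop("transcript ", df$transcript_id[i], ": malformed exon blocks")
    o <- order(s); s <- s[o]; e <- e[o]
    if (any(e <= s))
      stop("transcript ", df$transcript_id[i], ": exon start must precede end")
    if (length(s) > 1L && any(s[-1L] <= e[-length(e)]))
      stop("transcript ", df$transcript_id[i],
           ": exons must be separated by at least one base")
    starts[[i]] <- s; ends[[i]] <- e
  }
  if (!all(df$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  df$exon_starts <- .join_int_list(starts)
  df$exon_ends <- .join_int_list(ends)
  class(df) <- c("transcript_annotation", "data.frame")
  df
}

#' Read transcript annotation from GTF or BED12
#'
#' GTF exon features are grouped by `transcript_id`; BED12 blocks become
#' exons. The format is auto-detected from the extension and can be forced.
#'
#' @param path File path.
#' @param format `"auto"`, `"gtf"`, `"bed"`, or `"tsv"` (the package's native
#'   transcript table).
#' @return A `transcript_annotation` data.frame (0-based half-open).
#' @export
read_annotation <- function(path, format = c("auto", "gtf", "bed", "tsv")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, gtf = "gtf", gff = "gtf", gff3 = "gtf",
                     bed = "bed", "tsv")
  }
  if (format == "tsv") {
    return(as_annotation(read.delim(path, comment.char = "#",
                                    stringsAsFactors = FALSE)))
  }
  gr <- rtracklayer::import(path, format = format)
  if (format == "gtf") {
    gr <- gr[gr$type == "exon"]
    key <- paste(gr$transcript_id, gr$gene_id, sep = "\r")
    sp <- split(gr, key)
    df <- data.frame(
      transcript_id = vapply(sp, function(g) g$transcript_id[1], ""),
      gene_id = vapply(sp, function(g) g$gene_id[1], ""),
      chrom = vapply(sp, function(g) as.character(GenomicRanges::seqnames(g))[1], ""),
      strand = vapply(sp, function(g) as.character(GenomicRanges::strand(g))[1], ""),
      exon_starts = vapply(sp, function(g)
        paste(sort(GenomicRanges::start(g)) - 1L, collapse = ","), ""),
      exon_ends = vapply(sp, function(g)
        paste(sort(GenomicRanges::end(g)), collapse = ","), ""),
      row.names = NULL, stringsAsFactors = FALSE)
  } else {
    blocks <- rtracklayer::blocks(gr)
    df <- data.frame(
      transcript_id = gr$name,
      gene_id = if (!is.null(gr$geneName)) gr$geneName else gr$name,
      chrom = as.character(GenomicRanges::seqnames(gr)),
      strand = as.character(GenomicRanges::strand(gr)),
      exon_starts = vapply(seq_along(gr), function(i)
        paste(GenomicRanges::start(blocks[[i]]) - 1L, collapse = ","), ""),
      exon_ends = vapply(seq_along(gr), function(i)
        paste(GenomicRanges::end(blocks[[i]]), collapse = ","), ""),
      stringsAsFactors = FALSE)
  }
  as_annotation(df)
}

#' Write a transcript annotation table
#'
#' @param anno A `transcript_annotation`.
#' @param path Output path.
#' @param format `"tsv"` (native table) or `"gtf"`.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(anno, path, format = c("tsv", "gtf")) {
  format <- match.arg(format)
  if (format == "tsv") {
    con <- file(path, "w")
    writeLines("# transcript annotation; coordinates 0-based half-open", con)
    suppressWarnings(write.table(anno, con, sep = "\t", quote = FALSE,
                                 row.names = FALSE))
    close(con)
  } else {
    starts <- .parse_int_list(anno$exon_starts)
    ends <- .parse_int_list(anno$exon_ends)
    lines <- character(0)
    for (i in seq_len(nrow(anno))) {
      attr_str <- sprintf('gene_id "%s"; transcript_id "%s";',
                          anno$gene_id[i], anno$transcript_id[i])
      lines <- c(lines, sprintf("%s\tspliceq\texon\t%d\t%d\t.\t%s\t.\t%s",
                                anno$chrom[i], starts[[i]] + 1L, ends[[i]],
                                anno$strand[i], attr_str))
    }
    writeLines(lines, path)
  }
  invisible(path)
}

# ---------------------------------------------------------------------------
# Gene models
# ---------------------------------------------------------------------------

#' Build gene models from a transcript annotation
#'
#' Transcripts are grouped strictly by `gene_id`. Each gene model records the
#' merged exon-union blocks of all member transcripts, the model length (sum
#' of union block lengths), and the gene's known splice sites. Splice sites
#' are collected only from internal exon boundaries: for each transcript the
#' end of every exon except its genomically last is a left (intron-start)
#' site and the start of every exon except its genomically first is a right
#' (intron-end) site. On the plus strand left sites are donors and right
#' sites acceptors; on the minus strand the roles are reversed.
#'
#' @param anno A `transcript_annotation` (or coercible data.frame).
#' @param genome Optional `genome_ref`; when supplied, exons are checked
#'   against chromosome bounds.
#' @return A `gene_model_set`: a named list of `gene_model` objects.
#' @export
load_gene_models <- function(anno, genome = NULL) {
  anno <- as_annotation(anno)
  starts <- .parse_int_list(anno$exon_starts)
  ends <- .parse_int_list(anno$exon_ends)
  lens <- if (!is.null(genome)) seq_lengths(genome) else NULL
  models <- list()
  for (gid in unique(anno$gene_id)) {
    idx <- which(anno$gene_id == gid)
    chrom <- unique(anno$chrom[idx])
    strand <- unique(anno$strand[idx])
    if (length(chrom) > 1L)
      stop("gene ", gid, ": transcripts on different chromosomes")
    if (length(strand) > 1L)
      stop("gene ", gid, ": transcripts on different strands")
    if (!is.null(lens)) {
      if (!chrom %in% names(lens))
        stop("gene ", gid, ": unknown chromosome ", chrom)
      if (any(unlist(ends[idx]) > lens[[chrom]]) ||
          any(unlist(starts[idx]) < 0L))
        stop("gene ", gid, ": exon outside chromosome bounds")
    }
    txs <- lapply(idx, function(i) {
      ex <- cbind(start = starts[[i]], end = ends[[i]])
      k <- nrow(ex)
      list(transcript_id = anno$transcript_id[i],
           exons = ex,
           tss = unname(if (strand == "+") ex[1L, "start"] else ex[k, "end"]),
           pacs = unname(if (strand == "+") ex[k, "end"] else ex[1L, "start"]))
    })
    names(txs) <- vapply(txs, `[[`, "", "transcript_id")
    allr <- IRanges::IRanges(unlist(starts[idx]) + 1L, unlist(ends[idx]))
    un <- IRanges::reduce(allr)
    union <- cbind(start = IRanges::start(un) - 1L, end = IRanges::end(un))
    left_sites <- sort(unique(unlist(lapply(txs, function(t)
      t$exons[-nrow(t$exons), "end"]))))
    right_sites <- sort(unique(unlist(lapply(txs, function(t)
      t$exons[-1L, "start"]))))
    models[[gid]] <- structure(list(
      gene_id = gid, chrom = chrom, strand = strand,
      transcripts = txs, exon_union = union,
      model_length = sum(union[, "end"] - union[, "start"]),
      left_sites = as.integer(left_sites),
      right_sites = as.integer(right_sites),
      donors = if (strand == "+") as.integer(left_sites) else as.integer(right_sites),
      acceptors = if (strand == "+") as.integer(right_sites) else as.integer(left_sites),
      span = c(min(union[, "start"]), max(union[, "end"]))
    ), class = "gene_model")
  }
  structure(models, class = "gene_model_set")
}

#' @export
print.gene_model <- function(x, ...) {
  cat("<gene_model> ", x$gene_id, " ", x$chrom, x$strand, " ",
      length(x$transcripts), " transcript(s), ", nrow(x$exon_union),
      " union block(s), model length ", x$model_length, "\n", sep = "")
  invisible(x)
}

#' @export
print.gene_model_set <- function(x, ...) {
  cat("<gene_model_set> ", length(x), " gene(s)\n", sep = "")
  invisible(x)
}

#' @export
`[.gene_model_set` <- function(x, i) {
  structure(NextMethod(), class = "gene_model_set")
}

#' Serialize gene models back to a transcript annotation table
#' @param models A `gene_model_set`.
#' @return A `transcript_annotation` data.frame.
#' @export
models_to_annotation <- function(models) {
  rows <- lapply(unclass(models), function(g) {
    data.frame(
      transcript_id = vapply(g$transcripts, `[[`, "", "transcript_id"),
      gene_id = g$gene_id, chrom = g$chrom, strand = g$strand,
      exon_starts = vapply(g$transcripts, function(t)
        paste(t$exons[, "start"], collapse = ","), ""),
      exon_ends = vapply(g$transcripts, function(t)
        paste(t$exons[, "end"], collapse = ","), ""),
      stringsAsFactors = FALSE, row.names = NULL)
  })
  as_annotation(do.call(rbind, rows))
}

# ---------------------------------------------------------------------------
# Junction enumeration and the junction contig library
# ---------------------------------------------------------------------------

# union block containing a given base; returns row index or NA
.union_block_of <- function(gene, pos) {
  u <- gene$exon_union
  hit <- which(u[, "start"] <= pos & pos < u[, "end"])
  if (length(hit)) hit[1L] else NA_integer_
}

#' Enumerate all forward splice junctions of a gene
#'
#' Pairs every known intron-start site with every known intron-end site that
#' lies strictly downstream in transcription direction ("exon n splices to
#' exon m, m > n"). Junctions are stored in genomic orientation:
#' `donor_end` is the first intronic base (0-based) and `acceptor_start` the
#' first exonic base after the intron, with `donor_end < acceptor_start`
#' regardless of strand.
#'
#' @param gene A `gene_model`.
#' @return A data.frame with columns `chrom`, `strand`, `donor_end`,
#'   `acceptor_start`, `gene_id`, and the maximal exonic flank available on
#'   each side (`max_left`, `max_right`, bounded by the containing exon-union
#'   block).
#' @export
enumerate_junctions <- function(gene) {
  stopifnot(inherits(gene, "gene_model"))
  L <- gene$left_sites; R <- gene$right_sites
  if (!length(L) || !length(R))
    return(data.frame(chrom = character(0), strand = character(0),
                      donor_end = integer(0), acceptor_start = integer(0),
                      gene_id = character(0), max_left = integer(0),
                      max_right = integer(0)))
  pairs <- expand.grid(donor_end = L, acceptor_start = R)
  pairs <- pairs[pairs$donor_end < pairs$acceptor_start, , drop = FALSE]
  u <- gene$exon_union
  max_left <- vapply(pairs$donor_end, function(l) {
    b <- .union_block_of(gene, l - 1L)
    as.integer(l - u[b, "start"])
  }, 1L)
  max_right <- vapply(pairs$acceptor_start, function(r) {
    b <- .union_block_of(gene, r)
    as.integer(u[b, "end"] - r)
  }, 1L)
  out <- data.frame(chrom = gene$chrom, strand = gene$strand,
                    donor_end = as.integer(pairs$donor_end),
                    acceptor_start = as.integer(pairs$acceptor_start),
                    gene_id = gene$gene_id,
                    max_left = max_left, max_right = max_right,
                    stringsAsFactors = FALSE)
  out <- out[order(out$donor_end, out$acceptor_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Junction table for a whole gene model set
#' @param models A `gene_model_set`.
#' @return Row-bound [enumerate_junctions()] output for every gene.
#' @export
junction_table <- function(models) {
  do.call(rbind, c(lapply(unclass(models), enumerate_junctions),
                   list(make.row.names = FALSE)))
}

#' Build the splice-junction contig library
#'
#' Each junction becomes a contig made of the last `overhang` exonic bases
#' before the intron followed by the first `overhang` exonic bases after it.
#' Flanks are truncated (never padded) where the containing exon-union block
#' or the chromosome is shorter; actual flank lengths are recorded in the
#' contig name, which follows the fixed grammar
#' `JUNC|<chrom>|<donor_end>|<acceptor_start>|<strand>|<gene_id>|<left>|<right>`.
#'
#' @param junctions Junction table from [enumerate_junctions()] /
#'   [junction_table()].
#' @param genome A `genome_ref`.
#' @param overhang Flank length in nt (default: read length minus one, so a
#'   full-length read on a contig necessarily crosses the splice point).
#' @param path Optional FASTA output path.
#' @return A named [Biostrings::DNAStringSet] of junction contigs.
#' @export
write_junction_library <- function(junctions, genome, overhang, path = NULL) {
  stopifnot(overhang >= 1)
  j <- junctions[!duplicated(junctions[c("chrom", "donor_end",
                                         "acceptor_start", "strand",
                                         "gene_id")]), , drop = FALSE]
  lens <- seq_lengths(genome)
  lf <- pmin(overhang, j$max_left, j$donor_end)
  rf <- pmin(overhang, j$max_right, lens[j$chrom] - j$acceptor_start)
  seqs <- paste0(
    genome_seq(genome, j$chrom, j$donor_end - lf, j$donor_end),
    genome_seq(genome, j$chrom, j$acceptor_start, j$acceptor_start + rf))
  nm <- sprintf("JUNC|%s|%d|%d|%s|%s|%d|%d", j$chrom, j$donor_end,
                j$acceptor_start, j$strand, j$gene_id, lf, rf)
  if (anyDuplicated(nm)) stop("duplicate junction contig names")
  out <- Biostrings::DNAStringSet(setNames(seqs, nm))
  if (!is.null(path)) Biostrings::writeXStringSet(out, path)
  out
}

#' Parse junction contig names back to their coordinates
#' @param x Character vector of contig names in the library grammar.
#' @return data.frame with `chrom`, `donor_end`, `acceptor_start`, `strand`,
#'   `gene_id`, `left_flank`, `right_flank`.
#' @export
parse_junction_name <- function(x) {
  parts <- strsplit(x, "|", fixed = TRUE)
  bad <- vapply(parts, length, 1L) != 8L |
    vapply(parts, `[[`, "", 1L) != "JUNC"
  if (any(bad))
    stop("not a junction contig name: ", x[bad][1L])
  m <- do.call(rbind, parts)
  data.frame(chrom = m[, 2L], donor_end = as.integer(m[, 3L]),
             acceptor_start = as.integer(m[, 4L]), strand = m[, 5L],
             gene_id = m[, 6L], left_flank = as.integer(m[, 7L]),
             right_flank = as.integer(m[, 8L]), stringsAsFactors = FALSE)
}

#' Test whether reference names follow the junction contig grammar
#' @param x Character vector of reference names.
#' @return Logical vector.
#' @export
is_junction_ref <- function(x) startsWith(x, "JUNC|")

# ---------------------------------------------------------------------------
# Two-isoform event construction
# ---------------------------------------------------------------------------

.jtok <- function(d, a) sprintf("J:%d-%d", d, a)
.itok <- function(s, e) sprintf("I:%d-%d", s, e)

.empty_events <- function() {
  data.frame(event_id = character(0), event_type = character(0),
             gene_id = character(0), chrom = character(0),
             strand = character(0), focus_start = integer(0),
             focus_end = integer(0), a_support = character(0),
             b_support = character(0), stringsAsFactors = FALSE)
}

.event_row <- function(gene, type, focus, a, b) {
  data.frame(event_id = paste(gene$gene_id, type, focus[1L], focus[2L],
                              sep = ":"),
             event_type = type, gene_id = gene$gene_id, chrom = gene$chrom,
             strand = gene$strand, focus_start = as.integer(focus[1L]),
             focus_end = as.integer(focus[2L]),
             a_support = paste(a, collapse = ";"),
             b_support = paste(b, collapse = ";"),
             stringsAsFactors = FALSE)
}

#' Candidate cassette (skipped) exon events
#'
#' One event per internal exon-union block. Isoform A (inclusion) evidence is
#' the set of junctions landing on either boundary of the block from known
#' splice sites outside it; isoform B (skip) evidence is every junction from
#' a known intron-start site strictly outside the block on its 5' side to a
#' known intron-end site strictly outside on its 3' side. Both sides are
#' junction evidence only, so the inclusion:skip statistic is not biased by
#' exon length.
#'
#' @param gene A `gene_model`.
#' @return Event data.frame (see [find_events()]).
#' @export
find_cassette_events <- function(gene) {
  u <- gene$exon_union
  if (nrow(u) < 3L) return(.empty_events())
  L <- gene$left_sites; R <- gene$right_sites
  rows <- list()
  for (i in 2:(nrow(u) - 1L)) {
    bs <- u[i, "start"]; be <- u[i, "end"]
    a <- character(0)
    if (bs %in% R)
      a <- c(a, .jtok(L[L < bs], bs))
    if (be %in% L)
      a <- c(a, .jtok(be, R[R > be]))
    b <- character(0)
    dl <- L[L < bs]; ar <- R[R > be]
    if (length(dl) && length(ar)) {
      g <- expand.grid(d = dl, r = ar)
      b <- .jtok(g$d, g$r)
    }
    rows[[length(rows) + 1L]] <-
      .event_row(gene, "cassette", c(bs, be), a, b)
  }
  do.call(rbind, rows)
}

#' Candidate retained-intron events
#'
#' One event per gap between adjacent exon-union blocks whose flanking exons
#' are locally constitutive: every transcript whose genomic span covers the
#' gap must contain an exon ending exactly at the gap start and an exon
#' beginning exactly at the gap end (and at least one transcript must span
#' the gap). Isoform A evidence is the intron interval; isoform B evidence is
#' the two flanking exon-union blocks.
#'
#' @param gene A `gene_model`.
#' @return Event data.frame (see [find_events()]).
#' @export
find_retained_intron_events <- function(gene) {
  u <- gene$exon_union
  if (nrow(u) < 2L) return(.empty_events())
  rows <- list()
  for (i in seq_len(nrow(u) - 1L)) {
    gs <- u[i, "end"]; ge <- u[i + 1L, "start"]
    spanning <- Filter(function(t) {
      t$exons[1L, "start"] <= gs && t$exons[nrow(t$exons), "end"] >= ge
    }, gene$transcripts)
    if (!length(spanning)) next
    ok <- all(vapply(spanning, function(t) {
      any(t$exons[, "end"] == gs) && any(t$exons[, "start"] == ge)
    }, TRUE))
    if (!ok) next
    rows[[length(rows) + 1L]] <- .event_row(
      gene, "retained_intron", c(gs, ge),
      .itok(gs, ge),
      c(.itok(u[i, "start"], u[i, "end"]),
        .itok(u[i + 1L, "start"], u[i + 1L, "end"])))
  }
  if (!length(rows)) return(.empty_events())
  do.call(rbind, rows)
}

# setdiff/intersect on 0-based half-open interval matrices via IRanges
.iv_ranges <- function(m) IRanges::IRanges(m[, 1L] + 1L, m[, 2L])
.ranges_iv <- function(r) cbind(start = IRanges::start(r) - 1L,
                                end = IRanges::end(r))

#' Candidate alternative terminal exon events
#'
#' For every distinct transcription start site (TSS) except the 5'-most, and
#' every distinct poly-adenylation/cleavage site (PACS) except the 3'-most,
#' an event compares reads supporting the candidate terminal exon(s)
#' (isoform A: first/last exons of transcripts using that site, minus exonic
#' regions of transcripts with a more extreme site) with reads in exon-union
#' regions more distal than the candidate site (isoform B). Events with an
#' empty side are dropped. All orderings are taken in transcription
#' direction, so the construction mirrors correctly on the minus strand.
#'
#' @param gene A `gene_model`.
#' @return Event data.frame (see [find_events()]).
#' @export
find_terminal_events <- function(gene) {
  u <- gene$exon_union
  plus <- gene$strand == "+"
  rows <- list()

  build <- function(kind) {
    # kind "tss": candidate terminal = transcription start side
    # kind "pacs": candidate terminal = poly-A/cleavage side
    site_of <- function(t) if (kind == "tss") t$tss else t$pacs
    # terminal exon of a transcript on the relevant side (genomic row index)
    term_exon <- function(t) {
      k <- nrow(t$exons)
      first_genomic <- (kind == "tss") == plus
      if (first_genomic) t$exons[1L, , drop = FALSE]
      else t$exons[k, , drop = FALSE]
    }
    sites <- vapply(gene$transcripts, site_of, 1)
    vals <- unique(sites)
    if (length(vals) < 2L) return()
    # "more extreme" = more 5' for TSS, more 3' for PACS, in transcription
    # direction; genomically that is smaller for (+ tss | - pacs), larger
    # for the other two combinations.
    smaller_is_extreme <- (kind == "tss") == plus
    extreme <- if (smaller_is_extreme) min(vals) else max(vals)
    for (t0 in setdiff(vals, extreme)) {
      cand <- gene$transcripts[sites == t0]
      more_extreme <- gene$transcripts[
        if (smaller_is_extreme) sites < t0 else sites > t0]
      a_r <- IRanges::reduce(.iv_ranges(do.call(rbind, lapply(cand, term_exon))))
      ex_r <- IRanges::reduce(.iv_ranges(do.call(rbind, lapply(
        more_extreme, function(t) t$exons))))
      a_r <- IRanges::setdiff(a_r, ex_r)
      # distal (isoform B) region: exon-union strictly beyond the candidate
      # site on its extreme side
      span <- gene$span
      b_win <- if (smaller_is_extreme) c(span[1L], t0) else c(t0, span[2L])
      b_r <- IRanges::intersect(.iv_ranges(u),
                                .iv_ranges(matrix(b_win, ncol = 2L)))
      if (!length(a_r) || !length(b_r)) next
      am <- .ranges_iv(a_r); bm <- .ranges_iv(b_r)
      rows[[length(rows) + 1L]] <<- .event_row(
        gene, if (kind == "tss") "alt_tss" else "alt_pacs",
        c(min(am[, "start"]), max(am[, "end"])),
        .itok(am[, "start"], am[, "end"]),
        .itok(bm[, "start"], bm[, "end"]))
    }
  }
  build("tss")
  build("pacs")
  if (!length(rows)) return(.empty_events())
  do.call(rbind, rows)
}

#' All candidate two-isoform events of a gene model set
#'
#' @param models A `gene_model_set`.
#' @param types Event types to generate.
#' @return A data.frame with one row per event: `event_id`, `event_type`,
#'   `gene_id`, `chrom`, `strand`, `focus_start`, `focus_end` and the two
#'   evidence columns `a_support`/`b_support` (`;`-joined `J:<d>-<a>`
#'   junction or `I:<s>-<e>` interval tokens, 0-based half-open).
#' @export
find_events <- function(models,
                        types = c("cassette", "retained_intron",
                                  "alt_tss", "alt_pacs")) {
  types <- match.arg(types, several.ok = TRUE)
  out <- lapply(unclass(models), function(g) {
    parts <- list()
    if ("cassette" %in% types) parts <- c(parts, list(find_cassette_events(g)))
    if ("retained_intron" %in% types)
      parts <- c(parts, list(find_retained_intron_events(g)))
    if (any(c("alt_tss", "alt_pacs") %in% types)) {
      te <- find_terminal_events(g)
      parts <- c(parts, list(te[te$event_type %in% types, , drop = FALSE]))
    }
    do.call(rbind, parts)
  })
  res <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  if (is.null(res)) .empty_events() else res
}

#' Decode support tokens of one event side
#' @param tokens A `;`-joined token string (`J:<d>-<a>` / `I:<s>-<e>`).
#' @return list with data.frames `junctions` (donor_end, acceptor_start) and
#'   `intervals` (start, end).
#' @export
parse_support <- function(tokens) {
  tok <- strsplit(tokens, ";", fixed = TRUE)[[1]]
  tok <- tok[nzchar(tok)]
  j <- tok[startsWith(tok, "J:")]
  i <- tok[startsWith(tok, "I:")]
  jm <- if (length(j)) do.call(rbind, strsplit(sub("^J:", "", j), "-")) else
    matrix(integer(0), 0, 2)
  im <- if (length(i)) do.call(rbind, strsplit(sub("^I:", "", i), "-")) else
    matrix(integer(0), 0, 2)
  list(junctions = data.frame(donor_end = as.integer(jm[, 1]),
                              acceptor_start = as.integer(jm[, 2])),
       intervals = data.frame(start = as.integer(im[, 1]),
                              end = as.integer(im[, 2])))
}

#' Write / read the event table
#' @param events Event data.frame from [find_events()].
#' @param path File path.
#' @return `path` (write) or the event data.frame (read).
#' @export
write_events <- function(events, path) {
  con <- file(path, "w")
  writeLines("# two-isoform events; coordinates 0-based half-open", con)
  suppressWarnings(write.table(events, con, sep = "\t", quote = FALSE,
                               row.names = FALSE))
  close(con)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
             colClasses = c(focus_start = "integer", focus_end = "integer"))
}
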