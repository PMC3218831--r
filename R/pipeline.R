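# ---------------------------------------------------------------------------
# Pipeline glue: sample sheets, alignment import, placement serialization,
# QC summaries and two-group comparisons.
# ---------------------------------------------------------------------------

#' Read a sample sheet
#'
#' @param path TSV with columns `sample_id`, `group`, `path` (SAM/BAM,
#'   relative to the sheet), `read_len`, `adaptor_len`, `paired`.
#' @return data.frame with `path` resolved against the sheet directory.
#' @export
read_sample_sheet <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("sample_id", "group", "path")
  if (!all(need %in% names(df)))
    stop("sample sheet must have columns: ", paste(need, collapse = ", "))
  if (is.null(df$read_len)) df$read_len <- 36L
  if (is.null(df$adaptor_len)) df$adaptor_len <- 50L
  if (is.null(df$paired)) df$paired <- FALSE
  rel <- !grepl("^/", df$path)
  df$path[rel] <- file.path(dirname(path), df$path[rel])
  df
}

#' Import alignments for one sample
#'
#' Runs the full placement chain: parse SAM/BAM, lift junction-contig hits
#' to genome space, match spliced-alignment gaps against annotated
#' junctions, select unique-best placements and resolve pairs.
#'
#' @param paths SAM/BAM file path(s) for the sample (genome-space and
#'   junction-space hits may come in separate files).
#' @param models A `gene_model_set` (junction annotation); optional.
#' @param sample_id Sample label.
#' @param chroms Optional valid genomic reference names for validation.
#' @return A resolved `placement_set`.
#' @export
import_alignments <- function(paths, models = NULL, sample_id = "sample",
                              chroms = NULL) {
  cs <- parse_alignments(paths, chroms = chroms)
  cs <- lift_candidates(cs)
  if (!is.null(models))
    cs <- annotate_gaps(cs, junction_table(models))
  resolve_pairs(select_unique_best(cs, sample_id = sample_id))
}

#' Import every sample of a sample sheet
#' @param sheet Sample sheet path or data.frame ([read_sample_sheet()]).
#' @param models A `gene_model_set`.
#' @return Named list of `placement_set`s.
#' @export
import_project <- function(sheet, models = NULL) {
  if (is.character(sheet)) sheet <- read_sample_sheet(sheet)
  out <- lapply(seq_len(nrow(sheet)), function(i)
    import_alignments(sheet$path[i], models,
                      sample_id = sheet$sample_id[i]))
  setNames(out, sheet$sample_id)
}

#' Serialize / deserialize placements as the sorted tabular intermediate
#'
#' One row per placement; blocks and crossed junctions are token-encoded
#' (`<start>-<end>` and `<donor>-<acceptor>:<left_anchor>:<right_anchor>`,
#' `;`-joined). Pair records are reconstructed on read from read ids with
#' both ends placed.
#'
#' @param pset A `placement_set`.
#' @param path Output/input path.
#' @return `path` (write) / a `placement_set` (read).
#' @export
write_placements <- function(pset, path) {
  pl <- pset$placements
  bl <- pset$blocks
  jn <- pset$juncs
  btok <- vapply(split(paste0(bl$start, "-", bl$end),
                       factor(bl$pl_id, levels = pl$pl_id)),
                 paste, "", collapse = ";")
  jtok <- rep("", nrow(pl))
  if (!is.null(jn) && nrow(jn)) {
    jt <- vapply(split(sprintf("%d-%d:%d:%d", jn$donor_end,
                               jn$acceptor_start, jn$left_anchor,
                               jn$right_anchor),
                       factor(jn$pl_id, levels = pl$pl_id)),
                 paste, "", collapse = ";")
    jtok <- unname(jt)
  }
  df <- data.frame(pl[c("read_id", "end", "sample_id", "chrom", "strand",
                        "nm", "source", "n_gaps", "njunc")],
                   blocks = unname(btok), juncs = jtok)
  df <- df[order(df$chrom, vapply(strsplit(df$blocks, "-"),
                                  function(x) as.integer(x[1]), 1L),
                 df$read_id, df$end), , drop = FALSE]
  con <- file(path, "w")
  writeLines("# read placements; coordinates 0-based half-open", con)
  suppressWarnings(write.table(df, con, sep = "\t", quote = FALSE,
                               row.names = FALSE))
  close(con)
  invisible(path)
}

#' @rdname write_placements
#' @export
read_placements <- function(path) {
  df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                   colClasses = c(blocks = "character",
                                  juncs = "character"))
  df$pl_id <- seq_len(nrow(df))
  bl_tok <- strsplit(df$blocks, ";", fixed = TRUE)
  nb <- lengths(bl_tok)
  bm <- do.call(rbind, strsplit(unlist(bl_tok), "-", fixed = TRUE))
  blocks <- data.frame(pl_id = rep(df$pl_id, nb),
                       start = as.integer(bm[, 1]),
                       end = as.integer(bm[, 2]))
  jrows <- which(nzchar(df$juncs) & !is.na(df$juncs))
  juncs <- data.frame(chrom = character(0), donor_end = integer(0),
                      acceptor_start = integer(0), left_anchor = integer(0),
                      right_anchor = integer(0), pl_id = integer(0))
  if (length(jrows)) {
    jt <- strsplit(df$juncs[jrows], ";", fixed = TRUE)
    nj <- lengths(jt)
    jm <- do.call(rbind, strsplit(unlist(jt), "[-:]"))
    juncs <- data.frame(chrom = rep(df$chrom[jrows], nj),
                        donor_end = as.integer(jm[, 1]),
                        acceptor_start = as.integer(jm[, 2]),
                        left_anchor = as.integer(jm[, 3]),
                        right_anchor = as.integer(jm[, 4]),
                        pl_id = rep(df$pl_id[jrows], nj))
  }
  pl <- df[c("pl_id", "read_id", "end", "sample_id", "chrom", "strand",
             "nm", "source", "n_gaps", "njunc")]
  p1 <- pl[pl$end == 1L, c("read_id", "pl_id")]
  p2 <- pl[pl$end == 2L, c("read_id", "pl_id")]
  pairs <- merge(p1, p2, by = "read_id", suffixes = c("1", "2"))
  names(pairs) <- c("read_id", "pl1", "pl2")
  structure(list(placements = pl, blocks = blocks, juncs = juncs,
                 status = data.frame(sample_id = pl$sample_id,
                                     read_id = pl$read_id, end = pl$end,
                                     status = "unique",
                                     stringsAsFactors = FALSE),
                 pairs = pairs),
            class = "placement_set")
}

#' Paired-end distance QC summary
#'
#' Classifies every resolved pair and summarizes: category fractions, the
#' canonical-distance ECDF, and the complete library size.
#'
#' @param pset A resolved `placement_set`.
#' @param models A `gene_model_set`.
#' @param read_len,adaptor_len Library-size arithmetic inputs.
#' @return list with `categories` (fractions), `pairs` (per-pair table) and
#'   `library` ([library_size_summary()] output).
#' @export
pairdist_summary <- function(pset, models, read_len = 36, adaptor_len = 50) {
  cls <- classify_pairs(pset, models)
  lev <- c("DIFF_CHROM", "SAME_STRAND", "MINUS_UPSTREAM", "INTRON_BETWEEN",
           "CANONICAL")
  frac <- table(factor(cls$category, levels = lev)) /
    max(1L, nrow(cls))
  list(categories = as.data.frame(frac, responseName = "fraction"),
       pairs = cls,
       library = library_size_summary(
         cls$distance[cls$category == "CANONICAL"], read_len, adaptor_len))
}

#' Two-group gene-level comparison from a count table
#'
#' Pools member-lane counts per group (counts for a group of lanes are the
#' sums of the lanes' counts), estimates effective totals with
#' minimize-significant-changes and runs the binomial change test per gene.
#'
#' @param gct A `gene_count_table`.
#' @param group1,group2 Sample names (or indices) of the two groups.
#' @param p_cutoff,fold_cutoff,bh See [gene_test()].
#' @param conf Confidence level for the MSC intervals.
#' @return A `gene_test_table`.
#' @export
compare_groups <- function(gct, group1, group2, p_cutoff = 1e-4,
                           fold_cutoff = 2, bh = FALSE, conf = 0.95) {
  g1 <- .pool_cols(gct$counts, group1)
  g2 <- .pool_cols(gct$counts, group2)
  names(g1) <- names(g2) <- rownames(gct$counts)
  N <- sum(gct$totals[group1]) + sum(gct$totals[group2])
  norm <- minimize_significant_changes(g1, g2, conf = conf, N = N)
  gene_test(g1, g2, norm = norm, p_cutoff = p_cutoff,
            fold_cutoff = fold_cutoff, bh = bh)
}

#' Write a gene or event test table as TSV
#' @param x A `gene_test_table` or `event_test_table`.
#' @param path Output path.
#' @export
write_test_table <- function(x, path) {
  con <- file(path, "w")
  norm <- attr(x, "norm")
  writeLines(c("# change table",
               if (!is.null(norm))
                 sprintf("# msc: q2=%.6f N=%g n1=%.1f n2=%.1f",
                         norm$q2, norm$N, norm$n1, norm$n2)), con)
  suppressWarnings(write.table(as.data.frame(x), con, sep = "\t",
                               quote = FALSE, row.names = FALSE))
  close(con)
  invisible(path)
}

#' Read a change table written by [write_test_table()]
#' @param path TSV path.
#' @return data.frame.
#' @export
read_test_table <- function(path) {
  read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}
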