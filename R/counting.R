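# ---------------------------------------------------------------------------
# Read accumulation: gene counts, RPKM, event evidence counts, pileups,
# paired-end scatter data.
# ---------------------------------------------------------------------------

.pset_list <- function(psets) {
  if (inherits(psets, "placement_set")) psets <- list(psets)
  stopifnot(all(vapply(psets, inherits, TRUE, "placement_set")))
  psets
}

# per-placement: indices of genes whose exon union fully contains all blocks
.exonic_hits <- function(pl, bl, models) {
  mods <- unclass(models)
  nub <- vapply(mods, function(g) nrow(g$exon_union), 1L)
  ug <- GenomicRanges::GRanges(
    rep(vapply(mods, `[[`, "", "chrom"), nub),
    IRanges::IRanges(
      unlist(lapply(mods, function(g) g$exon_union[, "start"])) + 1L,
      unlist(lapply(mods, function(g) g$exon_union[, "end"]))))
  gene_of <- rep(seq_along(mods), nub)
  bg <- GenomicRanges::GRanges(pl$chrom[match(bl$pl_id, pl$pl_id)],
                               IRanges::IRanges(bl$start + 1L, bl$end))
  nblocks <- tabulate(match(bl$pl_id, pl$pl_id), nbins = nrow(pl))
  ov <- GenomicRanges::findOverlaps(bg, ug, type = "within")
  if (!length(ov))
    return(data.frame(pl = integer(0), gene = integer(0)))
  hits <- unique(data.frame(
    pl = match(bl$pl_id, pl$pl_id)[S4Vectors::queryHits(ov)],
    gene = gene_of[S4Vectors::subjectHits(ov)],
    blk = S4Vectors::queryHits(ov)))
  agg <- stats::aggregate(blk ~ pl + gene, data = hits, FUN = length)
  agg[agg$blk == nblocks[agg$pl], c("pl", "gene")]
}

#' Count reads for gene models
#'
#' A placement counts towards every gene whose exon union contains all of
#' its aligned positions (possibly split by a junction), on either strand.
#' A read overlapping intronic or intergenic sequence counts for no gene; a
#' read inside an exon shared by overlapping genes counts for each of them.
#'
#' @param psets A `placement_set` or list of them (one per sample).
#' @param models A `gene_model_set`.
#' @return A `gene_count_table`: list with `counts` (gene x sample integer
#'   matrix), `model_length` (named), and `totals` (uniquely placed read
#'   ends per sample).
#' @export
count_genes <- function(psets, models) {
  psets <- .pset_list(psets)
  mods <- unclass(models)
  gene_ids <- names(mods)
  samples <- vapply(psets, function(p) p$placements$sample_id[1L], "")
  samples[is.na(samples)] <- paste0("sample", which(is.na(samples)))
  counts <- matrix(0L, length(gene_ids), length(psets),
                   dimnames = list(gene_ids, samples))
  totals <- setNames(integer(length(psets)), samples)
  for (i in seq_along(psets)) {
    pl <- psets[[i]]$placements
    totals[i] <- nrow(pl)
    if (!nrow(pl)) next
    hits <- .exonic_hits(pl, psets[[i]]$blocks, models)
    if (nrow(hits)) {
      tab <- table(factor(hits$gene, levels = seq_along(mods)))
      counts[, i] <- as.integer(tab)
    }
  }
  structure(list(counts = counts,
                 model_length = setNames(
                   vapply(mods, `[[`, 1, "model_length"), gene_ids),
                 totals = totals),
            class = "gene_count_table")
}

#' @export
print.gene_count_table <- function(x, ...) {
  cat("<gene_count_table> ", nrow(x$counts), " gene(s) x ",
      ncol(x$counts), " sample(s); totals: ",
      paste(x$totals, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Reads per kilobase gene model per million total reads
#'
#' @param count Read count(s) for the gene.
#' @param model_length Gene model length in nt (sum of exon-union blocks).
#' @param total_reads Total uniquely aligned reads in the sample.
#' @return RPKM value(s).
#' @export
rpkm <- function(count, model_length, total_reads) {
  if (any(model_length <= 0)) stop("model_length must be positive")
  if (any(total_reads <= 0)) stop("total_reads must be positive")
  count / ((model_length / 1000) * (total_reads / 1e6))
}

#' RPKM matrix of a gene count table
#' @param gct A `gene_count_table`.
#' @return Numeric matrix parallel to `gct$counts`.
#' @export
rpkm_matrix <- function(gct) {
  sweep(gct$counts / (gct$model_length / 1000), 2,
        gct$totals / 1e6, "/")
}

#' Write the gene count table (counts + RPKM) as TSV
#' @param gct A `gene_count_table`.
#' @param path Output path.
#' @export
write_gene_counts <- function(gct, path) {
  rp <- rpkm_matrix(gct)
  df <- data.frame(gene_id = rownames(gct$counts),
                   model_length = gct$model_length,
                   gct$counts,
                   setNames(as.data.frame(rp),
                            paste0("rpkm_", colnames(rp))),
                   check.names = FALSE)
  con <- file(path, "w")
  writeLines("# gene counts; coordinates 0-based half-open", con)
  suppressWarnings(write.table(df, con, sep = "\t", quote = FALSE,
                               row.names = FALSE))
  close(con)
  invisible(path)
}

#' Count evidence reads for two-isoform events
#'
#' Junction evidence is matched by a placement that crosses exactly that
#' junction with both anchors at least `min_anchor` nt; interval evidence is
#' matched by a placement crossing no junction or gap whose aligned
#' positions are all contained in the side's interval union. A placement
#' increments one side of one event at most once; a placement matching both
#' sides of an event indicates a malformed event and is an error.
#'
#' @param psets A `placement_set` or list of them (one per sample).
#' @param events Event table from [find_events()].
#' @param min_anchor Minimum junction anchor length in nt (default 1; the
#'   junction library built with overhang `read_len - 1` already guarantees
#'   1-nt anchors).
#' @return An `event_count_table`: list with integer matrices `a` and `b`
#'   (event x sample) and the `events` table.
#' @export
count_events <- function(psets, events, min_anchor = 1L) {
  psets <- .pset_list(psets)
  samples <- vapply(psets, function(p) p$placements$sample_id[1L], "")
  nE <- nrow(events)
  a <- matrix(0L, nE, length(psets), dimnames = list(events$event_id, samples))
  b <- a
  supp_a <- lapply(events$a_support, parse_support)
  supp_b <- lapply(events$b_support, parse_support)

  # flatten evidence: junction tokens and interval tokens with event/side
  flat_j <- do.call(rbind, lapply(seq_len(nE), function(i) {
    rbind(
      if (nrow(supp_a[[i]]$junctions))
        cbind(supp_a[[i]]$junctions, ev = i, side = "a"),
      if (nrow(supp_b[[i]]$junctions))
        cbind(supp_b[[i]]$junctions, ev = i, side = "b"))
  }))
  flat_i <- do.call(rbind, lapply(seq_len(nE), function(i) {
    rbind(
      if (nrow(supp_a[[i]]$intervals))
        cbind(supp_a[[i]]$intervals, ev = i, side = "a"),
      if (nrow(supp_b[[i]]$intervals))
        cbind(supp_b[[i]]$intervals, ev = i, side = "b"))
  }))

  for (s in seq_along(psets)) {
    pl <- psets[[s]]$placements
    bl <- psets[[s]]$blocks
    jn <- psets[[s]]$juncs
    matches <- NULL
    if (!is.null(flat_j) && nrow(flat_j) && !is.null(jn) && nrow(jn)) {
      ok <- jn$left_anchor >= min_anchor & jn$right_anchor >= min_anchor
      jk <- paste(pl$chrom[match(jn$pl_id, pl$pl_id)],
                  jn$donor_end, jn$acceptor_start)[ok]
      ek <- paste(events$chrom[flat_j$ev], flat_j$donor_end,
                  flat_j$acceptor_start)
      hit <- match(jk, ek)
      sel <- which(!is.na(hit))
      # require the placement to cross only this junction ("exactly")
      plid <- jn$pl_id[ok][sel]
      single <- pl$njunc[match(plid, pl$pl_id)] == 1L &
        pl$n_gaps[match(plid, pl$pl_id)] <= 1L
      if (any(single))
        matches <- data.frame(pl = plid[single],
                              ev = flat_j$ev[hit[sel][single]],
                              side = flat_j$side[hit[sel][single]])
    }
    if (!is.null(flat_i) && nrow(flat_i) && nrow(pl)) {
      # only gap-free placements are eligible for interval evidence
      elig <- pl$pl_id[pl$njunc == 0L & pl$n_gaps == 0L &
                         pl$source == "genomic"]
      bsel <- bl[bl$pl_id %in% elig, , drop = FALSE]
      if (nrow(bsel)) {
        eg <- GenomicRanges::GRanges(
          events$chrom[flat_i$ev],
          IRanges::IRanges(flat_i$start + 1L, flat_i$end))
        bg <- GenomicRanges::GRanges(
          pl$chrom[match(bsel$pl_id, pl$pl_id)],
          IRanges::IRanges(bsel$start + 1L, bsel$end))
        ov <- GenomicRanges::findOverlaps(bg, eg, type = "within")
        if (length(ov)) {
          h <- unique(data.frame(
            pl = bsel$pl_id[S4Vectors::queryHits(ov)],
            ev = flat_i$ev[S4Vectors::subjectHits(ov)],
            side = flat_i$side[S4Vectors::subjectHits(ov)],
            blk = S4Vectors::queryHits(ov)))
          nblocks <- tabulate(bl$pl_id, nbins = max(bl$pl_id))
          agg <- stats::aggregate(blk ~ pl + ev + side, data = h,
                                  FUN = length)
          agg <- agg[agg$blk == nblocks[agg$pl], c("pl", "ev", "side")]
          matches <- rbind(matches, agg)
        }
      }
    }
    if (!is.null(matches) && nrow(matches)) {
      matches <- unique(matches)
      both <- duplicated(matches[c("pl", "ev")]) |
        duplicated(matches[c("pl", "ev")], fromLast = TRUE)
      if (any(both))
        stop("placement matches both sides of event ",
             events$event_id[matches$ev[which(both)[1L]]],
             ": evidence sets are not disjoint")
      ta <- table(factor(matches$ev[matches$side == "a"], levels = seq_len(nE)))
      tb <- table(factor(matches$ev[matches$side == "b"], levels = seq_len(nE)))
      a[, s] <- as.integer(ta)
      b[, s] <- as.integer(tb)
    }
  }
  structure(list(a = a, b = b, events = events),
            class = "event_count_table")
}

#' @export
print.event_count_table <- function(x, ...) {
  cat("<event_count_table> ", nrow(x$a), " event(s) x ", ncol(x$a),
      " sample(s)\n", sep = "")
  invisible(x)
}

#' Write the event count table as TSV
#' @param ect An `event_count_table`.
#' @param path Output path.
#' @export
write_event_counts <- function(ect, path) {
  samples <- colnames(ect$a)
  df <- data.frame(event_id = rownames(ect$a),
                   event_type = ect$events$event_type,
                   gene_id = ect$events$gene_id)
  for (s in samples) {
    df[[paste0("a_", s)]] <- ect$a[, s]
    df[[paste0("b_", s)]] <- ect$b[, s]
  }
  con <- file(path, "w")
  writeLines("# event evidence counts (a = isoform A, b = isoform B)", con)
  suppressWarnings(write.table(df, con, sep = "\t", quote = FALSE,
                               row.names = FALSE))
  close(con)
  invisible(path)
}

#' Read pileup and junction-spanning counts for a region
#'
#' @param pset A `placement_set`.
#' @param chrom Chromosome.
#' @param start,end 0-based half-open region bounds.
#' @return A `pileup_track`: list with `region`, `depth` (integer vector of
#'   length `end - start`; `depth[i]` is the number of aligned bases over
#'   position `start + i - 1`) and `junctions` (data.frame `donor_end`,
#'   `acceptor_start`, `count` of reads spanning the junction with both
#'   anchors inside the region).
#' @export
pileup <- function(pset, chrom, start, end) {
  stopifnot(end > start)
  pl <- pset$placements
  bl <- pset$blocks
  sel <- bl[pl$chrom[match(bl$pl_id, pl$pl_id)] == chrom, , drop = FALSE]
  sel <- sel[sel$end > start & sel$start < end, , drop = FALSE]
  depth <- integer(end - start)
  if (nrow(sel)) {
    cov <- IRanges::coverage(
      IRanges::IRanges(pmax(sel$start, start) + 1L, pmin(sel$end, end)),
      width = end)
    depth <- as.integer(cov)[(start + 1L):end]
  }
  jn <- pset$juncs
  jout <- data.frame(donor_end = integer(0), acceptor_start = integer(0),
                     count = integer(0))
  if (!is.null(jn) && nrow(jn)) {
    jn <- jn[pl$chrom[match(jn$pl_id, pl$pl_id)] == chrom &
               jn$donor_end - jn$left_anchor >= start &
               jn$acceptor_start + jn$right_anchor <= end, , drop = FALSE]
    if (nrow(jn)) {
      tab <- stats::aggregate(
        count ~ donor_end + acceptor_start,
        data = data.frame(jn[c("donor_end", "acceptor_start")], count = 1L),
        FUN = sum)
      jout <- tab
    }
  }
  structure(list(region = list(chrom = chrom, start = start, end = end),
                 depth = depth, junctions = jout),
            class = "pileup_track")
}

#' @export
print.pileup_track <- function(x, ...) {
  cat("<pileup_track> ", x$region$chrom, ":", x$region$start, "-",
      x$region$end, "; max depth ", max(c(0L, x$depth)), "; ",
      nrow(x$junctions), " junction(s)\n", sep = "")
  invisible(x)
}

#' Paired-end scatter data for a region
#'
#' Aggregates canonical pairs by the positions of the last sequenced bases
#' of their two ends (x = plus-strand end, y = minus-strand end).
#'
#' @param pair_cls Output of [classify_pairs()].
#' @param chrom Chromosome.
#' @param start,end 0-based half-open region bounds.
#' @return data.frame `plus_pos`, `minus_pos`, `count`.
#' @export
pair_scatter <- function(pair_cls, chrom, start, end) {
  sel <- pair_cls[pair_cls$category == "CANONICAL" &
                    pair_cls$chrom == chrom &
                    pair_cls$plus_last >= start & pair_cls$plus_last < end &
                    pair_cls$minus_last >= start & pair_cls$minus_last < end,
                  , drop = FALSE]
  if (!nrow(sel))
    return(data.frame(plus_pos = integer(0), minus_pos = integer(0),
                      count = integer(0)))
  tab <- stats::aggregate(
    count ~ plus_pos + minus_pos,
    data = data.frame(plus_pos = sel$plus_last, minus_pos = sel$minus_last,
                      count = 1L),
    FUN = sum)
  tab[order(tab$plus_pos, tab$minus_pos), , drop = FALSE]
}
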