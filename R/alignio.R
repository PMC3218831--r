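# ---------------------------------------------------------------------------
# Alignment input: SAM/BAM -> alignment candidates -> unique-best placements
#
# A candidate set holds one row per alignment record plus a long-format block
# table (0-based half-open, from the CIGAR M/=/X/D operations, split at N
# gaps). Junction-contig hits are lifted to genome space before selection so
# that genome and junction alignments compete in one space.
# ---------------------------------------------------------------------------

#' Parse SAM/BAM alignments into candidate groups
#'
#' Reads one or more SAM/BAM files (SAM is converted on the fly). Records
#' aligned to junction contigs are recognized by the `JUNC|...` reference
#' name grammar; any other reference must be a genomic chromosome. Unmapped
#' records are kept as empty candidate groups so that non-matching reads can
#' be tallied.
#'
#' @param path SAM or BAM file path(s); candidates from all files are pooled
#'   (genome-space and junction-space alignments of the same reads may live
#'   in separate files).
#' @param chroms Optional character vector of valid genomic reference names;
#'   when supplied, a reference that is neither genomic nor a junction
#'   contig is an error.
#' @return A `candidate_set`: list with `cands` (one row per mapped record:
#'   `cand_id`, `read_id`, `end` (0 = single, 1, 2), `ref`, `strand`, `nm`,
#'   `is_junction`), `blocks` (`cand_id`, `start`, `end`), and `universe`
#'   (every (`read_id`, `end`) seen, mapped or not).
#' @export
parse_alignments <- function(path, chroms = NULL) {
  parts <- lapply(path, .parse_one_alignment_file)
  cands <- do.call(rbind, lapply(parts, `[[`, "cands"))
  blocks <- do.call(rbind, lapply(parts, `[[`, "blocks"))
  universe <- unique(do.call(rbind, lapply(parts, `[[`, "universe")))
  if (nrow(cands)) {
    # renumber candidate ids across files
    off <- c(0L, cumsum(vapply(parts, function(p) nrow(p$cands), 1L)))
    for (i in seq_along(parts)) {
      sel <- which(blocks$file == i)
      blocks$cand_id[sel] <- blocks$cand_id[sel] + off[i]
    }
    cands$cand_id <- seq_len(nrow(cands))
  }
  blocks$file <- NULL
  if (!is.null(chroms) && nrow(cands)) {
    bad <- !cands$is_junction & !(cands$ref %in% chroms)
    if (any(bad))
      stop("reference is neither genomic nor a junction contig: ",
           cands$ref[which(bad)[1L]])
  }
  structure(list(cands = cands, blocks = blocks, universe = universe),
            class = "candidate_set")
}

.parse_one_alignment_file <- function(path) {
  if (tolower(tools::file_ext(path)) == "sam") {
    dest <- tempfile(fileext = "")
    path <- suppressMessages(Rsamtools::asBam(path, dest,
                                              indexDestination = FALSE))
  }
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "cigar"), tag = "NM")
  b <- Rsamtools::scanBam(path, param = p)[[1]]
  flag <- b$flag
  end <- ifelse(bitwAnd(flag, 1L) == 0L, 0L,
                ifelse(bitwAnd(flag, 64L) != 0L, 1L, 2L))
  mapped <- bitwAnd(flag, 4L) == 0L
  universe <- unique(data.frame(read_id = b$qname, end = end,
                                stringsAsFactors = FALSE))
  nm <- b$tag$NM
  if (is.null(nm)) nm <- rep(0L, length(flag))
  nm[is.na(nm)] <- 0L
  idx <- which(mapped)
  if (!length(idx)) {
    return(list(cands = data.frame(cand_id = integer(0),
                                   read_id = character(0), end = integer(0),
                                   ref = character(0), strand = character(0),
                                   nm = integer(0), is_junction = logical(0),
                                   stringsAsFactors = FALSE),
                blocks = data.frame(cand_id = integer(0), start = integer(0),
                                    end = integer(0), file = integer(0)),
                universe = universe))
  }
  rl <- GenomicAlignments::extractAlignmentRangesOnReference(
    b$cigar[idx], pos = b$pos[idx], drop.D.ranges = FALSE)
  nb <- S4Vectors::elementNROWS(rl)
  fl <- unlist(rl, use.names = FALSE)
  cands <- data.frame(
    cand_id = seq_along(idx),
    read_id = b$qname[idx], end = end[idx],
    ref = as.character(b$rname[idx]),
    strand = ifelse(bitwAnd(flag[idx], 16L) != 0L, "-", "+"),
    nm = as.integer(nm[idx]),
    stringsAsFactors = FALSE)
  cands$is_junction <- is_junction_ref(cands$ref)
  blocks <- data.frame(cand_id = rep(cands$cand_id, nb),
                       start = IRanges::start(fl) - 1L,
                       end = IRanges::end(fl), file = 1L)
  list(cands = cands, blocks = blocks, universe = universe)
}

#' Lift a junction-contig alignment to genome coordinates
#'
#' Contig position `c < left_flank` maps to `donor_end - left_flank + c`;
#' `c >= left_flank` maps to `acceptor_start + (c - left_flank)`. An
#' alignment crossing the flank boundary becomes two genome blocks abutting
#' the junction; an alignment entirely within one flank is reclassified as a
#' plain genomic alignment (no junction crossed).
#'
#' @param start,end 0-based half-open alignment interval on the contig.
#' @param donor_end,acceptor_start Junction coordinates (genomic).
#' @param left_flank Length of the contig's left (donor-side) flank.
#' @return list with `blocks` (matrix of genome-space start/end) and
#'   `junction` (c(donor_end, acceptor_start) or NULL when no junction is
#'   crossed).
#' @export
liftover_junction <- function(start, end, donor_end, acceptor_start,
                              left_flank) {
  stopifnot(start >= 0, end > start)
  if (end <= left_flank) {
    off <- donor_end - left_flank
    return(list(blocks = cbind(start = off + start, end = off + end),
                junction = NULL))
  }
  if (start >= left_flank) {
    off <- acceptor_start - left_flank
    return(list(blocks = cbind(start = off + start, end = off + end),
                junction = NULL))
  }
  list(blocks = cbind(
    start = c(donor_end - left_flank + start, acceptor_start),
    end = c(donor_end, acceptor_start + (end - left_flank))),
    junction = c(donor_end = donor_end, acceptor_start = acceptor_start))
}

#' Lift all junction-contig candidates of a candidate set to genome space
#'
#' @param candset A `candidate_set` from [parse_alignments()].
#' @return A `candidate_set` entirely in genome space, with per-candidate
#'   junction records (`junctions`: `cand_id`, `chrom`, `donor_end`,
#'   `acceptor_start`, `left_anchor`, `right_anchor`) and a gap count column
#'   `n_gaps` on `cands`. Genome-space spliced alignments (N-gap CIGARs) keep
#'   their gaps; gaps are matched against annotated junctions later.
#' @export
lift_candidates <- function(candset) {
  cands <- candset$cands
  blocks <- candset$blocks
  juncs <- data.frame(cand_id = integer(0), chrom = character(0),
                      donor_end = integer(0), acceptor_start = integer(0),
                      left_anchor = integer(0), right_anchor = integer(0),
                      stringsAsFactors = FALSE)
  if (any(cands$is_junction)) {
    jc <- which(cands$is_junction)
    meta <- parse_junction_name(cands$ref[jc])
    # junction alignments are ungapped single blocks on the contig
    bidx <- match(cands$cand_id[jc], blocks$cand_id)
    multi <- cands$cand_id[jc] %in% blocks$cand_id[duplicated(blocks$cand_id)]
    if (any(multi))
      stop("gapped alignment on a junction contig is not supported")
    s <- blocks$start[bidx]; e <- blocks$end[bidx]
    lf <- meta$left_flank
    crosses <- s < lf & e > lf
    # crossing reads: two blocks around the junction
    new_blocks <- vector("list", length(jc))
    for (k in seq_along(jc)) {
      lo <- liftover_junction(s[k], e[k], meta$donor_end[k],
                              meta$acceptor_start[k], lf[k])
      new_blocks[[k]] <- cbind(cand_id = cands$cand_id[jc[k]], lo$blocks)
    }
    nb <- do.call(rbind, new_blocks)
    blocks <- blocks[-bidx[order(bidx)], , drop = FALSE]
    blocks <- rbind(blocks,
                    data.frame(cand_id = nb[, "cand_id"],
                               start = nb[, "start"], end = nb[, "end"]))
    cands$ref[jc] <- meta$chrom
    cands$source <- ifelse(cands$is_junction, "junction", "genomic")
    cands$source[jc][!crosses] <- "genomic"
    if (any(crosses)) {
      kk <- jc[crosses]
      juncs <- data.frame(cand_id = cands$cand_id[kk],
                          chrom = meta$chrom[crosses],
                          donor_end = meta$donor_end[crosses],
                          acceptor_start = meta$acceptor_start[crosses],
                          left_anchor = lf[crosses] - s[crosses],
                          right_anchor = e[crosses] - lf[crosses],
                          stringsAsFactors = FALSE)
    }
    cands$is_junction <- FALSE
  } else {
    cands$source <- rep("genomic", nrow(cands))
  }
  blocks <- blocks[order(blocks$cand_id, blocks$start), , drop = FALSE]
  rownames(blocks) <- NULL
  # per-candidate gap count (spliced genome alignments)
  nb <- tabulate(blocks$cand_id, nbins = max(0L, nrow(cands)))
  cands$n_gaps <- pmax(nb[cands$cand_id] - 1L, 0L)
  structure(list(cands = cands, blocks = blocks, juncs = juncs,
                 universe = candset$universe),
            class = "candidate_set")
}

#' Match genome-space alignment gaps against annotated junctions
#'
#' A spliced (N-gap) alignment crosses an annotated junction when one of its
#' inter-block gaps coincides exactly with the junction's intron. Gaps that
#' match no annotated junction remain plain gaps: such reads support no
#' junction evidence, but still count for genes when exon-contained.
#'
#' @param candset A lifted `candidate_set`.
#' @param junctions Junction table ([junction_table()]).
#' @return The candidate set with gap-derived junction records appended.
#' @export
annotate_gaps <- function(candset, junctions) {
  cands <- candset$cands
  blocks <- candset$blocks
  gapped <- which(cands$n_gaps > 0L &
                    !(cands$cand_id %in% candset$juncs$cand_id))
  if (length(gapped) && nrow(junctions)) {
    b <- blocks[blocks$cand_id %in% cands$cand_id[gapped], , drop = FALSE]
    # gaps between consecutive blocks of one candidate
    same <- b$cand_id[-1L] == b$cand_id[-nrow(b)]
    gi <- which(same)
    gaps <- data.frame(cand_id = b$cand_id[gi],
                       donor_end = b$end[gi],
                       acceptor_start = b$start[gi + 1L],
                       left_anchor = b$end[gi] - b$start[gi],
                       right_anchor = b$end[gi + 1L] - b$start[gi + 1L])
    gaps$chrom <- cands$ref[match(gaps$cand_id, cands$cand_id)]
    jk <- paste(junctions$chrom, junctions$donor_end,
                junctions$acceptor_start)
    hit <- paste(gaps$chrom, gaps$donor_end, gaps$acceptor_start) %in% jk
    if (any(hit)) {
      add <- gaps[hit, c("cand_id", "chrom", "donor_end", "acceptor_start",
                         "left_anchor", "right_anchor")]
      candset$juncs <- rbind(candset$juncs, add)
    }
  }
  candset
}

#' Select the unique best placement of every read end
#'
#' Candidates of one read end are first de-duplicated on identical
#' genome-space blocks (a genome hit and a junction hit lifting to the same
#' blocks are one candidate), then ranked by mismatch count alone. A read
#' end with exactly one minimal-mismatch candidate yields a placement; zero
#' candidates is a non-match and two or more distinct best candidates a
#' multi-match.
#'
#' @param candset A lifted (and optionally gap-annotated) `candidate_set`.
#' @param sample_id Sample label stored on the output.
#' @return A `placement_set`: list with `placements`, `blocks`, `juncs`
#'   (junctions crossed per placement) and `status` (one row per read end:
#'   `unique` / `nonmatch` / `mult`).
#' @export
select_unique_best <- function(candset, sample_id = "sample") {
  cands <- candset$cands
  blocks <- candset$blocks
  if (nrow(cands)) {
    sig <- vapply(split(paste0(blocks$start, "-", blocks$end),
                        factor(blocks$cand_id, levels = cands$cand_id)),
                  paste, "", collapse = ";")
    sig <- paste(cands$ref, cands$strand, sig)
    grp <- paste(cands$read_id, cands$end, sep = "\r")
    keep <- !duplicated(data.frame(grp, sig))
    # junction-crossing hit wins the de-dup slot over a same-blocks genomic
    # hit (they are the same placement; keep the junction record)
    has_junc <- cands$cand_id %in% candset$juncs$cand_id
    ord <- order(grp, sig, !has_junc)
    keep <- !duplicated(data.frame(grp, sig)[ord, ])[order(ord)]
    cands <- cands[keep, , drop = FALSE]
    grp <- grp[keep]
    best_nm <- stats::ave(cands$nm, grp, FUN = min)
    is_best <- cands$nm == best_nm
    n_best <- stats::ave(as.integer(is_best), grp, FUN = sum)
    winner <- is_best & n_best == 1L
    status_grp <- data.frame(
      read_id = cands$read_id, end = cands$end, grp = grp,
      stringsAsFactors = FALSE)
    status_grp <- status_grp[!duplicated(grp), , drop = FALSE]
    mult_grps <- unique(grp[is_best & n_best > 1L])
    status_grp$status <- ifelse(status_grp$grp %in% mult_grps,
                                "mult", "unique")
    pl <- cands[winner, , drop = FALSE]
  } else {
    status_grp <- data.frame(read_id = character(0), end = integer(0),
                             grp = character(0), status = character(0))
    pl <- cands
  }
  # read ends never seen mapped -> nonmatch
  uni <- candset$universe
  uni$grp <- paste(uni$read_id, uni$end, sep = "\r")
  missing <- !(uni$grp %in% status_grp$grp)
  status <- rbind(status_grp[c("read_id", "end", "status")],
                  data.frame(read_id = uni$read_id[missing],
                             end = uni$end[missing],
                             status = rep("nonmatch", sum(missing))))
  status$sample_id <- sample_id
  pl_ids <- pl$cand_id
  placements <- data.frame(
    pl_id = seq_len(nrow(pl)), read_id = pl$read_id, end = pl$end,
    sample_id = rep(sample_id, nrow(pl)), chrom = pl$ref,
    strand = pl$strand, nm = pl$nm, source = pl$source,
    n_gaps = pl$n_gaps, stringsAsFactors = FALSE)
  bl <- blocks[blocks$cand_id %in% pl_ids, , drop = FALSE]
  bl$pl_id <- match(bl$cand_id, pl_ids)
  jn <- candset$juncs[candset$juncs$cand_id %in% pl_ids, , drop = FALSE]
  jn$pl_id <- match(jn$cand_id, pl_ids)
  placements$njunc <- tabulate(jn$pl_id, nbins = nrow(placements))
  structure(list(placements = placements,
                 blocks = bl[c("pl_id", "start", "end")],
                 juncs = jn[setdiff(names(jn), "cand_id")],
                 status = status[c("sample_id", "read_id", "end", "status")],
                 pairs = NULL),
            class = "placement_set")
}

#' Resolve paired-end reads after unique-best selection
#'
#' A pair with both ends uniquely placed is kept as a paired-unique pair; a
#' pair with exactly one unique end keeps that end as a single-end rescue;
#' otherwise each end contributes to the non-match/multi-match tallies.
#'
#' @param pset A `placement_set` from [select_unique_best()].
#' @return The placement set with a `pairs` table (`read_id`, `pl1`, `pl2`)
#'   and a `pair_status` column on `status` (`paired_unique`,
#'   `single_rescued`, or `NA` for unpaired/unplaced ends). Placements whose
#'   end was not retained are dropped.
#' @export
resolve_pairs <- function(pset) {
  st <- pset$status
  st$pair_status <- NA_character_
  paired <- st$end > 0L
  if (any(paired)) {
    u1 <- st$read_id[paired & st$end == 1L & st$status == "unique"]
    u2 <- st$read_id[paired & st$end == 2L & st$status == "unique"]
    both <- intersect(u1, u2)
    one <- setdiff(union(u1, u2), both)
    st$pair_status[paired & st$read_id %in% both &
                     st$status == "unique"] <- "paired_unique"
    st$pair_status[paired & st$read_id %in% one &
                     st$status == "unique"] <- "single_rescued"
    pl <- pset$placements
    p1 <- pl[pl$end == 1L & pl$read_id %in% both, c("read_id", "pl_id")]
    p2 <- pl[pl$end == 2L & pl$read_id %in% both, c("read_id", "pl_id")]
    pairs <- merge(p1, p2, by = "read_id", suffixes = c("1", "2"))
    names(pairs) <- c("read_id", "pl1", "pl2")
    pset$pairs <- pairs
  } else {
    pset$pairs <- data.frame(read_id = character(0), pl1 = integer(0),
                             pl2 = integer(0))
  }
  pset$status <- st
  pset
}

#' @export
print.placement_set <- function(x, ...) {
  cat("<placement_set> ", nrow(x$placements), " placement(s), ",
      nrow(x$status), " read end(s)",
      if (!is.null(x$pairs)) paste0(", ", nrow(x$pairs), " pair(s)"),
      "\n", sep = "")
  invisible(x)
}

# ---------------------------------------------------------------------------
# QC classifications
# ---------------------------------------------------------------------------

#' Tally read types per sample
#'
#' Counts read ends by alignment outcome: `Nonmatch`, `Mult`, and for
#' uniquely placed ends either `Genomic`/`Junction` (single-end data) or
#' `PairedUnique`/`SingleRescued` (paired data). Counts are in units of read
#' records (ends), so the categories sum to the number of reads processed.
#'
#' @param pset A resolved `placement_set`.
#' @return data.frame `sample_id`, `category`, `count`.
#' @export
tally_read_types <- function(pset) {
  st <- pset$status
  pl <- pset$placements
  if (is.null(st$pair_status)) st$pair_status <- NA_character_
  st$category <- ifelse(st$status == "nonmatch", "Nonmatch",
                        ifelse(st$status == "mult", "Mult", NA))
  uni <- which(st$status == "unique")
  if (length(uni)) {
    key <- paste(st$sample_id, st$read_id, st$end)[uni]
    pk <- paste(pl$sample_id, pl$read_id, pl$end)
    idx <- match(key, pk)
    is_junc <- pl$njunc[idx] > 0L | pl$source[idx] == "junction"
    cat_se <- ifelse(is_junc, "Junction", "Genomic")
    ps <- st$pair_status[uni]
    st$category[uni] <- ifelse(is.na(ps), cat_se,
                               ifelse(ps == "paired_unique", "PairedUnique",
                                      "SingleRescued"))
  }
  out <- as.data.frame(table(sample_id = st$sample_id,
                             category = st$category),
                       stringsAsFactors = FALSE)
  names(out)[3] <- "count"
  out[out$count > 0, , drop = FALSE]
}

#' Matching type of placed reads
#'
#' Classifies every placement as `Junction` (crosses an annotated junction),
#' `Exon` (all aligned positions within the exon union of at least one
#' gene), `Intron` (all positions within the span of at least one gene), or
#' `Intergenic`.
#'
#' @param pset A `placement_set`.
#' @param models A `gene_model_set`.
#' @return Character vector parallel to `pset$placements`.
#' @export
matching_type <- function(pset, models) {
  pl <- pset$placements
  bl <- pset$blocks
  type <- rep("Intergenic", nrow(pl))
  type[pl$njunc > 0L | pl$source == "junction"] <- "Junction"
  undecided <- which(type == "Intergenic")
  if (!length(undecided)) return(type)

  mods <- unclass(models)
  ug <- GenomicRanges::GRanges(
    rep(vapply(mods, `[[`, "", "chrom"),
        vapply(mods, function(g) nrow(g$exon_union), 1L)),
    IRanges::IRanges(
      unlist(lapply(mods, function(g) g$exon_union[, "start"])) + 1L,
      unlist(lapply(mods, function(g) g$exon_union[, "end"]))))
  ug$gene <- rep(seq_along(mods),
                 vapply(mods, function(g) nrow(g$exon_union), 1L))
  bsel <- bl[bl$pl_id %in% pl$pl_id[undecided], , drop = FALSE]
  bg <- GenomicRanges::GRanges(pl$chrom[match(bsel$pl_id, pl$pl_id)],
                               IRanges::IRanges(bsel$start + 1L, bsel$end))
  nblocks <- tabulate(bsel$pl_id, nbins = max(pl$pl_id))
  ov <- GenomicRanges::findOverlaps(bg, ug, type = "within")
  if (length(ov)) {
    key <- paste(bsel$pl_id[S4Vectors::queryHits(ov)],
                 ug$gene[S4Vectors::subjectHits(ov)])
    tab <- table(unique(data.frame(
      pl = bsel$pl_id[S4Vectors::queryHits(ov)],
      gene = ug$gene[S4Vectors::subjectHits(ov)],
      blk = S4Vectors::queryHits(ov)))[, c("pl", "gene")])
    full <- which(tab == nblocks[as.integer(rownames(tab))], arr.ind = TRUE)
    exonic_pl <- unique(as.integer(rownames(tab)[full[, 1L]]))
    type[match(exonic_pl, pl$pl_id)] <- "Exon"
  }
  undecided <- which(type == "Intergenic")
  if (length(undecided)) {
    sg <- GenomicRanges::GRanges(
      vapply(mods, `[[`, "", "chrom"),
      IRanges::IRanges(vapply(mods, function(g) g$span[1L], 1) + 1L,
                       vapply(mods, function(g) g$span[2L], 1)))
    # placement span
    agg_min <- tapply(bl$start, bl$pl_id, min)
    agg_max <- tapply(bl$end, bl$pl_id, max)
    spans <- GenomicRanges::GRanges(
      pl$chrom[undecided],
      IRanges::IRanges(
        agg_min[as.character(pl$pl_id[undecided])] + 1L,
        agg_max[as.character(pl$pl_id[undecided])]))
    ov <- GenomicRanges::findOverlaps(spans, sg, type = "within")
    type[undecided[unique(S4Vectors::queryHits(ov))]] <- "Intron"
  }
  type
}

#' Classify read pairs for paired-end QC
#'
#' Categories are tested in fixed priority order: the two ends align to
#' different chromosomes (`DIFF_CHROM`); to the same strand
#' (`SAME_STRAND`); the minus-strand end lies wholly upstream of the
#' plus-strand end (`MINUS_UPSTREAM`); at least one annotated intron lies
#' entirely within the open interval between the two inner alignment ends
#' (`INTRON_BETWEEN`); otherwise `CANONICAL`, for which the distance is the
#' genomic distance between the last sequenced bases of the two ends
#' (negative when the alignments overlap).
#'
#' @param pset A resolved `placement_set` with pairs.
#' @param models A `gene_model_set` supplying annotated introns (exon-union
#'   gaps).
#' @return data.frame with one row per pair: `read_id`, `category`,
#'   `distance` (`NA` unless canonical), `plus_last`, `minus_last`.
#' @export
classify_pairs <- function(pset, models) {
  pairs <- pset$pairs
  pl <- pset$placements
  bl <- pset$blocks
  if (is.null(pairs) || !nrow(pairs))
    return(data.frame(read_id = character(0), category = character(0),
                      distance = integer(0), plus_last = integer(0),
                      minus_last = integer(0)))
  bmin <- tapply(bl$start, bl$pl_id, min)
  bmax <- tapply(bl$end, bl$pl_id, max)
  g1 <- match(pairs$pl1, pl$pl_id); g2 <- match(pairs$pl2, pl$pl_id)
  chr1 <- pl$chrom[g1]; chr2 <- pl$chrom[g2]
  st1 <- pl$strand[g1]; st2 <- pl$strand[g2]
  plus_idx <- ifelse(st1 == "+", g1, g2)
  minus_idx <- ifelse(st1 == "+", g2, g1)
  pmin_ <- bmin[as.character(pl$pl_id[plus_idx])]
  pmax_ <- bmax[as.character(pl$pl_id[plus_idx])]
  mmin_ <- bmin[as.character(pl$pl_id[minus_idx])]
  mmax_ <- bmax[as.character(pl$pl_id[minus_idx])]
  plus_last <- as.integer(pmax_) - 1L
  minus_last <- as.integer(mmin_)
  category <- rep("CANONICAL", nrow(pairs))
  category[mmax_ <= pmin_] <- "MINUS_UPSTREAM"
  category[st1 == st2] <- "SAME_STRAND"
  category[chr1 != chr2] <- "DIFF_CHROM"
  # annotated introns fully inside the open inter-end interval
  cand <- which(category == "CANONICAL" & minus_last - plus_last > 1L)
  if (length(cand)) {
    mods <- unclass(models)
    introns <- do.call(rbind, lapply(mods, function(g) {
      u <- g$exon_union
      if (nrow(u) < 2L) return(NULL)
      data.frame(chrom = g$chrom, s = u[-nrow(u), "end"],
                 e = u[-1L, "start"])
    }))
    if (!is.null(introns) && nrow(introns)) {
      ig <- GenomicRanges::GRanges(introns$chrom,
                                   IRanges::IRanges(introns$s + 1L,
                                                    introns$e))
      gap <- GenomicRanges::GRanges(chr1[cand],
                                    IRanges::IRanges(plus_last[cand] + 2L,
                                                     minus_last[cand]))
      ov <- GenomicRanges::findOverlaps(ig, gap, type = "within")
      category[cand[unique(S4Vectors::subjectHits(ov))]] <- "INTRON_BETWEEN"
    }
  }
  distance <- ifelse(category == "CANONICAL",
                     minus_last - plus_last, NA_integer_)
  data.frame(read_id = pairs$read_id, sample_id = pl$sample_id[g1],
             chrom = chr1, category = category,
             distance = as.integer(distance),
             plus_last = as.integer(plus_last),
             minus_last = as.integer(minus_last),
             stringsAsFactors = FALSE)
}

#' Median paired-end distance and complete library size
#'
#' The complete library size adds both read lengths and both sequencing
#' adaptors to the median canonical-pair distance (for 36-nt reads and 50-nt
#' adaptors the additive constant is 172 nt).
#'
#' @param distances Canonical-pair distances (nt; may be negative).
#' @param read_len Read length in nt.
#' @param adaptor_len Adaptor length in nt per end.
#' @return list with `median_distance`, `library_size`, and an `ecdf`
#'   data.frame (`distance`, `fraction`). With no canonical pairs both
#'   scalars are `NA`.
#' @export
library_size_summary <- function(distances, read_len = 36,
                                 adaptor_len = 50) {
  distances <- distances[!is.na(distances)]
  if (!length(distances)) {
    return(list(median_distance = NA_real_, library_size = NA_real_,
                ecdf = data.frame(distance = numeric(0),
                                  fraction = numeric(0))))
  }
  med <- median(distances)
  s <- sort(distances)
  ecdf <- data.frame(distance = unique(s),
                     fraction = cumsum(tabulate(match(s, unique(s)))) /
                       length(s))
  list(median_distance = med,
       library_size = med + 2 * read_len + 2 * adaptor_len,
       ecdf = ecdf)
}
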