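# ---------------------------------------------------------------------------
# Deterministic synthetic data: toy genome, multi-isoform annotation and
# simulated single/paired-end reads with known expression levels, depth
# ratios, splicing ratios and insert geometry. Reads are emitted pre-aligned
# (genome-space SAM with N gaps for spliced reads); a FASTQ emitter exists
# for integration with external aligners but is not on the main path.
# ---------------------------------------------------------------------------

.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = .GlobalEnv)
  on.exit(if (had) assign(".Random.seed", old, envir = .GlobalEnv) else
    rm(".Random.seed", envir = .GlobalEnv))
  set.seed(seed)
  force(expr)
}

#' Deterministic gene plan for the synthetic-data generator
#'
#' Draws per-gene structure (exon count, isoform type), expression level,
#' fold change and isoform-A fraction under a fixed seed. Levels are
#' log-normal (median `median_level` expected reads at depth factor 1), a
#' fraction `prop_changed` of genes carry a fold change of `fold` (half up,
#' half down), and isoform types are drawn from `type_props`.
#'
#' @param n_genes Number of genes.
#' @param seed Seed for the plan draw.
#' @param prop_changed Fraction of genes with a planted fold change.
#' @param fold Planted fold change (sample 2 relative to sample 1).
#' @param median_level Median expected read count per gene at depth 1.
#' @param sdlog Log-normal spread of levels.
#' @param type_props Named proportions over
#'   `c(simple, cassette, retained, alt_tss, alt_pacs)`.
#' @param frac Isoform-A fraction for two-isoform genes.
#' @return data.frame `gene_id`, `type`, `n_exons`, `level`, `fold`,
#'   `frac`.
#' @export
sim_gene_plan <- function(n_genes, seed = 1, prop_changed = 0.05, fold = 8,
                          median_level = 30, sdlog = 1,
                          type_props = c(simple = 0.7, cassette = 0.15,
                                         retained = 0.05, alt_tss = 0.05,
                                         alt_pacs = 0.05),
                          frac = 0.5) {
  .with_seed(seed, {
    type <- sample(names(type_props), n_genes, replace = TRUE,
                   prob = type_props)
    n_exons <- sample(2:5, n_genes, replace = TRUE)
    n_exons[type == "cassette"] <- pmax(n_exons[type == "cassette"], 3L)
    level <- stats::rlnorm(n_genes, log(median_level), sdlog)
    fold_v <- rep(1, n_genes)
    n_changed <- round(prop_changed * n_genes)
    if (n_changed > 0) {
      ch <- sample.int(n_genes, n_changed)
      up <- ch[seq_len(ceiling(n_changed / 2))]
      dn <- setdiff(ch, up)
      fold_v[up] <- fold
      fold_v[dn] <- 1 / fold
    }
    data.frame(gene_id = sprintf("G%05d", seq_len(n_genes)), type = type,
               n_exons = n_exons, level = level, fold = fold_v,
               frac = ifelse(type == "simple", 1, frac),
               stringsAsFactors = FALSE)
  })
}

#' Synthetic experiment configuration
#'
#' Bundles the gene plan, the sample plan, read geometry and the master
#' seed. Depth factors control the true read fraction of each sample
#' (`q2 = depth2 / (depth1 + depth2)` for a pair of samples with mostly
#' unchanged genes); `apply_fold` marks the samples in which the planted
#' per-gene fold changes act.
#'
#' @param genes Gene plan (see [sim_gene_plan()]).
#' @param samples data.frame `sample_id`, `depth`, `apply_fold`.
#' @param seed Master seed; reference construction and every sample's read
#'   stream derive their own sub-seed from it, so adding a sample never
#'   perturbs another sample's reads.
#' @param read_len Read length (nt).
#' @param paired Generate paired-end reads?
#' @param insert_mean,insert_sd Outer fragment length distribution
#'   (Normal, nt) for paired mode.
#' @param adaptor_len Sequencing adaptor length per end (nt), used in
#'   library-size arithmetic.
#' @param exon_len,intron_len Ranges for exon/intron lengths (nt).
#' @param n_chroms Number of chromosomes to spread genes over.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(genes,
                       samples = data.frame(
                         sample_id = c("s1", "s2"), depth = c(1, 1),
                         apply_fold = c(FALSE, TRUE)),
                       seed = 1, read_len = 36, paired = FALSE,
                       insert_mean = 200, insert_sd = 30, adaptor_len = 50,
                       exon_len = c(150, 250), intron_len = c(80, 200),
                       n_chroms = 2) {
  stopifnot(all(genes$level >= 0), all(genes$frac >= 0 & genes$frac <= 1),
            all(samples$depth > 0), read_len >= 1)
  structure(list(genes = genes, samples = samples, seed = seed,
                 read_len = read_len, paired = paired,
                 insert_mean = insert_mean, insert_sd = insert_sd,
                 adaptor_len = adaptor_len, exon_len = exon_len,
                 intron_len = intron_len, n_chroms = n_chroms),
            class = "sim_config")
}

# isoform structures per gene type; returns list of block matrices named by
# transcript, plus which transcript is isoform A. Terminal-exon structures
# are built in transcription direction: on the minus strand the alternative
# TSS lives at the genomically-last intron and vice versa.
.make_isoforms <- function(type, exons, gaps, strand = "+") {
  if (strand == "-") {
    if (type == "alt_tss") type <- ".alt_right"
    if (type == "alt_pacs") type <- ".alt_left"
  } else {
    if (type == "alt_tss") type <- ".alt_left"
    if (type == "alt_pacs") type <- ".alt_right"
  }
  n <- nrow(exons)
  full <- exons
  switch(type,
    simple = list(tx = list(t1 = full), a = "t1"),
    cassette = {
      mid <- as.integer(ceiling(n / 2))
      list(tx = list(t1 = full, t2 = full[-mid, , drop = FALSE]), a = "t1")
    },
    retained = {
      # intron retention is observed in reads, not annotated: only the
      # spliced transcript goes into the annotation, while the
      # intron-retaining isoform exists purely as a read source
      k <- as.integer(ceiling((n - 1) / 2))  # retained intron index
      merged <- full
      merged[k, "end"] <- merged[k + 1L, "end"]
      merged <- merged[-(k + 1L), , drop = FALSE]
      list(tx = list(t1 = full, t2 = merged), a = "t2", unannotated = "t2")
    },
    .alt_left = {
      # novel exon inside the genomically-first intron, replacing exon 1
      g <- gaps[1L, ]
      alt_len <- max(40L, min(80L, (g["end"] - g["start"]) %/% 2L))
      alt <- c(start = g[["start"]] + 10L, end = g[["start"]] + 10L + alt_len)
      t2 <- rbind(alt, full[-1L, , drop = FALSE])
      rownames(t2) <- NULL
      list(tx = list(t1 = full, t2 = t2), a = "t2")
    },
    .alt_right = {
      g <- gaps[nrow(gaps), ]
      alt_len <- max(40L, min(80L, (g["end"] - g["start"]) %/% 2L))
      alt <- c(start = g[["end"]] - 10L - alt_len, end = g[["end"]] - 10L)
      t2 <- rbind(full[-n, , drop = FALSE], alt)
      rownames(t2) <- NULL
      list(tx = list(t1 = full, t2 = t2), a = "t2")
    },
    stop("unknown gene type: ", type))
}

#' Build the synthetic reference (genome + annotation)
#'
#' Lays the planned genes out over random-sequence chromosomes and realizes
#' every requested isoform structure as transcripts. Identical seeds give
#' byte-identical outputs.
#'
#' @param config A `sim_config`.
#' @return A `sim_reference`: list with `genome` (a `genome_ref`),
#'   `annotation` (transcript table), `gene_info` (placement and isoform
#'   metadata per gene) and the `config`.
#' @export
make_reference <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  .with_seed(config$seed, {
    genes <- config$genes
    n <- nrow(genes)
    chrom_of <- if (n) paste0("chr", (seq_len(n) - 1L) %% config$n_chroms + 1L)
      else character(0)
    cursor <- setNames(rep(200L, config$n_chroms),
                       paste0("chr", seq_len(config$n_chroms)))
    gene_info <- vector("list", n)
    anno_rows <- list()
    for (i in seq_len(n)) {
      ne <- genes$n_exons[i]
      el <- sample(config$exon_len[1]:config$exon_len[2], ne, replace = TRUE)
      il <- sample(config$intron_len[1]:config$intron_len[2],
                   max(ne - 1L, 0L), replace = TRUE)
      chrom <- chrom_of[i]
      s0 <- cursor[[chrom]]
      starts <- s0 + c(0L, cumsum(el[-ne] + il))
      exons <- cbind(start = as.integer(starts),
                     end = as.integer(starts + el))
      gaps <- if (ne > 1L)
        cbind(start = exons[-ne, "end"], end = exons[-1L, "start"])
      else matrix(integer(0), 0, 2, dimnames = list(NULL, c("start", "end")))
      strand <- sample(c("+", "-"), 1L)
      iso <- .make_isoforms(genes$type[i], exons, gaps, strand)
      gid <- genes$gene_id[i]
      for (tn in setdiff(names(iso$tx), iso$unannotated)) {
        ex <- iso$tx[[tn]]
        anno_rows[[length(anno_rows) + 1L]] <- data.frame(
          transcript_id = paste0(gid, ".", tn), gene_id = gid,
          chrom = chrom, strand = strand,
          exon_starts = paste(ex[, "start"], collapse = ","),
          exon_ends = paste(ex[, "end"], collapse = ","),
          stringsAsFactors = FALSE)
      }
      gene_info[[i]] <- list(gene_id = gid, chrom = chrom, strand = strand,
                             isoforms = iso$tx, a_transcript = iso$a,
                             type = genes$type[i], frac = genes$frac[i])
      cursor[[chrom]] <- max(exons[, "end"],
                             max(vapply(iso$tx, function(e)
                               max(e[, "end"]), 1L))) +
        sample(200:500, 1L)
    }
    lens <- cursor + 200L
    seqs <- vapply(names(lens), function(cn)
      paste(sample(c("A", "C", "G", "T"), lens[[cn]], replace = TRUE),
            collapse = ""), "")
    anno <- if (length(anno_rows)) as_annotation(do.call(rbind, anno_rows))
      else as_annotation(data.frame(transcript_id = character(0),
                                    gene_id = character(0),
                                    chrom = character(0),
                                    strand = character(0),
                                    exon_starts = character(0),
                                    exon_ends = character(0)))
    names(gene_info) <- genes$gene_id
    structure(list(genome = genome_ref(seqs), annotation = anno,
                   gene_info = gene_info, config = config),
              class = "sim_reference")
  })
}

#' @export
print.sim_reference <- function(x, ...) {
  cat("<sim_reference> ", length(x$gene_info), " gene(s) on ",
      length(seq_lengths(x$genome)), " chromosome(s)\n", sep = "")
  invisible(x)
}

# map a transcript-space interval [s, e) through genomic blocks; returns
# genomic block matrix
.tx_to_genome <- function(blocks, cum0, s, e) {
  bi <- findInterval(s, cum0)
  bj <- findInterval(e - 1L, cum0)
  idx <- bi:bj
  gs <- blocks[idx, "start"] + pmax(0L, s - cum0[idx])
  ge <- blocks[idx, "start"] +
    pmin(blocks[idx, "end"] - blocks[idx, "start"], e - cum0[idx])
  cbind(start = as.integer(gs), end = as.integer(ge))
}

.blocks_to_cigar <- function(m) {
  w <- m[, "end"] - m[, "start"]
  if (nrow(m) == 1L) return(paste0(w, "M"))
  gaps <- m[-1L, "start"] - m[-nrow(m), "end"]
  paste0(paste0(w[-length(w)], "M", gaps, "N", collapse = ""),
         w[length(w)], "M")
}

#' Simulate reads for one sample
#'
#' Per gene the read count is Poisson with mean
#' `depth * level * fold` (fold only in samples with `apply_fold`); each
#' read picks isoform A with probability `frac` and a uniform start on the
#' chosen isoform's transcript sequence. Paired mode draws the outer
#' fragment length from `Normal(insert_mean, insert_sd)` (clamped to the
#' transcript) and emits FR proper pairs. Output alignments are genome-space
#' SAM records with N gaps for spliced reads; the generator is
#' seed-deterministic per (seed, sample).
#'
#' @param ref A `sim_reference`.
#' @param sample_id Sample to simulate (must appear in the config's sample
#'   plan).
#' @return list with `sam` (record data.frame for [write_sam()]) and
#'   `truth` (list: `gene` realized/expected counts, `reads` per-read
#'   provenance).
#' @export
simulate_reads <- function(ref, sample_id) {
  config <- ref$config
  si <- match(sample_id, config$samples$sample_id)
  if (is.na(si)) stop("unknown sample: ", sample_id)
  depth <- config$samples$depth[si]
  apply_fold <- isTRUE(config$samples$apply_fold[si])
  rl <- config$read_len
  .with_seed(config$seed * 1009L + si * 101L, {
    recs <- list(); prov <- list()
    realized <- integer(nrow(config$genes))
    expected <- numeric(nrow(config$genes))
    for (i in seq_len(nrow(config$genes))) {
      g <- config$genes[i, ]
      gi <- ref$gene_info[[g$gene_id]]
      lambda <- depth * g$level * (if (apply_fold) g$fold else 1)
      expected[i] <- lambda
      nreads <- stats::rpois(1L, lambda)
      realized[i] <- nreads
      if (nreads == 0L) next
      iso_names <- names(gi$isoforms)
      is_a <- stats::runif(nreads) < gi$frac
      tx_name <- ifelse(is_a, gi$a_transcript,
                        if (length(iso_names) > 1L)
                          setdiff(iso_names, gi$a_transcript)[1L]
                        else gi$a_transcript)
      for (tn in unique(tx_name)) {
        blocks <- gi$isoforms[[tn]]
        widths <- as.integer(blocks[, "end"] - blocks[, "start"])
        tl <- sum(widths)
        cum0 <- cumsum(c(0L, widths[-length(widths)]))
        if (tl < rl)
          stop("read length ", rl, " exceeds transcript ", g$gene_id,
               ".", tn, " length ", tl)
        ridx <- which(tx_name == tn)
        nr <- length(ridx)
        qn <- sprintf("%s_%s_%06d", sample_id, g$gene_id, ridx)
        # vectorized placement of one read interval [s, s + rl)
        place <- function(s) {
          bi <- findInterval(s, cum0)
          bj <- findInterval(s + rl - 1L, cum0)
          pos <- blocks[bi, "start"] + (s - cum0[bi]) + 1L
          cigar <- rep(paste0(rl, "M"), length(s))
          spliced <- which(bj > bi)
          for (k in spliced) {
            m <- .tx_to_genome(blocks, cum0, s[k], s[k] + rl)
            cigar[k] <- .blocks_to_cigar(m)
          }
          last <- blocks[bj, "start"] + (s + rl - cum0[bj])  # 0-based end
          list(pos = as.integer(pos), cigar = cigar, end0 = as.integer(last))
        }
        if (config$paired) {
          f <- pmin(tl, pmax(2L * rl,
                             as.integer(round(stats::rnorm(
                               nr, config$insert_mean, config$insert_sd)))))
          smax <- tl - f
          s <- as.integer(floor(stats::runif(nr) * (smax + 1L)))
          p1 <- place(s)
          p2 <- place(s + f - rl)
          span <- p2$end0 - (p1$pos - 1L)
          recs[[length(recs) + 1L]] <- data.frame(
            qname = rep(qn, 2L), flag = rep(c(99L, 147L), each = nr),
            rname = gi$chrom, pos = c(p1$pos, p2$pos),
            cigar = c(p1$cigar, p2$cigar), rnext = "=",
            pnext = c(p2$pos, p1$pos), tlen = c(span, -span),
            stringsAsFactors = FALSE)
        } else {
          s <- sample.int(tl - rl + 1L, nr, replace = TRUE) - 1L
          p1 <- place(s)
          recs[[length(recs) + 1L]] <- data.frame(
            qname = qn, flag = sample(c(0L, 16L), nr, replace = TRUE),
            rname = gi$chrom, pos = p1$pos, cigar = p1$cigar,
            rnext = "*", pnext = 0L, tlen = 0L, stringsAsFactors = FALSE)
        }
        prov[[length(prov) + 1L]] <- data.frame(
          read_id = qn, gene_id = g$gene_id, transcript = tn,
          isoform = if (tn == gi$a_transcript) "A" else "B",
          tstart = s, stringsAsFactors = FALSE)
      }
    }
    sam <- if (length(recs)) do.call(rbind, recs) else
      data.frame(qname = character(0), flag = integer(0),
                 rname = character(0), pos = integer(0),
                 cigar = character(0), rnext = character(0),
                 pnext = integer(0), tlen = integer(0))
    sam <- sam[order(sam$qname, sam$flag), , drop = FALSE]
    rownames(sam) <- NULL
    prov <- if (length(prov)) do.call(rbind, prov) else NULL
    list(sam = sam,
         truth = list(gene = data.frame(gene_id = config$genes$gene_id,
                                        expected = expected,
                                        realized = realized),
                      reads = prov))
  })
}

#' Write simulated records as SAM (and optionally FASTQ)
#'
#' @param records Record data.frame from [simulate_reads()].
#' @param genome The reference `genome_ref` (for the header and sequences).
#' @param path Output SAM path.
#' @param fastq Optional FASTQ output path (sequences strand-normalized to
#'   the original read orientation).
#' @return `path`, invisibly.
#' @export
write_sam <- function(records, genome, path, fastq = NULL) {
  lens <- seq_lengths(genome)
  header <- c("@HD\tVN:1.6\tSO:unknown",
              sprintf("@SQ\tSN:%s\tLN:%d", names(lens), lens))
  if (nrow(records)) {
    # sequence = concatenation of aligned block sequences (forward strand)
    rl <- GenomicAlignments::extractAlignmentRangesOnReference(
      records$cigar, pos = records$pos)
    nb <- S4Vectors::elementNROWS(rl)
    fl <- unlist(rl, use.names = FALSE)
    part <- genome_seq(genome, rep(records$rname, nb),
                       IRanges::start(fl) - 1L, IRanges::end(fl))
    seqs <- vapply(split(part, rep(seq_len(nrow(records)), nb)),
                   paste, "", collapse = "")
    body <- sprintf("%s\t%d\t%s\t%d\t255\t%s\t%s\t%d\t%d\t%s\t*\tNM:i:0",
                    records$qname, records$flag, records$rname, records$pos,
                    records$cigar, records$rnext, records$pnext,
                    records$tlen, seqs)
  } else {
    body <- character(0)
    seqs <- character(0)
  }
  writeLines(c(header, body), path)
  if (!is.null(fastq) && nrow(records)) {
    rc <- bitwAnd(records$flag, 16L) != 0L
    out <- seqs
    out[rc] <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(out[rc])))
    end_tag <- ifelse(bitwAnd(records$flag, 64L) != 0L, "/1",
                      ifelse(bitwAnd(records$flag, 128L) != 0L, "/2", ""))
    writeLines(rbind(paste0("@", records$qname, end_tag), out,
                     "+", strrep("I", nchar(out))), fastq)
  }
  invisible(path)
}

#' Write a full synthetic experiment to a directory
#'
#' Emits `genome.fa`, `annotation.gtf`, `annotation.tsv`, one SAM per
#' sample, a `sample_sheet.tsv` and per-sample truth tables.
#'
#' @param config A `sim_config`.
#' @param dir Output directory (created if needed).
#' @return The `sim_reference`, invisibly.
#' @export
simulate_experiment <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ref <- make_reference(config)
  write_genome_fasta(ref$genome, file.path(dir, "genome.fa"))
  write_annotation(ref$annotation, file.path(dir, "annotation.gtf"), "gtf")
  write_annotation(ref$annotation, file.path(dir, "annotation.tsv"), "tsv")
  sheet <- data.frame(sample_id = config$samples$sample_id,
                      group = ifelse(config$samples$apply_fold, "g2", "g1"),
                      path = paste0(config$samples$sample_id, ".sam"),
                      read_len = config$read_len,
                      adaptor_len = config$adaptor_len,
                      paired = config$paired)
  write.table(sheet, file.path(dir, "sample_sheet.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  for (sid in config$samples$sample_id) {
    sim <- simulate_reads(ref, sid)
    write_sam(sim$sam, ref$genome, file.path(dir, paste0(sid, ".sam")))
    write.table(sim$truth$gene,
                file.path(dir, paste0(sid, "_gene_truth.tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(sim$truth$reads))
      write.table(sim$truth$reads,
                  file.path(dir, paste0(sid, "_read_truth.tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(ref)
}

#' Expected junction-evidence inclusion fraction of a cassette gene
#'
#' For a simulated cassette gene, the chance that a uniform-start read
#' crosses an inclusion junction differs between isoforms (two crossable
#' junction positions on the inclusion isoform versus one skip junction on
#' the skip isoform, and different transcript lengths), so the expected
#' evidence fraction `a/(a+b)` is not the isoform fraction itself. This
#' computes the analytic expectation under the generator's geometry.
#'
#' @param ref A `sim_reference`.
#' @param gene_id A cassette-type gene in the reference.
#' @return Expected `a/(a+b)` among junction-evidence reads.
#' @export
expected_cassette_fraction <- function(ref, gene_id) {
  gi <- ref$gene_info[[gene_id]]
  stopifnot(gi$type == "cassette")
  rl <- ref$config$read_len
  rate <- function(blocks, n_junc_evid) {
    tl <- sum(blocks[, "end"] - blocks[, "start"])
    n_junc_evid * (rl - 1) / (tl - rl + 1)
  }
  ra <- rate(gi$isoforms[[gi$a_transcript]], 2L)
  b_tx <- setdiff(names(gi$isoforms), gi$a_transcript)[1L]
  rb <- rate(gi$isoforms[[b_tx]], 1L)
  f <- gi$frac
  f * ra / (f * ra + (1 - f) * rb)
}
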