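test_that("SAM records parse into candidates with 0-based blocks", {
  sam <- tempfile(fileext = ".sam")
  write_test_sam(sam, c(
    sam_rec("r1", 0L, "chr1", 101L, "36M"),
    sam_rec("r2", 4L, "*", 0L, "*"),
    sam_rec("r3", 0L, "chr1", 51L, "20M100N16M")),
    c(chr1 = 1000L))
  cs <- parse_alignments(sam)
  expect_equal(nrow(cs$cands), 2)
  b1 <- cs$blocks[cs$blocks$cand_id ==
                    cs$cands$cand_id[cs$cands$read_id == "r1"], ]
  expect_equal(unname(unlist(b1[c("start", "end")])), c(100, 136))
  b3 <- cs$blocks[cs$blocks$cand_id ==
                    cs$cands$cand_id[cs$cands$read_id == "r3"], ]
  expect_equal(b3$start, c(50, 170))
  expect_equal(b3$end, c(70, 186))
  # unmapped read is an empty candidate group but stays in the universe
  expect_true("r2" %in% cs$universe$read_id)
  # unknown reference rejected when chromosomes are declared
  expect_error(parse_alignments(sam, chroms = "chr9"), "neither genomic")
})

test_that("junction liftover maps contig positions around the splice point", {
  # forced mapping: 36-nt read at contig pos 10, flanks 35/35
  lo <- liftover_junction(10, 46, donor_end = 1000, acceptor_start = 2000,
                          left_flank = 35)
  expect_equal(unname(lo$blocks[, "start"]), c(975, 2000))
  expect_equal(unname(lo$blocks[, "end"]), c(1000, 2011))
  expect_equal(unname(lo$junction), c(1000, 2000))

  # 1-nt right anchor
  lo2 <- liftover_junction(0, 36, 1000, 2000, 35)
  expect_equal(unname(lo2$blocks[, "start"]), c(965, 2000))
  expect_equal(unname(lo2$blocks[, "end"]), c(1000, 2001))

  # entirely within the left flank: reclassified genomic, no junction
  lo3 <- liftover_junction(0, 30, 1000, 2000, 35)
  expect_null(lo3$junction)
  expect_equal(unname(lo3$blocks[1, ]), c(965, 995))
})

test_that("liftover preserves read length on randomized candidates", {
  set.seed(31)
  for (i in 1:200) {
    lf <- sample(10:60, 1); rf <- sample(10:60, 1)
    de <- sample(500:5000, 1); as <- de + sample(50:5000, 1)
    w <- sample(5:(lf + rf), 1)
    s <- sample(0:(lf + rf - w), 1)
    lo <- liftover_junction(s, s + w, de, as, lf)
    expect_equal(sum(lo$blocks[, "end"] - lo$blocks[, "start"]), w)
    if (!is.null(lo$junction)) {
      expect_equal(unname(lo$blocks[2, "start"] - lo$blocks[1, "end"]),
                   as - de)
    }
  }
})

test_that("unique-best selection keeps single minimal-mismatch placements", {
  genome_refs <- c(chr1 = 5000L, chr2 = 5000L)
  mk <- function(recs) {
    sam <- tempfile(fileext = ".sam")
    write_test_sam(sam, recs, genome_refs)
    select_unique_best(lift_candidates(parse_alignments(sam)), "s")
  }
  # no candidates -> nonmatch
  ps0 <- mk(sam_rec("r1", 4L, "*", 0L, "*"))
  expect_equal(ps0$status$status, "nonmatch")
  # best-score rule: 0-mismatch genomic beats 1-mismatch elsewhere
  ps1 <- mk(c(sam_rec("r1", 0L, "chr1", 101L, "36M", nm = 0L),
              sam_rec("r1", 0L, "chr2", 501L, "36M", nm = 1L)))
  expect_equal(nrow(ps1$placements), 1)
  expect_equal(ps1$placements$chrom, "chr1")
  # two 0-mismatch hits at distinct loci -> mult
  ps2 <- mk(c(sam_rec("r1", 0L, "chr1", 101L, "36M"),
              sam_rec("r1", 0L, "chr2", 501L, "36M")))
  expect_equal(nrow(ps2$placements), 0)
  expect_equal(ps2$status$status, "mult")
})

test_that("selection is invariant to candidate order and de-duplicates across spaces", {
  genome <- toy_genome(c(chr1 = 3000L))
  anno <- tx_row("t1", "g1", c(500, 2000), c(1000, 2500))
  models <- load_gene_models(anno, genome)
  lib <- write_junction_library(junction_table(models), genome, 35)
  refs <- c(chr1 = 3000L)
  jname <- names(lib)
  # a junction hit lifting to [975,1000)+[2000,2011) and the same placement
  # as a genomic N-gap hit: must de-duplicate to one candidate, not MULT
  recs <- c(sam_rec("r1", 0L, jname, 11L, "36M"),
            sam_rec("r1", 0L, "chr1", 976L, "25M1000N11M"))
  for (ord in list(1:2, 2:1)) {
    sam <- tempfile(fileext = ".sam")
    writeLines(c("@HD\tVN:1.6",
                 sprintf("@SQ\tSN:%s\tLN:%d", names(refs), refs),
                 sprintf("@SQ\tSN:%s\tLN:%d", jname, 70L),
                 recs[ord]), sam)
    cs <- annotate_gaps(lift_candidates(parse_alignments(sam)),
                        junction_table(models))
    ps <- select_unique_best(cs, "s")
    expect_equal(nrow(ps$placements), 1)
    expect_equal(ps$placements$njunc, 1)
    expect_equal(ps$status$status, "unique")
  }
})

test_that("a junction placement always crosses its recorded junction", {
  genome <- toy_genome(c(chr1 = 4000L))
  anno <- tx_row("t1", "g1", c(500, 2000, 3000), c(1000, 2500, 3500))
  models <- load_gene_models(anno, genome)
  lib <- write_junction_library(junction_table(models), genome, 35)
  set.seed(41)
  recs <- character(0)
  metas <- parse_junction_name(names(lib))
  for (i in seq_len(50)) {
    j <- sample(nrow(metas), 1)
    s <- sample(0:34, 1)
    recs <- c(recs, sam_rec(paste0("r", i), 0L, names(lib)[j],
                            s + 1L, "36M"))
  }
  sam <- tempfile(fileext = ".sam")
  writeLines(c("@HD\tVN:1.6", "@SQ\tSN:chr1\tLN:4000",
               sprintf("@SQ\tSN:%s\tLN:%d", names(lib),
                       Biostrings::width(lib)), recs), sam)
  ps <- select_unique_best(lift_candidates(parse_alignments(sam)), "s")
  expect_equal(nrow(ps$placements), 50)
  for (k in seq_len(nrow(ps$juncs))) {
    pid <- ps$juncs$pl_id[k]
    bl <- ps$blocks[ps$blocks$pl_id == pid, ]
    expect_equal(bl$end[1], ps$juncs$donor_end[k])
    expect_equal(bl$start[2], ps$juncs$acceptor_start[k])
    expect_equal(bl$start[2] - bl$end[1],
                 ps$juncs$acceptor_start[k] - ps$juncs$donor_end[k])
  }
})

test_that("pair resolution keeps both-unique pairs and rescues single ends", {
  refs <- c(chr1 = 5000L)
  sam <- tempfile(fileext = ".sam")
  write_test_sam(sam, c(
    # both ends unique
    sam_rec("p1", 99L, "chr1", 101L, "36M", rnext = "=", pnext = 401L),
    sam_rec("p1", 147L, "chr1", 401L, "36M", rnext = "=", pnext = 101L),
    # end2 multi-maps
    sam_rec("p2", 99L, "chr1", 601L, "36M", rnext = "=", pnext = 901L),
    sam_rec("p2", 147L, "chr1", 901L, "36M", rnext = "=", pnext = 601L),
    sam_rec("p2", 147L, "chr1", 2901L, "36M", rnext = "=", pnext = 601L),
    # both ends unmapped
    sam_rec("p3", 77L, "*", 0L, "*"),
    sam_rec("p3", 141L, "*", 0L, "*")),
    refs)
  ps <- resolve_pairs(select_unique_best(lift_candidates(
    parse_alignments(sam)), "s"))
  expect_equal(nrow(ps$pairs), 1)
  expect_equal(ps$pairs$read_id, "p1")
  st <- ps$status
  expect_equal(sum(st$pair_status == "paired_unique", na.rm = TRUE), 2)
  expect_equal(st$pair_status[st$read_id == "p2" & st$status == "unique"],
               "single_rescued")
  expect_equal(sort(st$status[st$read_id == "p3"]), c("nonmatch", "nonmatch"))
  tt <- tally_read_types(ps)
  expect_setequal(tt$category[tt$count > 0],
                  c("PairedUnique", "SingleRescued", "Mult", "Nonmatch"))
  expect_equal(sum(tt$count), 6)
})

test_that("matching types follow the junction > exon > intron priority", {
  anno <- tx_row("t1", "g1", c(100, 300), c(200, 400))
  models <- load_gene_models(anno)
  refs <- c(chr1 = 1000L)
  sam <- tempfile(fileext = ".sam")
  write_test_sam(sam, c(
    sam_rec("exonic", 0L, "chr1", 111L, "36M"),
    sam_rec("straddle", 0L, "chr1", 181L, "36M"),
    sam_rec("intronic", 0L, "chr1", 221L, "36M"),
    sam_rec("outside", 0L, "chr1", 701L, "36M"),
    sam_rec("spliced", 0L, "chr1", 181L, "20M100N16M")),
    refs)
  ps <- select_unique_best(annotate_gaps(lift_candidates(
    parse_alignments(sam)), junction_table(models)), "s")
  mt <- setNames(matching_type(ps, models), ps$placements$read_id)
  expect_equal(mt[["exonic"]], "Exon")
  expect_equal(mt[["straddle"]], "Intron")
  expect_equal(mt[["intronic"]], "Intron")
  expect_equal(mt[["outside"]], "Intergenic")
  expect_equal(mt[["spliced"]], "Junction")
})

test_that("pair classification applies the fixed category priority", {
  anno <- tx_row("t1", "g1", c(100, 300), c(200, 400))
  models <- load_gene_models(anno)
  refs <- c(chr1 = 5000L, chr2 = 5000L)
  sam <- tempfile(fileext = ".sam")
  mkpair <- function(id, r1, p1, f1, r2, p2, f2)
    c(sam_rec(id, f1, r1, p1, "36M", rnext = "=", pnext = p2),
      sam_rec(id, f2, r2, p2, "36M", rnext = "=", pnext = p1))
  write_test_sam(sam, c(
    mkpair("diff", "chr1", 101L, 99L, "chr2", 301L, 147L),
    mkpair("same", "chr1", 501L, 67L, "chr1", 701L, 131L),
    mkpair("minusup", "chr1", 2001L, 99L, "chr1", 1001L, 147L),
    # plus ends at base 165 (0-based 164), minus starts at 0-based 364:
    # the model intron [200,300) lies between them
    mkpair("intron", "chr1", 130L, 99L, "chr1", 365L, 147L),
    # canonical: distance 200
    mkpair("canon", "chr1", 1030L, 99L, "chr1", 1230L, 147L),
    # overlapping: negative distance
    mkpair("overlap", "chr1", 3001L, 99L, "chr1", 2991L, 147L)),
    refs)
  ps <- resolve_pairs(select_unique_best(lift_candidates(
    parse_alignments(sam)), "s"))
  cls <- classify_pairs(ps, models)
  cat_of <- setNames(cls$category, cls$read_id)
  expect_equal(cat_of[["diff"]], "DIFF_CHROM")
  expect_equal(cat_of[["same"]], "SAME_STRAND")
  expect_equal(cat_of[["minusup"]], "MINUS_UPSTREAM")
  expect_equal(cat_of[["intron"]], "INTRON_BETWEEN")
  expect_equal(cat_of[["canon"]], "CANONICAL")
  expect_equal(cls$distance[cls$read_id == "canon"],
               (1230L - 1L) - (1030L + 35L - 1L))
  expect_equal(cat_of[["overlap"]], "CANONICAL")
  expect_equal(cls$distance[cls$read_id == "overlap"],
               (2991L - 1L) - (3001L + 35L - 1L))
})

test_that("library size arithmetic adds reads and adaptors to the median", {
  r <- library_size_summary(c(100, 200, 300), read_len = 36,
                            adaptor_len = 50)
  expect_equal(r$median_distance, 200)
  expect_equal(r$library_size, 372)
  expect_equal(r$library_size - r$median_distance, 172)
  r2 <- library_size_summary(-5, 36, 50)
  expect_equal(r2$median_distance, -5)
  r3 <- library_size_summary(numeric(0))
  expect_true(is.na(r3$library_size))
  expect_equal(tail(r$ecdf$fraction, 1), 1)
})

test_that("read-type tallies conserve the number of reads seen", {
  plan <- sim_gene_plan(20, seed = 13)
  cfg <- sim_config(plan, samples = data.frame(
    sample_id = "s1", depth = 1, apply_fold = FALSE), seed = 13)
  d <- file.path(tempdir(), "tally")
  ref <- simulate_experiment(cfg, d)
  models <- load_gene_models(ref$annotation)
  pset <- import_alignments(file.path(d, "s1.sam"), models, "s1")
  tt <- tally_read_types(pset)
  expect_equal(sum(tt$count), nrow(pset$status))
  mt <- matching_type(pset, models)
  expect_equal(length(mt), nrow(pset$placements))
  expect_true(all(mt %in% c("Exon", "Intron", "Intergenic", "Junction")))
})
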