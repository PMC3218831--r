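test_that("gene models merge transcript exons into union blocks", {
  m <- load_gene_models(tx_row("t1", "g1", c(100, 300), c(200, 400)))
  g <- m[["g1"]]
  expect_equal(unname(g$exon_union[, "start"]), c(100, 300))
  expect_equal(unname(g$exon_union[, "end"]), c(200, 400))
  expect_equal(g$model_length, 200)

  m2 <- load_gene_models(rbind(
    tx_row("t1", "g1", 100, 200),
    tx_row("t2", "g1", 150, 250)))
  expect_equal(unname(m2[["g1"]]$exon_union[1, ]), c(100, 250))
  expect_equal(m2[["g1"]]$model_length, 150)
})

test_that("inconsistent gene grouping and out-of-bounds exons are rejected", {
  bad_strand <- rbind(tx_row("t1", "g1", 100, 200, strand = "+"),
                      tx_row("t2", "g1", 300, 400, strand = "-"))
  expect_error(load_gene_models(bad_strand), "g1")
  bad_chrom <- rbind(tx_row("t1", "g1", 100, 200, chrom = "chr1"),
                     tx_row("t2", "g1", 300, 400, chrom = "chr2"))
  expect_error(load_gene_models(bad_chrom), "chromosome")
  genome <- toy_genome(c(chr1 = 300L))
  expect_error(load_gene_models(tx_row("t1", "g1", 100, 400), genome),
               "bounds")
})

test_that("transcript invariants are enforced", {
  expect_error(as_annotation(tx_row("t1", "g1", c(100, 150), c(200, 250))),
               "separated")
  expect_error(as_annotation(tx_row("t1", "g1", 200, 100)), "precede")
})

test_that("TSS and PACS are the strand-appropriate extremes", {
  mp <- load_gene_models(tx_row("t1", "g1", c(100, 300), c(200, 400)))
  expect_equal(mp[["g1"]]$transcripts$t1$tss, 100)
  expect_equal(mp[["g1"]]$transcripts$t1$pacs, 400)
  mm <- load_gene_models(tx_row("t1", "g1", c(100, 300), c(200, 400),
                                strand = "-"))
  expect_equal(mm[["g1"]]$transcripts$t1$tss, 400)
  expect_equal(mm[["g1"]]$transcripts$t1$pacs, 100)
})

test_that("junction enumeration realizes every forward combination", {
  # single-exon gene: no junctions; minus strand stored genomically
  m1 <- load_gene_models(tx_row("t1", "g1", 100, 200))
  expect_equal(nrow(enumerate_junctions(m1[["g1"]])), 0)

  mneg <- load_gene_models(tx_row("t1", "g1", c(100, 300, 500),
                                  c(200, 400, 600), strand = "-"))
  jneg <- enumerate_junctions(mneg[["g1"]])
  expect_equal(nrow(jneg), 3)
  expect_true(all(jneg$donor_end < jneg$acceptor_start))

  # E(E-1)/2 for single-transcript genes, against brute-force enumeration
  for (E in 1:8) {
    starts <- seq(100, by = 200, length.out = E)
    m <- load_gene_models(tx_row("t1", "g", starts, starts + 100))
    j <- enumerate_junctions(m[["g"]])
    expect_equal(nrow(j), E * (E - 1) / 2)
    # brute force over exon index pairs n < m
    if (E > 1) {
      brute <- expand.grid(n = 1:E, m = 1:E)
      brute <- brute[brute$n < brute$m, ]
      keys <- sort(paste(starts[brute$n] + 100, starts[brute$m]))
      expect_equal(sort(paste(j$donor_end, j$acceptor_start)), keys)
    }
  }
})

test_that("junction contigs round-trip through the genome and the name grammar", {
  genome <- toy_genome(c(chr1 = 2000L))
  anno <- rbind(cassette_annotation(),
                tx_row("t3", "g2", c(700, 760), c(720, 820)))
  models <- load_gene_models(anno, genome)
  jt <- junction_table(models)
  lib <- write_junction_library(jt, genome, overhang = 35)
  meta <- parse_junction_name(names(lib))
  left <- genome_seq(genome, meta$chrom, meta$donor_end - meta$left_flank,
                     meta$donor_end)
  right <- genome_seq(genome, meta$chrom, meta$acceptor_start,
                      meta$acceptor_start + meta$right_flank)
  expect_identical(paste0(left, right), unname(as.character(lib)))
  expect_false(anyDuplicated(names(lib)) > 0)
  # duplicate junctions from two transcripts collapse to one contig
  expect_equal(sum(meta$gene_id == "g1"), 3)
  # short upstream exon (g2: 20 nt) truncates the flank, recorded in name
  g2m <- meta[meta$gene_id == "g2", ]
  expect_equal(g2m$left_flank, 20L)
  expect_equal(Biostrings::width(lib[meta$gene_id == "g2"]), 20L + 35L)
})

test_that("forced junction contig geometry matches the construction rule", {
  genome <- toy_genome(c(chr1 = 3000L))
  anno <- tx_row("t1", "g1", c(500, 2000), c(1000, 2500))
  models <- load_gene_models(anno, genome)
  lib <- write_junction_library(junction_table(models), genome, 35)
  expect_equal(unname(Biostrings::width(lib)), 70L)
  expect_equal(substr(as.character(lib[[1]]), 1, 35),
               genome_seq(genome, "chr1", 965, 1000))
  expect_equal(substr(as.character(lib[[1]]), 36, 70),
               genome_seq(genome, "chr1", 2000, 2035))
})

test_that("cassette events follow the internal-exon rule", {
  m <- load_gene_models(cassette_annotation())
  ev <- find_cassette_events(m[["g1"]])
  expect_equal(nrow(ev), 1)
  a <- parse_support(ev$a_support)$junctions
  b <- parse_support(ev$b_support)$junctions
  expect_setequal(paste(a$donor_end, a$acceptor_start),
                  c("200 300", "400 500"))
  expect_equal(paste(b$donor_end, b$acceptor_start), "200 500")

  # 4-exon gene: two internal exons -> two events; terminal exons none
  m4 <- load_gene_models(tx_row("t1", "g1", c(1, 3, 5, 7) * 100,
                                c(1, 3, 5, 7) * 100 + 50))
  expect_equal(nrow(find_cassette_events(m4[["g1"]])), 2)
  m2 <- load_gene_models(tx_row("t1", "g1", c(100, 300), c(200, 400)))
  expect_equal(nrow(find_cassette_events(m2[["g1"]])), 0)
})

test_that("retained-intron events require locally constitutive flanks", {
  # simple 2-exon gene: one event, a = intron, b = both exons
  m <- load_gene_models(tx_row("t1", "g1", c(100, 300), c(200, 400)))
  ev <- find_retained_intron_events(m[["g1"]])
  expect_equal(nrow(ev), 1)
  expect_equal(ev$a_support, "I:200-300")
  expect_setequal(strsplit(ev$b_support, ";")[[1]],
                  c("I:100-200", "I:300-400"))

  # a transcript skipping the left flank entirely kills the event
  skip_left <- rbind(
    tx_row("t1", "g1", c(100, 300, 500), c(200, 400, 600)),
    tx_row("t2", "g1", c(100, 500), c(200, 600)))
  ev2 <- find_retained_intron_events(load_gene_models(skip_left)[["g1"]])
  expect_equal(nrow(ev2), 0)

  # a transcript not spanning the gap at all does not vote
  nonspan <- rbind(
    tx_row("t1", "g1", c(100, 300), c(200, 400)),
    tx_row("t2", "g1", 500, 600))
  ev3 <- find_retained_intron_events(load_gene_models(nonspan)[["g1"]])
  expect_equal(nrow(ev3), 1)
  expect_equal(ev3$focus_start, 200)
})

test_that("terminal events exist for all but the extreme TSS/PACS", {
  # two TSSs on + strand, non-overlapping alternative first exon
  anno <- rbind(
    tx_row("t1", "g1", c(100, 500, 800), c(200, 600, 900)),
    tx_row("t2", "g1", c(300, 500, 800), c(380, 600, 900)))
  ev <- find_terminal_events(load_gene_models(anno)[["g1"]])
  ev_tss <- ev[ev$event_type == "alt_tss", ]
  expect_equal(nrow(ev_tss), 1)
  expect_equal(ev_tss$focus_start, 300)
  expect_equal(ev_tss$focus_end, 380)
  expect_equal(parse_support(ev_tss$b_support)$intervals,
               data.frame(start = 100L, end = 200L))

  # single TSS + single PACS: nothing
  single <- load_gene_models(tx_row("t1", "g1", c(100, 300), c(200, 400)))
  expect_equal(nrow(find_terminal_events(single[["g1"]])), 0)

  # two PACS on minus strand: event for the less extreme (genomically
  # rightmost start is 3'-most on minus; the other PACS is the candidate)
  annom <- rbind(
    tx_row("t1", "g1", c(100, 500), c(200, 600), strand = "-"),
    tx_row("t2", "g1", c(300, 500), c(380, 600), strand = "-"))
  evm <- find_terminal_events(load_gene_models(annom)[["g1"]])
  evm_pacs <- evm[evm$event_type == "alt_pacs", ]
  expect_equal(nrow(evm_pacs), 1)
  expect_equal(evm_pacs$focus_start, 300)
})

test_that("event evidence is disjoint and within the gene span", {
  plan <- sim_gene_plan(30, seed = 21,
                        type_props = c(simple = 0.2, cassette = 0.3,
                                       retained = 0.2, alt_tss = 0.15,
                                       alt_pacs = 0.15))
  ref <- make_reference(sim_config(plan, seed = 21))
  models <- load_gene_models(ref$annotation)
  ev <- find_events(models)
  expect_gt(nrow(ev), 10)
  for (i in seq_len(nrow(ev))) {
    a <- strsplit(ev$a_support[i], ";")[[1]]
    b <- strsplit(ev$b_support[i], ";")[[1]]
    expect_length(intersect(a, b), 0)
    g <- models[[ev$gene_id[i]]]
    pa <- parse_support(ev$a_support[i]); pb <- parse_support(ev$b_support[i])
    coords <- c(pa$junctions$donor_end, pa$junctions$acceptor_start,
                pa$intervals$start, pa$intervals$end,
                pb$junctions$donor_end, pb$junctions$acceptor_start,
                pb$intervals$start, pb$intervals$end)
    expect_true(all(coords >= g$span[1] & coords <= g$span[2]))
  }
})

test_that("annotation and gene models survive serialization round trips", {
  plan <- sim_gene_plan(12, seed = 8)
  ref <- make_reference(sim_config(plan, seed = 8))
  models <- load_gene_models(ref$annotation)

  tsv <- tempfile(fileext = ".tsv")
  write_annotation(models_to_annotation(models), tsv)
  models2 <- load_gene_models(read_annotation(tsv))
  expect_equal(unclass(models2), unclass(models))

  gtf <- tempfile(fileext = ".gtf")
  write_annotation(ref$annotation, gtf, format = "gtf")
  models3 <- load_gene_models(read_annotation(gtf))
  expect_equal(sort(names(models3)), sort(names(models)))
  for (g in names(models))
    expect_equal(models3[[g]]$exon_union, models[[g]]$exon_union)

  ev <- find_events(models)
  evf <- tempfile(fileext = ".tsv")
  write_events(ev, evf)
  expect_equal(read_events(evf), ev)
})
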