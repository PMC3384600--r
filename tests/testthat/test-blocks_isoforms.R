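toy <- make_toy_ref()
store <- toy$store

mk_candidates <- function(store, ids, seqs, frac = 30 / 76) {
  reads <- toy_reads(ids, seqs)
  pp <- split_reads(reads, frac, frac)
  ev <- reunite_and_assign(align_default(pseudo_read_set(pp), store), pp, store)
  ev <- filter_same_gene(ev); ev <- filter_unaligned(ev)
  ev <- filter_insert_geometry(ev, store)
  collect_candidates(ev)
}

# junction reads into EB2 (txB pos 101..200) or EB1 (txB pos 1..100)
jr_eb2 <- function(b1) toy_junction_read(substr(toy$seqs$txA, 51, 110),
                                         substr(toy$seqs$txB, 101, 200), b1)
jr_eb1 <- function(b1) toy_junction_read(substr(toy$seqs$txA, 51, 110),
                                         substr(toy$seqs$txB, 1, 100), b1)

test_that("overlapping reads merge into one block; disjoint exon targets split", {
  cands <- mk_candidates(store, sprintf("j%d", 1:5),
                         c(jr_eb2(30), jr_eb2(33), jr_eb2(36),
                           jr_eb1(31), jr_eb1(35)))
  expect_length(cands, 1L)
  b <- build_blocks(cands[[1L]], store)
  expect_equal(nrow(b$g1_blocks), 1L)          # all mate-1 hits overlap on EA2
  expect_equal(nrow(b$g2_blocks), 2L)          # EB1 and EB2 clusters disjoint
  expect_equal(nrow(b$combos), 2L)
  expect_equal(sum(b$combos$isoreads), 5L)
  # block partition: every read in exactly one block per gene
  expect_setequal(unlist(b$g1_blocks$reads), sprintf("j%d", 1:5))
  expect_equal(sum(lengths(b$g2_blocks$reads)), 5L)
  # single read -> block equals its own genomic footprint
  single <- mk_candidates(store, "solo", jr_eb2(40))
  bs <- build_blocks(single[[1L]], store)
  seg <- transcript_to_genomic(store, "txA", 111 - 40, 140 - 40)
  expect_equal(bs$g1_blocks$start, min(seg$genomic_start))
  expect_equal(bs$g1_blocks$end, max(seg$genomic_end))
})

test_that("blocks within a gene never overlap and unions cover member reads", {
  cands <- mk_candidates(store, sprintf("k%d", 1:6),
                         c(jr_eb2(30), jr_eb2(44), jr_eb1(30), jr_eb1(44),
                           jr_eb2(37), jr_eb1(37)))
  b <- build_blocks(cands[[1L]], store)
  g2 <- b$g2_blocks
  if (nrow(g2) > 1L)
    for (i in 1:(nrow(g2) - 1L))
      expect_true(g2$end[i] < g2$start[i + 1L])
  expect_equal(sum(b$combos$isoreads), nrow(cands[[1L]]$evidence))
})

test_that("repeat-class coincidence removes block combinations (5B)", {
  toyr <- make_toy_ref(repeat_bed = TRUE)
  cands <- mk_candidates(toyr$store, sprintf("r%d", 1:4),
                         c(jr_eb2(32), jr_eb2(35), jr_eb1(32), jr_eb1(35)))
  b <- build_blocks(cands[[1L]], toyr$store)
  expect_equal(nrow(b$combos), 2L)
  f <- filter_repeat_blocks(b, toyr$store)
  # EA2 block and EB2 block are both Alu -> dropped; EB1 combo is Alu vs L1 -> kept
  expect_equal(nrow(f$combos), 1L)
  expect_setequal(f$repeat_filtered_reads, c("r1", "r2"))
  expect_setequal(unlist(f$combos$reads), c("r3", "r4"))
  # disabled or absent annotation: inert
  expect_equal(nrow(filter_repeat_blocks(b, toyr$store, enabled = FALSE)$combos), 2L)
  expect_equal(nrow(filter_repeat_blocks(b, store)$combos), 2L)
})

test_that("assign_exons picks the nearest junction-side exon boundary (with oracle)", {
  cands <- mk_candidates(store, c("a", "b"), c(jr_eb2(30), jr_eb2(33)))
  b <- build_blocks(cands[[1L]], store)
  iso <- assign_exons(b, cands[[1L]], store)
  # b1=30 read reaches the EA2 3' end exactly -> g1 expos 0; the G2 block
  # starts min(d2)=13 bases into EB2 (expos pairs of one read sum to the gap)
  expect_equal(iso$g1_exon, "EA2"); expect_equal(iso$g1_expos, 0L)
  expect_equal(iso$g2_exon, "EB2"); expect_equal(iso$g2_expos, 13L)
  # exhaustive oracle on a single-read candidate ending short of the boundary
  solo <- mk_candidates(store, "s", jr_eb2(43))        # ends 13 bp short
  bs <- build_blocks(solo[[1L]], store)
  isos <- assign_exons(bs, solo[[1L]], store)
  ex1 <- store$exons[gene_id == "geneA"]
  d_or <- min(abs(ex1$g_end - bs$g1_blocks$end))       # plus strand: 3' = g_end
  expect_equal(isos$g1_expos, as.integer(d_or))
  expect_equal(isos$g1_expos, 13L)
  expect_equal(isos$g2_expos, 3L)                      # 46-43 bases short on G2
  # minus-strand G1: fusion from geneC's 3' exon (EC2, genomic 101-200)
  jc <- toy_junction_read(toy$seqs$txC, substr(toy$seqs$txB, 101, 200), 31)
  cc <- mk_candidates(store, "c", jc)
  bc <- build_blocks(cc[[1L]], store)
  ic <- assign_exons(bc, cc[[1L]], store)
  expect_equal(ic$g1_exon, "EC2")
  # minus-strand 3' edge is the genomic-left block edge
  expect_equal(ic$g1_expos, abs(bc$g1_blocks$start - 101L))
  expect_equal(ic$g1_expos, 1L)
})

test_that("min-read threshold and isoform/totalreads accounting hold", {
  cands <- mk_candidates(store, sprintf("m%d", 1:4),
                         c(jr_eb2(30), jr_eb2(33), jr_eb1(31), jr_eb1(35)))
  fc <- analyze_candidate(cands[[1L]], store)
  expect_equal(fc$totalreads, 4L)
  expect_equal(sum(fc$isoforms$isoreads), fc$totalreads)
  expect_equal(nrow(fc$isoforms), 2L)
  expect_length(apply_min_reads(list(fc), 4L)$kept, 1L)   # == threshold kept
  expect_length(apply_min_reads(list(fc), 5L)$kept, 0L)
  expect_length(apply_min_reads(list(fc), 1L)$kept, 1L)   # identity
})

test_that("categorisation truth table covers all four labels", {
  expect_equal(categorize_pair(store, "geneA", "geneC"), "INTERCHROMOSOMAL")
  expect_setequal(categorize_pair(store, "geneA", "geneB"),
                  c("POTENTIAL_READTHROUGH", "INTRACHROMOSOMAL"))
  expect_setequal(categorize_pair(store, "geneC", "geneD"),
                  c("INVERSION", "INTRACHROMOSOMAL"))
  # 19,000 bp gap: read-through at the default 20 kb, not at 10 kb
  expect_setequal(categorize_pair(store, "geneB", "geneE"),
                  c("POTENTIAL_READTHROUGH", "INTRACHROMOSOMAL"))
  expect_equal(categorize_pair(store, "geneB", "geneE",
                               readthrough_max = 10000L),
               "INTRACHROMOSOMAL")
  # INTERCHROMOSOMAL is always exclusive
  expect_length(categorize_pair(store, "geneA", "geneC"), 1L)
})
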