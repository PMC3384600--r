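toy <- make_toy_ref()
store <- toy$store

# run toy parent reads through split -> mate alignment -> reunite
mk_ev <- function(store, ids, seqs, frac = 30 / 76) {
  reads <- toy_reads(ids, seqs)
  pp <- split_reads(reads, frac, frac)
  res <- align_default(pseudo_read_set(pp), store)
  reunite_and_assign(res, pp, store)
}

# geneA(EA2) -> geneB(EB2) junction read: b1 bases of EA2's 3' end followed
# by 76-b1 bases of EB2's 5' start; with 30-mer mates d1 = b1-30, d2 = 46-b1
jread <- function(b1) toy_junction_read(substr(toy$seqs$txA, 51, 110),
                                        substr(toy$seqs$txB, 101, 200), b1)

test_that("reunite_and_assign resolves genes and canonicalises orientation", {
  ev <- mk_ev(store, c("f", "r", "junk"),
              c(jread(32), revcomp(jread(40)), rand_dna(76, seed = 21)))
  expect_equal(nrow(ev), 3L)
  expect_equal(plain(ev[parent_id == "f", .(g1, g2, orient)]),
               data.table::data.table(g1 = "geneA", g2 = "geneB",
                                      orient = "forward"))
  # reverse-complemented parent: mate roles swap, candidate unchanged
  expect_equal(plain(ev[parent_id == "r", .(g1, g2, orient)]),
               data.table::data.table(g1 = "geneA", g2 = "geneB",
                                      orient = "reverse"))
  expect_true(is.na(ev[parent_id == "junk"]$g1))
  expect_true(all(ev$status == "live"))
  # ids without /1-/2 suffixes are rejected
  bad <- align_default(toy_reads("plain", "ACGTACGTACGTACGT"),
                       Biostrings::DNAStringSet(c(t = rand_dna(50, seed = 1))))
  expect_error(reunite_and_assign(bad, split_reads(toy_reads("p", jread(32)),
                                                   0.4), store),
               "suffix")
})

test_that("4A/4B flag same-gene and unaligned pairs, leaving the rest alone", {
  same_gene <- paste0(substr(toy$seqs$txB, 1, 30), rand_dna(16, seed = 22),
                      substr(toy$seqs$txB, 120, 149))
  ev <- mk_ev(store, c("sg", "ok", "jk"),
              c(same_gene, jread(34), rand_dna(76, seed = 23)))
  ev <- filter_same_gene(ev)
  ev <- filter_unaligned(ev)
  expect_equal(ev[parent_id == "sg"]$status, "STEP4A_SAME_GENE")
  expect_equal(ev[parent_id == "jk"]$status, "STEP4B_UNALIGNED")
  expect_equal(ev[parent_id == "ok"]$status, "live")
})

test_that("4C removes annotated paralog pairs and honours the disable toggle", {
  toyp <- make_toy_ref(paralog_tsv = TRUE)    # geneA/geneB listed
  ev <- mk_ev(toyp$store, "p", jread(33))
  expect_equal(filter_paralogs(data.table::copy(ev), toyp$store)$status,
               "STEP4C_PARALOG")
  expect_equal(filter_paralogs(data.table::copy(ev), toyp$store,
                               enabled = FALSE)$status, "live")
  expect_equal(filter_paralogs(data.table::copy(ev), store)$status, "live")
})

test_that("4D removes pairs of genes overlapping on opposite strands", {
  # geneC (minus) and geneD (plus) overlap on chrT2
  cd <- paste0(substr(toy$seqs$txC, 31, 60), rand_dna(16, seed = 24),
               substr(toy$seqs$txD, 40, 69))
  ev <- mk_ev(store, "cd", cd)
  expect_equal(ev$g1, "geneC"); expect_equal(ev$g2, "geneD")
  expect_equal(filter_antisense(data.table::copy(ev), store)$status,
               "STEP4D_ANTISENSE")
  expect_equal(filter_antisense(data.table::copy(ev), store,
                                enabled = FALSE)$status, "live")
  # non-overlapping opposite-strand genes survive (geneC vs geneA)
  ca <- paste0(substr(toy$seqs$txC, 1, 30), rand_dna(16, seed = 25),
               substr(toy$seqs$txA, 81, 110))
  ev2 <- filter_antisense(mk_ev(store, "ca", ca), store)
  expect_equal(ev2$status, "live")
})

test_that("4E keeps exactly the pairs satisfying d1 + d2 = gap", {
  # b1=32 -> d1=2, d2=14 ; b1=30 -> d1=0, d2=16 ; both sum to the 16-bp gap
  good1 <- jread(32); good2 <- jread(30)
  # mate positions 10 bp short of each exon boundary: d1=10, d2=10, sum 20
  bad <- paste0(substr(toy$seqs$txA, 71, 100), rand_dna(16, seed = 26),
                substr(toy$seqs$txB, 111, 140))
  # strand-inconsistent pair: forward mate1, reverse-complement mate2
  mixed <- paste0(substr(toy$seqs$txA, 71, 100), rand_dna(16, seed = 27),
                  revcomp(substr(toy$seqs$txB, 101, 130)))
  ev <- mk_ev(store, c("g1r", "g2r", "bad", "mixed", "rcgood"),
              c(good1, good2, bad, mixed, revcomp(jread(40))))
  ev <- filter_insert_geometry(ev, store)
  expect_equal(plain(ev[parent_id == "g1r", .(d1, d2, status)]),
               data.table::data.table(d1 = 2L, d2 = 14L, status = "live"))
  expect_equal(plain(ev[parent_id == "g2r", .(d1, d2, status)]),
               data.table::data.table(d1 = 0L, d2 = 16L, status = "live"))
  expect_equal(plain(ev[parent_id == "bad", .(d1, d2, status)]),
               data.table::data.table(d1 = 10L, d2 = 10L,
                                      status = "STEP4E_GEOMETRY"))
  expect_equal(ev[parent_id == "mixed"]$status, "STEP4E_GEOMETRY")
  expect_equal(ev[parent_id == "rcgood"]$status, "live")
  expect_equal(ev[parent_id == "rcgood", d1 + d2], 16L)
})

test_that("4F flags pairs whose mates co-map to one shared-exon gene", {
  # a third gene carrying copies of both fused exon sequences
  dir <- tempfile(); dir.create(dir)
  extra <- c(readLines(toy$gtf),
             gtf_line("chrT1", 40000, 40059, "+", "geneS", "txS", "ES1"),
             gtf_line("chrT1", 40200, 40299, "+", "geneS", "txS", "ES2"))
  gtf2 <- file.path(dir, "shared.gtf"); writeLines(extra, gtf2)
  txS <- paste0(substr(toy$seqs$txA, 51, 110), substr(toy$seqs$txB, 101, 200))
  fa2 <- file.path(dir, "shared.fa")
  writeLines(c(sprintf(">%s", names(toy$seqs)), ""), tempfile())  # unused
  writeLines(unlist(mapply(function(n, s) c(paste0(">", n), s),
                           c(names(toy$seqs), "txS"),
                           c(unlist(toy$seqs), txS), SIMPLIFY = FALSE)), fa2)
  store2 <- load_reference(fa2, NULL, gtf2)
  ev <- mk_ev(store2, c("amb", "uniq"), c(jread(34),
              paste0(substr(toy$seqs$txA, 21, 50), rand_dna(16, seed = 28),
                     substr(toy$seqs$txB, 11, 40))))
  ev <- filter_multimap(data.table::copy(ev), store2)
  expect_equal(ev[parent_id == "amb"]$status, "STEP4F_MULTIMAP")
  expect_equal(ev[parent_id == "uniq"]$status, "live")
  # drop_candidate mode removes the whole gene pair
  ev2 <- mk_ev(store2, c("amb", "uniq2"), c(jread(34), jread(36)))
  ev2 <- filter_multimap(ev2, store2, drop_candidate = TRUE)
  expect_true(all(ev2$status == "STEP4F_MULTIMAP"))
  # without the shared gene nothing is flagged
  ev3 <- filter_multimap(mk_ev(store, "ok", jread(34)), store)
  expect_equal(ev3$status, "live")
})

test_that("filters are idempotent and conserve every pair exactly once", {
  seqs <- c(jread(30), jread(32), jread(45),
            paste0(substr(toy$seqs$txB, 1, 30), rand_dna(16, seed = 29),
                   substr(toy$seqs$txB, 120, 149)),
            rand_dna(76, seed = 30),
            paste0(substr(toy$seqs$txA, 71, 100), rand_dna(16, seed = 31),
                   substr(toy$seqs$txB, 111, 140)))
  ev <- mk_ev(store, sprintf("e%d", seq_along(seqs)), seqs)
  n0 <- nrow(ev)
  pipeline <- function(e) {
    e <- filter_same_gene(e); e <- filter_unaligned(e)
    e <- filter_paralogs(e, store); e <- filter_antisense(e, store)
    e <- filter_insert_geometry(e, store); filter_multimap(e, store)
  }
  ev <- pipeline(ev)
  snapshot <- data.table::copy(ev)
  ev <- pipeline(ev)                      # idempotence
  expect_equal(ev$status, snapshot$status)
  expect_equal(nrow(ev), n0)              # conservation: no row lost
  expect_true(all(ev$status %in% c("live", "STEP4A_SAME_GENE",
                                   "STEP4B_UNALIGNED", "STEP4E_GEOMETRY")))
  counts <- filter_counts(ev)
  expect_equal(sum(counts$n), n0)
})

test_that("collect_candidates groups live evidence by directed gene pair", {
  seqs <- c(jread(30), jread(32), jread(40),       # geneA:geneB x3
            paste0(substr(toy$seqs$txC, 131, 160), rand_dna(16, seed = 32),
                   substr(toy$seqs$txE, 1, 30)),   # geneC:geneE x2
            paste0(substr(toy$seqs$txC, 131, 160), rand_dna(16, seed = 33),
                   substr(toy$seqs$txE, 1, 30)))
  ev <- mk_ev(store, sprintf("c%d", 1:5), seqs)
  cands <- collect_candidates(ev)
  expect_length(cands, 2L)
  sizes <- sapply(cands, function(cd) nrow(cd$evidence))
  keys <- sapply(cands, function(cd) paste(cd$g1, cd$g2))
  expect_setequal(paste(keys, sizes), c("geneA geneB 3", "geneC geneE 2"))
  expect_length(collect_candidates(ev[0L]), 0L)
})
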