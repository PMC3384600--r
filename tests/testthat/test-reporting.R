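toy <- make_toy_ref()
store <- toy$store

mk_fusions <- function(store, ids, seqs, frac = 30 / 76) {
  reads <- toy_reads(ids, seqs)
  pp <- split_reads(reads, frac, frac)
  ev <- reunite_and_assign(align_default(pseudo_read_set(pp), store), pp, store)
  ev <- filter_same_gene(ev); ev <- filter_unaligned(ev)
  ev <- filter_insert_geometry(ev, store)
  list(fusions = lapply(collect_candidates(ev), analyze_candidate,
                        store = store),
       ev = ev)
}

jr_ab <- function(b1) toy_junction_read(substr(toy$seqs$txA, 51, 110),
                                        substr(toy$seqs$txB, 101, 200), b1)
jr_ce <- function(b1) toy_junction_read(toy$seqs$txC,
                                        substr(toy$seqs$txE, 1, 100), b1)

test_that("summary file carries the exact column set, ranked by evidence", {
  out <- mk_fusions(store, sprintf("x%d", 1:5),
                    c(jr_ab(30), jr_ab(33), jr_ab(36), jr_ce(31), jr_ce(34)))
  tab <- summary_table(out$fusions)
  expect_identical(names(tab),
                   c("Index Number", "G1_Ensembl_HGNC_ID", "G1_chromosome",
                     "G2_Ensembl_HGNC_ID", "G2_chromosome", "totalreads",
                     "G1_blocks", "G2_blocks", "isoforms", "category"))
  expect_equal(tab$totalreads, c(3L, 2L))                    # descending
  expect_equal(tab$`Index Number`, 1:2)
  expect_equal(tab$`G1_Ensembl_HGNC_ID`[1], "geneA (geneA)")
  f <- tempfile(fileext = ".tsv")
  write_summary(out$fusions, f)
  back <- data.table::fread(f, sep = "\t")
  expect_equal(nrow(back), 2L)
  # empty candidate list -> header-only file
  write_summary(list(), f)
  expect_equal(readLines(f), paste(names(tab), collapse = "\t"))
})

test_that("isoform rows reconcile with totals and carry the full column set", {
  out <- mk_fusions(store, sprintf("y%d", 1:4),
                    c(jr_ab(30), jr_ab(33),
                      toy_junction_read(substr(toy$seqs$txA, 51, 110),
                                        substr(toy$seqs$txB, 1, 100), 31),
                      jr_ab(35)))
  iso <- isoform_table(out$fusions)
  expect_identical(names(iso),
                   c("G1_Ensembl_HGNC_ID", "G1_chromosome",
                     "G2_Ensembl_HGNC_ID", "G2_chromosome", "isoreads",
                     "totalreads", "G1_block", "G1_exon", "G1_expos",
                     "G1_str", "G2_block", "G2_exon", "G2_expos", "G2_str"))
  expect_equal(sum(iso$isoreads), unique(iso$totalreads))
  expect_equal(unique(iso$totalreads), 4L)
  expect_true(all(grepl("^\\d+-\\d+$", iso$G1_block)))
  expect_equal(unique(iso$G1_str), 1L)
  # tie on totalreads orders by g1 id
  two <- mk_fusions(store, sprintf("z%d", 1:2), c(jr_ab(31), jr_ce(33)))
  tab <- summary_table(two$fusions)
  expect_equal(tab$`G1_Ensembl_HGNC_ID`,
               c("geneA (geneA)", "geneC (geneC)"))
})

test_that("read evidence, filter log and stats reconcile with the input", {
  seqs <- c(jr_ab(30), jr_ab(34), rand_dna(76, seed = 41),
            paste0(substr(toy$seqs$txB, 1, 30), rand_dna(16, seed = 42),
                   substr(toy$seqs$txB, 120, 149)))
  out <- mk_fusions(store, sprintf("w%d", 1:4), seqs)
  fe <- tempfile(); fl <- tempfile(); fs <- tempfile()
  write_read_evidence(out$fusions, fe)
  ev_tab <- data.table::fread(fe, sep = "\t")
  expect_equal(nrow(ev_tab), 2L)
  # every reported parent read reconstructs from its pseudo mates
  for (i in seq_len(nrow(ev_tab))) {
    expect_true(startsWith(ev_tab$parent_seq[i], ev_tab$mate1_seq[i]))
    expect_true(endsWith(ev_tab$parent_seq[i], ev_tab$mate2_seq[i]))
  }
  write_filter_log(out$ev, fl)
  log <- data.table::fread(fl, sep = "\t")
  expect_setequal(log$read_id, c("w3", "w4"))
  expect_setequal(log$stage, c("STEP4B_UNALIGNED", "STEP4A_SAME_GENE"))
  counts <- filter_counts(out$ev)
  write_stats(setNames(as.list(counts$n), counts$stage), fs)
  stats <- data.table::fread(fs, sep = "\t")
  expect_equal(sum(stats$n), 4L)                     # conservation
})

test_that("three-frame translation matches an independent codon-table oracle", {
  expect_equal(translate_three_frames("ATGTAA")[1], "M*")
  expect_equal(translate_three_frames("AATGTAA")[2], "M*")
  expect_equal(translate_three_frames("ATGNNNTAA")[1], "MX*")
  expect_error(translate_three_frames("ATGU"), "A,C,G,T,N")
  # oracle: direct lookup in the standard genetic code table
  set.seed(51)
  s <- rand_dna(300)
  code <- Biostrings::GENETIC_CODE
  for (f in 0:2) {
    sub <- substr(s, f + 1, 300)
    n <- nchar(sub) %/% 3
    codons <- substring(sub, 3 * seq_len(n) - 2, 3 * seq_len(n))
    expect_equal(translate_three_frames(s)[f + 1],
                 paste(unname(code[codons]), collapse = ""))
  }
})

test_that("breakpoint alignment lays junction reads gap-free across the junction", {
  out <- mk_fusions(store, c("p", "q"), c(jr_ab(32), revcomp(jr_ab(40))))
  f <- out$fusions[[1L]]
  rep <- breakpoint_alignment(f, 1L, store)
  expect_equal(nchar(rep$window), 60L)
  expect_equal(rep$junction_col, 30L)
  # window is G1-exon tail + G2-exon head in transcript orientation
  expect_equal(rep$window, paste0(substr(toy$seqs$txA, 81, 110),
                                  substr(toy$seqs$txB, 101, 130)))
  expect_equal(nrow(rep$reads), 2L)
  for (i in 1:2) {
    off <- rep$reads$offset[i]; s <- rep$reads$sequence[i]
    # overlap of the read with the window must match base for base
    a <- max(1L, off); b <- min(60L, off + nchar(s) - 1L)
    expect_equal(substr(rep$window, a, b),
                 substr(s, a - off + 1L, b - off + 1L))
  }
  # minus-strand G1 window comes from transcript-orientation sequence
  outc <- mk_fusions(store, "mc", jr_ce(31))
  repc <- breakpoint_alignment(outc$fusions[[1L]], 1L, store)
  expect_equal(substr(repc$window, 1, 30), substr(toy$seqs$txC, 131, 160))
  txt <- tempfile()
  write_breakpoint_report(rep, txt)
  expect_true(any(grepl("junction", readLines(txt))))
})
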