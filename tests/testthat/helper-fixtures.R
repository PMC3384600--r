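# Shared fixtures: a small hand-built annotation (two plus-strand genes, one
# minus-strand gene, one antisense-overlap pair), written as GTF + FASTA at
# test time, plus an independent brute-force aligner oracle.

rand_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

revcomp <- function(s) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1L]]), collapse = ""))
}

gtf_line <- function(chrom, start, end, strand, gid, tid, eid,
                     biotype = "protein_coding") {
  paste(chrom, "test", "exon", start, end, ".", strand, ".",
        sprintf('gene_id "%s"; transcript_id "%s"; exon_id "%s"; gene_name "%s"; gene_biotype "%s";',
                gid, tid, eid, gid, biotype),
        sep = "\t")
}

# Toy world:
#  geneA chrT1 +  exons EA1 101-150 (50), EA2 201-260 (60)          -> txA 110
#  geneB chrT1 +  exons EB1 5000-5099 (100), EB2 5200-5299 (100)    -> txB 200
#  geneC chrT2 -  exons (genomic) 101-200 (100), 301-360 (60)       -> txC 160
#  geneD chrT2 +  exon 150-280: overlaps geneC on the opposite strand
#  geneE chrT1 +  exon 24300-24399; exactly 19,000 bp downstream of geneB
make_toy_ref <- function(dir = tempfile("toyref"), paralog_tsv = FALSE,
                         repeat_bed = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(424242)
  gseq <- list(
    EA1 = rand_dna(50), EA2 = rand_dna(60),
    EB1 = rand_dna(100), EB2 = rand_dna(100),
    EC1g = rand_dna(100), EC2g = rand_dna(60),   # genomic-strand sequences
    ED1 = rand_dna(131), EE1 = rand_dna(100))
  txA <- paste0(gseq$EA1, gseq$EA2)
  txB <- paste0(gseq$EB1, gseq$EB2)
  # minus-strand splice: revcomp of the ascending genomic concatenation
  txC <- revcomp(paste0(gseq$EC1g, gseq$EC2g))
  txD <- gseq$ED1
  txE <- gseq$EE1
  gtf <- c(
    gtf_line("chrT1", 101, 150, "+", "geneA", "txA", "EA1"),
    gtf_line("chrT1", 201, 260, "+", "geneA", "txA", "EA2"),
    gtf_line("chrT1", 5000, 5099, "+", "geneB", "txB", "EB1"),
    gtf_line("chrT1", 5200, 5299, "+", "geneB", "txB", "EB2"),
    gtf_line("chrT2", 101, 200, "-", "geneC", "txC", "EC2"),
    gtf_line("chrT2", 301, 360, "-", "geneC", "txC", "EC1"),
    gtf_line("chrT2", 150, 280, "+", "geneD", "txD", "ED1"),
    gtf_line("chrT1", 24300, 24399, "+", "geneE", "txE", "EE1"))
  gtf_path <- file.path(dir, "toy.gtf")
  writeLines(gtf, gtf_path)
  fa_path <- file.path(dir, "toy.fa")
  writeLines(c(">txA", txA, ">txB", txB, ">txC", txC, ">txD", txD,
               ">txE", txE), fa_path)
  ptsv <- NULL
  if (paralog_tsv) {
    ptsv <- file.path(dir, "paralogs.tsv")
    writeLines("geneA\tgeneB", ptsv)
  }
  rbed <- NULL
  if (repeat_bed) {
    rbed <- file.path(dir, "repeats.bed")
    # BED 0-based starts; Alu over EA2's 3' half and EB2's 5' start, L1 on EB1
    writeLines(c("chrT1\t214\t260\tAlu", "chrT1\t5199\t5235\tAlu",
                 "chrT1\t5009\t5040\tL1"), rbed)
  }
  store <- load_reference(fa_path, NULL, gtf_path, ptsv, rbed)
  list(store = store, dir = dir, gtf = gtf_path, fasta = fa_path,
       paralogs = ptsv, repeats = rbed,
       seqs = list(txA = txA, txB = txB, txC = txC, txD = txD, txE = txE),
       gseq = gseq)
}

# Build a junction read for a planted toy fusion: last `b1` bases of the G1
# exon followed by the first `L - b1` bases of the G2 exon.
toy_junction_read <- function(exon1_seq, exon2_seq, b1, L = 76L) {
  paste0(substr(exon1_seq, nchar(exon1_seq) - b1 + 1L, nchar(exon1_seq)),
         substr(exon2_seq, 1L, L - b1))
}

# ---- independent brute-force aligner oracle -------------------------------
# Enumerates every offset on every transcript and both read orientations;
# valid iff ungapped end-to-end with <= max_mm mismatches in total and
# <= max_mm within the first seed_len bases of the read.
bf_align_one <- function(read, refseqs, max_mm = 2L, seed_len = 28L) {
  w <- nchar(read)
  seed <- min(seed_len, w)
  hits <- list()
  for (tid in names(refseqs)) {
    tseq <- as.character(refseqs[[tid]])
    for (strand in c("forward", "reverse_complement")) {
      pat <- if (strand == "forward") read else revcomp(read)
      pv <- strsplit(pat, "")[[1L]]
      for (off in seq_len(max(0L, nchar(tseq) - w + 1L))) {
        sv <- strsplit(substr(tseq, off, off + w - 1L), "")[[1L]]
        mism <- pv != sv
        # read-coordinate positions of the mismatches
        readpos <- if (strand == "forward") which(mism) else w - which(mism) + 1L
        if (sum(mism) <= max_mm && sum(readpos <= seed) <= max_mm)
          hits[[length(hits) + 1L]] <- data.table::data.table(
            transcript_id = tid, t_start = off, strand = strand,
            mismatches = sum(mism))
      }
    }
  }
  if (length(hits)) data.table::rbindlist(hits) else
    data.table::data.table(transcript_id = character(), t_start = integer(),
                           strand = character(), mismatches = integer())
}

# strip S3 veneer for value comparisons
plain <- function(dt) {
  out <- data.table::copy(dt)
  data.table::setattr(out, "class", c("data.table", "data.frame"))
  out
}

toy_reads <- function(ids, seqs) {
  rs <- data.table::data.table(read_id = ids, sequence = seqs,
                               quality = strrep("I", nchar(seqs)))
  data.table::setattr(rs, "class", c("read_set", class(rs)))
  rs
}

# mutate exactly k positions of a sequence (guaranteed base changes)
mutate_k <- function(s, pos) {
  v <- strsplit(s, "")[[1L]]
  for (p in pos) v[p] <- setdiff(c("A", "C", "G", "T"), v[p])[1L]
  paste(v, collapse = "")
}
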