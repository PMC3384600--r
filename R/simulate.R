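# Synthetic transcriptome + RNA-Seq read simulator with planted fusions,
# and the sensitivity/PPV evaluation used to score predictions against the
# simulation truth.

# uniform integer in [lo, hi] avoiding base sample()'s length-1 surprise
runifint <- function(lo, hi, n = 1L) {
  as.integer(lo + floor(stats::runif(n) * (hi - lo + 1L)))
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

mutate_dna <- function(seq, rate) {
  if (rate <= 0) return(seq)
  v <- strsplit(seq, "", fixed = TRUE)[[1L]]
  hit <- which(stats::runif(length(v)) < rate)
  for (i in hit) v[i] <- sample(setdiff(c("A", "C", "G", "T"), v[i]), 1L)
  paste(v, collapse = "")
}

#' Simulation configuration
#'
#' Defaults describe the simulated benchmark world: a few-hundred-gene
#' synthetic transcriptome containing homologous gene families, 55 planted
#' single-exon-to-single-exon fusions whose junction read counts are drawn
#' uniformly from 1 to 295 (every junction read carrying at least 30 bases
#' of either exon), 10,000 random junk reads, 75 nt reads, and roughly half
#' of all reads reverse-complemented. Background expression per transcript
#' follows a log-normal stand-in for an empirical RNA-Seq count
#' distribution. Reads are error-free unless `error_rate` is set.
#'
#' @param n_genes number of genes in the synthetic transcriptome
#' @param n_families number of homologous gene families among them
#' @param family_size members per family
#' @param family_identity within-family sequence identity (fraction)
#' @param n_chromosomes synthetic chromosomes the genes are placed on
#' @param exon_count_range,exon_length_range,intron_length_range,intergenic_range
#'   gene-structure ranges (bp)
#' @param read_length read length in nt
#' @param expressed_fraction fraction of genes expressed in the background
#' @param depth_meanlog,depth_sdlog log-normal parameters of the
#'   per-transcript background read count
#' @param n_fusions number of planted fusions
#' @param junction_reads_range inclusive range junction read counts are
#'   drawn from (uniformly)
#' @param junk_reads number of random-sequence junk reads
#' @param min_overhang minimum bases of each exon in every junction read
#' @param revcomp_prob probability a read is reverse-complemented
#' @param error_rate per-base substitution rate (default 0)
#' @param seed random seed recorded in the manifest
#' @return a `sim_config`
#' @export
sim_config <- function(n_genes = 300L, n_families = 8L, family_size = 2L,
                       family_identity = 0.95, n_chromosomes = 5L,
                       exon_count_range = c(2L, 6L),
                       exon_length_range = c(120L, 400L),
                       intron_length_range = c(200L, 2000L),
                       intergenic_range = c(1000L, 5000L),
                       read_length = 75L, expressed_fraction = 0.7,
                       depth_meanlog = 4, depth_sdlog = 1.2,
                       n_fusions = 55L, junction_reads_range = c(1L, 295L),
                       junk_reads = 10000L, min_overhang = 30L,
                       revcomp_prob = 0.5, error_rate = 0, seed = 1L) {
  stopifnot(min_overhang >= 1L, 2L * min_overhang <= read_length,
            family_identity > 0, family_identity <= 1)
  structure(as.list(environment()), class = "sim_config")
}

#' Generate a synthetic transcriptome (FASTA + GTF + family map)
#'
#' Multi-exon genes with random sequence are placed non-overlapping on
#' synthetic chromosomes, alternating strand at random; designated gene
#' families are mutated copies of a founder sharing the configured percent
#' identity. One transcript per gene. The GTF/FASTA pair satisfies the
#' annotation-store invariants and loads with [load_reference()].
#'
#' @param config a `sim_config`
#' @param dir output directory (created if missing)
#' @return list with paths `coding_fasta`, `annotation_gtf`, `family_tsv`
#'   and tables `genes` (gene_id, chromosome, strand, family) and
#'   `families`
#' @export
generate_transcriptome <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  ng <- config$n_genes
  fam_members <- config$n_families * config$family_size
  if (fam_members > ng) stop("more family members than genes")
  # founders are the first gene of each family; copies follow
  family <- rep(NA_integer_, ng)
  founder_of <- rep(NA_integer_, ng)
  if (config$n_families > 0L) {
    idx <- seq_len(fam_members)
    family[idx] <- rep(seq_len(config$n_families), each = config$family_size)
    founder_of[idx] <- rep(idx[seq(1L, fam_members, by = config$family_size)],
                           each = config$family_size)
  }
  exon_seqs <- vector("list", ng)   # transcript-orientation exon sequences
  for (g in seq_len(ng)) {
    if (!is.na(founder_of[g]) && founder_of[g] != g) {
      tmpl <- exon_seqs[[founder_of[g]]]
      exon_seqs[[g]] <- vapply(tmpl, mutate_dna, "",
                               rate = 1 - config$family_identity)
    } else {
      ne <- runifint(config$exon_count_range[1L], config$exon_count_range[2L])
      lens <- runifint(config$exon_length_range[1L],
                       config$exon_length_range[2L], ne)
      exon_seqs[[g]] <- vapply(lens, random_dna, "")
    }
  }
  # place genes left to right on chromosomes
  chrom_of <- sample(rep_len(seq_len(config$n_chromosomes), ng))
  strand_of <- sample(c("+", "-"), ng, replace = TRUE)
  cursor <- setNames(rep(1L, config$n_chromosomes),
                     paste0("chr", seq_len(config$n_chromosomes)))
  gtf <- character(0)
  fasta_ids <- character(ng); fasta_seqs <- character(ng)
  genes <- vector("list", ng)
  for (g in seq_len(ng)) {
    gid <- sprintf("SGENE%04d", g)
    tid <- sprintf("STX%04d", g)
    chrom <- paste0("chr", chrom_of[g])
    strand <- strand_of[g]
    lens <- nchar(exon_seqs[[g]])
    ne <- length(lens)
    pos <- cursor[chrom] + runifint(config$intergenic_range[1L],
                                    config$intergenic_range[2L])
    # genomic exon order: transcript order for +, reversed for -
    glens <- if (strand == "+") lens else rev(lens)
    starts <- integer(ne); ends <- integer(ne)
    for (k in seq_len(ne)) {
      starts[k] <- pos
      ends[k] <- pos + glens[k] - 1L
      pos <- ends[k] + runifint(config$intron_length_range[1L],
                                config$intron_length_range[2L])
    }
    cursor[chrom] <- ends[ne]
    exon_ids <- sprintf("%s.E%d", tid, seq_len(ne))     # transcript order
    g_order <- if (strand == "+") seq_len(ne) else rev(seq_len(ne))
    for (k in seq_len(ne)) {
      tk <- g_order[k]  # transcript rank of the k-th genomic exon
      gtf <- c(gtf, paste(chrom, "sim", "exon", starts[k], ends[k], ".",
                          strand, ".",
                          sprintf(paste0('gene_id "%s"; transcript_id "%s"; ',
                                         'exon_id "%s"; gene_name "%s"; ',
                                         'gene_biotype "protein_coding";'),
                                  gid, tid, exon_ids[tk], gid),
                          sep = "\t"))
    }
    tseq <- paste(exon_seqs[[g]], collapse = "")
    fasta_ids[g] <- tid; fasta_seqs[g] <- tseq
    genes[[g]] <- data.table(gene_id = gid, transcript_id = tid,
                             chromosome = chrom, strand = strand,
                             family = family[g], n_exons = ne,
                             tx_length = nchar(tseq))
  }
  genes <- rbindlist(genes)
  fa <- file.path(dir, "coding.fa")
  seqs <- Biostrings::DNAStringSet(fasta_seqs); names(seqs) <- fasta_ids
  Biostrings::writeXStringSet(seqs, fa)
  gtf_path <- file.path(dir, "annotation.gtf")
  writeLines(gtf, gtf_path)
  fam_tab <- genes[!is.na(family), .(gene_id, family)]
  fam_path <- file.path(dir, "families.tsv")
  fwrite(fam_tab, fam_path, sep = "\t")
  list(coding_fasta = fa, annotation_gtf = gtf_path, family_tsv = fam_path,
       genes = genes, families = fam_tab, exon_seqs = exon_seqs)
}

#' Plant random fusions (the simulation truth)
#'
#' Pairs of transcripts from different genes are selected at random; the
#' fused sequence joins one randomly chosen exon of each (the 3' end of the
#' G1 exon to the 5' start of the G2 exon). Junction read counts are drawn
#' uniformly from the configured range. Exons shorter than
#' `read_length - min_overhang` are not used so every junction read can
#' carry the minimum overhang on both sides.
#'
#' @param config a `sim_config`
#' @param txome result of [generate_transcriptome()]
#' @return `simulation_truth` data.table: fusion_id, g1, g2, g1_exon rank,
#'   g2_exon rank, junction_reads
#' @export
plant_fusions <- function(config, txome) {
  ok_exon <- function(g) which(nchar(txome$exon_seqs[[g]]) >=
                                 config$read_length - config$min_overhang)
  eligible <- which(vapply(seq_len(nrow(txome$genes)),
                           function(g) length(ok_exon(g)) > 0L, TRUE))
  truth <- vector("list", config$n_fusions)
  used <- character()
  for (i in seq_len(config$n_fusions)) {
    repeat {
      pick <- sample(eligible, 2L)
      key <- paste(sort(pick), collapse = ":")
      if (pick[1L] != pick[2L] && !(key %in% used)) break
    }
    used <- c(used, key)
    ex1 <- ok_exon(pick[1L]); ex2 <- ok_exon(pick[2L])
    e1 <- ex1[runifint(1L, length(ex1))]
    e2 <- ex2[runifint(1L, length(ex2))]
    truth[[i]] <- data.table(
      fusion_id = sprintf("FUS%03d", i),
      g1 = txome$genes$gene_id[pick[1L]], g2 = txome$genes$gene_id[pick[2L]],
      g1_idx = pick[1L], g2_idx = pick[2L],
      g1_exon_rank = e1, g2_exon_rank = e2,
      junction_reads = runifint(config$junction_reads_range[1L],
                                config$junction_reads_range[2L]))
  }
  out <- rbindlist(truth)
  setattr(out, "class", unique(c("simulation_truth", class(out))))
  out
}

#' Simulate an RNA-Seq read set with planted fusion junction reads
#'
#' Background reads are drawn uniformly across each expressed transcript
#' with per-transcript counts from the configured log-normal; junction
#' reads span each planted breakpoint with at least `min_overhang` bases of
#' either exon; junk reads are uniform random sequence. A configured
#' fraction of all reads is reverse-complemented. The manifest records
#' every read's origin.
#'
#' @param config a `sim_config`
#' @param txome result of [generate_transcriptome()]
#' @param truth result of [plant_fusions()]
#' @param dir output directory
#' @return list with paths `fastq`, `truth_tsv`, `manifest_tsv` and the
#'   `manifest` table
#' @export
simulate_reads <- function(config, txome, truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  L <- config$read_length
  ids <- character(); seqs <- character(); origin <- character()
  src <- character()
  # background
  expressed <- which(stats::runif(nrow(txome$genes)) < config$expressed_fraction)
  for (g in expressed) {
    len <- txome$genes$tx_length[g]
    if (len < L) next
    n <- round(stats::rlnorm(1L, config$depth_meanlog, config$depth_sdlog))
    if (n < 1L) next
    tseq <- paste(txome$exon_seqs[[g]], collapse = "")
    st <- sample.int(len - L + 1L, n, replace = TRUE)
    ids <- c(ids, sprintf("bg_%s_%d", txome$genes$transcript_id[g], seq_len(n)))
    seqs <- c(seqs, substring(tseq, st, st + L - 1L))
    origin <- c(origin, rep("background", n))
    src <- c(src, rep(txome$genes$gene_id[g], n))
  }
  # fusion junction reads
  for (i in seq_len(nrow(truth))) {
    e1 <- txome$exon_seqs[[truth$g1_idx[i]]][truth$g1_exon_rank[i]]
    e2 <- txome$exon_seqs[[truth$g2_idx[i]]][truth$g2_exon_rank[i]]
    fused <- paste0(e1, e2)
    n <- truth$junction_reads[i]
    lo <- max(config$min_overhang, L - nchar(e2))
    hi <- min(L - config$min_overhang, nchar(e1))
    b1 <- runifint(lo, hi, n)  # bases taken from exon 1
    st <- nchar(e1) - b1 + 1L
    ids <- c(ids, sprintf("%s_r%d", truth$fusion_id[i], seq_len(n)))
    seqs <- c(seqs, substring(fused, st, st + L - 1L))
    origin <- c(origin, rep("fusion", n))
    src <- c(src, rep(truth$fusion_id[i], n))
  }
  # junk
  if (config$junk_reads > 0L) {
    ids <- c(ids, sprintf("junk_%d", seq_len(config$junk_reads)))
    seqs <- c(seqs, vapply(seq_len(config$junk_reads),
                           function(i) random_dna(L), ""))
    origin <- c(origin, rep("junk", config$junk_reads))
    src <- c(src, rep(".", config$junk_reads))
  }
  if (config$error_rate > 0)
    seqs <- vapply(seqs, mutate_dna, "", rate = config$error_rate,
                   USE.NAMES = FALSE)
  rc <- stats::runif(length(seqs)) < config$revcomp_prob
  if (any(rc))
    seqs[rc] <- as.character(reverseComplement(Biostrings::DNAStringSet(seqs[rc])))
  reads <- as_read_set(ids, seqs)
  fq <- file.path(dir, "reads.fastq")
  write_fastq(reads, fq)
  manifest <- data.table(read_id = ids, origin = origin, source = src,
                         revcomp = rc)
  man_path <- file.path(dir, "manifest.tsv")
  fwrite(manifest, man_path, sep = "\t")
  truth_path <- file.path(dir, "truth.tsv")
  fwrite(truth[, .(fusion_id, g1, g2, g1_exon_rank, g2_exon_rank,
                   junction_reads)], truth_path, sep = "\t")
  list(fastq = fq, truth_tsv = truth_path, manifest_tsv = man_path,
       manifest = manifest)
}

#' Generate a complete simulated dataset
#'
#' Convenience wrapper: transcriptome, planted fusions and reads under one
#' seed, all written to `dir`.
#'
#' @param config a `sim_config`
#' @param dir output directory
#' @return list(txome=, truth=, reads=) with all paths
#' @export
simulate_dataset <- function(config, dir) {
  txome <- generate_transcriptome(config, dir)   # seeds the RNG
  truth <- plant_fusions(config, txome)
  reads <- simulate_reads(config, txome, truth, dir)
  list(txome = txome, truth = truth, reads = reads)
}

#' Score fusion predictions against the simulation truth
#'
#' A prediction is a true positive when its unordered gene pair matches a
#' planted fusion. A prediction matching a planted fusion only after
#' substituting one or both partners by members of the same gene family is
#' a synonymous fusion and counts as a false positive, as does anything
#' else unmatched. Sensitivity_i = TP/(TP+FN) and PPV_i = TP/(TP+FP),
#' computed over predictions evidenced by at least `i` reads; FN counts the
#' planted fusions not recovered at that threshold, so TP+FN equals the
#' number planted.
#'
#' @param predictions summary table from [summary_table()] (or a data.table
#'   with columns g1, g2, totalreads)
#' @param truth a `simulation_truth`
#' @param families optional data.table(gene_id, family) for synonymous
#'   accounting
#' @param thresholds integer vector of evidence thresholds i
#' @return an `evaluation_result`: list(metrics = per-threshold data.table
#'   with TP/FP/FN/sensitivity/PPV, labels = per-prediction data.table)
#' @export
evaluate <- function(predictions, truth, families = NULL, thresholds = 1L) {
  pred <- as.data.table(predictions)
  if ("G1_Ensembl_HGNC_ID" %in% names(pred)) {
    pred <- pred[, .(g1 = sub(" .*$", "", `G1_Ensembl_HGNC_ID`),
                     g2 = sub(" .*$", "", `G2_Ensembl_HGNC_ID`),
                     totalreads = totalreads)]
  }
  fam_of <- function(g) {
    if (is.null(families)) return(rep(NA_integer_, length(g)))
    families$family[match(g, families$gene_id)]
  }
  tkey <- paste(pmin(truth$g1, truth$g2), pmax(truth$g1, truth$g2))
  label_one <- function(a, b) {
    key <- paste(min(a, b), max(a, b))
    if (key %in% tkey) return("true_positive")
    fa <- fam_of(a); fb <- fam_of(b)
    syn <- FALSE
    if (!is.na(fa) || !is.na(fb)) {
      tf1 <- fam_of(truth$g1); tf2 <- fam_of(truth$g2)
      same <- function(x, fx, ty, tfy) x == ty | (!is.na(fx) & !is.na(tfy) & fx == tfy)
      syn <- any((same(a, fa, truth$g1, tf1) & same(b, fb, truth$g2, tf2)) |
                 (same(a, fa, truth$g2, tf2) & same(b, fb, truth$g1, tf1)))
    }
    if (syn) "synonymous_fusion" else "false_positive"
  }
  labels <- if (nrow(pred)) {
    data.table(g1 = pred$g1, g2 = pred$g2, totalreads = pred$totalreads,
               label = mapply(label_one, pred$g1, pred$g2))
  } else data.table(g1 = character(), g2 = character(),
                    totalreads = integer(), label = character())
  metrics <- rbindlist(lapply(thresholds, function(i) {
    sub <- labels[totalreads >= i]
    matched <- unique(paste(pmin(sub$g1, sub$g2),
                            pmax(sub$g1, sub$g2))[sub$label == "true_positive"])
    tp <- length(matched)
    fp <- sum(sub$label != "true_positive")
    fn <- length(tkey) - tp
    data.table(i = i, TP = tp, FP = fp, FN = fn,
               sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
               PPV = if (tp + fp > 0) tp / (tp + fp) else NA_real_)
  }))
  structure(list(metrics = metrics, labels = labels),
            class = "evaluation_result")
}

#' Sensitivity and PPV from printed confusion counts
#'
#' @param TP,FP,FN counts of true positive, false positive and false
#'   negative fusion genes
#' @return list(sensitivity=, PPV=), each NA when undefined
#' @export
performance_measures <- function(TP, FP, FN) {
  list(sensitivity = if (TP + FN > 0) TP / (TP + FN) else NA_real_,
       PPV = if (TP + FP > 0) TP / (TP + FP) else NA_real_)
}

#' @export
print.evaluation_result <- function(x, ...) {
  print(x$metrics)
  invisible(x)
}
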