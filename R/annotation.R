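#' @import data.table
#' @importFrom Biostrings DNAStringSet readDNAStringSet reverseComplement
#' @importFrom stats setNames
NULL

# Internal: parse the attribute column of a GTF into a named character vector
# per row for the requested keys. Missing keys yield NA.
gtf_attr <- function(attrs, key) {
  pat <- paste0(key, "\\s+\"([^\"]*)\"")
  m <- regmatches(attrs, regexpr(pat, attrs, perl = TRUE))
  out <- rep(NA_character_, length(attrs))
  hit <- grepl(pat, attrs, perl = TRUE)
  out[hit] <- sub(pat, "\\1", m, perl = TRUE)
  out
}

#' Load a transcriptome reference from flat files
#'
#' Builds an annotation store from a coding-transcriptome FASTA, an optional
#' non-coding FASTA, a GTF with exon features, and optional paralog-pair and
#' repeat side-car files. The store indexes genes, transcripts and exons and
#' carries the transcript-to-genome coordinate maps used by the downstream
#' filters.
#'
#' Every FASTA record id must have a matching `transcript_id` in the GTF;
#' transcripts annotated in the GTF but absent from both FASTA files are kept
#' for coordinate arithmetic but excluded from the alignment references.
#' Coordinates are 1-based inclusive throughout; BED repeat starts are
#' converted from 0-based on input.
#'
#' @param coding_fasta path to the coding transcript FASTA (record ids are
#'   transcript ids; sequences are spliced, transcript orientation)
#' @param noncoding_fasta optional path to a non-coding transcript FASTA
#' @param annotation_gtf path to a GTF containing `exon` features with
#'   `gene_id`, `transcript_id` attributes (`exon_id`, `gene_name`,
#'   `gene_biotype` honoured when present)
#' @param paralog_tsv optional two-column TSV of paralogous gene-id pairs
#'   (unordered)
#' @param repeat_bed optional BED-like file: chrom, start (0-based), end,
#'   repeat class
#' @return an object of class `annotation_store`
#' @export
load_reference <- function(coding_fasta, noncoding_fasta = NULL,
                           annotation_gtf, paralog_tsv = NULL,
                           repeat_bed = NULL) {
  seqs_cod <- readDNAStringSet(coding_fasta)
  names(seqs_cod) <- sub("\\s.*$", "", names(seqs_cod))
  if (anyDuplicated(names(seqs_cod)))
    stop("duplicate transcript id in coding FASTA: ",
         names(seqs_cod)[duplicated(names(seqs_cod))][1L])
  seqs_nc <- NULL
  if (!is.null(noncoding_fasta)) {
    seqs_nc <- readDNAStringSet(noncoding_fasta)
    names(seqs_nc) <- sub("\\s.*$", "", names(seqs_nc))
    if (anyDuplicated(c(names(seqs_cod), names(seqs_nc))))
      stop("duplicate transcript id across FASTA files")
  }

  raw <- readLines(annotation_gtf)
  keep <- !grepl("^#", raw) & nzchar(raw)
  lineno <- which(keep)
  fields <- strsplit(raw[keep], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 9L))
    stop("malformed GTF line ", lineno[which(nf != 9L)[1L]],
         ": expected 9 tab-separated fields, got ", nf[nf != 9L][1L])
  gtf <- data.table(
    chrom   = vapply(fields, `[`, "", 1L),
    feature = vapply(fields, `[`, "", 3L),
    start   = suppressWarnings(as.integer(vapply(fields, `[`, "", 4L))),
    end     = suppressWarnings(as.integer(vapply(fields, `[`, "", 5L))),
    strand  = vapply(fields, `[`, "", 7L),
    attrs   = vapply(fields, `[`, "", 9L),
    line    = lineno
  )
  if (anyNA(gtf$start) || anyNA(gtf$end))
    stop("malformed GTF line ", gtf$line[which(is.na(gtf$start) | is.na(gtf$end))[1L]],
         ": non-numeric coordinate")
  ex <- gtf[feature == "exon"]
  if (nrow(ex) == 0L) stop("GTF contains no exon features")
  bad <- ex[!(strand %in% c("+", "-"))]
  if (nrow(bad)) stop("malformed GTF line ", bad$line[1L], ": strand must be + or -")
  ex[, `:=`(gene_id = gtf_attr(attrs, "gene_id"),
            transcript_id = gtf_attr(attrs, "transcript_id"),
            exon_id = gtf_attr(attrs, "exon_id"),
            gene_name = gtf_attr(attrs, "gene_name"),
            biotype = gtf_attr(attrs, "gene_biotype"))]
  if (anyNA(ex$gene_id) || anyNA(ex$transcript_id))
    stop("malformed GTF line ",
         ex$line[which(is.na(ex$gene_id) | is.na(ex$transcript_id))[1L]],
         ": missing gene_id/transcript_id attribute")
  if (anyNA(ex$exon_id))
    ex[is.na(exon_id), exon_id := paste0(transcript_id, ".E", seq_len(.N)),
       by = transcript_id]
  if (any(ex$start > ex$end))
    stop("malformed GTF line ", ex$line[which(ex$start > ex$end)[1L]],
         ": start > end")

  # exon order 5'->3' in transcript orientation
  ex <- ex[order(transcript_id, ifelse(strand == "+", 1L, -1L) * start)]
  ex[, rank := seq_len(.N), by = transcript_id]
  ex[, width := end - start + 1L]
  ex[, t_end := cumsum(width), by = transcript_id]
  ex[, t_start := t_end - width + 1L]
  exons <- ex[, .(transcript_id, exon_id, rank, chrom, g_start = start,
                  g_end = end, strand = ifelse(strand == "+", 1L, -1L),
                  t_start, t_end, width, gene_id)]

  tx <- exons[, .(gene_id = gene_id[1L], chrom = chrom[1L],
                  strand = strand[1L], length = sum(width),
                  n_exons = .N), by = transcript_id]
  bt <- ex[, .(biotype = biotype[1L]), by = transcript_id]
  tx <- merge(tx, bt, by = "transcript_id", sort = FALSE)
  if (anyNA(tx$biotype)) {
    warning(sum(is.na(tx$biotype)),
            " transcript(s) carry no biotype attribute; assuming coding")
    tx[is.na(biotype), biotype := "protein_coding"]
  }
  tx[, biotype := ifelse(biotype %in% c("protein_coding", "coding"),
                         "coding", "noncoding")]

  all_seqs <- if (is.null(seqs_nc)) seqs_cod else c(seqs_cod, seqs_nc)
  missing_gtf <- setdiff(names(all_seqs), tx$transcript_id)
  if (length(missing_gtf))
    stop("FASTA record with no GTF annotation: ", missing_gtf[1L])
  have_seq <- tx$transcript_id %in% names(all_seqs)
  tx[, in_coding := transcript_id %in% names(seqs_cod)]
  tx[, in_noncoding := transcript_id %in% names(seqs_nc)]
  chk <- tx[have_seq]
  wlen <- setNames(Biostrings::width(all_seqs), names(all_seqs))
  badlen <- chk[length != wlen[transcript_id]]
  if (nrow(badlen))
    stop("transcript ", badlen$transcript_id[1L], ": FASTA sequence length ",
         wlen[badlen$transcript_id[1L]], " != summed exon length ",
         badlen$length[1L])

  nm <- ex[, .(name = {
    v <- gene_name[!is.na(gene_name)]
    if (length(v)) v[1L] else gene_id[1L]
  }), by = gene_id]
  genes <- exons[, .(chrom = chrom[1L], strand = strand[1L],
                     span_start = min(g_start), span_end = max(g_end)),
                 by = gene_id]
  genes <- merge(genes, nm, by = "gene_id", sort = FALSE)
  if (any(genes[, uniqueN(chrom) > 1L | uniqueN(strand) > 1L, by = gene_id]$V1))
    stop("gene with exons on multiple chromosomes or strands")

  paralogs <- NULL
  if (!is.null(paralog_tsv)) {
    pp <- fread(paralog_tsv, header = FALSE, sep = "\t",
                col.names = c("a", "b")[1:2], colClasses = "character")
    paralogs <- unique(pp[, .(a = pmin(a, b), b = pmax(a, b))])
  }
  repeats <- NULL
  if (!is.null(repeat_bed)) {
    rp <- fread(repeat_bed, header = FALSE, sep = "\t")
    if (ncol(rp) < 4L) stop("repeat BED needs >= 4 columns (chrom,start,end,class)")
    repeats <- data.table(chrom = as.character(rp[[1L]]),
                          start = as.integer(rp[[2L]]) + 1L,  # BED 0-based
                          end = as.integer(rp[[3L]]),
                          class = as.character(rp[[4L]]))
    if (any(repeats$start > repeats$end)) stop("repeat interval with start > end")
  }

  setkey(exons, transcript_id, t_start)
  setkey(tx, transcript_id)
  setkey(genes, gene_id)
  structure(list(genes = genes, transcripts = tx, exons = exons,
                 sequences = all_seqs,
                 coding_ids = names(seqs_cod),
                 noncoding_ids = if (is.null(seqs_nc)) character() else names(seqs_nc),
                 paralogs = paralogs, repeats = repeats),
            class = "annotation_store")
}

#' @export
print.annotation_store <- function(x, ...) {
  cat("annotation_store:", nrow(x$genes), "genes,", nrow(x$transcripts),
      "transcripts,", nrow(x$exons), "exon records\n")
  cat("  coding sequences:", length(x$coding_ids),
      " non-coding:", length(x$noncoding_ids), "\n")
  if (!is.null(x$paralogs)) cat("  paralog pairs:", nrow(x$paralogs), "\n")
  if (!is.null(x$repeats)) cat("  repeat intervals:", nrow(x$repeats), "\n")
  invisible(x)
}

tx_exons <- function(store, transcript_id) {
  tid <- transcript_id
  e <- store$exons[.(tid)]
  if (nrow(e) == 0L || is.na(e$exon_id[1L]))
    stop("unknown transcript id: ", transcript_id)
  e
}

#' Transpose a transcript interval to genomic coordinates
#'
#' Maps a 1-based inclusive interval on a spliced transcript to one or more
#' genomic segments, splitting at exon junctions. On minus-strand transcripts
#' ascending transcript positions map to descending genomic positions; each
#' returned segment is still reported with `genomic_start <= genomic_end`.
#'
#' @param store an `annotation_store`
#' @param transcript_id transcript to map on
#' @param t_start,t_end 1-based inclusive transcript coordinates
#' @return data.table with columns chromosome, genomic_start, genomic_end,
#'   strand, exon_id — one row per exon-bounded segment, ordered 5' to 3' in
#'   transcript orientation
#' @export
transcript_to_genomic <- function(store, transcript_id, t_start, t_end) {
  e <- tx_exons(store, transcript_id)
  len <- e$t_end[nrow(e)]
  if (t_start < 1L || t_end > len || t_start > t_end)
    stop("interval [", t_start, ",", t_end, "] out of range for ",
         transcript_id, " (length ", len, ")")
  qs <- as.integer(t_start); qe <- as.integer(t_end)
  hit <- e[t_end >= qs & t_start <= qe]
  segs <- hit[, {
    a <- max(t_start, qs); b <- min(t_end, qe)
    if (strand == 1L) {
      gs <- g_start + (a - t_start); ge <- g_start + (b - t_start)
    } else {
      gs <- g_end - (b - t_start); ge <- g_end - (a - t_start)
    }
    .(chromosome = chrom, genomic_start = gs, genomic_end = ge,
      strand = strand, exon_id = exon_id)
  }, by = rank][, rank := NULL][]
  segs
}

#' Map a genomic position back to transcript coordinates
#'
#' Inverse of [transcript_to_genomic()] for a single base.
#'
#' @inheritParams transcript_to_genomic
#' @param chromosome,g_pos genomic location
#' @return 1-based transcript coordinate, or NA if the base is not exonic in
#'   this transcript
#' @export
genomic_to_transcript <- function(store, transcript_id, chromosome, g_pos) {
  e <- tx_exons(store, transcript_id)
  h <- e[chrom == chromosome & g_start <= g_pos & g_end >= g_pos]
  if (nrow(h) == 0L) return(NA_integer_)
  h <- h[1L]
  if (h$strand == 1L) h$t_start + (g_pos - h$g_start)
  else h$t_start + (h$g_end - g_pos)
}

#' Distance from a transcript position to an exon boundary
#'
#' Finds the exon containing a transcript position and measures, in
#' transcript coordinates, the distance to that exon's 3' end or 5' start.
#'
#' @inheritParams transcript_to_genomic
#' @param t_pos 1-based transcript coordinate
#' @param side `"3prime"` (distance to the exon's transcript-3' last base) or
#'   `"5prime"` (distance from the exon's transcript-5' first base)
#' @return list(exon_id=, distance=) with distance >= 0
#' @export
distance_to_exon_boundary <- function(store, transcript_id, t_pos,
                                      side = c("3prime", "5prime")) {
  side <- match.arg(side)
  e <- tx_exons(store, transcript_id)
  len <- e$t_end[nrow(e)]
  if (t_pos < 1L || t_pos > len)
    stop("position ", t_pos, " out of range for ", transcript_id)
  h <- e[t_start <= t_pos & t_end >= t_pos][1L]
  d <- if (side == "3prime") h$t_end - t_pos else t_pos - h$t_start
  list(exon_id = h$exon_id, distance = as.integer(d))
}

#' Relative geometry of a gene pair
#'
#' Chromosome, strand and span-gap relationships used by the read-through /
#' inversion categoriser and the antisense filter. The gap is measured
#' between the nearest span boundaries (0 when spans overlap) and is NA when
#' the genes lie on different chromosomes.
#'
#' @param store an `annotation_store`
#' @param g1,g2 gene ids
#' @return list(same_chromosome=, same_strand=, gap_bp=,
#'   spans_overlap_opposite_strand=)
#' @export
gene_pair_geometry <- function(store, g1, g2) {
  a <- store$genes[.(g1)]; b <- store$genes[.(g2)]
  if (is.na(a$chrom)) stop("unknown gene id: ", g1)
  if (is.na(b$chrom)) stop("unknown gene id: ", g2)
  same_chr <- a$chrom == b$chrom
  same_str <- a$strand == b$strand
  gap <- NA_integer_
  overlap <- FALSE
  if (same_chr) {
    gap <- as.integer(if (a$span_start > b$span_end)
      a$span_start - b$span_end - 1L
      else if (b$span_start > a$span_end) b$span_start - a$span_end - 1L
      else 0L)
    overlap <- gap == 0L && !same_str &&
      a$span_start <= b$span_end && b$span_start <= a$span_end
  }
  list(same_chromosome = same_chr, same_strand = same_str,
       gap_bp = gap, spans_overlap_opposite_strand = overlap)
}

# exon sequence in transcript orientation, looked up through any transcript
# containing the exon
exon_sequence <- function(store, exon_id) {
  eid <- exon_id
  e <- store$exons[exon_id == eid]
  if (nrow(e) == 0L) stop("unknown exon id: ", exon_id)
  e <- e[transcript_id %in% names(store$sequences)]
  if (nrow(e) == 0L) stop("no sequence available for exon ", exon_id)
  e <- e[1L]
  as.character(Biostrings::subseq(store$sequences[[e$transcript_id]],
                                  e$t_start, e$t_end))
}
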