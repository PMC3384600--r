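fmt_gene <- function(id, name) paste0(id, " (", name, ")")

summary_columns <- c("Index Number", "G1_Ensembl_HGNC_ID", "G1_chromosome",
                     "G2_Ensembl_HGNC_ID", "G2_chromosome", "totalreads",
                     "G1_blocks", "G2_blocks", "isoforms", "category")

isoform_columns <- c("G1_Ensembl_HGNC_ID", "G1_chromosome",
                     "G2_Ensembl_HGNC_ID", "G2_chromosome", "isoreads",
                     "totalreads", "G1_block", "G1_exon", "G1_expos",
                     "G1_str", "G2_block", "G2_exon", "G2_expos", "G2_str")

#' Build the ranked summary table of fusion candidates
#'
#' One row per candidate, ranked by evidence strength (totalreads
#' descending, ties by G1 gene id).
#'
#' @param fusions list of `fusion_candidate`
#' @return data.table with the summary column set
#' @export
summary_table <- function(fusions) {
  fusions <- Filter(function(f) !isTRUE(f$empty), fusions)
  if (length(fusions) == 0L) {
    out <- setNames(data.table(matrix(nrow = 0L, ncol = length(summary_columns))),
                    summary_columns)
    return(out)
  }
  dt <- rbindlist(lapply(fusions, function(f) data.table(
    g1id = f$g1,
    `G1_Ensembl_HGNC_ID` = fmt_gene(f$g1, f$g1_name),
    `G1_chromosome` = f$g1_chromosome,
    `G2_Ensembl_HGNC_ID` = fmt_gene(f$g2, f$g2_name),
    `G2_chromosome` = f$g2_chromosome,
    totalreads = f$totalreads, `G1_blocks` = f$g1_blocks,
    `G2_blocks` = f$g2_blocks, isoforms = nrow(f$isoforms),
    category = paste(f$categories, collapse = ","))))
  setorder(dt, -totalreads, g1id)
  dt[, `Index Number` := seq_len(.N)]
  dt[, g1id := NULL]
  setcolorder(dt, summary_columns)
  dt[]
}

#' Write the candidate summary TSV
#' @param fusions list of `fusion_candidate`
#' @param path output path
#' @return the path, invisibly
#' @export
write_summary <- function(fusions, path) {
  fwrite(summary_table(fusions), path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Build the per-isoform detail table
#'
#' One row per isoform (block combination) per candidate, with block
#' genomic coordinates, nearest exon ids, exon-boundary distances (expos)
#' and gene strands. Candidates appear in summary ranking order.
#'
#' @param fusions list of `fusion_candidate`
#' @return data.table with the isoform column set
#' @export
isoform_table <- function(fusions) {
  fusions <- Filter(function(f) !isTRUE(f$empty), fusions)
  if (length(fusions) == 0L) {
    return(setNames(data.table(matrix(nrow = 0L, ncol = length(isoform_columns))),
                    isoform_columns))
  }
  ord <- order(-vapply(fusions, `[[`, 0L, "totalreads"),
               vapply(fusions, `[[`, "", "g1"))
  rbindlist(lapply(fusions[ord], function(f) {
    iso <- f$isoforms
    data.table(
      `G1_Ensembl_HGNC_ID` = fmt_gene(f$g1, f$g1_name),
      `G1_chromosome` = f$g1_chromosome,
      `G2_Ensembl_HGNC_ID` = fmt_gene(f$g2, f$g2_name),
      `G2_chromosome` = f$g2_chromosome,
      isoreads = iso$isoreads, totalreads = f$totalreads,
      `G1_block` = paste0(iso$g1_block_start, "-", iso$g1_block_end),
      `G1_exon` = iso$g1_exon, `G1_expos` = iso$g1_expos,
      `G1_str` = f$g1_strand,
      `G2_block` = paste0(iso$g2_block_start, "-", iso$g2_block_end),
      `G2_exon` = iso$g2_exon, `G2_expos` = iso$g2_expos,
      `G2_str` = f$g2_strand)
  }))
}

#' Write the per-isoform detail TSV
#' @inheritParams write_summary
#' @export
write_isoforms <- function(fusions, path) {
  fwrite(isoform_table(fusions), path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Write the per-isoform read evidence TSV
#'
#' One row per supporting read per isoform: the full-length parent read and
#' the two pseudo mates derived from it.
#'
#' @inheritParams write_summary
#' @export
write_read_evidence <- function(fusions, path) {
  fusions <- Filter(function(f) !isTRUE(f$empty), fusions)
  rows <- rbindlist(lapply(fusions, function(f) {
    rbindlist(lapply(seq_len(nrow(f$isoforms)), function(i) {
      ids <- f$isoforms$reads[[i]]
      ev <- f$evidence[match(ids, parent_id)]
      data.table(G1 = f$g1, G2 = f$g2, isoform = i,
                 read_id = ev$parent_id, parent_seq = ev$parent_seq,
                 mate1_seq = ev$seq1, mate2_seq = ev$seq2)
    }))
  }))
  if (nrow(rows) == 0L)
    rows <- data.table(G1 = character(), G2 = character(),
                       isoform = integer(), read_id = character(),
                       parent_seq = character(), mate1_seq = character(),
                       mate2_seq = character())
  fwrite(rows, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Write the filtered-read log TSV
#'
#' One row per read pair removed by the cascade, with the stage flag at
#' which it was filtered and the mate hit coordinates known at that point.
#'
#' @param ev an `evidence_set`
#' @param path output path
#' @export
write_filter_log <- function(ev, path) {
  log <- ev[status != "live",
            .(read_id = parent_id, stage = status, g1, g2,
              mate1_transcript = t1, mate1_pos = ts1,
              mate2_transcript = t2, mate2_pos = ts2)]
  fwrite(log, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Write the pipeline read-accounting statistics TSV
#'
#' Raw read counts per fate: rejected at intake, aligned to the normal
#' coding transcriptome at step 1, filtered at each cascade stage, and live
#' in the final candidates. Rows sum to the input FASTQ record count.
#'
#' @param counters named integer vector or list
#' @param path output path
#' @export
write_stats <- function(counters, path) {
  fwrite(data.table(stage = names(counters),
                    n = as.integer(unlist(counters))),
         path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Forward three-frame translation of a nucleotide sequence
#'
#' Standard codon table; stops rendered `*`; codons containing N translate
#' to `X`; trailing partial codons are dropped.
#'
#' @param fused_sequence nucleotide string over A,C,G,T,N
#' @return character vector of the three peptides (frames 0, 1, 2)
#' @export
translate_three_frames <- function(fused_sequence) {
  s <- toupper(fused_sequence)
  if (grepl("[^ACGTN]", s)) stop("sequence must be over A,C,G,T,N")
  vapply(0:2, function(f) {
    sub <- substr(s, f + 1L, nchar(s))
    keep <- nchar(sub) %/% 3L * 3L
    if (keep == 0L) return("")
    as.character(Biostrings::translate(DNAString(substr(sub, 1L, keep)),
                                       if.fuzzy.codon = "X"))
  }, "")
}

#' Breakpoint alignment report for one isoform
#'
#' Lays the supporting full-length parent reads against a window made of the
#' last 30 bases of the G1 exon joined to the first 30 bases of the G2 exon
#' (both in transcript orientation), marking the junction column, and adds a
#' forward three-frame translation of the fused window. Parent reads
#' sequenced from the opposite strand are reverse-complemented so every read
#' is displayed in fusion-transcript orientation.
#'
#' @param fusion a `fusion_candidate`
#' @param isoform isoform row index
#' @param store an `annotation_store`
#' @param flank bases shown on each side of the junction (default 30)
#' @return a `breakpoint_report`
#' @export
breakpoint_alignment <- function(fusion, isoform, store, flank = 30L) {
  iso <- fusion$isoforms[isoform]
  e1 <- exon_sequence(store, iso$g1_exon)
  e2 <- exon_sequence(store, iso$g2_exon)
  left <- substr(e1, max(1L, nchar(e1) - flank + 1L), nchar(e1))
  right <- substr(e2, 1L, min(flank, nchar(e2)))
  window <- paste0(left, right)
  junction_col <- nchar(left)
  ids <- iso$reads[[1L]]
  ev <- fusion$evidence[match(ids, parent_id)]
  reads <- rbindlist(lapply(seq_len(nrow(ev)), function(i) {
    seq <- ev$parent_seq[i]
    if (!is.na(ev$orient[i]) && ev$orient[i] == "reverse")
      seq <- as.character(reverseComplement(DNAString(seq)))
    # bases of the read inside the G1 exon = 5' mate length + its distance
    # to the exon end
    in_g1 <- ev$five_len[i] + ev$d1[i]
    offset <- junction_col - in_g1 + 1L  # 1-based column of the read start
    data.table(read_id = ev$parent_id[i], offset = offset, sequence = seq)
  }))
  # reads must overlap the displayed window
  reads <- reads[offset <= nchar(window) & offset + nchar(sequence) - 1L >= 1L]
  structure(list(g1 = fusion$g1, g2 = fusion$g2,
                 g1_name = fusion$g1_name, g2_name = fusion$g2_name,
                 g1_exon = iso$g1_exon, g2_exon = iso$g2_exon,
                 window = window, junction_col = junction_col,
                 reads = reads,
                 translations = translate_three_frames(window)),
            class = "breakpoint_report")
}

#' @export
print.breakpoint_report <- function(x, ...) {
  cat("Breakpoint alignment ", x$g1_name, " (", x$g1_exon, ") : ",
      x$g2_name, " (", x$g2_exon, ")\n", sep = "")
  w <- nchar(x$window)
  marker <- paste0(strrep(" ", x$junction_col - 1L), "|<- junction")
  cat(x$window, "\n", marker, "\n", sep = "")
  for (i in seq_len(nrow(x$reads))) {
    off <- x$reads$offset[i]
    s <- x$reads$sequence[i]
    if (off < 1L) { s <- substr(s, 2L - off, nchar(s)); off <- 1L }
    cat(strrep(" ", off - 1L), s, "  ", x$reads$read_id[i], "\n", sep = "")
  }
  cat("Three-frame translation:\n")
  for (f in 1:3)
    cat("  frame ", f - 1L, ": ",
        paste(strsplit(x$translations[f], "")[[1L]], collapse = "  "),
        "\n", sep = "")
  invisible(x)
}

#' Render a breakpoint report to a text file
#' @param report a `breakpoint_report`
#' @param path output path
#' @export
write_breakpoint_report <- function(report, path) {
  con <- file(path, "w")
  on.exit(close(con))
  sink(con); on.exit(sink(), add = TRUE, after = FALSE)
  print(report)
  invisible(path)
}
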