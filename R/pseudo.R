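#' Select reads that failed the first-pass coding-transcriptome alignment
#'
#' Reads aligning end-to-end to a normal coding transcript are explained by
#' normal transcription and discarded; the remainder — novel transcripts,
#' poor-quality reads, and reads spanning a fusion junction — continue into
#' pseudo-pair splitting.
#'
#' @param reads the full-length `read_set` given to the first alignment pass
#' @param step1_result the `alignment_result` of that pass
#' @return a `read_set` containing exactly the unaligned reads, input order
#'   preserved
#' @export
select_unaligned <- function(reads, step1_result) {
  missing <- setdiff(reads$read_id, step1_result$reads$read_id)
  if (length(missing))
    stop("read absent from alignment result: ", missing[1L])
  un <- unaligned_ids(step1_result)
  out <- reads[reads$read_id %in% un]
  setattr(out, "class", unique(c("read_set", class(out))))
  out
}

#' Split full-length reads into pseudo paired-end mates
#'
#' Each read of length L yields mate 1 = its first `floor(L * fraction5)`
#' bases and mate 2 = its last `floor(L * fraction3)` bases, with qualities
#' sliced identically. Mate ids append "/1" and "/2" to the parent id so the
#' pair can be reunited after independent alignment. The implied insert gap
#' is `L - n5 - n3` (16 for a 76-mer split into two 30-mers).
#'
#' @param reads a `read_set` of full-length reads
#' @param fraction5,fraction3 fraction of the read length used for the 5'
#'   and 3' mate; each must lie in (0, 0.5]
#' @return a `pseudo_pairs` object: data.table with parent_id, n5, n3,
#'   gap_bp, mate sequences and qualities
#' @export
split_reads <- function(reads, fraction5 = 0.4, fraction3 = fraction5) {
  for (f in c(fraction5, fraction3))
    if (f <= 0 || f > 0.5)
      stop("pseudo-read fraction must be in (0, 0.5], got ", f)
  len <- nchar(reads$sequence)
  n5 <- as.integer(floor(len * fraction5))
  n3 <- as.integer(floor(len * fraction3))
  if (any(n5 < 1L | n3 < 1L))
    stop("read too short for the requested fractions")
  pp <- data.table(
    parent_id = reads$read_id,
    length = len, n5 = n5, n3 = n3, gap_bp = len - n5 - n3,
    seq1 = substr(reads$sequence, 1L, n5),
    qual1 = substr(reads$quality, 1L, n5),
    seq2 = substr(reads$sequence, len - n3 + 1L, len),
    qual2 = substr(reads$quality, len - n3 + 1L, len),
    parent_seq = reads$sequence,
    parent_qual = reads$quality)
  setattr(pp, "class", unique(c("pseudo_pairs", class(pp))))
  pp
}

#' Split one read (scalar convenience wrapper around [split_reads()])
#' @param read single-row `read_set`
#' @inheritParams split_reads
#' @return single-row `pseudo_pairs`
#' @export
split_read <- function(read, fraction5 = 0.4, fraction3 = fraction5) {
  split_reads(read, fraction5, fraction3)
}

#' Interleave pseudo mates as a read set (for alignment or FASTQ export)
#' @param pairs a `pseudo_pairs` object
#' @return a `read_set` with ids `<parent>/1`, `<parent>/2`
#' @export
pseudo_read_set <- function(pairs) {
  rs <- data.table(
    read_id = c(rbind(paste0(pairs$parent_id, "/1"),
                      paste0(pairs$parent_id, "/2"))),
    sequence = c(rbind(pairs$seq1, pairs$seq2)),
    quality = c(rbind(pairs$qual1, pairs$qual2)))
  setattr(rs, "class", unique(c("read_set", class(rs))))
  rs
}

#' Per-position mean base quality of a read set
#'
#' The headless stand-in for the quality line graph: one row per read
#' position with the mean phred score over all reads covering it.
#'
#' @param reads a `read_set`
#' @return data.table(position, n_reads, mean_phred)
#' @export
quality_profile <- function(reads) {
  if (nrow(reads) == 0L)
    return(data.table(position = integer(), n_reads = integer(),
                      mean_phred = numeric()))
  maxw <- max(nchar(reads$quality))
  acc <- numeric(maxw); cnt <- integer(maxw)
  for (s in reads$quality) {
    ph <- utf8ToInt(s) - 33L
    i <- seq_along(ph)
    acc[i] <- acc[i] + ph
    cnt[i] <- cnt[i] + 1L
  }
  data.table(position = seq_len(maxw), n_reads = cnt,
             mean_phred = acc / cnt)
}
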