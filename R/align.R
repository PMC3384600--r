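#' @importFrom Biostrings PDict matchPDict extractAt DNAString BStringSet
#' @importFrom IRanges IRanges
#' @importFrom utils head tail
NULL

# Bowtie-default-like semantics, built in: a read aligns iff it matches a
# transcript end-to-end, ungapped, on either strand, with at most
# `max_mismatch` mismatches in total and at most `max_mismatch` within the
# first `seed_length` bases of the read (the whole read when shorter).
# Matching is exact-band accelerated: any alignment with <= 2 mismatches
# must contain an exact third of the read (pigeonhole), so three trusted-band
# PDict passes enumerate every candidate, which is then verified base by base.

build_ref_index <- function(seqs, spacer = 200L) {
  if (length(seqs) == 0L) stop("empty alignment reference")
  w <- Biostrings::width(seqs)
  gap <- spacer
  off <- cumsum(c(1L, head(w + gap, -1L)))
  parts <- character(2L * length(seqs) - 1L)
  parts[seq(1L, by = 2L, length.out = length(seqs))] <- as.character(seqs)
  if (length(seqs) > 1L)
    parts[seq(2L, by = 2L, length.out = length(seqs) - 1L)] <- strrep("N", gap)
  subject <- DNAString(paste0(parts, collapse = ""))
  list(subject = subject,
       map = data.table(transcript_id = names(seqs),
                        off = off, len = w))
}

seq_to_charmat <- function(x) {
  matrix(unlist(strsplit(x, "", fixed = TRUE), use.names = FALSE),
         ncol = nchar(x[1L]), byrow = TRUE)
}

# candidate (pattern, subject-start) positions for all patterns of equal
# width against the concatenated subject, <= max_mismatch total mismatches
pdict_candidates <- function(pats, subject, max_mismatch) {
  w <- nchar(pats[1L])
  nb <- max_mismatch + 1L
  cuts <- floor(w * seq_len(nb - 1L) / nb)
  starts <- c(1L, cuts + 1L)
  ends <- c(cuts, w)
  dna <- Biostrings::DNAStringSet(pats)
  res <- vector("list", nb)
  for (i in seq_len(nb)) {
    pd <- PDict(dna, tb.start = starts[i], tb.end = ends[i])
    m <- matchPDict(pd, subject, max.mismatch = max_mismatch)
    cnt <- S4Vectors::elementNROWS(m)
    if (sum(cnt) == 0L) { res[[i]] <- data.table(pat = integer(), start = integer()); next }
    ir <- unlist(m)
    res[[i]] <- data.table(pat = rep(seq_along(cnt), cnt),
                           start = IRanges::start(ir))
  }
  unique(rbindlist(res))
}

align_group <- function(seqs, ids, idx, max_mismatch, seed_length) {
  w <- nchar(seqs[1L])
  seed <- min(seed_length, w)
  out <- vector("list", 2L)
  for (s in 1:2) {
    pats <- if (s == 1L) seqs else
      as.character(reverseComplement(Biostrings::DNAStringSet(seqs)))
    ok <- !grepl("[^ACGT]", pats)
    if (!any(ok)) { out[[s]] <- NULL; next }
    cand <- pdict_candidates(pats[ok], idx$subject, max_mismatch)
    if (nrow(cand) == 0L) { out[[s]] <- NULL; next }
    cand[, pat := which(ok)[pat]]
    # clip to hits fully inside one transcript
    m <- idx$map
    cand[, tpos := findInterval(start, m$off)]
    cand <- cand[tpos >= 1L & start + w - 1L <= m$off[tpos] + m$len[tpos] - 1L]
    if (nrow(cand) == 0L) { out[[s]] <- NULL; next }
    # verify mismatch counts (total and within the read's seed)
    hitseq <- as.character(extractAt(idx$subject,
                                     IRanges(cand$start, width = w)))
    pm <- seq_to_charmat(pats[cand$pat])
    hm <- seq_to_charmat(hitseq)
    diff <- pm != hm
    mm <- rowSums(diff)
    seed_cols <- if (s == 1L) seq_len(seed) else (w - seed + 1L):w
    mm_seed <- rowSums(diff[, seed_cols, drop = FALSE])
    keep <- mm <= max_mismatch & mm_seed <= max_mismatch
    cand <- cand[keep]
    if (nrow(cand) == 0L) { out[[s]] <- NULL; next }
    out[[s]] <- data.table(
      read_id = ids[cand$pat],
      transcript_id = m$transcript_id[cand$tpos],
      t_start = cand$start - m$off[cand$tpos] + 1L,
      strand = if (s == 1L) "forward" else "reverse_complement",
      mismatches = as.integer(mm[keep]))
  }
  rbindlist(out)
}

align_builtin <- function(reads, refseqs, mode = c("default", "all"),
                          max_mismatch = 2L, seed_length = 28L) {
  mode <- match.arg(mode)
  if (length(refseqs) == 0L) stop("empty alignment reference")
  idx <- build_ref_index(refseqs, spacer = max(nchar(reads$sequence), 50L) + 10L)
  wid <- nchar(reads$sequence)
  hits <- rbindlist(lapply(split(seq_len(nrow(reads)), wid), function(ii) {
    align_group(reads$sequence[ii], reads$read_id[ii], idx,
                max_mismatch, seed_length)
  }))
  if (nrow(hits) == 0L)
    hits <- data.table(read_id = character(), transcript_id = character(),
                       t_start = integer(), strand = character(),
                       mismatches = integer())
  if (mode == "default" && nrow(hits)) {
    setorder(hits, read_id, mismatches, transcript_id, t_start, strand)
    hits <- hits[, .SD[1L], by = read_id]
  } else {
    setorder(hits, read_id, transcript_id, t_start, strand)
  }
  structure(list(hits = hits,
                 reads = data.table(read_id = reads$read_id, width = wid),
                 mode = mode),
            class = "alignment_result")
}

#' Align reads to a transcriptome reference (single best hit per read)
#'
#' Bowtie-default-like behaviour: each read either aligns end-to-end and
#' ungapped to some transcript, on either strand, with at most 2 mismatches
#' (counted over the whole read and within the first 28-base seed), or is
#' unaligned. When several placements are valid the hit with the fewest
#' mismatches and then the lexicographically smallest
#' (transcript_id, position, strand) is reported, making runs fully
#' deterministic.
#'
#' @param reads a `read_set`
#' @param store an `annotation_store` (or a named DNAStringSet of transcripts)
#' @param reference which reference to align against: `"coding"`,
#'   `"noncoding"` or `"both"` (ignored when `store` is a DNAStringSet)
#' @param max_mismatch maximum mismatches (default 2)
#' @param seed_length seed length in bases (default 28)
#' @return an `alignment_result` with at most one hit per read
#' @export
align_default <- function(reads, store, reference = "coding",
                          max_mismatch = 2L, seed_length = 28L) {
  align_builtin(reads, reference_seqs(store, reference), mode = "default",
                max_mismatch = max_mismatch, seed_length = seed_length)
}

#' Align reads reporting all valid hits
#'
#' Same validity criterion as [align_default()] but every valid placement is
#' reported. Used by the multi-mapping filter to find genes whose transcripts
#' are hit by both pseudo mates.
#'
#' @inheritParams align_default
#' @return an `alignment_result` with zero or more hits per read
#' @export
align_all <- function(reads, store, reference = "coding",
                      max_mismatch = 2L, seed_length = 28L) {
  align_builtin(reads, reference_seqs(store, reference), mode = "all",
                max_mismatch = max_mismatch, seed_length = seed_length)
}

reference_seqs <- function(store, reference = "coding") {
  if (inherits(store, "DNAStringSet")) return(store)
  if (inherits(store, "annotation_store")) {
    ids <- switch(reference,
                  coding = store$coding_ids,
                  noncoding = store$noncoding_ids,
                  both = c(store$coding_ids, store$noncoding_ids),
                  stop("unknown reference selector: ", reference))
    if (length(ids) == 0L) stop("no ", reference, " sequences in the store")
    return(store$sequences[ids])
  }
  stop("store must be an annotation_store or DNAStringSet")
}

#' @export
print.alignment_result <- function(x, ...) {
  n <- nrow(x$reads)
  cat("alignment_result (", x$mode, " mode): ", n, " reads, ",
      nrow(x$hits), " hits, ", n - length(unique(x$hits$read_id)),
      " unaligned\n", sep = "")
  invisible(x)
}

#' Read ids with no alignment hit
#' @param result an `alignment_result`
#' @return character vector in input-read order
#' @export
unaligned_ids <- function(result) {
  setdiff(result$reads$read_id, result$hits$read_id)
}

#' Write an alignment result as SAM
#'
#' One row per read; unaligned reads carry flag 4. Reverse-complement hits
#' carry flag 16. Mismatch counts go to the NM tag. Sequence/quality columns
#' are populated when a matching `read_set` is supplied, else `*`.
#'
#' @param result an `alignment_result`
#' @param path output path
#' @param reference named DNAStringSet or `annotation_store` (for \code{@SQ}
#'   header lines); optional
#' @param reads optional `read_set` to fill SEQ/QUAL
#' @export
write_sam <- function(result, path, reference = NULL, reads = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unsorted", con)
  if (!is.null(reference)) {
    seqs <- if (inherits(reference, "annotation_store"))
      reference_seqs(reference, "both") else reference
    writeLines(sprintf("@SQ\tSN:%s\tLN:%d", names(seqs),
                       Biostrings::width(seqs)), con)
  } else if (nrow(result$hits)) {
    writeLines(sprintf("@SQ\tSN:%s\tLN:0", unique(result$hits$transcript_id)), con)
  }
  h <- result$hits
  rd <- result$reads
  seqof <- function(id) {
    if (is.null(reads)) return(rep("*", length(id)))
    reads$sequence[match(id, reads$read_id)]
  }
  qualof <- function(id) {
    if (is.null(reads)) return(rep("*", length(id)))
    reads$quality[match(id, reads$read_id)]
  }
  lines <- character(nrow(rd))
  hi <- match(rd$read_id, h$read_id)
  for (i in seq_len(nrow(rd))) {
    id <- rd$read_id[i]
    j <- hi[i]
    if (is.na(j)) {
      lines[i] <- paste(id, 4L, "*", 0L, 0L, "*", "*", 0L, 0L,
                        seqof(id), qualof(id), sep = "\t")
    } else {
      rc <- h$strand[j] == "reverse_complement"
      sq <- seqof(id); ql <- qualof(id)
      if (rc && sq != "*") {
        sq <- as.character(reverseComplement(DNAString(sq)))
        ql <- paste(rev(strsplit(ql, "")[[1L]]), collapse = "")
      }
      lines[i] <- paste(id, if (rc) 16L else 0L, h$transcript_id[j],
                        h$t_start[j], 255L, paste0(rd$width[i], "M"),
                        "*", 0L, 0L, sq, ql,
                        paste0("NM:i:", h$mismatches[j]), sep = "\t")
    }
  }
  writeLines(lines, con)
  invisible(path)
}

#' Read a SAM file into an alignment result
#'
#' Accepts output of [write_sam()] or of an external Bowtie-compatible
#' aligner run in ungapped end-to-end mode. Reference names must be known
#' transcript ids when a store is given.
#'
#' @param path SAM file
#' @param store optional `annotation_store` used to validate reference names
#' @return an `alignment_result`
#' @export
read_sam <- function(path, store = NULL) {
  raw <- readLines(path)
  hdr <- grepl("^@", raw)
  sq <- raw[hdr & grepl("^@SQ", raw)]
  refnames <- sub(".*\tSN:([^\t]+).*", "\\1", sq)
  body <- which(!hdr & nzchar(raw))
  ids <- character(length(body)); widths <- integer(length(body))
  hits <- vector("list", length(body))
  for (k in seq_along(body)) {
    ln <- body[k]
    f <- strsplit(raw[ln], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 11L)
      stop("malformed SAM line ", ln, ": fewer than 11 fields")
    flag <- suppressWarnings(as.integer(f[2L]))
    if (is.na(flag)) stop("malformed SAM line ", ln, ": bad FLAG")
    ids[k] <- f[1L]
    widths[k] <- if (f[10L] != "*") nchar(f[10L]) else NA_integer_
    if (bitwAnd(flag, 4L) == 0L) {
      tid <- f[3L]
      if (!is.null(store) && !(tid %in% store$transcripts$transcript_id))
        stop("SAM line ", ln, ": unknown transcript ", tid)
      if (length(refnames) && !(tid %in% refnames))
        stop("SAM line ", ln, ": reference ", tid, " not declared in header")
      nm <- regmatches(raw[ln], regexpr("NM:i:(\\d+)", raw[ln]))
      hits[[k]] <- data.table(
        read_id = f[1L], transcript_id = tid,
        t_start = as.integer(f[4L]),
        strand = if (bitwAnd(flag, 16L)) "reverse_complement" else "forward",
        mismatches = if (length(nm)) as.integer(sub("NM:i:", "", nm)) else 0L)
    }
  }
  ht <- rbindlist(hits)
  if (nrow(ht) == 0L)
    ht <- data.table(read_id = character(), transcript_id = character(),
                     t_start = integer(), strand = character(),
                     mismatches = integer())
  rd <- unique(data.table(read_id = ids, width = widths), by = "read_id")
  mode <- if (anyDuplicated(ht$read_id)) "all" else "default"
  structure(list(hits = ht, reads = rd, mode = mode),
            class = "alignment_result")
}
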