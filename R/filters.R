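# Stage flags recorded when a read pair is removed by the cascade
FILTER_FLAGS <- c("STEP4A_SAME_GENE", "STEP4B_UNALIGNED", "STEP4C_PARALOG",
                  "STEP4D_ANTISENSE", "STEP4E_GEOMETRY", "STEP4F_MULTIMAP",
                  "STEP5B_REPEAT", "STEP5D_MINREADS")

tx_gene <- function(store, transcript_id) {
  store$transcripts$gene_id[match(transcript_id,
                                  store$transcripts$transcript_id)]
}

#' Reunite pseudo mates with their alignment hits
#'
#' Joins the independent mate alignments back onto their parent reads (via
#' the "/1"/"/2" id suffixes) and resolves the gene each mate hit. The
#' orientation of the putative fused transcript is taken from the hit
#' strands: when both mates aligned forward, mate 1 evidences the 5' gene
#' (G1); when both aligned as reverse complements the parent read was
#' sequenced from the opposite strand, so the roles swap and mate 2
#' evidences G1. Strand-inconsistent (mixed) pairs keep the literal mate
#' order and are removed later by the insert-geometry filter.
#'
#' @param pseudo_alignments `alignment_result` for the pseudo mates
#' @param pairs the `pseudo_pairs` the mates came from
#' @param store an `annotation_store`
#' @return an `evidence_set`: one row per parent read, status "live"
#' @export
reunite_and_assign <- function(pseudo_alignments, pairs, store) {
  h <- pseudo_alignments$hits
  allids <- pseudo_alignments$reads$read_id
  bad <- allids[!grepl("/[12]$", allids)]
  if (length(bad))
    stop("pseudo read id without /1 or /2 suffix: ", bad[1L])
  parents <- unique(sub("/[12]$", "", allids))
  orphan <- setdiff(parents, pairs$parent_id)
  if (length(orphan))
    stop("aligned pseudo read with no parent in the pair set: ", orphan[1L])

  ev <- copy(pairs)
  for (m in 1:2) {
    hm <- h[endsWith(read_id, paste0("/", m))]
    hm[, parent_id := sub("/[12]$", "", read_id)]
    idx <- match(ev$parent_id, hm$parent_id)
    ev[, paste0(c("t", "ts", "str", "mm"), m) :=
         .(hm$transcript_id[idx], hm$t_start[idx], hm$strand[idx],
           hm$mismatches[idx])]
  }
  ev[, g_m1 := tx_gene(store, t1)]
  ev[, g_m2 := tx_gene(store, t2)]
  ev[, orient := fifelse(is.na(str1) | is.na(str2), NA_character_,
                  fifelse(str1 == "forward" & str2 == "forward", "forward",
                   fifelse(str1 == "reverse_complement" &
                           str2 == "reverse_complement", "reverse", "mixed")))]
  # canonical 5'-side / 3'-side roles relative to the fused transcript
  rev <- !is.na(ev$orient) & ev$orient == "reverse"
  ev[, `:=`(g1 = g_m1, g2 = g_m2,
            five_t = t1, five_ts = ts1, five_len = n5,
            three_t = t2, three_ts = ts2, three_len = n3)]
  ev[rev, `:=`(g1 = g_m2, g2 = g_m1,
               five_t = t2, five_ts = ts2, five_len = n3,
               three_t = t1, three_ts = ts1, three_len = n5)]
  ev[, status := "live"]
  setattr(ev, "class", unique(c("evidence_set", class(ev))))
  ev
}

#' @export
print.evidence_set <- function(x, ...) {
  cat("evidence_set:", nrow(x), "read pairs;",
      sum(x$status == "live"), "live\n")
  tab <- table(x$status[x$status != "live"])
  for (nm in names(tab)) cat(" ", nm, tab[[nm]], "\n")
  invisible(x)
}

flag_rows <- function(ev, rows, flag) {
  ev[rows & status == "live", status := flag]
  ev
}

#' Step 4A: drop pairs whose mates hit the same gene
#' @param ev an `evidence_set`
#' @return the `evidence_set` with same-gene pairs flagged
#' @export
filter_same_gene <- function(ev) {
  flag_rows(ev, !is.na(ev$g1) & !is.na(ev$g2) & ev$g1 == ev$g2,
            "STEP4A_SAME_GENE")
}

#' Step 4B: drop pairs with an unaligned mate
#' @param ev an `evidence_set`
#' @return the `evidence_set` with half-aligned and unaligned pairs flagged
#' @export
filter_unaligned <- function(ev) {
  flag_rows(ev, is.na(ev$t1) | is.na(ev$t2), "STEP4B_UNALIGNED")
}

#' Step 4C: drop pairs whose genes are annotated paralogs
#'
#' Inert when the store carries no paralog table or `enabled = FALSE`.
#' @param ev an `evidence_set`
#' @param store an `annotation_store`
#' @param enabled set FALSE to disable (command-line toggle)
#' @return the filtered `evidence_set`
#' @export
filter_paralogs <- function(ev, store, enabled = TRUE) {
  if (!enabled || is.null(store$paralogs) || nrow(store$paralogs) == 0L)
    return(ev)
  key <- paste(pmin(ev$g1, ev$g2), pmax(ev$g1, ev$g2))
  pk <- paste(store$paralogs$a, store$paralogs$b)
  flag_rows(ev, !is.na(ev$g1) & !is.na(ev$g2) & key %in% pk, "STEP4C_PARALOG")
}

#' Step 4D: drop pairs of genes overlapping on opposite strands
#'
#' Reads from the antisense strand of a locus where two genes overlap
#' head-to-head can masquerade as fusion evidence; such gene pairs are
#' removed. Inert when `enabled = FALSE`.
#' @inheritParams filter_paralogs
#' @return the filtered `evidence_set`
#' @export
filter_antisense <- function(ev, store, enabled = TRUE) {
  if (!enabled) return(ev)
  live <- ev$status == "live" & !is.na(ev$g1) & !is.na(ev$g2)
  prs <- unique(ev[live, .(g1, g2)])
  if (nrow(prs) == 0L) return(ev)
  prs[, anti := mapply(function(a, b)
    gene_pair_geometry(store, a, b)$spans_overlap_opposite_strand, g1, g2)]
  bad <- prs[anti == TRUE]
  flag_rows(ev, paste(ev$g1, ev$g2) %in% paste(bad$g1, bad$g2),
            "STEP4D_ANTISENSE")
}

#' Step 4E: insert-geometry filter
#'
#' For a genuine junction read, the bases removed between the two pseudo
#' mates must sit entirely between the mates' mapped positions and the
#' canonical boundaries of the exons abutting the putative fusion point:
#' with d1 the transcript-coordinate distance from the 5'-side mate's
#' alignment end to the 3' end of the exon containing it and d2 the distance
#' from the 5' start of the exon containing the 3'-side mate's start to that
#' start, a pair is kept iff d1 + d2 equals the insert gap exactly (a 76-mer
#' split into 30-mers leaves a 16-base gap). Strand-inconsistent pairs
#' cannot describe a single fused transcript and are removed here too.
#'
#' @param ev an `evidence_set`
#' @param store an `annotation_store`
#' @return the filtered `evidence_set`, with junction-side distances and
#'   exons recorded in columns d1, d2, j_exon1, j_exon2
#' @export
filter_insert_geometry <- function(ev, store) {
  if (!("d1" %in% names(ev))) ev[, `:=`(d1 = NA_integer_, d2 = NA_integer_,
                                        j_exon1 = NA_character_,
                                        j_exon2 = NA_character_)]
  live <- which(ev$status == "live" & !is.na(ev$t1) & !is.na(ev$t2))
  for (i in live) {
    if (ev$orient[i] %in% c("forward", "reverse")) {
      e1 <- ev$five_ts[i] + ev$five_len[i] - 1L
      b1 <- distance_to_exon_boundary(store, ev$five_t[i], e1, "3prime")
      b2 <- distance_to_exon_boundary(store, ev$three_t[i], ev$three_ts[i],
                                      "5prime")
      set(ev, i, c("d1", "d2"), list(b1$distance, b2$distance))
      set(ev, i, c("j_exon1", "j_exon2"), list(b1$exon_id, b2$exon_id))
      if (b1$distance + b2$distance != ev$gap_bp[i])
        set(ev, i, "status", "STEP4E_GEOMETRY")
    } else {
      set(ev, i, "status", "STEP4E_GEOMETRY")
    }
  }
  ev
}

#' Step 4F: multi-mapping filter
#'
#' The surviving mates are realigned in all-hits mode against the coding
#' reference and, when present, the non-coding reference. If some gene —
#' in either reference — has transcripts hit by mate 1 and by mate 2 of the
#' same pair, the two mates may simply come from that one gene (shared or
#' duplicated exonic sequence), so the pair is not fusion evidence. By
#' default only the offending read pairs are flagged; with
#' `drop_candidate = TRUE` one ambiguous pair removes every pair of its
#' G1:G2 candidate.
#'
#' @param ev an `evidence_set`
#' @param store an `annotation_store`
#' @param aligner all-hits alignment function, `(read_set, store, reference)
#'   -> alignment_result` (defaults to the built-in [align_all()])
#' @param drop_candidate if TRUE, flag all pairs of a candidate containing
#'   any ambiguous pair
#' @return the filtered `evidence_set`
#' @export
filter_multimap <- function(ev, store, aligner = align_all,
                            drop_candidate = FALSE) {
  live <- which(ev$status == "live")
  if (length(live) == 0L) return(ev)
  rs <- data.table(
    read_id = c(paste0(ev$parent_id[live], "/1"),
                paste0(ev$parent_id[live], "/2")),
    sequence = c(ev$seq1[live], ev$seq2[live]),
    quality = c(ev$qual1[live], ev$qual2[live]))
  setattr(rs, "class", unique(c("read_set", class(rs))))
  refs <- "coding"
  if (length(store$noncoding_ids)) refs <- c(refs, "noncoding")
  hitgenes <- rbindlist(lapply(refs, function(r) {
    res <- aligner(rs, store, reference = r)
    h <- copy(res$hits)
    h[, gene_id := tx_gene(store, transcript_id)]
    h[, .(read_id, gene_id)]
  }))
  hitgenes[, `:=`(parent_id = sub("/[12]$", "", read_id),
                  mate = sub("^.*/", "", read_id))]
  shared <- hitgenes[, .(both = uniqueN(mate) == 2L),
                     by = .(parent_id, gene_id)][both == TRUE]
  ambiguous <- unique(shared$parent_id)
  if (drop_candidate) {
    badpairs <- unique(ev[parent_id %in% ambiguous & status == "live",
                          .(g1, g2)])
    flag_rows(ev, paste(ev$g1, ev$g2) %in% paste(badpairs$g1, badpairs$g2),
              "STEP4F_MULTIMAP")
  } else {
    flag_rows(ev, ev$parent_id %in% ambiguous, "STEP4F_MULTIMAP")
  }
  ev
}

#' Group surviving evidence into candidate gene pairs
#'
#' @param ev an `evidence_set`
#' @return list of `candidate_pair` objects (g1, g2, evidence rows), one per
#'   directed G1:G2 pair with at least one live read pair
#' @export
collect_candidates <- function(ev) {
  live <- ev[status == "live" & !is.na(g1) & !is.na(g2)]
  if (nrow(live) == 0L) return(list())
  keys <- unique(live[, .(g1, g2)])
  setorder(keys, g1, g2)
  lapply(seq_len(nrow(keys)), function(i) {
    structure(list(g1 = keys$g1[i], g2 = keys$g2[i],
                   evidence = live[g1 == keys$g1[i] & g2 == keys$g2[i]]),
              class = "candidate_pair")
  })
}

#' @export
print.candidate_pair <- function(x, ...) {
  cat("candidate_pair ", x$g1, ":", x$g2, " (", nrow(x$evidence),
      " read pairs)\n", sep = "")
  invisible(x)
}

#' Per-stage filter counts for an evidence set
#' @param ev an `evidence_set`
#' @return data.table(stage, n) including a "live" row
#' @export
filter_counts <- function(ev) {
  tab <- table(factor(ev$status, levels = c(FILTER_FLAGS, "live")))
  data.table(stage = names(tab), n = as.integer(tab))
}
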