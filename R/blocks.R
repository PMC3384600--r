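# Step 5: merge genomic read evidence into alignment blocks, drop
# repeat-coincident block combinations, resolve nearest exons, enumerate
# isoforms, apply the minimum-read threshold and categorise candidates.

# union-find over n nodes
uf_new <- function(n) seq_len(n)
uf_find <- function(p, i) { while (p[i] != i) i <- p[i]; i }
uf_union <- function(p, a, b) { ra <- uf_find(p, a); rb <- uf_find(p, b)
  if (ra != rb) p[rb] <- ra; p }

# genomic segments of one mate alignment, one row per exon-bounded piece
mate_segments <- function(store, tid, ts, len) {
  transcript_to_genomic(store, tid, ts, ts + len - 1L)
}

#' Step 5A: build alignment blocks for a candidate
#'
#' Every surviving mate alignment is transposed to genomic coordinates; per
#' gene, reads whose genomic intervals overlap (>= 1 shared base, applied
#' transitively) merge into one alignment block. Distinct blocks on a gene
#' indicate distinct fused exons, i.e. different fusion isoforms.
#'
#' @param candidate a `candidate_pair`
#' @param store an `annotation_store`
#' @return list(g1_blocks=, g2_blocks=, combos=) where the block tables
#'   carry block_id, chromosome, start, end and the combo table maps each
#'   (g1 block, g2 block) combination to its supporting parent reads
#' @export
build_blocks <- function(candidate, store) {
  ev <- candidate$evidence
  side_blocks <- function(which_side) {
    segs <- rbindlist(lapply(seq_len(nrow(ev)), function(i) {
      if (which_side == 1L)
        s <- mate_segments(store, ev$five_t[i], ev$five_ts[i], ev$five_len[i])
      else
        s <- mate_segments(store, ev$three_t[i], ev$three_ts[i], ev$three_len[i])
      s[, parent_id := ev$parent_id[i]]
      s
    }))
    red <- IRanges::reduce(IRanges(segs$genomic_start, segs$genomic_end))
    ol <- IRanges::findOverlaps(IRanges(segs$genomic_start, segs$genomic_end), red)
    segs[, piece := S4Vectors::subjectHits(ol)]
    # a read whose alignment spans an intron links its pieces into one block
    p <- uf_new(length(red))
    for (pid in unique(segs$parent_id)) {
      pcs <- unique(segs$piece[segs$parent_id == pid])
      if (length(pcs) > 1L)
        for (k in 2:length(pcs)) p <- uf_union(p, pcs[1L], pcs[k])
    }
    comp <- vapply(seq_along(p), function(i) uf_find(p, i), 1L)
    segs[, comp := comp[piece]]
    blk <- segs[, .(chromosome = chromosome[1L],
                    start = min(genomic_start), end = max(genomic_end),
                    reads = list(unique(parent_id))), by = comp]
    setorder(blk, start)
    blk[, block_id := seq_len(.N)]
    readmap <- segs[, .(block_id = blk$block_id[match(comp[1L], blk$comp)]),
                    by = parent_id]
    list(blocks = blk[, .(block_id, chromosome, start, end, reads)],
         readmap = readmap)
  }
  s1 <- side_blocks(1L); s2 <- side_blocks(2L)
  combos <- merge(s1$readmap, s2$readmap, by = "parent_id",
                  suffixes = c("_g1", "_g2"))
  combos <- combos[, .(reads = list(parent_id), isoreads = .N),
                   by = .(block_g1 = block_id_g1, block_g2 = block_id_g2)]
  setorder(combos, block_g1, block_g2)
  list(g1_blocks = s1$blocks, g2_blocks = s2$blocks, combos = combos)
}

#' Step 5B: drop block combinations sharing a repeat class
#'
#' When the G1 block and the G2 block of a combination both overlap a repeat
#' interval of the same class, the apparent junction plausibly arises from
#' repeat-mediated mispairing and the combination is removed. Inert when the
#' store carries no repeat annotation or `enabled = FALSE`.
#'
#' @param blocks result of [build_blocks()]
#' @param store an `annotation_store`
#' @param enabled set FALSE to disable (command-line toggle)
#' @return `blocks` with the offending combos removed and their reads listed
#'   in `$repeat_filtered_reads`
#' @export
filter_repeat_blocks <- function(blocks, store, enabled = TRUE) {
  blocks$repeat_filtered_reads <- character()
  if (!enabled || is.null(store$repeats) || nrow(store$repeats) == 0L ||
      nrow(blocks$combos) == 0L)
    return(blocks)
  rep_classes <- function(btab, id) {
    b <- btab[block_id == id]
    unique(store$repeats[chrom == b$chromosome & start <= b$end &
                           end >= b$start, class])
  }
  co <- blocks$combos
  drop <- logical(nrow(co))
  for (i in seq_len(nrow(co))) {
    c1 <- rep_classes(blocks$g1_blocks, co$block_g1[i])
    c2 <- rep_classes(blocks$g2_blocks, co$block_g2[i])
    drop[i] <- length(intersect(c1, c2)) > 0L
  }
  blocks$repeat_filtered_reads <- unique(unlist(co$reads[drop]))
  blocks$combos <- co[!drop]
  # a block may lose all its combinations; keep only referenced blocks
  blocks$g1_blocks <- blocks$g1_blocks[block_id %in% blocks$combos$block_g1]
  blocks$g2_blocks <- blocks$g2_blocks[block_id %in% blocks$combos$block_g2]
  blocks
}

#' Step 5C: resolve the exons closest to a block combination
#'
#' The junction-side extremity of each block (the transcript-orientation 3'
#' edge on G1, 5' edge on G2 — genomic left or right depending on gene
#' strand) is compared against the matching canonical boundary of every exon
#' of the gene; the nearest exon and its distance in bp become the isoform's
#' exon assignment and `expos`. Ties break to the smallest exon id.
#'
#' @param blocks result of [build_blocks()]
#' @param candidate the `candidate_pair` the blocks belong to
#' @param store an `annotation_store`
#' @return data.table of isoforms: block coordinates, exon ids, expos,
#'   strands, isoreads and supporting reads
#' @export
assign_exons <- function(blocks, candidate, store) {
  g1 <- store$genes[.(candidate$g1)]; g2 <- store$genes[.(candidate$g2)]
  nearest <- function(gene, block, side) {
    exns <- unique(store$exons[gene_id == gene$gene_id,
                               .(exon_id, g_start, g_end)])
    if (side == "3prime") {
      extremity <- if (gene$strand == 1L) block$end else block$start
      boundary <- if (gene$strand == 1L) exns$g_end else exns$g_start
    } else {
      extremity <- if (gene$strand == 1L) block$start else block$end
      boundary <- if (gene$strand == 1L) exns$g_start else exns$g_end
    }
    d <- abs(boundary - extremity)
    ord <- order(d, exns$exon_id)
    list(exon_id = exns$exon_id[ord[1L]], expos = as.integer(d[ord[1L]]))
  }
  co <- blocks$combos
  if (nrow(co) == 0L)
    return(data.table(block_g1 = integer(), block_g2 = integer(),
                      g1_block_start = integer(), g1_block_end = integer(),
                      g1_exon = character(), g1_expos = integer(),
                      g2_block_start = integer(), g2_block_end = integer(),
                      g2_exon = character(), g2_expos = integer(),
                      isoreads = integer(), reads = list()))
  iso <- vector("list", nrow(co))
  for (i in seq_len(nrow(co))) {
    b1 <- blocks$g1_blocks[block_id == co$block_g1[i]]
    b2 <- blocks$g2_blocks[block_id == co$block_g2[i]]
    n1 <- nearest(g1, b1, "3prime")
    n2 <- nearest(g2, b2, "5prime")
    iso[[i]] <- data.table(
      block_g1 = co$block_g1[i], block_g2 = co$block_g2[i],
      g1_block_start = b1$start, g1_block_end = b1$end,
      g1_exon = n1$exon_id, g1_expos = n1$expos,
      g2_block_start = b2$start, g2_block_end = b2$end,
      g2_exon = n2$exon_id, g2_expos = n2$expos,
      isoreads = co$isoreads[i], reads = co$reads[i])
  }
  rbindlist(iso)
}

#' Analyse one candidate into a fusion candidate (Steps 5A-5C, 5E)
#'
#' @param candidate a `candidate_pair`
#' @param store an `annotation_store`
#' @param repeat_filter apply the repeat-class block filter (Step 5B)
#' @param readthrough_max maximum span gap (bp) for the potential
#'   read-through category (default 20000)
#' @return a `fusion_candidate`, or NULL when every block combination was
#'   repeat-filtered; reads removed by the repeat filter are listed in
#'   `$repeat_filtered_reads`
#' @export
analyze_candidate <- function(candidate, store, repeat_filter = TRUE,
                              readthrough_max = 20000L) {
  blocks <- build_blocks(candidate, store)
  blocks <- filter_repeat_blocks(blocks, store, enabled = repeat_filter)
  iso <- assign_exons(blocks, candidate, store)
  if (nrow(iso) == 0L) {
    return(structure(list(g1 = candidate$g1, g2 = candidate$g2,
                          empty = TRUE,
                          repeat_filtered_reads = blocks$repeat_filtered_reads),
                     class = "fusion_candidate"))
  }
  g1 <- store$genes[.(candidate$g1)]; g2 <- store$genes[.(candidate$g2)]
  structure(list(
    g1 = candidate$g1, g2 = candidate$g2,
    g1_name = g1$name, g2_name = g2$name,
    g1_chromosome = g1$chrom, g2_chromosome = g2$chrom,
    g1_strand = g1$strand, g2_strand = g2$strand,
    isoforms = iso,
    totalreads = sum(iso$isoreads),
    g1_blocks = nrow(blocks$g1_blocks), g2_blocks = nrow(blocks$g2_blocks),
    categories = categorize_pair(store, candidate$g1, candidate$g2,
                                 readthrough_max),
    repeat_filtered_reads = blocks$repeat_filtered_reads,
    evidence = candidate$evidence,
    empty = FALSE), class = "fusion_candidate")
}

#' @export
print.fusion_candidate <- function(x, ...) {
  if (isTRUE(x$empty)) { cat("fusion_candidate (empty)\n"); return(invisible(x)) }
  cat("fusion_candidate ", x$g1_name, ":", x$g2_name, " — ", x$totalreads,
      " reads, ", nrow(x$isoforms), " isoform(s), ",
      paste(x$categories, collapse = ","), "\n", sep = "")
  invisible(x)
}

#' Step 5E: categorise a gene pair
#'
#' Different chromosomes give INTERCHROMOSOMAL. Same chromosome gives
#' INTRACHROMOSOMAL, plus POTENTIAL_READTHROUGH when the genes share a
#' strand and their spans lie at most `readthrough_max` bp apart, plus
#' INVERSION when the strands differ.
#'
#' @param store an `annotation_store`
#' @param g1,g2 gene ids
#' @param readthrough_max read-through distance cutoff in bp
#' @return character vector of categories
#' @export
categorize_pair <- function(store, g1, g2, readthrough_max = 20000L) {
  geo <- gene_pair_geometry(store, g1, g2)
  if (!geo$same_chromosome) return("INTERCHROMOSOMAL")
  out <- character()
  if (geo$same_strand && !is.na(geo$gap_bp) && geo$gap_bp <= readthrough_max)
    out <- c(out, "POTENTIAL_READTHROUGH")
  if (!geo$same_strand) out <- c(out, "INVERSION")
  c(out, "INTRACHROMOSOMAL")
}

#' Step 5D: minimum evidence threshold
#'
#' Drops fusion candidates evidenced by fewer than `min_reads` surviving
#' read pairs.
#'
#' @param fusions list of `fusion_candidate`
#' @param min_reads minimum total supporting read pairs
#' @return list(kept=, dropped=) of `fusion_candidate` lists
#' @export
apply_min_reads <- function(fusions, min_reads = 1L) {
  nonempty <- Filter(function(f) !isTRUE(f$empty), fusions)
  keep <- vapply(nonempty, function(f) f$totalreads >= min_reads, TRUE)
  list(kept = nonempty[keep], dropped = nonempty[!keep])
}
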