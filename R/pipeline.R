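#' Pipeline configuration
#'
#' @param fastq path(s) to the input FASTQ; two paths switch on paired-end
#'   mode (each mate file treated as a separate single-end pool)
#' @param coding_fasta,noncoding_fasta,annotation_gtf,paralog_tsv,repeat_bed
#'   reference flat files (see [load_reference()]); alternatively pass a
#'   prebuilt store via `store`
#' @param store optional prebuilt `annotation_store` (overrides the file
#'   arguments)
#' @param fraction5,fraction3 pseudo-read fractions in (0, 0.5] (default 0.4)
#' @param min_reads minimum pseudo read pairs evidencing a reported
#'   candidate (default 1)
#' @param readthrough_max read-through category distance cutoff in bp
#' @param paralog_filter,antisense_filter,repeat_filter stage toggles
#' @param multimap_drop_candidate if TRUE one ambiguous read removes its
#'   whole candidate at the multi-mapping stage (default: only the read)
#' @param min_read_length full-length reads shorter than this are rejected
#' @param max_mismatch,seed_length aligner parameters
#' @param out_dir output directory for report files (NULL: no files written)
#' @param seed random seed (the pipeline itself is deterministic; recorded
#'   for provenance)
#' @return a `pipeline_config`
#' @export
pipeline_config <- function(fastq, coding_fasta = NULL, noncoding_fasta = NULL,
                            annotation_gtf = NULL, paralog_tsv = NULL,
                            repeat_bed = NULL, store = NULL,
                            fraction5 = 0.4, fraction3 = fraction5,
                            min_reads = 1L, readthrough_max = 20000L,
                            paralog_filter = TRUE, antisense_filter = TRUE,
                            repeat_filter = TRUE,
                            multimap_drop_candidate = FALSE,
                            min_read_length = 50L, max_mismatch = 2L,
                            seed_length = 28L, out_dir = NULL, seed = 1L) {
  stopifnot(fraction5 > 0, fraction5 <= 0.5, fraction3 > 0, fraction3 <= 0.5,
            min_reads >= 1L)
  structure(as.list(environment()), class = "pipeline_config")
}

pipeline_store <- function(config) {
  if (!is.null(config$store)) return(config$store)
  load_reference(config$coding_fasta, config$noncoding_fasta,
                 config$annotation_gtf, config$paralog_tsv,
                 config$repeat_bed)
}

#' Run the full fusion-discovery pipeline
#'
#' Executes the five analysis steps in order: (1) align full-length reads
#' to the coding reference and keep the non-matching ones, (2) split them
#' into pseudo paired-end mates (and profile base qualities), (3) align the
#' mates independently, (4) reunite mates and run the false-positive filter
#' cascade, (5) merge evidence into alignment blocks, resolve exons and
#' isoforms, apply the minimum-read threshold and categorise candidates.
#' When `out_dir` is set the summary, isoform, evidence, breakpoint,
#' filter-log, statistics and quality-profile files are written there.
#'
#' @param config a `pipeline_config`
#' @return a `pipeline_result`: list with the kept `fusions`, the
#'   `summary` and `isoforms` tables, the full `evidence` set, per-stage
#'   `stats` and the loaded `store`
#' @export
run_pipeline <- function(config) {
  set.seed(config$seed)
  store <- pipeline_store(config)
  if (length(config$fastq) > 1L) return(run_pe(config, store))

  reads <- read_fastq(config$fastq)
  n_input <- nrow(reads)
  reads <- enforce_min_length(reads, config$min_read_length)
  n_short <- attr(reads, "n_rejected")

  step1 <- align_default(reads, store, "coding",
                         max_mismatch = config$max_mismatch,
                         seed_length = config$seed_length)
  unal <- select_unaligned(reads, step1)
  n_aligned <- nrow(reads) - nrow(unal)

  qp <- quality_profile(reads)
  pairs <- split_reads(unal, config$fraction5, config$fraction3)
  mates <- pseudo_read_set(pairs)
  step3 <- align_default(mates, store, "coding",
                         max_mismatch = config$max_mismatch,
                         seed_length = config$seed_length)

  ev <- reunite_and_assign(step3, pairs, store)
  ev <- filter_same_gene(ev)
  ev <- filter_unaligned(ev)
  ev <- filter_paralogs(ev, store, enabled = config$paralog_filter)
  ev <- filter_antisense(ev, store, enabled = config$antisense_filter)
  ev <- filter_insert_geometry(ev, store)
  ev <- filter_multimap(ev, store,
                        drop_candidate = config$multimap_drop_candidate)
  candidates <- collect_candidates(ev)

  fusions <- lapply(candidates, analyze_candidate, store = store,
                    repeat_filter = config$repeat_filter,
                    readthrough_max = config$readthrough_max)
  # reads lost to the repeat block filter
  rep_reads <- unlist(lapply(fusions, `[[`, "repeat_filtered_reads"))
  if (length(rep_reads))
    ev[parent_id %in% rep_reads & status == "live", status := "STEP5B_REPEAT"]
  thr <- apply_min_reads(fusions, config$min_reads)
  for (f in thr$dropped)
    ev[parent_id %in% unlist(f$isoforms$reads) & status == "live",
       status := "STEP5D_MINREADS"]
  kept <- thr$kept

  stats <- c(list(input_reads = n_input, rejected_short = n_short,
                  aligned_step1 = n_aligned),
             setNames(as.list(filter_counts(ev)$n), filter_counts(ev)$stage))
  res <- structure(list(fusions = kept, summary = summary_table(kept),
                        isoforms = isoform_table(kept), evidence = ev,
                        quality_profile = qp, stats = stats, store = store,
                        config = config), class = "pipeline_result")
  if (!is.null(config$out_dir)) write_outputs(res, config$out_dir)
  res
}

write_outputs <- function(res, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_summary(res$fusions, file.path(dir, "summary.tsv"))
  write_isoforms(res$fusions, file.path(dir, "isoforms.tsv"))
  write_read_evidence(res$fusions, file.path(dir, "read_evidence.tsv"))
  write_filter_log(res$evidence, file.path(dir, "filter_log.tsv"))
  write_stats(res$stats, file.path(dir, "stats.tsv"))
  fwrite(res$quality_profile, file.path(dir, "quality_profile.tsv"),
         sep = "\t")
  # one breakpoint report per isoform of every kept candidate
  bp <- file.path(dir, "breakpoints.txt")
  if (file.exists(bp)) unlink(bp)
  con <- file(bp, "w"); sink(con)
  for (f in res$fusions)
    for (i in seq_len(nrow(f$isoforms))) {
      print(breakpoint_alignment(f, i, res$store)); cat("\n")
    }
  sink(); close(con)
  invisible(dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("pipeline_result:", length(x$fusions), "fusion candidate(s)\n")
  if (nrow(x$summary)) print(x$summary)
  invisible(x)
}

#' Run the pipeline on paired-end data
#'
#' Each mate file is treated as an independent single-end pool: the two
#' FASTQs are concatenated with original mate suffixes ("/1", "/2")
#' rewritten to "_m1"/"_m2" so that the pseudo-mate suffixes added later
#' stay unambiguous, then the single-end pipeline runs unchanged.
#'
#' @param config a `pipeline_config` whose `fastq` holds two paths
#' @param store optional preloaded `annotation_store`
#' @return a `pipeline_result`
#' @export
run_pe <- function(config, store = NULL) {
  stopifnot(length(config$fastq) == 2L)
  r1 <- read_fastq(config$fastq[1L])
  r2 <- read_fastq(config$fastq[2L])
  fold <- function(r, tag) {
    r$read_id <- paste0(sub("/[12]$", "", r$read_id), tag)
    r
  }
  pooled <- rbind(fold(r1, "_m1"), fold(r2, "_m2"))
  setattr(pooled, "class", unique(c("read_set", class(pooled))))
  tmp <- tempfile(fileext = ".fastq")
  write_fastq(pooled, tmp)
  cfg <- config
  cfg$fastq <- tmp
  on.exit(unlink(tmp))
  if (!is.null(store)) cfg$store <- store
  run_pipeline(cfg)
}
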