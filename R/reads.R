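#' Read a FASTQ file into a read set
#'
#' @param path FASTQ file (uncompressed or gzipped)
#' @return a `read_set`: data.table with columns read_id, sequence, quality
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  ids <- sub("\\s.*$", "", names(x))
  rs <- data.table(read_id = ids,
                   sequence = as.character(x),
                   quality = as.character(S4Vectors::mcols(x)$qualities))
  setattr(rs, "class", c("read_set", class(rs)))
  rs
}

#' Write a read set as FASTQ
#'
#' @param reads a `read_set` (data.table with read_id, sequence, quality)
#' @param path output path
#' @export
write_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(reads$sequence)
  names(x) <- reads$read_id
  q <- Biostrings::BStringSet(reads$quality)
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = q)
  invisible(path)
}

as_read_set <- function(read_id, sequence, quality = NULL) {
  if (is.null(quality)) quality <- strrep("I", nchar(sequence))
  rs <- data.table(read_id = read_id, sequence = sequence, quality = quality)
  setattr(rs, "class", c("read_set", class(rs)))
  rs
}

#' Drop reads shorter than a minimum length
#'
#' Full-length input reads below the minimum (default 50 nt, the shortest
#' read the pseudo-pair strategy is designed for) are rejected at intake
#' with a counted warning rather than trimmed.
#'
#' @param reads a `read_set`
#' @param min_length minimum read length in nt
#' @return the filtered `read_set`; the number dropped is available as
#'   `attr(, "n_rejected")`
#' @export
enforce_min_length <- function(reads, min_length = 50L) {
  n <- nchar(reads$sequence)
  bad <- n < min_length
  if (any(bad))
    warning(sum(bad), " read(s) shorter than ", min_length, " nt rejected")
  out <- reads[!bad]
  setattr(out, "class", unique(c("read_set", class(out))))
  setattr(out, "n_rejected", sum(bad))
  out
}
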