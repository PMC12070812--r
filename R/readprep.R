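#' Read and write FASTQ
#'
#' Minimal 4-line FASTQ IO for small-RNA libraries. Quality strings are
#' written as constant 'I'. Gzipped files are handled transparently on
#' read and written when the path ends in `.gz`.
#'
#' @param path FASTQ file path.
#' @return `read_fastq`: data.table with `read_id`, `sequence`.
#' @rdname fastq_io
#' @export
read_fastq <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  lines <- readLines(con)
  if (length(lines) %% 4L != 0L)
    stop("malformed FASTQ: line count not a multiple of 4", call. = FALSE)
  ids <- sub("^@", "", sub("\\s.*$", "", lines[seq(1L, length(lines), 4L)]))
  data.table::data.table(read_id = ids,
                         sequence = toupper(lines[seq(2L, length(lines), 4L)]))
}

#' @param reads data.frame with `read_id` and `sequence` columns.
#' @rdname fastq_io
#' @export
write_fastq <- function(reads, path) {
  qual <- strrep("I", nchar(reads$sequence))
  out <- rbind(paste0("@", reads$read_id), reads$sequence, "+", qual)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  writeLines(c(out), con)
  invisible(path)
}

#' Trim 3' ends and collapse reads to unique species
#'
#' Small-RNA reads carry 3' adaptor sequence past the insert. `fixed3p`
#' mode removes a fixed number of bases (default 30) from the 3' end;
#' `adapter` mode removes everything from the first occurrence of the
#' first 8 nt of the adapter sequence onwards (reads without a match are
#' kept whole). Identical post-trim sequences are collapsed into one read
#' species with their occurrence counts summed; reads shorter than
#' `min_len` after trimming are dropped (a message reports how many).
#'
#' @param reads data.frame with a `sequence` column (e.g. from
#'   [read_fastq()]) or a character vector of read sequences.
#' @param mode `"fixed3p"` or `"adapter"`.
#' @param trim_len bases removed from the 3' end in `fixed3p` mode.
#' @param adapter_seq adapter sequence (>= 8 nt) for `adapter` mode.
#' @param min_len minimum post-trim length kept.
#' @return a `read_species` data.table: `species_id`, `sequence`, `count`,
#'   ordered by decreasing count.
#' @export
trim_and_collapse <- function(reads, mode = c("fixed3p", "adapter"),
                              trim_len = 30L, adapter_seq = NULL,
                              min_len = 15L) {
  mode <- match.arg(mode)
  seqs <- if (is.character(reads)) reads else reads$sequence
  if (!length(seqs)) {
    warning("no input reads")
    return(collapse_species(character(0)))
  }
  seqs <- toupper(seqs)
  if (mode == "fixed3p") {
    trimmed <- substr(seqs, 1L, pmax(0L, nchar(seqs) - as.integer(trim_len)))
  } else {
    if (is.null(adapter_seq) || nchar(adapter_seq) < 8L)
      stop("adapter mode requires 'adapter_seq' of >= 8 nt", call. = FALSE)
    probe <- toupper(substr(adapter_seq, 1L, 8L))
    pos <- regexpr(probe, seqs, fixed = TRUE)
    trimmed <- ifelse(pos > 0L, substr(seqs, 1L, pos - 1L), seqs)
  }
  short <- nchar(trimmed) < min_len
  if (any(short))
    message(sprintf("trim_and_collapse: dropped %d read(s) shorter than %d nt",
                    sum(short), min_len))
  collapse_species(trimmed[!short])
}

#' Collapse sequences into counted read species
#'
#' @param seqs character vector of (already trimmed) read sequences.
#' @return a `read_species` data.table.
#' @export
collapse_species <- function(seqs) {
  dt <- data.table::data.table(sequence = as.character(seqs))
  sp <- dt[, .(count = .N), by = sequence]
  data.table::setorder(sp, -count, sequence)
  sp[, species_id := sprintf("sp%07d", .I)]
  data.table::setcolorder(sp, c("species_id", "sequence", "count"))
  data.table::setattr(sp, "class", c("read_species", class(sp)))
  sp[]
}

#' Filter read species by length and build a size histogram
#'
#' piRNAs populate the 23-28 nt window; the histogram reports the
#' count-weighted size distribution over the conventional 19-35 nt
#' reporting range.
#'
#' @param species a `read_species` table.
#' @param lo,hi inclusive length window kept.
#' @param hist_range range over which the histogram is tabulated.
#' @return list with `species` (kept subset) and `histogram` (data.frame:
#'   `length`, `count` = summed read counts at that length).
#' @export
size_filter <- function(species, lo = 23L, hi = 28L, hist_range = c(19L, 35L)) {
  if (lo > hi) stop("lo must be <= hi", call. = FALSE)
  len <- nchar(species$sequence)
  hl <- seq.int(hist_range[1], hist_range[2])
  counts <- vapply(hl, function(L) sum(species$count[len == L]), numeric(1))
  kept <- species[len >= lo & len <= hi]
  list(species = kept,
       histogram = data.frame(length = hl, count = counts))
}
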