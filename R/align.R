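#' Align read species to a consensus TE panel by exact matching
#'
#' Reports every perfect full-length occurrence of each species on the
#' forward strand of every panel sequence, and of its reverse complement
#' (recorded as strand `-`). This mirrors a short-read aligner run with
#' non-perfect mappings excluded, which is how TE-mapped piRNAs are
#' quantified; species containing `N` never match. Multi-mapping reads are
#' apportioned: `n_locations` is the total number of perfect-match
#' locations of the species across the panel (both strands) and each
#' location receives `weight = count / n_locations`, so summing a species'
#' weights over its locations returns its count exactly.
#'
#' Matching is done per read length by joining the species sequences (and
#' their reverse complements) against the table of all panel substrings of
#' that length.
#'
#' @param species a `read_species` table ([trim_and_collapse()]).
#' @param panel a [te_panel()].
#' @param max_mismatches must be 0; mismatch-tolerant alignment is out of
#'   scope (use the SAM import path with an external aligner instead).
#' @param min_len minimum species length aligned (shorter species are
#'   reported unaligned).
#' @return a `weighted_alignments` data.table with columns `species_id`,
#'   `sequence`, `count`, `ref_id`, `strand`, `start`, `end` (0-based
#'   half-open), `n_locations`, `weight`; attributes `ref_lengths` (named
#'   integer) and `unaligned` (species_ids with zero locations).
#' @export
align_species <- function(species, panel, max_mismatches = 0L, min_len = 15L) {
  stopifnot(inherits(panel, "te_panel"))
  if (max_mismatches != 0L)
    stop("only exact matching (max_mismatches = 0) is supported", call. = FALSE)
  sp <- data.table::as.data.table(species)[, .(species_id, sequence, count)]
  sp[, len := nchar(sequence)]
  eligible <- sp[len >= min_len]
  hits <- list()
  for (L in sort(unique(eligible$len))) {
    keep <- panel$length >= L
    if (!any(keep)) next
    subs <- lapply(which(keep), function(r) {
      st <- seq_len(panel$length[r] - L + 1L)
      data.table::data.table(
        seq = substring(panel$sequence[r], st, st + L - 1L),
        ref_id = panel$id[r], start = st - 1L)
    })
    subdt <- data.table::rbindlist(subs)
    spL <- eligible[len == L]
    spL[, rc := revcomp(sequence)]
    fwd <- merge(subdt, spL[, .(seq = sequence, species_id, sequence, count)],
                 by = "seq", allow.cartesian = TRUE)
    rev <- merge(subdt, spL[, .(seq = rc, species_id, sequence, count)],
                 by = "seq", allow.cartesian = TRUE)
    fwd[, strand := "+"]
    rev[, strand := "-"]
    both <- data.table::rbindlist(list(fwd, rev))
    if (nrow(both)) {
      both[, `:=`(end = start + L, seq = NULL)]
      hits[[as.character(L)]] <- both
    }
  }
  aln <- data.table::rbindlist(hits)
  if (!nrow(aln))
    aln <- data.table::data.table(species_id = character(), sequence = character(),
                                  count = integer(), ref_id = character(),
                                  strand = character(), start = integer(),
                                  end = integer())
  aln[, n_locations := .N, by = species_id]
  aln[, weight := count / n_locations]
  data.table::setcolorder(aln, c("species_id", "sequence", "count", "ref_id",
                                 "strand", "start", "end", "n_locations", "weight"))
  data.table::setorder(aln, species_id, ref_id, strand, start)
  data.table::setattr(aln, "ref_lengths",
                      stats::setNames(as.integer(panel$length), panel$id))
  data.table::setattr(aln, "unaligned", setdiff(sp$species_id, aln$species_id))
  data.table::setattr(aln, "class", c("weighted_alignments", class(aln)))
  aln[]
}

#' Import alignments from a SAM file
#'
#' Alternative entry point for users who align with an external tool.
#' Primary and secondary alignments of a species are both interpreted as
#' mapping locations for apportioning; unmapped records are skipped. Only
#' pure-match CIGARs (`<n>M`) are accepted, consistent with the
#' perfect-mapping filter of the pipeline.
#'
#' @param path SAM file (text).
#' @param panel a [te_panel()] supplying reference lengths.
#' @param counts optional named vector of read-species counts keyed by
#'   query name; defaults to 1 per species.
#' @return a `weighted_alignments` table as from [align_species()].
#' @export
import_alignments_sam <- function(path, panel, counts = NULL) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  if (!length(lines)) stop("SAM file contains no alignment records", call. = FALSE)
  f <- data.table::tstrsplit(lines, "\t", fixed = TRUE, keep = 1:10)
  dt <- data.table::data.table(species_id = f[[1]], flag = as.integer(f[[2]]),
                               ref_id = f[[3]], pos = as.integer(f[[4]]),
                               cigar = f[[6]], seq = f[[10]])
  dt <- dt[bitwAnd(flag, 4L) == 0L]
  bad <- !grepl("^[0-9]+M$", dt$cigar)
  if (any(bad)) {
    message(sprintf("import_alignments_sam: skipping %d non-perfect record(s)",
                    sum(bad)))
    dt <- dt[!bad]
  }
  dt[, len := as.integer(sub("M$", "", cigar))]
  dt[, strand := ifelse(bitwAnd(flag, 16L) > 0L, "-", "+")]
  dt[, start := pos - 1L]
  dt[, end := start + len]
  # recover as-sequenced orientation; secondary records may carry SEQ "*"
  dt[, sequence := ifelse(seq == "*", NA_character_,
                          ifelse(strand == "-", revcomp_or_na(seq), seq))]
  dt[, sequence := sequence[which(!is.na(sequence))[1]], by = species_id]
  cnt <- if (is.null(counts)) stats::setNames(rep(1L, length(unique(dt$species_id))),
                                              unique(dt$species_id)) else counts
  dt[, count := cnt[species_id]]
  dt[, n_locations := .N, by = species_id]
  dt[, weight := count / n_locations]
  aln <- dt[, .(species_id, sequence, count, ref_id, strand, start, end,
                n_locations, weight)]
  data.table::setattr(aln, "ref_lengths",
                      stats::setNames(as.integer(panel$length), panel$id))
  data.table::setattr(aln, "unaligned", character(0))
  data.table::setattr(aln, "class", c("weighted_alignments", class(aln)))
  aln[]
}

revcomp_or_na <- function(x) {
  out <- rep(NA_character_, length(x))
  ok <- !is.na(x) & x != "*"
  if (any(ok)) out[ok] <- revcomp(x[ok])
  out
}

#' Read a BED file of reference regions
#'
#' BED intervals are 0-based half-open; the first three columns are
#' required, the fourth (name) defaults to `chrom:start-end`.
#'
#' @param path BED file.
#' @return data.frame with `ref_id`, `start`, `end`, `name`.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, 1L) < 3L)
  if (length(bad))
    stop(sprintf("malformed BED line %d: fewer than 3 fields", bad[1]), call. = FALSE)
  start <- suppressWarnings(as.integer(vapply(parts, `[[`, "", 2L)))
  end <- suppressWarnings(as.integer(vapply(parts, `[[`, "", 3L)))
  if (anyNA(start) || anyNA(end))
    stop(sprintf("malformed BED line %d: non-integer coordinates",
                 which(is.na(start) | is.na(end))[1]), call. = FALSE)
  nm <- vapply(seq_along(parts), function(i)
    if (length(parts[[i]]) >= 4L) parts[[i]][4L]
    else sprintf("%s:%d-%d", parts[[i]][1L], start[i], end[i]), "")
  data.frame(ref_id = vapply(parts, `[[`, "", 1L), start = start, end = end,
             name = nm, stringsAsFactors = FALSE)
}

#' Subset alignments by annotated regions
#'
#' An alignment belongs to a region iff its interval overlaps the region
#' by at least 1 nt (half-open intervals); an alignment spanning several
#' regions is assigned to each of them.
#'
#' @param alignments a `weighted_alignments` table.
#' @param regions data.frame from [read_bed()] or with the same columns.
#' @return named list of `weighted_alignments` subsets, one per region.
#' @export
assign_to_regions <- function(alignments, regions) {
  missing_ref <- setdiff(regions$ref_id, names(attr(alignments, "ref_lengths")))
  if (length(missing_ref))
    stop("region reference(s) not in panel: ", paste(missing_ref, collapse = ", "),
         call. = FALSE)
  out <- lapply(seq_len(nrow(regions)), function(i) {
    r <- regions[i, ]
    sub <- alignments[ref_id == r$ref_id & start < r$end & end > r$start]
    for (a in c("ref_lengths", "unaligned"))
      data.table::setattr(sub, a, attr(alignments, a))
    data.table::setattr(sub, "class", class(alignments))
    sub
  })
  stats::setNames(out, regions$name)
}

#' Build per-reference, per-strand 5'/3' end profiles
#'
#' Aggregates apportioned alignment weight by end position. Positions are
#' reported in transcript orientation: on the `+` strand 5' = start and
#' 3' = end - 1; on the `-` strand the reference-coordinate ends
#' (5' = end - 1, 3' = start) are transformed by `p -> L - 1 - p` so that
#' within-strand distances read left-to-right along the piRNA.
#'
#' @param alignments a `weighted_alignments` table.
#' @return an `end_profiles` data.table with columns `ref_id`, `strand`,
#'   `end` (`"p5"`/`"p3"`), `pos`, `weight`; attribute `ref_lengths`.
#' @export
build_end_profiles <- function(alignments) {
  rl <- attr(alignments, "ref_lengths")
  dt <- data.table::as.data.table(alignments)
  dt[, L := rl[ref_id]]
  p5 <- data.table::fifelse(dt$strand == "+", dt$start, dt$L - dt$end)
  p3 <- data.table::fifelse(dt$strand == "+", dt$end - 1L, dt$L - 1L - dt$start)
  long <- data.table::rbindlist(list(
    data.table::data.table(ref_id = dt$ref_id, strand = dt$strand,
                           end = "p5", pos = p5, weight = dt$weight),
    data.table::data.table(ref_id = dt$ref_id, strand = dt$strand,
                           end = "p3", pos = p3, weight = dt$weight)))
  prof <- long[, .(weight = sum(weight)), by = .(ref_id, strand, end, pos)]
  data.table::setorder(prof, ref_id, strand, end, pos)
  data.table::setattr(prof, "ref_lengths", rl)
  data.table::setattr(prof, "class", c("end_profiles", class(prof)))
  prof[]
}
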