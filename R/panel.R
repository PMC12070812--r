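#' Consensus transposon panel
#'
#' A `te_panel` is the mapping reference of the pipeline: a set of named
#' consensus transposable-element (TE) sequences, each with a length and a
#' tissue-compartment label (`germline`, `somatic` or `unknown`).
#'
#' @param id character vector of unique TE identifiers.
#' @param sequence character vector of DNA sequences (ACGT).
#' @param compartment compartment label per TE, recycled if length 1.
#' @return a `te_panel`: a data.frame with columns `id`, `sequence`,
#'   `length`, `compartment`.
#' @export
te_panel <- function(id, sequence, compartment = "unknown") {
  if (length(id) != length(sequence))
    stop("'id' and 'sequence' must have the same length", call. = FALSE)
  if (anyDuplicated(id)) stop("TE ids must be unique", call. = FALSE)
  compartment <- rep_len(as.character(compartment), length(id))
  bad <- !compartment %in% c("germline", "somatic", "unknown")
  if (any(bad)) stop("compartment must be germline/somatic/unknown", call. = FALSE)
  out <- data.frame(id = as.character(id), sequence = toupper(sequence),
                    length = nchar(sequence), compartment = compartment,
                    stringsAsFactors = FALSE)
  class(out) <- c("te_panel", "data.frame")
  out
}

#' @export
print.te_panel <- function(x, ...) {
  cat(sprintf("te_panel: %d consensus sequences, %d nt total (%d-%d nt)\n",
              nrow(x), sum(x$length), min(x$length), max(x$length)))
  tab <- table(x$compartment)
  cat("  compartments:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' Read / write a consensus TE panel as FASTA
#'
#' Compartment labels may be carried in the FASTA description after the id
#' (e.g. `>gypsy germline`); missing labels default to `unknown`.
#'
#' @param path FASTA file path.
#' @rdname te_panel_io
#' @export
read_te_panel <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  nm <- names(ss)
  id <- sub("\\s.*$", "", nm)
  desc <- ifelse(grepl("\\s", nm), sub("^\\S+\\s+", "", nm), "unknown")
  desc[!desc %in% c("germline", "somatic")] <- "unknown"
  te_panel(id, as.character(ss), desc)
}

#' @param panel a `te_panel`.
#' @rdname te_panel_io
#' @export
write_te_panel <- function(panel, path) {
  ss <- Biostrings::DNAStringSet(panel$sequence)
  names(ss) <- paste(panel$id, panel$compartment)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Specification for a synthetic consensus TE panel
#'
#' @param n_te number of TE consensus sequences.
#' @param length_range `c(min, max)` sequence length in nt; lengths are
#'   drawn log-uniformly within the range.
#' @param repeat_fraction fraction of TE pairs that share one copied 60-nt
#'   segment, planting multi-mapping read locations.
#' @param seed integer RNG seed.
#' @return a validated `te_panel_spec` list.
#' @export
te_panel_spec <- function(n_te, length_range = c(500, 5000),
                          repeat_fraction = 0, seed = 1L) {
  n_te <- .check_count(n_te, "n_te")
  if (length(length_range) != 2L || length_range[1] < 100 ||
      length_range[1] > length_range[2])
    stop("length_range must be c(min, max) with 100 <= min <= max", call. = FALSE)
  .check_fraction(repeat_fraction, "repeat_fraction")
  structure(list(n_te = n_te, length_range = as.integer(length_range),
                 repeat_fraction = repeat_fraction, seed = as.integer(seed)),
            class = "te_panel_spec")
}

#' Generate a synthetic consensus TE panel
#'
#' Sequences are i.i.d. uniform ACGT with log-uniform lengths. A
#' `repeat_fraction` of disjoint TE pairs share one exact 60-nt segment
#' copied between them, so reads drawn from that segment map to two
#' locations (multi-mapping bait for the apportioning logic). Deterministic
#' given the spec's seed.
#'
#' @param spec a [te_panel_spec()].
#' @return a [te_panel()].
#' @export
generate_te_panel <- function(spec) {
  stopifnot(inherits(spec, "te_panel_spec"))
  with_seed(spec$seed, {
    lr <- spec$length_range
    lens <- round(exp(runif(spec$n_te, log(lr[1]), log(lr[2]))))
    lens <- pmin(pmax(lens, lr[1]), lr[2])
    seqs <- vapply(lens, function(L)
      paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""),
      character(1))
    n_pairs <- floor(spec$repeat_fraction * (spec$n_te %/% 2L))
    seg_len <- 60L
    if (n_pairs > 0) {
      for (k in seq_len(n_pairs)) {
        i <- 2L * k - 1L; j <- 2L * k
        from <- sample.int(lens[i] - seg_len + 1L, 1L)
        seg <- substr(seqs[i], from, from + seg_len - 1L)
        at <- sample.int(lens[j] - seg_len + 1L, 1L)
        substr(seqs[j], at, at + seg_len - 1L) <- seg
      }
    }
    comp <- rep(c("germline", "somatic"), length.out = spec$n_te)
    te_panel(sprintf("TE%03d", seq_len(spec$n_te)), seqs, comp)
  })
}
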