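#' TE count table
#'
#' Container for per-TE (optionally per-strand) counts across samples,
#' with the reference lengths needed for pkb/rpkm layers and a
#' sample-to-genotype map. Feature ids are TE ids, or `TE:strand` when
#' quantified per strand.
#'
#' @param counts numeric matrix, features x samples, with dimnames.
#' @param lengths named vector of feature lengths in nt (the TE length for
#'   per-strand features too).
#' @param genotypes named character vector or plain vector mapping each
#'   sample (column) to a genotype label.
#' @return a `te_count_table` list with elements `counts`, `lengths`,
#'   `samples` (data.frame sample/genotype).
#' @export
te_count_table <- function(counts, lengths, genotypes) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have feature rownames and sample colnames", call. = FALSE)
  if (any(counts < 0)) stop("counts must be >= 0", call. = FALSE)
  if (!all(rownames(counts) %in% names(lengths)))
    stop("every feature needs a length", call. = FALSE)
  genotypes <- rep_len(as.character(genotypes), ncol(counts))
  structure(list(counts = counts,
                 lengths = lengths[rownames(counts)],
                 samples = data.frame(sample = colnames(counts),
                                      genotype = genotypes,
                                      stringsAsFactors = FALSE)),
            class = "te_count_table")
}

#' @export
print.te_count_table <- function(x, ...) {
  cat(sprintf("te_count_table: %d features x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  tab <- table(x$samples$genotype)
  cat("  genotypes:", paste(sprintf("%s (n=%d)", names(tab), tab),
                            collapse = ", "), "\n")
  invisible(x)
}

#' Quantify TE-level abundance from apportioned alignments
#'
#' The count of a TE (or TE strand) is the sum of the apportioned weights
#' of the alignments on it, so multi-mapping species contribute their full
#' read count split across locations. Two normalised layers are attached:
#' `pkb` (reads per kilobase, count / length x 1000) and `rpkm`
#' (count / (length in kb x total aligned reads in millions)).
#'
#' @param alignments a `weighted_alignments` table for one library.
#' @param panel the [te_panel()] the alignments refer to.
#' @param per_strand split features into `TE:+` and `TE:-`.
#' @param min_species_count drop species below this read count before
#'   summing (the piRNA analyses use 5; RNA-level analyses use 0).
#' @return data.table: `feature`, `te_id`, (`strand`,) `count`, `pkb`,
#'   `rpkm`, one row per feature, all panel TEs present (zeros kept).
#' @export
quantify_te <- function(alignments, panel, per_strand = FALSE,
                        min_species_count = 0L) {
  stopifnot(inherits(panel, "te_panel"))
  bad <- setdiff(unique(alignments$ref_id), panel$id)
  if (length(bad))
    stop("alignment reference(s) not in panel: ", paste(bad, collapse = ", "),
         call. = FALSE)
  aln <- alignments[count >= min_species_count]
  if (per_strand) {
    grid <- data.table::CJ(te_id = panel$id, strand = c("+", "-"))
    obs <- aln[, .(count = sum(weight)), by = .(te_id = ref_id, strand)]
    out <- merge(grid, obs, by = c("te_id", "strand"), all.x = TRUE)
    out[, feature := paste0(te_id, ":", strand)]
  } else {
    grid <- data.table::data.table(te_id = panel$id)
    obs <- aln[, .(count = sum(weight)), by = .(te_id = ref_id)]
    out <- merge(grid, obs, by = "te_id", all.x = TRUE)
    out[, feature := te_id]
  }
  out[is.na(count), count := 0]
  out[, length := panel$length[match(te_id, panel$id)]]
  total <- sum(out$count)
  out[, pkb := count / length * 1000]
  out[, rpkm := if (total > 0) count / ((length / 1000) * (total / 1e6)) else 0]
  data.table::setcolorder(out, c("feature", "te_id"))
  out[]
}

#' Combine per-library quantifications into a count table
#'
#' @param quant_list named list of [quantify_te()] outputs (one per
#'   sample, identical feature sets).
#' @param genotypes genotype label per sample, recycled if length 1.
#' @return a [te_count_table()].
#' @export
combine_quantifications <- function(quant_list, genotypes) {
  stopifnot(length(quant_list) >= 1, !is.null(names(quant_list)))
  feats <- quant_list[[1]]$feature
  counts <- vapply(quant_list, function(q) {
    if (!identical(q$feature, feats))
      stop("feature sets differ across libraries", call. = FALSE)
    q$count
  }, numeric(length(feats)))
  counts <- matrix(counts, nrow = length(feats),
                   dimnames = list(feats, names(quant_list)))
  te_count_table(counts,
                 lengths = stats::setNames(quant_list[[1]]$length, feats),
                 genotypes = genotypes)
}

#' pkb / rpkm layers of a count table
#'
#' @param tab a [te_count_table()].
#' @return matrix of the same shape as `tab$counts`.
#' @rdname count_layers
#' @export
pkb_layer <- function(tab) tab$counts / tab$lengths * 1000

#' @rdname count_layers
#' @export
rpkm_layer <- function(tab) {
  libsize <- colSums(tab$counts)
  sweep(tab$counts / (tab$lengths / 1000), 2, libsize / 1e6, "/")
}

#' Median-of-ratios normalization
#'
#' Size factors are computed DESeq-style: a per-feature geometric mean is
#' taken over samples using only features with no zero counts, and each
#' sample's factor is the median of its count / geometric-mean ratios.
#' When no zero-free feature exists the function falls back to total-count
#' scaling with a warning.
#'
#' @param x a [te_count_table()] or a counts matrix.
#' @return list with `normalized` (matrix, count / size factor) and
#'   `size_factors` (named vector, geometric mean 1 under the fallback,
#'   median-ratio scale otherwise).
#' @export
normalize_counts <- function(x) {
  counts <- if (inherits(x, "te_count_table")) x$counts else as.matrix(x)
  if (ncol(counts) < 2L) stop("need >= 2 samples", call. = FALSE)
  nz <- rowSums(counts == 0) == 0L
  if (!any(nz)) {
    warning("no zero-free features; falling back to total-count scaling")
    libsize <- colSums(counts)
    sf <- libsize / exp(mean(log(libsize)))
  } else {
    logg <- rowMeans(log(counts[nz, , drop = FALSE]))
    sf <- apply(counts[nz, , drop = FALSE], 2,
                function(col) stats::median(exp(log(col) - logg)))
  }
  list(normalized = sweep(counts, 2, sf, "/"), size_factors = sf)
}
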