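#' Genetic-interaction scores for double mutants
#'
#' The GI score of a TE is the ratio of its linear fold change in the
#' double mutant (vs. the shared control) to the sum of its fold changes
#' in the two single mutants: `gi = fc_double / (fc_single1 + fc_single2)`.
#' A score above 1 means the double mutant de-silences the TE more than
#' the combined action of the single mutants; scores above 2 mark strong
#' positive genetic interactions.
#'
#' @param fc_double,fc_single1,fc_single2 named numeric vectors of linear
#'   fold changes (e.g. from [linear_fc()]), or `de_result` tables.
#' @param desilenced optional character vector of de-silenced TE ids; when
#'   given, a summary over that set (count and percent with GI > 2) is
#'   attached as attribute `"desilenced_summary"`.
#' @return a `gi_record` data.frame: `te_id`, `fc_double`, `fc_single1`,
#'   `fc_single2`, `gi`, `strong` (gi > 2), `positive` (gi > 1). TEs
#'   missing from any input are excluded (a message reports how many);
#'   `gi` is `NA` where the denominator is 0.
#' @export
gi_scores <- function(fc_double, fc_single1, fc_single2, desilenced = NULL) {
  as_fc <- function(x) if (inherits(x, "de_result")) linear_fc(x) else x
  d <- as_fc(fc_double); s1 <- as_fc(fc_single1); s2 <- as_fc(fc_single2)
  te <- Reduce(intersect, list(names(d), names(s1), names(s2)))
  n_drop <- length(unique(c(names(d), names(s1), names(s2)))) - length(te)
  if (n_drop > 0)
    message(sprintf("gi_scores: excluded %d TE(s) missing from an input", n_drop))
  denom <- s1[te] + s2[te]
  gi <- ifelse(denom > 0, d[te] / denom, NA_real_)
  out <- data.frame(te_id = te, fc_double = unname(d[te]),
                    fc_single1 = unname(s1[te]), fc_single2 = unname(s2[te]),
                    gi = unname(gi), strong = unname(gi > 2),
                    positive = unname(gi > 1),
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("gi_record", "data.frame")
  if (!is.null(desilenced)) {
    sub <- out[out$te_id %in% desilenced & !is.na(out$gi), ]
    attr(out, "desilenced_summary") <-
      list(n = nrow(sub), n_strong = sum(sub$strong),
           percent_strong = if (nrow(sub)) 100 * sum(sub$strong) / nrow(sub)
                            else NA_real_)
  }
  out
}

#' Length-by-expression quadrant analysis of de-silenced TEs
#'
#' TEs are partitioned into four quadrants by log10 length and log10
#' expression (control rpkm): `long` iff log10(length) >= `len_cut_log10`
#' (default 3.7, ~5,000 nt) and `high` iff log10(rpkm) >= `expr_cut_log10`
#' (default 1, 10 rpkm); boundary TEs are assigned upward. For each
#' quadrant the summary reports the distribution percent (that quadrant's
#' share of all de-silenced TEs) and the density percent (de-silenced TEs
#' among total TEs within the quadrant).
#'
#' @param lengths named vector of TE lengths (nt, > 0).
#' @param rpkm named vector of control-genotype expression (rpkm); TEs
#'   with zero expression are classified `low` and flagged.
#' @param desilenced character vector of de-silenced TE ids.
#' @param len_cut_log10,expr_cut_log10 quadrant cutoffs.
#' @return list with `records` (te_id, log10_length, log10_rpkm, quadrant,
#'   desilenced, zero_expression) and `summary` (per quadrant: total,
#'   desilenced, distribution_pct, density_pct).
#' @export
quadrant_analysis <- function(lengths, rpkm, desilenced,
                              len_cut_log10 = 3.7, expr_cut_log10 = 1.0) {
  if (any(lengths <= 0)) stop("TE lengths must be > 0", call. = FALSE)
  te <- names(lengths)
  if (is.null(te) || !all(te %in% names(rpkm)))
    stop("lengths and rpkm must be named over the same TEs", call. = FALSE)
  llen <- log10(lengths)
  lexp <- log10(rpkm[te])  # -Inf for zero expression -> low side
  quadrant <- paste0(ifelse(llen >= len_cut_log10, "long", "short"), "-",
                     ifelse(lexp >= expr_cut_log10, "high", "low"))
  records <- data.frame(te_id = te, log10_length = unname(llen),
                        log10_rpkm = unname(lexp), quadrant = quadrant,
                        desilenced = te %in% desilenced,
                        zero_expression = unname(rpkm[te] == 0),
                        row.names = NULL, stringsAsFactors = FALSE)
  quads <- c("long-high", "long-low", "short-high", "short-low")
  n_des_total <- sum(records$desilenced)
  summary <- do.call(rbind, lapply(quads, function(q) {
    inq <- records$quadrant == q
    nd <- sum(records$desilenced[inq])
    data.frame(quadrant = q, total = sum(inq), desilenced = nd,
               distribution_pct = if (n_des_total > 0) 100 * nd / n_des_total
                                  else NA_real_,
               density_pct = if (any(inq)) 100 * nd / sum(inq) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  list(records = records, summary = summary)
}

#' Concomitant sense/antisense reduction grouping
#'
#' For TEs whose both-strand piRNAs are reduced at least `cutoff`-fold,
#' classifies the relative strand contribution: group 1 = sense reduction
#' at least `cutoff`-fold stronger than antisense
#' (`fc_sense <= fc_antisense / cutoff`), group 3 = the reverse, group 2 =
#' comparable reduction. Also reports the percent of the reduced set whose
#' sense (or antisense) piRNAs are themselves reduced >= `cutoff`-fold.
#'
#' @param records data.frame with `te_id`, `fc_sense`, `fc_antisense`
#'   (linear fold changes > 0, e.g. from [split_strand_fc()]).
#' @param reduced_set TE ids whose both-strand piRNAs are reduced; records
#'   outside it are skipped.
#' @param cutoff linear fold-change cutoff.
#' @return list with `records` (plus `group`), `group_pct` (named percent
#'   per group) and `concomitant_pct` (percent of the reduced set with
#'   sense, antisense reduction >= cutoff).
#' @export
concomitant_grouping <- function(records, reduced_set, cutoff = 2.0) {
  rec <- records[records$te_id %in% reduced_set, , drop = FALSE]
  skipped <- nrow(records) - nrow(rec)
  if (skipped > 0)
    message(sprintf("concomitant_grouping: skipped %d record(s) outside the reduced set",
                    skipped))
  if (any(rec$fc_sense <= 0 | rec$fc_antisense <= 0, na.rm = TRUE))
    stop("fold changes must be > 0", call. = FALSE)
  grp <- ifelse(rec$fc_sense <= rec$fc_antisense / cutoff, 1L,
                ifelse(rec$fc_antisense <= rec$fc_sense / cutoff, 3L, 2L))
  rec$group <- grp
  n <- nrow(rec)
  group_pct <- stats::setNames(vapply(1:3, function(g)
    if (n > 0) 100 * sum(grp == g, na.rm = TRUE) / n else NA_real_,
    numeric(1)), c("group1", "group2", "group3"))
  concomitant_pct <- c(
    sense = if (n > 0) 100 * sum(rec$fc_sense <= 1 / cutoff, na.rm = TRUE) / n
            else NA_real_,
    antisense = if (n > 0)
      100 * sum(rec$fc_antisense <= 1 / cutoff, na.rm = TRUE) / n
      else NA_real_)
  list(records = rec, group_pct = group_pct,
       concomitant_pct = concomitant_pct)
}

#' Assign piRNA species to PIWI-clade IP groups
#'
#' Species are assigned to the PIWI-clade protein (e.g. Aub, Ago3, Piwi)
#' whose immunoprecipitate enriches them at least `fold`-fold over both
#' other IPs, after depth normalization to counts-per-million and addition
#' of a pseudocount; species satisfying the rule for no protein are
#' `ambiguous`. Species below `min_count` raw counts in every library are
#' dropped. With `fold > 1` the resulting groups are mutually exclusive by
#' construction.
#'
#' @param counts numeric matrix, species x 3 IP libraries; rownames are
#'   the species sequences, colnames the protein labels.
#' @param fold enrichment threshold.
#' @param pseudocount added to CPM values before comparison.
#' @param min_count raw-count floor; species below it in all libraries
#'   are dropped.
#' @return an `ip_assignment` data.frame: `sequence`, one CPM column per
#'   protein, `assigned` (protein label or `"ambiguous"`).
#' @export
ip_group_assignment <- function(counts, fold = 3.0, pseudocount = 0.5,
                                min_count = 5L) {
  counts <- as.matrix(counts)
  if (ncol(counts) != 3L)
    stop("need exactly three IP libraries", call. = FALSE)
  if (is.null(colnames(counts)) || is.null(rownames(counts)))
    stop("counts must carry species rownames and protein colnames", call. = FALSE)
  depth <- colSums(counts)
  keep <- apply(counts, 1, max) >= min_count
  counts <- counts[keep, , drop = FALSE]
  cpm <- sweep(counts, 2, depth / 1e6, "/") + pseudocount
  assigned <- rep("ambiguous", nrow(cpm))
  for (j in seq_len(ncol(cpm))) {
    others <- cpm[, -j, drop = FALSE]
    hit <- cpm[, j] >= fold * others[, 1] & cpm[, j] >= fold * others[, 2]
    assigned[hit] <- colnames(cpm)[j]
  }
  out <- data.frame(sequence = rownames(cpm), cpm,
                    assigned = assigned, row.names = NULL,
                    stringsAsFactors = FALSE)
  class(out) <- c("ip_assignment", "data.frame")
  out
}

#' Fraction of a sample's reads matching each IP group
#'
#' @param species sample species table (`sequence`, `count`).
#' @param assignments an [ip_group_assignment()] result.
#' @return named list: percent of the sample's total read count whose
#'   species sequence appears in each group, plus `combined` (any group).
#' @export
ip_group_overlap <- function(species, assignments) {
  total <- sum(species$count)
  if (total == 0) {
    warning("empty sample; overlap undefined")
    return(NULL)
  }
  groups <- setdiff(unique(assignments$assigned), "ambiguous")
  out <- lapply(groups, function(g) {
    seqs <- assignments$sequence[assignments$assigned == g]
    100 * sum(species$count[species$sequence %in% seqs]) / total
  })
  names(out) <- groups
  any_seqs <- assignments$sequence[assignments$assigned != "ambiguous"]
  out$combined <- 100 * sum(species$count[species$sequence %in% any_seqs]) / total
  out
}
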