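#' Differential expression between two genotype groups
#'
#' Counts are normalized by median-of-ratios ([normalize_counts()]),
#' features with zero counts in all samples are dropped (a message reports
#' how many), and per-feature fold changes are computed as
#' `log2((meanB + 0.5) / (meanA + 0.5))` on normalized counts (pseudocount
#' 0.5). P-values come from a two-sided Welch t-test on
#' `log2(normalized + 0.5)` (`method = "welch_log"`), or from permutation
#' of the group labels under the same statistic
#' (`method = "permutation"`, exact enumeration when there are at most
#' 2000 label assignments). Benjamini-Hochberg adjustment is applied
#' across all tested features and calls use the standard cutoffs
#' p-adj <= 0.05, |log2FC| >= 0.58. `method = "fc_only"` skips testing and
#' calls up/down by a plain linear fold-change cutoff (default 2-fold),
#' the mode used for piRNA-level strand analyses.
#'
#' @param tab a [te_count_table()].
#' @param groupA,groupB genotype labels (reference and test group).
#' @param alpha adjusted-p cutoff for calls.
#' @param lfc_theta |log2FC| cutoff for calls.
#' @param method `"welch_log"`, `"permutation"`, or `"fc_only"`.
#' @param fc_cutoff linear fold-change cutoff used by `"fc_only"`.
#' @param n_perm maximum number of permutations.
#' @return a `de_result` data.frame: `feature`, `baseMeanA`, `baseMeanB`,
#'   `log2FC`, `p`, `p_adj`, `call` (`up`/`down`/`unchanged`).
#' @export
differential_expression <- function(tab, groupA, groupB, alpha = 0.05,
                                    lfc_theta = 0.58,
                                    method = c("welch_log", "permutation",
                                               "fc_only"),
                                    fc_cutoff = 2, n_perm = 2000L) {
  method <- match.arg(method)
  stopifnot(inherits(tab, "te_count_table"))
  selA <- tab$samples$genotype == groupA
  selB <- tab$samples$genotype == groupB
  if (!any(selA) || !any(selB))
    stop("group labels not found among sample genotypes", call. = FALSE)
  nA <- sum(selA); nB <- sum(selB)
  if (method == "welch_log" && (nA < 2L || nB < 2L))
    stop("welch_log needs >= 2 replicates per group", call. = FALSE)
  if (method == "permutation" && (nA < 3L || nB < 3L))
    stop("permutation needs >= 3 replicates per group", call. = FALSE)
  norm <- normalize_counts(tab)$normalized
  zero <- rowSums(tab$counts) == 0
  if (any(zero)) {
    message(sprintf("differential_expression: dropping %d all-zero feature(s)",
                    sum(zero)))
    norm <- norm[!zero, , drop = FALSE]
  }
  A <- norm[, selA, drop = FALSE]
  B <- norm[, selB, drop = FALSE]
  meanA <- rowMeans(A); meanB <- rowMeans(B)
  log2fc <- log2((meanB + 0.5) / (meanA + 0.5))

  if (method == "fc_only") {
    fc <- (meanB + 0.5) / (meanA + 0.5)
    call <- ifelse(fc >= fc_cutoff, "up",
                   ifelse(fc <= 1 / fc_cutoff, "down", "unchanged"))
    p <- p_adj <- rep(NA_real_, length(fc))
  } else {
    lA <- log2(A + 0.5); lB <- log2(B + 0.5)
    welch_p <- function(a, b) {
      if (stats::sd(a) == 0 && stats::sd(b) == 0)
        return(if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0)
      stats::t.test(b, a)$p.value
    }
    if (method == "welch_log") {
      p <- vapply(seq_len(nrow(lA)), function(i) welch_p(lA[i, ], lB[i, ]),
                  numeric(1))
    } else {
      welch_t <- function(a, b) {
        va <- stats::var(a) / length(a); vb <- stats::var(b) / length(b)
        if (va + vb == 0) return(if (mean(a) == mean(b)) 0 else Inf)
        (mean(b) - mean(a)) / sqrt(va + vb)
      }
      dat <- cbind(lA, lB)
      labs <- utils::combn(nA + nB, nA)
      if (ncol(labs) > n_perm)
        labs <- labs[, sample.int(ncol(labs), n_perm), drop = FALSE]
      p <- vapply(seq_len(nrow(dat)), function(i) {
        x <- dat[i, ]
        t_obs <- abs(welch_t(x[seq_len(nA)], x[nA + seq_len(nB)]))
        t_perm <- apply(labs, 2, function(ia)
          abs(welch_t(x[ia], x[-ia])))
        (1 + sum(t_perm >= t_obs - 1e-12)) / (1 + length(t_perm))
      }, numeric(1))
    }
    p_adj <- stats::p.adjust(p, method = "BH")
    call <- ifelse(p_adj <= alpha & log2fc >= lfc_theta, "up",
                   ifelse(p_adj <= alpha & log2fc <= -lfc_theta, "down",
                          "unchanged"))
  }
  out <- data.frame(feature = rownames(norm), baseMeanA = meanA,
                    baseMeanB = meanB, log2FC = log2fc, p = p, p_adj = p_adj,
                    call = call, row.names = NULL, stringsAsFactors = FALSE)
  structure(out, class = c("de_result", "data.frame"),
            groupA = groupA, groupB = groupB, alpha = alpha,
            lfc_theta = lfc_theta, method = method, fc_cutoff = fc_cutoff)
}

#' Linear fold changes of a DE result
#'
#' @param de a `de_result`.
#' @return named numeric vector of `2^log2FC` keyed by feature.
#' @export
linear_fc <- function(de) stats::setNames(2^de$log2FC, de$feature)

#' Join sense / antisense / both-strand fold changes per TE
#'
#' Builds one record per TE holding the linear fold change and call from
#' the sense-strand, antisense-strand and both-strand DE tables. A TE
#' missing from a table is flagged, not dropped. Per-strand DE tables are
#' expected to carry `TE:+` / `TE:-` feature ids (as produced by
#' [quantify_te()] with `per_strand = TRUE`); plain TE ids also work.
#'
#' @param sense,antisense,both `de_result` tables.
#' @return data.frame: `te_id`, `fc_sense`, `fc_antisense`, `fc_both`,
#'   `call_sense`, `call_antisense`, `call_both`, `missing_sense`,
#'   `missing_antisense`, `missing_both`.
#' @export
split_strand_fc <- function(sense, antisense, both) {
  strip <- function(de) {
    te <- sub(":[+-]$", "", de$feature)
    if (anyDuplicated(te)) stop("duplicated TE ids in a DE table", call. = FALSE)
    data.frame(te_id = te, fc = 2^de$log2FC, call = de$call,
               stringsAsFactors = FALSE)
  }
  s <- strip(sense); a <- strip(antisense); b <- strip(both)
  te <- sort(unique(c(s$te_id, a$te_id, b$te_id)))
  pick <- function(d, col) d[[col]][match(te, d$te_id)]
  out <- data.frame(te_id = te,
                    fc_sense = pick(s, "fc"), fc_antisense = pick(a, "fc"),
                    fc_both = pick(b, "fc"),
                    call_sense = pick(s, "call"),
                    call_antisense = pick(a, "call"),
                    call_both = pick(b, "call"),
                    stringsAsFactors = FALSE)
  out$missing_sense <- is.na(out$fc_sense)
  out$missing_antisense <- is.na(out$fc_antisense)
  out$missing_both <- is.na(out$fc_both)
  out
}
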