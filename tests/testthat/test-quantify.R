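test_that("pkb and rpkm identities hold for every feature", {
  p <- manual_panel(c(random_seq(1000, seed = 50), random_seq(5000, seed = 51)))
  # 10 total weight on the 1 kb TE, 50 on the 5 kb TE -> pkb 10 each
  s1 <- substr(p$sequence[1], 101, 126)
  s2 <- substr(p$sequence[2], 501, 526)
  sp <- collapse_species(c(rep(s1, 10), rep(s2, 50)))
  q <- quantify_te(align_species(sp, p), p)
  expect_equal(q[q$te_id == "TE01"]$count, 10)
  expect_equal(q[q$te_id == "TE01"]$pkb, 10)
  expect_equal(q[q$te_id == "TE02"]$pkb, 10)
  expect_equal(q$rpkm, q$count / (q$length / 1000) / (sum(q$count) / 1e6))
  # species mapping twice within one TE contributes its full count
  seg <- substr(p$sequence[1], 201, 226)
  p2 <- manual_panel(paste0(substr(p$sequence[1], 1, 400), seg,
                            random_seq(100, seed = 52)))
  spd <- collapse_species(rep(seg, 6))
  q2 <- quantify_te(align_species(spd, p2), p2)
  expect_equal(q2$count, 6)
  # per-strand split and species-count filter
  sp3 <- collapse_species(c(rep(s1, 6), rep(revcomp(s1), 3)))
  q3 <- quantify_te(align_species(sp3, p), p, per_strand = TRUE,
                    min_species_count = 5)
  expect_equal(q3[feature == "TE01:+"]$count, 6)
  expect_equal(q3[feature == "TE01:-"]$count, 0)  # count-3 species filtered
})

test_that("median-of-ratios size factors behave like the DESeq recipe", {
  set.seed(53)
  base <- rpois(40, 200) + 1
  m <- cbind(A = base, B = base)
  rownames(m) <- sprintf("TE%02d", 1:40)
  expect_equal(unname(normalize_counts(m)$size_factors), c(1, 1))
  m2 <- cbind(A = base, B = 2 * base)
  sf <- normalize_counts(m2)$size_factors
  expect_equal(unname(sf[2] / sf[1]), 2, tolerance = 1e-9)
  # spiking one feature 100x leaves the factor ~1 (median robustness)
  m3 <- cbind(A = base, B = base)
  m3[1, "B"] <- m3[1, "B"] * 100
  sf3 <- normalize_counts(m3)$size_factors
  expect_lt(abs(sf3[["B"]] / sf3[["A"]] - 1), 0.05)
  # no zero-free features -> total-count fallback with warning
  m4 <- cbind(A = c(0, 5), B = c(5, 0))
  rownames(m4) <- c("a", "b")
  expect_warning(normalize_counts(m4), "total-count")
})

test_that("differential expression calls follow the stated cutoffs", {
  p <- generate_te_panel(te_panel_spec(40, c(500, 800), seed = 54))
  ctrl <- condition_effect("WT")
  mut <- condition_effect("mut", te_fc_map = c(TE001 = 8, TE002 = 1/8))
  tab <- simulate_count_table(p, list(ctrl, mut), n_reps = 5,
                              dispersion = 0.05, seed = 55)
  de <- differential_expression(tab, "WT", "mut")
  expect_s3_class(de, "de_result")
  expect_equal(de$call[de$feature == "TE001"], "up")
  expect_equal(de$call[de$feature == "TE002"], "down")
  expect_gt(mean(de$call == "unchanged"), 0.8)
  # identical groups give log2FC 0 everywhere
  same <- te_count_table(tab$counts[, 1:4],
                         lengths = tab$lengths,
                         genotypes = c("g1", "g1", "g2", "g2"))
  # duplicate columns pairwise so groups are identical
  cc <- cbind(tab$counts[, 1:2], tab$counts[, 1:2])
  colnames(cc) <- c("a1", "a2", "b1", "b2")
  same <- te_count_table(cc, tab$lengths, c("A", "A", "B", "B"))
  de0 <- differential_expression(same, "A", "B")
  expect_true(all(de0$log2FC == 0))
  expect_true(all(de0$call == "unchanged"))
  # label swap negates log2FC and preserves p-values
  de_fwd <- differential_expression(tab, "WT", "mut")
  de_rev <- differential_expression(tab, "mut", "WT")
  expect_equal(de_fwd$log2FC, -de_rev$log2FC, tolerance = 1e-12)
  expect_equal(de_fwd$p, de_rev$p, tolerance = 1e-12)
  # fc_only mode with the 2-fold cutoff
  fc <- differential_expression(tab, "WT", "mut", method = "fc_only")
  expect_true(all(is.na(fc$p)))
  expect_equal(fc$call[fc$feature == "TE001"], "up")
  expect_error(differential_expression(tab, "WT", "nope"), "not found")
})

test_that("Benjamini-Hochberg adjustment matches the hand-computed example", {
  # independent check frozen from the BH definition: p * n / rank, cummin
  expect_equal(p.adjust(c(0.01, 0.02, 0.03, 0.04), "BH"),
               c(0.04, 0.04, 0.04, 0.04))
})

test_that("the internal DE engine agrees with DESeq2 on planted effects", {
  p <- generate_te_panel(te_panel_spec(60, c(500, 800), seed = 56))
  fc <- stats::setNames(rep(4, 8), sprintf("TE%03d", 1:8))
  tab <- simulate_count_table(p, list(condition_effect("WT"),
                                      condition_effect("mut", te_fc_map = fc)),
                              n_reps = 4, dispersion = 0.05, seed = 57)
  de <- differential_expression(tab, "WT", "mut")
  suppressPackageStartupMessages(requireNamespace("DESeq2"))
  cd <- data.frame(condition = factor(tab$samples$genotype,
                                      levels = c("WT", "mut")))
  dds <- DESeq2::DESeqDataSetFromMatrix(round(tab$counts), cd, ~condition)
  dds <- suppressMessages(DESeq2::DESeq(dds, quiet = TRUE))
  res <- DESeq2::results(dds)
  common <- intersect(de$feature, rownames(res))
  r <- cor(de$log2FC[match(common, de$feature)],
           res$log2FoldChange[match(common, rownames(res))])
  expect_gt(r, 0.95)
  planted_up_ours <- de$feature[de$call == "up"]
  expect_true(all(names(fc) %in% planted_up_ours))
})

test_that("permutation p-values broadly agree with Welch p-values", {
  p <- generate_te_panel(te_panel_spec(30, c(500, 700), seed = 58))
  fc <- stats::setNames(rep(5, 5), sprintf("TE%03d", 1:5))
  tab <- simulate_count_table(p, list(condition_effect("WT"),
                                      condition_effect("mut", te_fc_map = fc)),
                              n_reps = 4, dispersion = 0.05, seed = 59)
  dw <- differential_expression(tab, "WT", "mut")
  dp <- differential_expression(tab, "WT", "mut", method = "permutation")
  # planted features rank among the smallest permutation p-values
  expect_true(all(dp$p[match(names(fc), dp$feature)] <=
                  min(dp$p) + 1e-12))
  expect_gt(cor(rank(dw$p), rank(dp$p), method = "spearman"), 0.5)
})

test_that("strand-joined fold-change records flag missing strands", {
  mk_de <- function(features, l2fc, call) {
    structure(data.frame(feature = features, baseMeanA = 1, baseMeanB = 1,
                         log2FC = l2fc, p = NA, p_adj = NA, call = call,
                         stringsAsFactors = FALSE),
              class = c("de_result", "data.frame"))
  }
  sense <- mk_de(c("TE1:+", "TE2:+"), c(log2(0.4), 0), c("down", "unchanged"))
  anti <- mk_de("TE1:-", 0, "unchanged")
  both <- mk_de(c("TE1", "TE2"), c(-1, 0), c("down", "unchanged"))
  j <- split_strand_fc(sense, anti, both)
  expect_equal(j$fc_sense[j$te_id == "TE1"], 0.4, tolerance = 1e-12)
  expect_true(j$missing_antisense[j$te_id == "TE2"])
  expect_false(any(j$missing_both))
  dup <- mk_de(c("TE1:+", "TE1:+"), c(0, 0), c("unchanged", "unchanged"))
  expect_error(split_strand_fc(dup, anti, both), "duplicated")
})
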