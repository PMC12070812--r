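test_that("pair-distance histograms match hand examples and brute force", {
  A <- data.frame(pos = 100L, weight = 1)
  B <- data.frame(pos = 109L, weight = 1)
  h <- pair_distance_histogram(A, B, "pingpong_5p5p", c(1, 30))
  expect_equal(h$weight[h$distance == 10], 1)
  expect_equal(sum(h$weight), 1)
  # weight product
  h2 <- pair_distance_histogram(data.frame(pos = 100L, weight = 2),
                                data.frame(pos = 109L, weight = 3),
                                "pingpong_5p5p", c(1, 30))
  expect_equal(h2$weight[h2$distance == 10], 6)
  # brute-force oracle on 200 random positions each
  set.seed(40)
  A <- data.frame(pos = sample.int(500, 200), weight = runif(200))
  B <- data.frame(pos = sample.int(500, 200), weight = runif(200))
  for (kind in c("pingpong_5p5p", "phase_3p5p", "phase_5p5p")) {
    off <- switch(kind, pingpong_5p5p = 1L, phase_3p5p = -1L, phase_5p5p = 0L)
    win <- c(-20L, 60L)
    got <- pair_distance_histogram(A, B, kind, win)
    expect_hist_equal(got, brute_hist(A$pos, A$weight, B$pos, B$weight,
                                      win, off))
  }
  # self-pair exclusion at identical positions
  C <- data.frame(pos = c(5L, 9L), weight = c(2, 3))
  h3 <- pair_distance_histogram(C, C, "phase_5p5p", c(0, 10),
                                exclude_self = TRUE)
  expect_equal(h3$weight[h3$distance == 0], 0)
  expect_equal(h3$weight[h3$distance == 4], 6)
})

test_that("Z10 equals an independent closed-form computation", {
  # background bins alternate 4 and 6 over 1..9 and 11..20; signal 55
  bg_d <- c(1:9, 11:20)
  bg_v <- rep(c(4, 6), length.out = 19)
  h <- structure(data.frame(distance = c(bg_d, 10L), weight = c(bg_v, 55),
                            normalized = NA),
                 class = c("distance_histogram", "data.frame"))
  z <- pirnasig:::.signature_z(h, 10L, c(1:9, 11:20), "Z10")
  expect_equal(z$value, (55 - mean(bg_v)) / sd(bg_v))
  # uniform histogram: sd = 0 -> undefined
  hu <- structure(data.frame(distance = c(bg_d, 10L), weight = rep(5, 20),
                             normalized = NA),
                  class = c("distance_histogram", "data.frame"))
  zu <- pirnasig:::.signature_z(hu, 10L, c(1:9, 11:20), "Z10")
  expect_false(zu$defined)
  expect_true(is.na(zu$value))
})

test_that("a pure ping-pong library concentrates mass at distance 10", {
  p <- generate_te_panel(te_panel_spec(5, c(600, 1500), seed = 41))
  lib <- simulate_library(p, library_sim_spec(4000, pingpong_fraction = 1,
                                              seed = 42))
  aln <- align_species(collapse_species(lib$reads$sequence), p)
  pp <- pingpong_signature(build_end_profiles(aln))
  expect_equal(pp$histogram$normalized[pp$histogram$distance == 10], 1)
  expect_gt(pp$score$value, 10)
  expect_true(all(c("ref_id", "z10") %in% names(pp$per_ref)))
})

test_that("phasing distances follow the head-to-tail conventions", {
  # reads [100,126) and [126,152) on + strand: 3'-5' d = 0, 5'-5' d = 26
  p <- manual_panel(random_seq(400, seed = 43))
  sp <- collapse_species(c(substr(p$sequence[1], 101, 126),
                           substr(p$sequence[1], 127, 152)))
  ph <- phasing_signature(build_end_profiles(align_species(sp, p)))
  expect_equal(ph$hist_3p5p$weight[ph$hist_3p5p$distance == 0], 1)
  expect_equal(ph$hist_5p5p$weight[ph$hist_5p5p$distance == 26], 1)
  expect_gt(ph$hist_3p5p$weight[ph$hist_3p5p$distance == 0],
            sum(ph$hist_3p5p$weight[ph$hist_3p5p$distance != 0]) - 1e-12)
})

test_that("library-level signature histograms equal brute-force enumeration", {
  p <- generate_te_panel(te_panel_spec(3, c(300, 700), repeat_fraction = 0.5,
                                       seed = 44))
  lib <- simulate_library(p, library_sim_spec(
    300, pingpong_fraction = 0.3, phased_fraction = 0.3, seed = 45))
  aln <- align_species(collapse_species(lib$reads$sequence), p)
  prof <- build_end_profiles(aln)
  ref <- brute_signature_hists(aln)
  pp <- pingpong_signature(prof)
  ph <- phasing_signature(prof)
  expect_hist_equal(pp$histogram, ref$pp)
  expect_hist_equal(ph$hist_3p5p, ref$p3)
  expect_hist_equal(ph$hist_5p5p, ref$p5)
})

test_that("Z scores are invariant to count scaling and position shifts", {
  p <- generate_te_panel(te_panel_spec(4, c(500, 900), seed = 46))
  lib <- simulate_library(p, library_sim_spec(
    2000, pingpong_fraction = 0.4, phased_fraction = 0.3, seed = 47))
  sp <- collapse_species(lib$reads$sequence)
  aln <- align_species(sp, p)
  z1 <- pingpong_signature(build_end_profiles(aln))$score$value
  z0_1 <- phasing_signature(build_end_profiles(aln))$score$value
  # scale every count by 7
  sp2 <- data.table::copy(sp)[, count := count * 7L]
  aln2 <- align_species(sp2, p)
  expect_equal(pingpong_signature(build_end_profiles(aln2))$score$value, z1,
               tolerance = 1e-9)
  expect_equal(phasing_signature(build_end_profiles(aln2))$score$value, z0_1,
               tolerance = 1e-9)
  # shift all alignments by a constant offset (pad the references)
  pad <- strrep("G", 37)
  p_shift <- te_panel(p$id, paste0(pad, p$sequence), p$compartment)
  aln3 <- align_species(sp, p_shift)
  expect_equal(pingpong_signature(build_end_profiles(aln3))$score$value, z1,
               tolerance = 1e-6)
  expect_equal(phasing_signature(build_end_profiles(aln3))$score$value, z0_1,
               tolerance = 1e-6)
})

test_that("peak/baseline metrics follow the valley definition", {
  mk <- function(vals) {
    d <- as.integer(names(vals))
    structure(data.frame(distance = d, weight = unname(vals),
                         normalized = unname(vals) / max(vals)),
              class = c("distance_histogram", "data.frame"))
  }
  v <- stats::setNames(rep(10, 100), 1:100)
  v[c("27", "54")] <- 100
  pk <- peak_baseline_metrics(mk(v), 27, 2)
  expect_equal(pk$peaks$distance, c(27L, 54L))
  expect_equal(pk$baseline, 10)
  expect_equal(pk$height, 90)
  # flat histogram: height 0
  flat <- mk(stats::setNames(rep(3, 100), 1:100))
  expect_equal(peak_baseline_metrics(flat, 27, 2)$height, 0)
  # period-28 data found within the +/-2 tolerance windows
  v2 <- stats::setNames(rep(1, 100), 1:100)
  v2[c("28", "55")] <- 50
  pk2 <- peak_baseline_metrics(mk(v2), 27, 2)
  expect_equal(pk2$peaks$distance, c(28L, 55L))
  # window too small for two peaks
  small <- mk(stats::setNames(rep(1, 30), 1:30))
  expect_error(peak_baseline_metrics(small, 27, 2), "too small")
})

test_that("nucleotide bias applies the 5-count eligibility selector", {
  sp <- data.frame(
    sequence = c("TAAAAAAAAA", "TCCCCCCCCC", "GAAAAAAAAA", "ACCCCCCCCC"),
    count = c(5, 9, 100, 5))
  b <- nucleotide_bias(sp, 1, "U")
  expect_equal(b$percent, 50)
  expect_equal(b$n_eligible, 4L)
  # a 4-count species affects neither numerator nor denominator
  sp2 <- rbind(sp, data.frame(sequence = "TGGGGGGGGG", count = 4))
  expect_equal(nucleotide_bias(sp2, 1, "T")$percent, 50)
  # all species with A at 10
  sp3 <- data.frame(sequence = c("CCCCCCCCCA", "GGGGGGGGGA"), count = c(6, 7))
  expect_equal(nucleotide_bias(sp3, 10, "A")$percent, 100)
  # species shorter than the position are eligible non-hits
  sp4 <- data.frame(sequence = c("CCCCCCCCCA", "CCCCC"), count = c(6, 7))
  expect_equal(nucleotide_bias(sp4, 10, "A")$percent, 50)
  # zero eligible species -> undefined
  none <- nucleotide_bias(data.frame(sequence = "ACGT", count = 1), 1, "T")
  expect_false(none$defined)
})

test_that("IP-scoped bias equals the plain bias on the full group", {
  sp <- data.frame(sequence = c("TAAAAAAAAA", "GCCCCCCCCC"), count = c(8, 8))
  ipa <- data.frame(sequence = sp$sequence, assigned = "Aub")
  class(ipa) <- c("ip_assignment", "data.frame")
  b_all <- nucleotide_bias(sp, 1, "T")
  b_ip <- ip_overlap_bias(sp, ipa, "Aub", 1, "T")
  expect_equal(b_ip$percent, b_all$percent)
  # disjoint group -> undefined
  ipa2 <- data.frame(sequence = "AAAAAAAAAA", assigned = "Ago3")
  expect_false(ip_overlap_bias(sp, ipa2, "Ago3", 1, "T")$defined)
})
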