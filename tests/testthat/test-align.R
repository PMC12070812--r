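ref <- random_seq(400, seed = 21)
panel1 <- manual_panel(ref)

test_that("exact matches are reported with the stated coordinates", {
  fwd <- substr(ref, 11, 36)                   # 0-based [10, 36)
  rc <- revcomp(fwd)
  sp <- collapse_species(c(fwd, rc))
  aln <- align_species(sp, panel1)
  plus <- aln[strand == "+"]
  minus <- aln[strand == "-"]
  expect_equal(plus$start, 10L)
  expect_equal(plus$end, 36L)
  expect_equal(minus$start, 10L)
  expect_equal(minus$end, 36L)
  # the minus alignment's 5' end sits at reference position 35
  prof <- build_end_profiles(aln)
  p5_minus <- prof[strand == "-" & end == "p5"]
  expect_equal(400L - 1L - p5_minus$pos, 35L)   # back-transform to ref coords
})

test_that("multi-mappers are apportioned count / n_locations", {
  seg <- random_seq(30, seed = 22)
  p <- manual_panel(c(paste0(random_seq(100, seed = 23), seg,
                             random_seq(100, seed = 24)),
                      paste0(seg, random_seq(150, seed = 25))))
  sp <- collapse_species(rep(substr(seg, 1, 26), 6))
  aln <- align_species(sp, p)
  expect_equal(nrow(aln), 2L)
  expect_equal(aln$n_locations, c(2L, 2L))
  expect_equal(aln$weight, c(3, 3))
  expect_equal(sum(aln$weight), 6)
})

test_that("species with N or no hit are reported unaligned", {
  hit <- substr(ref, 51, 76)
  withN <- paste0(substr(hit, 1, 25), "N")
  sp <- collapse_species(c(hit, withN, strrep("AC", 13)))
  aln <- align_species(sp, panel1)
  expect_equal(length(unique(aln$species_id)), 1L)
  expect_equal(length(attr(aln, "unaligned")), 2L)
})

test_that("n_locations matches a naive scan of every reference position", {
  p <- generate_te_panel(te_panel_spec(3, c(150, 300), repeat_fraction = 1,
                                       seed = 26))
  lib <- simulate_library(p, library_sim_spec(60, seed = 27))
  sp <- collapse_species(lib$reads$sequence)
  aln <- align_species(sp, p)
  tally <- table(aln$species_id)
  for (sid in sp$species_id) {
    seqq <- sp$sequence[sp$species_id == sid]
    expected <- naive_locations(seqq, p)
    got <- if (sid %in% names(tally)) as.integer(tally[[sid]]) else 0L
    expect_equal(got, expected, info = sid)
    if (got > 0)
      expect_equal(unique(aln[species_id == sid]$n_locations), expected)
  }
})

test_that("alignment recovers every planted read location (round-trip)", {
  p <- generate_te_panel(te_panel_spec(5, c(500, 1500), repeat_fraction = 0.4,
                                       seed = 28))
  lib <- simulate_library(p, library_sim_spec(
    2000, pingpong_fraction = 0.4, phased_fraction = 0.3, seed = 29))
  sp <- collapse_species(lib$reads$sequence)
  aln <- align_species(sp, p)
  seq_of <- stats::setNames(sp$sequence, sp$species_id)
  keys <- unique(paste(seq_of[aln$species_id], aln$ref_id, aln$strand,
                       aln$start, aln$end))
  planted <- unique(paste(lib$reads$sequence, lib$truth$te_id,
                          lib$truth$strand, lib$truth$start, lib$truth$end))
  expect_true(all(planted %in% keys))
  # weight conservation: total weight equals total aligned read count
  aligned_counts <- sp$count[!sp$species_id %in% attr(aln, "unaligned")]
  expect_equal(sum(aln$weight), sum(aligned_counts), tolerance = 1e-9)
})

test_that("reverse-complementing the panel swaps strands but preserves phasing", {
  p <- generate_te_panel(te_panel_spec(4, c(400, 900), seed = 30))
  lib <- simulate_library(p, library_sim_spec(1500, phased_fraction = 0.6,
                                              seed = 31))
  sp <- collapse_species(lib$reads$sequence)
  aln <- align_species(sp, p)
  prc <- te_panel(p$id, revcomp(p$sequence), p$compartment)
  aln_rc <- align_species(sp, prc)
  # strand totals swap
  expect_equal(sum(aln$strand == "+"), sum(aln_rc$strand == "-"))
  expect_equal(sum(aln$strand == "-"), sum(aln_rc$strand == "+"))
  # within-strand distance statistics are invariant in transcript orientation
  ph1 <- phasing_signature(build_end_profiles(aln))
  ph2 <- phasing_signature(build_end_profiles(aln_rc))
  expect_equal(ph1$hist_3p5p$weight, ph2$hist_3p5p$weight, tolerance = 1e-9)
  expect_equal(ph1$hist_5p5p$weight, ph2$hist_5p5p$weight, tolerance = 1e-9)
})

test_that("end profiles follow the orientation conventions", {
  p <- manual_panel(random_seq(1000, seed = 32))
  fwd <- substr(p$sequence[1], 101, 126)        # + alignment [100, 126)
  sp <- collapse_species(rep(fwd, 2))
  prof <- build_end_profiles(align_species(sp, p))
  expect_equal(prof[strand == "+" & end == "p5"]$pos, 100L)
  expect_equal(prof[strand == "+" & end == "p3"]$pos, 125L)
  expect_equal(prof[strand == "+" & end == "p5"]$weight, 2)
  # minus alignment at [100, 126): transcript-orientation 5' = 1000 - 126
  sp2 <- collapse_species(revcomp(fwd))
  prof2 <- build_end_profiles(align_species(sp2, p))
  expect_equal(prof2[strand == "-" & end == "p5"]$pos, 1000L - 126L)
  expect_equal(prof2[strand == "-" & end == "p3"]$pos, 1000L - 1L - 100L)
  # additivity of weights at a shared position
  sp3 <- collapse_species(c(rep(fwd, 1), rep(substr(p$sequence[1], 101, 128), 3)))
  prof3 <- build_end_profiles(align_species(sp3, p))
  expect_equal(prof3[strand == "+" & end == "p5" & pos == 100]$weight, 4)
})

test_that("region assignment uses half-open >= 1 nt overlap", {
  p <- manual_panel(random_seq(1000, seed = 33))
  sp <- collapse_species(substr(p$sequence[1], 101, 126))  # [100, 126)
  aln <- align_species(sp, p)
  regions <- data.frame(ref_id = "TE01", start = c(0L, 126L, 120L),
                        end = c(1000L, 200L, 130L),
                        name = c("all", "after", "spanning"))
  out <- assign_to_regions(aln, regions)
  expect_equal(nrow(out$all), 1L)
  expect_equal(nrow(out$after), 0L)     # half-open: no overlap at the border
  expect_equal(nrow(out$spanning), 1L)
  expect_error(assign_to_regions(aln, data.frame(ref_id = "nope", start = 0,
                                                 end = 10, name = "x")),
               "not in panel")
})

test_that("BED parsing is 0-based half-open and flags bad lines", {
  f <- tempfile(fileext = ".bed")
  writeLines(c("TE01\t0\t500\tcluster42AB", "TE01\t500\t900"), f)
  bed <- read_bed(f)
  expect_equal(bed$start, c(0L, 500L))
  expect_equal(bed$name[1], "cluster42AB")
  expect_equal(bed$name[2], "TE01:500-900")
  writeLines(c("TE01\t0\t500", "TE01\tx\t900"), f)
  expect_error(read_bed(f), "line 2")
})

test_that("SAM import reproduces internal alignments", {
  p <- manual_panel(random_seq(600, seed = 34))
  fwd <- substr(p$sequence[1], 51, 76)
  rc <- revcomp(substr(p$sequence[1], 201, 226))
  f <- tempfile(fileext = ".sam")
  writeLines(c(
    "@HD\tVN:1.6",
    "@SQ\tSN:TE01\tLN:600",
    paste("s1", 0, "TE01", 51, 255, "26M", "*", 0, 0, fwd, strrep("I", 26),
          sep = "\t"),
    paste("s2", 16, "TE01", 201, 255, "26M", "*", 0, 0,
          revcomp(rc), strrep("I", 26), sep = "\t"),
    paste("s3", 4, "*", 0, 0, "*", "*", 0, 0, "ACGT", "IIII", sep = "\t")), f)
  aln <- import_alignments_sam(f, p, counts = c(s1 = 4, s2 = 2))
  expect_equal(nrow(aln), 2L)
  expect_equal(aln[species_id == "s1"]$start, 50L)
  expect_equal(aln[species_id == "s1"]$strand, "+")
  expect_equal(aln[species_id == "s2"]$strand, "-")
  expect_equal(aln[species_id == "s2"]$sequence, rc)  # as-sequenced orientation
  expect_equal(aln$weight, aln$count / aln$n_locations)
})
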