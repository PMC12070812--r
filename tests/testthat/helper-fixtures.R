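suppressMessages(library(data.table))

# hand-built panel from explicit sequences
manual_panel <- function(seqs, compartment = "unknown") {
  te_panel(sprintf("TE%02d", seq_along(seqs)), seqs, compartment)
}

random_seq <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# independent brute-force pair-distance histogram: full double loop over
# position pairs, d = posB - posA + offset
brute_hist <- function(posA, wA, posB, wB, window, offset,
                       exclude_self = FALSE) {
  ds <- seq.int(window[1], window[2])
  out <- stats::setNames(numeric(length(ds)), ds)
  for (i in seq_along(posA)) for (j in seq_along(posB)) {
    if (exclude_self && posA[i] == posB[j]) next
    d <- posB[j] - posA[i] + offset
    if (d >= window[1] && d <= window[2])
      out[as.character(d)] <- out[as.character(d)] + wA[i] * wB[j]
  }
  out
}

# independent naive scan for all perfect-match locations of one sequence
naive_locations <- function(seq, panel) {
  hits <- 0L
  rc <- pirnasig::revcomp(seq)
  L <- nchar(seq)
  for (r in seq_len(nrow(panel))) {
    ref <- panel$sequence[r]
    nL <- nchar(ref)
    if (nL < L) next
    for (s in seq_len(nL - L + 1L)) {
      win <- substr(ref, s, s + L - 1L)
      if (win == seq) hits <- hits + 1L
      if (win == rc) hits <- hits + 1L
    }
  }
  hits
}

# brute-force library-level signature histograms recomputed directly from
# a weighted_alignments table (reference coordinates throughout)
brute_signature_hists <- function(aln, window_pp = c(1, 30),
                                  window_3 = c(-10, 50),
                                  window_5 = c(1, 100)) {
  rl <- attr(aln, "ref_lengths")
  dpp <- stats::setNames(numeric(diff(window_pp) + 1),
                         seq.int(window_pp[1], window_pp[2]))
  d3 <- stats::setNames(numeric(diff(window_3) + 1),
                        seq.int(window_3[1], window_3[2]))
  d5 <- stats::setNames(numeric(diff(window_5) + 1),
                        seq.int(window_5[1], window_5[2]))
  for (r in unique(aln$ref_id)) {
    sub <- aln[aln$ref_id == r, ]
    plus <- sub[sub$strand == "+", ]
    minus <- sub[sub$strand == "-", ]
    # ping-pong: sense 5' = start, antisense 5' = end - 1 (ref coords)
    if (nrow(plus) && nrow(minus)) {
      for (i in seq_len(nrow(plus))) for (j in seq_len(nrow(minus))) {
        d <- (minus$end[j] - 1L) - plus$start[i] + 1L
        if (d >= window_pp[1] && d <= window_pp[2])
          dpp[as.character(d)] <- dpp[as.character(d)] +
            plus$weight[i] * minus$weight[j]
      }
    }
    # phasing in transcript orientation, per strand
    for (str in c("+", "-")) {
      ss <- sub[sub$strand == str, ]
      if (!nrow(ss)) next
      if (str == "+") { p5 <- ss$start; p3 <- ss$end - 1L }
      else { p5 <- rl[r] - ss$end; p3 <- rl[r] - 1L - ss$start }
      w <- ss$weight
      # aggregate by position first (self-exclusion is position-level)
      a5 <- tapply(w, p5, sum); a3 <- tapply(w, p3, sum)
      pos5 <- as.integer(names(a5)); pos3 <- as.integer(names(a3))
      for (i in seq_along(pos3)) for (j in seq_along(pos5)) {
        d <- pos5[j] - pos3[i] - 1L
        if (d >= window_3[1] && d <= window_3[2])
          d3[as.character(d)] <- d3[as.character(d)] + a3[i] * a5[j]
      }
      for (i in seq_along(pos5)) for (j in seq_along(pos5)) {
        if (i == j) next
        d <- pos5[j] - pos5[i]
        if (d >= window_5[1] && d <= window_5[2])
          d5[as.character(d)] <- d5[as.character(d)] + a5[i] * a5[j]
      }
    }
  }
  list(pp = dpp, p3 = d3, p5 = d5)
}

expect_hist_equal <- function(hist, expected, tol = 1e-9) {
  expect_equal(stats::setNames(hist$weight, hist$distance), expected,
               tolerance = tol)
}
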