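# Weighted pair-distance accumulation. A and B are position/weight pairs
# on one reference; d = posB - posA + offset. Every (a, b) pair with d in
# `window` adds wA * wB to bin d. When `exclude_self` is TRUE, pairs at
# identical positions (the same location paired with itself, d == offset)
# are removed.
.pair_hist <- function(posA, wA, posB, wB, window, offset,
                       exclude_self = FALSE) {
  ds <- seq.int(window[1], window[2])
  out <- numeric(length(ds))
  if (!length(posA) || !length(posB))
    return(stats::setNames(out, ds))
  maxB <- max(posB)
  vec <- numeric(maxB + 1L)
  vec[posB + 1L] <- wB
  for (i in seq_along(ds)) {
    idx <- posA + (ds[i] - offset)
    ok <- idx >= 0L & idx <= maxB
    if (any(ok)) out[i] <- sum(wA[ok] * vec[idx[ok] + 1L])
  }
  if (exclude_self && offset >= window[1] && offset <= window[2]) {
    common <- intersect(posA, posB)
    if (length(common)) {
      i <- match(offset, ds)
      out[i] <- out[i] - sum(wA[match(common, posA)] * wB[match(common, posB)])
    }
  }
  stats::setNames(out, ds)
}

.as_histogram <- function(vals, kind) {
  h <- data.frame(distance = as.integer(names(vals)), weight = unname(vals))
  h$normalized <- if (max(h$weight) > 0) h$weight / max(h$weight) else h$weight
  structure(h, kind = kind, class = c("distance_histogram", "data.frame"))
}

#' Histogram of pairwise end distances
#'
#' Accumulates `weight(a) * weight(b)` over all position pairs of two end
#' selections on the same reference, binned by an integer distance. The
#' three conventions used by the piRNA signatures are: `"pingpong_5p5p"`
#' (`d = b - a + 1`, so a canonical ping-pong pair scores 10),
#' `"phase_3p5p"` (`d = b - a - 1`, so a head-to-tail junction scores 0)
#' and `"phase_5p5p"` (`d = b - a`).
#'
#' @param A,B data.frames with `pos` and `weight` columns (end selections
#'   of an [build_end_profiles()] profile on one reference).
#' @param kind distance convention, see above.
#' @param window `c(min, max)` inclusive integer distance window.
#' @param exclude_self drop pairs of a position with itself; set when A
#'   and B are the same end of the same profile.
#' @return a `distance_histogram` data.frame: `distance`, `weight`,
#'   `normalized` (scaled to max 1).
#' @export
pair_distance_histogram <- function(A, B,
                                    kind = c("pingpong_5p5p", "phase_3p5p",
                                             "phase_5p5p"),
                                    window, exclude_self = FALSE) {
  kind <- match.arg(kind)
  if (window[1] > window[2]) stop("empty window", call. = FALSE)
  offset <- switch(kind, pingpong_5p5p = 1L, phase_3p5p = -1L, phase_5p5p = 0L)
  vals <- .pair_hist(A$pos, A$weight, B$pos, B$weight, window, offset,
                     exclude_self)
  .as_histogram(vals, kind)
}

.signature_z <- function(h, signal, background, type) {
  bg <- h$weight[match(background, h$distance)]
  bg[is.na(bg)] <- 0
  sig <- h$weight[match(signal, h$distance)]
  if (is.na(sig)) sig <- 0
  s <- stats::sd(bg)
  structure(list(type = type, signal = signal, background = background,
                 value = if (s > 0) (sig - mean(bg)) / s else NA_real_,
                 defined = s > 0),
            class = "signature_score")
}

#' @export
print.signature_score <- function(x, ...) {
  cat(sprintf("%s signature score: %s\n", x$type,
              if (x$defined) sprintf("%.3f", x$value) else
                "undefined (zero background sd)"))
  invisible(x)
}

.prof_sel <- function(profiles, ref, str, which_end) {
  sub <- profiles[ref_id == ref & strand == str & end == which_end]
  data.frame(pos = sub$pos, weight = sub$weight)
}

#' Ping-pong signature (Z10)
#'
#' For every reference carrying reads on both strands, computes the 5'-5'
#' sense-antisense distance histogram in reference coordinates,
#' `d = (antisense 5') - (sense 5') + 1`, so the 10-nt overlap diagnostic
#' of the ping-pong amplification cycle falls in bin 10. Histograms are
#' summed across references before scoring. Z10 is the 10-nt bin against
#' the background bins 1-9 and 11-20, standardised by the sample (n-1)
#' standard deviation of the background.
#'
#' @param profiles an `end_profiles` table ([build_end_profiles()]).
#' @param window inclusive distance window of the histogram; must contain
#'   1-20.
#' @return list with `histogram` (`distance_histogram`), `score`
#'   (`signature_score`), and `per_ref` (data.frame of per-reference Z10).
#' @export
pingpong_signature <- function(profiles, window = c(1L, 30L)) {
  rl <- attr(profiles, "ref_lengths")
  ds <- seq.int(window[1], window[2])
  total <- stats::setNames(numeric(length(ds)), ds)
  per_ref <- list()
  refs <- unique(profiles$ref_id)
  for (r in refs) {
    sense <- .prof_sel(profiles, r, "+", "p5")
    anti <- .prof_sel(profiles, r, "-", "p5")
    if (!nrow(sense) || !nrow(anti)) next
    anti$pos <- rl[r] - 1L - anti$pos  # back to reference coordinates
    vals <- .pair_hist(sense$pos, sense$weight, anti$pos, anti$weight,
                       window, 1L)
    total <- total + vals
    zr <- .signature_z(.as_histogram(vals, "pingpong_5p5p"), 10L,
                       c(1:9, 11:20), "Z10")
    per_ref[[r]] <- data.frame(ref_id = r, z10 = zr$value,
                               defined = zr$defined)
  }
  hist <- .as_histogram(total, "pingpong_5p5p")
  list(histogram = hist,
       score = .signature_z(hist, 10L, c(1:9, 11:20), "Z10"),
       per_ref = if (length(per_ref)) do.call(rbind, per_ref) else
         data.frame(ref_id = character(), z10 = numeric(), defined = logical()))
}

#' Phasing signatures (Z0, 3'-to-5' and 5'-to-5' distances)
#'
#' Within each (reference, strand) in transcript orientation, computes the
#' 3'-to-5' distance histogram `d = 5'(downstream) - 3'(upstream) - 1`
#' (head-to-tail junctions of phased piRNA trails score 0) and the 5'-5'
#' distance histogram `d = 5'(down) - 5'(up)` whose ~27-nt periodicity
#' reflects successive phased cuts. Histograms are summed across
#' references and strands before scoring. Z0 is the 0 bin of the 3'-to-5'
#' histogram against the background bins -10..-1 and 1..50 (sample sd).
#'
#' @param profiles an `end_profiles` table.
#' @param window_3p5p,window_5p5p inclusive distance windows.
#' @return list with `hist_3p5p`, `hist_5p5p`, `score` (Z0) and `per_ref`.
#' @export
phasing_signature <- function(profiles, window_3p5p = c(-10L, 50L),
                              window_5p5p = c(1L, 100L)) {
  d3 <- seq.int(window_3p5p[1], window_3p5p[2])
  d5 <- seq.int(window_5p5p[1], window_5p5p[2])
  tot3 <- stats::setNames(numeric(length(d3)), d3)
  tot5 <- stats::setNames(numeric(length(d5)), d5)
  bg <- c(-10:-1, 1:50)
  per_ref <- list()
  combos <- unique(data.frame(ref_id = profiles$ref_id,
                              strand = profiles$strand))
  for (i in seq_len(nrow(combos))) {
    r <- combos$ref_id[i]; s <- combos$strand[i]
    p5 <- .prof_sel(profiles, r, s, "p5")
    p3 <- .prof_sel(profiles, r, s, "p3")
    if (!nrow(p5)) next
    v3 <- .pair_hist(p3$pos, p3$weight, p5$pos, p5$weight, window_3p5p, -1L)
    v5 <- .pair_hist(p5$pos, p5$weight, p5$pos, p5$weight, window_5p5p, 0L,
                     exclude_self = TRUE)
    tot3 <- tot3 + v3
    tot5 <- tot5 + v5
    key <- paste(r, s)
    zr <- .signature_z(.as_histogram(v3, "phase_3p5p"), 0L, bg, "Z0")
    per_ref[[key]] <- data.frame(ref_id = r, strand = s, z0 = zr$value,
                                 defined = zr$defined)
  }
  h3 <- .as_histogram(tot3, "phase_3p5p")
  h5 <- .as_histogram(tot5, "phase_5p5p")
  list(hist_3p5p = h3, hist_5p5p = h5,
       score = .signature_z(h3, 0L, bg, "Z0"),
       per_ref = if (length(per_ref)) do.call(rbind, per_ref) else
         data.frame(ref_id = character(), strand = character(),
                    z0 = numeric(), defined = logical()))
}

#' Periodicity peaks and peak height over baseline
#'
#' Locates the first `n_peaks` periodicity peaks of a 5'-5' distance
#' histogram (peak k = argmax within `k * period +/- tolerance`), takes
#' the baseline as the mean histogram value over the valley strictly
#' between peak 1 and peak 2 excluding `tolerance` bins around each peak,
#' and reports peak height = value(peak 1) - baseline.
#'
#' @param hist a `distance_histogram` (typically `hist_5p5p`).
#' @param expected_period expected peak spacing in nt.
#' @param tolerance search half-width around each multiple of the period.
#' @param n_peaks number of peaks to locate (>= 2).
#' @return list with `periodicity`, `peaks` (data.frame k/distance/value),
#'   `baseline`, `height`.
#' @export
peak_baseline_metrics <- function(hist, expected_period = 27L, tolerance = 2L,
                                  n_peaks = 2L) {
  if (!nrow(hist)) stop("empty histogram", call. = FALSE)
  if (n_peaks < 2L) stop("need at least two peaks", call. = FALSE)
  peaks <- lapply(seq_len(n_peaks), function(k) {
    rng <- seq.int(k * expected_period - tolerance, k * expected_period + tolerance)
    rows <- hist[hist$distance %in% rng, , drop = FALSE]
    if (!nrow(rows))
      stop("histogram window too small to hold the requested peaks",
           call. = FALSE)
    best <- rows[which.max(rows$weight), ]
    data.frame(k = k, distance = best$distance, value = best$weight)
  })
  peaks <- do.call(rbind, peaks)
  p1 <- peaks$distance[1]; p2 <- peaks$distance[2]
  valley <- seq.int(p1 + tolerance + 1L, p2 - tolerance - 1L)
  if (length(valley) < 3L)
    stop("fewer than 3 distances between the first two peaks", call. = FALSE)
  vals <- hist$weight[match(valley, hist$distance)]
  vals[is.na(vals)] <- 0
  baseline <- mean(vals)
  list(periodicity = expected_period, peaks = peaks, baseline = baseline,
       height = peaks$value[1] - baseline)
}

#' Positional nucleotide bias of read species
#'
#' Fraction of eligible read species carrying a given base at a given
#' read position (1 = the 5'-most sequenced nucleotide). A species is
#' eligible when its read count is at least `min_count`; each eligible
#' species contributes exactly once (1 if it carries the base, else 0),
#' and species shorter than the queried position count as 0. The two
#' standard queries are 1U (`position = 1, base = "T"`, the primary /
#' antisense piRNA signature) and 10A (`position = 10, base = "A"`, the
#' ping-pong responder signature).
#'
#' @param species a table with `sequence` and `count` columns.
#' @param position 1-based read position queried.
#' @param base queried base; `"U"` is accepted as an alias of `"T"`.
#' @param min_count eligibility threshold on the species read count.
#' @param scope label recorded in the result (e.g. `"sense"`).
#' @return a `nucleotide_bias` list: `scope`, `position`, `base`,
#'   `n_eligible`, `n_hit`, `percent`, `defined`.
#' @export
nucleotide_bias <- function(species, position, base, min_count = 5L,
                            scope = "both") {
  base <- toupper(base)
  if (base == "U") base <- "T"
  elig <- species[species$count >= min_count, , drop = FALSE]
  n_eligible <- nrow(elig)
  n_hit <- if (n_eligible) sum(substr(elig$sequence, position, position) == base)
           else 0L
  structure(list(scope = scope, position = as.integer(position), base = base,
                 n_eligible = n_eligible, n_hit = n_hit,
                 percent = if (n_eligible > 0) 100 * n_hit / n_eligible
                           else NA_real_,
                 defined = n_eligible > 0),
            class = "nucleotide_bias")
}

#' @export
print.nucleotide_bias <- function(x, ...) {
  cat(sprintf("%d%s bias (%s strand): %s  [%d/%d species]\n", x$position,
              ifelse(x$base == "T", "U", x$base), x$scope,
              if (x$defined) sprintf("%.1f%%", x$percent) else "undefined",
              x$n_hit, x$n_eligible))
  invisible(x)
}

#' Extract the species aligned to a strand scope
#'
#' @param alignments a `weighted_alignments` table.
#' @param scope `"sense"` (at least one `+` alignment), `"antisense"`
#'   (at least one `-`), or `"both"` (any alignment).
#' @return a species data.table (`species_id`, `sequence`, `count`).
#' @export
strand_species <- function(alignments, scope = c("both", "sense", "antisense")) {
  scope <- match.arg(scope)
  sub <- switch(scope, both = alignments,
                sense = alignments[strand == "+"],
                antisense = alignments[strand == "-"])
  unique(sub[, .(species_id, sequence, count)])
}

#' Nucleotide bias restricted to an IP-assigned piRNA group
#'
#' Identical to [nucleotide_bias()] but scoped to the intersection of the
#' sample's species with one PIWI-clade IP group (species are matched by
#' sequence).
#'
#' @param species sample species table (`sequence`, `count`).
#' @param assignments an `ip_assignment` table ([ip_group_assignment()]).
#' @param group one of the assigned group labels (e.g. `"Ago3"`).
#' @inheritParams nucleotide_bias
#' @return a `nucleotide_bias` result (undefined if the intersection is
#'   empty).
#' @export
ip_overlap_bias <- function(species, assignments, group, position, base,
                            min_count = 5L) {
  grp_seqs <- assignments$sequence[assignments$assigned == group]
  sub <- species[species$sequence %in% grp_seqs, , drop = FALSE]
  nucleotide_bias(sub, position, base, min_count, scope = paste0("IP:", group))
}
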