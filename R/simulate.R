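#' Specification of a synthetic small-RNA library
#'
#' Describes one simulated ovary small-RNA library over a consensus TE
#' panel. Reads are emitted by three pathways: ping-pong sense/antisense
#' pairs with an exact 10-nt 5'-5' overlap, head-to-tail phased trails
#' (3'-to-5' junction distance 0, ~one-read-length 5'-5' periodicity), and
#' uniform background noise. Reads not allocated to ping-pong or phasing
#' are emitted as noise, so `noise_fraction` is a floor, not a cap.
#'
#' Nucleotide biases (1U at phased-read 5' ends, 10A at ping-pong sense
#' position 10) are imposed by rejection-sampling placement positions
#' against the fixed reference, never by mutating reads, so every read
#' stays a perfect match to its source TE. The acceptance probability for
#' a non-matching candidate site is solved from the reference base
#' frequency p and the target marginal bias t: q = p(1-t) / (t(1-p))
#' (roles swap when t < p), which makes the realized marginal exactly t
#' when candidate-site bases occur at frequency p.
#'
#' @param n_reads total reads to emit.
#' @param pingpong_fraction fraction of reads emitted as 10-nt-overlap
#'   sense/antisense pairs.
#' @param phased_fraction fraction emitted as head-to-tail phased trails.
#' @param noise_fraction minimum fraction of uniform background reads.
#' @param read_length_mean,read_length_sd normal read-length model (nt),
#'   rounded and clipped to `read_length_range`.
#' @param read_length_range length clip window, within 19-35 nt.
#' @param u1_prob probability that a phased read's 5' base sits on a
#'   reference T (1U bias).
#' @param a10_prob probability that a ping-pong sense read has reference A
#'   at read position 10 (10A bias).
#' @param seed integer RNG seed.
#' @param genotype label attached to the library.
#' @param sense_scale,antisense_scale per-strand emission multipliers;
#'   reads on the down-weighted strand are thinned after emission with
#'   probability `scale / max(scales, 1)`.
#' @return a validated `library_sim_spec` list.
#' @export
library_sim_spec <- function(n_reads, pingpong_fraction = 0, phased_fraction = 0,
                             noise_fraction = NULL,
                             read_length_mean = 26.5, read_length_sd = 1.5,
                             read_length_range = c(23, 28),
                             u1_prob = 0.78, a10_prob = 0.65,
                             seed = 1L, genotype = "WT",
                             sense_scale = 1, antisense_scale = 1) {
  n_reads <- .check_count(n_reads, "n_reads")
  .check_fraction(pingpong_fraction, "pingpong_fraction")
  .check_fraction(phased_fraction, "phased_fraction")
  if (is.null(noise_fraction))
    noise_fraction <- max(0, 1 - pingpong_fraction - phased_fraction)
  .check_fraction(noise_fraction, "noise_fraction")
  if (pingpong_fraction + phased_fraction + noise_fraction > 1 + 1e-9)
    stop("pingpong_fraction + phased_fraction + noise_fraction must be <= 1",
         call. = FALSE)
  rr <- as.integer(read_length_range)
  if (length(rr) != 2L || rr[1] < 19L || rr[2] > 35L || rr[1] > rr[2])
    stop("read_length_range must lie within [19, 35]", call. = FALSE)
  .check_fraction(u1_prob, "u1_prob")
  .check_fraction(a10_prob, "a10_prob")
  if (sense_scale < 0 || antisense_scale < 0)
    stop("strand scales must be >= 0", call. = FALSE)
  structure(list(n_reads = n_reads, pingpong_fraction = pingpong_fraction,
                 phased_fraction = phased_fraction, noise_fraction = noise_fraction,
                 read_length_mean = read_length_mean, read_length_sd = read_length_sd,
                 read_length_range = rr, u1_prob = u1_prob, a10_prob = a10_prob,
                 seed = as.integer(seed), genotype = genotype,
                 sense_scale = sense_scale, antisense_scale = antisense_scale),
            class = "library_sim_spec")
}

#' Per-genotype pathway suppression
#'
#' Emulates mutant genotypes (e.g. an *aub* knockdown collapsing the
#' ping-pong cycle, or a double mutant suppressing both pathways) as
#' multipliers applied to a library spec and, for count-table simulation,
#' per-TE RNA fold changes.
#'
#' @param genotype genotype label.
#' @param pingpong_scale,phased_scale multipliers on the pathway fractions.
#' @param sense_scale,antisense_scale per-strand emission multipliers.
#' @param te_fc_map named numeric vector of per-TE RNA fold changes for
#'   [simulate_count_table()]; unnamed TEs default to 1.
#' @return a `condition_effect` list.
#' @export
condition_effect <- function(genotype, pingpong_scale = 1, phased_scale = 1,
                             sense_scale = 1, antisense_scale = 1,
                             te_fc_map = NULL) {
  sc <- c(pingpong_scale, phased_scale, sense_scale, antisense_scale)
  if (any(sc < 0) || (!is.null(te_fc_map) && any(te_fc_map < 0)))
    stop("all multipliers must be >= 0", call. = FALSE)
  structure(list(genotype = genotype, pingpong_scale = pingpong_scale,
                 phased_scale = phased_scale, sense_scale = sense_scale,
                 antisense_scale = antisense_scale, te_fc_map = te_fc_map),
            class = "condition_effect")
}

#' Apply a genotype effect to a library spec
#'
#' Pathway fractions are multiplied by the effect's scales and the freed
#' probability mass is re-normalized into noise; the genotype label and
#' strand scales are attached.
#'
#' @param spec a [library_sim_spec()].
#' @param effect a [condition_effect()].
#' @return a new `library_sim_spec`.
#' @export
apply_condition_effect <- function(spec, effect) {
  stopifnot(inherits(spec, "library_sim_spec"), inherits(effect, "condition_effect"))
  pp <- spec$pingpong_fraction * effect$pingpong_scale
  ph <- spec$phased_fraction * effect$phased_scale
  if (pp > 1 || ph > 1 || pp + ph > 1)
    stop("scaled pathway fractions fall outside [0, 1]", call. = FALSE)
  library_sim_spec(
    n_reads = spec$n_reads, pingpong_fraction = pp, phased_fraction = ph,
    noise_fraction = 1 - pp - ph,
    read_length_mean = spec$read_length_mean, read_length_sd = spec$read_length_sd,
    read_length_range = spec$read_length_range,
    u1_prob = spec$u1_prob, a10_prob = spec$a10_prob,
    seed = spec$seed, genotype = effect$genotype,
    sense_scale = spec$sense_scale * effect$sense_scale,
    antisense_scale = spec$antisense_scale * effect$antisense_scale)
}

# Acceptance probabilities for rejection sampling a site whose base should
# equal `base` with marginal probability t, given background frequency p.
.reject_q <- function(p, t) {
  if (t >= p) list(match = 1, other = p * (1 - t) / (t * (1 - p)))
  else list(match = t * (1 - p) / (p * (1 - t)), other = 1)
}

# Discretized read-length distribution over the clip window (rounding mass
# outside the window is lumped onto the bounds).
.length_pmf <- function(spec) {
  vals <- seq.int(spec$read_length_range[1], spec$read_length_range[2])
  lo_edge <- vals - 0.5; hi_edge <- vals + 0.5
  lo_edge[1] <- -Inf; hi_edge[length(vals)] <- Inf
  p <- stats::pnorm(hi_edge, spec$read_length_mean, spec$read_length_sd) -
       stats::pnorm(lo_edge, spec$read_length_mean, spec$read_length_sd)
  stats::setNames(p / sum(p), vals)
}

# A phased-trail junction can only land on the handful of sites reachable
# by the possible read lengths, so the single-site acceptance probability
# under-biases it. Solve the non-match acceptance q numerically so that
# the expected fraction of junctions landing on the target base, averaged
# over i.i.d. site configurations, equals t:
#   E_config[ W_match / (W_match + q * W_other) ] = t
# where W are the length-pmf masses of matching / non-matching sites.
.solve_junction_q <- function(w, p, t) {
  k <- length(w)
  configs <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), k)))
  prob <- apply(configs, 1, function(m) prod(ifelse(m, p, 1 - p)))
  wm <- as.vector(configs %*% w)
  wo <- sum(w) - wm
  marg <- function(q) sum(prob * ifelse(wm + q * wo > 0, wm / (wm + q * wo), 0))
  if (marg(0) <= t) return(0)  # t at or above the attainable maximum
  if (marg(1) >= t) return(1)
  stats::uniroot(function(q) marg(q) - t, c(0, 1), tol = 1e-9)$root
}

.draw_lengths <- function(n, spec) {
  if (n == 0L) return(integer(0))
  L <- as.integer(round(rnorm(n, spec$read_length_mean, spec$read_length_sd)))
  pmin(pmax(L, spec$read_length_range[1]), spec$read_length_range[2])
}

# Vectorised rejection sampling of positions in [lo, hi] (0-based): the
# checked site is chars[pos + site_offset + 1]; accept with prob acc$match
# when it equals `base`, else acc$other. Falls back to uniform after 500
# rounds (degenerate references).
.reject_positions <- function(chars, lo, hi, site_offset, base, acc) {
  n <- length(lo)
  out <- integer(n)
  pending <- seq_len(n)
  for (round in 1:500) {
    cand <- lo[pending] +
      as.integer(floor(runif(length(pending)) * (hi[pending] - lo[pending] + 1)))
    p_acc <- ifelse(chars[cand + site_offset + 1L] == base, acc$match, acc$other)
    take <- runif(length(pending)) < p_acc
    out[pending[take]] <- cand[take]
    pending <- pending[!take]
    if (!length(pending)) break
  }
  if (length(pending))
    out[pending] <- lo[pending] +
      as.integer(floor(runif(length(pending)) * (hi[pending] - lo[pending] + 1)))
  out
}

#' Simulate a small-RNA library with ground truth
#'
#' Emits reads from a consensus TE panel through three pathways (see
#' [library_sim_spec()]) and records, for every read, its source TE,
#' strand, 0-based half-open reference interval, pathway and pair/trail
#' identifier.
#'
#' Ping-pong pairs place the sense read's 5' end at `s` and the antisense
#' partner's 5' end at `s + 9` in reference coordinates, so the 5'-5'
#' overlap is exactly 10 nt by construction. Phased trails are consecutive
#' same-strand reads with `5'(i+1) = 3'(i) + 1` (3'-to-5' distance 0);
#' trail lengths are geometric with mean 6 reads, one trail per random
#' start. Every read is an exact substring of its source TE (reverse
#' complement on the minus strand); TEs are chosen with probability
#' proportional to length.
#'
#' @param panel a [te_panel()].
#' @param spec a [library_sim_spec()].
#' @return list with `reads` (data.table: read_id, sequence) and `truth`
#'   (data.table: read_id, te_id, strand, start, end, pathway, group_id),
#'   plus the spec echoed back.
#' @export
simulate_library <- function(panel, spec) {
  stopifnot(inherits(panel, "te_panel"), inherits(spec, "library_sim_spec"))
  max_rl <- spec$read_length_range[2]
  if (any(panel$length < max_rl + 10L))
    stop("panel sequences too short for requested read lengths", call. = FALSE)
  with_seed(spec$seed, {
    chars <- strsplit(panel$sequence, "", fixed = TRUE)
    comp_map <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
    rc_chars <- lapply(chars, function(x) rev(unname(comp_map[x])))
    all_bases <- unlist(chars, use.names = FALSE)
    # phased trails run on either strand: T frequency at a random site is
    # the average of T on + and T on - (= A on +)
    pT <- (sum(all_bases == "T") + sum(all_bases == "A")) / (2 * length(all_bases))
    pA_plus <- mean(all_bases == "A")  # ping-pong 10A sites sit on the + strand
    lens <- panel$length
    te_w <- lens / sum(lens)

    n_pairs <- round(spec$n_reads * spec$pingpong_fraction) %/% 2L
    n_phase <- as.integer(round(spec$n_reads * spec$phased_fraction))

    te_idx <- list(); strand <- list(); start <- list(); end <- list()
    pathway <- list(); group <- list()

    ## ping-pong pairs -----------------------------------------------------
    if (n_pairs > 0) {
      acc <- .reject_q(pA_plus, spec$a10_prob)
      te_pp <- sample.int(nrow(panel), n_pairs, replace = TRUE, prob = te_w)
      Ls <- .draw_lengths(n_pairs, spec)
      La <- .draw_lengths(n_pairs, spec)
      s <- integer(n_pairs)
      for (t in unique(te_pp)) {
        ii <- which(te_pp == t); L <- lens[t]
        lo <- pmax(0L, La[ii] - 10L)
        hi <- pmin(L - Ls[ii], L - 10L)
        s[ii] <- .reject_positions(chars[[t]], lo, hi, 9L, "A", acc)
      }
      pair_id <- sprintf("pp%06d", seq_len(n_pairs))
      te_idx[["pp"]] <- rep(te_pp, 2L)
      strand[["pp"]] <- rep(c("+", "-"), each = n_pairs)
      start[["pp"]] <- c(s, s + 10L - La)
      end[["pp"]] <- c(s + Ls, s + 10L)
      pathway[["pp"]] <- rep("pingpong", 2L * n_pairs)
      group[["pp"]] <- rep(pair_id, 2L)
    }

    ## phased trails -------------------------------------------------------
    if (n_phase > 0) {
      acc <- .reject_q(pT, spec$u1_prob)
      lpmf <- .length_pmf(spec)
      len_vals <- as.integer(names(lpmf))
      qj <- .solve_junction_q(lpmf, pT, spec$u1_prob)
      min_rl <- spec$read_length_range[1]
      ph_te <- integer(n_phase); ph_str <- character(n_phase)
      ph_a <- integer(n_phase); ph_len <- integer(n_phase)
      ph_grp <- integer(n_phase)
      emitted <- 0L; trail <- 0L
      while (emitted < n_phase) {
      trail <- trail + 1L
      t <- sample.int(nrow(panel), 1L, prob = te_w)
      str <- if (runif(1) < 0.5) "+" else "-"
      tch <- if (str == "+") chars[[t]] else rc_chars[[t]]
      Lt <- lens[t]
      k <- rgeom(1L, 1 / 6) + 1L
      k <- min(k, n_phase - emitted)
      len1 <- .draw_lengths(1L, spec)
      a <- .reject_positions(tch, 0L, Lt - max_rl - 1L, 0L, "T", acc)
      for (i in seq_len(k)) {
        # read i starts at a; its length fixes the next 5' junction, which
        # is rejection-sampled for the 1U bias unless this is the last read
        if (i < k && a + max_rl + min_rl <= Lt) {
          # junction = next read's 5' site; categorical draw over candidate
          # lengths reweighted by the solved acceptance (equivalent to
          # rejection sampling restricted to the reachable sites)
          fits <- a + len_vals + min_rl <= Lt
          site_t <- tch[a + len_vals + 1L] == "T"
          w <- lpmf * ifelse(site_t, 1, qj) * fits
          if (sum(w) == 0) w <- lpmf * fits
          li <- len_vals[sample.int(length(len_vals), 1L, prob = w)]
        } else {
          li <- min(.draw_lengths(1L, spec), Lt - a)
        }
        emitted <- emitted + 1L
        ph_te[emitted] <- t; ph_str[emitted] <- str
        ph_a[emitted] <- a; ph_len[emitted] <- li
        ph_grp[emitted] <- trail
        a <- a + li
        if (i < k && a + min_rl > Lt) break  # trail ran off the reference
        if (emitted >= n_phase) break
      }
      }
      # transcript coords -> reference coords for minus-strand trails
      ref_start <- ifelse(ph_str == "+", ph_a, lens[ph_te] - (ph_a + ph_len))
      te_idx[["ph"]] <- ph_te
      strand[["ph"]] <- ph_str
      start[["ph"]] <- as.integer(ref_start)
      end[["ph"]] <- as.integer(ref_start + ph_len)
      pathway[["ph"]] <- rep("phased", n_phase)
      group[["ph"]] <- sprintf("tr%06d", ph_grp)
    }

    ## background noise ----------------------------------------------------
    n_noise <- spec$n_reads - 2L * n_pairs - n_phase
    if (n_noise > 0) {
      te_n <- sample.int(nrow(panel), n_noise, replace = TRUE, prob = te_w)
      ln <- .draw_lengths(n_noise, spec)
      st <- as.integer(floor(runif(n_noise) * (lens[te_n] - ln + 1)))
      te_idx[["ns"]] <- te_n
      strand[["ns"]] <- sample(c("+", "-"), n_noise, replace = TRUE)
      start[["ns"]] <- st
      end[["ns"]] <- st + ln
      pathway[["ns"]] <- rep("noise", n_noise)
      group[["ns"]] <- sprintf("ns%06d", seq_len(n_noise))
    }

    truth <- data.table::data.table(
      te_idx = unlist(te_idx), strand = unlist(strand),
      start = unlist(start), end = unlist(end),
      pathway = unlist(pathway), group_id = unlist(group))

    ## per-strand thinning -------------------------------------------------
    m <- max(spec$sense_scale, spec$antisense_scale, 1)
    if (spec$sense_scale / m < 1 || spec$antisense_scale / m < 1) {
      keep_p <- ifelse(truth$strand == "+", spec$sense_scale / m,
                       spec$antisense_scale / m)
      truth <- truth[runif(nrow(truth)) < keep_p]
    }

    truth[, read_id := sprintf("r%07d", .I)]
    truth[, te_id := panel$id[te_idx]]
    seqs <- substring(panel$sequence[truth$te_idx], truth$start + 1L, truth$end)
    neg <- truth$strand == "-"
    if (any(neg)) seqs[neg] <- revcomp(seqs[neg])
    reads <- data.table::data.table(read_id = truth$read_id, sequence = seqs)
    truth <- truth[, .(read_id, te_id, strand, start, end, pathway, group_id)]
    list(reads = reads, truth = truth, spec = spec)
  })
}

#' Simulate a replicated TE count table
#'
#' Per-TE baseline means are drawn once (log-normal), per-genotype means
#' are the baseline times the genotype's `te_fc_map`, and replicate counts
#' are drawn from a negative-binomial count model with variance
#' `mu + dispersion * mu^2` (`dispersion = 0` gives Poisson counts).
#'
#' @param panel a [te_panel()].
#' @param genotypes list of [condition_effect()]s; the first is treated as
#'   the reference when naming samples.
#' @param n_reps replicates per genotype (>= 2).
#' @param dispersion negative-binomial overdispersion (>= 0).
#' @param seed integer RNG seed.
#' @param baseline_log_mean,baseline_log_sd log-normal baseline model.
#' @return a [te_count_table()].
#' @export
simulate_count_table <- function(panel, genotypes, n_reps, dispersion = 0.1,
                                 seed = 1L, baseline_log_mean = log(200),
                                 baseline_log_sd = 1) {
  stopifnot(inherits(panel, "te_panel"))
  n_reps <- .check_count(n_reps, "n_reps", min = 2L)
  if (dispersion < 0) stop("dispersion must be >= 0", call. = FALSE)
  if (!length(genotypes) || !all(vapply(genotypes, inherits, TRUE, "condition_effect")))
    stop("genotypes must be a list of condition_effect objects", call. = FALSE)
  with_seed(seed, {
    n_te <- nrow(panel)
    baseline <- exp(rnorm(n_te, baseline_log_mean, baseline_log_sd))
    cols <- list(); samples <- list()
    for (g in genotypes) {
      fc <- rep(1, n_te)
      if (!is.null(g$te_fc_map)) {
        hit <- match(names(g$te_fc_map), panel$id)
        if (anyNA(hit)) stop("te_fc_map names not in panel", call. = FALSE)
        fc[hit] <- g$te_fc_map
      }
      mu <- baseline * fc
      for (r in seq_len(n_reps)) {
        nm <- sprintf("%s_rep%d", g$genotype, r)
        cnt <- if (dispersion == 0) rpois(n_te, mu)
               else rnbinom(n_te, mu = mu, size = 1 / dispersion)
        cols[[nm]] <- cnt
        samples[[nm]] <- g$genotype
      }
    }
    counts <- do.call(cbind, cols)
    rownames(counts) <- panel$id
    te_count_table(counts,
                   lengths = stats::setNames(panel$length, panel$id),
                   genotypes = unlist(samples))
  })
}
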