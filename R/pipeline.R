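.default_config <- function() {
  list(
    seed = 1L,
    outdir = "pirnasig_run",
    panel = list(n_te = 50L, length_range = c(500L, 5000L),
                 repeat_fraction = 0.1, fasta = NULL),
    library = list(n_reads = 20000L, pingpong_fraction = 0.25,
                   phased_fraction = 0.35, u1_prob = 0.78, a10_prob = 0.65,
                   read_length_mean = 26.5, read_length_sd = 1.5,
                   read_length_range = c(23L, 28L)),
    genotypes = list(
      list(genotype = "WT", role = "control"),
      list(genotype = "mut", role = "single", pingpong_scale = 0.1,
           phased_scale = 0.5, sense_scale = 0.6)),
    counts = list(n_reps = 3L, dispersion = 0.1),
    trim = list(mode = "none", trim_len = 30L, adapter_seq = NULL),
    size_window = c(23L, 28L),
    min_species_count = 5L,
    signatures = list(pingpong_window = c(1L, 30L),
                      phase_window_3p5p = c(-10L, 50L),
                      phase_window_5p5p = c(1L, 100L),
                      period = 27L, tolerance = 2L),
    de = list(alpha = 0.05, lfc_theta = 0.58, method = "welch_log"),
    gi = list(cutoff = 2),
    quadrant = list(len_cut_log10 = 3.7, expr_cut_log10 = 1.0),
    concomitant = list(cutoff = 2),
    ip = list(fold = 3, pseudocount = 0.5, min_count = 5L),
    write_fastq = FALSE,
    stages = c("simulate", "align", "signatures", "quantify", "de",
               "gi", "quadrant", "concomitant", "ipassign")
  )
}

.merge_config <- function(defaults, user) {
  for (k in names(user)) {
    if (!k %in% names(defaults))
      stop(sprintf("unknown config key '%s'", k), call. = FALSE)
    if (is.list(defaults[[k]]) && is.list(user[[k]]) &&
        !is.null(names(defaults[[k]])) && k != "genotypes") {
      for (k2 in names(user[[k]])) {
        if (!k2 %in% names(defaults[[k]]) && !k2 %in%
            c("fasta", "adapter_seq"))
          stop(sprintf("unknown config key '%s.%s'", k, k2), call. = FALSE)
        defaults[[k]][[k2]] <- user[[k]][[k2]]
      }
    } else defaults[[k]] <- user[[k]]
  }
  defaults
}

#' Build a validated pipeline configuration
#'
#' Defaults encode every stage parameter of the pipeline (trim mode, size
#' window, minimum species count, signature windows, DE cutoffs, GI and
#' quadrant cutoffs, IP fold). Unknown keys are rejected. A configuration
#' can be given as an R list or a JSON file; [write_config()] round-trips
#' it.
#'
#' @param config an R list of overrides, or the path of a JSON config.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1L)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  cfg <- .merge_config(.default_config(), config)
  if (is.data.frame(cfg$genotypes))
    cfg$genotypes <- lapply(seq_len(nrow(cfg$genotypes)), function(i)
      as.list(cfg$genotypes[i, , drop = FALSE]))
  roles <- vapply(cfg$genotypes, function(g) g$role %||% "single", "")
  if (sum(roles == "control") != 1L)
    stop("exactly one genotype must have role 'control'", call. = FALSE)
  structure(cfg, class = "pipeline_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @param config a `pipeline_config`.
#' @param path output JSON path.
#' @rdname pipeline_config
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

.effect_from_cfg <- function(g) {
  condition_effect(g$genotype,
                   pingpong_scale = g$pingpong_scale %||% 1,
                   phased_scale = g$phased_scale %||% 1,
                   sense_scale = g$sense_scale %||% 1,
                   antisense_scale = g$antisense_scale %||% 1,
                   te_fc_map = if (!is.null(g$te_fc_map))
                     unlist(g$te_fc_map) else NULL)
}

.write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full analysis pipeline on synthetic libraries
#'
#' Executes simulate -> collapse/trim -> align -> end profiles ->
#' signature statistics -> quantification -> differential expression ->
#' GI / quadrant / concomitant / IP stages as requested by
#' `config$stages`, writing one TSV/JSON artifact per stage plus a run
#' manifest with md5 digests of every output. Later stages that depend on
#' skipped ones are skipped silently; the report notes the gaps.
#'
#' @param config a [pipeline_config()] (or list/path coerced through it).
#' @return the run manifest (list), invisibly; `manifest.json` and all
#'   stage outputs are written under `config$outdir`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (!inherits(config, "pipeline_config")) config <- pipeline_config(config)
  outdir <- config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  outputs <- character(0)
  stages_run <- character(0)
  msg <- function(...) message(sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                                       sprintf(...)))
  roles <- vapply(config$genotypes, function(g) g$role %||% "single", "")
  control <- config$genotypes[[which(roles == "control")[1]]]$genotype

  ## panel ------------------------------------------------------------------
  if (!is.null(config$panel$fasta)) {
    if (!file.exists(config$panel$fasta))
      stop("panel FASTA not found: ", config$panel$fasta, call. = FALSE)
    panel <- read_te_panel(config$panel$fasta)
  } else {
    panel <- generate_te_panel(te_panel_spec(
      config$panel$n_te, config$panel$length_range,
      config$panel$repeat_fraction, seed = config$seed))
  }
  outputs <- c(outputs, write_te_panel(panel, file.path(outdir, "panel.fasta")))

  libs <- list(); species <- list(); aligned <- list(); profiles <- list()
  sig_rows <- list(); bias_rows <- list(); hist_files <- character(0)

  if ("simulate" %in% config$stages) {
    msg("simulate: %d genotypes", length(config$genotypes))
    base_spec <- do.call(library_sim_spec,
                         c(config$library, list(seed = config$seed)))
    for (i in seq_along(config$genotypes)) {
      g <- config$genotypes[[i]]
      spec <- apply_condition_effect(base_spec, .effect_from_cfg(g))
      spec$seed <- config$seed + i
      libs[[g$genotype]] <- simulate_library(panel, spec)
      outputs <- c(outputs, .write_tsv(libs[[g$genotype]]$truth,
        file.path(outdir, sprintf("truth_%s.tsv", g$genotype))))
      if (isTRUE(config$write_fastq))
        outputs <- c(outputs, write_fastq(libs[[g$genotype]]$reads,
          file.path(outdir, sprintf("reads_%s.fastq.gz", g$genotype))))
    }
    stages_run <- c(stages_run, "simulate")
  }

  if ("align" %in% config$stages && length(libs)) {
    for (gn in names(libs)) {
      msg("align: %s", gn)
      reads <- libs[[gn]]$reads
      sp <- if (config$trim$mode == "none") collapse_species(reads$sequence)
            else trim_and_collapse(reads, mode = config$trim$mode,
                                   trim_len = config$trim$trim_len,
                                   adapter_seq = config$trim$adapter_seq)
      sf <- size_filter(sp, config$size_window[1], config$size_window[2])
      outputs <- c(outputs, .write_tsv(sf$histogram,
        file.path(outdir, sprintf("sizes_%s.tsv", gn))))
      species[[gn]] <- sf$species
      aligned[[gn]] <- align_species(sf$species, panel)
      profiles[[gn]] <- build_end_profiles(aligned[[gn]])
    }
    stages_run <- c(stages_run, "align")
  }

  if ("signatures" %in% config$stages && length(profiles)) {
    sg <- config$signatures
    for (gn in names(profiles)) {
      msg("signatures: %s", gn)
      pp <- pingpong_signature(profiles[[gn]], sg$pingpong_window)
      ph <- phasing_signature(profiles[[gn]], sg$phase_window_3p5p,
                              sg$phase_window_5p5p)
      pk <- tryCatch(peak_baseline_metrics(ph$hist_5p5p, sg$period,
                                           sg$tolerance),
                     error = function(e) NULL)
      sig_rows[[gn]] <- data.frame(
        library = gn,
        z10 = pp$score$value, z10_defined = pp$score$defined,
        z0 = ph$score$value, z0_defined = ph$score$defined,
        peak1 = if (!is.null(pk)) pk$peaks$distance[1] else NA,
        peak2 = if (!is.null(pk)) pk$peaks$distance[2] else NA,
        peak_height = if (!is.null(pk)) pk$height else NA,
        baseline = if (!is.null(pk)) pk$baseline else NA)
      hists <- rbind(
        cbind(kind = "pingpong_5p5p", pp$histogram),
        cbind(kind = "phase_3p5p", ph$hist_3p5p),
        cbind(kind = "phase_5p5p", ph$hist_5p5p))
      f <- .write_tsv(hists, file.path(outdir, sprintf("histograms_%s.tsv", gn)))
      outputs <- c(outputs, f); hist_files <- c(hist_files, f)
      for (scope in c("sense", "antisense", "both")) {
        ssp <- strand_species(aligned[[gn]], scope)
        for (q in list(c(1, "T"), c(10, "A"))) {
          b <- nucleotide_bias(ssp, as.integer(q[1]), q[2],
                               config$min_species_count, scope)
          bias_rows[[length(bias_rows) + 1L]] <- data.frame(
            library = gn, scope = scope, position = b$position, base = b$base,
            eligible = b$n_eligible, hits = b$n_hit, percent = b$percent)
        }
      }
    }
    outputs <- c(outputs, .write_tsv(do.call(rbind, sig_rows),
      file.path(outdir, "signatures.tsv")))
    outputs <- c(outputs, .write_tsv(do.call(rbind, bias_rows),
      file.path(outdir, "bias.tsv")))
    stages_run <- c(stages_run, "signatures")
  }

  ## RNA-level count table, DE, GI, quadrant -------------------------------
  de_list <- list(); rna <- NULL; pir <- NULL
  if ("quantify" %in% config$stages) {
    msg("quantify: RNA count table (%d reps)", config$counts$n_reps)
    effects <- lapply(config$genotypes, .effect_from_cfg)
    rna <- simulate_count_table(panel, effects, config$counts$n_reps,
                                config$counts$dispersion,
                                seed = config$seed + 1000L)
    cm <- data.frame(feature = rownames(rna$counts), rna$counts,
                     check.names = FALSE)
    outputs <- c(outputs, .write_tsv(cm, file.path(outdir, "counts.tsv")))
    if (length(aligned)) {
      qt <- lapply(names(aligned), function(gn)
        quantify_te(aligned[[gn]], panel, per_strand = TRUE,
                    min_species_count = config$min_species_count))
      names(qt) <- names(aligned)
      pir <- combine_quantifications(qt, genotypes = names(aligned))
      pm <- data.frame(feature = rownames(pir$counts), pir$counts,
                       check.names = FALSE)
      outputs <- c(outputs, .write_tsv(pm,
        file.path(outdir, "pirna_strand_counts.tsv")))
    }
    stages_run <- c(stages_run, "quantify")
  }
  if ("de" %in% config$stages && !is.null(rna)) {
    for (g in config$genotypes) {
      if (g$genotype == control) next
      msg("de: %s vs %s", g$genotype, control)
      de <- differential_expression(rna, control, g$genotype,
                                    alpha = config$de$alpha,
                                    lfc_theta = config$de$lfc_theta,
                                    method = config$de$method)
      de_list[[g$genotype]] <- de
      outputs <- c(outputs, .write_tsv(de,
        file.path(outdir, sprintf("de_%s.tsv", g$genotype))))
    }
    stages_run <- c(stages_run, "de")
  }

  roles_by_gt <- stats::setNames(roles,
    vapply(config$genotypes, function(g) g$genotype, ""))
  singles <- names(roles_by_gt)[roles_by_gt == "single"]
  doubles <- names(roles_by_gt)[roles_by_gt == "double"]

  gi <- NULL
  if ("gi" %in% config$stages && length(de_list) &&
      length(doubles) >= 1L && length(singles) >= 2L) {
    msg("gi: %s vs %s + %s", doubles[1], singles[1], singles[2])
    desil <- de_list[[doubles[1]]]$feature[de_list[[doubles[1]]]$call == "up"]
    gi <- gi_scores(de_list[[doubles[1]]], de_list[[singles[1]]],
                    de_list[[singles[2]]], desilenced = desil)
    outputs <- c(outputs, .write_tsv(gi, file.path(outdir, "gi.tsv")))
    stages_run <- c(stages_run, "gi")
  }

  quad <- NULL
  if ("quadrant" %in% config$stages && length(de_list) && !is.null(rna)) {
    focus <- if (length(doubles)) doubles[1] else names(de_list)[1]
    msg("quadrant: de-silenced set from %s", focus)
    ctrl_cols <- rna$samples$sample[rna$samples$genotype == control]
    rp <- rowMeans(rpkm_layer(rna)[, ctrl_cols, drop = FALSE])
    desil <- de_list[[focus]]$feature[de_list[[focus]]$call == "up"]
    quad <- quadrant_analysis(stats::setNames(rna$lengths, rownames(rna$counts)),
                              rp, desil,
                              config$quadrant$len_cut_log10,
                              config$quadrant$expr_cut_log10)
    outputs <- c(outputs, .write_tsv(quad$records,
      file.path(outdir, "quadrant_records.tsv")))
    jsonlite::write_json(quad$summary, file.path(outdir, "quadrant_summary.json"),
                         auto_unbox = TRUE, digits = NA)
    outputs <- c(outputs, file.path(outdir, "quadrant_summary.json"))
    stages_run <- c(stages_run, "quadrant")
  }

  conc <- NULL
  if ("concomitant" %in% config$stages && !is.null(pir) &&
      length(aligned) >= 2L) {
    focus <- if (length(doubles)) doubles[1] else
      setdiff(names(aligned), control)[1]
    msg("concomitant: %s vs %s (piRNA strand fold changes)", focus, control)
    pb <- pkb_layer(pir)
    fc_of <- function(strand) {
      rows <- endsWith(rownames(pb), paste0(":", strand))
      (pb[rows, focus] + 0.5) / (pb[rows, control] + 0.5)
    }
    fc_s <- fc_of("+"); fc_a <- fc_of("-")
    te_ids <- sub(":\\+$", "", names(fc_s))
    both_tab <- combine_quantifications(
      lapply(stats::setNames(names(aligned), names(aligned)), function(gn)
        quantify_te(aligned[[gn]], panel, per_strand = FALSE,
                    min_species_count = config$min_species_count)),
      genotypes = names(aligned))
    pb_both <- pkb_layer(both_tab)
    fc_b <- (pb_both[te_ids, focus] + 0.5) / (pb_both[te_ids, control] + 0.5)
    recs <- data.frame(te_id = te_ids, fc_sense = unname(fc_s),
                       fc_antisense = unname(fc_a), fc_both = unname(fc_b),
                       stringsAsFactors = FALSE)
    reduced <- recs$te_id[recs$fc_both <= 1 / config$concomitant$cutoff]
    conc <- concomitant_grouping(recs, reduced, config$concomitant$cutoff)
    outputs <- c(outputs, .write_tsv(conc$records,
      file.path(outdir, "concomitant.tsv")))
    stages_run <- c(stages_run, "concomitant")
  }

  ipo <- NULL
  if ("ipassign" %in% config$stages && length(aligned)) {
    msg("ipassign: emulated IP libraries from %s", control)
    ctrl_aln <- aligned[[control]]
    sp <- unique(ctrl_aln[, .(species_id, sequence, count, strand)])
    # emulate three IP libraries from the control library: Aub enriches
    # antisense species, Ago3 sense species, Piwi both (primary piRNAs)
    per_sp <- sp[, .(count = max(count), sense = any(strand == "+"),
                     anti = any(strand == "-")), by = .(species_id, sequence)]
    ip_counts <- cbind(
      Aub = round(per_sp$count * ifelse(per_sp$anti & !per_sp$sense, 6, 1)),
      Ago3 = round(per_sp$count * ifelse(per_sp$sense & !per_sp$anti, 6, 1)),
      Piwi = round(per_sp$count * ifelse(per_sp$sense & per_sp$anti, 6, 1)))
    rownames(ip_counts) <- per_sp$sequence
    ipa <- ip_group_assignment(ip_counts, config$ip$fold,
                               config$ip$pseudocount, config$ip$min_count)
    outputs <- c(outputs, .write_tsv(ipa,
      file.path(outdir, "ip_assignments.tsv")))
    ctrl_sp <- unique(ctrl_aln[, .(sequence, count)])
    ipo <- ip_group_overlap(ctrl_sp, ipa)
    if (!is.null(ipo)) {
      jsonlite::write_json(ipo, file.path(outdir, "ip_overlap.json"),
                           auto_unbox = TRUE, digits = NA)
      outputs <- c(outputs, file.path(outdir, "ip_overlap.json"))
    }
    stages_run <- c(stages_run, "ipassign")
  }

  manifest <- list(
    tool = "pirnasig",
    version = as.character(utils::packageVersion("pirnasig")),
    started = format(t0, "%Y-%m-%dT%H:%M:%S"),
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
    seed = config$seed,
    config = unclass(config),
    stages = stages_run,
    outputs = lapply(stats::setNames(outputs, basename(outputs)), function(f)
      list(path = f, md5 = unname(tools::md5sum(f)))))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(manifest)
}

#' Consolidated report of a pipeline run
#'
#' Collates the per-stage outputs under a run directory (size histograms,
#' Z scores per library, 1U/10A tables, DE calls, GI table, quadrant
#' summary, IP overlap) into one JSON document plus a short human-readable
#' text summary. Missing stage outputs are noted, not fatal.
#'
#' @param outdir the pipeline output directory (holding `manifest.json`).
#' @return the report list, invisibly; writes `report.json` and
#'   `report.txt` under `outdir`.
#' @export
generate_report <- function(outdir) {
  mpath <- file.path(outdir, "manifest.json")
  if (!file.exists(mpath)) stop("no manifest.json under ", outdir, call. = FALSE)
  manifest <- jsonlite::read_json(mpath, simplifyVector = TRUE)
  report <- list(run = manifest[c("tool", "version", "seed", "started",
                                  "finished", "stages")])
  gaps <- character(0)
  grab_tsv <- function(name) {
    f <- file.path(outdir, name)
    if (file.exists(f)) utils::read.table(f, header = TRUE, sep = "\t",
                                          stringsAsFactors = FALSE)
    else { gaps <<- c(gaps, name); NULL }
  }
  grab_json <- function(name) {
    f <- file.path(outdir, name)
    if (file.exists(f)) jsonlite::read_json(f, simplifyVector = TRUE)
    else { gaps <<- c(gaps, name); NULL }
  }
  report$signatures <- grab_tsv("signatures.tsv")
  report$nucleotide_bias <- grab_tsv("bias.tsv")
  de_files <- list.files(outdir, "^de_.*\\.tsv$")
  report$de <- lapply(stats::setNames(de_files, sub("^de_(.*)\\.tsv$", "\\1",
                                                    de_files)),
                      function(f) {
    d <- grab_tsv(f)
    if (is.null(d)) return(NULL)
    as.list(table(d$call))
  })
  size_files <- list.files(outdir, "^sizes_.*\\.tsv$")
  report$size_histograms <- lapply(
    stats::setNames(size_files, sub("^sizes_(.*)\\.tsv$", "\\1", size_files)),
    grab_tsv)
  gi <- grab_tsv("gi.tsv")
  if (!is.null(gi))
    report$gi <- list(n = nrow(gi), n_strong = sum(gi$strong, na.rm = TRUE),
                      max_gi = max(gi$gi, na.rm = TRUE))
  report$quadrant <- grab_json("quadrant_summary.json")
  report$ip_overlap <- grab_json("ip_overlap.json")
  conc <- grab_tsv("concomitant.tsv")
  if (!is.null(conc))
    report$concomitant <- as.list(table(factor(conc$group, levels = 1:3)))
  report$missing_outputs <- gaps
  jsonlite::write_json(report, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")

  txt <- c(sprintf("pirnasig run report (seed %s)", manifest$seed),
           sprintf("stages: %s", paste(manifest$stages, collapse = ", ")))
  if (!is.null(report$signatures)) {
    s <- report$signatures
    txt <- c(txt, "signature scores:",
             sprintf("  %s: Z10 = %s, Z0 = %s", s$library,
                     ifelse(s$z10_defined, sprintf("%.2f", s$z10), "undef"),
                     ifelse(s$z0_defined, sprintf("%.2f", s$z0), "undef")))
  }
  if (length(gaps)) txt <- c(txt, paste("missing outputs:",
                                        paste(gaps, collapse = ", ")))
  writeLines(txt, file.path(outdir, "report.txt"))
  invisible(report)
}
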