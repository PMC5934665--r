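log_msg <- function(stage, seed, fmt, ..., inputs = NULL) {
  hash <- ""
  if (!is.null(inputs)) {
    inputs <- inputs[file.exists(inputs)]
    if (length(inputs)) {
      h <- substr(unname(tools::md5sum(inputs)), 1, 8)
      hash <- paste0(" inputs=", paste(paste0(basename(inputs), ":", h),
                                       collapse = ","))
    }
  }
  message(sprintf("[%s seed=%s]%s %s", stage, seed, hash, sprintf(fmt, ...)))
}

#' Pipeline stage: simulate the study dataset and write it to disk
#'
#' Writes genome.fasta, genes.gff3, sites_truth.tsv, the four bedGraph
#' coverage tracks, counts.tsv, samples.tsv, the planted site models
#' (planted_motifs.meme) and a config echo (config.yaml).
#'
#' @param config a [sim_config()].
#' @param outdir output directory (created if missing).
#' @param group_pwms site models used for planting.
#' @return the in-memory dataset from [simulate_dataset()], invisibly.
#' @export
stage_simulate <- function(config, outdir, group_pwms = default_group_pwms()) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_dataset(config, group_pwms)
  write_sim_config(config, file.path(outdir, "config.yaml"))
  write_genome_fasta(sim$genome, file.path(outdir, "genome.fasta"))
  write_panel_gff3(sim$panel, file.path(outdir, "genes.gff3"),
                   genome_length = config$genome_length)
  write_tsv(sim$sites, file.path(outdir, "sites_truth.tsv"))
  for (f in c("Fnr1", "Fnr3")) {
    pre <- tolower(f)
    write_bedgraph(sim$chip[[f]]$ip, file.path(outdir, paste0(pre, "_ip.bedGraph")))
    write_bedgraph(sim$chip[[f]]$input,
                   file.path(outdir, paste0(pre, "_input.bedGraph")))
  }
  write_counts_tsv(sim$counts, file.path(outdir, "counts.tsv"))
  write_tsv(sim$samples, file.path(outdir, "samples.tsv"))
  write_meme(group_pwms, file.path(outdir, "planted_motifs.meme"))
  log_msg("simulate", config$seed,
          "%d genes, %d planted sites, genome %d bp",
          nrow(sim$panel), nrow(sim$sites), config$genome_length)
  invisible(sim)
}

#' Pipeline stage: call peaks for both factors from cached coverage
#'
#' Reads the bedGraph pairs written by [stage_simulate()] (or supplied by
#' the user in the same layout), scores sliding windows, calls peaks and
#' links them to promoters. Writes peaks_<factor>.tsv / .bed and
#' links_<factor>.tsv.
#'
#' @param outdir directory holding the stage inputs.
#' @param width,step,pseudocount see [score_windows()].
#' @param alpha,gap see [call_peaks()].
#' @param upstream,downstream see [peak_at_promoter()].
#' @return list per factor with `peaks` and `links`, invisibly.
#' @export
stage_peaks <- function(outdir, width = 300L, step = 50L, pseudocount = 0.5,
                        alpha = 1e-4, gap = 1L,
                        upstream = 400L, downstream = 100L) {
  genome <- read_genome_fasta(file.path(outdir, "genome.fasta"))
  L <- Biostrings::width(genome)[1]
  panel <- read_panel_gff3(file.path(outdir, "genes.gff3"))
  out <- list()
  for (f in c("Fnr1", "Fnr3")) {
    pre <- tolower(f)
    ip_path <- file.path(outdir, paste0(pre, "_ip.bedGraph"))
    in_path <- file.path(outdir, paste0(pre, "_input.bedGraph"))
    ip <- read_bedgraph(ip_path, L)
    input <- read_bedgraph(in_path, L)
    win <- score_windows(ip, input, width, step, pseudocount)
    peaks <- call_peaks(win, alpha, gap, factor = f, ip = ip, input = input)
    links <- peak_at_promoter(peaks, panel, upstream, downstream)
    links$factor <- if (nrow(links)) f else character(0)
    write_tsv(peaks, file.path(outdir, paste0("peaks_", pre, ".tsv")))
    write_peaks_bed(peaks, file.path(outdir, paste0("peaks_", pre, ".bed")), f)
    write_tsv(links, file.path(outdir, paste0("links_", pre, ".tsv")))
    log_msg("peaks", "-", "%s: %d peaks, %d promoter links", f,
            nrow(peaks), nrow(links), inputs = c(ip_path, in_path))
    out[[f]] <- list(peaks = peaks, links = links)
  }
  invisible(out)
}

#' Pipeline stage: differential expression over the seven comparisons
#'
#' Reads counts.tsv, runs [run_comparisons()] and writes de_results.tsv.
#'
#' @param outdir directory holding counts.tsv.
#' @param phi optional fixed dispersion (estimated when `NULL`).
#' @return the DE table, invisibly.
#' @export
stage_de <- function(outdir, phi = NULL) {
  cp <- file.path(outdir, "counts.tsv")
  cm <- read_counts_tsv(cp)
  de <- run_comparisons(cm$counts, cm$samples, phi = phi)
  write_tsv(de, file.path(outdir, "de_results.tsv"))
  log_msg("de", "-", "%d genes x %d comparisons, %d significant calls",
          length(unique(de$gene)), length(unique(de$comparison)),
          sum(de$significant), inputs = cp)
  invisible(de)
}

#' Pipeline stage: regulon classification
#'
#' Reads the promoter links and DE table, classifies promoters with
#' [classify_regulons()] and writes regulons.tsv plus
#' regulon_summary.json.
#'
#' @param outdir directory holding links_fnr*.tsv and de_results.tsv.
#' @param peak_alpha,ambiguous_alpha see [classify_regulons()].
#' @return the assignment table, invisibly.
#' @export
stage_classify <- function(outdir, peak_alpha = 1e-5, ambiguous_alpha = 1e-4) {
  ins <- file.path(outdir, c("links_fnr1.tsv", "links_fnr3.tsv",
                             "de_results.tsv"))
  l1 <- read_tsv(ins[1]); l3 <- read_tsv(ins[2]); de <- read_tsv(ins[3])
  assign <- classify_regulons(l1, l3, de, peak_alpha, ambiguous_alpha)
  summ <- summarize_regulons(assign)
  write_tsv(assign, file.path(outdir, "regulons.tsv"))
  jsonlite::write_json(summ, file.path(outdir, "regulon_summary.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  log_msg("classify", "-", "groups I/II/III = %d/%d/%d (+%d none)",
          summ$groups[["I"]], summ$groups[["II"]], summ$groups[["III"]],
          summ$groups[["none"]], inputs = ins)
  invisible(assign)
}

#' Pipeline stage: motif discovery and half-site analysis
#'
#' For each regulon group, extracts 300-bp strand-specific windows around
#' the binding factor's peak summits (Fnr1 for Groups I and III, Fnr3 for
#' Group II), runs ZOOPS EM motif discovery, writes the windows
#' (windows_group<g>.fasta), the motifs (motifs.meme), per-sequence site
#' tables, the half-site hybrid report (half_site_report.json) and the
#' TSS-offset report (site_positions.tsv).
#'
#' @param outdir directory with regulons.tsv, links and the genome.
#' @param seed seed for EM start selection (defaults to the config echo's
#'   seed).
#' @param n_starts EM restarts per group.
#' @param flank half-window in bp.
#' @return list with per-group `motif` results, `hybrid` report and
#'   `positions`, invisibly.
#' @export
stage_motifs <- function(outdir, seed = NULL, n_starts = 10L, flank = 150L) {
  cfg_path <- file.path(outdir, "config.yaml")
  if (is.null(seed))
    seed <- if (file.exists(cfg_path)) read_sim_config(cfg_path)$seed else 1L
  genome <- read_genome_fasta(file.path(outdir, "genome.fasta"))
  panel <- read_panel_gff3(file.path(outdir, "genes.gff3"))
  assign <- read_tsv(file.path(outdir, "regulons.tsv"))
  links <- list(Fnr1 = read_tsv(file.path(outdir, "links_fnr1.tsv")),
                Fnr3 = read_tsv(file.path(outdir, "links_fnr3.tsv")))
  summit_factor <- c(I = "Fnr1", II = "Fnr3", III = "Fnr1")

  motifs <- list(); metas <- list()
  for (grp in c("I", "II", "III")) {
    genes <- assign$gene[assign$group == grp]
    lk <- links[[summit_factor[[grp]]]]
    lk <- lk[lk$gene_id %in% genes, , drop = FALSE]
    # one summit per gene: keep the most significant link
    lk <- lk[order(lk$gene_id, lk$peak_p), ]
    lk <- lk[!duplicated(lk$gene_id), , drop = FALSE]
    i <- match(lk$gene_id, panel$gene_id)
    meta <- data.frame(gene_id = lk$gene_id, contig = panel$contig[i],
                       summit = lk$summit, strand = panel$strand[i],
                       tss = panel$tss[i], stringsAsFactors = FALSE)
    seqs <- extract_windows(meta, genome, flank)
    meta <- meta[meta$gene_id %in% names(seqs), , drop = FALSE]
    write_windows_fasta(seqs, file.path(outdir,
                                        paste0("windows_group", grp, ".fasta")))
    if (length(seqs) < 5L) {
      warning("group ", grp, ": fewer than 5 windows; motif search skipped")
      next
    }
    mr <- em_motif_search(seqs, W = 14L, n_starts = n_starts, seed = seed)
    motifs[[grp]] <- mr
    metas[[grp]] <- meta
    log_msg("motifs", seed, "group %s: %d windows, consensus %s, logL %.1f",
            grp, length(seqs), mr$consensus, mr$loglik)
  }

  # phase-anchor Groups II and III on the Group I motif, whose strongly
  # conserved flanks pin its phase; EM fixes weak-flanked motifs only up
  # to a small column shift (see align_pwm)
  if ("I" %in% names(motifs)) {
    for (grp in intersect(c("II", "III"), names(motifs))) {
      al <- align_pwm(motifs[[grp]]$pwm, motifs$I$pwm)
      if (al$shift != 0L) {
        motifs[[grp]]$pwm <- al$pwm
        motifs[[grp]]$consensus <- pwm_consensus(al$pwm)
        motifs[[grp]]$sites$offset <- motifs[[grp]]$sites$offset + al$shift
        motifs[[grp]]$phase_shift <- al$shift
        log_msg("motifs", seed, "group %s phase-aligned to Group I (shift %+d)",
                grp, al$shift)
      }
    }
  }
  for (grp in names(motifs)) {
    write_tsv(motifs[[grp]]$sites,
              file.path(outdir, paste0("motif_sites_group", grp, ".tsv")))
  }

  hybrid <- NULL
  if (all(c("I", "II", "III") %in% names(motifs))) {
    write_meme(lapply(motifs, `[[`, "pwm"), file.path(outdir, "motifs.meme"),
               nsites = vapply(motifs, `[[`, integer(1), "n_seq"))
    hybrid <- hybrid_test(motifs$I$pwm, motifs$II$pwm, motifs$III$pwm)
    jsonlite::write_json(
      list(distances = hybrid$distances,
           upstream_matches_II = hybrid$upstream_matches_II,
           downstream_matches_I = hybrid$downstream_matches_I),
      file.path(outdir, "half_site_report.json"),
      auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }

  positions <- do.call(rbind, lapply(names(motifs), function(grp) {
    rep <- site_position_report(motifs[[grp]], metas[[grp]], flank)
    if (nrow(rep$offsets) == 0L) return(NULL)
    cbind(group = grp, rep$offsets)
  }))
  pos_summary <- NULL
  if (!is.null(positions)) {
    write_tsv(positions, file.path(outdir, "site_positions.tsv"))
    pos_summary <- list(median = median(positions$offset),
                        mad = mad(positions$offset))
    log_msg("motifs", seed, "site offsets: median %g, MAD %.1f",
            pos_summary$median, pos_summary$mad)
  }
  invisible(list(motifs = motifs, hybrid = hybrid, positions = positions,
                 position_summary = pos_summary))
}

#' Run the full inference pipeline on a synthetic dataset
#'
#' Executes simulate, peaks, DE, classify and motifs in order inside
#' `outdir`, then writes a machine-readable run report (report.json).
#' Every stage writes its outputs to disk and downstream stages read only
#' those files, so re-running a downstream stage on cached inputs is
#' deterministic.
#'
#' @param config a [sim_config()] (or path to a YAML config).
#' @param outdir output directory.
#' @param seed optional override of `config$seed`.
#' @param group_pwms site models used for planting.
#' @return list of class `run_report` (also serialized to report.json).
#' @export
run_pipeline <- function(config = sim_config(), outdir, seed = NULL,
                         group_pwms = default_group_pwms()) {
  if (is.character(config)) config <- read_sim_config(config)
  if (!is.null(seed)) {
    config$seed <- as.integer(seed)
    config <- validate_sim_config(config)
  }
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

  stage_simulate(config, outdir, group_pwms)
  pk <- stage_peaks(outdir)
  de <- stage_de(outdir)
  assign <- stage_classify(outdir)
  mo <- stage_motifs(outdir, seed = config$seed)

  summ <- summarize_regulons(assign)
  de_counts <- lapply(split(de, de$comparison), function(x) {
    list(significant = sum(x$significant),
         up = sum(x$significant & x$direction == "up"),
         down = sum(x$significant & x$direction == "down"))
  })
  report <- list(
    package_version = as.character(utils::packageVersion("fnrscape")),
    seed = config$seed,
    config = unclass(config),
    peaks = lapply(pk, function(x) nrow(x$peaks)),
    de = de_counts,
    regulons = summ[c("groups", "fnr1_total", "fnr3_total",
                      "n_ambiguous", "n_bound_no_de")],
    motif_consensus = lapply(mo$motifs, `[[`, "consensus"),
    hybrid = if (!is.null(mo$hybrid)) list(
      upstream_matches_II = mo$hybrid$upstream_matches_II,
      downstream_matches_I = mo$hybrid$downstream_matches_I
    ),
    site_position = mo$position_summary
  )
  jsonlite::write_json(report, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  class(report) <- "run_report"
  invisible(report)
}

# mean per-column total-variation distance between two PWMs
pwm_tv_distance <- function(pwm_a, pwm_b) {
  a <- unclass(pwm_a); b <- unclass(pwm_b)
  stopifnot(ncol(a) == ncol(b))
  mean(colSums(abs(a - b)) / 2)
}

#' Score pipeline outputs against the planted truth
#'
#' Compares regulons.tsv with sites_truth.tsv and the discovered motifs
#' with the planted site models. Only meaningful for synthetic runs where
#' the truth sidecar exists.
#'
#' @param outdir a directory produced by [run_pipeline()].
#' @return list: per-group `precision`/`recall`, overall `accuracy`
#'   (fraction of planted promoters assigned their true group),
#'   `cross_group_errors` (planted promoters assigned a *different*
#'   group), `summit_error` (per planted site, distance from the nearest
#'   linked summit of its binding factor), and `motif_tv` (mean
#'   per-column total-variation distance to the planted PWM, per group).
#' @export
score_against_truth <- function(outdir) {
  truth_path <- file.path(outdir, "sites_truth.tsv")
  if (!file.exists(truth_path))
    stop("no sites_truth.tsv in ", outdir, "; scoring needs a synthetic run")
  truth <- read_tsv(truth_path)
  assign <- read_tsv(file.path(outdir, "regulons.tsv"))

  called <- assign$group[match(truth$promoter_id, assign$gene)]
  called[is.na(called)] <- "none"
  per_group <- lapply(c(I = "I", II = "II", III = "III"), function(g) {
    tp <- sum(truth$group == g & called == g)
    n_called <- sum(assign$group == g)
    n_true <- sum(truth$group == g)
    list(precision = if (n_called) tp / n_called else NA_real_,
         recall = tp / n_true, n_true = n_true, n_called = n_called)
  })
  accuracy <- mean(called == truth$group)
  cross <- sum(called != truth$group & called != "none")

  summit_err <- rep(NA_real_, nrow(truth))
  factor_of <- c(I = "fnr1", II = "fnr3", III = "fnr1")
  for (f in c("fnr1", "fnr3")) {
    lp <- file.path(outdir, paste0("links_", f, ".tsv"))
    if (!file.exists(lp)) next
    lk <- read_tsv(lp)
    idx <- which(factor_of[truth$group] == f)
    for (i in idx) {
      s <- lk$summit[lk$gene_id == truth$promoter_id[i]]
      if (length(s)) summit_err[i] <- min(abs(s - truth$center[i]))
    }
  }

  motif_tv <- NULL
  meme_path <- file.path(outdir, "motifs.meme")
  planted_path <- file.path(outdir, "planted_motifs.meme")
  if (file.exists(meme_path) && file.exists(planted_path)) {
    found <- read_meme(meme_path)
    planted <- read_meme(planted_path)
    # recovery distance is defined up to a small phase shift; align to the
    # planted model before comparing column-wise
    motif_tv <- vapply(intersect(names(found), names(planted)), function(g) {
      pwm_tv_distance(align_pwm(found[[g]], planted[[g]])$pwm, planted[[g]])
    }, numeric(1))
  }

  list(per_group = per_group, accuracy = accuracy,
       cross_group_errors = cross,
       summit_error = summit_err,
       summit_error_median = median(summit_err, na.rm = TRUE),
       motif_tv = motif_tv)
}
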