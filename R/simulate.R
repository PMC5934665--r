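#' Generate a synthetic genome and gene panel
#'
#' Draws an i.i.d. uniform-composition chromosome and places `n_genes`
#' non-overlapping genes on it, alternating gene placement over regular
#' slots with random within-slot jitter and random strand. Regulatory
#' classes (Group I / II / III / constitutive) and modes
#' (activated / repressed) are assigned at random according to
#' `config$group_sizes` and `config$n_repressed`.
#'
#' The transcription start site (TSS, 1-based) is the gene's first base in
#' gene-strand orientation; every gene keeps >= 250 bp clear on both sides
#' so a binding site centred at TSS-42 never collides with a neighbour or a
#' contig edge.
#'
#' @param config a [sim_config()].
#' @return list with `genome` (a [Biostrings::DNAStringSet] of one contig)
#'   and `panel` (data.frame: gene_id, contig, start, end, strand, tss,
#'   class, mode) with 1-based inclusive coordinates.
#' @export
generate_genome <- function(config) {
  config <- validate_sim_config(config)
  set.seed(stage_seed(config$seed, "genome"))
  L <- config$genome_length
  n <- config$n_genes

  seq_chars <- sample(DNA_BASES, L, replace = TRUE)
  genome <- Biostrings::DNAStringSet(paste(seq_chars, collapse = ""))
  names(genome) <- config$contig

  slot <- L %/% n
  margin <- 250L
  glen <- config$gene_length
  if (slot < glen + 2L * margin)
    stop("genome too short for requested gene count and gene length")
  jitter_max <- slot - glen - 2L * margin
  starts0 <- (seq_len(n) - 1L) * slot + margin +
    sample.int(jitter_max + 1L, n, replace = TRUE) - 1L   # 0-based
  strand <- sample(c("+", "-"), n, replace = TRUE)
  start1 <- starts0 + 1L                   # 1-based inclusive
  end1 <- start1 + glen - 1L
  tss <- ifelse(strand == "+", start1, end1)

  cls <- rep("constitutive", n)
  planted <- sample.int(n, sum(config$group_sizes))
  cls[planted] <- rep(c("I", "II", "III"), times = config$group_sizes)
  mode <- rep("none", n)
  mode[cls %in% c("I", "II", "III")] <- "activated"
  for (g in 1:2) {
    idx <- which(cls == c("I", "II")[g])
    if (config$n_repressed[g] > 0L)
      mode[sample(idx, config$n_repressed[g])] <- "repressed"
  }

  panel <- data.frame(
    gene_id = sprintf("gene_%04d", seq_len(n)),
    contig = config$contig,
    start = start1, end = end1, strand = strand,
    tss = as.integer(tss),
    class = cls, mode = mode,
    stringsAsFactors = FALSE
  )
  list(genome = genome, panel = panel)
}

#' Plant group-specific binding sites into a genome
#'
#' For every non-constitutive gene, a 14-mer is sampled column-wise from
#' that group's PWM and written into the genome so that the site centre
#' falls at TSS-42 in gene-strand coordinates (the Class II promoter
#' geometry). For minus-strand genes the sampled 14-mer is
#' reverse-complemented before insertion, so reading the site on the gene
#' strand recovers the sampled sequence.
#'
#' Coordinates: the site centre `c` is 0-based and the site occupies the
#' half-open interval `[c - 7, c + 7)`, i.e. 14 bp whose midpoint is `c`.
#'
#' @param genome a [Biostrings::DNAStringSet] (single contig).
#' @param panel gene panel from [generate_genome()].
#' @param group_pwms named list of [pwm()]s for groups `I`, `II`, `III`
#'   (width 14); defaults to [default_group_pwms()].
#' @param seed integer seed for the site-sampling stream.
#' @return list with the modified `genome` and `sites`, a data.frame
#'   (promoter_id, contig, center, strand, group, consensus_realization,
#'   mode) where `center` is 0-based.
#' @export
plant_sites <- function(genome, panel, group_pwms = default_group_pwms(),
                        seed = 1L) {
  stopifnot(all(c("I", "II", "III") %in% names(group_pwms)))
  for (p in group_pwms[c("I", "II", "III")]) {
    stopifnot(inherits(p, "pwm"), ncol(p) == 14L)
  }
  set.seed(stage_seed(seed, "sites"))
  tgt <- panel[panel$class %in% c("I", "II", "III"), , drop = FALSE]
  if (nrow(tgt) == 0L) return(list(genome = genome, sites = tgt))

  tss0 <- tgt$tss - 1L
  center <- ifelse(tgt$strand == "+", tss0 - 42L, tss0 + 42L)
  clen <- Biostrings::width(genome)[match(tgt$contig, names(genome))]
  if (any(center - 7L < 0L | center + 7L > clen))
    stop("planted site would overrun a contig edge")
  if (any(center < 150L | center > clen - 150L))
    stop("site centre must lie >= 150 bp from contig edges")

  kmer <- character(nrow(tgt))
  for (i in seq_len(nrow(tgt)))
    kmer[i] <- pwm_sample(group_pwms[[tgt$class[i]]], 1L)
  inserted <- ifelse(tgt$strand == "+", kmer, revcomp(kmer))

  # all sites live on the single contig; replace in one vectorized call
  at <- IRanges::IRanges(start = center - 7L + 1L, width = 14L)
  genome[[1]] <- Biostrings::replaceAt(genome[[1]], at,
                                       Biostrings::DNAStringSet(inserted))

  sites <- data.frame(
    promoter_id = tgt$gene_id,
    contig = tgt$contig,
    center = as.integer(center),
    strand = tgt$strand,
    group = tgt$class,
    consensus_realization = kmer,
    mode = tgt$mode,
    stringsAsFactors = FALSE
  )
  list(genome = genome, sites = sites)
}

# sample fragment lengths from N(mean, sd) truncated to [100, 500]
sample_fraglen <- function(n, mean, sd) {
  out <- rnorm(n, mean, sd)
  bad <- which(out < 100 | out > 500)
  while (length(bad)) {
    out[bad] <- rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] < 100 | out[bad] > 500]
  }
  as.integer(round(out))
}

# accumulate per-base coverage for fragments [start0, start0 + len) clipped
# to [0, L); returns integer vector of length L
fragment_coverage <- function(start0, len, L) {
  s <- pmax(start0, 0L)
  e <- pmin(start0 + len, L)
  keep <- e > s
  s <- s[keep]; e <- e[keep]
  delta <- tabulate(s + 1L, nbins = L + 1L) - tabulate(e + 1L, nbins = L + 1L)
  cov <- cumsum(delta)[seq_len(L)]
  as.integer(cov)
}

#' A per-base coverage track
#' @param contig contig name.
#' @param coverage non-negative integer vector, one value per base.
#' @return object of class `coverage_track` with fields `contig`,
#'   `coverage` and `library_size` (total read-bases, i.e.
#'   `sum(coverage)`).
#' @export
coverage_track <- function(contig, coverage) {
  coverage <- as.integer(coverage)
  if (any(coverage < 0)) stop("coverage must be non-negative")
  structure(list(contig = contig, coverage = coverage,
                 library_size = sum(as.numeric(coverage))),
            class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf("coverage_track %s: %d bp, %.0f read-bases, mean depth %.2f\n",
              x$contig, length(x$coverage), x$library_size,
              x$library_size / length(x$coverage)))
  invisible(x)
}

#' Simulate a paired IP / input ChIP coverage track for one factor
#'
#' The input (total DNA) library is a homogeneous fragment process: a
#' Poisson number of fragments with truncated-normal lengths and uniform
#' placement, which yields per-base coverage that is Poisson with mean
#' `background_depth` after fragment smoothing. The IP library adds, at
#' every site bound by `factor`, a pileup of `Poisson(depth * (fold - 1))`
#' fragments centred on the site (centre jitter sd 20 bp), so the expected
#' summit coverage is approximately `background_depth * enrichment_fold`.
#'
#' Factor specificity follows the study design: Fnr1 binds Group I and
#' Group III sites, Fnr3 binds Group II and Group III sites.
#'
#' @param contig_length length of the simulated contig (bp).
#' @param sites data.frame from [plant_sites()] (may have zero rows for a
#'   null track).
#' @param factor `"Fnr1"` or `"Fnr3"`.
#' @param config a [sim_config()].
#' @param seed optional seed override (defaults to `config$seed`).
#' @return list of two [coverage_track()]s: `ip` and `input`.
#' @export
simulate_chip_coverage <- function(contig_length, sites, factor,
                                   config, seed = NULL) {
  config <- validate_sim_config(config)
  factor <- match.arg(factor, c("Fnr1", "Fnr3"))
  seed <- seed %||% config$seed
  set.seed(stage_seed(seed, if (factor == "Fnr1") "chip1" else "chip3"))

  L <- as.integer(contig_length)
  depth <- config$background_depth
  fold <- config$enrichment_fold
  fl_mean <- config$fragment_len_mean
  fl_sd <- config$fragment_len_sd

  bg_tracks <- lapply(1:2, function(dummy) {
    nf <- rpois(1L, depth * L / fl_mean)
    len <- sample_fraglen(nf, fl_mean, fl_sd)
    ctr <- floor(runif(nf, 0, L))
    fragment_coverage(as.integer(ctr - len %/% 2L), len, L)
  })
  ip_cov <- bg_tracks[[1]]
  input_cov <- bg_tracks[[2]]

  bound_groups <- if (factor == "Fnr1") c("I", "III") else c("II", "III")
  bound <- sites[sites$group %in% bound_groups, , drop = FALSE]
  if (nrow(bound) > 0L && fold > 1) {
    n_extra <- rpois(nrow(bound), depth * (fold - 1))
    ctr <- rep(bound$center, n_extra) + as.integer(round(rnorm(sum(n_extra), 0, 20)))
    len <- sample_fraglen(sum(n_extra), fl_mean, fl_sd)
    ip_cov <- ip_cov + fragment_coverage(as.integer(ctr - len %/% 2L), len, L)
  }

  contig <- if (nrow(sites) > 0L) sites$contig[1] else config$contig
  list(ip = coverage_track(contig, ip_cov),
       input = coverage_track(contig, input_cov))
}

# expression multiplier implementing the regulatory logic of the three
# promoter groups across strains and conditions
expression_multiplier <- function(class, mode, strain, condition,
                                  induction_fold, partial_fold) {
  if (condition == "C" || class == "constitutive" || mode == "none") return(1)
  if (mode == "activated") {
    switch(class,
      I = if (strain == "WT") induction_fold else 1,
      II = if (strain %in% c("WT", "D1")) induction_fold else 1,
      III = if (strain == "WT") induction_fold else partial_fold
    )
  } else {  # repressed: factor active => expression divided by induction_fold
    switch(class,
      # Fnr1 requires Fnr3, so Fnr1-mediated repression only occurs in WT
      I = if (strain == "WT") 1 / induction_fold else 1,
      II = if (strain %in% c("WT", "D1")) 1 / induction_fold else 1,
      III = stop("repressed Group III promoters are not part of the design")
    )
  }
}

#' Simulate the RNA-Seq count matrix
#'
#' Counts are negative binomial, `NB(mu = baseline_g * multiplier,
#' size = 1/phi)` (Poisson when `phi = 0`), over the six samples
#' {WT, D1, D3} x {C, S} with `config$replicates` replicates each.
#' Per-gene baselines vary log-normally around `nb_mean_baseline`
#' (sd 0.25 on log2) so that average expression spreads as in real
#' libraries. The multiplier encodes the regulatory logic:
#'
#' * Group I (Fnr1-dependent, and Fnr1 itself needs Fnr3): induced
#'   `induction_fold`-fold in WT-S only.
#' * Group II (Fnr3-only): induced in WT-S and D1-S, not in D3-S.
#' * Group III (co-activated): fully induced in WT-S, only
#'   `partial_fold`-fold in either single deletion.
#' * Repressed promoters: expression divided by `induction_fold` upon the
#'   switch in strains where the binding factor is active.
#'
#' @param panel gene panel from [generate_genome()].
#' @param config a [sim_config()].
#' @param seed optional seed override (defaults to `config$seed`).
#' @return list with `counts` (integer matrix, genes x samples, columns
#'   named `<strain>_<condition>_<replicate>`) and `samples` (data.frame:
#'   sample, strain, condition, replicate).
#' @export
simulate_counts <- function(panel, config, seed = NULL) {
  config <- validate_sim_config(config)
  seed <- seed %||% config$seed
  set.seed(stage_seed(seed, "counts"))

  samples <- expand.grid(replicate = seq_len(config$replicates),
                         condition = c("C", "S"),
                         strain = c("WT", "D1", "D3"),
                         stringsAsFactors = FALSE)
  samples <- samples[, c("strain", "condition", "replicate")]
  samples$sample <- sprintf("%s_%s_%d", samples$strain, samples$condition,
                            samples$replicate)

  n <- nrow(panel)
  baseline <- config$nb_mean_baseline * 2^rnorm(n, 0, 0.25)
  phi <- config$nb_dispersion

  counts <- matrix(0L, nrow = n, ncol = nrow(samples),
                   dimnames = list(panel$gene_id, samples$sample))
  for (j in seq_len(nrow(samples))) {
    mult <- vapply(seq_len(n), function(i) {
      expression_multiplier(panel$class[i], panel$mode[i],
                            samples$strain[j], samples$condition[j],
                            config$induction_fold, config$partial_fold)
    }, numeric(1))
    mu <- baseline * mult
    counts[, j] <- if (phi > 0) {
      rnbinom(n, size = 1 / phi, mu = mu)
    } else {
      rpois(n, mu)
    }
  }
  list(counts = counts, samples = samples[, c("sample", "strain",
                                              "condition", "replicate")])
}

#' Simulate the complete study dataset in memory
#'
#' Runs genome generation, site planting, ChIP coverage simulation for both
#' factors and RNA-Seq count simulation under a single configuration, each
#' stage on its own seed stream derived from `config$seed`.
#'
#' @param config a [sim_config()].
#' @param group_pwms PWMs used to plant sites; see [plant_sites()].
#' @return list: `config`, `genome`, `panel`, `sites`, `chip` (list
#'   `Fnr1`/`Fnr3`, each with `ip` and `input` [coverage_track()]s),
#'   `counts`, `samples`, `group_pwms`.
#' @export
simulate_dataset <- function(config = sim_config(),
                             group_pwms = default_group_pwms()) {
  config <- validate_sim_config(config)
  gg <- generate_genome(config)
  ps <- plant_sites(gg$genome, gg$panel, group_pwms, seed = config$seed)
  chip <- lapply(c(Fnr1 = "Fnr1", Fnr3 = "Fnr3"), function(f) {
    simulate_chip_coverage(config$genome_length, ps$sites, f, config)
  })
  cm <- simulate_counts(gg$panel, config)
  list(config = config, genome = ps$genome, panel = gg$panel,
       sites = ps$sites, chip = chip,
       counts = cm$counts, samples = cm$samples,
       group_pwms = group_pwms)
}
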