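#' Configuration for the synthetic study generator
#'
#' Bundles every knob of the simulated experimental design: a bacterial
#' chromosome with annotated genes, three classes of planted 14-bp Fnr
#' binding sites, paired IP/input ChIP coverage for Fnr1 and Fnr3, and a
#' negative-binomial RNA-Seq count matrix over strains {WT, D1 (fnr1
#' deletion), D3 (fnr3 deletion)} x conditions {C (high aeration control),
#' S (switch to low aeration)}.
#'
#' Defaults reflect the emulated study design: group sizes near the 39/23/18
#' promoter classes, sonication fragments of 100-500 bp centred on 300 bp,
#' and three RNA-Seq replicates per sample. The default 600-gene panel
#' keeps planted regulon members a small minority (~14%) of the
#' transcriptome, as in a real bacterial RNA-Seq experiment, which the
#' median-of-ratios library normalization relies on.
#'
#' @param seed integer master seed; every stage derives its own stream.
#' @param genome_length chromosome length in bp.
#' @param n_genes number of annotated genes (must fit in the genome at
#'   2 kb per gene or more).
#' @param group_sizes integer triple: planted promoters in Groups I
#'   (Fnr1-only), II (Fnr3-only) and III (co-bound).
#' @param n_repressed integer pair: how many Group I and Group II promoters
#'   are repressed rather than activated (Group III is never repressed).
#' @param background_depth mean sequencing coverage (reads per base) of the
#'   input (total DNA) library.
#' @param enrichment_fold expected IP/input fold change at a bound site
#'   summit; must be >= 1 (1 means no enrichment, a null track).
#' @param fragment_len_mean,fragment_len_sd sonication fragment length
#'   model, normal truncated to [100, 500] bp.
#' @param nb_mean_baseline baseline expression mean (counts) per gene.
#' @param nb_dispersion negative-binomial dispersion phi >= 0 (variance =
#'   mu + phi * mu^2); 0 gives Poisson counts. The default 0.02
#'   (biological CV ~14%) matches replicate cultures of an isogenic
#'   bacterial strain; dispersions near 0.1 are typical of outbred
#'   samples, not of this design.
#' @param induction_fold activation multiplier upon the oxygen switch for a
#'   fully activated promoter.
#' @param partial_fold multiplier for Group III promoters when only one of
#'   the two factors is present (single-deletion strains); must satisfy
#'   1 <= partial_fold < induction_fold (or both equal to 1 for a null
#'   design). The default 2 makes partial activation genuinely
#'   intermediate while keeping the single-deletion decrease
#'   (induction_fold / partial_fold = 4-fold) detectable under the DE
#'   decision rule, as it was for every co-regulated promoter reported.
#' @param replicates RNA-Seq replicates per strain x condition cell (>= 2).
#' @param gene_length annotated gene length in bp.
#' @param contig name of the single simulated chromosome.
#' @return an object of class `sim_config` (a validated named list).
#' @export
sim_config <- function(seed = 1L,
                       genome_length = 1500000L,
                       n_genes = 600L,
                       group_sizes = c(40L, 24L, 18L),
                       n_repressed = c(5L, 2L),
                       background_depth = 20,
                       enrichment_fold = 8,
                       fragment_len_mean = 300,
                       fragment_len_sd = 80,
                       nb_mean_baseline = 100,
                       nb_dispersion = 0.02,
                       induction_fold = 8,
                       partial_fold = 2,
                       replicates = 3L,
                       gene_length = 900L,
                       contig = "synth1") {
  cfg <- list(
    seed = as.integer(seed),
    genome_length = as.integer(genome_length),
    n_genes = as.integer(n_genes),
    group_sizes = as.integer(group_sizes),
    n_repressed = as.integer(n_repressed),
    background_depth = background_depth,
    enrichment_fold = enrichment_fold,
    fragment_len_mean = fragment_len_mean,
    fragment_len_sd = fragment_len_sd,
    nb_mean_baseline = nb_mean_baseline,
    nb_dispersion = nb_dispersion,
    induction_fold = induction_fold,
    partial_fold = partial_fold,
    replicates = as.integer(replicates),
    gene_length = as.integer(gene_length),
    contig = as.character(contig)
  )
  validate_sim_config(structure(cfg, class = "sim_config"))
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (length(cfg$group_sizes) != 3L || any(cfg$group_sizes < 1L))
    stop("group_sizes must be three counts, each >= 1")
  if (length(cfg$n_repressed) != 2L || any(cfg$n_repressed < 0L))
    stop("n_repressed must be two non-negative counts")
  if (any(cfg$n_repressed > cfg$group_sizes[1:2]))
    stop("n_repressed cannot exceed the corresponding group size")
  if (cfg$nb_dispersion < 0) stop("nb_dispersion must be >= 0")
  if (cfg$enrichment_fold < 1) stop("enrichment_fold must be >= 1")
  if (cfg$n_genes < sum(cfg$group_sizes))
    stop("n_genes must be at least sum(group_sizes)")
  if (cfg$genome_length < cfg$n_genes * 2000L)
    stop("genome too short: need genome_length >= n_genes * 2000")
  if (cfg$replicates < 2L) stop("replicates must be >= 2")
  pos <- c("background_depth", "fragment_len_mean", "fragment_len_sd",
           "nb_mean_baseline", "induction_fold", "partial_fold",
           "gene_length")
  for (f in pos) if (cfg[[f]] <= 0) stop(f, " must be positive")
  if (cfg$partial_fold < 1) stop("partial_fold must be >= 1")
  if (cfg$induction_fold > 1 && cfg$partial_fold >= cfg$induction_fold)
    stop("partial_fold must be < induction_fold")
  if (cfg$induction_fold == 1 && cfg$partial_fold != 1)
    stop("a null design (induction_fold = 1) requires partial_fold = 1")
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:",
      sprintf("%d bp genome, %d genes, groups %s (repressed %s)",
              x$genome_length, x$n_genes,
              paste(x$group_sizes, collapse = "/"),
              paste(x$n_repressed, collapse = "/")), "\n")
  cat(sprintf("  chip: depth %g, fold %g, fragments N(%g, %g) in [100, 500]\n",
              x$background_depth, x$enrichment_fold,
              x$fragment_len_mean, x$fragment_len_sd))
  cat(sprintf("  rnaseq: baseline %g, phi %g, induction %gx, partial %gx, %d reps\n",
              x$nb_mean_baseline, x$nb_dispersion, x$induction_fold,
              x$partial_fold, x$replicates))
  cat(sprintf("  seed %d\n", x$seed))
  invisible(x)
}

#' Write / read a simulation configuration as YAML
#' @param cfg a [sim_config()].
#' @param path file path.
#' @return `read_sim_config` returns a validated [sim_config()];
#'   `write_sim_config` returns `path` invisibly.
#' @export
write_sim_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  lst <- yaml::read_yaml(path)
  known <- names(formals(sim_config))
  bad <- setdiff(names(lst), known)
  if (length(bad))
    stop("unknown config keys: ", paste(bad, collapse = ", "))
  do.call(sim_config, lst)
}
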