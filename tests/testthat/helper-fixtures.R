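# shared fixtures; everything is generated in code at test time

empty_sites <- function() {
  data.frame(promoter_id = character(), contig = character(),
             center = integer(), strand = character(), group = character(),
             consensus_realization = character(), mode = character(),
             stringsAsFactors = FALSE)
}

# a small but complete study configuration that keeps full pipeline runs fast
small_config <- function(seed = 301L, ...) {
  sim_config(seed = seed, genome_length = 400000L, n_genes = 160L,
             group_sizes = c(10L, 8L, 6L), n_repressed = c(2L, 1L), ...)
}

# a delta PWM putting all probability on the given 14-mer
delta_pwm <- function(kmer) {
  idx <- match(strsplit(kmer, "")[[1]], c("A", "C", "G", "T"))
  m <- matrix(0, 4, length(idx), dimnames = list(c("A", "C", "G", "T"), NULL))
  m[cbind(idx, seq_along(idx))] <- 1
  pwm(m)
}

random_seqs <- function(n, len, seed = 1) {
  set.seed(seed)
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, character(1))
}

# the default-condition pipeline run is shared by several acceptance checks;
# run it once per session and cache the output directory
.run_cache <- new.env(parent = emptyenv())
default_run_dir <- function(seed = 101L) {
  key <- paste0("run_", seed)
  if (is.null(.run_cache[[key]])) {
    od <- file.path(tempdir(), paste0("fnrscape_default_", seed))
    suppressMessages(run_pipeline(sim_config(seed = seed), outdir = od))
    .run_cache[[key]] <- od
  }
  .run_cache[[key]]
}
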