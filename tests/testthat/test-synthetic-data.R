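test_that("genome generation is deterministic and writes valid outputs", {
  cfg <- sim_config(seed = 11, genome_length = 50000, n_genes = 10,
                    group_sizes = c(2, 2, 2), n_repressed = c(0, 0))
  g1 <- generate_genome(cfg)
  g2 <- generate_genome(cfg)
  expect_identical(as.character(g1$genome), as.character(g2$genome))
  expect_identical(g1$panel, g2$panel)

  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  suppressMessages(stage_simulate(cfg, d1))
  suppressMessages(stage_simulate(cfg, d2))
  for (f in c("genome.fasta", "genes.gff3", "sites_truth.tsv", "counts.tsv",
              "fnr1_ip.bedGraph", "fnr3_input.bedGraph")) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     info = f)
  }

  # 10 non-overlapping genes, 1-based inclusive coordinates in the GFF
  p <- g1$panel
  expect_equal(nrow(p), 10L)
  o <- order(p$start)
  expect_true(all(p$start[o][-1] > p$end[o][-10]))
  expect_true(all(p$start >= 1 & p$end <= 50000))
  back <- read_panel_gff3(file.path(d1, "genes.gff3"))
  expect_equal(back$start, p$start)
  expect_equal(back$end, p$end)
  expect_equal(back$tss, p$tss)
  expect_equal(back$class, p$class)
})

test_that("background sequence composition is uniform at 1 Mb", {
  cfg <- sim_config(seed = 3, genome_length = 1000000, n_genes = 500,
                    group_sizes = c(1, 1, 1), n_repressed = c(0, 0))
  g <- generate_genome(cfg)
  freq <- Biostrings::letterFrequency(g$genome[[1]], c("A", "C", "G", "T"),
                                      as.prob = TRUE)
  expect_true(all(abs(freq - 0.25) < 0.01))
})

test_that("genome sizing errors are caught", {
  expect_error(sim_config(genome_length = 10000, n_genes = 10,
                          group_sizes = c(2, 2, 2), n_repressed = c(0, 0)),
               "genome too short")
})

test_that("site planting places exact sequences at TSS-42 on both strands", {
  cfg <- sim_config(seed = 17, genome_length = 60000, n_genes = 20,
                    group_sizes = c(4, 3, 3), n_repressed = c(1, 0))
  gg <- generate_genome(cfg)
  kmer <- "TTGATACGTATCAA"
  pwms <- list(I = delta_pwm(kmer), II = delta_pwm(kmer),
               III = delta_pwm(kmer))
  ps <- plant_sites(gg$genome, gg$panel, pwms, seed = 17)
  expect_equal(nrow(ps$sites), 10L)
  expect_true(all(ps$sites$consensus_realization == kmer))
  seqchr <- as.character(ps$genome[[1]])
  for (i in seq_len(nrow(ps$sites))) {
    s <- ps$sites[i, ]
    g <- gg$panel[gg$panel$gene_id == s$promoter_id, ]
    # centre sits at TSS-42 in gene-strand coordinates
    t0 <- g$tss - 1
    expect_equal(if (g$strand == "+") s$center - t0 else t0 - s$center, -42)
    # the genome window read on the gene strand recovers the planted 14-mer
    win <- substr(seqchr, s$center - 7 + 1, s$center + 7)
    if (g$strand == "-") win <- revcomp(win)
    expect_identical(win, kmer)
  }
})

test_that("ChIP simulation obeys factor specificity and pileup expectations", {
  # many sites in one run give the replicate-averaged summit height
  n_sites <- 100
  centers <- seq(5000, by = 3000, length.out = n_sites)
  sites <- data.frame(promoter_id = sprintf("p%03d", seq_len(n_sites)),
                      contig = "synth1", center = centers, strand = "+",
                      group = rep(c("I", "II"), length.out = n_sites),
                      consensus_realization = "X", mode = "activated",
                      stringsAsFactors = FALSE)
  L <- max(centers) + 5000
  cfg <- sim_config(seed = 23, genome_length = L, n_genes = 100,
                    background_depth = 20, enrichment_fold = 8)
  cc <- simulate_chip_coverage(L, sites, "Fnr1", cfg)

  # library size is recorded exactly, coverage matches depth
  expect_identical(cc$input$library_size, sum(as.numeric(cc$input$coverage)))
  expect_equal(mean(cc$input$coverage), 20, tolerance = 0.05)

  # Fnr1 enriches Group I sites: expected summit coverage ~ depth * fold
  g1 <- sites$center[sites$group == "I"] + 1
  expect_equal(mean(cc$ip$coverage[g1]), 20 * 8, tolerance = 0.1)
  # ... but not Group II sites (Fnr3-only), which stay at background
  g2 <- sites$center[sites$group == "II"] + 1
  expect_equal(mean(cc$ip$coverage[g2]), 20, tolerance = 0.1)

  # fold 1 is a null track: IP indistinguishable from input on average
  cfg0 <- sim_config(seed = 23, genome_length = L, n_genes = 100,
                     background_depth = 20, enrichment_fold = 1)
  cc0 <- simulate_chip_coverage(L, sites, "Fnr1", cfg0)
  # total fragment counts are Poisson(~20000) per track, so the mean
  # ratio fluctuates by ~1%; allow a 3-sigma-ish band
  expect_equal(mean(cc0$ip$coverage) / mean(cc0$input$coverage), 1,
               tolerance = 0.05)
})

test_that("count simulation realizes the group regulatory logic", {
  mult <- fnrscape:::expression_multiplier
  F <- 8; pf <- 2
  # Group I needs Fnr1 which needs Fnr3: induction in WT-S only
  expect_equal(mult("I", "activated", "WT", "S", F, pf), F)
  expect_equal(mult("I", "activated", "D1", "S", F, pf), 1)
  expect_equal(mult("I", "activated", "D3", "S", F, pf), 1)
  # Group II needs Fnr3 only: no down regulation in the fnr1 deletion
  expect_equal(mult("II", "activated", "D1", "S", F, pf),
               mult("II", "activated", "WT", "S", F, pf))
  expect_equal(mult("II", "activated", "D3", "S", F, pf), 1)
  # Group III: partial activation with either single factor
  expect_equal(mult("III", "activated", "D1", "S", F, pf), pf)
  expect_equal(mult("III", "activated", "D3", "S", F, pf), pf)
  # repression mirrors activation where the factor is active
  expect_equal(mult("I", "repressed", "WT", "S", F, pf), 1 / F)
  expect_equal(mult("I", "repressed", "D3", "S", F, pf), 1)
  expect_equal(mult("II", "repressed", "D1", "S", F, pf), 1 / F)
  # control condition is always baseline
  for (cl in c("I", "II", "III")) {
    expect_equal(mult(cl, "activated", "WT", "C", F, pf), 1)
  }
})

test_that("sample means recover the planted fold changes", {
  cfg <- sim_config(seed = 31, genome_length = 200000, n_genes = 80,
                    group_sizes = c(5, 5, 5), n_repressed = c(0, 0),
                    partial_fold = 3, replicates = 200)
  gg <- generate_genome(cfg)
  cm <- simulate_counts(gg$panel, cfg)
  g3 <- gg$panel$gene_id[gg$panel$class == "III"]
  d1s <- rowMeans(cm$counts[g3, cm$samples$strain == "D1" &
                              cm$samples$condition == "S"])
  d1c <- rowMeans(cm$counts[g3, cm$samples$strain == "D1" &
                              cm$samples$condition == "C"])
  expect_equal(unname(log2(d1s / d1c)), rep(log2(3), length(g3)),
               tolerance = 0.05)

  # NB moment check: within-cell variance ~ mu + phi mu^2
  wts <- cm$counts[, cm$samples$strain == "WT" & cm$samples$condition == "S"]
  m <- rowMeans(wts); v <- apply(wts, 1, var)
  phi_hat <- median(((v - m) / m^2)[m > 50])
  expect_equal(phi_hat, cfg$nb_dispersion, tolerance = 0.5)
})

test_that("a null design produces no induced genes", {
  cfg <- sim_config(seed = 41, genome_length = 100000, n_genes = 40,
                    group_sizes = c(3, 3, 3), n_repressed = c(0, 0),
                    induction_fold = 1, partial_fold = 1)
  gg <- generate_genome(cfg)
  cm <- simulate_counts(gg$panel, cfg)
  s <- rowMeans(cm$counts[, cm$samples$condition == "S"])
  c0 <- rowMeans(cm$counts[, cm$samples$condition == "C"])
  expect_equal(mean(log2(s / c0)), 0, tolerance = 0.05)
  expect_error(sim_config(induction_fold = 1, partial_fold = 2),
               "null design")
  expect_error(sim_config(induction_fold = 4, partial_fold = 5),
               "partial_fold")
})
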