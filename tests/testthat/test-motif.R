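test_that("window extraction is strand specific and edge safe", {
  genome <- Biostrings::DNAStringSet(paste(random_seqs(1, 2000, seed = 2)))
  names(genome) <- "c1"
  summits <- data.frame(gene_id = c("gp", "gm"), contig = "c1",
                        summit = 500L, strand = c("+", "-"),
                        stringsAsFactors = FALSE)
  w <- extract_windows(summits, genome, flank = 150)
  ref <- substr(as.character(genome[[1]]), 351, 650)   # [350, 650) 0-based
  expect_equal(nchar(w[["gp"]]), 300L)
  expect_identical(w[["gp"]], ref)
  expect_identical(w[["gm"]], revcomp(ref))

  # summit too close to the contig edge is skipped with a warning
  near <- data.frame(gene_id = "ge", contig = "c1", summit = 100L,
                     strand = "+", stringsAsFactors = FALSE)
  expect_warning(we <- extract_windows(near, genome), "skipped")
  expect_length(we, 0L)
})

test_that("EM recovers an exactly planted 14-mer and is monotone", {
  kmer <- "TTGATCGCAATCAA"
  set.seed(8)
  seqs <- random_seqs(25, 80, seed = 8)
  pos <- sample(60, 25, replace = TRUE)
  substr(seqs, pos, pos + 13) <- kmer
  mr <- em_motif_search(seqs, W = 14, seed = 4)
  expect_identical(mr$consensus, kmer)
  expect_true(all(diff(mr$ll_trace) >= -1e-8))
  expect_true(all(abs(colSums(unclass(mr$pwm)) - 1) < 1e-9))
  expect_true(all(mr$sites$offset >= 0 & mr$sites$offset <= 80 - 14))
  expect_equal(mr$sites$offset, pos - 1L)
  expect_gt(mr$gamma, 0.8)
})

test_that("EM null calibration: noise motifs stay well below planted ones", {
  # On random sequences ZOOPS EM still reports a motif: selecting the best
  # offset among ~290 per sequence enriches chance matches, which floors
  # the apparent information content near 0.65 bits/column at this problem
  # size (the same reason MEME attaches E-values to its motifs). What
  # matters for the pipeline is the separation between that noise floor
  # and genuinely planted motifs (>= 1 bit/column models recovered at
  # ~1.2-1.4 bits/column).
  ic <- vapply(1:20, function(r) {
    mr <- em_motif_search(random_seqs(30, 300, seed = 100 + r), W = 14,
                          n_starts = 3, seed = r)
    mean(pwm_ic(mr$pwm))
  }, numeric(1))
  expect_lt(mean(ic), 0.8)

  pwms <- default_group_pwms()
  seqs <- random_seqs(30, 300, seed = 55)
  set.seed(56)
  pos <- sample(280, 30, replace = TRUE)
  for (i in 1:30) substr(seqs[i], pos[i], pos[i] + 13) <- pwm_sample(pwms$I)
  planted_ic <- mean(pwm_ic(em_motif_search(seqs, seed = 57)$pwm))
  expect_gt(planted_ic, mean(ic) + 0.3)
})

test_that("discovery on reverse-complemented input finds the mirror motif", {
  pwms <- default_group_pwms()
  set.seed(21)
  seqs <- random_seqs(30, 120, seed = 21)
  pos <- sample(100, 30, replace = TRUE)
  for (i in 1:30) substr(seqs[i], pos[i], pos[i] + 13) <- pwm_sample(pwms$I)
  fwd <- em_motif_search(seqs, seed = 6)
  rev <- em_motif_search(revcomp(seqs), seed = 6)
  al <- align_pwm(pwm_revcomp(rev$pwm), fwd$pwm)
  expect_lt(fnrscape:::pwm_tv_distance(al$pwm, fwd$pwm), 0.1)
})

test_that("half-site distances match closed-form oracles", {
  p <- default_group_pwms()$I
  expect_equal(half_site_distance(p, p)$js, 0)

  # uniform vs delta column: JS = H(midpoint) - 1 bits
  uni <- pwm(matrix(0.25, 4, 1, dimnames = list(c("A", "C", "G", "T"), NULL)))
  del <- delta_pwm("TTGATACGTATCAA")[, 1, drop = FALSE]
  class(del) <- c("pwm", "matrix")
  mid <- (unclass(uni)[, 1] + unclass(del)[, 1]) / 2
  h <- -sum(mid[mid > 0] * log2(mid[mid > 0]))
  d <- half_site_distance(uni, del)$js
  expect_equal(d, h - 1, tolerance = 1e-12)
  expect_equal(d, 0.5488, tolerance = 1e-3)

  # symmetry on random PWMs
  set.seed(2)
  r1 <- pwm(apply(matrix(rexp(56), 4, 14), 2, function(x) x / sum(x)))
  r2 <- pwm(apply(matrix(rexp(56), 4, 14), 2, function(x) x / sum(x)))
  expect_equal(half_site_distance(r1, r2)$js, half_site_distance(r2, r1)$js)
  expect_error(half_site_distance(r1, pwm(unclass(r2)[, 1:7])), "widths")
})

test_that("the hybrid construction gives the expected verdicts", {
  pwms <- default_group_pwms()
  # Group III is literally II-half (+) I-half: both verdicts true with
  # zero distance on each half
  rep <- hybrid_test(pwms$I, pwms$II, pwms$III)
  expect_true(rep$upstream_matches_II)
  expect_true(rep$downstream_matches_I)
  d <- rep$distances
  expect_equal(d$js[d$half == "upstream" & d$comparison == "III_vs_II"], 0)
  expect_equal(d$js[d$half == "downstream" & d$comparison == "III_vs_I"], 0)

  # a Group III motif equal to Group I fails the upstream verdict
  rep2 <- hybrid_test(pwms$I, pwms$II, pwms$I)
  expect_false(rep2$upstream_matches_II)
})

test_that("site positions map back to TSS offsets exactly", {
  # constructed fixture: motif centred 100 bp upstream of the TSS
  mr <- structure(list(
    pwm = default_group_pwms()$I,
    sites = data.frame(seq = c("g1", "g2"), offset = c(93L, 113L),
                       strand = "+", posterior = c(0.99, 0.2),
                       stringsAsFactors = FALSE)
  ), class = "motif_result")
  meta <- data.frame(gene_id = c("g1", "g2"), tss = c(1251L, 1251L),
                     strand = "+", summit = c(1100L, 1100L),
                     stringsAsFactors = FALSE)
  rep <- site_position_report(mr, meta, flank = 150)
  # g1: window starts at 950 (0-based), site midpoint 950 + 93 + 7 = 1050,
  # TSS0 = 1250, offset = -200; g2 is dropped (posterior < 0.5)
  expect_equal(rep$offsets$gene_id, "g1")
  expect_equal(rep$offsets$offset, -200L)
  expect_equal(rep$median, -200)

  # translation invariance: shifting all coordinates leaves offsets alone
  meta2 <- meta; meta2$tss <- meta$tss + 5000L; meta2$summit <- meta$summit + 5000L
  rep2 <- site_position_report(mr, meta2, flank = 150)
  expect_equal(rep2$offsets$offset, rep$offsets$offset)

  # minus-strand geometry: same numbers through the mirrored mapping
  metam <- data.frame(gene_id = "g1", tss = 950L, strand = "-",
                      summit = 1100L, stringsAsFactors = FALSE)
  mrm <- mr; mrm$sites <- mr$sites[1, ]
  repm <- site_position_report(mrm, metam, flank = 150)
  # window [950, 1250) read on the minus strand; offset 93 puts the site
  # midpoint at genome 1250 - 93 - 7 = 1150; TSS0 = 949 so offset = -201
  expect_equal(repm$offsets$offset, 949L - 1150L + 0L)
})
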