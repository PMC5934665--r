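test_that("identical IP and input tracks give the exact null scores", {
  set.seed(2)
  cov <- rpois(3000, 20)
  ip <- coverage_track("c1", cov)
  input <- coverage_track("c1", cov)
  w <- score_windows(ip, input, width = 300, step = 100)
  expect_true(all(w$d == 0))
  expect_true(all(w$z == 0))
  expect_true(all(w$p == 0.5))
})

test_that("window scores follow the prescribed robust-normal statistic", {
  # independent recomputation of d, z and p from the raw coverage
  set.seed(7)
  ip <- coverage_track("c1", rpois(5000, 30))
  input <- coverage_track("c1", rpois(5000, 30))
  w <- score_windows(ip, input, width = 250, step = 250, pseudocount = 0.5)
  starts <- seq(0, 5000 - 250, by = 250)
  c_ip <- vapply(starts, function(s) sum(ip$coverage[(s + 1):(s + 250)]), 0)
  c_in <- vapply(starts, function(s) sum(input$coverage[(s + 1):(s + 250)]), 0)
  d <- log2((c_ip + 0.5) / ip$library_size) -
       log2((c_in + 0.5) / input$library_size)
  z <- (d - median(d)) / mad(d)
  expect_equal(w$d, d, tolerance = 1e-12)
  expect_equal(w$z, z, tolerance = 1e-12)
  expect_equal(w$p, pnorm(z, lower.tail = FALSE), tolerance = 1e-12)
})

test_that("d is invariant under joint rescaling of counts and library sizes", {
  set.seed(3)
  cov_ip <- rpois(2000, 25)
  cov_in <- rpois(2000, 25)
  w1 <- score_windows(coverage_track("c1", cov_ip),
                      coverage_track("c1", cov_in), 200, 100)
  w2 <- score_windows(coverage_track("c1", 2L * cov_ip),
                      coverage_track("c1", 2L * cov_in), 200, 100)
  # doubling both tracks doubles window counts and library sizes alike;
  # only the half-weight of the pseudocount changes, negligibly
  expect_equal(w1$d, w2$d, tolerance = 1e-3)
})

test_that("degenerate tracks are rejected", {
  z <- coverage_track("c1", integer(1000))
  ok <- coverage_track("c1", rep(1L, 1000))
  expect_error(score_windows(z, ok), "all-zero")
  expect_error(score_windows(ok, coverage_track("c2", rep(1L, 1000))),
               "different contigs")
  expect_error(score_windows(ok, coverage_track("c1", rep(1L, 500))),
               "length")
})

test_that("peak merging respects the threshold and gap rules", {
  mkw <- function(p) {
    n <- length(p)
    data.frame(contig = "c1", start = (0:(n - 1)) * 50,
               end = (0:(n - 1)) * 50 + 300,
               ip_norm = 2, input_norm = 1, d = 1 + seq_len(n) / 100,
               z = 1, p = p, stringsAsFactors = FALSE)
  }
  expect_equal(nrow(call_peaks(mkw(rep(0.5, 20)), alpha = 1e-4)), 0L)

  # two significant windows separated by more than the gap tolerance
  p <- rep(0.5, 20); p[c(3, 10)] <- 1e-6
  pk <- call_peaks(mkw(p), alpha = 1e-4, gap = 1)
  expect_equal(nrow(pk), 2L)

  # a single non-significant window inside a run is bridged when gap = 1
  p <- rep(0.5, 20); p[c(3, 5)] <- 1e-6
  expect_equal(nrow(call_peaks(mkw(p), alpha = 1e-4, gap = 1)), 1L)
  expect_equal(nrow(call_peaks(mkw(p), alpha = 1e-4, gap = 0)), 2L)

  # summit on the window grid = centre of the maximal-d window
  p <- rep(0.5, 20); p[4:6] <- 1e-6
  pk <- call_peaks(mkw(p), alpha = 1e-4)
  expect_equal(pk$summit, 5 * 50 + 150)
  expect_equal(pk$p, 1e-6)
})

test_that("null window p-values are calibrated at moderate tails", {
  cfg <- sim_config(seed = 53, genome_length = 6000000, n_genes = 3000,
                    background_depth = 150)
  cc <- simulate_chip_coverage(6e6, empty_sites(), "Fnr1", cfg)
  w <- score_windows(cc$ip, cc$input, width = 300, step = 300)
  keep <- w$p[seq(1, nrow(w), by = 3)]   # spaced windows are independent
  for (a in c(1e-2, 1e-3)) {
    band <- 3 * sqrt(a * (1 - a) / length(keep))
    expect_lt(abs(mean(keep < a) - a), band)
  }
})

test_that("promoters link to peaks by summit position on the gene strand", {
  panel <- data.frame(
    gene_id = c("gplus", "gminus", "gfar"),
    contig = "c1",
    start = c(10001, 14001, 40001), end = c(11000, 15000, 41000),
    strand = c("+", "-", "+"),
    tss = c(10001, 15000, 40001),
    class = "constitutive", mode = "none", stringsAsFactors = FALSE
  )
  peaks <- data.frame(contig = "c1", start = 9700, end = 10300,
                      summit = 9958, height = 6, p = 1e-8, n_windows = 3,
                      factor = "Fnr1", stringsAsFactors = FALSE)
  links <- peak_at_promoter(peaks, panel)
  # summit at TSS-42 of gplus links; 30 kb from gfar does not
  expect_identical(links$gene_id, "gplus")
  expect_equal(links$offset, -42L)

  # a summit between divergent promoters links to both and is flagged
  peaks2 <- data.frame(contig = "c1", start = 14500, end = 15500,
                       summit = 15100, height = 5, p = 1e-9, n_windows = 3,
                       factor = "Fnr1", stringsAsFactors = FALSE)
  panel2 <- panel
  panel2$tss[3] <- 15201; panel2$start[3] <- 15201; panel2$end[3] <- 16200
  links2 <- peak_at_promoter(peaks2, panel2)
  expect_setequal(links2$gene_id, c("gminus", "gfar"))
  expect_true(all(links2$shared_peak))
})

test_that("summit refinement recovers planted site centres at base resolution", {
  centers <- seq(20000, by = 4000, length.out = 30)
  sites <- data.frame(promoter_id = sprintf("p%02d", 1:30), contig = "synth1",
                      center = centers, strand = "+", group = "I",
                      consensus_realization = "X", mode = "activated",
                      stringsAsFactors = FALSE)
  L <- max(centers) + 20000
  cfg <- sim_config(seed = 71, genome_length = L, n_genes = 20,
                    group_sizes = c(2, 2, 2), n_repressed = c(0, 0),
                    background_depth = 20, enrichment_fold = 8)
  cc <- simulate_chip_coverage(L, sites, "Fnr1", cfg)
  w <- score_windows(cc$ip, cc$input)
  pk <- call_peaks(w, 1e-4, factor = "Fnr1", ip = cc$ip, input = cc$input)
  err <- vapply(centers, function(c0) min(abs(pk$summit - c0)), 0)
  expect_lt(median(err), 25)
  expect_true(mean(err <= 50) >= 0.9)
})
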