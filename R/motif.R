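#' Extract strand-specific windows around peak summits
#'
#' For every linked promoter, a window of `2 * flank` bp centred on the
#' peak summit (`[summit - flank, summit + flank)`, 0-based) is cut from
#' the genome and oriented by the linked gene's strand: windows of
#' minus-strand genes are reverse-complemented, so planted sites read in
#' their gene-strand orientation. Summits closer than `flank` to a contig
#' edge are skipped with a warning.
#'
#' @param summits data.frame with columns gene_id, contig, summit (0-based)
#'   and strand (the linked gene's strand; rows without one default to "+"
#'   and are flagged in the warning).
#' @param genome a [Biostrings::DNAStringSet].
#' @param flank half-window in bp (default 150, i.e. 300-bp windows).
#' @return named character vector of window sequences (names = gene_id).
#' @export
extract_windows <- function(summits, genome, flank = 150L) {
  if (nrow(summits) == 0L) return(character(0))
  strand <- summits$strand
  if (any(is.na(strand) | !strand %in% c("+", "-"))) {
    warning("summits without a linked gene strand default to '+'")
    strand[is.na(strand) | !strand %in% c("+", "-")] <- "+"
  }
  clen <- Biostrings::width(genome)[match(summits$contig, names(genome))]
  ok <- summits$summit >= flank & summits$summit + flank <= clen
  if (!all(ok))
    warning(sum(!ok), " window(s) skipped: summit within ", flank,
            " bp of a contig edge")
  out <- character(0)
  for (i in which(ok)) {
    s <- Biostrings::subseq(genome[[summits$contig[i]]],
                            start = summits$summit[i] - flank + 1L,
                            width = 2L * flank)
    s <- as.character(s)
    if (strand[i] == "-") s <- revcomp(s)
    out[summits$gene_id[i]] <- s
  }
  out
}

# near-delta PWM from a seed subsequence: weight on the observed base,
# remainder spread evenly
seed_pwm <- function(kmer, w = 0.7) {
  idx <- match(strsplit(kmer, "")[[1]], DNA_BASES)
  m <- matrix((1 - w) / 3, nrow = 4, ncol = length(idx),
              dimnames = list(DNA_BASES, NULL))
  m[cbind(idx, seq_along(idx))] <- w
  pwm(m)
}

# column-shift a PWM by s positions (s > 0 moves the motif window right
# along the sequence); vacated columns are filled with background
shift_pwm <- function(p, s) {
  m <- unclass(p)
  W <- ncol(m)
  out <- matrix(0.25, 4, W, dimnames = list(DNA_BASES, NULL))
  src <- seq_len(W) + s
  ok <- src >= 1 & src <= W
  out[, ok] <- m[, src[ok]]
  pwm(out)
}

# flattened base indices per motif column, built once per sequence set:
# idx[[w]][k] is the base (1..4) at offset position w of window k
offset_index <- function(E, W) {
  m <- ncol(E) - W + 1L
  lapply(seq_len(W), function(w) as.vector(E[, w:(w + m - 1L), drop = FALSE]))
}

# site log-likelihood matrix (n x m) for PWM log-probabilities lt
site_score_matrix <- function(idx, lt, n, m, base_ll) {
  S <- matrix(base_ll, n, m)
  W <- length(idx)
  ltv <- as.vector(lt)
  for (w in seq_len(W)) S <- S + ltv[idx[[w]] + 4L * (w - 1L)]
  S
}

# one EM run of the ZOOPS mixture from a given initial PWM; returns the
# fitted model plus the log-likelihood trace
zoops_em_run <- function(E, theta0, gamma0, pseudo, max_iter, tol,
                         idx = offset_index(E, ncol(theta0))) {
  n <- nrow(E); L <- ncol(E)
  W <- ncol(theta0)
  m <- L - W + 1L
  log_bg <- log(0.25)
  bg_ll <- L * log_bg
  theta <- unclass(theta0)
  gamma <- gamma0
  ll_trace <- numeric(0)
  ll_old <- -Inf
  for (iter in seq_len(max_iter)) {
    lt <- log(theta)
    # site log-likelihood for every (sequence, offset)
    S <- site_score_matrix(idx, lt, n, m, (L - W) * log_bg)
    lsite <- S + log(gamma) - log(m)
    lnone <- bg_ll + log(1 - gamma)
    # per-sequence log-likelihood via stable logsumexp over m + 1 components
    M <- pmax(apply(lsite, 1, max), lnone)
    sum_site <- rowSums(exp(lsite - M))
    li <- M + log(sum_site + exp(lnone - M))
    # the Dirichlet-smoothed M-step maximizes the MAP objective (data
    # log-likelihood + pseudocount * sum(log theta)); that objective, not
    # the raw likelihood, is what EM makes non-decreasing, so it is what
    # the trace records
    ll <- sum(li) + pseudo * sum(lt)
    ll_trace <- c(ll_trace, ll)
    q <- exp(lsite - li)                 # posterior over offsets, n x m
    # M-step
    counts <- matrix(pseudo, 4, W, dimnames = list(DNA_BASES, NULL))
    qv <- as.vector(q)
    for (w in seq_len(W)) {
      b <- idx[[w]]
      counts[, w] <- counts[, w] +
        vapply(1:4, function(x) sum(qv[b == x]), numeric(1))
    }
    theta <- sweep(counts, 2, colSums(counts), "/")
    gamma <- min(max(mean(rowSums(q)), 1e-6), 1 - 1e-6)
    if (ll - ll_old < tol && iter > 1L) break
    ll_old <- ll
  }
  # final responsibilities for reporting
  best_off <- apply(q, 1, which.max)
  list(pwm = pwm(theta), gamma = gamma, loglik = ll_trace[length(ll_trace)],
       ll_trace = ll_trace, q = q, best_offset = best_off - 1L,
       site_posterior = rowSums(q))
}

#' ZOOPS EM motif discovery
#'
#' Fits a zero-or-one-occurrence-per-sequence (ZOOPS) mixture by
#' expectation-maximization: each sequence either contains no site
#' (probability `1 - gamma`) or exactly one site of width `W` at a
#' uniformly distributed offset, emitted by the motif PWM against a uniform
#' background. Initialization follows the seed-subsequence scheme: candidate
#' W-mers sampled every W/2 positions from the data are converted to
#' near-delta PWMs and ranked by the likelihood after two EM iterations;
#' the best `n_starts` candidates are run to convergence and the fit with
#' the best final log-likelihood wins. Because weakly conserved flanking
#' columns make phase-shifted optima nearly equivalent, the winner is then
#' polished with MEME-style shift moves (EM restarts from +-1..3 column
#' shifts, kept only on likelihood improvement). The log-likelihood is
#' non-decreasing across iterations within every EM run (the usual EM
#' guarantee, asserted by the test suite).
#'
#' @param sequences character vector (or DNAStringSet) of equal-length
#'   sequences, each at least `W` long; at least 5 sequences.
#' @param W motif width (14 for the Fnr site).
#' @param n_starts number of seed-subsequence initializations.
#' @param seed integer seed for start selection.
#' @param gamma0 initial ZOOPS occupancy prior.
#' @param pseudo Dirichlet pseudocount per base in the M-step.
#' @param max_iter,tol EM stopping rule (log-likelihood gain below `tol`).
#' @return object of class `motif_result`: `pwm`, `sites` (data.frame with
#'   seq, offset (0-based), strand, posterior), `gamma`, `loglik` and
#'   `ll_trace` (the MAP objective: data log-likelihood plus the Dirichlet
#'   smoothing term; non-decreasing across iterations), `n_seq`,
#'   `consensus`.
#' @export
em_motif_search <- function(sequences, W = 14L, n_starts = 10L, seed = 1L,
                            gamma0 = 0.8, pseudo = 0.25,
                            max_iter = 200L, tol = 1e-6) {
  if (methods::is(sequences, "DNAStringSet")) {
    nm <- names(sequences)
    sequences <- as.character(sequences)
    names(sequences) <- nm
  }
  if (length(sequences) < 5L) stop("need at least 5 sequences")
  if (any(nchar(sequences) < W)) stop("sequences shorter than the motif width")
  if (length(unique(nchar(sequences))) != 1L)
    stop("sequences must share a common length")
  if (is.null(names(sequences)))
    names(sequences) <- sprintf("seq_%03d", seq_along(sequences))

  set.seed(stage_seed(seed, "motif"))
  E <- encode_dna(sequences)
  n <- nrow(E); L <- ncol(E); m <- L - W + 1L

  idx <- offset_index(E, W)

  # MEME-style starting-point search: candidate W-mers taken every W/2
  # positions from a subsample of the sequences, each scored in a single
  # pass by the summed best-offset site score of its near-delta PWM; only
  # the best n_starts candidates are run to convergence
  cand_seqs <- if (n > 12L) sort(sample.int(n, 12L)) else seq_len(n)
  offsets <- unique(c(seq.int(1L, m, by = max(1L, W %/% 2L)), m))
  cands <- expand.grid(i = cand_seqs, j = offsets)
  cand_score <- vapply(seq_len(nrow(cands)), function(k) {
    kmer <- paste(DNA_BASES[E[cands$i[k], cands$j[k]:(cands$j[k] + W - 1L)]],
                  collapse = "")
    S <- site_score_matrix(idx, log(unclass(seed_pwm(kmer))), n, m, 0)
    sum(apply(S, 1, max))
  }, numeric(1))
  top <- order(cand_score, decreasing = TRUE)[seq_len(min(n_starts, nrow(cands)))]

  best <- NULL
  for (k in top) {
    kmer <- paste(DNA_BASES[E[cands$i[k], cands$j[k]:(cands$j[k] + W - 1L)]],
                  collapse = "")
    fit <- zoops_em_run(E, seed_pwm(kmer), gamma0, pseudo, max_iter, tol, idx)
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }

  # phase-shift moves: EM often stalls one or two columns off when flanking
  # motif columns are weak; restart from shifted copies of the current
  # optimum and keep the best final likelihood (as MEME does)
  repeat {
    improved <- FALSE
    for (s in c(-3:-1, 1:3)) {
      fit <- zoops_em_run(E, shift_pwm(best$pwm, s), best$gamma, pseudo,
                          max_iter, tol, idx)
      if (fit$loglik > best$loglik + 1e-8) {
        best <- fit
        improved <- TRUE
      }
    }
    if (!improved) break
  }

  sites <- data.frame(
    seq = names(sequences),
    offset = best$best_offset,
    strand = "+",
    posterior = best$site_posterior,
    stringsAsFactors = FALSE
  )
  structure(list(pwm = best$pwm, sites = sites, gamma = best$gamma,
                 loglik = best$loglik, ll_trace = best$ll_trace,
                 n_seq = n, consensus = pwm_consensus(best$pwm)),
            class = "motif_result")
}

#' @export
print.motif_result <- function(x, ...) {
  cat(sprintf("motif_result: %d sequences, consensus %s, gamma %.2f, logL %.1f (%d EM iterations)\n",
              x$n_seq, x$consensus, x$gamma, x$loglik, length(x$ll_trace)))
  invisible(x)
}

#' Align one PWM to a reference by a small column shift
#'
#' Motif discovery fixes a motif only up to small translations when its
#' flanking columns are weakly informative: phase-shifted solutions differ
#' by fractions of a nat and the maximum-likelihood phase is effectively
#' random. Column-wise comparisons therefore require a common phase. This
#' helper tries shifts of up to `max_shift` columns, scores each by the
#' mean Jensen-Shannon divergence over the overlapping columns, and
#' returns the best-aligned copy (vacated edge columns are filled with
#' uniform background).
#'
#' @param p [pwm()] to align.
#' @param ref reference [pwm()] of the same width that anchors the phase
#'   (e.g. a motif with strongly conserved flanks, or the planted model in
#'   simulation scoring).
#' @param max_shift maximum absolute column shift considered.
#' @return list: `pwm` (aligned copy), `shift` (the column correction
#'   chosen; add it to site offsets to express them in the reference
#'   phase), `js` (mean JS divergence over overlapping columns at the
#'   chosen shift).
#' @export
align_pwm <- function(p, ref, max_shift = 3L) {
  W <- ncol(p)
  stopifnot(ncol(ref) == W)
  scores <- vapply(-max_shift:max_shift, function(s) {
    keep <- which(seq_len(W) + s >= 1L & seq_len(W) + s <= W)
    half_site_distance(shift_pwm(p, s), ref, keep)$js
  }, numeric(1))
  s <- (-max_shift:max_shift)[which.min(scores)]
  list(pwm = shift_pwm(p, s), shift = s, js = min(scores))
}

# Jensen-Shannon divergence (base 2) between two probability vectors
js_divergence <- function(p, q) {
  m <- (p + q) / 2
  kl <- function(a, b) {
    i <- a > 0
    sum(a[i] * (log2(a[i]) - log2(b[i])))
  }
  (kl(p, m) + kl(q, m)) / 2
}

#' Mean per-column distance between two PWMs
#'
#' The primary metric is the column-wise Jensen-Shannon divergence (base
#' 2, bounded in [0, 1] bits, symmetric); the Euclidean column distance is
#' returned alongside.
#'
#' @param pwm_a,pwm_b [pwm()]s with the same number of selected columns.
#' @param columns column indices to compare (default: all, requiring equal
#'   widths).
#' @return list with `js` (mean JS divergence, bits) and `euclidean`
#'   (mean column L2 distance).
#' @export
half_site_distance <- function(pwm_a, pwm_b, columns = NULL) {
  a <- unclass(pwm_a); b <- unclass(pwm_b)
  if (is.null(columns)) {
    if (ncol(a) != ncol(b)) stop("PWM widths differ; supply columns")
    ca <- seq_len(ncol(a)); cb <- ca
  } else if (is.list(columns)) {
    ca <- columns[[1]]; cb <- columns[[2]]
  } else {
    ca <- columns; cb <- columns
  }
  if (length(ca) != length(cb)) stop("column selections differ in length")
  js <- mean(vapply(seq_along(ca), function(i) {
    js_divergence(a[, ca[i]], b[, cb[i]])
  }, numeric(1)))
  eu <- mean(vapply(seq_along(ca), function(i) {
    sqrt(sum((a[, ca[i]] - b[, cb[i]])^2))
  }, numeric(1)))
  list(js = js, euclidean = eu)
}

#' Test the hybrid half-site hypothesis for the Group III motif
#'
#' Splits the three 14-column motifs into upstream (columns 1-7) and
#' downstream (columns 8-14) half-sites and asks whether the Group III
#' upstream half is closer to Group II than to Group I, and its downstream
#' half closer to Group I than to Group II - the signature expected if
#' Group III sites are bound by oriented Fnr3-Fnr1 heterodimers.
#'
#' @param pwm_I,pwm_II,pwm_III 14-column [pwm()]s.
#' @return list of class `half_site_report`: distance tables for both
#'   halves (`js` and `euclidean` per comparison) and the two boolean
#'   verdicts `upstream_matches_II`, `downstream_matches_I`.
#' @export
hybrid_test <- function(pwm_I, pwm_II, pwm_III) {
  for (p in list(pwm_I, pwm_II, pwm_III))
    if (ncol(p) != 14L) stop("all motifs must be 14 columns wide")
  up <- 1:7; dn <- 8:14
  d <- list(
    up_III_II = half_site_distance(pwm_III, pwm_II, up),
    up_III_I  = half_site_distance(pwm_III, pwm_I, up),
    dn_III_I  = half_site_distance(pwm_III, pwm_I, dn),
    dn_III_II = half_site_distance(pwm_III, pwm_II, dn)
  )
  structure(list(
    distances = data.frame(
      half = c("upstream", "upstream", "downstream", "downstream"),
      comparison = c("III_vs_II", "III_vs_I", "III_vs_I", "III_vs_II"),
      js = vapply(d, `[[`, numeric(1), "js"),
      euclidean = vapply(d, `[[`, numeric(1), "euclidean"),
      row.names = NULL
    ),
    upstream_matches_II = d$up_III_II$js < d$up_III_I$js,
    downstream_matches_I = d$dn_III_I$js < d$dn_III_II$js
  ), class = "half_site_report")
}

#' @export
print.half_site_report <- function(x, ...) {
  cat("half-site comparison (JS divergence, bits):\n")
  print(x$distances)
  cat(sprintf("upstream half closer to Group II: %s\n", x$upstream_matches_II))
  cat(sprintf("downstream half closer to Group I: %s\n", x$downstream_matches_I))
  invisible(x)
}

#' Locate discovered sites relative to the TSS
#'
#' Maps each discovered site back to genome coordinates and reports the
#' offset of the site midpoint from the linked gene's TSS in gene-strand
#' coordinates (negative = upstream). Promoters whose ZOOPS site posterior
#' falls below `min_posterior` are omitted. The promoter-architecture flag
#' marks a median offset within [-45, -39], the Class II geometry with the
#' activator centred at -42.
#'
#' @param motif_result a [em_motif_search()] result.
#' @param meta data.frame aligned by gene id with columns gene_id, tss
#'   (1-based), strand, summit (0-based).
#' @param flank half-window used in [extract_windows()].
#' @param min_posterior minimum site posterior for inclusion.
#' @return list: `offsets` (data.frame gene_id, offset, posterior),
#'   `median`, `mad`, `class_II` flag.
#' @export
site_position_report <- function(motif_result, meta, flank = 150L,
                                 min_posterior = 0.5) {
  W <- ncol(motif_result$pwm)
  sites <- motif_result$sites
  sites <- sites[sites$posterior >= min_posterior, , drop = FALSE]
  i <- match(sites$seq, meta$gene_id)
  if (anyNA(i)) stop("site sequences missing from metadata")
  t0 <- meta$tss[i] - 1L
  plus <- meta$strand[i] == "+"
  mid <- ifelse(plus,
                meta$summit[i] - flank + sites$offset + W %/% 2L,
                meta$summit[i] + flank - sites$offset - W %/% 2L)
  offset <- ifelse(plus, mid - t0, t0 - mid)
  med <- if (length(offset)) median(offset) else NA_real_
  list(
    offsets = data.frame(gene_id = sites$seq, offset = as.integer(offset),
                         posterior = sites$posterior,
                         stringsAsFactors = FALSE),
    median = med,
    mad = if (length(offset)) mad(offset) else NA_real_,
    class_II = is.finite(med) && med >= -45 && med <= -39
  )
}
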