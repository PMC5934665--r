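#' Effective library sizes by median-of-ratios normalization
#'
#' Per-sample depth-normalized counts are compared, gene by gene, with the
#' across-sample geometric mean; the per-sample median of those ratios is a
#' composition factor (geometric mean 1 across samples) and the effective
#' library size is the raw size times that factor. Doubling one sample's
#' counts therefore exactly doubles its effective size. Only genes with
#' nonzero counts in every sample enter the medians; if none exist, raw
#' sizes are returned with a warning.
#'
#' @param counts integer matrix, genes x samples.
#' @return named numeric vector of effective library sizes.
#' @export
normalize_libsizes <- function(counts) {
  lib <- colSums(counts)
  if (any(lib == 0)) stop("sample with zero total counts")
  ok <- rowSums(counts > 0) == ncol(counts)
  if (!any(ok)) {
    warning("no gene expressed in all samples; using raw library sizes")
    return(lib)
  }
  rate <- sweep(counts[ok, , drop = FALSE], 2, lib, "/")
  ref <- exp(rowMeans(log(rate)))
  f <- apply(rate / ref, 2, median)
  f <- f / exp(mean(log(f)))
  lib * f
}

#' Method-of-moments common dispersion
#'
#' Counts are rescaled to a common effective library size; within each
#' strain x condition cell the per-gene moment estimate
#' `phi = (s^2 - m) / m^2` is formed, averaged over cells, floored at zero
#' and pooled as the across-gene median.
#'
#' @param counts integer matrix, genes x samples.
#' @param samples sample table with `strain` and `condition` columns, rows
#'   aligned to `colnames(counts)`.
#' @param eff_sizes optional effective library sizes (defaults to
#'   [normalize_libsizes()]).
#' @return a single non-negative dispersion estimate.
#' @export
estimate_dispersion <- function(counts, samples, eff_sizes = NULL) {
  eff_sizes <- eff_sizes %||% normalize_libsizes(counts)
  common <- exp(mean(log(eff_sizes)))
  norm <- sweep(counts, 2, common / eff_sizes, "*")
  cell <- interaction(samples$strain, samples$condition, drop = TRUE)
  phi_cell <- sapply(levels(cell), function(cl) {
    x <- norm[, cell == cl, drop = FALSE]
    if (ncol(x) < 2L) return(rep(NA_real_, nrow(norm)))
    m <- rowMeans(x)
    v <- apply(x, 1, var)
    ifelse(m > 0, (v - m) / m^2, NA_real_)
  })
  phi_gene <- pmax(0, rowMeans(phi_cell, na.rm = TRUE))
  phi <- median(phi_gene, na.rm = TRUE)
  if (!is.finite(phi)) 0 else phi
}

#' Negative-binomial exact test for one gene
#'
#' Counts are rescaled to the common effective library size (rounded
#' half-to-even), the group sums `A` and `B` are modelled as
#' `NB(n_a * m, size = n_a / phi)` and `NB(n_b * m, size = n_b / phi)`
#' with `m` the pooled per-sample mean, and the two-sided exact p-value
#' conditions on the total `S = A + B`: it sums, over all splits of `S`,
#' the probabilities no larger than that of the observed split, normalized
#' by the total. With `phi = 0` the negative binomial degenerates to
#' Poisson and the conditional distribution is binomial.
#'
#' @param ya,yb raw counts for the two groups (single gene).
#' @param phi common NB dispersion (>= 0).
#' @param eff_a,eff_b effective library sizes for each group's samples.
#' @return list: `p`, `logFC` (log2 of B over A on normalized counts, with
#'   a 0.5 offset), `logCPM`.
#' @export
nb_exact_test <- function(ya, yb, phi, eff_a, eff_b) {
  stopifnot(length(ya) == length(eff_a), length(yb) == length(eff_b),
            length(ya) > 0L, length(yb) > 0L, phi >= 0)
  common <- exp(mean(log(c(eff_a, eff_b))))
  za <- ya * common / eff_a
  zb <- yb * common / eff_b
  logFC <- log2((mean(zb) + 0.5) / (mean(za) + 0.5))
  logCPM <- log2((mean(c(za, zb)) + 0.5) / common * 1e6)

  A <- round(sum(za))          # round() is half-to-even
  B <- round(sum(zb))
  S <- A + B
  if (S == 0) return(list(p = 1, logFC = 0, logCPM = logCPM))

  na <- length(ya); nb <- length(yb)
  m <- S / (na + nb)
  k <- 0:S
  if (phi > 0) {
    la <- dnbinom(k, size = na / phi, mu = na * m, log = TRUE)
    lb <- dnbinom(S - k, size = nb / phi, mu = nb * m, log = TRUE)
  } else {
    la <- dpois(k, na * m, log = TRUE)
    lb <- dpois(S - k, nb * m, log = TRUE)
  }
  lp <- la + lb
  lobs <- lp[A + 1L]
  keep <- lp <= lobs + 1e-10
  p <- exp(logsumexp(lp[keep]) - logsumexp(lp))
  list(p = min(p, 1), logFC = logFC, logCPM = logCPM)
}

# the seven pairwise comparisons of the study design; B over A
.DE_COMPARISONS <- list(
  WTCvWTS = list(a = c("WT", "C"), b = c("WT", "S")),
  D1CvD1S = list(a = c("D1", "C"), b = c("D1", "S")),
  D3CvD3S = list(a = c("D3", "C"), b = c("D3", "S")),
  WTCvD1C = list(a = c("WT", "C"), b = c("D1", "C")),
  WTCvD3C = list(a = c("WT", "C"), b = c("D3", "C")),
  WTSvD1S = list(a = c("WT", "S"), b = c("D1", "S")),
  WTSvD3S = list(a = c("WT", "S"), b = c("D3", "S"))
)

#' Run the seven differential-expression comparisons
#'
#' Applies [nb_exact_test()] gene-wise to each of the seven study
#' comparisons (control vs switch within strain; wild type vs deletion
#' within condition). A gene is significant when `p < 0.001` and
#' `|logFC| >= 1`; Benjamini-Hochberg q-values are reported per comparison
#' as an extra column but play no part in the decision rule.
#'
#' @param counts integer matrix, genes x samples.
#' @param samples sample table (sample, strain, condition, replicate).
#' @param phi common dispersion; estimated with [estimate_dispersion()]
#'   when `NULL`.
#' @param comparisons named list of comparisons (defaults to the seven of
#'   the study design); each element is `list(a = c(strain, condition),
#'   b = c(strain, condition))`.
#' @param p_threshold,lfc_threshold decision rule (defaults 0.001 and 1).
#' @return data.frame: gene, comparison, logFC, logCPM, p, q, significant,
#'   direction.
#' @export
run_comparisons <- function(counts, samples, phi = NULL,
                            comparisons = .DE_COMPARISONS,
                            p_threshold = 1e-3, lfc_threshold = 1) {
  stopifnot(identical(colnames(counts), samples$sample))
  eff <- normalize_libsizes(counts)
  if (is.null(phi)) phi <- estimate_dispersion(counts, samples, eff)

  out <- lapply(names(comparisons), function(nm) {
    cmp <- comparisons[[nm]]
    ia <- which(samples$strain == cmp$a[1] & samples$condition == cmp$a[2])
    ib <- which(samples$strain == cmp$b[1] & samples$condition == cmp$b[2])
    if (length(ia) == 0L || length(ib) == 0L) {
      warning("comparison ", nm, " skipped: missing sample cell")
      return(NULL)
    }
    res <- vapply(seq_len(nrow(counts)), function(g) {
      r <- nb_exact_test(counts[g, ia], counts[g, ib], phi,
                         eff[ia], eff[ib])
      c(r$p, r$logFC, r$logCPM)
    }, numeric(3))
    df <- data.frame(
      gene = rownames(counts),
      comparison = nm,
      logFC = res[2, ],
      logCPM = res[3, ],
      p = res[1, ],
      stringsAsFactors = FALSE
    )
    df$q <- stats::p.adjust(df$p, method = "BH")
    df$significant <- df$p < p_threshold & abs(df$logFC) >= lfc_threshold
    df$direction <- ifelse(df$logFC > 0, "up", "down")
    df
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
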