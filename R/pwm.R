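#' Position weight matrices for Fnr binding sites
#'
#' A PWM here is a 4 x W probability matrix (rows A, C, G, T; columns are
#' motif positions 1..W) with every column summing to 1. The Fnr motif is
#' 14 bp wide, read as two 7-bp half-sites: the upstream half (positions
#' 1-7) and the downstream half (positions 8-14), each contacted by one
#' subunit of the Fnr dimer.
#'
#' @param mat numeric 4 x W matrix of column probabilities; rows may be
#'   unnamed (assumed A, C, G, T) or named.
#' @return an object of class `pwm`.
#' @export
pwm <- function(mat) {
  mat <- as.matrix(mat)
  if (nrow(mat) != 4L) stop("a PWM needs 4 rows (A, C, G, T)")
  if (is.null(rownames(mat))) rownames(mat) <- DNA_BASES
  mat <- mat[DNA_BASES, , drop = FALSE]
  if (any(mat < 0)) stop("PWM probabilities must be non-negative")
  cs <- colSums(mat)
  if (any(abs(cs - 1) > 1e-3)) stop("PWM columns must sum to 1")
  mat <- sweep(mat, 2, cs, "/")
  dimnames(mat) <- list(DNA_BASES, NULL)
  structure(mat, class = c("pwm", "matrix"))
}

#' @export
print.pwm <- function(x, ...) {
  cat("PWM, width", ncol(x), "- consensus", pwm_consensus(x), "\n")
  print(unclass(round(x, 3)))
  invisible(x)
}

#' Consensus string of a PWM (most probable base per column)
#' @param x a [pwm()].
#' @return single character string of length `ncol(x)`.
#' @export
pwm_consensus <- function(x) {
  paste(DNA_BASES[apply(unclass(x), 2, which.max)], collapse = "")
}

#' Per-column information content of a PWM
#'
#' IC in bits against a uniform background: `2 - H(column)` where H is the
#' Shannon entropy in bits. Values lie in [0, 2].
#'
#' @param x a [pwm()].
#' @return numeric vector, one value per column.
#' @export
pwm_ic <- function(x) {
  p <- unclass(x)
  h <- apply(p, 2, function(col) {
    col <- col[col > 0]
    -sum(col * log2(col))
  })
  2 - h
}

#' Reverse complement of a PWM
#' @param x a [pwm()].
#' @return the reverse-complemented [pwm()].
#' @export
pwm_revcomp <- function(x) {
  m <- unclass(x)[c("T", "G", "C", "A"), rev(seq_len(ncol(x))), drop = FALSE]
  rownames(m) <- DNA_BASES
  pwm(m)
}

#' Sample k-mers column-wise from a PWM
#' @param x a [pwm()].
#' @param n number of k-mers to draw.
#' @return character vector of `n` strings of width `ncol(x)`.
#' @export
pwm_sample <- function(x, n = 1L) {
  W <- ncol(x)
  draws <- vapply(seq_len(W), function(j) {
    sample(DNA_BASES, n, replace = TRUE, prob = unclass(x)[, j])
  }, character(n))
  if (n == 1L) paste(draws, collapse = "") else apply(draws, 1, paste, collapse = "")
}

# Column probabilities used by the default site models. A "core" column puts
# weight w on one base and spreads the rest evenly; helper for readability.
.col <- function(base, w) {
  p <- rep((1 - w) / 3, 4)
  p[match(base, DNA_BASES)] <- w
  p
}

.col2 <- function(b1, w1, b2, w2) {
  p <- rep((1 - w1 - w2) / 2, 4)
  p[match(b1, DNA_BASES)] <- w1
  p[match(b2, DNA_BASES)] <- w2
  p
}

#' Default binding-site models for the three promoter groups
#'
#' Returns the three 14-column PWMs used by the synthetic-data generator,
#' built to reproduce the qualitative architecture of the discovered motifs:
#'
#' * **Group I** (Fnr1 homodimer): a strong inverted repeat with canonical
#'   Fnr-box arms TTGAT ... ATCAA, a well-conserved T at position 1 and A at
#'   position 14, and a weakly A/T-biased 4-bp spacer (positions 6-9).
#' * **Group II** (Fnr3 homodimer): the flanking position-1 T and
#'   position-14 A are poorly conserved, and positions 6 and 7 prefer C/G
#'   and C/T respectively (mirrored at 8 and 9 to keep the dyad).
#' * **Group III** (hybrid): upstream half-site (columns 1-7) taken from the
#'   Group II model, downstream half-site (columns 8-14) from Group I, the
#'   architecture expected for an oriented Fnr3-Fnr1 heterodimer.
#'
#' @return named list of three [pwm()] objects: `I`, `II`, `III`.
#' @export
default_group_pwms <- function() {
  core <- 0.92   # conserved arm positions
  g1 <- cbind(
    .col("T", core), .col("T", core), .col("G", core), .col("A", core),
    .col("T", core),
    # spacer, slight A/T bias
    c(0.35, 0.15, 0.15, 0.35), c(0.35, 0.15, 0.15, 0.35),
    c(0.35, 0.15, 0.15, 0.35), c(0.35, 0.15, 0.15, 0.35),
    .col("A", core), .col("T", core), .col("C", core), .col("A", core),
    .col("A", core)
  )
  # weakly conserved flanks for the Fnr3-type site
  flank1  <- c(0.28, 0.20, 0.20, 0.32)  # position 1, T slightly favoured
  flank14 <- c(0.32, 0.20, 0.20, 0.28)  # position 14, A slightly favoured
  g2 <- cbind(
    flank1, .col("T", core), .col("G", core), .col("A", core), .col("T", core),
    .col2("C", 0.60, "G", 0.32),  # position 6: C/G preference
    .col2("C", 0.60, "T", 0.32),  # position 7: C/T preference
    .col2("G", 0.60, "A", 0.32),  # position 8 mirrors 7
    .col2("G", 0.60, "C", 0.32),  # position 9 mirrors 6
    .col("A", core), .col("T", core), .col("C", core), .col("A", core),
    flank14
  )
  g3 <- cbind(g2[, 1:7], g1[, 8:14])
  rownames(g1) <- rownames(g2) <- rownames(g3) <- DNA_BASES
  list(I = pwm(g1), II = pwm(g2), III = pwm(g3))
}

#' Write PWMs in MEME minimal motif format
#'
#' @param pwms named list of [pwm()] objects.
#' @param path output file.
#' @param nsites optional integer vector of site counts per motif (goes in
#'   the `nsites=` field; defaults to 20).
#' @param background numeric length-4 background frequencies.
#' @return `path`, invisibly.
#' @export
write_meme <- function(pwms, path, nsites = NULL, background = rep(0.25, 4)) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "strands: + -", "",
               "Background letter frequencies",
               paste(sprintf("%s %.5f", DNA_BASES, background), collapse = " "),
               ""), con)
  if (is.null(nsites)) nsites <- rep(20L, length(pwms))
  for (i in seq_along(pwms)) {
    p <- pwms[[i]]
    writeLines(sprintf("MOTIF %s", names(pwms)[i] %||% paste0("motif_", i)), con)
    writeLines(sprintf(
      "letter-probability matrix: alength= 4 w= %d nsites= %d E= 0",
      ncol(p), nsites[i]), con)
    for (j in seq_len(ncol(p))) {
      writeLines(paste(sprintf("%.6f", unclass(p)[, j]), collapse = "  "), con)
    }
    writeLines("", con)
  }
  invisible(path)
}

#' Read PWMs from a MEME minimal motif file
#' @param path a file written by [write_meme()] (or MEME itself, minimal
#'   format, ACGT alphabet).
#' @return named list of [pwm()] objects.
#' @export
read_meme <- function(path) {
  lines <- readLines(path)
  out <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (grepl("^MOTIF\\s", lines[i])) {
      name <- strsplit(trimws(lines[i]), "\\s+")[[1]][2]
      j <- i + 1L
      while (j <= length(lines) && !grepl("^letter-probability", lines[j])) j <- j + 1L
      w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", lines[j]))
      rows <- lines[(j + 1L):(j + w)]
      mat <- t(vapply(rows, function(r) as.numeric(strsplit(trimws(r), "\\s+")[[1]]),
                      numeric(4)))
      out[[name]] <- pwm(t(mat))
      i <- j + w
    }
    i <- i + 1L
  }
  out
}
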