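#' @importFrom stats mad median pnorm rnorm rpois rnbinom runif dnbinom dpois
#'   quantile setNames var
#' @importFrom utils write.table read.delim head
NULL

DNA_BASES <- c("A", "C", "G", "T")

# Stage offsets added to the user seed so that each pipeline stage draws from
# its own reproducible stream. Offsets are small; user seeds up to ~2e9 stay
# valid 32-bit integers because we wrap with %% .Machine$integer.max.
.STAGE_SEEDS <- c(
  genome   = 101L,
  sites    = 211L,
  chip1    = 307L,
  chip3    = 311L,
  counts   = 401L,
  motif    = 503L
)

stage_seed <- function(seed, stage) {
  stopifnot(stage %in% names(.STAGE_SEEDS))
  as.integer((as.numeric(seed) + .STAGE_SEEDS[[stage]]) %% (.Machine$integer.max - 1L))
}

#' Reverse-complement a DNA string
#'
#' Thin wrapper around [Biostrings::reverseComplement()] that keeps plain
#' character vectors in and out, which is what the simulator and motif code
#' pass around.
#'
#' @param x character vector of DNA strings (A/C/G/T).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Encode DNA strings (all the same length) as an integer matrix, A=1..T=4.
encode_dna <- function(x) {
  stopifnot(length(unique(nchar(x))) == 1L)
  m <- matrix(match(unlist(strsplit(toupper(x), "")), DNA_BASES),
              nrow = length(x), byrow = TRUE)
  if (anyNA(m)) stop("non-ACGT character in sequence")
  m
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
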