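#' @importFrom stats lm pf rbinom runif setNames aggregate
#' @importFrom utils read.delim write.table head
NULL

DNA_BASES <- c("A", "C", "G", "T")

IUPAC_CODES <- c(
  A = "A", C = "C", G = "G", T = "T",
  R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC",
  B = "CGT", D = "AGT", H = "ACT", V = "ACG", N = "ACGT"
)

#' Reverse complement of nucleotide strings
#'
#' Vectorised wrapper over [Biostrings::reverseComplement()] that keeps
#' plain character vectors as the working representation.
#'
#' @param x character vector of IUPAC nucleotide strings.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Generate random DNA sequences
#'
#' @param n number of sequences.
#' @param len length of each sequence in bp.
#' @return character vector of `n` sequences of length `len` over A/C/G/T.
#' @keywords internal
random_dna <- function(n, len) {
  if (n == 0) return(character(0))
  vapply(seq_len(n), function(i) {
    paste(sample(DNA_BASES, len, replace = TRUE), collapse = "")
  }, character(1))
}

## Point-mutate each position independently with probability `rate`,
## always to a different base.
mutate_seq <- function(seq, rate) {
  if (rate <= 0) return(seq)
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- runif(length(ch)) < rate
  if (any(hit)) {
    ch[hit] <- vapply(ch[hit], function(b) {
      sample(setdiff(DNA_BASES, b), 1)
    }, character(1))
  }
  paste(ch, collapse = "")
}

## Hamming distance between two equal-length strings.
hamming <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  sum(strsplit(a, "", fixed = TRUE)[[1]] != strsplit(b, "", fixed = TRUE)[[1]])
}

## Character matrix (one row per string) for vectorised Hamming decoding.
seq_char_matrix <- function(x, len) {
  m <- matrix("", nrow = length(x), ncol = len)
  for (i in seq_along(x)) {
    ch <- strsplit(x[i], "", fixed = TRUE)[[1]]
    m[i, ] <- ch[seq_len(len)]
  }
  m
}

#' Round half away from zero
#'
#' Deterministic half-up rounding used for all printed percentages, so
#' that tabulated rates are reproducible to the digit.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

is_dna_string <- function(x, alphabet = DNA_BASES) {
  nzchar(x) & !grepl(paste0("[^", paste(alphabet, collapse = ""), "]"), x)
}

is_iupac_string <- function(x) {
  is_dna_string(x, alphabet = names(IUPAC_CODES))
}
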