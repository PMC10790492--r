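# Sequence encoding helpers shared across modules.
# Internal alphabet is DNA (A,C,G,T); U on input is mapped to T, and N is
# represented as 0 in integer encoding / a uniform 0.25 row in one-hot.

BASES <- c("A", "C", "G", "T")

#' Encode a DNA string as integers (A=1, C=2, G=3, T=4, N=0)
#' @param sequence character scalar over A/C/G/T/U/N (case-insensitive).
#' @return integer vector of length `nchar(sequence)`.
#' @keywords internal
seq_to_int <- function(sequence) {
  chars <- strsplit(toupper(chartr("Uu", "Tt", sequence)), "", fixed = TRUE)[[1]]
  idx <- match(chars, BASES)
  idx[is.na(idx)] <- 0L
  as.integer(idx)
}

int_to_seq <- function(ints) {
  chars <- c("N", BASES)[ints + 1L]
  paste(chars, collapse = "")
}

#' One-hot encode an integer-coded sequence
#'
#' N positions (code 0) become uniform 0.25 rows so they carry no base
#' information without producing NaNs downstream.
#'
#' @param seq_int integer vector from [seq_to_int()].
#' @return `length(seq_int)` x 4 matrix with columns A,C,G,T.
#' @keywords internal
one_hot <- function(seq_int) {
  L <- length(seq_int)
  X <- matrix(0, L, 4, dimnames = list(NULL, BASES))
  known <- seq_int > 0L
  X[cbind(which(known), seq_int[known])] <- 1
  X[!known, ] <- 0.25
  X
}

#' Reverse-complement a DNA string
#' @keywords internal
revcomp <- function(sequence) {
  comp <- chartr("ACGTacgtUu", "TGCAtgcaAa", sequence)
  paste(rev(strsplit(comp, "", fixed = TRUE)[[1]]), collapse = "")
}

# Deterministic sub-seed derivation: keeps derived seeds within 32-bit range.
derive_seed <- function(seed, salt) {
  (as.integer(seed) * 1103L + as.integer(salt) * 7919L) %% 2147483L
}
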