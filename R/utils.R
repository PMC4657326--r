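#' Standard amino-acid alphabet
#'
#' The 20 standard amino acids in alphabetical one-letter-code order. Every
#' 20-vector produced by this package (counts, encodings, matrix rows) uses
#' this order.
#'
#' @format Character vector of length 20.
#' @export
AMINO_ACIDS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Round half away from zero
#'
#' `base::round()` rounds half to even; expected pair counts are rounded half
#' up (2.5 -> 3) so that the worked-example convention is deterministic.
#'
#' @param x numeric vector (nonnegative in this package's use).
#' @return integer-valued numeric vector.
#' @export
round_half_up <- function(x) floor(x + 0.5)

#' Logistic sigmoid
#' @param eta linear predictor.
#' @return value in (0, 1).
#' @keywords internal
sigmoid <- function(eta) stats::plogis(eta)

# Deterministic per-fold / per-repeat seed derivation. Knuth multiplicative
# hash folded into [0, 2^31 - 2] so the result is a valid 32-bit seed.
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) * 2654435761 + as.double(index) * 97) %%
               2147483646) + 1L
}

# Percentage formatting used by the CLI (two decimals, matching the
# reporting style of the quantities this package computes).
fmt_pct <- function(x) sprintf("%.2f", x)
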