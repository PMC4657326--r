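#' Single-nucleotide codon-mutation amino-acid transition matrix
#'
#' Derives, from the standard genetic code, the probability that an amino
#' acid a mutates into amino acid b under one single-nucleotide codon
#' substitution. For each amino acid its codons are enumerated (weighted
#' uniformly: protein sequences carry no codon-usage information), each
#' codon's 9 single-nucleotide mutants are tallied by translated target,
#' and P(a -> b) = tally(b) / total.
#'
#' @param stop_handling `"exclude"` (default): mutants hitting a stop codon
#'   are removed from the tally and each row is renormalized over the
#'   remaining targets; `"renormalize"` is accepted as a synonym (both
#'   yield row-stochastic rows); `"keep"` keeps stop-codon mass in the
#'   denominator, so rows of stop-adjacent amino acids sum to < 1.
#' @param synonymous `"include"` (default) keeps a -> a transitions
#'   (synonymous or same-acid missense); `"exclude"` removes the diagonal
#'   before normalization.
#' @return A `mutation_matrix`: 20 x 20 numeric matrix, rows = source and
#'   columns = target amino acid in [AMINO_ACIDS] order, with the options
#'   stored in attributes.
#' @export
#' @examples
#' M <- build_mutation_matrix()
#' M["W", "R"]  # 2/7: two of UGG's seven non-stop mutants code Arg
build_mutation_matrix <- function(stop_handling = c("exclude", "renormalize",
                                                    "keep"),
                                  synonymous = c("include", "exclude")) {
  stop_handling <- match.arg(stop_handling)
  synonymous <- match.arg(synonymous)
  code <- Biostrings::GENETIC_CODE  # named by DNA codon, "*" = stop
  codons <- names(code)
  bases <- c("A", "C", "G", "T")
  tally <- matrix(0, 20L, 21L,
                  dimnames = list(AMINO_ACIDS, c(AMINO_ACIDS, "*")))
  for (cd in codons) {
    aa <- code[[cd]]
    if (aa == "*") next
    nt <- strsplit(cd, "", fixed = TRUE)[[1L]]
    for (p in 1:3) for (b in setdiff(bases, nt[p])) {
      mut <- nt
      mut[p] <- b
      tgt <- code[[paste(mut, collapse = "")]]
      tally[aa, tgt] <- tally[aa, tgt] + 1
    }
  }
  if (synonymous == "exclude") diag(tally[, AMINO_ACIDS]) <- 0
  if (stop_handling %in% c("exclude", "renormalize")) {
    P <- tally[, AMINO_ACIDS]
    P <- P / rowSums(P)
  } else {
    P <- tally[, AMINO_ACIDS] / rowSums(tally)
  }
  structure(P, class = c("mutation_matrix", class(P)),
            stop_handling = stop_handling, synonymous = synonymous)
}

#' Future amino-acid composition after one round of codon mutation
#'
#' Projects the protein's current composition one mutational step forward:
#' with current composition c_a = counts\[a\]/L, the future composition of
#' type b is 100 * sum_a c_a P(a -> b), in percent. With a row-stochastic
#' matrix the 20 percentages sum to 100.
#'
#' @param record a [protein_record()].
#' @param matrix a [build_mutation_matrix()] result (or any 20 x 20 matrix
#'   in [AMINO_ACIDS] order).
#' @return Named numeric 20-vector of percentages.
#' @export
future_composition <- function(record, matrix = build_mutation_matrix()) {
  stopifnot(inherits(record, "protein_record"))
  if (!all(dim(matrix) == c(20L, 20L)))
    stop("'matrix' must be 20 x 20")
  comp <- record$counts / record$length
  out <- as.numeric(100 * (comp %*% unclass(matrix)))
  stats::setNames(out, AMINO_ACIDS)
}
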