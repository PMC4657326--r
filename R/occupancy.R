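#' Partition-occupancy pattern of one residue type
#'
#' The distribution probability models the r residues of one amino-acid
#' type as r distinguishable balls dropped into n equal partitions (holes)
#' of the sequence, with n = r. This builds the occupancy pattern for the
#' observed positions: the sequence 1..L is cut into n contiguous
#' partitions whose lengths differ by at most one residue (the first
#' `L %% r` partitions are one residue longer), `occ[i]` counts the
#' positions falling in partition i, and `q[j+1]` counts the partitions
#' holding exactly j residues (j = 0..r).
#'
#' @param positions sorted 1-based positions of the residue type, length
#'   r >= 1, all within `[1, L]`.
#' @param L protein length.
#' @return An `occupancy_pattern`: list with `r`, `n`, `occ` (length n),
#'   `q` (length r + 1, counts for j = 0..r) and `bounds` (partition end
#'   positions).
#' @export
#' @examples
#' partition_occupancy(c(1, 4, 6), 6)$occ   # 1 1 1
partition_occupancy <- function(positions, L) {
  positions <- as.integer(positions)
  r <- length(positions)
  if (r < 1L) stop("r = 0: use the absent-residue convention (probability 0)")
  if (is.unsorted(positions, strictly = TRUE))
    stop("'positions' must be strictly increasing")
  if (positions[1L] < 1L || positions[r] > L)
    stop("positions must lie within [1, L]")
  if (L < r) stop("L must be >= number of positions")
  n <- r
  base <- L %/% n
  extra <- L %% n
  lens <- rep(base, n)
  if (extra > 0L) lens[seq_len(extra)] <- base + 1L
  bounds <- cumsum(lens)
  part <- findInterval(positions, c(0L, bounds), left.open = TRUE)
  occ <- tabulate(part, nbins = n)
  occupancy_pattern(occ, bounds = bounds)
}

#' Construct an occupancy pattern from an occupancy vector
#'
#' @param occ occupancy vector (r_1..r_n); n = length(occ) partitions and
#'   r = sum(occ) residues, with the package's convention n = r.
#' @param bounds optional partition end positions (informational).
#' @return An `occupancy_pattern` object.
#' @export
occupancy_pattern <- function(occ, bounds = NULL) {
  occ <- as.integer(occ)
  if (any(occ < 0L)) stop("occupancy entries must be >= 0")
  r <- sum(occ)
  n <- length(occ)
  if (r < 1L) stop("pattern must contain at least one residue")
  q <- tabulate(occ + 1L, nbins = r + 1L)  # q[j+1] = #partitions with j
  stopifnot(sum(q) == n, sum((0:r) * q) == r)
  structure(list(r = r, n = n, occ = occ, q = q, bounds = bounds),
            class = "occupancy_pattern")
}

#' @export
print.occupancy_pattern <- function(x, ...) {
  cat(sprintf("<occupancy_pattern> r = %d, n = %d, occ = (%s)\n",
              x$r, x$n, paste(x$occ, collapse = ",")))
  invisible(x)
}

#' Distribution probability of an occupancy pattern
#'
#' Probability of observing the given occupancy pattern when r
#' distinguishable balls are dropped uniformly into n holes:
#' \deqn{\frac{r!}{q_0!\,q_1!\cdots q_n!}\times
#'       \frac{r!}{r_1!\,r_2!\cdots r_n!}\times n^{-r}.}
#' The first factor counts the distinct orderings of the partition
#' occupancies, the second the assignments of balls to a fixed ordering.
#' Factorials are evaluated in log space (`lfactorial`), so arbitrarily
#' large r neither overflows nor loses leading digits; the single `exp` at
#' the end is the only rounding step.
#'
#' @param pattern an [occupancy_pattern()].
#' @return Probability in (0, 1].
#' @export
#' @examples
#' distribution_probability(occupancy_pattern(c(2, 1, 0)))  # 0.6667
distribution_probability <- function(pattern) {
  if (!inherits(pattern, "occupancy_pattern"))
    stop("'pattern' must be an occupancy_pattern")
  if (pattern$n != pattern$r)
    stop("this package uses n = r partitions for the distribution probability")
  r <- pattern$r
  lg <- lfactorial(r) - sum(lfactorial(pattern$q)) +
    lfactorial(r) - sum(lfactorial(pattern$occ)) -
    r * log(pattern$n)
  exp(lg)
}

#' Brute-force oracle for the distribution probability
#'
#' Enumerates all n^r assignments of r distinguishable balls to n holes and
#' returns the fraction whose sorted occupancy vector matches the sorted
#' observed one. Independent of the closed form; refuses r > 8.
#'
#' @param pattern an [occupancy_pattern()].
#' @return Probability in (0, 1].
#' @export
distribution_probability_bruteforce <- function(pattern) {
  if (!inherits(pattern, "occupancy_pattern"))
    stop("'pattern' must be an occupancy_pattern")
  r <- pattern$r; n <- pattern$n
  if (r > 8L) stop("brute force refused for r > 8 (n^r blow-up)")
  target <- sort(pattern$occ)
  grid <- as.matrix(expand.grid(rep(list(seq_len(n)), r)))
  hits <- 0L
  for (i in seq_len(nrow(grid))) {
    occ <- tabulate(grid[i, ], nbins = n)
    if (identical(sort(occ), target)) hits <- hits + 1L
  }
  hits / n^r
}

#' Distribution-probability encoding of a protein
#'
#' For each of the 20 amino-acid types (alphabetical order), the
#' distribution probability of its observed occupancy pattern; residue
#' types absent from the protein map to 0.
#'
#' @param record a [protein_record()].
#' @return Named numeric 20-vector in \[0, 1\].
#' @export
distribution_vector <- function(record) {
  stopifnot(inherits(record, "protein_record"))
  chars <- strsplit(record$sequence, "", fixed = TRUE)[[1L]]
  out <- stats::setNames(numeric(20L), AMINO_ACIDS)
  for (aa in AMINO_ACIDS) {
    pos <- which(chars == aa)
    if (length(pos) == 0L) next  # absent type -> 0
    out[[aa]] <- distribution_probability(
      partition_occupancy(pos, record$length))
  }
  out
}
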