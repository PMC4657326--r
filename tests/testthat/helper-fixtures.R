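# Shared fixtures and oracles, all built in code at test time.

# All occupancy multisets for r balls in n = r holes: integer partitions of
# r into at most r parts, padded with zeros to length r (non-increasing).
all_partitions <- function(r) {
  parts <- function(total, max_part) {
    if (total == 0L) return(list(integer(0)))
    out <- list()
    for (p in seq_len(min(total, max_part))) {
      for (tail in parts(total - p, p)) out[[length(out) + 1L]] <- c(p, tail)
    }
    out
  }
  lapply(parts(r, r), function(v) c(v, integer(r - length(v))))
}

rec <- function(seq, id = "p") protein_record(id, seq)

zero_counts <- function() stats::setNames(integer(20L), AMINO_ACIDS)

# Small labelled dataset of random-composition proteins with noise labels.
small_dataset <- function(n = 24L, seed = 7L, prevalence = 0.4,
                          length_range = c(30L, 80L)) {
  generate_dataset(synthetic_spec(
    n_proteins = n, length_range = length_range, label_model = "noise",
    prevalence = prevalence, seed = seed))
}

# Linearly separable 20-dim dataset: class mean shift on two coordinates.
separable_xy <- function(n = 200L, seed = 5L, gap = 4) {
  set.seed(seed)
  y <- rep(0:1, length.out = n)
  X <- matrix(rnorm(n * 20L), n, 20L)
  X[, 1L] <- X[, 1L] + gap * y
  X[, 2L] <- X[, 2L] - gap * y
  colnames(X) <- AMINO_ACIDS
  list(X = X, y = y)
}

tmpfile <- function(ext = "") tempfile(fileext = ext)
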