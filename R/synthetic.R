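# Synthetic sequence datasets with planted labels, emulating the study
# conditions of the crystallization screen: ~301 proteins, lengths
# 50-1000, prevalence 85/301, labels either pure noise or drawn from a
# logistic model with known coefficients on a chosen encoding.

#' Specify a synthetic dataset
#'
#' @param n_proteins number of proteins (default 301).
#' @param length_range integer min/max residue length (default 50-1000).
#' @param composition 20-simplex of residue frequencies in [AMINO_ACIDS]
#'   order (default uniform 0.05), or `"table1"` for a preset mimicking the
#'   composition of the 122-residue worked-example protein scaled to
#'   arbitrary length.
#' @param label_model `"noise"` (independent Bernoulli at `prevalence`) or
#'   `"planted_logistic"` (Bernoulli with probability
#'   sigmoid(b0 + sum b_i x_i) on `encoding`, b0 tuned to the target
#'   prevalence by bisection).
#' @param prevalence target positive fraction (default 85/301).
#' @param b true length-20 coefficient vector for the planted model.
#' @param encoding encoding the labels are planted on: `"distribution"`,
#'   `"future"`, or an encoder function.
#' @param seed integer seed; the dataset is fully determined by it.
#' @return A `synthetic_spec` object.
#' @export
synthetic_spec <- function(n_proteins = 301L,
                           length_range = c(50L, 1000L),
                           composition = rep(1 / 20, 20L),
                           label_model = c("noise", "planted_logistic"),
                           prevalence = 85 / 301,
                           b = NULL,
                           encoding = "distribution",
                           seed = 1L) {
  label_model <- match.arg(label_model)
  if (identical(composition, "table1")) composition <- table1_composition()
  composition <- as.numeric(composition)
  if (length(composition) != 20L || any(composition < 0) ||
      abs(sum(composition) - 1) > 1e-8)
    stop("'composition' must be a 20-simplex")
  if (length(length_range) != 2L || length_range[1L] < 2L ||
      length_range[1L] > length_range[2L])
    stop("'length_range' must be (min, max) with min >= 2")
  if (prevalence <= 0 || prevalence >= 1)
    stop("'prevalence' must be in (0, 1)")
  if (label_model == "planted_logistic") {
    if (is.null(b)) b <- default_planted_coefficients()
    if (length(b) != 20L) stop("'b' must have length 20")
  }
  structure(list(n_proteins = as.integer(n_proteins),
                 length_range = as.integer(length_range),
                 composition = stats::setNames(composition, AMINO_ACIDS),
                 label_model = label_model, prevalence = prevalence,
                 b = b, encoding = encoding, seed = as.integer(seed)),
            class = "synthetic_spec")
}

# Composition of the 122-residue worked-example protein (counts / 122).
table1_composition <- function() {
  counts <- c(A = 6, C = 1, D = 10, E = 9, F = 10, G = 7, H = 4, I = 9,
              K = 17, L = 6, M = 3, N = 3, P = 4, Q = 2, R = 1, S = 8,
              T = 8, V = 11, W = 1, Y = 2)
  counts[AMINO_ACIDS] / sum(counts)
}

# Moderate planted effects on a handful of residue types; scaled for
# distribution-probability encodings (features in [0, 1]).
default_planted_coefficients <- function() {
  b <- stats::setNames(numeric(20L), AMINO_ACIDS)
  b[c("A", "K", "S", "W")] <- c(3, -3, 2, -2)
  b
}

#' Generate a labeled synthetic dataset
#'
#' Sequences are drawn i.i.d. from the spec's composition with uniform
#' lengths in the range; labels come from the spec's label model. The
#' result is fully determined by the spec (including its seed).
#'
#' @param spec a [synthetic_spec()].
#' @return A `labeled_dataset`; the tuned planted intercept (if any) is in
#'   `attr(, "b0")`.
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, globalenv()))
  set.seed(spec$seed)
  n <- spec$n_proteins
  lens <- sample(seq(spec$length_range[1L], spec$length_range[2L]), n,
                 replace = TRUE)
  records <- vector("list", n)
  for (i in seq_len(n)) {
    s <- paste(sample(AMINO_ACIDS, lens[i], replace = TRUE,
                      prob = spec$composition), collapse = "")
    records[[i]] <- protein_record(sprintf("syn%04d", i), s)
  }
  ids <- vapply(records, function(r) r$id, "")
  b0 <- NULL
  if (spec$label_model == "noise") {
    y <- stats::rbinom(n, 1L, spec$prevalence)
  } else {
    encoder <- if (is.function(spec$encoding)) spec$encoding else
      switch(spec$encoding,
             distribution = distribution_vector,
             future = function(r) future_composition(r),
             stop(sprintf("unknown encoding '%s'", spec$encoding)))
    X <- t(vapply(records, function(r) as.numeric(encoder(r)), numeric(20L)))
    eta <- drop(X %*% spec$b)
    if (stats::sd(eta) == 0 && all(spec$b == 0) &&
        (spec$prevalence <= 0 || spec$prevalence >= 1))
      stop("infeasible prevalence tuning")
    b0 <- tune_intercept(eta, spec$prevalence)
    y <- stats::rbinom(n, 1L, stats::plogis(b0 + eta))
  }
  ds <- labeled_dataset(records, stats::setNames(as.integer(y), ids))
  attr(ds, "b0") <- b0
  ds
}

# Bisection for the intercept that matches the mean planted probability to
# the target prevalence.
tune_intercept <- function(eta, target, tol = 1e-10) {
  f <- function(b0) mean(stats::plogis(b0 + eta)) - target
  lo <- -50; hi <- 50
  if (f(lo) > 0 || f(hi) < 0) stop("infeasible prevalence tuning")
  for (it in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) hi <- mid else lo <- mid
    if (hi - lo < tol) break
  }
  (lo + hi) / 2
}

#' Generate a synthetic AAIndex1-format file
#'
#' Syntactically valid AAIndex1 records with reproducible pseudo-random
#' values (accessions `SYNT000001`...), round-tripping through
#' [parse_aaindex1()]. The defaults emulate the benchmark's cardinality of
#' 531 constant characteristics.
#'
#' @param n_entries number of entries (default 531).
#' @param seed integer seed.
#' @param include_na if TRUE, a few entries carry NA-masked residues.
#' @param path optional output path; when NULL a character vector of lines
#'   is returned.
#' @return `path` (invisibly) when writing, else the lines.
#' @export
toy_aaindex <- function(n_entries = 531L, seed = 1L, include_na = FALSE,
                        path = NULL) {
  if (n_entries < 1L) stop("n_entries must be >= 1")
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  tables <- vector("list", n_entries)
  for (k in seq_len(n_entries)) {
    vals <- round(stats::runif(20L, -5, 5), 3)
    names(vals) <- AMINO_ACIDS
    if (include_na && k %% 10L == 0L)
      vals[sample(20L, 2L)] <- NA_real_
    tables[[k]] <- characteristic_table(
      sprintf("SYNT%06d", k), vals,
      title = sprintf("Synthetic characteristic %d", k))
  }
  tmp <- if (is.null(path)) tempfile(fileext = ".aaindex1") else path
  write_aaindex1(tables, tmp)
  if (is.null(path)) {
    on.exit(unlink(tmp), add = TRUE)
    return(readLines(tmp))
  }
  invisible(path)
}
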