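#' Expected count of an adjacent amino-acid pair
#'
#' Under the independence assumption, the expected number of adjacent XY
#' pairs among the L - 1 overlapping pairs of an L-residue protein with
#' counts r: for X != Y, r_X/L * r_Y/(L-1) * (L-1) = r_X r_Y / L; for
#' X = Y, r_X/L * (r_X - 1)/(L-1) * (L-1) = r_X (r_X - 1) / L.
#'
#' @param counts named residue counts (as in a [protein_record()]), or the
#'   record itself.
#' @param L protein length (ignored when `counts` is a record).
#' @param X,Y one-letter amino-acid codes, first and second member of the
#'   ordered pair.
#' @return Expected count >= 0.
#' @export
#' @examples
#' cts <- setNames(integer(20), AMINO_ACIDS); cts[["K"]] <- 17L
#' expected_pair_count(cts, 122, "K", "K")  # 2.23
expected_pair_count <- function(counts, L, X, Y) {
  if (inherits(counts, "protein_record")) {
    L <- counts$length
    counts <- counts$counts
  }
  if (L < 2) stop("L must be >= 2 to form an adjacent pair")
  if (!all(c(X, Y) %in% AMINO_ACIDS))
    stop("X and Y must be standard one-letter amino-acid codes")
  rX <- counts[[X]]
  if (X == Y) rX * (rX - 1) / L else rX * counts[[Y]] / L
}

#' Classify adjacent amino-acid pairs as predictable or unpredictable
#'
#' Tallies the actual count of each of the 400 ordered pair types over the
#' L - 1 overlapping adjacent pairs, computes each type's expected count
#' from the composition ([expected_pair_count()]), and rounds it half-up to
#' the predicted integer count. Under the `strict` rule (default) a pair
#' type's actual pairs are all predictable iff actual == predicted,
#' otherwise all unpredictable; under the `min` rule, min(actual,
#' predicted) pairs of the type count as predictable. Portions are
#' percentages of the L - 1 pairs and sum to 100.
#'
#' @param record a [protein_record()] with length >= 2.
#' @param rule `"strict"` or `"min"`.
#' @return A `pair_report`: list with `pairs` (data.frame: pair_type,
#'   first, second, actual, expected, predicted, predictable),
#'   `predictable_portion` and `unpredictable_portion` (percent), `rule`
#'   and `n_pairs` (= L - 1).
#' @export
pair_predictability <- function(record, rule = c("strict", "min")) {
  rule <- match.arg(rule)
  stopifnot(inherits(record, "protein_record"))
  L <- record$length
  if (L < 2L) stop("pair predictability needs L >= 2")
  chars <- strsplit(record$sequence, "", fixed = TRUE)[[1L]]
  first <- chars[-L]
  second <- chars[-1L]
  obs <- table(factor(first, levels = AMINO_ACIDS),
               factor(second, levels = AMINO_ACIDS))
  grid <- expand.grid(second = AMINO_ACIDS, first = AMINO_ACIDS,
                      stringsAsFactors = FALSE)[, 2:1]
  actual <- as.integer(t(obs))  # row-major: first varies slowest
  expected <- mapply(function(x, y) expected_pair_count(record$counts, L, x, y),
                     grid$first, grid$second)
  predicted <- round_half_up(expected)
  type_pred <- actual == predicted
  n_predictable <- if (rule == "strict") {
    sum(actual[type_pred])
  } else {
    sum(pmin(actual, predicted))
  }
  pairs <- data.frame(
    pair_type = paste0(grid$first, grid$second),
    first = grid$first, second = grid$second,
    actual = actual, expected = expected, predicted = predicted,
    predictable = if (rule == "strict") type_pred else predicted >= actual,
    stringsAsFactors = FALSE)
  total <- L - 1L
  structure(list(
    pairs = pairs,
    predictable_portion = 100 * n_predictable / total,
    unpredictable_portion = 100 * (total - n_predictable) / total,
    rule = rule, n_pairs = total, id = record$id),
    class = "pair_report")
}

#' @export
print.pair_report <- function(x, ...) {
  cat(sprintf(
    "<pair_report> %s: %.2f%% predictable / %.2f%% unpredictable (%s rule, %d pairs)\n",
    x$id, x$predictable_portion, x$unpredictable_portion, x$rule, x$n_pairs))
  invisible(x)
}
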