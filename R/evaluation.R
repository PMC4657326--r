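# Confusion metrics, per-characteristic screening, delete-1 jackknife,
# ROC analysis and the predictable-portion group comparison.

#' Confusion counts of binary predictions
#'
#' Positive = crystallized (label 1). TP: predicted 1, actual 1; TN:
#' predicted 0, actual 0; FP: predicted 1, actual 0; FN: predicted 0,
#' actual 1.
#'
#' @param predicted binary 0/1 vector.
#' @param actual binary 0/1 vector of the same length.
#' @return A `confusion_counts` object (list TP, TN, FP, FN).
#' @export
confusion <- function(predicted, actual) {
  predicted <- as.integer(predicted)
  actual <- as.integer(actual)
  if (length(predicted) != length(actual))
    stop("'predicted' and 'actual' must have the same length")
  if (!all(c(predicted, actual) %in% c(0L, 1L)))
    stop("entries must be binary 0/1")
  structure(list(TP = sum(predicted == 1L & actual == 1L),
                 TN = sum(predicted == 0L & actual == 0L),
                 FP = sum(predicted == 1L & actual == 0L),
                 FN = sum(predicted == 0L & actual == 1L)),
            class = "confusion_counts")
}

#' Accuracy, sensitivity and specificity from confusion counts
#'
#' Accuracy = (TP+TN)/(TP+FP+TN+FN) x 100; Sensitivity = TP/(TP+FN) x 100;
#' Specificity = TN/(TN+FP) x 100. A zero denominator yields `NA`
#' (undefined, reported as missing rather than 0).
#'
#' @param counts a [confusion()] result.
#' @return Named numeric vector (accuracy, sensitivity, specificity) in
#'   percent.
#' @export
metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  n <- counts$TP + counts$TN + counts$FP + counts$FN
  if (n < 1L) stop("empty confusion counts")
  sens <- if (counts$TP + counts$FN == 0L) NA_real_ else
    100 * counts$TP / (counts$TP + counts$FN)
  spec <- if (counts$TN + counts$FP == 0L) NA_real_ else
    100 * counts$TN / (counts$TN + counts$FP)
  c(accuracy = 100 * (counts$TP + counts$TN) / n,
    sensitivity = sens, specificity = spec)
}

#' Assemble an evaluation report from per-sample predictions
#'
#' @param ids sample identifiers.
#' @param score predicted probabilities.
#' @param actual true 0/1 labels.
#' @param mode `"fit"` (trained and evaluated on the full set) or
#'   `"jackknife"` (held-out predictions).
#' @param threshold classification threshold.
#' @param flagged logical vector marking samples whose fold fell back to
#'   the prevalence prediction.
#' @return An `evaluation_report`: `counts`, `accuracy`, `sensitivity`,
#'   `specificity`, `per_sample` data.frame, `mode`.
#' @export
evaluation_report <- function(ids, score, actual, mode = "fit",
                              threshold = 0.5, flagged = NULL) {
  predicted <- classify(score, threshold)
  counts <- confusion(predicted, actual)
  m <- metrics(counts)
  per_sample <- data.frame(id = ids, score = score, predicted = predicted,
                           actual = as.integer(actual),
                           stringsAsFactors = FALSE)
  if (!is.null(flagged)) per_sample$flagged <- flagged
  structure(list(counts = counts, accuracy = m[["accuracy"]],
                 sensitivity = m[["sensitivity"]],
                 specificity = m[["specificity"]],
                 per_sample = per_sample, mode = mode),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf(
    "<evaluation_report> mode = %s, n = %d | acc %.2f%%, sens %s%%, spec %s%%\n",
    x$mode, nrow(x$per_sample), x$accuracy,
    ifelse(is.na(x$sensitivity), "NA", sprintf("%.2f", x$sensitivity)),
    ifelse(is.na(x$specificity), "NA", sprintf("%.2f", x$specificity))))
  invisible(x)
}

#' Screen characteristics one at a time
#'
#' For every encoding, fits the chosen classifier on the full dataset and
#' evaluates it on the same data (fit mode: the first-stage workability
#' screen). Rows are sorted by accuracy, ties broken by source id;
#' duplicated characteristics therefore land adjacent with identical
#' metrics. An encoding that fails is flagged (NA metrics) and screening
#' continues.
#'
#' @param dataset a `labeled_dataset` with both classes.
#' @param encodings named list of encoder functions
#'   (record -> 20-vector), e.g. from [encoder_set()].
#' @param model_kind `"logistic"` or `"nn"`.
#' @param seed seed for stochastic fitters.
#' @param ... passed to [fit_model()].
#' @return data.frame (source, accuracy, sensitivity, specificity, mode,
#'   error) sorted by accuracy descending; the full reports in
#'   `attr(, "reports")`.
#' @export
screen_characteristics <- function(dataset, encodings,
                                   model_kind = c("logistic", "nn"),
                                   seed = 1L, ...) {
  model_kind <- match.arg(model_kind)
  stopifnot(inherits(dataset, "labeled_dataset"))
  if (length(unique(dataset$labels)) < 2L)
    stop("dataset must contain both classes")
  if (!length(encodings)) stop("need at least one encoding")
  sources <- names(encodings)
  if (is.null(sources)) stop("'encodings' must be a named list")
  reports <- vector("list", length(encodings))
  names(reports) <- sources
  rows <- vector("list", length(encodings))
  for (k in seq_along(encodings)) {
    res <- tryCatch({
      enc <- encode_dataset(dataset, encodings[[k]])
      model <- fit_model(enc$X, enc$y, model_kind,
                         seed = derive_seed(seed, k), ...)
      rep <- evaluation_report(rownames(enc$X), predict_prob(model, enc$X),
                               enc$y, mode = "fit")
      reports[[k]] <- rep
      data.frame(source = sources[k], accuracy = rep$accuracy,
                 sensitivity = rep$sensitivity,
                 specificity = rep$specificity, mode = "fit",
                 error = NA_character_, stringsAsFactors = FALSE)
    }, error = function(e) {
      data.frame(source = sources[k], accuracy = NA_real_,
                 sensitivity = NA_real_, specificity = NA_real_,
                 mode = "fit", error = conditionMessage(e),
                 stringsAsFactors = FALSE)
    })
    rows[[k]] <- res
  }
  out <- do.call(rbind, rows)
  out <- out[order(-out$accuracy, out$source, na.last = TRUE), ]
  rownames(out) <- NULL
  attr(out, "reports") <- reports
  out
}

#' Delete-1 jackknife validation
#'
#' Leave-one-out: each of the n samples is predicted by a model trained on
#' the other n - 1, so exactly n held-out predictions are made. Per-fold
#' model seeds are derived deterministically from (seed, fold index). A
#' fold whose training labels are single-class (or whose fit fails) is
#' flagged and predicted by the training prevalence.
#'
#' @param dataset a `labeled_dataset`, n >= 3.
#' @param encoder encoder function (record -> 20-vector).
#' @param model_kind `"logistic"` or `"nn"`.
#' @param seed integer seed.
#' @param ... passed to [fit_model()].
#' @return An [evaluation_report()] with mode `"jackknife"`.
#' @export
jackknife_delete1 <- function(dataset, encoder,
                              model_kind = c("logistic", "nn"), seed = 1L,
                              ...) {
  model_kind <- match.arg(model_kind)
  stopifnot(inherits(dataset, "labeled_dataset"))
  enc <- encode_dataset(dataset, encoder)
  n <- nrow(enc$X)
  if (n < 3L) stop("jackknife needs n >= 3")
  score <- numeric(n)
  flagged <- logical(n)
  for (i in seq_len(n)) {
    ytr <- enc$y[-i]
    fold_seed <- derive_seed(seed, i)
    if (length(unique(ytr)) < 2L) {
      score[i] <- mean(ytr)
      flagged[i] <- TRUE
      next
    }
    score[i] <- tryCatch({
      model <- fit_model(enc$X[-i, , drop = FALSE], ytr, model_kind,
                         seed = fold_seed, ...)
      predict_prob(model, enc$X[i, , drop = FALSE])
    }, error = function(e) {
      flagged[i] <<- TRUE
      mean(ytr)
    })
  }
  evaluation_report(rownames(enc$X), score, enc$y, mode = "jackknife",
                    flagged = flagged)
}

#' ROC curve and AUC
#'
#' Sweeps the decision threshold over the distinct score values plus
#' +/-Inf sentinels (classification rule: score >= threshold), recording
#' sensitivity and specificity at each. The AUC is the trapezoidal area in
#' the standard sensitivity-vs-(1 - specificity) convention; the point
#' table also carries the sensitivity-vs-specificity plotting convention
#' used for visual comparison against the line of indiscrimination.
#'
#' @param scores real-valued classifier scores.
#' @param actual binary 0/1 labels; both classes required.
#' @return A `roc_curve`: `points` data.frame (threshold, sensitivity,
#'   specificity, fpr) and `auc` in \[0, 1\].
#' @export
roc_curve <- function(scores, actual) {
  actual <- as.integer(actual)
  if (length(scores) != length(actual)) stop("length mismatch")
  if (length(unique(actual)) < 2L)
    stop("ROC needs both classes present")
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE), -Inf)
  npos <- sum(actual == 1L); nneg <- sum(actual == 0L)
  sens <- spec <- numeric(length(thr))
  for (k in seq_along(thr)) {
    pred <- as.integer(scores >= thr[k])
    sens[k] <- 100 * sum(pred == 1L & actual == 1L) / npos
    spec[k] <- 100 * sum(pred == 0L & actual == 0L) / nneg
  }
  fpr <- (100 - spec) / 100
  tpr <- sens / 100
  ord <- order(fpr, tpr)
  auc <- sum(diff(fpr[ord]) * (tpr[ord][-1L] + tpr[ord][-length(tpr)]) / 2)
  structure(list(points = data.frame(threshold = thr, sensitivity = sens,
                                     specificity = spec, fpr = 100 * fpr),
                 auc = auc),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("<roc_curve> %d points, AUC = %.4f\n", nrow(x$points), x$auc))
  invisible(x)
}

#' Per-protein accuracy over repeated model fits
#'
#' Each protein's accuracy is the percentage of repeated model fits
#' (default 20 seeds) in which it is classified correctly — full-data
#' models in `fit` mode, held-out predictions in `jackknife` mode. With a
#' deterministic fitter (logistic) every repeat agrees and the accuracy is
#' 0 or 100.
#'
#' @param dataset a `labeled_dataset`.
#' @param encoder encoder function.
#' @param model_kind `"logistic"` or `"nn"`.
#' @param mode `"fit"` or `"jackknife"`.
#' @param n_repeats number of seeds, default 20.
#' @param seed base seed.
#' @param ... passed to [fit_model()].
#' @return data.frame (id, accuracy, actual).
#' @export
per_protein_accuracy <- function(dataset, encoder,
                                 model_kind = c("logistic", "nn"),
                                 mode = c("fit", "jackknife"),
                                 n_repeats = 20L, seed = 1L, ...) {
  model_kind <- match.arg(model_kind)
  mode <- match.arg(mode)
  enc <- encode_dataset(dataset, encoder)
  n <- nrow(enc$X)
  correct <- matrix(NA, n, n_repeats)
  for (s in seq_len(n_repeats)) {
    rep_seed <- derive_seed(seed, 1000L + s)
    rep_s <- if (mode == "fit") {
      model <- fit_model(enc$X, enc$y, model_kind, seed = rep_seed, ...)
      evaluation_report(rownames(enc$X), predict_prob(model, enc$X), enc$y)
    } else {
      jackknife_delete1(dataset, encoder, model_kind, seed = rep_seed, ...)
    }
    correct[, s] <- rep_s$per_sample$predicted == rep_s$per_sample$actual
  }
  data.frame(id = rownames(enc$X),
             accuracy = 100 * rowMeans(correct),
             actual = enc$y, stringsAsFactors = FALSE)
}

#' Compare predictable portions between high- and low-accuracy proteins
#'
#' Splits proteins at an accuracy cutoff (default 90 %) and compares their
#' predictable portions of amino-acid pairs between the two groups with a
#' two-sided Mann-Whitney rank-sum test (exact for small untied samples,
#' normal approximation with tie correction otherwise; if every value is
#' tied across both groups the test is degenerate and p = 1). Medians and
#' interquartile ranges are reported per group.
#'
#' @param per_protein data.frame with columns `id`, `accuracy` (percent)
#'   and `predictable_portion` (percent).
#' @param cutoff accuracy cutoff separating the groups, default 90.
#' @return List: `U` (Mann-Whitney U for the high-accuracy group),
#'   `p_value`, `group_summary` data.frame (group, n, median, q1, q3),
#'   `cutoff`.
#' @export
predictable_portion_group_test <- function(per_protein, cutoff = 90) {
  need <- c("accuracy", "predictable_portion")
  if (!all(need %in% names(per_protein)))
    stop("'per_protein' needs columns accuracy and predictable_portion")
  high <- per_protein$predictable_portion[per_protein$accuracy >= cutoff]
  low <- per_protein$predictable_portion[per_protein$accuracy < cutoff]
  if (!length(high) || !length(low))
    stop(sprintf("one group is empty at cutoff %g", cutoff))
  ties <- anyDuplicated(c(high, low)) > 0L
  if (length(unique(c(high, low))) == 1L) {
    U <- length(high) * length(low) / 2
    p <- 1
  } else {
    wt <- suppressWarnings(stats::wilcox.test(
      high, low, alternative = "two.sided",
      exact = (min(length(high), length(low)) <= 8L) && !ties,
      correct = TRUE))
    U <- unname(wt$statistic)
    p <- wt$p.value
  }
  summ <- function(v, g) {
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(group = g, n = length(v), median = q[2L], q1 = q[1L],
               q3 = q[3L], stringsAsFactors = FALSE)
  }
  list(U = U, p_value = p,
       group_summary = rbind(summ(high, sprintf(">=%g%%", cutoff)),
                             summ(low, sprintf("<%g%%", cutoff))),
       cutoff = cutoff)
}
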