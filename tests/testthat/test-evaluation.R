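test_that("confusion counts follow the four definitions", {
  actual <- c(rep(1L, 85), rep(0L, 216))
  perfect <- confusion(actual, actual)
  expect_equal(unlist(perfect[c("TP", "TN", "FP", "FN")]),
               c(TP = 85L, TN = 216L, FP = 0L, FN = 0L))
  allneg <- confusion(rep(0L, 301), actual)
  expect_equal(allneg$FN, 85L)
  expect_equal(allneg$TN, 216L)
  # swapping the label convention swaps TP<->TN and FP<->FN
  pred <- rbinom(301, 1, 0.5)
  a <- confusion(pred, actual)
  b <- confusion(1L - pred, 1L - actual)
  expect_equal(c(a$TP, a$FP), c(b$TN, b$FN))
  expect_error(confusion(c(0L, 1L), 0L), "same length")
})

test_that("metrics compute the three percentage formulas", {
  m <- metrics(confusion(c(rep(1L, 85), rep(0L, 216)),
                         c(rep(1L, 85), rep(0L, 216))))
  expect_equal(unname(m), c(100, 100, 100))

  # all-negative prediction at the 85/301 prevalence: the low-sensitivity /
  # high-specificity regime
  actual <- c(rep(1L, 85), rep(0L, 216))
  m2 <- metrics(confusion(rep(0L, 301), actual))
  expect_equal(m2[["accuracy"]], 100 * 216 / 301, tolerance = 1e-9)
  expect_equal(round(m2[["accuracy"]], 2), 71.76)
  expect_equal(m2[["sensitivity"]], 0)
  expect_equal(m2[["specificity"]], 100)

  m3 <- metrics(confusion(c(1L, 0L, 1L, 0L), c(1L, 1L, 0L, 0L)))
  expect_equal(unname(m3), c(50, 50, 50))

  # undefined sensitivity reported as missing, not 0
  m4 <- metrics(confusion(c(0L, 1L), c(0L, 0L)))
  expect_true(is.na(m4[["sensitivity"]]))
})

test_that("metrics agree with mean(prediction == actual)", {
  set.seed(12)
  for (i in 1:20) {
    n <- sample(5:60, 1)
    p <- rbinom(n, 1, 0.5)
    a <- rbinom(n, 1, 0.4)
    expect_equal(metrics(confusion(p, a))[["accuracy"]],
                 100 * mean(p == a))
  }
})

test_that("screening ranks encodings and ties duplicates bit-identically", {
  ds <- small_dataset(n = 40L, seed = 21L)
  vals <- stats::setNames(seq(0.1, 2, length.out = 20), AMINO_ACIDS)
  tb <- characteristic_table("DUPL000001", vals)
  tb2 <- characteristic_table("DUPL000002", vals)  # same values, new id
  encs <- encoder_set(list(tb, tb2), dynamic = TRUE)
  tab <- suppressMessages(suppressWarnings(
    screen_characteristics(ds, encs, "logistic")))
  expect_equal(nrow(tab), 4L)
  expect_false(is.unsorted(rev(tab$accuracy)))
  dup <- tab[grepl("DUPL", tab$source), ]
  expect_identical(dup$accuracy[1], dup$accuracy[2])
  expect_identical(dup$sensitivity[1], dup$sensitivity[2])
  # adjacent after the tie-break by source id
  expect_equal(dup$source, sort(dup$source))
})

test_that("a failing encoding is flagged and screening continues", {
  ds <- small_dataset(n = 30L, seed = 22L)
  encs <- list(good = distribution_vector,
               bad = function(r) stop("boom"))
  tab <- suppressMessages(suppressWarnings(
    screen_characteristics(ds, encs, "logistic")))
  expect_true(is.na(tab$accuracy[tab$source == "bad"]))
  expect_match(tab$error[tab$source == "bad"], "boom")
  expect_false(is.na(tab$accuracy[tab$source == "good"]))
})

test_that("the planted characteristic ranks first among decoys", {
  f <- tmpfile(".txt")
  toy_aaindex(55L, seed = 2L, path = f)
  tables <- parse_aaindex1(f)
  b <- stats::setNames(numeric(20), AMINO_ACIDS)
  b[c("A", "K", "S", "W")] <- c(8, -8, 6, -6)
  ds <- generate_dataset(synthetic_spec(
    n_proteins = 301L, label_model = "planted_logistic", b = b,
    encoding = "distribution", seed = 3L))
  encs <- encoder_set(tables, dynamic = TRUE)
  tab <- suppressMessages(suppressWarnings(
    screen_characteristics(ds, encs, "logistic", seed = 4L)))
  expect_equal(tab$source[1L], "distribution")
})

test_that("delete-1 jackknife makes exactly n held-out predictions", {
  ds <- small_dataset(n = 10L, seed = 25L)
  rep10 <- suppressMessages(suppressWarnings(
    jackknife_delete1(ds, distribution_vector, "logistic",
                      seed = 1L, lambda = 0.05)))
  expect_equal(nrow(rep10$per_sample), 10L)
  expect_equal(rep10$mode, "jackknife")
  expect_setequal(rep10$per_sample$id,
                  vapply(ds$records, `[[`, "", "id"))
})

test_that("jackknife held-out predictions ignore the other samples' order", {
  ds <- small_dataset(n = 12L, seed = 26L)
  r1 <- suppressMessages(suppressWarnings(
    jackknife_delete1(ds, distribution_vector, "logistic",
                      seed = 2L, lambda = 0.05)))
  perm <- c(5:12, 1:4)
  ds2 <- labeled_dataset(ds$records[perm], ds$labels[perm])
  r2 <- suppressMessages(suppressWarnings(
    jackknife_delete1(ds2, distribution_vector, "logistic",
                      seed = 2L, lambda = 0.05)))
  s1 <- r1$per_sample[order(r1$per_sample$id), ]
  s2 <- r2$per_sample[order(r2$per_sample$id), ]
  expect_equal(s1$score, s2$score, tolerance = 1e-8)
})

test_that("jackknife tracks fit accuracy on strongly separable data", {
  b <- stats::setNames(numeric(20), AMINO_ACIDS)
  b[c("A", "K", "S", "W")] <- c(20, -20, 15, -15)
  ds <- generate_dataset(synthetic_spec(
    n_proteins = 60L, length_range = c(30L, 120L),
    label_model = "planted_logistic", b = b, encoding = "distribution",
    prevalence = 0.4, seed = 28L))
  fitmod <- suppressMessages(suppressWarnings({
    enc <- encode_dataset(ds, distribution_vector)
    model <- fit_logistic(enc$X, enc$y, lambda = 0.01)
    evaluation_report(rownames(enc$X), predict_logistic(model, enc$X),
                      enc$y)
  }))
  jk <- suppressMessages(suppressWarnings(
    jackknife_delete1(ds, distribution_vector, "logistic", seed = 3L,
                      lambda = 0.01)))
  expect_lte(abs(jk$accuracy - fitmod$accuracy), 5)
})

test_that("jackknife on pure-noise labels sits near the prevalence baseline", {
  # study-scale null: with n >> p the leave-one-out logistic degenerates to
  # roughly the majority-class classifier
  ds <- generate_dataset(synthetic_spec(
    n_proteins = 301L, length_range = c(50L, 300L), label_model = "noise",
    seed = 29L))
  jk <- suppressMessages(suppressWarnings(
    jackknife_delete1(ds, distribution_vector, "logistic", seed = 4L)))
  baseline <- 100 * max(prevalence(ds), 1 - prevalence(ds))
  expect_lte(abs(jk$accuracy - baseline), 10)
})

test_that("ROC endpoints, extremes and the null regime behave", {
  y <- c(rep(1L, 5), rep(0L, 5))
  expect_equal(roc_curve(as.numeric(y), y)$auc, 1)
  expect_equal(roc_curve(1 - y, y)$auc, 0)
  set.seed(33)
  y2 <- rbinom(2000, 1, 0.4)
  rc <- roc_curve(runif(2000), y2)
  expect_lt(abs(rc$auc - 0.5), 0.03)
  # sweep endpoints: all-negative and all-positive corners
  pts <- rc$points
  expect_equal(pts$sensitivity[1L], 0)
  expect_equal(pts$specificity[1L], 100)
  expect_equal(pts$sensitivity[nrow(pts)], 100)
  expect_equal(pts$specificity[nrow(pts)], 0)
  expect_error(roc_curve(runif(5), rep(1L, 5)), "both classes")
})

test_that("AUC equals the Mann-Whitney identity and the pROC oracle", {
  set.seed(34)
  for (i in 1:5) {
    n <- 80
    y <- rbinom(n, 1, 0.45)
    if (length(unique(y)) < 2) next
    s <- rnorm(n) + 0.8 * y
    rc <- roc_curve(s, y)
    U <- sum(vapply(s[y == 1], function(si)
      sum(si > s[y == 0]) + 0.5 * sum(si == s[y == 0]), 0))
    expect_equal(rc$auc, U / (sum(y == 1) * sum(y == 0)), tolerance = 1e-9)
    oracle <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                             direction = "<")))
    expect_equal(rc$auc, oracle, tolerance = 1e-9)
  }
})

test_that("group comparison of predictable portions is a Mann-Whitney test", {
  # identical groups: midpoint U, p ~ 1
  pp <- data.frame(id = letters[1:10],
                   accuracy = rep(c(95, 50), each = 5),
                   predictable_portion = rep(c(60, 61, 62, 63, 64), 2))
  gt <- suppressWarnings(predictable_portion_group_test(pp))
  expect_equal(gt$U, 12.5)
  expect_gt(gt$p_value, 0.9)

  # complete separation: U = n1 * n2, minimal p
  pp2 <- data.frame(id = letters[1:12],
                    accuracy = rep(c(95, 50), each = 6),
                    predictable_portion = c(80:85, 40:45))
  gt2 <- predictable_portion_group_test(pp2)
  expect_equal(gt2$U, 36)
  expect_lt(gt2$p_value, 0.01)
  expect_equal(gt2$group_summary$n, c(6L, 6L))

  expect_error(predictable_portion_group_test(
    data.frame(accuracy = c(95, 96), predictable_portion = c(1, 2))),
    "empty")
})

test_that("a planted 15-point shift in portions is detected at p < 0.001", {
  set.seed(35)
  acc <- rep(c(95, 50), each = 50)
  portion <- c(rnorm(50, 70, 8), rnorm(50, 55, 8))
  pp <- data.frame(id = seq_len(100), accuracy = acc,
                   predictable_portion = portion)
  gt <- predictable_portion_group_test(pp)
  expect_lt(gt$p_value, 0.001)
})

test_that("per-protein accuracy over repeated fits is a percentage", {
  ds <- small_dataset(n = 16L, seed = 41L)
  acc <- suppressMessages(suppressWarnings(
    per_protein_accuracy(ds, distribution_vector, "logistic", "fit",
                         n_repeats = 3L, seed = 1L, lambda = 0.05)))
  expect_equal(nrow(acc), 16L)
  expect_true(all(acc$accuracy >= 0 & acc$accuracy <= 100))
  # deterministic fitter: every repeat agrees, so 0 or 100 only
  expect_true(all(acc$accuracy %in% c(0, 100)))
})
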