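test_that("accuracy is correct over total, per label decision for multi-label", {
  expect_identical(classification_accuracy(c(0, 1, 2), c(0, 1, 2)), 1)
  expect_identical(classification_accuracy(c(0, 1, 1, 0), c(0, 1, 0, 0)), 0.75)
  # 2 samples x 2 labels, 3 of 4 label decisions correct
  pred <- rbind(c(1L, 0L), c(0L, 1L))
  truth <- rbind(c(1L, 0L), c(1L, 1L))
  expect_identical(classification_accuracy(pred, truth), 0.75)
  expect_error(classification_accuracy(numeric(0), numeric(0)), "empty")
  expect_error(classification_accuracy(c(1, 2), c(1, 2, 3)), "mismatch")
})

# Independent oracle: count positive-negative pairs directly.
brute_force_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + (p > q) + 0.5 * (p == q)
  }
  total / (length(pos) * length(neg))
}

test_that("binary AUC equals the pairwise-comparison construction", {
  expect_identical(auc_roc(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1), "binary"), 1)
  expect_identical(auc_roc(rep(0.5, 6), rep(0:1, 3), "binary"), 0.5)
  # pos {0.9, 0.4}, neg {0.5, 0.1}: 3 wins of 4 pairs
  expect_identical(
    auc_roc(c(0.9, 0.4, 0.5, 0.1), c(1, 1, 0, 0), "binary"), 0.75)
  expect_error(auc_roc(c(0.1, 0.9), c(1, 1), "binary"), "one class")

  set.seed(31)
  for (rep in 1:200) {
    n <- sample(4:50, 1)
    labels <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    scores <- sample(seq(0, 1, by = 0.05), n, replace = TRUE)  # force ties
    expect_equal(auc_roc(scores, labels, "binary"),
                 brute_force_auc(scores, labels))
  }
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(32)
  for (rep in 1:20) {
    n <- 40
    labels <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    scores <- rnorm(n)
    a0 <- auc_roc(scores, labels, "binary")
    expect_equal(auc_roc(exp(scores), labels, "binary"), a0)
    expect_equal(auc_roc(3 * scores - 7, labels, "binary"), a0)
    expect_equal(auc_roc(atan(scores), labels, "binary"), a0)
  }
})

test_that("multi-class and multi-label AUC are macro averages", {
  set.seed(33)
  n <- 60
  labels <- sample(0:2, n, replace = TRUE)
  scores <- matrix(runif(n * 3), n, 3)
  macro <- mean(sapply(0:2, function(k) {
    brute_force_auc(scores[, k + 1], as.integer(labels == k))
  }))
  expect_equal(auc_roc(scores, labels, "multiclass"), macro)
  expect_error(auc_roc(scores, rep(0L, n), "multiclass"), "absent")

  y <- matrix(sample(0:1, n * 2, replace = TRUE), n, 2)
  y[1:2, ] <- rbind(c(0L, 0L), c(1L, 1L))
  s <- matrix(runif(n * 2), n, 2)
  expect_equal(auc_roc(s, y, "multilabel"),
               mean(c(brute_force_auc(s[, 1], y[, 1]),
                      brute_force_auc(s[, 2], y[, 2]))))
})

test_that("balanced error averages per-class recalls", {
  expect_identical(balanced_error(c(0, 1, 0, 1), c(0, 1, 0, 1)), 0)
  # class recalls (1.0, 0.5) -> 0.25
  expect_identical(balanced_error(c(0, 0, 1, 0), c(0, 0, 1, 1)), 0.25)
  # 3-class confusion with recalls (0.9, 0.6, 0.3): written-out predictions
  labels <- rep(0:2, each = 10)
  preds <- c(rep(0, 9), 1,                 # recall 0.9
             rep(1, 6), rep(0, 4),         # recall 0.6
             rep(2, 3), rep(0, 7))         # recall 0.3
  expect_equal(balanced_error(preds, labels), 1 - mean(c(0.9, 0.6, 0.3)))
  expect_equal(balanced_error(preds, labels), 0.4)
  expect_error(balanced_error(c(0, 0), c(0, 0)), "every class")
})

test_that("balanced error equals 1 - accuracy when classes are balanced", {
  set.seed(34)
  for (rep in 1:20) {
    k <- sample(2:4, 1)
    n_per <- sample(5:20, 1)
    labels <- rep(seq_len(k) - 1L, each = n_per)
    preds <- sample(seq_len(k) - 1L, k * n_per, replace = TRUE)
    # balanced_error averages recalls over equally sized classes, which is
    # exactly the overall error rate here
    expect_equal(balanced_error(preds, labels),
                 1 - classification_accuracy(preds, labels))
  }
})

test_that("corruption-pair counting is a plain product", {
  expect_identical(count_corruption_pairs(11, 5), 55L)
  expect_identical(count_corruption_pairs(1, 1), 1L)
  expect_identical(count_corruption_pairs(3, 2), 6L)
})

test_that("self-normalised robustness is exactly (1, 1)", {
  set.seed(35)
  errs <- matrix(runif(55, 0.1, 0.6), 11, 5)
  tab <- corruption_error_table(0.08, 0.08, errs, errs)
  scores <- robustness_scores(tab)
  expect_identical(scores$BE, 1)
  expect_identical(scores$rBE, 1)
  expect_identical(robustness_scores(tab, mode = "pair_mean")$BE, 1)
})

test_that("toy robustness tables match hand-computed ratios", {
  # 2 corruptions x 1 severity, hand-set errors
  model <- matrix(c(0.2, 0.3), 2, 1)
  ref <- matrix(c(0.4, 0.2), 2, 1)
  tab <- corruption_error_table(0.1, 0.1, model, ref)
  s <- robustness_scores(tab)
  expect_equal(s$BE, mean(c(0.2 / 0.4, 0.3 / 0.2)))
  expect_equal(s$rBE, mean(c((0.2 - 0.1) / (0.4 - 0.1),
                             (0.3 - 0.1) / (0.2 - 0.1))))
  expect_equal(robustness_scores(tab, scale_100 = TRUE)$BE, 100 * s$BE)

  # candidate error drops below its clean error under corruption while the
  # reference degrades: rBE is negative and passes through unclamped
  tab_neg <- corruption_error_table(0.2, 0.2,
                                    matrix(0.15, 1, 1), matrix(0.5, 1, 1))
  expect_lt(robustness_scores(tab_neg)$rBE, 0)
  expect_equal(robustness_scores(tab_neg)$rBE, (0.15 - 0.2) / (0.5 - 0.2))

  # zero reference denominators are errors, not silent values
  expect_error(
    robustness_scores(corruption_error_table(0, 0, matrix(0.2), matrix(0))),
    "zero reference")
  expect_error(
    robustness_scores(corruption_error_table(0.1, 0.3,
                                             matrix(0.2), matrix(0.3))),
    "zero reference error increase")
})

test_that("corruption tables round-trip through CSV", {
  set.seed(36)
  tab <- corruption_error_table(
    0.05, 0.12,
    matrix(runif(55, 0.1, 0.9), 11, 5),
    matrix(runif(55, 0.1, 0.9), 11, 5)
  )
  path <- tempfile(fileext = ".csv")
  write_corruption_table(tab, path)
  back <- read_corruption_table(path)
  expect_equal(back$model_clean, tab$model_clean)
  expect_equal(back$ref_clean, tab$ref_clean)
  expect_equal(back$model_errors, tab$model_errors)
  expect_equal(back$ref_errors, tab$ref_errors)
  s1 <- robustness_scores(tab)
  s2 <- robustness_scores(back)
  expect_equal(s1$BE, s2$BE)
  expect_equal(s1$rBE, s2$rBE)
})

test_that("error tables validate shape and range", {
  expect_error(corruption_error_table(0.1, 0.1, matrix(0.2, 2, 2),
                                      matrix(0.2, 3, 2)), "same shape")
  expect_error(corruption_error_table(0.1, 1.2, matrix(0.2), matrix(0.2)),
               "\\[0, 1\\]")
})
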