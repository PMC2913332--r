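test_that("EC3 potency classes follow the cut-offs with upward boundaries", {
  expect_equal(as.character(classify_ec3(0.05)), "Extreme")
  expect_equal(as.character(classify_ec3(15)), "Weak")
  expect_equal(as.character(classify_ec3(1.0)), "Moderate")
  expect_equal(as.character(classify_ec3(0.1)), "Strong")
  expect_equal(as.character(classify_ec3(10)), "Weak")
  expect_equal(as.character(classify_ec3(NA)), "NC")
  expect_error(classify_ec3(0), "positive")
  expect_error(classify_ec3(-1), "positive")
})

test_that("binary schemes map potency classes as published", {
  cls <- c("NC", "Weak", "Moderate", "Strong", "Extreme")
  a <- binarize_classes(cls, "A")
  expect_equal(as.character(a), c("non-sensitiser", rep("sensitiser", 4)))
  b <- binarize_classes(cls, "B")
  expect_equal(as.character(b), c("non-sensitiser", "non-sensitiser", rep("sensitiser", 3)))
  expect_error(binarize_classes("Mild", "A"), "unknown")
})

test_that("stratified split reproduces the published allocations", {
  s1 <- stratified_split(rep(c("non", "sens"), c(42, 167)), 0.2, seed = 1)
  expect_equal(s1$counts$test, c(8, 34))
  expect_equal(s1$counts$train, c(34, 133))
  s2 <- stratified_split(rep(c("non", "sens"), c(108, 101)), 0.2, seed = 1)
  expect_equal(s2$counts$test, c(21, 21))
  expect_equal(s2$counts$train, c(87, 80))
  s3 <- stratified_split(rep("x", 10), 0.2, seed = 1)
  expect_equal(s3$counts$test, 2)
})

test_that("split partitions are exact and balanced within one compound", {
  withr::with_seed(77, {
    for (rep in 1:5) {
      n1 <- sample(20:120, 1)
      n2 <- sample(20:120, 1)
      lab <- sample(rep(c("u", "v"), c(n1, n2)))
      sp <- stratified_split(lab, 0.2, seed = rep)
      n <- n1 + n2
      expect_equal(sort(c(sp$train, sp$test)), seq_len(n))
      expect_length(intersect(sp$train, sp$test), 0)
      expect_equal(length(sp$test), round(0.2 * n))
      for (ci in seq_len(nrow(sp$counts))) {
        expect_lte(abs(sp$counts$test[ci] - 0.2 * sp$counts$n[ci]), 1)
      }
    }
  })
  expect_error(stratified_split(character(0), 0.2), "at least 1")
})

test_that("published domain ranges load and flag the tabulated excursions", {
  full <- domain_ranges("full")
  expect_equal(nrow(full), 14)
  ranges <- domain_ranges("train")
  # the published example: GNar 2.9 against training range [1.3, 2.3]
  res <- in_domain(tibble::tibble(GNar = 2.9), ranges[ranges$descriptor == "GNar", ])
  expect_false(res$in_domain)
  expect_equal(res$violations[[1]], "GNar above max")
})

test_that("domain check uses closed intervals and is monotone in the bounds", {
  ranges <- tibble::tibble(descriptor = c("a", "b"), min = c(0, -1), max = c(1, 1))
  at_min <- in_domain(tibble::tibble(a = 0, b = -1), ranges)
  expect_true(at_min$in_domain)
  mid <- in_domain(tibble::tibble(a = 0.5, b = 0), ranges)
  expect_true(mid$in_domain)
  expect_length(mid$violations[[1]], 0)
  out <- in_domain(tibble::tibble(a = 1.2, b = -2), ranges)
  expect_false(out$in_domain)
  expect_setequal(out$violations[[1]], c("a above max", "b below min"))
  # relaxing any bound never expels an in-domain point
  relaxed <- ranges
  relaxed$max <- relaxed$max + 1
  relaxed$min <- relaxed$min - 1
  expect_true(in_domain(tibble::tibble(a = 0.5, b = 0), relaxed)$in_domain)
  expect_error(in_domain(tibble::tibble(a = 1), ranges), "missing")
})

test_that("confusion statistics follow the published formulas", {
  # 40 predicted compounds: TP=30, TN=6, FP=2, FN=2 -> accuracy 90%
  pred <- rep(c("sensitiser", "non-sensitiser", "sensitiser", "non-sensitiser"),
              c(30, 2, 2, 6))
  act <- rep(c("sensitiser", "sensitiser", "non-sensitiser", "non-sensitiser"),
             c(30, 2, 2, 6))
  cm <- confusion_metrics(pred, act)
  expect_equal(unname(cm$counts[c("TP", "FN", "FP", "TN")]), c(30, 2, 2, 6))
  st <- setNames(cm$stats$percent, cm$stats$metric)
  expect_equal(unname(st["accuracy"]), 90)
  # exact rational identity: accuracy * n = TP + TN before rounding
  vals <- setNames(cm$stats$value, cm$stats$metric)
  expect_equal(vals[["accuracy"]] * 40, 30 + 6)
  # harmonic mean never exceeds either argument
  expect_lte(vals[["f_measure"]], min(vals[["precision"]], vals[["sensitivity"]]))
})

test_that("undefined ratios surface as NA, not 0 or 100", {
  cm <- confusion_metrics(rep("sensitiser", 5), rep("sensitiser", 5))
  st <- setNames(cm$stats$percent, cm$stats$metric)
  expect_equal(unname(st[c("accuracy", "precision", "sensitivity")]), c(100, 100, 100))
  expect_true(is.na(st[["specificity"]]))
  expect_error(confusion_metrics(rep("unpredicted", 3), rep("sensitiser", 3)),
               "no predicted")
})

test_that("unpredicted rows are suppressed exactly as flagged", {
  pred <- c("sensitiser", "unpredicted", "non-sensitiser")
  act <- c("sensitiser", "sensitiser", "non-sensitiser")
  cm <- confusion_metrics(pred, act)
  expect_equal(unname(cm$counts["n_predicted"]), 2)
  expect_equal(unname(cm$counts["n_unpredicted"]), 1)
  expect_equal(unname(cm$counts["TP"] + cm$counts["TN"]), 2)
})

test_that("cross-validation scores separable data perfectly and nulls near chance", {
  sep <- separable_1d(n_per_class = 30)
  trainer <- function(d, l) train_afp(d, l)
  cv <- cross_validate(trainer, sep$data, sep$labels, folds = 5, seed = 1)
  expect_equal(cv$score, 1.0)
  cv2 <- cross_validate(trainer, sep$data, sep$labels, folds = 5, seed = 1)
  expect_identical(cv$fold_scores, cv2$fold_scores)
  # permutation null: shuffled balanced labels score near 50%
  shuffled <- NULL
  withr::with_seed(42, shuffled <- sample(sep$labels))
  cv_null <- cross_validate(trainer, sep$data, shuffled, folds = 5, seed = 2)
  expect_lt(abs(cv_null$score - 0.5), 0.10)
  expect_error(cross_validate(trainer, sep$data, sep$labels, folds = 40, seed = 1),
               "smallest class")
})

test_that("F-measure is the harmonic mean on any common scale", {
  expect_equal(f_measure(0.5, 1), 2 / 3)
  expect_equal(round_half_up(f_measure(94, 100)), 97)
})
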