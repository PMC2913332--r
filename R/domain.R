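#' Assign LLNA potency classes from EC3 values
#'
#' EC3 is the concentration (%) eliciting a stimulation index of 3 in the
#' local lymph node assay; lower EC3 means a stronger sensitiser. Classes:
#' Extreme (EC3 < 0.1), Strong (0.1 <= EC3 < 1), Moderate (1 <= EC3 < 10),
#' Weak (EC3 >= 10). Boundary values fall on the weaker-potency side. The
#' non-classified class `NC` comes only from an explicit flag (an `NA`
#' EC3 with `nc = TRUE`), never from a numeric value.
#'
#' @param ec3 Numeric vector of EC3 percentages (`NA` where
#'   non-classified). Values must be positive.
#' @param nc Logical vector flagging non-classified compounds; defaults
#'   to `is.na(ec3)`.
#' @return Factor with levels `NC`, `Weak`, `Moderate`, `Strong`,
#'   `Extreme`.
#' @examples
#' classify_ec3(c(0.05, 0.5, 5, 15, NA))
#' @export
classify_ec3 <- function(ec3, nc = is.na(ec3)) {
  stopifnot(length(nc) == length(ec3))
  if (any(!nc & (is.na(ec3) | ec3 <= 0))) {
    abort("EC3 values must be positive (flag non-classified compounds via `nc`)")
  }
  out <- rep(NA_character_, length(ec3))
  out[nc] <- "NC"
  num <- !nc
  out[num & ec3 < 0.1] <- "Extreme"
  out[num & ec3 >= 0.1 & ec3 < 1] <- "Strong"
  out[num & ec3 >= 1 & ec3 < 10] <- "Moderate"
  out[num & ec3 >= 10] <- "Weak"
  factor(out, levels = c("NC", "Weak", "Moderate", "Strong", "Extreme"))
}

#' Collapse potency classes to a binary sensitiser label
#'
#' Scheme `A` treats only `NC` as non-sensitiser (42:167 split on the
#' reference dataset); scheme `B` also counts `Weak` as non-sensitiser
#' (108:101), giving a more balanced dataset.
#'
#' @param classes Factor or character of potency classes (`NC`, `Weak`,
#'   `Moderate`, `Strong`, `Extreme`).
#' @param scheme `"A"` or `"B"`.
#' @return Factor with levels `non-sensitiser`, `sensitiser`.
#' @export
binarize_classes <- function(classes, scheme = c("A", "B")) {
  scheme <- match.arg(scheme)
  classes <- as.character(classes)
  valid <- c("NC", "Weak", "Moderate", "Strong", "Extreme")
  if (!all(classes %in% valid)) abort("unknown potency class")
  non <- if (scheme == "A") "NC" else c("NC", "Weak")
  factor(
    ifelse(classes %in% non, "non-sensitiser", "sensitiser"),
    levels = c("non-sensitiser", "sensitiser")
  )
}

#' Random stratified train/test split
#'
#' Samples a test partition of `round(fraction * n)` compounds with class
#' proportions preserved: per-class test seats start at
#' `ceiling(fraction * class size)` and are trimmed, largest fractional
#' remainder first (ties toward the smaller class), until the total
#' matches. On the reference dataset this reproduces the published
#' allocations for both binary schemes (34/8 and 133/34; 87/21 and
#' 80/21).
#'
#' @param labels Class labels (factor or coercible); every class must be
#'   non-empty.
#' @param fraction Test fraction in (0, 1). Default 0.2.
#' @param seed Seed for the within-class sampling.
#' @return A list of class `split_spec`: `train` and `test` integer index
#'   vectors, a `counts` tibble (`class`, `n`, `train`, `test`),
#'   `fraction`, `seed`.
#' @examples
#' stratified_split(rep(c("non", "sens"), c(42, 167)), 0.2, seed = 1)$counts
#' @export
stratified_split <- function(labels, fraction = 0.2, seed = 1L) {
  stopifnot(fraction > 0, fraction < 1)
  labels <- droplevels(as.factor(labels))
  sizes <- table(labels)
  if (length(sizes) == 0 || any(sizes == 0)) {
    abort("every class must have at least 1 member")
  }
  n <- length(labels)
  target <- round(fraction * n)
  quota <- fraction * as.numeric(sizes)
  test_n <- ceiling(quota)
  over <- sum(test_n) - target
  if (over > 0) {
    remainder <- quota - floor(quota)
    # trim largest remainders first; ties go to the smaller class
    ord <- order(-remainder, quota)
    k <- 1
    while (over > 0) {
      cl <- ord[(k - 1) %% length(ord) + 1]
      if (test_n[cl] > 0) {
        test_n[cl] <- test_n[cl] - 1
        over <- over - 1
      }
      k <- k + 1
    }
  }
  test_idx <- integer(0)
  rng_local(seed, {
    for (ci in seq_along(sizes)) {
      idx <- sample(which(labels == names(sizes)[ci]))
      test_idx <- c(test_idx, idx[seq_len(test_n[ci])])
    }
  })
  test_idx <- sort(test_idx)
  structure(list(
    train = setdiff(seq_len(n), test_idx),
    test = test_idx,
    counts = tibble(
      class = names(sizes), n = as.integer(sizes),
      train = as.integer(sizes) - as.integer(test_n),
      test = as.integer(test_n)
    ),
    fraction = fraction, seed = seed
  ), class = "split_spec")
}

#' @export
print.split_spec <- function(x, ...) {
  cat(sprintf("<split_spec> %d train / %d test (fraction %.2f)\n",
              length(x$train), length(x$test), x$fraction))
  print(x$counts)
  invisible(x)
}

#' Published descriptor-space domain ranges
#'
#' Loads the per-descriptor minima and maxima of the reference LLNA
#' training and test partitions shipped with the package.
#'
#' @param partition `"train"` (default) returns columns
#'   `descriptor`, `min`, `max` ready for [in_domain()]; `"full"` returns
#'   all four range columns.
#' @return A tibble.
#' @export
domain_ranges <- function(partition = c("train", "full")) {
  partition <- match.arg(partition)
  path <- system.file("extdata", "descriptor_domain.json", package = "skinqsar")
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  full <- bind_rows(imap(doc$descriptors, function(v, nm) {
    tibble(descriptor = nm, train_min = v$train_min, train_max = v$train_max,
           test_min = v$test_min, test_max = v$test_max)
  }))
  if (partition == "full") return(full)
  tibble(descriptor = full$descriptor, min = full$train_min, max = full$train_max)
}

#' Min-max applicability domain check
#'
#' A compound is in the applicability domain when every ranged descriptor
#' value lies inside the closed training interval `[min, max]`. Relaxing
#' any bound can only keep points in the domain (monotonicity).
#'
#' @param data Data frame covering every descriptor named in `ranges`.
#' @param ranges Tibble with columns `descriptor`, `min`, `max` (e.g.
#'   [domain_ranges()], or ranges fitted on a training partition).
#' @return A tibble with `in_domain` (logical) and `violations`
#'   (list-column of strings like `"GNar above max"`).
#' @examples
#' in_domain(tibble::tibble(GNar = 2.9), tibble::tibble(
#'   descriptor = "GNar", min = 1.3, max = 2.3))
#' @export
in_domain <- function(data, ranges) {
  stopifnot(is.data.frame(data), all(c("descriptor", "min", "max") %in% names(ranges)))
  if (any(ranges$max < ranges$min)) abort("ranges must satisfy max >= min")
  missing_cols <- setdiff(ranges$descriptor, names(data))
  if (length(missing_cols) > 0) {
    abort(sprintf("data is missing descriptor(s): %s", paste(missing_cols, collapse = ", ")))
  }
  n <- nrow(data)
  viol <- rep(list(character(0)), n)
  for (r in seq_len(nrow(ranges))) {
    d <- ranges$descriptor[r]
    v <- data[[d]]
    below <- which(v < ranges$min[r])
    above <- which(v > ranges$max[r])
    for (i in below) viol[[i]] <- c(viol[[i]], paste(d, "below min"))
    for (i in above) viol[[i]] <- c(viol[[i]], paste(d, "above max"))
  }
  tibble(in_domain = lengths(viol) == 0, violations = viol)
}

#' Fitted per-descriptor training ranges
#'
#' Convenience builder of an [in_domain()] range table from a training
#' partition.
#'
#' @param data Data frame; numeric columns are ranged.
#' @return Tibble with `descriptor`, `min`, `max`.
#' @export
fit_domain_ranges <- function(data) {
  cols <- names(data)[vapply(data, is.numeric, logical(1))]
  tibble(
    descriptor = cols,
    min = map_dbl(cols, function(cl) min(data[[cl]])),
    max = map_dbl(cols, function(cl) max(data[[cl]]))
  )
}

#' F-measure from precision and sensitivity
#'
#' Harmonic mean `2 / (1/precision + 1/sensitivity)`, on whatever common
#' scale the inputs use (fractions or percentages).
#'
#' @param precision,sensitivity Numeric vectors on a common scale.
#' @return Numeric vector.
#' @examples
#' f_measure(94, 100) # 96.9...
#' @export
f_measure <- function(precision, sensitivity) {
  2 / (1 / precision + 1 / sensitivity)
}

#' Confusion-matrix validation statistics
#'
#' Counts true/false positives/negatives over prediction-label pairs and
#' derives accuracy `(TN+TP)/(TN+FN+FP+TP)`, precision `TP/(TP+FP)`,
#' sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)` and the F-measure
#' (harmonic mean of precision and sensitivity). Rows predicted
#' `"unpredicted"` are suppressed from the counts when
#' `suppress_unpredicted` is `TRUE`, mirroring how compounds outside the
#' model's applicability are excluded from reported statistics. Undefined
#' ratios (zero denominators) are reported as `NA`, never as 0 or 100.
#'
#' @param predicted Character/factor vector of predicted labels, possibly
#'   containing `"unpredicted"`.
#' @param actual Vector of reference labels, same length.
#' @param positive The positive-class label. Default `"sensitiser"`.
#' @param suppress_unpredicted Drop unpredicted rows from the counts.
#' @return An object of class `confusion_stats`: list with `counts`
#'   (named TP/FP/TN/FN plus `n_predicted`, `n_unpredicted`) and `stats`
#'   (tibble: `metric`, `value` exact fraction, `percent` rounded
#'   half-up to integer).
#' @examples
#' confusion_metrics(rep(c("sensitiser", "non-sensitiser"), c(6, 4)),
#'                   rep(c("sensitiser", "non-sensitiser"), each = 5))
#' @export
confusion_metrics <- function(predicted, actual, positive = "sensitiser",
                              suppress_unpredicted = TRUE) {
  stopifnot(length(predicted) == length(actual))
  predicted <- as.character(predicted)
  actual <- as.character(actual)
  keep <- if (suppress_unpredicted) predicted != "unpredicted" else rep(TRUE, length(predicted))
  predicted <- predicted[keep]
  actual <- actual[keep]
  if (length(predicted) == 0) abort("no predicted compounds to score")
  tp <- sum(predicted == positive & actual == positive)
  fp <- sum(predicted == positive & actual != positive)
  tn <- sum(predicted != positive & actual != positive)
  fn <- sum(predicted != positive & actual == positive)
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  acc <- ratio(tn + tp, tn + fn + fp + tp)
  prec <- ratio(tp, tp + fp)
  sens <- ratio(tp, tp + fn)
  spec <- ratio(tn, tn + fp)
  fm <- if (is.na(prec) || is.na(sens) || prec == 0 || sens == 0) NA_real_ else f_measure(prec, sens)
  stats <- tibble(
    metric = c("accuracy", "precision", "sensitivity", "specificity", "f_measure"),
    value = c(acc, prec, sens, spec, fm)
  )
  stats$percent <- ifelse(is.na(stats$value), NA_real_, round_half_up(stats$value * 100))
  structure(list(
    counts = c(TP = tp, FP = fp, TN = tn, FN = fn,
               n_predicted = length(predicted), n_unpredicted = sum(!keep)),
    stats = stats
  ), class = "confusion_stats")
}

#' @export
print.confusion_stats <- function(x, ...) {
  cat(sprintf(
    "<confusion_stats> TP %d FP %d TN %d FN %d (%d predicted, %d suppressed)\n",
    x$counts["TP"], x$counts["FP"], x$counts["TN"], x$counts["FN"],
    x$counts["n_predicted"], x$counts["n_unpredicted"]
  ))
  print(x$stats)
  invisible(x)
}

#' @describeIn confusion_metrics Tidy the five statistics into a tibble.
#' @param x A `confusion_stats`.
#' @param ... Unused.
#' @export
tidy.confusion_stats <- function(x, ...) x$stats

#' @describeIn confusion_metrics One-row summary with counts and rounded
#'   percentages.
#' @export
glance.confusion_stats <- function(x, ...) {
  wide <- setNames(as.list(x$stats$percent), x$stats$metric)
  bind_cols(as_tibble(as.list(x$counts)), as_tibble(wide))
}

#' Stratified cross-validation of a classifier
#'
#' Splits the data into stratified folds, trains on each complement and
#' scores accuracy on the held-out fold, suppressing unpredicted
#' compounds consistently with [confusion_metrics()].
#'
#' @param trainer Function `(data, labels) -> model` where the model has
#'   a [predict()] method returning a tibble with an `outcome` column.
#' @param data Data frame of descriptors.
#' @param labels Class labels.
#' @param folds Number of folds (>= 2, at most the smallest class size).
#' @param seed Seed for fold assignment.
#' @return A list of class `cv_result`: `fold_scores`, `score` (their
#'   mean), `folds`, `seed`.
#' @export
cross_validate <- function(trainer, data, labels, folds = 5, seed = 1L) {
  stopifnot(folds >= 2)
  labels <- droplevels(as.factor(labels))
  fold <- make_stratified_folds(labels, folds, derive_seed(seed, "cv"))
  scores <- vapply(seq_len(folds), function(f) {
    tr <- fold != f
    model <- trainer(data[tr, , drop = FALSE], labels[tr])
    pred <- predict(model, data[!tr, , drop = FALSE])
    keep <- pred$outcome != "unpredicted"
    if (!any(keep)) return(NA_real_)
    mean(pred$outcome[keep] == as.character(labels[!tr])[keep])
  }, numeric(1))
  structure(list(
    fold_scores = scores, score = mean(scores, na.rm = TRUE),
    folds = folds, seed = seed
  ), class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> mean accuracy %.3f over %d folds\n", x$score, x$folds))
  invisible(x)
}
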