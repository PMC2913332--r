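#' End-to-end pipeline configuration
#'
#' Bundles the choices of one modelling run: binary scheme (`A`: only NC
#' compounds are non-sensitisers; `B`: Weak joins the non-sensitisers),
#' descriptor selector (`hsa` or `corr-filter`), classifier (`afp` or
#' `mlp`), test fraction (default 0.2) and the single top-level seed from
#' which every stage derives its own sub-seed.
#'
#' @param scheme `"A"` or `"B"`.
#' @param selector `"hsa"` or `"corr-filter"`.
#' @param model `"afp"` or `"mlp"`.
#' @param split_fraction Test fraction in (0, 1). Default 0.2.
#' @param seed Top-level seed.
#' @param hsa,afp,mlp Stage configurations ([hsa_config()],
#'   [afp_config()], [mlp_config()]).
#' @param r_max,vif_max Thresholds for the `corr-filter` selector.
#' @param out_dir Optional directory; when set, every stage output is
#'   written there (CSV/JSON).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(scheme = c("A", "B"), selector = c("hsa", "corr-filter"),
                            model = c("afp", "mlp"), split_fraction = 0.2,
                            seed = 1L, hsa = NULL, afp = afp_config(),
                            mlp = NULL, r_max = 0.9, vif_max = 10,
                            out_dir = NULL) {
  scheme <- match.arg(scheme)
  selector <- match.arg(selector)
  model <- match.arg(model)
  stopifnot(split_fraction > 0, split_fraction < 1)
  structure(list(
    scheme = scheme, selector = selector, model = model,
    split_fraction = split_fraction, seed = seed,
    hsa = hsa %||% hsa_config(seed = derive_seed(seed, "hsa")),
    afp = afp,
    mlp = mlp %||% mlp_config(seed = derive_seed(seed, "mlp")),
    r_max = r_max, vif_max = vif_max, out_dir = out_dir
  ), class = "pipeline_config")
}

#' Run the full modelling pipeline
#'
#' Executes, in order: binary label construction (when potency classes
#' are supplied), stratified train/test split, min-max normalization
#' fitted on the training partition only, descriptor selection on the
#' training partition only, classifier training, applicability-domain
#' range fitting on the training partition, prediction of both
#' partitions, and validation statistics with unpredicted compounds
#' suppressed. Only the training partition ever reaches normalization,
#' selection or fitting. A manifest records the seed, stage sub-seeds,
#' selected descriptors, partition sizes and content hashes so that two
#' runs with the same inputs and seed are verifiably identical.
#'
#' @param data Data frame with an `id` column and descriptor columns, e.g.
#'   from [compute_descriptors()] or [generate_dataset()].
#' @param labels Either binary labels (factor with 2 levels) or potency
#'   classes (`NC`/`Weak`/`Moderate`/`Strong`/`Extreme`) to be binarized
#'   under `config$scheme`.
#' @param config A [pipeline_config()].
#' @return A list of class `pipeline_report`: `split`, `normalization`,
#'   `selection`, `fit`, `predictions` (tibble with partition, id,
#'   outcome, reference, in_domain), `metrics` (train/test
#'   `confusion_stats`), `cv` (training-partition [cross_validate()]
#'   result), `manifest`.
#' @export
run_pipeline <- function(data, labels, config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"), is.data.frame(data))
  if (!"id" %in% names(data)) data <- bind_cols(tibble(id = as.character(seq_len(nrow(data)))), data)
  labels <- as.factor(labels)
  if (length(labels) != nrow(data)) abort("labels must match rows of data")
  if (all(levels(labels) %in% c("NC", "Weak", "Moderate", "Strong", "Extreme"))) {
    labels <- binarize_classes(labels, config$scheme)
  }
  labels <- droplevels(labels)
  if (nlevels(labels) != 2) abort("pipeline needs binary labels")

  desc_cols <- names(data)[vapply(data, is.numeric, logical(1))]
  split <- stratified_split(labels, config$split_fraction, derive_seed(config$seed, "split"))
  train <- data[split$train, , drop = FALSE]
  test <- data[split$test, , drop = FALSE]
  y_train <- labels[split$train]
  y_test <- labels[split$test]

  norm <- normalize_minmax(train[desc_cols])
  train_n <- bind_cols(train["id"], norm$data)
  test_n <- bind_cols(test["id"], apply_normalization(test[desc_cols], norm$params))

  selection <- switch(config$selector,
    "hsa" = hsa_select(train_n[desc_cols], y_train, config$hsa),
    "corr-filter" = filter_collinear(train_n[desc_cols], config$r_max, config$vif_max)
  )
  sel <- selection$selected

  fit <- switch(config$model,
    "afp" = train_afp(train_n[sel], y_train, config$afp),
    "mlp" = train_mlp(train_n[sel], y_train, config$mlp)
  )
  trainer <- switch(config$model,
    "afp" = function(d, l) train_afp(d, l, config$afp),
    "mlp" = function(d, l) train_mlp(d, l, config$mlp)
  )
  cv <- cross_validate(trainer, train_n[sel], y_train,
                       folds = 5, seed = derive_seed(config$seed, "cv"))

  ranges <- fit_domain_ranges(train[sel])
  predict_part <- function(tbl_n, tbl_raw, y, partition) {
    pred <- predict(fit, tbl_n[sel])
    dom <- in_domain(tbl_raw[sel], ranges)
    bind_cols(
      tibble(partition = partition, id = tbl_raw$id),
      pred["outcome"],
      tibble(reference = as.character(y), in_domain = dom$in_domain,
             violations = dom$violations)
    )
  }
  preds <- bind_rows(
    predict_part(train_n, train, y_train, "train"),
    predict_part(test_n, test, y_test, "test")
  )
  positive <- levels(labels)[2]
  metrics <- list(
    train = confusion_metrics(preds$outcome[preds$partition == "train"],
                              preds$reference[preds$partition == "train"],
                              positive = positive),
    test = confusion_metrics(preds$outcome[preds$partition == "test"],
                             preds$reference[preds$partition == "test"],
                             positive = positive)
  )

  manifest <- list(
    package_version = as.character(utils::packageVersion("skinqsar")),
    seed = config$seed,
    stage_seeds = list(
      split = derive_seed(config$seed, "split"),
      hsa = config$hsa$seed, mlp = config$mlp$seed,
      cv = derive_seed(config$seed, "cv")
    ),
    scheme = config$scheme, selector = config$selector, model = config$model,
    n = nrow(data), n_train = length(split$train), n_test = length(split$test),
    class_counts = as.list(table(labels)),
    selected = sel,
    hashes = list(
      split = rlang::hash(split[c("train", "test")]),
      normalization = rlang::hash(norm$params),
      selection = rlang::hash(selection$selected),
      model = rlang::hash(unclass(fit)),
      predictions = rlang::hash(preds$outcome)
    )
  )
  report <- structure(list(
    config = config, split = split, normalization = norm$params,
    selection = selection, fit = fit, cv = cv, ranges = ranges,
    predictions = preds, metrics = metrics, manifest = manifest
  ), class = "pipeline_report")
  if (!is.null(config$out_dir)) write_pipeline_outputs(report, data)
  report
}

write_pipeline_outputs <- function(report, data) {
  dir <- report$config$out_dir
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(data, file.path(dir, "descriptors.csv"), row.names = FALSE)
  write_selection_result(report$selection, file.path(dir, "selection.json"))
  if (inherits(report$fit, "afp_fit")) {
    write_afp_model(report$fit, file.path(dir, "model.json"),
                    normalization = report$normalization)
  } else {
    write_mlp_model(report$fit, file.path(dir, "model.json"))
  }
  preds_flat <- report$predictions
  preds_flat$violations <- map_chr(preds_flat$violations, paste, collapse = "; ")
  utils::write.csv(preds_flat, file.path(dir, "predictions.csv"), row.names = FALSE)
  metrics_doc <- map(report$metrics, function(m) {
    list(counts = as.list(m$counts),
         statistics = setNames(as.list(m$stats$percent), m$stats$metric),
         exact = setNames(as.list(m$stats$value), m$stats$metric))
  })
  metrics_doc$cv_accuracy <- report$cv$score
  jsonlite::write_json(metrics_doc, file.path(dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  jsonlite::write_json(report$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf(
    "<pipeline_report> scheme %s | %s | %s\n",
    x$config$scheme, x$config$selector, x$config$model
  ))
  cat(sprintf("  %d train / %d test; selected: %s\n",
              length(x$split$train), length(x$split$test),
              paste(x$selection$selected, collapse = ", ")))
  cat(sprintf("  train accuracy %s%% | test accuracy %s%% | CV %.0f%%\n",
              x$metrics$train$stats$percent[1], x$metrics$test$stats$percent[1],
              100 * x$cv$score))
  invisible(x)
}

#' @describeIn run_pipeline One row per partition and metric.
#' @param x A `pipeline_report`.
#' @param ... Unused.
#' @export
tidy.pipeline_report <- function(x, ...) {
  bind_rows(
    mutate(x$metrics$train$stats, partition = "train"),
    mutate(x$metrics$test$stats, partition = "test")
  )[, c("partition", "metric", "value", "percent")]
}

#' @describeIn run_pipeline One-row run summary.
#' @export
glance.pipeline_report <- function(x, ...) {
  tibble(
    scheme = x$config$scheme, selector = x$config$selector,
    model = x$config$model, n_train = length(x$split$train),
    n_test = length(x$split$test), n_selected = length(x$selection$selected),
    train_accuracy = x$metrics$train$stats$percent[1],
    test_accuracy = x$metrics$test$stats$percent[1],
    cv_accuracy = round_half_up(100 * x$cv$score)
  )
}
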