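#' Multilayer perceptron configuration
#'
#' Parameters for [train_mlp()]: one hidden layer of `hidden` tanh units,
#' full-batch gradient descent on squared error with momentum, inputs
#' scaled to `-1..1`, training capped at `max_epochs` (default 1000) with
#' early stopping when the held-out validation error has not improved for
#' `patience` epochs; the saved weights are those at the validation
#' minimum.
#'
#' @param hidden Hidden units (positive integer).
#' @param learn_rate Learning rate (> 0). Default 0.01.
#' @param momentum Momentum coefficient in `[0, 1)`. Default 0.7.
#' @param max_epochs Epoch cap. Default 1000.
#' @param patience Epochs without validation improvement before stopping.
#' @param validation_fraction Stratified fraction of the training
#'   partition held out for early stopping. Default 0.2.
#' @param seed Seed for the weight initialisation and validation split.
#' @return A list of class `mlp_config`.
#' @export
mlp_config <- function(hidden = 4, learn_rate = 0.01, momentum = 0.7,
                       max_epochs = 1000, patience = 20,
                       validation_fraction = 0.2, seed = 1L) {
  stopifnot(
    hidden >= 1, learn_rate > 0, momentum >= 0, momentum < 1,
    max_epochs >= 1, patience >= 1,
    validation_fraction > 0, validation_fraction < 1
  )
  structure(list(
    hidden = as.integer(hidden), learn_rate = learn_rate, momentum = momentum,
    max_epochs = as.integer(max_epochs), patience = as.integer(patience),
    validation_fraction = validation_fraction, seed = seed
  ), class = "mlp_config")
}

#' Train a one-hidden-layer tanh perceptron with momentum and early stopping
#'
#' Binary classification with classes coded -1/+1 on a tanh output unit.
#' Inputs are min-max scaled to `-1..1` (scaling fitted on the training
#' rows and stored). A stratified validation subset is held out; after
#' every epoch of full-batch momentum gradient descent on mean squared
#' error the validation error is recorded, and the returned weights are
#' those of the epoch with the lowest validation error.
#'
#' @param data Data frame of descriptors (numeric columns are inputs).
#' @param labels Binary labels (factor or coercible; first level codes -1,
#'   second +1). Both classes must be present at least twice.
#' @param config An [mlp_config()].
#' @return An object of class `mlp_fit`: scaling parameters, weight
#'   matrices `W1`, `b1`, `w2`, `b2`, per-epoch `train_trace` and
#'   `val_trace`, `best_epoch`, class `levels`, `config`.
#' @export
train_mlp <- function(data, labels, config = mlp_config()) {
  stopifnot(is.data.frame(data), inherits(config, "mlp_config"))
  labels <- droplevels(as.factor(labels))
  if (nlevels(labels) != 2) abort("labels must contain exactly 2 classes")
  if (min(table(labels)) < 2) abort("need at least 2 examples per class")
  cols <- names(data)[vapply(data, is.numeric, logical(1))]
  if (length(cols) == 0) abort("no numeric input columns")
  norm <- normalize_minmax(data[cols])
  x_all <- as.matrix(norm$data)
  y_all <- ifelse(as.integer(labels) == 1, -1, 1)

  n <- nrow(x_all)
  val_idx <- integer(0)
  rng_local(derive_seed(config$seed, "mlp-val"), {
    for (cl in levels(labels)) {
      idx <- sample(which(labels == cl))
      k <- max(1, round(config$validation_fraction * length(idx)))
      val_idx <- c(val_idx, idx[seq_len(k)])
    }
  })
  tr_idx <- setdiff(seq_len(n), val_idx)
  x <- x_all[tr_idx, , drop = FALSE]; y <- y_all[tr_idx]
  xv <- x_all[val_idx, , drop = FALSE]; yv <- y_all[val_idx]

  p <- ncol(x); h <- config$hidden
  W1 <- NULL; b1 <- NULL; w2 <- NULL; b2 <- NULL
  rng_local(derive_seed(config$seed, "mlp-init"), {
    W1 <- matrix(runif(p * h, -1, 1) / sqrt(p), p, h)
    b1 <- runif(h, -1, 1) / sqrt(p)
    w2 <- runif(h, -1, 1) / sqrt(h)
    b2 <- runif(1, -1, 1) / sqrt(h)
  })
  vW1 <- W1 * 0; vb1 <- b1 * 0; vw2 <- w2 * 0; vb2 <- 0

  forward <- function(X, W1, b1, w2, b2) {
    H <- tanh(sweep(X %*% W1, 2, b1, "+"))
    o <- tanh(drop(H %*% w2) + b2)
    list(H = H, o = o)
  }
  mse <- function(o, y) mean((o - y)^2)

  train_trace <- numeric(config$max_epochs)
  val_trace <- numeric(config$max_epochs)
  best <- list(err = Inf, epoch = 0L, W1 = W1, b1 = b1, w2 = w2, b2 = b2)
  since_best <- 0L
  n_tr <- nrow(x)
  epochs_run <- 0L
  for (epoch in seq_len(config$max_epochs)) {
    fw <- forward(x, W1, b1, w2, b2)
    err_o <- (fw$o - y) * (1 - fw$o^2)              # d(mse)/d(pre-activation)
    g_w2 <- drop(crossprod(fw$H, err_o)) * 2 / n_tr
    g_b2 <- 2 * mean(err_o)
    err_h <- (err_o %o% w2) * (1 - fw$H^2)
    g_W1 <- crossprod(x, err_h) * 2 / n_tr
    g_b1 <- 2 * colMeans(err_h)
    vW1 <- config$momentum * vW1 - config$learn_rate * g_W1
    vb1 <- config$momentum * vb1 - config$learn_rate * g_b1
    vw2 <- config$momentum * vw2 - config$learn_rate * g_w2
    vb2 <- config$momentum * vb2 - config$learn_rate * g_b2
    W1 <- W1 + vW1; b1 <- b1 + vb1; w2 <- w2 + vw2; b2 <- b2 + vb2

    train_trace[epoch] <- mse(forward(x, W1, b1, w2, b2)$o, y)
    val_err <- mse(forward(xv, W1, b1, w2, b2)$o, yv)
    val_trace[epoch] <- val_err
    epochs_run <- epoch
    if (val_err < best$err - 1e-12) {
      best <- list(err = val_err, epoch = epoch, W1 = W1, b1 = b1, w2 = w2, b2 = b2)
      since_best <- 0L
    } else {
      since_best <- since_best + 1L
      if (since_best >= config$patience) break
    }
  }
  structure(list(
    scaling = norm$params, cols = cols, levels = levels(labels),
    W1 = best$W1, b1 = best$b1, w2 = best$w2, b2 = best$b2,
    train_trace = train_trace[seq_len(epochs_run)],
    val_trace = val_trace[seq_len(epochs_run)],
    best_epoch = best$epoch, config = config
  ), class = "mlp_fit")
}

#' Predict with a fitted perceptron
#'
#' Applies the stored input scaling and the saved best weights. The sign
#' of the tanh output selects the class; a raw output of exactly 0 breaks
#' the tie toward the positive (second-level) class.
#'
#' @param object An `mlp_fit`.
#' @param newdata Data frame containing the training input columns.
#' @param ... Unused.
#' @return A tibble with `outcome` (class label) and `score` (raw network
#'   output in `(-1, 1)`).
#' @export
predict.mlp_fit <- function(object, newdata, ...) {
  stopifnot(is.data.frame(newdata))
  missing_cols <- setdiff(object$cols, names(newdata))
  if (length(missing_cols) > 0) {
    abort(sprintf("newdata is missing column(s): %s", paste(missing_cols, collapse = ", ")))
  }
  X <- as.matrix(apply_normalization(newdata[object$cols], object$scaling))
  H <- tanh(sweep(X %*% object$W1, 2, object$b1, "+"))
  o <- tanh(drop(H %*% object$w2) + object$b2)
  tibble(
    outcome = ifelse(o < 0, object$levels[1], object$levels[2]),
    score = o
  )
}

#' Choose the hidden-layer size by cross-validated error
#'
#' Trains each candidate hidden size several times (distinct sub-seeds)
#' and compares mean minimum validation errors; returns the smallest
#' candidate whose mean error is within one standard error of the best
#' (parsimony rule). The selection criterion — lowest validation error
#' over repeated training runs — is searched exhaustively over the small
#' candidate grid.
#'
#' @param data,labels,config As in [train_mlp()].
#' @param candidates Integer vector of hidden sizes.
#' @param repeats Training repetitions per candidate. Default 3.
#' @return The chosen hidden size (integer).
#' @export
select_hidden_size <- function(data, labels, config = mlp_config(),
                               candidates = c(2, 4, 8), repeats = 3) {
  candidates <- sort(unique(as.integer(candidates)))
  stopifnot(length(candidates) >= 1)
  if (length(candidates) == 1) return(candidates)
  res <- map(candidates, function(h) {
    errs <- vapply(seq_len(repeats), function(r) {
      cfg <- config
      cfg$hidden <- h
      cfg$seed <- derive_seed(config$seed, paste0("hsize-", h, "-", r))
      fit <- train_mlp(data, labels, cfg)
      min(fit$val_trace)
    }, numeric(1))
    c(mean = mean(errs), se = stats::sd(errs) / sqrt(length(errs)))
  })
  means <- map_dbl(res, "mean")
  ses <- map_dbl(res, "se")
  best <- which.min(means)
  threshold <- means[best] + ifelse(is.na(ses[best]), 0, ses[best])
  candidates[which(means <= threshold)[1]]
}

#' @export
print.mlp_fit <- function(x, ...) {
  cat(sprintf(
    "<mlp_fit> %d-%d-1 tanh network; best epoch %d/%d (val MSE %.4f)\n",
    length(x$cols), x$config$hidden, x$best_epoch, length(x$val_trace),
    x$val_trace[x$best_epoch]
  ))
  invisible(x)
}

#' @describeIn train_mlp One row per weight: layer, from, to, value.
#' @param x,object An `mlp_fit`.
#' @param ... Unused.
#' @export
tidy.mlp_fit <- function(x, ...) {
  h <- seq_len(x$config$hidden)
  bind_rows(
    tidyr::expand_grid(from = x$cols, to = paste0("h", h)) |>
      mutate(layer = "input-hidden",
             weight = as.vector(x$W1)[
               (match(.data$to, paste0("h", h)) - 1) * length(x$cols) +
                 match(.data$from, x$cols)
             ]),
    tibble(from = "bias", to = paste0("h", h), layer = "input-hidden", weight = x$b1),
    tibble(from = paste0("h", h), to = "output", layer = "hidden-output", weight = x$w2),
    tibble(from = "bias", to = "output", layer = "hidden-output", weight = x$b2)
  )
}

#' @describeIn train_mlp One-row summary with traces' minima and the best
#'   epoch.
#' @export
glance.mlp_fit <- function(x, ...) {
  tibble(
    hidden = x$config$hidden,
    epochs_run = length(x$val_trace),
    best_epoch = x$best_epoch,
    train_mse = x$train_trace[x$best_epoch],
    val_mse = x$val_trace[x$best_epoch]
  )
}

#' @describeIn train_mlp Plot training and validation error traces with
#'   the saved best epoch marked.
#' @export
autoplot.mlp_fit <- function(object, ...) {
  df <- bind_rows(
    tibble(epoch = seq_along(object$train_trace), mse = object$train_trace,
           partition = "training"),
    tibble(epoch = seq_along(object$val_trace), mse = object$val_trace,
           partition = "validation")
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$epoch, .data$mse, colour = .data$partition)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$best_epoch, linetype = "dashed") +
    ggplot2::labs(
      x = "epoch", y = "mean squared error",
      title = "Perceptron learning curves",
      subtitle = "dashed line: epoch of the saved (best-validation) weights"
    )
}

#' Serialize / read a perceptron model as JSON
#'
#' @param x An `mlp_fit`.
#' @param path File path.
#' @return `write_mlp_model()` returns `path` invisibly;
#'   `read_mlp_model()` returns an `mlp_fit`.
#' @export
write_mlp_model <- function(x, path) {
  stopifnot(inherits(x, "mlp_fit"))
  doc <- list(
    version = "1", model = "mlp", config = unclass(x$config),
    cols = x$cols, levels = x$levels,
    scaling = as.list(x$scaling),
    weights = list(W1 = as.vector(x$W1), b1 = x$b1, w2 = x$w2, b2 = x$b2,
                   dim_W1 = dim(x$W1)),
    train_trace = x$train_trace, val_trace = x$val_trace,
    best_epoch = x$best_epoch
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_mlp_model
#' @export
read_mlp_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(doc$version)) abort("model document has no version field")
  cfg <- do.call(mlp_config, as.list(doc$config)[names(doc$config) %in% names(formals(mlp_config))])
  structure(list(
    scaling = as_tibble(as.data.frame(doc$scaling, stringsAsFactors = FALSE)),
    cols = doc$cols, levels = doc$levels,
    W1 = matrix(doc$weights$W1, doc$weights$dim_W1[1], doc$weights$dim_W1[2]),
    b1 = doc$weights$b1, w2 = doc$weights$w2, b2 = doc$weights$b2,
    train_trace = doc$train_trace, val_trace = doc$val_trace,
    best_epoch = doc$best_epoch, config = cfg
  ), class = "mlp_fit")
}
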