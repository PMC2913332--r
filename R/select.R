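#' Cross-correlation and collinearity descriptor filter
#'
#' Two-stage reduction used ahead of the perceptron branch. Stage one
#' greedily removes one member of every descriptor pair with
#' `|Pearson r| > r_max`, keeping the member with the larger variance.
#' Stage two iteratively removes the descriptor with the largest
#' variance-inflation factor until all VIF are at or below `vif_max`
#' (exact linear combinations have infinite VIF and fall first).
#'
#' @param data Data frame of descriptors (numeric columns are filtered;
#'   non-numeric columns such as identifiers are ignored).
#' @param r_max Absolute pairwise correlation ceiling, in (0, 1]. Default 0.9.
#' @param vif_max Variance-inflation ceiling. Default 10.
#' @return A `selection_result`: list with `selected` (names), `removed`
#'   (tibble: `descriptor`, `stage`, `value`), `trace` (`NULL`),
#'   `fitness` (`NA`), `method`.
#' @export
filter_collinear <- function(data, r_max = 0.9, vif_max = 10) {
  stopifnot(is.data.frame(data), r_max > 0, r_max <= 1)
  cols <- names(data)[vapply(data, is.numeric, logical(1))]
  if (length(cols) < 2) abort("need at least 2 numeric descriptors")
  x <- data[cols]
  vars <- vapply(x, var, numeric(1))
  if (all(vars == 0)) abort("all descriptors are constant")
  removed <- list()
  drop_col <- function(cl, stage, value) {
    removed[[length(removed) + 1]] <<- tibble(descriptor = cl, stage = stage, value = value)
    x[[cl]] <<- NULL
  }
  for (cl in cols[vars == 0]) drop_col(cl, "constant", 0)

  repeat {
    if (ncol(x) < 2) break
    r <- abs(cor(x))
    diag(r) <- 0
    if (max(r) <= r_max) break
    idx <- which(r == max(r), arr.ind = TRUE)[1, ]
    pair <- colnames(r)[idx]
    victim <- pair[which.min(vapply(x[pair], var, numeric(1)))]
    drop_col(victim, "correlation", max(r))
  }
  repeat {
    if (ncol(x) < 2) break
    vifs <- vapply(names(x), function(cl) {
      fit <- lm(x[[cl]] ~ ., data = x[setdiff(names(x), cl)])
      # an exact linear combination fits perfectly; its warning is expected
      r2 <- suppressWarnings(summary(fit)$r.squared)
      if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
    }, numeric(1))
    if (max(vifs) <= vif_max) break
    victim <- names(which.max(vifs))
    drop_col(victim, "vif", unname(max(vifs)))
  }
  new_selection_result(
    selected = names(x),
    removed = if (length(removed)) bind_rows(removed) else
      tibble(descriptor = character(0), stage = character(0), value = numeric(0)),
    trace = NULL, fitness = NA_real_, method = "corr-filter"
  )
}

#' Hybrid selection algorithm configuration
#'
#' Parameter object for [hsa_select()]. Defaults are the values used for
#' the sensitisation dataset: fuzzy scoring (weighting coefficient 1.5,
#' tolerance 0.001, 30 iterations, 6 clusters), genetic search (10
#' chromosomes, 8 initially active descriptors, 1 crossover point,
#' rejection fraction 0.1, crossover fraction 0.8, mutation fraction 0.05,
#' 10 generations) and stepwise refinement (ascending coefficient 0.02,
#' descending coefficient -0.02).
#'
#' @param weighting,tolerance,iterations,clusters Fuzzy fitness-model
#'   parameters: validation-score weight, convergence tolerance, iteration
#'   cap and maximum fuzzy subspaces inside the fitness model.
#' @param chromosomes,initial_active,crossover_points,rejection_fraction,crossover_fraction,mutation_fraction,generations
#'   Genetic-algorithm parameters.
#' @param ascending,descending Stepwise add/drop thresholds on the
#'   cross-validated fitness (`ascending > 0 > descending`).
#' @param folds Cross-validation folds inside the fitness. Default 5.
#' @param seed Random seed.
#' @return A list of class `hsa_config`.
#' @export
hsa_config <- function(weighting = 1.5, tolerance = 0.001, iterations = 30,
                       clusters = 6, chromosomes = 10, initial_active = 8,
                       crossover_points = 1, rejection_fraction = 0.1,
                       crossover_fraction = 0.8, mutation_fraction = 0.05,
                       generations = 10, ascending = 0.02, descending = -0.02,
                       folds = 5, seed = 1L) {
  cfg <- list(
    weighting = weighting, tolerance = tolerance, iterations = iterations,
    clusters = clusters, chromosomes = chromosomes, initial_active = initial_active,
    crossover_points = crossover_points, rejection_fraction = rejection_fraction,
    crossover_fraction = crossover_fraction, mutation_fraction = mutation_fraction,
    generations = generations, ascending = ascending, descending = descending,
    folds = folds, seed = seed
  )
  fracs <- c(cfg$rejection_fraction, cfg$crossover_fraction, cfg$mutation_fraction)
  stopifnot(
    all(fracs >= 0 & fracs <= 1),
    cfg$chromosomes >= 1, cfg$generations >= 1, cfg$clusters >= 1,
    cfg$ascending > 0, cfg$descending < 0
  )
  structure(cfg, class = "hsa_config")
}

#' Read an HSA configuration from a flat JSON file
#'
#' @param path Path to a JSON object whose keys are [hsa_config()]
#'   arguments; absent keys take their defaults.
#' @return An `hsa_config`.
#' @export
read_hsa_config <- function(path) {
  vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(hsa_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0) abort(sprintf("unknown HSA config key(s): %s", paste(unknown, collapse = ", ")))
  do.call(hsa_config, vals)
}

# Stratified k-fold assignment, deterministic under `seed`.
make_stratified_folds <- function(labels, k, seed) {
  labels <- as.factor(labels)
  if (min(table(labels)) < k) abort("fold count exceeds the smallest class size")
  fold <- integer(length(labels))
  rng_local(seed, {
    for (cl in levels(labels)) {
      idx <- sample(which(labels == cl))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

# Evaluate a seeded expression without disturbing the caller's RNG state.
rng_local <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  eval.parent(substitute(expr))
}

# Cross-validated fitness of a descriptor subset: a depth-limited fuzzy
# partition (at most `clusters` subspaces, coarse cut grid) scored as
# (train accuracy + weighting * validation accuracy) / (1 + weighting),
# averaged over stratified folds. Unpredicted compounds count as errors so
# that abstention is never rewarded during selection.
hsa_fitness <- function(data, labels, cols, cfg, fold) {
  k <- max(fold)
  afp_cfg <- afp_config(
    max_iterations = cfg$clusters - 1, tolerance = cfg$tolerance,
    weighting = cfg$weighting, cut_candidates = 9
  )
  scores <- vapply(seq_len(k), function(f) {
    tr <- fold != f
    fit <- train_afp(data[tr, cols, drop = FALSE], labels[tr], afp_cfg)
    acc <- function(rows) {
      pred <- predict(fit, data[rows, cols, drop = FALSE])
      mean(pred$outcome == as.character(labels[rows]))
    }
    (acc(tr) + cfg$weighting * acc(!tr)) / (1 + cfg$weighting)
  }, numeric(1))
  mean(scores)
}

#' Hybrid GA + stepwise descriptor selection
#'
#' Selects a descriptor subset by a genetic algorithm over binary
#' chromosomes (1-point crossover, bit-flip mutation, rejection of the
#' worst fraction each generation, elitism) followed by stepwise
#' refinement of the best chromosome: descriptors are added while the
#' cross-validated fitness gain exceeds the ascending coefficient, then
#' dropped while the loss from removal stays below the magnitude of the
#' descending coefficient. Fitness is the stratified cross-validated score
#' of a depth-limited fuzzy-partition classifier on the candidate subset,
#' combining training-fold and validation-fold accuracy with the
#' validation side up-weighted by the weighting coefficient.
#'
#' @param data Data frame of (normalized) descriptors; numeric columns are
#'   candidates.
#' @param labels Binary class labels (factor or coercible).
#' @param config An [hsa_config()].
#' @return A `selection_result`: `selected` descriptor names, `trace` of
#'   best-so-far fitness per generation, final cross-validated `fitness`.
#' @export
hsa_select <- function(data, labels, config = hsa_config()) {
  stopifnot(is.data.frame(data), inherits(config, "hsa_config"))
  labels <- as.factor(labels)
  if (nlevels(droplevels(labels)) < 2) abort("labels must contain at least 2 classes")
  cols <- names(data)[vapply(data, is.numeric, logical(1))]
  p <- length(cols)
  if (p == 0) abort("no numeric descriptor columns")
  if (p == 1) {
    return(new_selection_result(cols, trace = numeric(0), fitness = NA_real_, method = "hsa"))
  }
  fold <- make_stratified_folds(labels, config$folds, derive_seed(config$seed, "hsa-folds"))
  cache <- new.env(parent = emptyenv())
  fitness_of <- function(active) {
    key <- paste(which(active), collapse = ",")
    if (!is.null(cache[[key]])) return(cache[[key]])
    val <- hsa_fitness(data, labels, cols[active], config, fold)
    cache[[key]] <- val
    val
  }

  n_chrom <- config$chromosomes
  trace <- numeric(0)
  rng_local(derive_seed(config$seed, "hsa-ga"), {
    pop <- replicate(n_chrom, {
      act <- logical(p)
      if (p <= config$initial_active) act[] <- TRUE else act[sample(p, config$initial_active)] <- TRUE
      act
    }, simplify = FALSE)
    best <- NULL
    best_fit <- -Inf
    for (gen in seq_len(config$generations)) {
      fits <- vapply(pop, fitness_of, numeric(1))
      if (max(fits) > best_fit) {
        best_fit <- max(fits)
        best <- pop[[which.max(fits)]]
      }
      trace <- c(trace, best_fit)
      ord <- order(fits, decreasing = TRUE)
      n_reject <- min(n_chrom - 1, ceiling(config$rejection_fraction * n_chrom))
      pool <- pop[head(ord, n_chrom - n_reject)]
      offspring <- list(best) # elitism
      while (length(offspring) < n_chrom) {
        parents <- pool[sample(length(pool), 2, replace = TRUE)]
        child <- if (runif(1) < config$crossover_fraction) {
          cut <- sample(p - 1, 1)
          c(parents[[1]][seq_len(cut)], parents[[2]][(cut + 1):p])
        } else {
          parents[[1]]
        }
        flip <- runif(p) < config$mutation_fraction
        child <- xor(child, flip)
        if (!any(child)) child[sample(p, 1)] <- TRUE
        offspring[[length(offspring) + 1]] <- child
      }
      pop <- offspring
    }
    # stepwise refinement: forward additions ...
    current <- best
    cur_fit <- fitness_of(current)
    repeat {
      cand <- which(!current)
      if (length(cand) == 0) break
      gains <- vapply(cand, function(j) {
        trial <- current; trial[j] <- TRUE
        fitness_of(trial) - cur_fit
      }, numeric(1))
      if (max(gains) > config$ascending) {
        j <- cand[which.max(gains)]
        current[j] <- TRUE
        cur_fit <- cur_fit + max(gains)
      } else break
    }
    # ... then backward drops while removal costs less than |descending|
    repeat {
      inc <- which(current)
      if (length(inc) <= 1) break
      losses <- vapply(inc, function(j) {
        trial <- current; trial[j] <- FALSE
        cur_fit - fitness_of(trial)
      }, numeric(1))
      if (min(losses) < abs(config$descending)) {
        j <- inc[which.min(losses)]
        current[j] <- FALSE
        cur_fit <- cur_fit - min(losses)
      } else break
    }
    best <- current
    best_fit <- cur_fit
  })
  new_selection_result(cols[best], trace = trace, fitness = best_fit, method = "hsa")
}

new_selection_result <- function(selected, removed = NULL, trace = NULL,
                                 fitness = NA_real_, method = "hsa") {
  if (length(selected) == 0) abort("selection produced an empty descriptor set")
  structure(
    list(selected = selected, removed = removed, trace = trace,
         fitness = fitness, method = method),
    class = "selection_result"
  )
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf(
    "<selection_result: %s> %d descriptor(s): %s\n",
    x$method, length(x$selected), paste(x$selected, collapse = ", ")
  ))
  if (!is.na(x$fitness)) cat(sprintf("  CV fitness: %.4f\n", x$fitness))
  invisible(x)
}

#' @describeIn hsa_select Tidy a selection result into one row per
#'   selected descriptor.
#' @param x A `selection_result`.
#' @param ... Unused.
#' @export
tidy.selection_result <- function(x, ...) {
  tibble(descriptor = x$selected, rank = seq_along(x$selected))
}

#' @describeIn hsa_select One-row summary of a selection result.
#' @export
glance.selection_result <- function(x, ...) {
  tibble(
    method = x$method, n_selected = length(x$selected),
    n_removed = if (is.null(x$removed)) NA_integer_ else nrow(x$removed),
    fitness = x$fitness
  )
}

#' @describeIn hsa_select Plot the best-so-far fitness trace of the
#'   genetic search.
#' @param object A `selection_result`.
#' @export
autoplot.selection_result <- function(object, ...) {
  if (is.null(object$trace) || length(object$trace) == 0) {
    abort("no fitness trace to plot (filter-based selection has none)")
  }
  df <- tibble(generation = seq_along(object$trace), fitness = object$trace)
  ggplot2::ggplot(df, ggplot2::aes(.data$generation, .data$fitness)) +
    ggplot2::geom_step() +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "generation", y = "best cross-validated fitness",
      title = "Hybrid selection: best-so-far fitness"
    )
}

#' Serialize / read a selection result as JSON
#'
#' @param x A `selection_result`.
#' @param path File path.
#' @return `write_selection_result()` returns `path` invisibly;
#'   `read_selection_result()` returns a `selection_result`.
#' @export
write_selection_result <- function(x, path) {
  stopifnot(inherits(x, "selection_result"))
  jsonlite::write_json(
    list(version = "1", method = x$method, selected = x$selected,
         trace = x$trace %||% numeric(0), fitness = x$fitness),
    path, auto_unbox = TRUE, digits = NA, null = "null"
  )
  invisible(path)
}

#' @rdname write_selection_result
#' @export
read_selection_result <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  new_selection_result(
    selected = obj$selected, trace = obj$trace,
    fitness = obj$fitness %||% NA_real_, method = obj$method %||% "hsa"
  )
}
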