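#' Adaptive Fuzzy Partition configuration
#'
#' Training parameters for [train_afp()]. Defaults are the values used for
#' the sensitisation models: at most 30 rules per class, at least 2
#' compounds per rule, at most 5 cuts per axis, membership-weighting
#' exponent 1.5, convergence tolerance 0.001, at most 30 partition
#' iterations, and trapezoid shape ratios `p/w = 1.25` (support width over
#' interval width) and `q/w = 0.45` (core width over interval width).
#'
#' @param max_rules_per_class Cap on rules per class. Default 30.
#' @param min_rule_support Minimum training compounds per rule. Default 2.
#' @param max_cuts_per_axis Cap on cuts per descriptor axis. Default 5.
#' @param weighting Exponent applied to memberships in the purity score.
#' @param tolerance Minimum separation score to accept a further split.
#' @param max_iterations Cap on partition iterations (splits). Default 30.
#' @param p_ratio,q_ratio Trapezoid support/core width ratios.
#' @param cut_candidates `"midpoints"` (midpoints between consecutive
#'   unique member values, the default) or an integer: use that many
#'   quantile-based candidate cuts per axis (a fast coarse grid, used
#'   inside descriptor-selection fitness).
#' @return A list of class `afp_config`.
#' @export
afp_config <- function(max_rules_per_class = 30, min_rule_support = 2,
                       max_cuts_per_axis = 5, weighting = 1.5,
                       tolerance = 0.001, max_iterations = 30,
                       p_ratio = 1.25, q_ratio = 0.45,
                       cut_candidates = "midpoints") {
  stopifnot(
    max_rules_per_class >= 1, min_rule_support >= 1, max_cuts_per_axis >= 1,
    weighting > 0, tolerance >= 0, max_iterations >= 1,
    p_ratio >= 1, q_ratio > 0, q_ratio <= 1
  )
  structure(list(
    max_rules_per_class = max_rules_per_class, min_rule_support = min_rule_support,
    max_cuts_per_axis = max_cuts_per_axis, weighting = weighting,
    tolerance = tolerance, max_iterations = max_iterations,
    p_ratio = p_ratio, q_ratio = q_ratio, cut_candidates = cut_candidates
  ), class = "afp_config")
}

#' Trapezoidal membership function
#'
#' Membership of `x` in the fuzzy set built on the interval `[a, b]` of
#' width `w = b - a`: the support is centred on the interval with width
#' `p_ratio * w`, the core is centred with width `q_ratio * w`, membership
#' is 1 on the core, 0 outside the support, and linear on the shoulders.
#' A side flagged in `open` is a partition border that was never produced
#' by a cut: it saturates at 1 outward (half-trapezoid), the usual
#' convention for the first and last fuzzy set on an axis. A zero-width
#' interval degenerates to an indicator at `a`.
#'
#' @param x Numeric vector of positions.
#' @param a,b Interval endpoints (`a <= b`).
#' @param p_ratio,q_ratio Shape ratios; see [afp_config()].
#' @param open Length-2 logical: saturate the lower / upper side.
#' @return Membership degrees in `[0, 1]`.
#' @examples
#' trapezoid_membership(c(-0.2, 0.5, 1.2), 0, 1)
#' @export
trapezoid_membership <- function(x, a, b, p_ratio = 1.25, q_ratio = 0.45,
                                 open = c(FALSE, FALSE)) {
  w <- b - a
  if (w <= 0) return(as.numeric(x == a))
  s_lo <- a - (p_ratio - 1) / 2 * w
  s_hi <- b + (p_ratio - 1) / 2 * w
  mid <- (a + b) / 2
  c_lo <- mid - q_ratio / 2 * w
  c_hi <- mid + q_ratio / 2 * w
  up <- if (open[1]) rep(1, length(x)) else (x - s_lo) / (c_lo - s_lo)
  down <- if (open[2]) rep(1, length(x)) else (s_hi - x) / (s_hi - c_hi)
  pmax(0, pmin(1, pmin(up, down)))
}

trapezoid_geometry <- function(a, b, p_ratio = 1.25, q_ratio = 0.45) {
  w <- b - a
  mid <- (a + b) / 2
  list(
    interval = c(a, b),
    support = c(a - (p_ratio - 1) / 2 * w, b + (p_ratio - 1) / 2 * w),
    core = c(mid - q_ratio / 2 * w, mid + q_ratio / 2 * w)
  )
}

# membership of rows of matrix `x` in a subspace given its per-axis fuzzy
# sets (each a list(iv = c(lo, hi), open = c(lgl, lgl)))
subspace_membership <- function(x, sets, cfg, exclude_axis = NULL) {
  m <- rep(1, nrow(x))
  for (ax in names(sets)) {
    if (!is.null(exclude_axis) && ax == exclude_axis) next
    s <- sets[[ax]]
    m <- pmin(m, trapezoid_membership(x[, ax], s$iv[1], s$iv[2],
                                      cfg$p_ratio, cfg$q_ratio, s$open))
  }
  m
}

# per-class degrees of membership for rows of matrix `x` under a rule set
afp_degrees <- function(rules, classes, cfg, x) {
  degrees <- matrix(0, nrow(x), length(classes), dimnames = list(NULL, classes))
  for (r in rules) {
    act <- rep(r$weight, nrow(x))
    for (ax in names(r$sets)) {
      s <- r$sets[[ax]]
      act <- pmin(act, r$weight * trapezoid_membership(
        x[, ax], s$iv[1], s$iv[2], cfg$p_ratio, cfg$q_ratio, s$open
      ))
    }
    degrees[, r$class] <- pmax(degrees[, r$class], act)
  }
  degrees
}

outcome_from_degrees <- function(degrees, classes) {
  if (nrow(degrees) == 0) return(character(0))
  top <- max.col(degrees, ties.method = "first")
  top_deg <- degrees[cbind(seq_len(nrow(degrees)), top)]
  ifelse(top_deg > 0.5, classes[top], "unpredicted")
}

# membership-weighted class shares with exponent `weighting`
purity_shares <- function(m, y, weighting, classes) {
  mw <- m^weighting
  tot <- sum(mw)
  if (tot <= 0) return(rep(0, length(classes)))
  vapply(classes, function(cl) sum(mw[y == cl]) / tot, numeric(1))
}

candidate_cuts <- function(values, lo, hi, cfg) {
  if (identical(cfg$cut_candidates, "midpoints")) {
    u <- sort(unique(values))
    if (length(u) < 2) return(numeric(0))
    cuts <- (u[-1] + u[-length(u)]) / 2
  } else {
    g <- as.integer(cfg$cut_candidates)
    cuts <- unique(unname(quantile(values, probs = seq_len(g) / (g + 1), type = 7)))
  }
  cuts[cuts > lo & cuts < hi]
}

#' Train an Adaptive Fuzzy Partition classifier
#'
#' Recursively partitions the descriptor space into fuzzy subspaces with
#' trapezoidal membership functions. Each iteration scans every terminal
#' subspace, axis and candidate cut position, ranks candidate splits by
#' the local separation score — the largest between-child difference in
#' membership-weighted class shares, memberships raised to the weighting
#' coefficient — and applies the best-ranked split whose resulting rule
#' set improves the global training classification score (fraction of
#' compounds attributed to their own class; abstentions count as misses)
#' by at least the tolerance. Partitioning stops when no such split
#' exists, when a child would hold fewer than the minimum compounds, when
#' an axis reaches its cut cap, when a class reaches its rule cap, or at
#' the iteration cap. Each terminal subspace emits one fuzzy rule for its
#' majority class, weighted by the class's share of the subspace's
#' training members.
#'
#' Inputs are expected on the normalized `-1..+1` scale produced by
#' [normalize_minmax()] (any common scale works; cut positions are
#' scale-free).
#'
#' @param data Data frame of descriptors (numeric columns become axes).
#' @param labels Class labels (factor or coercible). A single-class input
#'   yields one universal rule for that class.
#' @param config An [afp_config()].
#' @return An object of class `afp_fit` with elements `rules`, `classes`,
#'   `axes`, `cuts_per_axis`, `iterations`, `config`.
#' @examples
#' d <- tibble::tibble(x = c(seq(-1, -0.2, length = 20), seq(0.2, 1, length = 20)))
#' fit <- train_afp(d, rep(c("A", "B"), each = 20))
#' predict(fit, tibble::tibble(x = c(-0.5, 0.6)))
#' @export
train_afp <- function(data, labels, config = afp_config()) {
  stopifnot(is.data.frame(data), inherits(config, "afp_config"))
  if (nrow(data) == 0) abort("empty training table")
  labels <- droplevels(as.factor(labels))
  if (length(labels) != nrow(data)) abort("labels must match rows of data")
  axes <- names(data)[vapply(data, is.numeric, logical(1))]
  if (length(axes) == 0) abort("no numeric descriptor columns")
  classes <- levels(labels)
  x <- as.matrix(data[axes])
  y_chr <- as.character(labels)

  subspaces <- list(list(sets = list(), members = seq_len(nrow(data))))
  cuts_per_axis <- setNames(integer(length(axes)), axes)
  iterations <- 0L

  y_int <- as.integer(labels)
  rules_of <- function(subs) {
    map(subs, function(s) {
      tab <- tabulate(y_int[s$members], nbins = length(classes))
      ci <- which.max(tab)
      list(class = classes[ci], weight = tab[ci] / sum(tab),
           n = length(s$members), sets = s$sets)
    })
  }
  # global training classification score: fraction of compounds attributed
  # to their own class (unpredicted counts as a miss)
  global_score <- function(subs) {
    deg <- afp_degrees(rules_of(subs), classes, config, x)
    mean(outcome_from_degrees(deg, classes) == y_chr)
  }

  if (length(classes) > 1) {
    current_score <- global_score(subspaces)
    repeat {
      if (iterations >= config$max_iterations) break
      # best candidate cut per (subspace, axis) by the local separation score
      cands <- list()
      for (si in seq_along(subspaces)) {
        S <- subspaces[[si]]
        members <- S$members
        if (length(members) < 2 * config$min_rule_support) next
        for (ax in axes) {
          if (cuts_per_axis[[ax]] >= config$max_cuts_per_axis) next
          set_ax <- S$sets[[ax]] %||%
            list(iv = range(x[members, ax]), open = c(TRUE, TRUE))
          iv <- set_ax$iv
          v <- x[members, ax]
          cuts <- candidate_cuts(v, iv[1], iv[2], config)
          if (length(cuts) == 0) next
          base <- subspace_membership(x[members, , drop = FALSE], S$sets, config,
                                      exclude_axis = ax)
          y <- labels[members]
          yb <- y_int[members] == 1L
          best <- NULL
          for (t in cuts) {
            n1 <- sum(v <= t)
            if (n1 < config$min_rule_support || length(v) - n1 < config$min_rule_support) next
            m1 <- pmin(base, trapezoid_membership(v, iv[1], t, config$p_ratio,
                                                  config$q_ratio, c(set_ax$open[1], FALSE)))
            m2 <- pmin(base, trapezoid_membership(v, t, iv[2], config$p_ratio,
                                                  config$q_ratio, c(FALSE, set_ax$open[2])))
            sc <- if (length(classes) == 2) {
              mw1 <- m1^config$weighting
              mw2 <- m2^config$weighting
              t1 <- sum(mw1); t2 <- sum(mw2)
              if (t1 <= 0 || t2 <= 0) 0 else abs(sum(mw1[yb]) / t1 - sum(mw2[yb]) / t2)
            } else {
              max(abs(
                purity_shares(m1, y, config$weighting, classes) -
                  purity_shares(m2, y, config$weighting, classes)
              ))
            }
            if (is.null(best) || sc > best$score + 1e-12) {
              best <- list(score = sc, si = si, axis = ax, cut = t, set = set_ax)
            }
          }
          if (!is.null(best)) cands[[length(cands) + 1]] <- best
        }
      }
      if (length(cands) == 0) break
      cands <- cands[order(-map_dbl(cands, "score"))]
      applied <- FALSE
      for (cand in head(cands, 20)) {
        S <- subspaces[[cand$si]]
        v <- x[S$members, cand$axis]
        left <- S$members[v <= cand$cut]
        right <- S$members[v > cand$cut]
        s1 <- S$sets
        s1[[cand$axis]] <- list(iv = c(cand$set$iv[1], cand$cut),
                                open = c(cand$set$open[1], FALSE))
        s2 <- S$sets
        s2[[cand$axis]] <- list(iv = c(cand$cut, cand$set$iv[2]),
                                open = c(FALSE, cand$set$open[2]))
        trial <- subspaces
        trial[[cand$si]] <- list(sets = s1, members = left)
        trial[[length(trial) + 1]] <- list(sets = s2, members = right)
        maj <- vapply(trial, function(s) {
          which.max(tabulate(y_int[s$members], nbins = length(classes)))
        }, integer(1))
        if (any(tabulate(maj, nbins = length(classes)) > config$max_rules_per_class)) next
        trial_score <- global_score(trial)
        if (trial_score - current_score < config$tolerance) next
        current_score <- trial_score
        subspaces <- trial
        cuts_per_axis[[cand$axis]] <- cuts_per_axis[[cand$axis]] + 1L
        iterations <- iterations + 1L
        applied <- TRUE
        break
      }
      if (!applied) break
    }
  }

  rules <- rules_of(subspaces)
  structure(list(
    rules = rules, classes = classes, axes = axes,
    cuts_per_axis = cuts_per_axis, iterations = iterations, config = config
  ), class = "afp_fit")
}

#' Class membership profile under an AFP model
#'
#' For each row, each rule's activation is its weight times the minimum of
#' its trapezoid memberships (a rule with no constrained axis activates at
#' its weight everywhere); each class's degree of membership is the
#' maximum activation over that class's rules. A row is attributed to the
#' class of its highest degree only when that degree is strictly greater
#' than 0.5; otherwise it is `"unpredicted"` — in particular a row that
#' activates no rule lies outside the partition's own applicability
#' region.
#'
#' @param object An `afp_fit`.
#' @param newdata Data frame covering every axis the model uses.
#' @return A tibble with one `degree_<class>` column per class and an
#'   `outcome` column (class label or `"unpredicted"`).
#' @export
afp_membership <- function(object, newdata) {
  stopifnot(inherits(object, "afp_fit"), is.data.frame(newdata))
  used <- unique(unlist(map(object$rules, function(r) names(r$sets))))
  missing_ax <- setdiff(used, names(newdata))
  if (length(missing_ax) > 0) {
    abort(sprintf("newdata is missing model axis(es): %s", paste(missing_ax, collapse = ", ")))
  }
  n <- nrow(newdata)
  x <- if (length(used) > 0) {
    as.matrix(newdata[used])
  } else {
    matrix(numeric(0), nrow = n, ncol = 0)
  }
  degrees <- afp_degrees(object$rules, object$classes, object$config, x)
  out <- as_tibble(as.data.frame(degrees))
  names(out) <- paste0("degree_", object$classes)
  out$outcome <- outcome_from_degrees(degrees, object$classes)
  out
}

#' @describeIn afp_membership Predict method; identical columns, one row
#'   per row of `newdata`.
#' @param ... Unused.
#' @export
predict.afp_fit <- function(object, newdata, ...) {
  afp_membership(object, newdata)
}

#' @export
print.afp_fit <- function(x, ...) {
  cat(sprintf(
    "<afp_fit> %d rule(s) over %d class(es) [%s]; %d iteration(s)\n",
    length(x$rules), length(x$classes), paste(x$classes, collapse = ", "),
    x$iterations
  ))
  invisible(x)
}

#' @describeIn train_afp One row per rule and constrained axis, with
#'   interval, support and core geometry.
#' @param x,object An `afp_fit`.
#' @param ... Unused.
#' @export
tidy.afp_fit <- function(x, ...) {
  rows <- list()
  for (ri in seq_along(x$rules)) {
    r <- x$rules[[ri]]
    if (length(r$sets) == 0) {
      rows[[length(rows) + 1]] <- tibble(
        rule = ri, class = r$class, weight = r$weight, n = r$n,
        axis = NA_character_, lo = NA_real_, hi = NA_real_,
        open_lo = NA, open_hi = NA,
        support_lo = NA_real_, support_hi = NA_real_,
        core_lo = NA_real_, core_hi = NA_real_
      )
      next
    }
    for (ax in names(r$sets)) {
      s <- r$sets[[ax]]
      geo <- trapezoid_geometry(s$iv[1], s$iv[2], x$config$p_ratio, x$config$q_ratio)
      rows[[length(rows) + 1]] <- tibble(
        rule = ri, class = r$class, weight = r$weight, n = r$n, axis = ax,
        lo = geo$interval[1], hi = geo$interval[2],
        open_lo = s$open[1], open_hi = s$open[2],
        support_lo = if (s$open[1]) -Inf else geo$support[1],
        support_hi = if (s$open[2]) Inf else geo$support[2],
        core_lo = geo$core[1], core_hi = geo$core[2]
      )
    }
  }
  bind_rows(rows)
}

#' @describeIn train_afp One-row model summary.
#' @export
glance.afp_fit <- function(x, ...) {
  tibble(
    n_rules = length(x$rules), n_classes = length(x$classes),
    n_axes_used = sum(x$cuts_per_axis > 0), iterations = x$iterations,
    max_cuts_used = if (length(x$cuts_per_axis)) max(x$cuts_per_axis) else 0L
  )
}

#' @describeIn train_afp Plot rule intervals (with support extents) per
#'   axis, coloured by class.
#' @export
autoplot.afp_fit <- function(object, ...) {
  df <- tidy(object)
  df <- df[!is.na(df$axis), ]
  if (nrow(df) == 0) abort("model has no axis-constrained rules to plot")
  df$support_lo[is.infinite(df$support_lo)] <- df$lo[is.infinite(df$support_lo)]
  df$support_hi[is.infinite(df$support_hi)] <- df$hi[is.infinite(df$support_hi)]
  ggplot2::ggplot(df, ggplot2::aes(y = factor(.data$rule), colour = .data$class)) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$support_lo, xend = .data$support_hi,
                                       yend = factor(.data$rule)), linetype = "dotted") +
    ggplot2::geom_segment(ggplot2::aes(x = .data$lo, xend = .data$hi,
                                       yend = factor(.data$rule)),
                          linewidth = 2, alpha = 0.8) +
    ggplot2::facet_wrap(~axis, scales = "free_x") +
    ggplot2::labs(
      x = "normalized descriptor value", y = "rule",
      title = "AFP rule intervals (solid) and supports (dotted)"
    )
}

#' Serialize / read an AFP model as JSON
#'
#' The document carries a mandatory `version` field, the configuration,
#' optional normalization parameters, and per rule: class, weight, member
#' count and per-axis interval/support/core.
#'
#' @param x An `afp_fit`.
#' @param path File path.
#' @param normalization Optional parameter tibble from
#'   [normalize_minmax()], stored alongside the model.
#' @return `write_afp_model()` returns `path` invisibly;
#'   `read_afp_model()` returns an `afp_fit` (with attribute
#'   `"normalization"` if one was stored).
#' @export
write_afp_model <- function(x, path, normalization = NULL) {
  stopifnot(inherits(x, "afp_fit"))
  doc <- list(
    version = "1",
    model = "afp",
    config = unclass(x$config),
    classes = x$classes,
    axes = x$axes,
    cuts_per_axis = as.list(x$cuts_per_axis),
    iterations = x$iterations,
    normalization = if (!is.null(normalization)) as.list(normalization) else NULL,
    rules = map(x$rules, function(r) {
      list(
        class = r$class, weight = r$weight, n = r$n,
        axes = imap(r$sets, function(s, ax) {
          geo <- trapezoid_geometry(s$iv[1], s$iv[2], x$config$p_ratio, x$config$q_ratio)
          list(interval = geo$interval, open = s$open,
               support = geo$support, core = geo$core)
        })
      )
    })
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_afp_model
#' @export
read_afp_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(doc$version)) abort("model document has no version field")
  cfg <- do.call(afp_config, doc$config[names(doc$config) %in% names(formals(afp_config))])
  rules <- map(doc$rules, function(r) {
    list(
      class = r$class, weight = r$weight, n = r$n,
      sets = map(r$axes, function(a) {
        list(iv = as.numeric(unlist(a$interval)),
             open = as.logical(unlist(a$open)))
      })
    )
  })
  fit <- structure(list(
    rules = rules,
    classes = as.character(unlist(doc$classes)),
    axes = as.character(unlist(doc$axes)),
    cuts_per_axis = unlist(doc$cuts_per_axis) %||%
      setNames(integer(0), character(0)),
    iterations = doc$iterations %||% NA_integer_,
    config = cfg
  ), class = "afp_fit")
  if (!is.null(doc$normalization)) {
    attr(fit, "normalization") <- as_tibble(as.data.frame(
      lapply(doc$normalization, unlist),
      stringsAsFactors = FALSE
    ))
  }
  fit
}
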