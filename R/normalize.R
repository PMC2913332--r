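#' Min-max normalization to the -1..+1 range
#'
#' Fits per-descriptor affine maps sending the observed minimum to -1 and
#' the observed maximum to +1. Constant columns are flagged and mapped to
#' 0. The fitted parameters are returned so that test data can be
#' transformed with the *training* ranges (values outside the training
#' range then fall outside `[-1, 1]`, deliberately unclipped).
#'
#' @param data A data frame; all numeric columns are normalized (other
#'   columns are passed through untouched).
#' @param cols Optional character vector restricting which columns to
#'   normalize.
#' @return A list with `data` (normalized tibble) and `params`
#'   (tibble: `descriptor`, `min`, `max`, `constant`).
#' @examples
#' normalize_minmax(tibble::tibble(x = c(0, 5, 10)))$data
#' @export
normalize_minmax <- function(data, cols = NULL) {
  stopifnot(is.data.frame(data))
  if (nrow(data) < 2) abort("normalization needs at least 2 rows")
  num <- names(data)[vapply(data, is.numeric, logical(1))]
  cols <- cols %||% num
  if (!all(cols %in% num)) abort("all normalized columns must be numeric")
  params <- tibble(
    descriptor = cols,
    min = map_dbl(cols, function(cl) min(data[[cl]])),
    max = map_dbl(cols, function(cl) max(data[[cl]]))
  )
  params$constant <- params$max == params$min
  if (any(params$constant)) {
    warn(sprintf(
      "constant column(s) flagged and mapped to 0: %s",
      paste(params$descriptor[params$constant], collapse = ", ")
    ))
  }
  list(data = apply_normalization(data, params), params = params)
}

#' Apply fitted normalization parameters
#'
#' @param data A data frame containing the parameterised columns.
#' @param params Parameter tibble from [normalize_minmax()].
#' @return The data with parameterised columns affinely mapped; values
#'   beyond the fitted range map beyond `[-1, 1]` without clipping.
#' @export
apply_normalization <- function(data, params) {
  out <- as_tibble(data)
  for (r in seq_len(nrow(params))) {
    cl <- params$descriptor[r]
    if (!cl %in% names(out)) abort(sprintf("column '%s' missing from data", cl))
    out[[cl]] <- if (params$constant[r]) {
      rep(0, nrow(out))
    } else {
      2 * (out[[cl]] - params$min[r]) / (params$max[r] - params$min[r]) - 1
    }
  }
  out
}

#' Invert a min-max normalization
#'
#' @inheritParams apply_normalization
#' @return The data mapped back to original descriptor units (constant
#'   columns are restored to their fitted constant value).
#' @export
invert_normalization <- function(data, params) {
  out <- as_tibble(data)
  for (r in seq_len(nrow(params))) {
    cl <- params$descriptor[r]
    if (!cl %in% names(out)) abort(sprintf("column '%s' missing from data", cl))
    out[[cl]] <- if (params$constant[r]) {
      rep(params$min[r], nrow(out))
    } else {
      (out[[cl]] + 1) / 2 * (params$max[r] - params$min[r]) + params$min[r]
    }
  }
  out
}
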