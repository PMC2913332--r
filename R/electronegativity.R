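#' Carbon-scaled Sanderson electronegativities
#'
#' Sanderson electronegativity for the elements handled by the descriptor
#' panel, divided by the carbon value so that carbon maps to exactly 1.
#' These constants feed the mean-electronegativity descriptor `Me`.
#'
#' @return A tibble with columns `element`, `sanderson` (raw) and
#'   `scaled` (carbon = 1).
#' @examples
#' sanderson_electronegativity()
#' @export
sanderson_electronegativity <- function() {
  raw <- c(
    H = 2.592, C = 2.746, N = 3.194, O = 3.654, S = 2.957,
    P = 2.515, F = 4.000, Cl = 3.475, Br = 3.219, I = 2.778
  )
  tibble(
    element = names(raw),
    sanderson = unname(raw),
    scaled = unname(raw / raw[["C"]])
  )
}

scaled_en <- function(elements) {
  en <- sanderson_electronegativity()
  idx <- match(elements, en$element)
  if (anyNA(idx)) {
    missing <- unique(elements[is.na(idx)])
    abort(
      sprintf("no Sanderson electronegativity for element(s): %s", paste(missing, collapse = ", ")),
      class = "skinqsar_descriptor_error"
    )
  }
  en$scaled[idx]
}
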