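#' The HEI-2005 component standards
#'
#' Returns the 12-component scoring rulebook of the Healthy Eating Index
#' 2005: per component, the maximum points (5, 10 or 20), the direction
#' (adequacy or moderation), the basis (per-1000-kcal density or percent
#' of energy), and the densities earning the maximum and minimum score.
#' Adequacy components earn full points at or above `max_standard` and
#' zero only at zero intake; moderation components earn full points at or
#' below `max_standard` and zero at or beyond `min_standard`. Scores
#' between the anchors are prorated linearly.
#'
#' @return A tibble with one row per component.
#' @export
#' @examples
#' hei_standards()
hei_standards <- function() {
  readr::read_csv(
    childdqi_file("hei2005_standards.csv"),
    col_types = readr::cols(
      component = readr::col_character(),
      max_points = readr::col_double(),
      direction = readr::col_character(),
      basis = readr::col_character(),
      max_standard = readr::col_double(),
      min_standard = readr::col_double(),
      units = readr::col_character(),
      source_field = readr::col_character()
    )
  )
}

#' Score an adequacy component
#'
#' Linear proration from zero points at zero intake up to the maximum at
#' the standard density: `max_points * min(1, density / max_standard)`.
#' The score is zero if and only if the density is zero.
#'
#' @param density Non-negative density (serving units per 1000 kcal, or
#'   percent of energy for energy-relative components).
#' @param standard A one-row standard (a row of [hei_standards()]), or a
#'   list with `max_points` and `max_standard`.
#' @return Points in `[0, max_points]`.
#' @export
#' @examples
#' std <- hei_standards()[1, ] # total fruit, 5 points at 0.8 c/1000 kcal
#' score_adequacy(c(0, 0.4, 0.8, 2), std)
score_adequacy <- function(density, standard) {
  if (any(density < 0)) {
    abort("`density` must be non-negative.")
  }
  standard$max_points * pmin(1, density / standard$max_standard)
}

#' Score a moderation component
#'
#' Full points at or below the quality standard, zero at or beyond the
#' lower-quality bound, linear in between:
#' `max_points * (min_standard - value) / (min_standard - max_standard)`.
#'
#' @param value Non-negative measured quantity (density or % of energy).
#' @param standard A one-row standard with `max_points`, `max_standard`
#'   (full-score bound) and `min_standard` (zero-score bound,
#'   `min_standard > max_standard`).
#' @return Points in `[0, max_points]`.
#' @export
#' @examples
#' std <- hei_standards()[hei_standards()$component == "sat_fat", ]
#' score_moderation(c(7, 11, 15), std)
score_moderation <- function(value, standard) {
  if (any(value < 0)) {
    abort("`value` must be non-negative.")
  }
  frac <- (standard$min_standard - value) /
    (standard$min_standard - standard$max_standard)
  standard$max_points * pmin(1, pmax(0, frac))
}

#' Score children under the HEI-2005
#'
#' Computes the 12 HEI-2005 component scores and their 100-point total
#' for each child from two-day averaged intakes. Food-group, oil and
#' sodium amounts are first expressed per 1000 kcal of the child's energy
#' intake; percent-of-energy fields (saturated fat, SoFAAS) are used as
#' reported.
#'
#' @param usual A tibble of per-child averaged intakes (see
#'   [average_intake()]); `energy` must be strictly positive.
#' @return A tibble with `child_id`, the twelve component scores and
#'   `total` (0-100).
#' @export
score_hei <- function(usual) {
  usual <- tibble::as_tibble(usual)
  validate_intake(usual)
  standards <- hei_standards()
  out <- tibble::tibble(child_id = usual$child_id)
  for (i in seq_len(nrow(standards))) {
    std <- standards[i, ]
    raw <- usual[[std$source_field]]
    value <- if (std$basis == "density") {
      density_per_1000kcal(raw, usual$energy)
    } else {
      raw
    }
    out[[std$component]] <- if (std$direction == "adequacy") {
      score_adequacy(value, std)
    } else {
      score_moderation(value, std)
    }
  }
  out$total <- rowSums(as.matrix(out[standards$component]))
  out
}
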