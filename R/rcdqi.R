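#' Load an RC-DQI target table
#'
#' The Revised Children's Diet Quality Index scores 13 components against
#' age-indexed targets for ages 2-18. Two printed variants of the target
#' table exist, differing in the food-group amounts (total grains, whole
#' grains, fruit, vegetables), the upper iron bands and the per-age
#' Estimated Energy Requirement (EER); they correspond to different
#' age-appropriate energy patterns. Both are shipped; `"table_b"` is the
#' default throughout the package.
#'
#' @param variant `"table_b"` or `"table_c"`.
#' @return An object of class `rcdqi_table`: a list with the banded
#'   age-indexed targets, iron bands, macronutrient rules and TV-hours
#'   imputation bands.
#' @export
#' @examples
#' tbl <- rcdqi_targets("table_b")
#' lookup_target("fruit", age = 4, table = tbl)
rcdqi_targets <- function(variant = c("table_b", "table_c")) {
  variant <- match.arg(variant)
  targets <- readr::read_csv(
    childdqi_file("rcdqi_targets.csv"),
    col_types = readr::cols(
      variant = readr::col_character(),
      component = readr::col_character(),
      age_lo = readr::col_integer(),
      age_hi = readr::col_integer(),
      value = readr::col_double(),
      units = readr::col_character()
    )
  )
  iron <- readr::read_csv(
    childdqi_file("rcdqi_iron_bands.csv"),
    col_types = readr::cols(
      variant = readr::col_character(),
      age_lo = readr::col_integer(),
      age_hi = readr::col_integer(),
      ear_max = readr::col_double(),
      rda_min = readr::col_double()
    )
  )
  macro <- readr::read_csv(
    childdqi_file("rcdqi_macro_rules.csv"),
    col_types = readr::cols(
      component = readr::col_character(),
      max_points = readr::col_double(),
      rule = readr::col_character(),
      age_lo = readr::col_integer(),
      age_hi = readr::col_integer(),
      lo = readr::col_double(),
      hi = readr::col_double(),
      source_field = readr::col_character()
    )
  )
  tv <- readr::read_csv(
    childdqi_file("rcdqi_tv_imputation.csv"),
    col_types = readr::cols(
      age_lo = readr::col_integer(),
      age_hi = readr::col_integer(),
      hours = readr::col_double()
    )
  )
  structure(
    list(
      variant = variant,
      targets = targets[targets$variant == variant, ],
      iron = iron[iron$variant == variant, ],
      macro = macro,
      tv_impute = tv
    ),
    class = "rcdqi_table"
  )
}

#' @export
print.rcdqi_table <- function(x, ...) {
  cat("RC-DQI target table (variant ", x$variant, ")\n", sep = "")
  cat("Age-indexed targets:\n")
  print(x$targets, n = Inf)
  invisible(x)
}

band_lookup <- function(bands, age, value_col) {
  idx <- vapply(age, function(a) {
    hit <- which(bands$age_lo <= a & a <= bands$age_hi)
    if (length(hit) != 1L) NA_integer_ else hit
  }, integer(1))
  if (anyNA(idx)) {
    abort("Age does not resolve to exactly one target band.")
  }
  bands[[value_col]][idx]
}

check_age_2_18 <- function(age) {
  if (any(!is.finite(age)) || any(age < 2 | age > 18)) {
    abort("`age` must be between 2 and 18 years.")
  }
}

#' Look up the age-indexed target of an RC-DQI component
#'
#' @param component One of `"total_grains"`, `"whole_grains"`, `"fruit"`,
#'   `"vegetable"`, `"excess_juice"`, `"dairy"`, `"eer"`.
#' @param age Age(s) in completed years, 2-18.
#' @param table An [rcdqi_targets()] object.
#' @return Numeric target(s) in the component's units.
#' @export
lookup_target <- function(component, age, table = rcdqi_targets()) {
  check_age_2_18(age)
  bands <- table$targets[table$targets$component == component, ]
  if (nrow(bands) == 0) {
    abort(paste0("Unknown RC-DQI component: ", sQuote(component)))
  }
  band_lookup(bands, floor(age), "value")
}

#' Score a food-group component by proportional deduction
#'
#' Children consuming at or above the age target earn the maximum;
#' partial consumption earns a proportional share; only zero consumption
#' earns zero: `max_points * min(1, intake / target)`.
#'
#' @param intake Non-negative servings per day.
#' @param target Positive age-indexed target, same units.
#' @param max_points Maximum points of the component.
#' @return Points in `[0, max_points]`.
#' @export
#' @examples
#' score_food_group(c(0, 0.75, 1.5, 3), target = 1.5, max_points = 10)
score_food_group <- function(intake, target, max_points) {
  if (any(intake < 0)) {
    abort("`intake` must be non-negative.")
  }
  if (any(target <= 0)) {
    abort("`target` must be strictly positive.")
  }
  max_points * pmin(1, intake / target)
}

#' Score a macronutrient range component
#'
#' Full points inside the acceptable range `[lo, hi]`; below the range
#' the score decays as `value / lo`, above it as `hi / value`. The score
#' is continuous at both range edges, zero only at zero intake, and never
#' reaches zero from above.
#'
#' @param value Non-negative percent of energy.
#' @param lo,hi Range bounds, `0 < lo < hi`.
#' @param max_points Maximum points of the component.
#' @return Points in `[0, max_points]`.
#' @export
#' @examples
#' score_range(c(0, 15, 30, 35, 40, 80), lo = 30, hi = 40, max_points = 2.5)
score_range <- function(value, lo, hi, max_points) {
  if (any(value < 0)) {
    abort("`value` must be non-negative.")
  }
  if (any(!(lo > 0 & hi > lo))) {
    abort("Range must satisfy 0 < lo < hi.")
  }
  pts <- ifelse(
    value < lo,
    max_points * value / lo,
    ifelse(value > hi, max_points * hi / value, max_points)
  )
  pmin(max_points, pmax(0, pts))
}

#' Score a capped component
#'
#' Full points at or below the cap; above it the score decays as
#' `cap / value`, so it is continuous at the cap and approaches (but
#' never reaches) zero for extreme overconsumption.
#'
#' @param value Non-negative measured quantity.
#' @param cap Positive cap, same units.
#' @param max_points Maximum points of the component.
#' @return Points in `(0, max_points]`, or `max_points` at `value = 0`.
#' @export
#' @examples
#' score_cap(c(5, 10, 20, 40), cap = 10, max_points = 10)
score_cap <- function(value, cap, max_points) {
  if (any(value < 0)) {
    abort("`value` must be non-negative.")
  }
  if (any(cap <= 0)) {
    abort("`cap` must be strictly positive.")
  }
  ifelse(value <= cap, max_points, max_points * cap / value)
}

#' Score iron intake categorically against the age-band DRI thresholds
#'
#' Iron is the one categorical RC-DQI component: intakes at or below the
#' age band's EAR-derived bound earn 0 points, intakes at or above the
#' RDA-derived bound earn 10, intakes in between earn 5. The four bands
#' (2-3, 4-8, 9-13, 14-18 years) follow the DRI age groups.
#'
#' @param intake Non-negative iron intake in mg/day.
#' @param age Age(s) in years, 2-18.
#' @param table An [rcdqi_targets()] object.
#' @return Points: 0, 5 or 10.
#' @export
#' @examples
#' score_iron(c(2, 5, 7), age = 3)
score_iron <- function(intake, age, table = rcdqi_targets()) {
  if (any(intake < 0)) {
    abort("`intake` must be non-negative.")
  }
  check_age_2_18(age)
  ear <- band_lookup(table$iron, floor(age), "ear_max")
  rda <- band_lookup(table$iron, floor(age), "rda_min")
  ifelse(intake <= ear, 0, ifelse(intake >= rda, 10, 5))
}

#' Score daily television hours
#'
#' Two hours or less of TV per day earns the full 10 points; above two
#' hours the score decays proportionally as `10 * 2 / hours`. Children
#' with unreported TV time are imputed the age-band viewing hours used
#' for RC-DQI coding (2-6 years: 2 h; 7-14 years: 4 h; 15-18 years:
#' 3.5 h).
#'
#' @param tv_hours Hours of TV per day; `NA` = not reported.
#' @param age Age(s) in years, 2-18 (used for imputation).
#' @param table An [rcdqi_targets()] object.
#' @return Points in `(0, 10]`.
#' @export
#' @examples
#' score_tv(c(1, 2, 4, NA), age = c(5, 5, 5, 5))
score_tv <- function(tv_hours, age, table = rcdqi_targets()) {
  check_age_2_18(age)
  if (any(!is.na(tv_hours) & tv_hours < 0)) {
    abort("`tv_hours` must be non-negative where reported.")
  }
  tv_hours <- rep_len(tv_hours, length(age))
  imputed <- band_lookup(table$tv_impute, floor(age), "hours")
  h <- ifelse(is.na(tv_hours), imputed, tv_hours)
  ifelse(h <= 2, 10, 10 * 2 / h)
}

#' Score energy intake against the Estimated Energy Requirement window
#'
#' Energy within +/-10% of the age-indexed EER earns the full 10 points.
#' Outside the window the default `"proportional"` formula decays the
#' score proportionally from the nearer window edge:
#' `10 * energy / (0.9 * eer)` below and `10 * (1.1 * eer) / energy`
#' above, so the score is continuous at both edges and zero only at zero
#' intake. The `"literal"` mode applies the percentage-deduction reading
#' of the published footnote (`10 * (1 - energy/edge)`, clamped to
#' `[0, 10]`), kept for auditability; it is discontinuous at the window
#' edges.
#'
#' @param energy Non-negative energy intake, kcal/day.
#' @param eer Positive age-indexed EER, kcal/day.
#' @param method `"proportional"` (default) or `"literal"`.
#' @return Points in `[0, 10]`.
#' @export
#' @examples
#' score_energy(c(900, 1000, 1100, 2200), eer = 1000)
score_energy <- function(energy, eer, method = c("proportional", "literal")) {
  method <- match.arg(method)
  if (any(energy < 0)) {
    abort("`energy` must be non-negative.")
  }
  if (any(eer <= 0)) {
    abort("`eer` must be strictly positive.")
  }
  lo <- 0.9 * eer
  hi <- 1.1 * eer
  if (method == "proportional") {
    ifelse(
      energy < lo, 10 * energy / lo,
      ifelse(energy > hi, 10 * hi / energy, 10)
    )
  } else {
    pts <- ifelse(
      energy < lo, 10 * (1 - energy / lo),
      ifelse(energy > hi, 10 * (1 - energy / hi), 10)
    )
    pmin(10, pmax(0, pts))
  }
}

# Food-group components scored by proportional deduction, with the
# intake field each reads and its maximum points.
rcdqi_food_groups <- tibble::tibble(
  component = c("total_grains", "whole_grains", "fruit", "vegetable", "dairy"),
  source_field = c("total_grains", "whole_grains", "total_fruit", "total_veg", "dairy"),
  max_points = c(5, 5, 10, 10, 10)
)

#' Score children under the RC-DQI
#'
#' Computes the 13 RC-DQI component scores and their 90-point total for
#' each child: five food groups by proportional deduction against the
#' age-indexed targets, excess fruit juice against the pediatric
#' age-appropriate limit, five macronutrient rules (added sugar cap, fat
#' and fatty-acid ranges, DHA+EPA cap), categorical iron, and the
#' combined TV/energy score `(TV score + EER score) / 2`.
#'
#' @param profiles Per-child demographics with `child_id`, `age` and
#'   `tv_hours` (see [child_profiles()]).
#' @param usual Per-child averaged intakes (see [average_intake()]).
#' @param variant RC-DQI table variant, `"table_b"` (default) or
#'   `"table_c"`.
#' @param eer_formula Energy-score mode passed to [score_energy()].
#' @return A tibble with `child_id`, the thirteen component scores and
#'   `total` (0-90).
#' @export
score_rcdqi <- function(profiles, usual,
                        variant = c("table_b", "table_c"),
                        eer_formula = c("proportional", "literal")) {
  variant <- match.arg(variant)
  eer_formula <- match.arg(eer_formula)
  table <- rcdqi_targets(variant)
  usual <- tibble::as_tibble(usual)
  validate_intake(usual)
  profiles <- tibble::as_tibble(profiles)
  dat <- dplyr::inner_join(
    profiles[, c("child_id", "age", "tv_hours")], usual,
    by = "child_id"
  )
  if (nrow(dat) < nrow(usual)) {
    warn("Some intake rows had no matching child profile and were dropped.")
  }
  check_age_2_18(dat$age)
  age <- floor(dat$age)

  out <- tibble::tibble(child_id = dat$child_id)
  for (i in seq_len(nrow(table$macro))) {
    rule <- table$macro[i, ]
    # age-banded rules (fat) contribute only to children in their band
    if (!(rule$component %in% names(out))) {
      out[[rule$component]] <- NA_real_
    }
    in_band <- age >= rule$age_lo & age <= rule$age_hi
    value <- dat[[rule$source_field]][in_band]
    out[[rule$component]][in_band] <- if (rule$rule == "cap") {
      score_cap(value, rule$hi, rule$max_points)
    } else {
      score_range(value, rule$lo, rule$hi, rule$max_points)
    }
  }
  for (i in seq_len(nrow(rcdqi_food_groups))) {
    fg <- rcdqi_food_groups[i, ]
    target <- lookup_target(fg$component, age, table)
    out[[fg$component]] <-
      score_food_group(dat[[fg$source_field]], target, fg$max_points)
  }
  juice_limit <- lookup_target("excess_juice", age, table)
  out$excess_juice <- score_cap(dat$fruit_juice, juice_limit, 10)
  out$iron <- score_iron(dat$iron, age, table)
  eer <- lookup_target("eer", age, table)
  out$tv_energy <- (score_tv(dat$tv_hours, age, table) +
    score_energy(dat$energy, eer, eer_formula)) / 2
  components <- setdiff(names(out), "child_id")
  out$total <- rowSums(as.matrix(out[components]))
  out
}
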