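#' Assign the study age group
#'
#' Children are analysed in three mutually exclusive age groups:
#' preschoolers (2-5 years), school-age children (6-11 years) and
#' teenagers (12-18 years). Ages are completed integer years; fractional
#' ages are floored with a warning.
#'
#' @param age Integer vector of ages in years, all in `[2, 18]`.
#' @return Character vector with values `"preschool_2_5"`, `"school_6_11"`
#'   or `"teen_12_18"`.
#' @export
#' @examples
#' assign_age_group(c(2, 5, 6, 11, 12, 18))
assign_age_group <- function(age) {
  if (!is.numeric(age) || anyNA(age)) {
    abort("`age` must be numeric and non-missing.")
  }
  if (any(age != floor(age))) {
    warn("Non-integer ages floored to completed years.")
    age <- floor(age)
  }
  if (any(age < 2 | age > 18)) {
    abort("All ages must be between 2 and 18 years.")
  }
  dplyr::case_when(
    age <= 5 ~ "preschool_2_5",
    age <= 11 ~ "school_6_11",
    TRUE ~ "teen_12_18"
  )
}

#' Assign the income group from the poverty-income ratio
#'
#' Households are classified by the income-eligibility cut points of the
#' USDA food assistance programs: low income at PIR <= 1.85 (eligible),
#' high income at PIR >= 3.5, medium otherwise. PIR values above 5.0 are
#' truncated to 5.0 (the survey's top-coding) with a warning.
#'
#' @param pir Numeric vector of poverty-income ratios, non-negative.
#' @return Character vector with values `"low"`, `"medium"`, `"high"`.
#' @export
#' @examples
#' assign_income_group(c(0.9, 1.85, 2.5, 3.5, 5))
assign_income_group <- function(pir) {
  if (!is.numeric(pir) || anyNA(pir)) {
    abort("`pir` must be numeric and non-missing.")
  }
  if (any(pir < 0)) {
    abort("`pir` must be non-negative.")
  }
  if (any(pir > 5)) {
    warn("PIR values above 5.0 truncated to 5.0.")
    pir <- pmin(pir, 5)
  }
  dplyr::case_when(
    pir <= 1.85 ~ "low",
    pir >= 3.5 ~ "high",
    TRUE ~ "medium"
  )
}

# Raw survey race/ethnicity categories and their analytic grouping,
# chosen to reflect cultural eating patterns.
ethnicity_map <- c(
  "mexican american" = "hispanic_other",
  "other hispanic" = "hispanic_other",
  "american indian or alaskan native" = "hispanic_other",
  "asian" = "hispanic_other",
  "native hawaiian or pacific islander" = "hispanic_other",
  "other non-hispanic" = "hispanic_other",
  "other/multiethnic" = "hispanic_other",
  "white" = "nonhispanic_white",
  "black or african american" = "nonhispanic_black"
)

#' Recode raw race/ethnicity categories into three analytic groups
#'
#' Mexican American, other Hispanic and the remaining non-white/non-black
#' categories are pooled as `"hispanic_other"`; white maps to
#' `"nonhispanic_white"` and black or African American to
#' `"nonhispanic_black"`. Matching is case-insensitive.
#'
#' @param ethnicity_raw Character vector of raw survey categories.
#' @return Character vector of `"hispanic_other"`, `"nonhispanic_white"`,
#'   `"nonhispanic_black"`.
#' @export
#' @examples
#' recode_ethnicity(c("Mexican American", "white", "black or African American"))
recode_ethnicity <- function(ethnicity_raw) {
  key <- tolower(trimws(as.character(ethnicity_raw)))
  out <- unname(ethnicity_map[key])
  if (anyNA(out)) {
    bad <- unique(ethnicity_raw[is.na(out)])
    abort(paste0(
      "Unknown ethnicity categories: ",
      paste(sQuote(bad), collapse = ", ")
    ))
  }
  out
}

#' Average the recall days of one child into a usual intake
#'
#' The usual intake is the field-wise arithmetic mean of the child's
#' available 24-hour recall days. All rows must belong to the same child.
#'
#' @param records A data frame of daily intake rows for one child, with
#'   columns `child_id`, `day` and the intake amount fields.
#' @return A one-row tibble with the averaged amount fields and
#'   `n_days_used`.
#' @seealso [average_intake()] for the whole-dataset version.
#' @export
average_days <- function(records) {
  records <- tibble::as_tibble(records)
  if (nrow(records) == 0) {
    abort("`records` must contain at least one daily intake row.")
  }
  if (length(unique(records$child_id)) != 1L) {
    abort("All records passed to `average_days()` must share one child_id.")
  }
  cols <- intersect(intake_amount_cols, names(records))
  out <- dplyr::summarise(
    records,
    dplyr::across(dplyr::all_of(cols), mean),
    .by = "child_id"
  )
  out$n_days_used <- nrow(records)
  out
}

#' Two-day average intakes for every child in a dataset
#'
#' @param intake A data frame of daily intake rows (all children).
#' @return A tibble with one row per child: averaged amount fields and
#'   `n_days_used`.
#' @export
average_intake <- function(intake) {
  intake <- tibble::as_tibble(intake)
  cols <- intersect(intake_amount_cols, names(intake))
  dplyr::summarise(
    intake,
    dplyr::across(dplyr::all_of(cols), mean),
    n_days_used = dplyr::n(),
    .by = "child_id"
  )
}

#' Express an intake amount as a density per 1000 kcal
#'
#' @param amount Numeric vector of serving amounts (cup/oz equivalents or
#'   grams per day).
#' @param energy Numeric vector of energy intakes in kcal, strictly
#'   positive.
#' @return `amount * 1000 / energy`, in serving units per 1000 kcal.
#' @export
#' @examples
#' density_per_1000kcal(1.6, 2000)
density_per_1000kcal <- function(amount, energy) {
  if (any(!is.finite(energy)) || any(energy <= 0)) {
    abort("`energy` must be finite and strictly positive.")
  }
  if (any(amount < 0)) {
    abort("`amount` must be non-negative.")
  }
  amount * 1000 / energy
}

#' Validate a table of daily or averaged intakes
#'
#' Checks the schema invariants: all amounts non-negative, energy strictly
#' positive, whole fruit within total fruit and whole grains within total
#' grains (to numerical tolerance), percentage-of-energy fields in
#' `[0, 100]`.
#'
#' @param intake A data frame of intake rows.
#' @param tol Numerical tolerance for the subset constraints.
#' @return `intake`, invisibly, if valid; otherwise an error.
#' @export
validate_intake <- function(intake, tol = 1e-8) {
  cols <- intersect(intake_amount_cols, names(intake))
  missing_cols <- setdiff(intake_amount_cols, names(intake))
  if (length(missing_cols) > 0) {
    abort(paste0(
      "Intake table is missing columns: ",
      paste(missing_cols, collapse = ", ")
    ))
  }
  for (col in cols) {
    v <- intake[[col]]
    if (!is.numeric(v) || anyNA(v)) {
      abort(paste0("Intake column `", col, "` must be numeric, no missing values."))
    }
    if (any(v < 0)) {
      abort(paste0("Intake column `", col, "` contains negative values."))
    }
  }
  if (any(intake$energy <= 0)) {
    abort("`energy` must be strictly positive for every record.")
  }
  if (any(intake$whole_fruit > intake$total_fruit + tol)) {
    abort("`whole_fruit` exceeds `total_fruit` for some records.")
  }
  if (any(intake$whole_grains > intake$total_grains + tol)) {
    abort("`whole_grains` exceeds `total_grains` for some records.")
  }
  for (col in intake_pct_cols) {
    if (any(intake[[col]] > 100)) {
      abort(paste0("Percentage column `", col, "` exceeds 100."))
    }
  }
  invisible(intake)
}

#' Build child profiles from a raw demographics table
#'
#' Adds the three analytic strata (age group, ethnic group, income group)
#' to a table of per-child demographics. Every child receives exactly one
#' level of each stratum.
#'
#' @param children A data frame with columns `child_id`, `age`, `sex`,
#'   `ethnicity_raw`, `pir` and `tv_hours` (`NA` = not reported).
#' @return A tibble with the input columns plus `age_group`,
#'   `ethnic_group` and `income_group`.
#' @export
child_profiles <- function(children) {
  children <- tibble::as_tibble(children)
  needed <- c("child_id", "age", "sex", "ethnicity_raw", "pir", "tv_hours")
  missing_cols <- setdiff(needed, names(children))
  if (length(missing_cols) > 0) {
    abort(paste0(
      "Children table is missing columns: ",
      paste(missing_cols, collapse = ", ")
    ))
  }
  if (anyDuplicated(children$child_id)) {
    abort("Duplicate child_id in children table.")
  }
  if (!all(children$sex %in% c("male", "female"))) {
    abort("`sex` must be \"male\" or \"female\".")
  }
  if (any(!is.na(children$tv_hours) & children$tv_hours < 0)) {
    abort("`tv_hours` must be non-negative where reported.")
  }
  dplyr::mutate(
    children,
    age = floor(.data$age),
    age_group = assign_age_group(.data$age),
    ethnic_group = recode_ethnicity(.data$ethnicity_raw),
    income_group = assign_income_group(.data$pir)
  )
}

#' Read the per-child demographics CSV
#'
#' @param path Path to `children.csv` (columns `child_id`, `age`, `sex`,
#'   `ethnicity_raw`, `pir`, `tv_hours`; empty cell = missing TV hours).
#' @return A tibble of child profiles (see [child_profiles()]).
#' @export
read_children <- function(path) {
  children <- readr::read_csv(
    path,
    col_types = readr::cols(
      child_id = readr::col_character(),
      age = readr::col_double(),
      sex = readr::col_character(),
      ethnicity_raw = readr::col_character(),
      pir = readr::col_double(),
      tv_hours = readr::col_double()
    )
  )
  child_profiles(children)
}

#' Read the per-child-per-day intake CSV
#'
#' Children with fewer than two recall days are excluded by default,
#' matching the study inclusion rule; set `keep_single_day = TRUE` for
#' sensitivity runs.
#'
#' @param path Path to `intake.csv` (one row per child-day).
#' @param keep_single_day Keep children with a single recall day?
#' @return A validated tibble of daily intakes.
#' @export
read_intake <- function(path, keep_single_day = FALSE) {
  intake <- readr::read_csv(
    path,
    col_types = readr::cols(
      child_id = readr::col_character(),
      day = readr::col_integer(),
      .default = readr::col_double()
    )
  )
  missing_cols <- setdiff(c("child_id", "day", intake_amount_cols), names(intake))
  if (length(missing_cols) > 0) {
    abort(paste0(
      "Intake file is missing columns: ",
      paste(missing_cols, collapse = ", ")
    ))
  }
  if (!keep_single_day) {
    days <- dplyr::count(intake, .data$child_id)
    drop <- days$child_id[days$n < 2]
    if (length(drop) > 0) {
      inform(paste0(
        length(drop),
        " children with fewer than 2 recall days excluded."
      ))
      intake <- dplyr::filter(intake, !(.data$child_id %in% drop))
    }
  }
  validate_intake(intake)
  tibble::as_tibble(intake)
}
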