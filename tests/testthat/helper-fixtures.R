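# In-code fixtures: one-row intake and profile builders with valid
# defaults, overridable per test.

make_usual <- function(..., child_id = "c1") {
  defaults <- tibble::tibble(
    child_id = child_id,
    energy = 1500,
    total_fruit = 0.9, whole_fruit = 0.4, fruit_juice = 4,
    total_veg = 0.8, dgo_veg_legumes = 0.2,
    total_grains = 4, whole_grains = 0.8,
    dairy = 1.8, meat_beans = 2.2, oils = 10,
    sat_fat_pct = 11, sodium = 2.4, sofaas_pct = 32,
    added_sugar_pct = 14, total_fat_pct = 32,
    linoleic_pct = 6, linolenic_pct = 0.7,
    dha_epa_pct_of_ala = 4, iron = 11
  )
  overrides <- list(...)
  for (nm in names(overrides)) defaults[[nm]] <- overrides[[nm]]
  defaults
}

make_profile <- function(..., child_id = "c1") {
  defaults <- tibble::tibble(
    child_id = child_id, age = 9, sex = "female",
    ethnicity_raw = "white", pir = 2.5, tv_hours = 1.5
  )
  overrides <- list(...)
  for (nm in names(overrides)) defaults[[nm]] <- overrides[[nm]]
  child_profiles(defaults)
}

# A diet at or beyond every HEI-2005 full-score standard (per 1000 kcal,
# at 1000 kcal so densities equal amounts) and at/below all moderation
# full-score bounds.
hei_perfect_usual <- function(child_id = "c1") {
  make_usual(
    child_id = child_id,
    energy = 1000, total_fruit = 0.8, whole_fruit = 0.4,
    total_veg = 1.1, dgo_veg_legumes = 0.4,
    total_grains = 3, whole_grains = 1.5, dairy = 1.3,
    meat_beans = 2.5, oils = 12,
    sat_fat_pct = 7, sodium = 0.7, sofaas_pct = 20
  )
}

# A diet meeting every RC-DQI target for a given age (table_b).
rcdqi_perfect_usual <- function(age, child_id = "c1") {
  tbl <- rcdqi_targets("table_b")
  make_usual(
    child_id = child_id,
    energy = lookup_target("eer", age, tbl),
    total_grains = lookup_target("total_grains", age, tbl),
    whole_grains = lookup_target("whole_grains", age, tbl),
    total_fruit = lookup_target("fruit", age, tbl),
    whole_fruit = lookup_target("fruit", age, tbl) / 2,
    total_veg = lookup_target("vegetable", age, tbl),
    dairy = lookup_target("dairy", age, tbl),
    fruit_juice = lookup_target("excess_juice", age, tbl),
    added_sugar_pct = 10, total_fat_pct = if (age <= 3) 35 else 30,
    linoleic_pct = 7, linolenic_pct = 0.9, dha_epa_pct_of_ala = 5,
    iron = 20
  )
}

# Zero consumption of the five comparable food groups; otherwise valid.
five_group_zero_usual <- function(child_id = "c1") {
  make_usual(
    child_id = child_id,
    total_fruit = 0, whole_fruit = 0, total_veg = 0,
    dgo_veg_legumes = 0, total_grains = 0, whole_grains = 0, dairy = 0
  )
}

intake_cols <- setdiff(names(make_usual()), "child_id")

# Independent sum-formula Pearson oracle (no call to stats::cor).
pearson_oracle <- function(x, y) {
  n <- length(x)
  num <- n * sum(x * y) - sum(x) * sum(y)
  den <- sqrt(n * sum(x^2) - sum(x)^2) * sqrt(n * sum(y^2) - sum(y)^2)
  num / den
}

# Independent piecewise-linear interpolation oracle for prorated scores.
prorate_oracle <- function(x, x_zero, x_full, max_points) {
  lo <- min(x_zero, x_full)
  hi <- max(x_zero, x_full)
  stats::approx(
    x = c(x_zero, x_full), y = c(0, max_points),
    xout = pmin(hi, pmax(lo, x))
  )$y
}
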