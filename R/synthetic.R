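default_food_groups <- function() {
  # Per-child mean consumption for consumers. `basis = "density"` groups
  # are parameterised per 1000 kcal and scale with the child's energy;
  # `per_day` groups (juice) are absolute daily amounts. `p_zero` is the
  # probability that a child never consumes the group (zero on both
  # recall days); `lambda` is the loading of the shared latent
  # diet-quality factor on the log-mean.
  tibble::tibble(
    group = c(
      "total_fruit", "fruit_juice", "total_veg", "dgo_veg_legumes",
      "total_grains", "dairy", "meat_beans", "oils", "sodium"
    ),
    basis = c(
      "density", "per_day", "density", "density",
      "density", "density", "density", "density", "density"
    ),
    mean = c(0.55, 6.0, 0.55, 0.12, 3.1, 1.05, 1.45, 8.5, 1.55),
    shape = c(1.2, 1.5, 1.8, 0.9, 4.0, 2.0, 3.0, 3.0, 12.0),
    p_zero = c(0.10, 0.30, 0.04, 0.35, 0.01, 0.03, 0.02, 0.02, 0.0),
    lambda = c(0.40, -0.15, 0.35, 0.45, 0.20, 0.30, 0.10, 0.05, -0.05)
  )
}

default_pct_fields <- function() {
  # Percent-of-energy fields: truncated-normal per child, with a latent
  # quality shift (negative for the moderation-type quantities).
  tibble::tibble(
    field = c(
      "sat_fat_pct", "sofaas_pct", "added_sugar_pct", "total_fat_pct",
      "linoleic_pct", "linolenic_pct"
    ),
    mean = c(11, 35, 16, 33, 6.0, 0.65),
    sd = c(2.5, 8, 6, 5, 1.5, 0.20),
    z_shift = c(-0.8, -4, -3, -0.5, 0.2, 0.05),
    lower = c(0, 0, 0, 5, 0.2, 0.02),
    upper = c(40, 95, 80, 65, 18, 3)
  )
}

#' Configure the synthetic NHANES-like generator
#'
#' Builds a configuration for [simulate_children()]. The defaults emulate
#' the structure of a national two-day-recall sample of children 2-18:
#' age groups in the study proportions 1405 : 1586 : 2945
#' (preschool : school : teen), zero-inflated gamma food-group amounts
#' with a shared standard-normal latent diet-quality factor `z` (loading
#' `lambda` per group induces weak positive inter-component correlation),
#' lognormal day-to-day variation, energy centred on the age-indexed EER,
#' and TV hours with a missingness rate.
#'
#' @param n_children Number of children to simulate.
#' @param seed Integer seed; the run is fully determined by it.
#' @param age_group_props Proportions of the three age groups (summing
#'   to 1).
#' @param ethnicity_probs Named probabilities over the raw survey
#'   race/ethnicity categories.
#' @param food_groups Tibble of per-group consumption parameters (see
#'   the default for the columns).
#' @param pct_fields Tibble of truncated-normal parameters for the
#'   percent-of-energy fields.
#' @param day_cv Within-person day-to-day coefficient of variation of
#'   amounts (lognormal).
#' @param energy_sigma Lognormal spread of a child's mean energy about
#'   the age EER.
#' @param whole_fruit_beta,whole_grain_beta Beta parameters of the whole
#'   fraction within total fruit / total grains.
#' @param p_zero_whole_grains Probability that a grain-consuming child
#'   eats no whole grains.
#' @param pir_shape,pir_scale Gamma parameters of the poverty-income
#'   ratio (truncated at 5).
#' @param tv_mean,tv_shape Gamma parameters of daily TV hours.
#' @param tv_missing_rate Probability that TV hours are unreported.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_children = 1000,
                       seed = 1L,
                       age_group_props = c(
                         preschool_2_5 = 1405, school_6_11 = 1586,
                         teen_12_18 = 2945
                       ) / 5936,
                       ethnicity_probs = c(
                         "Mexican American" = 0.30,
                         "other Hispanic" = 0.06,
                         "white" = 0.29,
                         "black or African American" = 0.28,
                         "Asian" = 0.03,
                         "American Indian or Alaskan Native" = 0.02,
                         "Native Hawaiian or Pacific Islander" = 0.01,
                         "other non-Hispanic" = 0.01
                       ),
                       food_groups = default_food_groups(),
                       pct_fields = default_pct_fields(),
                       day_cv = 0.35,
                       energy_sigma = 0.20,
                       whole_fruit_beta = c(2, 2),
                       whole_grain_beta = c(1.5, 7),
                       p_zero_whole_grains = 0.22,
                       pir_shape = 2.0,
                       pir_scale = 1.25,
                       tv_mean = 2.6,
                       tv_shape = 3.0,
                       tv_missing_rate = 0.08) {
  config <- list(
    n_children = as.integer(n_children),
    seed = as.integer(seed),
    age_group_props = age_group_props,
    ethnicity_probs = ethnicity_probs,
    food_groups = food_groups,
    pct_fields = pct_fields,
    day_cv = day_cv,
    energy_sigma = energy_sigma,
    whole_fruit_beta = whole_fruit_beta,
    whole_grain_beta = whole_grain_beta,
    p_zero_whole_grains = p_zero_whole_grains,
    pir_shape = pir_shape,
    pir_scale = pir_scale,
    tv_mean = tv_mean,
    tv_shape = tv_shape,
    tv_missing_rate = tv_missing_rate
  )
  validate_sim_config(config)
  structure(config, class = "sim_config")
}

validate_sim_config <- function(config) {
  if (config$n_children < 1) {
    abort("`n_children` must be at least 1.")
  }
  if (abs(sum(config$age_group_props) - 1) > 1e-8 ||
    any(config$age_group_props < 0)) {
    abort("`age_group_props` must be non-negative and sum to 1.")
  }
  if (abs(sum(config$ethnicity_probs) - 1) > 1e-8 ||
    any(config$ethnicity_probs < 0)) {
    abort("`ethnicity_probs` must be non-negative and sum to 1.")
  }
  fg <- config$food_groups
  if (any(fg$p_zero < 0 | fg$p_zero > 1)) {
    abort("Food-group `p_zero` must lie in [0, 1].")
  }
  if (any(fg$mean <= 0) || any(fg$shape <= 0)) {
    abort("Food-group `mean` and `shape` must be positive.")
  }
  if (config$day_cv < 0) {
    abort("`day_cv` must be non-negative.")
  }
  invisible(config)
}

#' Study-shaped generator preset
#'
#' The [sim_config()] defaults at the study's sample size: N = 5,936
#' children with the age groups in proportion 1405 : 1586 : 2945,
#' moderate zero-inflation for whole grains and fruit juice, and latent
#' loadings that place the within-index score correlations in the weak
#' positive range.
#'
#' @param seed Integer seed.
#' @return A `sim_config`.
#' @export
preset_study_shape <- function(seed = 1L) {
  sim_config(n_children = 5936, seed = seed)
}

# mean-1 lognormal day-to-day noise at a given coefficient of variation
day_noise <- function(n, cv) {
  if (cv == 0) {
    return(rep(1, n))
  }
  sdlog <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Simulate an NHANES-like child dietary dataset
#'
#' Draws `n_children` child profiles and exactly two daily intake
#' records per child. Food-group amounts are zero-inflated gamma: each
#' child is a never-consumer of a group with probability `p_zero`;
#' consumers get a gamma-distributed personal mean density whose
#' log-mean is shifted by `lambda * z` for a shared latent diet-quality
#' factor `z ~ N(0, 1)`, then day-level amounts multiply in lognormal
#' noise with the configured day-to-day CV. Energy is lognormal about
#' the age-indexed EER. All intake-schema invariants hold by
#' construction (non-negative amounts, whole within total, positive
#' energy).
#'
#' @param config A [sim_config()].
#' @return A list with `children` (one row per child) and `intake` (two
#'   rows per child), both tibbles in the package's input schemas.
#' @export
#' @examples
#' sim <- simulate_children(sim_config(n_children = 50, seed = 7))
#' head(sim$intake)
simulate_children <- function(config = sim_config()) {
  validate_sim_config(config)
  set.seed(config$seed)
  n <- config$n_children

  group_ranges <- list(
    preschool_2_5 = 2:5, school_6_11 = 6:11, teen_12_18 = 12:18
  )
  grp <- sample(names(group_ranges), n, replace = TRUE,
    prob = config$age_group_props)
  age <- vapply(grp, function(g) {
    r <- group_ranges[[g]]
    r[sample.int(length(r), 1)]
  }, numeric(1))
  sex <- sample(c("male", "female"), n, replace = TRUE)
  ethnicity_raw <- sample(names(config$ethnicity_probs), n,
    replace = TRUE, prob = config$ethnicity_probs)
  pir <- pmin(5, rgamma(n, shape = config$pir_shape,
    scale = config$pir_scale))
  tv_hours <- rgamma(n, shape = config$tv_shape,
    scale = config$tv_mean / config$tv_shape)
  tv_hours[runif(n) < config$tv_missing_rate] <- NA_real_

  children <- tibble::tibble(
    child_id = sprintf("c%05d", seq_len(n)),
    age = age,
    sex = sex,
    ethnicity_raw = ethnicity_raw,
    pir = round(pir, 2),
    tv_hours = round(tv_hours, 1)
  )

  z <- rnorm(n)

  # energy anchored on the age-indexed EER (sedentary pattern)
  eer <- lookup_target("eer", age, rcdqi_targets("table_b"))
  energy_mean <- eer * rlnorm(n,
    meanlog = -config$energy_sigma^2 / 2, sdlog = config$energy_sigma
  )
  long <- tibble::tibble(
    child_id = rep(children$child_id, each = 2),
    day = rep(1:2, n),
    idx = rep(seq_len(n), each = 2)
  )
  m <- nrow(long)
  energy <- energy_mean[long$idx] * day_noise(m, config$day_cv / 2)

  amounts <- list(energy = energy)
  for (i in seq_len(nrow(config$food_groups))) {
    fg <- config$food_groups[i, ]
    consumer <- rbinom(n, 1, 1 - fg$p_zero) == 1
    child_mean <- fg$mean * exp(fg$lambda * z - fg$lambda^2 / 2)
    base <- rgamma(n, shape = fg$shape, scale = child_mean / fg$shape)
    base[!consumer] <- 0
    per_day <- base[long$idx] * day_noise(m, config$day_cv)
    if (fg$basis == "density") {
      per_day <- per_day * energy / 1000
    }
    amounts[[fg$group]] <- per_day
  }

  wf_frac <- stats::rbeta(n, config$whole_fruit_beta[1],
    config$whole_fruit_beta[2])
  amounts$whole_fruit <- amounts$total_fruit * wf_frac[long$idx]
  wg_consumer <- rbinom(n, 1, 1 - config$p_zero_whole_grains)
  wg_frac <- stats::rbeta(n, config$whole_grain_beta[1],
    config$whole_grain_beta[2]) * wg_consumer
  amounts$whole_grains <- amounts$total_grains * wg_frac[long$idx]

  for (i in seq_len(nrow(config$pct_fields))) {
    pf <- config$pct_fields[i, ]
    child_val <- pmin(pf$upper, pmax(pf$lower,
      rnorm(n, mean = pf$mean + pf$z_shift * z, sd = pf$sd)
    ))
    amounts[[pf$field]] <- pmin(pf$upper, pmax(pf$lower,
      child_val[long$idx] * day_noise(m, config$day_cv / 4)
    ))
  }

  # DHA+EPA as a percentage of alpha-linolenic acid intake; long-tailed
  dha_child <- rgamma(n, shape = 1.2, scale = 6 / 1.2)
  amounts$dha_epa_pct_of_ala <- dha_child[long$idx] *
    day_noise(m, config$day_cv / 2)

  # iron (mg/day), increasing with age
  iron_child <- rlnorm(n, meanlog = log(9 + 0.4 * age), sdlog = 0.3)
  amounts$iron <- iron_child[long$idx] * day_noise(m, config$day_cv / 2)

  intake <- tibble::tibble(child_id = long$child_id, day = long$day)
  for (col in intake_amount_cols) {
    intake[[col]] <- amounts[[col]]
  }
  validate_intake(intake)
  list(children = children, intake = intake)
}
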