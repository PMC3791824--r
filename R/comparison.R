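# The five recommendations present in both indexes, in report order.
comparable_components <- c(
  "dairy", "fruit", "vegetables", "total_grains", "whole_grains"
)

#' Rescale the five comparable components to 0-5 points
#'
#' Both indexes score dairy, fruit, vegetables, total grains and whole
#' grains, but with different maxima. To compare them directly every
#' component is brought to a 0-5 scale: the HEI milk score and the
#' RC-DQI fruit, vegetable and dairy scores (maximum 10) are divided by
#' two; the grain components (maximum 5 in both indexes) are unchanged.
#' The subscore is the sum of the five rescaled components, 0-25 points.
#'
#' HEI fruits are represented by the total-fruit component
#' (juice-inclusive) and vegetables by total vegetables, the indexes'
#' top-level groups.
#'
#' @param hei HEI-2005 scores from [score_hei()].
#' @param rcdqi RC-DQI scores from [score_rcdqi()].
#' @return A tibble with one row per child and index: `child_id`,
#'   `index` (`"HEI2005"` / `"RCDQI"`), the five components (each 0-5)
#'   and `subscore` (0-25).
#' @export
rescale_components <- function(hei, rcdqi) {
  hei_part <- tibble::tibble(
    child_id = hei$child_id,
    index = "HEI2005",
    dairy = hei$milk / 2,
    fruit = hei$total_fruit,
    vegetables = hei$total_veg,
    total_grains = hei$total_grains,
    whole_grains = hei$whole_grains
  )
  rcdqi_part <- tibble::tibble(
    child_id = rcdqi$child_id,
    index = "RCDQI",
    dairy = rcdqi$dairy / 2,
    fruit = rcdqi$fruit / 2,
    vegetables = rcdqi$vegetable / 2,
    total_grains = rcdqi$total_grains,
    whole_grains = rcdqi$whole_grains
  )
  out <- dplyr::bind_rows(hei_part, rcdqi_part)
  out$subscore <- rowSums(as.matrix(out[comparable_components]))
  out
}

# Pearson r with a two-sided t-test on n - 2 df; returns NA when either
# column is constant (r undefined, reported as missing rather than 0).
pearson_with_p <- function(x, y) {
  n <- length(x)
  if (n < 3 || stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(r = NA_real_, p = NA_real_, n = n))
  }
  r <- cor(x, y)
  if (abs(r) >= 1) {
    p <- 0
  } else {
    t <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * pt(-abs(t), df = n - 2)
  }
  list(r = r, p = p, n = n)
}

p_flag <- function(p) {
  dplyr::case_when(
    is.na(p) ~ NA_character_,
    p < 0.01 ~ "p<0.01",
    p < 0.05 ~ "p<0.05",
    TRUE ~ "ns"
  )
}

#' Within-index correlation matrix of the comparable components
#'
#' Pairwise Pearson correlations between the five rescaled components of
#' one index over the children of a stratum, with two-sided significance
#' flags at the 0.05 and 0.01 levels (t-test, n - 2 df). A component
#' that is constant within the stratum yields missing correlations.
#'
#' @param scores A per-child tibble containing `components` columns (one
#'   index's rescaled scores; see [rescale_components()]).
#' @param components Character vector of score columns to correlate.
#' @param stratum Label attached to the output rows.
#' @return A tibble of component pairs (`i <= j`) with `r`, `p_value`,
#'   `p_flag`, `n` and `stratum`.
#' @export
correlation_matrix <- function(scores, components = comparable_components,
                               stratum = "total") {
  scores <- tibble::as_tibble(scores)
  if (nrow(scores) < 3) {
    abort("At least 3 children are needed to correlate scores.")
  }
  pairs <- which(
    upper.tri(diag(length(components)), diag = TRUE),
    arr.ind = TRUE
  )
  rows <- lapply(seq_len(nrow(pairs)), function(k) {
    a <- components[pairs[k, "row"]]
    b <- components[pairs[k, "col"]]
    res <- pearson_with_p(scores[[a]], scores[[b]])
    tibble::tibble(
      component_a = a, component_b = b,
      r = res$r, p_value = res$p, p_flag = p_flag(res$p),
      n = res$n, stratum = stratum
    )
  })
  dplyr::bind_rows(rows)
}

#' Between-index correlations of the comparable components
#'
#' The full 5 x 5 matrix of Pearson correlations between each HEI-2005
#' rescaled component and each RC-DQI rescaled component over the same
#' children, with significance flags as in [correlation_matrix()].
#'
#' @param rescaled Output of [rescale_components()] (both indexes).
#' @param stratum Label attached to the output rows.
#' @return A tibble with `hei_component`, `rcdqi_component`, `r`,
#'   `p_value`, `p_flag`, `n`, `stratum`.
#' @export
cross_index_correlations <- function(rescaled, stratum = "total") {
  hei <- dplyr::filter(rescaled, .data$index == "HEI2005")
  rcd <- dplyr::filter(rescaled, .data$index == "RCDQI")
  both <- dplyr::inner_join(
    hei[, c("child_id", comparable_components)],
    rcd[, c("child_id", comparable_components)],
    by = "child_id", suffix = c("_hei", "_rcdqi")
  )
  if (nrow(both) < 3) {
    abort("At least 3 children scored under both indexes are needed.")
  }
  grid <- expand.grid(
    hei_component = comparable_components,
    rcdqi_component = comparable_components,
    stringsAsFactors = FALSE
  )
  rows <- lapply(seq_len(nrow(grid)), function(k) {
    a <- paste0(grid$hei_component[k], "_hei")
    b <- paste0(grid$rcdqi_component[k], "_rcdqi")
    res <- pearson_with_p(both[[a]], both[[b]])
    tibble::tibble(
      hei_component = grid$hei_component[k],
      rcdqi_component = grid$rcdqi_component[k],
      r = res$r, p_value = res$p, p_flag = p_flag(res$p),
      n = res$n, stratum = stratum
    )
  })
  dplyr::bind_rows(rows)
}

#' Distribution classes of the rescaled scores
#'
#' For each index and component (and the 0-25 subscore), the proportion
#' of children at the minimum possible score (0), strictly between, and
#' at the maximum (5, or 25 for the subscore). Boundary membership is
#' exact up to `tol`. The three proportions sum to 1.
#'
#' @param rescaled Output of [rescale_components()].
#' @param stratum Label attached to the output rows.
#' @param tol Tolerance for boundary classification.
#' @return A tibble with `index`, `component`, `prop_min`, `prop_mid`,
#'   `prop_max`, `n`, `stratum`.
#' @export
distribution_classes <- function(rescaled, stratum = "total", tol = 1e-9) {
  rescaled <- tibble::as_tibble(rescaled)
  if (nrow(rescaled) == 0) {
    abort("Cannot compute distribution classes for an empty stratum.")
  }
  cols <- c(comparable_components, "subscore")
  maxima <- c(rep(5, length(comparable_components)), 25)
  rows <- lapply(split(rescaled, rescaled$index), function(part) {
    dplyr::bind_rows(lapply(seq_along(cols), function(k) {
      x <- part[[cols[k]]]
      at_min <- abs(x) <= tol
      at_max <- abs(x - maxima[k]) <= tol
      tibble::tibble(
        index = part$index[1],
        component = cols[k],
        prop_min = mean(at_min),
        prop_mid = mean(!at_min & !at_max),
        prop_max = mean(at_max),
        n = length(x),
        stratum = stratum
      )
    }))
  })
  dplyr::bind_rows(rows)
}

strata_definitions <- c("age_group", "ethnic_group", "income_group")

#' Full stratified comparison report
#'
#' Runs the comparison for the total sample and stratified by age group,
#' ethnic group and income group: within-index correlation matrices for
#' each index, the between-index correlation matrix, and the
#' distribution classes.
#'
#' @param profiles Child profiles with the stratum columns (see
#'   [child_profiles()]).
#' @param hei HEI-2005 scores from [score_hei()].
#' @param rcdqi RC-DQI scores from [score_rcdqi()].
#' @return A list of tibbles: `within` (with an `index` column), `cross`
#'   and `classes`, each carrying a `stratum` label of the form
#'   `"total"` or `"<variable>=<level>"`.
#' @export
stratified_report <- function(profiles, hei, rcdqi) {
  rescaled <- rescale_components(hei, rcdqi)
  rescaled <- dplyr::left_join(
    rescaled,
    profiles[, c("child_id", strata_definitions)],
    by = "child_id"
  )
  strata <- list(total = rep(TRUE, nrow(rescaled)))
  for (var in strata_definitions) {
    for (level in sort(unique(rescaled[[var]]))) {
      strata[[paste0(var, "=", level)]] <- rescaled[[var]] == level
    }
  }
  within <- list()
  cross <- list()
  classes <- list()
  for (label in names(strata)) {
    part <- rescaled[strata[[label]], ]
    for (idx in c("HEI2005", "RCDQI")) {
      w <- correlation_matrix(
        part[part$index == idx, ],
        stratum = label
      )
      w$index <- idx
      within[[paste(label, idx)]] <- w
    }
    cross[[label]] <- cross_index_correlations(part, stratum = label)
    classes[[label]] <- distribution_classes(part, stratum = label)
  }
  list(
    within = dplyr::bind_rows(within),
    cross = dplyr::bind_rows(cross),
    classes = dplyr::bind_rows(classes)
  )
}
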