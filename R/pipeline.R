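#' Write a simulated dataset to CSV
#'
#' Runs [simulate_children()] and writes `children.csv` and `intake.csv`
#' in the package's input schemas.
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the paths of the written files.
#' @export
dqi_simulate <- function(config = sim_config(), out_dir = ".") {
  sim <- simulate_children(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    children = file.path(out_dir, "children.csv"),
    intake = file.path(out_dir, "intake.csv")
  )
  readr::write_csv(sim$children, paths["children"], na = "")
  readr::write_csv(sim$intake, paths["intake"], na = "")
  inform(paste0(
    "Simulated ", nrow(sim$children), " children (seed ", config$seed,
    ") to ", out_dir
  ))
  invisible(paths)
}

#' Score a dataset under both indexes
#'
#' Loads (or accepts) the demographics and daily-intake tables, averages
#' the recall days, and scores every child under the HEI-2005 and the
#' RC-DQI. Children with fewer than two recall days are excluded unless
#' `keep_single_day = TRUE`. A `weights` column, if present, is ignored
#' with a warning (all analyses are unweighted).
#'
#' @param children Path to `children.csv`, or a tibble.
#' @param intake Path to `intake.csv`, or a tibble of daily rows.
#' @param variant RC-DQI target-table variant.
#' @param eer_formula Energy-score mode (see [score_energy()]).
#' @param keep_single_day Keep children with one recall day?
#' @param out_dir If non-`NULL`, write `hei_scores.csv` and
#'   `rcdqi_scores.csv` there.
#' @return A list with `profiles`, `usual`, `hei` and `rcdqi` tibbles.
#' @export
dqi_score <- function(children, intake,
                      variant = c("table_b", "table_c"),
                      eer_formula = c("proportional", "literal"),
                      keep_single_day = FALSE,
                      out_dir = NULL) {
  variant <- match.arg(variant)
  eer_formula <- match.arg(eer_formula)
  profiles <- if (is.character(children)) {
    read_children(children)
  } else {
    child_profiles(children)
  }
  if ("weights" %in% names(profiles)) {
    warn("A `weights` column was found and ignored: analyses are unweighted.")
  }
  daily <- if (is.character(intake)) {
    read_intake(intake, keep_single_day = keep_single_day)
  } else {
    tbl <- tibble::as_tibble(intake)
    if (!keep_single_day) {
      days <- dplyr::count(tbl, .data$child_id)
      drop <- days$child_id[days$n < 2]
      if (length(drop) > 0) {
        inform(paste0(
          length(drop), " children with fewer than 2 recall days excluded."
        ))
        tbl <- dplyr::filter(tbl, !(.data$child_id %in% drop))
      }
    }
    validate_intake(tbl)
    tbl
  }
  usual <- average_intake(daily)
  hei <- score_hei(usual)
  rcdqi <- score_rcdqi(profiles, usual,
    variant = variant, eer_formula = eer_formula
  )
  inform(paste0(
    "Scored ", nrow(hei), " children (RC-DQI variant ", variant,
    ", EER formula ", eer_formula, ")."
  ))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(hei, file.path(out_dir, "hei_scores.csv"))
    readr::write_csv(rcdqi, file.path(out_dir, "rcdqi_scores.csv"))
  }
  list(profiles = profiles, usual = usual, hei = hei, rcdqi = rcdqi)
}

#' Run the five-component comparison and write the report files
#'
#' Rescales the comparable components, and writes
#' `within_correlations.csv`, `cross_correlations.csv` and
#' `distribution_classes.csv` for the total sample and the age, ethnic
#' and income strata.
#'
#' @param scored Output of [dqi_score()].
#' @param out_dir If non-`NULL`, directory for the report CSVs.
#' @return The [stratified_report()] list, invisibly if writing.
#' @export
dqi_compare <- function(scored, out_dir = NULL) {
  report <- stratified_report(scored$profiles, scored$hei, scored$rcdqi)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(report$within,
      file.path(out_dir, "within_correlations.csv"))
    readr::write_csv(report$cross,
      file.path(out_dir, "cross_correlations.csv"))
    readr::write_csv(report$classes,
      file.path(out_dir, "distribution_classes.csv"))
    inform(paste0("Comparison reports written to ", out_dir))
    return(invisible(report))
  }
  report
}

#' Combined score and comparison report
#'
#' Convenience wrapper: [dqi_score()] then [dqi_compare()], returning
#' everything in one list.
#'
#' @inheritParams dqi_score
#' @param out_dir If non-`NULL`, directory for score and report CSVs.
#' @return A list with the scored tables, the rescaled components and
#'   the stratified report.
#' @export
dqi_report <- function(children, intake,
                       variant = c("table_b", "table_c"),
                       eer_formula = c("proportional", "literal"),
                       keep_single_day = FALSE,
                       out_dir = NULL) {
  scored <- dqi_score(children, intake,
    variant = variant, eer_formula = eer_formula,
    keep_single_day = keep_single_day, out_dir = out_dir
  )
  report <- dqi_compare(scored, out_dir = out_dir)
  c(scored,
    list(
      rescaled = rescale_components(scored$hei, scored$rcdqi),
      report = report
    )
  )
}

#' Plot the distribution classes
#'
#' Stacked-bar summary of the minimum / intermediate / maximum class
#' proportions per component and index, one panel per stratum. Requires
#' ggplot2.
#'
#' @param classes The `classes` tibble of [stratified_report()] (or
#'   [distribution_classes()] output).
#' @return A ggplot object.
#' @export
plot_distribution_classes <- function(classes) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    abort("ggplot2 is required for plotting.")
  }
  long <- tidyr::pivot_longer(
    classes,
    cols = c("prop_min", "prop_mid", "prop_max"),
    names_to = "class", values_to = "proportion"
  )
  long$class <- factor(long$class,
    levels = c("prop_max", "prop_mid", "prop_min"),
    labels = c("at maximum", "intermediate", "at minimum")
  )
  ggplot2::ggplot(
    long,
    ggplot2::aes(x = .data$component, y = .data$proportion,
      fill = .data$class)
  ) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::facet_grid(
      rows = ggplot2::vars(.data$index),
      cols = ggplot2::vars(.data$stratum)
    ) +
    ggplot2::labs(x = NULL, y = "proportion of children", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
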