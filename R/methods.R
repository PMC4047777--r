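#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
print.cea_results <- function(x, ...) {
  cat("<cea_results> ", nrow(x$results), " reported cells (",
    paste(unique(x$results$cancer), collapse = ", "), "; models ",
    paste(range(x$scenarios$model_id), collapse = "-"), ")\n",
    sep = ""
  )
  if (x$baseline_only) cat("  baseline arm only\n")
  print(x$results, n = 10)
  invisible(x)
}

#' Tidy a model-grid result into a long tibble
#'
#' One row per reported cell and metric, convenient for ggplot2 and joins.
#'
#' @param x A `cea_results` object from [run_model_grid()].
#' @param ... Unused.
#' @return A long tibble with columns `cancer`, `model_id`, `ethnicity`,
#'   `age_band`, `metric`, `value`.
#' @export
tidy.cea_results <- function(x, ...) {
  x$results |>
    dplyr::select(-dplyr::any_of("icer_status")) |>
    tidyr::pivot_longer(
      cols = dplyr::where(is.numeric) & !dplyr::any_of("model_id"),
      names_to = "metric", values_to = "value"
    )
}

#' One-row summary of a model-grid run
#'
#' @param x A `cea_results` object.
#' @param ... Unused.
#' @return A one-row tibble: numbers of cancers, models, and cells, the
#'   intervention settings, and (when both arms were run) the ICER range.
#' @export
glance.cea_results <- function(x, ...) {
  out <- tibble(
    n_cancers = length(unique(x$results$cancer)),
    n_models = length(unique(x$results$model_id)),
    n_cells = nrow(x$results),
    effect = x$intervention$effect,
    direct_monthly_cost = x$intervention$direct_monthly_cost,
    discount_rate = x$intervention$discount_rate,
    reference_ethnicity = x$reference_ethnicity
  )
  if (!x$baseline_only) {
    out$icer_min <- min(x$results$icer, na.rm = TRUE)
    out$icer_max <- max(x$results$icer, na.rm = TRUE)
  }
  out
}

#' Plot incremental HALY gains per case across the heterogeneity ladder
#'
#' Shows how the modelled per-case gain moves as ethnic-specific parameter
#' layers are added, by cancer and age band, coloured by ethnicity.
#'
#' @param object A `cea_results` object with both arms.
#' @param metric Column of `object$results` to plot (default
#'   `inc_haly_per_case`).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cea_results <- function(object, metric = "inc_haly_per_case", ...) {
  if (object$baseline_only && metric != "baseline_haly_per_case") {
    metric <- "baseline_haly_per_case"
  }
  ggplot2::ggplot(
    object$results,
    ggplot2::aes(
      x = .data$model_id, y = .data[[metric]],
      colour = .data$ethnicity, group = .data$ethnicity
    )
  ) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_grid(
      rows = ggplot2::vars(.data$cancer),
      cols = ggplot2::vars(.data$age_band),
      scales = "free_y"
    ) +
    ggplot2::labs(
      x = "heterogeneity model", y = metric, colour = "ethnicity"
    ) +
    ggplot2::theme_minimal()
}

#' Plot an ICER sensitivity surface
#'
#' @param sens A [sensitivity_grid()] tibble.
#' @return A ggplot object: ICER against effect size, one line per direct
#'   cost, faceted by ethnicity.
#' @export
plot_sensitivity <- function(sens) {
  ggplot2::ggplot(
    dplyr::filter(sens, .data$icer_status != "undefined"),
    ggplot2::aes(
      x = .data$effect, y = .data$icer,
      colour = factor(.data$direct_cost), group = .data$direct_cost
    )
  ) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(ggplot2::vars(.data$ethnicity)) +
    ggplot2::labs(
      x = "excess-mortality reduction", y = "ICER (NZ$/HALY)",
      colour = "direct $/month"
    ) +
    ggplot2::theme_minimal()
}

#' Format a model-grid result at reporting precision
#'
#' Applies the reporting conventions: HALYs to 2 decimals, percent changes
#' to 1 decimal, relative risks to 2 decimals, ICERs to the nearest 100,
#' per-100,000 gains to the nearest integer. Internal computation is always
#' at full precision; rounding happens only here.
#'
#' @param x A `cea_results` object with both arms.
#' @return A wide tibble, one row per (cancer, model, ethnicity, age band).
#' @export
format_table3 <- function(x) {
  stopifnot(inherits(x, "cea_results"), !x$baseline_only)
  x$results |>
    dplyr::transmute(
      cancer = .data$cancer,
      model = .data$model_id,
      ethnicity = .data$ethnicity,
      age_band = .data$age_band,
      haly_per_100k = round(.data$haly_per_100k),
      baseline_haly_per_case = round(.data$baseline_haly_per_case, 2),
      inc_haly_per_case = round(.data$inc_haly_per_case, 2),
      pct_change = round(.data$pct_change_vs_model1, 1),
      icer = round(.data$icer / 100) * 100,
      rr_per_case = round(.data$rr_per_case, 2),
      rr_per_100k = round(.data$rr_per_100k, 2)
    ) |>
    dplyr::arrange(.data$cancer, .data$ethnicity, .data$age_band, .data$model)
}

#' Write a run's outputs to disk
#'
#' Writes the reporting-precision wide table (`table3.csv`), the
#' full-precision long table (`results_tidy.csv`), and a JSON run log with
#' the seed, intervention settings, a content hash of the results, and
#' package/R versions. Outputs are reproducible bit-for-bit from the same
#' bundle and settings.
#'
#' @param x A `cea_results` object.
#' @param dir Output directory (created if needed).
#' @param sens Optional [sensitivity_grid()] tibble, written as
#'   `sensitivity.csv`.
#' @return `dir`, invisibly.
#' @export
cea_report <- function(x, dir, sens = NULL) {
  stopifnot(inherits(x, "cea_results"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!x$baseline_only) {
    readr::write_csv(format_table3(x), file.path(dir, "table3.csv"), progress = FALSE)
  }
  readr::write_csv(tidy(x), file.path(dir, "results_tidy.csv"), progress = FALSE)
  if (!is.null(sens)) {
    readr::write_csv(sens, file.path(dir, "sensitivity.csv"), progress = FALSE)
  }
  log <- list(
    seed = x$meta$seed,
    generator = x$meta$generator,
    intervention = x$intervention,
    reference_ethnicity = x$reference_ethnicity,
    models = x$scenarios$model_id,
    results_hash = rlang::hash(x$results),
    r_version = as.character(getRversion()),
    package_version = as.character(utils::packageVersion("equicea"))
  )
  jsonlite::write_json(log, file.path(dir, "run_log.json"),
    auto_unbox = TRUE, pretty = TRUE
  )
  invisible(dir)
}
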