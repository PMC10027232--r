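# paired manual-vs-system helpers ------------------------------------------

get_pairs <- function(pairs) {
  nm <- names(pairs)
  man <- if ("manual" %in% nm) "manual" else if ("manual_cm" %in% nm)
    "manual_cm" else NULL
  sys <- if ("system" %in% nm) "system" else if ("system_cm" %in% nm)
    "system_cm" else NULL
  if (is.null(man) || is.null(sys)) {
    abort("paired measurements need `manual`/`system` (or *_cm) columns.")
  }
  if (nrow(pairs) < 1) abort("paired measurements are empty.")
  list(manual = pairs[[man]], system = pairs[[sys]])
}

#' Root mean square error of paired measurements
#'
#' `sqrt(mean((manual - system)^2))`, in the units of the inputs (cm here).
#'
#' @param pairs Data frame with `manual` and `system` columns (or `manual_cm`
#'   / `system_cm`).
#' @return RMSE.
#' @export
rmse <- function(pairs) {
  p <- get_pairs(pairs)
  sqrt(mean((p$manual - p$system)^2))
}

#' Coefficient of determination of paired measurements
#'
#' `1 - sum((manual - system)^2) / sum((manual - mean(manual))^2)`: the
#' fraction of manual-measurement variance explained by the system values.
#' Note this differs from the squared Pearson correlation unless the system
#' values are an ordinary least-squares fit of the manual ones;
#' [eval_report()] reports both.
#'
#' @inheritParams rmse
#' @return R-squared (dimensionless, <= 1).
#' @export
r_squared <- function(pairs) {
  p <- get_pairs(pairs)
  if (length(p$manual) < 2) abort("R-squared needs at least 2 pairs.")
  denom <- sum((p$manual - mean(p$manual))^2)
  if (denom == 0) abort("manual values are all equal; R-squared undefined.")
  1 - sum((p$manual - p$system)^2) / denom
}

#' Per-item relative errors
#'
#' `100 * |manual - system| / manual` per pair, with max/min/mean summaries.
#'
#' @inheritParams rmse
#' @return A list with `percent` (per item), `max`, `min`, `mean`.
#' @export
relative_errors <- function(pairs) {
  p <- get_pairs(pairs)
  if (any(p$manual <= 0)) {
    abort("relative errors need strictly positive manual values.")
  }
  pct <- 100 * abs(p$manual - p$system) / p$manual
  list(percent = pct, max = max(pct), min = min(pct), mean = mean(pct))
}

#' Group means of paired measurements
#'
#' @inheritParams rmse
#' @return A one-row tibble with `manual_mean`, `system_mean` and
#'   `mean_abs_error` (arithmetic means of the manual column, the system
#'   column and the absolute errors).
#' @export
group_summary <- function(pairs) {
  p <- get_pairs(pairs)
  tibble::tibble(manual_mean = mean(p$manual),
                 system_mean = mean(p$system),
                 mean_abs_error = mean(abs(p$manual - p$system)))
}

#' Full evaluation report for manual-vs-system comparisons
#'
#' Computes, overall and per group, the measurement-agreement statistics:
#' R-squared ([r_squared()]), squared Pearson correlation, RMSE, mean
#' absolute error, and the relative-error summary.
#'
#' @inheritParams rmse
#' @param group Optional character vector of grouping column names present
#'   in `pairs` (e.g. `c("date", "group")`).
#' @return An object of class `eval_report`; `tidy()` returns the per-group
#'   table, `glance()` the overall row.
#' @export
eval_report <- function(pairs, group = NULL) {
  pairs <- tibble::as_tibble(pairs)
  summarise_block <- function(df) {
    p <- get_pairs(df)
    re <- relative_errors(df)
    tibble::tibble(
      n = length(p$manual),
      manual_mean = mean(p$manual), system_mean = mean(p$system),
      mae = mean(abs(p$manual - p$system)), rmse = rmse(df),
      r_squared = if (length(p$manual) >= 2 &&
                      sd(p$manual) > 0) r_squared(df) else NA_real_,
      pearson_r2 = if (length(p$manual) >= 2 && sd(p$manual) > 0 &&
                       sd(p$system) > 0)
        cor(p$manual, p$system)^2 else NA_real_,
      rel_err_max = re$max, rel_err_min = re$min, rel_err_mean = re$mean)
  }
  overall <- summarise_block(pairs)
  by_group <- if (!is.null(group)) {
    missing_cols <- setdiff(group, names(pairs))
    if (length(missing_cols) > 0) {
      abort(paste0("grouping column(s) not found: ",
                   paste(missing_cols, collapse = ", ")))
    }
    pairs |>
      dplyr::group_by(dplyr::across(dplyr::all_of(group))) |>
      dplyr::group_modify(~ summarise_block(.x)) |>
      dplyr::ungroup()
  } else {
    NULL
  }
  structure(list(overall = overall, by_group = by_group, pairs = pairs,
                 group = group),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("Evaluation over %d pairs: RMSE %.2f cm, R^2 %.4f (Pearson r^2 %.4f)\n",
              x$overall$n, x$overall$rmse, x$overall$r_squared,
              x$overall$pearson_r2))
  if (!is.null(x$by_group)) {
    cat("Per-group statistics:\n")
    print(x$by_group)
  }
  invisible(x)
}

#' @export
tidy.eval_report <- function(x, ...) {
  if (is.null(x$by_group)) x$overall else x$by_group
}

#' @export
glance.eval_report <- function(x, ...) x$overall

#' Manual-vs-system scatter of an evaluation report
#'
#' @param object An [eval_report()].
#' @param ... Unused.
#' @return A ggplot: system against manual values with the identity line and
#'   an ordinary least-squares fit.
#' @export
autoplot.eval_report <- function(object, ...) {
  p <- get_pairs(object$pairs)
  df <- tibble::tibble(manual = p$manual, system = p$system)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$manual, y = .data$system)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "steelblue") +
    ggplot2::geom_point() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "manual measurement (cm)",
                  y = "system measurement (cm)") +
    ggplot2::theme_minimal()
}

#' Bundled maize plant-height validation table
#'
#' Manual versus LiDAR-derived plant heights for maize variety AD268 at
#' three planting densities (2,500, 4,000 and 5,500 plants per plot area),
#' measured on 2020-08-14 and 2020-08-27 during the jointing stage: 30
#' plants in total, 15 per date. Heights in centimetres.
#'
#' @return A tibble with columns `date`, `variety`, `group` (planting
#'   density), `plant_no`, `manual_cm`, `system_cm`.
#' @export
height_validation <- function() {
  path <- system.file("extdata", "maize_height_validation.csv",
                      package = "phenocloud", mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    date = readr::col_character(),
                    variety = readr::col_character(),
                    group = readr::col_integer(),
                    plant_no = readr::col_integer(),
                    manual_cm = readr::col_double(),
                    system_cm = readr::col_double()))
}
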