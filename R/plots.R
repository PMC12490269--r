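#' @importFrom ggplot2 ggplot aes geom_point geom_line geom_hline geom_tile
#'   scale_x_log10 scale_fill_gradient labs theme_minimal autoplot
NULL

#' Plot a concentration-response curve with its median-effect fit
#'
#' @param data Data frame with `concentration` (µM) and `viability`
#'   (percent) for one treatment; replicate wells are drawn as points.
#' @param fit Optional `median_effect_fit`; when given, the fitted curve
#'   `100 * (1 - fa(D))` is overlaid.
#' @return A ggplot object.
#' @export
plot_dose_response <- function(data, fit = NULL) {
  data <- filter(as_tibble(data), .data$concentration > 0)
  p <- ggplot(data, aes(x = .data$concentration, y = .data$viability)) +
    geom_point(alpha = 0.7) +
    scale_x_log10() +
    labs(x = "concentration (µM)", y = "% viability") +
    theme_minimal()
  if (!is.null(fit)) {
    grid <- exp(seq(log(min(data$concentration)),
                    log(max(data$concentration)), length.out = 100))
    curve <- tibble(concentration = grid,
                    viability = 100 * (1 - predict_fa(fit, grid)))
    p <- p + geom_line(data = curve, color = "firebrick")
  }
  p
}

#' Fa-CI plot of a combination-index profile
#'
#' Combination index against fraction affected, with the additivity line
#' `CI = 1`; points below the line indicate synergism, above antagonism.
#' Clipped points are dropped.
#'
#' @param object A `ci_profile`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.ci_profile <- function(object, ...) {
  d <- filter(as_tibble(object), !.data$clipped)
  ggplot(d, aes(x = .data$fa, y = .data$ci, color = .data$pair)) +
    geom_hline(yintercept = 1, linetype = "dashed") +
    geom_point(size = 2) +
    labs(x = "fraction affected", y = "combination index") +
    theme_minimal()
}

#' Heatmap of a screen matrix
#'
#' Treatments by model lines, colored with the screening convention:
#' darkest red is 0% viability (100% inhibition), white is 100% viability
#' (no inhibition). Cells above 100% are rendered white (and are already
#' flagged upstream by [normalize_viability()]).
#'
#' @param object A `screen_matrix`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.screen_matrix <- function(object, ...) {
  long <- tidyr::pivot_longer(as_tibble(object), -"treatment_id",
                              names_to = "model_id", values_to = "value") |>
    mutate(shown = pmin(.data$value, 100))
  ggplot(long, aes(x = .data$model_id, y = .data$treatment_id,
                   fill = .data$shown)) +
    geom_tile(color = "grey80") +
    scale_fill_gradient(low = "darkred", high = "white",
                        limits = c(0, 100), name = "% viability") +
    labs(x = NULL, y = NULL) +
    theme_minimal()
}

#' Plot tumor growth curves by treatment arm
#'
#' Group mean volume over time with per-animal trajectories underneath.
#'
#' @param study A growth study tibble; volumes added if absent.
#' @return A ggplot object.
#' @export
plot_growth_study <- function(study) {
  if (!"volume" %in% names(study)) study <- add_tumor_volumes(study)
  means <- study |>
    group_by(.data$group, .data$day) |>
    summarise(volume = mean(.data$volume), .groups = "drop")
  ggplot(study, aes(x = .data$day, y = .data$volume, color = .data$group)) +
    geom_line(aes(group = .data$animal_id), alpha = 0.25) +
    geom_line(data = means, linewidth = 1.2) +
    labs(x = "day", y = expression("tumor volume (mm"^3 * ")")) +
    theme_minimal()
}
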