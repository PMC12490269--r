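#' Normalize raw plate absorbance to percent viability
#'
#' Converts raw absorbance wells to percent cell viability relative to the
#' vehicle-control wells of the same model line:
#' `viability = treated / mean(control) * 100`. Control wells therefore
#' average exactly 100%. Values above 100% (wells reading higher than the
#' control mean) are retained and flagged in the `over_control` column
#' rather than clamped.
#'
#' @param records A data frame of plate wells with columns `model_id`,
#'   `treatment_id`, `concentration` (µM, 0 for vehicle), `replicate`,
#'   `absorbance` and logical `is_control`. See [read_plate_csv()].
#'
#' @return A tibble with the input identifier columns plus `viability`
#'   (percent, unbounded above) and `over_control` (logical).
#'
#' @details Normalization is per `model_id`: every model group must contain
#'   at least one control well with positive mean absorbance, otherwise an
#'   error naming the group is raised. Negative absorbance values are
#'   rejected outright.
#'
#' @examples
#' plate <- tibble::tibble(
#'   model_id = "MM-1", treatment_id = c("vehicle", "drugA", "drugA"),
#'   concentration = c(0, 1, 10), replicate = 1L,
#'   absorbance = c(0.5, 0.25, 0.1),
#'   is_control = c(TRUE, FALSE, FALSE)
#' )
#' normalize_viability(plate)
#' @export
normalize_viability <- function(records) {
  records <- as_tibble(records)
  check_columns(records, c(
    "model_id", "treatment_id", "concentration",
    "replicate", "absorbance", "is_control"
  ), "plate records")
  bad <- which(!is.finite(records$absorbance) | records$absorbance < 0)
  if (length(bad) > 0) {
    abort(sprintf(
      "negative or non-finite absorbance in record(s): %s",
      paste(utils::head(bad, 10), collapse = ", ")
    ))
  }
  ctrl <- records |>
    filter(.data$is_control) |>
    group_by(.data$model_id) |>
    summarise(control_mean = mean(.data$absorbance), .groups = "drop")
  all_models <- unique(records$model_id)
  no_ctrl <- setdiff(all_models, ctrl$model_id[ctrl$control_mean > 0])
  if (length(no_ctrl) > 0) {
    abort(sprintf(
      "no control wells with positive mean absorbance for model(s): %s",
      paste(no_ctrl, collapse = ", ")
    ))
  }
  records |>
    left_join(ctrl, by = "model_id") |>
    mutate(
      viability = .data$absorbance / .data$control_mean * 100,
      over_control = .data$viability > 100
    ) |>
    select(-"control_mean")
}

#' Serial-dilution dose ladder anchored at a top concentration
#'
#' Generates the concentration series of an n-point dose–response curve by
#' repeated division of the top dose, the screening design in which the top
#' dose is the drug's clinical peak plasma concentration (C_max).
#'
#' @param top Top concentration in µM (the C_max anchor), > 0.
#' @param n_points Number of points (default 6).
#' @param dilution_factor Fold dilution between successive points, > 1.
#'   Default `sqrt(10)` (half-log steps), so a 6-point ladder spans 2.5
#'   orders of magnitude and contains both `top` and `0.1 * top`.
#'
#' @return Numeric vector of `n_points` doses, decreasing from `top`.
#'
#' @examples
#' make_ladder(10, n_points = 6, dilution_factor = 10)
#' make_ladder(1)
#' @export
make_ladder <- function(top, n_points = 6L, dilution_factor = sqrt(10)) {
  check_number(top, "top", lower = 0, strict_lower = TRUE)
  check_number(n_points, "n_points", lower = 2)
  check_number(dilution_factor, "dilution_factor", lower = 1,
               strict_lower = TRUE)
  top / dilution_factor^(seq_len(n_points) - 1)
}

#' Fit the median-effect concentration-response model
#'
#' Fits the median-effect model `fa / fu = (D / Dm)^m` (with
#' `fa = 1 - viability/100` the fraction of cells affected and
#' `fu = 1 - fa`) by ordinary least squares of `log10(fa/fu)` on `log10(D)`,
#' the classical median-effect plot. The slope is the sigmoidicity `m`
#' and `Dm = 10^(-intercept/m)` is the dose producing 50% effect.
#'
#' @param data A data frame with columns `concentration` (µM) and
#'   `viability` (percent) for a single treatment in a single model line.
#'   Replicates are averaged to one fraction affected per dose before
#'   regression; per-dose SD is retained in the returned object. Zero-dose
#'   (control) rows are dropped.
#' @param clip_eps Fractions affected outside `(0, 1)` — viability at or
#'   above 100% or at or below 0% — are clipped to
#'   `[clip_eps, 1 - clip_eps]` (default 0.005) because the
#'   log-linearization is undefined at the boundary.
#' @param include_clipped Include clipped points in the regression
#'   (default `FALSE`: clipped doses are flagged and excluded).
#'
#' @return An object of class `median_effect_fit`: a list with elements
#'   `Dm`, `m`, `r2`, `n_points_used`, `n_clipped` and a `points` tibble
#'   (dose, mean fa, per-dose sd, clipped flag, used flag). Supports
#'   [predict_fa()], [dose_for_effect()], `tidy()` and `glance()`.
#'
#' @examples
#' doses <- make_ladder(10)
#' fa <- predict_fa(list(Dm = 1, m = 2), doses)
#' fit <- fit_median_effect(
#'   tibble::tibble(concentration = doses, viability = 100 * (1 - fa))
#' )
#' fit$Dm; fit$m
#' @export
fit_median_effect <- function(data, clip_eps = 0.005,
                              include_clipped = FALSE) {
  data <- as_tibble(data)
  check_columns(data, c("concentration", "viability"), "dose-response data")
  check_number(clip_eps, "clip_eps", lower = 0, upper = 0.5,
               strict_lower = TRUE)
  data <- filter(data, .data$concentration > 0)
  if (nrow(data) == 0) abort("no positive-dose points to fit.")
  pts <- data |>
    group_by(dose = .data$concentration) |>
    summarise(
      fa_raw = mean(1 - .data$viability / 100),
      fa_sd = stats::sd(1 - .data$viability / 100),
      n_rep = n(),
      .groups = "drop"
    ) |>
    arrange(.data$dose)
  cl <- clip_fa(pts$fa_raw, clip_eps)
  pts$fa <- cl$fa
  pts$clipped <- cl$clipped
  pts$used <- if (include_clipped) rep(TRUE, nrow(pts)) else !pts$clipped
  use <- pts[pts$used, ]
  if (nrow(use) < 2) {
    abort(sprintf(
      "fewer than 2 usable points after clipping (%d of %d doses clipped).",
      sum(pts$clipped), nrow(pts)
    ))
  }
  x <- log10(use$dose)
  y <- log10(use$fa / (1 - use$fa))
  ls <- stats::lm(y ~ x)
  m <- unname(stats::coef(ls)[2])
  intercept <- unname(stats::coef(ls)[1])
  if (!is.finite(m) || m <= 0) {
    abort(sprintf("median-effect fit degenerate: slope m = %.4g <= 0.", m))
  }
  # direct r2 (summary.lm warns on noiseless, i.e. perfect, fits)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - sum(stats::residuals(ls)^2) / ss_tot else 1
  structure(
    list(
      Dm = 10^(-intercept / m),
      m = m,
      r2 = if (is.finite(r2)) r2 else 1,
      n_points_used = nrow(use),
      n_clipped = sum(pts$clipped),
      clip_eps = clip_eps,
      points = pts
    ),
    class = "median_effect_fit"
  )
}

#' Fit median-effect models for every treatment in every model line
#'
#' Convenience wrapper mapping [fit_median_effect()] over the
#' `(model_id, treatment_id)` groups of a normalized viability table.
#'
#' @param viability Output of [normalize_viability()] (control rows are
#'   ignored).
#' @inheritParams fit_median_effect
#' @return A tibble with one row per group: `model_id`, `treatment_id`,
#'   `Dm`, `m`, `r2`, `n_points_used`, `n_clipped` and a `fit` list-column
#'   holding the full `median_effect_fit` objects.
#' @export
fit_median_effects <- function(viability, clip_eps = 0.005,
                               include_clipped = FALSE) {
  viability <- as_tibble(viability)
  check_columns(viability, c("model_id", "treatment_id", "concentration",
                             "viability"), "viability table")
  if ("is_control" %in% names(viability)) {
    viability <- filter(viability, !.data$is_control)
  }
  viability |>
    tidyr::nest(curve = -c("model_id", "treatment_id")) |>
    mutate(
      fit = purrr::map(.data$curve, fit_median_effect,
                       clip_eps = clip_eps,
                       include_clipped = include_clipped),
      Dm = purrr::map_dbl(.data$fit, "Dm"),
      m = purrr::map_dbl(.data$fit, "m"),
      r2 = purrr::map_dbl(.data$fit, "r2"),
      n_points_used = purrr::map_int(.data$fit, ~ as.integer(.x$n_points_used)),
      n_clipped = purrr::map_int(.data$fit, ~ as.integer(.x$n_clipped))
    ) |>
    select(-"curve")
}

#' Predict fraction affected from a median-effect fit
#'
#' Forward median-effect equation
#' `fa = (D/Dm)^m / (1 + (D/Dm)^m)`; `fa(0) = 0` and `fa` is strictly
#' increasing in dose.
#'
#' @param fit A `median_effect_fit` (or any list with elements `Dm`, `m`).
#' @param dose Dose(s) in µM, >= 0. Vectorized.
#' @return Fraction(s) affected in `[0, 1)`.
#' @examples
#' predict_fa(list(Dm = 1, m = 1), c(0, 1, 3))  # 0, 0.5, 0.75
#' @export
predict_fa <- function(fit, dose) {
  if (!is.numeric(dose) || any(!is.finite(dose)) || any(dose < 0)) {
    abort("`dose` must be finite and >= 0.")
  }
  ratio <- (dose / fit$Dm)^fit$m
  ratio / (1 + ratio)
}

#' @export
print.median_effect_fit <- function(x, ...) {
  cat("Median-effect fit\n")
  cat(sprintf("  Dm = %.4g uM, m = %.4g, r2 = %.4f\n", x$Dm, x$m, x$r2))
  cat(sprintf("  points used: %d (clipped: %d)\n",
              x$n_points_used, x$n_clipped))
  invisible(x)
}
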