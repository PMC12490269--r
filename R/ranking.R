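#' Trapezoidal area under a curve
#'
#' The screening AUC formula: the sum over adjacent points of
#' `dX * (Y1 + Y2) / 2`.
#'
#' @param xs Strictly increasing x coordinates (length >= 2).
#' @param ys Responses (percent viability) at `xs`, same length.
#' @return The trapezoidal AUC.
#' @examples
#' auc_trapezoid(c(0, 1), c(100, 100))  # 100
#' auc_trapezoid(c(0, 1), c(100, 0))    # 50
#' @export
auc_trapezoid <- function(xs, ys) {
  if (!is.numeric(xs) || !is.numeric(ys) || length(xs) != length(ys)) {
    abort("`xs` and `ys` must be numeric vectors of equal length.")
  }
  if (length(xs) < 2) abort("need at least 2 points for a trapezoidal AUC.")
  if (any(diff(xs) <= 0)) abort("`xs` must be strictly increasing.")
  sum(diff(xs) * (utils::head(ys, -1) + utils::tail(ys, -1)) / 2)
}

# AUC of one replicate-averaged curve on the configured dose axis
curve_auc <- function(dose, viability, dose_scale = c("log10", "linear")) {
  dose_scale <- match.arg(dose_scale)
  d <- tibble(dose = dose, viability = viability) |>
    filter(.data$dose > 0) |>
    group_by(.data$dose) |>
    summarise(viability = mean(.data$viability), .groups = "drop") |>
    arrange(.data$dose)
  if (nrow(d) < 2) abort("need >= 2 positive doses for an AUC.")
  xs <- if (dose_scale == "log10") log10(d$dose) else d$dose
  auc_trapezoid(xs, d$viability)
}

#' Bootstrap confidence limits for a dose-response AUC
#'
#' Nonparametric bootstrap over replicate wells within each dose: each
#' resample redraws the replicates per dose with replacement, averages, and
#' recomputes the trapezoidal AUC on the configured dose axis.
#'
#' @param data Data frame with columns `concentration` and `viability`
#'   (replicate wells for one treatment in one model line).
#' @param n_boot Number of resamples (default 1000).
#' @param conf Confidence level (default 0.95).
#' @param dose_scale `"log10"` (default) or `"linear"` x axis.
#' @param seed Integer seed; the resampling is reproducible under it.
#' @return A tibble with `auc`, `lower`, `upper`, `n_boot`, `conf`.
#' @export
auc_bootstrap <- function(data, n_boot = 1000L, conf = 0.95,
                          dose_scale = c("log10", "linear"), seed = 1L) {
  dose_scale <- match.arg(dose_scale)
  data <- as_tibble(data)
  check_columns(data, c("concentration", "viability"), "dose-response data")
  data <- filter(data, .data$concentration > 0)
  groups <- split(data$viability, data$concentration)
  obs <- curve_auc(data$concentration, data$viability, dose_scale)
  boots <- withr::with_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      means <- vapply(groups, function(v) mean(sample(v, replace = TRUE)),
                      numeric(1))
      doses <- as.numeric(names(groups))
      xs <- if (dose_scale == "log10") log10(sort(doses)) else sort(doses)
      auc_trapezoid(xs, means[order(doses)])
    }, numeric(1))
  })
  alpha <- (1 - conf) / 2
  qs <- stats::quantile(boots, c(alpha, 1 - alpha), names = FALSE)
  tibble(auc = obs, lower = qs[1], upper = qs[2],
         n_boot = n_boot, conf = conf)
}

#' Treatments-by-models screen matrix
#'
#' Summarizes a normalized viability table into the matrix behind the
#' screening heatmaps: one row per treatment, one column per model line,
#' cells holding either the percent viability at a fixed-ratio level of the
#' ladder or the AUC over the whole ladder.
#'
#' @param viability Output of [normalize_viability()]; control rows are
#'   ignored.
#' @param level Fixed-ratio level: the dose summarized is
#'   `level * max(dose)` of each treatment's ladder (default 0.1, the
#'   10% C_max level; use 1 for full C_max). Only used for
#'   `metric = "viability"`.
#' @param metric `"viability"` (percent viability at the level dose,
#'   default) or `"auc"` (trapezoidal AUC over the ladder).
#' @param dose_scale AUC x axis, `"log10"` (default) or `"linear"`.
#'
#' @return A tibble of class `screen_matrix`: first column `treatment_id`,
#'   one numeric column per model. No cell may be missing: absent
#'   `(treatment, model)` combinations (or a ladder lacking the level dose)
#'   raise a completeness error listing the offending cells — missing data
#'   are never silently zero.
#' @export
build_screen_matrix <- function(viability, level = 0.1,
                                metric = c("viability", "auc"),
                                dose_scale = c("log10", "linear")) {
  metric <- match.arg(metric)
  dose_scale <- match.arg(dose_scale)
  check_number(level, "level", lower = 0, upper = 1, strict_lower = TRUE)
  viability <- as_tibble(viability)
  check_columns(viability, c("model_id", "treatment_id", "concentration",
                             "viability"), "viability table")
  if ("is_control" %in% names(viability)) {
    viability <- filter(viability, !.data$is_control)
  }
  viability <- filter(viability, .data$concentration > 0)
  if (nrow(viability) == 0) abort("no treatment wells in input.")

  cells <- viability |>
    group_by(.data$treatment_id, .data$model_id) |>
    summarise(
      value = if (metric == "auc") {
        curve_auc(.data$concentration, .data$viability, dose_scale)
      } else {
        top <- max(.data$concentration)
        target <- level * top
        hit <- abs(.data$concentration - target) <= 1e-8 * target
        if (!any(hit)) NA_real_ else mean(.data$viability[hit])
      },
      .groups = "drop"
    )
  missing_cells <- cells |> filter(is.na(.data$value))
  # also require the full treatment x model grid
  grid <- tidyr::expand_grid(
    treatment_id = unique(viability$treatment_id),
    model_id = unique(viability$model_id)
  )
  absent <- dplyr::anti_join(grid, cells, by = c("treatment_id", "model_id"))
  bad <- bind_rows(missing_cells[c("treatment_id", "model_id")], absent)
  if (nrow(bad) > 0) {
    abort(sprintf(
      "screen matrix incomplete; missing/unsummarizable cell(s): %s",
      paste(sprintf("(%s, %s)", bad$treatment_id, bad$model_id),
            collapse = "; ")
    ))
  }
  wide <- tidyr::pivot_wider(cells, names_from = "model_id",
                             values_from = "value") |>
    arrange(.data$treatment_id)
  attr(wide, "level") <- level
  attr(wide, "metric") <- metric
  class(wide) <- c("screen_matrix", class(wide))
  wide
}

#' Rank treatments across model lines
#'
#' Orders treatments by their overall ability to decrease cell viability:
#' ascending cross-model mean of the matrix cells (lower viability or AUC =
#' more effective = rank 1). Ties are broken lexicographically by treatment
#' id and flagged.
#'
#' @param matrix A [build_screen_matrix()] result, or any data frame whose
#'   first column is `treatment_id` and remaining columns are per-model
#'   scores.
#' @return A tibble with `rank`, `treatment_id`, `mean_score`, `tie`
#'   (logical) plus the per-model columns.
#' @export
rank_treatments <- function(matrix) {
  matrix <- as_tibble(matrix)
  check_columns(matrix, "treatment_id", "screen matrix")
  value_cols <- setdiff(names(matrix), "treatment_id")
  if (nrow(matrix) == 0 || length(value_cols) == 0) {
    abort("empty screen matrix.")
  }
  vals <- as.matrix(matrix[value_cols])
  if (any(!is.finite(vals))) abort("screen matrix contains missing cells.")
  out <- matrix |>
    mutate(mean_score = rowMeans(vals)) |>
    arrange(.data$mean_score, .data$treatment_id) |>
    mutate(
      rank = dplyr::row_number(),
      tie = duplicated(.data$mean_score) |
        duplicated(.data$mean_score, fromLast = TRUE)
    ) |>
    select("rank", "treatment_id", "mean_score", "tie",
           all_of(value_cols))
  out
}

#' Write a screen matrix (and optional ranking) to disk
#'
#' The matrix goes to CSV with treatments as rows and models as columns; if
#' `json_path` is given, a companion JSON records the ranking, cross-model
#' means and tie flags.
#'
#' @param matrix A `screen_matrix`.
#' @param path CSV output path.
#' @param json_path Optional JSON output path for the ranking companion.
#' @return `path`, invisibly.
#' @export
write_screen_matrix_csv <- function(matrix, path, json_path = NULL) {
  readr::write_csv(as_tibble(matrix), path)
  if (!is.null(json_path)) {
    ranking <- rank_treatments(matrix)
    jsonlite::write_json(
      list(
        level = attr(matrix, "level"),
        metric = attr(matrix, "metric"),
        ranking = ranking
      ),
      json_path, auto_unbox = TRUE, digits = NA
    )
  }
  invisible(path)
}
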