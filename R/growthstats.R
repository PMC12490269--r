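#' Tumor volume from caliper measurements
#'
#' `volume = length * width^2 / 2`, the standard ellipsoid approximation
#' for subcutaneous tumors measured with calipers.
#'
#' @param length_mm,width_mm Caliper length and width in mm, >= 0.
#'   Vectorized.
#' @return Volume(s) in mm^3.
#' @examples
#' tumor_volume(10, 10)  # 500
#' tumor_volume(8, 5)    # 100
#' @export
tumor_volume <- function(length_mm, width_mm) {
  if (!is.numeric(length_mm) || !is.numeric(width_mm) ||
      any(length_mm < 0) || any(width_mm < 0)) {
    abort("`length_mm` and `width_mm` must be >= 0.")
  }
  length_mm * width_mm^2 / 2
}

#' Add tumor volumes to a growth study table
#'
#' Computes per-measurement volumes via [tumor_volume()]. By convention
#' length >= width; rows violating it are swapped and flagged in the
#' `swapped` column.
#'
#' @param study Data frame with columns `animal_id`, `group`, `day`,
#'   `length_mm`, `width_mm` (see [read_measurements_csv()]).
#' @return The input tibble with `volume` (mm^3) and `swapped` columns.
#' @export
add_tumor_volumes <- function(study) {
  study <- as_tibble(study)
  check_columns(study, c("animal_id", "group", "day", "length_mm",
                         "width_mm"), "growth study")
  swapped <- study$length_mm < study$width_mm
  l <- pmax(study$length_mm, study$width_mm)
  w <- pmin(study$length_mm, study$width_mm)
  study |>
    mutate(
      length_mm = l, width_mm = w, swapped = swapped,
      volume = tumor_volume(l, w)
    )
}

#' Per-animal growth summaries
#'
#' Reduces each animal's volume time series to a single number used as the
#' unit of the randomization test: the trapezoidal AUC of volume over days
#' (default) or the endpoint (last-day) volume.
#'
#' @param study A growth study table; volumes are computed with
#'   [add_tumor_volumes()] if absent.
#' @param stat `"auc"` (default) or `"endpoint"`.
#' @return A tibble with `animal_id`, `group`, `summary`.
#' @export
growth_summaries <- function(study, stat = c("auc", "endpoint")) {
  stat <- match.arg(stat)
  if (!"volume" %in% names(study)) study <- add_tumor_volumes(study)
  study |>
    group_by(.data$animal_id, .data$group) |>
    arrange(.data$day, .by_group = TRUE) |>
    summarise(
      summary = if (stat == "auc") {
        if (n() < 2) abort(sprintf(
          "animal %s has < 2 measurement days; AUC summary undefined.",
          .data$animal_id[1]
        ))
        auc_trapezoid(.data$day, .data$volume)
      } else {
        .data$volume[n()]
      },
      .groups = "drop"
    )
}

#' Randomization test for two tumor growth arms
#'
#' Two-sided permutation test of the difference in group means of a
#' per-animal growth summary under random relabeling of animals between the
#' two arms. When the number of distinct relabelings
#' (`choose(n_a + n_b, n_a)`) is at most `exact_limit` the null
#' distribution is enumerated exhaustively and the p-value is the exact
#' proportion of relabelings with `|mean_a - mean_b|` at least the observed
#' one; otherwise `n_perm` Monte Carlo relabelings are drawn and the
#' add-one correction `p = (b + 1) / (n_perm + 1)` is used.
#'
#' @param study A growth study table (see [add_tumor_volumes()]).
#' @param group_a,group_b The two arm labels to compare.
#' @param stat Per-animal summary, `"auc"` (default) or `"endpoint"`; see
#'   [growth_summaries()].
#' @param n_perm Monte Carlo permutations when enumeration is infeasible
#'   (default 10000; < 100 is an error).
#' @param seed Integer seed for the Monte Carlo draws.
#' @param exact_limit Enumerate exhaustively up to this many relabelings
#'   (default 20000).
#' @return An object of class `randomization_test`: list with `p_value`,
#'   `observed` (mean_a - mean_b), `method` ("exact" or "monte-carlo"),
#'   `n_relabelings`, `stat`, `groups`, `n_a`, `n_b`, `seed`. Supports
#'   `glance()`.
#' @export
randomization_test <- function(study, group_a, group_b,
                               stat = c("auc", "endpoint"),
                               n_perm = 10000L, seed = 1L,
                               exact_limit = 20000L) {
  stat <- match.arg(stat)
  if (n_perm < 100) abort("`n_perm` must be at least 100.")
  sums <- growth_summaries(study, stat = stat)
  xa <- sums$summary[sums$group == group_a]
  xb <- sums$summary[sums$group == group_b]
  if (length(xa) == 0 || length(xb) == 0) {
    abort(sprintf(
      "empty group(s): %s",
      paste(c(group_a, group_b)[c(length(xa) == 0, length(xb) == 0)],
            collapse = ", ")
    ))
  }
  pooled <- c(xa, xb)
  n_a <- length(xa)
  n_tot <- length(pooled)
  observed <- mean(xa) - mean(xb)
  total_mean <- sum(pooled) / n_tot
  # |mean_a - mean_b| is monotone in |sum_a - n_a * total_mean|, so each
  # relabeling only needs the sum of the values assigned to arm A
  abs_diff_from_sum_a <- function(sum_a) {
    abs(sum_a / n_a - (sum(pooled) - sum_a) / (n_tot - n_a))
  }
  n_exact <- choose(n_tot, n_a)
  tol <- 1e-12 * (abs(observed) + stats::sd(pooled) + 1)
  if (n_exact <= exact_limit) {
    idx <- utils::combn(n_tot, n_a)
    sums_a <- colSums(matrix(pooled[idx], nrow = n_a))
    p <- mean(abs_diff_from_sum_a(sums_a) >= abs(observed) - tol)
    method <- "exact"
    n_rel <- n_exact
  } else {
    b <- withr::with_seed(seed, {
      sum(vapply(seq_len(n_perm), function(i) {
        sum_a <- sum(sample(pooled, n_a))
        abs_diff_from_sum_a(sum_a) >= abs(observed) - tol
      }, logical(1)))
    })
    p <- (b + 1) / (n_perm + 1)
    method <- "monte-carlo"
    n_rel <- n_perm
  }
  structure(
    list(
      p_value = p, observed = observed, method = method,
      n_relabelings = n_rel, stat = stat,
      groups = c(group_a, group_b), n_a = n_a, n_b = n_tot - n_a,
      seed = seed
    ),
    class = "randomization_test"
  )
}

#' @export
print.randomization_test <- function(x, ...) {
  cat(sprintf("Randomization test (%s): %s vs %s\n",
              x$stat, x$groups[1], x$groups[2]))
  cat(sprintf("  observed mean difference: %.4g\n", x$observed))
  cat(sprintf("  p = %.4g (%s, %d relabelings)\n",
              x$p_value, x$method, x$n_relabelings))
  invisible(x)
}

#' Bonferroni multiple-comparison adjustment
#'
#' Each p-value is multiplied by the family size and capped at 1.
#'
#' @param p_values P-values in `[0, 1]`.
#' @param family Family size (default `length(p_values)`).
#' @return Adjusted p-values.
#' @examples
#' bonferroni_adjust(c(0.01, 0.03))  # 0.02 0.06
#' @export
bonferroni_adjust <- function(p_values, family = length(p_values)) {
  if (!is.numeric(p_values) || any(!is.finite(p_values)) ||
      any(p_values < 0 | p_values > 1)) {
    abort("`p_values` must lie in [0, 1].")
  }
  check_number(family, "family", lower = 1)
  pmin(p_values * family, 1)
}

#' Pairwise randomization tests against a reference arm
#'
#' Runs [randomization_test()] of every other arm against `reference` and
#' applies the Bonferroni correction across the family of comparisons.
#'
#' @inheritParams randomization_test
#' @param reference The control arm label (default: first group in the
#'   data).
#' @return A tibble with `group`, `observed`, `p_value`, `p_adjusted`,
#'   `method`, `n_relabelings`.
#' @export
growth_tests <- function(study, reference = NULL,
                         stat = c("auc", "endpoint"),
                         n_perm = 10000L, seed = 1L,
                         exact_limit = 20000L) {
  stat <- match.arg(stat)
  study <- as_tibble(study)
  groups <- unique(study$group)
  if (length(groups) < 2) abort("need >= 2 groups for testing.")
  reference <- reference %||% groups[1]
  others <- setdiff(groups, reference)
  tests <- purrr::map(others, function(g) {
    randomization_test(study, g, reference, stat = stat,
                       n_perm = n_perm, seed = seed,
                       exact_limit = exact_limit)
  })
  tibble(
    group = others,
    reference = reference,
    observed = purrr::map_dbl(tests, "observed"),
    p_value = purrr::map_dbl(tests, "p_value"),
    p_adjusted = bonferroni_adjust(purrr::map_dbl(tests, "p_value"),
                                   family = length(others)),
    method = purrr::map_chr(tests, "method"),
    n_relabelings = purrr::map_dbl(tests, "n_relabelings")
  )
}
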