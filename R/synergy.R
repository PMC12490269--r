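#' Fixed-ratio combination design from C_max values
#'
#' Defines a two-drug combination in which each drug is present at the same
#' scale factor times its own clinical C_max, so the molar ratio
#' `cmax_a : cmax_b` is constant while total dose varies (a fixed-ratio
#' design). The screening design evaluates two levels: full C_max
#' (`level = 1`) and 10% C_max (`level = 0.1`).
#'
#' @param drug_a,drug_b Treatment identifiers.
#' @param cmax_a,cmax_b Clinical C_max of each drug in µM, > 0.
#' @param levels Scale factors applied to both C_max values
#'   (default `c(1, 0.1)`), each in `(0, 1]`.
#'
#' @return An object of class `combination_design`: list with the inputs
#'   plus mixing weights `w_a = cmax_a / (cmax_a + cmax_b)`,
#'   `w_b = 1 - w_a` and `total_cmax = cmax_a + cmax_b`. At level `s` the
#'   combination delivers doses `(s * cmax_a, s * cmax_b)`, i.e. total dose
#'   `s * total_cmax` split by the weights.
#' @examples
#' combination_design("cobimetinib", "regorafenib", 0.5, 8)
#' @export
combination_design <- function(drug_a, drug_b, cmax_a, cmax_b,
                               levels = c(1, 0.1)) {
  check_number(cmax_a, "cmax_a", lower = 0, strict_lower = TRUE)
  check_number(cmax_b, "cmax_b", lower = 0, strict_lower = TRUE)
  if (any(levels <= 0 | levels > 1)) {
    abort("`levels` must lie in (0, 1].")
  }
  structure(
    list(
      drug_a = drug_a, drug_b = drug_b,
      cmax_a = cmax_a, cmax_b = cmax_b,
      w_a = cmax_a / (cmax_a + cmax_b),
      w_b = cmax_b / (cmax_a + cmax_b),
      total_cmax = cmax_a + cmax_b,
      levels = levels,
      pair_id = paste(drug_a, drug_b, sep = "+")
    ),
    class = "combination_design"
  )
}

#' @export
print.combination_design <- function(x, ...) {
  cat(sprintf("Fixed-ratio design %s\n", x$pair_id))
  cat(sprintf("  C_max: %.4g + %.4g uM (w_a = %.3f)\n",
              x$cmax_a, x$cmax_b, x$w_a))
  cat(sprintf("  levels: %s\n", paste(x$levels, collapse = ", ")))
  invisible(x)
}

#' Dose of a single agent producing a given effect level
#'
#' Inverts the median-effect model:
#' `Dx = Dm * (fa / (1 - fa))^(1/m)`, so that
#' `predict_fa(fit, Dx) == fa`.
#'
#' @param fit A `median_effect_fit`.
#' @param fa Fraction(s) affected, strictly inside `(0, 1)`. Vectorized.
#' @return Dose(s) in µM.
#' @examples
#' dose_for_effect(list(Dm = 1, m = 1), 0.75)  # 3
#' @export
dose_for_effect <- function(fit, fa) {
  if (!is.numeric(fa) || any(!is.finite(fa)) || any(fa <= 0) ||
      any(fa >= 1)) {
    abort("`fa` must be strictly inside (0, 1).")
  }
  fit$Dm * (fa / (1 - fa))^(1 / fit$m)
}

#' Chou-Talalay combination index
#'
#' For a fixed-ratio combination delivering total dose `D` split into
#' `D1 = w_a * D` and `D2 = w_b * D`, the (mutually exclusive)
#' combination index at effect level `fa` is
#' `CI = D1 / Dx1(fa) + D2 / Dx2(fa)`, with `Dx` the single-agent doses
#' producing `fa` from each drug's median-effect fit. `CI < 1` indicates
#' synergism, `CI = 1` an additive effect and `CI > 1` antagonism.
#'
#' @param fit_a,fit_b Single-agent `median_effect_fit` objects.
#' @param design A [combination_design()] supplying the mixing weights.
#' @param total_dose Total combination dose(s) in µM, > 0.
#' @param fa Observed fraction(s) affected at those doses, in `(0, 1)`.
#' @return Numeric combination index values (vectorized over
#'   `total_dose`/`fa`).
#' @examples
#' a <- list(Dm = 1, m = 1); b <- list(Dm = 2, m = 1)
#' d <- combination_design("A", "B", 1, 2)
#' combination_index(a, b, d, total_dose = 1.5, fa = 0.5)  # 1: additive
#' @export
combination_index <- function(fit_a, fit_b, design, total_dose, fa) {
  if (!is.numeric(total_dose) || any(total_dose <= 0)) {
    abort("`total_dose` must be > 0.")
  }
  if (fit_a$m <= 0 || fit_b$m <= 0) {
    abort("degenerate median-effect fit: m must be > 0.")
  }
  d1 <- design$w_a * total_dose
  d2 <- design$w_b * total_dose
  d1 / dose_for_effect(fit_a, fa) + d2 / dose_for_effect(fit_b, fa)
}

#' Label a combination index value
#'
#' Strictly, `CI < 1` is synergism, `CI = 1` additive and `CI > 1`
#' antagonism; with measurement noise an exact 1 is never observed, so
#' values within `tol` of 1 are reported "additive".
#'
#' @param ci Combination index values, > 0.
#' @param tol Half-width of the additive band (default 0.05).
#' @return Character vector: "synergism", "additive" or "antagonism".
#' @export
ci_label <- function(ci, tol = 0.05) {
  dplyr::case_when(
    abs(ci - 1) <= tol ~ "additive",
    ci < 1 ~ "synergism",
    TRUE ~ "antagonism"
  )
}

#' Combination-index profile along a fixed-ratio dose ladder
#'
#' The Fa-CI analysis: for each dose of a measured fixed-ratio combination
#' curve, the fraction affected is taken from the combination's own
#' viability (`fa = 1 - viability/100`, replicate-averaged) while the
#' iso-effective single-agent doses `Dx` come from the single-agent
#' median-effect fits, giving one `(fa, total_dose, CI)` point per dose.
#'
#' @param combo_data Data frame with columns `concentration` (total
#'   combination dose, µM) and `viability` (percent) for the combination
#'   arm; replicates allowed.
#' @param fit_a,fit_b Single-agent `median_effect_fit` objects.
#' @param design The [combination_design()] of the pair.
#' @param clip_eps Points whose fa falls outside
#'   `[clip_eps, 1 - clip_eps]` are flagged `clipped` and get `ci = NA`
#'   (excluded from interpretation), as in [fit_median_effect()].
#'
#' @return A tibble of class `ci_profile` with columns `pair`, `fa`,
#'   `total_dose`, `ci`, `label`, `clipped`. If every point is clipped the
#'   profile is returned fully flagged with a warning; an input with no
#'   positive-dose points is an error.
#' @export
ci_profile <- function(combo_data, fit_a, fit_b, design, clip_eps = 0.005) {
  combo_data <- as_tibble(combo_data)
  check_columns(combo_data, c("concentration", "viability"),
                "combination curve")
  combo_data <- filter(combo_data, .data$concentration > 0)
  if (nrow(combo_data) == 0) {
    abort("empty combination-index profile: no positive-dose points.")
  }
  pts <- combo_data |>
    group_by(total_dose = .data$concentration) |>
    summarise(fa_raw = mean(1 - .data$viability / 100), .groups = "drop") |>
    arrange(.data$total_dose)
  cl <- clip_fa(pts$fa_raw, clip_eps)
  out <- tibble(
    pair = design$pair_id,
    fa = cl$fa,
    total_dose = pts$total_dose,
    ci = NA_real_,
    label = NA_character_,
    clipped = cl$clipped
  )
  ok <- !out$clipped
  if (!any(ok)) {
    warn("all combination points clipped (fa outside (0,1)); profile is fully flagged.")
  } else {
    out$ci[ok] <- combination_index(fit_a, fit_b, design,
                                    out$total_dose[ok], out$fa[ok])
    out$label[ok] <- ci_label(out$ci[ok])
  }
  class(out) <- c("ci_profile", class(out))
  out
}

#' Write a combination-index profile to CSV
#'
#' Tabular export of the Fa-CI analysis: columns `pair`, `model_id`, `fa`,
#' `total_dose_uM`, `CI`, `label`.
#'
#' @param profile A `ci_profile` tibble (or several row-bound together).
#' @param path Output file path.
#' @param model_id Model line identifier recorded in the file.
#' @return `path`, invisibly.
#' @export
write_ci_profile_csv <- function(profile, path, model_id = NA_character_) {
  out <- tibble(
    pair = profile$pair,
    model_id = if ("model_id" %in% names(profile)) profile$model_id else model_id,
    fa = profile$fa,
    total_dose_uM = profile$total_dose,
    CI = profile$ci,
    label = profile$label
  )
  readr::write_csv(out, path)
  invisible(path)
}
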