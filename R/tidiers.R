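#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a median-effect fit
#'
#' @param x A `median_effect_fit`.
#' @param ... Unused.
#' @return A tibble with one row per parameter (`Dm` in µM, `m`).
#' @exportS3Method generics::tidy
#' @export
tidy.median_effect_fit <- function(x, ...) {
  tibble(term = c("Dm", "m"), estimate = c(x$Dm, x$m))
}

#' One-row fit summary of a median-effect fit
#'
#' @param x A `median_effect_fit`.
#' @param ... Unused.
#' @return A tibble with `Dm`, `m`, `r2`, `n_points_used`, `n_clipped`.
#' @exportS3Method generics::glance
#' @export
glance.median_effect_fit <- function(x, ...) {
  tibble(Dm = x$Dm, m = x$m, r2 = x$r2,
         n_points_used = x$n_points_used, n_clipped = x$n_clipped)
}

#' One-row summary of a randomization test
#'
#' @param x A `randomization_test`.
#' @param ... Unused.
#' @return A tibble with the observed difference, p-value, method and
#'   relabeling count.
#' @exportS3Method generics::glance
#' @export
glance.randomization_test <- function(x, ...) {
  tibble(
    group_a = x$groups[1], group_b = x$groups[2], stat = x$stat,
    observed = x$observed, p_value = x$p_value, method = x$method,
    n_relabelings = x$n_relabelings, n_a = x$n_a, n_b = x$n_b
  )
}
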