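#' @importFrom rlang abort warn .data %||%
#' @importFrom dplyr mutate filter group_by ungroup summarise arrange select
#'   bind_rows left_join across all_of n
#' @importFrom tibble tibble as_tibble is_tibble
NULL

# single scalar checks used across modules; abort with a field name so the
# caller sees which argument was bad
check_number <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (strict_lower && x <= lower) {
    abort(sprintf("`%s` must be > %s (got %s).", name, lower, x))
  }
  if (!strict_lower && x < lower) {
    abort(sprintf("`%s` must be >= %s (got %s).", name, lower, x))
  }
  if (x > upper) {
    abort(sprintf("`%s` must be <= %s (got %s).", name, upper, x))
  }
  invisible(x)
}

check_columns <- function(data, cols, what = "data") {
  missing <- setdiff(cols, names(data))
  if (length(missing) > 0) {
    abort(sprintf(
      "%s is missing required column(s): %s.",
      what, paste(missing, collapse = ", ")
    ))
  }
  invisible(data)
}

# clip fraction affected into the open unit interval; returns list with the
# clipped values and a logical flag marking the points that were moved
clip_fa <- function(fa, clip_eps) {
  clipped <- fa < clip_eps | fa > 1 - clip_eps
  list(fa = pmin(pmax(fa, clip_eps), 1 - clip_eps), clipped = clipped)
}
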