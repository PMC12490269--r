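#' Read a long-format plate CSV
#'
#' The documented plate dialect has header
#' `model_id,treatment_id,concentration_uM,replicate,absorbance,is_control`.
#' Validation is strict: a file with any malformed row is rejected as a
#' whole (listing the offending line numbers) rather than silently dropping
#' rows, because silent row loss corrupts downstream ranking matrices.
#'
#' @param path Path to the CSV file.
#' @return A tibble of plate records with the internal column names used by
#'   [normalize_viability()] (`concentration` in µM).
#' @export
read_plate_csv <- function(path) {
  required <- c("model_id", "treatment_id", "concentration_uM",
                "replicate", "absorbance", "is_control")
  # parse problems are re-raised below as structured errors with line
  # numbers, so readr's own warning is redundant
  raw <- suppressWarnings(readr::read_csv(
    path,
    col_types = readr::cols(
      model_id = readr::col_character(),
      treatment_id = readr::col_character(),
      concentration_uM = readr::col_double(),
      replicate = readr::col_integer(),
      absorbance = readr::col_double(),
      is_control = readr::col_logical()
    ),
    progress = FALSE, show_col_types = FALSE
  ))
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    abort(sprintf("plate CSV %s is missing column(s): %s",
                  path, paste(missing, collapse = ", ")))
  }
  probs <- readr::problems(raw)
  bad_rows <- which(
    is.na(raw$concentration_uM) | is.na(raw$absorbance) |
      is.na(raw$is_control) | is.na(raw$replicate) |
      raw$concentration_uM < 0 | raw$absorbance < 0
  )
  lines <- sort(unique(c(probs$row, bad_rows))) + 1  # +1 for the header
  if (length(lines) > 0) {
    abort(sprintf(
      "plate CSV %s rejected: invalid value(s) on line(s) %s",
      path, paste(lines, collapse = ", ")
    ))
  }
  if (!any(raw$is_control)) {
    abort(sprintf("plate CSV %s contains no control wells.", path))
  }
  raw |>
    dplyr::rename(concentration = "concentration_uM") |>
    as_tibble()
}

#' Write plate records to the documented CSV dialect
#'
#' @param records A plate tibble (internal column names).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_plate_csv <- function(records, path) {
  records |>
    dplyr::rename(concentration_uM = "concentration") |>
    readr::write_csv(path)
  invisible(path)
}

#' Read a drug C_max metadata CSV
#'
#' Two-column dialect `drug,cmax_uM`; a synthetic template ships at
#' `system.file("extdata", "cmax_synthetic.csv", package = "comboscreen")`.
#'
#' @param path Path to the CSV file.
#' @return A tibble with `drug` and `cmax_uM` (> 0).
#' @export
read_cmax_csv <- function(path) {
  raw <- readr::read_csv(
    path,
    col_types = readr::cols(drug = readr::col_character(),
                            cmax_uM = readr::col_double()),
    progress = FALSE, show_col_types = FALSE
  )
  check_columns(raw, c("drug", "cmax_uM"), sprintf("C_max CSV %s", path))
  if (any(is.na(raw$cmax_uM) | raw$cmax_uM <= 0)) {
    abort(sprintf("C_max CSV %s has missing or nonpositive values.", path))
  }
  as_tibble(raw)
}

#' Read an in vivo tumor measurement CSV
#'
#' Dialect `animal_id,group,day,length_mm,width_mm`.
#'
#' @param path Path to the CSV file.
#' @return A growth study tibble (see [add_tumor_volumes()]).
#' @export
read_measurements_csv <- function(path) {
  raw <- readr::read_csv(
    path,
    col_types = readr::cols(
      animal_id = readr::col_character(),
      group = readr::col_character(),
      day = readr::col_double(),
      length_mm = readr::col_double(),
      width_mm = readr::col_double()
    ),
    progress = FALSE, show_col_types = FALSE
  )
  check_columns(raw, c("animal_id", "group", "day", "length_mm",
                       "width_mm"), sprintf("measurement CSV %s", path))
  if (any(is.na(raw$length_mm) | is.na(raw$width_mm) |
            raw$length_mm < 0 | raw$width_mm < 0)) {
    abort(sprintf("measurement CSV %s has missing or negative sizes.", path))
  }
  as_tibble(raw)
}

#' Screen configuration
#'
#' Collects the knobs of the screen-to-ranking pipeline: the drug C_max
#' table, ladder settings, fixed-ratio levels, fa clipping, AUC axis,
#' bootstrap resamples and the top-level seed from which all stage seeds
#' are derived.
#'
#' @param cmax Named numeric vector or a tibble (`drug`, `cmax_uM`) mapping
#'   drug names to C_max in µM.
#' @param n_points Ladder points (default 6).
#' @param dilution_factor Ladder fold dilution (default `sqrt(10)`).
#' @param levels Fixed-ratio levels in `(0, 1]` (default `c(1, 0.1)`).
#' @param clip_eps Fraction-affected clipping bound (default 0.005).
#' @param dose_scale AUC x axis, `"log10"` or `"linear"`.
#' @param n_boot Bootstrap resamples for AUC confidence limits.
#' @param seed Top-level seed; per-stage seeds are derived from it.
#' @return A `screen_config` list.
#' @export
screen_config <- function(cmax, n_points = 6L, dilution_factor = sqrt(10),
                          levels = c(1, 0.1), clip_eps = 0.005,
                          dose_scale = c("log10", "linear"),
                          n_boot = 1000L, seed = 1L) {
  dose_scale <- match.arg(dose_scale)
  if (is.data.frame(cmax)) {
    check_columns(cmax, c("drug", "cmax_uM"), "cmax table")
    cmax <- stats::setNames(cmax$cmax_uM, cmax$drug)
  }
  if (is.null(names(cmax)) || any(!nzchar(names(cmax)))) {
    abort("`cmax` must be a named vector or a drug,cmax_uM table.")
  }
  if (any(cmax <= 0)) abort("all C_max values must be > 0.")
  if (any(levels <= 0 | levels > 1)) abort("`levels` must lie in (0, 1].")
  structure(
    list(cmax = cmax, n_points = n_points,
         dilution_factor = dilution_factor, levels = levels,
         clip_eps = clip_eps, dose_scale = dose_scale,
         n_boot = n_boot, seed = as.integer(seed)),
    class = "screen_config"
  )
}

#' Read a screen configuration from YAML or JSON
#'
#' @param path Path to a YAML (`.yml`/`.yaml`, requires the yaml package)
#'   or JSON file whose fields mirror the arguments of [screen_config()];
#'   `cmax` is a mapping of drug name to µM.
#' @return A `screen_config`.
#' @export
read_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      abort("the yaml package is required to read YAML configs.")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  args <- raw[intersect(names(raw), names(formals(screen_config)))]
  args$cmax <- unlist(raw$cmax)
  do.call(screen_config, args)
}

# split "A+B" treatment ids into component drugs
split_treatment <- function(treatment_id) {
  strsplit(treatment_id, "+", fixed = TRUE)
}

#' Run the screen-to-ranking pipeline
#'
#' Orchestrates the full analysis on a set of plates: viability
#' normalization, single-agent median-effect fits, combination-index
#' profiles for every fixed-ratio pair with both single agents fitted in
#' the same model line, screen matrices and treatment rankings at each
#' configured level, and (optionally) randomization tests on an in vivo
#' measurement table. The bundle is deterministic given inputs, config and
#' seed.
#'
#' @param config A [screen_config()]. Every drug referenced by a plate
#'   treatment id (combination ids are `"drugA+drugB"`) must appear in the
#'   config's C_max table; unknown drugs are a configuration error raised
#'   before any computation.
#' @param plates Plate records (one tibble, e.g. from [read_plate_csv()]
#'   or the simulators), nonempty.
#' @param measurements Optional growth study tibble; when given,
#'   [growth_tests()] is run against its first group.
#' @return A list of class `screen_bundle`: `viability`, `fits` (tibble
#'   from [fit_median_effects()] of single agents), `ci_profiles` (tibble
#'   with `model_id` column), `matrices` and `rankings` (one per level,
#'   named `level_<s>`), optional `growth`, and `log` (package version,
#'   seed, config hash, timestamp-free).
#' @export
run_pipeline <- function(config, plates, measurements = NULL) {
  if (!inherits(config, "screen_config")) abort("`config` must be a screen_config.")
  plates <- as_tibble(plates)
  if (nrow(plates) == 0) abort("`plates` is empty.")
  check_columns(plates, c("model_id", "treatment_id", "concentration",
                          "replicate", "absorbance", "is_control"),
                "plates")
  trt_ids <- unique(plates$treatment_id[!plates$is_control])
  drugs <- unique(unlist(split_treatment(trt_ids)))
  unknown <- setdiff(drugs, names(config$cmax))
  if (length(unknown) > 0) {
    abort(sprintf("config error: drug(s) not in C_max table: %s",
                  paste(unknown, collapse = ", ")))
  }

  viability <- normalize_viability(plates)
  singles <- trt_ids[lengths(split_treatment(trt_ids)) == 1]
  combos <- trt_ids[lengths(split_treatment(trt_ids)) == 2]

  fits <- if (length(singles) > 0) {
    fit_median_effects(
      filter(viability, .data$treatment_id %in% singles),
      clip_eps = config$clip_eps
    )
  } else {
    tibble()
  }

  profiles <- list()
  for (combo in combos) {
    parts <- split_treatment(combo)[[1]]
    design <- combination_design(parts[1], parts[2],
                                 config$cmax[[parts[1]]],
                                 config$cmax[[parts[2]]],
                                 levels = config$levels)
    for (model in unique(viability$model_id[viability$treatment_id == combo])) {
      fa_row <- fits[fits$model_id == model &
                       fits$treatment_id == parts[1], ]
      fb_row <- fits[fits$model_id == model &
                       fits$treatment_id == parts[2], ]
      if (nrow(fa_row) == 0 || nrow(fb_row) == 0) next
      prof <- ci_profile(
        filter(viability, .data$treatment_id == combo,
               .data$model_id == model),
        fa_row$fit[[1]], fb_row$fit[[1]], design,
        clip_eps = config$clip_eps
      )
      prof$model_id <- model
      profiles[[length(profiles) + 1]] <- prof
    }
  }
  ci_profiles <- if (length(profiles) > 0) bind_rows(profiles) else tibble()

  matrices <- list()
  rankings <- list()
  for (s in config$levels) {
    key <- paste0("level_", format(s))
    m <- build_screen_matrix(viability, level = s, metric = "viability",
                             dose_scale = config$dose_scale)
    matrices[[key]] <- m
    rankings[[key]] <- rank_treatments(m)
  }

  growth <- NULL
  if (!is.null(measurements)) {
    growth <- growth_tests(measurements, seed = config$seed + 1L)
  }

  structure(
    list(
      viability = viability, fits = fits, ci_profiles = ci_profiles,
      matrices = matrices, rankings = rankings, growth = growth,
      log = list(
        package_version = as.character(utils::packageVersion("comboscreen")),
        seed = config$seed,
        config_hash = rlang::hash(config),
        n_plates_rows = nrow(plates),
        treatments = sort(trt_ids)
      )
    ),
    class = "screen_bundle"
  )
}

#' @export
print.screen_bundle <- function(x, ...) {
  cat("Screen analysis bundle\n")
  cat(sprintf("  %d treatments, %d model lines\n",
              length(x$log$treatments),
              length(unique(x$viability$model_id))))
  cat(sprintf("  single-agent fits: %d; CI profile points: %d\n",
              nrow(x$fits), nrow(x$ci_profiles)))
  cat(sprintf("  matrices at levels: %s\n",
              paste(names(x$matrices), collapse = ", ")))
  if (!is.null(x$growth)) {
    cat(sprintf("  growth comparisons: %d\n", nrow(x$growth)))
  }
  invisible(x)
}
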