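#' Ground-truth description of a simulated drug
#'
#' @param drug Drug identifier.
#' @param Dm Median-effect dose (µM) producing 50% effect, > 0.
#' @param m Sigmoidicity of the median-effect curve, > 0.
#' @param cmax Clinical C_max (µM) anchoring the dose ladder, > 0.
#' @return A `drug_truth` list usable wherever a `median_effect_fit` is
#'   (it carries `Dm` and `m`).
#' @export
drug_truth <- function(drug, Dm, m, cmax) {
  check_number(Dm, "Dm", lower = 0, strict_lower = TRUE)
  check_number(m, "m", lower = 0, strict_lower = TRUE)
  check_number(cmax, "cmax", lower = 0, strict_lower = TRUE)
  structure(list(drug = drug, Dm = Dm, m = m, cmax = cmax),
            class = c("drug_truth", "list"))
}

#' Ground-truth description of a tumor growth arm
#'
#' Deterministic exponential growth `v0 * exp(rate * effect * day)` with
#' multiplicative lognormal measurement noise.
#'
#' @param group Arm label.
#' @param v0 Initial tumor volume in mm^3 (default 70, the randomization
#'   threshold of the emulated studies), > 0.
#' @param rate Exponential growth rate per day (default 0.15, i.e. a
#'   doubling time of ~4.6 days).
#' @param effect Treatment effect as a multiplier on the growth rate
#'   (1 = untreated; 0.5 halves the rate).
#' @param noise_sd SD of the lognormal measurement noise on the log scale
#'   (default 0.1), >= 0.
#' @return A `growth_truth` list.
#' @export
growth_truth <- function(group, v0 = 70, rate = 0.15, effect = 1,
                         noise_sd = 0.1) {
  check_number(v0, "v0", lower = 0, strict_lower = TRUE)
  check_number(noise_sd, "noise_sd", lower = 0)
  structure(list(group = group, v0 = v0, rate = rate, effect = effect,
                 noise_sd = noise_sd),
            class = c("growth_truth", "list"))
}

# multiplicative Gaussian plate noise, truncated at zero: plate readers
# scale with signal
plate_noise <- function(base, noise_sd) {
  pmax(0, base * (1 + stats::rnorm(length(base), sd = noise_sd)))
}

control_records <- function(model_id, n_controls, noise_sd) {
  tibble(
    model_id = model_id,
    treatment_id = "vehicle",
    concentration = 0,
    replicate = seq_len(n_controls),
    absorbance = plate_noise(rep(1, n_controls), noise_sd),
    is_control = TRUE
  )
}

#' Simulate a single-agent dose-response plate
#'
#' Generates plate wells for one drug on its C_max-anchored ladder: control
#' absorbance has mean 1.0, treated absorbance is
#' `(1 - fa(D)) * control` under the median-effect ground truth, and all
#' wells receive multiplicative Gaussian noise truncated at zero.
#' Deterministic under `seed`.
#'
#' @param truth A [drug_truth()].
#' @param ladder Dose ladder (µM); default the 6-point half-log ladder
#'   from `truth$cmax`.
#' @param replicates Wells per dose (default 3).
#' @param noise_sd Relative noise SD (default 0.05), >= 0.
#' @param seed Integer seed.
#' @param model_id Model line label (default `"model_1"`).
#' @param n_controls Number of vehicle-control wells (default 8).
#' @return A tibble of plate records (see [normalize_viability()]).
#' @export
simulate_single_agent_plate <- function(truth,
                                        ladder = make_ladder(truth$cmax),
                                        replicates = 3L, noise_sd = 0.05,
                                        seed = 1L,
                                        model_id = "model_1",
                                        n_controls = 8L) {
  check_number(noise_sd, "noise_sd", lower = 0)
  fa <- predict_fa(truth, ladder)
  withr::with_seed(seed, {
    treated <- tibble(
      model_id = model_id,
      treatment_id = truth$drug,
      concentration = rep(ladder, each = replicates),
      replicate = rep(seq_len(replicates), times = length(ladder)),
      absorbance = plate_noise(rep(1 - fa, each = replicates), noise_sd),
      is_control = FALSE
    )
    bind_rows(control_records(model_id, n_controls, noise_sd), treated)
  })
}

#' Fraction affected of a combination under scaled Loewe additivity
#'
#' Solves, by vectorized bisection, for the fraction affected `fa` of a
#' combination delivering doses `(d_a, d_b)` under Loewe additivity with a
#' potency-boost interaction `psi`:
#' `psi * d_a / Dx_a(fa) + psi * d_b / Dx_b(fa) = 1`.
#' `psi = 1` is the Loewe-additive null, `psi > 1` synergy (the combination
#' behaves as if doses were multiplied by `psi`), `psi < 1` antagonism; by
#' construction the downstream combination index equals `1/psi`.
#'
#' @param d_a,d_b Doses of each drug (µM), vectorized, >= 0.
#' @param truth_a,truth_b [drug_truth()] (or fit) objects with `Dm`, `m`.
#' @param psi Potency-boost interaction factor, > 0 (default 1).
#' @param tol Bisection convergence tolerance on fa (default 1e-12).
#' @param max_iter Maximum bisection iterations (default 200).
#' @return Fraction(s) affected in `[0, 1)` (0 where both doses are 0).
#' @export
loewe_fa <- function(d_a, d_b, truth_a, truth_b, psi = 1,
                     tol = 1e-12, max_iter = 200L) {
  check_number(psi, "psi", lower = 0, strict_lower = TRUE)
  if (any(d_a < 0) || any(d_b < 0)) abort("doses must be >= 0.")
  n <- max(length(d_a), length(d_b))
  d_a <- rep_len(d_a, n)
  d_b <- rep_len(d_b, n)
  out <- numeric(n)
  active <- d_a > 0 | d_b > 0
  if (!any(active)) return(out)
  da <- psi * d_a[active]
  db <- psi * d_b[active]
  # g(fa) = da/Dx_a(fa) + db/Dx_b(fa) - 1 is strictly decreasing in fa,
  # from +Inf at fa -> 0 to -1 at fa -> 1, so the root is unique
  g <- function(fa) {
    da / dose_for_effect(truth_a, fa) + db / dose_for_effect(truth_b, fa) - 1
  }
  lo <- rep(1e-15, length(da))
  hi <- rep(1 - 1e-15, length(da))
  for (i in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    gm <- g(mid)
    pos <- gm > 0
    lo[pos] <- mid[pos]
    hi[!pos] <- mid[!pos]
    if (max(hi - lo) < tol) break
  }
  if (max(hi - lo) >= tol) {
    abort(sprintf(
      "Loewe bisection did not converge: max interval %.3g after %d iterations (psi = %g).",
      max(hi - lo), max_iter, psi
    ))
  }
  out[active] <- (lo + hi) / 2
  out
}

#' Simulate a fixed-ratio combination plate
#'
#' Generates plate wells for a two-drug fixed-ratio combination along a
#' ladder of total dose anchored at `cmax_a + cmax_b`. The combination's
#' fraction affected at each dose pair comes from the scaled-Loewe model
#' ([loewe_fa()]); absorbance is generated as in
#' [simulate_single_agent_plate()]. Deterministic under `seed`.
#'
#' @param truth_a,truth_b [drug_truth()] objects.
#' @param psi Interaction ground truth: potency-boost factor (> 0;
#'   1 = Loewe-additive).
#' @param design [combination_design()]; default built from the two
#'   truths' C_max values.
#' @param ladder Ladder of total dose (µM); default 6-point half-log from
#'   `design$total_cmax`.
#' @inheritParams simulate_single_agent_plate
#' @return A tibble of plate records; the combination's `treatment_id` is
#'   `"drug_a+drug_b"`.
#' @export
simulate_combination_plate <- function(truth_a, truth_b, psi = 1,
                                       design = combination_design(
                                         truth_a$drug, truth_b$drug,
                                         truth_a$cmax, truth_b$cmax
                                       ),
                                       ladder = make_ladder(design$total_cmax),
                                       replicates = 3L, noise_sd = 0.05,
                                       seed = 1L,
                                       model_id = "model_1",
                                       n_controls = 8L) {
  check_number(noise_sd, "noise_sd", lower = 0)
  fa <- loewe_fa(design$w_a * ladder, design$w_b * ladder,
                 truth_a, truth_b, psi = psi)
  withr::with_seed(seed, {
    treated <- tibble(
      model_id = model_id,
      treatment_id = design$pair_id,
      concentration = rep(ladder, each = replicates),
      replicate = rep(seq_len(replicates), times = length(ladder)),
      absorbance = plate_noise(rep(1 - fa, each = replicates), noise_sd),
      is_control = FALSE
    )
    bind_rows(control_records(model_id, n_controls, noise_sd), treated)
  })
}

#' Simulate a multi-model fixed-ratio combination screen
#'
#' Builds the synthetic analog of a cross-model combination screen:
#' `n_combos` drug pairs tested in `n_models` model lines along fixed-ratio
#' ladders, with per-model drug potencies drawn around each drug's C_max
#' and one planted winner given a synergistic potency boost
#' (`psi_planted`) while all other pairs are Loewe-additive
#' (`psi_others`).
#'
#' @param n_combos Number of drug pairs (default 5).
#' @param n_models Number of model lines (default 7).
#' @param planted Index of the planted winning pair (default 1).
#' @param psi_planted Potency boost of the planted pair (default 4).
#' @param psi_others Interaction of the remaining pairs (default 1,
#'   Loewe-additive).
#' @param cmax C_max (µM) assigned to every simulated drug (default 1).
#' @param dm_sdlog Lognormal spread of per-model `Dm` around `cmax`
#'   (default 0.3).
#' @inheritParams simulate_single_agent_plate
#' @return A list with `plates` (row-bound plate records for all
#'   combination arms in all models) and `truth` (tibble of pair, model,
#'   psi, planted flag).
#' @export
simulate_screen <- function(n_combos = 5L, n_models = 7L, planted = 1L,
                            psi_planted = 4, psi_others = 1, cmax = 1,
                            dm_sdlog = 0.3, replicates = 3L,
                            noise_sd = 0.05, seed = 1L) {
  stopifnot(planted >= 1, planted <= n_combos)
  withr::with_seed(seed, {
    combos <- sprintf("combo_%02d", seq_len(n_combos))
    models <- sprintf("model_%02d", seq_len(n_models))
    plates <- vector("list", n_combos * n_models)
    truth <- vector("list", n_combos * n_models)
    k <- 0L
    for (ci in seq_len(n_combos)) {
      psi <- if (ci == planted) psi_planted else psi_others
      for (mi in seq_len(n_models)) {
        ta <- drug_truth(sprintf("%s_a", combos[ci]),
                         Dm = stats::rlnorm(1, log(cmax), dm_sdlog),
                         m = stats::rlnorm(1, log(1.5), 0.1),
                         cmax = cmax)
        tb <- drug_truth(sprintf("%s_b", combos[ci]),
                         Dm = stats::rlnorm(1, log(cmax), dm_sdlog),
                         m = stats::rlnorm(1, log(1.5), 0.1),
                         cmax = cmax)
        k <- k + 1L
        plate <- simulate_combination_plate(
          ta, tb, psi = psi,
          design = combination_design(combos[ci], paste0(combos[ci], "x"),
                                      ta$cmax, tb$cmax),
          replicates = replicates, noise_sd = noise_sd,
          seed = sample.int(.Machine$integer.max - 1L, 1),
          model_id = models[mi]
        )
        plate$treatment_id[!plate$is_control] <- combos[ci]
        plates[[k]] <- plate
        truth[[k]] <- tibble(pair = combos[ci], model_id = models[mi],
                             psi = psi, planted = ci == planted)
      }
    }
    list(plates = bind_rows(plates), truth = bind_rows(truth))
  })
}

#' Simulate an in vivo tumor growth study
#'
#' Per-animal exponential trajectories under each arm's [growth_truth()],
#' with lognormal measurement noise, converted to caliper (length, width)
#' pairs consistent with [tumor_volume()] (length = width =
#' `(2 * volume)^(1/3)`). Deterministic under `seed`.
#'
#' @param truths List of [growth_truth()] objects, one per arm.
#' @param n_per_group Animals per arm (default 8, >= 3).
#' @param days Measurement days (default `seq(0, 21, by = 3)`).
#' @param seed Integer seed.
#' @return A growth study tibble: `animal_id`, `group`, `day`,
#'   `length_mm`, `width_mm`.
#' @export
simulate_growth_study <- function(truths, n_per_group = 8L,
                                  days = seq(0, 21, by = 3), seed = 1L) {
  if (length(days) == 0) abort("`days` must be nonempty.")
  check_number(n_per_group, "n_per_group", lower = 3)
  if (inherits(truths, "growth_truth")) truths <- list(truths)
  withr::with_seed(seed, {
    rows <- purrr::imap(truths, function(tr, gi) {
      purrr::map(seq_len(n_per_group), function(ai) {
        vol <- tr$v0 * exp(tr$rate * tr$effect * days) *
          exp(stats::rnorm(length(days), sd = tr$noise_sd))
        w <- (2 * vol)^(1 / 3)
        tibble(
          animal_id = sprintf("%s_%02d", tr$group, ai),
          group = tr$group,
          day = days,
          length_mm = w,
          width_mm = w
        )
      })
    })
    bind_rows(purrr::list_flatten(rows))
  })
}
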