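test_that("dose_for_effect inverts the median-effect curve", {
  expect_equal(dose_for_effect(list(Dm = 1, m = 1), 0.5), 1)
  expect_equal(dose_for_effect(list(Dm = 1, m = 1), 0.75), 3)
  expect_error(dose_for_effect(list(Dm = 1, m = 1), 1), "fa")
  expect_error(dose_for_effect(list(Dm = 1, m = 1), 0), "fa")

  # round trip and agreement with a bisection oracle over random fits
  set.seed(11)
  for (i in 1:50) {
    f <- random_fit()
    fa <- runif(1, 0.05, 0.95)
    dx <- dose_for_effect(f, fa)
    expect_lt(abs(predict_fa(f, dx) - fa), 1e-9)
    oracle <- uniroot(function(d) predict_fa(f, d) - fa,
                      c(1e-9, 1e6), tol = 1e-12)$root
    expect_equal(dx, oracle, tolerance = 1e-6)
  }
})

test_that("combination design fixes the C_max mixing ratio across levels", {
  d <- combination_design("A", "B", 0.5, 8)
  expect_equal(d$w_a, 0.5 / 8.5)
  expect_equal(d$w_a + d$w_b, 1)
  expect_equal(d$total_cmax, 8.5)
  # at each level both drugs sit at level * own C_max
  for (s in d$levels) {
    total <- s * d$total_cmax
    expect_equal(d$w_a * total, s * 0.5)
    expect_equal(d$w_b * total, s * 8)
  }
  expect_error(combination_design("A", "B", -1, 2), "cmax_a")
  expect_error(combination_design("A", "B", 1, 2, levels = c(1, 1.5)),
               "levels")
})

test_that("combination index reproduces its defining algebra", {
  a <- list(Dm = 1, m = 1)
  b <- list(Dm = 2, m = 1)
  d <- combination_design("A", "B", 1, 2)
  # doses (0.5, 1.0) at fa = 0.5: CI = 0.5/1 + 1/2 = 1 (Loewe oracle, m = 1)
  expect_equal(combination_index(a, b, d, total_dose = 1.5, fa = 0.5), 1)
  # CI is linear in dose at fixed fa
  ci1 <- combination_index(a, b, d, 1.5, 0.3)
  ci2 <- combination_index(a, b, d, 0.75, 0.3)
  expect_equal(ci2, ci1 / 2)
  expect_error(combination_index(a, list(Dm = 1, m = -1), d, 1, 0.5),
               "degenerate")
})

test_that("sham self-combination is exactly additive at every fa", {
  set.seed(3)
  fa_grid <- seq(0.1, 0.9, by = 0.1)
  for (i in 1:10) {
    f <- random_fit()
    w <- runif(1, 0.05, 0.95)  # arbitrary fixed ratio of the self-pair
    d <- combination_design("X", "X'", w, 1 - w)
    for (fa in fa_grid) {
      total <- dose_for_effect(f, fa)
      expect_equal(combination_index(f, f, d, total, fa), 1,
                   tolerance = 1e-6)
    }
  }
})

test_that("closed-form CI equals a bisection-inversion oracle", {
  set.seed(19)
  for (i in 1:100) {
    fa <- runif(1, 0.05, 0.95)
    fit_a <- random_fit()
    fit_b <- random_fit()
    d <- combination_design("A", "B", runif(1, 0.1, 10),
                            runif(1, 0.1, 10))
    total <- runif(1, 0.01, 5)
    ci <- combination_index(fit_a, fit_b, d, total, fa)
    dx <- vapply(list(fit_a, fit_b), function(f) {
      uniroot(function(dd) predict_fa(f, dd) - fa, c(1e-10, 1e8),
              tol = 1e-14)$root
    }, numeric(1))
    oracle <- d$w_a * total / dx[1] + d$w_b * total / dx[2]
    expect_equal(ci, oracle, tolerance = 1e-8)
  }
})

test_that("ci_profile scores a measured fixed-ratio curve point by point", {
  ta <- drug_truth("A", Dm = 0.8, m = 1.6, cmax = 2)
  tb <- drug_truth("B", Dm = 1.5, m = 1.2, cmax = 4)
  design <- combination_design("A", "B", ta$cmax, tb$cmax)
  ladder <- make_ladder(design$total_cmax)
  fa <- loewe_fa(design$w_a * ladder, design$w_b * ladder, ta, tb, psi = 1)
  combo <- tibble::tibble(concentration = ladder,
                          viability = 100 * (1 - fa))
  prof <- ci_profile(combo, ta, tb, design)
  ok <- !prof$clipped
  expect_true(any(ok))
  expect_true(all(abs(prof$ci[ok] - 1) < 1e-6))
  expect_true(all(prof$label[ok] == "additive"))

  # a potency boost of psi makes the combination act as if doses doubled:
  # CI = 1/psi at every usable point
  fa2 <- loewe_fa(design$w_a * ladder, design$w_b * ladder, ta, tb, psi = 2)
  prof2 <- ci_profile(tibble::tibble(concentration = ladder,
                                     viability = 100 * (1 - fa2)),
                      ta, tb, design)
  ok2 <- !prof2$clipped
  expect_true(all(abs(prof2$ci[ok2] - 0.5) < 1e-6))
  expect_true(all(prof2$label[ok2] == "synergism"))
})

test_that("fully ineffective combination yields an all-flagged profile", {
  d <- combination_design("A", "B", 1, 1)
  flat <- tibble::tibble(concentration = make_ladder(2),
                         viability = rep(100, 6))
  expect_warning(
    prof <- ci_profile(flat, list(Dm = 1, m = 1), list(Dm = 1, m = 1), d),
    "flagged"
  )
  expect_true(all(prof$clipped))
  expect_true(all(is.na(prof$ci)))
  expect_error(
    ci_profile(flat[0, ], list(Dm = 1, m = 1), list(Dm = 1, m = 1), d),
    "empty"
  )
})

test_that("median CI decreases as the potency boost psi grows", {
  ta <- drug_truth("A", Dm = 1, m = 1.5, cmax = 2)
  tb <- drug_truth("B", Dm = 2, m = 1.1, cmax = 3)
  design <- combination_design("A", "B", ta$cmax, tb$cmax)
  ladder <- make_ladder(design$total_cmax)
  med_ci <- vapply(c(0.5, 1, 2, 4), function(psi) {
    fa <- loewe_fa(design$w_a * ladder, design$w_b * ladder, ta, tb,
                   psi = psi)
    prof <- ci_profile(tibble::tibble(concentration = ladder,
                                      viability = 100 * (1 - fa)),
                       ta, tb, design)
    median(prof$ci, na.rm = TRUE)
  }, numeric(1))
  expect_true(all(diff(med_ci) < 0))
  expect_equal(med_ci, 1 / c(0.5, 1, 2, 4), tolerance = 1e-6)
})

test_that("ci_label applies the additive tolerance band", {
  expect_equal(ci_label(c(0.5, 0.98, 1, 1.04, 1.3)),
               c("synergism", "additive", "additive", "additive",
                 "antagonism"))
})
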