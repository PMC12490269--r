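test_that("viability normalizes against the control mean and flags >100%", {
  plate <- tiny_plate(c(0.50, 0.25, 0.60), control = 0.5)
  v <- normalize_viability(plate)
  treated <- v[!v$is_control, ]
  expect_equal(treated$viability, c(100, 50, 120))
  expect_equal(treated$over_control, c(FALSE, FALSE, TRUE))
  # control wells average exactly 100%
  expect_equal(mean(v$viability[v$is_control]), 100)

  # multiple control replicates: the mean, not any single well, is the anchor
  plate2 <- tibble::tibble(
    model_id = "M", treatment_id = c("vehicle", "vehicle", "d"),
    concentration = c(0, 0, 1), replicate = c(1L, 2L, 1L),
    absorbance = c(0.4, 0.6, 0.25), is_control = c(TRUE, TRUE, FALSE)
  )
  v2 <- normalize_viability(plate2)
  expect_equal(v2$viability[3], 0.25 / 0.5 * 100)
  expect_equal(mean(v2$viability[v2$is_control]), 100)
})

test_that("normalization errors name the offending group or record", {
  plate <- tiny_plate(c(0.2))
  no_ctrl <- dplyr::mutate(plate, is_control = FALSE)
  expect_error(normalize_viability(no_ctrl), "MM-1")
  zero_ctrl <- plate
  zero_ctrl$absorbance[1] <- 0
  expect_error(normalize_viability(zero_ctrl), "MM-1")
  neg <- plate
  neg$absorbance[2] <- -0.1
  expect_error(normalize_viability(neg), "negative")
})

test_that("dose ladders divide down from the top concentration", {
  expect_equal(make_ladder(10, 6, 10), c(10, 1, 0.1, 0.01, 0.001, 0.0001))
  expect_equal(make_ladder(1, 2, 2), c(1, 0.5))
  # default half-log 6-point ladder contains both C_max and 10% C_max
  lad <- make_ladder(7)
  expect_true(any(abs(lad - 7) < 1e-12))
  expect_true(any(abs(lad - 0.7) < 1e-9))
  # with a non-10-divisible factor, 10%*top is absent
  lad3 <- make_ladder(7, 6, 3)
  expect_false(any(abs(lad3 - 0.7) < 1e-9))
  expect_error(make_ladder(-1), "top")
  expect_error(make_ladder(1, 6, 1), "dilution_factor")
})

test_that("median-effect fit recovers noiseless parameters exactly", {
  for (pars in list(c(1, 2), c(0.3, 0.8), c(5, 1.5))) {
    fit <- fit_median_effect(noiseless_curve(pars[1], pars[2]))
    expect_equal(fit$Dm, pars[1], tolerance = 1e-9)
    expect_equal(fit$m, pars[2], tolerance = 1e-9)
    expect_equal(fit$r2, 1, tolerance = 1e-9)
  }
})

test_that("fa = 0.5 observed at D = 1 pins Dm at 1", {
  # two points fix the line; one of them is the median effect itself
  curve <- tibble::tibble(concentration = c(1, 4),
                          viability = c(50, 100 * (1 - 16 / 17)))
  fit <- fit_median_effect(curve)
  expect_equal(fit$Dm, 1, tolerance = 1e-9)
})

test_that("fit matches an independent grid-search least-squares oracle", {
  set.seed(42)
  doses <- make_ladder(10)
  fa_true <- predict_fa(list(Dm = 1.3, m = 1.8), doses)
  viab <- 100 * (1 - fa_true) * exp(rnorm(length(doses), sd = 0.03))
  curve <- tibble::tibble(concentration = doses, viability = viab)
  fit <- fit_median_effect(curve)

  # brute force over (Dm, m): same least-squares objective in log space,
  # over the same usable points (boundary fa values excluded, as the
  # default fit does)
  fa_obs <- 1 - viab / 100
  used <- fa_obs > 0.005 & fa_obs < 0.995
  y <- log10(fa_obs[used] / (1 - fa_obs[used]))
  lx <- log10(doses[used])
  sse <- function(Dm, m) sum((y - m * (lx - log10(Dm)))^2)
  grid <- expand.grid(Dm = exp(seq(log(0.3), log(5), length.out = 400)),
                      m = seq(0.5, 4, length.out = 400))
  best <- grid[which.min(mapply(sse, grid$Dm, grid$m)), ]
  expect_equal(fit$Dm, best$Dm, tolerance = 0.02)
  expect_equal(fit$m, best$m, tolerance = 0.02)
  expect_lt(sse(fit$Dm, fit$m), sse(best$Dm, best$m) + 1e-10)
})

test_that("clipping excludes boundary points and errors when too few remain", {
  doses <- make_ladder(10)
  fa <- predict_fa(list(Dm = 1, m = 2), doses)
  viab <- 100 * (1 - fa)
  viab[6] <- 104  # over-control well: fa < 0
  fit <- fit_median_effect(tibble::tibble(concentration = doses,
                                          viability = viab))
  expect_equal(fit$n_clipped, 1)
  expect_equal(fit$n_points_used, 5)
  expect_equal(fit$Dm, 1, tolerance = 1e-9)

  all_flat <- tibble::tibble(concentration = doses,
                             viability = rep(100, 6))
  expect_error(fit_median_effect(all_flat), "usable points")
})

test_that("predict_fa follows the forward median-effect equation", {
  fit <- list(Dm = 1, m = 1)
  expect_equal(predict_fa(fit, 1), 0.5)
  expect_equal(predict_fa(fit, 0), 0)
  expect_equal(predict_fa(fit, 3), 0.75)
  expect_error(predict_fa(fit, -1), "dose")
})

test_that("round trip: predict then fit recovers parameters; fa is monotone", {
  set.seed(7)
  for (i in 1:20) {
    f <- random_fit()
    curve <- noiseless_curve(f$Dm, f$m, make_ladder(f$Dm * 10))
    refit <- fit_median_effect(curve)
    expect_equal(refit$Dm, f$Dm, tolerance = 1e-8)
    expect_equal(refit$m, f$m, tolerance = 1e-8)
    doses <- sort(runif(25, 0, 50))
    expect_true(all(diff(predict_fa(f, doses)) >= 0))
  }
})

test_that("fit_median_effects maps over model/treatment groups", {
  p1 <- simulate_single_agent_plate(drug_truth("a", 1, 2, 10),
                                    noise_sd = 0, seed = 1,
                                    model_id = "M1")
  p2 <- simulate_single_agent_plate(drug_truth("b", 0.5, 1, 5),
                                    noise_sd = 0, seed = 2,
                                    model_id = "M1")
  fits <- fit_median_effects(normalize_viability(dplyr::bind_rows(p1, p2)))
  expect_equal(nrow(fits), 2)
  expect_equal(sort(fits$treatment_id), c("a", "b"))
  expect_equal(fits$Dm[fits$treatment_id == "a"], 1, tolerance = 1e-8)
  expect_equal(fits$m[fits$treatment_id == "b"], 1, tolerance = 1e-8)
})
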