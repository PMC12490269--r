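# shared fixtures: noiseless median-effect curves and small plate tables

# viability table for one treatment generated exactly from the model
noiseless_curve <- function(Dm, m, doses = make_ladder(10)) {
  fa <- predict_fa(list(Dm = Dm, m = m), doses)
  tibble::tibble(concentration = doses, viability = 100 * (1 - fa))
}

# minimal valid plate with one control and treated wells
tiny_plate <- function(absorbances, control = 0.5, model = "MM-1",
                       treatment = "drugA") {
  tibble::tibble(
    model_id = model,
    treatment_id = c("vehicle", rep(treatment, length(absorbances))),
    concentration = c(0, seq_along(absorbances)),
    replicate = 1L,
    absorbance = c(control, absorbances),
    is_control = c(TRUE, rep(FALSE, length(absorbances)))
  )
}

# random, well-conditioned median-effect fit for property tests
random_fit <- function() {
  list(Dm = stats::runif(1, 0.05, 20), m = stats::runif(1, 0.5, 4))
}
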