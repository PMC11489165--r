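# Shared fixtures built in code. The litter-design vector mirrors a
# two-experiment developmental study: a pooled control (10 + 11 litters)
# plus eight dose groups of 8-10 litters.
adult_kp <- function() population_parameters("adult")
child_kp <- function() population_parameters("child")

two_experiment_litter_design <- c(21, 10, 10, 10, 10, 10, 10, 8, 8)

fixture_dose_response <- function(seed = 101) {
  gen_dose_response(n_litters = two_experiment_litter_design, seed = seed)
}

# draw a random valid kinetic parameter set (for property tests)
random_kp <- function() {
  kinetic_parameters(
    q_u = stats::runif(1, 0.01, 0.05),
    f_ue = stats::runif(1, 0.2, 1),
    mw_parent = stats::runif(1, 250, 500),
    mw_metabolite = stats::runif(1, 100, 249),
    population = "random"
  )
}

flat_dose_response <- function(seed = 7) {
  set.seed(seed)
  doses <- c(0, 5, 20, 50, 100, 250, 625)
  dose_response_dataset(data.frame(
    dose = rep(doses, each = 8),
    response = 7.7 * exp(stats::rnorm(8 * length(doses), 0, 0.2))
  ))
}
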