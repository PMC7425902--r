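# Shared fixtures, all generated in code.

# Canonical generating parameters (the mean preliminary estimates).
gen_params <- function() model_params(beta = 4.38, u = 0.56)

# A small heterogeneous-target stimulus table with simulated choices,
# suitable for likelihood/fitting tests.
sim_choice_data <- function(n = 216, seed = 1, params = gen_params()) {
  set.seed(seed)
  stim <- generate_stimulus_set(
    stimulus_spec(0.5, n, jitter_sd = 0.15), seed = seed + 100)
  simulate_choices(stim[, c("P", "a", "A")], params)
}

# A compact simulated experiment (both groups) for analysis tests.
sim_experiment_small <- function(hypothesis = "none", n_subjects = 6,
                                 seed = 1, ...) {
  simulate_experiment(design_spec(n_subjects = n_subjects),
                      scenario_spec(hypothesis, ...), seed = seed)
}

# Fabricate a density_estimate from an analytic density function, bypassing
# KDE, for crossing tests on exact densities.
analytic_density <- function(f, grid, median, rng = NULL) {
  if (is.null(rng)) rng <- range(grid)
  structure(list(grid = grid, density = f(grid), bandwidth = NA_real_,
                 n = Inf, median = median, range = rng),
            class = "density_estimate")
}

# Equal-variance two-component Gaussian mixture density.
gauss_mix <- function(p, m1 = 300, m2 = 700, s = 50) {
  function(x) p * stats::dnorm(x, m1, s) + (1 - p) * stats::dnorm(x, m2, s)
}
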