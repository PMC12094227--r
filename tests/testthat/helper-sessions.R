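# Shared fixtures: small synthetic sessions built in code.

make_session <- function(seed = 1, n_trials = 150, mix = default_unit_mix()) {
  sched <- generate_schedule(n_trials = n_trials, seed = seed)
  units <- generate_units(sched, mix = mix, seed = seed + 1)
  list(schedule = sched, units = units)
}

# One-archetype mix with the generator's default rates.
mix_of <- function(arch, n) {
  mx <- default_unit_mix()
  mx <- mx[mx$archetype %in% arch, ]
  mx$n <- n
  mx
}

# Homogeneous Poisson train on [0, t_end).
poisson_train <- function(rate, t_end, seed) {
  withr::with_seed(seed, sort(runif(rpois(1, rate * t_end), 0, t_end)))
}

# Single-row units tibble wrapping a spike-time vector.
unit_row <- function(spikes, unit_id = "u1", area = "VISp", ...) {
  tibble::tibble(unit_id = unit_id, area = area, spikes = list(spikes), ...)
}
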