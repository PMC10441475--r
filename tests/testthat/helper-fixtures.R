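# Shared fixtures: random-but-plausible kinetic parameter draws and small
# schedules used across test files.

random_two_state <- function() {
  two_state_params(kon1 = 10^runif(1, 3, 6), koff1 = 10^runif(1, -3, -1),
                   kon2 = 10^runif(1, -4, -2), koff2 = 10^runif(1, -4, -2),
                   Rmax = runif(1, 100, 1000))
}

random_one_to_one <- function() {
  one_to_one_params(kon = 10^runif(1, 4, 6), koff = 10^runif(1, -3, -1),
                    Rmax = runif(1, 100, 1000))
}

# coarse grid keeps simulation-heavy tests quick
fast_schedule <- function() single_cycle_schedule(sample_rate = 1)
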