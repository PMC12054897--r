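# Shared fixtures: the default four-neuron configuration and small grids
# sized for fast unit tests.

default_pop <- function(c = -0.1, A = 1) {
  build_population(4, tuning = tuning_model("rectified_cosine", A = A, c = c))
}

vm_pop <- function(w = 1, N = 4) {
  build_population(N, tuning = tuning_model("von_mises", w = w))
}

gauss <- function(sigma = 0.1) noise_spec("gaussian", sigma = sigma)

small_grid <- decode_grid(4096)

# numeric integral of the summed population tuning over one period
population_mass <- function(pop, n = 20001) {
  th <- 2 * pi * (seq_len(n) - 1) / n
  sum(tuning_matrix(pop, th)) * 2 * pi / n
}
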