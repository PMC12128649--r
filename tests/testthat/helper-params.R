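# Small parameter sets reused across tests. All tests use pinned seeds so
# that stochastic assertions are reproducible run to run.

soft_params <- function(...) {
  clutch_params(k_s = 0.1, ...)
}

stiff_params <- function(...) {
  clutch_params(k_s = 1, ...)
}

# random engaged-clutch configurations for solver property tests
random_engaged_config <- function(n_max = 30, x_max = 500) {
  m <- sample.int(n_max, 1)
  sort(runif(m, 0, x_max))
}
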