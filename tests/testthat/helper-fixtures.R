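# Shared fixtures: ground-truth parameter sets and small cached datasets.

truth_params <- function() synthetic_truth()$parameters

truth_theta <- function() {
  tr <- synthetic_truth()
  c(tr$parameters, scale_low = tr$observation$scale_low)
}

truth_obs <- function() synthetic_truth()$observation

# default-design datasets reused across tests (built once per run)
noisefree_dataset <- local({
  ds <- NULL
  function() {
    if (is.null(ds)) ds <<- generate_dataset(noise = noise_model(cv = 0), seed = 1)
    ds
  }
})

noisy_dataset <- local({
  ds <- NULL
  function() {
    if (is.null(ds)) ds <<- generate_dataset(seed = 1)
    ds
  }
})

# random non-negative parameter draw for a variant, log-uniform in a
# dynamically plausible window around the packaged defaults
random_params <- function(variant, scale_decades = 1) {
  base <- default_parameters(variant)
  base * 10^runif(length(base), -scale_decades, scale_decades)
}

expect_rel_equal <- function(object, expected, tol) {
  expect_lt(abs(object - expected) / max(abs(expected), .Machine$double.eps),
            tol)
}
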