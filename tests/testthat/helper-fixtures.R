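# shared fixtures: reference parameter objects and one cached noise-free
# run (the simulator is deterministic, so caching is safe)

ref_hcvr <- function() hcvr_parameters(8.3, 41, 44, 2.5)

ref_run <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulate_run(ref_hcvr())
    cache
  }
})

# tiny six-subject trial used by pipeline-level tests
tiny_trial <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_trial(trial_design(n_per_arm = 3, seed = 11))
    }
    cache
  }
})

expect_signif_equal <- function(object, expected, digits = 3) {
  expect_equal(signif(object, digits), signif(expected, digits),
               tolerance = 10^(-(digits + 2)))
}

tiny_fit <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- fit_study(tiny_trial(),
                          study_config(seed = 11, n_per_arm = 3,
                                       n_boot = 200))
    }
    cache
  }
})
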