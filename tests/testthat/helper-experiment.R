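# The default full-scale experiment (dev n = 461, val n = 499, seed 42) is
# expensive, so it is computed once and shared by every test that needs it.
default_experiment <- local({
  cached <- NULL
  function() {
    if (is.null(cached))
      cached <<- suppressWarnings(
        run_experiment(experiment_config(seed = 42, quiet = TRUE)))
    cached
  }
})
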