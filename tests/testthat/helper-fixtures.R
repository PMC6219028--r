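# Small in-code fixtures shared across test files.

small_spec <- function(seed = 3, ...) {
  phantom_spec(size = 96, r1 = 14, r2 = 40, n_seeds = 16, seed = seed, ...)
}

# one small labeled phantom plus its feature table, built once per test run
small_features <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ph <- generate_phantom(small_spec())
      cache <<- list(phantom = ph,
                     features = extract_features(ph$frame, ph$mask, ph$labels))
    }
    cache
  }
})

# a tiny fitted cascade on the small phantom (training = evaluation frame
# is fine for structural checks)
small_model <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- train_multilevel(small_features()$features, seed = 7)
    cache
  }
})
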