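# Expensive fitted models are trained once per test run and shared between
# test files through this cache.
.fit_cache <- new.env(parent = emptyenv())

learnability_fit <- function() {
  if (is.null(.fit_cache$learn)) {
    bench <- learnability_benchmark(seed = 1L)
    fit <- cerex(bench$train, validation = bench$validation,
                 config = cerex_config(seed = 1L, epochs = 30L),
                 paradigm = "multi_corpora")
    .fit_cache$learn <- list(fit = fit, bench = bench,
                             report = evaluate_model(fit, bench$test))
  }
  .fit_cache$learn
}

# A small, quickly trained model for structural tests that need a model
# with usable (not necessarily strong) heads.
quick_fit <- function() {
  if (is.null(.fit_cache$quick)) {
    x <- generate_corpus(synthetic_config("ADE", c("Drug", "Disease"), "ADE",
                                          n_sentences = 80L,
                                          relation_prob = 1, seed = 5L))
    sp <- split_subsets(x, 4L, seed = 6L)
    tr <- cerex:::merge_corpora(sp$parts[1:3], "tr")
    va <- sp$parts[[4L]]
    fit <- cerex(tr, validation = va,
                 config = cerex_config(seed = 2L, epochs = 8L))
    .fit_cache$quick <- list(fit = fit, train = tr, val = va)
  }
  .fit_cache$quick
}
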