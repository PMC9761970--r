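# Reference experimental setups: fixed synthetic study conditions reused by
# the examples, the test suite and the reproduction script, so every entry
# point measures the same thing.

#' Two-corpus learnability benchmark data
#'
#' A noise-free benchmark over the full global label space: a Drug-Disease
#' corpus with the ADE relation and a Drug-Protein corpus with the CPR
#' relation (3 entity types, 2 relation labels). Each corpus is generated at
#' 350 sentences with a deterministic relation rule (`relation_prob = 1`,
#' `noise_rate = 0`) and partitioned into 5/1/1 fifties -- 250 train, 50
#' validation, 50 test -- so that, as with real corpus splits, the splits
#' share a lexicon but no sentences. Totals across the two corpora: 500
#' train / 100 validation / 100 test.
#'
#' @param seed integer seed controlling generation and partitioning.
#' @return list with `train` (list of two corpora), `validation`, `test`.
#' @export
learnability_benchmark <- function(seed = 1L) {
  seed <- as.integer(seed)
  part <- function(name, types, rel, sd) {
    x <- generate_corpus(synthetic_config(name, types, rel,
                                          n_sentences = 350L,
                                          relation_prob = 1, noise_rate = 0,
                                          seed = sd))
    split_subsets(x, 7L, seed = sd + 1L)
  }
  sa <- part("ADE", c("Drug", "Disease"), "ADE", seed * 17L + 100L)
  sb <- part("CPR", c("Drug", "Protein"), "CPR", seed * 17L + 200L)
  list(train = list(merge_corpora(sa$parts[1:5], "ADE_train"),
                    merge_corpora(sb$parts[1:5], "CPR_train")),
       validation = merge_corpora(c(sa$parts[6], sb$parts[6]), "validation"),
       test = merge_corpora(c(sa$parts[7], sb$parts[7]), "test"))
}

#' Two-corpus forgetting benchmark data
#'
#' Study conditions for measuring catastrophic forgetting: corpus A
#' (Drug-Disease, ADE relation) and corpus B (Drug-Protein, CPR relation)
#' have disjoint relation labels, so nothing in B's training signal supports
#' A's relation head. Each corpus is generated at 200 sentences
#' (deterministic relation rule) and split into four fifties: parts 1-2
#' train, part 3 validation, part 4 test.
#'
#' @param seed integer seed.
#' @return list with `train_a`, `train_b`, `validation` (pooled A+B
#'   validation parts), `test_a` (corpus A's held-out part).
#' @export
forgetting_benchmark <- function(seed = 1L) {
  seed <- as.integer(seed)
  part <- function(name, types, rel, sd) {
    x <- generate_corpus(synthetic_config(name, types, rel,
                                          n_sentences = 200L,
                                          relation_prob = 1, noise_rate = 0,
                                          seed = sd))
    split_subsets(x, 4L, seed = sd + 1L)
  }
  sa <- part("ADE", c("Drug", "Disease"), "ADE", seed * 23L + 300L)
  sb <- part("CPR", c("Drug", "Protein"), "CPR", seed * 23L + 400L)
  list(train_a = merge_corpora(sa$parts[1:2], "A_train"),
       train_b = merge_corpora(sb$parts[1:2], "B_train"),
       validation = merge_corpora(c(sa$parts[3], sb$parts[3]), "validation"),
       test_a = sa$parts[[4L]])
}

#' Measure forgetting under continual versus replay-mixing schedules
#'
#' Trains the model twice over the [forgetting_benchmark()] corpora: once
#' with a plain continual schedule (A then B) and once with the continual
#' multi-corpora schedule (A split across steps, B mixed in), then scores
#' relation micro-F1 on A's held-out test set at three points: right after
#' the A-only step, after the full continual run, and after the full
#' replay-mixing run. The gap between the first two is the catastrophic-
#' forgetting drop; the third shows how much partial data replay recovers.
#'
#' @param seed integer seed (data and training).
#' @param epochs epochs per schedule step (default 20).
#' @return named numeric vector: `post_a`, `continual`, `cmc`.
#' @export
forgetting_experiment <- function(seed = 1L, epochs = 20L) {
  bench <- forgetting_benchmark(seed)
  cfg <- cerex_config(seed = as.integer(seed), epochs = as.integer(epochs))
  corpora <- list(bench$train_a, bench$train_b)
  cont <- cerex(build_schedule(corpora, "continual", seed = seed),
                validation = bench$validation, config = cfg)
  post_a <- evaluate_model(checkpoint_model(cont, 1L), bench$test_a,
                           conditional = FALSE)$RE$f1
  f_cont <- evaluate_model(cont, bench$test_a, conditional = FALSE)$RE$f1
  cmc <- cerex(build_schedule(corpora, "continual_multi_corpora", seed = seed),
               validation = bench$validation, config = cfg)
  f_cmc <- evaluate_model(cmc, bench$test_a, conditional = FALSE)$RE$f1
  c(post_a = post_a, continual = f_cont, cmc = f_cmc)
}
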