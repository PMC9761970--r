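test_that("generation is a deterministic function of the config", {
  cfg <- synthetic_config("ADE", c("Drug", "Disease"), "ADE",
                          n_sentences = 10L, seed = 9L)
  expect_identical(generate_corpus(cfg), generate_corpus(cfg))
  cfg2 <- cfg; cfg2$seed <- 10L
  expect_false(identical(generate_corpus(cfg), generate_corpus(cfg2)))
})

test_that("relation probability bounds force relation counts", {
  cfg0 <- synthetic_config("ADE", c("Drug", "Disease"), "ADE",
                           n_sentences = 40L, relation_prob = 0, seed = 2L)
  expect_identical(sum(lengths(generate_corpus(cfg0)$relations)), 0L)
  # with exactly one Drug and one Disease per sentence and p = 1, every
  # sentence carries exactly one relation
  tmpl <- list(c("{Drug}", "induced", "{Disease}", "in", "patients"))
  cfg1 <- synthetic_config("ADE", c("Drug", "Disease"), "ADE",
                           n_sentences = 50L, relation_prob = 1,
                           templates = tmpl, seed = 3L)
  x <- generate_corpus(cfg1)
  expect_identical(unname(lengths(x$relations)), rep(1L, 50L))
  expect_identical(sum(lengths(x$relations)), 50L)
})

test_that("label noise flips types only, never spans", {
  tmpl <- list(c("{Drug}", "induced", "{Disease}", "in", "patients"))
  mkcfg <- function(r) synthetic_config("ADE", c("Drug", "Disease"), "ADE",
                                        n_sentences = 100L, noise_rate = r,
                                        multi_token_prob = 0,
                                        templates = tmpl, seed = 4L)
  clean <- generate_corpus(mkcfg(0))
  noisy <- generate_corpus(mkcfg(0.3))
  spans_of <- function(x) lapply(x$mentions, function(ms)
    lapply(ms, function(m) c(m$start, m$end)))
  expect_identical(spans_of(clean), spans_of(noisy))
  types <- function(x) unlist(lapply(x$mentions, function(ms)
    vapply(ms, function(m) m$type_label, character(1))))
  frac_flipped <- mean(types(clean) != types(noisy))
  expect_gt(frac_flipped, 0.15)
  expect_lt(frac_flipped, 0.45)
})

test_that("subset splitting partitions sentences into near-equal parts", {
  x <- generate_corpus(synthetic_config("ADE", c("Drug", "Disease"), "ADE",
                                        n_sentences = 9L, seed = 5L))
  sp <- split_subsets(x, 3L, seed = 1L)
  expect_identical(sp$part_sizes, rep(3L, 3))
  x10 <- generate_corpus(synthetic_config("ADE", c("Drug", "Disease"), "ADE",
                                          n_sentences = 10L, seed = 5L))
  expect_identical(split_subsets(x10, 3L, seed = 1L)$part_sizes, c(4L, 3L, 3L))
  # union of parts = corpus (as a multiset of sentence ids)
  ids <- function(x) sort(vapply(x$sentences, function(s) s$sentence_id,
                                 character(1)))
  sp10 <- split_subsets(x10, 3L, seed = 1L)
  expect_identical(sort(unlist(lapply(sp10$parts, ids))), ids(x10))
  # k = 1 is the corpus itself (possibly permuted)
  expect_identical(ids(split_subsets(x10, 1L, seed = 2L)$parts[[1]]), ids(x10))
  expect_error(split_subsets(x10, 11L), "k must be")
})

test_that("schedules realise the three paradigms with sentence conservation", {
  mk <- function(name, n, seed) generate_corpus(
    synthetic_config(name, c("Drug", "Disease"), "ADE", n_sentences = n,
                     seed = seed))
  ade <- mk("ADE", 9L, 6L); ddi <- mk("DDI", 8L, 7L); cpr <- mk("CPR", 7L, 8L)
  ids <- function(x) vapply(x$sentences, function(s) s$sentence_id, character(1))
  all_ids <- sort(c(ids(ade), ids(ddi), ids(cpr)))

  cont <- build_schedule(list(ade, ddi, cpr), "continual", seed = 1L)
  expect_length(cont$steps, 3L)
  expect_identical(sort(ids(cont$steps[[1]]$pool)), sort(ids(ade)))
  expect_identical(sort(ids(cont$steps[[3]]$pool)), sort(ids(cpr)))

  mc <- build_schedule(list(ade, ddi, cpr), "multi_corpora", seed = 1L)
  expect_length(mc$steps, 1L)
  expect_identical(sort(ids(mc$steps[[1]]$pool)), all_ids)

  cmc <- build_schedule(list(ade, ddi, cpr), "continual_multi_corpora", seed = 1L)
  expect_length(cmc$steps, 3L)
  # step 1 = first third of ADE; step 2 = ADE part 2 + DDI part 1;
  # step 3 = ADE part 3 + DDI part 2 + all of CPR
  expect_identical(names(cmc$steps[[1]]$components), "ADE_sub1")
  expect_identical(names(cmc$steps[[2]]$components), c("ADE_sub2", "DDI_sub1"))
  expect_identical(names(cmc$steps[[3]]$components),
                   c("ADE_sub3", "DDI_sub2", "CPR_sub1"))
  expect_identical(sort(unname(unlist(lapply(cmc$steps,
                                             function(st) ids(st$pool))))),
                   all_ids)
  # corpus i first appears at step i, each subset used exactly once
  expect_identical(length(ids(cmc$steps[[1]]$pool)), 3L)

  one <- build_schedule(list(ade), "continual", seed = 1L)
  expect_length(one$steps, 1L)
  expect_identical(sort(ids(one$steps[[1]]$pool)), sort(ids(ade)))
  expect_error(build_schedule(list(), "continual"), "at least one")
})

test_that("schedules and splits are seed-deterministic", {
  mk <- function(seed) generate_corpus(
    synthetic_config("ADE", c("Drug", "Disease"), "ADE", n_sentences = 12L,
                     seed = seed))
  a <- mk(1L)
  expect_identical(split_subsets(a, 3L, seed = 4L), split_subsets(a, 3L, seed = 4L))
  expect_identical(build_schedule(list(a, mk(2L)), "continual_multi_corpora", 9L),
                   build_schedule(list(a, mk(2L)), "continual_multi_corpora", 9L))
})

test_that("foreign corpora shift lexicon and can remap annotation guidelines", {
  cfg <- synthetic_config("ADE", c("Drug", "Disease"), "ADE",
                          n_sentences = 60L, seed = 11L)
  base <- generate_corpus(cfg)
  f0 <- generate_foreign_corpus(cfg, fresh_lexicon_frac = 0.5, seed = 99L)
  expect_identical(f0$name, "ADE_foreign")
  # some mention surfaces are new relative to the training lexicon
  surf <- function(x) unique(unlist(lapply(seq_along(x$sentences), function(i)
    lapply(x$mentions[[i]], function(m)
      paste(x$sentences[[i]]$tokens[(m$start + 1):(m$end + 1)], collapse = " ")))))
  expect_gt(length(setdiff(surf(f0), surf(base))), 0L)
  f1 <- generate_foreign_corpus(cfg, remap_frac = 0.5, remap_from = "Drug",
                                remap_to = "Disease", seed = 99L)
  ty <- function(x) table(unlist(lapply(x$mentions, function(ms)
    vapply(ms, function(m) m$type_label, character(1)))))
  expect_lt(ty(f1)[["Drug"]], ty(f0)[["Drug"]])
})
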