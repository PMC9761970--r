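mention_list <- function(...) {
  specs <- list(...)
  lapply(seq_along(specs), function(k)
    entity_mention(specs[[k]][[1]], specs[[k]][[2]], specs[[k]][[3]],
                   sprintf("T%d", k)))
}

triple <- function(a, b, label) list(a = a, b = b, label = label)

test_that("span scoring pools token counts and excludes O by default", {
  expect_equal(evaluate_sp(list(c("S", "O", "B", "E")),
                           list(c("S", "O", "B", "E")))$f1, 1)
  # all-O predictions have zero recall against gold entities
  r <- evaluate_sp(list(rep("O", 4)), list(c("S", "O", "B", "E")))
  expect_equal(r$recall, 0)
  # worked counting case
  r2 <- evaluate_sp(list(c("S", "O", "B", "E")), list(c("S", "O", "O", "O")))
  expect_identical(unname(r2$counts), c(1, 2, 0))
  expect_equal(r2$precision, 1 / 3)
  expect_equal(r2$recall, 1)
  expect_equal(r2$f1, 0.5)
  # counting O as a class turns the same case into token accuracy-like pooling
  r3 <- evaluate_sp(list(c("S", "O", "B", "E")), list(c("S", "O", "O", "O")),
                    include_o = TRUE)
  expect_identical(unname(r3$counts), c(2, 2, 2))
  expect_error(evaluate_sp(list(c("S", "O")), list(c("S"))), "length")
})

test_that("entity scoring demands exact span and type", {
  gold <- list(mention_list(list(0, 0, "Drug")))
  expect_identical(unname(evaluate_et(gold, gold)$counts), c(1, 0, 0))
  # right span, wrong type: both an FP and an FN
  pred <- list(mention_list(list(0, 0, "Disease")))
  expect_identical(unname(evaluate_et(pred, gold)$counts), c(0, 1, 1))
  # no predictions against 3 gold
  gold3 <- list(mention_list(list(0, 0, "Drug"), list(2, 3, "Disease"),
                             list(5, 5, "Drug")))
  r <- evaluate_et(list(list()), gold3)
  expect_identical(unname(r$counts), c(0, 0, 3))
  expect_equal(r$f1, 0)
})

test_that("relation scoring matches unordered exact triples", {
  ga <- entity_mention(0, 0, "Drug", "T1")
  gb <- entity_mention(3, 4, "Disease", "T2")
  gold <- list(list(triple(ga, gb, "ADE")))
  # order of the pair does not matter
  expect_identical(unname(evaluate_re(list(list(triple(gb, ga, "ADE"))),
                                      gold)$counts), c(1, 0, 0))
  # correct pair, wrong label: FP and FN
  expect_identical(unname(evaluate_re(list(list(triple(ga, gb, "DDI"))),
                                      gold)$counts), c(0, 1, 1))
  # pred {t1,t2} vs gold {t1}
  extra <- triple(entity_mention(6, 6, "Drug", "T3"), gb, "ADE")
  r <- evaluate_re(list(list(triple(ga, gb, "ADE"), extra)), gold)
  expect_identical(unname(r$counts), c(1, 1, 0))
  expect_equal(r$f1, 2 / 3, tolerance = 1e-12)
  # wrong endpoint type breaks the triple
  ga_wrong <- entity_mention(0, 0, "Disease", "T1")
  expect_identical(unname(evaluate_re(list(list(triple(ga_wrong, gb, "ADE"))),
                                      gold)$counts), c(0, 1, 1))
})

test_that("combined scoring pools counts before the ratio", {
  a <- list(counts = c(tp = 1, fp = 1, fn = 0))
  b <- list(counts = c(tp = 0, fp = 0, fn = 1))
  r <- evaluate_combined(list(a, b))
  expect_equal(r$precision, 0.5)
  expect_equal(r$recall, 0.5)
  expect_equal(r$f1, 0.5)
  one <- evaluate_sp(list(c("S", "O")), list(c("S", "S")))
  expect_identical(evaluate_combined(list(one))[c("precision", "recall", "f1")],
                   one[c("precision", "recall", "f1")])
  perfect <- list(counts = c(tp = 5, fp = 0, fn = 0))
  expect_equal(evaluate_combined(list(perfect, perfect))$f1, 1)
})

test_that("united-tag NER scoring counts joint span+type matches", {
  gold <- list(mention_list(list(0, 0, "Drug"), list(2, 2, "Drug"),
                            list(4, 5, "Disease"), list(7, 7, "Drug")))
  pred <- list(mention_list(list(0, 0, "Drug"), list(2, 2, "Drug"),
                            list(4, 5, "Drug"), list(7, 7, "Drug")))
  expect_identical(unname(evaluate_united_ner(pred, gold)$counts), c(3, 1, 1))
  expect_equal(evaluate_united_ner(gold, gold)$f1, 1)
  d1 <- list(mention_list(list(0, 1, "Drug"), list(3, 3, "Drug")))
  d2 <- list(mention_list(list(5, 5, "Drug"), list(7, 8, "Drug")))
  expect_equal(evaluate_united_ner(d1, d2)$f1, 0)
})

test_that("every scorer equals the brute-force matcher on randomized cases", {
  set.seed(77)
  types <- c("Drug", "Disease", "Protein")
  rels <- c("ADE", "DDI")
  for (case in 1:500) {
    kind <- case %% 3L
    if (kind == 0L) {
      pred <- list(); gold <- list()
      for (s in 1:2) {
        n <- sample(1:8, 1)
        pred[[s]] <- sample(c("B", "I", "O", "E", "S"), n, replace = TRUE)
        gold[[s]] <- sample(c("B", "I", "O", "E", "S"), n, replace = TRUE)
      }
      got <- evaluate_sp(pred, gold)
      cnt <- oracle_sp_counts(pred, gold)
      expect_identical(unname(got$counts), unname(as.numeric(cnt)))
      expect_equal(got$f1, oracle_prf(cnt), tolerance = 1e-12)
    } else if (kind == 1L) {
      pred <- list(random_mentions(10, types))
      gold <- list(random_mentions(10, types))
      got <- evaluate_et(pred, gold)
      cnt <- oracle_match_counts(
        vapply(pred[[1]], function(m) paste(m$start, m$end, m$type_label),
               character(1)),
        vapply(gold[[1]], function(m) paste(m$start, m$end, m$type_label),
               character(1)))
      expect_identical(unname(got$counts), unname(as.numeric(cnt)))
      expect_equal(got$f1, oracle_prf(cnt), tolerance = 1e-12)
    } else {
      mk_triples <- function() {
        ms <- random_mentions(12, types)
        if (length(ms) < 2) return(list())
        out <- list()
        for (r in seq_len(sample(0:3, 1))) {
          ij <- sample(seq_along(ms), 2)
          out[[length(out) + 1L]] <- triple(ms[[ij[1]]], ms[[ij[2]]],
                                            sample(rels, 1))
        }
        out
      }
      pred <- list(mk_triples()); gold <- list(mk_triples())
      key <- function(tr) {
        ka <- paste(tr$a$start, tr$a$end, tr$a$type_label)
        kb <- paste(tr$b$start, tr$b$end, tr$b$type_label)
        paste(paste(sort(c(ka, kb)), collapse = "&"), tr$label)
      }
      got <- evaluate_re(pred, gold)
      cnt <- oracle_match_counts(vapply(pred[[1]], key, character(1)),
                                 vapply(gold[[1]], key, character(1)))
      expect_identical(unname(got$counts), unname(as.numeric(cnt)))
      expect_equal(got$f1, oracle_prf(cnt), tolerance = 1e-12)
    }
  }
})

test_that("corpus-adaptation evaluation guards its preconditions", {
  qf <- quick_fit()
  cfg <- synthetic_config("ADE", c("Drug", "Disease"), "ADE",
                          n_sentences = 20L, relation_prob = 1, seed = 61L)
  foreign <- generate_foreign_corpus(cfg, seed = 62L)
  rep <- corpus_adaptation_eval(qf$fit, foreign)
  expect_s3_class(rep, "cerex_report")
  expect_true(all(vapply(c("SP", "ET", "RE"), function(t)
    rep[[t]]$f1 >= 0 && rep[[t]]$f1 <= 1, logical(1))))
  expect_error(corpus_adaptation_eval(qf$fit, corpus("empty", list())), "empty")
  alien <- generate_corpus(synthetic_config("CPR", c("Drug", "Protein"), "CPR",
                                            n_sentences = 5L, seed = 63L))
  expect_error(corpus_adaptation_eval(qf$fit, alien), "outside the model")
})

test_that("guideline remapping degrades typing monotonically in the remap rate", {
  qf <- quick_fit()
  cfg <- synthetic_config("ADE", c("Drug", "Disease"), "ADE",
                          n_sentences = 60L, relation_prob = 1, seed = 64L)
  f1s <- vapply(c(0, 0.2, 0.4), function(f) {
    foreign <- generate_foreign_corpus(cfg, fresh_lexicon_frac = 0,
                                       remap_frac = f, remap_from = "Drug",
                                       remap_to = "Disease", seed = 65L)
    corpus_adaptation_eval(qf$fit, foreign)$ET$f1
  }, numeric(1))
  expect_true(f1s[1] >= f1s[2] && f1s[2] >= f1s[3])
})
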