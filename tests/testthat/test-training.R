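small_corpus <- function(n = 20L, seed = 51L, types = c("Drug", "Disease"),
                         rel = "ADE") {
  generate_corpus(synthetic_config("ADE", types, rel, n_sentences = n,
                                   relation_prob = 1, seed = seed))
}

fresh_model <- function(x, cfg = cerex_config(seed = 2L)) {
  m <- cerex:::model_init(cfg)
  cerex:::model_expand_for_corpus(m, x)
}

test_that("a training step is deterministic and zero learning rate is inert", {
  x <- small_corpus()
  m <- fresh_model(x)
  batch <- cerex:::corpus_batch(x, 1:4)
  s1 <- train_step(m, batch)
  s2 <- train_step(m, batch)
  expect_identical(s1$model$params, s2$model$params)
  expect_identical(s1$loss, s2$loss)
  s0 <- train_step(m, batch, lr = 0)
  expect_identical(s0$model$params, m$params)
})

test_that("repeated steps on an easy batch drive the loss down", {
  x <- small_corpus(8L)
  m <- fresh_model(x, cerex_config(seed = 3L, lr = 5e-4))
  batch <- cerex:::corpus_batch(x, 1:8)
  first <- train_step(m, batch)
  loss0 <- first$loss
  m <- first$model
  for (i in 1:49) {
    st <- train_step(m, batch)
    m <- st$model
  }
  expect_lt(st$loss, loss0 * 0.5)
})

test_that("schedules grow vocabulary and heads exactly when new labels appear", {
  a <- small_corpus(16L, seed = 52L)
  b <- generate_corpus(synthetic_config("CPR", c("Drug", "Protein"), "CPR",
                                        n_sentences = 16L, relation_prob = 1,
                                        seed = 53L))
  cfg <- cerex_config(seed = 4L, epochs = 1L)
  fit <- cerex(build_schedule(list(a, b), "continual", seed = 1L), config = cfg)
  expect_identical(fit$vocab$entity_types, c("Drug", "Disease", "Protein"))
  expect_identical(fit$vocab$relation_types, c("ADE", "CPR"))
  # step-1 checkpoint predates the CPR head and Protein head
  ck1 <- fit$checkpoints[[1]]
  expect_identical(ck1$vocab$relation_types, "ADE")
  expect_false("re_head.CPR.W1" %in% names(ck1$params))
  expect_true("re_head.CPR.W1" %in% names(fit$params))
  # parameters only ever grow across a schedule
  expect_true(all(names(ck1$params) %in% names(fit$params)))
  # heads present at step 1 keep their shapes
  for (k in grep("^(sp|et)\\.", names(ck1$params), value = TRUE))
    expect_identical(dim(ck1$params[[k]]), dim(fit$params[[k]]))
  expect_length(fit$checkpoints, 2L)
})

test_that("a one-step schedule equals plain multi-corpora training", {
  a <- small_corpus(16L, seed = 54L)
  cfg <- cerex_config(seed = 5L, epochs = 2L)
  f1 <- cerex(build_schedule(list(a), "multi_corpora", seed = 9L), config = cfg)
  f2 <- cerex(build_schedule(list(a), "continual", seed = 9L), config = cfg)
  expect_identical(f1$params, f2$params)
})

test_that("the inference cascade degrades gracefully and enumerates pairs", {
  x <- small_corpus(30L, seed = 55L)
  m <- fresh_model(x)   # untrained: outputs exist but are uninformative
  s <- x$sentences[[1]]
  inf <- infer_sentence(m, s)
  expect_length(inf$tags, s$n)
  expect_true(all(inf$tags %in% c("B", "I", "O", "E", "S")))
  # all-O tags yield no mentions and no relations
  m2 <- m
  m2$params[["sp.W2"]][] <- 0
  m2$params[["sp.b2"]] <- c(-10, -10, 10, -10, -10)  # force O everywhere
  inf2 <- infer_sentence(m2, s)
  expect_identical(inf2$tags, rep("O", s$n))
  expect_length(inf2$mentions, 0L)
  expect_length(inf2$relations, 0L)
  # k predicted mentions -> k(k-1)/2 relation candidate evaluations
  qf <- quick_fit()
  for (i in 1:5) {
    inf3 <- infer_sentence(qf$fit, qf$val$sentences[[i]])
    k <- length(inf3$mentions)
    cand <- cerex:::predict_relations(qf$fit, qf$val$sentences[[i]],
                                      inf3$mentions)
    expect_lte(length(cand), k * (k - 1) / 2)
    if (k < 2) expect_length(inf3$relations, 0L)
  }
})

test_that("gold-conditioned inference substitutes upstream stages", {
  qf <- quick_fit()
  x <- qf$val
  i <- which(lengths(x$mentions) >= 2L)[1]
  s <- x$sentences[[i]]; gm <- x$mentions[[i]]
  c1 <- infer_conditional(qf$fit, s, gm, "gold_sp")
  # ET+ mentions sit exactly on gold spans
  for (m in c1$mentions) {
    hit <- any(vapply(gm, function(g) g$start == m$start && g$end == m$end,
                      logical(1)))
    expect_true(hit)
  }
  expect_lte(length(c1$mentions), length(gm))
  c2 <- infer_conditional(qf$fit, s, gm, "gold_sp_et")
  for (r in c2$relations) expect_true(r$label %in% qf$fit$vocab$relation_types)
  # zero gold mentions -> no conditioned predictions
  empty_i <- which(lengths(x$mentions) == 0L)
  if (length(empty_i)) {
    c0 <- infer_conditional(qf$fit, x$sentences[[empty_i[1]]], list(), "gold_sp")
    expect_length(c0$mentions, 0L)
  }
  # when SP predictions happen to equal gold spans, gold_sp typing equals
  # the pipeline's typing
  for (j in seq_along(x$sentences)) {
    inf <- infer_sentence(qf$fit, x$sentences[[j]])
    pred_spans <- lapply(inf$mentions, function(m) c(m$start, m$end))
    gold_spans <- lapply(x$mentions[[j]], function(m) c(m$start, m$end))
    if (length(gold_spans) && identical(pred_spans, gold_spans)) {
      cg <- infer_conditional(qf$fit, x$sentences[[j]], x$mentions[[j]],
                              "gold_sp")
      expect_identical(lapply(cg$mentions, function(m) m$type_label),
                       lapply(inf$mentions, function(m) m$type_label))
      break
    }
  }
})

test_that("training rejects marker augmentation with hard sharing at config time", {
  expect_error(cerex_config(sharing = "hard", augmentation = "entity_marker"),
               "incompatible")
  expect_silent(cerex_config(sharing = "hard", augmentation = "vanilla"))
})
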