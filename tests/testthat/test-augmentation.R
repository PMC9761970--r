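test_that("entity markers reproduce the worked example and round-trip", {
  s <- sentence(c("Pravastatin", "is", "associated", "with", "myotonia",
                  "in", "animals"))
  m <- list(entity_mention(0, 0, "Drug", "T1"),
            entity_mention(4, 4, "Disease", "T2"))
  mk <- insert_entity_markers(s, m)
  expect_identical(mk$tokens,
                   c("[Drug_start]", "Pravastatin", "[Drug_end]", "is",
                     "associated", "with", "[Disease_start]", "myotonia",
                     "[Disease_end]", "in", "animals"))
  expect_identical(mk$n, s$n + 2L * length(m))
  expect_identical(strip_markers(mk)$tokens, s$tokens)
  expect_identical(unname(mk$marker_start), c(0L, 6L))
  # no mentions: unchanged, empty maps
  mk0 <- insert_entity_markers(s, list())
  expect_identical(mk0$tokens, s$tokens)
  expect_length(mk0$marker_start, 0L)
  # adjacent single-token mentions
  s2 <- toy_sentence(4)
  mk2 <- insert_entity_markers(s2, list(entity_mention(0, 0, "Drug", "a"),
                                        entity_mention(1, 1, "Disease", "b")))
  expect_identical(mk2$n, 8L)
  expect_identical(strip_markers(mk2)$tokens, s2$tokens)
})

test_that("marker insertion round-trips on random mention sets", {
  set.seed(17)
  for (rep in 1:1000) {
    n <- sample(1:12, 1)
    s <- toy_sentence(n)
    ments <- random_mentions(n)
    mk <- insert_entity_markers(s, ments)
    expect_identical(strip_markers(mk)$tokens, s$tokens)
    expect_identical(mk$n, n + 2L * length(ments))
  }
})

test_that("prototypes are pooled means of untrained base-encoder vectors", {
  toks <- c("aspirin", "ibuprofen", "fever", "caused", "by")
  b <- encoder_bundle(toks, d = 64L, seed = 8L)
  s1 <- sentence(c("aspirin", "caused", "fever"))
  s2 <- sentence(c("ibuprofen", "caused", "fever"))
  x <- corpus("c", list(s1, s2),
              list(list(entity_mention(0, 0, "Drug", "T1"),
                        entity_mention(2, 2, "Disease", "T2")),
                   list(entity_mention(0, 0, "Drug", "T3"))))
  P <- compute_prototypes(x, b, dim = 50L)
  expect_identical(dim(P), c(2L, 50L))
  # independent mean oracle: pool each mention token vector, then average
  pool <- function(v) {
    ends <- ceiling(seq_len(50) * length(v) / 50)
    starts <- c(1, head(ends, -1) + 1)
    sapply(seq_len(50), function(i) max(v[starts[i]:ends[i]]))
  }
  h1 <- encode_tokens(b, "RE", s1$tokens)
  h2 <- encode_tokens(b, "RE", s2$tokens)
  expect_equal(unname(P["Drug", ]), unname((pool(h1[1, ]) + pool(h2[1, ])) / 2),
               tolerance = 1e-12)
  # t = 1: the single token's pooled vector
  expect_equal(unname(P["Disease", ]), unname(pool(h1[3, ])), tolerance = 1e-12)
  # a type with no mentions is an error
  x2 <- corpus("c2", list(s1), list(list(entity_mention(0, 0, "Drug", "T1"))))
  expect_silent(compute_prototypes(x2, b))
  expect_error(compute_prototypes(corpus("c3", list(s1), list(list())), b))
})

test_that("prototype tables stay bit-identical through model training", {
  x <- generate_corpus(synthetic_config("ADE", c("Drug", "Disease"), "ADE",
                                        n_sentences = 30L, relation_prob = 1,
                                        seed = 31L))
  cfg1 <- cerex_config(augmentation = "prototype", seed = 4L, epochs = 1L)
  cfg4 <- cerex_config(augmentation = "prototype", seed = 4L, epochs = 4L)
  fit1 <- cerex(x, config = cfg1)
  fit4 <- cerex(x, config = cfg4)
  # identical data and seed, three extra epochs of training: the frozen
  # prototype table must not move while the trained parameters do
  expect_identical(fit1$proto, fit4$proto)
  expect_false(identical(fit1$params[["re.E"]], fit4$params[["re.E"]]))
})

test_that("pair representations follow the four modes and swap symmetrically", {
  set.seed(23)
  d <- 6L
  n <- 8L
  H <- matrix(rnorm(n * d), n, d)
  ej <- entity_mention(1, 2, "Drug", "T1")
  ek <- entity_mention(5, 5, "Disease", "T2")

  v <- pair_representation("vanilla", H, ej, ek)
  expect_length(v, 2L * d)
  expect_equal(as.numeric(v), c(colSums(H[2:3, ]), H[6, ]), tolerance = 1e-12)
  # single-token spans concatenate the token vectors themselves
  v1 <- pair_representation("vanilla", H, entity_mention(0, 0, "Drug", "a"),
                            entity_mention(4, 4, "Disease", "b"))
  expect_equal(as.numeric(v1), c(H[1, ], H[5, ]), tolerance = 1e-12)

  emb <- type_embedding_table(c("Drug", "Disease"), dim = 5L, seed = 2L)
  vt <- pair_representation("type_embedding", H, ej, ek, aux = emb,
                            type_labels = c("Drug", "Disease"))
  expect_length(vt, 2L * d + 10L)
  # independent concatenate(sum, lookup, sum, lookup) oracle
  expect_equal(as.numeric(vt),
               c(colSums(H[2:3, ]), emb["Drug", ], H[6, ], emb["Disease", ]),
               tolerance = 1e-12)
  # swapping the mentions permutes the two halves exactly
  vt_sw <- pair_representation("type_embedding", H, ek, ej, aux = emb,
                               type_labels = c("Disease", "Drug"))
  k <- d + 5L
  expect_equal(as.numeric(vt_sw), c(as.numeric(vt)[(k + 1):(2 * k)],
                                    as.numeric(vt)[1:k]), tolerance = 1e-12)

  s <- toy_sentence(n)
  mk <- insert_entity_markers(s, list(ej, ek))
  Hm <- matrix(rnorm(mk$n * d), mk$n, d)
  vm <- pair_representation("entity_marker", Hm, ej, ek, aux = mk)
  expect_length(vm, 2L * d)
  expect_equal(as.numeric(vm),
               c(Hm[mk$marker_start[["T1"]] + 1L, ],
                 Hm[mk$marker_start[["T2"]] + 1L, ]), tolerance = 1e-12)
  expect_error(pair_representation("entity_marker", Hm, ej,
                                   entity_mention(6, 6, "Drug", "T9"),
                                   aux = mk), "T9")
  expect_error(pair_representation("type_embedding", H, ej, ek),
               "type_labels|table")
  expect_error(pair_representation("vanilla", H, ej,
                                   entity_mention(7, 9, "Drug", "T8")),
               "outside")
})
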