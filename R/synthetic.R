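# Deterministic RNG scoping: evaluate expr under a seed, restoring the
# caller's RNG state afterwards, so generators never perturb a session.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Type-specific pseudo-word inventories. Each entity type draws surface forms
# from its own syllable stock, so lexicons are disjoint across types and the
# surface form carries a learnable type signal -- the property real chemical,
# disease and protein names have (suffixes like -ine, -itis, gene symbols).
.lexicon_parts <- list(
  Drug = list(pre = c("me", "pra", "lo", "va", "flu", "ami", "keta", "dexa", "carba", "rito"),
              mid = c("quita", "flox", "stat", "pril", "vir", "cycl", "mab", "zep", "metho", "glit"),
              suf = c("ine", "ol", "in", "ide", "azone", "amide", "avir", "azine"),
              mod = c("hydrochloride", "sodium", "acetate", "sulfate")),
  Disease = list(pre = c("derm", "hepat", "neur", "card", "nephr", "arthr", "gastr", "myel", "pancre", "encephal"),
                 mid = c("ato", "opath", "oto", "ito", "omal", "ulo"),
                 suf = c("itis", "osis", "emia", "algia", "opathy", "oma"),
                 mod = c("acute", "chronic", "severe", "recurrent")),
  Protein = list(pre = c("MMP", "CYP", "TNF", "IL", "EGFR", "JAK", "MAPK", "ABC", "HDAC", "PARP"),
                 mid = character(),
                 suf = as.character(1:30),
                 mod = c("receptor", "kinase", "isoform"))
)

# Connective filler vocabulary shared by all templates.
.filler_tokens <- c("the", "a", "of", "in", "with", "was", "were", "and",
                    "patients", "patient", "reported", "observed", "study",
                    "after", "during", "treatment", "cases", "two", "at",
                    "baseline", "clinical", "data", "findings", "not")

# Built-in sentence templates per relation label. "{Type}" marks a mention
# slot; templates with fewer or zero slots keep the per-sentence mention
# count variable, as in the real corpora.
default_templates <- function(relation_label) {
  switch(relation_label,
    ADE = list(
      c("two", "cases", "of", "{Drug}", "induced", "{Disease}", "were", "reported"),
      c("a", "patient", "developed", "{Disease}", "after", "receiving", "{Drug}"),
      c("{Drug}", "therapy", "was", "complicated", "by", "{Disease}"),
      c("treatment", "with", "{Drug}", "may", "cause", "{Disease}", "in", "patients"),
      c("{Drug}", "and", "{Drug}", "were", "associated", "with", "{Disease}"),
      c("the", "patient", "received", "{Drug}", "during", "the", "study"),
      c("{Disease}", "was", "documented", "at", "baseline")),
    DDI = list(
      c("{Drug}", "may", "potentiate", "the", "toxic", "effects", "of", "{Drug}"),
      c("coadministration", "of", "{Drug}", "and", "{Drug}", "is", "not", "recommended"),
      c("{Drug}", "did", "not", "alter", "the", "pharmacokinetics", "of", "{Drug}"),
      c("{Drug}", "increased", "plasma", "levels", "of", "{Drug}", "in", "patients"),
      c("{Drug}", "was", "well", "tolerated", "in", "the", "study")),
    CPR = list(
      c("{Drug}", "activities", "against", "{Protein}", "were", "observed"),
      c("{Drug}", "is", "a", "potent", "inhibitor", "of", "{Protein}"),
      c("{Protein}", "expression", "was", "unchanged", "by", "{Drug}"),
      c("binding", "of", "{Drug}", "to", "{Protein}", "was", "reported"),
      c("{Protein}", "levels", "were", "measured", "at", "baseline")),
    stop("no built-in templates for relation label '", relation_label,
         "'; supply config$templates")
  )
}

# Alternative phrasings used by the foreign-corpus variant.
foreign_templates <- function(relation_label) {
  switch(relation_label,
    ADE = list(
      c("{Disease}", "occurred", "in", "a", "patient", "treated", "with", "{Drug}"),
      c("we", "describe", "{Drug}", "related", "{Disease}", "in", "two", "cases"),
      c("onset", "of", "{Disease}", "followed", "exposure", "to", "{Drug}"),
      c("{Drug}", "was", "withdrawn", "after", "{Disease}", "appeared"),
      c("no", "adverse", "events", "were", "recorded", "for", "{Drug}")),
    DDI = list(
      c("interaction", "between", "{Drug}", "and", "{Drug}", "was", "suspected"),
      c("{Drug}", "exposure", "rose", "when", "combined", "with", "{Drug}"),
      c("{Drug}", "monotherapy", "was", "continued")),
    CPR = list(
      c("{Protein}", "was", "inhibited", "by", "{Drug}", "in", "vitro"),
      c("exposure", "to", "{Drug}", "reduced", "{Protein}", "activity"),
      c("{Protein}", "assays", "were", "negative")),
    stop("no foreign templates for relation label '", relation_label, "'")
  )
}

#' Configuration for the synthetic-corpus generator
#'
#' Describes one synthetic corpus emulating the structure of the adverse drug
#' event / drug-drug interaction / chemical-protein corpora: each corpus
#' annotates its own subset of the global entity types (chemical/drug,
#' phenotype/disease, protein/gene) and a single relation label connecting an
#' admissible pair of those types.
#'
#' @param corpus_name name for the generated corpus.
#' @param entity_type_set entity types this corpus annotates.
#' @param relation_label the corpus's relation label (e.g. "ADE").
#' @param relation_arg_types length-2 character vector: the entity types an
#'   instance of `relation_label` connects (order irrelevant; may repeat,
#'   e.g. `c("Drug","Drug")`).
#' @param n_sentences number of sentences to generate.
#' @param lexicon_size surface forms per entity type.
#' @param multi_token_prob probability a surface form spans two tokens.
#' @param relation_prob probability a co-occurring admissible mention pair is
#'   annotated with the relation.
#' @param noise_rate fraction of mention type labels flipped (labels only,
#'   never spans) within `entity_type_set`, emulating annotation-guideline
#'   deviations.
#' @param templates optional list of token-vector templates with `{Type}`
#'   slots; defaults to a built-in set for `relation_label`.
#' @param seed integer seed; the whole corpus is a deterministic function of
#'   the config.
#' @return an object of class `cerex_synth_config`.
#' @export
synthetic_config <- function(corpus_name, entity_type_set, relation_label,
                             relation_arg_types = NULL,
                             n_sentences = 100L, lexicon_size = 40L,
                             multi_token_prob = 0.25, relation_prob = 0.9,
                             noise_rate = 0, templates = NULL, seed = 1L) {
  if (n_sentences < 1L) stop("n_sentences must be >= 1")
  stopifnot(relation_prob >= 0, relation_prob <= 1,
            noise_rate >= 0, noise_rate <= 1,
            multi_token_prob >= 0, multi_token_prob <= 1)
  if (is.null(relation_arg_types)) {
    relation_arg_types <- switch(relation_label,
      ADE = c("Drug", "Disease"), DDI = c("Drug", "Drug"),
      CPR = c("Drug", "Protein"),
      stop("relation_arg_types must be given for label '", relation_label, "'"))
  }
  if (!all(relation_arg_types %in% entity_type_set))
    stop("relation argument types must belong to entity_type_set")
  if (is.null(templates)) templates <- default_templates(relation_label)
  used <- unique(unlist(lapply(templates, function(tp)
    sub("^\\{(.+)\\}$", "\\1", tp[grepl("^\\{.+\\}$", tp)]))))
  if (!all(used %in% entity_type_set))
    stop("templates reference types outside entity_type_set: ",
         paste(setdiff(used, entity_type_set), collapse = ", "))
  structure(list(corpus_name = corpus_name,
                 entity_type_set = entity_type_set,
                 relation_label = relation_label,
                 relation_arg_types = relation_arg_types,
                 n_sentences = as.integer(n_sentences),
                 lexicon_size = as.integer(lexicon_size),
                 multi_token_prob = multi_token_prob,
                 relation_prob = relation_prob,
                 noise_rate = noise_rate,
                 templates = templates,
                 seed = as.integer(seed)),
            class = "cerex_synth_config")
}

# Build a lexicon of surface forms (list of token vectors) for one type.
build_lexicon <- function(type, size, multi_token_prob) {
  parts <- .lexicon_parts[[type]]
  if (is.null(parts)) stop("no syllable inventory for entity type '", type, "'")
  forms <- list()
  seen <- character()
  guard <- 0L
  while (length(forms) < size) {
    guard <- guard + 1L
    if (guard > 50L * size) stop("lexicon for type '", type, "' exhausted")
    if (type == "Protein") {
      w <- paste0(sample(parts$pre, 1L), sample(parts$suf, 1L))
    } else {
      w <- paste0(sample(parts$pre, 1L),
                  if (length(parts$mid)) sample(parts$mid, 1L) else "",
                  sample(parts$suf, 1L))
    }
    if (w %in% seen) next
    seen <- c(seen, w)
    if (stats::runif(1) < multi_token_prob) {
      form <- if (type == "Disease") c(sample(parts$mod, 1L), w)
              else c(w, sample(parts$mod, 1L))
    } else form <- w
    forms[[length(forms) + 1L]] <- form
  }
  forms
}

#' Generate a synthetic annotated corpus
#'
#' Sentences are built from templates whose `{Type}` slots are filled with
#' surface forms from per-type lexicons (disjoint across types); every filled
#' slot becomes a gold mention, and every co-occurring mention pair whose
#' types match the corpus's relation argument types is annotated with the
#' corpus relation label with probability `relation_prob`. With
#' `noise_rate` r, a fraction r of mention type labels are flipped to another
#' type from the corpus's type set (spans untouched). The output is a
#' deterministic function of the config, including its seed.
#'
#' @param config a [synthetic_config()].
#' @return a `cerex_corpus`.
#' @export
generate_corpus <- function(config) {
  stopifnot(inherits(config, "cerex_synth_config"))
  with_seed(config$seed, generate_corpus_impl(config))
}

generate_corpus_impl <- function(config) {
  lex <- lapply(stats::setNames(config$entity_type_set, config$entity_type_set),
                function(t) build_lexicon(t, config$lexicon_size,
                                          config$multi_token_prob))
  for (t in names(lex)) if (!length(lex[[t]]))
    stop("empty lexicon for required type '", t, "'")

  sents <- vector("list", config$n_sentences)
  mentions <- vector("list", config$n_sentences)
  relations <- vector("list", config$n_sentences)
  tid <- 0L
  for (si in seq_len(config$n_sentences)) {
    tp <- config$templates[[sample.int(length(config$templates), 1L)]]
    toks <- character(0)
    ms <- list()
    for (piece in tp) {
      if (grepl("^\\{.+\\}$", piece)) {
        type <- sub("^\\{(.+)\\}$", "\\1", piece)
        form <- lex[[type]][[sample.int(length(lex[[type]]), 1L)]]
        st <- length(toks)                     # 0-based start
        toks <- c(toks, form)
        tid <- tid + 1L
        ms[[length(ms) + 1L]] <-
          entity_mention(st, st + length(form) - 1L, type, sprintf("T%d", tid))
      } else {
        toks <- c(toks, piece)
      }
    }
    # label noise: flip type labels only
    if (config$noise_rate > 0 && length(ms) && length(config$entity_type_set) > 1L) {
      for (k in seq_along(ms)) {
        if (stats::runif(1) < config$noise_rate) {
          others <- setdiff(config$entity_type_set, ms[[k]]$type_label)
          ms[[k]]$type_label <- others[[sample.int(length(others), 1L)]]
        }
      }
    }
    # relations over admissible co-occurring pairs
    rs <- list()
    arg <- sort(config$relation_arg_types)
    if (length(ms) >= 2L) {
      for (a in seq_len(length(ms) - 1L)) for (b in (a + 1L):length(ms)) {
        pair <- sort(c(ms[[a]]$type_label, ms[[b]]$type_label))
        if (identical(pair, arg) && stats::runif(1) < config$relation_prob) {
          rs[[length(rs) + 1L]] <- relation_instance(ms[[a]]$mention_id,
                                                     ms[[b]]$mention_id,
                                                     config$relation_label)
        }
      }
    }
    sents[[si]] <- sentence(toks, corpus_name = config$corpus_name,
                            sentence_id = sprintf("%s_s%d", config$corpus_name, si))
    mentions[[si]] <- ms
    relations[[si]] <- rs
  }
  corpus(config$corpus_name, sents, mentions, relations)
}

#' Generate a "foreign" corpus for corpus-adaptation evaluation
#'
#' Produces a corpus drawn from the same global label space as `config` but
#' from a different "annotation effort": different sentence templates, a
#' lexicon in which a fraction of surface forms are new, and a
#' guideline-style relabelling of a fraction of mentions of one type --
#' emulating an independently annotated held-out corpus used to measure
#' cross-corpus generalisation.
#'
#' @param config a [synthetic_config()] describing the training-domain corpus.
#' @param fresh_lexicon_frac fraction of surface forms replaced with unseen ones.
#' @param remap_frac fraction of mentions of `remap_from` whose gold type is
#'   relabelled `remap_to` (annotation-guideline deviation); 0 disables.
#' @param remap_from,remap_to entity types for the guideline remap.
#' @param seed seed for the foreign corpus (independent of `config$seed`).
#' @return a `cerex_corpus` named `<corpus_name>_foreign`.
#' @export
generate_foreign_corpus <- function(config, fresh_lexicon_frac = 0.5,
                                    remap_frac = 0, remap_from = NULL,
                                    remap_to = NULL, seed = config$seed + 1000L) {
  stopifnot(inherits(config, "cerex_synth_config"))
  if (remap_frac > 0 &&
      (is.null(remap_from) || is.null(remap_to) ||
       !all(c(remap_from, remap_to) %in% config$entity_type_set)))
    stop("remap_from/remap_to must name types in entity_type_set")
  fc <- config
  fc$corpus_name <- paste0(config$corpus_name, "_foreign")
  fc$templates <- foreign_templates(config$relation_label)
  fc$seed <- as.integer(seed)
  out <- with_seed(fc$seed, {
    x <- generate_corpus_impl(fc)
    # shift part of the lexicon: regenerate a fraction of mention surfaces
    # from a reseeded lexicon so they were never seen in training
    if (fresh_lexicon_frac > 0) {
      fresh <- lapply(stats::setNames(config$entity_type_set, config$entity_type_set),
                      function(t) build_lexicon(t, config$lexicon_size,
                                                config$multi_token_prob))
      for (si in seq_along(x$sentences)) {
        ms <- x$mentions[[si]]
        if (!length(ms)) next
        for (k in seq_along(ms)) {
          if (stats::runif(1) >= fresh_lexicon_frac) next
          m <- ms[[k]]
          span_len <- m$end - m$start + 1L
          pool <- Filter(function(f) length(f) == span_len, fresh[[m$type_label]])
          if (!length(pool)) next
          form <- pool[[sample.int(length(pool), 1L)]]
          toks <- x$sentences[[si]]$tokens
          toks[(m$start + 1L):(m$end + 1L)] <- form
          x$sentences[[si]]$tokens <- toks
        }
      }
    }
    # guideline-style type remap of gold labels
    if (remap_frac > 0)
      x <- generate_foreign_remap(x, remap_from, remap_to, remap_frac)
    x
  })
  validate_corpus(out)
  out
}

# Relabel a deterministic fraction of `from`-type mentions as `to`.
generate_foreign_remap <- function(x, from, to, frac) {
  for (si in seq_along(x$sentences)) {
    ms <- x$mentions[[si]]
    for (k in seq_along(ms)) {
      if (ms[[k]]$type_label == from && stats::runif(1) < frac)
        x$mentions[[si]][[k]]$type_label <- to
    }
  }
  x
}

#' Split a corpus into near-equal subsets
#'
#' Sentences are randomly permuted under `seed`, then cut into `k` contiguous
#' parts whose sizes differ by at most one (the remainder goes to the
#' earliest parts). Mentions and relations travel with their sentences.
#'
#' @param x a `cerex_corpus`.
#' @param k number of parts, `1 <= k <= number of sentences`.
#' @param seed permutation seed.
#' @return an object of class `cerex_split`: list with `parent`, `parts`
#'   (list of corpora named `<name>_sub<i>`), and `part_sizes`.
#' @export
split_subsets <- function(x, k, seed = 1L) {
  ns <- length(x$sentences)
  k <- as.integer(k)
  if (k < 1L || k > ns) stop("k must be in [1, ", ns, "]")
  perm <- with_seed(seed, sample.int(ns))
  sizes <- rep(ns %/% k, k) + as.integer(seq_len(k) <= ns %% k)
  ends <- cumsum(sizes)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  parts <- lapply(seq_len(k), function(i) {
    idx <- perm[starts[i]:ends[i]]
    corpus(sprintf("%s_sub%d", x$name, i),
           x$sentences[idx], x$mentions[idx], x$relations[idx],
           validate = FALSE)
  })
  structure(list(parent = x$name, parts = parts, part_sizes = sizes),
            class = "cerex_split")
}

#' Merge several corpora into one
#'
#' Concatenates the sentences, mentions and relations of the given corpora
#' (subsets from [split_subsets()], or whole corpora) into a single pool,
#' optionally shuffling sentence order under a seed.
#'
#' @param corpora list of `cerex_corpus` objects.
#' @param name name of the merged corpus.
#' @param shuffle permute sentence order (default FALSE).
#' @param seed permutation seed when shuffling.
#' @return a `cerex_corpus`.
#' @export
merge_corpora <- function(corpora, name = "merged", shuffle = FALSE, seed = 1L) {
  sents <- do.call(c, lapply(corpora, function(x) x$sentences))
  ments <- do.call(c, lapply(corpora, function(x) x$mentions))
  rels <- do.call(c, lapply(corpora, function(x) x$relations))
  if (shuffle && length(sents) > 1L) {
    perm <- with_seed(seed, sample.int(length(sents)))
    sents <- sents[perm]; ments <- ments[perm]; rels <- rels[perm]
  }
  corpus(name, sents, ments, rels, validate = FALSE)
}

#' Build a training schedule over an ordered list of corpora
#'
#' Realises one of three learning paradigms as an ordered list of steps, each
#' a bag of corpus subsets:
#' \describe{
#'   \item{continual}{one step per corpus, in the given order (pipeline
#'     style: the model for step t is initialised from step t-1).}
#'   \item{multi_corpora}{a single step containing all corpora, sentences
#'     shuffled together.}
#'   \item{continual_multi_corpora}{over corpora C1..Ck: k steps; corpus Ci
#'     (entering at step i) is split into k-i+1 equal parts, and step t
#'     contains part t-i+1 of every Ci with i <= t, shuffled. For three
#'     corpora this is the 3/2/1 split: step 1 = C1 part 1; step 2 = C1 part
#'     2 + C2 part 1; step 3 = C1 part 3 + C2 part 2 + all of C3 -- partial
#'     data replay of earlier corpora inside later steps.}
#' }
#'
#' @param corpora ordered list of `cerex_corpus` objects.
#' @param paradigm one of `"continual"`, `"multi_corpora"`,
#'   `"continual_multi_corpora"`.
#' @param seed seed for subset splitting and within-step shuffling.
#' @return an object of class `cerex_schedule`: list of steps, each with
#'   `components` (named subset corpora) and `pool` (merged shuffled corpus).
#' @export
build_schedule <- function(corpora, paradigm = c("continual", "multi_corpora",
                                                 "continual_multi_corpora"),
                           seed = 1L) {
  paradigm <- match.arg(paradigm)
  if (!length(corpora)) stop("need at least one corpus")
  k <- length(corpora)
  steps <- switch(paradigm,
    continual = lapply(seq_len(k), function(i) {
      list(components = stats::setNames(list(corpora[[i]]), corpora[[i]]$name),
           pool = merge_corpora(corpora[i], name = sprintf("step%d", i),
                                shuffle = TRUE, seed = seed + i))
    }),
    multi_corpora = list(list(
      components = stats::setNames(corpora,
                                   vapply(corpora, function(x) x$name, character(1))),
      pool = merge_corpora(corpora, name = "step1", shuffle = TRUE,
                           seed = seed + 1L))),
    continual_multi_corpora = {
      if (k < 2L) {
        list(list(components = stats::setNames(list(corpora[[1L]]), corpora[[1L]]$name),
                  pool = merge_corpora(corpora, name = "step1",
                                       shuffle = TRUE, seed = seed + 1L)))
      } else {
        splits <- lapply(seq_len(k), function(i)
          split_subsets(corpora[[i]], k - i + 1L, seed = seed + i))
        lapply(seq_len(k), function(t) {
          comps <- list()
          for (i in seq_len(t)) {
            part <- splits[[i]]$parts[[t - i + 1L]]
            comps[[part$name]] <- part
          }
          list(components = comps,
               pool = merge_corpora(comps, name = sprintf("step%d", t),
                                    shuffle = TRUE, seed = seed + 100L + t))
        })
      }
    })
  structure(list(paradigm = paradigm, steps = steps), class = "cerex_schedule")
}

#' @export
print.cerex_schedule <- function(x, ...) {
  cat("<cerex_schedule> paradigm:", x$paradigm, "—", length(x$steps), "step(s)\n")
  for (t in seq_along(x$steps)) {
    st <- x$steps[[t]]
    cat(sprintf("  step %d: %s (%d sentences)\n", t,
                paste(names(st$components), collapse = " + "),
                length(st$pool$sentences)))
  }
  invisible(x)
}
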