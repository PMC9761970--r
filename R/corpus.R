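#' Construct a tokenised sentence
#'
#' A sentence is the atomic text unit: an ordered vector of tokens, plus the
#' name of the corpus it came from and a stable identifier. Token indices used
#' throughout the package (mention spans, tag positions) are 0-based and refer
#' to positions in `tokens`.
#'
#' @param tokens character vector of tokens, length >= 1.
#' @param corpus_name name of the owning corpus.
#' @param sentence_id stable identifier string.
#' @return an object of class `cerex_sentence`.
#' @export
sentence <- function(tokens, corpus_name = "", sentence_id = "") {
  tokens <- as.character(tokens)
  if (length(tokens) < 1L) stop("a sentence must contain at least one token")
  bad <- grepl("^\\[.+_(start|end)\\]$", tokens)
  if (any(bad)) {
    stop("tokens contain reserved entity-marker strings: ",
         paste(unique(tokens[bad]), collapse = ", "))
  }
  structure(list(tokens = tokens, n = length(tokens),
                 corpus_name = corpus_name, sentence_id = sentence_id),
            class = "cerex_sentence")
}

#' Construct an entity mention
#'
#' Spans are 0-based and inclusive on both ends: a single-token mention has
#' `start == end`.
#'
#' @param start,end 0-based inclusive token indices.
#' @param type_label entity-type string.
#' @param mention_id stable identifier string.
#' @return an object of class `cerex_mention`.
#' @export
entity_mention <- function(start, end, type_label, mention_id = "") {
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start < 0L || end < start)
    stop("invalid mention span [", start, ", ", end, "]")
  structure(list(start = start, end = end,
                 type_label = as.character(type_label),
                 mention_id = as.character(mention_id)),
            class = "cerex_mention")
}

#' Construct a relation instance
#'
#' Relations are unordered pairs of mentions within one sentence. The two
#' mention ids must differ.
#'
#' @param mention_a,mention_b mention ids within the same sentence.
#' @param label relation label string.
#' @return an object of class `cerex_relation`.
#' @export
relation_instance <- function(mention_a, mention_b, label) {
  if (identical(mention_a, mention_b))
    stop("a relation must connect two distinct mentions")
  structure(list(mention_a = as.character(mention_a),
                 mention_b = as.character(mention_b),
                 label = as.character(label)),
            class = "cerex_relation")
}

#' Assemble an annotated corpus
#'
#' A corpus bundles sentences with per-sentence mention and relation lists.
#' Validation checks span bounds, mention-id references and overlap: gold
#' mentions must be non-overlapping and non-nested, because the one-tag-per-
#' token BIOES scheme cannot represent anything else.
#'
#' @param name corpus name.
#' @param sentences list of [sentence()] objects.
#' @param mentions list (parallel to `sentences`) of lists of [entity_mention()].
#' @param relations list (parallel to `sentences`) of lists of [relation_instance()].
#' @param validate check invariants (default TRUE).
#' @return an object of class `cerex_corpus`.
#' @export
corpus <- function(name, sentences, mentions = NULL, relations = NULL,
                   validate = TRUE) {
  ns <- length(sentences)
  if (is.null(mentions)) mentions <- rep(list(list()), ns)
  if (is.null(relations)) relations <- rep(list(list()), ns)
  if (length(mentions) != ns || length(relations) != ns)
    stop("mentions/relations must be parallel to sentences")
  obj <- structure(list(name = name, sentences = sentences,
                        mentions = mentions, relations = relations),
                   class = "cerex_corpus")
  if (validate) validate_corpus(obj)
  obj
}

#' Validate corpus invariants
#'
#' @param x a `cerex_corpus`.
#' @return `x` invisibly; errors describe the offending sentence/record.
#' @export
validate_corpus <- function(x) {
  for (i in seq_along(x$sentences)) {
    s <- x$sentences[[i]]
    ms <- x$mentions[[i]]
    ids <- vapply(ms, function(m) m$mention_id, character(1))
    if (anyDuplicated(ids[nzchar(ids)]))
      stop("sentence ", i, ": duplicate mention ids")
    for (m in ms) {
      if (m$end >= s$n)
        stop("sentence ", i, ": mention ", m$mention_id,
             " span [", m$start, ",", m$end, "] outside sentence of length ", s$n)
    }
    check_no_overlap(ms, where = paste0("sentence ", i))
    for (r in x$relations[[i]]) {
      if (!(r$mention_a %in% ids) || !(r$mention_b %in% ids))
        stop("sentence ", i, ": relation references unknown mention id '",
             setdiff(c(r$mention_a, r$mention_b), ids)[1], "'")
    }
  }
  invisible(x)
}

# Reject overlapping or nested mentions, naming the offending pair.
check_no_overlap <- function(mentions, where = "") {
  if (length(mentions) < 2L) return(invisible(TRUE))
  st <- vapply(mentions, function(m) m$start, integer(1))
  en <- vapply(mentions, function(m) m$end, integer(1))
  o <- order(st, en)
  for (k in seq_len(length(o) - 1L)) {
    a <- o[k]; b <- o[k + 1L]
    if (st[b] <= en[a]) {
      stop(where, ": overlapping/nested mentions '",
           mentions[[a]]$mention_id, "' [", st[a], ",", en[a], "] and '",
           mentions[[b]]$mention_id, "' [", st[b], ",", en[b], "]")
    }
  }
  invisible(TRUE)
}

#' @export
print.cerex_corpus <- function(x, ...) {
  nm <- sum(lengths(x$mentions))
  nr <- sum(lengths(x$relations))
  cat("<cerex_corpus> '", x$name, "': ", length(x$sentences),
      " sentences, ", nm, " mentions, ", nr, " relations\n", sep = "")
  et <- sort(unique(unlist(lapply(x$mentions, function(ms)
    vapply(ms, function(m) m$type_label, character(1))))))
  rl <- sort(unique(unlist(lapply(x$relations, function(rs)
    vapply(rs, function(r) r$label, character(1))))))
  if (length(et)) cat("  entity types:   ", paste(et, collapse = ", "), "\n")
  if (length(rl)) cat("  relation labels:", paste(rl, collapse = ", "), "\n")
  invisible(x)
}

#' Encode mention spans as a BIOES tag sequence
#'
#' Span detection uses the BIOES alphabet (Beginning, Inside, Outside, End,
#' Single): a single-token mention is tagged `S`; a multi-token mention gets
#' `B` at its start, `E` at its end and `I` strictly between; every other
#' token is `O`.
#'
#' @param sent a [sentence()].
#' @param mentions list of non-overlapping [entity_mention()] objects.
#' @return character vector of tags, one per token.
#' @examples
#' s <- sentence(c("Two", "cases", "of", "mequitazine", "induced",
#'                 "photosensitivity", "reactions"))
#' m <- list(entity_mention(3, 3, "Drug", "T1"),
#'           entity_mention(5, 6, "Disease", "T2"))
#' bioes_encode(s, m)  # O O O S O B E
#' @export
bioes_encode <- function(sent, mentions) {
  check_no_overlap(mentions, where = "bioes_encode")
  tags <- rep("O", sent$n)
  for (m in mentions) {
    if (m$end >= sent$n)
      stop("mention span [", m$start, ",", m$end,
           "] outside sentence of length ", sent$n)
    i0 <- m$start + 1L; i1 <- m$end + 1L
    if (i0 == i1) {
      tags[i0] <- "S"
    } else {
      tags[i0] <- "B"
      tags[i1] <- "E"
      if (i1 - i0 > 1L) tags[(i0 + 1L):(i1 - 1L)] <- "I"
    }
  }
  tags
}

#' Decode a BIOES tag sequence into spans
#'
#' The inverse of [bioes_encode()], total on the tag alphabet. Decoding is
#' conservative: only well-formed segments yield spans (`S`, or `B` followed
#' by zero or more `I` then `E`). Malformed fragments -- an `I`/`E` with no
#' open `B`, or a `B` never closed by `E` -- produce no span, so downstream
#' relation extraction is never fed a fabricated boundary.
#'
#' @param tags character vector over \{B, I, O, E, S\}.
#' @return a list of `c(start, end)` integer pairs, 0-based inclusive.
#' @examples
#' bioes_decode(c("S", "O", "B", "E"))  # spans (0,0) and (2,3)
#' bioes_decode(c("O", "I", "E", "O"))  # empty: no opening B
#' @export
bioes_decode <- function(tags) {
  if (length(tags) && !all(tags %in% c("B", "I", "O", "E", "S")))
    stop("tags outside the BIOES alphabet: ",
         paste(unique(setdiff(tags, c("B", "I", "O", "E", "S"))), collapse = ", "))
  spans <- list()
  open <- NA_integer_  # 1-based position of the pending B
  for (i in seq_along(tags)) {
    t <- tags[i]
    if (t == "S") {
      spans[[length(spans) + 1L]] <- c(i - 1L, i - 1L)
      open <- NA_integer_
    } else if (t == "B") {
      open <- i
    } else if (t == "I") {
      # only valid while a B is open; otherwise discard silently
      if (is.na(open)) next
    } else if (t == "E") {
      if (!is.na(open)) {
        spans[[length(spans) + 1L]] <- c(open - 1L, i - 1L)
      }
      open <- NA_integer_
    } else {  # O
      open <- NA_integer_
    }
  }
  spans
}

#' Create a label vocabulary
#'
#' Ordered, append-only registries of entity types (size M) and relation
#' labels (size N). Indices are 1-based positions in the vectors and are
#' stable: appending new labels never renumbers existing ones, which is what
#' lets classifier head banks grow across corpora without invalidating old
#' heads.
#'
#' @param entity_types,relation_types initial character vectors (no duplicates).
#' @return an object of class `cerex_vocab`.
#' @export
label_vocabulary <- function(entity_types = character(), relation_types = character()) {
  if (anyDuplicated(entity_types) || anyDuplicated(relation_types))
    stop("duplicate labels in vocabulary")
  structure(list(entity_types = as.character(entity_types),
                 relation_types = as.character(relation_types)),
            class = "cerex_vocab")
}

#' Expand a label vocabulary
#'
#' Genuinely new labels are appended at the end; labels already present are
#' ignored, so the call is idempotent and existing indices never move.
#'
#' @param vocab a [label_vocabulary()].
#' @param new_entity_types,new_relation_types labels to add.
#' @return the expanded `cerex_vocab`.
#' @export
expand_vocabulary <- function(vocab, new_entity_types = character(),
                              new_relation_types = character()) {
  vocab$entity_types <- c(vocab$entity_types,
                          setdiff(unique(as.character(new_entity_types)),
                                  vocab$entity_types))
  vocab$relation_types <- c(vocab$relation_types,
                            setdiff(unique(as.character(new_relation_types)),
                                    vocab$relation_types))
  vocab
}

#' @export
print.cerex_vocab <- function(x, ...) {
  cat("<cerex_vocab> M =", length(x$entity_types),
      "entity types; N =", length(x$relation_types), "relation labels\n")
  invisible(x)
}

#' Rewrite entity-type and relation labels through normalisation maps
#'
#' Different corpora annotate compatible concepts under different guideline
#' names (e.g. a "Drug_n" type folded into "Drug", or several fine-grained
#' drug-drug interaction labels collapsed into one). Both maps must be total
#' on the labels actually present; counts of sentences, mentions and
#' relations are unchanged.
#'
#' @param x a `cerex_corpus`.
#' @param type_map,relation_map named character vectors (old label -> new label).
#' @return the corpus with rewritten labels.
#' @export
normalize_labels <- function(x, type_map = NULL, relation_map = NULL) {
  map1 <- function(lbl, map, what) {
    if (is.null(map)) return(lbl)
    if (!lbl %in% names(map))
      stop(what, " label '", lbl, "' absent from the normalisation map")
    unname(map[[lbl]])
  }
  x$mentions <- lapply(x$mentions, function(ms) lapply(ms, function(m) {
    m$type_label <- map1(m$type_label, type_map, "entity-type"); m
  }))
  x$relations <- lapply(x$relations, function(rs) lapply(rs, function(r) {
    r$label <- map1(r$label, relation_map, "relation"); r
  }))
  x
}

# Labels present in a corpus, in first-appearance order.
corpus_entity_types <- function(x) {
  out <- character()
  for (ms in x$mentions) for (m in ms)
    if (!m$type_label %in% out) out <- c(out, m$type_label)
  out
}

corpus_relation_types <- function(x) {
  out <- character()
  for (rs in x$relations) for (r in rs)
    if (!r$label %in% out) out <- c(out, r$label)
  out
}

# All tokens of a corpus (used to build encoder token vocabularies).
corpus_tokens <- function(x) {
  unique(unlist(lapply(x$sentences, function(s) s$tokens), use.names = FALSE))
}
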