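# Micro P/R/F1 from pooled counts.
micro_prf <- function(tp, fp, fn) {
  p <- if (tp + fp > 0) tp / (tp + fp) else 0
  r <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (p + r > 0) 2 * p * r / (p + r) else 0
  list(counts = c(tp = as.numeric(tp), fp = as.numeric(fp), fn = as.numeric(fn)),
       precision = p, recall = r, f1 = f1)
}

#' Token-level span-detection micro-F1
#'
#' Scores predicted against gold BIOES tag sequences token by token,
#' micro-averaged over the tags treated as classes and pooled across
#' sentences before the precision/recall ratio. By default the O tag is not
#' a positive class (counting it would collapse micro-F1 into token accuracy
#' and mask boundary errors); set `include_o = TRUE` to count it.
#'
#' @param pred,gold lists of tag character vectors, aligned by sentence.
#' @param include_o count O as a positive class (default FALSE).
#' @return list with `counts` (tp/fp/fn), `precision`, `recall`, `f1`.
#' @export
evaluate_sp <- function(pred, gold, include_o = FALSE) {
  if (length(pred) != length(gold)) stop("pred and gold differ in length")
  classes <- if (include_o) .bioes_tags else setdiff(.bioes_tags, "O")
  tp <- fp <- fn <- 0L
  for (i in seq_along(pred)) {
    p <- pred[[i]]; g <- gold[[i]]
    if (length(p) != length(g))
      stop("sentence ", i, ": tag sequences of different length")
    for (cl in classes) {
      tp <- tp + sum(p == cl & g == cl)
      fp <- fp + sum(p == cl & g != cl)
      fn <- fn + sum(g == cl & p != cl)
    }
  }
  micro_prf(tp, fp, fn)
}

# Canonical key of a mention: exact boundary + type.
mention_key <- function(m) paste(m$start, m$end, m$type_label, sep = ":")

# One-to-one exact matching of two key multisets: TP is the multiset
# intersection; every unmatched prediction is FP, every unmatched gold FN.
# A wrong-type prediction on a correct span therefore counts both FP (the
# prediction) and FN (the gold it failed to consume).
match_keys <- function(pred_keys, gold_keys) {
  tp <- 0L
  gtab <- table(gold_keys)
  ptab <- table(pred_keys)
  common <- intersect(names(gtab), names(ptab))
  for (k in common) tp <- tp + min(gtab[[k]], ptab[[k]])
  c(tp = tp, fp = length(pred_keys) - tp, fn = length(gold_keys) - tp)
}

#' Entity-typing micro-F1 (exact span and type)
#'
#' A predicted mention is a true positive only when both its boundary and
#' its type exactly match a gold mention; otherwise it is a false positive,
#' and each unmatched gold mention is a false negative.
#'
#' @param pred,gold lists (per sentence) of [entity_mention()] lists.
#' @return list with `counts`, `precision`, `recall`, `f1`.
#' @export
evaluate_et <- function(pred, gold) {
  if (length(pred) != length(gold)) stop("pred and gold differ in length")
  tp <- fp <- fn <- 0L
  for (i in seq_along(pred)) {
    cnt <- match_keys(vapply(pred[[i]], mention_key, character(1)),
                      vapply(gold[[i]], mention_key, character(1)))
    tp <- tp + cnt[["tp"]]; fp <- fp + cnt[["fp"]]; fn <- fn + cnt[["fn"]]
  }
  micro_prf(tp, fp, fn)
}

# Canonical key of a relation triple: unordered pair of (span, type)
# endpoint keys plus the relation label.
triple_key <- function(tr) {
  ka <- mention_key(tr$a); kb <- mention_key(tr$b)
  ep <- sort(c(ka, kb))
  paste(ep[1], ep[2], tr$label, sep = "|")
}

#' Relation-extraction micro-F1 (exact triples)
#'
#' A predicted triple counts as a true positive only when both entities
#' (exact span and type) and the relation label all match a gold triple;
#' pairs are unordered. Non-matching predictions are false positives
#' (including a correct pair with the wrong label) and missing gold triples
#' false negatives, so span/type errors upstream propagate into this score.
#'
#' @param pred,gold lists (per sentence) of triples, each a list with
#'   elements `a` and `b` ([entity_mention()]s) and `label`.
#' @return list with `counts`, `precision`, `recall`, `f1`.
#' @export
evaluate_re <- function(pred, gold) {
  if (length(pred) != length(gold)) stop("pred and gold differ in length")
  tp <- fp <- fn <- 0L
  for (i in seq_along(pred)) {
    cnt <- match_keys(vapply(pred[[i]], triple_key, character(1)),
                      vapply(gold[[i]], triple_key, character(1)))
    tp <- tp + cnt[["tp"]]; fp <- fp + cnt[["fp"]]; fn <- fn + cnt[["fn"]]
  }
  micro_prf(tp, fp, fn)
}

#' Combined micro-F1 over several corpora
#'
#' Multi-corpus evaluation regards all data as one corpus: the TP/FP/FN
#' counts are summed across the per-corpus results first and precision,
#' recall and F1 computed once from the pooled counts (micro pooling, not an
#' average of per-corpus F1 values).
#'
#' @param reports list of per-corpus results as returned by the scorers.
#' @return list with pooled `counts`, `precision`, `recall`, `f1`.
#' @export
evaluate_combined <- function(reports) {
  tp <- sum(vapply(reports, function(r) r$counts[["tp"]], numeric(1)))
  fp <- sum(vapply(reports, function(r) r$counts[["fp"]], numeric(1)))
  fn <- sum(vapply(reports, function(r) r$counts[["fn"]], numeric(1)))
  micro_prf(tp, fp, fn)
}

#' Micro-F1 under the united NER tagging contract
#'
#' Scores named-entity recognition the traditional way, where one united tag
#' carries both position and type (B_Drug, I_Drug, ...): a mention counts
#' only when the exact (span, type) pair matches, which is what decoding
#' united tags and comparing them amounts to. This is the comparison column
#' for united-versus-separated tagging analyses.
#'
#' @param pred,gold lists (per sentence) of [entity_mention()] lists.
#' @return list with `counts`, `precision`, `recall`, `f1`.
#' @export
evaluate_united_ner <- function(pred, gold) {
  evaluate_et(pred, gold)
}
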