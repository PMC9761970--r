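# Independent brute-force oracles, deliberately written as plain loops with
# no shared code with the package internals.

# Decode BIOES by explicit scan over every start position: a span is either
# a single S, or a B..E with only I strictly inside.
oracle_bioes_decode <- function(tags) {
  n <- length(tags)
  spans <- list()
  taken <- rep(FALSE, n)
  for (i in seq_len(n)) {
    if (taken[i]) next
    if (tags[i] == "S") {
      spans[[length(spans) + 1L]] <- c(i - 1L, i - 1L)
      taken[i] <- TRUE
    } else if (tags[i] == "B") {
      j <- i + 1L
      while (j <= n && tags[j] == "I") j <- j + 1L
      if (j <= n && tags[j] == "E") {
        spans[[length(spans) + 1L]] <- c(i - 1L, j - 1L)
        taken[i:j] <- TRUE
      }
    }
  }
  spans
}

# Exact one-to-one matching of two key vectors by greedy removal.
oracle_match_counts <- function(pred_keys, gold_keys) {
  gold_left <- gold_keys
  tp <- 0L
  for (k in pred_keys) {
    hit <- match(k, gold_left)
    if (!is.na(hit)) {
      tp <- tp + 1L
      gold_left <- gold_left[-hit]
    }
  }
  c(tp = tp, fp = length(pred_keys) - tp, fn = length(gold_keys) - tp)
}

oracle_prf <- function(cnt) {
  p <- if (cnt[["tp"]] + cnt[["fp"]] > 0) cnt[["tp"]] / (cnt[["tp"]] + cnt[["fp"]]) else 0
  r <- if (cnt[["tp"]] + cnt[["fn"]] > 0) cnt[["tp"]] / (cnt[["tp"]] + cnt[["fn"]]) else 0
  if (p + r > 0) 2 * p * r / (p + r) else 0
}

# Token-level SP counts by explicit per-class loops.
oracle_sp_counts <- function(pred, gold, classes = c("B", "I", "E", "S")) {
  tp <- fp <- fn <- 0L
  for (i in seq_along(pred)) {
    for (j in seq_along(pred[[i]])) {
      p <- pred[[i]][j]; g <- gold[[i]][j]
      if (p %in% classes && p == g) tp <- tp + 1L
      if (p %in% classes && p != g) fp <- fp + 1L
      if (g %in% classes && p != g) fn <- fn + 1L
    }
  }
  c(tp = tp, fp = fp, fn = fn)
}

# Random non-overlapping 0-based spans on a sentence of length n.
random_span_set <- function(n) {
  spans <- list()
  i <- 0L
  while (i < n) {
    if (runif(1) < 0.4) {
      len <- sample(1:min(3L, n - i), 1L)
      spans[[length(spans) + 1L]] <- c(i, i + len - 1L)
      i <- i + len
    } else i <- i + 1L
  }
  spans
}

random_mentions <- function(n, types = c("Drug", "Disease", "Protein")) {
  spans <- random_span_set(n)
  out <- list()
  for (k in seq_along(spans)) {
    out[[k]] <- entity_mention(spans[[k]][1], spans[[k]][2],
                               sample(types, 1L), sprintf("T%d", k))
  }
  out
}

toy_sentence <- function(n, name = "toy") {
  sentence(paste0("tok", seq_len(n)), corpus_name = name,
           sentence_id = paste0(name, "_s", n))
}
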