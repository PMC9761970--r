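# ---- feed-forward heads ---------------------------------------------------

init_head_params <- function(prefix, in_dim, hidden, out_dim) {
  p <- list()
  p[[paste0(prefix, ".W1")]] <- matrix(stats::rnorm(in_dim * hidden,
                                                    sd = 1 / sqrt(in_dim)),
                                       in_dim, hidden)
  p[[paste0(prefix, ".b1")]] <- numeric(hidden)
  p[[paste0(prefix, ".W2")]] <- matrix(stats::rnorm(hidden * out_dim,
                                                    sd = 1 / sqrt(hidden)),
                                       hidden, out_dim)
  p[[paste0(prefix, ".b2")]] <- numeric(out_dim)
  p
}

# Forward through a two-layer feed-forward head. X: rows are inputs.
head_forward <- function(params, prefix, X) {
  if (!is.matrix(X)) X <- matrix(X, nrow = 1L)
  W1 <- params[[paste0(prefix, ".W1")]]
  if (ncol(X) != nrow(W1))
    stop("head '", prefix, "': input dim ", ncol(X), " != expected ", nrow(W1))
  P <- sweep(X %*% W1, 2L, params[[paste0(prefix, ".b1")]], "+")
  R <- pmax(P, 0)
  logits <- sweep(R %*% params[[paste0(prefix, ".W2")]], 2L,
                  params[[paste0(prefix, ".b2")]], "+")
  list(logits = logits, X = X, mask = P > 0, R = R)
}

# Backward: writes weight grads into acc, returns dX.
head_backward <- function(params, prefix, fw, dlogits, acc) {
  if (!is.matrix(dlogits)) dlogits <- matrix(dlogits, nrow = nrow(fw$R))
  W1 <- params[[paste0(prefix, ".W1")]]
  W2 <- params[[paste0(prefix, ".W2")]]
  acc_add(acc, paste0(prefix, ".W2"), t(fw$R) %*% dlogits)
  acc_add(acc, paste0(prefix, ".b2"), colSums(dlogits))
  dR <- dlogits %*% t(W2)
  dP <- dR * fw$mask
  acc_add(acc, paste0(prefix, ".W1"), t(fw$X) %*% dP)
  acc_add(acc, paste0(prefix, ".b1"), colSums(dP))
  dP %*% t(W1)
}

#' Create a standalone two-layer feed-forward classification head
#'
#' @param in_dim input width.
#' @param out_dim number of output logits (task label count, or 1 for a
#'   binary head).
#' @param hidden hidden width (default 64).
#' @param seed initialisation seed.
#' @return an object of class `cerex_head`.
#' @export
ff_head <- function(in_dim, out_dim, hidden = 64L, seed = 1L) {
  params <- with_seed(seed, init_head_params("h", in_dim, hidden, out_dim))
  structure(list(in_dim = as.integer(in_dim), out_dim = as.integer(out_dim),
                 hidden = as.integer(hidden), params = params),
            class = "cerex_head")
}

#' Score inputs with a standalone head
#'
#' @param head a [ff_head()].
#' @param x numeric vector (one input) or matrix (rows are inputs).
#' @return logit matrix, one row per input.
#' @export
head_logits <- function(head, x) {
  head_forward(head$params, "h", x)$logits
}

# ---- multi-head banks -----------------------------------------------------

#' Create an expandable bank of one-vs-rest binary heads
#'
#' One independent binary classifier per label, in vocabulary order. Each
#' head emits a single logit; the confidence compared across heads is the
#' sigmoid probability, and a prediction requires at least one head to clear
#' the decision threshold `theta`. New heads can be appended with
#' [add_head()] without touching existing ones, which is how the label
#' vocabulary grows across corpora.
#'
#' @param labels initial label set (may be empty).
#' @param in_dim input width of every head.
#' @param hidden hidden width (default 64).
#' @param theta decision threshold on the sigmoid probability (default 0.5).
#' @param seed initialisation seed.
#' @return an object of class `cerex_bank`.
#' @export
multihead_bank <- function(labels, in_dim, hidden = 64L, theta = 0.5, seed = 1L) {
  params <- with_seed(seed, {
    p <- list()
    for (lab in labels) p <- c(p, init_head_params(lab, in_dim, hidden, 1L))
    p
  })
  structure(list(labels = as.character(labels), in_dim = as.integer(in_dim),
                 hidden = as.integer(hidden), theta = theta, params = params),
            class = "cerex_bank")
}

#' Append a freshly initialised binary head for a new label
#'
#' All pre-existing heads' parameters are bit-identical before and after the
#' expansion; adding a label that already has a head is an error.
#'
#' @param bank a [multihead_bank()].
#' @param new_label label for the new head.
#' @param seed initialisation seed for the new head.
#' @return the expanded bank.
#' @export
add_head <- function(bank, new_label, seed = length(bank$labels) + 1L) {
  if (new_label %in% bank$labels)
    stop("label '", new_label, "' already has a head")
  new_p <- with_seed(seed, init_head_params(new_label, bank$in_dim,
                                            bank$hidden, 1L))
  bank$labels <- c(bank$labels, new_label)
  bank$params <- c(bank$params, new_p)
  bank
}

#' Sigmoid scores of every head in a bank on one input
#'
#' @param bank a [multihead_bank()].
#' @param x input vector of length `in_dim`.
#' @return named numeric vector of per-label probabilities, vocabulary order.
#' @export
bank_scores <- function(bank, x) {
  z <- vapply(bank$labels, function(lab)
    head_forward(bank$params, lab, x)$logits[1L, 1L], numeric(1))
  stats::setNames(plogis(z), bank$labels)
}

#' Aggregate multi-head scores into a single prediction
#'
#' Labels whose score exceeds `theta` are candidates; with one or more
#' candidates the most confident head wins (ties break to the lowest
#' vocabulary index, i.e. the earliest element of `scores`); with none the
#' result is `NA` (no label).
#'
#' @param scores named numeric vector of probabilities in vocabulary order.
#' @param theta decision threshold.
#' @return list with `label` (character or NA) and `confidence`.
#' @export
aggregate_multihead <- function(scores, theta = 0.5) {
  cand <- which(scores > theta)
  if (!length(cand)) {
    return(list(label = NA_character_,
                confidence = if (length(scores)) max(scores) else 0))
  }
  best <- cand[which.max(scores[cand])]  # which.max takes the earliest max
  list(label = names(scores)[best], confidence = unname(scores[best]))
}

# ---- task predictions -----------------------------------------------------

#' Per-token span-detection distributions
#'
#' Applies the span-detection head to every NER hidden-state row, returning
#' one normalised distribution over the BIOES alphabet per token; the
#' row-wise argmax is the predicted tag sequence.
#'
#' @param h_ner n x d NER hidden states of the raw (unmarked) sentence.
#' @param head the SP head: a [ff_head()] with 5 outputs, or an internal
#'   parameter list with prefix "sp".
#' @return n x 5 matrix of probabilities, columns named B, I, O, E, S.
#' @export
predict_sp <- function(h_ner, head) {
  logits <- if (inherits(head, "cerex_head")) head_logits(head, h_ner)
            else head_forward(head, "sp", h_ner)$logits
  probs <- row_softmax(logits)
  colnames(probs) <- c("B", "I", "O", "E", "S")
  probs
}

# Tag sequence from SP probabilities.
sp_tags <- function(probs) colnames(probs)[max.col(probs, ties.method = "first")]

#' Entity-type prediction for one span
#'
#' The classifier input is the sum of the NER hidden states over the span.
#' A multi-head bank is aggregated with [aggregate_multihead()]; a
#' single-head classifier takes the argmax over its classes.
#'
#' @param h_ner n x d NER hidden states.
#' @param span `c(start, end)` 0-based inclusive token indices.
#' @param bank_or_head a [multihead_bank()] (labels = entity types) or a
#'   [ff_head()] whose outputs follow a `labels` attribute/argument.
#' @param labels class labels for a single-head classifier.
#' @return list with `label` (NA if no head clears the threshold) and
#'   `confidence`.
#' @export
predict_et <- function(h_ner, span, bank_or_head, labels = NULL) {
  if (span[1] < 0L || span[2] >= nrow(h_ner) || span[2] < span[1])
    stop("invalid span [", span[1], ", ", span[2], "]")
  rows <- (span[1] + 1L):(span[2] + 1L)
  u <- if (length(rows) == 1L) h_ner[rows, ] else colSums(h_ner[rows, , drop = FALSE])
  classify_vec(u, bank_or_head, labels)
}

#' Relation prediction for one pair representation
#'
#' A multi-head bank aggregates its binary relation heads; when no head
#' clears the threshold the pair has no relation. A single-head classifier
#' includes an explicit no-relation class and takes the argmax.
#'
#' @param v a [pair_representation()] (or plain numeric vector).
#' @param bank_or_head a [multihead_bank()] (labels = relation types) or a
#'   [ff_head()] over `c(NO_RELATION, labels)`.
#' @param labels relation labels for a single-head classifier.
#' @return list with `label` (NA = no relation) and `confidence`.
#' @export
predict_re <- function(v, bank_or_head, labels = NULL) {
  v <- as.numeric(v)
  if (inherits(bank_or_head, "cerex_bank"))
    return(classify_vec(v, bank_or_head))
  lg <- head_logits(bank_or_head, v)[1L, ]
  probs <- as.numeric(row_softmax(matrix(lg, nrow = 1L)))
  cls <- c(NA_character_, labels)  # class 1 is the explicit no-relation class
  best <- which.max(probs)
  list(label = cls[best], confidence = probs[best])
}

classify_vec <- function(u, bank_or_head, labels = NULL) {
  if (inherits(bank_or_head, "cerex_bank")) {
    aggregate_multihead(bank_scores(bank_or_head, u), bank_or_head$theta)
  } else {
    lg <- head_logits(bank_or_head, u)[1L, ]
    probs <- as.numeric(row_softmax(matrix(lg, nrow = 1L)))
    best <- which.max(probs)
    lab <- if (is.null(labels)) as.character(best) else labels[best]
    list(label = lab, confidence = probs[best])
  }
}

# ---- losses ---------------------------------------------------------------

# Stable binary cross-entropy from a logit. y in {0,1}.
bce_logit <- function(z, y) {
  # -[y log s(z) + (1-y) log(1-s(z))] = max(z,0) - z y + log1p(exp(-|z|))
  pmax(z, 0) - z * y + log1p(exp(-abs(z)))
}

# Softmax cross-entropy of one logit row against a target index.
ce_softmax <- function(logits, target) {
  m <- max(logits)
  (m + log(sum(exp(logits - m)))) - logits[target]
}

#' Loss weights for the joint objective
#'
#' @param sp,et,re nonnegative task weights; defaults 0.4, 0.25 and 0.35.
#' @return named numeric vector of class `cerex_weights`.
#' @export
loss_weights <- function(sp = 0.4, et = 0.25, re = 0.35) {
  if (any(c(sp, et, re) < 0)) stop("loss weights must be nonnegative")
  structure(c(sp = sp, et = et, re = re), class = "cerex_weights")
}

#' Weighted joint training loss
#'
#' The total objective is the weighted sum of the three task losses:
#' span detection (softmax cross-entropy over BIOES tags), entity typing and
#' relation extraction (softmax cross-entropy in single-head mode; the sum
#' over the bank's per-head binary cross-entropies in multi-head mode). The
#' task losses may be given either as already-computed scalars or as
#' `list(logits =, gold =)` pairs, where `gold` holds target class indices
#' (single-head, matching logit rows) or a 0/1 target matrix aligned with
#' the logit matrix (multi-head binary).
#'
#' @param sp,et,re task losses (scalars or logits/gold lists; NULL = 0).
#' @param weights a [loss_weights()].
#' @param mode `"single"` or `"multi"`: how `et`/`re` logits are reduced.
#' @return the scalar total loss (nonnegative).
#' @export
joint_loss <- function(sp = NULL, et = NULL, re = NULL,
                       weights = loss_weights(), mode = c("multi", "single")) {
  mode <- match.arg(mode)
  eval1 <- function(x, multi) {
    if (is.null(x)) return(0)
    if (is.numeric(x) && length(x) == 1L) return(as.numeric(x))
    if (!is.list(x)) stop("task loss must be a scalar or list(logits, gold)")
    L <- x$logits
    if (!is.matrix(L)) L <- matrix(L, nrow = 1L)
    if (multi) {
      Y <- x$gold
      if (!is.matrix(Y)) Y <- matrix(Y, nrow = nrow(L))
      if (!all(dim(Y) == dim(L))) stop("misaligned logits and targets")
      sum(bce_logit(L, Y)) / nrow(L)
    } else {
      tgt <- as.integer(x$gold)
      if (length(tgt) != nrow(L)) stop("misaligned logits and targets")
      mean(vapply(seq_len(nrow(L)), function(i) ce_softmax(L[i, ], tgt[i]),
                  numeric(1)))
    }
  }
  total <- weights[["sp"]] * eval1(sp, multi = FALSE) +
    weights[["et"]] * eval1(et, multi = (mode == "multi")) +
    weights[["re"]] * eval1(re, multi = (mode == "multi"))
  as.numeric(total)
}
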