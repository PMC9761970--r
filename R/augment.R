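# Marker token surface forms, e.g. "[Drug_start]" / "[Drug_end]". Markers
# are indivisible tokens registered in the encoder vocabulary.
marker_tokens <- function(types) {
  as.vector(rbind(paste0("[", types, "_start]"), paste0("[", types, "_end]")))
}

#' Insert typed entity markers into a sentence
#'
#' For every mention of type T, the token `[T_start]` is inserted immediately
#' before the mention and `[T_end]` immediately after it, preserving
#' left-to-right order. The relation encoder reads this marked sequence, so
#' both the span and the type of each entity are visible in its input. The
#' returned object records where each mention's start marker landed and how
#' marked positions map back to raw ones, so [strip_markers()] recovers the
#' original sentence exactly.
#'
#' @param sent a [sentence()].
#' @param mentions non-overlapping [entity_mention()] list with known types.
#' @return an object of class `cerex_marked`: `tokens`, `n`,
#'   `marker_start` (named 0-based positions of each mention's start marker),
#'   `orig_of` (0-based raw position per marked position, NA at markers).
#' @examples
#' s <- sentence(c("Pravastatin", "is", "associated", "with",
#'                 "myotonia", "in", "animals"))
#' m <- list(entity_mention(0, 0, "Drug", "T1"),
#'           entity_mention(4, 4, "Disease", "T2"))
#' insert_entity_markers(s, m)$tokens
#' @export
insert_entity_markers <- function(sent, mentions) {
  check_no_overlap(mentions, where = "insert_entity_markers")
  if (length(mentions)) {
    mentions <- mentions[order(vapply(mentions, function(m) m$start, integer(1)))]
  }
  toks <- character(0)
  orig_of <- integer(0)
  marker_start <- integer(0)
  names(marker_start) <- character(0)
  cursor <- 0L  # next raw 0-based index to copy
  emit_raw <- function(upto) {
    # copy raw tokens cursor..upto-1
    if (upto > cursor) {
      idx <- (cursor + 1L):upto
      toks <<- c(toks, sent$tokens[idx])
      orig_of <<- c(orig_of, idx - 1L)
      cursor <<- upto
    }
  }
  for (m in mentions) {
    if (m$end >= sent$n)
      stop("mention span outside sentence bounds")
    emit_raw(m$start)
    marker_start[[m$mention_id]] <- length(toks)      # 0-based marked position
    toks <- c(toks, paste0("[", m$type_label, "_start]"))
    orig_of <- c(orig_of, NA_integer_)
    emit_raw(m$end + 1L)
    toks <- c(toks, paste0("[", m$type_label, "_end]"))
    orig_of <- c(orig_of, NA_integer_)
  }
  emit_raw(sent$n)
  structure(list(tokens = toks, n = length(toks),
                 marker_start = marker_start, orig_of = orig_of,
                 corpus_name = sent$corpus_name, sentence_id = sent$sentence_id),
            class = "cerex_marked")
}

#' Remove entity markers from a marked sentence
#'
#' Exact inverse of [insert_entity_markers()].
#'
#' @param marked a `cerex_marked` object.
#' @return the original [sentence()].
#' @export
strip_markers <- function(marked) {
  keep <- !is.na(marked$orig_of)
  sentence(marked$tokens[keep], corpus_name = marked$corpus_name,
           sentence_id = marked$sentence_id)
}

# ---- type embeddings and prototypes ---------------------------------------

#' Create a learned entity-type embedding table
#'
#' One trainable `dim`-dimensional vector per entity type (a linear embedding
#' of the one-hot type label), used by the `type_embedding` pair-
#' representation mode. Rows are appended when the type vocabulary grows.
#'
#' @param types entity-type labels (row order fixes the lookup order).
#' @param dim embedding width (default 50).
#' @param seed initialisation seed.
#' @return matrix of class `cerex_type_emb` with one row per type.
#' @export
type_embedding_table <- function(types, dim = 50L, seed = 1L) {
  M <- with_seed(seed, matrix(stats::rnorm(length(types) * dim, sd = 0.1),
                              length(types), dim))
  rownames(M) <- types
  class(M) <- c("cerex_type_emb", class(M))
  M
}

# Deterministic d -> out max-pooling: the vector is cut into `out` contiguous
# chunks (sizes differing by at most one) and each chunk contributes its max.
chunk_maxpool <- function(v, out = 50L) {
  d <- length(v)
  if (d < out) stop("cannot max-pool a length-", d, " vector to ", out, " dims")
  ends <- ceiling(seq_len(out) * d / out)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  vapply(seq_len(out), function(i) max(v[starts[i]:ends[i]]), numeric(1))
}

#' Compute frozen entity-type prototype vectors
#'
#' For each entity type, every token belonging to a mention of that type in
#' the training corpus is encoded with the *untrained base* encoder (the RE
#' branch of a freshly initialised bundle), max-pooled from d to `dim`
#' dimensions (contiguous-chunk max), and the pooled vectors are averaged.
#' The table is computed once before training and never updated, so it is a
#' fixed, training-independent description of each type's surface
#' distribution.
#'
#' @param train_corpus a `cerex_corpus` in which every entity type has at
#'   least one mention token.
#' @param bundle the untrained [encoder_bundle()] to read token vectors from.
#' @param dim prototype width (default 50).
#' @return matrix of class `cerex_prototypes`, one row per entity type.
#' @export
compute_prototypes <- function(train_corpus, bundle, dim = 50L) {
  sums <- list()
  counts <- list()
  for (si in seq_along(train_corpus$sentences)) {
    ms <- train_corpus$mentions[[si]]
    if (!length(ms)) next
    H <- encode_tokens(bundle, "RE", train_corpus$sentences[[si]]$tokens)
    for (m in ms) {
      for (i in (m$start + 1L):(m$end + 1L)) {
        pooled <- chunk_maxpool(H[i, ], dim)
        if (is.null(sums[[m$type_label]])) {
          sums[[m$type_label]] <- pooled
          counts[[m$type_label]] <- 1L
        } else {
          sums[[m$type_label]] <- sums[[m$type_label]] + pooled
          counts[[m$type_label]] <- counts[[m$type_label]] + 1L
        }
      }
    }
  }
  types <- corpus_entity_types(train_corpus)
  if (!length(types))
    stop("training corpus contains no entity mentions to build prototypes from")
  zero <- setdiff(types, names(sums))
  if (length(zero))
    stop("entity type(s) with zero mention tokens: ", paste(zero, collapse = ", "))
  P <- t(vapply(types, function(t) sums[[t]] / counts[[t]], numeric(dim)))
  rownames(P) <- types
  class(P) <- c("cerex_prototypes", class(P))
  P
}

# ---- pair representations -------------------------------------------------

# Internal: build the pair vector plus the bookkeeping needed to backprop
# into the hidden-state rows (and the type-embedding rows, if any).
pair_rep_build <- function(mode, h_re, e_j, e_k, aux = NULL,
                           type_labels = NULL) {
  n <- nrow(h_re); d <- ncol(h_re)
  span_rows <- function(m) {
    rows <- (m$start + 1L):(m$end + 1L)
    if (m$start < 0L || m$end >= n) stop("mention span outside hidden states")
    rows
  }
  sum_rows <- function(rows) if (length(rows) == 1L) h_re[rows, ] else colSums(h_re[rows, , drop = FALSE])
  lookup <- function(tab, lab, what) {
    if (is.null(tab)) stop("mode '", mode, "' requires a ", what, " table")
    if (!lab %in% rownames(tab)) stop("unknown entity type '", lab, "' in ", what)
    tab[lab, ]
  }
  if (mode %in% c("vanilla", "type_embedding", "prototype")) {
    rj <- span_rows(e_j); rk <- span_rows(e_k)
    sj <- sum_rows(rj); sk <- sum_rows(rk)
    if (mode == "vanilla") {
      v <- c(sj, sk)
      info <- list(rows_j = rj, rows_k = rk, d = d, aux_rows = NULL)
    } else {
      if (is.null(type_labels) || length(type_labels) != 2L)
        stop("mode '", mode, "' requires type_labels for both mentions")
      tab <- aux
      aj <- lookup(tab, type_labels[[1]], mode)
      ak <- lookup(tab, type_labels[[2]], mode)
      v <- c(sj, aj, sk, ak)
      info <- list(rows_j = rj, rows_k = rk, d = d, e = length(aj),
                   aux_rows = c(type_labels[[1]], type_labels[[2]]))
    }
  } else if (mode == "entity_marker") {
    if (is.null(aux)) stop("mode 'entity_marker' requires the marker position map")
    mm <- if (inherits(aux, "cerex_marked")) aux$marker_start else aux
    for (id in c(e_j$mention_id, e_k$mention_id))
      if (!id %in% names(mm))
        stop("marker position missing for mention '", id, "'")
    pj <- mm[[e_j$mention_id]]; pk <- mm[[e_k$mention_id]]
    rj <- pj + 1L; rk <- pk + 1L
    if (rj > n || rk > n) stop("marker position outside hidden states")
    v <- c(h_re[rj, ], h_re[rk, ])
    info <- list(rows_j = rj, rows_k = rk, d = d, aux_rows = NULL)
  } else stop("unknown augmentation mode '", mode, "'")
  list(v = v, mode = mode, info = info)
}

# Scatter a gradient on the pair vector back onto hidden-state rows; returns
# type-embedding row gradients when the mode has a learned table.
pair_rep_backward <- function(pr, dv, dH) {
  info <- pr$info; d <- info$d
  emb_grads <- NULL
  if (pr$mode %in% c("vanilla", "entity_marker")) {
    gj <- dv[1:d]; gk <- dv[(d + 1L):(2L * d)]
  } else {
    e <- info$e
    gj <- dv[1:d]
    ga <- dv[(d + 1L):(d + e)]
    gk <- dv[(d + e + 1L):(2L * d + e)]
    gb <- dv[(2L * d + e + 1L):(2L * d + 2L * e)]
    emb_grads <- list(labels = info$aux_rows, G = rbind(ga, gb))
  }
  for (r in info$rows_j) dH[r, ] <- dH[r, ] + gj
  for (r in info$rows_k) dH[r, ] <- dH[r, ] + gk
  list(dH = dH, emb = emb_grads)
}

#' Build the joint pair representation for relation classification
#'
#' Four augmentation modes assemble the vector the relation head scores:
#' \describe{
#'   \item{vanilla}{concatenation of the two mentions' span-summed RE hidden
#'     states (length 2d).}
#'   \item{type_embedding}{span sums interleaved with learned 50-dim type
#'     embeddings looked up by each mention's type label (length 2d+100).}
#'   \item{prototype}{as above but with the frozen [compute_prototypes()]
#'     vectors (length 2d+100).}
#'   \item{entity_marker}{concatenation of the hidden states at the two
#'     mentions' *start-marker* positions in the marked sentence (length 2d);
#'     `h_re` must then be the encoding of the marked token sequence and
#'     `aux` the marked sentence (or its marker position map).}
#' }
#' Type labels are gold during training and predicted during inference. Span
#' sums are plain sums, not means.
#'
#' @param mode one of `"vanilla"`, `"type_embedding"`, `"prototype"`,
#'   `"entity_marker"`.
#' @param h_re hidden-state matrix of the RE branch (marked coordinates for
#'   `entity_marker`, raw otherwise).
#' @param e_j,e_k the two [entity_mention()] objects.
#' @param aux mode-dependent: a `cerex_type_emb`, `cerex_prototypes`,
#'   `cerex_marked` (or marker map), or NULL for vanilla.
#' @param type_labels length-2 character vector of the two mentions' type
#'   labels (required by `type_embedding` and `prototype`).
#' @return numeric vector of class `cerex_pair_rep` with attributes `mode`
#'   and `mentions`.
#' @export
pair_representation <- function(mode, h_re, e_j, e_k, aux = NULL,
                                type_labels = NULL) {
  pr <- pair_rep_build(mode, h_re, e_j, e_k, aux, type_labels)
  structure(pr$v, mode = mode,
            mentions = c(e_j$mention_id, e_k$mention_id),
            class = "cerex_pair_rep")
}
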