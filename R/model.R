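# ---- model construction ---------------------------------------------------

# Width of the relation pair representation under the configured mode.
pair_dim <- function(config) {
  2L * config$d +
    if (config$augmentation %in% c("type_embedding", "prototype"))
      2L * config$emb_dim else 0L
}

model_init <- function(config) {
  tokens <- "<unk>"
  params <- with_seed(config$seed, {
    p <- init_encoder_params("ner", length(tokens), config$d, config$n_layers)
    if (config$sharing != "hard")
      p <- c(p, init_encoder_params("re", length(tokens), config$d,
                                    config$n_layers))
    c(p, init_head_params("sp", config$d, config$hidden, 5L))
  })
  base_keys <- grep("^(ner|re)\\.", names(params), value = TRUE)
  structure(list(config = config,
                 vocab = label_vocabulary(),
                 tokens = tokens,
                 params = params,
                 base_params = params[base_keys],  # untrained copy (prototypes)
                 proto = NULL,
                 opt = adamw_state(),
                 expand_counter = 0L,
                 history = NULL,
                 checkpoints = list()),
            class = "cerex")
}

# Derived seed for deterministic expansion / shuffling, kept in 32-bit range.
derived_seed <- function(seed, a, b = 0L) {
  as.integer((as.double(seed) * 1009 + a * 97 + b * 13) %% 2147483647)
}

# Register new tokens, entity types and relation labels ahead of a training
# step: embedding rows, classifier heads and (if configured) type-embedding
# or prototype rows are appended; nothing pre-existing is touched.
model_expand_for_corpus <- function(model, pool) {
  cfg <- model$config
  new_ents <- setdiff(corpus_entity_types(pool), model$vocab$entity_types)
  new_rels <- setdiff(corpus_relation_types(pool), model$vocab$relation_types)
  new_toks <- setdiff(corpus_tokens(pool), model$tokens)
  if (cfg$augmentation == "entity_marker")
    new_toks <- c(new_toks, setdiff(marker_tokens(c(model$vocab$entity_types,
                                                    new_ents)), model$tokens))
  model$expand_counter <- model$expand_counter + 1L
  sd <- derived_seed(cfg$seed, model$expand_counter)

  if (length(new_toks)) {
    model$tokens <- c(model$tokens, new_toks)
    add <- with_seed(sd, matrix(stats::rnorm(length(new_toks) * cfg$d, sd = 0.3),
                                length(new_toks), cfg$d))
    for (pref in intersect(c("ner", "re"), sub("\\..*$", "", names(model$params)))) {
      key <- paste0(pref, ".E")
      if (!is.null(model$params[[key]])) {
        model$params[[key]] <- rbind(model$params[[key]], add)
        model$base_params[[key]] <- rbind(model$base_params[[key]], add)
      }
    }
  }

  if (length(new_ents)) {
    model$vocab <- expand_vocabulary(model$vocab, new_entity_types = new_ents)
    if (cfg$classifier == "multi") {
      for (i in seq_along(new_ents))
        model$params <- c(model$params,
                          with_seed(derived_seed(sd, i, 1L),
                                    init_head_params(paste0("et.", new_ents[i]),
                                                     cfg$d, cfg$hidden, 1L)))
    } else {
      model$params <- grow_single_head(model$params, "et.head", cfg$d,
                                       cfg$hidden, length(new_ents),
                                       derived_seed(sd, 0L, 2L))
    }
    if (cfg$augmentation == "type_embedding") {
      add <- with_seed(derived_seed(sd, 0L, 3L),
                       matrix(stats::rnorm(length(new_ents) * cfg$emb_dim,
                                           sd = 0.1),
                              length(new_ents), cfg$emb_dim))
      rownames(add) <- new_ents
      model$params[["type_emb"]] <-
        if (is.null(model$params[["type_emb"]])) add
        else rbind(model$params[["type_emb"]], add)
    }
  }

  if (cfg$augmentation == "prototype") {
    missing <- setdiff(model$vocab$entity_types,
                       rownames(model$proto) %||% character())
    if (length(missing))
      model$proto <- append_prototypes(model, pool, missing)
  }

  if (length(new_rels)) {
    model$vocab <- expand_vocabulary(model$vocab, new_relation_types = new_rels)
    pd <- pair_dim(cfg)
    if (cfg$classifier == "multi") {
      for (i in seq_along(new_rels))
        model$params <- c(model$params,
                          with_seed(derived_seed(sd, i, 4L),
                                    init_head_params(paste0("re_head.", new_rels[i]),
                                                     pd, cfg$hidden, 1L)))
    } else {
      # single head over c(NO_RELATION, relations): ensure the no-relation
      # output exists, then one output per new label
      n_new <- length(new_rels) +
        if (is.null(model$params[["re_head.head.W2"]])) 1L else 0L
      model$params <- grow_single_head(model$params, "re_head.head", pd,
                                       cfg$hidden, n_new,
                                       derived_seed(sd, 0L, 5L))
    }
  }
  model
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Grow (or create) a single softmax head by n_new output units; existing
# output columns are untouched.
grow_single_head <- function(params, prefix, in_dim, hidden, n_new, seed) {
  if (n_new < 1L) return(params)
  if (is.null(params[[paste0(prefix, ".W1")]])) {
    params <- c(params, with_seed(seed, init_head_params(prefix, in_dim,
                                                         hidden, n_new)))
    return(params)
  }
  addW <- with_seed(seed, matrix(stats::rnorm(hidden * n_new,
                                              sd = 1 / sqrt(hidden)),
                                 hidden, n_new))
  params[[paste0(prefix, ".W2")]] <- cbind(params[[paste0(prefix, ".W2")]], addW)
  params[[paste0(prefix, ".b2")]] <- c(params[[paste0(prefix, ".b2")]],
                                       numeric(n_new))
  params
}

# Frozen prototype rows for newly seen types, computed from the *untrained*
# base encoder over the current pool.
append_prototypes <- function(model, pool, types) {
  cfg <- model$config
  prefix <- if (cfg$sharing == "hard") "ner" else "re"
  sums <- stats::setNames(vector("list", length(types)), types)
  counts <- stats::setNames(integer(length(types)), types)
  for (si in seq_along(pool$sentences)) {
    ms <- Filter(function(m) m$type_label %in% types, pool$mentions[[si]])
    if (!length(ms)) next
    ids <- tokens_to_ids(pool$sentences[[si]]$tokens, model$tokens)
    H <- enc_forward(model$base_params, prefix, ids, cfg$n_layers)$H
    for (m in ms) {
      for (i in (m$start + 1L):(m$end + 1L)) {
        pooled <- chunk_maxpool(H[i, ], cfg$emb_dim)
        if (is.null(sums[[m$type_label]])) sums[[m$type_label]] <- pooled
        else sums[[m$type_label]] <- sums[[m$type_label]] + pooled
        counts[[m$type_label]] <- counts[[m$type_label]] + 1L
      }
    }
  }
  zero <- types[counts == 0L]
  if (length(zero))
    stop("cannot build prototypes: no mention tokens for type(s) ",
         paste(zero, collapse = ", "))
  P <- t(vapply(types, function(t) sums[[t]] / counts[[t]],
                numeric(cfg$emb_dim)))
  rownames(P) <- types
  out <- if (is.null(model$proto)) P else rbind(model$proto, P)
  class(out) <- c("cerex_prototypes", "matrix", "array")
  out
}

# ---- forward/backward over one annotated sentence -------------------------

# Compute the three task losses for one sentence and (when `acc` is given)
# accumulate all parameter gradients of the alpha-weighted joint loss.
sentence_pass <- function(model, sent, mentions, relations, acc = NULL) {
  cfg <- model$config
  p <- model$params
  alpha <- cfg$alpha
  train <- !is.null(acc)
  n <- sent$n

  ids <- tokens_to_ids(sent$tokens, model$tokens)
  fwN <- enc_forward(p, "ner", ids, cfg$n_layers)
  Hn <- fwN$H
  dHn <- if (train) matrix(0, n, cfg$d) else NULL

  # --- span detection
  spfw <- head_forward(p, "sp", Hn)
  tgt <- match(bioes_encode(sent, mentions), .bioes_tags)
  probs <- row_softmax(spfw$logits)
  idx <- cbind(seq_len(n), tgt)
  L_sp <- -mean(log(pmax(probs[idx], 1e-12)))
  if (train) {
    dlog <- probs
    dlog[idx] <- dlog[idx] - 1
    dHn <- dHn + head_backward(p, "sp", spfw, dlog * (alpha[["sp"]] / n), acc)
  }

  # --- entity typing (gold spans only)
  L_et <- 0
  M <- length(model$vocab$entity_types)
  if (length(mentions) && M > 0L) {
    nm <- length(mentions)
    for (m in mentions) {
      rows <- (m$start + 1L):(m$end + 1L)
      u <- if (length(rows) == 1L) Hn[rows, ] else colSums(Hn[rows, , drop = FALSE])
      if (cfg$classifier == "multi") {
        du <- numeric(cfg$d)
        for (lab in model$vocab$entity_types) {
          hf <- head_forward(p, paste0("et.", lab), u)
          z <- hf$logits[1L, 1L]
          y <- as.numeric(lab == m$type_label)
          L_et <- L_et + bce_logit(z, y) / nm
          if (train) {
            dz <- (plogis(z) - y) * (alpha[["et"]] / nm)
            du <- du + as.numeric(head_backward(p, paste0("et.", lab), hf, dz, acc))
          }
        }
      } else {
        hf <- head_forward(p, "et.head", u)
        ti <- match(m$type_label, model$vocab$entity_types)
        L_et <- L_et + ce_softmax(hf$logits[1L, ], ti) / nm
        if (train) {
          dl <- as.numeric(row_softmax(hf$logits))
          dl[ti] <- dl[ti] - 1
          du <- as.numeric(head_backward(p, "et.head", hf,
                                         dl * (alpha[["et"]] / nm), acc))
        } else du <- NULL
      }
      if (train) for (r in rows) dHn[r, ] <- dHn[r, ] + du
    }
  }

  # --- relation extraction (all unordered gold-mention pairs)
  L_re <- 0
  N <- length(model$vocab$relation_types)
  n_pairs <- if (length(mentions) >= 2L) choose(length(mentions), 2L) else 0L
  if (n_pairs > 0L && (N > 0L)) {
    marker_mode <- cfg$augmentation == "entity_marker"
    if (marker_mode) {
      marked <- insert_entity_markers(sent, mentions)
      ids_re <- tokens_to_ids(marked$tokens, model$tokens)
    } else {
      marked <- NULL
      ids_re <- ids
    }
    if (cfg$sharing == "hard") {
      re_prefix <- "ner"
      fwR <- fwN                      # hard sharing forbids markers: same input
    } else {
      re_prefix <- "re"
      fuse_ctx <- if (cfg$sharing == "soft")
        enc_forward(p, "ner", ids_re, cfg$n_layers)$H else NULL
      fwR <- enc_forward(p, re_prefix, ids_re, cfg$n_layers, fuse_ctx)
    }
    Hr <- fwR$H
    dHr <- if (train) matrix(0, nrow(Hr), cfg$d) else NULL

    aux <- switch(cfg$augmentation,
                  entity_marker = marked,
                  type_embedding = p[["type_emb"]],
                  prototype = model$proto,
                  vanilla = NULL)
    gold_map <- list()
    for (r in relations) {
      k <- paste(sort(c(r$mention_a, r$mention_b)), collapse = "|")
      gold_map[[k]] <- r$label
    }
    nm <- length(mentions)
    for (a in seq_len(nm - 1L)) for (b in (a + 1L):nm) {
      mj <- mentions[[a]]; mk <- mentions[[b]]
      labs <- c(mj$type_label, mk$type_label)
      pr <- pair_rep_build(cfg$augmentation, Hr, mj, mk, aux, labs)
      gold_lab <- gold_map[[paste(sort(c(mj$mention_id, mk$mention_id)),
                                  collapse = "|")]]
      if (cfg$classifier == "multi") {
        dv <- if (train) numeric(length(pr$v)) else NULL
        for (lab in model$vocab$relation_types) {
          hf <- head_forward(p, paste0("re_head.", lab), pr$v)
          z <- hf$logits[1L, 1L]
          y <- as.numeric(identical(lab, gold_lab))
          L_re <- L_re + bce_logit(z, y) / n_pairs
          if (train) {
            dz <- (plogis(z) - y) * (alpha[["re"]] / n_pairs)
            dv <- dv + as.numeric(head_backward(p, paste0("re_head.", lab),
                                                hf, dz, acc))
          }
        }
      } else {
        hf <- head_forward(p, "re_head.head", pr$v)
        ti <- if (is.null(gold_lab)) 1L
              else 1L + match(gold_lab, model$vocab$relation_types)
        L_re <- L_re + ce_softmax(hf$logits[1L, ], ti) / n_pairs
        if (train) {
          dl <- as.numeric(row_softmax(hf$logits))
          dl[ti] <- dl[ti] - 1
          dv <- as.numeric(head_backward(p, "re_head.head", hf,
                                         dl * (alpha[["re"]] / n_pairs), acc))
        } else dv <- NULL
      }
      if (train) {
        bk <- pair_rep_backward(pr, dv, dHr)
        dHr <- bk$dH
        if (!is.null(bk$emb) && cfg$augmentation == "type_embedding") {
          ridx <- match(bk$emb$labels, rownames(p[["type_emb"]]))
          acc_add_rows(acc, "type_emb", ridx, bk$emb$G)
        }
      }
    }
    if (train) {
      if (cfg$sharing == "hard") {
        dHn <- dHn + dHr
      } else {
        enc_backward(p, re_prefix, fwR, dHr, acc)
      }
    }
  }

  if (train) enc_backward(p, "ner", fwN, dHn, acc)
  total <- alpha[["sp"]] * L_sp + alpha[["et"]] * L_et + alpha[["re"]] * L_re
  c(total = as.numeric(total), sp = L_sp, et = as.numeric(L_et),
    re = as.numeric(L_re))
}

# Pull (sentence, mentions, relations) triples out of a corpus.
corpus_batch <- function(x, idx) {
  lapply(idx, function(i) list(sent = x$sentences[[i]],
                               mentions = x$mentions[[i]],
                               relations = x$relations[[i]]))
}

#' One optimiser update on a batch of annotated sentences
#'
#' Computes the joint loss (weighted span/type/relation cross-entropies,
#' all three tasks trained simultaneously from the same sentences) over the
#' batch, backpropagates, and applies one AdamW update. Deterministic:
#' identical model states and batches give identical parameter deltas.
#'
#' @param model a `cerex` model.
#' @param batch list of `list(sent =, mentions =, relations =)` items (see
#'   internal corpus accessors, or build directly).
#' @param lr learning rate override (default: the model's configured rate;
#'   0 leaves parameters unchanged).
#' @return list with the updated `model` and the batch-mean `loss`.
#' @export
train_step <- function(model, batch, lr = model$config$lr) {
  acc <- new_acc()
  losses <- vapply(batch, function(b)
    sentence_pass(model, b$sent, b$mentions, b$relations, acc)[["total"]],
    numeric(1))
  loss <- mean(losses)
  if (!is.finite(loss)) {
    bad <- which(!is.finite(losses))[1]
    stop("non-finite loss on batch item ", bad, " (sentence '",
         batch[[bad]]$sent$sentence_id, "')")
  }
  grads <- collapse_grads(acc, model$params, scale = 1 / length(batch))
  if (lr > 0) {
    upd <- adamw_update(model$params, grads, model$opt, lr,
                        weight_decay = model$config$weight_decay)
    model$params <- upd$params
    model$opt <- upd$state
  }
  list(model = model, loss = loss)
}

# ---- fitting --------------------------------------------------------------

#' Fit a joint entity-relation extractor over a training schedule
#'
#' Trains span detection, entity typing and relation extraction
#' simultaneously under the configured encoder sharing, pair-representation
#' augmentation and classifier regime, following the schedule's steps in
#' order. Before each step, any entity types, relation labels or tokens that
#' step introduces expand the label vocabulary, the classifier banks and the
#' embedding tables -- parameters only ever grow. Step t+1 starts from the
#' parameters selected at step t; when a validation corpus is supplied, the
#' epoch with the best validation relation micro-F1 is selected per step
#' (ties to the earlier epoch), otherwise the last epoch is kept.
#'
#' @param x a [build_schedule()] result, a single corpus, or a list of
#'   corpora (then assembled into a schedule under `paradigm`).
#' @param validation optional corpus scored after every epoch.
#' @param config a [cerex_config()].
#' @param paradigm schedule paradigm used when `x` is not already a schedule.
#' @param epochs epochs per step (default from `config`).
#' @param verbose print per-epoch progress.
#' @return a fitted model of class `cerex`, with `$history` (per-epoch
#'   losses and validation metrics) and `$checkpoints` (per-step parameter
#'   snapshots with their vocabulary).
#' @export
cerex <- function(x, validation = NULL, config = cerex_config(),
                  paradigm = c("multi_corpora", "continual",
                               "continual_multi_corpora"),
                  epochs = config$epochs, verbose = FALSE) {
  if (inherits(x, "cerex_corpus")) x <- list(x)
  if (!inherits(x, "cerex_schedule")) {
    paradigm <- match.arg(paradigm)
    x <- build_schedule(x, paradigm, seed = config$seed)
  }
  model <- model_init(config)
  hist <- list()
  for (t in seq_along(x$steps)) {
    pool <- x$steps[[t]]$pool
    if (!length(pool$sentences)) stop("schedule step ", t, " is empty")
    model <- model_expand_for_corpus(model, pool)
    model$opt <- adamw_state()        # fresh optimiser per step
    ns <- length(pool$sentences)
    best_f1 <- -Inf
    best_params <- model$params
    for (ep in seq_len(epochs)) {
      ord <- with_seed(derived_seed(config$seed, t, ep), sample.int(ns))
      starts <- seq(1L, ns, by = config$batch_size)
      ep_loss <- 0
      for (s in starts) {
        idx <- ord[s:min(s + config$batch_size - 1L, ns)]
        st <- train_step(model, corpus_batch(pool, idx))
        model <- st$model
        ep_loss <- ep_loss + st$loss * length(idx)
      }
      ep_loss <- ep_loss / ns
      val <- c(sp = NA_real_, et = NA_real_, re = NA_real_)
      if (!is.null(validation)) {
        rep <- evaluate_model(model, validation, conditional = FALSE)
        val <- c(sp = rep$SP$f1, et = rep$ET$f1, re = rep$RE$f1)
        if (val[["re"]] > best_f1) {
          best_f1 <- val[["re"]]
          best_params <- model$params
        }
      }
      hist[[length(hist) + 1L]] <- data.frame(
        step = t, epoch = ep, loss = ep_loss,
        val_sp = val[["sp"]], val_et = val[["et"]], val_re = val[["re"]])
      if (verbose)
        message(sprintf("step %d epoch %2d  loss %.4f  val RE F1 %s",
                        t, ep, ep_loss,
                        ifelse(is.na(val[["re"]]), "-",
                               sprintf("%.3f", val[["re"]]))))
    }
    if (!is.null(validation)) model$params <- best_params
    model$checkpoints[[t]] <- list(step = t, params = model$params,
                                   vocab = model$vocab, tokens = model$tokens,
                                   proto = model$proto)
  }
  model$history <- do.call(rbind, hist)
  model$paradigm <- x$paradigm
  model
}

#' Run a training schedule (alias for the fitting engine)
#'
#' @inheritParams cerex
#' @param schedule a [build_schedule()] result.
#' @return a fitted `cerex` model; per-step checkpoints in `$checkpoints`,
#'   per-epoch validation metrics in `$history`.
#' @export
run_schedule <- function(schedule, config = cerex_config(), validation = NULL,
                         epochs = config$epochs, verbose = FALSE) {
  cerex(schedule, validation = validation, config = config, epochs = epochs,
        verbose = verbose)
}

# Restore a checkpoint as a standalone model (for post-step scoring).
checkpoint_model <- function(model, t) {
  ck <- model$checkpoints[[t]]
  out <- model
  out$params <- ck$params
  out$vocab <- ck$vocab
  out$tokens <- ck$tokens
  out$proto <- ck$proto
  out
}

# ---- inference ------------------------------------------------------------

# Bank-style scores from the model's flat parameters.
model_bank_scores <- function(model, prefix, labels, x) {
  z <- vapply(labels, function(lab)
    head_forward(model$params, paste0(prefix, lab), x)$logits[1L, 1L],
    numeric(1))
  stats::setNames(plogis(z), labels)
}

model_predict_type <- function(model, u) {
  if (model$config$classifier == "multi") {
    aggregate_multihead(model_bank_scores(model, "et.",
                                          model$vocab$entity_types, u),
                        model$config$theta)
  } else {
    lg <- head_forward(model$params, "et.head", u)$logits[1L, ]
    probs <- as.numeric(row_softmax(matrix(lg, nrow = 1L)))
    best <- which.max(probs)
    list(label = model$vocab$entity_types[best], confidence = probs[best])
  }
}

model_predict_relation <- function(model, v) {
  if (model$config$classifier == "multi") {
    aggregate_multihead(model_bank_scores(model, "re_head.",
                                          model$vocab$relation_types, v),
                        model$config$theta)
  } else {
    lg <- head_forward(model$params, "re_head.head", v)$logits[1L, ]
    probs <- as.numeric(row_softmax(matrix(lg, nrow = 1L)))
    best <- which.max(probs)
    list(label = c(NA_character_, model$vocab$relation_types)[best],
         confidence = probs[best])
  }
}

# Relation predictions over all unordered pairs of `mentions`, building the
# configured pair representation from hidden states of the RE branch.
predict_relations <- function(model, sent, mentions) {
  cfg <- model$config
  if (length(mentions) < 2L) return(list())
  marker_mode <- cfg$augmentation == "entity_marker"
  if (marker_mode) {
    marked <- insert_entity_markers(sent, mentions)
    ids_re <- tokens_to_ids(marked$tokens, model$tokens)
  } else {
    marked <- NULL
    ids_re <- tokens_to_ids(sent$tokens, model$tokens)
  }
  prefix <- if (cfg$sharing == "hard") "ner" else "re"
  fuse_ctx <- if (cfg$sharing == "soft")
    enc_forward(model$params, "ner", ids_re, cfg$n_layers)$H else NULL
  Hr <- enc_forward(model$params, prefix, ids_re, cfg$n_layers, fuse_ctx)$H
  aux <- switch(cfg$augmentation,
                entity_marker = marked,
                type_embedding = model$params[["type_emb"]],
                prototype = model$proto,
                vanilla = NULL)
  out <- list()
  nm <- length(mentions)
  for (a in seq_len(nm - 1L)) for (b in (a + 1L):nm) {
    mj <- mentions[[a]]; mk <- mentions[[b]]
    pr <- pair_rep_build(cfg$augmentation, Hr, mj, mk, aux,
                         c(mj$type_label, mk$type_label))
    res <- model_predict_relation(model, pr$v)
    if (!is.na(res$label))
      out[[length(out) + 1L]] <- list(a = mj, b = mk, label = res$label,
                                      confidence = res$confidence)
  }
  out
}

#' Full-pipeline inference on one raw sentence
#'
#' The inference cascade mirrors the conditioning structure of the model:
#' (1) span detection tags the raw sentence and the tags are conservatively
#' decoded into spans; (2) each span is typed (spans that no type head
#' accepts are dropped); (3) every unordered pair of typed mentions gets a
#' pair representation -- with markers inserted according to the *predicted*
#' spans and types when marker augmentation is configured -- and is scored
#' by the relation classifier; only pairs assigned a relation are returned.
#'
#' @param model a fitted `cerex` model.
#' @param sent a [sentence()] (no gold annotation needed).
#' @return list with `tags` (predicted BIOES sequence), `mentions`
#'   (predicted [entity_mention()]s) and `relations` (triples `a`, `b`,
#'   `label`, `confidence`).
#' @export
infer_sentence <- function(model, sent) {
  cfg <- model$config
  ids <- tokens_to_ids(sent$tokens, model$tokens)
  Hn <- enc_forward(model$params, "ner", ids, cfg$n_layers)$H
  probs <- row_softmax(head_forward(model$params, "sp", Hn)$logits)
  tags <- .bioes_tags[max.col(probs, ties.method = "first")]
  spans <- bioes_decode(tags)
  mentions <- list()
  for (sp in spans) {
    rows <- (sp[1] + 1L):(sp[2] + 1L)
    u <- if (length(rows) == 1L) Hn[rows, ] else colSums(Hn[rows, , drop = FALSE])
    ty <- model_predict_type(model, u)
    if (is.na(ty$label)) next
    mentions[[length(mentions) + 1L]] <-
      entity_mention(sp[1], sp[2], ty$label,
                     sprintf("P%d", length(mentions) + 1L))
  }
  list(tags = tags, mentions = mentions,
       relations = predict_relations(model, sent, mentions))
}

#' Gold-conditioned inference isolating error propagation
#'
#' Replaces upstream pipeline stages by gold annotations: with condition
#' `"gold_sp"` entity types are predicted on the gold spans (the ET+
#' protocol); with `"gold_sp_et"` relations are predicted with gold spans
#' *and* gold types, markers placed from gold (the RE+ protocol). Comparing
#' these scores with the full pipeline separates a stage's own errors from
#' the errors it inherits.
#'
#' @param model a fitted `cerex` model.
#' @param sent a [sentence()].
#' @param gold_mentions the sentence's gold [entity_mention()] list.
#' @param condition `"gold_sp"` or `"gold_sp_et"`.
#' @return for `"gold_sp"`: list with `mentions` (gold spans, predicted
#'   types); for `"gold_sp_et"`: list with `relations` over the gold
#'   mentions.
#' @export
infer_conditional <- function(model, sent, gold_mentions,
                              condition = c("gold_sp", "gold_sp_et")) {
  condition <- match.arg(condition)
  if (is.null(gold_mentions)) stop("gold mentions are required")
  cfg <- model$config
  if (condition == "gold_sp") {
    ids <- tokens_to_ids(sent$tokens, model$tokens)
    Hn <- enc_forward(model$params, "ner", ids, cfg$n_layers)$H
    mentions <- list()
    for (m in gold_mentions) {
      rows <- (m$start + 1L):(m$end + 1L)
      u <- if (length(rows) == 1L) Hn[rows, ] else colSums(Hn[rows, , drop = FALSE])
      ty <- model_predict_type(model, u)
      if (is.na(ty$label)) next
      mentions[[length(mentions) + 1L]] <-
        entity_mention(m$start, m$end, ty$label, m$mention_id)
    }
    list(mentions = mentions)
  } else {
    list(relations = predict_relations(model, sent, gold_mentions))
  }
}

# ---- model-level evaluation ----------------------------------------------

#' Score a fitted model on an annotated corpus
#'
#' Runs the full inference pipeline over the corpus and applies the
#' propagation-aware scoring rules: token-level span micro-F1, exact
#' span+type entity micro-F1, exact-triple relation micro-F1, plus (when
#' `conditional`) the gold-conditioned ET+ and RE+ variants and the united-
#' tag NER score.
#'
#' @param model a fitted `cerex` model.
#' @param x a `cerex_corpus` with gold annotation.
#' @param conditional also compute ET+/RE+ and united NER (default TRUE).
#' @return an object of class `cerex_report`.
#' @export
evaluate_model <- function(model, x, conditional = TRUE) {
  ns <- length(x$sentences)
  pred_tags <- vector("list", ns); gold_tags <- vector("list", ns)
  pred_ment <- vector("list", ns); pred_rel <- vector("list", ns)
  gold_rel <- vector("list", ns)
  etp_ment <- vector("list", ns); rep_rel <- vector("list", ns)
  for (i in seq_len(ns)) {
    s <- x$sentences[[i]]; gm <- x$mentions[[i]]
    inf <- infer_sentence(model, s)
    pred_tags[[i]] <- inf$tags
    gold_tags[[i]] <- bioes_encode(s, gm)
    pred_ment[[i]] <- inf$mentions
    pred_rel[[i]] <- inf$relations
    by_id <- stats::setNames(gm, vapply(gm, function(m) m$mention_id, character(1)))
    gold_rel[[i]] <- lapply(x$relations[[i]], function(r)
      list(a = by_id[[r$mention_a]], b = by_id[[r$mention_b]], label = r$label))
    if (conditional) {
      etp_ment[[i]] <- infer_conditional(model, s, gm, "gold_sp")$mentions
      rep_rel[[i]] <- infer_conditional(model, s, gm, "gold_sp_et")$relations
    }
  }
  out <- list(
    corpus = x$name,
    SP = evaluate_sp(pred_tags, gold_tags, include_o = model$config$sp_include_o),
    ET = evaluate_et(pred_ment, x$mentions),
    RE = evaluate_re(pred_rel, gold_rel))
  if (conditional) {
    out$NER_united <- evaluate_united_ner(pred_ment, x$mentions)
    out$ET_plus <- evaluate_et(etp_ment, x$mentions)
    out$RE_plus <- evaluate_re(rep_rel, gold_rel)
  }
  structure(out, class = "cerex_report")
}

#' Corpus-adaptation evaluation on a held-out foreign corpus
#'
#' Scores the model on a corpus from a different annotation effort than any
#' training corpus (full-pipeline inference, same scoring rules), measuring
#' cross-corpus generalisation in the continual-learning setting. The
#' foreign corpus must be non-empty and its labels must lie inside the
#' model's vocabulary.
#'
#' @param model a fitted `cerex` model.
#' @param foreign_corpus a `cerex_corpus` never seen in training.
#' @return a `cerex_report`.
#' @export
corpus_adaptation_eval <- function(model, foreign_corpus) {
  if (!length(foreign_corpus$sentences))
    stop("foreign corpus is empty")
  bad_e <- setdiff(corpus_entity_types(foreign_corpus),
                   model$vocab$entity_types)
  bad_r <- setdiff(corpus_relation_types(foreign_corpus),
                   model$vocab$relation_types)
  if (length(bad_e) || length(bad_r))
    stop("foreign corpus labels outside the model vocabulary: ",
         paste(c(bad_e, bad_r), collapse = ", "))
  evaluate_model(model, foreign_corpus)
}

#' @export
print.cerex_report <- function(x, ...) {
  cat("<cerex_report> corpus:", x$corpus, "\n")
  rows <- intersect(c("SP", "ET", "ET_plus", "RE", "RE_plus", "NER_united"),
                    names(x))
  for (r in rows) {
    m <- x[[r]]
    cat(sprintf("  %-10s P %.3f  R %.3f  F1 %.3f  (tp %.0f fp %.0f fn %.0f)\n",
                r, m$precision, m$recall, m$f1,
                m$counts[["tp"]], m$counts[["fp"]], m$counts[["fn"]]))
  }
  invisible(x)
}

# ---- S3 methods -----------------------------------------------------------

#' @export
print.cerex <- function(x, ...) {
  cfg <- x$config
  cat("<cerex> joint entity-relation extractor\n")
  cat(sprintf("  encoder: tiny d=%d x %d layers, sharing=%s\n",
              cfg$d, cfg$n_layers, cfg$sharing))
  cat(sprintf("  augmentation=%s, classifier=%s\n",
              cfg$augmentation, cfg$classifier))
  cat(sprintf("  vocabulary: %d entity types (%s); %d relations (%s)\n",
              length(x$vocab$entity_types),
              paste(x$vocab$entity_types, collapse = ", "),
              length(x$vocab$relation_types),
              paste(x$vocab$relation_types, collapse = ", ")))
  if (!is.null(x$history))
    cat(sprintf("  trained: %d step(s), %d epoch rows; final loss %.4f\n",
                max(x$history$step), nrow(x$history),
                x$history$loss[nrow(x$history)]))
  invisible(x)
}

#' @export
summary.cerex <- function(object, ...) {
  print(object)
  h <- object$history
  if (!is.null(h) && any(!is.na(h$val_re))) {
    cat("  validation RE micro-F1 by step (selected epoch):\n")
    for (t in unique(h$step)) {
      hs <- h[h$step == t & !is.na(h$val_re), ]
      if (!nrow(hs)) next
      b <- hs[which.max(hs$val_re), ]
      cat(sprintf("    step %d: F1 %.3f (epoch %d)\n", t, b$val_re, b$epoch))
    }
  }
  invisible(object)
}

#' Predict mentions and relations for new sentences
#'
#' @param object a fitted `cerex` model.
#' @param newdata a `cerex_corpus` or a list of [sentence()]s.
#' @param condition `"pipeline"` (default, raw sentences only),
#'   `"gold_sp"` or `"gold_sp_et"` (require `newdata` to carry gold
#'   mentions; see [infer_conditional()]).
#' @param ... unused.
#' @return a list of per-sentence prediction lists.
#' @export
predict.cerex <- function(object, newdata,
                          condition = c("pipeline", "gold_sp", "gold_sp_et"),
                          ...) {
  condition <- match.arg(condition)
  is_corpus <- inherits(newdata, "cerex_corpus")
  sents <- if (is_corpus) newdata$sentences else newdata
  lapply(seq_along(sents), function(i) {
    if (condition == "pipeline") return(infer_sentence(object, sents[[i]]))
    if (!is_corpus) stop("gold-conditioned prediction needs an annotated corpus")
    infer_conditional(object, sents[[i]], newdata$mentions[[i]], condition)
  })
}

#' Plot training loss and validation F1 curves
#'
#' @param x a fitted `cerex` model.
#' @param ... passed to [graphics::plot()].
#' @export
plot.cerex <- function(x, ...) {
  h <- x$history
  if (is.null(h)) stop("model has no training history")
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  idx <- seq_len(nrow(h))
  graphics::plot(idx, h$loss, type = "l", xlab = "epoch (all steps)",
                 ylab = "joint loss", main = "training loss", ...)
  for (t in unique(h$step))
    graphics::abline(v = max(idx[h$step == t]), lty = 3, col = "grey")
  if (any(!is.na(h$val_re))) {
    graphics::plot(idx, h$val_re, type = "l", ylim = c(0, 1),
                   xlab = "epoch (all steps)", ylab = "micro-F1",
                   main = "validation", ...)
    graphics::lines(idx, h$val_sp, lty = 2)
    graphics::lines(idx, h$val_et, lty = 3)
    graphics::legend("bottomright", c("RE", "SP", "ET"), lty = 1:3, bty = "n")
  }
  invisible(x)
}
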