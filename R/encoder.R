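# ---- numerics -------------------------------------------------------------

# Row-wise softmax, numerically stabilised.
row_softmax <- function(S) {
  S <- S - apply(S, 1L, max)
  E <- exp(S)
  E / rowSums(E)
}

# Backward through a row-wise softmax: given A = softmax(S) and dA, return dS.
row_softmax_bwd <- function(A, dA) {
  A * (dA - rowSums(dA * A))
}

# Sinusoidal positional encodings, cached per (n, d).
.pe_cache <- new.env(parent = emptyenv())
sinusoid_pe <- function(n, d) {
  key <- paste0(n, "x", d)
  pe <- .pe_cache[[key]]
  if (!is.null(pe)) return(pe)
  pos <- seq_len(n) - 1L
  half <- d %/% 2L
  freq <- 1 / (10000^((seq_len(half) - 1L) / half))
  ang <- outer(pos, freq)
  pe <- matrix(0, n, d)
  pe[, seq_len(half) * 2L - 1L] <- sin(ang)
  pe[, seq_len(half) * 2L] <- cos(ang)
  .pe_cache[[key]] <- pe
  pe
}

# ---- parameter containers -------------------------------------------------

# All trainable arrays live in one flat named list; key prefixes identify the
# component ("ner.", "re.", "sp.", "et.<label>.", ...). This keeps the AdamW
# state, gradient accumulation and head-bank expansion uniform.

init_encoder_params <- function(prefix, n_tokens, d, n_layers) {
  p <- list()
  # embeddings carry the lexical signal; larger init than the mixing weights
  p[[paste0(prefix, ".E")]] <- matrix(stats::rnorm(n_tokens * d, sd = 0.3),
                                      n_tokens, d)
  for (l in seq_len(n_layers)) {
    lp <- sprintf("%s.l%d.", prefix, l)
    sd_in <- 1 / sqrt(d)
    p[[paste0(lp, "Wq")]] <- matrix(stats::rnorm(d * d, sd = sd_in), d, d)
    p[[paste0(lp, "Wk")]] <- matrix(stats::rnorm(d * d, sd = sd_in), d, d)
    p[[paste0(lp, "Wv")]] <- matrix(stats::rnorm(d * d, sd = sd_in), d, d)
    # residual-stream writers start small to keep the stack stable
    p[[paste0(lp, "Wo")]] <- matrix(stats::rnorm(d * d, sd = 0.05), d, d)
    p[[paste0(lp, "W1")]] <- matrix(stats::rnorm(d * d, sd = sd_in), d, d)
    p[[paste0(lp, "b1")]] <- numeric(d)
    p[[paste0(lp, "W2")]] <- matrix(stats::rnorm(d * d, sd = 0.05), d, d)
  }
  p
}

# Gradient accumulator: an environment collecting per-call contributions.
new_acc <- function() new.env(parent = emptyenv())

acc_add <- function(acc, key, val) {
  cur <- acc[[key]]
  acc[[key]] <- if (is.null(cur)) val else cur + val
  invisible(NULL)
}

# Embedding gradients are collected as (row ids, gradient rows) pairs and
# scattered once per batch.
acc_add_rows <- function(acc, key, ids, G) {
  k <- paste0(key, "#rows")
  acc[[k]] <- c(acc[[k]], list(list(ids = ids, G = G)))
  invisible(NULL)
}

# Collapse an accumulator into a gradient list shaped like `params`.
collapse_grads <- function(acc, params, scale = 1) {
  g <- list()
  for (key in ls(acc)) {
    if (endsWith(key, "#rows")) {
      base <- sub("#rows$", "", key)
      dE <- matrix(0, nrow(params[[base]]), ncol(params[[base]]))
      for (chunk in acc[[key]]) {
        # scatter-add with duplicate ids handled by rowsum
        rs <- rowsum(chunk$G, chunk$ids)
        rid <- as.integer(rownames(rs))
        dE[rid, ] <- dE[rid, ] + rs
      }
      g[[base]] <- if (is.null(g[[base]])) dE * scale else g[[base]] + dE * scale
    } else {
      gv <- acc[[key]] * scale
      g[[key]] <- if (is.null(g[[key]])) gv else g[[key]] + gv
    }
  }
  g
}

# ---- encoder forward / backward -------------------------------------------

# Forward pass of the tiny encoder: token embeddings + sinusoidal positions,
# then n_layers of (single-head self-attention + position-wise feed-forward),
# both with residual connections. `fuse_ctx` (n x d), when given, applies the
# cross-attention fusion after every layer (soft parameter sharing).
enc_forward <- function(params, prefix, ids, n_layers, fuse_ctx = NULL) {
  E <- params[[paste0(prefix, ".E")]]
  d <- ncol(E)
  n <- length(ids)
  X <- E[ids, , drop = FALSE] + sinusoid_pe(n, d)
  caches <- vector("list", n_layers)
  for (l in seq_len(n_layers)) {
    lp <- sprintf("%s.l%d.", prefix, l)
    Wq <- params[[paste0(lp, "Wq")]]; Wk <- params[[paste0(lp, "Wk")]]
    Wv <- params[[paste0(lp, "Wv")]]; Wo <- params[[paste0(lp, "Wo")]]
    W1 <- params[[paste0(lp, "W1")]]; b1 <- params[[paste0(lp, "b1")]]
    W2 <- params[[paste0(lp, "W2")]]
    Q <- X %*% Wq; K <- X %*% Wk; V <- X %*% Wv
    A <- row_softmax(Q %*% t(K) / sqrt(d))
    Z <- A %*% V
    Xp <- X + Z %*% Wo
    P <- sweep(Xp %*% W1, 2L, b1, "+")
    R <- pmax(P, 0)
    Xout <- Xp + R %*% W2
    cache <- list(X = X, Q = Q, K = K, V = V, A = A, Z = Z, Xp = Xp,
                  mask = P > 0, R = R)
    if (!is.null(fuse_ctx)) {
      fz <- fuse_forward(Xout, fuse_ctx)
      cache$fuse <- list(Xout = Xout, A2 = fz$A, W = fz$W)
      Xout <- fz$H
    }
    caches[[l]] <- cache
    X <- Xout
  }
  list(H = X, ids = ids, caches = caches, fuse_ctx = fuse_ctx)
}

# Backward pass mirroring enc_forward; writes weight gradients into `acc`
# under the same keys and scatters embedding-row gradients. The fusion
# context (NER final states under soft sharing) is treated as a constant.
enc_backward <- function(params, prefix, fw, dH, acc) {
  E <- params[[paste0(prefix, ".E")]]
  d <- ncol(E)
  n_layers <- length(fw$caches)
  dX <- dH
  for (l in rev(seq_len(n_layers))) {
    lp <- sprintf("%s.l%d.", prefix, l)
    cc <- fw$caches[[l]]
    if (!is.null(cc$fuse)) {
      fz <- cc$fuse
      dXout <- dX * fz$W                       # elementwise product path
      dW <- dX * fz$Xout
      dA2 <- dW %*% t(fw$fuse_ctx)
      dS2 <- row_softmax_bwd(fz$A2, dA2)
      dXout <- dXout + dS2 %*% fw$fuse_ctx / sqrt(d)
      dX <- dXout
    }
    W1 <- params[[paste0(lp, "W1")]]; W2 <- params[[paste0(lp, "W2")]]
    Wq <- params[[paste0(lp, "Wq")]]; Wk <- params[[paste0(lp, "Wk")]]
    Wv <- params[[paste0(lp, "Wv")]]; Wo <- params[[paste0(lp, "Wo")]]
    # feed-forward sublayer
    dR <- dX %*% t(W2)
    dP <- dR * cc$mask
    acc_add(acc, paste0(lp, "W2"), t(cc$R) %*% dX)
    acc_add(acc, paste0(lp, "W1"), t(cc$Xp) %*% dP)
    acc_add(acc, paste0(lp, "b1"), colSums(dP))
    dXp <- dX + dP %*% t(W1)
    # attention sublayer
    dZ <- dXp %*% t(Wo)
    acc_add(acc, paste0(lp, "Wo"), t(cc$Z) %*% dXp)
    dA <- dZ %*% t(cc$V)
    dV <- t(cc$A) %*% dZ
    dS <- row_softmax_bwd(cc$A, dA) / sqrt(d)
    dQ <- dS %*% cc$K
    dK <- t(dS) %*% cc$Q
    acc_add(acc, paste0(lp, "Wq"), t(cc$X) %*% dQ)
    acc_add(acc, paste0(lp, "Wk"), t(cc$X) %*% dK)
    acc_add(acc, paste0(lp, "Wv"), t(cc$X) %*% dV)
    dX <- dXp + dQ %*% t(Wq) + dK %*% t(Wk) + dV %*% t(Wv)
  }
  acc_add_rows(acc, paste0(prefix, ".E"), fw$ids, dX)
  invisible(NULL)
}

# ---- cross-attention fusion (soft sharing) --------------------------------

fuse_forward <- function(H_re, H_ner) {
  d <- ncol(H_re)
  A <- row_softmax(H_re %*% t(H_ner) / sqrt(d))
  W <- A %*% H_ner
  list(H = W * H_re, A = A, W = W)
}

#' Cross-attention fusion of RE-layer states with final NER states
#'
#' Soft parameter sharing lets each relation-encoder layer attend over the
#' NER encoder's final-layer states: attention scores are the scaled dot
#' products between the RE layer's states and the NER states, row-normalised
#' with a softmax; the attention-weighted sum of NER states is then combined
#' with the RE states by an elementwise product. (The trailing product is
#' elementwise -- a matrix product of two n-by-d matrices would be
#' dimensionally inconsistent.) Both inputs must cover the same token
#' sequence.
#'
#' @param h_re_l n x d hidden states of one RE-encoder layer.
#' @param h_ner_L n x d final-layer hidden states of the NER encoder.
#' @return the fused n x d matrix; the row-stochastic attention matrix is
#'   attached as attribute `"attention"`.
#' @export
cross_attention_fuse <- function(h_re_l, h_ner_L) {
  if (!is.matrix(h_re_l) || !is.matrix(h_ner_L) ||
      !all(dim(h_re_l) == dim(h_ner_L)))
    stop("h_re_l and h_ner_L must be matrices of identical shape")
  fz <- fuse_forward(h_re_l, h_ner_L)
  structure(fz$H, attention = fz$A)
}

# ---- encoder bundle -------------------------------------------------------

#' Create a pair of token encoders for the NER and RE branches
#'
#' Three parameter-sharing regimes: `"hard"` (one encoder serves both
#' branches), `"soft"` (two encoders; every RE layer is fused with the NER
#' encoder's final-layer states via [cross_attention_fuse()]), and `"none"`
#' (two fully independent encoders -- the default). The encoder is the
#' package's tiny transformer: learned token embeddings plus sinusoidal
#' positions followed by `n_layers` self-attention blocks; `encoder_kind`
#' other than `"tiny"` is reserved for externally pretrained language models
#' and is not provided.
#'
#' @param tokens character vector of known tokens (the lexical vocabulary);
#'   marker tokens must be registered here before encoding marked sentences.
#' @param sharing_mode `"none"`, `"soft"` or `"hard"`.
#' @param d hidden dimension (default 64).
#' @param n_layers self-attention layers per encoder (default 2).
#' @param encoder_kind only `"tiny"` is available.
#' @param seed initialisation seed.
#' @return an object of class `cerex_bundle`.
#' @export
encoder_bundle <- function(tokens, sharing_mode = c("none", "soft", "hard"),
                           d = 64L, n_layers = 2L, encoder_kind = "tiny",
                           seed = 1L) {
  sharing_mode <- match.arg(sharing_mode)
  if (!identical(encoder_kind, "tiny"))
    stop("encoder_kind '", encoder_kind, "' is not provided; use 'tiny'")
  vocab <- unique(c("<unk>", as.character(tokens)))
  params <- with_seed(seed, {
    p <- init_encoder_params("ner", length(vocab), d, n_layers)
    if (sharing_mode != "hard")
      p <- c(p, init_encoder_params("re", length(vocab), d, n_layers))
    p
  })
  structure(list(sharing_mode = sharing_mode, d = as.integer(d),
                 n_layers = as.integer(n_layers), encoder_kind = encoder_kind,
                 vocab = vocab, params = params),
            class = "cerex_bundle")
}

# Branch prefix under the bundle's sharing mode.
branch_prefix <- function(sharing_mode, branch) {
  if (sharing_mode == "hard") "ner" else if (branch == "NER") "ner" else "re"
}

# Map tokens to embedding-row ids; unknown ordinary tokens fall back to
# <unk>, but unregistered *marker* tokens are an error (a marker the encoder
# has never seen means the vocabulary was not expanded before training).
tokens_to_ids <- function(tokens, vocab) {
  ids <- match(tokens, vocab)
  if (anyNA(ids)) {
    missing <- tokens[is.na(ids)]
    marker <- grepl("^\\[.+_(start|end)\\]$", missing)
    if (any(marker))
      stop("unregistered marker token(s): ",
           paste(unique(missing[marker]), collapse = ", "))
    ids[is.na(ids)] <- 1L  # <unk>
  }
  ids
}

#' Encode a token sequence with one branch of an encoder bundle
#'
#' Returns one d-dimensional hidden-state row per input token. Outputs are
#' deterministic functions of the bundle parameters; under hard sharing the
#' NER and RE branches produce identical encodings of the same sentence.
#'
#' @param bundle a [encoder_bundle()].
#' @param branch `"NER"` or `"RE"`.
#' @param tokens character vector of tokens (possibly containing registered
#'   marker tokens on the RE branch).
#' @return an n x d numeric matrix of hidden states.
#' @export
encode_tokens <- function(bundle, branch = c("NER", "RE"), tokens) {
  branch <- match.arg(branch)
  if (!length(tokens)) stop("tokens must be non-empty")
  ids <- tokens_to_ids(tokens, bundle$vocab)
  prefix <- branch_prefix(bundle$sharing_mode, branch)
  fuse_ctx <- NULL
  if (bundle$sharing_mode == "soft" && branch == "RE") {
    fuse_ctx <- enc_forward(bundle$params, "ner", ids, bundle$n_layers)$H
  }
  enc_forward(bundle$params, prefix, ids, bundle$n_layers, fuse_ctx)$H
}

# ---- AdamW ----------------------------------------------------------------

# Decoupled weight-decay Adam. State lazily tracks new parameters (head
# expansion) and pads its moments when a matrix gains rows (embedding
# growth), preserving the moments of pre-existing rows.
adamw_state <- function() {
  list(t = 0L, m = list(), v = list())
}

grow_like <- function(mom, param) {
  if (is.null(mom)) {
    if (is.matrix(param)) return(matrix(0, nrow(param), ncol(param)))
    return(numeric(length(param)))
  }
  if (is.matrix(param) && nrow(mom) < nrow(param)) {
    pad <- matrix(0, nrow(param) - nrow(mom), ncol(param))
    return(rbind(mom, pad))
  }
  if (!is.matrix(param) && length(mom) < length(param))
    return(c(mom, numeric(length(param) - length(mom))))
  mom
}

adamw_update <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                         eps = 1e-8, weight_decay = 0.01) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (key in names(grads)) {
    g <- grads[[key]]
    p <- params[[key]]
    m <- grow_like(state$m[[key]], p)
    v <- grow_like(state$v[[key]], p)
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g * g
    step <- lr * (m / bc1) / (sqrt(v / bc2) + eps)
    if (weight_decay > 0 && is.matrix(p) && !grepl("\\.b[0-9]*$", key))
      step <- step + lr * weight_decay * p
    params[[key]] <- p - step
    state$m[[key]] <- m
    state$v[[key]] <- v
  }
  list(params = params, state = state)
}
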