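.bioes_tags <- c("B", "I", "O", "E", "S")

#' Build a run configuration
#'
#' Collects every tunable of the joint extractor with its default: batch
#' size 8, learning rate 5e-4 (AdamW), task loss weights 0.4/0.25/0.35
#' (span/type/relation), binary-head threshold 0.5, and 50-dimensional type
#' embeddings and prototypes. Invalid combinations are rejected here: entity
#' -marker augmentation needs the NER branch to read the raw sentence while
#' the RE branch reads the marked one, which a single hard-shared encoder
#' input stream cannot satisfy, so `augmentation = "entity_marker"` with
#' `sharing = "hard"` is an error.
#'
#' @param sharing encoder parameter sharing: `"none"`, `"soft"` or `"hard"`.
#' @param augmentation pair-representation mode: `"entity_marker"`,
#'   `"vanilla"`, `"type_embedding"` or `"prototype"`.
#' @param classifier `"multi"` (expandable binary-head banks) or `"single"`.
#' @param d encoder hidden dimension.
#' @param n_layers self-attention layers per encoder.
#' @param hidden hidden width of the feed-forward classification heads.
#' @param batch_size sentences per optimiser step.
#' @param lr AdamW learning rate.
#' @param weight_decay AdamW decoupled weight decay.
#' @param epochs training epochs per schedule step.
#' @param alpha a [loss_weights()] vector.
#' @param theta binary-head decision threshold.
#' @param emb_dim width of type embeddings / prototypes.
#' @param repetitions seeds averaged when replicating a run.
#' @param sp_include_o include the O tag as a positive class in span-
#'   detection micro-F1 (default FALSE).
#' @param seed base random seed.
#' @return an object of class `cerex_config`.
#' @export
cerex_config <- function(sharing = "none", augmentation = "entity_marker",
                         classifier = "multi", d = 64L, n_layers = 2L,
                         hidden = 64L, batch_size = 8L, lr = 5e-4,
                         weight_decay = 0.01, epochs = 30L,
                         alpha = loss_weights(), theta = 0.5, emb_dim = 50L,
                         repetitions = 5L, sp_include_o = FALSE, seed = 1L) {
  sharing <- match.arg(sharing, c("none", "soft", "hard"))
  augmentation <- match.arg(augmentation, c("entity_marker", "vanilla",
                                            "type_embedding", "prototype"))
  classifier <- match.arg(classifier, c("multi", "single"))
  if (!inherits(alpha, "cerex_weights")) alpha <- do.call(loss_weights, as.list(alpha))
  stopifnot(batch_size >= 1, lr > 0, epochs >= 1, d >= 1, n_layers >= 1,
            hidden >= 1, theta >= 0, theta <= 1, repetitions >= 1)
  if (augmentation == "entity_marker" && sharing == "hard")
    stop("entity_marker augmentation is incompatible with hard parameter ",
         "sharing: the NER branch must read the raw sentence while the RE ",
         "branch reads the marked one")
  if (augmentation == "prototype" && d < emb_dim)
    stop("prototype augmentation needs d >= emb_dim for the max-pool reduction")
  structure(list(sharing = sharing, augmentation = augmentation,
                 classifier = classifier, d = as.integer(d),
                 n_layers = as.integer(n_layers), hidden = as.integer(hidden),
                 batch_size = as.integer(batch_size), lr = lr,
                 weight_decay = weight_decay, epochs = as.integer(epochs),
                 alpha = alpha, theta = theta, emb_dim = as.integer(emb_dim),
                 repetitions = as.integer(repetitions),
                 sp_include_o = isTRUE(sp_include_o), seed = as.integer(seed)),
            class = "cerex_config")
}

#' Load a run configuration from a YAML file
#'
#' Missing keys take the [cerex_config()] defaults; an empty file yields the
#' full default configuration. Parsing is strict: unknown keys are rejected
#' by name rather than silently ignored, since a silently misspelled key
#' would corrupt an ablation study. `alpha` may be given as a mapping with
#' keys `sp`, `et`, `re`.
#'
#' @param path path to a YAML file.
#' @return a `cerex_config`.
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known <- names(formals(cerex_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  if (!is.null(raw$alpha)) raw$alpha <- do.call(loss_weights, as.list(raw$alpha))
  do.call(cerex_config, raw)
}

#' @export
print.cerex_config <- function(x, ...) {
  cat("<cerex_config>\n")
  cat(sprintf("  encoder: tiny d=%d, %d layers; sharing=%s\n",
              x$d, x$n_layers, x$sharing))
  cat(sprintf("  augmentation=%s, classifier=%s (theta=%.2f)\n",
              x$augmentation, x$classifier, x$theta))
  cat(sprintf("  optimiser: AdamW lr=%g wd=%g, batch=%d, epochs=%d\n",
              x$lr, x$weight_decay, x$batch_size, x$epochs))
  cat(sprintf("  loss weights: sp=%.2f et=%.2f re=%.2f\n",
              x$alpha[["sp"]], x$alpha[["et"]], x$alpha[["re"]]))
  invisible(x)
}
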