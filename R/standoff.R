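#' Read a corpus from token-index standoff files
#'
#' The on-disk format is a pre-tokenised variant of BRAT-style standoff:
#' `<path>.txt` holds one sentence per line, tokens separated by single
#' spaces; `<path>.ann` holds mention records
#' `T<id>\tTYPE start end\tsurface` and relation records
#' `R<id>\tLABEL Arg1:T<i> Arg2:T<j>`. Indices are *token* indices (0-based,
#' inclusive), counted over the document's concatenated token stream, so a
#' mention's line is recovered from its offsets; spans may not cross line
#' boundaries. A `#` header line in the `.ann` file documents the dialect.
#'
#' @param path file stem: `<path>.txt` and `<path>.ann` are read.
#' @param name corpus name; defaults to the file stem's basename.
#' @return a `cerex_corpus`.
#' @export
read_corpus <- function(path, name = basename(path)) {
  txt_file <- paste0(path, ".txt")
  ann_file <- paste0(path, ".ann")
  if (!file.exists(txt_file)) stop("missing sentence file: ", txt_file)
  if (!file.exists(ann_file)) stop("missing annotation file: ", ann_file)

  lines <- readLines(txt_file, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  sents <- lapply(seq_along(lines), function(i)
    sentence(strsplit(lines[[i]], " ", fixed = TRUE)[[1]],
             corpus_name = name, sentence_id = sprintf("s%d", i)))
  n_tok <- vapply(sents, function(s) s$n, integer(1))
  sent_start <- cumsum(c(0L, n_tok[-length(n_tok)]))  # global offset of token 0

  ns <- length(sents)
  mentions <- rep(list(list()), ns)
  relations <- rep(list(list()), ns)
  ment_sent <- integer()   # sentence index per mention id
  names(ment_sent) <- character()

  ann <- readLines(ann_file, encoding = "UTF-8")
  for (ln in seq_along(ann)) {
    rec <- ann[[ln]]
    if (!nzchar(rec) || startsWith(rec, "#")) next
    fields <- strsplit(rec, "\t", fixed = TRUE)[[1]]
    id <- fields[[1]]
    if (startsWith(id, "T")) {
      if (length(fields) < 2L)
        stop(ann_file, ":", ln, ": malformed mention record")
      parts <- strsplit(fields[[2]], " ", fixed = TRUE)[[1]]
      if (length(parts) != 3L)
        stop(ann_file, ":", ln, ": expected 'TYPE start end', got '",
             fields[[2]], "'")
      type <- parts[[1]]
      g0 <- suppressWarnings(as.integer(parts[[2]]))
      g1 <- suppressWarnings(as.integer(parts[[3]]))
      if (is.na(g0) || is.na(g1) || g0 < 0L || g1 < g0)
        stop(ann_file, ":", ln, ": invalid token span '", fields[[2]], "'")
      si <- findInterval(g0, sent_start)
      if (si < 1L || si > ns || g1 >= sent_start[si] + n_tok[si])
        stop(ann_file, ":", ln, ": span [", g0, ",", g1,
             "] outside sentence bounds (spans may not cross lines)")
      mentions[[si]][[length(mentions[[si]]) + 1L]] <-
        entity_mention(g0 - sent_start[si], g1 - sent_start[si], type, id)
      ment_sent[[id]] <- si
    } else if (startsWith(id, "R")) {
      if (length(fields) < 2L)
        stop(ann_file, ":", ln, ": malformed relation record")
      parts <- strsplit(fields[[2]], " ", fixed = TRUE)[[1]]
      if (length(parts) != 3L || !startsWith(parts[[2]], "Arg1:") ||
          !startsWith(parts[[3]], "Arg2:"))
        stop(ann_file, ":", ln, ": expected 'LABEL Arg1:Ti Arg2:Tj'")
      a <- sub("^Arg1:", "", parts[[2]])
      b <- sub("^Arg2:", "", parts[[3]])
      for (ref in c(a, b)) if (!ref %in% names(ment_sent))
        stop(ann_file, ":", ln, ": relation references unknown mention '",
             ref, "'")
      if (ment_sent[[a]] != ment_sent[[b]])
        stop(ann_file, ":", ln, ": cross-sentence relation ", id)
      si <- ment_sent[[a]]
      relations[[si]][[length(relations[[si]]) + 1L]] <-
        relation_instance(a, b, parts[[1]])
    } else {
      stop(ann_file, ":", ln, ": unknown record type '", id, "'")
    }
  }
  corpus(name, sents, mentions, relations)
}

#' Write a corpus to token-index standoff files
#'
#' Inverse of [read_corpus()]. Output is deterministic: sentences in corpus
#' order, mentions within a sentence by start index, relations in stored
#' order; two writes of the same corpus are byte-identical.
#'
#' @param x a `cerex_corpus`.
#' @param path file stem: `<path>.txt` and `<path>.ann` are written.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(x, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  txt <- vapply(x$sentences, function(s) paste(s$tokens, collapse = " "),
                character(1))
  writeLines(txt, paste0(path, ".txt"), useBytes = TRUE)

  n_tok <- vapply(x$sentences, function(s) s$n, integer(1))
  sent_start <- cumsum(c(0L, n_tok[-length(n_tok)]))

  out <- c("# cerex token-index standoff v1 (0-based inclusive token offsets, global over the .txt token stream)")
  tid <- 0L; rid <- 0L
  id_map <- character()
  t_lines <- character(); r_lines <- character()
  for (si in seq_along(x$sentences)) {
    s <- x$sentences[[si]]
    ms <- x$mentions[[si]]
    if (length(ms)) ms <- ms[order(vapply(ms, function(m) m$start, integer(1)))]
    for (m in ms) {
      tid <- tid + 1L
      new_id <- sprintf("T%d", tid)
      id_map[[m$mention_id]] <- new_id
      g0 <- sent_start[si] + m$start
      g1 <- sent_start[si] + m$end
      surf <- paste(s$tokens[(m$start + 1L):(m$end + 1L)], collapse = " ")
      t_lines <- c(t_lines,
                   sprintf("%s\t%s %d %d\t%s", new_id, m$type_label, g0, g1, surf))
    }
    for (r in x$relations[[si]]) {
      rid <- rid + 1L
      r_lines <- c(r_lines, sprintf("R%d\t%s Arg1:%s Arg2:%s", rid, r$label,
                                    id_map[[r$mention_a]], id_map[[r$mention_b]]))
    }
  }
  writeLines(c(out, t_lines, r_lines), paste0(path, ".ann"), useBytes = TRUE)
  invisible(path)
}
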