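#' Linguistic annotation layers for a clinical document
#'
#' Feature extraction consumes gold or automatically produced linguistic
#' annotations -- tokens with lemma/POS/chunk tags, one constituency tree per
#' sentence, dependency edges, PropBank-style semantic-role frames and
#' PDTB-style discourse relations.  These layers normally arrive as a JSON
#' sidecar file produced offline by external parsers; a degraded-mode
#' fallback annotator lets the system run without them.
#'
#' @param tokens Data frame: `i` (0-based index), `text`, `lemma`, `pos`,
#'   `chunk` (BIO tag), `start`, `end` (0-based half-open character span),
#'   `sent` (0-based sentence index).
#' @param trees List of node tables (see [trees]), one per sentence.
#' @param deps Data frame: `head`, `dep` (0-based token indices, head `-1`
#'   for the root), `label`.
#' @param srl List of frames: each `list(pred = <token index>,
#'   args = data.frame(label, start_tok, end_tok))` (token intervals
#'   inclusive).
#' @param discourse Data frame: `a1s`, `a1e`, `a2s`, `a2e` (character
#'   intervals), `sense`, `kind` (`"EXPLICIT"`/`"IMPLICIT"`), `conn`.
#' @return An object of class `docann`.
#' @export
document_annotations <- function(tokens, trees = list(), deps = empty_deps(),
                                 srl = list(), discourse = empty_discourse()) {
  structure(list(tokens = tokens, trees = trees, deps = deps, srl = srl,
                 discourse = discourse),
            class = "docann")
}

#' @rdname document_annotations
#' @export
empty_tokens <- function() {
  data.frame(i = integer(), text = character(), lemma = character(),
             pos = character(), chunk = character(), start = integer(),
             end = integer(), sent = integer(), stringsAsFactors = FALSE)
}

#' @rdname document_annotations
#' @export
empty_deps <- function() {
  data.frame(head = integer(), dep = integer(), label = character(),
             stringsAsFactors = FALSE)
}

#' @rdname document_annotations
#' @export
empty_discourse <- function() {
  data.frame(a1s = integer(), a1e = integer(), a2s = integer(),
             a2e = integer(), sense = character(), kind = character(),
             conn = character(), stringsAsFactors = FALSE)
}

#' Verify that all annotation layers align with a document
#'
#' @param ann A `docann`.
#' @param doc The `clindoc` the layers describe.
#' @return Invisibly `TRUE`; stops at the first offending token otherwise.
#' @export
validate_annotations <- function(ann, doc) {
  tk <- ann$tokens
  if (nrow(tk)) {
    if (!identical(tk$i, seq_len(nrow(tk)) - 1L)) {
      stop("integrity error: token indices are not contiguous from 0")
    }
    got <- span_text(doc$text, tk$start, tk$end)
    bad <- which(got != tk$text)
    if (length(bad)) {
      stop("integrity error: token ", tk$i[bad[1]],
           " does not match the document text at its span")
    }
    if (is.unsorted(tk$sent)) {
      stop("integrity error: token sentence indices must be non-decreasing")
    }
  }
  if (length(ann$trees)) {
    for (s in seq_along(ann$trees)) {
      tree <- ann$trees[[s]]
      leaves <- tree$token[!is.na(tree$token)]
      expect <- tk$i[tk$sent == s - 1L]
      if (!identical(sort(leaves), expect) || is.unsorted(leaves)) {
        stop("integrity error: tree ", s - 1L,
             " leaves do not align with sentence tokens")
      }
    }
  }
  if (nrow(ann$deps)) {
    if (any(ann$deps$dep == ann$deps$head)) {
      stop("integrity error: dependency self-loop")
    }
    if (anyDuplicated(ann$deps$dep)) {
      stop("integrity error: token with more than one dependency head")
    }
    if (!all(ann$deps$dep %in% tk$i) ||
        !all(ann$deps$head %in% c(-1L, tk$i))) {
      stop("integrity error: dependency endpoint outside tokenization")
    }
  }
  for (fr in ann$srl) {
    ps <- tk$sent[match(fr$pred, tk$i)]
    asent <- tk$sent[match(fr$args$start_tok, tk$i)]
    if (any(is.na(c(ps, asent))) || any(asent != ps)) {
      stop("integrity error: SRL argument outside the predicate's sentence")
    }
  }
  dc <- ann$discourse
  if (nrow(dc)) {
    if (any(dc$kind == "IMPLICIT" & !is.na(dc$conn) & nzchar(dc$conn))) {
      stop("integrity error: implicit discourse relation with a connective")
    }
  }
  invisible(TRUE)
}

#' Load a JSON sidecar of linguistic annotations
#'
#' @param path Path to the sidecar JSON file.
#' @param doc The `clindoc` the sidecar describes; all alignment invariants
#'   are verified against it.
#' @return A `docann`.
#' @export
load_annotations <- function(path, doc) {
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  tok <- if (length(j$tokens)) {
    do.call(rbind, lapply(j$tokens, function(t) {
      data.frame(i = as.integer(t$i), text = t$text, lemma = t$lemma,
                 pos = t$pos, chunk = t$chunk, start = as.integer(t$start),
                 end = as.integer(t$end), sent = as.integer(t$sent),
                 stringsAsFactors = FALSE)
    }))
  } else empty_tokens()
  tok <- tok[order(tok$i), , drop = FALSE]
  rownames(tok) <- NULL
  trees <- lapply(seq_along(j$trees), function(s) {
    first <- tok$i[tok$sent == s - 1L][1]
    parse_penn(j$trees[[s]], first_token = if (is.na(first)) 0L else first)
  })
  deps <- if (length(j$deps)) {
    do.call(rbind, lapply(j$deps, function(d) {
      data.frame(head = as.integer(d$head), dep = as.integer(d$dep),
                 label = d$label, stringsAsFactors = FALSE)
    }))
  } else empty_deps()
  srl <- lapply(j$srl, function(fr) {
    args <- if (length(fr$args)) {
      do.call(rbind, lapply(fr$args, function(a) {
        data.frame(label = a$label, start_tok = as.integer(a$start_tok),
                   end_tok = as.integer(a$end_tok), stringsAsFactors = FALSE)
      }))
    } else data.frame(label = character(), start_tok = integer(),
                      end_tok = integer(), stringsAsFactors = FALSE)
    list(pred = as.integer(fr$pred), args = args)
  })
  disc <- if (length(j$discourse)) {
    do.call(rbind, lapply(j$discourse, function(d) {
      data.frame(a1s = as.integer(d$a1[[1]]), a1e = as.integer(d$a1[[2]]),
                 a2s = as.integer(d$a2[[1]]), a2e = as.integer(d$a2[[2]]),
                 sense = d$sense, kind = toupper(d$kind),
                 conn = if (is.null(d$conn)) NA_character_ else d$conn,
                 stringsAsFactors = FALSE)
    }))
  } else empty_discourse()
  ann <- document_annotations(tok, trees, deps, srl, disc)
  validate_annotations(ann, doc)
  ann
}

#' Write annotation layers to a JSON sidecar
#' @param ann A `docann`.
#' @param path Output path.
#' @return Invisibly `path`.
#' @export
save_annotations <- function(ann, path) {
  tk <- ann$tokens
  j <- list(
    tokens = lapply(seq_len(nrow(tk)), function(r) {
      list(i = tk$i[r], text = tk$text[r], lemma = tk$lemma[r],
           pos = tk$pos[r], chunk = tk$chunk[r], start = tk$start[r],
           end = tk$end[r], sent = tk$sent[r])
    }),
    trees = lapply(ann$trees, deparse_penn),
    deps = lapply(seq_len(nrow(ann$deps)), function(r) {
      list(head = ann$deps$head[r], dep = ann$deps$dep[r],
           label = ann$deps$label[r])
    }),
    srl = lapply(ann$srl, function(fr) {
      list(pred = fr$pred, args = lapply(seq_len(nrow(fr$args)), function(r) {
        list(label = fr$args$label[r], start_tok = fr$args$start_tok[r],
             end_tok = fr$args$end_tok[r])
      }))
    }),
    discourse = lapply(seq_len(nrow(ann$discourse)), function(r) {
      d <- ann$discourse[r, ]
      list(a1 = list(d$a1s, d$a1e), a2 = list(d$a2s, d$a2e),
           sense = d$sense, kind = d$kind,
           conn = if (is.na(d$conn)) NULL else d$conn)
    })
  )
  jsonlite::write_json(j, path, auto_unbox = TRUE, null = "null")
  invisible(path)
}

.fallback_pos <- function(w) {
  if (grepl("^[[:punct:]]+$", w)) return(w)
  if (grepl("^[0-9]+([.,:/-][0-9]+)*$", w)) return("CD")
  lw <- tolower(w)
  if (lw %in% c("the", "a", "an")) return("DT")
  if (lw %in% c("in", "on", "of", "with", "to", "for", "at", "by", "from")) return("IN")
  if (lw %in% c("and", "or", "but")) return("CC")
  if (lw %in% c("is", "was", "are", "were", "be", "been", "has", "had", "have")) return("VBD")
  if (endsWith(lw, "ly")) return("RB")
  if (endsWith(lw, "ing")) return("VBG")
  if (endsWith(lw, "ed")) return("VBD")
  if (endsWith(lw, "s")) return("NNS")
  "NN"
}

#' Degraded-mode annotator
#'
#' Produces a minimal but invariant-satisfying annotation: whitespace and
#' punctuation tokenization, sentence splits on terminators, heuristic
#' suffix-rule POS tags, one flat tree per sentence, and empty dependency,
#' SRL and discourse layers.  The POS heuristics are deliberately
#' low-fidelity; features derived from a fallback annotation should be
#' treated as degraded.
#'
#' @param doc A `clindoc`.
#' @return A `docann` passing all alignment invariants.
#' @export
fallback_annotate <- function(doc) {
  m <- gregexpr("[^\\s]+", doc$text, perl = TRUE)[[1]]
  if (m[1] == -1L) {
    return(document_annotations(empty_tokens()))
  }
  words <- regmatches(doc$text, gregexpr("[^\\s]+", doc$text, perl = TRUE))[[1]]
  starts <- as.integer(m) - 1L
  # split trailing punctuation into its own token
  tok_text <- character(); tok_start <- integer()
  for (k in seq_along(words)) {
    w <- words[k]; s <- starts[k]
    mm <- regmatches(w, regexec("^(.*?)([.,;:!?]*)$", w))[[1]]
    core <- mm[2]; tail <- mm[3]
    if (nzchar(core)) { tok_text <- c(tok_text, core); tok_start <- c(tok_start, s) }
    if (nzchar(tail)) {
      for (j in seq_len(nchar(tail))) {
        tok_text <- c(tok_text, substr(tail, j, j))
        tok_start <- c(tok_start, s + nchar(core) + j - 1L)
      }
    }
  }
  n <- length(tok_text)
  sent <- integer(n); cur <- 0L
  for (k in seq_len(n)) {
    sent[k] <- cur
    if (tok_text[k] %in% c(".", "!", "?")) cur <- cur + 1L
  }
  tk <- data.frame(
    i = seq_len(n) - 1L, text = tok_text, lemma = tolower(tok_text),
    pos = vapply(tok_text, .fallback_pos, "", USE.NAMES = FALSE),
    chunk = "O", start = tok_start, end = tok_start + nchar(tok_text),
    sent = sent, stringsAsFactors = FALSE)
  trees <- lapply(sort(unique(sent)), function(s) {
    rows <- tk[tk$sent == s, ]
    bracket <- paste0("(S ", paste0("(", rows$pos, " ", rows$text, ")",
                                    collapse = " "), ")")
    parse_penn(bracket, first_token = rows$i[1])
  })
  ann <- document_annotations(tk, trees)
  validate_annotations(ann, doc)
  ann
}

entity_tokens <- function(entity, ann) {
  tk <- ann$tokens
  which(tk$start < entity$end & tk$end > entity$start)
}

#' Head token of an annotated entity
#'
#' Deterministic head selection: the rightmost token within the entity span
#' whose POS tag is nominal, verbal or adjectival; if none, the last token
#' in the span.
#'
#' @param entity One-row entity data frame (from [get_entity()]).
#' @param ann A `docann`.
#' @return The head token row of `ann$tokens`.
#' @export
head_token <- function(entity, ann) {
  rows <- entity_tokens(entity, ann)
  if (!length(rows)) {
    stop("alignment error: entity ", entity$id,
         " overlaps no token")
  }
  tk <- ann$tokens[rows, , drop = FALSE]
  content <- grepl("^(N|V|J)", tk$pos)
  pick <- if (any(content)) max(which(content)) else nrow(tk)
  tk[pick, , drop = FALSE]
}

#' Shortest label path between two entities in the parse tree
#'
#' The path runs from the head token's preterminal of `e1` through the
#' lowest common ancestor to the head preterminal of `e2`.  Only defined for
#' same-sentence entities; cross-sentence input raises an applicability
#' error (upstream feature extractors convert this to a NULL feature).
#'
#' @param e1,e2 One-row entity data frames.
#' @param ann A `docann`.
#' @return Character vector of node labels from `e1` to `e2` inclusive.
#' @export
tree_path <- function(e1, e2, ann) {
  h1 <- head_token(e1, ann); h2 <- head_token(e2, ann)
  if (h1$sent != h2$sent) {
    stop("applicability error: tree_path() requires same-sentence entities")
  }
  tree <- ann$trees[[h1$sent + 1L]]
  a <- tree_preterminal_for_token(tree, h1$i)
  b <- tree_preterminal_for_token(tree, h2$i)
  ids <- tree_node_path(tree, a, b)
  tree$label[match(ids, tree$id)]
}

#' Does e1 syntactically dominate e2?
#'
#' True when a node covering `e1`'s head token properly dominates the node
#' covering `e2`'s head token (i.e. `e2`'s head preterminal lies below
#' `e1`'s maximal projection on the path).  Operationalized as: `e1`'s head
#' preterminal is an ancestor of `e2`'s head leaf, or the minimal covering
#' node of `e1`'s span dominates `e2`'s head leaf.
#'
#' @param e1,e2 One-row entity data frames.
#' @param ann A `docann`.
#' @return Logical; `FALSE` for cross-sentence pairs.
#' @export
syntactic_dominates <- function(e1, e2, ann) {
  h1 <- head_token(e1, ann); h2 <- head_token(e2, ann)
  if (h1$sent != h2$sent) return(FALSE)
  tree <- ann$trees[[h1$sent + 1L]]
  cover <- tree_covering_node(tree, ann$tokens$i[entity_tokens(e1, ann)])
  leaf2 <- tree_leaf_for_token(tree, h2$i)
  cover %in% tree_ancestors(tree, leaf2)
}
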