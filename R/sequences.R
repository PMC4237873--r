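#' Sequence representations of an entity pair
#'
#' For nearest-neighbour similarity features, a pair of annotated entities in
#' one sentence is represented as a token sequence in five ways:
#' \enumerate{
#'   \item the POS-tag sequence of the whole sentence;
#'   \item the phrase-chunk-type sequence between the two entities;
#'   \item the word-lemma sequence from two tokens before the first entity up
#'     to and including the second token after the second entity;
#'   \item the event-type sequence of all events in the sentence;
#'   \item the shortest dependency-path sequence connecting the two entities.
#' }
#' In every method the two entities themselves are replaced by type
#' placeholders such as `test_e1_` and `problem_e2_` before generation.
#'
#' @param method Integer 1..5.
#' @param e1,e2 One-row entity data frames (see [get_entity()]); `e1` must
#'   precede `e2` in the text.
#' @param doc The `clindoc`.
#' @param ann The `docann`.
#' @return Character vector of sequence items.  For method 5 the attribute
#'   `"n_up"` records how many path labels are ascending (towards the common
#'   head); [render_sequence()] uses it for display.
#' @export
generate_sequence <- function(method, e1, e2, doc, ann) {
  if (!method %in% 1:5) stop("argument error: method must be in 1..5")
  tk <- ann$tokens
  t1 <- entity_tokens(e1, ann) - 1L  # 0-based token indices
  t2 <- entity_tokens(e2, ann) - 1L
  ph1 <- paste0(tolower(e1$type), "_e1_")
  ph2 <- paste0(tolower(e2$type), "_e2_")
  sent <- tk$sent[match(t1[1], tk$i)]

  replace_entities <- function(items_by_token, idx) {
    # idx: 0-based token indices the items correspond to
    out <- character(); k <- 1L
    while (k <= length(idx)) {
      if (idx[k] %in% t1) {
        out <- c(out, ph1); while (k <= length(idx) && idx[k] %in% t1) k <- k + 1L
      } else if (idx[k] %in% t2) {
        out <- c(out, ph2); while (k <= length(idx) && idx[k] %in% t2) k <- k + 1L
      } else {
        out <- c(out, items_by_token[k]); k <- k + 1L
      }
    }
    out
  }

  if (method == 1L) {
    rows <- which(tk$sent == sent)
    return(replace_entities(tk$pos[rows], tk$i[rows]))
  }
  if (method == 2L) {
    lo <- max(t1) + 1L; hi <- min(t2) - 1L
    if (lo > hi) return(character())
    rows <- match(lo:hi, tk$i)
    ch <- tk$chunk[rows]
    out <- character(); prev <- ""
    for (c0 in ch) {
      if (c0 == "O") { prev <- ""; next }
      typ <- sub("^[BI]-", "", c0)
      if (startsWith(c0, "B-") || typ != prev) out <- c(out, typ)
      prev <- typ
    }
    return(out)
  }
  if (method == 3L) {
    lo <- max(min(t1) - 2L, tk$i[tk$sent == sent][1])
    hi <- min(max(t2) + 2L, max(tk$i[tk$sent == sent]))
    rows <- match(lo:hi, tk$i)
    return(replace_entities(tk$lemma[rows], tk$i[rows]))
  }
  if (method == 4L) {
    ev <- doc$events
    h <- vapply(seq_len(nrow(ev)), function(r) {
      rows <- which(tk$start < ev$end[r] & tk$end > ev$start[r])
      if (!length(rows)) return(NA_integer_)
      tk$i[rows[1]]
    }, integer(1))
    keep <- which(!is.na(h) & tk$sent[match(h, tk$i)] == sent)
    keep <- keep[order(h[keep])]
    out <- character()
    for (r in keep) {
      if (ev$id[r] == e1$id) out <- c(out, ph1)
      else if (ev$id[r] == e2$id) out <- c(out, ph2)
      else out <- c(out, tolower(ev$type[r]))
    }
    return(out)
  }
  # method 5: shortest dependency path
  h1 <- head_token(e1, ann)$i; h2 <- head_token(e2, ann)$i
  path <- dep_path(ann$deps, h1, h2)
  if (is.null(path)) {
    out <- c(ph1, ph2)
    attr(out, "n_up") <- 0L
    return(out)
  }
  out <- c(ph1, path$labels, ph2)
  attr(out, "n_up") <- path$n_up
  out
}

# Shortest path between two tokens in the dependency tree; returns the edge
# labels in order plus how many of them are ascending (dependent -> head).
dep_path <- function(deps, a, b) {
  if (!nrow(deps)) return(NULL)
  up <- function(x) {
    chain <- list(); cur <- x
    repeat {
      i <- which(deps$dep == cur)
      if (!length(i)) break
      h <- deps$head[i[1]]
      chain[[length(chain) + 1L]] <- list(node = h, label = deps$label[i[1]])
      if (h < 0L) break
      cur <- h
    }
    chain
  }
  ca <- up(a); cb <- up(b)
  nodes_a <- c(a, vapply(ca, `[[`, integer(1), "node"))
  nodes_b <- c(b, vapply(cb, `[[`, integer(1), "node"))
  common <- intersect(nodes_a, nodes_b)
  if (!length(common)) return(NULL)
  anc <- common[which.min(match(common, nodes_a))]
  ia <- match(anc, nodes_a) - 1L  # edges ascended from a
  ib <- match(anc, nodes_b) - 1L
  up_labels <- vapply(ca[seq_len(ia)], `[[`, "", "label")
  down_labels <- rev(vapply(cb[seq_len(ib)], `[[`, "", "label"))
  list(labels = c(up_labels, down_labels), n_up = ia)
}

#' Render a sequence as its printable string
#'
#' Items are joined with single spaces; an item consisting of sentence
#' punctuation attaches to the previous item without a space.  Method-5
#' sequences are rendered with their ascending labels joined by right arrows
#' and descending labels by left arrows between em-dash-delimited entity
#' placeholders.
#'
#' @param x A sequence from [generate_sequence()].
#' @param method The method that produced it (default 0: plain join).
#' @return A single string.
#' @export
render_sequence <- function(x, method = 0L) {
  if (method == 5L) {
    n_up <- attr(x, "n_up")
    labs <- x[-c(1L, length(x))]
    if (!length(labs)) return(paste0(x[1], "—", x[length(x)]))
    ups <- labs[seq_len(n_up)]
    downs <- labs[setdiff(seq_along(labs), seq_len(n_up))]
    mid <- paste(c(if (length(ups)) paste(ups, collapse = " → "),
                   if (length(downs)) paste(downs, collapse = " ← ")),
                 collapse = " → ")
    return(paste0(x[1], "—", mid, "—", x[length(x)]))
  }
  if (!length(x)) return("")
  out <- x[1]
  for (k in seq_along(x)[-1]) {
    if (grepl("^[.,;:!?]+$", x[k])) out <- paste0(out, x[k])
    else out <- paste(out, x[k])
  }
  out
}

#' Token-level Levenshtein distance
#'
#' Minimum number of unit-cost insertions, deletions and substitutions of
#' whole tokens turning `a` into `b`.
#'
#' @param a,b Character vectors of tokens.
#' @return Integer distance.
#' @export
levenshtein <- function(a, b) {
  lev_dist_cpp(as.character(a), as.character(b))
}

#' Pairwise Levenshtein distances between two lists of token sequences
#' @param xs,ys Lists of character vectors.
#' @return Integer matrix of `length(xs)` x `length(ys)` distances.
#' @export
levenshtein_matrix <- function(xs, ys) {
  lev_dist_matrix_cpp(lapply(xs, as.character), lapply(ys, as.character))
}
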