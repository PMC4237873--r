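#' Constituency trees
#'
#' Trees are stored as node tables: a data frame with columns `id` (preorder,
#' 1-based), `parent` (0 for the root), `label` and `token` (the 0-based
#' document-level token index for word leaves, `NA` elsewhere).  Word leaves
#' appear in token order; a preterminal is the parent of a single word leaf.
#'
#' @name trees
NULL

#' Parse a Penn-bracketed tree string into a node table
#'
#' @param s Bracketed tree string, e.g. `"(S (NP (DT the) (NN dog)) (VP (VBD barked)))"`.
#' @param first_token 0-based document-level index of the sentence's first
#'   token; leaves are numbered consecutively from it.
#' @return A node-table data frame (see [trees]).
#' @export
parse_penn <- function(s, first_token = 0L) {
  toks <- regmatches(s, gregexpr("\\(|\\)|[^\\s()]+", s, perl = TRUE))[[1]]
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[pos] else NA_character_
  nodes <- list()
  ntok <- first_token
  parse_node <- function(parent) {
    if (!identical(peek(), "(")) stop("parse error: expected '(' in tree string")
    pos <<- pos + 1L
    label <- peek(); pos <<- pos + 1L
    id <- length(nodes) + 1L
    nodes[[id]] <<- list(id = id, parent = parent, label = label,
                         token = NA_integer_)
    repeat {
      nxt <- peek()
      if (is.na(nxt)) stop("parse error: unbalanced tree string")
      if (nxt == ")") { pos <<- pos + 1L; break }
      if (nxt == "(") {
        parse_node(id)
      } else {
        lid <- length(nodes) + 1L
        nodes[[lid]] <<- list(id = lid, parent = id, label = nxt,
                              token = ntok)
        ntok <<- ntok + 1L
        pos <<- pos + 1L
      }
    }
    id
  }
  parse_node(0L)
  if (pos <= length(toks)) stop("parse error: trailing content in tree string")
  do.call(rbind, lapply(nodes, function(n) {
    data.frame(id = n$id, parent = n$parent, label = n$label,
               token = n$token, stringsAsFactors = FALSE)
  }))
}

#' Serialize a node table back to a bracketed string
#' @param tree A node table.
#' @return A Penn-bracketed string.
#' @export
deparse_penn <- function(tree) {
  rec <- function(id) {
    kids <- tree$id[tree$parent == id]
    row <- tree[tree$id == id, ]
    if (!length(kids)) return(row$label)
    paste0("(", row$label, " ", paste(vapply(kids, rec, ""), collapse = " "), ")")
  }
  rec(tree$id[tree$parent == 0L])
}

tree_children <- function(tree, id) tree$id[tree$parent == id]

tree_ancestors <- function(tree, id) {
  # path from id to root, excluding id
  out <- integer()
  p <- tree$parent[match(id, tree$id)]
  while (p != 0L) {
    out <- c(out, p)
    p <- tree$parent[match(p, tree$id)]
  }
  out
}

tree_leaf_for_token <- function(tree, token) {
  i <- which(!is.na(tree$token) & tree$token == token)
  if (!length(i)) return(NA_integer_)
  tree$id[i[1]]
}

tree_preterminal_for_token <- function(tree, token) {
  leaf <- tree_leaf_for_token(tree, token)
  if (is.na(leaf)) return(NA_integer_)
  tree$parent[match(leaf, tree$id)]
}

tree_tokens_under <- function(tree, id) {
  # all token indices covered by node id
  acc <- integer()
  stack <- id
  while (length(stack)) {
    cur <- stack[1]; stack <- stack[-1]
    tk <- tree$token[match(cur, tree$id)]
    if (!is.na(tk)) acc <- c(acc, tk)
    stack <- c(stack, tree_children(tree, cur))
  }
  sort(acc)
}

#' Lowest common ancestor of two nodes in a node table
#' @param tree A node table.
#' @param a,b Node ids.
#' @return The LCA node id.
#' @export
tree_lca <- function(tree, a, b) {
  pa <- c(a, tree_ancestors(tree, a))
  pb <- c(b, tree_ancestors(tree, b))
  pa[pa %in% pb][1]
}

#' Node-id path between two nodes (through their LCA)
#' @param tree A node table.
#' @param a,b Node ids.
#' @return Integer vector of node ids from `a` to `b` inclusive.
#' @export
tree_node_path <- function(tree, a, b) {
  lca <- tree_lca(tree, a, b)
  up <- c(a, tree_ancestors(tree, a))
  up <- up[seq_len(match(lca, up))]
  down <- c(b, tree_ancestors(tree, b))
  down <- down[seq_len(match(lca, down) - 1L)]
  c(up, rev(down))
}

#' Minimal constituent covering a token interval
#' @param tree A node table.
#' @param tokens Integer vector of 0-based token indices.
#' @return Node id of the lowest non-terminal whose leaves cover all of
#'   `tokens` (for a single token, its preterminal).
#' @export
tree_covering_node <- function(tree, tokens) {
  leaf <- tree_leaf_for_token(tree, tokens[1])
  if (is.na(leaf)) return(NA_integer_)
  cand <- tree_ancestors(tree, leaf)
  for (id in cand) {
    if (all(tokens %in% tree_tokens_under(tree, id))) return(id)
  }
  NA_integer_
}
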