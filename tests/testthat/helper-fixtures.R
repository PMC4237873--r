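# Shared fixtures, cached across test files (one R session per run).

.fix_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (is.null(.fix_cache[[key]])) assign(key, builder(), envir = .fix_cache)
  .fix_cache[[key]]
}

fix_medsem_corpus <- function() {
  cached("sco", function() {
    generate_corpus(11, 20, template_mix = semrel_template_mix(),
                    sentences_per_doc = 6)
  })
}

fix_medsem_model <- function() {
  cached("medsem", function() {
    sco <- fix_medsem_corpus()
    suppressWarnings(train_semrel_ensemble(
      semrel_instances_from(sco), sco$docs, sco$anns, sco$lex))
  })
}

fix_corpus <- function() {
  cached("co", function() generate_corpus(7, 10, sentences_per_doc = 6))
}

fix_system <- function() {
  cached("sys", function() {
    co <- fix_corpus()
    suppressWarnings(train_relation_system(
      co, co$lex, medsem_model = fix_medsem_model()))
  })
}

fix_stage <- function() {
  cached("stage", function() {
    suppressWarnings(train_identification_stage(fix_corpus(), fix_system()))
  })
}

# single-template document (one sentence group, no variants randomness
# beyond the seed)
one_template_doc <- function(id, seed = 1) {
  mix <- stats::setNames(1, id)
  co <- generate_corpus(seed, 1, template_mix = mix, sentences_per_doc = 1L)
  list(doc = co$docs[[1]], ann = co$anns[[1]], corpus = co)
}

template_pair <- function(fx) {
  # the planted (e1, e2) entity pair of a one-template document
  tl <- fx$doc$tlinks
  if (nrow(tl)) {
    return(list(e1 = get_entity(fx$doc, tl$from[1]),
                e2 = get_entity(fx$doc, tl$to[1])))
  }
  sr <- fx$corpus$semrel
  list(e1 = get_entity(fx$doc, sr$e1[1]), e2 = get_entity(fx$doc, sr$e2[1]))
}

# ---- independent oracles --------------------------------------------------

# exhaustive recursive edit-distance (no DP)
lev_oracle <- function(a, b) {
  if (!length(a)) return(length(b))
  if (!length(b)) return(length(a))
  min(lev_oracle(a[-1], b) + 1L,
      lev_oracle(a, b[-1]) + 1L,
      lev_oracle(a[-1], b[-1]) + (a[1] != b[1]))
}

# random bracketed sentence tree over n tokens
rand_bracket <- function(tokens, labels = c("NP", "VP", "PP", "ADJP", "S2")) {
  if (length(tokens) == 1L) {
    return(paste0("(", sample(c("NN", "VB", "JJ", "IN"), 1), " ",
                  tokens, ")"))
  }
  k <- sample(2:min(3, length(tokens)), 1)
  cuts <- sort(sample(seq_len(length(tokens) - 1L), k - 1L))
  parts <- split(tokens, findInterval(seq_along(tokens), cuts + 1L))
  inner <- vapply(parts, rand_bracket, "", labels = labels)
  paste0("(", sample(labels, 1), " ", paste(inner, collapse = " "), ")")
}

# shortest path between two nodes via breadth-first search on the
# undirected node-table graph (independent of the LCA implementation)
bfs_path_oracle <- function(tree, a, b) {
  adj <- lapply(tree$id, function(id) {
    c(tree$parent[tree$id == id], tree$id[tree$parent == id])
  })
  names(adj) <- tree$id
  prev <- stats::setNames(rep(NA_integer_, nrow(tree)), tree$id)
  visited <- stats::setNames(logical(nrow(tree)), tree$id)
  queue <- a; visited[as.character(a)] <- TRUE
  while (length(queue)) {
    cur <- queue[1]; queue <- queue[-1]
    if (cur == b) break
    for (nb in adj[[as.character(cur)]]) {
      if (nb == 0L) next
      if (!visited[as.character(nb)]) {
        visited[as.character(nb)] <- TRUE
        prev[as.character(nb)] <- cur
        queue <- c(queue, nb)
      }
    }
  }
  path <- b
  while (!is.na(prev[as.character(path[1])])) {
    path <- c(unname(prev[as.character(path[1])]), path)
  }
  unname(path)
}

# all convolution-kernel fragments of a node-table tree:
# list(serial -> data.frame(size, count))
fragments_oracle <- function(tree) {
  kids_of <- function(id) tree$id[tree$parent == id]
  lab <- function(id) tree$label[tree$id == id]
  frags_at <- function(id) {
    kids <- kids_of(id)
    if (!length(kids)) return(character())
    per_child <- lapply(kids, function(k) {
      sub <- frags_at(k)
      c(lab(k), sub)  # cut at the child, or expand into any child fragment
    })
    combos <- expand.grid(per_child, stringsAsFactors = FALSE)
    apply(combos, 1, function(row) {
      paste0("(", lab(id), " ", paste(unlist(row), collapse = " "), ")")
    })
  }
  all_frags <- unlist(lapply(tree$id, frags_at))
  tab <- table(all_frags)
  data.frame(serial = names(tab), count = as.integer(tab),
             size = vapply(names(tab),
                           function(s) lengths(regmatches(s, gregexpr("\\(", s))),
                           integer(1)),
             stringsAsFactors = FALSE)
}

tree_kernel_oracle <- function(t1, t2, lambda) {
  f1 <- fragments_oracle(t1); f2 <- fragments_oracle(t2)
  common <- merge(f1, f2, by = "serial")
  if (!nrow(common)) return(0)
  sum(common$count.x * common$count.y * lambda^common$size.x)
}

# random small node-table tree (internal labels from a small alphabet,
# leaves are word nodes)
rand_node_tree <- function(n_tokens, seed_labels = letters[1:4]) {
  toks <- paste0("w", sample(seq_len(20), n_tokens))
  parse_penn(rand_bracket(toks, labels = seed_labels))
}

# boolean-matrix fixed-point closure oracle
closure_oracle <- function(links) {
  ids <- sort(unique(c(links$from, links$to)))
  n <- length(ids)
  B <- matrix(FALSE, n, n, dimnames = list(ids, ids))
  O <- matrix(FALSE, n, n, dimnames = list(ids, ids))
  for (i in seq_len(nrow(links))) {
    a <- links$from[i]; b <- links$to[i]
    switch(links$relation[i],
           BEFORE3 = { B[a, b] <- TRUE },
           AFTER3 = { B[b, a] <- TRUE },
           OVERLAP3 = { O[a, b] <- TRUE })
  }
  repeat {
    B2 <- B | ((B %*% B) > 0)
    O2 <- O | t(O)
    if (identical(B2, B) && identical(O2, O)) break
    B <- B2; O <- O2
  }
  out <- list()
  for (a in ids) for (b in ids) {
    if (a == b) next
    if (B[a, b]) {
      out[[length(out) + 1L]] <- c(a, b, "BEFORE3")
      out[[length(out) + 1L]] <- c(b, a, "AFTER3")
    }
    if (O[a, b]) {
      out[[length(out) + 1L]] <- c(a, b, "OVERLAP3")
      out[[length(out) + 1L]] <- c(b, a, "OVERLAP3")
    }
  }
  df <- as.data.frame(do.call(rbind, out), stringsAsFactors = FALSE)
  names(df) <- c("from", "to", "relation")
  unique(df)
}

closure_keys <- function(df) {
  sort(paste(df$from, df$to, df$relation))
}
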