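#' Medical semantic-relation classification
#'
#' An 11-class classifier for the semantic relation between two medical
#' concepts (TEST / PROBLEM / TREATMENT events) in one sentence: eight
#' positive classes (TrIP, TrWP, TrCP, PIP, TeRP, TrAP, TrNAP, TeCP) and
#' three "no relation" classes (NTrP, NTeP, NPP).  Three classifiers -- a
#' flat-feature SVM bank, a convolution tree-kernel SVM bank over simple
#' expansion trees, and a weighted nearest-neighbour classifier over lemma
#' sequences -- are combined through an 11-element probability vector.
#'
#' @name semrel
NULL

#' The 11 medical semantic-relation types
#' @return Character vector of class names (canonical order).
#' @export
medsem_types <- function() {
  c("TrIP", "TrWP", "TrCP", "PIP", "TeRP", "TrAP", "TrNAP", "TeCP",
    "NTrP", "NTeP", "NPP")
}

#' @rdname medsem_types
#' @export
positive_medsem_types <- function() setdiff(medsem_types(), c("NTrP", "NTeP", "NPP"))

#' A candidate medical semantic-relation instance
#'
#' Both entities must be TEST/PROBLEM/TREATMENT events in the same
#' sentence; `e1` precedes `e2` in the text.  Labelling is commutative: the
#' same label applies to the reversed pair.
#'
#' @param doc_id Document id.
#' @param e1,e2 Entity ids.
#' @param sent 0-based sentence index.
#' @param label Optional `medsem_types()` member.
#' @param assertion1,assertion2 Assertion attributes of PROBLEM entities.
#' @return A `semrel_instance`.
#' @export
semrel_instance <- function(doc_id, e1, e2, sent, label = NA_character_,
                            assertion1 = NA_character_,
                            assertion2 = NA_character_) {
  structure(list(doc = doc_id, e1 = e1, e2 = e2, sent = sent, label = label,
                 assertion1 = assertion1, assertion2 = assertion2),
            class = "semrel_instance")
}

semrel_sequences <- function(inst, doc, ann) {
  e1 <- get_entity(doc, inst$e1); e2 <- get_entity(doc, inst$e2)
  lapply(1:5, function(m) generate_sequence(m, e1, e2, doc, ann))
}

#' Nearest-neighbour probability vector
#'
#' The k nearest training sequences (token-level Levenshtein distance;
#' ties broken by distance then training index) vote with weight 0.5 for
#' the single nearest neighbour and 0.5/(k-1) for each of the remaining
#' k-1.  With fewer than k bank entries the nearest still receives 0.5 and
#' the remainder split 0.5 evenly (with a warning).
#'
#' @param seq Character vector: the query sequence (lemma sequence,
#'   generation method 3).
#' @param bank A semrel bank (see [build_semrel_bank()]).
#' @param k Number of neighbours (default 200).
#' @return Named numeric vector over [medsem_types()], summing to 1.
#' @export
knn_probability_vector <- function(seq, bank, k = 200L) {
  n <- length(bank$labels)
  if (!n) stop("empty training bank")
  d <- as.vector(levenshtein_matrix(list(seq), bank$seqs[[3]]))
  ord <- order(d, seq_len(n))
  m <- min(k, n)
  if (n < k) {
    warn_once(paste0("knn_bank_", n, "_", k),
              paste0("training bank smaller than k = ", k,
                     "; vote weights rescaled over ", n, " neighbours"))
  }
  take <- ord[seq_len(m)]
  w <- if (m == 1L) 1 else c(0.5, rep(0.5 / (m - 1L), m - 1L))
  out <- stats::setNames(numeric(length(medsem_types())), medsem_types())
  for (j in seq_len(m)) {
    cls <- bank$labels[take[j]]
    out[cls] <- out[cls] + w[j]
  }
  out
}

# Uniform class proportions among the k nearest neighbours under one
# generation method; the similarity feature group.
knn_class_percentages <- function(seq, bank, method, k = 200L) {
  n <- length(bank$labels)
  d <- as.vector(levenshtein_matrix(list(seq), bank$seqs[[method]]))
  ord <- order(d, seq_len(n))
  take <- ord[seq_len(min(k, n))]
  tab <- table(factor(bank$labels[take], levels = medsem_types()))
  as.numeric(tab) / length(take)
}

#' Build the nearest-neighbour sequence bank from labeled instances
#'
#' @param insts List of labeled `semrel_instance`s.
#' @param docs,anns Named lists of documents / annotations keyed by doc id.
#' @return A bank: `seqs` (five lists of token sequences, one per
#'   generation method) and `labels`.
#' @export
build_semrel_bank <- function(insts, docs, anns) {
  seqs <- lapply(1:5, function(m) {
    lapply(insts, function(i) {
      generate_sequence(m, get_entity(docs[[i$doc]], i$e1),
                        get_entity(docs[[i$doc]], i$e2),
                        docs[[i$doc]], anns[[i$doc]])
    })
  })
  list(seqs = seqs, labels = vapply(insts, function(i) i$label, ""))
}

#' Flat feature groups for a semantic-relation instance
#'
#' Thirty-seven feature groups in five categories: Context (inter-entity
#' words / POS / bigrams / chunk and concept-type sequences, neighbouring
#' words, associated predicates, a conjunction-regular-expression flag),
#' Similarity (per generation method, the class percentages among the k
#' nearest neighbours), Single-concept (lemmas, descriptive words, types,
#' strings, concatenated assertions, sentiment categories), Wikipedia
#' (offline link-table features) and Vicinity (neighbouring event types).
#'
#' @param inst A `semrel_instance`.
#' @param doc,ann Document and annotations.
#' @param lex A [lexicon_set()].
#' @param bank Optional sequence bank for the similarity features.
#' @param k Neighbour count for the similarity features.
#' @return A feature vector.
#' @export
extract_semrel_flat <- function(inst, doc, ann, lex, bank = NULL, k = 200L) {
  e1 <- get_entity(doc, inst$e1); e2 <- get_entity(doc, inst$e2)
  tk <- ann$tokens
  t1 <- entity_tokens(e1, ann); t2 <- entity_tokens(e2, ann)
  lo <- tk$i[t1[length(t1)]] + 1L; hi <- tk$i[t2[1]] - 1L
  btw <- if (lo <= hi) match(lo:hi, tk$i) else integer()
  fv <- list()
  words <- tolower(tk$text[btw])
  fv$ctx.between_words <- paste(sort(unique(words)), collapse = " ")
  fv$ctx.between_pos <- paste(tk$pos[btw], collapse = " ")
  fv$ctx.between_bigrams <- if (length(words) > 1L) {
    paste(paste(words[-length(words)], words[-1L]), collapse = "|")
  } else NA_character_
  fv$ctx.between_string <- paste(words, collapse = " ")
  fv$ctx.between_chunks <- paste(generate_sequence(2L, e1, e2, doc, ann),
                                 collapse = " ")
  betw_ev <- doc$events$type[doc$events$start >= e1$end &
                               doc$events$end <= e2$start]
  fv$ctx.between_concepts <- paste(betw_ev, collapse = " ")
  fv$ctx.e1_prev_word <- window_tokens(e1, ann, -1L)
  fv$ctx.e2_prev_word <- window_tokens(e2, ann, -1L)
  fv$ctx.e1_next3 <- paste(window_tokens(e1, ann, 1:3), collapse = " ")
  fv$ctx.e2_next3 <- paste(window_tokens(e2, ann, 1:3), collapse = " ")
  pred_of <- function(ent) {
    h <- head_token(ent, ann)$i
    for (fr in ann$srl) {
      a <- fr$args
      if (any(a$start_tok <= h & a$end_tok >= h)) {
        return(tolower(tk$text[match(fr$pred, tk$i)]))
      }
    }
    NA_character_
  }
  fv$ctx.e1_pred <- pred_of(e1); fv$ctx.e2_pred <- pred_of(e2)
  fv$ctx.conj_regex <- as.numeric(grepl(",|\\band\\b|\\bor\\b",
                                        between_text(e1, e2, doc)))
  if (!is.null(bank)) {
    for (m in 1:5) {
      seq_m <- generate_sequence(m, e1, e2, doc, ann)
      pct <- knn_class_percentages(seq_m, bank, m, k)
      for (ci in seq_along(medsem_types())) {
        fv[[paste0("sim.m", m, ".", medsem_types()[ci])]] <- pct[ci]
      }
    }
  }
  h1 <- head_token(e1, ann); h2 <- head_token(e2, ann)
  fv$con.e1_lemmas <- paste(sort(tk$lemma[t1]), collapse = " ")
  fv$con.e2_lemmas <- paste(sort(tk$lemma[t2]), collapse = " ")
  fv$con.e1_desc <- paste(setdiff(tolower(tk$text[t1]), tolower(h1$text)),
                          collapse = " ")
  fv$con.e2_desc <- paste(setdiff(tolower(tk$text[t2]), tolower(h2$text)),
                          collapse = " ")
  fv$con.e1_type <- e1$type; fv$con.e2_type <- e2$type
  fv$con.e1_string <- tolower(e1$text); fv$con.e2_string <- tolower(e2$text)
  fv$con.assert_concat <- paste(inst$assertion1, inst$assertion2, sep = "|")
  senti <- function(h) {
    v <- lex$sentiment[tolower(h$text)]
    if (length(v) && !is.na(v)) unname(v) else NA_character_
  }
  fv$con.e1_sentiment <- senti(h1); fv$con.e2_sentiment <- senti(h2)

  titles <- unique(c(lex$wiki_links$from, lex$wiki_links$to,
                     names(lex$wiki_categories)))
  art <- function(ent, h) {
    cand <- c(tolower(ent$text), tolower(h$text))
    hit <- cand[cand %in% tolower(titles)]
    if (length(hit)) hit[1] else NA_character_
  }
  a1 <- art(e1, h1); a2 <- art(e2, h2)
  linked <- function(x, y) {
    !is.na(x) && !is.na(y) &&
      any(tolower(lex$wiki_links$from) == x & tolower(lex$wiki_links$to) == y)
  }
  fv$wik.no_article <- as.numeric(is.na(a1) && is.na(a2))
  fv$wik.link_e1_e2 <- as.numeric(linked(a1, a2))
  fv$wik.link_e2_e1 <- as.numeric(linked(a2, a1))
  fv$wik.links_both <- as.numeric(linked(a1, a2) && linked(a2, a1))
  fv$wik.links_absent <- as.numeric(!is.na(a1) && !is.na(a2) &&
                                      !linked(a1, a2) && !linked(a2, a1))
  cat_of <- function(a) {
    if (is.na(a)) return(NA_character_)
    v <- lex$wiki_categories[match(a, tolower(names(lex$wiki_categories)))]
    if (length(v) && !is.na(v)) unname(v) else NA_character_
  }
  c1 <- cat_of(a1); c2 <- cat_of(a2)
  fv$wik.same_category <- as.numeric(!is.na(c1) && !is.na(c2) && c1 == c2)

  ev <- doc$events[order(doc$events$start), ]
  prev_types <- ev$type[ev$end <= e1$start]
  next_types <- ev$type[ev$start >= e2$end]
  fv$vic.e1_prev_event <- paste(e1$type,
                                if (length(prev_types)) prev_types[length(prev_types)] else "NONE",
                                sep = "|")
  fv$vic.e2_next_event <- paste(e2$type,
                                if (length(next_types)) next_types[1] else "NONE",
                                sep = "|")
  fv
}

#' Simple expansion tree for an entity pair
#'
#' The portion of the sentence's constituency tree containing (i) every
#' node on the shortest path between the two entities' minimal covering
#' nodes and (ii) every immediate child of those nodes that is not a word
#' leaf.  The label of the node covering each entity (or, for the
#' identification variant, its parent) is replaced by the entity's
#' attribute value (its type).
#'
#' @param inst A `semrel_instance` or [instance_pair()].
#' @param doc,ann Document and annotations.
#' @param replace_at `"covering"` (default) or `"parent"`.
#' @return A node table (class `setree`) with word leaves removed.
#' @export
extract_simple_expansion_tree <- function(inst, doc, ann,
                                          replace_at = c("covering", "parent")) {
  replace_at <- match.arg(replace_at)
  e1 <- get_entity(doc, inst$e1); e2 <- get_entity(doc, inst$e2)
  s1 <- entity_sentence(e1, ann); s2 <- entity_sentence(e2, ann)
  if (is.na(s1) || is.na(s2) || s1 != s2) {
    stop("applicability error: simple expansion tree requires a ",
         "same-sentence pair")
  }
  tree <- ann$trees[[s1 + 1L]]
  n1 <- tree_covering_node(tree, ann$tokens$i[entity_tokens(e1, ann)])
  n2 <- tree_covering_node(tree, ann$tokens$i[entity_tokens(e2, ann)])
  path <- tree_node_path(tree, n1, n2)
  is_leaf <- !is.na(tree$token)
  keep <- unique(c(path, unlist(lapply(path, function(id) {
    kids <- tree_children(tree, id)
    kids[!is_leaf[match(kids, tree$id)]]
  }))))
  keep <- sort(keep)
  sub <- tree[match(keep, tree$id), , drop = FALSE]
  lca <- path[which.min(vapply(path, function(id)
    length(tree_ancestors(tree, id)), integer(1)))]
  sub$parent[sub$id == lca] <- 0L
  sub$parent[sub$parent != 0L & !(sub$parent %in% keep)] <- 0L  # safety
  relabel <- function(node, value) {
    target <- node
    if (replace_at == "parent") {
      par <- tree$parent[match(node, tree$id)]
      if (par %in% keep) target <- par
    }
    sub$label[sub$id == target] <<- value
  }
  relabel(n1, e1$type)
  relabel(n2, e2$type)
  # renumber preorder-compatible (original preorder ids preserved order)
  newid <- match(sub$id, sub$id)
  sub$parent <- ifelse(sub$parent == 0L, 0L, match(sub$parent, sub$id))
  sub$id <- newid
  sub$token <- NA_integer_
  rownames(sub) <- NULL
  class(sub) <- c("setree", class(sub))
  sub
}

#' Convolution tree kernel
#'
#' Counts common subtree fragments of two labeled ordered trees, where a
#' fragment must include entire productions; each production in a fragment
#' contributes a decay factor `lambda`, so a fragment with d productions
#' has weight `lambda^d`.  Symmetric and positive for identical non-trivial
#' trees.
#'
#' @param t1,t2 Node tables (e.g. from [extract_simple_expansion_tree()]).
#' @param lambda Decay in (0, 1]; default 0.4.
#' @return Non-negative kernel value.
#' @export
tree_kernel <- function(t1, t2, lambda = 0.4) {
  tree_kernel_cpp(list(label = t1$label, parent = t1$parent),
                  list(label = t2$label, parent = t2$parent), lambda)
}

#' Kernel matrix between two lists of trees
#' @param ts1,ts2 Lists of node tables.
#' @param lambda Decay.
#' @return Numeric matrix.
#' @export
tree_kernel_matrix <- function(ts1, ts2, lambda = 0.4) {
  tree_kernel_matrix_cpp(
    lapply(ts1, function(t) list(label = t$label, parent = t$parent)),
    lapply(ts2, function(t) list(label = t$label, parent = t$parent)),
    lambda)
}

scale_confidences <- function(conf) {
  # per-instance min-max over available class confidences, then
  # sum-normalization; unavailable classes contribute 0
  out <- stats::setNames(numeric(length(conf)), names(conf))
  ok <- !is.na(conf)
  if (!any(ok)) return(out)
  x <- conf[ok]
  if (max(x) == min(x)) {
    out[ok] <- 1 / sum(ok)
  } else {
    mm <- (x - min(x)) / (max(x) - min(x))
    if (sum(mm) == 0) mm[] <- 1 / length(mm)
    out[ok] <- mm / sum(mm)
  }
  out
}

.ovr_linear_bank <- function(X, y, classes, C) {
  # one-vs-rest linear SVMs with signed-distance outputs
  models <- stats::setNames(vector("list", length(classes)), classes)
  for (cls in classes) {
    pos <- y == cls
    if (!any(pos) || all(pos)) next
    yy <- factor(ifelse(pos, "POS", "NEG"), levels = c("POS", "NEG"))
    m <- e1071::svm(X, yy, kernel = "linear", cost = C, scale = FALSE)
    dv <- attr(stats::predict(m, X, decision.values = TRUE),
               "decision.values")[, 1]
    sgn <- if (mean(dv[pos]) >= mean(dv[!pos])) 1 else -1
    models[[cls]] <- list(svm = m, sign = sgn)
  }
  models
}

.ovr_linear_decisions <- function(models, X, classes) {
  out <- matrix(NA_real_, nrow(X), length(classes),
                dimnames = list(NULL, classes))
  for (cls in classes) {
    m <- models[[cls]]
    if (is.null(m)) next
    dv <- attr(stats::predict(m$svm, X, decision.values = TRUE),
               "decision.values")[, 1]
    out[, cls] <- m$sign * dv
  }
  out
}

#' Train the medical semantic-relation ensemble
#'
#' Trains the three member classifiers on labeled instances and stores the
#' combination weights.  The three "no relation" classes are downsampled to
#' at most `downsample_factor` times the largest positive class (seeded).
#' The flat bank is a one-vs-rest linear SVM bank (regularization
#' `C_flat`); the tree bank is a one-vs-rest precomputed tree-kernel SVM
#' bank (`C_tree`) whose per-class positive:negative ratio can be tuned on
#' held-out documents; the nearest-neighbour member uses lemma sequences.
#'
#' @param insts List of labeled `semrel_instance`s.
#' @param docs,anns Named lists keyed by doc id.
#' @param lex A [lexicon_set()].
#' @param cfg Configuration list (see [default_config()], entry `semrel`).
#' @return A `semrel_ensemble` model.
#' @export
train_semrel_ensemble <- function(insts, docs, anns, lex, cfg = NULL) {
  cfg <- modify_list(default_config()$semrel, cfg)
  with_seed(cfg$seed, {
    labels <- vapply(insts, function(i) i$label, "")
    pos_counts <- table(factor(labels, levels = positive_medsem_types()))
    cap <- max(1L, cfg$downsample_factor * max(as.integer(pos_counts), 1L))
    keep <- logical(length(insts))
    for (cls in medsem_types()) {
      idx <- which(labels == cls)
      if (cls %in% positive_medsem_types() || length(idx) <= cap) {
        keep[idx] <- TRUE
      } else {
        keep[sample(idx, cap)] <- TRUE
      }
    }
    insts <- insts[keep]; labels <- labels[keep]
    absent <- setdiff(medsem_types(), unique(labels))
    if (length(absent)) {
      warning("classes absent from training: ",
              paste(absent, collapse = ", "),
              "; their member confidences contribute 0")
    }
    bank <- build_semrel_bank(insts, docs, anns)
    fvs <- lapply(insts, function(i) {
      extract_semrel_flat(i, docs[[i$doc]], anns[[i$doc]], lex, bank,
                          cfg$knn_k)
    })
    vocab <- build_feature_vocab(fvs)
    X <- encode_features(fvs, vocab)
    flat_models <- .ovr_linear_bank(X, labels, medsem_types(), cfg$C_flat)

    trees <- lapply(insts, function(i) {
      extract_simple_expansion_tree(i, docs[[i$doc]], anns[[i$doc]])
    })
    Kfull <- tree_kernel_matrix(trees, trees, cfg$lambda)
    ratio <- cfg$tree_ratio
    if (isTRUE(cfg$tune_tree_ratio)) {
      ratio <- tune_tree_ratio(trees, labels, Kfull, insts, cfg)
    }
    tree_models <- stats::setNames(vector("list", length(medsem_types())),
                                   medsem_types())
    for (cls in medsem_types()) {
      pos <- which(labels == cls); neg <- which(labels != cls)
      if (!length(pos) || !length(neg)) next
      nneg <- min(length(neg), max(1L, ceiling(ratio * length(pos))))
      neg <- sort(sample(neg, nneg))
      idx <- sort(c(pos, neg))
      yy <- factor(ifelse(labels[idx] == cls, "POS", "NEG"),
                   levels = c("POS", "NEG"))
      K <- kernlab::as.kernelMatrix(Kfull[idx, idx, drop = FALSE])
      m <- kernlab::ksvm(K, yy, type = "C-svc", C = cfg$C_tree)
      dv <- kernlab::predict(m, kernlab::as.kernelMatrix(
        Kfull[idx, idx[kernlab::SVindex(m)], drop = FALSE]),
        type = "decision")[, 1]
      sgn <- if (mean(dv[yy == "POS"]) >= mean(dv[yy == "NEG"])) 1 else -1
      tree_models[[cls]] <- list(svm = m, idx = idx, sign = sgn)
    }
    structure(list(cfg = cfg, classes = medsem_types(),
                   flat = list(vocab = vocab, models = flat_models),
                   tree = list(models = tree_models, trees = trees,
                               ratio = ratio),
                   bank = bank, lex = lex,
                   majority = names(which.max(table(labels)))),
              class = "semrel_ensemble")
  })
}

tune_tree_ratio <- function(trees, labels, Kfull, insts, cfg) {
  docs_ids <- unique(vapply(insts, function(i) i$doc, ""))
  n_dev <- min(30L, max(1L, floor(length(docs_ids) * 0.2)))
  if (length(docs_ids) < 4L) return(cfg$tree_ratio)
  dev_docs <- sample(docs_ids, n_dev)
  dev <- vapply(insts, function(i) i$doc %in% dev_docs, TRUE)
  if (!any(dev) || all(dev)) return(cfg$tree_ratio)
  best <- cfg$tree_ratio; best_acc <- -1
  for (ratio in cfg$tree_ratio_grid) {
    correct <- 0L
    for (cls in unique(labels[!dev])) {
      pos <- which(!dev & labels == cls); neg <- which(!dev & labels != cls)
      if (!length(pos) || !length(neg)) next
      nneg <- min(length(neg), max(1L, ceiling(ratio * length(pos))))
      neg <- sort(sample(neg, nneg))
      idx <- sort(c(pos, neg))
      yy <- factor(ifelse(labels[idx] == cls, "POS", "NEG"),
                   levels = c("POS", "NEG"))
      m <- kernlab::ksvm(kernlab::as.kernelMatrix(Kfull[idx, idx]),
                         yy, type = "C-svc", C = cfg$C_tree)
      dv <- kernlab::predict(m, kernlab::as.kernelMatrix(
        Kfull[which(dev), idx[kernlab::SVindex(m)], drop = FALSE]),
        type = "decision")[, 1]
      correct <- correct + sum((dv >= 0) == (labels[dev] == cls))
    }
    if (correct > best_acc) { best_acc <- correct; best <- ratio }
  }
  best
}

#' Predict with the semantic-relation ensemble
#'
#' Each member classifier produces an 11-element probability vector (SVM
#' confidences are min-max scaled to \[0, 1\] per instance and normalized
#' to sum 1; the nearest-neighbour vector is the weighted vote tally).
#' They are combined as `w_tree * P_tree + w_flat * P_flat + w_knn *
#' P_knn` and the label is the argmax of the combined vector.
#'
#' @param model A `semrel_ensemble`.
#' @param insts List of `semrel_instance`s.
#' @param docs,anns Named lists keyed by doc id.
#' @param weights Optional override of the combination weights (named
#'   `tree`, `flat`, `knn`).
#' @return List with `labels`, `probs` (combined matrix), the member
#'   matrices `P_tree`, `P_flat`, `P_knn`, and `tree_labels` (the tree
#'   bank's own max-confidence decisions).
#' @export
predict_semrel <- function(model, insts, docs, anns, weights = NULL) {
  w <- if (is.null(weights)) model$cfg$weights else weights
  classes <- model$classes
  n <- length(insts)
  fvs <- lapply(insts, function(i) {
    extract_semrel_flat(i, docs[[i$doc]], anns[[i$doc]], model$lex,
                        model$bank, model$cfg$knn_k)
  })
  X <- encode_features(fvs, model$flat$vocab)
  flat_dec <- .ovr_linear_decisions(model$flat$models, X, classes)

  test_trees <- lapply(insts, function(i) {
    extract_simple_expansion_tree(i, docs[[i$doc]], anns[[i$doc]])
  })
  tree_dec <- matrix(NA_real_, n, length(classes),
                     dimnames = list(NULL, classes))
  for (cls in classes) {
    tm <- model$tree$models[[cls]]
    if (is.null(tm)) next
    Kt <- tree_kernel_matrix(test_trees, model$tree$trees[tm$idx],
                             model$cfg$lambda)
    dv <- kernlab::predict(tm$svm, kernlab::as.kernelMatrix(
      Kt[, kernlab::SVindex(tm$svm), drop = FALSE]), type = "decision")[, 1]
    tree_dec[, cls] <- tm$sign * dv
  }

  P_flat <- t(apply(flat_dec, 1, scale_confidences))
  P_tree <- t(apply(tree_dec, 1, scale_confidences))
  P_knn <- t(vapply(seq_len(n), function(r) {
    seq3 <- generate_sequence(3L, get_entity(docs[[insts[[r]]$doc]], insts[[r]]$e1),
                              get_entity(docs[[insts[[r]]$doc]], insts[[r]]$e2),
                              docs[[insts[[r]]$doc]], anns[[insts[[r]]$doc]])
    knn_probability_vector(seq3, model$bank, model$cfg$knn_k)
  }, numeric(length(classes))))
  colnames(P_knn) <- classes

  combined <- w[["tree"]] * P_tree + w[["flat"]] * P_flat + w[["knn"]] * P_knn
  labels <- classes[apply(combined, 1, which.max)]
  tree_labels <- classes[apply(
    ifelse(is.na(tree_dec), -Inf, tree_dec), 1, which.max)]
  list(labels = labels, probs = combined, P_tree = P_tree, P_flat = P_flat,
       P_knn = P_knn, tree_labels = tree_labels)
}

#' Micro-averaged scores over the positive semantic-relation classes
#'
#' Correct predictions of the three "no relation" classes are not counted.
#'
#' @param pred,gold Character vectors of class labels.
#' @return List with `precision`, `recall`, `f` (micro-averaged over the
#'   eight positive classes; 0 with a warning when no positive instances
#'   exist on either side).
#' @export
evaluate_semrel <- function(pred, gold) {
  stopifnot(length(pred) == length(gold))
  pos <- positive_medsem_types()
  tp <- sum(pred == gold & gold %in% pos)
  npred <- sum(pred %in% pos)
  ngold <- sum(gold %in% pos)
  if (npred == 0 && ngold == 0) {
    warning("no positive-class instances; F reported as 0")
    return(list(precision = 0, recall = 0, f = 0))
  }
  p <- if (npred) tp / npred else 0
  r <- if (ngold) tp / ngold else 0
  f <- if (p + r > 0) 2 * p * r / (p + r) else 0
  list(precision = p, recall = r, f = f)
}
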