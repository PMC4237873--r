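#' Feature extraction for candidate temporal-relation instances
#'
#' An instance pair is a text-ordered pair of annotated entities (`e1`
#' precedes `e2`) together with its routing scheme: `EE_INTRA` and
#' `ET_INTRA` for same-sentence event-event and event-time pairs,
#' `EE_ADJACENT` for event pairs one sentence apart, `EE_COREF` for
#' head-matching event pairs further apart.  Extractors are pure functions
#' of the document, annotation layers, lexicons and (for the medical
#' semantic-relation feature) a trained ensemble; missing layers yield NULL
#' (`NA`) features, never errors.
#'
#' @param doc_id Document id.
#' @param e1,e2 Entity ids (text order).
#' @param scheme One of `"EE_INTRA"`, `"ET_INTRA"`, `"EE_ADJACENT"`,
#'   `"EE_COREF"`.
#' @param label Optional fine relation type or `"NO_RELATION"`.
#' @return An `instance_pair` (a named list).
#' @export
instance_pair <- function(doc_id, e1, e2, scheme, label = NA_character_) {
  structure(list(doc = doc_id, e1 = e1, e2 = e2, scheme = scheme,
                 label = label),
            class = "instance_pair")
}

entity_sentence <- function(ent, ann) {
  rows <- entity_tokens(ent, ann)
  if (!length(rows)) return(NA_integer_)
  ann$tokens$sent[rows[1]]
}

between_text <- function(ent1, ent2, doc) {
  if (ent1$end >= ent2$start) return("")
  substr(doc$text, ent1$end + 1L, ent2$start)
}

window_tokens <- function(ent, ann, offsets) {
  rows <- entity_tokens(ent, ann)
  tk <- ann$tokens
  lo <- tk$i[rows[1]]; hi <- tk$i[rows[length(rows)]]
  vapply(offsets, function(o) {
    idx <- if (o < 0) lo + o else hi + o
    r <- match(idx, tk$i)
    if (is.na(r)) NA_character_ else tolower(tk$text[r])
  }, "")
}

window_pos <- function(ent, ann, offsets) {
  rows <- entity_tokens(ent, ann)
  tk <- ann$tokens
  lo <- tk$i[rows[1]]; hi <- tk$i[rows[length(rows)]]
  vapply(offsets, function(o) {
    idx <- if (o < 0) lo + o else hi + o
    r <- match(idx, tk$i)
    if (is.na(r)) NA_character_ else tk$pos[r]
  }, "")
}

sentence_tree <- function(ent, ann) {
  s <- entity_sentence(ent, ann)
  if (is.na(s) || s + 1L > length(ann$trees)) return(NULL)
  ann$trees[[s + 1L]]
}

prep_lexeme_under <- function(tree, id, ann) {
  toks <- tree_tokens_under(tree, id)
  tk <- ann$tokens
  pos <- tk$pos[match(toks, tk$i)]
  pick <- which(pos %in% c("IN", "TO"))
  if (!length(pick)) return(NA_character_)
  tolower(tk$text[match(toks[pick[1]], tk$i)])
}

# minimal covering node of the entity span, if labeled `lab`
headed_by <- function(ent, ann, lab) {
  tree <- sentence_tree(ent, ann)
  if (is.null(tree)) return(NA_integer_)
  toks <- ann$tokens$i[entity_tokens(ent, ann)]
  id <- tree_covering_node(tree, toks)
  if (!is.na(id) && tree$label[match(id, tree$id)] == lab) id else NA_integer_
}

# nearest ancestor of the entity's head leaf with the given label
governed_by <- function(ent, ann, lab) {
  tree <- sentence_tree(ent, ann)
  if (is.null(tree)) return(list(tree = NULL, id = NA_integer_))
  leaf <- tree_leaf_for_token(tree, head_token(ent, ann)$i)
  anc <- tree_ancestors(tree, leaf)
  hit <- anc[tree$label[match(anc, tree$id)] == lab]
  list(tree = tree, id = if (length(hit)) hit[1] else NA_integer_)
}

vp_head_pos <- function(tree, id, ann) {
  toks <- tree_tokens_under(tree, id)
  tk <- ann$tokens
  pos <- tk$pos[match(toks, tk$i)]
  pick <- which(startsWith(pos, "VB"))
  if (!length(pick)) return(NA_character_)
  pos[pick[1]]
}

# prepositions / verb POS tags collected on the path from the entity's head
# leaf to the root of its parse tree
root_trace <- function(ent, ann, what = c("prep", "verb")) {
  what <- match.arg(what)
  tree <- sentence_tree(ent, ann)
  if (is.null(tree)) return("")
  leaf <- tree_leaf_for_token(tree, head_token(ent, ann)$i)
  anc <- tree_ancestors(tree, leaf)
  acc <- character()
  for (id in anc) {
    lab <- tree$label[match(id, tree$id)]
    if (what == "prep" && lab == "PP") {
      p <- prep_lexeme_under(tree, id, ann)
      if (!is.na(p)) acc <- c(acc, p)
    }
    if (what == "verb" && startsWith(lab, "VP")) {
      v <- vp_head_pos(tree, id, ann)
      if (!is.na(v)) acc <- c(acc, v)
    }
  }
  paste(acc, collapse = "+")
}

dep_roles <- function(ent, ann) {
  h <- head_token(ent, ann)$i
  lab <- ann$deps$label[ann$deps$dep == h]
  c(subj = as.numeric(any(grepl("subj", lab))),
    obj = as.numeric(any(grepl("obj", lab))))
}

sct_relation <- function(ent, doc) {
  if (!nrow(doc$sectimes) || !nrow(doc$tlinks)) return(NA_character_)
  st_ids <- doc$sectimes$id
  tl <- doc$tlinks
  hit <- which(tl$from == ent$id & tl$to %in% st_ids)
  if (length(hit)) return(.sct_broad(tl$relation[hit[1]]))
  hit <- which(tl$to == ent$id & tl$from %in% st_ids)
  if (length(hit)) return(.sct_broad(invert_relation(tl$relation[hit[1]])))
  NA_character_
}

.sct_broad <- function(r) {
  switch(unname(.broad_table[if (r %in% names(.broad_table)) r else invert_relation(r)]),
         BEFORE3 = "BEFORE", AFTER3 = "AFTER", OVERLAP3 = "OVERLAP")
}

#' Baseline feature set (six families)
#'
#' Lexical context and heads, grammatical (POS context, PP/VP government,
#' dominance, tree path, dependency roles), entity attributes, distance,
#' semantic (temporal-role subordination, first synset) and
#' section-creation-time features.
#'
#' @param p An [instance_pair()].
#' @param doc A `clindoc`.
#' @param ann A `docann`.
#' @param lex Optional [lexicon_set()] (used for the first-synset feature).
#' @return A feature vector (named list).
#' @export
extract_baseline <- function(p, doc, ann, lex = NULL) {
  e1 <- get_entity(doc, p$e1); e2 <- get_entity(doc, p$e2)
  h1 <- head_token(e1, ann); h2 <- head_token(e2, ann)
  fv <- list()

  # lexical
  fv$lex.e1_str <- tolower(e1$text); fv$lex.e2_str <- tolower(e2$text)
  fv$lex.e1_head <- tolower(h1$text); fv$lex.e2_head <- tolower(h2$text)
  fv$lex.same_string <- as.numeric(tolower(e1$text) == tolower(e2$text))
  w1 <- window_tokens(e1, ann, c(-2L, -1L, 1L, 2L))
  w2 <- window_tokens(e2, ann, c(-2L, -1L, 1L, 2L))
  fv$lex.e1_wm2 <- w1[1]; fv$lex.e1_wm1 <- w1[2]
  fv$lex.e1_wp1 <- w1[3]; fv$lex.e1_wp2 <- w1[4]
  fv$lex.e2_wm2 <- w2[1]; fv$lex.e2_wm1 <- w2[2]
  fv$lex.e2_wp1 <- w2[3]; fv$lex.e2_wp2 <- w2[4]
  fv$lex.e1_prev_bigram <- paste(w1[1], w1[2])
  fv$lex.e1_next_bigram <- paste(w1[3], w1[4])
  fv$lex.e2_prev_bigram <- paste(w2[1], w2[2])
  fv$lex.e2_next_bigram <- paste(w2[3], w2[4])
  fv$lex.e1_trigram <- paste(w1[2], fv$lex.e1_head, w1[3])
  fv$lex.e2_trigram <- paste(w2[2], fv$lex.e2_head, w2[3])

  # grammatical
  fv$gram.e1_head_pos <- h1$pos; fv$gram.e2_head_pos <- h2$pos
  p1 <- window_pos(e1, ann, c(-5:-1, 1:5))
  p2 <- window_pos(e2, ann, c(-5:-1, 1:5))
  for (k in seq_along(p1)) {
    o <- c(-5:-1, 1:5)[k]
    fv[[sprintf("gram.e1_pos%+d", o)]] <- p1[k]
    fv[[sprintf("gram.e2_pos%+d", o)]] <- p2[k]
  }
  fv$gram.e1_prev_pos_bigram <- paste(p1[5], h1$pos)
  fv$gram.e2_prev_pos_bigram <- paste(p2[5], h2$pos)
  fv$gram.head_pos_pair <- paste(h1$pos, h2$pos)
  for (nm in c("e1", "e2")) {
    ent <- if (nm == "e1") e1 else e2
    hb <- headed_by(ent, ann, "PP")
    fv[[paste0("gram.", nm, "_pp_headed")]] <-
      if (is.na(hb)) NA_character_ else prep_lexeme_under(sentence_tree(ent, ann), hb, ann)
    gv <- governed_by(ent, ann, "PP")
    fv[[paste0("gram.", nm, "_pp_governed")]] <-
      if (is.na(gv$id)) NA_character_ else prep_lexeme_under(gv$tree, gv$id, ann)
    gv <- governed_by(ent, ann, "VP")
    fv[[paste0("gram.", nm, "_vp_governed_pos")]] <-
      if (is.na(gv$id)) NA_character_ else vp_head_pos(gv$tree, gv$id, ann)
  }
  same_sent <- !is.na(h1$sent) && h1$sent == h2$sent
  fv$gram.dominates <- as.numeric(same_sent && syntactic_dominates(e1, e2, ann))
  fv$gram.tree_path <- if (same_sent) {
    paste(tree_path(e1, e2, ann), collapse = "/")
  } else NA_character_
  r1 <- dep_roles(e1, ann); r2 <- dep_roles(e2, ann)
  fv$gram.e1_dep_subj <- r1[["subj"]]; fv$gram.e1_dep_obj <- r1[["obj"]]
  fv$gram.e2_dep_subj <- r2[["subj"]]; fv$gram.e2_dep_obj <- r2[["obj"]]

  # entity attributes (times have NULL modality/polarity)
  fv$ent.e1_type <- e1$type; fv$ent.e2_type <- e2$type
  fv$ent.e1_modality <- if (e1$kind == "EVENT") e1$modality else NA_character_
  fv$ent.e2_modality <- if (e2$kind == "EVENT") e2$modality else NA_character_
  fv$ent.e1_polarity <- if (e1$kind == "EVENT") e1$polarity else NA_character_
  fv$ent.e2_polarity <- if (e2$kind == "EVENT") e2$polarity else NA_character_
  fv$ent.type_pair <- paste(e1$type, e2$type)
  fv$ent.modality_pair <- paste(fv$ent.e1_modality, fv$ent.e2_modality)

  # distance
  fv$dist.tokens <- abs(h2$i - h1$i)
  fv$dist.same_sentence <- as.numeric(same_sent)

  # semantic
  tmp_sub <- function(ent) {
    h <- head_token(ent, ann)$i
    for (fr in ann$srl) {
      a <- fr$args
      hit <- which(a$label == "TMP" & a$start_tok <= h & a$end_tok >= h)
      if (length(hit)) {
        return(tolower(ann$tokens$text[match(a$start_tok[hit[1]],
                                             ann$tokens$i)]))
      }
    }
    NA_character_
  }
  fv$sem.e1_tmp_sub <- tmp_sub(e1); fv$sem.e2_tmp_sub <- tmp_sub(e2)
  syn <- function(h) {
    if (is.null(lex) || !length(lex$synsets)) return(NA_character_)
    v <- lex$synsets[tolower(h$text)]
    if (is.na(v)) NA_character_ else unname(v)
  }
  fv$sem.e1_synset <- syn(h1); fv$sem.e2_synset <- syn(h2)

  # section creation time
  fv$sct.e1 <- sct_relation(e1, doc); fv$sct.e2 <- sct_relation(e2, doc)
  fv$sct.differ <- if (is.na(fv$sct.e1) || is.na(fv$sct.e2)) NA_real_ else
    as.numeric(fv$sct.e1 != fv$sct.e2)
  fv
}

#' Pairwise features
#'
#' Features computed from both entities at once: paired heads, paired
#' prepositional lexemes, the (type, modality) quadruple, and the
#' preposition and verb "trace" features collected on each entity's path to
#' the root of its parse tree.
#'
#' @inheritParams extract_baseline
#' @return A feature vector.
#' @export
extract_pairwise <- function(p, doc, ann) {
  e1 <- get_entity(doc, p$e1); e2 <- get_entity(doc, p$e2)
  h1 <- head_token(e1, ann); h2 <- head_token(e2, ann)
  fv <- list()
  fv$pair.heads <- paste(tolower(h1$text), tolower(h2$text), sep = "|")
  pp <- function(ent) {
    hb <- headed_by(ent, ann, "PP")
    if (!is.na(hb)) return(prep_lexeme_under(sentence_tree(ent, ann), hb, ann))
    NA_character_
  }
  gv <- function(ent) {
    g <- governed_by(ent, ann, "PP")
    if (is.na(g$id)) NA_character_ else prep_lexeme_under(g$tree, g$id, ann)
  }
  fv$pair.pp_headed <- paste(pp(e1), pp(e2), sep = "|")
  fv$pair.pp_governed <- paste(gv(e1), gv(e2), sep = "|")
  fv$pair.quad <- paste(e1$type,
                        if (e1$kind == "EVENT") e1$modality else "NULL",
                        e2$type,
                        if (e2$kind == "EVENT") e2$modality else "NULL",
                        sep = "|")
  fv$pair.prep_trace <- paste(root_trace(e1, ann, "prep"),
                              root_trace(e2, ann, "prep"), sep = "||")
  fv$pair.verb_trace <- paste(root_trace(e1, ann, "verb"),
                              root_trace(e2, ann, "verb"), sep = "||")
  fv
}

#' Lexical-relation features (thesaurus and wordnet variants)
#'
#' Eight binary flags per variant: whether each entity's head word appears
#' in the other's synonym / related / near-antonym / antonym lists
#' (thesaurus) or hypernym / hyponym / troponym / similar lists (wordnet).
#'
#' @inheritParams extract_baseline
#' @param lex A [lexicon_set()].
#' @return A feature vector of 16 binary flags.
#' @export
extract_lexical_relations <- function(p, doc, ann, lex) {
  e1 <- get_entity(doc, p$e1); e2 <- get_entity(doc, p$e2)
  h1 <- tolower(head_token(e1, ann)$text)
  h2 <- tolower(head_token(e2, ann)$text)
  fv <- list()
  for (variant in c("thesaurus", "wordnet")) {
    pre <- if (variant == "thesaurus") "thes" else "wn"
    rels <- if (variant == "thesaurus") thesaurus_relations() else wordnet_relations()
    l1 <- lexicon_lookup(lex[[variant]], h1)
    l2 <- lexicon_lookup(lex[[variant]], h2)
    for (r in rels) {
      fv[[paste0(pre, ".e1_in_e2_", r)]] <- as.numeric(h1 %in% l2[[r]])
      fv[[paste0(pre, ".e2_in_e1_", r)]] <- as.numeric(h2 %in% l1[[r]])
    }
  }
  fv
}

#' Predicate-argument features
#'
#' One binary per pairing of a numbered argument (A0..A5) with a predicate
#' role in either direction, plus eight binaries for the directional,
#' manner, temporal and cause modifier relations.
#'
#' @inheritParams extract_baseline
#' @return A feature vector of 20 binary flags (all zero without an SRL
#'   layer).
#' @export
extract_predarg <- function(p, doc, ann) {
  e1 <- get_entity(doc, p$e1); e2 <- get_entity(doc, p$e2)
  h1 <- head_token(e1, ann)$i; h2 <- head_token(e2, ann)$i
  numbered <- paste0("A", 0:5)
  mods <- c("DIR", "MNR", "TMP", "CAU")
  fv <- list()
  for (a in c(numbered, mods)) {
    fv[[paste0("srl.e1_pred_e2_", a)]] <- 0
    fv[[paste0("srl.e2_pred_e1_", a)]] <- 0
  }
  for (fr in ann$srl) {
    for (r in seq_len(nrow(fr$args))) {
      a <- fr$args[r, ]
      if (!a$label %in% c(numbered, mods)) next
      if (fr$pred == h1 && a$start_tok <= h2 && a$end_tok >= h2) {
        fv[[paste0("srl.e1_pred_e2_", a$label)]] <- 1
      }
      if (fr$pred == h2 && a$start_tok <= h1 && a$end_tok >= h1) {
        fv[[paste0("srl.e2_pred_e1_", a$label)]] <- 1
      }
    }
  }
  fv
}

entity_in_interval <- function(ent, ann, s, e) {
  h <- head_token(ent, ann)
  h$start >= s && h$end <= e
}

#' Discourse-relation features
#'
#' Four categorical features: the sense of an explicit relation with e1 in
#' Arg1 and e2 in Arg2, the same with the entities swapped, and the two
#' implicit-relation counterparts; plus the triggering connective of the
#' matched explicit relation.  An entity "is in" an argument iff its head
#' token's span lies within the argument's character interval.
#'
#' @inheritParams extract_baseline
#' @return A feature vector (NULL-valued when not applicable).
#' @export
extract_discourse <- function(p, doc, ann) {
  e1 <- get_entity(doc, p$e1); e2 <- get_entity(doc, p$e2)
  fv <- list(disc.explicit_e1a1_e2a2 = NA_character_,
             disc.explicit_e2a1_e1a2 = NA_character_,
             disc.implicit_e1a1_e2a2 = NA_character_,
             disc.implicit_e2a1_e1a2 = NA_character_,
             disc.connective = NA_character_)
  dc <- ann$discourse
  for (r in seq_len(nrow(dc))) {
    d <- dc[r, ]
    in11 <- entity_in_interval(e1, ann, d$a1s, d$a1e)
    in12 <- entity_in_interval(e1, ann, d$a2s, d$a2e)
    in21 <- entity_in_interval(e2, ann, d$a1s, d$a1e)
    in22 <- entity_in_interval(e2, ann, d$a2s, d$a2e)
    key <- tolower(d$kind)
    if (in11 && in22) {
      nm <- paste0("disc.", key, "_e1a1_e2a2")
      if (is.na(fv[[nm]])) fv[[nm]] <- d$sense
      if (d$kind == "EXPLICIT" && is.na(fv$disc.connective)) {
        fv$disc.connective <- d$conn
      }
    }
    if (in21 && in12) {
      nm <- paste0("disc.", key, "_e2a1_e1a2")
      if (is.na(fv[[nm]])) fv[[nm]] <- d$sense
      if (d$kind == "EXPLICIT" && is.na(fv$disc.connective)) {
        fv$disc.connective <- d$conn
      }
    }
  }
  fv
}

medsem_applicable <- function(e1, e2, ann, scope = "intra") {
  if (e1$kind != "EVENT" || e2$kind != "EVENT") return(FALSE)
  pair <- sort(c(e1$type, e2$type))
  ok <- identical(pair, c("PROBLEM", "TREATMENT")) ||
    identical(pair, c("PROBLEM", "TEST")) ||
    identical(pair, c("PROBLEM", "PROBLEM"))
  if (!ok) return(FALSE)
  if (scope == "intra") {
    s1 <- entity_sentence(e1, ann); s2 <- entity_sentence(e2, ann)
    return(!is.na(s1) && !is.na(s2) && s1 == s2)
  }
  TRUE
}

#' Medical semantic-relation features
#'
#' For applicable pairs (TREATMENT-PROBLEM, TEST-PROBLEM or PROBLEM-PROBLEM
#' within one sentence by default; the scope is configurable), one feature
#' carries the 11-class relation label predicted by the trained semantic
#' relation ensemble and the remaining features re-use the subsystem's flat
#' feature groups under the `med.` prefix.  All features are NULL for
#' non-applicable pairs.
#'
#' @inheritParams extract_baseline
#' @param model A trained semrel ensemble (see [train_semrel_ensemble()]),
#'   or `NULL` to emit only NULLs.
#' @param lex A [lexicon_set()].
#' @param scope `"intra"` (default) or `"inter"`.
#' @return A feature vector.
#' @export
extract_medsem <- function(p, doc, ann, model, lex, scope = "intra") {
  e1 <- get_entity(doc, p$e1); e2 <- get_entity(doc, p$e2)
  if (is.null(model) || !medsem_applicable(e1, e2, ann, scope)) {
    return(list(med.pred = NA_character_))
  }
  inst <- semrel_instance(p$doc, p$e1, p$e2,
                          sent = entity_sentence(e1, ann))
  docs <- stats::setNames(list(doc), p$doc)
  anns <- stats::setNames(list(ann), p$doc)
  pred <- predict_semrel(model, list(inst), docs, anns)
  fv <- list(med.pred = pred$labels[1])
  flat <- extract_semrel_flat(inst, doc, ann, model$lex, model$bank,
                              k = model$cfg$knn_k)
  names(flat) <- paste0("med.", names(flat))
  c(fv, flat)
}

#' Extract the full feature set for an instance pair
#'
#' Combines the baseline six families with the pairwise, lexical-relation,
#' predicate-argument, discourse and medical semantic-relation families.
#'
#' @inheritParams extract_baseline
#' @param lex A [lexicon_set()].
#' @param medsem_model Optional trained semrel ensemble.
#' @param medsem_scope `"intra"` or `"inter"`.
#' @return A feature vector.
#' @export
extract_features <- function(p, doc, ann, lex, medsem_model = NULL,
                             medsem_scope = "intra") {
  c(extract_baseline(p, doc, ann, lex),
    extract_pairwise(p, doc, ann),
    extract_lexical_relations(p, doc, ann, lex),
    extract_predarg(p, doc, ann),
    extract_discourse(p, doc, ann),
    extract_medsem(p, doc, ann, medsem_model, lex, medsem_scope))
}
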