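#' Relation-extraction pipeline
#'
#' Candidate pairs are routed to four specialized classifiers: same-sentence
#' event-event (`EE_INTRA`) and event-time (`ET_INTRA`) pairs, event pairs
#' in adjacent sentences (`EE_ADJACENT`), and head-matching (naively
#' coreferent) event pairs farther apart (`EE_COREF`).  Five system
#' architectures combine the learned classifiers with the hand-crafted
#' ruleset; a relation identification stage with tunable decision
#' thresholds filters candidate pairs in the harder evaluation setting.
#'
#' @name relation_pipeline
NULL

pair_schemes <- function() c("EE_INTRA", "ET_INTRA", "EE_ADJACENT", "EE_COREF")

all_entities <- function(doc) {
  ev <- doc$events[, c("id", "start", "end")]
  if (nrow(ev)) ev$kind <- "EVENT"
  tm <- doc$times[, c("id", "start", "end")]
  if (nrow(tm)) tm$kind <- "TIME"
  out <- rbind(ev, tm)
  out[order(out$start, out$end), , drop = FALSE]
}

entity_sent_map <- function(doc, ann) {
  ents <- all_entities(doc)
  ents$sent <- vapply(seq_len(nrow(ents)), function(r) {
    rows <- which(ann$tokens$start < ents$end[r] &
                    ann$tokens$end > ents$start[r])
    if (!length(rows)) NA_integer_ else ann$tokens$sent[rows[1]]
  }, integer(1))
  ents$head <- vapply(seq_len(nrow(ents)), function(r) {
    ent <- get_entity(doc, ents$id[r])
    tolower(head_token(ent, ann)$lemma)
  }, "")
  ents$head_i <- vapply(seq_len(nrow(ents)), function(r) {
    ent <- get_entity(doc, ents$id[r])
    head_token(ent, ann)$i
  }, integer(1))
  ents
}

gold_fine_links <- function(doc) {
  tl <- doc$tlinks
  if (!nrow(tl)) return(tl)
  ids <- c(doc$events$id, doc$times$id)
  tl <- tl[tl$from %in% ids & tl$to %in% ids, , drop = FALSE]
  tl[tl$relation %in% fine_relation_types(), , drop = FALSE]
}

gold_label_between <- function(doc, a, b) {
  tl <- gold_fine_links(doc)
  i <- which(tl$from == a & tl$to == b)
  if (length(i)) return(tl$relation[i[1]])
  i <- which(tl$from == b & tl$to == a)
  if (length(i)) return(invert_relation(tl$relation[i[1]]))
  NA_character_
}

route_scheme <- function(ents, ia, ib) {
  sa <- ents$sent[ia]; sb <- ents$sent[ib]
  if (is.na(sa) || is.na(sb)) return(NA_character_)
  ka <- ents$kind[ia]; kb <- ents$kind[ib]
  if (sa == sb) {
    if (ka == "EVENT" && kb == "EVENT") return("EE_INTRA")
    if (xor(ka == "TIME", kb == "TIME")) return("ET_INTRA")
    return(NA_character_)
  }
  if (ka != "EVENT" || kb != "EVENT") return(NA_character_)
  if (abs(sb - sa) == 1L) return("EE_ADJACENT")
  if (ents$head[ia] == ents$head[ib]) return("EE_COREF")
  NA_character_
}

main_event_rows <- function(ents) {
  # first and last event of each sentence
  ev <- which(ents$kind == "EVENT" & !is.na(ents$sent))
  out <- integer()
  for (s in unique(ents$sent[ev])) {
    rows <- ev[ents$sent[ev] == s]
    out <- c(out, rows[1], rows[length(rows)])
  }
  unique(out)
}

#' Build classification instances for the four specialized classifiers
#'
#' Training mode: positives are text-ordered pairs carrying one of the 12
#' relation types under each scheme's locality rule (same sentence; one
#' sentence apart for event pairs; coreferent event pairs at any
#' distance); negatives are adjacent unrelated same-sentence pairs,
#' unrelated adjacent-sentence main-event pairs, and unrelated coreferent
#' main-event pairs, labeled `NO_RELATION`.  Test mode creates instances
#' the same way as the negative training instances (all such candidate
#' pairs, whatever their gold status), carrying the gold label when one
#' exists.
#'
#' @param doc,ann Document and annotations.
#' @param for_training Logical.
#' @return List of [instance_pair()]s.
#' @export
build_classification_instances <- function(doc, ann, for_training = TRUE) {
  ents <- entity_sent_map(doc, ann)
  out <- list()
  push <- function(ia, ib, scheme) {
    a <- ents$id[ia]; b <- ents$id[ib]
    lab <- gold_label_between(doc, a, b)
    if (for_training || !is.na(lab) || TRUE) {
      out[[length(out) + 1L]] <<- instance_pair(
        doc$id, a, b, scheme,
        label = if (is.na(lab)) no_relation() else lab)
    }
  }
  seen <- character()
  mark <- function(ia, ib) {
    k <- paste(ents$id[ia], ents$id[ib])
    if (k %in% seen) return(FALSE)
    seen <<- c(seen, k); TRUE
  }
  # intra-sentence schemes
  for (s in unique(stats::na.omit(ents$sent))) {
    rows <- which(ents$sent == s)
    if (for_training) {
      # positives: every related pair of the right kinds
      if (length(rows) > 1L) {
        for (x in seq_along(rows)[-length(rows)]) {
          for (y in (x + 1L):length(rows)) {
            ia <- rows[x]; ib <- rows[y]
            sch <- route_scheme(ents, ia, ib)
            if (is.na(sch)) next
            if (!is.na(gold_label_between(doc, ents$id[ia], ents$id[ib])) &&
                mark(ia, ib)) push(ia, ib, sch)
          }
        }
      }
    }
    # adjacent pairs (negative creation scheme; the test scheme)
    if (length(rows) > 1L) {
      for (x in seq_len(length(rows) - 1L)) {
        ia <- rows[x]; ib <- rows[x + 1L]
        sch <- route_scheme(ents, ia, ib)
        if (is.na(sch)) next
        related <- !is.na(gold_label_between(doc, ents$id[ia], ents$id[ib]))
        if ((for_training && !related) || !for_training) {
          if (mark(ia, ib)) push(ia, ib, sch)
        }
      }
    }
  }
  # adjacent-sentence event pairs
  ev <- which(ents$kind == "EVENT" & !is.na(ents$sent))
  main <- main_event_rows(ents)
  if (length(ev) > 1L) {
    for (x in seq_along(ev)[-length(ev)]) {
      for (y in (x + 1L):length(ev)) {
        ia <- ev[x]; ib <- ev[y]
        ds <- ents$sent[ib] - ents$sent[ia]
        if (ds == 1L) {
          related <- !is.na(gold_label_between(doc, ents$id[ia], ents$id[ib]))
          if (for_training && related) {
            if (mark(ia, ib)) push(ia, ib, "EE_ADJACENT")
          } else if (ia %in% main && ib %in% main) {
            if ((for_training && !related) || !for_training) {
              if (mark(ia, ib)) push(ia, ib, "EE_ADJACENT")
            }
          }
        } else if (ds > 1L && ents$head[ia] == ents$head[ib]) {
          related <- !is.na(gold_label_between(doc, ents$id[ia], ents$id[ib]))
          if (for_training && related) {
            if (mark(ia, ib)) push(ia, ib, "EE_COREF")
          } else if (ia %in% main && ib %in% main) {
            if ((for_training && !related) || !for_training) {
              if (mark(ia, ib)) push(ia, ib, "EE_COREF")
            }
          }
        }
      }
    }
  }
  out
}

#' Build labeled identification instances (HAS_RELATION / NO_RELATION)
#'
#' Every routable event-event and event-time pair that carries a relation
#' is a positive; the remaining routable pairs are negatives.  For
#' training, simple pruning heuristics bound the negative skew: negatives
#' whose head tokens are more than `max_token_distance` apart within a
#' sentence are dropped, and cross-sentence negatives beyond
#' `max_sentence_distance` sentences are dropped unless coreferent.
#'
#' @param doc,ann Document and annotations.
#' @param cfg Identifier configuration (see [default_config()]).
#' @param prune Apply the negative pruning heuristics (training only).
#' @return List of [instance_pair()]s labeled `"HAS_RELATION"` or
#'   `"NO_RELATION"`.
#' @export
build_identification_instances <- function(doc, ann,
                                           cfg = default_config()$identifier,
                                           prune = TRUE) {
  ents <- entity_sent_map(doc, ann)
  out <- list()
  n <- nrow(ents)
  if (n < 2L) return(out)
  for (x in seq_len(n - 1L)) {
    for (y in (x + 1L):n) {
      sch <- route_scheme(ents, x, y)
      if (is.na(sch)) next
      lab <- gold_label_between(doc, ents$id[x], ents$id[y])
      positive <- !is.na(lab)
      if (!positive && prune) {
        if (sch %in% c("EE_INTRA", "ET_INTRA") &&
            abs(ents$head_i[y] - ents$head_i[x]) > cfg$max_token_distance) next
        ds <- abs(ents$sent[y] - ents$sent[x])
        if (sch == "EE_ADJACENT" && ds > cfg$max_sentence_distance) next
      }
      out[[length(out) + 1L]] <- instance_pair(
        doc$id, ents$id[x], ents$id[y], sch,
        label = if (positive) "HAS_RELATION" else no_relation())
    }
  }
  out
}

#' Extract features / rule contexts for a list of instances
#'
#' @param insts List of [instance_pair()]s.
#' @param docs,anns Named lists keyed by doc id.
#' @param lex A [lexicon_set()].
#' @param medsem_model Optional trained semrel ensemble.
#' @param cfg Full configuration.
#' @return `prepare_features()`: list of feature vectors;
#'   `prepare_contexts()`: list of rule contexts.
#' @export
prepare_features <- function(insts, docs, anns, lex, medsem_model, cfg) {
  lapply(insts, function(p) {
    extract_features(p, docs[[p$doc]], anns[[p$doc]], lex, medsem_model,
                     cfg$medsem_scope)
  })
}

#' @rdname prepare_features
#' @param fvs Feature vectors from `prepare_features()`.
#' @export
prepare_contexts <- function(insts, docs, anns, fvs) {
  lapply(seq_along(insts), function(k) {
    p <- insts[[k]]
    build_rule_context(p, docs[[p$doc]], anns[[p$doc]], fvs[[k]])
  })
}

.constant_model <- function(scheme, label) {
  structure(list(scheme = scheme, constant = label), class = "specialized_model")
}

#' Train the four specialized relation classifiers
#'
#' One multiclass SVM (linear kernel) per scheme over one-hot encoded
#' features with the vocabulary frozen at training.  The regularization
#' constant can be selected by grid search on a held-out fraction of the
#' training instances (`tune_C`); schemes without positive instances yield
#' a constant `NO_RELATION` model with a warning.
#'
#' @param insts List of labeled [instance_pair()]s.
#' @param fvs Parallel list of feature vectors.
#' @param cfg Classifier configuration (see [default_config()]).
#' @return Named list of `specialized_model`s by scheme.
#' @export
train_specialized <- function(insts, fvs, cfg = default_config()$classifier) {
  schemes <- vapply(insts, function(p) p$scheme, "")
  labels <- vapply(insts, function(p) p$label, "")
  models <- list()
  for (sch in pair_schemes()) {
    idx <- which(schemes == sch)
    if (!length(idx) || !any(labels[idx] %in% fine_relation_types())) {
      warning("scheme ", sch, " has no positive training instances; ",
              "constant NO_RELATION model")
      models[[sch]] <- .constant_model(sch, no_relation())
      next
    }
    y <- labels[idx]
    vocab <- build_feature_vocab(fvs[idx])
    X <- encode_features(fvs[idx], vocab)
    classes <- sort(unique(y))
    majority <- names(which.max(table(y[y %in% fine_relation_types()])))
    if (length(classes) == 1L) {
      m <- .constant_model(sch, classes)
      m$vocab <- vocab; m$majority <- majority
      models[[sch]] <- m
      next
    }
    C <- cfg$C
    if (isTRUE(cfg$tune_C) && length(idx) >= 10L) {
      C <- with_seed(cfg$seed, .tune_C(X, y, cfg))
    }
    svm <- e1071::svm(X, factor(y), kernel = "linear", cost = C,
                      scale = FALSE)
    models[[sch]] <- structure(
      list(scheme = sch, svm = svm, vocab = vocab, classes = classes,
           C = C, majority = majority),
      class = "specialized_model")
  }
  models
}

.tune_C <- function(X, y, cfg) {
  n <- nrow(X)
  dev <- sample(n, max(1L, floor(n * cfg$dev_fraction)))
  tr <- setdiff(seq_len(n), dev)
  if (length(unique(y[tr])) < 2L) return(cfg$C)
  best <- cfg$C_grid[1]; best_acc <- -1
  for (C in cfg$C_grid) {
    m <- e1071::svm(X[tr, , drop = FALSE], factor(y[tr]), kernel = "linear",
                    cost = C, scale = FALSE)
    acc <- mean(as.character(stats::predict(
      m, X[dev, , drop = FALSE])) == y[dev])
    if (acc > best_acc) { best_acc <- acc; best <- C }
  }
  best
}

predict_specialized <- function(model, fvs) {
  if (!is.null(model$constant)) return(rep(model$constant, length(fvs)))
  X <- encode_features(fvs, model$vocab)
  as.character(stats::predict(model$svm, X))
}

#' Train a relation-classification system
#'
#' Builds training instances over the corpus, extracts features, measures
#' and orders the ruleset, and trains the specialized classifiers both
#' without and with rules-as-features (the latter backing the combined
#' architectures).
#'
#' @param corpus A fixture corpus or any list with named `docs`, `anns`.
#' @param lex A [lexicon_set()].
#' @param rules_text Rule lines (default [starter_rules()]).
#' @param medsem_model Optional trained [train_semrel_ensemble()] model.
#' @param cfg Full configuration (see [default_config()]).
#' @return A `relation_system`.
#' @export
train_relation_system <- function(corpus, lex, rules_text = starter_rules(),
                                  medsem_model = NULL,
                                  cfg = default_config()) {
  docs <- corpus$docs; anns <- corpus$anns
  insts <- unlist(lapply(names(docs), function(d) {
    build_classification_instances(docs[[d]], anns[[d]], for_training = TRUE)
  }), recursive = FALSE)
  fvs <- prepare_features(insts, docs, anns, lex, medsem_model, cfg)
  ctxs <- prepare_contexts(insts, docs, anns, fvs)
  rules <- parse_rules(rules_text)
  class_rules <- Filter(function(r)
    r$output %in% fine_relation_types(), rules)
  neg_rules <- Filter(function(r) r$output == no_relation(), rules)
  measured <- lapply(class_rules, measure_accuracy, contexts = ctxs)
  ruleset_all <- order_and_filter(measured, 0)
  ruleset_high <- order_and_filter(measured, cfg$rules$min_accuracy)
  rule_fvs <- lapply(seq_along(insts), function(k) {
    c(fvs[[k]], rules_as_features(class_rules, ctxs[[k]]))
  })
  models_plain <- train_specialized(insts, fvs, cfg$classifier)
  models_rf <- train_specialized(insts, rule_fvs, cfg$classifier)
  structure(list(rules = measured, neg_rules = neg_rules,
                 ruleset_all = ruleset_all, ruleset_high = ruleset_high,
                 models_plain = models_plain, models_rf = models_rf,
                 lex = lex, medsem_model = medsem_model, cfg = cfg),
            class = "relation_system")
}

architecture_modes <- function() {
  c("FEATURES", "ALL_RULES", "HIGH_ACC_RULES",
    "FEATURES_PLUS_RULE_FEATURES", "HYBRID")
}

#' Classify instances under one of the five system architectures
#'
#' `FEATURES`: classifier only.  `ALL_RULES` / `HIGH_ACC_RULES`:
#' first-applicable rule only; instances no rule fires on receive the
#' scheme's majority training label.  `FEATURES_PLUS_RULE_FEATURES`: the
#' classifier trained with rules as additional features.  `HYBRID`: the
#' label of the first firing high-accuracy (>= 0.75) rule, else the
#' rules-as-features classifier.
#'
#' @param system A `relation_system`.
#' @param insts Instances.
#' @param fvs,ctxs Their features and rule contexts.
#' @param arch One of [architecture_modes()].
#' @return Character vector of labels (fine types or `NO_RELATION`).
#' @export
classify_instances <- function(system, insts, fvs, ctxs,
                               arch = "HYBRID") {
  arch <- match.arg(arch, architecture_modes())
  schemes <- vapply(insts, function(p) p$scheme, "")
  n <- length(insts)
  out <- rep(NA_character_, n)
  class_rules <- Filter(function(r) r$output %in% fine_relation_types(),
                        system$rules)
  with_rule_features <- arch %in% c("FEATURES_PLUS_RULE_FEATURES", "HYBRID")
  models <- if (with_rule_features) system$models_rf else system$models_plain
  use_fvs <- if (with_rule_features) {
    lapply(seq_len(n), function(k) c(fvs[[k]],
                                     rules_as_features(class_rules, ctxs[[k]])))
  } else fvs
  majority_of <- function(sch) {
    m <- models[[sch]]
    if (!is.null(m$majority)) m$majority else no_relation()
  }
  if (arch %in% c("ALL_RULES", "HIGH_ACC_RULES")) {
    rs <- if (arch == "ALL_RULES") system$ruleset_all else system$ruleset_high
    for (k in seq_len(n)) {
      lab <- apply_first(rs, ctxs[[k]])
      out[k] <- if (lab == "NONE_APPLICABLE") majority_of(schemes[k]) else lab
    }
    return(out)
  }
  if (arch == "HYBRID") {
    for (k in seq_len(n)) {
      lab <- apply_first(system$ruleset_high, ctxs[[k]])
      if (lab != "NONE_APPLICABLE") out[k] <- lab
    }
  }
  todo <- which(is.na(out))
  for (sch in unique(schemes[todo])) {
    idx <- todo[schemes[todo] == sch]
    model <- models[[sch]]
    if (is.null(model)) {
      stop("configuration error: no model for scheme ", sch)
    }
    out[idx] <- predict_specialized(model, use_fvs[idx])
  }
  out
}

normalize_kernel <- function(K, self_row, self_col) {
  s1 <- ifelse(self_row <= 0, 1, self_row)
  s2 <- ifelse(self_col <= 0, 1, self_col)
  K / sqrt(outer(s1, s2))
}

#' Train a relation identifier for one scheme
#'
#' A binary SVM deciding HAS_RELATION versus NO_RELATION from one of three
#' instance representations: the flat one-hot feature vector under a
#' normalized linear kernel (`FLAT`), the simple expansion tree with entity
#' attributes substituted at the entity parent nodes under the convolution
#' tree kernel (`TREE`), or their mixture `alpha * K_flat + (1 - alpha) *
#' K_tree` (`COMPOSITE`).  Cross-sentence schemes have no spanning parse
#' tree, so TREE/COMPOSITE requests fall back to FLAT with a message.  The
#' decision is `signed_distance >= threshold`, threshold 0 by default.
#'
#' @param insts Labeled identification instances of one scheme.
#' @param fvs Their feature vectors.
#' @param docs,anns Named lists keyed by doc id.
#' @param mode `"FLAT"`, `"TREE"` or `"COMPOSITE"`.
#' @param cfg Identifier configuration.
#' @return An `identifier_model`.
#' @export
train_identifier <- function(insts, fvs, docs, anns, mode = "FLAT",
                             cfg = default_config()$identifier) {
  mode <- match.arg(mode, c("FLAT", "TREE", "COMPOSITE"))
  scheme <- insts[[1]]$scheme
  y <- vapply(insts, function(p) p$label, "")
  if (length(unique(y)) < 2L) {
    return(structure(list(scheme = scheme, constant = unique(y),
                          threshold = 0),
                     class = "identifier_model"))
  }
  if (mode != "FLAT" && !scheme %in% c("EE_INTRA", "ET_INTRA")) {
    message("scheme ", scheme, " is cross-sentence; identifier falls back ",
            "to FLAT features")
    mode <- "FLAT"
  }
  vocab <- build_feature_vocab(fvs)
  X <- encode_features(fvs, vocab)
  lin_self <- rowSums(X * X)
  Klin <- normalize_kernel(tcrossprod(X), lin_self, lin_self)
  trees <- NULL; tree_self <- NULL; Ktree <- NULL
  if (mode != "FLAT") {
    trees <- lapply(insts, function(p) {
      extract_simple_expansion_tree(p, docs[[p$doc]], anns[[p$doc]],
                                    replace_at = "parent")
    })
    Kt <- tree_kernel_matrix(trees, trees, cfg$lambda)
    tree_self <- diag(Kt)
    Ktree <- normalize_kernel(Kt, tree_self, tree_self)
  }
  K <- switch(mode,
              FLAT = Klin,
              TREE = Ktree,
              COMPOSITE = cfg$alpha * Klin + (1 - cfg$alpha) * Ktree)
  yy <- factor(y, levels = c("HAS_RELATION", no_relation()))
  m <- kernlab::ksvm(kernlab::as.kernelMatrix(K), yy, type = "C-svc",
                     C = cfg$C)
  dv <- kernlab::predict(m, kernlab::as.kernelMatrix(
    K[, kernlab::SVindex(m), drop = FALSE]), type = "decision")[, 1]
  sgn <- if (mean(dv[yy == "HAS_RELATION"]) >= mean(dv[yy != "HAS_RELATION"])) 1 else -1
  structure(list(scheme = scheme, mode = mode, vocab = vocab, X = X,
                 lin_self = lin_self, trees = trees, tree_self = tree_self,
                 svm = m, sign = sgn, alpha = cfg$alpha,
                 lambda = cfg$lambda, threshold = cfg$threshold),
            class = "identifier_model")
}

#' Signed identification distances for new instances
#' @param model An `identifier_model`.
#' @param insts Instances of the model's scheme.
#' @param fvs Their feature vectors.
#' @param docs,anns Named lists keyed by doc id.
#' @return Numeric vector of signed distances (HAS_RELATION side positive).
#' @export
identifier_decision_values <- function(model, insts, fvs, docs, anns) {
  if (!is.null(model$constant)) {
    return(rep(if (model$constant == "HAS_RELATION") Inf else -Inf,
               length(insts)))
  }
  X <- encode_features(fvs, model$vocab)
  self <- rowSums(X * X)
  Klin <- normalize_kernel(X %*% t(model$X), self, model$lin_self)
  K <- Klin
  if (model$mode != "FLAT") {
    trees <- lapply(insts, function(p) {
      extract_simple_expansion_tree(p, docs[[p$doc]], anns[[p$doc]],
                                    replace_at = "parent")
    })
    Kt <- tree_kernel_matrix(trees, model$trees, model$lambda)
    tself <- vapply(trees, function(t) tree_kernel(t, t, model$lambda), 0)
    Ktree <- normalize_kernel(Kt, tself, model$tree_self)
    K <- switch(model$mode, TREE = Ktree,
                COMPOSITE = model$alpha * Klin + (1 - model$alpha) * Ktree)
  }
  dv <- kernlab::predict(model$svm, kernlab::as.kernelMatrix(
    K[, kernlab::SVindex(model$svm), drop = FALSE]), type = "decision")[, 1]
  model$sign * dv
}

#' Train the identification stage (rules plus learned identifiers)
#'
#' Positive identification rules are the classification rules with their
#' outputs read as HAS_RELATION; negative rules come from the same rule
#' file.  Both are re-measured on identification instances and ordered by
#' accuracy.  One learned identifier is trained per scheme as fallback.
#'
#' @param corpus Corpus with named `docs`, `anns`.
#' @param system A trained `relation_system`.
#' @param cfg Full configuration.
#' @return An `identification_stage` with `ruleset`, `identifiers`,
#'   and the training instances' schemes.
#' @export
train_identification_stage <- function(corpus, system,
                                       cfg = default_config()) {
  docs <- corpus$docs; anns <- corpus$anns
  insts <- unlist(lapply(names(docs), function(d) {
    build_identification_instances(docs[[d]], anns[[d]], cfg$identifier,
                                   prune = cfg$identifier$prune)
  }), recursive = FALSE)
  fvs <- prepare_features(insts, docs, anns, system$lex,
                          system$medsem_model, cfg)
  ctxs <- prepare_contexts(insts, docs, anns, fvs)
  pos_rules <- lapply(
    Filter(function(r) r$output %in% fine_relation_types(), system$rules),
    function(r) { r$output <- "HAS_RELATION"; r$accuracy <- NA_real_; r })
  id_rules <- c(pos_rules, system$neg_rules)
  measured <- lapply(id_rules, measure_accuracy, contexts = ctxs)
  ruleset <- order_and_filter(measured, 0)
  schemes <- vapply(insts, function(p) p$scheme, "")
  identifiers <- list()
  for (sch in unique(schemes)) {
    idx <- which(schemes == sch)
    identifiers[[sch]] <- train_identifier(insts[idx], fvs[idx], docs, anns,
                                           mode = cfg$identifier$mode,
                                           cfg = cfg$identifier)
  }
  structure(list(ruleset = ruleset, identifiers = identifiers, cfg = cfg),
            class = "identification_stage")
}

identify_instances <- function(stage, insts, fvs, ctxs, docs, anns,
                               thresholds = NULL) {
  n <- length(insts)
  out <- rep(NA, n)
  for (k in seq_len(n)) {
    lab <- apply_first(stage$ruleset, ctxs[[k]])
    if (lab == "HAS_RELATION") out[k] <- TRUE
    else if (lab == no_relation()) out[k] <- FALSE
  }
  todo <- which(is.na(out))
  schemes <- vapply(insts, function(p) p$scheme, "")
  for (sch in unique(schemes[todo])) {
    idx <- todo[schemes[todo] == sch]
    model <- stage$identifiers[[sch]]
    if (is.null(model)) { out[idx] <- FALSE; next }
    thr <- if (!is.null(thresholds) && !is.null(thresholds[[sch]])) {
      thresholds[[sch]]
    } else model$threshold
    dv <- identifier_decision_values(model, insts[idx], fvs[idx], docs, anns)
    out[idx] <- dv >= thr
  }
  out
}

#' Run the full pipeline over a corpus
#'
#' Setting 1 classifies the gold-standard pair list of every document;
#' setting 2 first runs the identification stage over all candidate pairs
#' and classifies only the accepted ones.
#'
#' @param corpus Corpus with named `docs`, `anns`.
#' @param system A `relation_system`.
#' @param setting 1 or 2.
#' @param arch Architecture (see [architecture_modes()]).
#' @param stage An `identification_stage` (required for setting 2).
#' @param thresholds Optional per-scheme identification thresholds.
#' @param map3 Also return the broad-type mapping of the output.
#' @return A data frame of predicted links (`doc`, `from`, `to`,
#'   `relation`, `origin`); with `map3`, a list of `fine` and `broad`.
#' @export
run_pipeline <- function(corpus, system, setting = 1, arch = "HYBRID",
                         stage = NULL, thresholds = NULL, map3 = FALSE) {
  stopifnot(setting %in% c(1, 2))
  docs <- corpus$docs; anns <- corpus$anns
  cfg <- system$cfg
  all_links <- list()
  for (d in names(docs)) {
    doc <- docs[[d]]; ann <- anns[[d]]
    if (setting == 1) {
      insts <- gold_pair_instances(doc, ann)
    } else {
      if (is.null(stage)) {
        stop("configuration error: setting 2 requires an identification stage")
      }
      insts <- build_identification_instances(doc, ann, cfg$identifier,
                                              prune = FALSE)
    }
    if (!length(insts)) next
    fvs <- prepare_features(insts, docs, anns, system$lex,
                            system$medsem_model, cfg)
    ctxs <- prepare_contexts(insts, docs, anns, fvs)
    if (setting == 2) {
      keep <- identify_instances(stage, insts, fvs, ctxs, docs, anns,
                                 thresholds)
      insts <- insts[keep]; fvs <- fvs[keep]; ctxs <- ctxs[keep]
      if (!length(insts)) next
    }
    labels <- classify_instances(system, insts, fvs, ctxs, arch)
    keep <- labels %in% fine_relation_types()
    if (!any(keep)) next
    all_links[[d]] <- data.frame(
      doc = d,
      from = vapply(insts[keep], function(p) p$e1, ""),
      to = vapply(insts[keep], function(p) p$e2, ""),
      relation = labels[keep],
      origin = "CLASSIFIER",
      stringsAsFactors = FALSE)
  }
  fine <- if (length(all_links)) do.call(rbind, all_links) else
    cbind(doc = character(), empty_tlinks()[, -1])
  rownames(fine) <- NULL
  if (!map3) return(fine)
  list(fine = fine, broad = map_12_to_3(fine))
}

#' Text-ordered instances for a document's gold pair list
#'
#' Every gold fine-typed link becomes an instance ordered by text position
#' (labels inverted where needed) and routed to its scheme; unroutable
#' pairs are skipped with a message.
#'
#' @param doc,ann Document and annotations.
#' @return List of [instance_pair()]s.
#' @export
gold_pair_instances <- function(doc, ann) {
  ents <- entity_sent_map(doc, ann)
  tl <- gold_fine_links(doc)
  out <- list()
  for (i in seq_len(nrow(tl))) {
    ia <- match(tl$from[i], ents$id); ib <- match(tl$to[i], ents$id)
    lab <- tl$relation[i]
    if (ents$start[ia] > ents$start[ib]) {
      tmp <- ia; ia <- ib; ib <- tmp
      lab <- invert_relation(lab)
    }
    sch <- route_scheme(ents, ia, ib)
    if (is.na(sch)) {
      message("gold pair ", tl$from[i], "-", tl$to[i],
              " is not routable to a specialized classifier; skipped")
      next
    }
    out[[length(out) + 1L]] <- instance_pair(doc$id, ents$id[ia],
                                             ents$id[ib], sch, lab)
  }
  out
}

#' Tune identification thresholds on a development corpus
#'
#' For each specialized identifier independently, scans the signed
#' distances observed on the development instances (plus 0) and keeps the
#' threshold maximizing the downstream classification F-score (micro or
#' macro) of the full setting-2 pipeline.  Because 0 is always in the
#' grid, the tuned development F is never below the untuned one.
#'
#' @param corpus_dev Development corpus with gold links.
#' @param system A `relation_system`.
#' @param stage An `identification_stage`.
#' @param arch Architecture used downstream.
#' @param objective `"micro"` or `"macro"`.
#' @return Named list of thresholds by scheme.
#' @export
tune_thresholds <- function(corpus_dev, system, stage, arch = "HYBRID",
                            objective = c("micro", "macro")) {
  objective <- match.arg(objective)
  docs <- corpus_dev$docs; anns <- corpus_dev$anns
  gold <- corpus_gold_links(corpus_dev)
  insts <- unlist(lapply(names(docs), function(d) {
    build_identification_instances(docs[[d]], anns[[d]],
                                   system$cfg$identifier, prune = FALSE)
  }), recursive = FALSE)
  if (!length(insts)) {
    warning("no development instances; thresholds stay 0")
    return(lapply(stage$identifiers, function(m) m$threshold))
  }
  fvs <- prepare_features(insts, docs, anns, system$lex,
                          system$medsem_model, system$cfg)
  ctxs <- prepare_contexts(insts, docs, anns, fvs)
  schemes <- vapply(insts, function(p) p$scheme, "")
  # identification rule decisions (TRUE/FALSE/NA), fixed across thresholds
  rule_dec <- rep(NA, length(insts))
  for (k in seq_along(insts)) {
    lab <- apply_first(stage$ruleset, ctxs[[k]])
    if (lab == "HAS_RELATION") rule_dec[k] <- TRUE
    else if (lab == no_relation()) rule_dec[k] <- FALSE
  }
  # signed distances per scheme, fixed across thresholds
  dv <- rep(-Inf, length(insts))
  for (sch in unique(schemes)) {
    idx <- which(schemes == sch)
    model <- stage$identifiers[[sch]]
    if (is.null(model)) next
    dv[idx] <- identifier_decision_values(model, insts[idx], fvs[idx],
                                          docs, anns)
  }
  # classification labels for every candidate, fixed across thresholds
  labels <- classify_instances(system, insts, fvs, ctxs, arch)
  score_of <- function(thresholds) {
    thr <- vapply(schemes, function(s) {
      t0 <- thresholds[[s]]
      if (is.null(t0)) 0 else t0
    }, 0)
    keep <- ifelse(is.na(rule_dec), dv >= thr, rule_dec)
    keep <- keep & labels %in% fine_relation_types()
    pred <- data.frame(
      doc = vapply(insts[keep], function(p) p$doc, ""),
      from = vapply(insts[keep], function(p) p$e1, ""),
      to = vapply(insts[keep], function(p) p$e2, ""),
      relation = labels[keep], stringsAsFactors = FALSE)
    rep <- suppressMessages(score_12class(pred, gold))
    if (objective == "micro") rep$micro$f else rep$macro_f
  }
  thresholds <- lapply(stage$identifiers, function(m) m$threshold)
  for (sch in names(stage$identifiers)) {
    model <- stage$identifiers[[sch]]
    if (!is.null(model$constant)) next
    dvs <- dv[schemes == sch & is.na(rule_dec) & is.finite(dv)]
    if (!length(dvs)) {
      warning("no development decision values for scheme ", sch,
              "; threshold stays at its default")
      next
    }
    grid <- sort(unique(c(model$threshold, dvs, max(dvs) + 1e-6)))
    best <- thresholds[[sch]]; best_f <- -1
    for (thr in grid) {
      cand <- thresholds; cand[[sch]] <- thr
      f <- score_of(cand)
      if (f > best_f) { best_f <- f; best <- thr }
    }
    thresholds[[sch]] <- best
  }
  thresholds
}

#' All gold fine-typed links of a corpus as one data frame
#' @param corpus Corpus with named `docs`.
#' @return Data frame with `doc`, `from`, `to`, `relation`.
#' @export
corpus_gold_links <- function(corpus) {
  out <- lapply(names(corpus$docs), function(d) {
    tl <- gold_fine_links(corpus$docs[[d]])
    if (!nrow(tl)) return(NULL)
    cbind(doc = d, tl[, c("from", "to", "relation")])
  })
  out <- out[!vapply(out, is.null, TRUE)]
  if (!length(out)) {
    return(data.frame(doc = character(), from = character(),
                      to = character(), relation = character(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
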