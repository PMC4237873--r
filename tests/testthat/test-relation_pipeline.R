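three_event_doc <- function() {
  txt <- "alpha helped beta calmed gamma."
  ev <- data.frame(id = c("A", "B", "C"),
                   start = c(0L, 13L, 25L), end = c(5L, 17L, 30L),
                   text = c("alpha", "beta", "gamma"),
                   type = "PROBLEM", polarity = "POS", modality = "FACTUAL",
                   stringsAsFactors = FALSE)
  tl <- data.frame(id = "L1", from = "A", to = "C", relation = "Before",
                   origin = "GOLD", stringsAsFactors = FALSE)
  doc <- clinical_document("t3", txt, events = ev, tlinks = tl)
  list(doc = doc, ann = fallback_annotate(doc))
}

test_that("intra-sentence instance creation uses the adjacency rule", {
  fx <- three_event_doc()
  insts <- build_classification_instances(fx$doc, fx$ann,
                                          for_training = TRUE)
  key <- vapply(insts, function(p) paste(p$e1, p$e2, p$label), "")
  expect_setequal(key, c("A C Before", "A B NO_RELATION",
                         "B C NO_RELATION"))
  # test mode: instances created the same way as the negatives
  test_insts <- build_classification_instances(fx$doc, fx$ann,
                                               for_training = FALSE)
  tkey <- vapply(test_insts, function(p) paste(p$e1, p$e2), "")
  expect_setequal(tkey, c("A B", "B C"))
})

test_that("adjacent-sentence pairs route by kind and coreference by head", {
  co <- generate_corpus(19, 1, sentences_per_doc = 8)
  doc <- co$docs[[1]]; ann <- co$anns[[1]]
  insts <- build_classification_instances(doc, ann, for_training = TRUE)
  schemes <- vapply(insts, function(p) p$scheme, "")
  expect_true(all(schemes %in% pair_schemes()))
  # no event-time pair is ever routed to the adjacent-sentence scheme
  for (p in insts[schemes == "EE_ADJACENT"]) {
    expect_true(p$e1 %in% doc$events$id && p$e2 %in% doc$events$id)
  }
  # coreferent pairs several sentences apart are instances
  for (p in insts[schemes == "EE_COREF"]) {
    e1 <- get_entity(doc, p$e1); e2 <- get_entity(doc, p$e2)
    h1 <- tolower(head_token(e1, ann)$lemma)
    h2 <- tolower(head_token(e2, ann)$lemma)
    expect_equal(h1, h2)
  }
})

test_that("a single-class training set yields a constant predictor", {
  fx <- three_event_doc()
  insts <- list(instance_pair("t3", "A", "C", "EE_INTRA", "Before"),
                instance_pair("t3", "A", "B", "EE_INTRA", "Before"))
  fvs <- lapply(insts, function(p)
    extract_features(p, fx$doc, fx$ann, lexicon_set()))
  models <- suppressWarnings(train_specialized(insts, fvs))
  out <- classify_instances(
    structure(list(models_plain = models, models_rf = models,
                   rules = list(), ruleset_all = structure(list(), class = "ruleset"),
                   ruleset_high = structure(list(), class = "ruleset"),
                   cfg = default_config()),
              class = "relation_system"),
    insts, fvs, lapply(seq_along(insts), function(k)
      build_rule_context(insts[[k]], fx$doc, fx$ann, fvs[[k]])),
    arch = "FEATURES")
  expect_equal(out, c("Before", "Before"))
})

test_that("training is deterministic under a fixed seed and configuration", {
  co <- fix_corpus()
  sys <- fix_system()
  pred_a <- run_pipeline(co, sys, setting = 1, arch = "FEATURES")
  pred_b <- run_pipeline(co, sys, setting = 1, arch = "FEATURES")
  expect_identical(pred_a, pred_b)
})

test_that("identification instances label gold pairs positive and prune", {
  co <- fix_corpus()
  d <- names(co$docs)[1]
  insts <- build_identification_instances(co$docs[[d]], co$anns[[d]],
                                          prune = FALSE)
  labs <- vapply(insts, function(p) p$label, "")
  keys <- vapply(insts, function(p) paste(p$e1, p$e2), "")
  gold <- co$docs[[d]]$tlinks
  for (i in seq_len(nrow(gold))) {
    k <- which(keys %in% c(paste(gold$from[i], gold$to[i]),
                           paste(gold$to[i], gold$from[i])))
    expect_true(length(k) == 1L && labs[k] == "HAS_RELATION")
  }
  # pruning never drops positives and never increases the instance count
  pruned <- build_identification_instances(co$docs[[d]], co$anns[[d]],
                                           prune = TRUE)
  expect_lte(length(pruned), length(insts))
  plabs <- vapply(pruned, function(p) p$label, "")
  expect_equal(sum(plabs == "HAS_RELATION"), sum(labs == "HAS_RELATION"))
})

test_that("composite kernels degenerate to their pure components", {
  co <- fix_corpus()
  docs <- co$docs; anns <- co$anns
  insts <- unlist(lapply(names(docs)[1:4], function(d) {
    build_identification_instances(docs[[d]], anns[[d]], prune = FALSE)
  }), recursive = FALSE)
  insts <- Filter(function(p) p$scheme == "EE_INTRA", insts)
  fvs <- prepare_features(insts, docs, anns, co$lex, NULL, default_config())
  cfg <- default_config()$identifier
  cfg1 <- cfg; cfg1$alpha <- 1; cfg1$mode <- "COMPOSITE"
  cfg0 <- cfg; cfg0$alpha <- 0; cfg0$mode <- "COMPOSITE"
  m_flat <- train_identifier(insts, fvs, docs, anns, "FLAT", cfg)
  m_tree <- train_identifier(insts, fvs, docs, anns, "TREE", cfg)
  m_c1 <- train_identifier(insts, fvs, docs, anns, "COMPOSITE", cfg1)
  m_c0 <- train_identifier(insts, fvs, docs, anns, "COMPOSITE", cfg0)
  dv <- function(m) identifier_decision_values(m, insts, fvs, docs, anns)
  if (is.null(m_flat$constant)) {
    expect_equal(dv(m_c1) >= 0, dv(m_flat) >= 0)
    expect_equal(dv(m_c0) >= 0, dv(m_tree) >= 0)
  } else {
    expect_identical(m_c1$constant, m_flat$constant)
  }
})

test_that("identifier kernel matrices are symmetric positive semidefinite", {
  co <- fix_corpus()
  docs <- co$docs; anns <- co$anns
  insts <- unlist(lapply(names(docs)[1:3], function(d) {
    build_identification_instances(docs[[d]], anns[[d]], prune = FALSE)
  }), recursive = FALSE)
  insts <- Filter(function(p) p$scheme == "EE_INTRA", insts)[1:12]
  trees <- lapply(insts, function(p) {
    extract_simple_expansion_tree(p, docs[[p$doc]], anns[[p$doc]],
                                  replace_at = "parent")
  })
  K <- tree_kernel_matrix(trees, trees, 0.4)
  expect_equal(K, t(K), tolerance = 1e-10)
  ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev > -1e-8 * max(abs(ev))))
})

test_that("architecture precedence and fallback behave as specified", {
  co <- fix_corpus()
  sys <- fix_system()
  docs <- co$docs; anns <- co$anns
  d <- names(docs)[1]
  insts <- gold_pair_instances(docs[[d]], anns[[d]])
  fvs <- prepare_features(insts, docs, anns, sys$lex, sys$medsem_model,
                          sys$cfg)
  ctxs <- prepare_contexts(insts, docs, anns, fvs)
  hybrid <- classify_instances(sys, insts, fvs, ctxs, "HYBRID")
  rf <- classify_instances(sys, insts, fvs, ctxs,
                           "FEATURES_PLUS_RULE_FEATURES")
  fired <- vapply(ctxs, function(c0)
    apply_first(sys$ruleset_high, c0), "")
  # where a high-accuracy rule fires, HYBRID returns the rule's label
  expect_equal(hybrid[fired != "NONE_APPLICABLE"],
               fired[fired != "NONE_APPLICABLE"])
  # where none fires, HYBRID equals the rules-as-features classifier
  expect_equal(hybrid[fired == "NONE_APPLICABLE"],
               rf[fired == "NONE_APPLICABLE"])
  # pure-rule output equals first-match application everywhere it fires
  all_rules <- classify_instances(sys, insts, fvs, ctxs, "ALL_RULES")
  fired_all <- vapply(ctxs, function(c0)
    apply_first(sys$ruleset_all, c0), "")
  expect_equal(all_rules[fired_all != "NONE_APPLICABLE"],
               fired_all[fired_all != "NONE_APPLICABLE"])
})

test_that("setting-2 output pairs are a subset of identified candidates", {
  co <- fix_corpus()
  sys <- fix_system()
  stage <- fix_stage()
  pred <- run_pipeline(co, sys, setting = 2, arch = "HYBRID", stage = stage)
  for (d in unique(pred$doc)) {
    cand <- build_identification_instances(co$docs[[d]], co$anns[[d]],
                                           prune = FALSE)
    ckeys <- vapply(cand, function(p) paste(p$e1, p$e2), "")
    sub <- pred[pred$doc == d, ]
    expect_true(all(paste(sub$from, sub$to) %in% ckeys))
  }
})

test_that("setting-2 scores never beat setting-1 on the same corpus", {
  co <- fix_corpus()
  sys <- fix_system()
  gold <- corpus_gold_links(co)
  f1 <- suppressMessages(score_12class(
    run_pipeline(co, sys, setting = 1, arch = "HYBRID"), gold))$micro$f
  f2 <- suppressMessages(score_12class(
    run_pipeline(co, sys, setting = 2, arch = "HYBRID",
                 stage = fix_stage()), gold))$micro$f
  expect_lte(f2, f1 + 1e-12)
})

test_that("setting 1 with the hybrid system reproduces the gold links", {
  co <- fix_corpus()
  pred <- run_pipeline(co, fix_system(), setting = 1, arch = "HYBRID")
  gold <- corpus_gold_links(co)
  rep <- suppressMessages(score_12class(pred, gold))
  expect_equal(rep$micro$f, 1)
  # every output pair appears among the document's candidate pairs
  for (d in unique(pred$doc)) {
    ents <- c(co$docs[[d]]$events$id, co$docs[[d]]$times$id)
    sub <- pred[pred$doc == d, ]
    expect_true(all(sub$from %in% ents) && all(sub$to %in% ents))
  }
})
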