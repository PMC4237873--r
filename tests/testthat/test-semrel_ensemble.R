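mk_bank <- function(labels, seqs3 = NULL) {
  n <- length(labels)
  if (is.null(seqs3)) seqs3 <- replicate(n, c("x"), simplify = FALSE)
  list(seqs = list(seqs3, seqs3, seqs3, seqs3, seqs3), labels = labels)
}

test_that("nearest-neighbour voting uses the 0.5 / 0.5(k-1) weighting", {
  # 200 neighbours all of one class
  bank <- mk_bank(rep("TeRP", 200))
  v <- knn_probability_vector(c("x"), bank, k = 200L)
  expect_equal(unname(v["TeRP"]), 1)
  expect_equal(sum(v), 1)
  # nearest TrIP at distance 0, the other 199 at distance 1
  seqs <- c(list(c("x")), replicate(199, c("y"), simplify = FALSE))
  bank <- mk_bank(c("TrIP", rep("TeRP", 199)), seqs)
  v <- knn_probability_vector(c("x"), bank, k = 200L)
  expect_equal(unname(v["TrIP"]), 0.5)
  expect_equal(unname(v["TeRP"]), 199 * (0.5 / 199))
  # nearest TrIP, then 100 TeRP and 99 PIP
  seqs <- c(list(c("x")), replicate(199, c("y"), simplify = FALSE))
  bank <- mk_bank(c("TrIP", rep("TeRP", 100), rep("PIP", 99)), seqs)
  v <- knn_probability_vector(c("x"), bank, k = 200L)
  expect_equal(unname(v["TrIP"]), 0.5)
  expect_equal(unname(v["TeRP"]), 100 * 0.5 / 199)
  expect_equal(unname(v["PIP"]), 99 * 0.5 / 199)
  expect_equal(sum(v), 1, tolerance = 1e-12)
})

test_that("small banks rescale the remainder weights with a warning", {
  bank <- mk_bank(c("TrIP", "TeRP", "TeRP"),
                  list(c("x"), c("y"), c("y")))
  # first call in the session warns; weight split is 0.5 + 2 x 0.25
  v <- suppressWarnings(knn_probability_vector(c("x"), bank, k = 200L))
  expect_equal(unname(v["TrIP"]), 0.5)
  expect_equal(unname(v["TeRP"]), 0.5)
})

test_that("tie-breaking among equidistant neighbours is by training index", {
  seqs <- list(c("x"), c("x"))
  bank <- mk_bank(c("PIP", "TeRP"), seqs)
  v <- suppressWarnings(knn_probability_vector(c("x"), bank, k = 2L))
  expect_equal(unname(v["PIP"]), 0.5)   # earlier index is the nearest
  expect_equal(unname(v["TeRP"]), 0.5)
})

test_that("simple expansion trees match the definitional construction", {
  # siblings directly under one parent
  doc <- clinical_document(
    "s", "aspirin helped pain",
    events = data.frame(id = c("E0", "E1"), start = c(0L, 15L),
                        end = c(7L, 19L), text = c("aspirin", "pain"),
                        type = c("TREATMENT", "PROBLEM"), polarity = "POS",
                        modality = "FACTUAL", stringsAsFactors = FALSE))
  tk <- data.frame(i = 0:2, text = c("aspirin", "helped", "pain"),
                   lemma = c("aspirin", "help", "pain"),
                   pos = c("NN", "VBD", "NN"), chunk = c("B-NP", "B-VP", "B-NP"),
                   start = c(0L, 8L, 15L), end = c(7L, 14L, 19L), sent = 0L,
                   stringsAsFactors = FALSE)
  tree <- parse_penn("(S (NN aspirin) (VBD helped) (NN pain))")
  ann <- document_annotations(tk, list(tree))
  inst <- semrel_instance("s", "E0", "E1", 0L)
  se <- extract_simple_expansion_tree(inst, doc, ann)
  # parent S plus its three non-leaf children, with entity labels replaced
  expect_equal(nrow(se), 4L)
  expect_setequal(se$label, c("S", "TREATMENT", "VBD", "PROBLEM"))
  expect_equal(sum(se$parent == 0L), 1L)
})

test_that("expansion-tree node sets equal a brute-force construction", {
  set.seed(12)
  for (trial in 1:30) {
    n <- sample(4:7, 1)
    toks <- paste0("w", seq_len(n))
    tree <- parse_penn(rand_bracket(toks))
    txt <- paste(toks, collapse = " ")
    starts <- c(0L, cumsum(nchar(toks) + 1L))[seq_len(n)]
    pick <- sort(sample(seq_len(n), 2))
    doc <- clinical_document(
      "r", txt,
      events = data.frame(id = c("E0", "E1"), start = starts[pick],
                          end = starts[pick] + nchar(toks[pick]),
                          text = toks[pick], type = "PROBLEM",
                          polarity = "POS", modality = "FACTUAL",
                          stringsAsFactors = FALSE))
    tk <- data.frame(i = seq_len(n) - 1L, text = toks, lemma = toks,
                     pos = "NN", chunk = "O", start = starts,
                     end = starts + nchar(toks), sent = 0L,
                     stringsAsFactors = FALSE)
    ann <- document_annotations(tk, list(tree))
    se <- extract_simple_expansion_tree(
      semrel_instance("r", "E0", "E1", 0L), doc, ann)
    # brute force from the definition: shortest-path nodes (BFS oracle)
    # plus their immediate non-leaf children
    n1 <- tree_covering_node(tree, pick[1] - 1L)
    n2 <- tree_covering_node(tree, pick[2] - 1L)
    path <- bfs_path_oracle(tree, n1, n2)
    want <- unique(c(path, unlist(lapply(path, function(id) {
      kids <- tree$id[tree$parent == id]
      kids[is.na(tree$token[match(kids, tree$id)])]
    }))))
    expect_equal(nrow(se), length(want))
    # attribute replacement visible
    expect_true("PROBLEM" %in% se$label)
  }
})

test_that("the tree kernel is symmetric, label-sensitive and oracle-exact", {
  set.seed(77)
  for (trial in 1:25) {
    t1 <- rand_node_tree(sample(2:4, 1))
    t2 <- rand_node_tree(sample(2:4, 1))
    k12 <- tree_kernel(t1, t2, 0.4)
    expect_equal(k12, tree_kernel(t2, t1, 0.4))
    expect_gte(k12, 0)
    expect_equal(k12, tree_kernel_oracle(t1, t2, 0.4), tolerance = 1e-10)
    expect_gt(tree_kernel(t1, t1, 0.4), 0)
  }
  # disjoint label alphabets -> 0
  ta <- parse_penn("(A (B x) (C y))")
  tb <- parse_penn("(D (E x) (F y))")
  expect_equal(tree_kernel(ta, tb, 0.4), 0)
})

test_that("probability vectors sum to one everywhere", {
  sco <- fix_medsem_corpus()
  insts <- semrel_instances_from(sco)[1:12]
  m <- fix_medsem_model()
  pred <- suppressWarnings(predict_semrel(m, insts, sco$docs, sco$anns))
  for (mat in list(pred$probs, pred$P_tree, pred$P_flat, pred$P_knn)) {
    expect_true(all(abs(rowSums(mat) - 1) < 1e-9))
  }
})

test_that("degenerate ensemble weights reproduce the member classifiers", {
  sco <- fix_medsem_corpus()
  insts <- semrel_instances_from(sco)[1:15]
  m <- fix_medsem_model()
  pred <- suppressWarnings(predict_semrel(m, insts, sco$docs, sco$anns))
  for (w in list(c(tree = 1, flat = 0, knn = 0),
                 c(tree = 0, flat = 1, knn = 0),
                 c(tree = 0, flat = 0, knn = 1))) {
    single <- suppressWarnings(predict_semrel(m, insts, sco$docs, sco$anns,
                                              weights = w))
    member <- list(pred$P_tree, pred$P_flat, pred$P_knn)[[which(w == 1)]]
    expect_equal(single$labels,
                 medsem_types()[apply(member, 1, which.max)])
  }
})

test_that("identical member vectors pass through the combination", {
  p <- c(0.2, 0.3, 0.5)
  w <- default_config()$semrel$weights
  expect_equal(w[["tree"]] * p + w[["flat"]] * p + w[["knn"]] * p, p)
  # one-hot disagreement resolves to the flat member at weight 0.5
  d <- function(i) { v <- numeric(3); v[i] <- 1; v }
  comb <- w[["tree"]] * d(1) + w[["flat"]] * d(2) + w[["knn"]] * d(3)
  expect_equal(which.max(comb), 2L)
  expect_equal(max(comb), 0.5)
})

test_that("combination weights default to (0.4, 0.5, 0.1) via config", {
  w <- default_config()$semrel$weights
  expect_equal(unname(w[c("tree", "flat", "knn")]), c(0.4, 0.5, 0.1))
  expect_equal(unname(fix_medsem_model()$cfg$weights[c("tree", "flat", "knn")]),
               c(0.4, 0.5, 0.1))
  # a YAML override is honoured
  f <- tempfile(fileext = ".yaml")
  writeLines(c("semrel:", "  weights:", "    tree: 0.2", "    flat: 0.2",
               "    knn: 0.6"), f)
  cfg <- load_config(f)
  expect_equal(unname(cfg$semrel$weights[c("tree", "flat", "knn")]),
               c(0.2, 0.2, 0.6))
})

test_that("the ensemble is at least as accurate as each member on training data", {
  sco <- fix_medsem_corpus()
  insts <- semrel_instances_from(sco)
  gold <- vapply(insts, function(i) i$label, "")
  m <- fix_medsem_model()
  pred <- suppressWarnings(predict_semrel(m, insts, sco$docs, sco$anns))
  acc <- function(labels) mean(labels == gold)
  ens <- acc(pred$labels)
  for (mat in list(pred$P_tree, pred$P_flat, pred$P_knn)) {
    expect_gte(ens, acc(medsem_types()[apply(mat, 1, which.max)]))
  }
  expect_equal(suppressWarnings(
    evaluate_semrel(pred$labels, gold))$f, 1)
})

test_that("similarity percentages normalize and wiki features degrade", {
  sco <- fix_medsem_corpus()
  inst <- semrel_instances_from(sco)[[1]]
  doc <- sco$docs[[inst$doc]]; ann <- sco$anns[[inst$doc]]
  m <- fix_medsem_model()
  fv <- extract_semrel_flat(inst, doc, ann, sco$lex, m$bank, m$cfg$knn_k)
  for (meth in 1:5) {
    vals <- unlist(fv[paste0("sim.m", meth, ".", medsem_types())])
    expect_equal(sum(vals), 1, tolerance = 1e-12)
  }
  # empty offline link table: no matching article flagged, link flags zero
  fv0 <- extract_semrel_flat(inst, doc, ann, lexicon_set(), NULL)
  expect_equal(fv0$wik.no_article, 1)
  expect_equal(fv0$wik.link_e1_e2, 0)
  expect_equal(fv0$wik.link_e2_e1, 0)
  expect_equal(fv0$wik.links_both, 0)
})

test_that("positive-class micro scoring ignores correct no-relation calls", {
  pred <- c("TrIP", "TeRP", "NPP", "NPP", "PIP", "TeRP", "TrIP", "NTrP",
            "TeCP", "NPP")
  gold <- c("TrIP", "TeRP", "NPP", "PIP", "PIP", "TrAP", "NTeP", "NTrP",
            "TeCP", "NPP")
  # hand tally: tp = 4 (TrIP, TeRP, PIP, TeCP); predicted positive = 6;
  # gold positive = 6
  s <- evaluate_semrel(pred, gold)
  expect_equal(s$precision, 4 / 6)
  expect_equal(s$recall, 4 / 6)
  expect_equal(s$f, 2 * (4 / 6) * (4 / 6) / (8 / 6))
  expect_equal(evaluate_semrel(c("TrIP"), c("TrIP"))$f, 1)
  expect_warning(s0 <- evaluate_semrel(rep("NPP", 3), rep("NPP", 3)),
                 "positive")
  expect_equal(s0$f, 0)
})
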