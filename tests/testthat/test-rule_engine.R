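mk_ctx <- function(label = NA_character_, features = list(),
                   etype1 = "PROBLEM", etype2 = "TREATMENT",
                   scheme = "EE_INTRA", same_sentence = TRUE,
                   between = "", head1 = "a", head2 = "b") {
  list(etype1 = etype1, etype2 = etype2, scheme = scheme,
       same_sentence = same_sentence, head1 = head1, head2 = head2,
       features = features, between = between, label = label)
}

test_that("rule accuracy is correct count over applied count", {
  rules <- parse_rules("r1 := f('x') == 1 => Before")
  ctxs <- c(
    lapply(1:8, function(i) mk_ctx("Before", list(x = 1))),
    lapply(1:2, function(i) mk_ctx("After", list(x = 1))),
    lapply(1:5, function(i) mk_ctx("Before", list(x = 0))))
  r <- measure_accuracy(rules[[1]], ctxs)
  expect_equal(r$applied, 10L)
  expect_equal(r$correct, 8L)
  expect_equal(r$accuracy, 0.8)
  # brute-force per-instance tally
  fired <- vapply(ctxs, function(c0) isTRUE(c0$features$x == 1), TRUE)
  ok <- vapply(ctxs, function(c0)
    isTRUE(c0$features$x == 1) && identical(c0$label, "Before"), TRUE)
  expect_equal(r$accuracy, sum(ok) / sum(fired))
})

test_that("a never-applicable rule gets accuracy 0 and count 0", {
  rules <- parse_rules("r0 := f('missing') == 'z' => Overlap")
  r <- measure_accuracy(rules[[1]], lapply(1:5, function(i) mk_ctx("Overlap")))
  expect_equal(r$applied, 0L)
  expect_equal(r$accuracy, 0)
})

test_that("ordering and the 75% filter behave as specified", {
  lines <- c("ra := f('a') == 1 => Before",
             "rb := f('b') == 1 => After",
             "rc := f('c') == 1 => Overlap")
  rules <- parse_rules(lines)
  ctxs <- c(
    lapply(1:10, function(i) mk_ctx("Before", list(a = 1, b = 1, c = 1))),
    lapply(1:3, function(i) mk_ctx("After", list(b = 1))),
    lapply(1:10, function(i) mk_ctx("Overlap", list(a = 1, c = 1))))
  # ra: applied 20 correct 10 (0.5); rb: 13 applied 3+10 -> wait, recompute
  measured <- lapply(rules, measure_accuracy, contexts = ctxs)
  acc <- vapply(measured, function(r) r$accuracy, 0)
  names(acc) <- c("ra", "rb", "rc")
  expect_equal(unname(acc["ra"]), 0.5)  # fires 20x, 10 labeled Before
  # rb outputs After; gold is After in 3 of its 13 firings
  expect_equal(measured[[2]]$correct, 3L)
  expect_equal(unname(acc["rb"]), 3 / 13)
  expect_equal(unname(acc["rc"]), 0.5)
  ordered <- order_and_filter(measured, 0)
  expect_equal(vapply(ordered, function(r) r$id, ""), c("ra", "rc", "rb"))
  kept <- order_and_filter(measured, 0.5)
  expect_equal(vapply(kept, function(r) r$id, ""), c("ra", "rc"))
  # the canonical example: accuracies 0.9 / 0.75 / 0.6 at threshold 0.75
  fake <- lapply(list(c("x", 0.9), c("y", 0.75), c("z", 0.6)), function(s) {
    r <- parse_rules(paste0(s[1], " := f('q') == 1 => Before"))[[1]]
    r$accuracy <- as.numeric(s[2]); r$applied <- 10L; r
  })
  out <- order_and_filter(fake, 0.75)
  expect_equal(vapply(out, function(r) r$id, ""), c("x", "y"))
})

test_that("ordering is deterministic under input permutations", {
  set.seed(2)
  fake <- lapply(1:6, function(i) {
    r <- parse_rules(paste0("r", i, " := f('q') == 1 => Before"))[[1]]
    r$accuracy <- c(0.9, 0.9, 0.8, 0.8, 0.7, 0.6)[i]
    r$applied <- c(5L, 9L, 4L, 4L, 2L, 1L)[i]
    r
  })
  ref <- vapply(order_and_filter(fake, 0), function(r) r$id, "")
  for (k in 1:5) {
    perm <- sample(fake)
    expect_equal(vapply(order_and_filter(perm, 0), function(r) r$id, ""), ref)
  }
  # ties: higher applied count first, then id
  expect_equal(ref[1:2], c("r2", "r1"))
  expect_equal(ref[3:4], c("r3", "r4"))
})

test_that("first-match semantics select the highest-accuracy firing rule", {
  fake <- lapply(list(list("hi", 0.9, "Before"), list("lo", 0.8, "After")),
                 function(s) {
    r <- parse_rules(paste0(s[[1]], " := f('q') == 1 => ", s[[3]]))[[1]]
    r$accuracy <- s[[2]]; r$applied <- 10L; r
  })
  rs <- order_and_filter(fake, 0)
  expect_equal(apply_first(rs, mk_ctx(features = list(q = 1))), "Before")
  expect_equal(apply_first(rs, mk_ctx(features = list(q = 0))),
               "NONE_APPLICABLE")
  # a single always-true rule decides every instance
  always <- parse_rules("all := TRUE => Simultaneous")[[1]]
  always$accuracy <- 1; always$applied <- 1L
  rs1 <- order_and_filter(list(always), 0)
  for (ctx in list(mk_ctx(), mk_ctx(features = list(q = 5)),
                   mk_ctx(etype1 = "TEST"))) {
    expect_equal(apply_first(rs1, ctx), "Simultaneous")
  }
})

test_that("the treatment-improves-problem pattern yields Ended_By", {
  fx <- one_template_doc("t8")
  tl <- fx$doc$tlinks
  p <- instance_pair(fx$doc$id, tl$from[1], tl$to[1], "EE_INTRA",
                     label = tl$relation[1])
  fv <- suppressWarnings(extract_features(p, fx$doc, fx$ann,
                                          fixture_lexicons(),
                                          fix_medsem_model()))
  ctx <- build_rule_context(p, fx$doc, fx$ann, fv)
  measured <- lapply(
    Filter(function(r) r$output %in% fine_relation_types(),
           parse_rules(starter_rules())),
    function(r) { r$accuracy <- 1; r$applied <- 1L; r })
  expect_equal(apply_first(order_and_filter(measured, 0), ctx), "Ended_By")
})

test_that("rules-as-features values agree with per-rule evaluation", {
  rules <- parse_rules(c("p := f('a') == 1 => Before",
                         "q := f('b') == 'yes' => After"))
  ctx <- mk_ctx(features = list(a = 1, b = "no"))
  fv <- rules_as_features(rules, ctx)
  expect_equal(fv$rule.p, "Before")
  expect_true(is.na(fv$rule.q))
  # no rule applicable -> all NULL
  fv0 <- rules_as_features(rules, mk_ctx(features = list()))
  expect_true(all(is.na(unlist(fv0))))
  # filtered vs full rulesets agree on shared rules
  m <- lapply(rules, function(r) { r$accuracy <- c(0.9, 0.5)[match(r$id, c("p", "q"))]; r$applied <- 2L; r })
  full <- rules_as_features(order_and_filter(m, 0), ctx)
  high <- rules_as_features(order_and_filter(m, 0.75), ctx)
  expect_length(full, 2L)
  expect_length(high, 1L)
  expect_equal(high$rule.p, full$rule.p)
})

test_that("rule coverage is monotone non-increasing in the filter threshold", {
  lines <- c("ra := f('a') == 1 => Before",
             "rb := f('b') == 1 => After")
  rules <- parse_rules(lines)
  ctxs <- c(lapply(1:6, function(i) mk_ctx("Before", list(a = 1))),
            lapply(1:4, function(i) mk_ctx("Before", list(b = 1))))
  measured <- lapply(rules, measure_accuracy, contexts = ctxs)
  coverage <- function(t) {
    rs <- order_and_filter(measured, t)
    sum(vapply(ctxs, function(c0) apply_first(rs, c0) != "NONE_APPLICABLE",
               TRUE))
  }
  covs <- vapply(c(0, 0.5, 0.9, 1), coverage, 0)
  expect_true(all(diff(covs) <= 0))
})

test_that("the condition language refuses unknown symbols", {
  expect_error(parse_rules("bad := system('ls') => Before"), "not allowed")
  expect_error(parse_rules("bad := readLines('/etc/passwd') => Before"),
               "not allowed")
  expect_error(parse_rules("bad := f('x') => NotALabel"), "taxonomy")
  expect_error(parse_rules("nonsense line"), "cannot parse")
})
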