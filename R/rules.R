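#' Hand-crafted decision rules
#'
#' Rules are written in a small side-effect-free condition language over
#' feature names/values and entity attributes, one rule per line:
#'
#' ```
#' id := condition => LABEL        # comment
#' ```
#'
#' The condition is an R-syntax boolean expression restricted to a
#' whitelist: the variables `etype1`, `etype2`, `scheme`, `same_sentence`,
#' `head1`, `head2`; the helpers `f(name)` (feature value, `NA` if
#' missing), `has(name)` (feature present and non-NULL) and
#' `between(pattern)` (regular-expression test on the inter-entity text);
#' comparison and boolean operators; and literals.  Any other symbol is
#' rejected at parse time, so a rule file cannot execute arbitrary code.
#' `LABEL` is a fine relation type, or `HAS_RELATION` / `NO_RELATION` for
#' identification rules.
#'
#' Rule accuracy is the number of times the rule yields the correct
#' relation type divided by the number of times it applies, measured on
#' training instances; a ruleset is ordered by decreasing accuracy and a
#' new instance is classified by the first applicable rule.
#'
#' @name rule_engine
NULL

.rule_whitelist <- c(
  "etype1", "etype2", "scheme", "same_sentence", "head1", "head2",
  "f", "has", "between",
  "&", "|", "&&", "||", "!", "==", "!=", "<", ">", "<=", ">=",
  "(", "c", "%in%", "xor", "isTRUE", "is.na", "TRUE", "FALSE", "NA")

check_rule_expr <- function(expr) {
  walk <- function(e) {
    if (is.symbol(e)) {
      s <- as.character(e)
      if (!s %in% .rule_whitelist) {
        stop("rule DSL error: symbol '", s, "' is not allowed")
      }
    } else if (is.call(e)) {
      lapply(as.list(e), walk)
    } else if (!(is.character(e) || is.numeric(e) || is.logical(e))) {
      stop("rule DSL error: unsupported literal in condition")
    }
    invisible(NULL)
  }
  walk(expr)
  expr
}

#' Parse rules from text lines or a rule file
#'
#' @param x Either a file path or a character vector of rule lines.
#' @return A list of `rule` objects with fields `id`, `condition`
#'   (unevaluated expression), `output`, `accuracy` (`NA` until measured),
#'   `applied`, `correct`.
#' @export
parse_rules <- function(x) {
  lines <- if (length(x) == 1L && file.exists(x)) readLines(x, warn = FALSE) else x
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  lapply(lines, function(ln) {
    m <- regexec("^([A-Za-z0-9_.-]+)\\s*:=\\s*(.*\\S)\\s*=>\\s*([A-Za-z0-9_]+)$", ln)
    g <- regmatches(ln, m)[[1]]
    if (length(g) != 4L) stop("rule DSL error: cannot parse line: ", ln)
    out <- g[4]
    if (!out %in% c(fine_relation_types(), "HAS_RELATION", no_relation())) {
      stop("taxonomy error: unknown rule output label ", out)
    }
    expr <- check_rule_expr(str2lang(g[3]))
    structure(list(id = g[2], condition = expr, condition_str = g[3],
                   output = out, accuracy = NA_real_, applied = 0L,
                   correct = 0L),
              class = "rule")
  })
}

#' Build the evaluation context a rule condition sees for one instance
#'
#' @param p An [instance_pair()].
#' @param doc,ann Document and annotations.
#' @param features Extracted feature vector for the instance.
#' @return A `rule_context` environment-backed list.
#' @export
build_rule_context <- function(p, doc, ann, features) {
  e1 <- get_entity(doc, p$e1); e2 <- get_entity(doc, p$e2)
  list(
    etype1 = e1$type, etype2 = e2$type, scheme = p$scheme,
    same_sentence = isTRUE(features$dist.same_sentence == 1),
    head1 = tolower(head_token(e1, ann)$text),
    head2 = tolower(head_token(e2, ann)$text),
    features = features,
    between = between_text(e1, e2, doc),
    label = p$label
  )
}

rule_applies <- function(rule, ctx) {
  env <- new.env(parent = baseenv())
  env$etype1 <- ctx$etype1; env$etype2 <- ctx$etype2
  env$scheme <- ctx$scheme; env$same_sentence <- ctx$same_sentence
  env$head1 <- ctx$head1; env$head2 <- ctx$head2
  feats <- ctx$features
  env$f <- function(name) {
    v <- feats[[name]]
    if (is.null(v)) NA else v
  }
  env$has <- function(name) {
    v <- feats[[name]]
    !is.null(v) && !all(is.na(v))
  }
  btw <- ctx$between
  env$between <- function(pattern) grepl(pattern, btw)
  isTRUE(eval(rule$condition, env))
}

#' Measure a rule's accuracy on labeled instances
#'
#' @param rule A `rule`.
#' @param contexts List of `rule_context`s for labeled instances (their
#'   `label` field is the gold answer; for identification rules any fine
#'   label counts as `HAS_RELATION`).
#' @return The rule with `accuracy`, `applied` and `correct` filled in; a
#'   never-applicable rule gets accuracy 0.  A rule whose condition errors
#'   is flagged invalid (`accuracy` `NA`, attribute `invalid`).
#' @export
measure_accuracy <- function(rule, contexts) {
  applied <- 0L; correct <- 0L
  for (ctx in contexts) {
    fired <- tryCatch(rule_applies(rule, ctx), error = function(e) {
      message("rule ", rule$id, " invalid: ", conditionMessage(e))
      NA
    })
    if (is.na(fired)) {
      rule$accuracy <- NA_real_
      attr(rule, "invalid") <- TRUE
      return(rule)
    }
    if (fired) {
      applied <- applied + 1L
      gold <- ctx$label
      if (rule$output %in% c("HAS_RELATION", no_relation())) {
        gold_id <- if (!is.na(gold) &&
                       (gold == "HAS_RELATION" ||
                          gold %in% fine_relation_types())) {
          "HAS_RELATION"
        } else no_relation()
        if (identical(rule$output, gold_id)) correct <- correct + 1L
      } else if (identical(rule$output, gold)) {
        correct <- correct + 1L
      }
    }
  }
  rule$applied <- applied; rule$correct <- correct
  rule$accuracy <- if (applied) correct / applied else 0
  rule
}

#' Order rules by accuracy and filter by a minimum accuracy
#'
#' Descending measured accuracy; ties broken by larger applied count, then
#' lexicographic id.  When `min_accuracy > 0`, rules below it are removed.
#'
#' @param rules List of measured `rule`s.
#' @param min_accuracy Threshold in \[0, 1\] (default 0: keep all).
#' @return A `ruleset` (ordered list of rules).
#' @export
order_and_filter <- function(rules, min_accuracy = 0) {
  rules <- Filter(function(r) !isTRUE(attr(r, "invalid")), rules)
  if (any(vapply(rules, function(r) is.na(r$accuracy), TRUE))) {
    stop("rules must be measured before ordering")
  }
  acc <- vapply(rules, function(r) r$accuracy, 0)
  app <- vapply(rules, function(r) r$applied, 0L)
  ids <- vapply(rules, function(r) r$id, "")
  ord <- order(-acc, -app, ids)
  rules <- rules[ord]
  if (min_accuracy > 0) {
    rules <- Filter(function(r) r$accuracy >= min_accuracy, rules)
  }
  structure(rules, class = "ruleset")
}

#' Classify an instance with the first applicable rule
#'
#' @param ruleset A `ruleset` from [order_and_filter()].
#' @param ctx A `rule_context`.
#' @return The first firing rule's output label, or `"NONE_APPLICABLE"`.
#' @export
apply_first <- function(ruleset, ctx) {
  for (rule in ruleset) {
    fired <- tryCatch(rule_applies(rule, ctx), error = function(e) FALSE)
    if (isTRUE(fired)) return(rule$output)
  }
  "NONE_APPLICABLE"
}

#' Rules as features
#'
#' One categorical feature per rule (all rules, regardless of accuracy):
#' the rule's predicted label when its condition holds, NULL otherwise.
#'
#' @param rules List of `rule`s (need not be measured).
#' @param ctx A `rule_context`.
#' @return A feature vector with names `rule.<id>`.
#' @export
rules_as_features <- function(rules, ctx) {
  fv <- list()
  for (rule in rules) {
    fired <- tryCatch(rule_applies(rule, ctx), error = function(e) FALSE)
    fv[[paste0("rule.", rule$id)]] <-
      if (isTRUE(fired)) rule$output else NA_character_
  }
  fv
}

#' The starter temporal-relation ruleset
#'
#' Encodes the worked decision rules that motivate each novel feature
#' family: the antonym-plus-"but" asynchrony rule, the destination-argument
#' rule, the restatement and asynchronous-connective discourse rules, the
#' five medical semantic-relation rules, and two negative identification
#' rules for unlinked inter-sentence pair schemes.
#'
#' @return Character vector of rule lines (parseable by [parse_rules()]).
#' @export
starter_rules <- function() {
  c(
    "antonym_but := same_sentence & (f('thes.e1_in_e2_antonyms') == 1 | f('thes.e2_in_e1_antonyms') == 1) & between('\\\\bbut\\\\b') => Before",
    "srl_destination := f('srl.e1_pred_e2_A4') == 1 => Begins",
    "disc_restatement := f('disc.implicit_e1a1_e2a2') == 'Restatement' & etype1 == 'PROBLEM' & etype2 == 'PROBLEM' => Overlap",
    "disc_thereafter := f('disc.explicit_e1a1_e2a2') == 'Asynchronous' & f('disc.connective') == 'thereafter' => Before",
    "med_trip := f('med.pred') == 'TrIP' => Ended_By",
    "med_tecp := f('med.pred') == 'TeCP' => Overlap_After",
    "med_pip := f('med.pred') == 'PIP' => Simultaneous",
    "med_terp_due := f('med.pred') == 'TeRP' & between('due to') => Overlap_After",
    "med_npp_series := f('med.pred') == 'NPP' & etype1 == 'PROBLEM' & etype2 == 'PROBLEM' & between(',') => Overlap",
    "neg_adjacent := scheme == 'EE_ADJACENT' & !has('disc.implicit_e1a1_e2a2') & !has('disc.explicit_e1a1_e2a2') => NO_RELATION",
    "neg_coref := scheme == 'EE_COREF' => NO_RELATION"
  )
}
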