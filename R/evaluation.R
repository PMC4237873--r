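#' Scoring temporal-relation output
#'
#' Two protocols are provided.  For classification over the 12 fine types,
#' micro precision/recall/F over all instances and macro F (the unweighted
#' mean of the 12 per-class F-scores); a predicted link matches a gold link
#' when its endpoints match directly, or in reversed order with the inverse
#' label.  For the shared-task style 3-class protocol, links are mapped to
#' broad types and scored against the deductive closure: system precision
#' is the fraction of system links verifiable in the gold closure, recall
#' the fraction of gold links verifiable in the system closure.
#'
#' @name evaluation
NULL

canonical_links <- function(links) {
  # reduce each link to a direction-canonical form: endpoint pair ordered
  # lexicographically, label inverted when the order is swapped
  if (!nrow(links)) {
    return(data.frame(pair = character(), label = character(),
                      stringsAsFactors = FALSE))
  }
  rel <- normalize_relation(links$relation)
  swap <- links$from > links$to
  a <- ifelse(swap, links$to, links$from)
  b <- ifelse(swap, links$from, links$to)
  lab <- ifelse(swap, invert_relation(rel), rel)
  data.frame(pair = paste(a, b, sep = "\r"), label = lab,
             stringsAsFactors = FALSE)
}

#' Micro and macro scores for 12-class relation classification
#'
#' @param pred,gold TLINK data frames (columns `from`, `to`, `relation`
#'   with fine types; a `doc` column, if present, is folded into the pair
#'   key so identical ids in different documents do not collide).
#' @return A `score_report` list: `micro` (precision, recall, f), `macro_f`,
#'   `per_class` (P/R/F for each of the 12 fine types), and `confusion`
#'   (fine types plus a NO_RELATION margin for unmatched pairs).
#' @export
score_12class <- function(pred, gold) {
  key_prefix <- function(df) {
    if ("doc" %in% names(df) && nrow(df)) paste0(df$doc, "\r") else ""
  }
  cp <- canonical_links(pred); cp$pair <- paste0(key_prefix(pred), cp$pair)
  cg <- canonical_links(gold); cg$pair <- paste0(key_prefix(gold), cg$pair)
  if (anyDuplicated(cp$pair)) {
    message("duplicate predicted links for ",
            sum(duplicated(cp$pair)), " pair(s); scored once")
    cp <- cp[!duplicated(cp$pair), , drop = FALSE]
  }
  cg <- cg[!duplicated(cg$pair), , drop = FALSE]
  classes <- fine_relation_types()
  gold_lab <- stats::setNames(cg$label, cg$pair)
  pred_lab <- stats::setNames(cp$label, cp$pair)
  all_pairs <- union(cg$pair, cp$pair)
  g <- gold_lab[all_pairs]; p <- pred_lab[all_pairs]
  g[is.na(g)] <- no_relation(); p[is.na(p)] <- no_relation()
  lev <- c(classes, no_relation())
  confusion <- table(gold = factor(g, lev), pred = factor(p, lev))
  tp <- sum(g == p & g != no_relation())
  npred <- nrow(cp); ngold <- nrow(cg)
  mp <- if (npred) tp / npred else 0
  mr <- if (ngold) tp / ngold else 0
  mf <- if (mp + mr > 0) 2 * mp * mr / (mp + mr) else 0
  per_class <- do.call(rbind, lapply(classes, function(cls) {
    ctp <- sum(g == cls & p == cls)
    cp_n <- sum(p == cls); cg_n <- sum(g == cls)
    pp <- if (cp_n) ctp / cp_n else 0
    rr <- if (cg_n) ctp / cg_n else 0
    ff <- if (pp + rr > 0) 2 * pp * rr / (pp + rr) else 0
    data.frame(class = cls, precision = pp, recall = rr, f = ff,
               support = cg_n, stringsAsFactors = FALSE)
  }))
  absent <- per_class$class[per_class$support == 0]
  if (length(absent)) {
    message("macro F averages over all 12 classes; absent in gold: ",
            paste(absent, collapse = ", "))
  }
  structure(list(micro = list(precision = mp, recall = mr, f = mf),
                 macro_f = mean(per_class$f), per_class = per_class,
                 confusion = confusion),
            class = "score_report")
}

#' Deductive closure of broad-type temporal assertions
#'
#' Seeds are augmented with their inverses (`BEFORE3` <-> `AFTER3`,
#' `OVERLAP3` symmetric) and with the transitive compositions of `BEFORE3`
#' chains (and hence `AFTER3` chains), iterated to a fixed point.  Only
#' sound rules over the three broad types are applied; no
#' overlap-with-precedence composition is inferred.  Contradictory seeds
#' are retained: the scorer is containment-based.
#'
#' @param links Data frame with columns `from`, `to`, `relation` (broad
#'   types).
#' @return A `closure_graph`: data frame of unique broad assertions
#'   containing its seeds.
#' @export
close_links <- function(links) {
  stopifnot(all(links$relation %in% broad_relation_types()))
  seen <- new.env(hash = TRUE, parent = emptyenv())
  key <- function(a, b, r) paste(a, b, r, sep = "\r")
  out_from <- character(); out_to <- character(); out_rel <- character()
  add <- function(a, b, r) {
    k <- key(a, b, r)
    if (!is.null(seen[[k]])) return(FALSE)
    assign(k, TRUE, envir = seen)
    out_from[[length(out_from) + 1L]] <<- a
    out_to[[length(out_to) + 1L]] <<- b
    out_rel[[length(out_rel) + 1L]] <<- r
    TRUE
  }
  for (i in seq_len(nrow(links))) {
    add(links$from[i], links$to[i], links$relation[i])
  }
  repeat {
    changed <- FALSE
    n <- length(out_from)
    # inverse augmentation
    for (i in seq_len(n)) {
      r <- out_rel[i]
      inv <- switch(r, BEFORE3 = "AFTER3", AFTER3 = "BEFORE3",
                    OVERLAP3 = "OVERLAP3")
      if (add(out_to[i], out_from[i], inv)) changed <- TRUE
    }
    # transitive BEFORE3 chains
    n <- length(out_from)
    bi <- which(out_rel == "BEFORE3")
    for (i in bi) {
      js <- bi[out_from[bi] == out_to[i]]
      for (j in js) {
        if (out_from[i] != out_to[j] &&
            add(out_from[i], out_to[j], "BEFORE3")) changed <- TRUE
      }
    }
    if (!changed) break
  }
  structure(data.frame(from = out_from, to = out_to, relation = out_rel,
                       stringsAsFactors = FALSE),
            class = c("closure_graph", "data.frame"))
}

in_closure <- function(links, closure) {
  if (!nrow(links)) return(logical())
  key <- paste(links$from, links$to, links$relation, sep = "\r")
  ckey <- paste(closure$from, closure$to, closure$relation, sep = "\r")
  key %in% ckey
}

#' Closure-based 3-class precision, recall and F
#'
#' Precision is the number of system links verifiable in the gold-standard
#' closure over the number of system links; recall is the number of gold
#' links verifiable in the system closure over the number of gold links.
#'
#' @param system,gold TLINK data frames in broad types (fine-typed input is
#'   mapped with [map_12_to_3()] first).  A `doc` column, if present,
#'   partitions the closure per document.
#' @return List with `precision`, `recall`, `f`.
#' @export
i2b2_score <- function(system, gold) {
  to_broad <- function(df) {
    if (nrow(df) && !all(df$relation %in% broad_relation_types())) {
      df <- map_12_to_3(df)
    }
    df
  }
  system <- to_broad(system); gold <- to_broad(gold)
  split_by_doc <- function(df) {
    if ("doc" %in% names(df) && nrow(df)) split(df, df$doc) else list(all = df)
  }
  sys_parts <- split_by_doc(system); gold_parts <- split_by_doc(gold)
  docs <- union(names(sys_parts), names(gold_parts))
  sys_ok <- 0L; gold_ok <- 0L
  for (d in docs) {
    s <- sys_parts[[d]]
    g <- gold_parts[[d]]
    if (is.null(s)) s <- gold[0, , drop = FALSE]
    if (is.null(g)) g <- system[0, , drop = FALSE]
    if (nrow(s)) sys_ok <- sys_ok + sum(in_closure(s, close_links(g)))
    if (nrow(g)) gold_ok <- gold_ok + sum(in_closure(g, close_links(s)))
  }
  nsys <- nrow(system); ngold <- nrow(gold)
  if (!nsys) warning("empty system output; precision reported as 0")
  p <- if (nsys) sys_ok / nsys else 0
  r <- if (ngold) gold_ok / ngold else 0
  f <- if (p + r > 0) 2 * p * r / (p + r) else 0
  list(precision = p, recall = r, f = f)
}
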