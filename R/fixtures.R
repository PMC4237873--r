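#' Synthetic fixture corpus generation
#'
#' Seeded generator of clinical-style documents with gold annotations
#' (events, time expressions, section times, temporal links), gold
#' linguistic sidecars (tokens, trees, dependencies, SRL frames, discourse
#' relations) and planted, recoverable relation patterns.  Every template
#' transcribes one of the worked example sentences that motivate the
#' system's feature families, so the planted gold links are exactly what
#' the starter rules and classifiers should recover.  All text is
#' synthetic; documents carry the two canonical sections and section
#' creation times.
#'
#' @name synthetic_fixtures
NULL

.tok <- function(spec) {
  # "text|POS|CHUNK" or "text|POS|CHUNK|lemma"
  parts <- strsplit(spec, "|", fixed = TRUE)[[1]]
  list(text = parts[1], pos = parts[2], chunk = parts[3],
       lemma = if (length(parts) >= 4) parts[4] else tolower(parts[1]))
}

.sent <- function(tokens, tree, deps = list(), srl = list()) {
  list(tokens = lapply(tokens, .tok), tree = tree, deps = deps, srl = srl)
}

.ent <- function(slot, sent, toks, kind, type, vtok = NULL,
                 variants = NULL, polarity = "POS", modality = "FACTUAL",
                 val = NA_character_, assertion = NA_character_) {
  list(slot = slot, sent = sent, toks = toks, kind = kind, type = type,
       vtok = vtok, variants = variants, polarity = polarity,
       modality = modality, val = val, assertion = assertion)
}

.template <- function(id, sentences, entities, gold = NA_character_,
                      semrel = NA_character_, discourse = NULL) {
  list(id = id, sentences = sentences, entities = entities, gold = gold,
       semrel = semrel, discourse = discourse)
}

#' The fixture template registry
#'
#' @return Named list of templates.  `default`-mix templates plant one
#'   temporal link each and are covered by the starter rules; additional
#'   templates cover event-time anchors and the remaining medical
#'   semantic-relation classes.
#' @export
fixture_templates <- function() {
  t <- list()

  # antonym + "but" coordination -> asynchronous (Before)
  t$t4 <- .template("t4",
    list(.sent(
      c("Her|PRP$|B-NP", "amylase|NN|I-NP", "was|VBD|B-VP",
        "mildly|RB|B-ADJP", "elevated|VBN|I-ADJP|elevate",
        "but|CC|O", "has|VBZ|B-VP", "been|VBN|I-VP", "down|JJ|B-ADVP",
        "since|IN|B-PP", "then|RB|B-NP", ".|.|O"),
      paste0("(S (NP (PRP$ #0) (NN #1)) (VP (VBD #2) (ADJP (RB #3) ",
             "(VBN #4)) (CC #5) (VP (VBZ #6) (VBN #7) (ADVP (JJ #8)) ",
             "(PP (IN #9) (NP (RB #10))))) (. #11))"),
      deps = list(c(-1L, 2L, "root"), c(2L, 1L, "nsubj"), c(1L, 0L, "poss"),
                  c(2L, 4L, "acomp"), c(4L, 3L, "advmod"),
                  c(2L, 8L, "conj"), c(8L, 9L, "prep")))),
    list(.ent("e1", 1L, c(3L, 4L), "EVENT", "PROBLEM"),
         .ent("e2", 1L, 8L, "EVENT", "OCCURRENCE")),
    gold = "Before")

  # destination (A4) argument of a predicate -> Begins
  t$t5 <- .template("t5",
    list(.sent(
      c("She|PRP|B-NP", "was|VBD|B-VP", "discharged|VBN|I-VP|discharge",
        "to|IN|B-PP", "rehab|NN|B-NP", ".|.|O"),
      "(S (NP (PRP #0)) (VP (VBD #1) (VP (VBN #2) (PP (IN #3) (NP (NN #4))))) (. #5))",
      deps = list(c(-1L, 2L, "root"), c(2L, 0L, "nsubjpass"),
                  c(2L, 3L, "prep"), c(3L, 4L, "pobj")),
      srl = list(list(pred = 2L, args = list(c("A1", 0L, 0L),
                                             c("A4", 4L, 4L)))))),
    list(.ent("e1", 1L, 2L, "EVENT", "OCCURRENCE"),
         .ent("e2", 1L, 4L, "EVENT", "CLINICAL_DEPT", vtok = 4L,
              variants = c("rehab", "radiology"))),
    gold = "Begins")

  # implicit Restatement between consecutive sentences -> Overlap
  t$t6 <- .template("t6",
    list(.sent(
      c("Hypotension|NN|B-NP", "was|VBD|B-VP", "noted|VBN|I-VP|note",
        "per|IN|B-PP", "the|DT|B-NP", "referral|NN|I-NP",
        "form|NN|I-NP", ".|.|O"),
      paste0("(S (NP (NN #0)) (VP (VBD #1) (VP (VBN #2) (PP (IN #3) ",
             "(NP (DT #4) (NN #5) (NN #6))))) (. #7))"),
      deps = list(c(-1L, 2L, "root"), c(2L, 0L, "nsubjpass"))),
      .sent(
      c("Initially|RB|B-ADVP", "there|EX|B-NP", "was|VBD|B-VP",
        "concern|NN|B-NP", "for|IN|B-PP", "sepsis|NN|B-NP",
        "in|IN|B-PP", "the|DT|B-NP", "setting|NN|I-NP", "of|IN|B-PP",
        "fevers|NNS|B-NP|fever", ".|.|O"),
      paste0("(S (ADVP (RB #0)) (NP (EX #1)) (VP (VBD #2) (NP (NN #3)) ",
             "(PP (IN #4) (NP (NN #5))) (PP (IN #6) (NP (DT #7) (NN #8) ",
             "(PP (IN #9) (NP (NNS #10)))))) (. #11))"),
      deps = list(c(-1L, 2L, "root"), c(2L, 3L, "nsubj"),
                  c(3L, 4L, "prep"), c(4L, 5L, "pobj")))),
    list(.ent("e1", 1L, 0L, "EVENT", "PROBLEM", assertion = "present"),
         .ent("e2", 2L, 5L, "EVENT", "PROBLEM", assertion = "possible")),
    gold = "Overlap",
    discourse = list(kind = "IMPLICIT", sense = "Restatement",
                     conn = NA_character_, arg1_sent = 1L, arg2_sent = 2L))

  # explicit Asynchronous triggered by "thereafter" -> Before
  t$t7 <- .template("t7",
    list(.sent(
      c("At|IN|B-PP", "operation|NN|B-NP", "there|EX|B-NP",
        "was|VBD|B-VP", "no|DT|B-NP", "gross|JJ|I-NP",
        "adenopathy|NN|I-NP", ".|.|O"),
      paste0("(S (PP (IN #0) (NP (NN #1))) (NP (EX #2)) (VP (VBD #3) ",
             "(NP (DT #4) (JJ #5) (NN #6))) (. #7))"),
      deps = list(c(-1L, 3L, "root"), c(3L, 0L, "prep"), c(0L, 1L, "pobj"))),
      .sent(
      c("The|DT|B-NP", "patient|NN|I-NP", "thereafter|RB|B-ADVP",
        "had|VBD|B-VP|have", "a|DT|B-NP", "benign|JJ|I-NP",
        "convalescence|NN|I-NP", ".|.|O"),
      paste0("(S (NP (DT #0) (NN #1)) (ADVP (RB #2)) (VP (VBD #3) ",
             "(NP (DT #4) (JJ #5) (NN #6))) (. #7))"),
      deps = list(c(-1L, 3L, "root"), c(3L, 1L, "nsubj"),
                  c(3L, 6L, "dobj")))),
    list(.ent("e1", 1L, 1L, "EVENT", "TREATMENT"),
         .ent("e2", 2L, c(5L, 6L), "EVENT", "OCCURRENCE")),
    gold = "Before",
    discourse = list(kind = "EXPLICIT", sense = "Asynchronous",
                     conn = "thereafter", arg1_sent = 1L, arg2_sent = 2L))

  # treatment improves problem (TrIP) -> Ended_By
  t$t8 <- .template("t8",
    list(.sent(
      c("The|DT|B-NP", "patient's|NN|I-NP", "pain|NN|I-NP",
        "resolved|VBD|B-VP|resolve", "with|IN|B-PP", "NTG|NN|B-NP",
        "and|CC|I-NP", "morphine|NN|I-NP", ".|.|O"),
      paste0("(S (NP (DT #0) (NN #1) (NN #2)) (VP (VBD #3) (PP (IN #4) ",
             "(NP (NN #5) (CC #6) (NN #7)))) (. #8))"),
      deps = list(c(-1L, 3L, "root"), c(3L, 2L, "nsubj"), c(2L, 0L, "det"),
                  c(3L, 4L, "prep"), c(4L, 5L, "pobj")))),
    list(.ent("e1", 1L, c(0L, 2L), "EVENT", "PROBLEM", vtok = 2L,
              variants = c("pain", "discomfort", "ache"),
              assertion = "present"),
         .ent("e2", 1L, 5L, "EVENT", "TREATMENT", vtok = 5L,
              variants = c("NTG", "nitroglycerin"))),
    gold = "Ended_By", semrel = "TrIP")

  # unrelated comma-series problems (NPP) -> Overlap
  t$t9 <- .template("t9",
    list(.sent(
      c("Patient|NN|B-NP", "returns|VBZ|B-VP|return", "from|IN|B-PP",
        "the|DT|B-NP", "nursing|NN|I-NP", "home|NN|I-NP", "with|IN|B-PP",
        "fever|NN|B-NP", ",|,|O", "leukocytosis|NN|B-NP", "and|CC|O",
        "azotemia|NN|B-NP", ".|.|O"),
      paste0("(S (NP (NN #0)) (VP (VBZ #1) (PP (IN #2) (NP (DT #3) ",
             "(NN #4) (NN #5))) (PP (IN #6) (NP (NP (NN #7)) (, #8) ",
             "(NP (NN #9)) (CC #10) (NP (NN #11))))) (. #12))"),
      deps = list(c(-1L, 1L, "root"), c(1L, 0L, "nsubj"),
                  c(1L, 6L, "prep"), c(6L, 7L, "pobj"),
                  c(7L, 9L, "conj"), c(7L, 11L, "conj")))),
    list(.ent("e1", 1L, 7L, "EVENT", "PROBLEM", vtok = 7L,
              variants = c("fever", "fevers"), assertion = "present"),
         .ent("e2", 1L, 9L, "EVENT", "PROBLEM", vtok = 9L,
              variants = c("leukocytosis", "eosinophilia"),
              assertion = "present")),
    gold = "Overlap", semrel = "NPP")

  # problem indicates problem (PIP) -> Simultaneous
  t$t10 <- .template("t10",
    list(.sent(
      c("Residual|JJ|B-NP", "deficits|NNS|I-NP|deficit",
        "include|VBP|B-VP", "anterior|JJ|B-NP", "aphasia|NN|I-NP",
        "with|IN|B-PP", "word|NN|B-NP", "finding|NN|I-NP",
        "difficulties|NNS|I-NP|difficulty", ".|.|O"),
      paste0("(S (NP (JJ #0) (NNS #1)) (VP (VBP #2) (NP (NP (JJ #3) ",
             "(NN #4)) (PP (IN #5) (NP (NN #6) (NN #7) (NNS #8))))) ",
             "(. #9))"),
      deps = list(c(-1L, 2L, "root"), c(2L, 1L, "nsubj"),
                  c(2L, 4L, "dobj"), c(4L, 5L, "prep"), c(5L, 8L, "pobj")))),
    list(.ent("e1", 1L, c(3L, 4L), "EVENT", "PROBLEM",
              assertion = "present"),
         .ent("e2", 1L, c(6L, 8L), "EVENT", "PROBLEM",
              assertion = "present")),
    gold = "Simultaneous", semrel = "PIP")

  # test conducted to investigate problem (TeCP) -> Overlap_After
  t$t11 <- .template("t11",
    list(.sent(
      c("The|DT|B-NP", "patient|NN|I-NP", "had|VBD|B-VP|have",
        "a|DT|B-NP", "bone|NN|I-NP", "marrow|NN|I-NP", "biopsy|NN|I-NP",
        "for|IN|B-PP", "persistent|JJ|B-NP", "pancytopenia|NN|I-NP",
        ".|.|O"),
      paste0("(S (NP (DT #0) (NN #1)) (VP (VBD #2) (NP (NP (DT #3) ",
             "(NN #4) (NN #5) (NN #6)) (PP (IN #7) (NP (JJ #8) ",
             "(NN #9))))) (. #10))"),
      deps = list(c(-1L, 2L, "root"), c(2L, 1L, "nsubj"),
                  c(2L, 6L, "dobj"), c(6L, 7L, "prep"), c(7L, 9L, "pobj")))),
    list(.ent("e1", 1L, c(4L, 6L), "EVENT", "TEST"),
         .ent("e2", 1L, c(8L, 9L), "EVENT", "PROBLEM", vtok = 9L,
              variants = c("pancytopenia", "anemia"),
              assertion = "present")),
    gold = "Overlap_After", semrel = "TeCP")

  # test reveals problem (TeRP) plus "due to" -> Overlap_After
  t$t12 <- .template("t12",
    list(.sent(
      c("Her|PRP$|B-NP", "creatinine|NN|I-NP", "continued|VBD|B-VP|continue",
        "to|TO|I-VP", "increase|VB|I-VP", "likely|RB|B-ADVP",
        "due|JJ|B-PP", "to|TO|I-PP", "her|PRP$|B-NP",
        "worsening|VBG|I-NP|worsen", "liver|NN|I-NP", "failure|NN|I-NP",
        ".|.|O"),
      paste0("(S (NP (PRP$ #0) (NN #1)) (VP (VBD #2) (VP (TO #3) ",
             "(VB #4)) (ADVP (RB #5)) (PP (JJ #6) (TO #7) (NP (PRP$ #8) ",
             "(VBG #9) (NN #10) (NN #11)))) (. #12))"),
      deps = list(c(-1L, 2L, "root"), c(2L, 1L, "nsubj"), c(1L, 0L, "poss"),
                  c(2L, 4L, "xcomp"), c(2L, 6L, "prep"), c(6L, 11L, "pobj")))),
    list(.ent("e1", 1L, c(0L, 1L), "EVENT", "TEST"),
         .ent("e2", 1L, c(8L, 11L), "EVENT", "PROBLEM",
              assertion = "present")),
    gold = "Overlap_After", semrel = "TeRP")

  # event anchored to a date -> Simultaneous (event-time template)
  t$t1 <- .template("t1",
    list(.sent(
      c("He|PRP|B-NP", "was|VBD|B-VP", "ready|JJ|B-ADJP", "for|IN|B-PP",
        "discharge|NN|B-NP", "home|NN|I-NP", "on|IN|B-PP",
        "postoperative|JJ|B-NP", "day|NN|I-NP", "3|CD|I-NP", ".|.|O"),
      paste0("(S (NP (PRP #0)) (VP (VBD #1) (ADJP (JJ #2)) (PP (IN #3) ",
             "(NP (NN #4) (NN #5))) (PP (IN #6) (NP (JJ #7) (NN #8) ",
             "(CD #9)))) (. #10))"),
      deps = list(c(-1L, 1L, "root"), c(1L, 0L, "nsubj"),
                  c(1L, 6L, "prep"), c(6L, 8L, "pobj")))),
    list(.ent("e1", 1L, 4L, "EVENT", "OCCURRENCE"),
         .ent("e2", 1L, c(7L, 9L), "TIME", "DATE", val = "POSTOP-DAY-3")),
    gold = "Simultaneous")

  # evidential ongoing problem -> Overlap_After
  t$t2 <- .template("t2",
    list(.sent(
      c("She|PRP|B-NP", "has|VBZ|B-VP|have", "not|RB|I-VP",
        "complained|VBN|I-VP|complain", "of|IN|B-PP", "any|DT|B-NP",
        "fever|NN|I-NP", ".|.|O"),
      paste0("(S (NP (PRP #0)) (VP (VBZ #1) (RB #2) (VP (VBN #3) ",
             "(PP (IN #4) (NP (DT #5) (NN #6))))) (. #7))"),
      deps = list(c(-1L, 3L, "root"), c(3L, 0L, "nsubj"),
                  c(3L, 4L, "prep"), c(4L, 6L, "pobj")))),
    list(.ent("e1", 1L, 3L, "EVENT", "EVIDENTIAL", polarity = "NEG"),
         .ent("e2", 1L, 6L, "EVENT", "PROBLEM", assertion = "absent")),
    gold = "Overlap_After")

  # the worked five-way sequence-generation sentence (TeRP)
  t$t_seq <- .template("t_seq",
    list(.sent(
      c("Postop|RB|B-ADVP", ",|VB,|O", "her|PRP$|B-NP", "exam|NN|I-NP",
        "only|RB|B-ADVP", "improved|VBD|B-VP|improve",
        "slightly|RB|B-ADVP", "in|IN|B-PP", "her|PRP$|B-NP",
        "hyperreflexia|NN|I-NP"),
      paste0("(S (ADVP (RB #0)) (, #1) (NP (PRP$ #2) (NN #3)) ",
             "(ADVP (RB #4)) (VP (VBD #5) (ADVP (RB #6)) (PP (IN #7) ",
             "(NP (PRP$ #8) (NN #9)))))"),
      deps = list(c(-1L, 5L, "root"), c(5L, 3L, "nsubj"), c(3L, 2L, "poss"),
                  c(5L, 0L, "advmod"), c(5L, 4L, "advmod"),
                  c(5L, 6L, "advmod"), c(5L, 7L, "prep"), c(7L, 9L, "pobj"),
                  c(9L, 8L, "poss")))),
    list(.ent("e1", 1L, c(2L, 3L), "EVENT", "TEST"),
         .ent("e2", 1L, c(8L, 9L), "EVENT", "PROBLEM",
              assertion = "present")),
    gold = "Overlap_After", semrel = "TeRP")

  # remaining semantic-relation classes (semrel corpus only)
  t$sr_trwp <- .template("sr_trwp",
    list(.sent(
      c("He|PRP|B-NP", "was|VBD|B-VP", "treated|VBN|I-VP|treat",
        "with|IN|B-PP", "Zofran|NN|B-NP", "with|IN|B-PP", "no|DT|B-NP",
        "relief|NN|I-NP", ".|.|O"),
      paste0("(S (NP (PRP #0)) (VP (VBD #1) (VP (VBN #2) (PP (IN #3) ",
             "(NP (NN #4))) (PP (IN #5) (NP (DT #6) (NN #7))))) (. #8))"),
      deps = list(c(-1L, 2L, "root"), c(2L, 3L, "prep"), c(3L, 4L, "pobj"),
                  c(2L, 5L, "prep"), c(5L, 7L, "pobj")))),
    list(.ent("e1", 1L, 4L, "EVENT", "TREATMENT", vtok = 4L,
              variants = c("Zofran", "ondansetron")),
         .ent("e2", 1L, c(6L, 7L), "EVENT", "PROBLEM",
              assertion = "present")),
    semrel = "TrWP")

  t$sr_trcp <- .template("sr_trcp",
    list(.sent(
      c("Transdermal|JJ|B-NP", "nitroglycerin|NN|I-NP",
        "caused|VBD|B-VP|cause", "headache|NN|B-NP", ".|.|O"),
      "(S (NP (JJ #0) (NN #1)) (VP (VBD #2) (NP (NN #3))) (. #4))",
      deps = list(c(-1L, 2L, "root"), c(2L, 1L, "nsubj"),
                  c(2L, 3L, "dobj")))),
    list(.ent("e1", 1L, c(0L, 1L), "EVENT", "TREATMENT"),
         .ent("e2", 1L, 3L, "EVENT", "PROBLEM", vtok = 3L,
              variants = c("headache", "nausea"), assertion = "present")),
    semrel = "TrCP")

  t$sr_terp <- .template("sr_terp",
    list(.sent(
      c("A|DT|B-NP", "postoperative|JJ|I-NP", "MRI|NN|I-NP",
        "revealed|VBD|B-VP|reveal", "remarkable|JJ|B-NP",
        "findings|NNS|I-NP|finding", ".|.|O"),
      paste0("(S (NP (DT #0) (JJ #1) (NN #2)) (VP (VBD #3) (NP (JJ #4) ",
             "(NNS #5))) (. #6))"),
      deps = list(c(-1L, 3L, "root"), c(3L, 2L, "nsubj"),
                  c(3L, 5L, "dobj")))),
    list(.ent("e1", 1L, c(0L, 2L), "EVENT", "TEST", vtok = 2L,
              variants = c("MRI", "radiograph")),
         .ent("e2", 1L, c(4L, 5L), "EVENT", "PROBLEM",
              assertion = "present")),
    semrel = "TeRP")

  t$sr_trap <- .template("sr_trap",
    list(.sent(
      c("He|PRP|B-NP", "was|VBD|B-VP", "started|VBN|I-VP|start",
        "on|IN|B-PP", "Decadron|NN|B-NP", "to|TO|B-VP",
        "prevent|VB|I-VP", "swelling|NN|B-NP", ".|.|O"),
      paste0("(S (NP (PRP #0)) (VP (VBD #1) (VP (VBN #2) (PP (IN #3) ",
             "(NP (NN #4))) (S (VP (TO #5) (VB #6) (NP (NN #7)))))) ",
             "(. #8))"),
      deps = list(c(-1L, 2L, "root"), c(2L, 3L, "prep"), c(3L, 4L, "pobj"),
                  c(2L, 6L, "xcomp"), c(6L, 7L, "dobj")))),
    list(.ent("e1", 1L, 4L, "EVENT", "TREATMENT", vtok = 4L,
              variants = c("Decadron", "dexamethasone")),
         .ent("e2", 1L, 7L, "EVENT", "PROBLEM", assertion = "hypothetical")),
    semrel = "TrAP")

  t$sr_trnap <- .template("sr_trnap",
    list(.sent(
      c("His|PRP$|B-NP", "Avandia|NN|I-NP", "was|VBD|B-VP",
        "discontinued|VBN|I-VP|discontinue", "secondary|JJ|B-ADJP",
        "to|TO|B-PP", "the|DT|B-NP", "side|NN|I-NP", "effects|NNS|I-NP|effect",
        ".|.|O"),
      paste0("(S (NP (PRP$ #0) (NN #1)) (VP (VBD #2) (VP (VBN #3) ",
             "(ADJP (JJ #4)) (PP (TO #5) (NP (DT #6) (NN #7) (NNS #8))))) ",
             "(. #9))"),
      deps = list(c(-1L, 3L, "root"), c(3L, 1L, "nsubjpass"),
                  c(3L, 5L, "prep"), c(5L, 8L, "pobj")))),
    list(.ent("e1", 1L, 1L, "EVENT", "TREATMENT"),
         .ent("e2", 1L, c(6L, 8L), "EVENT", "PROBLEM",
              assertion = "present")),
    semrel = "TrNAP")

  t$sr_tecp <- .template("sr_tecp",
    list(.sent(
      c("An|DT|B-NP", "ultrasound|NN|I-NP", "was|VBD|B-VP",
        "done|VBN|I-VP|do", "to|TO|B-VP", "rule|VB|I-VP", "out|RP|I-VP",
        "cholestasis|NN|B-NP", ".|.|O"),
      paste0("(S (NP (DT #0) (NN #1)) (VP (VBD #2) (VP (VBN #3) ",
             "(S (VP (TO #4) (VB #5) (PRT (RP #6)) (NP (NN #7)))))) ",
             "(. #8))"),
      deps = list(c(-1L, 3L, "root"), c(3L, 1L, "nsubjpass"),
                  c(3L, 5L, "xcomp"), c(5L, 7L, "dobj")))),
    list(.ent("e1", 1L, c(0L, 1L), "EVENT", "TEST"),
         .ent("e2", 1L, 7L, "EVENT", "PROBLEM", assertion = "possible")),
    semrel = "TeCP")

  t$sr_ntrp <- .template("sr_ntrp",
    list(.sent(
      c("The|DT|B-NP", "sutures|NNS|I-NP|suture", "were|VBD|B-VP",
        "intact|JJ|B-ADJP", "with|IN|B-PP", "no|DT|B-NP",
        "erythema|NN|I-NP", "noted|VBN|B-VP|note", ".|.|O"),
      paste0("(S (NP (DT #0) (NNS #1)) (VP (VBD #2) (ADJP (JJ #3)) ",
             "(PP (IN #4) (NP (DT #5) (NN #6) (VBN #7)))) (. #8))"),
      deps = list(c(-1L, 2L, "root"), c(2L, 1L, "nsubj"),
                  c(2L, 4L, "prep"), c(4L, 6L, "pobj")))),
    list(.ent("e1", 1L, c(0L, 1L), "EVENT", "TREATMENT"),
         .ent("e2", 1L, c(5L, 6L), "EVENT", "PROBLEM",
              assertion = "absent")),
    semrel = "NTrP")

  t$sr_ntep <- .template("sr_ntep",
    list(.sent(
      c("His|PRP$|B-NP", "laboratories|NNS|I-NP|laboratory",
        "remained|VBD|B-VP|remain", "normal|JJ|B-ADJP", "and|CC|O",
        "his|PRP$|B-NP", "pain|NN|I-NP", "was|VBD|B-VP",
        "controlled|VBN|I-VP|control", ".|.|O"),
      paste0("(S (S (NP (PRP$ #0) (NNS #1)) (VP (VBD #2) (ADJP (JJ #3)))) ",
             "(CC #4) (S (NP (PRP$ #5) (NN #6)) (VP (VBD #7) (VBN #8))) ",
             "(. #9))"),
      deps = list(c(-1L, 2L, "root"), c(2L, 1L, "nsubj"),
                  c(2L, 8L, "conj"), c(8L, 6L, "nsubjpass")))),
    list(.ent("e1", 1L, c(0L, 1L), "EVENT", "TEST"),
         .ent("e2", 1L, c(5L, 6L), "EVENT", "PROBLEM",
              assertion = "present")),
    semrel = "NTeP")

  t
}

#' Template ids of the default corpus mix
#' @return Character vector of the nine rule-covered template ids.
#' @export
default_template_mix <- function() {
  ids <- c("t4", "t5", "t6", "t7", "t8", "t9", "t10", "t11", "t12")
  stats::setNames(rep(1 / length(ids), length(ids)), ids)
}

#' Template ids carrying medical semantic-relation labels
#' @return Named mix covering all 11 semrel classes uniformly by template.
#' @export
semrel_template_mix <- function() {
  ids <- c("t8", "t9", "t10", "t11", "t12", "t_seq", "sr_trwp", "sr_trcp",
           "sr_terp", "sr_trap", "sr_trnap", "sr_tecp", "sr_ntrp",
           "sr_ntep")
  stats::setNames(rep(1 / length(ids), length(ids)), ids)
}

detok_join <- function(texts) {
  # single space between tokens; sentence punctuation attaches left
  out <- ""
  starts <- integer(length(texts))
  for (k in seq_along(texts)) {
    if (k > 1L && !grepl("^[.,;:!?]+$", texts[k])) out <- paste0(out, " ")
    starts[k] <- nchar(out)
    out <- paste0(out, texts[k])
  }
  list(text = out, starts = starts)
}

.header_sentences <- function(adm_date, dis_date) {
  list(
    list(tokens = lapply(c(paste0("ADMISSION|NN|O"), ":|:|O",
                           paste0(adm_date, "|CD|O"), ".|.|O"), .tok),
         tree = "(S (NN #0) (: #1) (CD #2) (. #3))",
         deps = list(), srl = list(), sectime = "ADMISSION",
         date_tok = 2L, date = adm_date),
    list(tokens = lapply(c(paste0("DISCHARGE|NN|O"), ":|:|O",
                           paste0(dis_date, "|CD|O"), ".|.|O"), .tok),
         tree = "(S (NN #0) (: #1) (CD #2) (. #3))",
         deps = list(), srl = list(), sectime = "DISCHARGE",
         date_tok = 2L, date = dis_date)
  )
}

apply_variants <- function(tmpl) {
  # pick one surface variant per entity slot (uses the current RNG)
  for (j in seq_along(tmpl$entities)) {
    ent <- tmpl$entities[[j]]
    if (!is.null(ent$variants) && length(ent$variants) > 1L) {
      v <- sample(ent$variants, 1L)
      tk <- tmpl$sentences[[ent$sent]]$tokens[[ent$vtok + 1L]]
      tk$text <- v; tk$lemma <- tolower(v)
      tmpl$sentences[[ent$sent]]$tokens[[ent$vtok + 1L]] <- tk
    }
  }
  tmpl
}

#' Assemble one synthetic document from template instances
#'
#' @param doc_id Document id.
#' @param tmpl_insts List of (variant-applied) templates.
#' @param adm_date,dis_date Section creation date strings.
#' @return List with `doc` (a `clindoc`), `ann` (a `docann`) and `semrel`
#'   (data frame of planted semantic-relation instances).
#' @export
assemble_document <- function(doc_id, tmpl_insts,
                              adm_date = "2014-02-05",
                              dis_date = "2014-02-12") {
  sents <- .header_sentences(adm_date, dis_date)
  sent_owner <- c(NA_integer_, NA_integer_)
  for (ti in seq_along(tmpl_insts)) {
    for (s in tmpl_insts[[ti]]$sentences) {
      sents[[length(sents) + 1L]] <- s
      sent_owner <- c(sent_owner, ti)
    }
  }
  # global token table and text
  tok_rows <- list(); text <- ""
  sent_first_tok <- integer(length(sents))
  sent_span <- matrix(0L, length(sents), 2)
  gi <- 0L
  for (s in seq_along(sents)) {
    texts <- vapply(sents[[s]]$tokens, `[[`, "", "text")
    joined <- detok_join(texts)
    off <- nchar(text) + if (nchar(text)) 1L else 0L
    if (nchar(text)) text <- paste0(text, " ")
    sent_first_tok[s] <- gi
    sent_span[s, ] <- c(off, off + nchar(joined$text))
    text <- paste0(text, joined$text)
    for (k in seq_along(sents[[s]]$tokens)) {
      tk <- sents[[s]]$tokens[[k]]
      tok_rows[[length(tok_rows) + 1L]] <- data.frame(
        i = gi, text = tk$text, lemma = tk$lemma, pos = tk$pos,
        chunk = tk$chunk, start = off + joined$starts[k],
        end = off + joined$starts[k] + nchar(tk$text), sent = s - 1L,
        stringsAsFactors = FALSE)
      gi <- gi + 1L
    }
  }
  tokens <- do.call(rbind, tok_rows)
  trees <- lapply(seq_along(sents), function(s) {
    br <- sents[[s]]$tree
    texts <- vapply(sents[[s]]$tokens, `[[`, "", "text")
    for (k in seq_along(texts)) {
      br <- sub(paste0("#", k - 1L, "\\b"), gsub("([\\\\$])", "\\\\\\1", texts[k]),
                br)
    }
    parse_penn(br, first_token = sent_first_tok[s])
  })
  deps <- list(); srl <- list()
  for (s in seq_along(sents)) {
    base <- sent_first_tok[s]
    for (d in sents[[s]]$deps) {
      h <- as.integer(d[1]); dp <- as.integer(d[2])
      deps[[length(deps) + 1L]] <- data.frame(
        head = if (h < 0L) -1L else h + base, dep = dp + base,
        label = d[3], stringsAsFactors = FALSE)
    }
    for (fr in sents[[s]]$srl) {
      args <- do.call(rbind, lapply(fr$args, function(a) {
        data.frame(label = a[1], start_tok = as.integer(a[2]) + base,
                   end_tok = as.integer(a[3]) + base, stringsAsFactors = FALSE)
      }))
      srl[[length(srl) + 1L]] <- list(pred = fr$pred + base, args = args)
    }
  }
  deps <- if (length(deps)) do.call(rbind, deps) else empty_deps()
  deps$head <- as.integer(deps$head); deps$dep <- as.integer(deps$dep)

  # entities, links, semrel annotations
  events <- list(); times <- list(); tlinks <- list(); semrel <- list()
  disc <- list()
  ne <- 0L; nt <- 0L; nl <- 0L
  tmpl_sent_global <- function(ti, local_s) {
    which(sent_owner == ti)[local_s]
  }
  for (ti in seq_along(tmpl_insts)) {
    tmpl <- tmpl_insts[[ti]]
    ids <- character(2)
    for (j in seq_along(tmpl$entities)) {
      ent <- tmpl$entities[[j]]
      gs <- tmpl_sent_global(ti, ent$sent)
      base <- sent_first_tok[gs]
      lo <- base + min(ent$toks); hi <- base + max(ent$toks)
      st <- tokens$start[match(lo, tokens$i)]
      en <- tokens$end[match(hi, tokens$i)]
      surface <- substr(text, st + 1L, en)
      if (ent$kind == "EVENT") {
        ne <- ne + 1L; id <- paste0("E", ne)
        events[[ne]] <- data.frame(
          id = id, start = st, end = en, text = surface, type = ent$type,
          polarity = ent$polarity, modality = ent$modality,
          stringsAsFactors = FALSE)
      } else {
        nt <- nt + 1L; id <- paste0("T", nt)
        times[[nt]] <- data.frame(
          id = id, start = st, end = en, text = surface, type = ent$type,
          val = ent$val, mod = NA_character_, stringsAsFactors = FALSE)
      }
      ids[match(ent$slot, c("e1", "e2"))] <- id
    }
    if (!is.na(tmpl$gold)) {
      nl <- nl + 1L
      tlinks[[nl]] <- data.frame(
        id = paste0("L", nl), from = ids[1], to = ids[2],
        relation = tmpl$gold, origin = "GOLD", stringsAsFactors = FALSE)
    }
    if (!is.na(tmpl$semrel)) {
      semrel[[length(semrel) + 1L]] <- data.frame(
        doc = doc_id, e1 = ids[1], e2 = ids[2],
        sent = tmpl_sent_global(ti, tmpl$entities[[1]]$sent) - 1L,
        label = tmpl$semrel,
        assertion1 = tmpl$entities[[1]]$assertion,
        assertion2 = tmpl$entities[[2]]$assertion,
        stringsAsFactors = FALSE)
    }
    if (!is.null(tmpl$discourse)) {
      d <- tmpl$discourse
      g1 <- tmpl_sent_global(ti, d$arg1_sent)
      g2 <- tmpl_sent_global(ti, d$arg2_sent)
      disc[[length(disc) + 1L]] <- data.frame(
        a1s = sent_span[g1, 1], a1e = sent_span[g1, 2],
        a2s = sent_span[g2, 1], a2e = sent_span[g2, 2],
        sense = d$sense, kind = d$kind, conn = d$conn,
        stringsAsFactors = FALSE)
    }
  }
  events <- if (length(events)) do.call(rbind, events) else empty_events()
  times <- if (length(times)) do.call(rbind, times) else empty_times()
  tlinks <- if (length(tlinks)) do.call(rbind, tlinks) else empty_tlinks()
  disc <- if (length(disc)) do.call(rbind, disc) else empty_discourse()
  semrel <- if (length(semrel)) do.call(rbind, semrel) else NULL

  # section times from the header sentences
  date_rows <- lapply(1:2, function(s) {
    ds <- sents[[s]]
    lo <- sent_first_tok[s] + ds$date_tok
    data.frame(id = paste0("S", s - 1L), section = ds$sectime,
               start = tokens$start[match(lo, tokens$i)],
               end = tokens$end[match(lo, tokens$i)], value = ds$date,
               stringsAsFactors = FALSE)
  })
  sectimes <- do.call(rbind, date_rows)
  # two sections split at the midpoint sentence
  nsent <- length(sents)
  mid <- max(3L, ceiling(nsent / 2) + 1L)
  mid <- min(mid, nsent)
  sections <- data.frame(
    name = c("HISTORY_OF_PRESENT_ILLNESS", "HOSPITAL_COURSE"),
    start = c(0L, sent_span[mid, 1]),
    end = c(sent_span[mid, 1] - 1L, nchar(text)),
    stringsAsFactors = FALSE)
  if (sections$end[1] <= sections$start[1]) sections <- sections[2, ]

  doc <- clinical_document(doc_id, text, sections = sections,
                           events = events, times = times,
                           sectimes = sectimes, tlinks = tlinks)
  ann <- document_annotations(tokens, trees, deps, srl, disc)
  validate_annotations(ann, doc)
  list(doc = doc, ann = ann, semrel = semrel)
}

#' Generate a synthetic fixture corpus
#'
#' Deterministic under `seed`.  Each document contains the two section
#' header sentences plus `sentences_per_doc` template draws from
#' `template_mix`; every planted link is recorded in the gold standard.
#'
#' @param seed Integer seed.
#' @param n_docs Number of documents.
#' @param template_mix Named probability vector over template ids
#'   (must sum to 1); default [default_template_mix()].
#' @param sentences_per_doc Template draws per document.
#' @param prefix Document id prefix (keep distinct when corpora are pooled).
#' @return A `fixture_corpus`: named `docs`, `anns`, `semrel` (data frame),
#'   `lex` (the fixture [lexicon_set()]) and a generation `manifest`.
#' @export
generate_corpus <- function(seed, n_docs,
                            template_mix = default_template_mix(),
                            sentences_per_doc = 6L, prefix = "doc") {
  stopifnot(abs(sum(template_mix) - 1) < 1e-8)
  templates <- fixture_templates()
  unknown <- setdiff(names(template_mix), names(templates))
  if (length(unknown)) {
    stop("configuration error: unknown template id(s): ",
         paste(unknown, collapse = ", "))
  }
  with_seed(seed, {
    docs <- list(); anns <- list(); semrel <- list()
    counts <- stats::setNames(rep(0L, length(template_mix)),
                              names(template_mix))
    for (d in seq_len(n_docs)) {
      did <- sprintf("%s%03d", prefix, d)
      draw <- if (sentences_per_doc > 0L) {
        sample(names(template_mix), sentences_per_doc, replace = TRUE,
               prob = template_mix)
      } else character()
      for (id in draw) counts[id] <- counts[id] + 1L
      insts <- lapply(draw, function(id) apply_variants(templates[[id]]))
      adm <- sprintf("2014-%02d-%02d", 1L + (d %% 12L), 1L + (d %% 27L))
      dis <- sprintf("2014-%02d-%02d", 1L + (d %% 12L), 2L + (d %% 27L))
      built <- assemble_document(did, insts, adm, dis)
      docs[[did]] <- built$doc
      anns[[did]] <- built$ann
      if (!is.null(built$semrel)) semrel[[did]] <- built$semrel
    }
    semrel <- if (length(semrel)) do.call(rbind, semrel) else
      data.frame(doc = character(), e1 = character(), e2 = character(),
                 sent = integer(), label = character(),
                 assertion1 = character(), assertion2 = character(),
                 stringsAsFactors = FALSE)
    rownames(semrel) <- NULL
    structure(list(docs = docs, anns = anns, semrel = semrel,
                   lex = fixture_lexicons(),
                   manifest = list(seed = seed, n_docs = n_docs,
                                   template_mix = template_mix,
                                   sentences_per_doc = sentences_per_doc,
                                   template_counts = counts,
                                   flips = NULL)),
              class = "fixture_corpus")
  })
}

#' Flip a fraction of the planted gold labels to random other types
#'
#' Each gold temporal link's relation is replaced, with probability
#' `flip_rate`, by a uniformly random *different* fine type.  The flips
#' are recorded in the manifest.
#'
#' @param corpus A `fixture_corpus`.
#' @param flip_rate In \[0, 1).
#' @param seed Integer seed.
#' @return The corpus with noised links and an updated manifest.
#' @export
plant_noise <- function(corpus, flip_rate, seed) {
  stopifnot(flip_rate >= 0, flip_rate < 1)
  if (flip_rate == 0) return(corpus)
  with_seed(seed, {
    flips <- list()
    for (d in names(corpus$docs)) {
      tl <- corpus$docs[[d]]$tlinks
      for (i in seq_len(nrow(tl))) {
        if (!tl$relation[i] %in% fine_relation_types()) next
        if (stats::runif(1) < flip_rate) {
          new <- sample(setdiff(fine_relation_types(), tl$relation[i]), 1L)
          flips[[length(flips) + 1L]] <- data.frame(
            doc = d, id = tl$id[i], old = tl$relation[i], new = new,
            stringsAsFactors = FALSE)
          tl$relation[i] <- new
        }
      }
      corpus$docs[[d]]$tlinks <- tl
    }
    corpus$manifest$flips <- if (length(flips)) do.call(rbind, flips) else
      data.frame(doc = character(), id = character(), old = character(),
                 new = character(), stringsAsFactors = FALSE)
    corpus$manifest$flip_rate <- flip_rate
    corpus$manifest$flip_seed <- seed
    corpus
  })
}

#' Semantic-relation instances planted in a fixture corpus
#' @param corpus A `fixture_corpus`.
#' @return List of labeled [semrel_instance()]s.
#' @export
semrel_instances_from <- function(corpus) {
  sr <- corpus$semrel
  lapply(seq_len(nrow(sr)), function(r) {
    semrel_instance(sr$doc[r], sr$e1[r], sr$e2[r], sr$sent[r], sr$label[r],
                    sr$assertion1[r], sr$assertion2[r])
  })
}

#' The bundled fixture lexicons
#'
#' Includes the worked lexical pairs (e.g. the elevated/down antonym entry)
#' so the motivating examples are executable, a small sentiment table, a
#' first-synset table and a tiny offline encyclopedia link table.
#'
#' @return A [lexicon_set()].
#' @export
fixture_lexicons <- function() {
  lexicon_set(
    thesaurus = list(
      elevated = list(synonyms = c("raised", "increased"),
                      related = c("high"),
                      near_antonyms = c("reduced"),
                      antonyms = c("down", "lowered")),
      down = list(synonyms = c("lowered"), related = c("low"),
                  near_antonyms = c("raised"),
                  antonyms = c("elevated", "up")),
      pain = list(synonyms = c("ache", "discomfort"), related = c("hurt"),
                  near_antonyms = character(), antonyms = c("comfort")),
      fever = list(synonyms = c("pyrexia"), related = c("febrile"),
                   near_antonyms = character(), antonyms = character())
    ),
    wordnet = list(
      fever = list(hypernyms = c("symptom"), hyponyms = character(),
                   troponyms = character(), similar = c("pyrexia")),
      pain = list(hypernyms = c("symptom"), hyponyms = c("ache"),
                  troponyms = character(), similar = c("hurting")),
      biopsy = list(hypernyms = c("examination"), hyponyms = character(),
                    troponyms = character(), similar = character())
    ),
    sentiment = c(improved = "positive", resolved = "positive",
                  worsening = "negative", pain = "negative",
                  fever = "negative", benign = "positive"),
    synsets = c(pain = "pain.n.01", fever = "fever.n.01",
                discharge = "discharge.n.01", biopsy = "biopsy.n.01",
                operation = "operation.n.01"),
    wiki_links = data.frame(
      from = c("ntg", "nitroglycerin", "fever"),
      to = c("nitroglycerin", "angina", "infection"),
      stringsAsFactors = FALSE),
    wiki_categories = c(ntg = "drug", nitroglycerin = "drug",
                        fever = "symptom", pain = "symptom")
  )
}
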