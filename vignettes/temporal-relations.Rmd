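---
title: "Temporal relation identification and classification in clinical narratives"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Temporal relation identification and classification in clinical narratives}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clintemprel)
```

## The task

A discharge summary describes clinically relevant events (tests, problems,
treatments, occurrences) and time expressions, and a reader reconstructs
their timeline.  `clintemprel` implements a knowledge-rich, hybrid system
for that reconstruction over gold-annotated entities: given an ordered pair
of annotated entities, decide (a) whether a temporal link (TLINK) holds and
(b) which of 12 fine-grained relation types it carries — Simultaneous,
Overlap, Before, After, Before_Overlap, Overlap_After, During, During_Inv,
Begins, Begun_By, Ends, Ended_By.  The 12 types form six inverse pairs
(`invert_relation()` is an involution), and merge into three broad
shared-task types: Overlap′ = {Overlap, Simultaneous, During}, Before′ =
{Before, Before_Overlap, Ended_By}, After′ = {After, Begun_By}; the four
remaining types are mapped by inverting the instance first (`map_12_to_3()`).

Two evaluation settings are supported.  In setting 1 the system labels a
given gold pair list; in setting 2 it must first *identify* which candidate
pairs are related, then classify the accepted ones.

## Inputs and annotation layers

Documents arrive as stand-off XML (events, TIMEX3 time expressions, section
times, TLINKs; offsets 0-based, half-open) and a JSON sidecar of linguistic
layers: tokens with lemma/POS/chunk, one constituency tree per sentence,
dependency edges, PropBank-style role frames and PDTB-style discourse
relations.  The sidecar replaces live runs of external parsers; this keeps
the feature extractors testable against *correct* linguistic structure and
the package free of gigabyte-scale models.  `fallback_annotate()` provides
a degraded mode (suffix-rule POS tags, flat trees, empty upper layers) so
the system still runs, with features from missing layers becoming NULL.
Fallback output should be treated as low-fidelity; none of the shipped
results rely on it.

## Features

Each candidate pair is represented by named features grouped into families
(the name prefix): the baseline six — lexical context and heads (`lex.`),
grammatical structure (`gram.`: POS context, PP/VP government, syntactic
dominance, tree path, dependency roles), entity attributes (`ent.`),
distance (`dist.`), lexical semantics (`sem.`) and section-creation-time
relations (`sct.`) — plus six knowledge-rich families: pairwise
combinations and root-path "traces" (`pair.`), thesaurus and wordnet-style
lexical relations (`thes.`, `wn.`; eight membership flags each, both
directions), predicate–argument relations (`srl.`: numbered arguments
A0–A5 and the directional/manner/temporal/cause modifiers, both
directions), discourse relations (`disc.`: explicit and implicit senses in
both argument orders, plus the triggering connective) and medical semantic
relations (`med.`, next section).  Extraction is a pure function of
(document, annotations, lexicons, model); missing information is NULL,
never fabricated.  Categorical features are one-hot encoded against a
vocabulary frozen at training time; unseen test values encode to zero.

Two constructions the literature names but does not define are fixed here:
"headed by a PP" means the entity span's minimal covering constituent is
labeled PP; "governed by a PP/VP" means the nearest such ancestor of the
entity's head leaf.  The head of an entity is the rightmost
noun/verb/adjective token in its span (else the last token).

## The medical semantic-relation ensemble

Clinical TREATMENT/TEST/PROBLEM pairs carry domain relations (11 classes:
TrIP, TrWP, TrCP, PIP, TeRP, TrAP, TrNAP, TeCP and three no-relation
classes) that are informative about temporal order — a treatment that
improves a problem is plausibly Ended_By it.  The classifier is an
ensemble of three members:

* a **flat-feature bank**: one-vs-rest linear SVMs over 37 feature groups
  (context, nearest-neighbour class percentages under five sequence
  representations, single-concept, offline encyclopedia link table,
  vicinity), regularization C = 10 000 — deliberately favouring fit over
  generalization;
* a **tree-kernel bank**: one-vs-rest SVMs (C = 100) over *simple
  expansion trees* — the parse fragment containing every node on the
  shortest path between the two entities plus those nodes' immediate
  non-leaf children, with each entity's covering-node label replaced by
  its type — compared by a convolution kernel that counts shared subtree
  fragments with decay λ = 0.4 per production (λ is configurable;
  0.4 is standard convolution-kernel practice);
* a **weighted nearest-neighbour classifier** over lemma sequences
  (generation method 3), token-level Levenshtein distance, k = 200
  neighbours: the nearest neighbour votes with weight 0.5 and each
  remaining neighbour with 0.5/199.  Smaller banks keep the 0.5 nearest
  weight and split the remainder evenly (with a warning); equidistant
  neighbours are ordered by training index for determinism.

Each member yields an 11-element probability vector.  SVM confidences are
min-max scaled to [0, 1] per instance and normalized to sum 1 (the mapping
from raw confidences to [0, 1] is underdetermined; per-instance min-max
was chosen as the least parametric option and is isolated in
`scale_confidences()`).  The vectors combine as

    C = 0.4 · P_tree + 0.5 · P_flat + 0.1 · P_knn

with the weights read from configuration, and the label is the argmax.
Classes absent from training contribute 0 from that member, with a
warning.  The three no-relation classes are downsampled before training to
at most twice the largest positive class (the exact ratio is not fixed by
the literature; 2× preserves the dominance of negatives while bounding
skew, and is configurable).  Evaluation is micro-F over the eight positive
classes only; correct no-relation predictions do not count.

## The rule engine

Hand-crafted rules are first-class: one per line, `id := condition =>
LABEL`, with conditions in a deliberately small, side-effect-free language
(feature tests, entity-type tests, regular-expression tests on the
inter-entity text; symbols outside the whitelist are rejected at parse
time, so a rule file cannot execute code).  A rule's accuracy is
correct/applied on the training instances; rules are ordered by
decreasing accuracy (ties: larger applied count, then id — the tie rule is
a determinism convention) and applied first-match.  The shipped starter
ruleset encodes the worked patterns behind each feature family — the
antonym-plus-*but* asynchrony rule, the destination-argument (A4) rule,
the Restatement and *thereafter*/Asynchronous discourse rules, five
medical-relation rules, and two negative identification rules.  The
antonym rule is restricted to same-sentence pairs, matching its motivating
construction (clauses coordinated by *but* inside one sentence).

## Architectures and the pipeline

Five architectures combine rules and classifiers: classifier only;
all rules; only rules measured at least 75% accurate; classifier trained
with every rule's prediction as an extra categorical feature; and the
hybrid — apply the ≥ 75% ruleset first and fall back to the
rules-as-features classifier.  Pure-rule systems must still answer on
instances no rule fires on; they predict the scheme's majority training
label (abstention would make the rule-only scores incomparable).

Classification uses four specialized multiclass SVMs by pair scheme:
same-sentence event–event and event–time pairs (negatives restricted to
adjacent unrelated pairs; test instances created the same way), event
pairs exactly one sentence apart (negatives from main events — the first
and last event of a sentence), and naively coreferent (head-matching,
case-insensitive on lemmas) event pairs farther apart.  The regularization
constant can be grid-tuned ({0.01 … 10 000}) on a 20% split.

Identification (setting 2) is hybrid too: classification rules act as
positive identification rules, negative rules come from the same file,
both re-measured and re-ordered on identification data; a learned binary
identifier per scheme is the fallback.  The identifier supports flat
(normalized linear kernel), tree (convolution kernel over simple expansion
trees with attributes substituted at the entity parent nodes) and
composite (`α·K_flat + (1−α)·K_tree`, α = 0.5 by default; the mixture form
is our choice, both kernels being normalized first) representations;
cross-sentence schemes have no spanning parse and fall back to flat.
Negative training instances are pruned to bound skew: heads more than 30
tokens apart within a sentence, or more than one sentence apart unless
coreferent (the caps are configurable; the locality mirrors the positive
instance creation rules).  The decision is signed distance ≥ threshold,
threshold 0 by default; `tune_thresholds()` scans observed development
distances per identifier independently and keeps the value maximizing
downstream classification F (micro and macro tuned separately).  Because
0 is always in the scanned grid, tuning can never lose to the default on
the development data.

## Evaluation

`score_12class()` reports micro P/R/F over instances and macro F as the
unweighted mean of the 12 per-class F-scores (absent classes contribute 0
— on corpora that do not exercise all 12 classes macro F is bounded below
1 by construction).  A predicted link matches gold directly or with both
order and label inverted.  `i2b2_score()` implements the closure-based
3-class protocol: precision is the fraction of system links verifiable in
the gold closure, recall the fraction of gold links verifiable in the
system closure.  The closure applies only sound rules over the broad
types — inverse augmentation and transitivity of Before′ chains; no
overlap-with-precedence composition is inferred (the official scorer's
exact rule table is not published with the papers; soundness was chosen
over completeness and the rule set is isolated in `close_links()`).

## The synthetic corpus generator

The restricted challenge corpora cannot be redistributed, so every module
is exercised on seeded synthetic documents (`generate_corpus()`).  Each
template transcribes one of the worked sentences motivating the feature
families — the antonym construction, the discharge-to-rehab destination
argument, the Restatement and *thereafter* discourse contexts, the
treatment-improves-problem sentence and its relatives — carrying its own
gold sidecar (tokens, tree, dependencies, frames, discourse) and a planted
gold link that the corresponding starter rule should recover.  Additional
templates cover the remaining semantic-relation classes and the worked
five-way sequence-generation sentence.  Documents have the two canonical
sections with section creation times; surface variation comes from small
per-slot synonym sets.  `plant_noise()` flips a seeded fraction of gold
labels to uniformly random different types and records every flip in the
manifest; under a flip rate φ a rule that is perfect on clean data has
expected measured accuracy 1 − φ.

What passing tests on this corpus do show: the feature extractors read the
annotation layers correctly, the rules and classifiers recover planted
regularities, the pipeline stages compose, and the scorers implement their
definitions.  What they do not show: performance on real clinical
language, whose lexical variety, annotation noise, long-range links and
parser errors the templates deliberately do not model.  Headline scores on
the restricted corpora are therefore out of scope here.

## Problem sizes and numerical choices

The shipped tests and the acceptance script use: a 20-document semantic
relation corpus (≈ 120 labeled pairs, all 11 classes), a 50-document
(tests) or 30-document (script) relation corpus at 6 planted links per
document, and a noise study of ≈ 1 800–5 400 instances at flip rate 0.25 —
sizes at which binomial fluctuation keeps measured rule accuracies well
inside (0.70, 0.80).  Probability vectors are validated to sum to 1 within
1e-9.  Kernel matrices are normalized with zero-self-similarity guards;
SVM decision signs are calibrated against training labels so "positive"
always means the relation side.  All sampling (template draws, variant
choices, downsampling, splits, flips) runs under explicit seeds restored
after use.

## Known limitations

* The fallback annotator is intentionally crude; run real parsers offline
  and supply sidecars for real text.
* Naive head-match coreference over-accepts; the identifier for that
  scheme inherits the problem.
* The closure rule set is sound but not complete, so `i2b2_score()` can
  differ from the official script on chains needing richer composition.
* The 167-feature inventory of the baseline cannot be reconciled
  feature-for-feature without the original implementation; families and
  members are implemented as described and counts are visible via
  `format_feature_vector()`.
* The medical-relation feature is gated intra-sententially by default (the
  subsystem is trained on intra-sentence pairs); a configuration switch
  (`medsem_scope: inter`) widens the gate for experimentation.
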