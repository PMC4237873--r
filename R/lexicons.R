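#' Lexical-relation lexicons and offline knowledge tables
#'
#' Two lexical-relation variants are supported: a thesaurus variant with
#' synonym / related-word / near-antonym / antonym lists per headword, and a
#' wordnet variant with hypernym / hyponym / troponym / similar lists.
#' Lookups are case-folded; a missing headword yields four empty lists.
#' A `lexicon_set` additionally bundles a sentiment table
#' (word -> "positive"/"negative"), a first-synset table, and an offline
#' encyclopedia link table (article-to-article links plus article
#' categories) replacing any live lookups.
#'
#' @param thesaurus,wordnet Named lists: headword -> list of four character
#'   vectors (see Details).
#' @param sentiment Named character vector: word -> sentiment category.
#' @param synsets Named character vector: word -> first synset id.
#' @param wiki_links Data frame with columns `from`, `to` (article titles).
#' @param wiki_categories Named character vector: title -> category.
#' @return A `lexicon_set`.
#' @export
lexicon_set <- function(thesaurus = list(), wordnet = list(),
                        sentiment = character(), synsets = character(),
                        wiki_links = data.frame(from = character(),
                                                to = character(),
                                                stringsAsFactors = FALSE),
                        wiki_categories = character()) {
  names(thesaurus) <- tolower(names(thesaurus))
  names(wordnet) <- tolower(names(wordnet))
  names(sentiment) <- tolower(names(sentiment))
  names(synsets) <- tolower(names(synsets))
  structure(list(thesaurus = thesaurus, wordnet = wordnet,
                 sentiment = sentiment, synsets = synsets,
                 wiki_links = wiki_links,
                 wiki_categories = wiki_categories),
            class = "lexicon_set")
}

thesaurus_relations <- function() {
  c("synonyms", "related", "near_antonyms", "antonyms")
}
wordnet_relations <- function() {
  c("hypernyms", "hyponyms", "troponyms", "similar")
}

#' Read a four-column lexical-relation lexicon file
#'
#' One headword per line followed by four tab-separated comma-delimited
#' relation lists (thesaurus variant: synonyms, related words, near-antonyms,
#' antonyms; wordnet variant: hypernyms, hyponyms, troponyms, similar).
#'
#' @param path File path.
#' @param variant `"thesaurus"` or `"wordnet"` (sets the list names).
#' @return Named list: headword -> list of four character vectors.
#' @export
read_lexicon <- function(path, variant = c("thesaurus", "wordnet")) {
  variant <- match.arg(variant)
  rel <- if (variant == "thesaurus") thesaurus_relations() else wordnet_relations()
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  out <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    head <- tolower(trimws(parts[1]))
    lists <- lapply(2:5, function(k) {
      if (k > length(parts) || !nzchar(trimws(parts[k]))) return(character())
      tolower(trimws(strsplit(parts[k], ",", fixed = TRUE)[[1]]))
    })
    names(lists) <- rel
    out[[head]] <- lists
  }
  out
}

#' Write a lexical-relation lexicon in the four-column format
#' @param lex Named list as produced by [read_lexicon()].
#' @param path Output path.
#' @return Invisibly `path`.
#' @export
write_lexicon <- function(lex, path) {
  lines <- vapply(names(lex), function(h) {
    paste(c(h, vapply(lex[[h]], paste, "", collapse = ",")),
          collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

lexicon_lookup <- function(lex_variant, word) {
  entry <- lex_variant[[tolower(word)]]
  if (is.null(entry)) {
    rel <- rep(list(character()), 4)
    return(rel)
  }
  entry
}
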