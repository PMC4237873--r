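#' Read an i2b2-dialect annotated clinical document
#'
#' Parses the stand-off XML dialect: a root element containing a `TEXT` node
#' and a `TAGS` node with `EVENT`, `TIMEX3`, `SECTIME`, `SECTION` and `TLINK`
#' elements carrying 0-based half-open character offsets.  TLINK attributes
#' are accepted under either `fromID`/`toID`/`type` or the lower-case
#' `fromid`/`toid`/`relType` spellings.  All spans are verified against the
#' text and relation strings are normalized to canonical taxonomy names.
#'
#' @param path Path to the XML file.
#' @return A [clinical_document()].
#' @export
parse_i2b2_xml <- function(path) {
  x <- tryCatch(xml2::read_xml(path), error = function(e) {
    stop("parse error in ", path, ": ", conditionMessage(e))
  })
  text_node <- xml2::xml_find_first(x, ".//TEXT")
  if (inherits(text_node, "xml_missing")) {
    stop("parse error: no TEXT element in ", path)
  }
  text <- xml2::xml_text(text_node)
  id <- xml2::xml_attr(x, "id")
  if (is.na(id)) id <- sub("\\.xml$", "", basename(path))

  attr1 <- function(nodes, ...) {
    # first present attribute among the given spellings
    alts <- c(...)
    out <- rep(NA_character_, length(nodes))
    for (a in alts) {
      v <- xml2::xml_attr(nodes, a)
      out[is.na(out)] <- v[is.na(out)]
    }
    out
  }
  grab <- function(tag) xml2::xml_find_all(x, paste0(".//TAGS/", tag))

  ev <- grab("EVENT")
  events <- data.frame(
    id = attr1(ev, "id"),
    start = as.integer(attr1(ev, "start")),
    end = as.integer(attr1(ev, "end")),
    text = attr1(ev, "text"),
    type = toupper(attr1(ev, "type")),
    polarity = attr1(ev, "polarity"),
    modality = attr1(ev, "modality"),
    stringsAsFactors = FALSE)
  if (!nrow(events)) events <- empty_events()

  tm <- grab("TIMEX3")
  times <- data.frame(
    id = attr1(tm, "id"),
    start = as.integer(attr1(tm, "start")),
    end = as.integer(attr1(tm, "end")),
    text = attr1(tm, "text"),
    type = toupper(attr1(tm, "type")),
    val = attr1(tm, "val"),
    mod = attr1(tm, "mod"),
    stringsAsFactors = FALSE)
  if (!nrow(times)) times <- empty_times()

  st <- grab("SECTIME")
  sectimes <- data.frame(
    id = attr1(st, "id"),
    section = toupper(attr1(st, "type")),
    start = as.integer(attr1(st, "start")),
    end = as.integer(attr1(st, "end")),
    value = attr1(st, "dvalue"),
    stringsAsFactors = FALSE)
  if (!nrow(sectimes)) sectimes <- empty_sectimes()

  sc <- grab("SECTION")
  sections <- data.frame(
    name = attr1(sc, "name"),
    start = as.integer(attr1(sc, "start")),
    end = as.integer(attr1(sc, "end")),
    stringsAsFactors = FALSE)
  if (!nrow(sections)) sections <- empty_sections()

  tl <- grab("TLINK")
  tlinks <- if (length(tl)) {
    data.frame(
      id = attr1(tl, "id"),
      from = attr1(tl, "fromID", "fromid"),
      to = attr1(tl, "toID", "toid"),
      relation = normalize_relation(attr1(tl, "type", "relType")),
      origin = "GOLD",
      stringsAsFactors = FALSE)
  } else empty_tlinks()

  clinical_document(id = id, text = text, sections = sections,
                    events = events, times = times, sectimes = sectimes,
                    tlinks = tlinks)
}

#' Write a clinical document as stand-off i2b2-dialect XML
#'
#' The output re-parses to a structurally equal document.  TLINK `origin`
#' is dropped on write; links carrying the `NO_RELATION` sentinel are
#' refused (they are pipeline internals, never corpus annotations).
#'
#' @param doc A [clinical_document()].
#' @param path Output file path.
#' @return Invisibly `path`.
#' @export
write_i2b2_xml <- function(doc, path) {
  validate_document(doc)
  if (nrow(doc$tlinks) && any(doc$tlinks$relation == no_relation())) {
    stop("taxonomy error: NO_RELATION links cannot be serialized")
  }
  root <- xml2::xml_new_root("ClinicalNarrativeTemporalAnnotation",
                             id = doc$id)
  xml2::xml_add_child(root, "TEXT", doc$text)
  tags <- xml2::xml_add_child(root, "TAGS")
  add <- function(tag, attrs) {
    do.call(xml2::xml_add_child,
            c(list(tags, tag), as.list(vapply(attrs, as.character, ""))))
  }
  sc <- doc$sections
  for (i in seq_len(nrow(sc))) {
    add("SECTION", list(name = sc$name[i], start = sc$start[i],
                        end = sc$end[i]))
  }
  ev <- doc$events
  for (i in seq_len(nrow(ev))) {
    add("EVENT", list(id = ev$id[i], start = ev$start[i], end = ev$end[i],
                      text = ev$text[i], type = ev$type[i],
                      polarity = ev$polarity[i], modality = ev$modality[i]))
  }
  tm <- doc$times
  for (i in seq_len(nrow(tm))) {
    add("TIMEX3", list(id = tm$id[i], start = tm$start[i], end = tm$end[i],
                       text = tm$text[i], type = tm$type[i],
                       val = tm$val[i], mod = tm$mod[i]))
  }
  st <- doc$sectimes
  for (i in seq_len(nrow(st))) {
    add("SECTIME", list(id = st$id[i], start = st$start[i], end = st$end[i],
                        text = span_text(doc$text, st$start[i], st$end[i]),
                        type = st$section[i], dvalue = st$value[i]))
  }
  tl <- doc$tlinks
  for (i in seq_len(nrow(tl))) {
    add("TLINK", list(id = tl$id[i], fromID = tl$from[i], toID = tl$to[i],
                      type = tl$relation[i]))
  }
  tryCatch(xml2::write_xml(root, path),
           error = function(e) stop("I/O error writing ", path, ": ",
                                    conditionMessage(e)))
  invisible(path)
}
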