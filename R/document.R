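#' Clinical document container
#'
#' A `clindoc` bundles the raw text of one discharge summary with its gold
#' annotation layers: events, time expressions, section creation times,
#' section boundaries and temporal links.  Character offsets are 0-based,
#' half-open (`start` inclusive, `end` exclusive), so the annotated substring
#' is `substr(text, start + 1, end)`.
#'
#' @param id Document identifier.
#' @param text Document text (single string).
#' @param sections Data frame with columns `name`, `start`, `end`; the two
#'   canonical sections are `"HISTORY_OF_PRESENT_ILLNESS"` and
#'   `"HOSPITAL_COURSE"`.
#' @param events Data frame with columns `id`, `start`, `end`, `text`,
#'   `type`, `polarity`, `modality`.
#' @param times Data frame with columns `id`, `start`, `end`, `text`,
#'   `type`, `val`, `mod`.
#' @param sectimes Data frame with columns `id`, `section`, `start`, `end`,
#'   `value` (`section` is `"ADMISSION"` or `"DISCHARGE"`).
#' @param tlinks Data frame with columns `id`, `from`, `to`, `relation`,
#'   `origin` (`origin` one of `"GOLD"`, `"RULE"`, `"CLASSIFIER"`).
#' @return An object of class `clindoc`.
#' @export
clinical_document <- function(id, text,
                              sections = empty_sections(),
                              events = empty_events(),
                              times = empty_times(),
                              sectimes = empty_sectimes(),
                              tlinks = empty_tlinks()) {
  doc <- structure(
    list(id = id, text = text, sections = sections, events = events,
         times = times, sectimes = sectimes, tlinks = tlinks),
    class = "clindoc")
  validate_document(doc)
  doc
}

#' @rdname clinical_document
#' @export
empty_events <- function() {
  data.frame(id = character(), start = integer(), end = integer(),
             text = character(), type = character(), polarity = character(),
             modality = character(), stringsAsFactors = FALSE)
}

#' @rdname clinical_document
#' @export
empty_times <- function() {
  data.frame(id = character(), start = integer(), end = integer(),
             text = character(), type = character(), val = character(),
             mod = character(), stringsAsFactors = FALSE)
}

#' @rdname clinical_document
#' @export
empty_sectimes <- function() {
  data.frame(id = character(), section = character(), start = integer(),
             end = integer(), value = character(), stringsAsFactors = FALSE)
}

#' @rdname clinical_document
#' @export
empty_tlinks <- function() {
  data.frame(id = character(), from = character(), to = character(),
             relation = character(), origin = character(),
             stringsAsFactors = FALSE)
}

#' @rdname clinical_document
#' @export
empty_sections <- function() {
  data.frame(name = character(), start = integer(), end = integer(),
             stringsAsFactors = FALSE)
}

event_types <- function() {
  c("TEST", "PROBLEM", "TREATMENT", "CLINICAL_DEPT", "EVIDENTIAL",
    "OCCURRENCE")
}

time_types <- function() c("DATE", "TIME", "DURATION", "FREQUENCY")

span_text <- function(text, start, end) {
  if (length(start) == 0L) return(character())
  substr(rep(text, length(start)), start + 1L, end)
}

#' Validate the structural invariants of a clinical document
#'
#' Checks that every annotation span lies inside the text and matches its
#' recorded surface string, that entity ids are unique, that every TLINK
#' endpoint resolves to an annotated entity, that relation strings are
#' taxonomy members, and that section intervals do not overlap.
#'
#' @param doc A `clindoc`.
#' @return Invisibly `TRUE`; stops with an informative error otherwise.
#' @export
validate_document <- function(doc) {
  stopifnot(inherits(doc, "clindoc"))
  n <- nchar(doc$text)
  check_span <- function(df, what) {
    bad <- which(df$start < 0L | df$end > n | df$start >= df$end)
    if (length(bad)) {
      stop("integrity error: ", what, " ", df$id[bad[1]],
           " has span outside the document text")
    }
  }
  check_span(doc$events, "EVENT")
  check_span(doc$times, "TIMEX3")
  if (nrow(doc$sectimes)) check_span(doc$sectimes, "SECTIME")
  for (layer in c("events", "times")) {
    df <- doc[[layer]]
    got <- span_text(doc$text, df$start, df$end)
    bad <- which(got != df$text)
    if (length(bad)) {
      stop("integrity error: annotation ", df$id[bad[1]],
           " text does not match the document substring at its span")
    }
  }
  if (nrow(doc$events) && !all(doc$events$type %in% event_types())) {
    stop("taxonomy error: unknown event type")
  }
  if (nrow(doc$times) && !all(doc$times$type %in% time_types())) {
    stop("taxonomy error: unknown time expression type")
  }
  if (nrow(doc$sectimes)) {
    if (!all(doc$sectimes$section %in% c("ADMISSION", "DISCHARGE"))) {
      stop("taxonomy error: SECTIME section must be ADMISSION or DISCHARGE")
    }
    if (anyDuplicated(doc$sectimes$section)) {
      stop("integrity error: at most one SECTIME per section")
    }
  }
  ids <- c(doc$events$id, doc$times$id, doc$sectimes$id)
  if (anyDuplicated(ids)) {
    stop("integrity error: duplicate entity id ", ids[duplicated(ids)][1])
  }
  if (nrow(doc$tlinks)) {
    normalize_relation(doc$tlinks$relation)
    unresolved <- setdiff(c(doc$tlinks$from, doc$tlinks$to), ids)
    if (length(unresolved)) {
      stop("integrity error: TLINK endpoint ", unresolved[1],
           " does not resolve to an annotation")
    }
    if (any(doc$tlinks$from == doc$tlinks$to)) {
      stop("integrity error: TLINK source equals target")
    }
  }
  if (nrow(doc$sections) > 1L) {
    o <- order(doc$sections$start)
    s <- doc$sections[o, ]
    if (any(s$end[-nrow(s)] > s$start[-1L])) {
      stop("integrity error: section intervals overlap")
    }
  }
  invisible(TRUE)
}

#' Look up an annotated entity (event or time) by id
#'
#' @param doc A `clindoc`.
#' @param id Entity id.
#' @return A one-row data frame with an added `kind` column
#'   (`"EVENT"` or `"TIME"`).
#' @export
get_entity <- function(doc, id) {
  i <- match(id, doc$events$id)
  if (!is.na(i)) {
    out <- doc$events[i, , drop = FALSE]
    out$kind <- "EVENT"
    return(out)
  }
  i <- match(id, doc$times$id)
  if (!is.na(i)) {
    out <- doc$times[i, , drop = FALSE]
    out$kind <- "TIME"
    return(out)
  }
  stop("integrity error: no entity with id ", id)
}

#' @export
print.clindoc <- function(x, ...) {
  cat(sprintf("<clindoc %s: %d chars, %d events, %d times, %d tlinks>\n",
              x$id, nchar(x$text), nrow(x$events), nrow(x$times),
              nrow(x$tlinks)))
  invisible(x)
}
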