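#' Relation-type taxonomy for clinical temporal links
#'
#' The i2b2-style corpus annotates temporal relations with 12 fine-grained
#' types defined on an ordered pair (e1, e2).  The shared-task evaluation
#' merges them into three broad types (here `BEFORE3`, `AFTER3`, `OVERLAP3`),
#' inverting the instance order for the four types whose reading points the
#' "wrong" way.  A `NO_RELATION` sentinel exists for pipeline internals
#' (identification negatives) and is never serialized.
#'
#' @name taxonomy
NULL

#' The 12 fine-grained temporal relation types
#' @return Character vector of the 12 canonical fine type names.
#' @export
fine_relation_types <- function() {
  c("Simultaneous", "Overlap", "Before", "After", "Before_Overlap",
    "Overlap_After", "During", "During_Inv", "Begins", "Begun_By",
    "Ends", "Ended_By")
}

#' The 3 broad shared-task relation types
#' @return Character vector `c("BEFORE3", "AFTER3", "OVERLAP3")`.
#' @export
broad_relation_types <- function() {
  c("BEFORE3", "AFTER3", "OVERLAP3")
}

#' Sentinel label for candidate pairs without a temporal relation
#' @return The string `"NO_RELATION"`.
#' @export
no_relation <- function() "NO_RELATION"

.inverse_table <- c(
  Before         = "After",
  After          = "Before",
  Before_Overlap = "Overlap_After",
  Overlap_After  = "Before_Overlap",
  During         = "During_Inv",
  During_Inv     = "During",
  Begins         = "Begun_By",
  Begun_By       = "Begins",
  Ends           = "Ended_By",
  Ended_By       = "Ends",
  Simultaneous   = "Simultaneous",
  # The corpus description fixes five inverse pairs plus the symmetric
  # Simultaneous; Overlap is taken as its own inverse so that inversion is a
  # total involution over the taxonomy.
  Overlap        = "Overlap"
)

# Direct (non-inverted) membership of fine types in broad types.  The four
# remaining fine types are inverted first, then looked up here.
.broad_table <- c(
  Overlap        = "OVERLAP3",
  Simultaneous   = "OVERLAP3",
  During         = "OVERLAP3",
  Before         = "BEFORE3",
  Before_Overlap = "BEFORE3",
  Ended_By       = "BEFORE3",
  After          = "AFTER3",
  Begun_By       = "AFTER3"
)

#' Normalize a relation string to its canonical fine-type name
#'
#' Accepts case-insensitive spellings as found in corpus XML
#' (e.g. `"SIMULTANEOUS"`, `"before_overlap"`).
#'
#' @param x Character vector of relation strings.
#' @return Canonical fine type names.
#' @export
normalize_relation <- function(x) {
  canon <- c(fine_relation_types(), broad_relation_types(), no_relation())
  idx <- match(toupper(x), toupper(canon))
  if (anyNA(idx)) {
    stop("taxonomy error: unknown relation string(s): ",
         paste(unique(x[is.na(idx)]), collapse = ", "))
  }
  canon[idx]
}

#' Invert a fine relation type
#'
#' Reading the relation on the reversed pair: if (e1, e2) has type r, then
#' (e2, e1) has type `invert_relation(r)`.  Inversion is an involution over
#' the 12 fine types.
#'
#' @param r Character vector of fine relation types.
#' @return The inverse fine type(s).
#' @export
invert_relation <- function(r) {
  out <- .inverse_table[r]
  if (anyNA(out)) {
    stop("taxonomy error: invert_relation() is defined on the 12 fine types ",
         "only; got: ", paste(unique(r[is.na(out)]), collapse = ", "))
  }
  unname(out)
}

#' Map a fine-typed temporal link to its broad shared-task assertion
#'
#' `OVERLAP3` collects Overlap, Simultaneous and During; `BEFORE3` collects
#' Before, Before_Overlap and Ended_By; `AFTER3` collects After and Begun_By.
#' The remaining four types (Overlap_After, During_Inv, Begins, Ends) are
#' first replaced by the inverted instance -- source and target swapped, type
#' inverted -- and then mapped.  An instance annotated `Ends` on (e1, e2) is
#' thus reported as (e2, e1) with `BEFORE3`.
#'
#' @param link A one-row TLINK data frame (columns `from`, `to`, `relation`)
#'   or a TLINK data frame of several rows.
#' @return The link(s) with `relation` replaced by a broad type and
#'   endpoints swapped where inversion applied.
#' @export
map_12_to_3 <- function(link) {
  stopifnot(is.data.frame(link), all(c("from", "to", "relation") %in% names(link)))
  rel <- normalize_relation(link$relation)
  if (any(!rel %in% fine_relation_types())) {
    stop("taxonomy error: map_12_to_3() expects fine relation types")
  }
  flip <- !(rel %in% names(.broad_table))
  if (any(flip)) {
    tmp <- link$from[flip]
    link$from[flip] <- link$to[flip]
    link$to[flip] <- tmp
    rel[flip] <- invert_relation(rel[flip])
  }
  link$relation <- unname(.broad_table[rel])
  link
}
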