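#' Feature vectors and one-hot encoding
#'
#' A feature vector is a named list whose values are length-1 character
#' strings (categorical), numbers (counts / binary flags) or `NA` (the legal
#' "not applicable" value).  The feature family is the name prefix up to the
#' first dot (`lex.`, `gram.`, `ent.`, `dist.`, `sem.`, `sct.`, `pair.`,
#' `thes.`, `wn.`, `srl.`, `disc.`, `med.`, `rule.`, plus the semantic
#' relation subsystem's `ctx.`, `sim.`, `con.`, `wik.`, `vic.`).
#'
#' Categorical features are one-hot encoded against a vocabulary frozen at
#' training time; unseen test values map to all-zero columns.
#'
#' @name encoding
NULL

#' Family tag of each feature in a vector
#' @param fv A feature vector (named list).
#' @return Named character vector of family prefixes.
#' @export
feature_families <- function(fv) {
  fams <- sub("\\..*$", "", names(fv))
  names(fams) <- names(fv)
  fams
}

#' Build a frozen encoding vocabulary from training feature vectors
#'
#' @param fvs List of feature vectors.
#' @return A `feature_vocab`: for every feature name, either `"numeric"` or
#'   the sorted set of observed categorical values.
#' @export
build_feature_vocab <- function(fvs) {
  all_names <- unique(unlist(lapply(fvs, names)))
  vocab <- lapply(all_names, function(nm) {
    vals <- lapply(fvs, function(fv) fv[[nm]])
    vals <- vals[!vapply(vals, function(v) is.null(v) || all(is.na(v)), TRUE)]
    if (!length(vals)) return(list(kind = "numeric"))
    if (all(vapply(vals, is.numeric, TRUE))) return(list(kind = "numeric"))
    list(kind = "categorical",
         levels = sort(unique(vapply(vals, as.character, ""))))
  })
  names(vocab) <- all_names
  structure(vocab, class = "feature_vocab")
}

#' Encode feature vectors as a numeric design matrix
#'
#' @param fvs List of feature vectors.
#' @param vocab A `feature_vocab` from [build_feature_vocab()].
#' @return Numeric matrix; one row per vector.  Numeric features pass
#'   through (`NA` becomes 0); categorical features expand to indicator
#'   columns `name=value`; unseen values yield all zeros.
#' @export
encode_features <- function(fvs, vocab) {
  cols <- character()
  for (nm in names(vocab)) {
    v <- vocab[[nm]]
    if (v$kind == "numeric") cols <- c(cols, nm)
    else cols <- c(cols, paste0(nm, "=", v$levels))
  }
  out <- matrix(0, nrow = length(fvs), ncol = length(cols),
                dimnames = list(NULL, cols))
  for (r in seq_along(fvs)) {
    fv <- fvs[[r]]
    for (nm in intersect(names(fv), names(vocab))) {
      val <- fv[[nm]]
      if (is.null(val) || all(is.na(val))) next
      v <- vocab[[nm]]
      if (v$kind == "numeric") {
        if (is.numeric(val)) out[r, nm] <- val
      } else {
        col <- paste0(nm, "=", as.character(val))
        if (col %in% cols) out[r, col] <- 1
      }
    }
  }
  out
}

#' Dump a feature vector as sparse name:value text lines
#' @param fv A feature vector.
#' @return Character vector of `name:value` lines (NA features omitted).
#' @export
format_feature_vector <- function(fv) {
  keep <- !vapply(fv, function(v) is.null(v) || all(is.na(v)), TRUE)
  vapply(names(fv)[keep],
         function(nm) paste0(nm, ":", as.character(fv[[nm]])), "")
}
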