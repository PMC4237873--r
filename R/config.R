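#' Default configuration
#'
#' All tunable parameters of the system, grouped by subsystem.  A YAML
#' configuration file with the same keys can override any subset (see
#' [load_config()]).
#'
#' Key values: ensemble combination weights (tree 0.4, flat 0.5, knn 0.1),
#' flat semrel regularization C = 10000, tree-bank C = 100, tree-kernel
#' decay lambda = 0.4, k = 200 nearest neighbours, no-relation downsampling
#' at twice the largest positive class, composite-kernel mixing weight
#' alpha = 0.5, identification thresholds default 0, negative-instance
#' pruning caps (30 tokens intra-sentence, 1 sentence otherwise), and the
#' regularization grid used when tuning the specialized classifiers.
#'
#' @return A nested named list.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    semrel = list(
      weights = c(tree = 0.4, flat = 0.5, knn = 0.1),
      C_flat = 10000,
      C_tree = 100,
      lambda = 0.4,
      knn_k = 200L,
      downsample_factor = 2L,
      tree_ratio = 1,
      tree_ratio_grid = c(1, 2, 4),
      tune_tree_ratio = FALSE,
      seed = 1L
    ),
    classifier = list(
      C = 10,
      C_grid = c(0.01, 0.1, 1, 10, 100, 1000, 10000),
      tune_C = FALSE,
      dev_fraction = 0.2,
      seed = 1L
    ),
    identifier = list(
      mode = "FLAT",
      alpha = 0.5,
      lambda = 0.4,
      C = 10,
      threshold = 0,
      prune = TRUE,
      max_token_distance = 30L,
      max_sentence_distance = 1L,
      seed = 1L
    ),
    rules = list(min_accuracy = 0.75),
    medsem_scope = "intra"
  )
}

#' Load a YAML configuration, merged over the defaults
#' @param path YAML file path (optional).
#' @return The merged configuration list.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  user <- yaml::read_yaml(path)
  if (!is.null(user$semrel$weights)) {
    user$semrel$weights <- unlist(user$semrel$weights)
  }
  modify_list(cfg, user)
}

# recursive utils::modifyList that tolerates NULL overrides
modify_list <- function(base, override) {
  if (is.null(override)) return(base)
  utils::modifyList(base, override)
}

.warned <- new.env(parent = emptyenv())

# emit a given warning only once per session
warn_once <- function(key, msg) {
  if (is.null(.warned[[key]])) {
    assign(key, TRUE, envir = .warned)
    warning(msg, call. = FALSE)
  }
  invisible(NULL)
}

# run code under a temporary RNG state seeded with `seed`
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  code
}
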