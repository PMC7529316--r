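#' PathwayRef: reference catalog of pathways and enzymatic reactions
#'
#' Holds the universal label set of \eqn{t} pathway definitions and the
#' universal reaction set of \eqn{r} EC numbers, plus the inverse map from
#' each reaction to the pathways containing it. The reaction ordering is
#' lexicographic over EC strings and the pathway ordering is fixed at load
#' time; together they define the column order of every vector and matrix
#' produced downstream (abundance blocks, label matrices, model weights).
#'
#' @slot pathwayIds character vector of unique pathway identifiers (length t).
#' @slot pathwayNames character vector of display names, parallel to ids.
#' @slot reactionSets list of character vectors: normalized ECs per pathway.
#'   A pathway may have an empty reaction set (pathways with few or no
#'   EC-mappable reactions exist and are retained as labels).
#' @slot keySets list of character vectors: key reactions, each a subset of
#'   the pathway's reaction set.
#' @slot taxonomicRange list of character vectors (may be empty).
#' @slot hierarchy list of character vectors: ordered class path (may be empty).
#' @slot reactions character vector: the reaction universe, sorted (length r).
#' @slot reactionMap named list: EC string -> character vector of pathway ids.
#'
#' @seealso [loadReference()], [saveReference()], [pathwayCoverage()]
#' @export
setClass("PathwayRef", slots = c(
  pathwayIds = "character",
  pathwayNames = "character",
  reactionSets = "list",
  keySets = "list",
  taxonomicRange = "list",
  hierarchy = "list",
  reactions = "character",
  reactionMap = "list"
))

setValidity("PathwayRef", function(object) {
  t <- length(object@pathwayIds)
  if (t == 0L) return("reference must contain at least one pathway")
  if (anyDuplicated(object@pathwayIds)) {
    dup <- object@pathwayIds[duplicated(object@pathwayIds)]
    return(paste0("duplicate pathway id(s): ", paste(unique(dup), collapse = ", ")))
  }
  if (any(!nzchar(object@pathwayIds))) return("pathway ids must be nonempty")
  for (nm in c("pathwayNames", "reactionSets", "keySets", "taxonomicRange", "hierarchy")) {
    if (length(slot(object, nm)) != t) return(paste0(nm, " length must equal number of pathways"))
  }
  for (j in seq_len(t)) {
    if (!all(object@keySets[[j]] %in% object@reactionSets[[j]])) {
      return(paste0("key reactions not a subset of reactions for pathway ",
                    object@pathwayIds[j]))
    }
  }
  allEC <- unique(unlist(object@reactionSets, use.names = FALSE))
  if (!setequal(allEC %||% character(), object@reactions)) {
    return("reaction universe must equal the union of pathway reaction sets")
  }
  if (is.unsorted(object@reactions, strictly = TRUE)) {
    return("reaction universe must be strictly sorted")
  }
  if (!identical(sort(names(object@reactionMap), method = "radix"), object@reactions)) {
    return("reactionMap names must equal the reaction universe")
  }
  # inverse-map consistency: bipartite edge conservation
  nEdgesFwd <- sum(lengths(object@reactionSets))
  nEdgesInv <- sum(lengths(object@reactionMap))
  if (nEdgesFwd != nEdgesInv) return("reactionMap is not the inverse of pathway reaction sets")
  TRUE
})

#' PathwayDataset: per-sample EC abundance profiles with optional labels
#'
#' A dataset of \eqn{n} samples, each a sparse map from EC number to a
#' non-negative abundance, optionally carrying an \eqn{n \times t} binary
#' pathway label matrix aligned to a [PathwayRef-class] pathway order.
#'
#' @slot sampleIds character vector of unique nonempty sample ids.
#' @slot abundances list of named numeric vectors (EC -> abundance >= 0).
#' @slot labels either NULL or an n x t binary matrix with pathway-id colnames.
#' @export
setClass("PathwayDataset", slots = c(
  sampleIds = "character",
  abundances = "list",
  labels = "ANY"
))

setValidity("PathwayDataset", function(object) {
  n <- length(object@sampleIds)
  if (anyDuplicated(object@sampleIds)) return("sample ids must be unique")
  if (any(!nzchar(object@sampleIds))) return("sample ids must be nonempty")
  if (length(object@abundances) != n) return("abundances length must equal number of samples")
  for (i in seq_len(n)) {
    a <- object@abundances[[i]]
    if (length(a)) {
      if (is.null(names(a)) || any(!nzchar(names(a)))) return("abundance vectors must be EC-named")
      if (any(!is.finite(a)) || any(a < 0)) return("abundances must be finite and >= 0")
    }
  }
  if (!is.null(object@labels)) {
    Y <- object@labels
    if (!is.matrix(Y) || nrow(Y) != n) return("labels must be an n x t matrix")
    if (is.null(colnames(Y))) return("label matrix must have pathway-id colnames")
    if (!all(Y %in% c(0, 1))) return("label entries must be 0/1")
  }
  TRUE
})

#' PathwayModel: trained one-vs-rest elastic-net logistic regression model
#'
#' Weight matrix \eqn{\Theta} (one row per pathway, intercept in column 1)
#' plus everything needed to reproduce the feature transformation at
#' prediction time: the feature configuration, the fitted min-max scaler,
#' and fingerprints of the feature layout and pathway order.
#'
#' @slot theta t x (m+1) numeric weight matrix; column 1 is the intercept.
#' @slot hyper list of training hyperparameters (see [hyperParameters()]).
#' @slot featureConfig the [featureConfig()] used to build features.
#' @slot scaler fitted min-max scaler (list with min/range), or empty list.
#' @slot pathwayIds character vector: pathway order of theta rows.
#' @slot featureNames character vector of m feature names (no intercept).
#' @slot layout data.frame of feature block layout (block, offset, width).
#' @slot fingerprints named character vector: features and pathway fingerprints.
#' @export
setClass("PathwayModel", slots = c(
  theta = "matrix",
  hyper = "list",
  featureConfig = "list",
  scaler = "list",
  pathwayIds = "character",
  featureNames = "character",
  layout = "data.frame",
  fingerprints = "character"
))

setValidity("PathwayModel", function(object) {
  if (!all(is.finite(object@theta))) return("model weights must be finite")
  if (nrow(object@theta) != length(object@pathwayIds)) {
    return("theta must have one row per pathway")
  }
  if (ncol(object@theta) != length(object@featureNames) + 1L) {
    return("theta must have one column per feature plus the intercept")
  }
  TRUE
})
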