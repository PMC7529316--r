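#' Construct a pathway reference from pathway definitions
#'
#' @param pathways a list of pathway definitions, each a list with elements
#'   \code{id} (required), \code{name}, \code{reactions} (character vector of
#'   EC numbers, may be empty), \code{key_reactions}, \code{taxonomic_range},
#'   \code{hierarchy}. Pathway order is preserved; the reaction universe is
#'   the sorted union of all reaction sets.
#' @return a validated [PathwayRef-class] object.
#' @examples
#' ref <- PathwayRef(list(
#'   list(id = "P1", reactions = c("1.1.1.1")),
#'   list(id = "P2", reactions = c("1.1.1.1", "2.7.1.1"))
#' ))
#' nPathways(ref)
#' @export
PathwayRef <- function(pathways) {
  if (!is.list(pathways) || length(pathways) == 0L) {
    stop("reference must contain at least one pathway", call. = FALSE)
  }
  ids <- vapply(pathways, function(p) as.character(p$id %||% ""), character(1))
  if (anyDuplicated(ids)) {
    stop("duplicate pathway id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  nms <- vapply(pathways, function(p) as.character(p$name %||% p$id %||% ""), character(1))
  getEC <- function(p, field) {
    v <- unlist(p[[field]], use.names = FALSE)
    if (is.null(v) || length(v) == 0L) character() else unique(normalizeEC(v))
  }
  rsets <- lapply(pathways, getEC, "reactions")
  ksets <- lapply(pathways, getEC, "key_reactions")
  tax <- lapply(pathways, function(p) as.character(unlist(p$taxonomic_range, use.names = FALSE) %||% character()))
  hier <- lapply(pathways, function(p) as.character(unlist(p$hierarchy, use.names = FALSE) %||% character()))
  universe <- .ecSort(unlist(rsets, use.names = FALSE) %||% character())
  rmap <- setNames(vector("list", length(universe)), universe)
  for (j in seq_along(ids)) {
    for (ec in rsets[[j]]) rmap[[ec]] <- c(rmap[[ec]], ids[j])
  }
  new("PathwayRef",
      pathwayIds = ids, pathwayNames = nms,
      reactionSets = setNames(rsets, ids), keySets = setNames(ksets, ids),
      taxonomicRange = setNames(tax, ids), hierarchy = setNames(hier, ids),
      reactions = universe, reactionMap = rmap)
}

#' Read / write a pathway reference in the JSON interchange format
#'
#' The interchange schema is a JSON object with a \code{"pathways"} array;
#' each entry has \code{id} (required), \code{name}, \code{reactions}
#' (array of EC strings), and optional \code{key_reactions},
#' \code{taxonomic_range}, \code{hierarchy}. Pathway order follows file
#' order; the reaction universe is sorted lexicographically. Save/load is an
#' identity on the data model and stable on ordering.
#'
#' @param path path to a JSON file.
#' @param ref a [PathwayRef-class] object.
#' @return \code{loadReference} returns a validated [PathwayRef-class];
#'   \code{saveReference} returns \code{path} invisibly.
#' @examples
#' ref <- loadReference(system.file("extdata", "synthetic_reference.json",
#'                                  package = "pathlogit"))
#' nPathways(ref)
#' @export
loadReference <- function(path) {
  if (!file.exists(path)) stop("reference file not found: ", path, call. = FALSE)
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(obj$pathways) || length(obj$pathways) == 0L) {
    stop("reference file has no pathways: ", path, call. = FALSE)
  }
  PathwayRef(obj$pathways)
}

#' @rdname loadReference
#' @export
saveReference <- function(ref, path) {
  stopifnot(is(ref, "PathwayRef"))
  pw <- lapply(seq_along(ref@pathwayIds), function(j) {
    list(id = ref@pathwayIds[j],
         name = ref@pathwayNames[j],
         reactions = as.list(ref@reactionSets[[j]]),
         key_reactions = as.list(ref@keySets[[j]]),
         taxonomic_range = as.list(ref@taxonomicRange[[j]]),
         hierarchy = as.list(ref@hierarchy[[j]]))
  })
  jsonlite::write_json(list(pathways = pw), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Export a reference as a pathway/reaction TSV
#'
#' One row per (pathway, reaction) pair with an \code{is_key} 0/1 flag.
#'
#' @inheritParams saveReference
#' @param path output TSV path.
#' @export
referenceToTSV <- function(ref, path) {
  stopifnot(is(ref, "PathwayRef"))
  rows <- do.call(rbind, lapply(seq_along(ref@pathwayIds), function(j) {
    rs <- ref@reactionSets[[j]]
    if (!length(rs)) return(NULL)
    data.frame(pathway_id = ref@pathwayIds[j], ec = rs,
               is_key = as.integer(rs %in% ref@keySets[[j]]))
  }))
  if (is.null(rows)) rows <- data.frame(pathway_id = character(), ec = character(), is_key = integer())
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Pathway coverage of an observed reaction set
#'
#' Coverage of pathway \eqn{j} is the fraction of its constituent reactions
#' present among the observed reactions:
#' \eqn{|reactions_j \cap observed| / |reactions_j|}, in \eqn{[0, 1]}.
#' A pathway with an empty reaction set has coverage 0 by convention.
#'
#' @param ref a [PathwayRef-class].
#' @param observed character vector of observed (normalized) EC numbers, or a
#'   named abundance vector whose names are ECs (positive entries count as
#'   observed).
#' @param id optional single pathway id; if given, a scalar coverage is
#'   returned, otherwise the named t-vector over all pathways.
#' @return numeric coverage value(s) in \eqn{[0, 1]}.
#' @examples
#' ref <- PathwayRef(list(list(id = "P1",
#'   reactions = c("1.1.1.1", "2.2.2.2", "3.3.3.3"))))
#' pathwayCoverage(ref, c("1.1.1.1", "2.2.2.2"))   # 2/3
#' @export
pathwayCoverage <- function(ref, observed, id = NULL) {
  stopifnot(is(ref, "PathwayRef"))
  obs <- .observedSet(observed)
  cov1 <- function(rs) {
    if (!length(rs)) return(0)
    sum(rs %in% obs) / length(rs)
  }
  if (!is.null(id)) {
    j <- match(id, ref@pathwayIds)
    if (is.na(j)) stop("unknown pathway id: ", id, call. = FALSE)
    return(cov1(ref@reactionSets[[j]]))
  }
  setNames(vapply(ref@reactionSets, cov1, numeric(1)), ref@pathwayIds)
}

# Key-reaction coverage, same convention (empty key set -> 0).
.keyCoverage <- function(ref, observed) {
  obs <- .observedSet(observed)
  vapply(ref@keySets, function(ks) {
    if (!length(ks)) return(0)
    sum(ks %in% obs) / length(ks)
  }, numeric(1))
}

# Accepts a character vector of ECs or a named abundance vector.
.observedSet <- function(observed) {
  if (is.numeric(observed)) names(observed)[observed > 0] else as.character(observed)
}

#' @rdname PathwayRef-class
#' @export
setMethod("nPathways", "PathwayRef", function(x) length(x@pathwayIds))

#' @rdname PathwayRef-class
#' @export
setMethod("nReactions", "PathwayRef", function(x) length(x@reactions))

#' @rdname PathwayRef-class
#' @export
setMethod("pathwayIds", "PathwayRef", function(x) x@pathwayIds)

#' @rdname PathwayRef-class
#' @export
setMethod("reactionIds", "PathwayRef", function(x) x@reactions)

#' @rdname PathwayRef-class
#' @export
setMethod("pathwayReactions", "PathwayRef", function(x, id) {
  j <- match(id, x@pathwayIds)
  if (is.na(j)) stop("unknown pathway id: ", id, call. = FALSE)
  x@reactionSets[[j]]
})

#' @rdname PathwayRef-class
#' @export
setMethod("keyReactions", "PathwayRef", function(x, id) {
  j <- match(id, x@pathwayIds)
  if (is.na(j)) stop("unknown pathway id: ", id, call. = FALSE)
  x@keySets[[j]]
})

#' @rdname PathwayRef-class
#' @export
setMethod("reactionPathways", "PathwayRef", function(x, ec) {
  x@reactionMap[[ec]] %||% character()
})

setMethod("show", "PathwayRef", function(object) {
  cat("PathwayRef with", length(object@pathwayIds), "pathways and",
      length(object@reactions), "enzymatic reactions\n")
  sz <- lengths(object@reactionSets)
  cat("  reactions per pathway: min", min(sz), "median", median(sz), "max", max(sz), "\n")
})
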