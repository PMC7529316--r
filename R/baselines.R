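# Reference predictors the learned model is compared against: direct
# coverage thresholding, a randomized naive linker, and MinPath-style
# parsimony (minimal pathway set explaining the observed reactions).

#' Coverage baseline predictor
#'
#' Maps the observed reactions of a sample directly onto the true pathway
#' definitions and predicts pathway j iff its coverage is at least
#' \code{threshold} (inclusive). Pathways with empty reaction sets are
#' never predicted.
#'
#' @param x a [PathwayDataset-class] (returns an n x t matrix) or a single
#'   sample: a character vector of observed ECs or a named abundance vector.
#' @param ref a [PathwayRef-class].
#' @param threshold coverage cutoff in \eqn{[0, 1]}, default 0.5.
#' @return binary t-vector, or n x t matrix for a dataset.
#' @export
baselinePredict <- function(x, ref, threshold = 0.5) {
  stopifnot(is(ref, "PathwayRef"))
  if (is(x, "PathwayDataset")) {
    out <- t(vapply(x@abundances, function(a) baselinePredict(a, ref, threshold),
                    numeric(nPathways(ref))))
    dimnames(out) <- list(sampleIds(x), pathwayIds(ref))
    return(out)
  }
  cov <- pathwayCoverage(ref, x)
  nonEmpty <- lengths(ref@reactionSets) > 0
  setNames(as.numeric(cov >= threshold & nonEmpty), pathwayIds(ref))
}

#' Randomized naive predictor
#'
#' Each observed reaction is independently kept with probability
#' \code{acceptProb}; a pathway is predicted present iff at least one of
#' its reactions was kept. Deterministic under the seed.
#'
#' @inheritParams baselinePredict
#' @param acceptProb per-reaction acceptance probability in \eqn{[0, 1]}.
#' @param seed integer seed.
#' @return binary t-vector, or n x t matrix for a dataset.
#' @export
naivePredict <- function(x, ref, acceptProb = 0.5, seed = 1L) {
  stopifnot(is(ref, "PathwayRef"))
  .assertNumber(acceptProb, "acceptProb", 0, 1)
  if (is(x, "PathwayDataset")) {
    out <- withr::with_seed(seed, {
      t(vapply(x@abundances, function(a) .naiveOne(a, ref, acceptProb),
               numeric(nPathways(ref))))
    })
    dimnames(out) <- list(sampleIds(x), pathwayIds(ref))
    return(out)
  }
  withr::with_seed(seed, .naiveOne(x, ref, acceptProb))
}

.naiveOne <- function(x, ref, acceptProb) {
  obs <- .observedSet(x)
  obs <- obs[obs %in% reactionIds(ref)]
  kept <- obs[runif(length(obs)) < acceptProb]
  if (acceptProb == 1) kept <- obs
  hit <- vapply(ref@reactionSets, function(rs) as.numeric(any(rs %in% kept)),
                numeric(1))
  setNames(hit, pathwayIds(ref))
}

#' Parsimony (minimal pathway set) predictor
#'
#' Selects a set of candidate pathways (those with at least one observed
#' reaction) that jointly covers every observed reaction mapping to at
#' least one pathway. \code{mode = "greedy"} repeatedly picks the candidate
#' covering the most uncovered reactions (ties by pathway id);
#' \code{mode = "exact"} runs a branch-and-bound search guaranteeing a
#' minimum-cardinality cover (ties resolved to the lexicographically
#' smallest id set), permitted when the number of candidates is at most
#' \code{exactLimit}.
#'
#' @param x a character vector of observed ECs or named abundance vector.
#' @param ref a [PathwayRef-class].
#' @param mode \code{"greedy"} or \code{"exact"}.
#' @param exactLimit maximum candidate count for exact search.
#' @return list of class \code{"ParsimonyResult"} with
#'   \code{selected_pathways}, \code{covered_reactions}, \code{method}.
#' @export
minpathPredict <- function(x, ref, mode = c("greedy", "exact"), exactLimit = 20L) {
  stopifnot(is(ref, "PathwayRef"))
  mode <- match.arg(mode)
  obs <- .observedSet(x)
  obs <- obs[obs %in% reactionIds(ref)]
  universe <- unique(obs)
  cand <- pathwayIds(ref)[vapply(ref@reactionSets,
                                 function(rs) any(rs %in% universe), logical(1))]
  if (!length(universe) || !length(cand)) {
    return(structure(list(selected_pathways = character(),
                          covered_reactions = character(), method = mode),
                     class = "ParsimonyResult"))
  }
  covers <- lapply(ref@reactionSets[cand], intersect, universe)
  sel <- if (mode == "greedy") {
    .greedyCover(cand, covers, universe)
  } else {
    if (length(cand) > exactLimit) {
      stop(length(cand), " candidate pathways exceed exactLimit = ", exactLimit,
           "; use mode = \"greedy\"", call. = FALSE)
    }
    .exactCover(cand, covers, universe)
  }
  structure(list(selected_pathways = sel,
                 covered_reactions = .ecSort(unlist(covers[sel], use.names = FALSE)),
                 method = mode),
            class = "ParsimonyResult")
}

.greedyCover <- function(cand, covers, universe) {
  uncovered <- universe
  sel <- character()
  ordIds <- sort(cand, method = "radix")
  while (length(uncovered)) {
    gain <- vapply(covers[ordIds], function(cv) sum(cv %in% uncovered), numeric(1))
    best <- ordIds[which.max(gain)]   # which.max takes the first -> id order ties
    sel <- c(sel, best)
    uncovered <- setdiff(uncovered, covers[[best]])
    ordIds <- setdiff(ordIds, best)
    if (!length(ordIds) && length(uncovered)) break
  }
  sel
}

# Branch-and-bound minimum set cover; ties to the lexicographically
# smallest selected-id set.
.exactCover <- function(cand, covers, universe) {
  cand <- sort(cand, method = "radix")
  covers <- covers[cand]
  best <- list(size = Inf, sel = NULL)
  recurse <- function(sel, uncovered, avail) {
    if (!length(uncovered)) {
      key <- paste(sort(sel), collapse = "|")
      if (length(sel) < best$size ||
          (length(sel) == best$size &&
           key < paste(sort(best$sel), collapse = "|"))) {
        best <<- list(size = length(sel), sel = sort(sel))
      }
      return(invisible())
    }
    if (length(sel) + 1 > best$size) return(invisible())
    # cheap lower bound: one more set can cover at most maxGain reactions
    gains <- vapply(covers[avail], function(cv) sum(cv %in% uncovered), numeric(1))
    if (!length(avail) || max(gains) == 0) return(invisible())
    if (length(sel) + ceiling(length(uncovered) / max(gains)) > best$size) {
      return(invisible())
    }
    # branch on an uncovered reaction with fewest covering candidates
    nCover <- vapply(uncovered, function(e) {
      sum(vapply(covers[avail], function(cv) e %in% cv, logical(1)))
    }, numeric(1))
    e <- uncovered[which.min(nCover)]
    for (p in avail[vapply(covers[avail], function(cv) e %in% cv, logical(1))]) {
      recurse(c(sel, p), setdiff(uncovered, covers[[p]]), setdiff(avail, p))
    }
    invisible()
  }
  recurse(character(), universe, cand)
  best$sel
}

#' Convert a parsimony result to a binary label vector
#'
#' @param res a \code{"ParsimonyResult"} from [minpathPredict()].
#' @param ref the [PathwayRef-class] defining the pathway order.
#' @return binary t-vector.
#' @export
parsimonyToLabels <- function(res, ref) {
  setNames(as.numeric(pathwayIds(ref) %in% res$selected_pathways), pathwayIds(ref))
}
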