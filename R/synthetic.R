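#' Synthetic dataset generation configuration
#'
#' Defines the study conditions the generator emulates: per sample the
#' number of encoded pathways is drawn from a Poisson distribution with
#' mean \code{pathwayMean} (rejected and redrawn until it lands in
#' \eqn{[1, t]}), the pathways are chosen uniformly without replacement,
#' and every reaction of every chosen pathway contributes
#' \eqn{1 + Poisson(abundanceMean - 1)} copies (shared reactions across
#' chosen pathways accumulate additively). Optional feature corruption
#' deletes each present reaction with probability \code{deletionRate} and
#' inserts each absent reference reaction with probability
#' \code{insertionRate}; labels are never touched by corruption.
#'
#' @param nSamples positive integer number of samples.
#' @param pathwayMean positive real: Poisson mean of pathways per sample.
#' @param abundanceMean real >= 1: mean copies per included reaction.
#' @param insertionRate,deletionRate corruption rates in \eqn{[0, 1]}.
#' @param noiseLevel shorthand setting both rates at once (overrides them).
#' @param seed integer seed; all randomness flows from it.
#' @return a list of class \code{"SynthesisConfig"}.
#' @export
synthesisConfig <- function(nSamples, pathwayMean, abundanceMean = 2,
                            insertionRate = 0, deletionRate = 0,
                            noiseLevel = NULL, seed = 1L) {
  .assertNumber(nSamples, "nSamples", lower = 1)
  .assertNumber(pathwayMean, "pathwayMean")
  if (pathwayMean <= 0) stop("pathwayMean must be > 0", call. = FALSE)
  .assertNumber(abundanceMean, "abundanceMean", lower = 1)
  if (!is.null(noiseLevel)) {
    .assertNumber(noiseLevel, "noiseLevel", lower = 0, upper = 1)
    insertionRate <- deletionRate <- noiseLevel
  }
  .assertNumber(insertionRate, "insertionRate", lower = 0, upper = 1)
  .assertNumber(deletionRate, "deletionRate", lower = 0, upper = 1)
  structure(list(nSamples = as.integer(nSamples), pathwayMean = pathwayMean,
                 abundanceMean = abundanceMean, insertionRate = insertionRate,
                 deletionRate = deletionRate, seed = as.integer(seed)),
            class = "SynthesisConfig")
}

#' Generate a synthetic pathway dataset
#'
#' Draws a labeled dataset from a reference under a [synthesisConfig()].
#' Every labeled pathway has coverage 1.0 in its uncorrupted sample and no
#' sample has zero labels. When the config's corruption rates are positive
#' the returned features are corrupted (labels unchanged), emulating a
#' noisy training corpus.
#'
#' @param ref a [PathwayRef-class].
#' @param cfg a [synthesisConfig()].
#' @return a labeled [PathwayDataset-class]; deterministic given (ref, cfg).
#' @export
generateDataset <- function(ref, cfg) {
  stopifnot(is(ref, "PathwayRef"), inherits(cfg, "SynthesisConfig"))
  t <- nPathways(ref)
  if (t == 0L) stop("reference has no pathways", call. = FALSE)
  n <- cfg$nSamples
  withr::with_seed(cfg$seed, {
    Y <- matrix(0, n, t, dimnames = list(NULL, pathwayIds(ref)))
    abund <- vector("list", n)
    for (i in seq_len(n)) {
      repeat {
        k <- rpois(1L, cfg$pathwayMean)
        if (k >= 1L && k <= t) break
      }
      chosen <- sample.int(t, k)
      Y[i, chosen] <- 1
      ecs <- unlist(ref@reactionSets[chosen], use.names = FALSE)
      if (length(ecs)) {
        draws <- 1 + rpois(length(ecs), cfg$abundanceMean - 1)
        agg <- rowsum(draws, ecs)
        abund[[i]] <- setNames(agg[, 1L], rownames(agg))
      } else {
        abund[[i]] <- setNames(numeric(), character())
      }
    }
    if (cfg$insertionRate > 0 || cfg$deletionRate > 0) {
      abund <- lapply(abund, .corruptAbundances, ref = ref,
                      pIns = cfg$insertionRate, pDel = cfg$deletionRate,
                      abundanceMean = cfg$abundanceMean)
    }
  })
  ids <- sprintf("S%0*d", nchar(n), seq_len(n))
  PathwayDataset(abund, sampleIds = ids, labels = Y)
}

# Corruption core; uses the current RNG stream.
.corruptAbundances <- function(a, ref, pIns, pDel, abundanceMean) {
  present <- names(a)[a > 0]
  keep <- if (length(present)) present[runif(length(present)) >= pDel] else character()
  a2 <- a[keep]
  absent <- setdiff(reactionIds(ref), present)
  ins <- if (length(absent)) absent[runif(length(absent)) < pIns] else character()
  if (length(ins)) {
    a2 <- c(a2, setNames(1 + rpois(length(ins), abundanceMean - 1), ins))
  }
  a2
}

#' Inject feature noise into a dataset
#'
#' Per sample, each present reaction is removed independently with
#' probability \code{pDel} and each absent reference reaction inserted with
#' probability \code{pIns}, with inserted abundances drawn as in
#' generation. Labels, sample count and pathway order are preserved
#' exactly: the noise perturbs features only, so models trained on clean
#' versus corrupted features are compared against the same truth.
#'
#' @param ds a [PathwayDataset-class].
#' @param ref a [PathwayRef-class].
#' @param pIns,pDel insertion/deletion probabilities in \eqn{[0, 1]}.
#' @param seed integer seed.
#' @param abundanceMean mean copies for inserted reactions (>= 1).
#' @return a [PathwayDataset-class] with identical labels.
#' @export
corruptDataset <- function(ds, ref, pIns, pDel, seed = 1L, abundanceMean = 2) {
  stopifnot(is(ds, "PathwayDataset"), is(ref, "PathwayRef"))
  .assertNumber(pIns, "pIns", 0, 1)
  .assertNumber(pDel, "pDel", 0, 1)
  .assertNumber(abundanceMean, "abundanceMean", lower = 1)
  if (pIns == 0 && pDel == 0) return(ds)
  abund <- withr::with_seed(seed, {
    lapply(ds@abundances, .corruptAbundances, ref = ref, pIns = pIns,
           pDel = pDel, abundanceMean = abundanceMean)
  })
  PathwayDataset(abund, sampleIds = ds@sampleIds, labels = ds@labels)
}

#' Iterative multi-label stratified split
#'
#' Splits a labeled dataset into train/validation/test parts by iterative
#' stratification: labels are processed rarest first; each still-unassigned
#' sample carrying the current label goes to the split with the greatest
#' remaining demand for that label, ties broken by remaining capacity and
#' then by a seeded random draw. Split capacities are apportioned by
#' largest remainder, so every split size is within one sample of
#' \code{n * fraction}. The three parts are pairwise disjoint and their
#' union is the input dataset.
#'
#' @param ds a labeled [PathwayDataset-class] with at least 3 samples.
#' @param fractions numeric vector of 3 positive fractions summing to 1.
#' @param seed integer seed for tie-breaking.
#' @return named list of [PathwayDataset-class]: train, validation, test.
#' @export
stratifiedSplit <- function(ds, fractions = c(0.7, 0.15, 0.15), seed = 1L) {
  stopifnot(is(ds, "PathwayDataset"))
  if (!hasLabels(ds)) stop("dataset has no labels", call. = FALSE)
  n <- nSamples(ds)
  if (n < 3L) stop("need at least 3 samples to split", call. = FALSE)
  if (length(fractions) != 3L || any(fractions < 0) ||
      abs(sum(fractions) - 1) > 1e-9) {
    stop("fractions must be 3 non-negative values summing to 1", call. = FALSE)
  }
  nf <- n * fractions
  cap <- floor(nf)
  extra <- n - sum(cap)
  if (extra > 0) {
    give <- order(-(nf - cap))[seq_len(extra)]
    cap[give] <- cap[give] + 1L
  }
  Y <- ds@labels
  demand <- outer(fractions, colSums(Y))   # 3 x t real-valued demand
  assigned <- rep(NA_integer_, n)
  withr::with_seed(seed, {
    repeat {
      un <- which(is.na(assigned))
      if (!length(un)) break
      counts <- colSums(Y[un, , drop = FALSE])
      open <- which(counts > 0)
      if (!length(open)) {
        # label-free leftovers: fill by remaining capacity
        for (i in un) {
          k <- which(cap == max(cap))
          k <- if (length(k) > 1L) sample(k, 1L) else k
          assigned[i] <- k
          cap[k] <- cap[k] - 1L
        }
        break
      }
      l <- open[which.min(counts[open])]
      for (i in un[Y[un, l] == 1]) {
        ok <- which(cap > 0)
        d <- demand[ok, l]
        k <- ok[d == max(d)]
        if (length(k) > 1L) {
          k <- k[cap[k] == max(cap[k])]
          if (length(k) > 1L) k <- sample(k, 1L)
        }
        assigned[i] <- k
        cap[k] <- cap[k] - 1L
        pos <- which(Y[i, ] == 1)
        demand[k, pos] <- demand[k, pos] - 1
      }
    }
  })
  list(train = ds[which(assigned == 1L)],
       validation = ds[which(assigned == 2L)],
       test = ds[which(assigned == 3L)])
}

#' Construct a randomized synthetic pathway reference
#'
#' Builds a reference with \code{nPathways} pathways over a pool of
#' \code{nReactions} synthetic EC numbers. Every reaction is assigned to at
#' least one pathway (round-robin), pathways are topped up with uniformly
#' drawn extra reactions until their target size, and a fraction of each
#' pathway's reactions is marked as key. This is a synthetic stand-in for a
#' curated pathway catalog, intended for simulation studies and tests.
#'
#' @param nPathways,nReactions positive integers.
#' @param minSize,maxSize pathway size range (reactions per pathway); sizes
#'   are drawn uniformly, but never below the round-robin base assignment.
#' @param keyFraction fraction of a pathway's reactions marked key (>= 1
#'   reaction when the pathway is nonempty).
#' @param seed integer seed.
#' @return a validated [PathwayRef-class].
#' @export
randomReference <- function(nPathways, nReactions, minSize = 3L, maxSize = 8L,
                            keyFraction = 0.3, seed = 1L) {
  .assertNumber(nPathways, "nPathways", lower = 1)
  .assertNumber(nReactions, "nReactions", lower = 1)
  pool <- .syntheticECPool(nReactions)
  withr::with_seed(seed, {
    base <- split(pool, rep_len(seq_len(nPathways), nReactions))
    pw <- lapply(seq_len(nPathways), function(j) {
      rs <- if (j <= length(base)) base[[j]] else character()
      target <- sample(minSize:maxSize, 1L)
      if (length(rs) < target) {
        extra <- sample(setdiff(pool, rs), min(target - length(rs),
                                               nReactions - length(rs)))
        rs <- c(rs, extra)
      }
      nk <- max(1L, floor(keyFraction * length(rs)))
      list(id = sprintf("PWY%04d", j), name = sprintf("synthetic pathway %d", j),
           reactions = rs, key_reactions = sample(rs, nk))
    })
  })
  PathwayRef(pw)
}

# Deterministic pool of distinct, valid synthetic EC strings.
.syntheticECPool <- function(nReactions) {
  i <- seq_len(nReactions)
  sprintf("%d.%d.%d.%d", (i - 1L) %% 7L + 1L, (i - 1L) %% 13L + 1L,
          (i - 1L) %% 31L + 1L, i)
}
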