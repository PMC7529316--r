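#' Feature configuration
#'
#' Selects and parameterizes the five feature blocks, concatenated in the
#' fixed order AB, RE, PE, PC, PP:
#' \describe{
#'   \item{AB}{reaction abundance: r-dimensional frequency vector of EC
#'     occurrence counts.}
#'   \item{RE}{reaction evidence: 68 sample-level statistics of the
#'     observed reactome (registry \code{"re-1"}).}
#'   \item{PE}{pathway evidence: 32 sample-level aggregates of the
#'     per-pathway coverage and key-reaction coverage vectors (registry
#'     \code{"pe-1"}).}
#'   \item{PC}{pathway common: r-dimensional binary vector flagging
#'     observed reactions shared by two or more pathways (the multiple
#'     mapping problem).}
#'   \item{PP}{possible pathway: 2t-dimensional binary vector, per pathway
#'     an any-hit indicator and a key-reactions-complete indicator.}
#' }
#'
#' @param blocks subset of \code{c("AB","RE","PE","PC","PP")}, at least one.
#' @param coverageThresholds ordered vector of exactly 4 coverage
#'   thresholds used by the PE registry.
#' @param scaling \code{"minmax"} (fit on training data only, see
#'   [fitMinMaxScaler()]) or \code{"none"}.
#' @return a list of class \code{"FeatureConfig"}.
#' @export
featureConfig <- function(blocks = c("AB", "RE", "PE", "PC", "PP"),
                          coverageThresholds = c(1, 0.75, 0.5, 0.25),
                          scaling = c("minmax", "none")) {
  allBlocks <- c("AB", "RE", "PE", "PC", "PP")
  if (!length(blocks) || !all(blocks %in% allBlocks)) {
    stop("at least one feature block among ", paste(allBlocks, collapse = ", "),
         " must be enabled", call. = FALSE)
  }
  blocks <- intersect(allBlocks, blocks)
  if (length(coverageThresholds) != 4L || is.unsorted(rev(coverageThresholds))) {
    stop("coverageThresholds must be 4 values in decreasing order", call. = FALSE)
  }
  structure(list(blocks = blocks,
                 reRegistry = "re-1", peRegistry = "pe-1",
                 coverageThresholds = as.numeric(coverageThresholds),
                 scaling = match.arg(scaling)),
            class = "FeatureConfig")
}

# ---- registries -----------------------------------------------------------

.reFeatureNames <- function() {
  c(as.vector(t(outer(paste0("class", 1:7),
                      c("distinct", "abundance", "frac_observed"),
                      paste, sep = ":"))),
    "global:distinct", "global:abundance", "global:mean", "global:median",
    "global:max", "global:sd",
    "frac_ref_observed", "frac_mapped_ge1", "frac_mapped_ge2",
    "orphan_count", "orphan_frac",
    paste0("hist_bin", 1:8),
    as.vector(t(outer(paste0("class", 1:7), c("max", "mean"), paste, sep = ":"))),
    "key_count", "key_frac", "count_ge2", "count_ge5",
    "partial_distinct", "partial_frac", "multi_pathway_copies",
    paste0("reserved", 1:7))
}

.peFeatureNames <- function(thr) {
  cats <- c("eq1", paste0("ge", format(thr, trim = TRUE)), "gt0")
  covPart <- as.vector(t(outer(cats, c("count", "frac"), paste, sep = ":")))
  keyCats <- cats
  dropFrac <- paste0("ge", format(thr[3:4], trim = TRUE), ":frac")
  keyPart <- setdiff(as.vector(t(outer(keyCats, c("count", "frac"), paste, sep = ":"))),
                     dropFrac)
  c(paste0("cov:", covPart),
    paste0("cov:", c("mean", "median", "max", "sd")),
    paste0("key:", keyPart),
    paste0("key:", c("mean", "median", "max", "sd")),
    "size_weighted_mean_cov", "mean_gap_count")
}

# ---- individual blocks ----------------------------------------------------

#' Reaction abundance block
#'
#' The r-dimensional frequency vector: position l holds the abundance of
#' reference reaction \eqn{e_l} in the sample (0 if absent). ECs absent from
#' the reference are ignored; their count is attached as attribute
#' \code{"unknown_ecs"}.
#'
#' @param abund named numeric vector (EC -> abundance) for one sample.
#' @param ref a [PathwayRef-class].
#' @return numeric vector of length \code{nReactions(ref)}.
#' @export
abundanceBlock <- function(abund, ref) {
  v <- setNames(numeric(nReactions(ref)), reactionIds(ref))
  if (length(abund)) {
    idx <- match(names(abund), reactionIds(ref))
    known <- !is.na(idx)
    v[idx[known]] <- v[idx[known]] + unname(abund[known])
    attr(v, "unknown_ecs") <- sum(!known)
  } else {
    attr(v, "unknown_ecs") <- 0L
  }
  v
}

#' Reaction evidence block (registry re-1, length 68)
#'
#' Sample-level statistics of the observed reactome, in a fixed documented
#' order: per top-level EC class 1-7 the distinct-EC count, total abundance
#' and fraction of that class's reference reactions observed (21); global
#' distinct count, total abundance and mean/median/max/sd of nonzero
#' abundances (6); fraction of reference reactions observed, fractions of
#' observed reactions mapping to >= 1 and >= 2 pathways, orphan (not in
#' reference) count and fraction (5); an 8-bin abundance histogram with
#' breaks at powers of two (8); per-class max and mean abundance (14);
#' count and fraction of observed reactions that are key in some pathway
#' and counts with abundance >= 2 and >= 5 (4); distinct partial-EC count,
#' partial fraction and total copies of multi-pathway reactions (3); 7
#' reserved zero features pad the registry to 68.
#'
#' @inheritParams abundanceBlock
#' @return named numeric vector of length 68.
#' @export
reactionEvidenceBlock <- function(abund, ref) {
  nm <- .reFeatureNames()
  out <- setNames(numeric(length(nm)), nm)
  stopifnot(length(out) == 68L)
  obs <- if (length(abund)) names(abund)[abund > 0] else character()
  a <- abund[obs]
  refEC <- reactionIds(ref)
  refCls <- .ecClass(refEC)
  obsCls <- .ecClass(obs)
  for (cl in 1:7) {
    sel <- which(obsCls == cl)
    out[sprintf("class%d:distinct", cl)] <- length(sel)
    out[sprintf("class%d:abundance", cl)] <- sum(a[sel])
    nref <- sum(refCls == cl, na.rm = TRUE)
    out[sprintf("class%d:frac_observed", cl)] <-
      if (nref > 0) sum(refEC[which(refCls == cl)] %in% obs) / nref else 0
    out[sprintf("class%d:max", cl)] <- if (length(sel)) max(a[sel]) else 0
    out[sprintf("class%d:mean", cl)] <- if (length(sel)) mean(a[sel]) else 0
  }
  out["global:distinct"] <- length(obs)
  out["global:abundance"] <- sum(a)
  if (length(obs)) {
    out["global:mean"] <- mean(a)
    out["global:median"] <- median(a)
    out["global:max"] <- max(a)
    out["global:sd"] <- if (length(obs) > 1L) sd(a) else 0
  }
  out["frac_ref_observed"] <-
    if (length(refEC)) sum(refEC %in% obs) / length(refEC) else 0
  nMap <- lengths(ref@reactionMap)[match(obs, refEC)]
  nMap[is.na(nMap)] <- 0L
  if (length(obs)) {
    out["frac_mapped_ge1"] <- mean(nMap >= 1L)
    out["frac_mapped_ge2"] <- mean(nMap >= 2L)
    out["orphan_count"] <- sum(nMap == 0L)
    out["orphan_frac"] <- mean(nMap == 0L)
    breaks <- c(0, 2^(1:7), Inf)
    out[paste0("hist_bin", 1:8)] <-
      tabulate(findInterval(a, breaks, left.open = TRUE, rightmost.closed = TRUE),
               nbins = 8L)
    allKey <- unique(unlist(ref@keySets, use.names = FALSE))
    out["key_count"] <- sum(obs %in% allKey)
    out["key_frac"] <- mean(obs %in% allKey)
    out["count_ge2"] <- sum(a >= 2)
    out["count_ge5"] <- sum(a >= 5)
    out["partial_distinct"] <- sum(.isPartialEC(obs))
    out["partial_frac"] <- mean(.isPartialEC(obs))
    out["multi_pathway_copies"] <- sum(a[nMap >= 2L])
  }
  out
}

#' Pathway evidence block (registry pe-1, length 32)
#'
#' Sample-level aggregates of the per-pathway coverage vector
#' \eqn{c \in [0,1]^t} and of the key-reaction coverage vector: count and
#' fraction of pathways with coverage = 1, >= each configured threshold and
#' > 0 (12); mean/median/max/sd of nonzero coverages (4); the same set
#' recomputed on key-reaction coverage but with the fractions for the two
#' lowest thresholds dropped (14); the pathway-size-weighted mean coverage
#' and the mean gap count (pathway size minus observed hits over pathways
#' with positive coverage) (2).
#'
#' @inheritParams abundanceBlock
#' @param thresholds the 4 coverage thresholds from the [featureConfig()].
#' @return named numeric vector of length 32.
#' @export
pathwayEvidenceBlock <- function(abund, ref, thresholds = c(1, 0.75, 0.5, 0.25)) {
  nm <- .peFeatureNames(thresholds)
  out <- setNames(numeric(length(nm)), nm)
  stopifnot(length(out) == 32L)
  obs <- if (length(abund)) names(abund)[abund > 0] else character()
  cov <- pathwayCoverage(ref, obs)
  kcov <- .keyCoverage(ref, obs)
  t <- nPathways(ref)
  catCounts <- function(v) {
    c(eq1 = sum(v == 1),
      setNames(vapply(thresholds, function(th) sum(v >= th), numeric(1)),
               paste0("ge", format(thresholds, trim = TRUE))),
      gt0 = sum(v > 0))
  }
  nzStats <- function(v) {
    nz <- v[v > 0]
    if (!length(nz)) return(c(mean = 0, median = 0, max = 0, sd = 0))
    c(mean = mean(nz), median = median(nz), max = max(nz),
      sd = if (length(nz) > 1L) sd(nz) else 0)
  }
  cc <- catCounts(cov)
  for (ct in names(cc)) {
    out[paste0("cov:", ct, ":count")] <- cc[ct]
    out[paste0("cov:", ct, ":frac")] <- cc[ct] / t
  }
  st <- nzStats(cov)
  out[paste0("cov:", names(st))] <- st
  kc <- catCounts(kcov)
  for (ct in names(kc)) {
    nmC <- paste0("key:", ct, ":count")
    nmF <- paste0("key:", ct, ":frac")
    out[nmC] <- kc[ct]
    if (nmF %in% nm) out[nmF] <- kc[ct] / t
  }
  stk <- nzStats(kcov)
  out[paste0("key:", names(stk))] <- stk
  sizes <- lengths(ref@reactionSets)
  out["size_weighted_mean_cov"] <-
    if (sum(sizes) > 0) sum(sizes * cov) / sum(sizes) else 0
  hit <- cov > 0
  out["mean_gap_count"] <-
    if (any(hit)) mean(sizes[hit] - round(sizes[hit] * cov[hit])) else 0
  out
}

#' Pathway common block
#'
#' r-dimensional binary vector: position l is 1 iff reference reaction
#' \eqn{e_l} is observed in the sample (abundance > 0) and maps to at least
#' two pathways, flagging the multiple-mapping ambiguity of shared enzymes.
#'
#' @inheritParams abundanceBlock
#' @return binary numeric vector of length \code{nReactions(ref)}.
#' @export
pathwayCommonBlock <- function(abund, ref) {
  refEC <- reactionIds(ref)
  v <- setNames(numeric(length(refEC)), refEC)
  obs <- if (length(abund)) names(abund)[abund > 0] else character()
  multi <- refEC[lengths(ref@reactionMap) >= 2L]
  v[refEC %in% obs & refEC %in% multi] <- 1
  v
}

#' Possible pathway block
#'
#' 2t-dimensional binary vector, pathway-major order: for each pathway an
#' any-hit indicator (1 iff at least one of its reactions is observed) and
#' a key-complete indicator (1 iff the pathway has a nonempty key set and
#' every key reaction is observed).
#'
#' @inheritParams abundanceBlock
#' @return binary numeric vector of length \code{2 * nPathways(ref)}.
#' @export
possiblePathwayBlock <- function(abund, ref) {
  obs <- if (length(abund)) names(abund)[abund > 0] else character()
  anyHit <- vapply(ref@reactionSets, function(rs) as.numeric(any(rs %in% obs)),
                   numeric(1))
  keyComplete <- vapply(ref@keySets, function(ks) {
    as.numeric(length(ks) > 0 && all(ks %in% obs))
  }, numeric(1))
  v <- as.vector(rbind(anyHit, keyComplete))
  names(v) <- as.vector(rbind(paste0("anyhit:", pathwayIds(ref)),
                              paste0("keycomplete:", pathwayIds(ref))))
  v
}

#' Build the feature matrix for a dataset
#'
#' Concatenates the enabled blocks in fixed order AB, RE, PE, PC, PP into
#' an n x m matrix. The block layout (name, offset, width) is recorded in
#' the \code{"layout"} attribute and the reference fingerprint in
#' \code{"refFingerprint"}. The returned features are raw (unscaled); fit a
#' scaler on the training matrix with [fitMinMaxScaler()] and apply it with
#' [applyMinMaxScaler()]. Featurization is a pure function of
#' (dataset, reference, config).
#'
#' @param ds a [PathwayDataset-class].
#' @param ref a [PathwayRef-class].
#' @param cfg a [featureConfig()].
#' @return numeric matrix with feature colnames and sample-id rownames.
#' @examples
#' ref <- randomReference(2, 3, minSize = 1, maxSize = 2)
#' ds <- generateDataset(ref, synthesisConfig(4, 1))
#' dim(featurize(ds, ref, featureConfig()))
#' @export
featurize <- function(ds, ref, cfg = featureConfig()) {
  stopifnot(is(ds, "PathwayDataset"), is(ref, "PathwayRef"),
            inherits(cfg, "FeatureConfig"))
  builders <- list(
    AB = function(a) abundanceBlock(a, ref),
    RE = function(a) reactionEvidenceBlock(a, ref),
    PE = function(a) pathwayEvidenceBlock(a, ref, cfg$coverageThresholds),
    PC = function(a) pathwayCommonBlock(a, ref),
    PP = function(a) possiblePathwayBlock(a, ref))
  builders <- builders[cfg$blocks]
  unknownTally <- 0L
  rows <- lapply(ds@abundances, function(a) {
    parts <- lapply(names(builders), function(b) {
      v <- builders[[b]](a)
      if (b == "AB") unknownTally <<- unknownTally + (attr(v, "unknown_ecs") %||% 0L)
      setNames(as.numeric(v), paste0(b, ":", names(v)))
    })
    unlist(parts, use.names = TRUE)
  })
  X <- do.call(rbind, rows)
  rownames(X) <- ds@sampleIds
  widths <- vapply(names(builders), function(b) {
    switch(b, AB = nReactions(ref), RE = 68L, PE = 32L, PC = nReactions(ref),
           PP = 2L * nPathways(ref))
  }, integer(1))
  stopifnot(sum(widths) == ncol(X))
  layout <- data.frame(block = names(builders),
                       offset = cumsum(c(0L, widths[-length(widths)])),
                       width = unname(widths))
  if (unknownTally > 0L) {
    warning(unknownTally, " observed EC occurrence(s) absent from the reference were ignored",
            call. = FALSE)
  }
  attr(X, "layout") <- layout
  attr(X, "refFingerprint") <- .fingerprint(c(pathwayIds(ref), reactionIds(ref)))
  attr(X, "config") <- cfg
  X
}

#' @rdname featurize
#' @param X a feature matrix from [featurize()].
#' @return \code{featureLayout} returns the block layout data.frame.
#' @export
featureLayout <- function(X) attr(X, "layout")

#' Min-max feature scaling
#'
#' \code{fitMinMaxScaler} learns per-feature minima and ranges on a
#' training feature matrix; \code{applyMinMaxScaler} maps features to
#' \eqn{[0, 1]} using those frozen parameters (constant features map to 0;
#' out-of-range inference values are clipped). Scaling parameters, once
#' fitted, are immutable and serialized with the model.
#'
#' @param X numeric feature matrix.
#' @return \code{fitMinMaxScaler}: a list with \code{min}, \code{range},
#'   \code{names}; \code{applyMinMaxScaler}: the scaled matrix.
#' @export
fitMinMaxScaler <- function(X) {
  list(min = apply(X, 2L, min), range = apply(X, 2L, max) - apply(X, 2L, min),
       names = colnames(X))
}

#' @rdname fitMinMaxScaler
#' @param scaler a fitted scaler.
#' @export
applyMinMaxScaler <- function(X, scaler) {
  if (!identical(colnames(X), scaler$names)) {
    stop("feature layout does not match the fitted scaler", call. = FALSE)
  }
  rng <- ifelse(scaler$range > 0, scaler$range, 1)
  Xs <- sweep(sweep(X, 2L, scaler$min, "-"), 2L, rng, "/")
  Xs[, scaler$range == 0] <- 0
  Xs <- pmin(pmax(Xs, 0), 1)
  attributes(Xs)[c("layout", "refFingerprint", "config")] <-
    attributes(X)[c("layout", "refFingerprint", "config")]
  dimnames(Xs) <- dimnames(X)
  Xs
}
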