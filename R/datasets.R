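#' Construct a pathway dataset
#'
#' @param abundances list of named numeric vectors, one per sample, mapping
#'   normalized EC numbers to non-negative abundances.
#' @param sampleIds character vector of unique sample ids.
#' @param labels optional n x t binary matrix with pathway-id colnames,
#'   aligned to a reference's pathway order.
#' @return a validated [PathwayDataset-class].
#' @export
PathwayDataset <- function(abundances, sampleIds = names(abundances), labels = NULL) {
  if (is.null(sampleIds)) sampleIds <- paste0("S", seq_along(abundances))
  if (!is.null(labels)) {
    labels <- as.matrix(labels)
    storage.mode(labels) <- "double"
    rownames(labels) <- sampleIds
  }
  new("PathwayDataset", sampleIds = as.character(sampleIds),
      abundances = unname(abundances), labels = labels)
}

#' @rdname PathwayDataset-class
#' @export
setMethod("nSamples", "PathwayDataset", function(x) length(x@sampleIds))

#' @rdname PathwayDataset-class
#' @export
setMethod("sampleIds", "PathwayDataset", function(x) x@sampleIds)

#' @rdname PathwayDataset-class
#' @export
setMethod("labelMatrix", "PathwayDataset", function(x) x@labels)

#' @rdname PathwayDataset-class
#' @export
setMethod("hasLabels", "PathwayDataset", function(x) !is.null(x@labels))

#' @rdname PathwayDataset-class
#' @export
setMethod("sampleAbundances", "PathwayDataset", function(x, id) {
  i <- match(id, x@sampleIds)
  if (is.na(i)) stop("unknown sample id: ", id, call. = FALSE)
  x@abundances[[i]]
})

#' @rdname PathwayDataset-class
#' @param i integer, logical or character index of samples.
#' @param j,drop,... ignored (samples only).
#' @export
setMethod("[", "PathwayDataset", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) i <- match(i, x@sampleIds)
  new("PathwayDataset",
      sampleIds = x@sampleIds[i],
      abundances = x@abundances[i],
      labels = if (is.null(x@labels)) NULL else x@labels[i, , drop = FALSE])
})

setMethod("show", "PathwayDataset", function(object) {
  cat("PathwayDataset with", length(object@sampleIds), "samples;",
      if (is.null(object@labels)) "unlabeled"
      else paste0("labels over ", ncol(object@labels), " pathways"), "\n")
})

#' Read a sample EC-abundance table
#'
#' Reads a TSV with header columns \code{sample_id}, \code{ec},
#' \code{abundance}. Rows sharing a (sample, EC) pair have their abundances
#' summed. ECs are normalized; ECs not present in any reference are kept
#' (the featurizer decides how to treat them).
#'
#' @param path TSV file path.
#' @return a [PathwayDataset-class] without labels, samples in first-seen order.
#' @export
readSampleTable <- function(path) {
  if (!file.exists(path)) stop("sample table not found: ", path, call. = FALSE)
  df <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("sample_id", "ec", "abundance")
  if (!all(need %in% names(df))) {
    stop("sample table must have columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  ab <- suppressWarnings(as.numeric(df$abundance))
  bad <- which(!is.finite(ab) | ab < 0)
  if (length(bad)) {
    stop("invalid abundance at line ", bad[1] + 1L, ": '", df$abundance[bad[1]], "'",
         call. = FALSE)
  }
  ec <- tryCatch(normalizeEC(df$ec), error = function(e) {
    badec <- which(!grepl(.EC_PATTERN, gsub("^[Ee][Cc][ :]*", "", trimws(df$ec))))
    stop("malformed EC at line ", badec[1] + 1L, ": '", df$ec[badec[1]], "'", call. = FALSE)
  })
  ids <- unique(df$sample_id)
  key <- paste(df$sample_id, ec, sep = "\x1f")
  agg <- rowsum(ab, key, reorder = FALSE)
  parts <- strsplit(rownames(agg), "\x1f", fixed = TRUE)
  sid <- vapply(parts, `[`, character(1), 1L)
  aec <- vapply(parts, `[`, character(1), 2L)
  abund <- lapply(ids, function(s) {
    sel <- sid == s
    setNames(agg[sel, 1L], aec[sel])
  })
  PathwayDataset(abund, sampleIds = ids)
}

#' @rdname readSampleTable
#' @param ds a [PathwayDataset-class].
#' @export
writeSampleTable <- function(ds, path) {
  stopifnot(is(ds, "PathwayDataset"))
  rows <- do.call(rbind, lapply(seq_along(ds@sampleIds), function(i) {
    a <- ds@abundances[[i]]
    if (!length(a)) return(NULL)
    data.frame(sample_id = ds@sampleIds[i], ec = names(a),
               abundance = sprintf("%.6g", unname(a)))
  }))
  if (is.null(rows)) rows <- data.frame(sample_id = character(), ec = character(),
                                        abundance = character())
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write pathway label tables (long format)
#'
#' Label TSVs have header columns \code{sample_id}, \code{pathway_id}; one
#' row per positive label. \code{readLabelTable} returns an n x t binary
#' matrix aligned to the reference pathway order for the given sample ids
#' (unknown pathway ids are an error).
#'
#' @param path TSV file path.
#' @param ref a [PathwayRef-class].
#' @param sampleIds character vector defining the row order.
#' @return binary matrix with sample-id rownames and pathway-id colnames.
#' @export
readLabelTable <- function(path, ref, sampleIds) {
  if (!file.exists(path)) stop("label table not found: ", path, call. = FALSE)
  df <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  if (!all(c("sample_id", "pathway_id") %in% names(df))) {
    stop("label table must have columns sample_id, pathway_id", call. = FALSE)
  }
  Y <- matrix(0, nrow = length(sampleIds), ncol = nPathways(ref),
              dimnames = list(sampleIds, pathwayIds(ref)))
  if (nrow(df)) {
    i <- match(df$sample_id, sampleIds)
    j <- match(df$pathway_id, pathwayIds(ref))
    if (anyNA(j)) stop("unknown pathway id in label table: ",
                       df$pathway_id[which(is.na(j))[1]], call. = FALSE)
    keep <- !is.na(i)
    Y[cbind(i[keep], j[keep])] <- 1
  }
  Y
}

#' @rdname readLabelTable
#' @param Y binary label matrix with sample-id rownames, pathway-id colnames.
#' @export
writeLabelTable <- function(Y, path) {
  idx <- which(Y == 1, arr.ind = TRUE)
  rows <- data.frame(sample_id = rownames(Y)[idx[, 1]],
                     pathway_id = colnames(Y)[idx[, 2]])
  rows <- rows[order(match(rows$sample_id, rownames(Y)), rows$pathway_id), , drop = FALSE]
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Multi-label dataset statistics
#'
#' Summary statistics of a labeled dataset in the style of multi-label
#' learning surveys: total labels L, label cardinality LCard = L/n, label
#' density LDen = LCard/L, distinct labels DL and their proportion PDL =
#' DL/n; the analogous quantities for reaction occurrences (R = sum of
#' stored abundances, RCard, RDen, DR, PDR), and the pathway-label-to-
#' reaction ratio PLR = L/R. Any ratio with a zero denominator is reported
#' as 0 and flagged in \code{zero_denominator}.
#'
#' @param ds a labeled [PathwayDataset-class].
#' @param ref optional [PathwayRef-class] (unused for the tallies; retained
#'   so callers can assert the label alignment).
#' @return named list of statistics.
#' @export
datasetStatistics <- function(ds, ref = NULL) {
  stopifnot(is(ds, "PathwayDataset"))
  if (!hasLabels(ds)) stop("dataset has no labels", call. = FALSE)
  if (!is.null(ref) && ncol(ds@labels) != nPathways(ref)) {
    stop("label matrix is not aligned to the reference pathway order", call. = FALSE)
  }
  n <- nSamples(ds)
  Y <- ds@labels
  L <- sum(Y)
  ratio <- function(num, den) if (den > 0) num / den else 0
  LCard <- ratio(L, n)
  LDen <- ratio(LCard, L)
  DL <- sum(colSums(Y) > 0)
  PDL <- ratio(DL, n)
  R <- sum(vapply(ds@abundances, sum, numeric(1)))
  RCard <- ratio(R, n)
  RDen <- ratio(RCard, R)
  DR <- length(unique(unlist(lapply(ds@abundances, function(a) names(a)[a > 0]),
                             use.names = FALSE)))
  PDR <- ratio(DR, n)
  PLR <- ratio(L, R)
  zeroDen <- c(if (L == 0) "LDen", if (R == 0) c("RDen", "PLR"))
  zeroDen <- as.character(zeroDen %||% character())
  list(n_instances = n, total_labels = L, label_cardinality = LCard,
       label_density = LDen, distinct_labels = DL, proportion_distinct_labels = PDL,
       total_reactions = R, reaction_cardinality = RCard, reaction_density = RDen,
       distinct_reactions = DR, proportion_distinct_reactions = PDR,
       pathway_label_ratio = PLR,
       zero_denominator = zeroDen)
}

#' Write / read a prediction report TSV
#'
#' Rows \code{sample_id}, \code{pathway_id}, \code{probability} (6 decimal
#' places), \code{predicted} (0/1), sorted by sample order then descending
#' probability with ties broken by pathway id.
#'
#' @param prob n x t probability matrix (sample-id rownames, pathway-id colnames).
#' @param predicted n x t binary decision matrix of the same shape.
#' @param path output TSV path.
#' @export
writePredictions <- function(prob, predicted, path) {
  stopifnot(identical(dim(prob), dim(predicted)))
  n <- nrow(prob)
  rows <- vector("list", n)
  sids <- rownames(prob) %||% paste0("S", seq_len(n))
  pids <- colnames(prob)
  for (i in seq_len(n)) {
    ord <- order(-prob[i, ], pids)
    rows[[i]] <- data.frame(sample_id = sids[i], pathway_id = pids[ord],
                            probability = sprintf("%.6f", prob[i, ord]),
                            predicted = as.integer(predicted[i, ord]))
  }
  out <- if (n) do.call(rbind, rows) else
    data.frame(sample_id = character(), pathway_id = character(),
               probability = character(), predicted = integer())
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writePredictions
#' @param ref a [PathwayRef-class] defining the pathway order.
#' @param sampleIds row order for the returned matrices.
#' @return \code{readPredictions} returns a list with \code{prob} and
#'   \code{predicted} matrices.
#' @export
readPredictions <- function(path, ref, sampleIds = NULL) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (is.null(sampleIds)) sampleIds <- unique(df$sample_id)
  P <- matrix(0, length(sampleIds), nPathways(ref),
              dimnames = list(sampleIds, pathwayIds(ref)))
  D <- P
  i <- match(df$sample_id, sampleIds)
  j <- match(df$pathway_id, pathwayIds(ref))
  P[cbind(i, j)] <- as.numeric(df$probability)
  D[cbind(i, j)] <- as.numeric(df$predicted)
  list(prob = P, predicted = D)
}
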