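#' Training hyperparameters
#'
#' Defaults follow the full-scale reference setup: penalty weight
#' \code{lambda = 10000}, elastic-net mixing \code{alpha = 0.65}, decision
#' threshold \code{tau = 0.5}, batch size 500, 3 epochs, learning rate
#' \eqn{\eta_u = 1 / (\lambda_{lr} + u)} with \eqn{u} a global step counter.
#' \code{lambdaLR} decouples the learning-rate schedule from the penalty
#' weight; when \code{NULL} it defaults to \code{lambda}. At small problem
#' sizes a much smaller penalty (e.g. \code{lambda = 1e-4}) with
#' \code{lambdaLR} around 10 and more epochs is appropriate; see the
#' package vignette.
#'
#' @param lambda positive elastic-net penalty weight.
#' @param alpha elastic-net mixing in \eqn{[0, 1]} (1 = lasso, 0 = ridge).
#' @param tau decision threshold in (0, 1).
#' @param beta adaptive decision ratio in (0, 1]; it cannot be 0 (that
#'   would retrieve every pathway).
#' @param batchSize positive integer mini-batch size.
#' @param epochs positive integer number of passes over the training data.
#' @param seed integer seed controlling initialization and batch order.
#' @param adaptive use the adaptive decision rule by default at prediction.
#' @param lambdaLR learning-rate offset; \code{NULL} means \code{lambda}.
#' @return a list of class \code{"Hyperparameters"}.
#' @export
hyperParameters <- function(lambda = 10000, alpha = 0.65, tau = 0.5, beta = 0.5,
                            batchSize = 500L, epochs = 3L, seed = 1L,
                            adaptive = FALSE, lambdaLR = NULL) {
  .assertNumber(lambda, "lambda")
  if (lambda <= 0) stop("lambda must be > 0", call. = FALSE)
  .assertNumber(alpha, "alpha", 0, 1)
  .assertNumber(tau, "tau")
  if (tau <= 0 || tau >= 1) stop("tau must be in (0, 1)", call. = FALSE)
  .assertNumber(beta, "beta")
  if (beta <= 0 || beta > 1) {
    stop("beta cannot be 0 (that would retrieve all pathways); it must be in (0, 1]",
         call. = FALSE)
  }
  .assertNumber(batchSize, "batchSize", lower = 1)
  .assertNumber(epochs, "epochs", lower = 1)
  .assertFlag(adaptive, "adaptive")
  if (!is.null(lambdaLR)) .assertNumber(lambdaLR, "lambdaLR", lower = 0)
  structure(list(lambda = lambda, alpha = alpha, tau = tau, beta = beta,
                 batchSize = as.integer(batchSize), epochs = as.integer(epochs),
                 seed = as.integer(seed), adaptive = adaptive,
                 lambdaLR = lambdaLR %||% lambda),
            class = "Hyperparameters")
}

# Numerically safe logistic with logit clipping at +/- 30.
.LOGIT_CLIP <- 30
.sigmoid <- function(z) plogis(pmin(pmax(z, -.LOGIT_CLIP), .LOGIT_CLIP))

# log(1 + exp(z)) without overflow
.log1pexp <- function(z) ifelse(z > 30, z, log1p(exp(pmin(z, 30))))

#' Elastic-net logistic objective and subgradient (single pathway)
#'
#' The per-pathway objective maximized during training is
#' \deqn{C(\theta) = \frac{1}{n}\sum_i \left[y_i \theta^\top \phi_i -
#'   \log(1 + e^{\theta^\top \phi_i})\right] -
#'   \lambda\left[\frac{1-\alpha}{2}\|\theta\|_2^2 +
#'   \alpha\|\theta\|_1\right],}
#' with the intercept excluded from the penalty. The subgradient uses
#' \eqn{sign(0) = 0} at the L1 kink.
#'
#' @param theta numeric weight vector; when \code{intercept = TRUE} its
#'   first coordinate is the (unpenalized) intercept and
#'   \code{length(theta) == ncol(X) + 1}.
#' @param X n x m feature matrix (no intercept column).
#' @param y binary response vector of length n.
#' @param lambda,alpha elastic-net penalty parameters.
#' @param intercept whether \code{theta[1]} is an intercept.
#' @return \code{enObjective}: scalar objective value; \code{enGradient}:
#'   subgradient vector of the same length as \code{theta}.
#' @export
enObjective <- function(theta, X, y, lambda, alpha, intercept = TRUE) {
  if (intercept) X <- cbind(1, X)
  stopifnot(length(theta) == ncol(X), length(y) == nrow(X), nrow(X) > 0)
  z <- drop(X %*% theta)
  ll <- mean(y * z - .log1pexp(z))
  pen <- theta
  if (intercept) pen <- pen[-1L]
  ll - lambda * ((1 - alpha) / 2 * sum(pen^2) + alpha * sum(abs(pen)))
}

#' @rdname enObjective
#' @export
enGradient <- function(theta, X, y, lambda, alpha, intercept = TRUE) {
  if (intercept) X <- cbind(1, X)
  stopifnot(length(theta) == ncol(X), length(y) == nrow(X), nrow(X) > 0)
  z <- drop(X %*% theta)
  g <- drop(crossprod(X, y - .sigmoid(z))) / nrow(X)
  pen <- lambda * ((1 - alpha) * theta + alpha * sign(theta))
  if (intercept) pen[1L] <- 0
  g - pen
}

#' Predicted pathway probabilities
#'
#' Applies the logistic model of each pathway to a feature matrix:
#' \eqn{q_j = \sigma(\theta_j^\top \Phi(x))} with logits clipped at
#' \eqn{\pm 30} for stability.
#'
#' @param model a [PathwayModel-class].
#' @param X scaled n x m feature matrix whose columns match the model's
#'   feature layout.
#' @return n x t matrix of probabilities in (0, 1).
#' @export
predictProba <- function(model, X) {
  stopifnot(is(model, "PathwayModel"))
  if (!identical(colnames(X), model@featureNames)) {
    stop("feature layout mismatch: model fingerprint ",
         model@fingerprints[["features"]], " vs matrix fingerprint ",
         .fingerprint(colnames(X) %||% character()), call. = FALSE)
  }
  Z <- cbind(1, X) %*% t(model@theta)
  Q <- .sigmoid(Z)
  dimnames(Q) <- list(rownames(X), model@pathwayIds)
  Q
}

#' Decision rules over predicted probabilities
#'
#' \code{decideThreshold} predicts pathway j iff \eqn{q_j \ge \tau}
#' (inclusive). \code{decideAdaptive} additionally accepts any pathway with
#' \eqn{q_j \ge \beta \cdot \max_k q_k} (the soft/adaptive decision rule);
#' its result is always a nonempty superset of the threshold rule's.
#'
#' @param q numeric probability vector, or an n x t matrix (rows handled
#'   independently).
#' @param tau threshold in (0, 1).
#' @param beta ratio in (0, 1]; 0 is rejected (it would retrieve all
#'   pathways).
#' @return binary vector or matrix of the same shape as \code{q}.
#' @export
decideThreshold <- function(q, tau = 0.5) {
  out <- (q >= tau) * 1
  out
}

#' @rdname decideThreshold
#' @export
decideAdaptive <- function(q, tau = 0.5, beta = 0.5) {
  if (!is.numeric(beta) || beta <= 0 || beta > 1) {
    stop("beta cannot be 0 (that would retrieve all pathways); it must be in (0, 1]",
         call. = FALSE)
  }
  if (is.matrix(q)) {
    cut <- pmin(tau, beta * apply(q, 1L, max))
    return((q >= cut) * 1)
  }
  ((q >= tau) | (q >= beta * max(q))) * 1
}

#' Fit the one-vs-rest elastic-net logistic model
#'
#' Trains t independent binary logistic classifiers by mini-batch
#' subgradient ascent on the elastic-net objective. Weights are
#' initialized uniformly in \eqn{[0, 1]}; each epoch visits a seeded
#' shuffled order of the samples in batches of \code{batchSize} (the final
#' short batch is used as-is with its own size in the 1/n factor); the
#' update is \eqn{\theta \leftarrow \theta + \eta_u g} with
#' \eqn{\eta_u = 1/(\lambda_{lr} + u)} and \eqn{u} a global step counter
#' starting at 1. Training is deterministic under the seed.
#'
#' @param X scaled n x m feature matrix (from [featurize()] +
#'   [applyMinMaxScaler()]).
#' @param Y n x t binary label matrix with pathway-id colnames.
#' @param hp a [hyperParameters()] list.
#' @param scaler optional fitted scaler to store with the model.
#' @return a [PathwayModel-class].
#' @export
fitModel <- function(X, Y, hp = hyperParameters(), scaler = list()) {
  stopifnot(is.matrix(X), is.matrix(Y), nrow(X) == nrow(Y), nrow(X) > 0)
  n <- nrow(X); m <- ncol(X); t <- ncol(Y)
  lamLR <- hp$lambdaLR
  Xa <- cbind(1, X)
  Theta <- NULL
  withr::with_seed(hp$seed, {
    Theta <- matrix(runif(t * (m + 1L)), nrow = t)
    u <- 0L
    for (ep in seq_len(hp$epochs)) {
      ord <- sample.int(n)
      starts <- seq.int(1L, n, by = hp$batchSize)
      for (s in starts) {
        idx <- ord[s:min(s + hp$batchSize - 1L, n)]
        nb <- length(idx)
        u <- u + 1L
        eta <- 1 / (lamLR + u)
        Z <- Xa[idx, , drop = FALSE] %*% t(Theta)
        Q <- .sigmoid(Z)
        G <- crossprod(Y[idx, , drop = FALSE] - Q, Xa[idx, , drop = FALSE]) / nb
        P <- hp$lambda * ((1 - hp$alpha) * Theta + hp$alpha * sign(Theta))
        P[, 1L] <- 0
        Theta <- Theta + eta * (G - P)
        if (any(!is.finite(Theta))) {
          bad <- which(!is.finite(Theta), arr.ind = TRUE)[1L, ]
          stop("non-finite weight at step ", u, " for pathway ",
               colnames(Y)[bad[1L]], call. = FALSE)
        }
      }
    }
  })
  featNames <- colnames(X) %||% paste0("f", seq_len(m))
  new("PathwayModel", theta = unname(Theta), hyper = unclass(hp),
      featureConfig = list(), scaler = scaler,
      pathwayIds = colnames(Y) %||% paste0("P", seq_len(t)),
      featureNames = featNames,
      layout = featureLayout(X) %||% data.frame(),
      fingerprints = c(features = .fingerprint(featNames),
                       pathways = .fingerprint(colnames(Y) %||% character())))
}

#' Train a pathway prediction model from a labeled dataset
#'
#' High-level pipeline: featurize the dataset, fit the min-max scaler on it
#' (training data only), scale, and fit the one-vs-rest model. The feature
#' configuration and scaler are stored in the model so prediction applies
#' the identical transformation.
#'
#' @param ds a labeled [PathwayDataset-class].
#' @param ref a [PathwayRef-class].
#' @param cfg a [featureConfig()].
#' @param hp a [hyperParameters()].
#' @return a [PathwayModel-class].
#' @export
trainPathwayModel <- function(ds, ref, cfg = featureConfig(), hp = hyperParameters()) {
  if (!hasLabels(ds)) stop("training dataset has no labels", call. = FALSE)
  X <- featurize(ds, ref, cfg)
  scaler <- list()
  if (cfg$scaling == "minmax") {
    scaler <- fitMinMaxScaler(X)
    X <- applyMinMaxScaler(X, scaler)
  }
  model <- fitModel(X, labelMatrix(ds), hp, scaler = scaler)
  model@featureConfig <- unclass(cfg)
  model
}

#' Predict pathways for a dataset with a trained model
#'
#' @param model a [PathwayModel-class] from [trainPathwayModel()].
#' @param ds a [PathwayDataset-class].
#' @param ref the [PathwayRef-class] the model was trained against.
#' @param tau,beta decision parameters (default from the model's
#'   hyperparameters).
#' @param adaptive use the adaptive decision rule.
#' @return list with \code{prob} (n x t probabilities) and \code{predicted}
#'   (n x t binary decisions).
#' @export
predictPathways <- function(model, ds, ref, tau = NULL, beta = NULL,
                            adaptive = NULL) {
  stopifnot(is(model, "PathwayModel"))
  cfg <- do.call(featureConfig, model@featureConfig[c("blocks", "coverageThresholds", "scaling")])
  X <- featurize(ds, ref, cfg)
  if (cfg$scaling == "minmax") {
    if (!length(model@scaler)) {
      stop("model has no fitted scaler; cannot featurize for inference", call. = FALSE)
    }
    X <- applyMinMaxScaler(X, model@scaler)
  }
  tau <- tau %||% model@hyper$tau
  beta <- beta %||% model@hyper$beta
  adaptive <- adaptive %||% model@hyper$adaptive
  Q <- predictProba(model, X)
  Yhat <- if (adaptive) decideAdaptive(Q, tau, beta) else decideThreshold(Q, tau)
  list(prob = Q, predicted = Yhat)
}

#' Top-weighted features for a pathway
#'
#' Ranks the k largest-magnitude (non-intercept) coordinates of the
#' pathway's weight vector, mapped to feature names; ties break by feature
#' index.
#'
#' @param model a [PathwayModel-class].
#' @param pathwayId a pathway id known to the model.
#' @param k number of features to return (capped at m).
#' @return data.frame with columns \code{feature} and \code{weight}.
#' @export
topFeatures <- function(model, pathwayId, k = 10L) {
  stopifnot(is(model, "PathwayModel"), k >= 1)
  j <- match(pathwayId, model@pathwayIds)
  if (is.na(j)) stop("unknown pathway id: ", pathwayId, call. = FALSE)
  w <- model@theta[j, -1L]
  ord <- order(-abs(w), seq_along(w))
  ord <- ord[seq_len(min(k, length(w)))]
  data.frame(feature = model@featureNames[ord], weight = unname(w[ord]))
}

#' Save / load a trained model as JSON
#'
#' Serializes the weight matrix, hyperparameters, feature configuration,
#' scaler parameters, pathway order and layout fingerprints into a single
#' JSON container.
#'
#' @param model a [PathwayModel-class].
#' @param path file path.
#' @export
saveModel <- function(model, path) {
  stopifnot(is(model, "PathwayModel"))
  obj <- list(theta = model@theta, hyper = model@hyper,
              featureConfig = model@featureConfig,
              scaler = model@scaler, pathwayIds = model@pathwayIds,
              featureNames = model@featureNames,
              layout = model@layout,
              fingerprints = as.list(model@fingerprints))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  sc <- obj$scaler
  if (length(sc)) sc <- list(min = unname(sc$min), range = unname(sc$range),
                             names = sc$names)
  hyper <- obj$hyper
  hyper$batchSize <- as.integer(hyper$batchSize)
  hyper$epochs <- as.integer(hyper$epochs)
  hyper$seed <- as.integer(hyper$seed)
  new("PathwayModel", theta = as.matrix(obj$theta), hyper = hyper,
      featureConfig = as.list(obj$featureConfig),
      scaler = if (length(sc)) sc else list(),
      pathwayIds = obj$pathwayIds, featureNames = obj$featureNames,
      layout = as.data.frame(obj$layout),
      fingerprints = unlist(obj$fingerprints))
}

setMethod("show", "PathwayModel", function(object) {
  cat("PathwayModel:", length(object@pathwayIds), "pathways x",
      length(object@featureNames), "features (+ intercept)\n")
  cat("  lambda =", object@hyper$lambda, " alpha =", object@hyper$alpha,
      " epochs =", object@hyper$epochs, "\n")
  nz <- mean(abs(object@theta[, -1L]) > 1e-6)
  cat("  nonzero weight fraction:", format(nz, digits = 3), "\n")
})
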