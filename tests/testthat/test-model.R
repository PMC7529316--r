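test_that("logistic probabilities follow the closed form with clipping", {
  # zero weights -> probability 0.5 everywhere
  X <- matrix(rnorm(12), 3, 4, dimnames = list(NULL, paste0("f", 1:4)))
  model <- new("PathwayModel",
               theta = matrix(0, 2, 5), hyper = unclass(hyperParameters()),
               featureConfig = list(), scaler = list(),
               pathwayIds = c("A", "B"), featureNames = paste0("f", 1:4),
               layout = data.frame(),
               fingerprints = c(features = "x", pathways = "y"))
  Q <- predictProba(model, X)
  expect_true(all(Q == 0.5))
  # z = ln 3 -> q = 0.75
  model@theta <- rbind(c(log(3), 0, 0, 0, 0), c(100, 0, 0, 0, 0))
  Q <- predictProba(model, X)
  expect_equal(unname(Q[, 1]), rep(0.75, 3))
  # z = 100 clipped to 30 -> within 1e-12 of 1
  expect_true(all(abs(Q[, 2] - 1) < 1e-12))
  # mismatched feature layout is an error
  X2 <- X; colnames(X2) <- paste0("g", 1:4)
  expect_error(predictProba(model, X2), "mismatch")
})

test_that("threshold decision rule is inclusive at tau", {
  expect_equal(unname(decideThreshold(c(0.7, 0.5, 0.2), 0.5)), c(1, 1, 0))
  expect_equal(unname(decideThreshold(c(0.49999), 0.5)), 0)
  expect_equal(unname(decideThreshold(c(0.2, 0.3), 0.9)), c(0, 0))
})

test_that("adaptive decision rule accepts near-maximum probabilities", {
  expect_equal(unname(decideAdaptive(c(0.9, 0.6, 0.2), 0.5, 0.5)), c(1, 1, 0))
  # below tau the arg-max alone survives at beta = 1
  expect_equal(unname(decideAdaptive(c(0.4, 0.3), 0.5, 1)), c(1, 0))
  expect_error(decideAdaptive(c(0.4, 0.3), 0.5, 0), "beta")
  # matrix form treats rows independently
  Q <- rbind(c(0.9, 0.6, 0.2), c(0.1, 0.05, 0.02))
  D <- decideAdaptive(Q, 0.5, 0.5)
  expect_equal(unname(D[2, ]), c(1, 1, 0))
})

test_that("adaptive predictions are a nonempty superset of threshold predictions", {
  withr::with_seed(101, {
    for (rep in 1:200) {
      q <- runif(sample(2:30, 1), min = 1e-6, max = 1 - 1e-6)
      tau <- runif(1, 0.05, 0.95)
      beta <- runif(1, 0.05, 1)
      hard <- decideThreshold(q, tau)
      soft <- decideAdaptive(q, tau, beta)
      expect_true(all(soft >= hard))
      expect_gte(sum(soft), 1)
    }
  })
})

test_that("objective at theta = 0 equals -log 2 and penalty limits hold", {
  withr::with_seed(7, {
    X <- matrix(rnorm(40), 8, 5)
    y <- rbinom(8, 1, 0.5)
  })
  th0 <- rep(0, 6)
  expect_equal(enObjective(th0, X, y, lambda = 5, alpha = 0.3), -log(2))
  th <- c(0.5, -1, 2, 0, 1, -0.5)
  # lambda = 0 reduces to the pure log-likelihood
  ll <- enObjective(th, X, y, lambda = 1e-12, alpha = 0.5)
  pen1 <- enObjective(th, X, y, lambda = 2, alpha = 1)
  expect_equal(pen1, ll - 2 * sum(abs(th[-1])), tolerance = 1e-9)
  pen0 <- enObjective(th, X, y, lambda = 2, alpha = 0)
  expect_equal(pen0, ll - sum(th[-1]^2), tolerance = 1e-9)
})

test_that("subgradient matches central finite differences away from kinks", {
  withr::with_seed(11, {
    for (alpha in c(0, 0.65, 1)) {
      X <- matrix(rnorm(20 * 8), 20, 8)
      y <- rbinom(20, 1, 0.5)
      theta <- runif(9, 0.15, 1) * sample(c(-1, 1), 9, replace = TRUE)
      g <- enGradient(theta, X, y, lambda = 0.1, alpha = alpha)
      h <- 1e-6
      fd <- vapply(seq_along(theta), function(k) {
        tp <- theta; tm <- theta
        tp[k] <- tp[k] + h; tm[k] <- tm[k] - h
        (enObjective(tp, X, y, 0.1, alpha) - enObjective(tm, X, y, 0.1, alpha)) / (2 * h)
      }, numeric(1))
      expect_lt(max(abs(g - fd) / pmax(abs(fd), 1e-3)), 1e-4)
    }
  })
})

test_that("gradient at zero weights with a single positive sample is phi/2", {
  phi <- c(2, -1, 0.5)
  g <- enGradient(rep(0, 4), matrix(phi, 1), y = 1, lambda = 3, alpha = 0.65)
  expect_equal(g, 0.5 * c(1, phi))   # sign(0) = 0 kills the L1 term
})

test_that("training is deterministic under the seed", {
  ref <- randomReference(6, 25, seed = 41)
  ds <- generateDataset(ref, synthesisConfig(60, 2, seed = 42))
  cfg <- featureConfig("AB", scaling = "none")
  hp <- hyperParameters(lambda = 1e-4, lambdaLR = 1, batchSize = 20,
                        epochs = 10, seed = 43)
  m1 <- trainPathwayModel(ds, ref, cfg, hp)
  m2 <- trainPathwayModel(ds, ref, cfg, hp)
  expect_identical(m1@theta, m2@theta)
  m3 <- trainPathwayModel(ds, ref, cfg, hyperParameters(lambda = 1e-4,
    lambdaLR = 1, batchSize = 20, epochs = 10, seed = 44))
  expect_false(identical(m1@theta, m3@theta))
})

test_that("separable synthetic classes are recovered with high F1", {
  ref <- randomReference(2, 16, minSize = 6, maxSize = 8, seed = 45)
  ds <- generateDataset(ref, synthesisConfig(500, 1, seed = 46))
  sp <- stratifiedSplit(ds, c(0.7, 0.15, 0.15), seed = 47)
  hp <- hyperParameters(lambda = 1e-4, alpha = 0.65, lambdaLR = 1,
                        batchSize = 100, epochs = 50, seed = 48)
  m <- trainPathwayModel(sp$train, ref, featureConfig("AB", scaling = "none"), hp)
  res <- predictPathways(m, sp$test, ref)
  f1 <- multilabelMetrics(labelMatrix(sp$test), res$predicted)$f1
  expect_gte(f1, 0.95)
})

test_that("stronger regularization shrinks the weight norm", {
  # swept within the convergent regime: at very large lambda the L1
  # subgradient limit-cycles with amplitude eta*lambda*alpha and the norm
  # no longer settles (see the methods vignette)
  ref <- randomReference(5, 20, seed = 51)
  ds <- generateDataset(ref, synthesisConfig(80, 2, seed = 52))
  cfg <- featureConfig("AB", scaling = "none")
  norms <- vapply(c(1e-4, 1e-2, 1), function(lam) {
    hp <- hyperParameters(lambda = lam, alpha = 0.65,
                          batchSize = 40, epochs = 50, seed = 53)
    sum(abs(trainPathwayModel(ds, ref, cfg, hp)@theta))
  }, numeric(1))
  expect_true(all(diff(norms) <= 0))
})

test_that("lasso produces at least as many near-zero weights as ridge", {
  ref <- randomReference(5, 20, seed = 54)
  ds <- generateDataset(ref, synthesisConfig(80, 2, seed = 55))
  cfg <- featureConfig("AB", scaling = "none")
  nzero <- vapply(c(0, 1), function(a) {
    hp <- hyperParameters(lambda = 0.05, alpha = a, lambdaLR = 1,
                          batchSize = 40, epochs = 20, seed = 56)
    sum(abs(trainPathwayModel(ds, ref, cfg, hp)@theta[, -1]) < 1e-6)
  }, numeric(1))
  expect_gte(nzero[2], nzero[1])
})

test_that("top features rank by weight magnitude with index ties", {
  model <- new("PathwayModel",
               theta = rbind(c(1, 0, 3, -5)), hyper = unclass(hyperParameters()),
               featureConfig = list(), scaler = list(),
               pathwayIds = "A", featureNames = c("f1", "f2", "f3"),
               layout = data.frame(),
               fingerprints = c(features = "x", pathways = "y"))
  tf <- topFeatures(model, "A", 2)
  expect_equal(tf$feature, c("f3", "f2"))
  expect_equal(tf$weight, c(-5, 3))
  expect_equal(nrow(topFeatures(model, "A", 99)), 3L)
  expect_error(topFeatures(model, "nope", 1), "unknown pathway")
})

test_that("model JSON serialization round-trips weights and predictions", {
  ref <- randomReference(4, 15, seed = 61)
  ds <- generateDataset(ref, synthesisConfig(40, 2, seed = 62))
  hp <- hyperParameters(lambda = 1e-4, lambdaLR = 1, batchSize = 20,
                        epochs = 5, seed = 63)
  m <- trainPathwayModel(ds, ref, featureConfig(scaling = "minmax"), hp)
  path <- withr::local_tempfile(fileext = ".json")
  saveModel(m, path)
  m2 <- loadModel(path)
  expect_equal(m2@theta, m@theta)
  r1 <- predictPathways(m, ds, ref)
  r2 <- predictPathways(m2, ds, ref)
  expect_equal(r2$prob, r1$prob)
})
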