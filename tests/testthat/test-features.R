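test_that("abundance block places abundances at the reference positions", {
  ref <- toyRef()  # reactions sorted: 1.1.1.1, 2.2.2.2, 2.7.1.1, 3.3.3.3
  v <- abundanceBlock(c("1.1.1.1" = 2, "3.3.3.3" = 5), ref)
  expect_equal(as.vector(v), c(2, 0, 0, 5))
  expect_equal(as.vector(abundanceBlock(numeric(), ref)), rep(0, 4))
  # unknown ECs are ignored but tallied
  v2 <- abundanceBlock(c("1.1.1.1" = 2, "9.9.9.9" = 1), ref)
  expect_equal(as.vector(v2), c(2, 0, 0, 0))
  expect_equal(attr(v2, "unknown_ecs"), 1L)
})

test_that("reaction evidence block has length 68 with documented entries", {
  ref <- toyRef()
  v <- reactionEvidenceBlock(c("1.1.1.1" = 2, "2.2.2.2" = 1), ref)
  expect_length(v, 68L)
  expect_equal(unname(v["class1:distinct"]), 1)
  expect_equal(unname(v["class2:distinct"]), 1)
  expect_equal(unname(v["class1:abundance"]), 2)
  expect_equal(unname(v["global:distinct"]), 2)
  # 2 of 4 reference reactions observed
  expect_equal(unname(v["frac_ref_observed"]), 0.5)
  # 1.1.1.1 maps to P1+P2, 2.2.2.2 only to P1
  expect_equal(unname(v["frac_mapped_ge2"]), 0.5)
  expect_equal(unname(v["multi_pathway_copies"]), 2)
  expect_equal(unname(v[paste0("reserved", 1:7)]), rep(0, 7))
  # empty sample: everything zero
  expect_equal(unname(reactionEvidenceBlock(numeric(), ref)), rep(0, 68))
})

test_that("pathway evidence block has length 32 and aggregates coverage", {
  ref <- PathwayRef(list(
    list(id = "A", reactions = c("1.1.1.1", "2.2.2.2"), key_reactions = "1.1.1.1"),
    list(id = "B", reactions = c("3.3.3.3", "4.4.4.4"))
  ))
  v <- pathwayEvidenceBlock(c("1.1.1.1" = 1, "2.2.2.2" = 1), ref)
  expect_length(v, 32L)
  # one of two pathways fully covered
  expect_equal(unname(v["cov:eq1:count"]), 1)
  expect_equal(unname(v["cov:eq1:frac"]), 0.5)
  expect_equal(unname(v["cov:mean"]), 1)   # mean of nonzero coverages
  expect_equal(unname(v["key:eq1:count"]), 1)
  expect_equal(unname(v["mean_gap_count"]), 0)
  # covering all reference reactions makes the full-coverage fraction 1
  allv <- pathwayEvidenceBlock(setNames(rep(1, 4), reactionIds(ref)), ref)
  expect_equal(unname(allv["cov:eq1:frac"]), 1)
  expect_length(pathwayEvidenceBlock(numeric(), ref), 32L)
})

test_that("pathway common block flags only observed multi-pathway reactions", {
  ref <- toyRef()
  # 1.1.1.1 is shared by P1 and P2; 2.2.2.2 belongs to P1 only
  v <- pathwayCommonBlock(c("1.1.1.1" = 1, "2.2.2.2" = 3), ref)
  expect_equal(unname(v), c(1, 0, 0, 0))
  expect_equal(unname(pathwayCommonBlock(numeric(), ref)), rep(0, 4))
})

test_that("possible pathway block emits any-hit and key-complete pairs", {
  ref <- toyRef()
  v <- possiblePathwayBlock(c("2.2.2.2" = 1), ref)
  expect_length(v, 6L)
  # P1: one of three reactions seen, key (1.1.1.1) not observed
  expect_equal(unname(v[c("anyhit:P1", "keycomplete:P1")]), c(1, 0))
  expect_equal(unname(v[c("anyhit:P2", "keycomplete:P2")]), c(0, 0))
  # empty key set never counts as complete
  full <- possiblePathwayBlock(setNames(rep(1, 4), reactionIds(ref)), ref)
  expect_equal(unname(full["keycomplete:P3"]), 0)
  expect_equal(unname(possiblePathwayBlock(numeric(), ref)), rep(0, 6))
})

test_that("feature matrix width is the sum of enabled block widths", {
  fx <- toyDataset()
  r <- nReactions(fx$ref); t <- nPathways(fx$ref)
  X <- suppressWarnings(featurize(fx$ds, fx$ref, featureConfig()))
  expect_equal(ncol(X), r + 68 + 32 + r + 2 * t)
  expect_equal(nrow(X), 3L)
  lay <- featureLayout(X)
  expect_equal(lay$width, c(r, 68L, 32L, r, 2L * t))
  expect_equal(lay$offset, cumsum(c(0L, lay$width[-5])))
  Xab <- suppressWarnings(featurize(fx$ds, fx$ref, featureConfig("AB")))
  expect_equal(ncol(Xab), r)
  expect_error(featureConfig(character()), "at least one")
})

test_that("featurization is pure: repeated calls are identical and finite", {
  ref <- randomReference(8, 30, seed = 31)
  ds <- generateDataset(ref, synthesisConfig(15, 2, seed = 32))
  X1 <- featurize(ds, ref)
  X2 <- featurize(ds, ref)
  expect_identical(X1, X2)
  expect_true(all(is.finite(X1)))
  # binary blocks really are binary
  lay <- featureLayout(X1)
  for (b in c("PC", "PP")) {
    off <- lay$offset[lay$block == b]; w <- lay$width[lay$block == b]
    expect_true(all(X1[, (off + 1):(off + w)] %in% c(0, 1)))
  }
})

test_that("min-max scaling maps training features into [0,1] and freezes", {
  ref <- randomReference(8, 30, seed = 33)
  ds <- generateDataset(ref, synthesisConfig(20, 2, seed = 34))
  X <- featurize(ds, ref)
  sc <- fitMinMaxScaler(X)
  Xs <- applyMinMaxScaler(X, sc)
  expect_true(all(Xs >= 0 & Xs <= 1))
  # constant features map to 0
  constCols <- which(sc$range == 0)
  expect_true(all(Xs[, constCols] == 0))
  # mismatched layout is rejected
  Xab <- featurize(ds, ref, featureConfig("AB"))
  expect_error(applyMinMaxScaler(Xab, sc), "does not match")
})

test_that("adding an observed reaction never decreases hit/coverage features", {
  ref <- randomReference(10, 40, seed = 35)
  withr::with_seed(36, {
    for (rep in 1:10) {
      obs <- sample(reactionIds(ref), 8)
      a1 <- setNames(rep(1, 8), obs)
      extra <- sample(setdiff(reactionIds(ref), obs), 1)
      a2 <- c(a1, setNames(1, extra))
      p1 <- possiblePathwayBlock(a1, ref); p2 <- possiblePathwayBlock(a2, ref)
      expect_true(all(p2 >= p1))
      c1 <- pathwayCoverage(ref, a1); c2 <- pathwayCoverage(ref, a2)
      expect_true(all(c2 >= c1))
    }
  })
})
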