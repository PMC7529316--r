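test_that("generator output is reproducible and respects the label contract", {
  ref <- randomReference(12, 50, seed = 3)
  cfg <- synthesisConfig(40, 3, seed = 17)
  ds1 <- generateDataset(ref, cfg)
  ds2 <- generateDataset(ref, cfg)
  expect_identical(ds1@abundances, ds2@abundances)
  expect_identical(labelMatrix(ds1), labelMatrix(ds2))
  # changing only the seed changes the output
  ds3 <- generateDataset(ref, synthesisConfig(40, 3, seed = 18))
  expect_false(identical(labelMatrix(ds1), labelMatrix(ds3)))
  # no sample has zero labels
  expect_true(all(rowSums(labelMatrix(ds1)) >= 1))
  # every labeled pathway has coverage 1.0 in its clean sample
  for (i in seq_len(nSamples(ds1))) {
    cov <- pathwayCoverage(ref, ds1@abundances[[i]])
    expect_true(all(cov[labelMatrix(ds1)[i, ] == 1] == 1))
  }
})

test_that("a single-pathway reference labels every sample with that pathway", {
  ref <- PathwayRef(list(list(id = "only", reactions = c("1.1.1.1", "2.2.2.2"))))
  ds <- generateDataset(ref, synthesisConfig(10, 4, seed = 1))
  expect_true(all(labelMatrix(ds) == 1))
})

test_that("mean labels per sample matches the truncated Poisson mean", {
  ref <- randomReference(50, 150, seed = 5)
  ds <- generateDataset(ref, synthesisConfig(5000, 5, seed = 23))
  mu <- 5
  se <- sqrt(mu) / sqrt(5000)
  expect_lt(abs(mean(rowSums(labelMatrix(ds))) - mu), 3 * se)
})

test_that("abundances are at least one copy per present reaction", {
  ref <- randomReference(8, 30, seed = 2)
  ds <- generateDataset(ref, synthesisConfig(50, 2, abundanceMean = 3, seed = 4))
  expect_true(all(unlist(ds@abundances) >= 1))
})

test_that("corruption with zero rates is the identity and full deletion empties samples", {
  ref <- randomReference(10, 40, seed = 6)
  ds <- generateDataset(ref, synthesisConfig(20, 3, seed = 7))
  expect_identical(corruptDataset(ds, ref, 0, 0, seed = 1), ds)
  gone <- corruptDataset(ds, ref, 0, 1, seed = 1)
  expect_true(all(lengths(gone@abundances) == 0))
  # p_del = 1 with insertion: all surviving reactions are insertions
  mixed <- corruptDataset(ds, ref, 0.5, 1, seed = 1)
  for (i in seq_len(nSamples(ds))) {
    orig <- names(ds@abundances[[i]])
    expect_length(intersect(names(mixed@abundances[[i]]), orig), 0)
  }
})

test_that("corruption preserves n, t and the label matrix exactly", {
  ref <- randomReference(10, 40, seed = 6)
  ds <- generateDataset(ref, synthesisConfig(30, 3, seed = 8))
  noisy <- corruptDataset(ds, ref, 0.3, 0.3, seed = 9)
  expect_equal(nSamples(noisy), nSamples(ds))
  expect_identical(labelMatrix(noisy), labelMatrix(ds))
})

test_that("empirical deletion fraction matches the configured rate", {
  ref <- randomReference(15, 60, seed = 11)
  ds <- generateDataset(ref, synthesisConfig(2000, 4, seed = 12))
  pDel <- 0.2
  noisy <- corruptDataset(ds, ref, 0, pDel, seed = 13)
  before <- sum(lengths(ds@abundances))
  after <- sum(lengths(noisy@abundances))
  se <- sqrt(pDel * (1 - pDel) / before)
  expect_lt(abs((before - after) / before - pDel), 3 * se)
})

test_that("stratified split sizes are within one sample of the target fractions", {
  ref <- randomReference(20, 80, seed = 14)
  ds <- generateDataset(ref, synthesisConfig(500, 3, seed = 15))
  fr <- c(0.725, 0.129, 0.146)
  sp <- stratifiedSplit(ds, fr, seed = 16)
  sizes <- vapply(sp, nSamples, integer(1))
  expect_equal(sum(sizes), 500L)
  expect_true(all(abs(sizes - 500 * fr) <= 1))
  # disjoint union equals the input
  ids <- unlist(lapply(sp, sampleIds))
  expect_setequal(ids, sampleIds(ds))
  expect_equal(anyDuplicated(ids), 0L)
})

test_that("degenerate split fractions put everything in one part", {
  ref <- randomReference(5, 20, seed = 1)
  ds <- generateDataset(ref, synthesisConfig(10, 2, seed = 2))
  sp <- stratifiedSplit(ds, c(1, 0, 0), seed = 3)
  expect_equal(nSamples(sp$train), 10L)
  expect_equal(nSamples(sp$validation), 0L)
  expect_error(stratifiedSplit(ds[1:2], c(1, 0, 0)), "at least 3")
  expect_error(stratifiedSplit(ds, c(0.5, 0.2, 0.2)), "summing to 1")
})

test_that("labels with enough positives are spread across splits", {
  ref <- randomReference(15, 60, seed = 21)
  ds <- generateDataset(ref, synthesisConfig(300, 4, seed = 22))
  sp <- stratifiedSplit(ds, c(0.5, 0.25, 0.25), seed = 23)
  counts <- sapply(sp, function(part) colSums(labelMatrix(part)))
  eligible <- rowSums(counts) >= 3
  nSplits <- rowSums(counts > 0)
  expect_true(all(nSplits[eligible] >= 2))
})
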