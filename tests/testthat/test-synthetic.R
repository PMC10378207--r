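test_that("flow samples are deterministic without noise and subject effects", {
  spec <- SyntheticSpec(nClasses = 3L, noiseSd = 0, subjectEffectSd = 0,
                        seed = 1L)
  s1 <- makeFlowSample(spec, 2L)
  s2 <- makeFlowSample(spec, 2L)
  expect_identical(tripletArray(s1$triplet), tripletArray(s2$triplet))
  # zero amplitude -> zero flow, all-0.5 triplet
  spec0 <- SyntheticSpec(nClasses = 3L, amplitude = 0, noiseSd = 0,
                         subjectEffectSd = 0, seed = 1L)
  s0 <- makeFlowSample(spec0, 1L)
  expect_equal(max(abs(flowU(s0$flow))), 0)
  expect_equal(unique(as.vector(tripletArray(s0$triplet))), 0.5)
  expect_error(makeFlowSample(spec, 9L), "class")
})

test_that("flow peak sits inside the class locus", {
  spec <- SyntheticSpec(nClasses = 3L, noiseSd = 0, subjectEffectSd = 0,
                        seed = 1L)
  for (k in 1:3) {
    fl <- makeFlowSample(spec, k)$flow
    mag <- sqrt(flowU(fl)^2 + flowV(fl)^2)
    pk <- arrayInd(which.max(mag), dim(mag))
    loci <- spec@motionLoci[spec@motionLoci$class == k, ]
    H <- spec@imageSize[1L]; W <- spec@imageSize[2L]
    dist <- sqrt((pk[1] - (loci$row * (H - 1) + 1))^2 +
                 (pk[2] - (loci$col * (W - 1) + 1))^2)
    expect_lte(min(dist), min(loci$radius) * min(H, W))
  }
})

test_that("sequences ramp to the recorded apex", {
  spec <- SyntheticSpec(nClasses = 2L, seqLen = 15L, apexFrac = 0.6,
                        imageSize = c(48L, 48L), seed = 4L)
  set.seed(4)
  sq <- makeSequence(spec, 1L)
  expect_identical(apexIndex(sq), as.integer(round(0.6 * 14) + 1L))
  mad <- vapply(frames(sq), function(f) mean(abs(f - frames(sq)[[1]])),
                numeric(1))
  expect_identical(which.max(mad), as.integer(apexIndex(sq)))
  # zero amplitude -> all frames identical
  spec0 <- SyntheticSpec(nClasses = 2L, amplitude = 0, seqLen = 8L,
                         imageSize = c(32L, 32L), seed = 4L)
  set.seed(4)
  sq0 <- makeSequence(spec0, 1L)
  expect_identical(frames(sq0)[[1]], frames(sq0)[[8]])
})

test_that("dataset generation is reproducible with exact class counts", {
  spec <- SyntheticSpec(nClasses = 3L, samplesPerClass = c(30L, 30L, 30L),
                        nSubjects = 10L, seed = 2L)
  ds <- makeDataset(spec)
  expect_length(ds$labels, 90L)
  expect_equal(as.vector(table(ds$labels)), c(30, 30, 30))
  expect_length(unique(ds$subjects), 10L)
  expect_equal(as.vector(table(ds$subjects)), rep(9, 10))
  ds2 <- makeDataset(spec)
  expect_identical(ds$triplets, ds2$triplets)
  expect_identical(ds$manifest, ds2$manifest)
  # skewed counts feed straight into the priors
  spec2 <- SyntheticSpec(nClasses = 2L, samplesPerClass = c(60L, 10L),
                         nSubjects = 5L, seed = 2L)
  ds3 <- makeDataset(spec2)
  expect_equal(classPriors(ds3$labels, 2L), c(6 / 7, 1 / 7))
  expect_error(makeDataset(SyntheticSpec(nClasses = 2L,
                                         samplesPerClass = c(2L, 1L),
                                         nSubjects = 8L, seed = 1L)))
})

test_that("a nearest-class-template classifier separates the benchmark under LOSO", {
  ds <- makeDataset(SyntheticSpec(seed = 31L))
  X <- matrix(ds$triplets, ncol = length(ds$labels))   # features x samples
  correct <- 0L
  for (fold in losoSplits(ds$subjects)) {
    tmpl <- sapply(sort(unique(ds$labels)), function(k)
      rowMeans(X[, intersect(fold$trainIdx, which(ds$labels == k)), drop = FALSE]))
    for (i in fold$testIdx) {
      sims <- apply(tmpl, 2L, function(tp)
        sum(tp * X[, i]) / sqrt(sum(tp^2) * sum(X[, i]^2)))
      if (which.max(sims) == ds$labels[i]) correct <- correct + 1L
    }
  }
  expect_gte(correct / length(ds$labels), 0.95)
})
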