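test_that("LOSO folds partition samples without subject leakage", {
  subjects <- rep(paste0("s", 1:5), each = 4)
  folds <- losoSplits(subjects)
  expect_length(folds, 5L)
  seen <- integer(0)
  for (f in folds) {
    expect_length(intersect(subjects[f$trainIdx], subjects[f$testIdx]), 0L)
    seen <- c(seen, f$testIdx)
  }
  expect_setequal(seen, seq_along(subjects))
  expect_length(seen, length(subjects))
  expect_error(losoSplits(rep("s1", 4)), "2 subjects")
})

test_that("confusion metrics match hand-computed values", {
  cm <- matrix(c(3, 1, 2, 4), 2, 2, byrow = TRUE)  # rows = truth
  m <- confusionMetrics(cm)
  expect_equal(m$accuracy, 0.7)
  expect_equal(m$perClass$accuracy, c(0.75, 2 / 3), tolerance = 1e-12)
  expect_equal(m$uar, mean(c(0.75, 2 / 3)), tolerance = 1e-12)
  expect_equal(m$perClass$F1, c(6 / 9, 8 / 11), tolerance = 1e-12)
  expect_equal(m$uf1, mean(c(6 / 9, 8 / 11)), tolerance = 1e-12)
  # perfect predictions
  mp <- confusionMetrics(diag(c(4, 5, 6)))
  expect_equal(mp$accuracy, 1); expect_equal(mp$uf1, 1); expect_equal(mp$uar, 1)
  # all-one-class predictions on balanced two-class data
  ma <- confusionMetrics(matrix(c(5, 0, 5, 0), 2, 2, byrow = TRUE))
  expect_equal(ma$accuracy, 0.5)
  expect_equal(ma$uar, 0.5)
  # absent class is excluded with a warning
  expect_warning(mz <- confusionMetrics(matrix(c(3, 0, 0, 0), 2, 2)), "absent")
  expect_equal(mz$uar, 1)
})

test_that("flow flip is an involution and strain stays mirrored", {
  set.seed(6)
  u <- matrix(stats::rnorm(100), 10, 10)
  v <- matrix(stats::rnorm(100), 10, 10)
  os <- strainMagnitude(opticalStrain(FlowField(u, v)))
  f1 <- flipFlow(u, v, os)
  f2 <- flipFlow(f1$u, f1$v, f1$os)
  expect_identical(f2$u, u); expect_identical(f2$v, v); expect_identical(f2$os, os)
  expect_identical(f1$os, os[, 10:1])
})

test_that("triplet augmentation keeps values in range and dithers per channel", {
  set.seed(7)
  x <- array(stats::runif(28 * 28 * 3), c(28, 28, 3))
  for (i in 1:10) {
    ax <- augmentTriplet(x)
    expect_identical(dim(ax), dim(x))
    expect_gte(min(ax), 0); expect_lte(max(ax), 1)
  }
})

test_that("training reduces the loss on separable data and is reproducible", {
  ds <- smallDataset()
  tc <- tinyTrainConfig(epochs = 3L)
  nc <- NetConfig(nClasses = 2L)
  fit1 <- trainFold(ds$triplets, ds$labels, tc, nc)
  expect_length(fit1$history, 3L)
  expect_lt(fit1$history[3], fit1$history[1])
  fit2 <- trainFold(ds$triplets, ds$labels, tc, nc)
  expect_identical(fit1$history, fit2$history)
  expect_identical(fit1$model@params, fit2$model@params)
  expect_error(trainFold(ds$triplets[, , , ds$labels == 1L],
                         ds$labels[ds$labels == 1L], tc, nc), "single class")
})

test_that("LOSO evaluation pools predictions consistently", {
  ds <- smallDataset()
  rep <- evaluateLoso(ds, tinyTrainConfig(epochs = 2L), NetConfig(nClasses = 2L))
  cm <- confusionMatrix(rep)
  expect_equal(sum(cm), length(ds$labels))
  # metrics from the pooled matrix equal metrics from stored predictions
  cm2 <- matrix(0L, 2, 2)
  for (i in seq_len(nrow(rep@predictions)))
    cm2[rep@predictions$truth[i], rep@predictions$predicted[i]] <-
      cm2[rep@predictions$truth[i], rep@predictions$predicted[i]] + 1L
  expect_equal(unname(unclass(cm)), cm2)
  expect_equal(pooledAccuracy(rep), sum(diag(cm)) / sum(cm))
  # error naming the offending fold when a training split degenerates
  dsBad <- ds
  dsBad$labels[dsBad$subjects != "subj01"] <- 1L
  dsBad$labels[dsBad$subjects == "subj01"] <- 2L
  expect_error(evaluateLoso(dsBad, tinyTrainConfig(epochs = 1L),
                            NetConfig(nClasses = 2L)), "subj")
})

test_that("with uniform priors LASCE and CE runs produce identical reports", {
  ds <- smallDataset()   # balanced two-class data -> uniform priors
  nc <- NetConfig(nClasses = 2L)
  r1 <- evaluateLoso(ds, tinyTrainConfig(epochs = 2L, loss = "lasce"), nc)
  r2 <- evaluateLoso(ds, tinyTrainConfig(epochs = 2L, loss = "ce"), nc)
  expect_equal(confusionMatrix(r1), confusionMatrix(r2))
  expect_equal(pooledAccuracy(r1), pooledAccuracy(r2))
})
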