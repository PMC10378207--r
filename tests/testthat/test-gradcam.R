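test_that("Grad-CAM returns a normalized input-resolution heatmap", {
  model <- flowNet(NetConfig(nClasses = 3L, seed = 14L))
  set.seed(14)
  tri <- FlowTriplet(array(stats::runif(28 * 28 * 3), c(28, 28, 3)))
  h <- gradCam(model, tri, classIdx = 2L)
  expect_identical(dim(h), c(28L, 28L))
  expect_gte(min(h), 0); expect_lte(max(h), 1)
  # defaults to the predicted class
  h2 <- gradCam(model, tri)
  expect_identical(dim(h2), c(28L, 28L))
  expect_error(gradCam(model, tri, target = "conv1"), "target")
  expect_error(gradCam(model, tri, classIdx = 7L), "range")
})

test_that("constant logits give an all-zero heatmap", {
  model <- flowNet(NetConfig(nClasses = 3L, seed = 15L))
  # zero out the head: every class logit is constant, gradients at the
  # target map vanish, and the degenerate-normalization rule yields zeros
  model@params[["fc.W"]][] <- 0
  set.seed(15)
  tri <- array(stats::runif(28 * 28 * 3), c(28, 28, 3))
  h <- gradCam(model, tri, classIdx = 1L)
  expect_equal(max(abs(h)), 0)
})
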