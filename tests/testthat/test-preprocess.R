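test_that("optical strain matches closed forms for analytic fields", {
  # rigid translation: exactly zero strain
  f <- FlowField(matrix(1.3, 12, 12), matrix(-0.4, 12, 12))
  expect_equal(max(strainMagnitude(opticalStrain(f))), 0)

  # u = 0.1 x, v = 0.2 y: os = sqrt(0.01 + 0.04) everywhere
  f <- linearFlowField(16, ax = 0.1, ay = 0.2, bx = 0, by = 0)
  os <- strainMagnitude(opticalStrain(f))
  expect_equal(max(abs(os - sqrt(0.05))), 0, tolerance = 1e-12)

  # simple shear u = 0.2 y: eps_xy = 0.1, os = sqrt(0.02)
  f <- linearFlowField(16, ax = 0, ay = 0, bx = 0.2, by = 0)
  os <- strainMagnitude(opticalStrain(f))
  expect_equal(max(abs(os - sqrt(0.02))), 0, tolerance = 1e-12)

  # quadratic field: central differences are exact for quadratics in the
  # interior, so compare against the analytic symmetric-gradient magnitude
  n <- 20
  x0 <- outer(rep(1, n), 0:(n - 1)); y0 <- outer(0:(n - 1), rep(1, n))
  f <- FlowField(0.001 * x0^2, 0.002 * x0 * y0)
  os <- strainMagnitude(opticalStrain(f))
  exx <- 0.002 * x0; eyy <- 0.002 * x0; exy <- 0.5 * 0.002 * y0
  ref <- sqrt(exx^2 + eyy^2 + 2 * exy^2)
  int <- 2:(n - 1)
  expect_lt(max(abs(os[int, int] - ref[int, int])), 1e-10)
})

test_that("optical strain rejects degenerate inputs", {
  expect_error(opticalStrain(FlowField(matrix(0, 2, 5), matrix(0, 2, 5))),
               "3x3")
})

test_that("TV-L1 flow recovers a known integer translation", {
  base <- texturedImage(64, 80, seed = 11)
  onset <- base[, 3:66]
  apex <- base[, 1:64]   # content moves +2 columns
  f <- computeOpticalFlow(onset, apex)
  int <- 9:56
  expect_lt(abs(stats::median(flowU(f)[int, int]) - 2), 0.25)
  expect_lt(abs(stats::median(flowV(f)[int, int])), 0.25)
})

test_that("flow of identical and constant frames is zero", {
  img <- texturedImage(32, 32, seed = 2)
  f <- computeOpticalFlow(img, img)
  expect_lt(max(abs(flowU(f)), abs(flowV(f))), 1e-3)
  fc <- computeOpticalFlow(matrix(0.5, 32, 32), matrix(0.5, 32, 32))
  expect_equal(max(abs(flowU(fc)), abs(flowV(fc))), 0)
})

test_that("flow input contracts are enforced", {
  a <- texturedImage(64, 64, seed = 3)
  expect_error(computeOpticalFlow(a, a[1:32, 1:32]), "shape")
  b <- a; b[1, 1] <- NA
  expect_error(computeOpticalFlow(a, b), "finite")
})

test_that("triplet assembly normalizes, resizes and handles degeneracy", {
  u <- matrix(stats::rnorm(40 * 40), 40, 40)
  v <- matrix(stats::rnorm(40 * 40), 40, 40)
  fl <- FlowField(u, v)
  tri <- flowToTriplet(fl, opticalStrain(fl), size = 28)
  a <- tripletArray(tri)
  expect_identical(dim(a), c(28L, 28L, 3L))
  expect_gte(min(a), 0); expect_lte(max(a), 1)

  # constant channel -> all 0.5
  fl2 <- FlowField(matrix(5, 28, 28), v[1:28, 1:28])
  tri2 <- flowToTriplet(fl2, opticalStrain(fl2), size = 28)
  expect_equal(unique(as.vector(tripletArray(tri2)[, , 1])), 0.5)

  # no-resize case: min maps to 0, max maps to 1 at the right pixels
  u3 <- matrix(0, 28, 28); u3[5, 7] <- -1; u3[20, 3] <- 1
  m <- minMaxNormalize(u3)
  expect_equal(m[5, 7], 0); expect_equal(m[20, 3], 1)

  # idempotence in range: normalizing twice changes nothing
  expect_equal(minMaxNormalize(m), m)
})

test_that("preprocessSample composes the chain and respects a given apex", {
  spec <- SyntheticSpec(nClasses = 2L, seqLen = 8L, imageSize = c(48L, 48L),
                        seed = 3L)
  set.seed(3)
  sq <- makeSequence(spec, class = 1L)
  expect_false(is.na(apexIndex(sq)))
  tri <- preprocessSample(sq, params = flowParams(nScales = 3L))
  expect_identical(dim(tripletArray(tri)), c(28L, 28L, 3L))
  expect_identical(attr(tripletArray(tri), "apexIdx"), apexIndex(sq))

  # onset == apex frame: zero flow, all-0.5 channels
  sq2 <- FrameSequence(rep(frames(sq)[1], 3), apexIdx = 1L)
  tri2 <- preprocessSample(sq2)
  expect_equal(unique(as.vector(tripletArray(tri2))), 0.5)
})

test_that("moved region carries larger u signal than static region", {
  spec <- SyntheticSpec(nClasses = 3L, imageSize = c(64L, 64L),
                        noiseSd = 0, subjectEffectSd = 0, seed = 9L)
  set.seed(9)
  sq <- makeSequence(spec, class = 1L)  # jawDrop: downward bump at (0.82, 0.5)
  onset <- frames(sq)[[1]]
  apex <- frames(sq)[[apexIndex(sq)]]
  f <- computeOpticalFlow(onset, apex, flowParams(nScales = 3L))
  vmag <- abs(flowV(f))
  inside <- vmag[44:62, 22:42]   # around the class locus
  outside <- vmag[2:26, 2:26]
  expect_gt(mean(inside), 3 * mean(outside))
})
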