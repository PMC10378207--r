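test_that("uniform LBP histogram equals the brute-force oracle", {
  set.seed(42)
  for (n in c(3, 4, 5, 8)) {
    for (rep in 1:5) {
      img <- matrix(stats::runif(n * n), n, n)
      expect_equal(lbpHistogram(img), bruteLbpHistogram(img), tolerance = 1e-12)
    }
  }
  # integer-valued image with ties exercises the ">=" comparison
  img <- matrix(sample(0:3, 36, replace = TRUE), 6, 6)
  expect_equal(lbpHistogram(img), bruteLbpHistogram(img), tolerance = 1e-12)
})

test_that("LBP histogram properties and degenerate cases", {
  img <- matrix(stats::runif(49), 7, 7)
  h <- lbpHistogram(img)
  expect_length(h, 59)
  expect_equal(sum(h), 1)
  expect_true(all(h >= 0))
  # constant region: every code is 11111111, one uniform bin carries all mass
  hc <- lbpHistogram(matrix(1, 9, 9))
  expect_equal(max(hc), 1)
  expect_equal(sum(hc > 0), 1)
  expect_error(lbpHistogram(matrix(1, 2, 5)), "3x3")
})

test_that("chi-squared distance behaves like a metric on histograms", {
  h1 <- c(1, rep(0, 58)); h2 <- c(0, 1, rep(0, 57))
  expect_equal(chi2Distance(h1, h1), 0)
  expect_equal(chi2Distance(h1, h2), 2, tolerance = 1e-8)
  set.seed(1)
  for (i in 1:5) {
    a <- stats::runif(59); a <- a / sum(a)
    b <- stats::runif(59); b <- b / sum(b)
    expect_equal(chi2Distance(a, b), chi2Distance(b, a))
    expect_gte(chi2Distance(a, b), 0)
  }
  expect_error(chi2Distance(h1, h1[1:10]), "length")
})

test_that("apex localization finds the tent-ramp peak", {
  spec <- SyntheticSpec(nClasses = 2L, seqLen = 20L, apexFrac = 12 / 19,
                        imageSize = c(64L, 64L), amplitude = 0.4, seed = 1L)
  set.seed(1)
  sq <- makeSequence(spec, class = 1L)
  truth <- apexIndex(sq)             # 13 (1-based)
  got <- locateApex(sq)
  expect_true(abs(as.integer(got) - truth) <= 1)
  expect_false(attr(got, "degenerate"))
})

test_that("apex search equals exhaustive argmax on monotone signals", {
  # strictly increasing deformation: apex must be the last frame
  spec <- SyntheticSpec(nClasses = 2L, seqLen = 12L, apexFrac = 0.999,
                        imageSize = c(48L, 48L), seed = 2L)
  set.seed(2)
  sq <- makeSequence(spec, class = 1L)
  expect_identical(as.integer(locateApex(sq)), 12L)
})

test_that("apex localization degenerate and error cases", {
  frame <- matrix(0.5, 32, 32)
  sq <- FrameSequence(rep(list(frame), 6))
  expect_warning(got <- locateApex(sq), "signal")
  expect_identical(as.integer(got), 2L)
  expect_true(attr(got, "degenerate"))
  sq2 <- FrameSequence(rep(list(frame), 2))
  expect_error(locateApex(sq2), "3 frames")
})
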