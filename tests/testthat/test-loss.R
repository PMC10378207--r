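test_that("class priors are exact frequencies", {
  expect_equal(classPriors(c(1, 1, 1, 2), 2), c(0.75, 0.25))
  expect_equal(classPriors(rep(1, 5), 3), c(1, 0, 0))
  expect_equal(classPriors(c(1, 2, 3, 1, 2, 3), 3), rep(1 / 3, 3))
  expect_error(classPriors(integer(0), 2), "non-empty")
  expect_error(classPriors(c(1, 4), 3), "range")
})

test_that("correction factors match the closed form log(p^tau + eps)", {
  expect_equal(correctionFactors(c(0.5, 0.5), tau = 0),
               rep(log(1 + 1e-12), 2))
  a <- correctionFactors(c(0.75, 0.25), tau = 0.5, eps = 1e-12)
  expect_equal(a, c(-0.1438410, -0.6931472), tolerance = 1e-6)
  # zero prior stays finite through the eps guard
  a0 <- correctionFactors(c(1, 0), tau = 0.5, eps = 1e-12)
  expect_true(all(is.finite(a0)))
  expect_equal(a0[2], log(1e-12))
})

test_that("LASCE reduces to cross-entropy at tau = 0 and is shift invariant", {
  set.seed(8)
  logits <- matrix(stats::rnorm(40), 8, 5)
  labels <- sample(5, 8, replace = TRUE)
  aZero <- correctionFactors(classPriors(labels, 5), tau = 0)
  expect_equal(lasceLoss(logits, labels, aZero), ceLoss(logits, labels),
               tolerance = 1e-6)
  # per-sample constant shifts leave the loss unchanged
  shifted <- logits + stats::rnorm(8)  # one constant per row (recycled)
  expect_equal(lasceLoss(shifted, labels, aZero), lasceLoss(logits, labels, aZero),
               tolerance = 1e-6)
  # two-class closed form: logits (0, 0), a = 0, label 1 -> ln 2
  expect_equal(lasceLoss(matrix(0, 1, 2), 1L), log(2), tolerance = 1e-12)
})

test_that("focal losses match closed forms and reduce correctly", {
  set.seed(9)
  logits <- matrix(stats::rnorm(30), 6, 5)
  labels <- sample(5, 6, replace = TRUE)
  a <- correctionFactors(classPriors(labels, 5), 0.5)
  expect_equal(focalLoss(logits, labels, gamma = 0), ceLoss(logits, labels),
               tolerance = 1e-6)
  expect_equal(laFocalLoss(logits, labels, a, gamma = 0),
               lasceLoss(logits, labels, a), tolerance = 1e-6)
  # well-classified sample q_y = 0.9, gamma = 2: term = 0.01 * (-ln 0.9)
  lg <- matrix(c(log(0.9), log(0.05), log(0.05)), 1, 3)
  expect_equal(focalLoss(lg, 1L, gamma = 2), 0.01 * (-log(0.9)),
               tolerance = 1e-6)
  expect_gte(focalLoss(logits, labels), 0)
  expect_gte(lasceLoss(logits, labels, a), 0)
  expect_error(focalLoss(logits, labels, gamma = -1), "gamma")
})

test_that("analytic loss gradients match finite differences", {
  set.seed(10)
  logits <- matrix(stats::rnorm(15), 3, 5)
  labels <- c(2L, 5L, 1L)
  a <- correctionFactors(c(0.3, 0.3, 0.2, 0.1, 0.1), 0.5)
  h <- 1e-6
  for (fn in list(
    function(z, wg) lasceLoss(z, labels, a, withGrad = wg),
    function(z, wg) laFocalLoss(z, labels, a, gamma = 2, withGrad = wg),
    function(z, wg) focalLoss(z, labels, gamma = 1.5, withGrad = wg))) {
    g <- fn(logits, TRUE)$grad
    for (i in c(1L, 7L, 12L)) {
      zp <- logits; zp[i] <- zp[i] + h
      zm <- logits; zm[i] <- zm[i] - h
      expect_equal(g[i], (fn(zp, FALSE) - fn(zm, FALSE)) / (2 * h),
                   tolerance = 1e-4)
    }
  }
  # LASCE gradient closed form: softmax(logits + a) - onehot, averaged
  gl <- lasceLoss(logits, labels, a, withGrad = TRUE)$grad
  adj <- sweep(logits, 2, a, `+`)
  q <- exp(adj) / rowSums(exp(adj))
  q[cbind(1:3, labels)] <- q[cbind(1:3, labels)] - 1
  expect_equal(gl, q / 3, tolerance = 1e-10)
})

test_that("uniform priors make all adjusted losses equal their plain forms", {
  set.seed(11)
  logits <- matrix(stats::rnorm(24), 6, 4)
  labels <- rep(1:4, length.out = 6)
  aU <- correctionFactors(rep(0.25, 4), tau = 0.7)
  expect_equal(lasceLoss(logits, labels, aU), ceLoss(logits, labels),
               tolerance = 1e-6)
  expect_equal(laFocalLoss(logits, labels, aU, gamma = 2),
               focalLoss(logits, labels, gamma = 2), tolerance = 1e-6)
})
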