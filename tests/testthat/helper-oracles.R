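# Independent oracles and small fixtures used across test files.

# smooth random texture that gives a flow solver plenty of gradient
texturedImage <- function(h, w, sigma = 1.5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  flowMER:::gauss_blur(matrix(stats::rnorm((h + 16) * (w + 16)), h + 16, w + 16),
                       sigma)[9:(h + 8), 9:(w + 8)]
}

# naive per-pixel uniform-LBP histogram: the brute-force oracle, written
# independently of the package implementation
bruteLbpHistogram <- function(region) {
  H <- nrow(region); W <- ncol(region)
  offs <- list(c(-1, -1), c(-1, 0), c(-1, 1), c(0, 1),
               c(1, 1), c(1, 0), c(1, -1), c(0, -1))
  isUniform <- function(bits) {
    sum(bits != bits[c(2:8, 1)]) <= 2
  }
  uniCodes <- Filter(function(code) {
    isUniform(as.integer(intToBits(code)[1:8]))
  }, 0:255)
  counts <- numeric(59)
  for (i in 2:(H - 1)) {
    for (j in 2:(W - 1)) {
      code <- 0
      for (b in 1:8) {
        nb <- region[i + offs[[b]][1], j + offs[[b]][2]]
        if (nb >= region[i, j]) code <- code + 2^(b - 1)
      }
      pos <- match(code, uniCodes)
      bin <- if (is.na(pos)) 59 else pos
      counts[bin] <- counts[bin] + 1
    }
  }
  counts / sum(counts)
}

# linear displacement fields with closed-form strain
linearFlowField <- function(n, ax, ay, bx, by) {
  x0 <- outer(rep(1, n), 0:(n - 1))   # x = column index
  y0 <- outer(0:(n - 1), rep(1, n))   # y = row index
  FlowField(ax * x0 + bx * y0, ay * y0 + by * x0)
}

# tiny, fast configs for tests that train
tinyTrainConfig <- function(epochs = 2L, seed = 1L, loss = "lasce",
                            augment = FALSE) {
  TrainConfig(epochs = epochs, seed = seed, loss = loss, augment = augment)
}

# one shared synthetic dataset for cheap tests
.testDataEnv <- new.env(parent = emptyenv())
smallDataset <- function() {
  if (is.null(.testDataEnv$ds))
    .testDataEnv$ds <- makeDataset(SyntheticSpec(
      nClasses = 2L, nSubjects = 4L, samplesPerClass = c(8L, 8L), seed = 5L))
  .testDataEnv$ds
}
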