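#' Flip a raw flow field horizontally
#'
#' Mirrors columns and negates the horizontal component (a mirrored face
#' moves the opposite way along x); the vertical component and the
#' sign-free strain magnitude are purely mirrored. Applying the operation
#' twice restores the input exactly.
#'
#' @param u,v,os matrices (strain may be `NULL`).
#' @return list with flipped `u`, `v`, `os`.
#' @export
flipFlow <- function(u, v, os = NULL) {
  mir <- function(m) m[, rev(seq_len(ncol(m))), drop = FALSE]
  list(u = -mir(u), v = mir(v), os = if (is.null(os)) NULL else mir(os))
}

#' Augment a normalized flow triplet
#'
#' With probability 1/2 the triplet is mirrored horizontally; on the
#' min-max-normalized u channel the sign flip of raw u corresponds to
#' `1 - mirror(u)`, while v and os are mirrored unchanged. Channel
#' dithering then applies a per-channel affine jitter (scale in
#' `[0.9, 1.1]`, shift in `[-0.05, 0.05]`) and clips back to `[0, 1]`.
#' Draws come from the current R RNG stream.
#'
#' @param x array `c(S, S, 3)`.
#' @return augmented array of the same shape.
#' @export
augmentTriplet <- function(x) {
  if (stats::runif(1) < 0.5) {
    rev_ <- rev(seq_len(ncol(x[, , 1L])))
    x[, , 1L] <- 1 - x[, rev_, 1L]
    x[, , 2L] <- x[, rev_, 2L]
    x[, , 3L] <- x[, rev_, 3L]
  }
  for (k in 1:3) {
    sc <- stats::runif(1, 0.9, 1.1)
    sh <- stats::runif(1, -0.05, 0.05)
    x[, , k] <- pmin(pmax(x[, , k] * sc + sh, 0), 1)
  }
  x
}

#' Train the network on one data split
#'
#' Mini-batch Adam with decoupled-from-nothing classic L2 weight decay
#' (added to the gradient), the configured loss, optional flip/dither
#' augmentation, and no schedule or early stopping. Class priors for the
#' logit-adjusted losses are computed from `labels` (the training split)
#' only. One seed (`trainConfig@seed`) governs weight initialization,
#' shuffling and augmentation, so a rerun is bit-identical.
#'
#' @param x array `c(S, S, 3, N)` of training triplets.
#' @param labels integer 1-based labels of length N, covering >= 2 classes.
#' @param trainConfig a [TrainConfig-class].
#' @param netConfig a [NetConfig-class]; its seed is overridden by the
#'   training seed so that one seed controls the run.
#' @return list with `model` ([FlowNetModel-class]) and `history` (mean
#'   epoch losses, length `epochs`).
#' @export
trainFold <- function(x, labels, trainConfig, netConfig) {
  stopifnot(is(trainConfig, "TrainConfig"), is(netConfig, "NetConfig"))
  N <- dim(x)[4L]
  if (N != length(labels)) stop("labels must match the number of samples")
  if (length(unique(labels)) < 2L)
    stop("training split contains a single class; cannot train")
  C <- netConfig@nClasses
  adjA <- numeric(C)
  if (trainConfig@loss %in% c("lasce", "la_focal"))
    adjA <- correctionFactors(classPriors(labels, C), trainConfig@tau,
                              trainConfig@eps)
  oldseed <- .Random.seed_save()
  on.exit(.Random.seed_restore(oldseed))
  set.seed(trainConfig@seed)
  netConfig@seed <- as.integer(stats::runif(1, 1, 2^30))
  model <- flowNet(netConfig)
  p <- model@params
  mom <- lapply(p, function(w) w * 0)
  vel <- lapply(p, function(w) w * 0)
  b1 <- 0.9; b2 <- 0.999; epsA <- 1e-8
  lr <- trainConfig@lr; wd <- trainConfig@weightDecay
  t <- 0L
  history <- numeric(trainConfig@epochs)
  for (ep in seq_len(trainConfig@epochs)) {
    ord <- sample.int(N)
    lossAcc <- 0; nb <- 0L
    for (start in seq(1L, N, by = trainConfig@batchSize)) {
      idx <- ord[start:min(start + trainConfig@batchSize - 1L, N)]
      xb <- x[, , , idx, drop = FALSE]
      if (trainConfig@augment)
        for (i in seq_along(idx)) xb[, , , i] <- augmentTriplet(xb[, , , i])
      fw <- netForward(model, xb, withCache = TRUE)
      ls <- .lossFn(trainConfig@loss, fw$logits, labels[idx], adjA,
                    trainConfig@gamma)
      bw <- netBackward(model, fw$cache, ls$grad)
      t <- t + 1L
      for (nm in names(p)) {
        g <- bw$grads[[nm]] + wd * p[[nm]]
        mom[[nm]] <- b1 * mom[[nm]] + (1 - b1) * g
        vel[[nm]] <- b2 * vel[[nm]] + (1 - b2) * g * g
        p[[nm]] <- p[[nm]] - lr * (mom[[nm]] / (1 - b1^t)) /
          (sqrt(vel[[nm]] / (1 - b2^t)) + epsA)
      }
      model@params <- p
      lossAcc <- lossAcc + ls$loss; nb <- nb + 1L
    }
    history[ep] <- lossAcc / nb
  }
  if (!all(vapply(p, function(w) all(is.finite(w)), logical(1))))
    stop("training diverged: non-finite weights")
  list(model = model, history = history)
}
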