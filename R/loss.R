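#' Class prior frequencies
#'
#' \eqn{p_y = n_y / n} over the training labels. Priors are always computed
#' on the training split of a fold, never on test subjects.
#'
#' @param labels integer vector of 1-based class labels.
#' @param nClasses total number of classes.
#' @return numeric vector of length `nClasses` summing to 1.
#' @export
classPriors <- function(labels, nClasses) {
  if (length(labels) == 0L) stop("labels must be non-empty")
  labels <- as.integer(labels)
  if (any(labels < 1L | labels > nClasses)) stop("label out of range")
  tabulate(labels, nbins = nClasses) / length(labels)
}

#' Logit-adjustment correction factors
#'
#' \eqn{a_y = \log(p_y^\tau + \epsilon)}; the additive guard keeps the
#' factor finite for classes absent from the training split. With
#' \eqn{\tau = 0} all factors are essentially zero and the adjusted loss
#' collapses to plain cross-entropy.
#'
#' @param p prior vector from [classPriors()].
#' @param tau adjustment strength (>= 0), 0.5 by default.
#' @param eps additive guard (> 0).
#' @return numeric vector of finite correction factors.
#' @export
correctionFactors <- function(p, tau = 0.5, eps = 1e-12) {
  stopifnot(tau >= 0, eps > 0)
  log(p^tau + eps)
}

#' Prior adjustment bundle
#'
#' Convenience constructor pairing priors and correction factors.
#'
#' @param labels,nClasses,tau,eps see [classPriors()] and
#'   [correctionFactors()].
#' @return list with `p`, `a`, `tau`, `eps`.
#' @export
priorAdjustment <- function(labels, nClasses, tau = 0.5, eps = 1e-12) {
  p <- classPriors(labels, nClasses)
  list(p = p, a = correctionFactors(p, tau, eps), tau = tau, eps = eps)
}

.logSoftmax <- function(z) {
  m <- apply(z, 1L, max)
  zs <- z - m
  zs - log(rowSums(exp(zs)))
}

#' Logit-adjusted softmax cross-entropy (LASCE)
#'
#' Standard softmax cross-entropy on prior-adjusted logits
#' \eqn{z_i + a}: per sample
#' \eqn{-\log\mathrm{softmax}(z_i + a)_{y_i}}, averaged over the batch,
#' evaluated in log-sum-exp stable form. Adding the log-prior factors to
#' the logits during training pushes the decision boundary toward minority
#' classes; at \eqn{\tau = 0} (constant `a`) the loss equals ordinary
#' cross-entropy by softmax shift invariance.
#'
#' @param logits B x C numeric matrix.
#' @param labels integer vector of 1-based labels, length B.
#' @param a correction-factor vector of length C (zeros give plain CE).
#' @param withGrad also return the gradient w.r.t. the logits.
#' @return scalar mean loss; with `withGrad`, a list `(loss, grad)` where
#'   `grad = (softmax(logits + a) - onehot) / B`.
#' @export
lasceLoss <- function(logits, labels, a = numeric(ncol(logits)),
                      withGrad = FALSE) {
  .checkLogits(logits, labels)
  B <- nrow(logits)
  adj <- sweep(logits, 2L, a, `+`)
  ls <- .logSoftmax(adj)
  loss <- -mean(ls[cbind(seq_len(B), labels)])
  if (!withGrad) return(loss)
  q <- exp(ls)
  q[cbind(seq_len(B), labels)] <- q[cbind(seq_len(B), labels)] - 1
  list(loss = loss, grad = q / B)
}

#' Plain softmax cross-entropy
#'
#' @inheritParams lasceLoss
#' @return as [lasceLoss()].
#' @export
ceLoss <- function(logits, labels, withGrad = FALSE) {
  lasceLoss(logits, labels, numeric(ncol(logits)), withGrad)
}

#' Focal loss and its logit-adjusted variant
#'
#' `focalLoss` computes the mean of
#' \eqn{-(1 - q_{y})^\gamma \log q_{y}} with `q = softmax(logits)`;
#' `laFocalLoss` applies the identical modulation to
#' `softmax(logits + a)`. At \eqn{\gamma = 0} they reduce to plain CE and
#' LASCE respectively.
#'
#' @inheritParams lasceLoss
#' @param gamma focusing parameter (>= 0).
#' @return scalar mean loss; with `withGrad`, list `(loss, grad)`.
#' @export
focalLoss <- function(logits, labels, gamma = 2, withGrad = FALSE) {
  laFocalLoss(logits, labels, a = numeric(ncol(logits)), gamma = gamma,
              withGrad = withGrad)
}

#' @rdname focalLoss
#' @export
laFocalLoss <- function(logits, labels, a = numeric(ncol(logits)), gamma = 2,
                        withGrad = FALSE) {
  if (gamma < 0) stop("gamma must be >= 0")
  .checkLogits(logits, labels)
  B <- nrow(logits); C <- ncol(logits)
  adj <- sweep(logits, 2L, a, `+`)
  ls <- .logSoftmax(adj)
  q <- exp(ls)
  iy <- cbind(seq_len(B), labels)
  qy <- q[iy]; lsy <- ls[iy]
  loss <- mean(-(1 - qy)^gamma * lsy)
  if (!withGrad) return(loss)
  # d/dz_k of -(1-qy)^g log qy equals comm * (q_k - [k = y]) with
  # comm = (1-qy)^g - g (1-qy)^(g-1) qy log qy
  comm <- (1 - qy)^gamma - gamma * (1 - qy)^pmax(gamma - 1, 0) * qy * lsy
  grad <- q * matrix(comm, B, C)
  grad[iy] <- grad[iy] - comm
  list(loss = loss, grad = grad / B)
}

.checkLogits <- function(logits, labels) {
  if (!is.matrix(logits)) stop("logits must be a matrix")
  if (any(!is.finite(logits))) stop("logits must be finite")
  if (length(labels) != nrow(logits)) stop("labels length must match batch")
  if (any(labels < 1L | labels > ncol(logits))) stop("label out of range")
  invisible(TRUE)
}

# dispatcher used by the training loop
.lossFn <- function(key, logits, labels, a, gamma) {
  switch(key,
    ce = ceLoss(logits, labels, withGrad = TRUE),
    lasce = lasceLoss(logits, labels, a, withGrad = TRUE),
    focal = focalLoss(logits, labels, gamma, withGrad = TRUE),
    la_focal = laFocalLoss(logits, labels, a, gamma, withGrad = TRUE),
    stop("unknown loss key: ", key))
}
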