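#' Grad-CAM heatmap at the post-MOFRW feature map
#'
#' Standard gradient-weighted class activation mapping: channel weights are
#' the spatially averaged gradients of the chosen class logit with respect
#' to the reweighted multi-flow feature map (the concatenated post-MOFRW
#' tensor), the weighted channel sum is rectified, bilinearly upsampled to
#' the input resolution, and min-max normalized. A constant (in particular
#' all-zero-gradient) map yields an all-zero heatmap.
#'
#' @param model a [FlowNetModel-class] (trained or initialized).
#' @param triplet a [FlowTriplet-class] or `c(S, S, 3)` array.
#' @param classIdx 1-based class whose logit is explained; defaults to the
#'   predicted class.
#' @param target feature map to explain; only `"mofrw"` (the post-MOFRW
#'   map) is defined.
#' @return S x S matrix in `[0, 1]`.
#' @export
gradCam <- function(model, triplet, classIdx = NULL, target = "mofrw") {
  if (!identical(target, "mofrw"))
    stop("unknown Grad-CAM target layer: ", target)
  if (is(triplet, "FlowTriplet")) triplet <- triplet@data
  x <- array(triplet, c(dim(triplet)[1:2], 3L, 1L))
  fw <- netForward(model, x, withCache = TRUE)
  if (is.null(classIdx)) classIdx <- which.max(fw$logits[1L, ])
  C <- model@config@nClasses
  if (classIdx < 1L || classIdx > C) stop("classIdx out of range")
  dlogits <- matrix(0, 1L, C)
  dlogits[1L, classIdx] <- 1
  bw <- netBackward(model, fw$cache, dlogits)
  A <- fw$cache$mf$out                      # (h, w, C3, 1)
  dA <- bw$dMofrw
  d <- dim(A)
  alpha <- colMeans(matrix(dA, d[1L] * d[2L], d[3L]))
  heat <- matrix(0, d[1L], d[2L])
  Am <- matrix(A, d[1L] * d[2L], d[3L])
  heat[] <- Am %*% alpha
  heat <- pmax(heat, 0)
  S <- dim(x)[1L]
  heat <- bilinear_resize(heat, S, S)
  lo <- min(heat); hi <- max(heat)
  if (hi - lo < 1e-12) return(matrix(0, S, S))
  (heat - lo) / (hi - lo)
}

#' Fraction of samples whose Grad-CAM peak hits the true motion locus
#'
#' For generated data the class motion sites are known; this helper scores
#' a set of samples by whether the heatmap argmax falls inside any of the
#' class's locus disks (disk radius twice the locus radius fraction, which
#' covers the 2-sigma support of the Gaussian bump).
#'
#' @param model trained [FlowNetModel-class].
#' @param dataset dataset list from [makeDataset()].
#' @param idx sample indices to score (default all).
#' @return named list: `rate`, and per-sample logical `hits`.
#' @export
gradCamLocalization <- function(model, dataset, idx = seq_along(dataset$labels)) {
  S <- dim(dataset$triplets)[1L]
  loci <- dataset$spec@motionLoci
  hits <- logical(length(idx))
  for (q in seq_along(idx)) {
    i <- idx[q]
    heat <- gradCam(model, dataset$triplets[, , , i],
                    classIdx = dataset$labels[i])
    pk <- arrayInd(which.max(heat), dim(heat))
    lc <- loci[loci$class == dataset$labels[i], , drop = FALSE]
    cy <- lc$row * (S - 1) + 1; cx <- lc$col * (S - 1) + 1
    rad <- 2 * lc$radius * S
    hits[q] <- any(sqrt((pk[1L] - cy)^2 + (pk[2L] - cx)^2) <= rad)
  }
  list(rate = mean(hits), hits = hits)
}
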