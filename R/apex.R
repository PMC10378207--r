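#' Default facial regions of interest
#'
#' Fixed fractional rectangles standing in for landmark-driven regions on a
#' pre-cropped face: mouth, left eye + brow, right eye + brow. Rows of the
#' matrix are regions; columns `row0, row1, col0, col1` are fractions of
#' image height/width.
#'
#' @return 3x4 numeric matrix.
#' @export
defaultRois <- function() {
  m <- rbind(mouth    = c(0.60, 0.95, 0.20, 0.80),
             leftEye  = c(0.10, 0.45, 0.05, 0.50),
             rightEye = c(0.10, 0.45, 0.50, 0.95))
  colnames(m) <- c("row0", "row1", "col0", "col1")
  m
}

.roiPixels <- function(frame, roi) {
  H <- nrow(frame); W <- ncol(frame)
  r0 <- max(1L, floor(roi[1L] * H) + 1L); r1 <- min(H, ceiling(roi[2L] * H))
  c0 <- max(1L, floor(roi[3L] * W) + 1L); c1 <- min(W, ceiling(roi[4L] * W))
  frame[r0:r1, c0:c1, drop = FALSE]
}

#' Locate the apex frame by divide-and-conquer over LBP differences
#'
#' For each region of interest the uniform-LBP histogram of every frame
#' `t > onset` is compared (chi-squared) against the first frame, giving a
#' difference signal `d_r(t)`. The region with the largest peak difference
#' is selected as the most active facial area, and its signal is searched
#' by halving: the index range is split in two, recursion descends into the
#' half with the larger mean difference, and once the window holds at most
#' three frames the argmax within it is returned (ties toward the lower
#' index). A sequence of identical frames carries no signal; the second
#' frame is returned with the `degenerate` attribute set to `TRUE`.
#'
#' @param seq a [FrameSequence-class] with at least 3 frames.
#' @param rois 3x4 fractional ROI matrix as from [defaultRois()].
#' @return integer frame index (1-based) with attribute `degenerate`
#'   (logical).
#' @export
locateApex <- function(seq, rois = defaultRois()) {
  stopifnot(is(seq, "FrameSequence"))
  fr <- seq@frames
  if (length(fr) < 3L) stop("apex localization needs at least 3 frames")
  if (any(rois[, 1L] >= rois[, 2L]) || any(rois[, 3L] >= rois[, 4L]) ||
      any(rois < 0) || any(rois > 1))
    stop("invalid ROI fractions")
  Tn <- length(fr)
  d <- matrix(0, nrow = nrow(rois), ncol = Tn)  # d[r, t], t = 1 is zero
  for (r in seq_len(nrow(rois))) {
    h0 <- lbpHistogram(.roiPixels(fr[[1L]], rois[r, ]))
    for (t in 2:Tn)
      d[r, t] <- chi2Distance(lbpHistogram(.roiPixels(fr[[t]], rois[r, ])), h0)
  }
  if (max(d) < 1e-12) {
    res <- 2L
    attr(res, "degenerate") <- TRUE
    warning("no LBP difference signal; returning the second frame")
    return(res)
  }
  rStar <- which.max(apply(d, 1L, max))
  sig <- d[rStar, ]
  lo <- 2L; hi <- Tn
  while (hi - lo + 1L > 3L) {
    mid <- (lo + hi) %/% 2L
    if (mean(sig[lo:mid]) >= mean(sig[(mid + 1L):hi])) hi <- mid else lo <- mid + 1L
  }
  res <- lo + which.max(sig[lo:hi]) - 1L
  attr(res, "degenerate") <- FALSE
  res
}

#' Preprocess one sequence into a network-ready flow triplet
#'
#' The full preprocessing chain: spot the apex if unset, resize onset and
#' apex frames to the working face resolution (170 x 140), compute TV-L1
#' flow from onset to apex, derive optical strain, and assemble the
#' normalized `size x size` (u, v, os) triplet.
#'
#' @param seq a [FrameSequence-class].
#' @param size triplet side length.
#' @param faceSize working resolution `c(H, W)` for the flow computation.
#' @param params flow-solver settings from [flowParams()].
#' @param rois ROI matrix for apex spotting when the apex index is unset.
#' @return a [FlowTriplet-class]; attribute `apexIdx` records the index used.
#' @export
preprocessSample <- function(seq, size = 28L, faceSize = c(170L, 140L),
                             params = flowParams(), rois = defaultRois()) {
  stopifnot(is(seq, "FrameSequence"))
  apex <- seq@apexIdx
  if (is.na(apex)) apex <- as.integer(locateApex(seq, rois))
  onset <- bilinear_resize(seq@frames[[seq@onsetIdx]], faceSize[1L], faceSize[2L])
  apexF <- bilinear_resize(seq@frames[[apex]], faceSize[1L], faceSize[2L])
  flow <- computeOpticalFlow(onset, apexF, params)
  tri <- flowToTriplet(flow, opticalStrain(flow), size = size)
  attr(tri@data, "apexIdx") <- apex
  tri
}
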