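#' Assemble the normalized (u, v, os) network input
#'
#' Each channel is independently min-max normalized to `[0, 1]` (a constant
#' channel maps to all 0.5, so "no motion" sits at the channel midpoint)
#' and then bilinearly resized to `size x size`. Normalization is
#' per-sample: no dataset-level statistics are assumed, so arbitrary user
#' data needs no calibration pass.
#'
#' @param flow a [FlowField-class].
#' @param strain a [StrainMap-class] of the same shape.
#' @param size output side length (28 by default).
#' @return a [FlowTriplet-class].
#' @export
flowToTriplet <- function(flow, strain, size = 28L) {
  stopifnot(is(flow, "FlowField"), is(strain, "StrainMap"))
  if (!identical(dim(flow@u), dim(strain@os)))
    stop("flow and strain must share one shape")
  size <- as.integer(size)
  chans <- list(flow@u, flow@v, strain@os)
  out <- array(0, dim = c(size, size, 3L))
  for (k in 1:3) {
    ch <- minMaxNormalize(chans[[k]])
    if (!identical(dim(ch), c(size, size)))
      ch <- pmin(pmax(bilinear_resize(ch, size, size), 0), 1)
    out[, , k] <- ch
  }
  FlowTriplet(out)
}

#' Min-max normalize a matrix to [0, 1]
#'
#' Degenerate rule: a (numerically) constant input maps to all 0.5.
#'
#' @param m numeric matrix, finite.
#' @return matrix of the same shape with values in `[0, 1]`.
#' @export
minMaxNormalize <- function(m) {
  if (!all(is.finite(m))) stop("input must be finite")
  lo <- min(m); hi <- max(m)
  if (hi - lo < 1e-12) {
    m[] <- 0.5
    return(m)
  }
  (m - lo) / (hi - lo)
}
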