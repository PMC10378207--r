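#' TV-L1 flow solver settings
#'
#' Parameters of the duality-based TV-L1 solver. `lambda` balances the L1
#' data term against total-variation regularity (intensities are rescaled
#' to `[0, 255]` internally, the range the default was calibrated for),
#' `theta` couples the data and regularity subproblems, `tau` is the dual
#' ascent step (must stay below 0.25 for stability of the Chambolle
#' scheme), and the pyramid is controlled by `nScales`/`zoom`.
#'
#' @param lambda data-term weight.
#' @param theta coupling parameter.
#' @param tau dual time step.
#' @param nScales maximum pyramid levels (clipped so the coarsest level
#'   keeps at least 16 px on its short side).
#' @param zoom downscaling factor between levels, in (0, 1).
#' @param warps image warps per level.
#' @param maxIter fixed-point iterations per warp.
#' @param epsilon stopping tolerance on the mean flow update.
#' @return named list of solver settings.
#' @export
flowParams <- function(lambda = 0.15, theta = 0.3, tau = 0.25, nScales = 5L,
                       zoom = 0.5, warps = 5L, maxIter = 50L,
                       epsilon = 0.01) {
  stopifnot(lambda > 0, theta > 0, tau > 0, tau <= 0.25,
            zoom > 0, zoom < 1, warps >= 1, maxIter >= 1)
  list(lambda = lambda, theta = theta, tau = tau, nScales = as.integer(nScales),
       zoom = zoom, warps = as.integer(warps), maxIter = as.integer(maxIter),
       epsilon = epsilon)
}

#' Dense optical flow between onset and apex frame
#'
#' Computes the displacement field carrying the onset frame onto the apex
#' frame with a coarse-to-fine total-variation / L1 solver: at each pyramid
#' level the linearized brightness-constancy residual is shrunk pointwise
#' (L1 data term) and each flow component is TV-denoised by dual ascent;
#' the level estimate warps the apex image before the next linearization.
#' Texture-free (constant) image pairs yield the zero field, the TV prior's
#' minimizer when the data term carries no information.
#'
#' @param onset,apex numeric matrices of equal shape, finite, intensities on
#'   a common scale.
#' @param params solver settings from [flowParams()].
#' @return a [FlowField-class].
#' @examples
#' img <- matrix(stats::runif(64 * 64), 64, 64)
#' f <- computeOpticalFlow(img, img)
#' max(abs(flowU(f)))  # ~0: identical frames carry no motion
#' @export
computeOpticalFlow <- function(onset, apex, params = flowParams()) {
  if (!is.matrix(onset) || !is.matrix(apex))
    stop("onset and apex must be matrices")
  if (!identical(dim(onset), dim(apex)))
    stop("onset and apex must share one shape")
  if (!all(is.finite(onset)) || !all(is.finite(apex)))
    stop("frames must be finite")
  H <- nrow(onset); W <- ncol(onset)
  if (H < 8L || W < 8L) stop("frames must be at least 8x8")
  # common intensity scale ~[0, 255] for the default lambda
  rng <- range(onset, apex)
  span <- rng[2L] - rng[1L]
  if (span < 1e-12) return(FlowField(matrix(0, H, W), matrix(0, H, W)))
  I0 <- (onset - rng[1L]) / span * 255
  I1 <- (apex - rng[1L]) / span * 255

  ns <- params$nScales
  maxNs <- max(1L, 1L + floor(log(min(H, W) / 16) / log(1 / params$zoom)))
  ns <- min(ns, maxNs)
  pyr0 <- vector("list", ns); pyr1 <- vector("list", ns)
  pyr0[[1L]] <- I0; pyr1[[1L]] <- I1
  if (ns > 1L) {
    sigma <- 0.6 * sqrt(1 / params$zoom^2 - 1)
    for (s in 2:ns) {
      h <- max(16L, as.integer(round(nrow(pyr0[[s - 1L]]) * params$zoom)))
      w <- max(16L, as.integer(round(ncol(pyr0[[s - 1L]]) * params$zoom)))
      pyr0[[s]] <- bilinear_resize(gauss_blur(pyr0[[s - 1L]], sigma), h, w)
      pyr1[[s]] <- bilinear_resize(gauss_blur(pyr1[[s - 1L]], sigma), h, w)
    }
  }
  u <- matrix(0, nrow(pyr0[[ns]]), ncol(pyr0[[ns]]))
  v <- u
  for (s in ns:1) {
    res <- tvl1_level(pyr0[[s]], pyr1[[s]], u, v, params$lambda, params$theta,
                      params$tau, params$warps, params$maxIter, params$epsilon)
    u <- res$u; v <- res$v
    if (s > 1L) {
      hn <- nrow(pyr0[[s - 1L]]); wn <- ncol(pyr0[[s - 1L]])
      su <- wn / ncol(u); sv <- hn / nrow(u)
      u <- bilinear_resize(u, hn, wn) * su
      v <- bilinear_resize(v, hn, wn) * sv
    }
  }
  FlowField(u, v)
}
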