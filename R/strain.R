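#' Optical strain magnitude of a flow field
#'
#' Forms the infinitesimal strain tensor, the symmetrized Jacobian of the
#' displacement field
#' \deqn{\varepsilon = \tfrac12\,[\nabla O_f + (\nabla O_f)^\top],\qquad
#'       O_f = (u, v)^\top,}
#' by central finite differences (one-sided at image borders), and reduces
#' it to the scalar magnitude
#' \deqn{os = \sqrt{\varepsilon_{xx}^2 + \varepsilon_{yy}^2 +
#'       2\,\varepsilon_{xy}^2},}
#' the standard reduction in the optical-strain literature (both symmetric
#' off-diagonal entries counted). Rigid translation (constant flow) gives
#' exactly zero strain; the measure responds only to local deformation,
#' which is what distinguishes muscle action from head motion.
#'
#' @param flow a [FlowField-class], at least 3x3.
#' @return a [StrainMap-class] of the same shape.
#' @examples
#' x <- outer(rep(1, 16), 0:15); y <- outer(0:15, rep(1, 16))
#' s <- opticalStrain(FlowField(0.1 * x, 0.2 * y))
#' strainMagnitude(s)[8, 8]  # sqrt(0.01 + 0.04)
#' @export
opticalStrain <- function(flow) {
  stopifnot(is(flow, "FlowField"))
  u <- flow@u; v <- flow@v
  if (nrow(u) < 3L || ncol(u) < 3L)
    stop("flow field must be at least 3x3 for central differences")
  exx <- .ddx(u)
  eyy <- .ddy(v)
  exy <- 0.5 * (.ddy(u) + .ddx(v))
  StrainMap(sqrt(exx^2 + eyy^2 + 2 * exy^2))
}

# d/dx along columns: central in the interior, one-sided at borders
.ddx <- function(m) {
  W <- ncol(m)
  d <- m
  d[, 2:(W - 1L)] <- (m[, 3:W] - m[, 1:(W - 2L)]) / 2
  d[, 1L] <- m[, 2L] - m[, 1L]
  d[, W] <- m[, W] - m[, W - 1L]
  d
}

.ddy <- function(m) t(.ddx(t(m)))
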