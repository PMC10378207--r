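#' Uniform LBP histogram of an image region
#'
#' Local binary patterns with 8 neighbors at radius 1, comparison
#' "neighbor >= center". Patterns with at most two circular 0/1 transitions
#' (the 58 uniform patterns) each get their own bin, in ascending code
#' order; every non-uniform pattern falls into a 59th bin. Codes are taken
#' at interior pixels only and the histogram is normalized to sum to 1.
#'
#' @param region numeric matrix, at least 3x3.
#' @return numeric vector of length 59 summing to 1.
#' @export
lbpHistogram <- function(region) {
  if (!is.matrix(region) || nrow(region) < 3L || ncol(region) < 3L)
    stop("region must be a matrix of at least 3x3")
  H <- nrow(region); W <- ncol(region)
  ctr <- region[2:(H - 1L), 2:(W - 1L), drop = FALSE]
  code <- matrix(0L, H - 2L, W - 2L)
  off <- .lbpOffsets()
  for (b in seq_len(8L)) {
    dy <- off[b, 1L]; dx <- off[b, 2L]
    nb <- region[(2L + dy):(H - 1L + dy), (2L + dx):(W - 1L + dx), drop = FALSE]
    code <- code + bitwShiftL(1L, b - 1L) * (nb >= ctr)
  }
  bins <- .lbpUniformMap()[code + 1L]
  h <- tabulate(bins, nbins = 59L)
  h / sum(h)
}

# circular neighbor order (dy, dx), clockwise from top-left
.lbpOffsets <- function() {
  cbind(c(-1L, -1L, -1L, 0L, 1L, 1L, 1L, 0L),
        c(-1L, 0L, 1L, 1L, 1L, 0L, -1L, -1L))
}

# 256-entry lookup: code -> bin in 1..59
.lbpUniformMap <- local({
  map <- NULL
  function() {
    if (is.null(map)) {
      codes <- 0:255
      bits <- t(sapply(codes, function(x) as.integer(bitwAnd(bitwShiftR(x, 0:7), 1L))))
      trans <- rowSums(bits != bits[, c(2:8, 1L)])
      uni <- codes[trans <= 2L]
      m <- rep(59L, 256L)
      m[uni + 1L] <- seq_along(uni)
      map <<- m
    }
    map
  }
})

#' Chi-squared distance between two histograms
#'
#' \eqn{d = \sum_b (h1_b - h2_b)^2 / (h1_b + h2_b + 10^{-10})}; symmetric,
#' zero iff the histograms are equal.
#'
#' @param h1,h2 numeric vectors of equal length, each summing to 1.
#' @return non-negative scalar.
#' @export
chi2Distance <- function(h1, h2) {
  if (length(h1) != length(h2)) stop("histograms must have equal length")
  sum((h1 - h2)^2 / (h1 + h2 + 1e-10))
}
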