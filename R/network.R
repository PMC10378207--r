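#' Initialize the three-branch attention flow network
#'
#' Builds seeded He-normal weights for the full architecture: per branch
#' (u, v, os) two inception blocks (6 then 16 kernels per scale, each
#' followed by 2x2 max pooling), a multi-scale fusion module (MSFF) joining
#' the two pyramid levels under spatial attention, then one channel
#' attention module (CAM) shared across branches whose scores compete
#' through a softmax over the three flows (MOFRW), and a global-average-pool
#' + fully-connected head.
#'
#' Channel arithmetic at the default configuration: 1 -> 24 (28x28) -> 24
#' (14x14) -> 64 -> 64 (7x7) -> 128 after MSFF -> 384 after MOFRW -> logits.
#'
#' @param config a [NetConfig-class].
#' @return a [FlowNetModel-class] with freshly initialized weights.
#' @export
flowNet <- function(config) {
  stopifnot(is(config, "NetConfig"))
  k1 <- config@kernelsBlock1; k2 <- config@kernelsBlock2
  C1 <- 4L * k1; C2 <- 4L * k2; Cb <- 2L * C2
  if (Cb < config@camReduction)
    warning("channel count below camReduction; clamping the CAM bottleneck to 1")
  hidden <- max(1L, Cb %/% config@camReduction)
  sk <- config@samKernel
  p <- list()
  oldseed <- .Random.seed_save()
  on.exit(.Random.seed_restore(oldseed))
  set.seed(config@seed)
  addConv <- function(name, k, cin, cout) {
    p[[paste0(name, ".W")]] <<- matrix(
      stats::rnorm(k * k * cin * cout, sd = sqrt(2 / (k * k * cin))),
      k * k * cin, cout)
    p[[paste0(name, ".b")]] <<- numeric(cout)
  }
  for (br in c("u", "v", "os")) {
    for (blk in c("inc1", "inc2")) {
      cin <- if (blk == "inc1") 1L else C1
      k <- if (blk == "inc1") k1 else k2
      nm <- paste0(br, ".", blk)
      addConv(paste0(nm, ".p1"), 1L, cin, k)
      addConv(paste0(nm, ".p3r"), 1L, cin, k)
      addConv(paste0(nm, ".p3"), 3L, k, k)
      addConv(paste0(nm, ".p5r"), 1L, cin, k)
      addConv(paste0(nm, ".p5"), 5L, k, k)
      addConv(paste0(nm, ".p4"), 1L, cin, k)
    }
    addConv(paste0(br, ".msff.align"), 1L, C1, C2)
    addConv(paste0(br, ".msff.sam1.conv"), sk, 2L, 1L)
    addConv(paste0(br, ".msff.sam2.conv"), sk, 2L, 1L)
  }
  p[["cam.W1"]] <- matrix(stats::rnorm(hidden * Cb, sd = sqrt(2 / Cb)), hidden, Cb)
  p[["cam.b1"]] <- numeric(hidden)
  p[["cam.W2"]] <- matrix(stats::rnorm(Cb * hidden, sd = sqrt(2 / hidden)), Cb, hidden)
  p[["cam.b2"]] <- numeric(Cb)
  p[["fc.W"]] <- matrix(stats::rnorm(3L * Cb * config@nClasses, sd = sqrt(2 / (3 * Cb))),
                        3L * Cb, config@nClasses)
  p[["fc.b"]] <- numeric(config@nClasses)
  new("FlowNetModel", params = p, config = config)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(s) {
  if (!is.null(s)) assign(".Random.seed", s, envir = globalenv())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- one backbone branch: inception x2 with pooling, then MSFF
.branchForward <- function(x, p, br, cfg) {
  k1 <- cfg@kernelsBlock1; k2 <- cfg@kernelsBlock2; sk <- cfg@samKernel
  i1 <- .inceptionF(x, p, paste0(br, ".inc1"), k1)
  a1 <- maxpool2_fwd(i1$out)
  i2 <- .inceptionF(a1$out, p, paste0(br, ".inc2"), k2)
  a2 <- maxpool2_fwd(i2$out)
  # MSFF: downsample + align the shallow map, sum with the deep map -> SAM;
  # the deep map alone -> its own SAM; concatenate.
  dprev <- maxpool2_fwd(a1$out)
  al <- .convF(dprev$out, p, paste0(br, ".msff.align"), 1L)
  s <- al$out + a2$out
  sam1 <- .samF(s, p, paste0(br, ".msff.sam1"), sk)
  sam2 <- .samF(a2$out, p, paste0(br, ".msff.sam2"), sk)
  out <- .concatC(list(sam1$out, sam2$out))
  list(out = out,
       cache = list(i1 = i1, a1 = a1, i2 = i2, a2 = a2, dprev = dprev,
                    al = al, sam1 = sam1, sam2 = sam2,
                    dims1 = dim(i1$out), dims2 = dim(i2$out)))
}

.branchBackward <- function(dout, cache, p, grads) {
  C2 <- dim(cache$a2$out)[3L]
  parts <- .splitC(dout, c(C2, C2))
  b1 <- .samB(parts[[1L]], cache$sam1$cache, p, grads); grads <- b1$grads
  b2 <- .samB(parts[[2L]], cache$sam2$cache, p, grads); grads <- b2$grads
  ds <- b1$dx
  da2 <- ds + b2$dx
  bal <- .convB(ds, cache$al, p, grads); grads <- bal$grads
  da1 <- maxpool2_bwd(bal$dx, cache$dprev$idx,
                      dim(cache$a1$out)[1L], dim(cache$a1$out)[2L])
  di2 <- maxpool2_bwd(da2, cache$a2$idx, cache$dims2[1L], cache$dims2[2L])
  bi2 <- .inceptionB(di2, cache$i2$cache, p, grads); grads <- bi2$grads
  da1 <- da1 + bi2$dx
  di1 <- maxpool2_bwd(da1, cache$a1$idx, cache$dims1[1L], cache$dims1[2L])
  bi1 <- .inceptionB(di1, cache$i1$cache, p, grads); grads <- bi1$grads
  list(dx = bi1$dx, grads = grads)
}

# ---- MOFRW: shared CAM per branch, softmax competition across branches,
# residual over the concatenated maps
.mofrwF <- function(fu, fv, fos, p) {
  if (!identical(dim(fu), dim(fv)) || !identical(dim(fu), dim(fos)))
    stop("branch maps must share one shape")
  camU <- .camF(fu, p); camV <- .camF(fv, p); camO <- .camF(fos, p)
  eu <- exp(camU$z); ev <- exp(camV$z); eo <- exp(camO$z)
  se <- eu + ev + eo
  att <- list(u = eu / se, v = ev / se, os = eo / se)  # 3-way simplex per (c, b)
  yu <- bcast_mul(fu, att$u); yv <- bcast_mul(fv, att$v)
  yo <- bcast_mul(fos, att$os)
  out <- .concatC(list(fu, fv, fos)) + .concatC(list(yu, yv, yo))
  list(out = out, att = att,
       cache = list(camU = camU, camV = camV, camO = camO, att = att,
                    fu = fu, fv = fv, fos = fos, dims = dim(fu)))
}

.mofrwB <- function(dout, cache, p, grads) {
  d <- cache$dims; C <- d[3L]
  att <- cache$att
  parts <- .splitC(dout, rep(C, 3L))
  dfu <- bcast_mul(parts[[1L]], att$u, plusOne = TRUE)
  dfv <- bcast_mul(parts[[2L]], att$v, plusOne = TRUE)
  dfo <- bcast_mul(parts[[3L]], att$os, plusOne = TRUE)
  dattU <- chan_spatial_dot(parts[[1L]], cache$fu)
  dattV <- chan_spatial_dot(parts[[2L]], cache$fv)
  dattO <- chan_spatial_dot(parts[[3L]], cache$fos)
  dot <- att$u * dattU + att$v * dattV + att$os * dattO
  dzU <- att$u * (dattU - dot)
  dzV <- att$v * (dattV - dot)
  dzO <- att$os * (dattO - dot)
  b <- .camB(dzU, cache$camU$cache, p, grads); grads <- b$grads; dfu <- dfu + b$dx
  b <- .camB(dzV, cache$camV$cache, p, grads); grads <- b$grads; dfv <- dfv + b$dx
  b <- .camB(dzO, cache$camO$cache, p, grads); grads <- b$grads; dfo <- dfo + b$dx
  list(dfu = dfu, dfv = dfv, dfo = dfo, grads = grads)
}

#' Forward pass of the flow network
#'
#' @param model a [FlowNetModel-class].
#' @param x numeric array `c(S, S, 3, B)` of flow triplets (channels u, v,
#'   os), or a single [FlowTriplet-class].
#' @param withCache keep intermediate activations for a backward pass or
#'   Grad-CAM.
#' @return list with `logits` (B x nClasses matrix) and, when requested,
#'   `cache`.
#' @export
netForward <- function(model, x, withCache = FALSE) {
  stopifnot(is(model, "FlowNetModel"))
  if (is(x, "FlowTriplet")) x <- array(x@data, c(dim(x@data), 1L))
  d <- dim(x)
  if (length(d) != 4L || d[3L] != 3L) stop("input must be S x S x 3 x B")
  if (!all(is.finite(x))) stop("input must be finite")
  cfg <- model@config; p <- model@params
  bu <- .branchForward(x[, , 1L, , drop = FALSE], p, "u", cfg)
  bv <- .branchForward(x[, , 2L, , drop = FALSE], p, "v", cfg)
  bo <- .branchForward(x[, , 3L, , drop = FALSE], p, "os", cfg)
  mf <- .mofrwF(bu$out, bv$out, bo$out, p)
  dm <- dim(mf$out); HW <- dm[1L] * dm[2L]; C3 <- dm[3L]; B <- dm[4L]
  g <- matrix(colMeans(matrix(mf$out, HW, C3 * B)), C3, B)
  logits <- t(g) %*% p[["fc.W"]] +
    matrix(p[["fc.b"]], B, cfg@nClasses, byrow = TRUE)
  out <- list(logits = logits)
  if (withCache)
    out$cache <- list(bu = bu, bv = bv, bo = bo, mf = mf, g = g, dims = dm)
  out
}

#' Backward pass: parameter gradients from logit gradients
#'
#' @param model a [FlowNetModel-class].
#' @param cache forward cache from [netForward()] with `withCache = TRUE`.
#' @param dlogits B x nClasses matrix of upstream gradients.
#' @return list with `grads` (named like the model's params), `dMofrw`
#'   (gradient at the post-MOFRW feature map, used by Grad-CAM) and `dx`
#'   (gradient at the input array).
#' @export
netBackward <- function(model, cache, dlogits) {
  p <- model@params
  grads <- lapply(p, function(w) {
    if (is.matrix(w)) matrix(0, nrow(w), ncol(w)) else numeric(length(w))
  })
  dm <- cache$dims; HW <- dm[1L] * dm[2L]; C3 <- dm[3L]; B <- dm[4L]
  grads[["fc.W"]] <- cache$g %*% dlogits
  grads[["fc.b"]] <- colSums(dlogits)
  dg <- p[["fc.W"]] %*% t(dlogits)               # (C3, B)
  dmf <- bcast_channel(dg / HW, dm[1L], dm[2L])
  mb <- .mofrwB(dmf, cache$mf$cache, p, grads)
  grads <- mb$grads
  b1 <- .branchBackward(mb$dfu, cache$bu$cache, p, grads); grads <- b1$grads
  b2 <- .branchBackward(mb$dfv, cache$bv$cache, p, grads); grads <- b2$grads
  b3 <- .branchBackward(mb$dfo, cache$bo$cache, p, grads); grads <- b3$grads
  dx <- .concatC(list(b1$dx, b2$dx, b3$dx))
  list(grads = grads, dMofrw = dmf, dx = dx)
}

#' Predict class labels for a batch of triplets
#'
#' Argmax over logits, ties broken toward the lowest class index.
#'
#' @param model a [FlowNetModel-class].
#' @param x array `c(S, S, 3, B)` or a [FlowTriplet-class].
#' @return integer vector of 1-based class indices.
#' @export
netPredict <- function(model, x) {
  lg <- netForward(model, x)$logits
  apply(lg, 1L, which.max)
}
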