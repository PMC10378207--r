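# Layer primitives over (H, W, C, B) activation arrays, each with an
# explicit backward pass. Convolution and pooling run in compiled code;
# everything else is vectorized R. Caches hold exactly what the backward
# pass needs.

.convF <- function(x, p, name, k) {
  W <- p[[paste0(name, ".W")]]
  out <- conv2d_fwd(x, W, p[[paste0(name, ".b")]], k)
  list(out = out, x = x, k = k, name = name)
}

.convB <- function(dout, cache, p, grads) {
  name <- cache$name
  g <- conv2d_bwd(cache$x, dout, p[[paste0(name, ".W")]], cache$k)
  grads[[paste0(name, ".W")]] <- grads[[paste0(name, ".W")]] + g$dW
  grads[[paste0(name, ".b")]] <- grads[[paste0(name, ".b")]] + g$db
  list(dx = g$dx, grads = grads)
}

.reluF <- function(x) {
  out <- relu_fwd(x)
  list(out = out)
}

.reluB <- function(dout, cache) {
  relu_bwd(dout, cache$out)
}

.sigmoid <- function(x) 1 / (1 + exp(-x))

.concatC <- function(lst) concat_channels(lst)

.splitC <- function(x, sizes) split_channels(x, as.integer(sizes))

# ---- inception block: 1x1 | 1x1->3x3 | 1x1->5x5 | pool3->1x1, ReLU, concat
.inceptionF <- function(x, p, name, k) {
  c1 <- .convF(x, p, paste0(name, ".p1"), 1L); r1 <- .reluF(c1$out)
  c3r <- .convF(x, p, paste0(name, ".p3r"), 1L); r3r <- .reluF(c3r$out)
  c3 <- .convF(r3r$out, p, paste0(name, ".p3"), 3L); r3 <- .reluF(c3$out)
  c5r <- .convF(x, p, paste0(name, ".p5r"), 1L); r5r <- .reluF(c5r$out)
  c5 <- .convF(r5r$out, p, paste0(name, ".p5"), 5L); r5 <- .reluF(c5$out)
  mp <- maxpool3s1_fwd(x)
  c4 <- .convF(mp$out, p, paste0(name, ".p4"), 1L); r4 <- .reluF(c4$out)
  out <- .concatC(list(r1$out, r3$out, r5$out, r4$out))
  list(out = out,
       cache = list(c1 = c1, r1 = r1, c3r = c3r, r3r = r3r, c3 = c3, r3 = r3,
                    c5r = c5r, r5r = r5r, c5 = c5, r5 = r5, mp = mp, c4 = c4,
                    r4 = r4, k = k))
}

.inceptionB <- function(dout, cache, p, grads) {
  k <- cache$k
  parts <- .splitC(dout, rep(k, 4L))
  dx <- array(0, dim(cache$c1$x))
  b <- .convB(.reluB(parts[[1L]], cache$r1), cache$c1, p, grads)
  grads <- b$grads; dx <- dx + b$dx
  b <- .convB(.reluB(parts[[2L]], cache$r3), cache$c3, p, grads)
  grads <- b$grads
  b2 <- .convB(.reluB(b$dx, cache$r3r), cache$c3r, p, grads)
  grads <- b2$grads; dx <- dx + b2$dx
  b <- .convB(.reluB(parts[[3L]], cache$r5), cache$c5, p, grads)
  grads <- b$grads
  b2 <- .convB(.reluB(b$dx, cache$r5r), cache$c5r, p, grads)
  grads <- b2$grads; dx <- dx + b2$dx
  b <- .convB(.reluB(parts[[4L]], cache$r4), cache$c4, p, grads)
  grads <- b$grads
  dx <- dx + maxpool3s1_bwd(b$dx, cache$mp$idx)
  list(dx = dx, grads = grads)
}

# ---- spatial attention: gate = sigmoid(conv_k([channel-mean, channel-max]))
.samF <- function(x, p, name, k) {
  mm <- chan_mean_max(x)
  cv <- .convF(mm$mnmx, p, paste0(name, ".conv"), k)
  attn <- .sigmoid(cv$out)                       # (H, W, 1, B), in (0, 1)
  out <- spatial_gate(x, attn)
  list(out = out, attn = attn,
       cache = list(x = x, cv = cv, attn = attn, amx = mm$amx,
                    C = dim(x)[3L]))
}

.samB <- function(dout, cache, p, grads) {
  dx <- spatial_gate(dout, cache$attn)
  dattn <- spatial_gate_bwd_attn(dout, cache$x)
  da <- dattn * cache$attn * (1 - cache$attn)
  b <- .convB(da, cache$cv, p, grads)
  grads <- b$grads
  dx2 <- chan_mean_max_bwd(b$dx, cache$amx, cache$C)
  list(dx = dx + dx2, grads = grads)
}

# ---- shared squeeze-excitation channel attention
.camF <- function(x, p) {
  d <- dim(x); HW <- d[1L] * d[2L]; C <- d[3L]; B <- d[4L]
  xm <- x; dim(xm) <- c(HW, C * B)
  g <- matrix(colMeans(xm), C, B)
  hPre <- p[["cam.W1"]] %*% g + p[["cam.b1"]]
  h <- pmax(hPre, 0)
  zPre <- p[["cam.W2"]] %*% h + p[["cam.b2"]]
  z <- .sigmoid(zPre)                            # (C, B), in (0, 1)
  list(z = z, cache = list(g = g, h = h, hPre = hPre, z = z, dims = d))
}

.camB <- function(dz, cache, p, grads) {
  d <- cache$dims; HW <- d[1L] * d[2L]
  dzPre <- dz * cache$z * (1 - cache$z)
  grads[["cam.W2"]] <- grads[["cam.W2"]] + dzPre %*% t(cache$h)
  grads[["cam.b2"]] <- grads[["cam.b2"]] + rowSums(dzPre)
  dh <- t(p[["cam.W2"]]) %*% dzPre
  dhPre <- dh * (cache$hPre > 0)
  grads[["cam.W1"]] <- grads[["cam.W1"]] + dhPre %*% t(cache$g)
  grads[["cam.b1"]] <- grads[["cam.b1"]] + rowSums(dhPre)
  dg <- t(p[["cam.W1"]]) %*% dhPre               # (C, B)
  dx <- bcast_channel(dg / HW, d[1L], d[2L])
  list(dx = dx, grads = grads)
}
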