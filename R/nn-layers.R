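## Neural-network primitives on plain R arrays, BLAS-backed.
##
## Tensors are arrays of dim (C, L, N): channels x length x batch. All
## convolutions are stride-1 "same" 1-D convolutions along the length axis,
## realised as an im2col gather followed by one matrix multiply; their
## input gradients are computed as the transposed convolution (same
## machinery with a flipped, transposed kernel), so no scatter-add is
## needed. Every layer returns its forward cache; backward functions are
## exact gradients, verified against finite differences in the test suite.

.sigmoid <- function(x) 1 / (1 + exp(-x))

.as3d <- function(x) {
  if (is.matrix(x)) dim(x) <- c(dim(x), 1L)
  stopifnot(length(dim(x)) == 3L, all(is.finite(x)))
  x
}

## ---- conv1d ---------------------------------------------------------------

## kernel W: matrix (C_out, C_in * k), column (j-1)*C_in + c = tap j, chan c
conv1d_init <- function(c_in, c_out, k) {
  sd <- sqrt(2 / (c_in * k))
  list(W = matrix(stats::rnorm(c_out * c_in * k, 0, sd), c_out),
       b = numeric(c_out))
}

.im2col_cache <- new.env(parent = emptyenv())

.im2col_index <- function(C, L, N, k) {
  key <- paste(C, L, N, k, sep = "_")
  hit <- .im2col_cache[[key]]
  if (!is.null(hit)) return(hit)
  pad <- (k - 1L) %/% 2L
  Lp <- L + 2L * pad
  cj <- as.vector(outer(seq_len(C), C * (0:(k - 1L)), "+"))
  tt <- C * (0:(L - 1L))
  nn <- C * Lp * (0:(N - 1L))
  idx <- rep(cj, times = L * N) +
    rep(rep(tt, each = C * k), times = N) +
    rep(nn, each = C * k * L)
  ## cache only modest sizes to bound memory
  if (length(idx) <= 2e7) .im2col_cache[[key]] <- idx
  idx
}

conv1d_forward <- function(x, par, k) {
  d <- dim(x); C <- d[1]; L <- d[2]; N <- d[3]
  pad <- (k - 1L) %/% 2L
  xp <- array(0, c(C, L + 2L * pad, N))
  xp[, pad + seq_len(L), ] <- x
  cols <- xp[.im2col_index(C, L, N, k)]
  dim(cols) <- c(C * k, L * N)
  y <- par$W %*% cols + par$b
  dim(y) <- c(nrow(par$W), L, N)
  list(y = y, cols = cols, dims = d)
}

conv1d_backward <- function(dy, cache, par, k) {
  d <- cache$dims; C <- d[1]; L <- d[2]; N <- d[3]
  c_out <- nrow(par$W)
  dym <- matrix(dy, c_out, L * N)
  dW <- dym %*% t(cache$cols)
  db <- rowSums(dym)
  ## transposed convolution: conv_same(dy, K2), K2[c,(j-1)*c_out+o] =
  ## W[o,(k-j')*C+c] with flipped taps
  Wa <- array(par$W, c(c_out, C, k))
  K2 <- matrix(aperm(Wa[, , k:1, drop = FALSE], c(2, 1, 3)), C, c_out * k)
  dx <- conv1d_forward(dy, list(W = K2, b = numeric(C)), k)$y
  list(dx = dx, dW = dW, db = db)
}

## ---- relu / maxpool -------------------------------------------------------

relu_forward <- function(x) {
  mask <- x > 0
  list(y = x * mask, mask = mask)
}
relu_backward <- function(dy, cache) dy * cache$mask

maxpool2_forward <- function(x) {
  d <- dim(x); C <- d[1]; L <- d[2]; N <- d[3]
  L2 <- L %/% 2L
  xr <- x[, seq_len(2L * L2), , drop = FALSE]
  dim(xr) <- c(C, 2L, L2, N)
  a1 <- xr[, 1L, , , drop = FALSE]; dim(a1) <- c(C, L2, N)
  a2 <- xr[, 2L, , , drop = FALSE]; dim(a2) <- c(C, L2, N)
  first <- a1 >= a2                       # ties to the first element
  y <- a1
  y[!first] <- a2[!first]
  list(y = y, first = first, in_dims = d)
}

maxpool2_backward <- function(dy, cache) {
  d <- cache$in_dims; C <- d[1]; L <- d[2]; N <- d[3]
  L2 <- L %/% 2L
  dxr <- array(0, c(C, 2L, L2, N))
  dxr[, 1L, , ] <- dy * cache$first
  dxr[, 2L, , ] <- dy * !cache$first
  dim(dxr) <- c(C, 2L * L2, N)
  if (2L * L2 < L) {                      # odd length: last column unpooled
    dx <- array(0, d); dx[, seq_len(2L * L2), ] <- dxr; dx
  } else dxr
}

## ---- CBAM: channel then spatial attention ---------------------------------

cbam_init <- function(C, reduction = 8L, spatial_kernel = 7L) {
  Cr <- max(1L, C %/% reduction)
  list(W1 = matrix(stats::rnorm(Cr * C, 0, sqrt(2 / C)), Cr),
       b1 = numeric(Cr),
       W2 = matrix(stats::rnorm(C * Cr, 0, sqrt(1 / Cr)), C),
       b2 = numeric(C),
       Wsp = conv1d_init(2L, 1L, spatial_kernel)$W,
       bsp = 0)
}

## max over the length axis with argmax; x (C, L, N) -> val/arg (C, N)
.max_over_length <- function(x) {
  d <- dim(x)
  xa <- aperm(x, c(2, 1, 3))
  m <- matrix(xa, d[2], d[1] * d[3])
  arg <- max.col(t(m), ties.method = "first")
  list(val = matrix(m[arg + (seq_along(arg) - 1L) * d[2]], d[1], d[3]),
       arg = arg)
}

## max over the channel axis with argmax; x (C, L, N) -> val/arg (L, N)
.max_over_channels <- function(x) {
  d <- dim(x)
  m <- matrix(x, d[1], d[2] * d[3])
  arg <- max.col(t(m), ties.method = "first")
  list(val = matrix(m[arg + (seq_along(arg) - 1L) * d[1]], d[2], d[3]),
       arg = arg)
}

channel_attention_forward <- function(x, par) {
  d <- dim(x); C <- d[1]; L <- d[2]; N <- d[3]
  avg <- colMeans(aperm(x, c(2, 1, 3)))           # (C, N)
  if (is.null(dim(avg))) avg <- matrix(avg, C, N)
  mx <- .max_over_length(x)
  h_a <- pmax(par$W1 %*% avg + par$b1, 0)
  h_m <- pmax(par$W1 %*% mx$val + par$b1, 0)
  z <- par$W2 %*% h_a + par$W2 %*% h_m + par$b2
  s <- .sigmoid(z)                                # (C, N)
  list(s = s, avg = avg, mx = mx, h_a = h_a, h_m = h_m)
}

.bcast_cn <- function(s, C, L, N) aperm(array(s, c(C, N, L)), c(1, 3, 2))
.bcast_ln <- function(p, C, L, N) aperm(array(p, c(L, N, C)), c(3, 1, 2))

channel_attention_backward <- function(ds, x, cache, par) {
  d <- dim(x); C <- d[1]; L <- d[2]; N <- d[3]
  s <- cache$s
  dz <- ds * s * (1 - s)
  dh_a <- (t(par$W2) %*% dz) * (cache$h_a > 0)
  dh_m <- (t(par$W2) %*% dz) * (cache$h_m > 0)
  grads <- list(
    W1 = dh_a %*% t(cache$avg) + dh_m %*% t(cache$mx$val),
    b1 = rowSums(dh_a) + rowSums(dh_m),
    W2 = dz %*% t(cache$h_a) + dz %*% t(cache$h_m),
    b2 = rowSums(dz))
  davg <- t(par$W1) %*% dh_a                      # (C, N)
  dmx <- t(par$W1) %*% dh_m
  dx <- .bcast_cn(davg / L, C, L, N)
  ## scatter max-branch gradient to the argmax positions; the argmax index
  ## refers to column (c, n) of the (L, C*N) layout used in the forward
  cn <- seq_len(C * N) - 1L
  cc <- cn %% C + 1L; nn <- cn %/% C + 1L
  idx <- cc + C * (cache$mx$arg - 1L) + C * L * (nn - 1L)
  dx[idx] <- dx[idx] + as.vector(dmx)
  list(dx = dx, grads = grads)
}

spatial_attention_forward <- function(x, par, sk = 7L) {
  d <- dim(x); C <- d[1]; L <- d[2]; N <- d[3]
  avg <- colMeans(x)                              # (L, N)
  if (is.null(dim(avg))) avg <- matrix(avg, L, N)
  mx <- .max_over_channels(x)
  z <- array(0, c(2L, L, N))
  z[1L, , ] <- avg; z[2L, , ] <- mx$val
  cv <- conv1d_forward(z, list(W = par$Wsp, b = par$bsp), sk)
  p <- .sigmoid(matrix(cv$y, L, N))               # (L, N)
  list(p = p, mx = mx, conv_cache = cv, z = z)
}

spatial_attention_backward <- function(dp, x, cache, par, sk = 7L) {
  d <- dim(x); C <- d[1]; L <- d[2]; N <- d[3]
  p <- cache$p
  dlogit <- dp * p * (1 - p)
  dim(dlogit) <- c(1L, L, N)
  cb <- conv1d_backward(dlogit, cache$conv_cache,
                        list(W = par$Wsp, b = par$bsp), sk)
  dz <- cb$dx                                     # (2, L, N)
  davg <- dz[1L, , ]; dmxv <- dz[2L, , ]
  dx <- .bcast_ln(matrix(davg, L, N) / C, C, L, N)
  ln <- seq_len(L * N) - 1L
  tt <- ln %% L + 1L; nn <- ln %/% L + 1L
  idx <- cache$mx$arg + C * (tt - 1L) + C * L * (nn - 1L)
  dx[idx] <- dx[idx] + as.vector(dmxv)
  list(dx = dx, grads = list(Wsp = cb$dW, bsp = cb$db))
}

cbam_forward <- function(x, par, sk = 7L) {
  d <- dim(x)
  ca <- channel_attention_forward(x, par)
  xc <- x * .bcast_cn(ca$s, d[1], d[2], d[3])
  sa <- spatial_attention_forward(xc, par, sk)
  y <- xc * .bcast_ln(sa$p, d[1], d[2], d[3])
  list(y = y, ca = ca, sa = sa, xc = xc, x = x)
}

cbam_backward <- function(dy, cache, par, sk = 7L) {
  d <- dim(cache$x); C <- d[1]; L <- d[2]; N <- d[3]
  parr <- .bcast_ln(cache$sa$p, C, L, N)
  dxc <- dy * parr
  dp <- matrix(colSums(dy * cache$xc), L, N)      # sum over channels
  sb <- spatial_attention_backward(dp, cache$xc, cache$sa, par, sk)
  dxc <- dxc + sb$dx
  sarr <- .bcast_cn(cache$ca$s, C, L, N)
  dx <- dxc * sarr
  ds <- matrix(colSums(aperm(dxc * cache$x, c(2, 1, 3))), C, N)
  cb <- channel_attention_backward(ds, cache$x, cache$ca, par)
  dx <- dx + cb$dx
  list(dx = dx, grads = c(cb$grads, sb$grads))
}

## ---- GRU ------------------------------------------------------------------

gru_init <- function(d_in, h) {
  u <- function(nr, nc) matrix(stats::runif(nr * nc, -1, 1) / sqrt(h), nr)
  list(Wz = u(h, d_in), Wr = u(h, d_in), Wn = u(h, d_in),
       Uz = u(h, h), Ur = u(h, h), Un = u(h, h),
       bz = numeric(h), br = numeric(h), bn = numeric(h), cn = numeric(h))
}

## x (D, T, B) -> outputs (H, T, B); one direction
gru_forward <- function(x, par) {
  d <- dim(x); T_ <- d[2]; B <- d[3]
  H <- nrow(par$Wz)
  h <- matrix(0, H, B)
  out <- array(0, c(H, T_, B))
  steps <- vector("list", T_)
  for (t in seq_len(T_)) {
    xt <- matrix(x[, t, ], d[1], B)
    z <- .sigmoid(par$Wz %*% xt + par$Uz %*% h + par$bz)
    r <- .sigmoid(par$Wr %*% xt + par$Ur %*% h + par$br)
    anh <- par$Un %*% h + par$cn
    n <- tanh(par$Wn %*% xt + par$bn + r * anh)
    h_new <- (1 - z) * n + z * h
    steps[[t]] <- list(z = z, r = r, n = n, anh = anh, h_prev = h, xt = xt)
    h <- h_new
    out[, t, ] <- h
  }
  list(y = out, steps = steps, dims = d)
}

gru_backward <- function(dy, cache, par) {
  d <- cache$dims; D <- d[1]; T_ <- d[2]; B <- d[3]
  H <- nrow(par$Wz)
  g <- lapply(par, function(p) if (is.matrix(p)) matrix(0, nrow(p), ncol(p))
              else numeric(length(p)))
  dx <- array(0, d)
  dh <- matrix(0, H, B)
  tUz <- t(par$Uz); tUr <- t(par$Ur); tUn <- t(par$Un)
  tWz <- t(par$Wz); tWr <- t(par$Wr); tWn <- t(par$Wn)
  for (t in rev(seq_len(T_))) {
    st <- cache$steps[[t]]
    dht <- matrix(dy[, t, ], H, B) + dh
    dz <- dht * (st$h_prev - st$n) * st$z * (1 - st$z)
    dn <- dht * (1 - st$z) * (1 - st$n^2)
    dr <- dn * st$anh * st$r * (1 - st$r)
    dnr <- dn * st$r
    txt <- t(st$xt); thp <- t(st$h_prev)
    g$Wz <- g$Wz + dz %*% txt; g$bz <- g$bz + rowSums(dz)
    g$Wr <- g$Wr + dr %*% txt; g$br <- g$br + rowSums(dr)
    g$Wn <- g$Wn + dn %*% txt; g$bn <- g$bn + rowSums(dn)
    g$Uz <- g$Uz + dz %*% thp
    g$Ur <- g$Ur + dr %*% thp
    g$Un <- g$Un + dnr %*% thp; g$cn <- g$cn + rowSums(dnr)
    dh <- dht * st$z + tUz %*% dz + tUr %*% dr + tUn %*% dnr
    dx[, t, ] <- tWz %*% dz + tWr %*% dr + tWn %*% dn
  }
  list(dx = dx, grads = g)
}

## bidirectional wrapper: concatenated outputs (2H, T, B)
bigru_forward <- function(x, par_f, par_b) {
  T_ <- dim(x)[2]
  f <- gru_forward(x, par_f)
  b <- gru_forward(x[, rev(seq_len(T_)), , drop = FALSE], par_b)
  yb <- b$y[, rev(seq_len(T_)), , drop = FALSE]
  H <- nrow(par_f$Wz)
  y <- array(0, c(2L * H, T_, dim(x)[3]))
  y[seq_len(H), , ] <- f$y
  y[H + seq_len(H), , ] <- yb
  list(y = y, f = f, b = b)
}

bigru_backward <- function(dy, cache, par_f, par_b) {
  H <- nrow(par_f$Wz)
  T_ <- dim(dy)[2]
  dyf <- dy[seq_len(H), , , drop = FALSE]
  dyb <- dy[H + seq_len(H), , , drop = FALSE][, rev(seq_len(T_)), ,
                                              drop = FALSE]
  gf <- gru_backward(dyf, cache$f, par_f)
  gb <- gru_backward(dyb, cache$b, par_b)
  dx <- gf$dx + gb$dx[, rev(seq_len(T_)), , drop = FALSE]
  list(dx = dx, grads_f = gf$grads, grads_b = gb$grads)
}

## ---- dense / dropout / loss ----------------------------------------------

dense_init <- function(d_in, d_out) {
  list(W = matrix(stats::rnorm(d_out * d_in, 0, sqrt(2 / d_in)), d_out),
       b = numeric(d_out))
}

dense_forward <- function(x, par) list(y = par$W %*% x + par$b, x = x)
dense_backward <- function(dy, cache, par) {
  list(dx = t(par$W) %*% dy, dW = dy %*% t(cache$x), db = rowSums(dy))
}

dropout_forward <- function(x, p, train) {
  if (!train || p <= 0) return(list(y = x, mask = NULL))
  mask <- (matrix(stats::runif(length(x)), nrow(x)) >= p) / (1 - p)
  list(y = x * mask, mask = mask)
}
dropout_backward <- function(dy, cache) {
  if (is.null(cache$mask)) dy else dy * cache$mask
}

## binary cross-entropy on probabilities; returns loss and dlogit (grad wrt
## the pre-sigmoid logit, averaged over elements)
bce_with_logits <- function(logit, y) {
  p <- .sigmoid(logit)
  eps <- 1e-12
  loss <- -mean(y * log(p + eps) + (1 - y) * log(1 - p + eps))
  list(loss = loss, p = p, dlogit = (p - y) / length(y))
}

## ---- Adam -----------------------------------------------------------------

adam_init <- function(params) {
  zero <- function(p) if (is.matrix(p)) matrix(0, nrow(p), ncol(p))
  else numeric(length(p))
  list(m = rapply(params, zero, how = "replace"),
       v = rapply(params, zero, how = "replace"), t = 0L)
}

## params/grads are nested named lists with identical structure
adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  upd <- function(p, g, m, v) {
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    mhat <- m / (1 - beta1^t)
    vhat <- v / (1 - beta2^t)
    list(p = p - lr * mhat / (sqrt(vhat) + eps), m = m, v = v)
  }
  walk <- function(p, g, m, v) {
    if (is.list(p)) {
      res <- Map(walk, p, g[names(p)], m[names(p)], v[names(p)])
      list(p = lapply(res, `[[`, "p"), m = lapply(res, `[[`, "m"),
           v = lapply(res, `[[`, "v"))
    } else upd(p, g, m, v)
  }
  res <- walk(params, grads, state$m, state$v)
  list(params = res$p, state = list(m = res$m, v = res$v, t = t))
}
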