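## The two networks. Both share a convolutional trunk: four 1-D
## convolutions along the tile length (the nine signature rows are the
## input channels), ReLU after each, max-pool (width 2) after blocks 2 and
## 4, then a CBAM attention block. The deletion classifier runs the
## flattened trunk features of `seq_len` consecutive tiles through a
## bidirectional GRU and a three-layer fully connected head with a sigmoid
## output per tile; the genotype classifier applies the head directly to
## one tile's trunk features (CNN + attention only, no recurrence).

#' Network and training configuration
#'
#' @param L Tile width the network expects (must match featurization).
#' @param conv_channels Output channels of the four convolution blocks.
#' @param kernel Convolution kernel width along the length axis.
#' @param cbam_reduction Channel-attention bottleneck reduction ratio.
#' @param spatial_kernel Spatial-attention convolution width.
#' @param gru_hidden Hidden units per GRU direction.
#' @param gru_layers Stacked bidirectional GRU layers.
#' @param seq_len Consecutive tiles per GRU sequence (deletion model).
#' @param fc_sizes Sizes of the first two fully connected layers.
#' @param fc_dropout Dropout rate after each of the first two FC layers.
#' @param decision_threshold Probability above which a tile is called.
#' @param lr,batch_size,epochs Adam learning rate, sequences (or tiles)
#'   per minibatch, training epochs.
#' @param seed Seed for initialisation, shuffling and dropout.
#' @return Named list of class `model_config`.
#' @export
model_config <- function(L = 200L, conv_channels = c(32L, 32L, 64L, 64L),
                         kernel = 3L, cbam_reduction = 8L,
                         spatial_kernel = 7L, gru_hidden = 64L,
                         gru_layers = 1L, seq_len = 25L,
                         fc_sizes = c(128L, 64L), fc_dropout = 0.4,
                         decision_threshold = 0.5, lr = 1e-3,
                         batch_size = 8L, epochs = 20L, seed = 42L) {
  stopifnot(length(conv_channels) == 4L, decision_threshold > 0,
            decision_threshold < 1, seq_len >= 1, gru_layers >= 1)
  structure(as.list(environment()), class = "model_config")
}

.trunk_feature_dim <- function(cfg) {
  cfg$conv_channels[4] * (cfg$L %/% 4L)
}

.init_trunk <- function(cfg, in_channels = 9L) {
  ch <- cfg$conv_channels
  list(conv1 = conv1d_init(in_channels, ch[1], cfg$kernel),
       conv2 = conv1d_init(ch[1], ch[2], cfg$kernel),
       conv3 = conv1d_init(ch[2], ch[3], cfg$kernel),
       conv4 = conv1d_init(ch[3], ch[4], cfg$kernel),
       cbam = cbam_init(ch[4], cfg$cbam_reduction, cfg$spatial_kernel))
}

.init_head <- function(cfg, d_in) {
  list(fc1 = dense_init(d_in, cfg$fc_sizes[1]),
       fc2 = dense_init(cfg$fc_sizes[1], cfg$fc_sizes[2]),
       fc3 = dense_init(cfg$fc_sizes[2], 1L))
}

#' Initialise a deletion or genotype model
#'
#' @param cfg A [model_config()].
#' @param kind `"deletion"` (trunk + bi-GRU + head, per-tile outputs) or
#'   `"genotype"` (trunk + head, one output per tile).
#' @param in_channels Input channels (signature rows).
#' @return List with `params`, `cfg`, `kind`.
#' @export
init_model <- function(cfg, kind = c("deletion", "genotype"),
                       in_channels = 9L) {
  kind <- match.arg(kind)
  set.seed(cfg$seed)
  params <- .init_trunk(cfg, in_channels)
  if (kind == "deletion") {
    d_in <- .trunk_feature_dim(cfg)
    for (l in seq_len(cfg$gru_layers)) {
      params[[paste0("gru_f", l)]] <- gru_init(d_in, cfg$gru_hidden)
      params[[paste0("gru_b", l)]] <- gru_init(d_in, cfg$gru_hidden)
      d_in <- 2L * cfg$gru_hidden
    }
    params <- c(params, .init_head(cfg, d_in))
  } else {
    params <- c(params, .init_head(cfg, .trunk_feature_dim(cfg)))
  }
  structure(list(params = params, cfg = cfg, kind = kind),
            class = "deepdel_model")
}

.trunk_forward <- function(params, cfg, x) {
  k <- cfg$kernel
  c1 <- conv1d_forward(x, params$conv1, k);  r1 <- relu_forward(c1$y)
  c2 <- conv1d_forward(r1$y, params$conv2, k); r2 <- relu_forward(c2$y)
  p1 <- maxpool2_forward(r2$y)
  c3 <- conv1d_forward(p1$y, params$conv3, k); r3 <- relu_forward(c3$y)
  c4 <- conv1d_forward(r3$y, params$conv4, k); r4 <- relu_forward(c4$y)
  p2 <- maxpool2_forward(r4$y)
  cb <- cbam_forward(p2$y, params$cbam, cfg$spatial_kernel)
  d <- dim(cb$y)
  feat <- matrix(cb$y, d[1] * d[2], d[3])
  list(feat = feat, out_dims = d,
       caches = list(c1 = c1, r1 = r1, c2 = c2, r2 = r2, p1 = p1, c3 = c3,
                     r3 = r3, c4 = c4, r4 = r4, p2 = p2, cb = cb))
}

.trunk_backward <- function(dfeat, fw, params, cfg) {
  k <- cfg$kernel
  ca <- fw$caches
  dy <- array(dfeat, fw$out_dims)
  g <- list()
  b <- cbam_backward(dy, ca$cb, params$cbam, cfg$spatial_kernel)
  g$cbam <- b$grads
  dy <- maxpool2_backward(b$dx, ca$p2)
  dy <- relu_backward(dy, ca$r4)
  b4 <- conv1d_backward(dy, ca$c4, params$conv4, k)
  g$conv4 <- list(W = b4$dW, b = b4$db)
  dy <- relu_backward(b4$dx, ca$r3)
  b3 <- conv1d_backward(dy, ca$c3, params$conv3, k)
  g$conv3 <- list(W = b3$dW, b = b3$db)
  dy <- maxpool2_backward(b3$dx, ca$p1)
  dy <- relu_backward(dy, ca$r2)
  b2 <- conv1d_backward(dy, ca$c2, params$conv2, k)
  g$conv2 <- list(W = b2$dW, b = b2$db)
  dy <- relu_backward(b2$dx, ca$r1)
  b1 <- conv1d_backward(dy, ca$c1, params$conv1, k)
  g$conv1 <- list(W = b1$dW, b = b1$db)
  list(grads = g, dx = b1$dx)
}

.head_forward <- function(params, cfg, x, train) {
  f1 <- dense_forward(x, params$fc1); a1 <- relu_forward(f1$y)
  d1 <- dropout_forward(a1$y, cfg$fc_dropout, train)
  f2 <- dense_forward(d1$y, params$fc2); a2 <- relu_forward(f2$y)
  d2 <- dropout_forward(a2$y, cfg$fc_dropout, train)
  f3 <- dense_forward(d2$y, params$fc3)
  list(logit = f3$y,
       caches = list(f1 = f1, a1 = a1, d1 = d1, f2 = f2, a2 = a2, d2 = d2,
                     f3 = f3))
}

.head_backward <- function(dlogit, fw, params) {
  ca <- fw$caches
  g <- list()
  b3 <- dense_backward(dlogit, ca$f3, params$fc3)
  g$fc3 <- list(W = b3$dW, b = b3$db)
  dy <- dropout_backward(b3$dx, ca$d2)
  dy <- relu_backward(dy, ca$a2)
  b2 <- dense_backward(dy, ca$f2, params$fc2)
  g$fc2 <- list(W = b2$dW, b = b2$db)
  dy <- dropout_backward(b2$dx, ca$d1)
  dy <- relu_backward(dy, ca$a1)
  b1 <- dense_backward(dy, ca$f1, params$fc1)
  g$fc1 <- list(W = b1$dW, b = b1$db)
  list(grads = g, dx = b1$dx)
}

#' Forward pass of the deletion classifier
#'
#' @param model A `deepdel_model` of kind `"deletion"`.
#' @param xseq Array of dim `(9, L, seq_len, B)`: `B` sequences of
#'   `seq_len` consecutive tile matrices.
#' @param train Enable dropout (training mode).
#' @return List with `probs` (`seq_len` x `B` matrix) and internal caches.
#' @export
deletion_forward <- function(model, xseq, train = FALSE) {
  cfg <- model$cfg
  d <- dim(xseq)
  if (length(d) == 3L) { dim(xseq) <- c(d, 1L); d <- dim(xseq) }
  if (d[1] != 9L || d[2] != cfg$L)
    stop("input matrices must be 9 x ", cfg$L)
  T_ <- d[3]; B <- d[4]
  x <- xseq; dim(x) <- c(d[1], d[2], T_ * B)
  tk <- .trunk_forward(model$params, cfg, x)
  feat <- tk$feat; dim(feat) <- c(nrow(tk$feat), T_, B)
  gcaches <- list(); gin <- feat
  for (l in seq_len(cfg$gru_layers)) {
    gr <- bigru_forward(gin, model$params[[paste0("gru_f", l)]],
                        model$params[[paste0("gru_b", l)]])
    gcaches[[l]] <- gr
    gin <- gr$y
  }
  hmat <- matrix(gin, dim(gin)[1], T_ * B)
  hd <- .head_forward(model$params, cfg, hmat, train)
  probs <- matrix(.sigmoid(hd$logit), T_, B)
  list(probs = probs, trunk = tk, gru = gcaches, head = hd,
       dims = c(T_ = T_, B = B))
}

.deletion_backward <- function(model, fw, dlogit) {
  cfg <- model$cfg
  T_ <- fw$dims[["T_"]]; B <- fw$dims[["B"]]
  hb <- .head_backward(matrix(dlogit, 1L), fw$head, model$params)
  g <- hb$grads
  dy <- hb$dx; dim(dy) <- c(nrow(dy), T_, B)
  for (l in rev(seq_len(cfg$gru_layers))) {
    gb <- bigru_backward(dy, fw$gru[[l]],
                         model$params[[paste0("gru_f", l)]],
                         model$params[[paste0("gru_b", l)]])
    g[[paste0("gru_f", l)]] <- gb$grads_f
    g[[paste0("gru_b", l)]] <- gb$grads_b
    dy <- gb$dx
  }
  dfeat <- matrix(dy, dim(dy)[1], T_ * B)
  tb <- .trunk_backward(dfeat, fw$trunk, model$params, cfg)
  c(g, tb$grads)
}

#' Forward pass of the genotype classifier
#'
#' @param model A `deepdel_model` of kind `"genotype"`.
#' @param x Array `(9, L, N)` of tile matrices (or a single 9 x L matrix).
#' @param train Enable dropout.
#' @return List with `probs` (length `N`) and caches.
#' @export
genotype_forward <- function(model, x, train = FALSE) {
  cfg <- model$cfg
  x <- .as3d(x)
  if (dim(x)[1] != 9L || dim(x)[2] != cfg$L)
    stop("input matrices must be 9 x ", cfg$L)
  tk <- .trunk_forward(model$params, cfg, x)
  hd <- .head_forward(model$params, cfg, tk$feat, train)
  list(probs = as.vector(.sigmoid(hd$logit)), trunk = tk, head = hd)
}

.genotype_backward <- function(model, fw, dlogit) {
  hb <- .head_backward(matrix(dlogit, 1L), fw$head, model$params)
  tb <- .trunk_backward(hb$dx, fw$trunk, model$params, model$cfg)
  c(hb$grads, tb$grads)
}

## masked BCE over a (T, B) probability grid; mask 0 drops padded tiles
.masked_bce_grad <- function(logit, y, mask) {
  p <- .sigmoid(logit)
  eps <- 1e-12
  n <- sum(mask)
  loss <- -sum(mask * (y * log(p + eps) + (1 - y) * log(1 - p + eps))) / n
  list(loss = loss, p = p, dlogit = mask * (p - y) / n)
}

#' Train the deletion classifier
#'
#' Minimises binary cross-entropy with Adam over minibatches of tile
#' sequences. Fully deterministic given `cfg$seed` on CPU.
#'
#' @param xseq Array `(9, L, seq_len, B)` of training sequences.
#' @param labels `seq_len` x `B` matrix of 0/1 tile labels.
#' @param cfg A [model_config()].
#' @param mask Optional `seq_len` x `B` 0/1 matrix; 0 excludes a (padded)
#'   tile from the loss.
#' @return A `deepdel_model` with a `history` element: `initial_loss` and
#'   per-epoch `loss` / `accuracy`.
#' @export
train_deletion_model <- function(xseq, labels, cfg = model_config(),
                                 mask = NULL) {
  labels <- as.matrix(labels)
  if (is.null(mask)) mask <- matrix(1, nrow(labels), ncol(labels))
  eff <- labels[mask > 0]
  if (length(unique(eff)) < 2L)
    stop("training labels contain a single class; need both 0 and 1")
  model <- init_model(cfg, "deletion")
  B <- dim(xseq)[4]
  fw0 <- deletion_forward(model, xseq, train = FALSE)
  initial <- .masked_bce_grad(matrix(fw0$head$logit, nrow(labels)), labels,
                              mask)$loss
  st <- adam_init(model$params)
  hist <- data.frame(epoch = integer(0), loss = numeric(0),
                     accuracy = numeric(0))
  for (ep in seq_len(cfg$epochs)) {
    ord <- sample.int(B)
    tot_loss <- 0; tot_n <- 0; correct <- 0
    for (bs in split(ord, ceiling(seq_along(ord) / cfg$batch_size))) {
      xb <- xseq[, , , bs, drop = FALSE]
      yb <- labels[, bs, drop = FALSE]
      mb <- mask[, bs, drop = FALSE]
      fw <- deletion_forward(model, xb, train = TRUE)
      lo <- .masked_bce_grad(matrix(fw$head$logit, nrow(yb)), yb, mb)
      grads <- .deletion_backward(model, fw, lo$dlogit)
      up <- adam_step(model$params, grads, st, lr = cfg$lr)
      model$params <- up$params; st <- up$state
      n <- sum(mb)
      tot_loss <- tot_loss + lo$loss * n; tot_n <- tot_n + n
      correct <- correct + sum(((lo$p > cfg$decision_threshold) == yb) * mb)
    }
    hist <- rbind(hist, data.frame(epoch = ep, loss = tot_loss / tot_n,
                                   accuracy = correct / tot_n))
  }
  model$history <- list(initial_loss = initial, epochs = hist)
  model
}

#' Train the genotype classifier
#'
#' Labels: 1 = homozygous, 0 = heterozygous deletion tile.
#'
#' @param x Array `(9, L, N)` of tile matrices over deletion regions.
#' @param labels 0/1 vector of length `N`.
#' @param cfg A [model_config()].
#' @return A `deepdel_model` (kind `"genotype"`) with training history.
#' @export
train_genotype_model <- function(x, labels, cfg = model_config()) {
  if (length(unique(labels)) < 2L)
    stop("training labels contain a single class; need both 0 and 1")
  model <- init_model(cfg, "genotype")
  N <- dim(x)[3]
  fw0 <- genotype_forward(model, x)
  initial <- bce_with_logits(as.vector(fw0$head$logit), labels)$loss
  st <- adam_init(model$params)
  hist <- data.frame(epoch = integer(0), loss = numeric(0),
                     accuracy = numeric(0))
  for (ep in seq_len(cfg$epochs)) {
    ord <- sample.int(N)
    tot_loss <- 0; tot_n <- 0; correct <- 0
    for (bs in split(ord, ceiling(seq_along(ord) / (8L * cfg$batch_size)))) {
      xb <- x[, , bs, drop = FALSE]
      yb <- labels[bs]
      fw <- genotype_forward(model, xb, train = TRUE)
      lo <- bce_with_logits(as.vector(fw$head$logit), yb)
      grads <- .genotype_backward(model, fw, lo$dlogit)
      up <- adam_step(model$params, grads, st, lr = cfg$lr)
      model$params <- up$params; st <- up$state
      n <- length(bs)
      tot_loss <- tot_loss + lo$loss * n; tot_n <- tot_n + n
      correct <- correct + sum((lo$p > cfg$decision_threshold) == yb)
    }
    hist <- rbind(hist, data.frame(epoch = ep, loss = tot_loss / tot_n,
                                   accuracy = correct / tot_n))
  }
  model$history <- list(initial_loss = initial, epochs = hist)
  model
}

#' Per-tile deletion probabilities for an ordered tile set
#'
#' Chops the tiles into consecutive sequences of `seq_len` (zero-padding
#' the last one), runs the deletion network in eval mode and returns one
#' probability per tile.
#'
#' @param model A deletion `deepdel_model`.
#' @param x Array `(9, L, M)` of consecutive tile matrices.
#' @return Numeric vector of length `M`.
#' @export
predict_subregion_probs <- function(model, x, chunk_seqs = 20L) {
  cfg <- model$cfg
  x <- .as3d(x)
  M <- dim(x)[3]
  T_ <- cfg$seq_len
  B <- ceiling(M / T_)
  xp <- array(0, c(9L, cfg$L, T_ * B))
  xp[, , seq_len(M)] <- x
  dim(xp) <- c(9L, cfg$L, T_, B)
  out <- numeric(T_ * B)
  ## fixed-size chunks keep the im2col index cache warm
  for (i0 in seq.int(1L, B, by = chunk_seqs)) {
    i1 <- min(i0 + chunk_seqs - 1L, B)
    idx <- i0:i1
    xb <- xp[, , , idx, drop = FALSE]
    if (length(idx) < chunk_seqs) {       # pad final chunk
      xc <- array(0, c(9L, cfg$L, T_, chunk_seqs))
      xc[, , , seq_along(idx)] <- xb
      xb <- xc
    }
    fw <- deletion_forward(model, xb, train = FALSE)
    out[(i0 - 1L) * T_ + seq_len(length(idx) * T_)] <-
      as.vector(fw$probs)[seq_len(length(idx) * T_)]
  }
  out[seq_len(M)]
}

## ---- standalone attention ops --------------------------------------------

#' Channel attention weights
#'
#' Per-channel gate of the CBAM block: average- and max-pooled channel
#' descriptors through a shared bottleneck MLP, summed and squashed with a
#' sigmoid. Weights are strictly in (0, 1) and equal across channels when
#' the channel statistics are identical.
#'
#' @param x Tensor `(C, L, N)` (or `C x L` matrix).
#' @param par CBAM parameters from [cbam_init()]; freshly initialised from
#'   the current RNG state when `NULL`.
#' @return `C x N` matrix of weights.
#' @export
channel_attention <- function(x, par = NULL) {
  x <- .as3d(x)
  if (is.null(par)) par <- cbam_init(dim(x)[1])
  channel_attention_forward(x, par)$s
}

#' Spatial attention map
#'
#' Per-position gate of the CBAM block: channel-wise mean and max maps,
#' convolved and squashed with a sigmoid. One weight per spatial position,
#' uniform for constant input.
#'
#' @inheritParams channel_attention
#' @param spatial_kernel Convolution width of the attention map.
#' @return `L x N` matrix of weights in (0, 1).
#' @export
spatial_attention <- function(x, par = NULL, spatial_kernel = 7L) {
  x <- .as3d(x)
  if (is.null(par)) par <- cbam_init(dim(x)[1], spatial_kernel = spatial_kernel)
  spatial_attention_forward(x, par, spatial_kernel)$p
}

#' Convolutional block attention (CBAM)
#'
#' Sequential channel-then-spatial multiplicative gating:
#' `x' = channel(x) * x; x'' = spatial(x') * x'`. Output shape equals the
#' input shape; for strictly positive input every output element is
#' strictly smaller than its input (two sub-unit gates).
#'
#' @inheritParams spatial_attention
#' @return Tensor of the same shape as `x`.
#' @export
cbam <- function(x, par = NULL, spatial_kernel = 7L) {
  x <- .as3d(x)
  if (is.null(par)) par <- cbam_init(dim(x)[1], spatial_kernel = spatial_kernel)
  cbam_forward(x, par, spatial_kernel)$y
}

## ---- persistence ----------------------------------------------------------

.flatten_params <- function(p, prefix = "") {
  out <- list()
  for (nm in names(p)) {
    v <- p[[nm]]
    key <- if (prefix == "") nm else paste0(prefix, ".", nm)
    if (is.list(v)) out <- c(out, .flatten_params(v, key))
    else out[[key]] <- v
  }
  out
}

#' Save a model checkpoint
#'
#' Writes `<path>.json` (config, kind, parameter shapes) and `<path>.bin`
#' (little-endian doubles, parameters concatenated in the order listed in
#' the sidecar).
#'
#' @param model A `deepdel_model`.
#' @param path Path prefix (no extension).
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  fl <- .flatten_params(model$params)
  shapes <- lapply(fl, function(v) if (is.matrix(v)) dim(v) else length(v))
  meta <- list(kind = model$kind,
               cfg = model$cfg[setdiff(names(model$cfg), "")],
               param_order = names(fl), shapes = shapes)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  con <- file(paste0(path, ".bin"), "wb")
  on.exit(close(con))
  for (v in fl) writeBin(as.double(v), con, size = 8L, endian = "little")
  invisible(path)
}

#' Load a model checkpoint written by [save_model()]
#' @param path Path prefix used when saving.
#' @return A `deepdel_model`.
#' @export
load_model <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  cfg <- do.call(model_config, meta$cfg[names(meta$cfg) %in%
                                          names(formals(model_config))])
  model <- init_model(cfg, meta$kind)
  fl <- .flatten_params(model$params)
  con <- file(paste0(path, ".bin"), "rb")
  on.exit(close(con))
  for (key in meta$param_order) {
    sh <- meta$shapes[[key]]
    n <- prod(sh)
    v <- readBin(con, "double", n, size = 8L, endian = "little")
    if (length(sh) == 2L) v <- matrix(v, sh[1], sh[2])
    fl[[key]] <- v
  }
  ## rebuild nested structure
  rebuild <- function(p, prefix = "") {
    for (nm in names(p)) {
      key <- if (prefix == "") nm else paste0(prefix, ".", nm)
      if (is.list(p[[nm]])) p[[nm]] <- rebuild(p[[nm]], key)
      else p[[nm]] <- fl[[key]]
    }
    p
  }
  model$params <- rebuild(model$params)
  model
}
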