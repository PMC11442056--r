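# Minimal neural-network primitives shared by the segmentation and
# classification networks. Activations live in 5-d arrays (D, H, W, C, N);
# convolution is delegated to the compiled im2col kernels, everything else is
# plain vectorised R. Channel broadcasting exploits column-major recycling:
# a vector of length D*H*W*C recycles exactly once per sample.

conv_fw <- function(x, w, b, stride = c(1L, 1L, 1L), pad = c(0L, 0L, 0L)) {
  .conv_forward(x, w, b, as.integer(stride), as.integer(pad))
}

conv_bw <- function(x, w, dy, stride = c(1L, 1L, 1L), pad = c(0L, 0L, 0L)) {
  .conv_backward(x, w, dy, as.integer(stride), as.integer(pad))
}

# He-normal initialisation for a conv kernel (kd,kh,kw,Cin,Cout).
conv_init <- function(kd, kh, kw, cin, cout) {
  fan_in <- kd * kh * kw * cin
  w <- array(stats::rnorm(fan_in * cout, sd = sqrt(2 / fan_in)),
             dim = c(kd, kh, kw, cin, cout))
  list(w = w, b = numeric(cout))
}

linear_init <- function(nin, nout, zero = FALSE) {
  w <- if (zero) matrix(0, nin, nout) else
    matrix(stats::rnorm(nin * nout, sd = sqrt(2 / nin)), nin, nout)
  list(w = w, b = numeric(nout))
}

linear_fw <- function(x, w, b) sweep(x %*% w, 2L, b, "+")

linear_bw <- function(x, w, dy) {
  list(dx = dy %*% t(w), dw = crossprod(x, dy), db = colSums(dy))
}

relu_fw <- function(x) {
  x[x < 0] <- 0
  x
}

relu_bw <- function(y, dy) {
  dy[y <= 0] <- 0
  dy
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# ---- batch normalisation over the channel axis of (D,H,W,C,N) -------------

bn_channel_stat <- function(x, C) {
  d <- dim(x)
  n <- d[length(d)]
  per_c <- length(x) %/% (C * n)  # D*H*W
  m1 <- .colMeans(x, per_c, C * n)  # no copy of the big array
  .rowMeans(matrix(m1, C, n), C, n)
}

bn_broadcast <- function(v, x_dim) {
  # length D*H*W*C vector that recycles across N
  per_c <- prod(x_dim[-c(length(x_dim) - 1L, length(x_dim))])
  rep(v, each = per_c)
}

bn_fw <- function(x, gamma, beta, state, training, eps = 1e-5,
                  momentum = 0.1) {
  C <- length(gamma)
  d <- dim(x)
  if (training) {
    mu <- bn_channel_stat(x, C)
    xc <- x - bn_broadcast(mu, d)
    va <- bn_channel_stat(xc * xc, C)
    state$mean <- (1 - momentum) * state$mean + momentum * mu
    state$var <- (1 - momentum) * state$var + momentum * va
  } else {
    mu <- state$mean
    va <- state$var
    xc <- x - bn_broadcast(mu, d)
  }
  inv <- 1 / sqrt(va + eps)
  xhat <- xc * bn_broadcast(inv, d)
  y <- xhat * bn_broadcast(gamma, d) + bn_broadcast(beta, d)
  dim(y) <- d
  list(y = y, state = state,
       cache = list(xhat = xhat, inv = inv, gamma = gamma, dim = d))
}

bn_bw <- function(cache, dy) {
  d <- cache$dim
  C <- length(cache$gamma)
  m <- length(dy) / C  # elements per channel
  dxhat <- dy * bn_broadcast(cache$gamma, d)
  dgamma <- bn_channel_stat(dy * cache$xhat, C) * m
  dbeta <- bn_channel_stat(dy, C) * m
  # dx = inv/m * (m*dxhat - sum(dxhat) - xhat * sum(dxhat*xhat)), per channel
  s1 <- bn_channel_stat(dxhat, C) * m
  s2 <- bn_channel_stat(dxhat * cache$xhat, C) * m
  dx <- (dxhat - bn_broadcast(s1, d) / m -
           cache$xhat * bn_broadcast(s2, d) / m) * bn_broadcast(cache$inv, d)
  dim(dx) <- d
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

bn_init <- function(C) {
  list(gamma = rep(1, C), beta = numeric(C),
       state = list(mean = numeric(C), var = rep(1, C)))
}

# ---- 2D average pooling / nearest upsampling on (1,H,W,C,N) ----------------

avgpool2_fw <- function(x) {
  d <- dim(x)
  H <- d[2]; W <- d[3]
  stopifnot(H %% 2 == 0, W %% 2 == 0)
  a <- x[, seq(1, H, 2), seq(1, W, 2), , , drop = FALSE]
  b <- x[, seq(2, H, 2), seq(1, W, 2), , , drop = FALSE]
  cc <- x[, seq(1, H, 2), seq(2, W, 2), , , drop = FALSE]
  e <- x[, seq(2, H, 2), seq(2, W, 2), , , drop = FALSE]
  (a + b + cc + e) / 4
}

avgpool2_bw <- function(dy, in_dim) {
  dx <- array(0, in_dim)
  H <- in_dim[2]; W <- in_dim[3]
  g <- dy / 4
  dx[, seq(1, H, 2), seq(1, W, 2), , ] <- g
  dx[, seq(2, H, 2), seq(1, W, 2), , ] <- g
  dx[, seq(1, H, 2), seq(2, W, 2), , ] <- g
  dx[, seq(2, H, 2), seq(2, W, 2), , ] <- g
  dx
}

upsample2_fw <- function(x) {
  d <- dim(x)
  x[, rep(seq_len(d[2]), each = 2), rep(seq_len(d[3]), each = 2), , ,
    drop = FALSE]
}

upsample2_bw <- function(dy) {
  d <- dim(dy)
  H <- d[2]; W <- d[3]
  a <- dy[, seq(1, H, 2), seq(1, W, 2), , , drop = FALSE]
  b <- dy[, seq(2, H, 2), seq(1, W, 2), , , drop = FALSE]
  cc <- dy[, seq(1, H, 2), seq(2, W, 2), , , drop = FALSE]
  e <- dy[, seq(2, H, 2), seq(2, W, 2), , , drop = FALSE]
  a + b + cc + e
}

concat_channels <- function(a, b) {
  da <- dim(a); db <- dim(b)
  stopifnot(all(da[-4] == db[-4]))
  out <- array(0, c(da[1:3], da[4] + db[4], da[5]))
  out[, , , seq_len(da[4]), ] <- a
  out[, , , da[4] + seq_len(db[4]), ] <- b
  out
}

split_channels <- function(dy, c1) {
  d <- dim(dy)
  list(a = dy[, , , seq_len(c1), , drop = FALSE],
       b = dy[, , , (c1 + 1):d[4], , drop = FALSE])
}

# ---- losses ----------------------------------------------------------------

# Softmax cross-entropy. logits: N x K matrix, labels: integer in 1..K.
softmax_ce <- function(logits, labels) {
  z <- logits - apply(logits, 1L, max)
  ez <- exp(z)
  p <- ez / rowSums(ez)
  n <- nrow(p)
  idx <- cbind(seq_len(n), labels)
  loss <- -mean(log(pmax(p[idx], 1e-12)))
  dlogits <- p
  dlogits[idx] <- dlogits[idx] - 1
  list(loss = loss, probs = p, dlogits = dlogits / n)
}

# Sigmoid + binary cross-entropy on per-pixel logits (any array shape).
sigmoid_bce <- function(logits, targets) {
  p <- sigmoid(logits)
  loss <- -mean(targets * log(pmax(p, 1e-12)) +
                  (1 - targets) * log(pmax(1 - p, 1e-12)))
  list(loss = loss, probs = p, dlogits = (p - targets) / length(p))
}

# ---- Adam ------------------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, opt, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - beta1^opt$t
  bc2 <- 1 - beta2^opt$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * g
    opt$v[[nm]] <- beta2 * opt$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (opt$m[[nm]] / bc1) / (sqrt(opt$v[[nm]] / bc2) + eps)
  }
  list(params = params, opt = opt)
}

# Add L2 weight-decay gradient (2 * lambda * w) to weight entries only
# (names ending in "_w"); biases and batch-norm parameters are exempt.
add_l2_grads <- function(grads, params, lambda) {
  if (lambda <= 0) return(grads)
  for (nm in names(grads)) {
    if (grepl("_w$", nm)) grads[[nm]] <- grads[[nm]] + 2 * lambda * params[[nm]]
  }
  grads
}

l2_penalty <- function(params, lambda) {
  if (lambda <= 0) return(0)
  lambda * sum(vapply(params[grepl("_w$", names(params))],
                      function(w) sum(w * w), numeric(1)))
}
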