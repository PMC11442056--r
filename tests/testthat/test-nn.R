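# Gradient checks of the native layer engine against central finite
# differences, plus loss-layer contracts. These guard the whole training
# stack: if they pass, backpropagation through both networks is correct.

e3d <- asNamespace("embryo3d")

num_grad <- function(f, x, eps = 1e-5) {
  vapply(seq_along(x), function(i) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    (f(xp) - f(xm)) / (2 * eps)
  }, numeric(1))
}

test_that("convolution gradients match finite differences (stride + pad)", {
  set.seed(42)
  x <- array(rnorm(5 * 6 * 6 * 2 * 2), c(5, 6, 6, 2, 2))
  w <- array(rnorm(3 * 3 * 3 * 2 * 3), c(3, 3, 3, 2, 3)) * 0.3
  b <- rnorm(3)
  st <- c(2L, 2L, 2L); pd <- c(1L, 1L, 1L)
  y <- e3d$conv_fw(x, w, b, st, pd)
  dy <- array(rnorm(length(y)), dim(y))
  bk <- e3d$conv_bw(x, w, dy, st, pd)
  loss <- function(xx, ww, bb) sum(e3d$conv_fw(xx, ww, bb, st, pd) * dy)
  expect_lt(max(abs(bk$dx - num_grad(function(v)
    loss(array(v, dim(x)), w, b), as.vector(x)))), 1e-6)
  expect_lt(max(abs(bk$dw - num_grad(function(v)
    loss(x, array(v, dim(w)), b), as.vector(w)))), 1e-6)
  expect_lt(max(abs(bk$db - num_grad(function(v) loss(x, w, v), b))), 1e-6)
})

test_that("batch-norm gradients match finite differences", {
  set.seed(43)
  x <- array(rnorm(1 * 4 * 4 * 3 * 4), c(1, 4, 4, 3, 4))
  g <- runif(3, 0.5, 1.5); be <- rnorm(3)
  st0 <- e3d$bn_init(3)$state
  fw <- e3d$bn_fw(x, g, be, st0, training = TRUE)
  dy <- array(rnorm(length(x)), dim(x))
  bw <- e3d$bn_bw(fw$cache, dy)
  lf <- function(v) sum(e3d$bn_fw(array(v, dim(x)), g, be, st0, TRUE)$y * dy)
  expect_lt(max(abs(bw$dx - num_grad(lf, as.vector(x)))), 1e-6)
  expect_lt(max(abs(bw$dgamma -
    num_grad(function(v) sum(e3d$bn_fw(x, v, be, st0, TRUE)$y * dy), g))), 1e-6)
  expect_lt(max(abs(bw$dbeta -
    num_grad(function(v) sum(e3d$bn_fw(x, g, v, st0, TRUE)$y * dy), be))), 1e-6)
})

test_that("segmentation network end-to-end gradient is exact", {
  set.seed(44)
  pairs <- lapply(1:2, function(i)
    list(slice = matrix(runif(64), 8, 8),
         mask = matrix(rbinom(64, 1, 0.4), 8, 8)))
  ini <- e3d$.seg_init(1L)
  xb <- e3d$.seg_batch(lapply(pairs, `[[`, "slice"))
  yb <- e3d$.seg_batch_masks(lapply(pairs, `[[`, "mask"))
  fw <- e3d$.seg_forward(ini$params, ini$states, xb, training = TRUE)
  grads <- e3d$.seg_backward(ini$params, fw$caches,
                             e3d$sigmoid_bce(fw$logits, yb)$dlogits)
  for (nm in c("c1_w", "c5_w", "c7_g", "c9_w", "c12_w", "c2_be")) {
    p0 <- ini$params[[nm]]
    idx <- seq_len(min(5, length(p0)))
    ng <- vapply(idx, function(i) {
      eps <- 1e-5
      up <- ini$params; up[[nm]][i] <- up[[nm]][i] + eps
      dn <- ini$params; dn[[nm]][i] <- dn[[nm]][i] - eps
      fu <- e3d$.seg_forward(up, ini$states, xb, TRUE)
      fd <- e3d$.seg_forward(dn, ini$states, xb, TRUE)
      (e3d$sigmoid_bce(fu$logits, yb)$loss -
          e3d$sigmoid_bce(fd$logits, yb)$loss) / (2 * eps)
    }, numeric(1))
    expect_lt(max(abs(as.vector(grads[[nm]])[idx] - ng)), 1e-6)
  }
})

test_that("fusion network end-to-end gradient is exact", {
  set.seed(45)
  mod <- build_fusion_model(train_config(seed = 3), "fusion3d")
  vols <- lapply(1:2, function(i)
    volume3d(paste0("e", i), array(runif(11 * 111 * 111), c(11, 111, 111))))
  cee <- matrix(runif(18), 2, 9)
  xb <- e3d$.cls_batch(vols, "fusion3d")
  fw <- e3d$.fusion_forward(mod, xb, cee, training = TRUE)
  ls <- e3d$softmax_ce(fw$logits, c(1L, 2L))
  grads <- e3d$.fusion_backward(mod, fw$caches, ls$dlogits)
  for (nm in c("v1_w", "v5_w", "v8_w", "l1_w", "l4_b")) {
    p0 <- mod$params[[nm]]
    idx <- seq_len(min(3, length(p0)))
    ng <- vapply(idx, function(i) {
      eps <- 1e-4
      up <- mod; up$params[[nm]][i] <- up$params[[nm]][i] + eps
      dn <- mod; dn$params[[nm]][i] <- dn$params[[nm]][i] - eps
      fu <- e3d$.fusion_forward(up, xb, cee, TRUE)
      fd <- e3d$.fusion_forward(dn, xb, cee, TRUE)
      (e3d$softmax_ce(fu$logits, c(1L, 2L))$loss -
          e3d$softmax_ce(fd$logits, c(1L, 2L))$loss) / (2 * eps)
    }, numeric(1))
    scale <- max(1, max(abs(ng)))
    expect_lt(max(abs(as.vector(grads[[nm]])[idx] - ng)) / scale, 2e-3,
              label = nm)
  }
})

test_that("loss layers behave at their contracts", {
  set.seed(46)
  logits <- matrix(rnorm(10), 5, 2)
  sm <- e3d$softmax_ce(logits, c(1L, 2L, 1L, 2L, 1L))
  expect_equal(rowSums(sm$probs), rep(1, 5), tolerance = 1e-12)
  expect_true(is.finite(sm$loss))

  bce <- e3d$sigmoid_bce(array(0, c(1, 2, 2, 1, 1)), array(1, c(1, 2, 2, 1, 1)))
  expect_equal(bce$loss, -log(0.5), tolerance = 1e-12)
})
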