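# Stage-1 AI: compact U-style encoder-decoder semantic segmentation that
# removes the well-frame background from each slice, plus IOU metrics.
#
# Architecture (12 convolutions, per-pixel sigmoid): two 3x3 conv blocks at
# full resolution, two at 1/2, a two-conv bottleneck at 1/4, then mirrored
# decoding with skip concatenations and two final 1x1 convs. Each slice is fed
# as two channels: intensity and normalized radial coordinate (the well
# geometry is rotationally symmetric, so the radius is the cheap positional
# cue that lets a small net separate the wall ring from the blastocyst).

.seg_conv_cfg <- list(
  c1 = list(cin = 2, cout = 4, k = 3, bn = TRUE),
  c2 = list(cin = 4, cout = 4, k = 3, bn = TRUE),
  c3 = list(cin = 4, cout = 8, k = 3, bn = TRUE),
  c4 = list(cin = 8, cout = 8, k = 3, bn = TRUE),
  c5 = list(cin = 8, cout = 16, k = 3, bn = TRUE),
  c6 = list(cin = 16, cout = 16, k = 3, bn = TRUE),
  c7 = list(cin = 24, cout = 8, k = 3, bn = TRUE),
  c8 = list(cin = 8, cout = 8, k = 3, bn = TRUE),
  c9 = list(cin = 12, cout = 8, k = 3, bn = TRUE),
  c10 = list(cin = 8, cout = 8, k = 1, bn = TRUE),
  c11 = list(cin = 8, cout = 8, k = 1, bn = TRUE),
  c12 = list(cin = 8, cout = 1, k = 1, bn = FALSE)
)

.seg_init <- function(seed) {
  set.seed(derive_seed(seed, "seg_init"))
  params <- list()
  states <- list()
  for (nm in names(.seg_conv_cfg)) {
    cfg <- .seg_conv_cfg[[nm]]
    ini <- conv_init(1, cfg$k, cfg$k, cfg$cin, cfg$cout)
    params[[paste0(nm, "_w")]] <- ini$w
    params[[paste0(nm, "_b")]] <- ini$b
    if (cfg$bn) {
      bi <- bn_init(cfg$cout)
      params[[paste0(nm, "_g")]] <- bi$gamma
      params[[paste0(nm, "_be")]] <- bi$beta
      states[[nm]] <- bi$state
    }
  }
  list(params = params, states = states)
}

# Forward pass; returns logits, per-layer caches and updated BN states.
.seg_forward <- function(params, states, xb, training) {
  caches <- list()
  cbr <- function(nm, x) {
    cfg <- .seg_conv_cfg[[nm]]
    pad <- if (cfg$k == 3) c(0L, 1L, 1L) else c(0L, 0L, 0L)
    y <- conv_fw(x, params[[paste0(nm, "_w")]], params[[paste0(nm, "_b")]],
                 pad = pad)
    cache <- list(x = x, pad = pad)
    if (cfg$bn) {
      bn <- bn_fw(y, params[[paste0(nm, "_g")]], params[[paste0(nm, "_be")]],
                  states[[nm]], training)
      states[[nm]] <<- bn$state
      cache$bn <- bn$cache
      y <- relu_fw(bn$y)
      cache$act <- y
    }
    caches[[nm]] <<- cache
    y
  }
  a1 <- cbr("c1", xb)
  a2 <- cbr("c2", a1)
  p1 <- avgpool2_fw(a2)
  a3 <- cbr("c3", p1)
  a4 <- cbr("c4", a3)
  p2 <- avgpool2_fw(a4)
  a5 <- cbr("c5", p2)
  a6 <- cbr("c6", a5)
  u2 <- concat_channels(upsample2_fw(a6), a4)
  a7 <- cbr("c7", u2)
  a8 <- cbr("c8", a7)
  u1 <- concat_channels(upsample2_fw(a8), a2)
  a9 <- cbr("c9", u1)
  a10 <- cbr("c10", a9)
  a11 <- cbr("c11", a10)
  logits <- cbr("c12", a11)
  caches$dims <- list(a2 = dim(a2), a4 = dim(a4))
  list(logits = logits, caches = caches, states = states)
}

.seg_backward <- function(params, caches, dlogits) {
  grads <- list()
  cbr_bw <- function(nm, dy) {
    cfg <- .seg_conv_cfg[[nm]]
    cache <- caches[[nm]]
    if (cfg$bn) {
      dy <- relu_bw(cache$act, dy)
      bb <- bn_bw(cache$bn, dy)
      grads[[paste0(nm, "_g")]] <<- bb$dgamma
      grads[[paste0(nm, "_be")]] <<- bb$dbeta
      dy <- bb$dx
    }
    cb <- conv_bw(cache$x, params[[paste0(nm, "_w")]], dy, pad = cache$pad)
    grads[[paste0(nm, "_w")]] <<- cb$dw
    grads[[paste0(nm, "_b")]] <<- cb$db
    cb$dx
  }
  d <- cbr_bw("c12", dlogits)
  d <- cbr_bw("c11", d)
  d <- cbr_bw("c10", d)
  du1 <- cbr_bw("c9", d)                      # gradient w.r.t. concat(up(a8), a2)
  sp <- split_channels(du1, dim(caches$c8$act)[4])
  d <- cbr_bw("c8", upsample2_bw(sp$a))
  du2 <- cbr_bw("c7", d)                      # gradient w.r.t. concat(up(a6), a4)
  sp2 <- split_channels(du2, dim(caches$c6$act)[4])
  d <- cbr_bw("c6", upsample2_bw(sp2$a))
  d <- cbr_bw("c5", d)
  d <- avgpool2_bw(d, caches$dims$a4) + sp2$b # pooled path + skip into a4
  d <- cbr_bw("c4", d)
  d <- cbr_bw("c3", d)
  d <- avgpool2_bw(d, caches$dims$a2) + sp$b  # pooled path + skip into a2
  d <- cbr_bw("c2", d)
  cbr_bw("c1", d)
  grads
}

#' Segmenter training configuration
#'
#' @param epochs maximum training epochs.
#' @param lr Adam learning rate.
#' @param batch_size mini-batch size.
#' @param val_fraction fraction of pairs held out for early stopping (when at
#'   least 4 pairs are available).
#' @param patience epochs without validation improvement before stopping.
#' @param seed integer seed (initialisation, shuffling, split).
#' @return a list of class `seg_config`.
#' @export
seg_config <- function(epochs = 10L, lr = 1e-3, batch_size = 8L,
                       val_fraction = 0.15, patience = 3L, seed = 1L) {
  structure(list(epochs = as.integer(epochs), lr = lr,
                 batch_size = as.integer(batch_size),
                 val_fraction = val_fraction, patience = as.integer(patience),
                 seed = as.integer(seed)), class = "seg_config")
}

# Build the (1,H,W,2,N) input batch: intensity + radial coordinate channel.
.seg_batch <- function(slices) {
  H <- nrow(slices[[1]])
  c0 <- (H + 1) / 2
  g <- seq_len(H) - c0
  rad <- sqrt(outer(g^2, g^2, "+")) / (H / 2)
  n <- length(slices)
  xb <- array(0, c(1, H, H, 2, n))
  for (i in seq_len(n)) {
    xb[1, , , 1, i] <- slices[[i]]
    xb[1, , , 2, i] <- rad
  }
  xb
}

.check_pair <- function(p) {
  if (!is.matrix(p$slice) || !is.matrix(p$mask) ||
      !all(dim(p$slice) == dim(p$mask)))
    stopf("slice/mask shape mismatch in training pair")
  if (nrow(p$slice) != ncol(p$slice) || nrow(p$slice) %% 4 != 0)
    stopf("slices must be square with side divisible by 4")
  if (!all(p$mask %in% c(0, 1))) stopf("masks must be binary")
}

#' Train the background-elimination segmenter
#'
#' Trains the 12-convolution encoder-decoder on (slice, mask) pairs with
#' pixel-wise binary cross-entropy, Adam, and early stopping on a held-out
#' validation split. Training is seeded and reproducible at a fixed thread
#' count.
#'
#' @param pairs list of `list(slice = matrix, mask = binary matrix)`.
#' @param config a [seg_config()].
#' @return an object of class `segmenter_model` (parameters, batch-norm
#'   state, training history).
#' @export
train_segmenter <- function(pairs, config = seg_config()) {
  stopifnot(length(pairs) >= 2)
  lapply(pairs, .check_pair)
  n <- length(pairs)
  set.seed(derive_seed(config$seed, "seg_split"))
  n_val <- if (n >= 4) max(1L, round(config$val_fraction * n)) else 0L
  perm <- sample.int(n)
  val_idx <- if (n_val > 0) perm[seq_len(n_val)] else integer(0)
  tr_idx <- setdiff(perm, val_idx)
  if (n_val == 0) val_idx <- tr_idx  # degenerate tiny input: validate on train

  mk <- function(idx) {
    list(x = .seg_batch(lapply(pairs[idx], `[[`, "slice")),
         y = .seg_batch_masks(lapply(pairs[idx], `[[`, "mask")))
  }
  va <- mk(val_idx)

  ini <- .seg_init(config$seed)
  params <- ini$params
  states <- ini$states
  opt <- adam_init(params)
  best <- list(loss = Inf, params = params, states = states)
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_loss = numeric())
  stall <- 0L
  set.seed(derive_seed(config$seed, "seg_train"))
  for (ep in seq_len(config$epochs)) {
    ord <- sample(tr_idx)
    tl <- 0; nb <- 0
    for (b0 in seq(1, length(ord), by = config$batch_size)) {
      bidx <- ord[b0:min(b0 + config$batch_size - 1, length(ord))]
      ba <- mk(bidx)
      fw <- .seg_forward(params, states, ba$x, training = TRUE)
      states <- fw$states
      ls <- sigmoid_bce(fw$logits, ba$y)
      grads <- .seg_backward(params, fw$caches, ls$dlogits)
      st <- adam_step(params, grads, opt, config$lr)
      params <- st$params; opt <- st$opt
      tl <- tl + ls$loss; nb <- nb + 1
    }
    vf <- .seg_forward(params, states, va$x, training = FALSE)
    vl <- sigmoid_bce(vf$logits, va$y)$loss
    if (!is.finite(vl)) stopf("validation loss is not finite at epoch %d", ep)
    history <- rbind(history, data.frame(epoch = ep, train_loss = tl / nb,
                                         val_loss = vl))
    if (vl < best$loss) {
      best <- list(loss = vl, params = params, states = states)
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= config$patience) break
    }
  }
  structure(list(params = best$params, states = best$states,
                 config = config, history = history,
                 best_val_loss = best$loss,
                 architecture = .seg_conv_cfg),
            class = "segmenter_model")
}

.seg_batch_masks <- function(masks) {
  H <- nrow(masks[[1]])
  n <- length(masks)
  y <- array(0, c(1, H, H, 1, n))
  for (i in seq_len(n)) y[1, , , 1, i] <- masks[[i]]
  y
}

#' Predict per-pixel foreground probabilities
#'
#' @param model a trained `segmenter_model`.
#' @param slices list of square matrices (side divisible by 4).
#' @param chunk maximum slices per forward batch.
#' @return list of probability matrices in `(0, 1)`.
#' @export
predict_foreground <- function(model, slices, chunk = 16L) {
  stopifnot(inherits(model, "segmenter_model"))
  for (s in slices)
    if (nrow(s) != ncol(s) || nrow(s) %% 4 != 0)
      stopf("slices must be square with side divisible by 4")
  out <- vector("list", length(slices))
  for (b0 in seq(1, length(slices), by = chunk)) {
    idx <- b0:min(b0 + chunk - 1, length(slices))
    xb <- .seg_batch(slices[idx])
    fw <- .seg_forward(model$params, model$states, xb, training = FALSE)
    p <- sigmoid(fw$logits)
    for (j in seq_along(idx))
      out[[idx[j]]] <- matrix(p[1, , , 1, j], nrow(slices[[idx[j]]]))
  }
  out
}

# Cheap deterministic fingerprint of a parameter set + threshold, used to
# record masking provenance on the output stack.
.seg_fingerprint <- function(params, threshold) {
  chk <- vapply(params, function(p) sum(as.numeric(p) *
                                          seq_along(p)), numeric(1))
  sprintf("segmask|%.17g|%.17g", sum(chk), threshold)
}

#' Eliminate the background of a slice stack
#'
#' Pixels whose predicted foreground probability is at least `threshold` keep
#' their original intensity; all other pixels are set to 0. The masked stack
#' records the masking provenance (model fingerprint + threshold), so
#' re-applying the same model and threshold returns the input unchanged —
#' the operation is exactly idempotent without re-segmenting already-masked
#' intensities (whose background context the model was never trained on).
#'
#' @param model a trained `segmenter_model`.
#' @param stack a `slice_stack`.
#' @param threshold foreground probability threshold in `(0, 1)`.
#' @return the masked `slice_stack` (attribute `masked_by` holds the
#'   provenance fingerprint).
#' @export
eliminate_background <- function(model, stack, threshold = 0.5) {
  stopifnot(inherits(stack, "slice_stack"), threshold > 0, threshold < 1)
  fp <- .seg_fingerprint(model$params, threshold)
  if (identical(attr(stack, "masked_by"), fp)) return(stack)
  probs <- predict_foreground(model, stack$slices)
  masked <- mapply(function(s, p) s * (p >= threshold), stack$slices, probs,
                   SIMPLIFY = FALSE)
  out <- slice_stack(stack$embryo_id, masked, stack$pixel_size_um,
                     stack$slice_pitch_um)
  attr(out, "masked_by") <- fp
  out
}

#' Intersection over union of two binary masks
#'
#' Defined as 1 when both masks are empty.
#'
#' @param pred_mask,true_mask binary matrices of identical shape.
#' @return IOU in `[0, 1]`.
#' @export
iou <- function(pred_mask, true_mask) {
  if (!all(dim(pred_mask) == dim(true_mask)))
    stopf("mask shape mismatch: %s vs %s",
          paste(dim(pred_mask), collapse = "x"),
          paste(dim(true_mask), collapse = "x"))
  stopifnot(all(pred_mask %in% c(0, 1)), all(true_mask %in% c(0, 1)))
  un <- sum(pred_mask == 1 | true_mask == 1)
  if (un == 0) return(1)
  sum(pred_mask == 1 & true_mask == 1) / un
}

#' Mean IOU of a segmenter over a test set
#'
#' @param model a trained `segmenter_model`.
#' @param test_pairs list of `list(slice, mask)` pairs.
#' @param threshold probability threshold for the predicted mask.
#' @return object of class `seg_metrics`: `per_image_iou`, `miou`, `miou_sd`
#'   (sample SD, n-1; 0 with `sd_undefined = TRUE` for a single pair),
#'   `iou_min`, `iou_max`.
#' @export
mean_iou <- function(model, test_pairs, threshold = 0.5) {
  if (length(test_pairs) < 1) stopf("empty test set")
  lapply(test_pairs, .check_pair)
  probs <- predict_foreground(model, lapply(test_pairs, `[[`, "slice"))
  ious <- mapply(function(p, pair) iou((p >= threshold) * 1L, pair$mask),
                 probs, test_pairs)
  seg_metrics(as.numeric(ious))
}

#' Segmentation metrics from per-image IOU values
#'
#' @param per_image_iou numeric vector of IOU values in `[0, 1]`.
#' @return object of class `seg_metrics`: mean, sample SD (n-1; reported as 0
#'   with `sd_undefined = TRUE` for a single value), min and max.
#' @export
seg_metrics <- function(per_image_iou) {
  stopifnot(length(per_image_iou) >= 1,
            all(per_image_iou >= 0 & per_image_iou <= 1))
  structure(list(per_image_iou = per_image_iou, miou = mean(per_image_iou),
                 miou_sd = if (length(per_image_iou) > 1)
                   stats::sd(per_image_iou) else 0,
                 sd_undefined = length(per_image_iou) == 1,
                 iou_min = min(per_image_iou), iou_max = max(per_image_iou)),
            class = "seg_metrics")
}

#' @export
print.seg_metrics <- function(x, ...) {
  cat(sprintf("mIOU %.3f +/- %.3f (n = %d, range %.3f-%.3f)\n", x$miou,
              x$miou_sd, length(x$per_image_iou), x$iou_min, x$iou_max))
  invisible(x)
}
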