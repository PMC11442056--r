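# Stage-2 AI: the fused 3D-CNN + CEE classifier, its training loop, and the
# nested fivefold cross-validation harness with the single-image and
# no-background ablations.
#
# Reference architecture (auditable in .fusion_arch): 8 convolutions with
# batch norm, a two-way catenation of a global-average-pooled mid-level
# feature with the final convolutional vector, a second catenation with the 9
# CEE scalars produced by the elementwise regression transforms (the
# "threading" stage broadcasts those nine univariate functions over the
# batch), 4 linear layers and a 2-class softmax whose implantation-class
# probability is the confidence score.

.fusion_variants <- c("fusion3d", "single_image", "no_background")

.fusion_arch <- function(variant) {
  flat <- variant == "single_image"
  kd <- function(k) if (flat) 1L else k
  sd <- function(s) if (flat) 1L else s
  list(
    input = if (flat) c(1L, 111L, 111L) else c(11L, 111L, 111L),
    conv = list(
      v1 = list(k = c(kd(3L), 5L, 5L), s = c(sd(2L), 3L, 3L), cin = 1L,
                cout = 4L, bn = TRUE, relu = TRUE),
      v2 = list(k = c(kd(3L), 3L, 3L), s = c(1L, 2L, 2L), cin = 4L,
                cout = 8L, bn = TRUE, relu = TRUE),
      v3 = list(k = c(kd(3L), 3L, 3L), s = c(1L, 2L, 2L), cin = 8L,
                cout = 16L, bn = TRUE, relu = TRUE),
      v4 = list(k = c(1L, 3L, 3L), s = c(1L, 1L, 1L), cin = 16L, cout = 16L,
                bn = TRUE, relu = TRUE),
      v5 = list(k = c(1L, 3L, 3L), s = c(1L, 1L, 1L), cin = 16L, cout = 16L,
                bn = TRUE, relu = TRUE),
      v6 = list(k = c(1L, 1L, 1L), s = c(1L, 1L, 1L), cin = 16L, cout = 16L,
                bn = TRUE, relu = FALSE),
      v7 = list(k = c(1L, 1L, 1L), s = c(1L, 1L, 1L), cin = 16L, cout = 16L,
                bn = TRUE, relu = FALSE),
      v8 = list(k = c(1L, 4L, 4L), s = c(1L, 1L, 1L), cin = 16L, cout = 32L,
                bn = FALSE, relu = FALSE)
    ),
    gap_from = "v5",      # catenation 1: GAP(v5) ++ flatten(v8) -> 48
    linear = list(l1 = c(48L, 16L),   # relu
                  l2 = c(25L, 16L),   # after catenation 2 with the 9 CEE scalars
                  l3 = c(16L, 8L),    # relu
                  l4 = c(8L, 2L)),    # softmax logits
    n_cee = 9L
  )
}

#' Training configuration for the fusion classifier
#'
#' Defaults follow the published training setup: batch size 64, learning rate
#' 8e-4 (printed as "8 x 10^4"; a positive exponent is not a usable learning
#' rate), L2 regularization 0.02 and 10-fold rotation augmentation.
#'
#' @param batch_size mini-batch size.
#' @param learning_rate Adam learning rate.
#' @param l2_lambda L2 penalty on convolution/linear weights.
#' @param augment_times rotation-augmentation multiplication factor (>= 1).
#' @param max_epochs maximum training epochs.
#' @param early_stopping_patience epochs without validation improvement
#'   before stopping.
#' @param seed integer seed.
#' @return object of class `train_config`.
#' @export
train_config <- function(batch_size = 64L, learning_rate = 8e-4,
                         l2_lambda = 0.02, augment_times = 10L,
                         max_epochs = 50L, early_stopping_patience = 5L,
                         seed = 1L) {
  stopifnot(batch_size >= 1, learning_rate > 0, l2_lambda >= 0,
            augment_times >= 1, max_epochs >= 1, early_stopping_patience >= 1)
  structure(list(batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, l2_lambda = l2_lambda,
                 augment_times = as.integer(augment_times),
                 max_epochs = as.integer(max_epochs),
                 early_stopping_patience = as.integer(early_stopping_patience),
                 seed = as.integer(seed)), class = "train_config")
}

#' Build an untrained fusion model
#'
#' @param config a [train_config()].
#' @param variant `"fusion3d"` (11-slice volume), `"single_image"` (centre
#'   slice only) or `"no_background"` (same architecture as fusion3d, meant
#'   for volumes reconstructed without background elimination).
#' @return object of class `fusion_model`.
#' @export
build_fusion_model <- function(config = train_config(),
                               variant = "fusion3d") {
  if (!variant %in% .fusion_variants)
    stopf("invalid variant '%s' (use %s)", variant,
          paste(.fusion_variants, collapse = ", "))
  arch <- .fusion_arch(variant)
  set.seed(derive_seed(config$seed, "fusion_init", variant))
  params <- list()
  states <- list()
  for (nm in names(arch$conv)) {
    cf <- arch$conv[[nm]]
    ini <- conv_init(cf$k[1], cf$k[2], cf$k[3], cf$cin, cf$cout)
    params[[paste0(nm, "_w")]] <- ini$w
    params[[paste0(nm, "_b")]] <- ini$b
    if (cf$bn) {
      bi <- bn_init(cf$cout)
      params[[paste0(nm, "_g")]] <- bi$gamma
      params[[paste0(nm, "_be")]] <- bi$beta
      states[[nm]] <- bi$state
    }
  }
  for (nm in names(arch$linear)) {
    dm <- arch$linear[[nm]]
    ini <- linear_init(dm[1], dm[2])
    params[[paste0(nm, "_w")]] <- ini$w
    params[[paste0(nm, "_b")]] <- ini$b
  }
  structure(list(variant = variant, arch = arch, params = params,
                 states = states, config = config, trained = FALSE,
                 meta = list()), class = "fusion_model")
}

# Assemble the (D,H,W,1,N) input batch for a variant from volume3d objects.
.cls_batch <- function(volumes, variant) {
  v1 <- volumes[[1]]$voxels
  d <- dim(v1)
  n <- length(volumes)
  if (variant == "single_image") {
    ctr <- (d[1] + 1L) %/% 2L
    xb <- array(0, c(1L, d[2], d[3], 1L, n))
    for (i in seq_len(n)) xb[1, , , 1, i] <- volumes[[i]]$voxels[ctr, , ]
  } else {
    xb <- array(0, c(d[1], d[2], d[3], 1L, n))
    for (i in seq_len(n)) xb[, , , 1, i] <- volumes[[i]]$voxels
  }
  xb
}

.fusion_forward <- function(model, xb, cee, training) {
  arch <- model$arch
  params <- model$params
  states <- model$states
  caches <- list()
  a <- xb
  for (nm in names(arch$conv)) {
    cf <- arch$conv[[nm]]
    y <- conv_fw(a, params[[paste0(nm, "_w")]], params[[paste0(nm, "_b")]],
                 stride = cf$s)
    cache <- list(x = a, s = cf$s)
    if (cf$bn) {
      bn <- bn_fw(y, params[[paste0(nm, "_g")]], params[[paste0(nm, "_be")]],
                  states[[nm]], training)
      states[[nm]] <- bn$state
      cache$bn <- bn$cache
      y <- bn$y
    }
    if (cf$relu) {
      y <- relu_fw(y)
      cache$act <- y
    }
    caches[[nm]] <- cache
    if (nm == arch$gap_from) caches$gap_in <- y
    a <- y
  }
  # catenation 1: GAP(mid features) ++ final conv vector
  gi <- caches$gap_in
  gd <- dim(gi)
  n <- gd[5]
  cmid <- gd[4]
  spat <- prod(gd[1:3])
  gap <- t(matrix(colMeans(matrix(gi, spat, cmid * n)), cmid, n))
  v8 <- t(matrix(a, length(a) / n, n))
  feat <- cbind(gap, v8)
  caches$gap_dim <- gd
  h1 <- relu_fw(linear_fw(feat, params$l1_w, params$l1_b))
  # catenation 2: image feature ++ 9 CEE elementwise scalars
  h1c <- cbind(h1, cee)
  h2 <- relu_fw(linear_fw(h1c, params$l2_w, params$l2_b))
  h3 <- relu_fw(linear_fw(h2, params$l3_w, params$l3_b))
  logits <- linear_fw(h3, params$l4_w, params$l4_b)
  caches$head <- list(feat = feat, h1 = h1, h1c = h1c, h2 = h2, h3 = h3)
  list(logits = logits, caches = caches, states = states)
}

.fusion_backward <- function(model, caches, dlogits) {
  arch <- model$arch
  params <- model$params
  grads <- list()
  hd <- caches$head
  lb <- linear_bw(hd$h3, params$l4_w, dlogits)
  grads$l4_w <- lb$dw; grads$l4_b <- lb$db
  d <- relu_bw(hd$h3, lb$dx)
  lb <- linear_bw(hd$h2, params$l3_w, d)
  grads$l3_w <- lb$dw; grads$l3_b <- lb$db
  d <- relu_bw(hd$h2, lb$dx)
  lb <- linear_bw(hd$h1c, params$l2_w, d)
  grads$l2_w <- lb$dw; grads$l2_b <- lb$db
  d <- relu_bw(hd$h1, lb$dx[, seq_len(ncol(hd$h1)), drop = FALSE])
  lb <- linear_bw(hd$feat, params$l1_w, d)
  grads$l1_w <- lb$dw; grads$l1_b <- lb$db
  dfeat <- lb$dx

  gd <- caches$gap_dim
  n <- gd[5]; cmid <- gd[4]; spat <- prod(gd[1:3])
  dgap <- dfeat[, seq_len(cmid), drop = FALSE]           # N x cmid
  dv8 <- dfeat[, cmid + seq_len(ncol(dfeat) - cmid), drop = FALSE]
  # GAP backward: spread evenly over the spatial positions
  dgap_arr <- array(rep(as.vector(t(dgap)) / spat, each = spat), gd)
  dy_skip <- dgap_arr  # gradient entering at the gap_from layer's output

  conv_names <- names(arch$conv)
  dy <- array(as.vector(t(dv8)), c(1, 1, 1, ncol(dv8), n))
  for (nm in rev(conv_names)) {
    cf <- arch$conv[[nm]]
    cache <- caches[[nm]]
    if (nm == arch$gap_from) dy <- dy + dy_skip
    if (cf$relu) dy <- relu_bw(cache$act, dy)
    if (cf$bn) {
      bb <- bn_bw(cache$bn, dy)
      grads[[paste0(nm, "_g")]] <- bb$dgamma
      grads[[paste0(nm, "_be")]] <- bb$dbeta
      dy <- bb$dx
    }
    cb <- conv_bw(cache$x, params[[paste0(nm, "_w")]], dy, stride = cache$s)
    grads[[paste0(nm, "_w")]] <- cb$dw
    grads[[paste0(nm, "_b")]] <- cb$db
    dy <- cb$dx
  }
  grads
}

#' Train the fusion classifier
#'
#' Minimizes softmax cross-entropy plus `l2_lambda * ||w||^2` (convolution and
#' linear weights only) with Adam, checkpointing the best validation loss and
#' stopping after `early_stopping_patience` epochs without improvement.
#' Training and validation sets must be disjoint by embryo id; augmentation
#' must have been applied to the training set only.
#'
#' @param train list with `volumes` (list of `volume3d`), `cee` (n x 9 feature
#'   matrix from [cee_feature_matrix()]), `labels` (0/1), `ids`.
#' @param val same structure, untouched by augmentation.
#' @param config a [train_config()].
#' @param model optionally a pre-built [build_fusion_model()] (its variant
#'   wins); built from `config` as `fusion3d` otherwise.
#' @return the trained `fusion_model` with `history` and `best_val_loss`.
#' @export
train_classifier <- function(train, val, config = train_config(),
                             model = NULL) {
  if (is.null(model)) model <- build_fusion_model(config, "fusion3d")
  leaked <- intersect(unique(train$ids), unique(val$ids))
  if (length(leaked))
    stopf("leakage: embryo id(s) present in both train and validation: %s",
          paste(utils::head(leaked, 5), collapse = ", "))
  stopifnot(length(train$volumes) == length(train$labels),
            nrow(train$cee) == length(train$labels))

  xv <- .cls_batch(val$volumes, model$variant)
  yv <- as.integer(val$labels) + 1L
  ntr <- length(train$volumes)
  params <- model$params
  states <- model$states
  opt <- adam_init(params)
  best <- list(loss = Inf, params = params, states = states, epoch = 0L)
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_loss = numeric())
  stall <- 0L
  set.seed(derive_seed(config$seed, "cls_train", model$variant))
  for (ep in seq_len(config$max_epochs)) {
    ord <- sample.int(ntr)
    tl <- 0; nb <- 0
    for (b0 in seq(1, ntr, by = config$batch_size)) {
      bidx <- ord[b0:min(b0 + config$batch_size - 1, ntr)]
      xb <- .cls_batch(train$volumes[bidx], model$variant)
      cb <- train$cee[bidx, , drop = FALSE]
      yb <- as.integer(train$labels[bidx]) + 1L
      model$params <- params; model$states <- states
      fw <- .fusion_forward(model, xb, cb, training = TRUE)
      states <- fw$states
      ls <- softmax_ce(fw$logits, yb)
      grads <- .fusion_backward(model, fw$caches, ls$dlogits)
      grads <- add_l2_grads(grads, params, config$l2_lambda)
      st <- adam_step(params, grads, opt, config$learning_rate)
      params <- st$params; opt <- st$opt
      tl <- tl + ls$loss + l2_penalty(params, config$l2_lambda)
      nb <- nb + 1
    }
    model$params <- params; model$states <- states
    vf <- .fusion_forward(model, xv, val$cee, training = FALSE)
    vl <- softmax_ce(vf$logits, yv)$loss
    if (!is.finite(vl))
      stopf("validation loss became non-finite at epoch %d (train loss %g)",
            ep, tl / nb)
    history <- rbind(history, data.frame(epoch = ep, train_loss = tl / nb,
                                         val_loss = vl))
    if (vl < best$loss - 1e-9) {
      best <- list(loss = vl, params = params, states = states, epoch = ep)
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= config$early_stopping_patience) break
    }
  }
  model$params <- best$params
  model$states <- best$states
  model$trained <- TRUE
  model$history <- history
  model$best_val_loss <- best$loss
  model$meta <- list(optimizer = "adam", seed = config$seed,
                     best_epoch = best$epoch,
                     l2_lambda = config$l2_lambda,
                     n_train = ntr, n_val = length(val$volumes))
  model
}

#' Predict implantation confidence scores
#'
#' Runs the fusion model in evaluation mode (batch-norm running statistics)
#' and returns the implantation-class softmax probability for each embryo.
#'
#' @param object a `fusion_model`.
#' @param volumes list of `volume3d`.
#' @param cee n x 9 CEE feature matrix.
#' @param ... unused.
#' @return numeric vector of confidence scores in `[0, 1]`.
#' @export
predict.fusion_model <- function(object, volumes, cee, ...) {
  if (is.null(dim(cee))) cee <- matrix(cee, nrow = 1)
  stopifnot(length(volumes) == nrow(cee), ncol(cee) == object$arch$n_cee)
  d <- dim(volumes[[1]]$voxels)
  want <- object$arch$input
  if (object$variant != "single_image" && !all(d == want))
    stopf("volume shape %s does not match model input %s",
          paste(d, collapse = "x"), paste(want, collapse = "x"))
  if (!all(d[2:3] == want[2:3]))
    stopf("slice size %s does not match model input %s",
          paste(d[2:3], collapse = "x"), paste(want[2:3], collapse = "x"))
  scores <- numeric(length(volumes))
  for (b0 in seq(1, length(volumes), by = 64L)) {
    idx <- b0:min(b0 + 63L, length(volumes))
    xb <- .cls_batch(volumes[idx], object$variant)
    fw <- .fusion_forward(object, xb, cee[idx, , drop = FALSE],
                          training = FALSE)
    z <- fw$logits - apply(fw$logits, 1L, max)
    p <- exp(z) / rowSums(exp(z))
    scores[idx] <- p[, 2]
  }
  scores
}

# ---- cross-validation plan ---------------------------------------------------

# Stratified k-way partition whose fold totals differ by at most one: each
# class's remainder goes to the folds with the currently smallest totals.
.strat_partition <- function(idx_by_class, k) {
  folds <- rep(list(integer(0)), k)
  totals <- integer(k)
  for (cls in idx_by_class) {
    mem <- sample(cls)
    b <- length(mem) %/% k
    e <- length(mem) - b * k
    sizes <- rep(b, k)
    if (e > 0) sizes[order(totals, sample.int(k))[seq_len(e)]] <- b + 1L
    at <- 0L
    for (f in seq_len(k)) {
      if (sizes[f] > 0)
        folds[[f]] <- c(folds[[f]], mem[at + seq_len(sizes[f])])
      at <- at + sizes[f]
    }
    totals <- totals + sizes
  }
  folds
}

#' Nested cross-validation plan
#'
#' A stratified fifth of the embryos becomes the outer test set; the remaining
#' four fifths are split into `k` stratified inner folds (each usable as the
#' validation set, the rest as training). Splits are by embryo, never by
#' augmented copy, and all fold sizes differ by at most one.
#'
#' @param n_embryos number of embryos (must be >= k^2).
#' @param k number of folds (default 5).
#' @param seed integer seed.
#' @param labels binary labels used for stratification.
#' @return object of class `cv_plan`: `test_idx`, `inner_folds` (list of `k`
#'   index vectors partitioning the non-test embryos), `k`, `seed`.
#' @export
make_cv_plan <- function(n_embryos, k = 5L, seed = 1L, labels) {
  k <- as.integer(k)
  stopifnot(length(labels) == n_embryos)
  if (n_embryos < k * k)
    stopf("need at least k^2 = %d embryos, got %d", k * k, n_embryos)
  labels <- as.integer(labels)
  cls <- split(seq_len(n_embryos), labels)
  small <- vapply(cls, length, integer(1)) < k
  if (any(small))
    stopf("stratification error: class %s has fewer than k = %d members",
          paste(names(cls)[small], collapse = ", "), k)
  set.seed(derive_seed(seed, "cv_plan"))
  outer <- .strat_partition(cls, k)
  test_idx <- sort(outer[[1L]])
  rest <- sort(unlist(outer[-1L]))
  cls_in <- split(rest, labels[rest])
  inner <- .strat_partition(cls_in, k)
  structure(list(test_idx = test_idx,
                 inner_folds = lapply(inner, sort),
                 k = k, seed = as.integer(seed), stratified = TRUE),
            class = "cv_plan")
}

# Hard leakage guard used by every harness run.
assert_no_leakage <- function(train_ids, val_ids, test_ids = character(0)) {
  bad <- union(intersect(unique(train_ids), unique(val_ids)),
               intersect(unique(train_ids), unique(test_ids)))
  if (length(bad))
    stopf("leakage: augmented/training embryo id(s) found in validation/test: %s",
          paste(utils::head(bad, 5), collapse = ", "))
  invisible(TRUE)
}

#' Run one nested-CV experiment for a model variant
#'
#' Trains on the inner folds (augmented training data only), validates on the
#' held-out inner fold, and evaluates the best-validation-loss model on the
#' outer test set. The leakage guard (augmented training ids disjoint from
#' validation and test ids) is asserted on every fold.
#'
#' @param volumes list of `volume3d` (for `no_background`, pass volumes
#'   reconstructed without masking).
#' @param cee n x 9 CEE feature matrix.
#' @param labels binary outcomes.
#' @param ids embryo ids.
#' @param variant model variant (see [build_fusion_model()]).
#' @param config a [train_config()].
#' @param plan a [make_cv_plan()]; built from `config$seed` if missing.
#' @param inner_folds_used how many of the k inner folds to train (1 for a
#'   single model, k for the full nested protocol).
#' @return list: `per_fold` (fold, best val loss, test AUC), `best_fold`,
#'   `test_scores` (best fold's), `test_roc`, `test_idx`, `models`.
#' @export
run_cv_experiment <- function(volumes, cee, labels, ids, variant = "fusion3d",
                              config = train_config(), plan = NULL,
                              inner_folds_used = 1L) {
  n <- length(volumes)
  stopifnot(length(labels) == n, length(ids) == n, nrow(cee) == n)
  if (is.null(plan)) plan <- make_cv_plan(n, seed = config$seed,
                                          labels = labels)
  test_idx <- plan$test_idx
  per_fold <- list()
  models <- list()
  for (f in seq_len(min(inner_folds_used, plan$k))) {
    val_idx <- plan$inner_folds[[f]]
    tr_idx <- setdiff(unlist(plan$inner_folds), val_idx)
    aug <- augment_dataset(volumes[tr_idx], labels[tr_idx],
                           times = config$augment_times,
                           seed = derive_seed(config$seed, "aug", f),
                           cee = cee[tr_idx, , drop = FALSE])
    assert_no_leakage(aug$ids, ids[val_idx], ids[test_idx])
    model <- build_fusion_model(config, variant)
    model <- train_classifier(
      train = list(volumes = aug$volumes, cee = aug$cee, labels = aug$labels,
                   ids = aug$ids),
      val = list(volumes = volumes[val_idx],
                 cee = cee[val_idx, , drop = FALSE],
                 labels = labels[val_idx], ids = ids[val_idx]),
      config = config, model = model)
    sc <- predict(model, volumes[test_idx], cee[test_idx, , drop = FALSE])
    per_fold[[f]] <- list(fold = f, val_loss = model$best_val_loss,
                          scores = sc, roc = roc_auc(sc, labels[test_idx]))
    models[[f]] <- model
  }
  vls <- vapply(per_fold, `[[`, numeric(1), "val_loss")
  best <- which.min(vls)
  list(per_fold = lapply(per_fold, function(p)
         list(fold = p$fold, val_loss = p$val_loss, auc = p$roc$auc)),
       best_fold = best,
       test_scores = per_fold[[best]]$scores,
       test_roc = per_fold[[best]]$roc,
       test_idx = test_idx,
       models = models)
}

#' Hyperparameter grid of test AUCs
#'
#' Trains one model per (l2, augment, seed) cell on the same CV plan and
#' records the outer-test AUC; the result feeds [two_way_anova()].
#'
#' @param volumes,cee,labels,ids as in [run_cv_experiment()].
#' @param l2_values,augment_values grid levels (>= 2 each).
#' @param seeds replicate seeds.
#' @param config base [train_config()].
#' @param plan optional shared [make_cv_plan()].
#' @return data.frame with columns `l2`, `augment`, `seed`, `auc`.
#' @export
hyperparameter_grid <- function(volumes, cee, labels, ids,
                                l2_values, augment_values, seeds,
                                config = train_config(), plan = NULL) {
  stopifnot(length(l2_values) >= 2, length(augment_values) >= 2)
  if (is.null(plan)) plan <- make_cv_plan(length(volumes),
                                          seed = config$seed, labels = labels)
  grid <- expand.grid(l2 = l2_values, augment = augment_values, seed = seeds)
  grid$auc <- vapply(seq_len(nrow(grid)), function(i) {
    cfg <- config
    cfg$l2_lambda <- grid$l2[i]
    cfg$augment_times <- as.integer(grid$augment[i])
    cfg$seed <- as.integer(grid$seed[i])
    run_cv_experiment(volumes, cee, labels, ids, variant = "fusion3d",
                      config = cfg, plan = plan)$test_roc$auc
  }, numeric(1))
  grid
}
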