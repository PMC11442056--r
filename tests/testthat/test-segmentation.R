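# Stage-1 segmentation: IOU metrics, training, background elimination.
#
# The training fixture follows the reference recipe (200 slice/mask pairs,
# 10 epochs, seed 3) on 96-px phantoms to stay inside the CI budget; the
# trained model is shared by the blocks below.

test_that("iou matches the pixel-counting oracle and its invariants", {
  full <- matrix(1, 8, 8)
  half <- full; half[, 5:8] <- 0
  expect_equal(iou(full, full), 1)
  expect_equal(iou(half, full), 32 / 64)

  a <- matrix(0, 6, 6); a[1:2, 1:2] <- 1
  b <- matrix(0, 6, 6); b[5:6, 5:6] <- 1
  expect_equal(iou(a, b), 0)
  expect_equal(iou(matrix(0, 4, 4), matrix(0, 4, 4)), 1)  # both empty
  expect_error(iou(matrix(0, 4, 4), matrix(0, 5, 5)), "mismatch")

  set.seed(71)
  for (rep in 1:10) {
    x <- matrix(rbinom(64, 1, 0.4), 8, 8)
    y <- matrix(rbinom(64, 1, 0.4), 8, 8)
    # oracle: explicit pixel counting
    inter <- sum(x == 1 & y == 1)
    un <- sum(x == 1 | y == 1)
    expect_equal(iou(x, y), if (un == 0) 1 else inter / un)
    # symmetry and invariance under a shared rotation/flip
    expect_equal(iou(x, y), iou(y, x))
    rot <- function(m) t(m[nrow(m):1, ])
    expect_equal(iou(rot(x), rot(y)), iou(x, y))
    expect_equal(iou(x[8:1, ], y[8:1, ]), iou(x, y))
  }
})

test_that("seg_metrics arithmetic and single-pair edge case", {
  m <- seg_metrics(c(1.0, 0.5))
  expect_equal(m$miou, 0.75)
  expect_equal(m$iou_min, 0.5)
  expect_equal(m$iou_max, 1.0)
  expect_equal(m$miou_sd, sd(c(1, 0.5)))
  m1 <- seg_metrics(0.8)
  expect_equal(m1$miou, 0.8)
  expect_equal(m1$miou_sd, 0)
  expect_true(m1$sd_undefined)
})

test_that("degenerate two-pair training runs and input validation errors", {
  p <- list(slice = matrix(runif(64), 8, 8), mask = matrix(0, 8, 8))
  m <- train_segmenter(list(p, p), seg_config(epochs = 1, seed = 1))
  expect_s3_class(m, "segmenter_model")
  expect_true(is.finite(m$best_val_loss))

  bad <- list(slice = matrix(0, 8, 8), mask = matrix(0, 8, 4))
  expect_error(train_segmenter(list(p, bad)), "mismatch")
})

# ---- shared trained fixture -------------------------------------------------

seg_train_pairs <- make_seg_pairs(19, seed0 = 100)[1:200]
seg_test_pairs <- make_seg_pairs(5, seed0 = 900)[1:50]
seg_model <- train_segmenter(seg_train_pairs, seg_config(epochs = 10, seed = 3))

test_that("trained segmenter reaches mIOU >= 0.85 on held-out phantoms", {
  met <- mean_iou(seg_model, seg_test_pairs)
  expect_gte(met$miou, 0.85)
  expect_true(met$iou_min <= met$miou && met$miou <= met$iou_max)
  # mean_iou equals the loop-of-iou oracle
  probs <- predict_foreground(seg_model, lapply(seg_test_pairs, `[[`, "slice"))
  by_hand <- mapply(function(p, pr) iou((p >= 0.5) * 1L, pr$mask),
                    probs, seg_test_pairs)
  expect_equal(met$per_image_iou, as.numeric(by_hand))
  expect_equal(met$miou, mean(by_hand))
})

test_that("training is reproducible for a fixed seed", {
  cfg <- seg_config(epochs = 2, seed = 11)
  m1 <- train_segmenter(seg_train_pairs[1:24], cfg)
  m2 <- train_segmenter(seg_train_pairs[1:24], cfg)
  expect_identical(m1$params, m2$params)
  expect_identical(m1$history, m2$history)
})

test_that("eliminate_background zeroes the well frame and is idempotent", {
  pp <- phantom_params(image_px = 96, seed = 77)
  sm <- generate_stack(pp, "ring_check")
  masked <- eliminate_background(seg_model, sm$stack)

  px <- 96
  g <- seq_len(px) - (px + 1) / 2
  rho <- sqrt(outer(g^2, g^2, "+"))
  ring <- rho > px / 2 - 9 * px / 280 & rho <= px / 2
  zeroed <- vapply(masked$slices, function(s) mean(s[ring] == 0), numeric(1))
  expect_true(all(zeroed >= 0.95))

  again <- eliminate_background(seg_model, masked)
  expect_identical(again$slices, masked$slices)

  # geometry preserved
  expect_equal(dim(masked$slices[[1]]), dim(sm$stack$slices[[1]]))
  expect_length(masked$slices, length(sm$stack$slices))
})

test_that("masked slices only ever contain 0 or the original intensity", {
  pp <- phantom_params(image_px = 96, seed = 78)
  sm <- generate_stack(pp, "passthrough")
  masked <- eliminate_background(seg_model, sm$stack)
  for (i in seq_along(masked$slices)) {
    m <- masked$slices[[i]]
    s <- sm$stack$slices[[i]]
    expect_true(all(m == 0 | m == s))
  }
  # high-quality segmentation: masked foreground covers most of the truth
  cover <- vapply(seq_along(masked$slices), function(i)
    sum(masked$slices[[i]] != 0 & sm$masks[[i]] == 1) / sum(sm$masks[[i]]),
    numeric(1))
  expect_gt(mean(cover), 0.9)
})
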