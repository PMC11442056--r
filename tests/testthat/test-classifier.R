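# Fusion classifier: model contracts, CV plan, training mechanics, grid.

test_that("forward pass yields valid, deterministic probability pairs", {
  cfg <- train_config(seed = 5)
  mod <- build_fusion_model(cfg, "fusion3d")
  vol <- volume3d("a", array(runif(11 * 111 * 111), c(11, 111, 111)))
  cee <- matrix(runif(9), 1, 9)

  s1 <- predict(mod, list(vol), cee)
  expect_true(s1 >= 0 && s1 <= 1)
  expect_identical(s1, predict(mod, list(vol), cee))

  # zero volume: the CEE branch alone still drives a valid output
  vz <- volume3d("z", array(0, c(11, 111, 111)))
  sz <- predict(mod, list(vz), cee)
  expect_true(is.finite(sz) && sz >= 0 && sz <= 1)

  # zeroed final layer -> logits (0, 0) -> score exactly 0.5
  mod0 <- mod
  mod0$params$l4_w[] <- 0
  mod0$params$l4_b[] <- 0
  expect_equal(predict(mod0, list(vol), cee), 0.5)

  expect_error(build_fusion_model(cfg, "nope"), "invalid variant")

  # single-image variant consumes the centre slice of the same volumes
  mod1 <- build_fusion_model(cfg, "single_image")
  s1i <- predict(mod1, list(vol), cee)
  expect_true(is.finite(s1i) && s1i >= 0 && s1i <= 1)
})

test_that("softmax pairs sum to one across a batch", {
  e3d <- asNamespace("embryo3d")
  mod <- build_fusion_model(train_config(seed = 6), "fusion3d")
  vols <- lapply(1:4, function(i)
    volume3d(paste0("b", i), array(runif(11 * 111 * 111), c(11, 111, 111))))
  xb <- e3d$.cls_batch(vols, "fusion3d")
  fw <- e3d$.fusion_forward(mod, xb, matrix(runif(36), 4, 9), training = FALSE)
  p <- exp(fw$logits) / rowSums(exp(fw$logits))
  expect_equal(rowSums(p), rep(1, 4), tolerance = 1e-6)
})

test_that("make_cv_plan: stratified sizes, partition, determinism, errors", {
  set.seed(81)
  labels977 <- c(rep(1, 458), rep(0, 519))[sample(977)]
  plan <- make_cv_plan(977, seed = 1, labels = labels977)
  expect_true(length(plan$test_idx) %in% c(195, 196))
  expect_true((977 - length(plan$test_idx)) %in% c(781, 782))

  inner <- unlist(plan$inner_folds)
  expect_length(intersect(plan$test_idx, inner), 0)
  expect_setequal(c(plan$test_idx, inner), 1:977)
  expect_equal(anyDuplicated(inner), 0)
  # inner folds balanced within one embryo
  sz <- lengths(plan$inner_folds)
  expect_lte(max(sz) - min(sz), 1)
  # stratification: test-fold prevalence close to the cohort's
  expect_lt(abs(mean(labels977[plan$test_idx]) - mean(labels977)), 0.01)

  plan2 <- make_cv_plan(977, seed = 1, labels = labels977)
  expect_identical(plan, plan2)

  labels25 <- rep(c(0, 1), length.out = 25)
  p25 <- make_cv_plan(25, seed = 2, labels = labels25)
  expect_true(all(lengths(p25$inner_folds) == 4))

  expect_error(make_cv_plan(25, seed = 1, labels = c(rep(0, 22), rep(1, 3))),
               "stratification")
  expect_error(make_cv_plan(20, seed = 1, labels = rep(c(0, 1), 10)),
               "at least")
})

# ---- tiny trainable fixture -------------------------------------------------

tiny <- local({
  cohort <- generate_cohort(40, seed = 23, image_px = 112)
  list(volumes = make_oracle_volumes(cohort),
       labels = vapply(cohort, `[[`, integer(1), "outcome"),
       ids = vapply(cohort, `[[`, character(1), "embryo_id"),
       cee = cee_feature_matrix(do.call(rbind, lapply(cohort, `[[`, "cee"))))
})

test_that("train_classifier: leakage guard, regularizer activity, NaN guard", {
  idx_tr <- 1:28
  idx_va <- 29:40
  mk <- function(idx) list(volumes = tiny$volumes[idx],
                           cee = tiny$cee[idx, , drop = FALSE],
                           labels = tiny$labels[idx], ids = tiny$ids[idx])
  cfg0 <- train_config(batch_size = 16, learning_rate = 3e-3, l2_lambda = 0,
                       augment_times = 1, max_epochs = 2,
                       early_stopping_patience = 2, seed = 7)
  m0 <- train_classifier(mk(idx_tr), mk(idx_va), cfg0)
  expect_true(m0$trained)
  expect_true(all(is.finite(m0$history$val_loss)))

  cfg2 <- cfg0
  cfg2$l2_lambda <- 0.02
  m2 <- train_classifier(mk(idx_tr), mk(idx_va), cfg2)
  expect_false(identical(m0$params$l1_w, m2$params$l1_w))

  # same config twice: identical weights (determinism contract)
  m0b <- train_classifier(mk(idx_tr), mk(idx_va), cfg0)
  expect_identical(m0$params, m0b$params)

  leaky <- mk(c(1:27, 29))
  expect_error(train_classifier(leaky, mk(idx_va), cfg0), "leakage")
})

test_that("augmented training does not hurt validation AUC (tiny scale)", {
  idx_tr <- 1:28
  idx_va <- 29:40
  base <- train_config(batch_size = 16, learning_rate = 3e-3,
                       augment_times = 1, max_epochs = 6,
                       early_stopping_patience = 6, seed = 9)
  run_with <- function(times) {
    aug <- augment_dataset(tiny$volumes[idx_tr], tiny$labels[idx_tr],
                           times = times, seed = 9,
                           cee = tiny$cee[idx_tr, , drop = FALSE])
    m <- train_classifier(
      list(volumes = aug$volumes, cee = aug$cee, labels = aug$labels,
           ids = aug$ids),
      list(volumes = tiny$volumes[idx_va],
           cee = tiny$cee[idx_va, , drop = FALSE],
           labels = tiny$labels[idx_va], ids = tiny$ids[idx_va]),
      base)
    roc_auc(predict(m, tiny$volumes[idx_va],
                    tiny$cee[idx_va, , drop = FALSE]),
            tiny$labels[idx_va])$auc
  }
  expect_gte(run_with(10), run_with(1) - 0.05)
})

test_that("run_cv_experiment splits cleanly and hyperparameter_grid counts cells", {
  cfg <- train_config(batch_size = 16, learning_rate = 3e-3,
                      augment_times = 1, max_epochs = 1,
                      early_stopping_patience = 1, seed = 3)
  plan <- make_cv_plan(40, seed = 3, labels = tiny$labels)
  exp1 <- run_cv_experiment(tiny$volumes, tiny$cee, tiny$labels, tiny$ids,
                            "fusion3d", cfg, plan)
  expect_length(exp1$test_scores, length(plan$test_idx))
  expect_s3_class(exp1$test_roc, "roc_result")

  grid <- hyperparameter_grid(tiny$volumes, tiny$cee, tiny$labels, tiny$ids,
                              l2_values = c(0, 0.02),
                              augment_values = c(1, 2), seeds = c(3, 4),
                              config = cfg, plan = plan)
  expect_equal(nrow(grid), 8)
  expect_true(all(grid$auc >= 0 & grid$auc <= 1))

  # null grid: identical configuration in every cell gives identical AUCs
  null_grid <- hyperparameter_grid(tiny$volumes, tiny$cee, tiny$labels,
                                   tiny$ids, l2_values = c(0.02, 0.02),
                                   augment_values = c(1, 1), seeds = 3,
                                   config = cfg, plan = plan)
  expect_equal(length(unique(null_grid$auc)), 1)
})
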