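# Shared end-to-end protocol for the acceptance suite (criterion-level
# fixture, built once per test run).
#
# Scaled-down choices, documented in the methods vignette: phantoms rendered
# at 112 px (the 280-um well spans the frame, geometry unchanged), one
# segmenter trained on the first 12 embryos' 132 slice/mask pairs for 12
# epochs, single-pass masking with provenance-based idempotence,
# rotation augmentation x2, and classifier batches of 16 at learning rate
# 3e-3 (the published batch 64 / 8e-4 assume ~7800 augmented training images
# and hundreds of epochs; the small-sample run needs more, larger updates).

e2e_config <- function(seed) {
  train_config(batch_size = 16, learning_rate = 3e-3, l2_lambda = 0.02,
               augment_times = 2, max_epochs = 15,
               early_stopping_patience = 5, seed = seed)
}

# Cohort + segmenter + both volume sets, built once and cached for the run.
e2e_fixture <- local({
  cache <- NULL
  function(n = 300L, seed = 1L) {
    if (!is.null(cache)) return(cache)
    cohort <- generate_cohort(n, seed = seed, weight_image = 0.5,
                              image_px = 112)
    pairs <- unlist(lapply(cohort[1:12], function(e)
      lapply(seq_along(e$stack$slices), function(j)
        list(slice = e$stack$slices[[j]], mask = e$masks[[j]]))),
      recursive = FALSE)
    seg <- train_segmenter(pairs, seg_config(epochs = 12, seed = seed))
    vol_masked <- lapply(cohort, function(e)
      reconstruct_volume(eliminate_background(seg, e$stack),
                         111))
    vol_raw <- lapply(cohort, function(e) reconstruct_volume(e$stack, 111))
    cache <<- list(
      cohort = cohort, segmenter = seg,
      vol_masked = vol_masked, vol_raw = vol_raw,
      labels = vapply(cohort, `[[`, integer(1), "outcome"),
      ids = vapply(cohort, `[[`, character(1), "embryo_id"),
      cee = cee_feature_matrix(do.call(rbind, lapply(cohort, `[[`, "cee"))))
    cache
  }
})

# Train one variant under one seed on the shared fixture; returns the
# experiment (scores, ROC, plan indices).
e2e_run_variant <- function(fx, variant, seed) {
  vols <- if (variant == "no_background") fx$vol_raw else fx$vol_masked
  plan <- make_cv_plan(length(fx$labels), seed = seed, labels = fx$labels)
  run_cv_experiment(vols, fx$cee, fx$labels, fx$ids, variant = variant,
                    config = e2e_config(seed), plan = plan)
}
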