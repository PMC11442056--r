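# Shared fixtures built in code. Kept small: larger training fixtures are
# constructed inside the test files that need them.

# (slice, mask) training pairs from easy phantoms; quality varies so the
# segmenter sees a spread of sizes and shell shapes.
make_seg_pairs <- function(n_embryos, seed0, image_px = 96L) {
  unlist(lapply(seq_len(n_embryos), function(i) {
    q <- (i %% 10) / 10
    pp <- phantom_params(image_px = image_px, seed = seed0 + i,
                         blastocyst_diameter_um = 130 + 120 * q,
                         irregularity = 1 - q, icm_scale = 0.5 + q)
    sm <- generate_stack(pp, embryo_id = paste0("fix_", seed0 + i))
    lapply(seq_along(sm$stack$slices), function(j)
      list(slice = sm$stack$slices[[j]], mask = sm$masks[[j]]))
  }), recursive = FALSE)
}

# Volumes with oracle masking (no segmenter), for classifier-only tests.
make_oracle_volumes <- function(cohort, target_px = 111L) {
  lapply(cohort, function(e) {
    masked <- slice_stack(e$embryo_id,
                          mapply(function(s, m) s * m, e$stack$slices,
                                 e$masks, SIMPLIFY = FALSE))
    reconstruct_volume(masked, target_px)
  })
}

# Brute-force AUC oracle: pair counting with ties worth one half.
pair_count_auc <- function(scores, labels) {
  xp <- scores[labels == 1]
  xn <- scores[labels == 0]
  tot <- 0
  for (a in xp) for (b in xn) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(xp) * length(xn))
}

# Youden index at one threshold (scores >= t predicted positive).
youden_j_at <- function(scores, labels, t) {
  mean(scores[labels == 1] >= t) + mean(scores[labels == 0] < t) - 1
}

# Exhaustive best-J oracle: J(t) is piecewise constant and can only change at
# observed score values, so sweeping just below/at/above every score visits
# every achievable classification.
youden_best_j <- function(scores, labels) {
  eps <- 1e-9
  cand <- sort(unique(c(scores - eps, scores, scores + eps,
                        min(scores) - 1, max(scores) + 1)))
  max(vapply(cand, function(t) youden_j_at(scores, labels, t), numeric(1)))
}
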