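# Statistical harness: ROC/AUC with DeLong variance and paired test, Youden
# cut-off, confusion statistics, Mann-Whitney U, two-way ANOVA over the
# hyperparameter grid, and SART age-band subgroup AUCs.

.check_scores_labels <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), all(is.finite(scores)))
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L))) stopf("labels must be binary 0/1")
  if (length(unique(labels)) < 2)
    stopf("both classes must be present to compute a ROC")
  labels
}

# DeLong structural components: V10 (per positive), V01 (per negative).
.delong_components <- function(scores, labels) {
  xp <- scores[labels == 1]
  xn <- scores[labels == 0]
  m <- length(xp); n <- length(xn)
  # psi(x, y) = 1 if x > y, 1/2 if tie, 0 otherwise
  cmp <- outer(xp, xn, function(a, b) (a > b) + 0.5 * (a == b))
  list(auc = mean(cmp), v10 = rowMeans(cmp), v01 = colMeans(cmp), m = m, n = n)
}

#' ROC curve and AUC with DeLong standard error
#'
#' The AUC is computed by the Mann-Whitney pair-counting estimator (ties count
#' one half), which equals the trapezoidal area under the empirical ROC curve;
#' both are computed and cross-checked. The standard error uses DeLong's
#' structural components and the 95% CI is `auc +/- 1.96 * se`, clipped to
#' `[0, 1]`.
#'
#' @param scores numeric confidence scores (higher = more positive).
#' @param labels binary 0/1 outcome labels.
#' @return an object of class `roc_result`: `auc`, `se`, `ci95`, and `curve`
#'   (data.frame of fpr, tpr, threshold, from (0,0) to (1,1)).
#' @export
roc_auc <- function(scores, labels) {
  labels <- .check_scores_labels(scores, labels)
  dc <- .delong_components(scores, labels)
  # empirical curve over distinct thresholds, descending
  th <- sort(unique(scores), decreasing = TRUE)
  P <- sum(labels == 1); N <- sum(labels == 0)
  tp <- vapply(th, function(t) sum(scores >= t & labels == 1), numeric(1))
  fp <- vapply(th, function(t) sum(scores >= t & labels == 0), numeric(1))
  curve <- data.frame(fpr = c(0, fp / N, 1), tpr = c(0, tp / P, 1),
                      threshold = c(Inf, th, -Inf))
  auc_trap <- sum(diff(curve$fpr) * (utils::head(curve$tpr, -1) +
                                       utils::tail(curve$tpr, -1)) / 2)
  if (abs(auc_trap - dc$auc) > 1e-12 * max(1, abs(dc$auc)) + 1e-12)
    stopf("internal ROC inconsistency: trapezoid %.15f vs pair-count %.15f",
          auc_trap, dc$auc)
  s10 <- if (dc$m > 1) stats::var(dc$v10) else 0
  s01 <- if (dc$n > 1) stats::var(dc$v01) else 0
  se <- sqrt(s10 / dc$m + s01 / dc$n)
  structure(list(auc = dc$auc, se = se, ci95 = ci95_from_auc_se(dc$auc, se),
                 curve = curve, n_pos = P, n_neg = N),
            class = "roc_result")
}

#' 95% confidence interval from an AUC and its standard error
#'
#' `auc +/- 1.96 * se`, clipped to `[0, 1]`.
#'
#' @param auc area under the curve.
#' @param se its standard error.
#' @return numeric vector `c(lower, upper)`.
#' @export
ci95_from_auc_se <- function(auc, se) {
  c(lower = max(0, auc - 1.96 * se), upper = min(1, auc + 1.96 * se))
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC: AUC = %.3f +/- %.3f (DeLong SE), 95%% CI %.3f-%.3f (n+ = %d, n- = %d)\n",
              x$auc, x$se, x$ci95[1], x$ci95[2], x$n_pos, x$n_neg))
  invisible(x)
}

#' DeLong paired test for two correlated AUCs
#'
#' Both score vectors must be computed on the same cases (same labels), e.g.
#' two model variants evaluated on one test set.
#'
#' @param scores_a,scores_b score vectors from the two models.
#' @param labels shared binary labels.
#' @return list with `auc_a`, `auc_b`, `z`, `p.value` (two-sided), and
#'   `degenerate` flag (TRUE when the variance of the difference is zero).
#' @export
delong_paired_test <- function(scores_a, scores_b, labels) {
  labels <- .check_scores_labels(scores_a, labels)
  stopifnot(length(scores_b) == length(labels), all(is.finite(scores_b)))
  da <- .delong_components(scores_a, labels)
  db <- .delong_components(scores_b, labels)
  m <- da$m; n <- da$n
  s10 <- stats::cov(cbind(da$v10, db$v10))
  s01 <- stats::cov(cbind(da$v01, db$v01))
  var_diff <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  diff <- da$auc - db$auc
  if (var_diff <= 0) {
    if (abs(diff) < 1e-12)
      return(list(auc_a = da$auc, auc_b = db$auc, z = 0, p.value = 1,
                  degenerate = TRUE))
    stopf("degenerate DeLong variance (0) with unequal AUCs")
  }
  z <- diff / sqrt(var_diff)
  list(auc_a = da$auc, auc_b = db$auc, z = z,
       p.value = min(1, 2 * stats::pnorm(-abs(z))), degenerate = FALSE)
}

#' Youden-optimal classification threshold
#'
#' Maximizes J = sensitivity + specificity - 1 over candidate thresholds (the
#' midpoints between consecutive distinct scores, plus one below the minimum
#' and one above the maximum). Ties are broken toward the higher threshold.
#' Scores >= threshold are classified positive.
#'
#' @param scores,labels as in [roc_auc()].
#' @return list with `threshold`, `j` (the maximal Youden index), and
#'   `anti_predictive` flag (TRUE when no threshold achieves J > 0).
#' @export
youden_cutoff <- function(scores, labels) {
  labels <- .check_scores_labels(scores, labels)
  s <- sort(unique(scores))
  cand <- c(s[1] - 1, if (length(s) > 1) (s[-1] + s[-length(s)]) / 2,
            s[length(s)] + 1)
  P <- sum(labels == 1); N <- sum(labels == 0)
  j <- vapply(cand, function(t) {
    sum(scores >= t & labels == 1) / P +
      sum(scores < t & labels == 0) / N - 1
  }, numeric(1))
  best <- max(j)
  thr <- max(cand[j >= best - 1e-12])  # ties toward the higher threshold
  list(threshold = thr, j = best, anti_predictive = best <= 0)
}

.confusion_build <- function(tp, fn, fp, tn, threshold = NA_real_) {
  total <- tp + fn + fp + tn
  structure(list(
    threshold = threshold, tp = tp, fp = fp, fn = fn, tn = tn,
    sensitivity = tp / (tp + fn), specificity = tn / (tn + fp),
    ppv = tp / (tp + fp), npv = tn / (tn + fn),
    accuracy = (tp + tn) / total
  ), class = "confusion_stats")
}

#' Confusion-matrix statistics at a threshold
#'
#' Scores greater than or equal to the threshold are predicted positive.
#'
#' @param scores,labels as in [roc_auc()] (a single class is allowed here).
#' @param threshold finite classification threshold.
#' @return a `confusion_stats` object: counts plus sensitivity, specificity,
#'   PPV, NPV, accuracy.
#' @export
confusion_stats <- function(scores, labels, threshold) {
  stopifnot(is.finite(threshold), length(scores) == length(labels))
  labels <- as.integer(labels)
  pred <- scores >= threshold
  .confusion_build(tp = sum(pred & labels == 1),
                   fn = sum(!pred & labels == 1),
                   fp = sum(pred & labels == 0),
                   tn = sum(!pred & labels == 0),
                   threshold = threshold)
}

#' Confusion-matrix statistics from counts
#'
#' @param tp,fn,fp,tn confusion-matrix counts.
#' @return a `confusion_stats` object.
#' @export
confusion_from_counts <- function(tp, fn, fp, tn)
  .confusion_build(tp, fn, fp, tn)

#' @export
print.confusion_stats <- function(x, ...) {
  cat(sprintf("Confusion (threshold %s): TP %d FN %d FP %d TN %d\n",
              ifelse(is.na(x$threshold), "from counts",
                     sprintf("%.3f", x$threshold)),
              x$tp, x$fn, x$fp, x$tn))
  cat(sprintf("  sensitivity %.3f  specificity %.3f  PPV %.3f  NPV %.3f  accuracy %.3f\n",
              x$sensitivity, x$specificity, x$ppv, x$npv, x$accuracy))
  invisible(x)
}

#' Two-sided Mann-Whitney U test
#'
#' Exact enumeration over all group assignments (with midranks, so ties are
#' handled) when the pooled sample size is at most 20; otherwise the normal
#' approximation with tie correction.
#'
#' @param group_a,group_b numeric samples.
#' @return list with `U` (statistic for group A), `p.value`, `method`.
#' @export
mann_whitney <- function(group_a, group_b) {
  stopifnot(length(group_a) >= 1, length(group_b) >= 1)
  na <- length(group_a); nb <- length(group_b)
  pooled <- c(group_a, group_b)
  rk <- rank(pooled)  # midranks
  U <- sum(rk[seq_len(na)]) - na * (na + 1) / 2
  mu <- na * nb / 2
  if (na + nb <= 20) {
    combos <- utils::combn(na + nb, na)
    us <- colSums(matrix(rk[combos], nrow = na)) - na * (na + 1) / 2
    p <- mean(abs(us - mu) >= abs(U - mu) - 1e-9)
    return(list(U = U, p.value = p, method = "exact"))
  }
  n <- na + nb
  ties <- table(pooled)
  tie_corr <- sum(ties^3 - ties) / (n * (n - 1))
  sigma2 <- na * nb / 12 * (n + 1 - tie_corr)
  if (sigma2 <= 0) return(list(U = U, p.value = 1, method = "normal"))
  z <- (U - mu) / sqrt(sigma2)
  list(U = U, p.value = min(1, 2 * stats::pnorm(-abs(z))), method = "normal")
}

#' Two-way fixed-effects ANOVA over an AUC grid
#'
#' Main effects only (no interaction), as used to assess the influence of the
#' L2-regularization strength and the augmentation factor on test AUC. The
#' grid must be balanced with at least two replicates per cell.
#'
#' @param auc_table data.frame with columns `l2`, `augment`, `auc` (one row
#'   per replicate).
#' @return list with `p_l2`, `p_augment`, and the full `anova` table.
#' @export
two_way_anova <- function(auc_table) {
  stopifnot(all(c("l2", "augment", "auc") %in% names(auc_table)))
  tabn <- table(auc_table$l2, auc_table$augment)
  if (length(unique(as.vector(tabn))) != 1)
    stopf("unbalanced grid: cell sizes %s",
          paste(sort(unique(as.vector(tabn))), collapse = ", "))
  if (min(tabn) < 2) stopf("need >= 2 replicates per cell")
  df <- data.frame(l2 = factor(auc_table$l2),
                   augment = factor(auc_table$augment),
                   auc = auc_table$auc)
  if (stats::var(df$auc) == 0)
    return(list(p_l2 = 1, p_augment = 1, anova = NULL))
  fit <- stats::aov(auc ~ l2 + augment, data = df)
  an <- summary(fit)[[1]]
  ms <- an[["Mean Sq"]]
  pv <- an[["Pr(>F)"]]
  ms_res <- ms[length(ms)]
  # a mean square below numerical noise counts as zero: zero effect variance
  # -> p = 1 (F = 0); nonzero effect over zero residual variance -> p = 0
  eps <- 1e-9 * stats::var(df$auc)
  fix_p <- function(i) {
    if (ms[i] <= eps) 1
    else if (ms_res <= eps) 0
    else pv[i]
  }
  list(p_l2 = fix_p(1), p_augment = fix_p(2), anova = an)
}

#' Default SART age bands
#'
#' `<35, 35-37, 38-40, 41-42, >=43` years (inclusive bounds). The published
#' convention prints the last band as ">=42", which would overlap "41-42"; the
#' non-overlapping resolution starts the last band at 43.
#'
#' @return data.frame with `label`, `lo`, `hi`.
#' @export
sart_age_bands <- function() {
  data.frame(label = c("<35", "35-37", "38-40", "41-42", ">=43"),
             lo = c(-Inf, 35, 38, 41, 43),
             hi = c(34, 37, 40, 42, Inf))
}

#' Per-age-band subgroup AUC
#'
#' @param scores,labels as in [roc_auc()].
#' @param ages numeric ages (years), same length.
#' @param bands band table as from [sart_age_bands()].
#' @return named list, one entry per band: either a `roc_result` or a list
#'   with `undefined = TRUE` and the class counts for that band.
#' @export
subgroup_auc <- function(scores, labels, ages, bands = sart_age_bands()) {
  stopifnot(length(ages) == length(scores))
  out <- vector("list", nrow(bands))
  names(out) <- bands$label
  for (i in seq_len(nrow(bands))) {
    in_band <- ages >= bands$lo[i] & ages <= bands$hi[i]
    lb <- labels[in_band]
    if (sum(in_band) == 0 || length(unique(lb)) < 2) {
      out[[i]] <- list(undefined = TRUE, n = sum(in_band),
                       n_pos = sum(lb == 1), n_neg = sum(lb == 0))
    } else {
      out[[i]] <- roc_auc(scores[in_band], lb)
    }
  }
  out
}
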