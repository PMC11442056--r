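# Conventional embryo evaluation (CEE) feature transforms: the nine published
# univariate regression functions mapping each clinical/morphological factor to
# a probability-like scalar, plus refitting with standard errors and a
# multicollinearity screen.

.cee_env <- new.env(parent = emptyenv())

.spec_families <- list(
  scaled_logistic = c("b0", "b1", "k"),
  logistic = c("b0", "b1"),
  scaled_gaussian = c("sigma", "m", "k"),
  linear = c("b0", "b1")
)

#' Construct a univariate regression spec
#'
#' @param name factor name (snake_case).
#' @param family one of `"scaled_logistic"` (`k/(1+exp(b0+b1*x))`),
#'   `"logistic"` (`1/(1+exp(b0+b1*x))`), `"scaled_gaussian"`
#'   (`k/sqrt(2*pi*sigma^2) * exp(-(x-m)^2/(2*sigma^2))`), or `"linear"`
#'   (`b0 + b1*x`). Evaluations are clipped to `[0, 1]`.
#' @param coef named list/vector of coefficients for the family.
#' @param se named list of coefficient standard errors (may be partial).
#' @param marginal optional marginal-distribution description used by the
#'   synthetic generator.
#' @param label human-readable factor label.
#' @return an object of class `regression_spec`.
#' @export
regression_spec <- function(name, family, coef, se = list(), marginal = NULL,
                            label = name) {
  if (!family %in% names(.spec_families))
    stopf("unknown regression family '%s'", family)
  need <- .spec_families[[family]]
  coef <- as.list(coef)
  miss <- setdiff(need, names(coef))
  if (length(miss))
    stopf("factor '%s': missing coefficient(s) %s", name,
          paste(miss, collapse = ", "))
  if (family == "scaled_gaussian" && coef$sigma <= 0)
    stopf("factor '%s': sigma must be positive", name)
  if ("k" %in% need && coef$k <= 0)
    stopf("factor '%s': k must be positive", name)
  structure(list(name = name, family = family, coef = coef[need],
                 se = as.list(se), marginal = marginal, label = label),
            class = "regression_spec")
}

#' Evaluate a regression spec, clipped to `[0, 1]`
#'
#' @param spec a [regression_spec()].
#' @param x numeric vector of factor values.
#' @return numeric vector in `[0, 1]`.
#' @export
eval_regression <- function(spec, x) {
  stopifnot(inherits(spec, "regression_spec"), all(is.finite(x)))
  cf <- spec$coef
  y <- switch(spec$family,
    scaled_logistic = cf$k / (1 + exp(cf$b0 + cf$b1 * x)),
    logistic = 1 / (1 + exp(cf$b0 + cf$b1 * x)),
    scaled_gaussian = cf$k / sqrt(2 * pi * cf$sigma^2) *
      exp(-(x - cf$m)^2 / (2 * cf$sigma^2)),
    linear = cf$b0 + cf$b1 * x
  )
  clip01(y)
}

.spec_from_json <- function(f) {
  regression_spec(f$name, f$family, f$coef, se = f$se %||% list(),
                  marginal = f$marginal, label = f$label %||% f$name)
}

#' Read regression specs from a JSON file
#'
#' @param path JSON file with a `factors` array (see the packaged
#'   `table2_specs.json` for the schema).
#' @return list of `regression_spec` objects.
#' @export
read_specs <- function(path) {
  js <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame =
                              FALSE, simplifyMatrix = FALSE)
  if (is.null(js$factors)) stopf("schema error: no 'factors' array in %s", path)
  lapply(js$factors, .spec_from_json)
}

#' Write regression specs to JSON
#'
#' @param specs list of `regression_spec` objects.
#' @param path output file.
#' @export
write_specs <- function(specs, path) {
  factors <- lapply(specs, function(s)
    list(name = s$name, label = s$label, family = s$family, coef = s$coef,
         se = s$se, marginal = s$marginal))
  jsonlite::write_json(list(factors = factors), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' The packaged published regression specs (nine CEE factors)
#'
#' Loads (and caches) the coefficient table shipped with the package, in the
#' canonical factor order: female_age, n_prev_transfers, amh,
#' day3_blastomeres, day3_grade, cryo_day, icm_grade, te_grade, avg_diameter.
#'
#' @return list of nine `regression_spec` objects.
#' @export
default_cee_specs <- function() {
  if (is.null(.cee_env$specs)) {
    path <- system.file("extdata", "table2_specs.json", package = "embryo3d",
                        mustWork = TRUE)
    .cee_env$specs <- read_specs(path)
  }
  .cee_env$specs
}

#' Canonical CEE factor names in table order
#' @return character vector of length 9.
#' @export
cee_factor_names <- function()
  vapply(default_cee_specs(), `[[`, character(1), "name")

#' Encode one CEE record as the 9-vector of regression-function values
#'
#' @param record named list or 1-row data.frame holding the factors named by
#'   the specs (extra columns are ignored).
#' @param specs list of regression specs, one per factor.
#' @return named numeric vector in `[0, 1]`, in spec order.
#' @export
cee_feature_vector <- function(record, specs = default_cee_specs()) {
  record <- as.list(record)
  out <- vapply(specs, function(sp) {
    if (is.null(record[[sp$name]]) || is.na(record[[sp$name]]))
      stopf("CEE record is missing factor '%s'", sp$name)
    eval_regression(sp, as.numeric(record[[sp$name]]))
  }, numeric(1))
  names(out) <- vapply(specs, `[[`, character(1), "name")
  out
}

#' Encode a whole CEE table as an n x 9 feature matrix
#'
#' @param tab data.frame with the nine factor columns.
#' @param specs regression specs.
#' @return numeric matrix, rows = records, columns = factors in spec order.
#' @export
cee_feature_matrix <- function(tab, specs = default_cee_specs()) {
  mats <- vapply(specs, function(sp) {
    if (is.null(tab[[sp$name]]))
      stopf("CEE table is missing factor '%s'", sp$name)
    eval_regression(sp, as.numeric(tab[[sp$name]]))
  }, numeric(nrow(tab)))
  m <- matrix(mats, nrow = nrow(tab))
  colnames(m) <- vapply(specs, `[[`, character(1), "name")
  m
}

# ---- fitting ----------------------------------------------------------------

# Collapse (x, y) observations to an empirical outcome-rate curve:
# exact categories when x has few distinct values, decile bins otherwise.
.rate_points <- function(xs, ys, max_categories = 12L, n_bins = 10L) {
  ux <- sort(unique(xs))
  if (length(ux) <= max_categories) {
    grp <- match(xs, ux)
    xb <- ux
  } else {
    br <- unique(stats::quantile(xs, probs = seq(0, 1, length.out = n_bins + 1)))
    grp <- findInterval(xs, br, rightmost.closed = TRUE, all.inside = TRUE)
    grp <- match(grp, sort(unique(grp)))
    xb <- as.numeric(rowsum(xs, grp) / tabulate(grp))
  }
  nb <- tabulate(grp)
  rate <- as.numeric(rowsum(ys, grp) / nb)
  binary <- all(ys %in% c(0, 1))
  va <- if (binary) {
    rs <- (rate * nb + 0.5) / (nb + 1)  # smoothed for variance only
    rs * (1 - rs) / nb
  } else {
    v <- as.numeric(rowsum((ys - rate[grp])^2, grp)) / pmax(nb - 1, 1)
    v / nb
  }
  list(x = as.numeric(xb), rate = as.numeric(rate),
       var = pmax(as.numeric(va), 1e-6), n = nb)
}

.family_start <- function(family, pt) {
  x <- pt$x; r <- pt$rate
  rc <- pmin(pmax(r, 1e-3), 1 - 1e-3)
  switch(family,
    linear = {
      f <- stats::lm(r ~ x, weights = 1 / pt$var)
      list(b0 = unname(stats::coef(f)[1]), b1 = unname(stats::coef(f)[2]))
    },
    logistic = {
      f <- stats::lm(log(1 / rc - 1) ~ x)
      list(b0 = unname(stats::coef(f)[1]), b1 = unname(stats::coef(f)[2]))
    },
    scaled_logistic = {
      k0 <- min(1.05 * max(rc), 1)
      q <- pmin(pmax(r / k0, 1e-3), 1 - 1e-3)
      f <- stats::lm(log(1 / q - 1) ~ x)
      list(b0 = unname(stats::coef(f)[1]), b1 = unname(stats::coef(f)[2]),
           k = k0)
    },
    scaled_gaussian = {
      w <- pmax(r, 1e-6)
      m0 <- sum(x * w) / sum(w)
      s0 <- sqrt(pmax(sum((x - m0)^2 * w) / sum(w), 0.25))
      list(sigma = s0, m = m0, k = max(r) * sqrt(2 * pi * s0^2))
    }
  )
}

.family_eval_raw <- function(family, cf, x) {
  switch(family,
    scaled_logistic = cf$k / (1 + exp(cf$b0 + cf$b1 * x)),
    logistic = 1 / (1 + exp(cf$b0 + cf$b1 * x)),
    scaled_gaussian = cf$k / sqrt(2 * pi * cf$sigma^2) *
      exp(-(x - cf$m)^2 / (2 * cf$sigma^2)),
    linear = cf$b0 + cf$b1 * x
  )
}

#' Fit a univariate regression transform to outcome data
#'
#' Collapses the observations to an empirical outcome-rate-versus-x curve
#' (exact categories for ordinal factors, decile bins for continuous ones) and
#' fits the requested family by variance-weighted nonlinear least squares.
#' Coefficient standard errors come from the asymptotic covariance
#' `(J' W J)^{-1}` with `W` the inverse binomial rate variances, which remains
#' defined even for exactly identified fits (as many parameters as support
#' points). The fit is deterministic given the data.
#'
#' @param xs factor values.
#' @param ys binary outcomes (0/1) or probabilities.
#' @param family regression family name.
#' @param name factor name stored in the returned spec.
#' @param n_bins number of quantile bins for continuous factors.
#' @return a `regression_spec` with fitted `coef`, `se`, and a `fit` attribute
#'   (rate points, fitted values, weighted SSE, convergence info).
#' @export
fit_regression <- function(xs, ys, family, name = "factor", n_bins = 10L) {
  stopifnot(length(xs) == length(ys), length(xs) >= 10,
            all(is.finite(xs)), all(is.finite(ys)))
  if (!family %in% names(.spec_families))
    stopf("unknown regression family '%s'", family)
  pt <- .rate_points(xs, ys, n_bins = n_bins)
  pn <- .spec_families[[family]]
  if (length(pt$x) < length(pn))
    stopf("factor '%s': %d support points cannot identify %d parameters",
          name, length(pt$x), length(pn))
  w <- 1 / pt$var
  start <- .family_start(family, pt)
  th0 <- unlist(start[pn])

  obj <- function(th) {
    cf <- as.list(th); names(cf) <- pn
    if (family == "scaled_gaussian" && cf$sigma <= 0) return(1e12)
    r <- .family_eval_raw(family, cf, pt$x) - pt$rate
    sum(w * r * r)
  }
  opt <- stats::optim(th0, obj, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-12))
  if (!is.finite(opt$value))
    stopf("fit for '%s' did not converge (last objective %g)", name, opt$value)
  th <- opt$par
  cf <- as.list(th); names(cf) <- pn

  # numerical Jacobian of the model at the optimum
  J <- vapply(seq_along(th), function(j) {
    h <- max(1e-6, 1e-6 * abs(th[j]))
    tp <- th; tp[j] <- tp[j] + h
    tm <- th; tm[j] <- tm[j] - h
    cp <- as.list(tp); names(cp) <- pn
    cm <- as.list(tm); names(cm) <- pn
    (.family_eval_raw(family, cp, pt$x) -
        .family_eval_raw(family, cm, pt$x)) / (2 * h)
  }, numeric(length(pt$x)))
  J <- matrix(J, nrow = length(pt$x))
  jwj <- crossprod(J, J * w)
  cov <- tryCatch(solve(jwj), error = function(e)
    stopf("fit for '%s': singular information matrix (%s); last iterate: %s",
          name, conditionMessage(e), paste(signif(th, 4), collapse = ", ")))
  se <- sqrt(pmax(diag(cov), 0))
  names(se) <- pn

  sp <- regression_spec(name, family, cf, se = as.list(se))
  attr(sp, "fit") <- list(points = pt, fitted =
                            .family_eval_raw(family, cf, pt$x),
                          wsse = opt$value, convergence = opt$convergence)
  sp
}

#' Screen candidate factors for multicollinearity
#'
#' Greedily drops one factor from every pair whose absolute Spearman
#' correlation exceeds the threshold. When an outcome is supplied, the factor
#' with the smaller univariate Mann-Whitney p-value versus the outcome is
#' kept; otherwise the earlier column wins. Constant columns are excluded with
#' a warning.
#'
#' @param tab data.frame of candidate factor columns (numeric).
#' @param outcome optional binary outcome vector used for the keep preference.
#' @param r_threshold absolute Spearman correlation above which a pair is
#'   considered collinear (default 0.8).
#' @return list with `retained` (character vector) and `dropped`
#'   (data.frame: dropped, kept, correlation).
#' @export
multicollinearity_screen <- function(tab, outcome = NULL, r_threshold = 0.8) {
  stopifnot(ncol(tab) >= 2)
  keep <- names(tab)
  const <- vapply(tab, function(v) stats::sd(v) == 0 || all(v == v[1]),
                  logical(1))
  if (any(const)) {
    warning(sprintf("excluding constant column(s): %s",
                    paste(keep[const], collapse = ", ")), call. = FALSE)
    keep <- keep[!const]
  }
  mwp <- function(col) {
    if (is.null(outcome)) return(NA_real_)
    mann_whitney(tab[[col]][outcome == 1], tab[[col]][outcome == 0])$p.value
  }
  dropped <- data.frame(dropped = character(), kept = character(),
                        correlation = numeric())
  repeat {
    if (length(keep) < 2) break
    cm <- abs(stats::cor(tab[keep], method = "spearman"))
    diag(cm) <- 0
    mx <- max(cm)
    if (mx <= r_threshold) break
    ij <- which(cm == mx, arr.ind = TRUE)[1, ]
    a <- keep[ij[1]]; b <- keep[ij[2]]
    pa <- mwp(a); pb <- mwp(b)
    drop <- if (!is.na(pa) && !is.na(pb) && pa != pb) {
      if (pa < pb) b else a
    } else b
    kept <- setdiff(c(a, b), drop)
    dropped <- rbind(dropped, data.frame(dropped = drop, kept = kept,
                                         correlation = mx))
    keep <- setdiff(keep, drop)
  }
  list(retained = keep, dropped = dropped)
}
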