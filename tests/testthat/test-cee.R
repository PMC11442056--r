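# The nine univariate CEE regression transforms: evaluation, fitting,
# multicollinearity screening.

specs <- default_cee_specs()
names(specs) <- cee_factor_names()

test_that("eval_regression reproduces hand-computed published values", {
  # linear families evaluate exactly
  expect_equal(eval_regression(specs$te_grade, 1), 0.791 - 0.182 * 1)   # 0.609
  expect_equal(eval_regression(specs$cryo_day, 1), 0.852 - 0.161 * 1)   # 0.691
  expect_equal(eval_regression(specs$icm_grade, 2), 0.789 - 0.200 * 2)

  # scaled logistic / gaussian against direct arithmetic
  expect_equal(eval_regression(specs$female_age, 35),
               0.506 / (1 + exp(-12.112 + 0.286 * 35)), tolerance = 1e-12)
  expect_equal(eval_regression(specs$day3_blastomeres, 8),
               6.737 / sqrt(2 * pi * 4.813^2) *
                 exp(-(8 - 10.063)^2 / (2 * 4.813^2)), tolerance = 1e-12)

  # constant linear family clips into [0, 1]
  sp <- regression_spec("c", "linear", list(b0 = 1.7, b1 = 0))
  expect_equal(eval_regression(sp, c(-50, 0, 50)), rep(1, 3))
})

test_that("cee_feature_vector equals the componentwise oracle", {
  rec <- list(female_age = 34, n_prev_transfers = 1, amh = 2.5,
              day3_blastomeres = 8, day3_grade = 2, cryo_day = 1,
              icm_grade = 1, te_grade = 1, avg_diameter = 188)
  fv <- cee_feature_vector(rec, default_cee_specs())
  oracle <- vapply(names(rec), function(nm)
    eval_regression(specs[[nm]], rec[[nm]]), numeric(1))
  expect_equal(unname(fv[names(rec)]), unname(oracle))
  expect_true(all(fv >= 0 & fv <= 1))

  # identical records give identical vectors; a missing factor errors by name
  expect_identical(fv, cee_feature_vector(rec, default_cee_specs()))
  expect_error(cee_feature_vector(rec[-8], default_cee_specs()), "te_grade")
})

test_that("transforms stay in [0,1] and are monotone over the factor range", {
  for (sp in specs) {
    m <- sp$marginal
    lo <- if (!is.null(m$min)) m$min else min(m$support)
    hi <- if (!is.null(m$max)) m$max else max(m$support)
    grid <- seq(lo - 10, hi + 10, length.out = 201)
    y <- eval_regression(sp, grid)
    expect_true(all(y >= 0 & y <= 1), info = sp$name)
    b1 <- sp$coef$b1
    dy <- diff(eval_regression(sp, seq(lo, hi, length.out = 101)))
    if (sp$family == "linear" || sp$family == "logistic") {
      if (b1 < 0 && sp$family == "linear") expect_true(all(dy <= 1e-12),
                                                       info = sp$name)
      if (b1 < 0 && sp$family == "logistic") expect_true(all(dy >= -1e-12),
                                                         info = sp$name)
    }
    if (sp$family == "scaled_logistic" && b1 > 0)
      expect_true(all(dy <= 1e-12), info = sp$name)
  }
})

test_that("fit_regression recovers generating coefficients and handles degenerate input", {
  # constant target, linear family
  set.seed(3)
  xs <- runif(200, 0, 10)
  fit <- fit_regression(xs, rep(0.5, 200), "linear", name = "const")
  expect_equal(fit$coef$b0, 0.5, tolerance = 1e-6)
  expect_equal(fit$coef$b1, 0, tolerance = 1e-6)

  # parameter recovery for the trophectoderm linear spec
  set.seed(4)
  xs <- sample(1:3, 5000, replace = TRUE)
  ys <- rbinom(5000, 1, eval_regression(specs$te_grade, xs))
  fit <- fit_regression(xs, ys, "linear", name = "te_grade")
  expect_lt(abs(fit$coef$b0 - 0.791), 3 * max(fit$se$b0, 0.018))
  expect_lt(abs(fit$coef$b1 + 0.182), 3 * max(fit$se$b1, 0.008))

  # scaled gaussian recovers the published mode location
  set.seed(5)
  xs <- pmin(pmax(round(rnorm(5000, 8.56, 2.01)), 3), 16)
  ys <- rbinom(5000, 1, eval_regression(specs$day3_blastomeres, xs))
  fit <- fit_regression(xs, ys, "scaled_gaussian", name = "blastomeres")
  expect_lt(abs(fit$coef$m - 10.063), 3 * max(fit$se$m, 0.874))

  expect_error(fit_regression(1:5, rep(0.5, 5), "linear"), "")
})

test_that("multicollinearity screen keeps independent factors, drops copies", {
  set.seed(6)
  tab <- as.data.frame(matrix(rnorm(1000 * 5), 1000, 5))
  names(tab) <- paste0("f", 1:5)
  res <- multicollinearity_screen(tab)
  expect_setequal(res$retained, names(tab))

  tab$f6 <- tab$f1 + 1e-9 * rnorm(1000)   # near-perfect copy
  outcome <- rbinom(1000, 1, plogis(tab$f1))
  res2 <- multicollinearity_screen(tab, outcome = outcome)
  expect_equal(sum(c("f1", "f6") %in% res2$retained), 1)
  expect_equal(nrow(res2$dropped), 1)
  expect_gt(res2$dropped$correlation[1], 0.99)

  # the nine generated CEE factors are independent by construction
  cee <- generate_cee_table(1000, seed = 8)
  res3 <- multicollinearity_screen(cee)
  expect_setequal(res3$retained, cee_factor_names())

  tab$f7 <- 1
  expect_warning(multicollinearity_screen(tab), "constant")
})
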