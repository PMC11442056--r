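# Synthetic blastocyst phantom: seeded generator of tomographic slice stacks
# with ground-truth foreground masks, CEE tables with published marginals, and
# implantation outcomes driven jointly by the CEE factors and a latent image
# quality, so that both branches of the fusion classifier carry signal.

#' Phantom rendering parameters
#'
#' Geometry follows the acquisition setup this package targets: 11 tomographic
#' slices at 10-um vertical pitch, 364 x 364 px frames, and a 280-um culture
#' micro-well whose circular wall spans the image frame. The blastocyst is
#' rendered as a sphere cross-sectioned per slice: a bright trophectoderm
#' shell, a dark blastocoel cavity, and a bright inner-cell-mass (ICM) blob on
#' slices near the ICM height.
#'
#' @param image_px frame side in pixels (must be a multiple of 4 and >= 64).
#' @param n_slices odd number of slices; the centre slice is the equator.
#' @param slice_pitch_um vertical pitch between slices (um).
#' @param well_diameter_um well diameter (um); mapped to the full frame width.
#' @param blastocyst_diameter_um blastocyst diameter (um). Must be smaller
#'   than the well diameter.
#' @param shell_thickness_um trophectoderm shell thickness (um).
#' @param icm_radius_um inner-cell-mass radius (um).
#' @param irregularity shell waviness in `[0, 1]`; 0 renders a perfect sphere.
#' @param icm_scale multiplicative ICM size factor.
#' @param noise_sd additive Gaussian noise SD (intensity units, image in 0..1).
#' @param blur_sigma_by_offset function mapping |vertical offset| in um to a
#'   Gaussian blur sigma in pixels (out-of-focus model).
#' @param seed integer seed; the same seed reproduces the stack bit-identically.
#' @return an object of class `phantom_params`.
#' @export
phantom_params <- function(image_px = 364L, n_slices = 11L,
                           slice_pitch_um = 10, well_diameter_um = 280,
                           blastocyst_diameter_um = 180.8,
                           shell_thickness_um = 12, icm_radius_um = 28,
                           irregularity = 0.5, icm_scale = 1,
                           noise_sd = 0.02,
                           blur_sigma_by_offset = function(dz_um)
                             0.5 + 0.015 * dz_um,
                           seed = 1L) {
  image_px <- as.integer(image_px)
  n_slices <- as.integer(n_slices)
  if (image_px < 64L || image_px %% 4L != 0L)
    stopf("image_px must be >= 64 and divisible by 4, got %d", image_px)
  if (n_slices %% 2L == 0L) stopf("n_slices must be odd, got %d", n_slices)
  if (blastocyst_diameter_um >= well_diameter_um)
    stopf("geometry error: blastocyst diameter (%.1f um) must be < well diameter (%.1f um)",
          blastocyst_diameter_um, well_diameter_um)
  structure(list(
    image_px = image_px, n_slices = n_slices, slice_pitch_um = slice_pitch_um,
    well_diameter_um = well_diameter_um,
    blastocyst_diameter_um = blastocyst_diameter_um,
    shell_thickness_um = shell_thickness_um, icm_radius_um = icm_radius_um,
    irregularity = irregularity, icm_scale = icm_scale, noise_sd = noise_sd,
    blur_sigma_by_offset = blur_sigma_by_offset, seed = as.integer(seed)
  ), class = "phantom_params")
}

# Background intensity levels (invented rendering model; see the methods
# vignette for rationale). The well-frame ring is the bright annulus the
# segmenter must learn to discard.
.bg_levels <- list(outside = 0.45, ring = 0.80, floor = 0.30,
                   shell = 0.85, cavity = 0.18, icm = 0.95,
                   ring_width_um = 9)

# Render the background-only frame (well floor + wall ring + outside).
.render_background <- function(px, well_d_um) {
  s <- px / well_d_um                    # pixels per um
  c0 <- (px + 1) / 2
  g <- seq_len(px) - c0
  rho <- sqrt(outer(g^2, g^2, "+"))
  r_well <- px / 2
  rw <- .bg_levels$ring_width_um * s
  img <- matrix(.bg_levels$floor, px, px)
  img[rho > r_well] <- .bg_levels$outside
  img[rho > r_well - rw & rho <= r_well] <- .bg_levels$ring
  img
}

#' Generate one synthetic tomographic slice stack with ground-truth masks
#'
#' Each slice renders the annular well-frame ring plus the blastocyst
#' cross-section at that slice's height (shell ring, dark cavity, ICM blob near
#' the ICM height), with slice-offset-dependent Gaussian blur and additive
#' noise. Masks mark exactly the blastocyst cross-section (shell + interior),
#' never the well frame.
#'
#' @param params a [phantom_params()] object.
#' @param embryo_id identifier stored in the returned stack.
#' @param return_noiseless also return the unblurred, noise-free foreground and
#'   background renders (used by correctness tests).
#' @return a list with `stack` (a `slice_stack`) and `masks` (list of 0/1
#'   matrices), plus `noiseless`/`background` when requested.
#' @export
generate_stack <- function(params, embryo_id = "embryo_1",
                           return_noiseless = FALSE) {
  stopifnot(inherits(params, "phantom_params"))
  p <- params
  if (p$blastocyst_diameter_um >= p$well_diameter_um)
    stopf("geometry error: blastocyst does not fit inside the well")
  set.seed(derive_seed(p$seed, "stack", embryo_id))

  px <- p$image_px
  s <- px / p$well_diameter_um
  c0 <- (px + 1) / 2
  g <- seq_len(px) - c0
  X <- matrix(g, px, px)                  # row offset
  Y <- matrix(g, px, px, byrow = TRUE)    # col offset
  rho <- sqrt(X^2 + Y^2)
  theta <- atan2(Y, X)

  R_um <- p$blastocyst_diameter_um / 2
  centre <- (p$n_slices - 1) / 2          # 0-based centre slice
  amp <- 0.08 * p$irregularity
  ph1 <- stats::runif(1, 0, 2 * pi)
  ph2 <- stats::runif(1, 0, 2 * pi)
  # ICM placed above the equator, offset from the axis
  icm_r_um <- p$icm_radius_um * p$icm_scale
  icm_z_um <- 0.35 * R_um
  icm_phi <- stats::runif(1, 0, 2 * pi)
  icm_d_px <- 0.45 * R_um * s
  icm_x <- icm_d_px * cos(icm_phi)
  icm_y <- icm_d_px * sin(icm_phi)
  rho_icm <- sqrt((X - icm_x)^2 + (Y - icm_y)^2)

  bg <- .render_background(px, p$well_diameter_um)
  slices <- vector("list", p$n_slices)
  masks <- vector("list", p$n_slices)
  clean <- if (return_noiseless) vector("list", p$n_slices)

  for (i in seq_len(p$n_slices)) {
    dz <- (i - 1 - centre) * p$slice_pitch_um
    r2 <- R_um^2 - dz^2
    img <- bg
    mask <- matrix(0L, px, px)
    if (r2 > 0) {
      r_base <- sqrt(r2) * s
      # wavy shell boundary; irregularity shrinks with latent quality
      r_out <- r_base * (1 + amp * sin(3 * theta + ph1) +
                           0.5 * amp * sin(5 * theta + ph2))
      t_px <- p$shell_thickness_um * s
      inside <- rho <= r_out
      shell <- inside & rho > pmax(r_out - t_px, 0)
      cavity <- inside & !shell
      img[cavity] <- .bg_levels$cavity
      img[shell] <- .bg_levels$shell
      ricm2 <- icm_r_um^2 - (dz - icm_z_um)^2
      if (ricm2 > 0) {
        icm <- cavity & rho_icm <= sqrt(ricm2) * s
        img[icm] <- .bg_levels$icm
      }
      mask[inside] <- 1L
    }
    if (return_noiseless) clean[[i]] <- img
    sig <- p$blur_sigma_by_offset(abs(dz))
    img <- gaussian_blur(img, sig)
    img <- img + stats::rnorm(px * px, sd = p$noise_sd)
    slices[[i]] <- quantize16(img)
    masks[[i]] <- mask
  }

  out <- list(stack = slice_stack(embryo_id, slices,
                                  pixel_size_um = 1 / s,
                                  slice_pitch_um = p$slice_pitch_um),
              masks = masks)
  if (return_noiseless) {
    out$noiseless <- clean
    out$background <- bg
  }
  out
}

# ---- CEE table generation ---------------------------------------------------

# Mean of a normal truncated to [lo, hi].
.truncnorm_mean <- function(mu, sd, lo, hi) {
  a <- (lo - mu) / sd
  b <- (hi - mu) / sd
  z <- stats::pnorm(b) - stats::pnorm(a)
  mu + sd * (stats::dnorm(a) - stats::dnorm(b)) / z
}

# Pre-truncation mean such that the truncated mean equals `target`.
.match_truncnorm_mu <- function(target, sd, lo, hi) {
  stats::uniroot(function(m) .truncnorm_mean(m, sd, lo, hi) - target,
                 lower = target - 3 * sd, upper = target + 3 * sd,
                 tol = 1e-9)$root
}

# Inverse-CDF sampling of the truncated normal from uniform quantiles.
.qtruncnorm <- function(u, mu, sd, lo, hi) {
  pa <- stats::pnorm(lo, mu, sd)
  pb <- stats::pnorm(hi, mu, sd)
  stats::qnorm(pa + u * (pb - pa), mu, sd)
}

# Maximum-entropy categorical distribution on `support` with a given mean:
# the exponential tilt p_i proportional to exp(theta * i).
.maxent_probs <- function(support, mean_target) {
  if (mean_target <= min(support) || mean_target >= max(support))
    stopf("target mean %.3f outside category support", mean_target)
  f <- function(th) {
    p <- exp(th * support)
    sum(p * support) / sum(p) - mean_target
  }
  th <- stats::uniroot(f, lower = -20, upper = 20, tol = 1e-10)$root
  p <- exp(th * support)
  p / sum(p)
}

# Draw one factor column from its published marginal. `u` optionally supplies
# the uniform quantiles (used to tie the diameter to the latent quality).
.sample_marginal <- function(marg, n, u = NULL) {
  if (is.null(u)) u <- stats::runif(n)
  switch(marg$type,
    continuous = ,
    count = {
      mu <- .match_truncnorm_mu(marg$mean, marg$sd, marg$min, marg$max)
      x <- .qtruncnorm(u, mu, marg$sd, marg$min, marg$max)
      if (marg$type == "count") x <- pmin(pmax(round(x), marg$min), marg$max)
      x
    },
    ordinal = {
      probs <- if (!is.null(marg$probs)) marg$probs else
        .maxent_probs(marg$support, marg$mean)
      marg$support[findInterval(u, cumsum(probs), left.open = TRUE) + 1L]
    },
    stopf("unknown marginal type '%s'", marg$type)
  )
}

#' Generate a synthetic CEE table with published marginal distributions
#'
#' Continuous factors are truncated normals whose post-truncation mean is
#' moment-matched to the published cohort mean; ordinal grades use the
#' maximum-entropy categorical distribution with the published mean (the
#' cryopreservation day uses the published day-5/6/7 counts directly). Factors
#' are generated independently; no joint correlation structure is claimed.
#'
#' @param n number of records.
#' @param seed integer seed.
#' @param specs list of regression specs carrying the marginals (defaults to
#'   the packaged published table).
#' @return a `data.frame` with the nine CEE columns in canonical order.
#' @export
generate_cee_table <- function(n, seed = 1L, specs = default_cee_specs()) {
  stopifnot(n >= 1)
  set.seed(derive_seed(seed, "cee_table"))
  cols <- lapply(specs, function(sp) .sample_marginal(sp$marginal, n))
  names(cols) <- vapply(specs, `[[`, character(1), "name")
  as.data.frame(cols)
}

#' Implantation probability and outcome for a synthetic embryo
#'
#' The implantation probability is the convex combination
#' `(1 - weight_image) * mean(f_i(x_i)) + weight_image * latent_quality`,
#' where `f_i` are the nine univariate regression transforms (each clipped to
#' `[0, 1]`). The label is a Bernoulli draw at that probability.
#'
#' @param cee a single CEE record (1-row data.frame or named list).
#' @param latent_quality latent image quality in `[0, 1]`.
#' @param specs the nine regression specs.
#' @param weight_image weight of the image-borne signal in `[0, 1]`.
#' @param seed integer seed for the Bernoulli draw.
#' @return list with `probability` and binary `outcome`.
#' @export
generate_outcome <- function(cee, latent_quality, specs = default_cee_specs(),
                             weight_image = 0.5, seed = 1L) {
  stopifnot(weight_image >= 0, weight_image <= 1,
            latent_quality >= 0, latent_quality <= 1)
  fv <- cee_feature_vector(cee, specs)
  p <- (1 - weight_image) * clip01(mean(fv)) + weight_image * latent_quality
  set.seed(derive_seed(seed, "outcome"))
  list(probability = p, outcome = as.integer(stats::runif(1) < p))
}

#' Generate a full synthetic cohort
#'
#' Draws, per embryo: a CEE record; a latent quality
#' `q = plogis(30 * (0.6 * u_diam + 0.4 * u_shape - 0.5))`, where `u_diam` is
#' the quantile of the drawn blastocyst diameter (the strongest published
#' morphometric factor) and `u_shape` independently drives inner-cell-mass
#' size and shell regularity (so the image carries signal beyond the
#' tabulated diameter, and the 3D view sees more of it than the centre slice
#' does: the ICM sits off the equator); the rendered slice stack with masks;
#' and the implantation outcome. The logistic sharpening makes the cohort a
#' mixture of clearly viable and clearly compromised embryos with a narrow
#' ambiguous band, placing the task's Bayes AUC near the scale reported for
#' clinical implantation prediction (see the methods vignette).
#'
#' @param n number of embryos.
#' @param seed integer run seed.
#' @param specs regression specs (with marginals).
#' @param weight_image image weight of the outcome model.
#' @param image_px frame side in pixels for rendering.
#' @param n_slices slices per stack.
#' @param render generate slice stacks (set `FALSE` for CEE-only cohorts).
#' @return list of `synthetic_embryo` objects: each has `stack`, `masks`,
#'   `cee` (1-row data.frame), `outcome`, `latent_quality`, `probability`.
#' @export
generate_cohort <- function(n, seed = 1L, specs = default_cee_specs(),
                            weight_image = 0.5, image_px = 364L,
                            n_slices = 11L, render = TRUE) {
  cee <- generate_cee_table(n, seed = derive_seed(seed, "cohort_cee"),
                            specs = specs)
  set.seed(derive_seed(seed, "cohort_latent"))
  u_shape <- stats::runif(n)
  u_diam <- stats::runif(n)
  dm <- specs[[which(vapply(specs, `[[`, character(1), "name") ==
                       "avg_diameter")]]$marginal
  mu <- .match_truncnorm_mu(dm$mean, dm$sd, dm$min, dm$max)
  diam <- .qtruncnorm(u_diam, mu, dm$sd, dm$min, dm$max)
  cee$avg_diameter <- diam
  quality <- stats::plogis(30 * (0.6 * u_diam + 0.4 * u_shape - 0.5))

  lapply(seq_len(n), function(i) {
    id <- sprintf("embryo_%04d", i)
    rec <- cee[i, , drop = FALSE]
    out <- generate_outcome(rec, quality[i], specs, weight_image,
                            seed = derive_seed(seed, "outcome", i))
    emb <- list(embryo_id = id, cee = rec, outcome = out$outcome,
                probability = out$probability, latent_quality = quality[i])
    if (render) {
      # keep the rendered blastocyst inside the well even for extreme draws
      d_render <- min(diam[i], 0.92 * 280)
      par_i <- phantom_params(
        image_px = image_px, n_slices = n_slices,
        blastocyst_diameter_um = d_render,
        irregularity = 1 - u_shape[i],
        icm_scale = 0.3 + 1.4 * u_shape[i],
        seed = derive_seed(seed, "phantom", i))
      sm <- generate_stack(par_i, embryo_id = id)
      emb$stack <- sm$stack
      emb$masks <- sm$masks
    }
    structure(emb, class = "synthetic_embryo")
  })
}
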