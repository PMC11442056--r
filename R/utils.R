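# Shared helpers.

#' @useDynLib embryo3d, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

clip01 <- function(x) pmin(pmax(x, 0), 1)

#' Derive a stage-local seed from a run seed and a tag
#'
#' All stochastic stages draw their RNG seed from the single run seed through
#' this stable string hash, so adding a stage never perturbs another stage's
#' stream. Result is always in `[0, 2^31 - 2]`.
#'
#' @param seed integer run seed.
#' @param ... character or numeric tags identifying the stage.
#' @return an integer seed.
#' @export
derive_seed <- function(seed, ...) {
  tags <- paste(vapply(list(...), as.character, character(1)), collapse = "/")
  h <- as.double(seed) %% 2147483647
  for (c in utf8ToInt(tags)) h <- (h * 31 + c) %% 2147483647
  as.integer(h)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# Quantize intensities to the 16-bit grid used by the TIFF writer, so a
# write/read round trip is bit-identical.
quantize16 <- function(x) round(clip01(x) * 65535) / 65535

# Row/column weight matrix for exact area-weighted 1-d resampling from
# `src` to `dst` samples: out = W %*% x with rows summing to 1.
resize_weights <- function(src, dst) {
  w <- matrix(0, dst, src)
  scale <- src / dst
  for (i in seq_len(dst)) {
    lo <- (i - 1) * scale
    hi <- i * scale
    j0 <- floor(lo) + 1
    j1 <- ceiling(hi)
    for (j in j0:min(j1, src)) {
      ov <- min(hi, j) - max(lo, j - 1)
      if (ov > 0) w[i, j] <- ov / scale
    }
  }
  w
}

# Separable Gaussian blur of a matrix (reflecting would be nicer at borders
# but renormalised truncation is fine for phantom rendering).
gaussian_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  n <- nrow(m)
  b <- matrix(0, n, n)
  for (o in -r:r) {
    idx <- pmin(pmax(seq_len(n) + o, 1L), n)
    b <- b + k[o + r + 1] * m[idx, , drop = FALSE]
  }
  b2 <- matrix(0, n, n)
  for (o in -r:r) {
    idx <- pmin(pmax(seq_len(n) + o, 1L), n)
    b2 <- b2 + k[o + r + 1] * b[, idx, drop = FALSE]
  }
  b2
}

# In-plane bilinear rotation of a square matrix about its centre, zero fill.
# Uses cospi/sinpi so right-angle rotations are exact index permutations.
rotate_matrix <- function(m, angle_deg) {
  n <- nrow(m)
  stopifnot(n == ncol(m), is.finite(angle_deg))
  ct <- cospi(angle_deg / 180)
  st <- sinpi(angle_deg / 180)
  c0 <- (n + 1) / 2
  g <- seq_len(n) - c0
  # inverse map: source = R(-angle) %*% target
  xs <- outer(g * ct, -g * st, "+") + c0   # row coordinate in source
  ys <- outer(g * st, g * ct, "+") + c0    # col coordinate in source
  x0 <- floor(xs); y0 <- floor(ys)
  fx <- xs - x0; fy <- ys - y0
  out <- numeric(n * n)
  pick <- function(ix, iy) {
    ok <- ix >= 1 & ix <= n & iy >= 1 & iy <= n
    v <- numeric(length(ix))
    v[ok] <- m[cbind(ix[ok], iy[ok])]
    v
  }
  v00 <- pick(x0, y0); v10 <- pick(x0 + 1, y0)
  v01 <- pick(x0, y0 + 1); v11 <- pick(x0 + 1, y0 + 1)
  out <- (1 - fx) * (1 - fy) * v00 + fx * (1 - fy) * v10 +
    (1 - fx) * fy * v01 + fx * fy * v11
  matrix(out, n, n)
}

json_hash <- function(x) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, force = TRUE),
             f)
  unname(tools::md5sum(f))
}
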