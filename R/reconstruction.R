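# Slice-stack and 3D-volume containers, volume reconstruction from masked
# stacks, and the in-plane rotation augmentation used during training.

#' One embryo's ordered tomographic slice stack
#'
#' @param embryo_id identifier.
#' @param slices list of equal-size square numeric matrices, ordered
#'   bottom-to-top.
#' @param pixel_size_um lateral pixel size (um).
#' @param slice_pitch_um vertical pitch between slices (um).
#' @return an object of class `slice_stack`.
#' @export
slice_stack <- function(embryo_id, slices, pixel_size_um = NA_real_,
                        slice_pitch_um = 10) {
  stopifnot(length(slices) >= 1)
  d1 <- dim(slices[[1]])
  for (s in slices) {
    if (!is.matrix(s) || !all(dim(s) == d1) || d1[1] != d1[2])
      stopf("all slices must be square matrices of identical size")
    if (!all(is.finite(s))) stopf("slice intensities must be finite")
  }
  structure(list(embryo_id = embryo_id, slices = slices,
                 pixel_size_um = pixel_size_um,
                 slice_pitch_um = slice_pitch_um),
            class = "slice_stack")
}

#' @export
print.slice_stack <- function(x, ...) {
  cat(sprintf("slice_stack '%s': %d slices of %d x %d px (pitch %.1f um)\n",
              x$embryo_id, length(x$slices), nrow(x$slices[[1]]),
              ncol(x$slices[[1]]), x$slice_pitch_um))
  invisible(x)
}

#' A reconstructed 3D volume (classifier input)
#'
#' @param embryo_id identifier.
#' @param voxels numeric array `n_slices x H x W`, values in `[0, 1]`.
#' @param intensity_scale description of the normalization applied.
#' @return object of class `volume3d`.
#' @export
volume3d <- function(embryo_id, voxels, intensity_scale = "minmax[0,1]") {
  stopifnot(is.array(voxels), length(dim(voxels)) == 3, all(is.finite(voxels)))
  structure(list(embryo_id = embryo_id, voxels = voxels,
                 intensity_scale = intensity_scale), class = "volume3d")
}

#' Reconstruct the classifier's 3D input volume from a (masked) stack
#'
#' Each slice is downsampled to `target_px` by exact area-weighted
#' interpolation, the slices are stacked bottom-to-top, and intensities are
#' min-max normalized over the whole volume to `[0, 1]`. A constant volume
#' (min = max) maps to all zeros and is flagged degenerate.
#'
#' @param masked a `slice_stack` (normally after background elimination).
#' @param target_px output side length (default 111).
#' @return a `volume3d` with voxel array `n_slices x target_px x target_px`;
#'   attribute `degenerate` is TRUE for constant input.
#' @export
reconstruct_volume <- function(masked, target_px = 111L) {
  stopifnot(inherits(masked, "slice_stack"))
  src <- nrow(masked$slices[[1]])
  if (src < target_px)
    stopf("slice size %d is smaller than target %d", src, target_px)
  W <- resize_weights(src, target_px)
  Wt <- t(W)
  n <- length(masked$slices)
  vox <- array(0, c(n, target_px, target_px))
  for (i in seq_len(n)) vox[i, , ] <- W %*% masked$slices[[i]] %*% Wt
  lo <- min(vox); hi <- max(vox)
  # constant input (up to resampling round-off) has no contrast to normalize
  degenerate <- (hi - lo) <= 1e-12 * max(abs(hi), abs(lo), 1)
  vox <- if (degenerate) array(0, dim(vox)) else (vox - lo) / (hi - lo)
  v <- volume3d(masked$embryo_id, vox,
                intensity_scale = sprintf("minmax from [%g, %g]", lo, hi))
  attr(v, "degenerate") <- degenerate
  v
}

#' Rotate a volume about the optical axis
#'
#' Applies the same in-plane 2D rotation (bilinear interpolation, zero fill)
#' to every slice, i.e. a rigid rotation of the volume about the vertical
#' axis, which preserves vertical coherence. Multiples of 90 degrees are exact
#' index permutations. Positive angles map the row axis onto the column axis
#' (`y[i,j] = x[n+1-j, i]` at 90 degrees).
#'
#' @param vol a `volume3d`.
#' @param angle_deg rotation angle in degrees.
#' @return the rotated `volume3d`.
#' @export
rotate_volume <- function(vol, angle_deg) {
  stopifnot(inherits(vol, "volume3d"), is.finite(angle_deg))
  d <- dim(vol$voxels)
  out <- vol$voxels
  for (i in seq_len(d[1])) {
    out[i, , ] <- rotate_matrix(matrix(vol$voxels[i, , ], d[2], d[3]),
                                angle_deg)
  }
  volume3d(vol$embryo_id, clip01(out), vol$intensity_scale)
}

#' Rotation-augment a training set of volumes
#'
#' Returns each original volume plus `times - 1` copies rotated by seeded
#' uniform-random angles in `[0, 360)`. Labels (and CEE rows, if given) are
#' copied. Apply to training folds only, never to validation or test data.
#'
#' @param volumes list of `volume3d`.
#' @param labels binary labels, one per volume.
#' @param times total multiplication factor (>= 1); `times = 1` returns the
#'   input unchanged.
#' @param seed integer seed for the angle sequence.
#' @param cee optional CEE feature matrix (rows follow `volumes`).
#' @return list with `volumes`, `labels`, `ids`, `angles`, and `cee` (when
#'   supplied), of size `times * length(volumes)`.
#' @export
augment_dataset <- function(volumes, labels, times, seed = 1L, cee = NULL) {
  if (times < 1) stopf("times must be >= 1, got %s", times)
  stopifnot(length(volumes) == length(labels))
  times <- as.integer(times)
  n <- length(volumes)
  ids <- vapply(volumes, `[[`, character(1), "embryo_id")
  if (times == 1L)
    return(list(volumes = volumes, labels = labels, ids = ids,
                angles = rep(0, n), cee = cee))
  set.seed(derive_seed(seed, "augment"))
  angles <- stats::runif(n * (times - 1L), 0, 360)
  out_vol <- vector("list", n * times)
  out_vol[seq_len(n)] <- volumes
  k <- n
  for (t in seq_len(times - 1L)) {
    for (i in seq_len(n)) {
      k <- k + 1L
      out_vol[[k]] <- rotate_volume(volumes[[i]], angles[(t - 1L) * n + i])
    }
  }
  rep_idx <- rep(seq_len(n), times)
  list(volumes = out_vol, labels = labels[rep_idx], ids = ids[rep_idx],
       angles = c(rep(0, n), angles),
       cee = if (!is.null(cee)) cee[rep_idx, , drop = FALSE])
}
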