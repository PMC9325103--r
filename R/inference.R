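## Full-volume inference: sliding-window patch prediction with per-pixel
## majority voting, and nearest-neighbour restoration of the predicted
## labels to the native acquisition grid.

## patch anchor offsets (0-based) covering 1..n with a given stride;
## the last patch is clamped to the border so every pixel is covered
.window_offsets <- function(n, patch, stride) {
  off <- seq(0L, n - patch, by = stride)
  if (off[length(off)] != n - patch) off <- c(off, n - patch)
  as.integer(off)
}

#' Segment a CT volume by sliding-window majority voting
#'
#' Runs the trained network over overlapping patches (stride in pixels,
#' default half a patch) of every coronal slice. Each covering patch casts
#' one vote per pixel — its argmax class — and the final label is the
#' majority vote, ties broken by the highest accumulated probability.
#' Volumes smaller than a patch in-plane are padded reflectively and the
#' prediction cropped back.
#'
#' @param model a trained `seg_model`
#' @param vol a [ct_volume()]; either raw HU (default) or already resampled
#'   and windowed (`prepared = TRUE`)
#' @param stride window stride in pixels, in `[1, patch]`
#' @param prepared set when `vol` is already on the isometric grid with
#'   windowed intensities
#' @param target_mm isometric grid pitch used when preparing (default 1)
#' @return a predicted [label_volume()] on the isometric grid
#' @export
predict_volume <- function(model, vol, stride = 64L, prepared = FALSE,
                           target_mm = 1.0) {
  stopifnot(inherits(model, "seg_model"), inherits(vol, "ct_volume"))
  patch <- model$config$patch_size
  if (stride < 1L || stride > patch) stop("stride must lie in [1, patch]")
  if (!prepared) vol <- window_hu(resample_isometric(vol, target_mm))
  d <- dim(vol$voxels)
  pad_r <- max(0L, patch - d[1]); pad_c <- max(0L, patch - d[2])
  vox <- vol$voxels
  if (pad_r > 0 || pad_c > 0) {
    message("in-plane dims ", d[1], "x", d[2], " smaller than patch ", patch,
            "; padding reflectively")
    ri <- .reflect_idx(seq_len(d[1] + pad_r), d[1])
    ci <- .reflect_idx(seq_len(d[2] + pad_c), d[2])
    vox <- vox[ri, ci, , drop = FALSE]
  }
  dd <- dim(vox)
  C <- n_classes()
  roff <- .window_offsets(dd[1], patch, stride)
  coff <- .window_offsets(dd[2], patch, stride)
  out <- array(0L, dd)
  for (k in seq_len(dd[3])) {
    sl <- vox[, , k]
    anchors <- expand.grid(r = roff, c = coff)
    patches <- lapply(seq_len(nrow(anchors)), function(i)
      sl[anchors$r[i] + seq_len(patch), anchors$c[i] + seq_len(patch)])
    pr <- predict_patches(model, patches)
    votes <- array(0, c(dd[1], dd[2], C))
    psum <- array(0, c(dd[1], dd[2], C))
    for (i in seq_len(nrow(anchors))) {
      rs <- anchors$r[i] + seq_len(patch); cs <- anchors$c[i] + seq_len(patch)
      pp <- pr[, , , i]
      am <- max.col(matrix(pp, ncol = C), "first")
      dim(am) <- c(patch, patch)
      for (c in seq_len(C)) {
        votes[rs, cs, c] <- votes[rs, cs, c] + (am == c)
        psum[rs, cs, c] <- psum[rs, cs, c] + pp[, , c]
      }
    }
    total <- max(votes) + 1
    score <- votes + psum / (total * C + 1)
    lab_k <- max.col(matrix(score, ncol = C), "first") - 1L
    dim(lab_k) <- dd[1:2]
    out[, , k] <- lab_k
  }
  out <- out[seq_len(d[1]), seq_len(d[2]), , drop = FALSE]
  label_volume(out, pixel_spacing = vol$pixel_spacing,
               slice_spacing = vol$slice_spacing, source_id = vol$source_id)
}

#' Restore predicted labels to the native acquisition grid
#'
#' Nearest-neighbour resampling of an isometric-grid prediction back onto
#' the pixel grid of the original volume; output dimensions equal the
#' original dimensions exactly and the output label set is a subset of the
#' input's.
#'
#' @param pred predicted [label_volume()] on the isometric grid
#' @param original the native-grid [ct_volume()] the prediction derives from
#' @return a [label_volume()] on the native grid
#' @export
restore_native_grid <- function(pred, original) {
  stopifnot(inherits(pred, "label_volume"), inherits(original, "ct_volume"))
  dp <- dim(pred$labels); do <- dim(original$voxels)
  if (dp[3] != do[3])
    stop("provenance mismatch: prediction has ", dp[3], " slices, original ", do[3])
  # the isometric grid must cover the same field of view
  fov_pred <- dp[1:2] * pred$pixel_spacing
  fov_orig <- do[1:2] * original$pixel_spacing
  if (any(abs(fov_pred - fov_orig) > pmax(pred$pixel_spacing, original$pixel_spacing) + 1e-6))
    stop("provenance mismatch: prediction field of view ",
         paste(round(fov_pred, 1), collapse = "x"), " mm vs original ",
         paste(round(fov_orig, 1), collapse = "x"), " mm")
  if (all(dp == do) && all(abs(pred$pixel_spacing - original$pixel_spacing) < 1e-12))
    return(pred)
  Ar <- .nn_resample_matrix(dp[1], pred$pixel_spacing[1], do[1], original$pixel_spacing[1])
  Ac <- .nn_resample_matrix(dp[2], pred$pixel_spacing[2], do[2], original$pixel_spacing[2])
  ri <- apply(Ar == 1, 1, which.max)
  ci <- apply(Ac == 1, 1, which.max)
  label_volume(pred$labels[ri, ci, , drop = FALSE],
               pixel_spacing = original$pixel_spacing,
               slice_spacing = original$slice_spacing,
               source_id = pred$source_id)
}
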