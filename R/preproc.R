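## Preprocessing: isometric resampling, display windowing, patch sampling,
## and flip-free augmentation.

## Cubic B-spline basis
.bspline3 <- function(t) {
  at <- abs(t)
  ifelse(at < 1, (4 - 6 * at^2 + 3 * at^3) / 6,
         ifelse(at < 2, (2 - at)^3 / 6, 0))
}

## round half away from zero (dimension rule for resampling)
.round_half_up <- function(x) floor(x + 0.5)

## 1D cubic-spline resampling operator: an (n_out x n_in) matrix A such that
## y_out = A %*% y_in evaluates the interpolating cubic B-spline of y_in
## (mirror-extended by 3 samples so constants are reproduced exactly) at the
## output pixel centers. Pixel centers of a grid with spacing s sit at
## (i - 0.5) * s; input and output grids share the physical field of view.
.spline_resample_matrix <- function(n_in, sp_in, n_out, sp_out) {
  if (n_in == 1L) return(matrix(1, n_out, 1))
  # whole-sample mirror boundary folded into the basis: coefficients at
  # reflected nodes equal those at their mirror images (c_{2-j} = c_j,
  # c_{2n-j} = c_j), which preserves the partition of unity — constants are
  # reproduced exactly across the whole field of view
  fold <- function(x, j)
    .bspline3(x - j) + .bspline3(x - 2 + j) + .bspline3(x - 2 * n_in + j)
  i <- seq_len(n_in)
  S <- outer(i, i, fold)                 # collocation at the sample points
  p <- ((seq_len(n_out) - 0.5) * sp_out) / sp_in + 0.5
  W <- outer(p, i, fold)
  W %*% solve(S)
}

## nearest-neighbour 1D resampling operator with the same grid convention
.nn_resample_matrix <- function(n_in, sp_in, n_out, sp_out) {
  p <- ((seq_len(n_out) - 0.5) * sp_out) / sp_in + 0.5
  j <- pmin(pmax(.round_half_up(p), 1L), n_in)
  A <- matrix(0, n_out, n_in); A[cbind(seq_len(n_out), j)] <- 1
  A
}

#' Resample a CT volume to an isometric in-plane grid
#'
#' In-plane resampling to square pixels of `target_mm` (default 1 mm) using
#' interpolating cubic B-splines (spline interpolation of order three),
#' applied separably to rows and columns of every coronal slice. Slice
#' spacing is untouched: the network operates on 2D coronal slices. Output
#' dimensions follow `round(dim * spacing / target)` with halves rounded
#' away from zero.
#'
#' @param vol a [ct_volume()]
#' @param target_mm target isotropic in-plane pixel size, > 0 (default 1)
#' @return a [ct_volume()] with `pixel_spacing = c(target_mm, target_mm)`
#' @export
resample_isometric <- function(vol, target_mm = 1.0) {
  stopifnot(inherits(vol, "ct_volume"))
  if (!is.finite(target_mm) || target_mm <= 0) stop("target_mm must be > 0")
  d <- dim(vol$voxels)
  n_out <- pmax(1L, as.integer(.round_half_up(d[1:2] * vol$pixel_spacing / target_mm)))
  Ar <- .spline_resample_matrix(d[1], vol$pixel_spacing[1], n_out[1], target_mm)
  Ac <- .spline_resample_matrix(d[2], vol$pixel_spacing[2], n_out[2], target_mm)
  out <- array(0, c(n_out, d[3]))
  for (k in seq_len(d[3])) out[, , k] <- Ar %*% vol$voxels[, , k] %*% t(Ac)
  ct_volume(out, pixel_spacing = c(target_mm, target_mm),
            slice_spacing = vol$slice_spacing, source_id = vol$source_id)
}

#' Resample a label volume with nearest-neighbour interpolation
#'
#' Companion to [resample_isometric()]: the label grid is resampled with
#' nearest-neighbour lookup on the same pixel-center convention, so the
#' output label set is always a subset of the input label set.
#'
#' @param lab a [label_volume()]
#' @param target_mm target isotropic in-plane pixel size (default 1)
#' @return a [label_volume()]
#' @export
resample_labels <- function(lab, target_mm = 1.0) {
  stopifnot(inherits(lab, "label_volume"))
  if (!is.finite(target_mm) || target_mm <= 0) stop("target_mm must be > 0")
  d <- dim(lab$labels)
  n_out <- pmax(1L, as.integer(.round_half_up(d[1:2] * lab$pixel_spacing / target_mm)))
  Ar <- .nn_resample_matrix(d[1], lab$pixel_spacing[1], n_out[1], target_mm)
  Ac <- .nn_resample_matrix(d[2], lab$pixel_spacing[2], n_out[2], target_mm)
  ri <- apply(Ar == 1, 1, which.max)
  ci <- apply(Ac == 1, 1, which.max)
  out <- lab$labels[ri, ci, , drop = FALSE]
  label_volume(out, pixel_spacing = c(target_mm, target_mm),
               slice_spacing = lab$slice_spacing, source_id = lab$source_id)
}

#' Window Hounsfield units for display/network input
#'
#' Clips HU to the soft-tissue display window
#' `[level - width/2, level + width/2]` (defaults 50/250 HU, i.e. -75..175)
#' and maps it affinely onto `[0, 1]`. The mapping is monotone
#' non-decreasing in HU.
#'
#' @param x numeric array of HU values, or a [ct_volume()]
#' @param level window level in HU (default 50)
#' @param width window width in HU, > 0 (default 250)
#' @return object of the same shape with values in `[0, 1]`
#' @export
window_hu <- function(x, level = 50, width = 250) {
  if (!is.finite(width) || width <= 0) stop("window width must be > 0")
  if (inherits(x, "ct_volume")) {
    x$voxels <- window_hu(x$voxels, level, width)
    return(x)
  }
  lo <- level - width / 2
  pmin(pmax((x - lo) / width, 0), 1)
}

## inverse of window_hu on the interior of the window
.unwindow <- function(x, level = 50, width = 250) (level - width / 2) + x * width

#' Sample balanced training patches from a slice stack
#'
#' Draws `n_patches` aligned image/label patches of size `patch` x `patch`
#' from random coronal slices and offsets. Half the patches (rounded up) are
#' "orbit" patches containing at least one muscle-labelled pixel, sampled so
#' the patch intersects the per-slice orbit region (bounding box of
#' non-background labels dilated by 8 px); the other half contain no muscle
#' pixels at all.
#'
#' @param vol windowed [ct_volume()] on the resampled grid (values in 0..1)
#' @param lab aligned [label_volume()]
#' @param n_patches number of patches to draw
#' @param patch patch side in pixels (default 128)
#' @param seed integer RNG seed
#' @return a `patch_set`: list with `images` (list of patch matrices),
#'   `labels` (list of integer matrices) and `provenance` (data.frame with
#'   source_id, slice, row_off, col_off and logical `orbit`); offsets are
#'   0-based.
#' @export
sample_patches <- function(vol, lab, n_patches, patch = 128L, seed = 1L) {
  stopifnot(inherits(vol, "ct_volume"), inherits(lab, "label_volume"))
  d <- dim(vol$voxels)
  if (!identical(d, dim(lab$labels))) stop("volume/label shape mismatch")
  if (d[1] < patch || d[2] < patch)
    stop(sprintf("volume in-plane size %dx%d is smaller than patch %d", d[1], d[2], patch))
  n_orbit <- ceiling(n_patches / 2)
  n_bg <- n_patches - n_orbit

  muscle_slices <- which(apply(lab$labels > 0, 3, any))
  if (length(muscle_slices) == 0 && n_orbit > 0)
    stop("no muscle-labelled slices: cannot draw orbit patches")
  # per-slice orbit region: label bbox dilated by 8 px
  bboxes <- lapply(muscle_slices, function(k) {
    w <- which(lab$labels[, , k] > 0, arr.ind = TRUE)
    c(max(1L, min(w[, 1]) - 8L), min(d[1], max(w[, 1]) + 8L),
      max(1L, min(w[, 2]) - 8L), min(d[2], max(w[, 2]) + 8L))
  })

  withr_seed <- .seed_guard(seed)
  on.exit(withr_seed())

  imgs <- vector("list", n_patches); labs <- vector("list", n_patches)
  prov <- data.frame(source_id = character(n_patches), slice = integer(n_patches),
                     row_off = integer(n_patches), col_off = integer(n_patches),
                     orbit = logical(n_patches), stringsAsFactors = FALSE)
  draw_one <- function(orbit) {
    for (attempt in seq_len(2000L)) {
      if (orbit) {
        si <- sample.int(length(muscle_slices), 1L)
        k <- muscle_slices[si]; bb <- bboxes[[si]]
        r0 <- sample(max(0L, bb[1] - patch):min(d[1] - patch, bb[2] - 1L), 1L)
        c0 <- sample(max(0L, bb[3] - patch):min(d[2] - patch, bb[4] - 1L), 1L)
      } else {
        k <- sample.int(d[3], 1L)
        r0 <- sample(0:(d[1] - patch), 1L)
        c0 <- sample(0:(d[2] - patch), 1L)
      }
      lp <- lab$labels[r0 + seq_len(patch), c0 + seq_len(patch), k]
      has_muscle <- any(lp > 0)
      if (has_muscle == orbit)
        return(list(k = k, r0 = r0, c0 = c0, lp = lp))
    }
    stop("could not draw a ", if (orbit) "orbit" else "non-orbit",
         " patch after 2000 attempts")
  }
  flags <- c(rep(TRUE, n_orbit), rep(FALSE, n_bg))
  for (i in seq_len(n_patches)) {
    p <- draw_one(flags[i])
    imgs[[i]] <- vol$voxels[p$r0 + seq_len(patch), p$c0 + seq_len(patch), p$k]
    labs[[i]] <- p$lp
    prov[i, ] <- list(vol$source_id, p$k, p$r0, p$c0, flags[i])
  }
  structure(list(images = imgs, labels = labs, provenance = prov,
                 patch = as.integer(patch)), class = "patch_set")
}

## evaluate-and-restore RNG guard so seeded helpers do not disturb the
## caller's RNG stream
.seed_guard <- function(seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  function() {
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  }
}

## reflect an index vector into 1..n (half-sample symmetry)
.reflect_idx <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  period <- 2L * n
  i <- ((i - 1L) %% period + period) %% period
  ifelse(i < n, i + 1L, period - i)
}

## rotate+scale a patch about its center; bilinear for intensities,
## nearest-neighbour for labels; reflected boundary; determinant of the
## transform is always +scale^2 (no flips by construction)
.affine_patch <- function(img, lab, angle_deg, scale) {
  n <- nrow(img)
  ctr <- (n + 1) / 2
  th <- angle_deg * pi / 180
  g <- as.matrix(expand.grid(r = seq_len(n) - ctr, c = seq_len(n) - ctr))
  # inverse map: source = R(-theta)/scale %*% target
  sr <- ( cos(th) * g[, 1] + sin(th) * g[, 2]) / scale + ctr
  sc <- (-sin(th) * g[, 1] + cos(th) * g[, 2]) / scale + ctr
  r0 <- floor(sr); c0 <- floor(sc)
  fr <- sr - r0; fc <- sc - c0
  at <- function(m, r, c) m[cbind(.reflect_idx(r, n), .reflect_idx(c, n))]
  img_out <- (1 - fr) * (1 - fc) * at(img, r0, c0) +
             (1 - fr) * fc       * at(img, r0, c0 + 1) +
             fr       * (1 - fc) * at(img, r0 + 1, c0) +
             fr       * fc       * at(img, r0 + 1, c0 + 1)
  lab_out <- at(lab, .round_half_up(sr), .round_half_up(sc))
  list(img = matrix(img_out, n, n), lab = matrix(as.integer(lab_out), n, n))
}

#' Augment a patch set (rotation, scaling, HU noise; never flips)
#'
#' Applies, per patch, a random rotation and isotropic scaling (identical
#' geometric transform to image and labels, labels nearest-neighbour) and
#' additive Gaussian intensity noise. Noise is added in Hounsfield units:
#' the windowed intensities are mapped back to HU, perturbed, and the
#' display window re-applied. Horizontal flipping is deliberately not
#' available: flips would exchange left- and right-side muscle identities.
#'
#' @param patchset a `patch_set` from [sample_patches()]
#' @param seed integer RNG seed
#' @param rotation_deg_range length-2 range of rotation angles in degrees
#' @param scale_range length-2 range of isotropic scale factors
#' @param noise_sd_hu Gaussian noise standard deviation in HU (default 10)
#' @param level,width display window re-applied after noise addition
#' @return an augmented `patch_set`
#' @export
augment <- function(patchset, seed = 1L, rotation_deg_range = c(-10, 10),
                    scale_range = c(0.9, 1.1), noise_sd_hu = 10,
                    level = 50, width = 250) {
  stopifnot(inherits(patchset, "patch_set"))
  restore <- .seed_guard(seed)
  on.exit(restore())
  n <- length(patchset$images)
  for (i in seq_len(n)) {
    ang <- stats::runif(1, rotation_deg_range[1], rotation_deg_range[2])
    sc <- stats::runif(1, scale_range[1], scale_range[2])
    if (abs(ang) > 1e-12 || abs(sc - 1) > 1e-12) {
      tr <- .affine_patch(patchset$images[[i]], patchset$labels[[i]], ang, sc)
      patchset$images[[i]] <- tr$img
      patchset$labels[[i]] <- tr$lab
    }
    if (noise_sd_hu > 0) {
      hu <- .unwindow(patchset$images[[i]], level, width)
      hu <- hu + stats::rnorm(length(hu), 0, noise_sd_hu)
      patchset$images[[i]] <- window_hu(hu, level, width)
    }
  }
  patchset
}
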