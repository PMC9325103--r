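## Quantitative evaluation: overlap metrics (Dice / IOU), three-region
## analysis along the muscle path, measurement-error statistics (MAE /
## MAPE), and the noise-robustness protocol.

#' Dice and IOU for one class
#'
#' `dice = 2|P∩G| / (|P|+|G|)` and `iou = |P∩G| / |P∪G|` over all voxels of
#' the class. When the class is empty in both volumes the metrics are
#' undefined and `c(NA, NA)` is returned (excluded from averages rather
#' than scored 1).
#'
#' @param pred,truth aligned [label_volume()]s
#' @param class class index 0..8
#' @return numeric `c(dice, iou)`
#' @export
dice_iou <- function(pred, truth, class) {
  stopifnot(inherits(pred, "label_volume"), inherits(truth, "label_volume"))
  if (!identical(dim(pred$labels), dim(truth$labels)))
    stop("volume shape mismatch: ", paste(dim(pred$labels), collapse = "x"),
         " vs ", paste(dim(truth$labels), collapse = "x"))
  p <- pred$labels == class; g <- truth$labels == class
  np <- sum(p); ng <- sum(g)
  if (np == 0 && ng == 0) return(c(dice = NA_real_, iou = NA_real_))
  i <- sum(p & g)
  c(dice = 2 * i / (np + ng), iou = i / (np + ng - i))
}

#' Split the muscle-bearing slab into three regions
#'
#' The contiguous run of slices containing any muscle label is partitioned
#' into three near-equal contiguous thirds: near insertion (anterior),
#' central part, near tendinous origin (posterior). A remainder of 1 goes
#' to the central part; a remainder of 2 adds one slice each to the central
#' part and the origin.
#'
#' @param truth a [label_volume()] (ground truth defines the slab)
#' @return a `region_split`: list of integer slice-index vectors
#'   `insertion`, `central`, `origin`
#' @export
split_regions <- function(truth) {
  stopifnot(inherits(truth, "label_volume"))
  has <- which(apply(truth$labels > 0, 3, any))
  if (length(has) < 3) stop("need at least 3 muscle-bearing slices, found ", length(has))
  slab <- seq.int(min(has), max(has))
  n <- length(slab)
  base <- n %/% 3; r <- n %% 3
  sizes <- c(base, base + (r >= 1), base + (r == 2))
  ends <- cumsum(sizes)
  structure(list(insertion = slab[seq_len(sizes[1])],
                 central = slab[(ends[1] + 1):ends[2]],
                 origin = slab[(ends[2] + 1):ends[3]]),
            class = "region_split")
}

#' Per-region overlap metrics
#'
#' Dice / IOU recomputed over each region's slices only.
#'
#' @param pred,truth aligned [label_volume()]s
#' @param split a `region_split` from [split_regions()]
#' @return data.frame with region, class, dice, iou
#' @export
regional_metrics <- function(pred, truth, split = split_regions(truth)) {
  out <- NULL
  for (rg in c("insertion", "central", "origin")) {
    ks <- split[[rg]]
    sub_p <- label_volume(pred$labels[, , ks, drop = FALSE],
                          pred$pixel_spacing, pred$slice_spacing, pred$source_id)
    sub_g <- label_volume(truth$labels[, , ks, drop = FALSE],
                          truth$pixel_spacing, truth$slice_spacing, truth$source_id)
    for (cls in muscle_classes()) {
      di <- dice_iou(sub_p, sub_g, cls)
      out <- rbind(out, data.frame(region = rg, class = cls,
                                   dice = di[1], iou = di[2]))
    }
  }
  out
}

#' Mean absolute error and mean absolute percentage error
#'
#' `MAE = mean(|pred - gt|)`; `MAPE = mean(|pred - gt| / |gt|) * 100`
#' (percent). Pairs with a zero ground-truth value are excluded from MAPE
#' with a warning.
#'
#' @param pred,gt paired numeric vectors of measurements
#' @return named numeric `c(mae, mape)`; `mape` in percent
#' @export
mae_mape <- function(pred, gt) {
  if (length(pred) != length(gt)) stop("pred/gt length mismatch")
  if (length(pred) == 0) stop("need at least one pair")
  ok <- is.finite(pred) & is.finite(gt)
  pred <- pred[ok]; gt <- gt[ok]
  mae <- mean(abs(pred - gt))
  nz <- gt != 0
  if (any(!nz)) warning(sum(!nz), " pair(s) with zero ground truth excluded from MAPE")
  mape <- if (any(nz)) mean(abs(pred[nz] - gt[nz]) / abs(gt[nz])) * 100 else NA_real_
  c(mae = mae, mape = mape)
}

#' Evaluate predictions against ground truth over a cohort
#'
#' For each study: per-class Dice / IOU on the isometric grid, the
#' three-region breakdown, and thickness / area measurements from
#' [measure_volume()] on the native grid (predictions restored with
#' [restore_native_grid()]) compared by MAE / MAPE.
#'
#' @param preds list of predicted [label_volume()]s (isometric grid)
#' @param studies list of studies as produced by [prepare_study()] (with
#'   `lab` and `native` populated)
#' @param measure_native measure sizes on the native grid (default) or on
#'   the isometric grid
#' @param noise_tag free-text tag recorded in the report
#' @return an `eval_report`: list with `per_study` (long data.frame of
#'   per-study per-class dice/iou), `per_class` (mean +/- sd across
#'   studies), `pooled` (overall mean +/- sd), `regional`, `measurements`
#'   (per-pair table) and `errors` (MAE/MAPE for thickness and area)
#' @export
evaluate_cohort <- function(preds, studies, measure_native = TRUE,
                            noise_tag = "baseline") {
  stopifnot(length(preds) == length(studies))
  per_study <- NULL; regional <- NULL; meas <- NULL
  n_undefined <- 0L
  for (i in seq_along(preds)) {
    pred <- preds[[i]]; st <- studies[[i]]
    for (cls in muscle_classes()) {
      di <- dice_iou(pred, st$lab, cls)
      if (all(is.na(di))) n_undefined <- n_undefined + 1L
      per_study <- rbind(per_study, data.frame(
        study = i, class = cls, dice = di[1], iou = di[2]))
    }
    rg <- regional_metrics(pred, st$lab)
    rg$study <- i
    regional <- rbind(regional, rg)

    truth_lab <- if (measure_native && !is.null(st$native$labels))
      st$native$labels else st$lab
    pred_meas <- if (measure_native && !is.null(st$native$ct))
      restore_native_grid(pred, st$native$ct) else pred
    rep_p <- measure_volume(pred_meas)$table
    rep_g <- measure_volume(truth_lab)$table
    meas <- rbind(meas, data.frame(
      study = i, class = rep_g$class,
      thickness_pred = rep_p$thickness_mm, thickness_gt = rep_g$thickness_mm,
      area_pred = rep_p$area_mm2, area_gt = rep_g$area_mm2))
  }
  per_class <- do.call(rbind, lapply(muscle_classes(), function(cls) {
    sub <- per_study[per_study$class == cls, ]
    data.frame(class = cls, name = class_name(cls),
               dice_mean = mean(sub$dice, na.rm = TRUE),
               dice_sd = stats::sd(sub$dice, na.rm = TRUE),
               iou_mean = mean(sub$iou, na.rm = TRUE),
               iou_sd = stats::sd(sub$iou, na.rm = TRUE))
  }))
  pooled <- c(dice_mean = mean(per_study$dice, na.rm = TRUE),
              dice_sd = stats::sd(per_study$dice, na.rm = TRUE),
              iou_mean = mean(per_study$iou, na.rm = TRUE),
              iou_sd = stats::sd(per_study$iou, na.rm = TRUE))
  errors <- rbind(
    data.frame(quantity = "thickness",
               t(mae_mape(meas$thickness_pred, meas$thickness_gt))),
    data.frame(quantity = "area", t(mae_mape(meas$area_pred, meas$area_gt))))
  structure(list(per_study = per_study, per_class = per_class, pooled = pooled,
                 regional = regional, measurements = meas, errors = errors,
                 n_undefined_pairs = n_undefined, noise_tag = noise_tag),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("eval_report [%s]: pooled Dice %.3f +/- %.3f, IOU %.3f +/- %.3f\n",
              x$noise_tag, x$pooled["dice_mean"], x$pooled["dice_sd"],
              x$pooled["iou_mean"], x$pooled["iou_sd"]))
  cat(sprintf("thickness MAE %.3f mm / MAPE %.1f%%; area MAE %.3f mm2 / MAPE %.1f%%\n",
              x$errors$mae[1], x$errors$mape[1], x$errors$mae[2], x$errors$mape[2]))
  invisible(x)
}

#' Noise-robustness evaluation
#'
#' Repeats the full evaluation after adding seeded Gaussian HU noise of each
#' given standard deviation to the native CT volumes before preprocessing
#' and prediction. `sd = 0` reproduces the baseline.
#'
#' @param model trained `seg_model`
#' @param studies list of studies (as for [evaluate_cohort()]), with native
#'   CT volumes present
#' @param sd_list noise standard deviations in HU (default 0, 5, 10)
#' @param stride sliding-window stride for prediction
#' @param seed RNG seed for the noise draws
#' @param measure_native passed through to [evaluate_cohort()]
#' @return named list of `eval_report`s, one per noise level
#' @export
noise_robustness <- function(model, studies, sd_list = c(0, 5, 10),
                             stride = 64L, seed = 1L, measure_native = TRUE) {
  out <- list()
  for (sd in sd_list) {
    restore <- .seed_guard(seed + round(1000 * sd))
    noisy <- lapply(studies, function(st) {
      ct <- st$native$ct
      if (sd > 0) {
        ct$voxels <- ct$voxels + array(stats::rnorm(length(ct$voxels), 0, sd),
                                       dim(ct$voxels))
      }
      prep <- prepare_study(ct, st$native$labels)
      prep$native <- st$native   # evaluate against the clean originals
      prep
    })
    restore()
    preds <- lapply(noisy, function(st)
      predict_volume(model, st$vol, stride = stride, prepared = TRUE))
    out[[sprintf("sd_%g", sd)]] <- evaluate_cohort(
      preds, noisy, measure_native = measure_native,
      noise_tag = sprintf("noise sd %g HU", sd))
  }
  out
}

#' Welch test comparing per-study pooled Dice between two reports
#'
#' Convenience wrapper used to probe whether a condition (for example added
#' noise) significantly changes per-study mean Dice.
#'
#' @param report_a,report_b `eval_report`s over the same cohort
#' @return the `htest` from [stats::t.test()]
#' @export
compare_reports <- function(report_a, report_b) {
  a <- stats::aggregate(dice ~ study, report_a$per_study, mean, na.rm = TRUE)
  b <- stats::aggregate(dice ~ study, report_b$per_study, mean, na.rm = TRUE)
  stats::t.test(a$dice, b$dice)
}
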