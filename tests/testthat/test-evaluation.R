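# Evaluation harness: overlap metrics, region splits, error statistics.

mk_lab <- function(arr) label_volume(arr, 1, 3)

test_that("dice_iou counts overlaps correctly", {
  a <- array(0L, c(10, 10, 1)); a[1:2, 1:5, 1] <- 1L        # 10 px
  b <- array(0L, c(10, 10, 1)); b[1:2, 3:7, 1] <- 1L        # 10 px, overlap 6
  expect_equal(dice_iou(mk_lab(a), mk_lab(a), 1), c(dice = 1, iou = 1))
  expect_equal(dice_iou(mk_lab(a), mk_lab(b), 1),
               c(dice = 0.6, iou = 6 / 14), tolerance = 1e-12)
  c2 <- array(0L, c(10, 10, 1)); c2[8:9, 8:9, 1] <- 1L
  expect_equal(dice_iou(mk_lab(a), mk_lab(c2), 1), c(dice = 0, iou = 0))
  # both-empty pairs are undefined, not perfect
  expect_true(all(is.na(dice_iou(mk_lab(a), mk_lab(a), 5))))
  wrong <- array(0L, c(5, 5, 1))
  expect_error(dice_iou(mk_lab(a), mk_lab(wrong), 1), "shape mismatch")
})

slab_volume <- function(n_muscle, lead = 2, trail = 2) {
  arr <- array(0L, c(20, 20, lead + n_muscle + trail))
  for (k in seq_len(n_muscle)) arr[5:10, 5:10, lead + k] <- 1L
  mk_lab(arr)
}

test_that("region split partitions the slab with the documented remainder rule", {
  for (case in list(c(9, 3, 3, 3), c(10, 3, 4, 3), c(11, 3, 4, 4))) {
    sp <- split_regions(slab_volume(case[1]))
    expect_equal(lengths(sp)[c("insertion", "central", "origin")],
                 c(insertion = case[2], central = case[3], origin = case[4]))
    # contiguous, ordered, disjoint, covering the slab
    all_slices <- c(sp$insertion, sp$central, sp$origin)
    expect_equal(all_slices, seq(min(all_slices), max(all_slices)))
    expect_equal(anyDuplicated(all_slices), 0)
  }
  expect_error(split_regions(slab_volume(2)), "at least 3")
})

test_that("region split ignores leading and trailing muscle-free slices", {
  s1 <- split_regions(slab_volume(9, lead = 0, trail = 5))
  s2 <- split_regions(slab_volume(9, lead = 5, trail = 0))
  expect_equal(lengths(s1), lengths(s2))
  expect_equal(s2$insertion - 5L, s1$insertion)
})

test_that("regional metrics are local and match recomputation on slices", {
  set.seed(17)
  truth <- array(0L, c(24, 24, 12))
  for (k in 3:10) truth[8:15, 8:15, k] <- sample(c(0L, 1L, 2L), 64, TRUE)
  pred <- truth
  # corrupt only the origin third
  sp <- split_regions(mk_lab(truth))
  for (k in sp$origin) pred[, , k] <- 0L
  rm_ <- regional_metrics(mk_lab(pred), mk_lab(truth), sp)
  ins <- rm_[rm_$region == "insertion" & rm_$class == 1, ]
  expect_equal(ins$dice, 1)
  org <- rm_[rm_$region == "origin" & rm_$class == 1, ]
  expect_equal(org$dice, 0)
  # slicing oracle: metric over a region equals dice_iou of the sliced arrays
  ks <- sp$central
  oracle <- dice_iou(mk_lab(pred[, , ks, drop = FALSE]),
                     mk_lab(truth[, , ks, drop = FALSE]), 2)
  cen <- rm_[rm_$region == "central" & rm_$class == 2, ]
  expect_equal(c(cen$dice, cen$iou), unname(oracle))
})

test_that("MAE and MAPE match hand arithmetic", {
  expect_equal(mae_mape(c(5, 4), c(4, 5)), c(mae = 1, mape = 22.5))
  expect_equal(mae_mape(c(3, 3), c(3, 3)), c(mae = 0, mape = 0))
  expect_equal(mae_mape(4.4, 4.0), c(mae = 0.4, mape = 10), tolerance = 1e-9)
  expect_warning(out <- mae_mape(c(1, 2), c(0, 2)), "zero ground truth")
  expect_equal(unname(out["mape"]), 0)
  # brute-force loop oracle on random vectors
  set.seed(23)
  pr <- runif(20, 1, 10); gt <- runif(20, 1, 10)
  acc_mae <- 0; acc_mape <- 0
  for (i in 1:20) {
    acc_mae <- acc_mae + abs(pr[i] - gt[i])
    acc_mape <- acc_mape + abs(pr[i] - gt[i]) / abs(gt[i])
  }
  expect_equal(mae_mape(pr, gt),
               c(mae = acc_mae / 20, mape = 100 * acc_mape / 20),
               tolerance = 1e-12)
})

test_that("evaluate_cohort with perfect predictions scores 1.0 and zero error", {
  ph <- fixture_phantom()
  st <- prepare_study(ph$ct, ph$labels)
  rep <- evaluate_cohort(list(st$lab), list(st), measure_native = FALSE)
  expect_equal(unname(rep$pooled["dice_mean"]), 1)
  expect_equal(unname(rep$pooled["iou_mean"]), 1)
  # measured sizes for pred == truth on the isometric grid match exactly
  expect_equal(rep$errors$mae, c(0, 0), tolerance = 1e-9)
  # single-pair relation IOU = Dice/(2 - Dice) on every (study, class) row
  ps <- rep$per_study
  expect_equal(ps$iou, ps$dice / (2 - ps$dice), tolerance = 1e-9)
})

test_that("noise robustness at sd 0 reproduces the baseline and is seeded", {
  ph <- generate_phantom(phantom_spec(seed = 31))
  st <- prepare_study(ph$ct, ph$labels)
  model <- build_unet(train_config(base_filters = 2L, patch_size = 32L, seed = 8L))
  base_pred <- predict_volume(model, st$vol, stride = 16L, prepared = TRUE)
  base <- evaluate_cohort(list(base_pred), list(st), measure_native = FALSE)
  nr <- noise_robustness(model, list(st), sd_list = c(0, 10), stride = 16L,
                         seed = 99, measure_native = FALSE)
  expect_equal(nr$sd_0$pooled, base$pooled)
  # same seed reproduces the noisy condition exactly
  nr2 <- noise_robustness(model, list(st), sd_list = 10, stride = 16L,
                          seed = 99, measure_native = FALSE)
  expect_equal(nr2$sd_10$pooled, nr$sd_10$pooled)
})
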