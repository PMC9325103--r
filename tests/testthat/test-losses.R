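# Loss functions against hand-computed values and brute-force oracles.

test_that("weighted cross-entropy matches closed forms", {
  # perfect one-hot prediction -> 0 for any weights
  g <- cbind(c(1, 0), c(0, 1))
  b <- loss_batch(g, g, class_weights = c(3, 0.5))
  expect_equal(wce_loss(b), 0)
  # 1 pixel, 2 classes, true-class prob 0.5 -> ln 2
  b2 <- loss_batch(matrix(c(0.5, 0.5), 1), matrix(c(1, 0), 1))
  expect_equal(wce_loss(b2), log(2), tolerance = 1e-12)
  # 2 pixels, true-class probs (0.8, 0.6) -> -(ln .8 + ln .6)/2
  b3 <- loss_batch(rbind(c(0.8, 0.2), c(0.4, 0.6)),
                   rbind(c(1, 0), c(0, 1)))
  expect_equal(wce_loss(b3), -(log(0.8) + log(0.6)) / 2, tolerance = 1e-12)
  expect_error(loss_batch(g, g, class_weights = c(-1, 1)), "non-negative")
})

test_that("Dice loss scores overlap with the factor-2 convention", {
  m <- matrix(0, 5, 5)
  a <- m; a[1:2, 1] <- 1          # 2 px
  c2 <- m; c2[2:3, 1] <- 1        # 2 px, overlapping a in 1
  expect_equal(dice_loss(pair_batch(a, a)), 0, tolerance = 1e-6)
  disj <- m; disj[4:5, 1:5] <- 1   # 10 px disjoint from a
  expect_equal(dice_loss(pair_batch(a, disj)), 1, tolerance = 1e-5)
  expect_equal(dice_loss(pair_batch(a, c2)), 0.5, tolerance = 1e-6)
})

test_that("IOU loss equals one minus intersection over union", {
  m <- matrix(0, 4, 4)
  a <- m; a[1:2, 1] <- 1
  b <- m; b[2:3, 1] <- 1          # overlap 1, union 3
  expect_equal(iou_loss(pair_batch(a, a)), 0, tolerance = 1e-9)
  expect_equal(iou_loss(pair_batch(b, a)), 1 - 1 / 3, tolerance = 1e-9)
  set.seed(42)
  for (rep in 1:5) {
    A <- matrix(rbinom(64, 1, 0.4), 8, 8)
    B <- matrix(rbinom(64, 1, 0.4), 8, 8)
    if (sum(A | B) == 0) next
    oracle <- 1 - sum(A & B) / sum(A | B)
    expect_equal(iou_loss(pair_batch(A, B)), oracle, tolerance = 1e-9)
  }
})

test_that("Focal-Tversky reduces to Dice at alpha=beta=0.5, gamma=1", {
  set.seed(7)
  A <- matrix(rbinom(64, 1, 0.3), 8, 8)
  B <- matrix(rbinom(64, 1, 0.3), 8, 8)
  b <- pair_batch(A, B, tversky_alpha = 0.5, tversky_beta = 0.5, gamma = 1)
  # identity holds up to O(epsilon): the two losses place the smoothing
  # epsilon differently
  expect_equal(focal_tversky_loss(b), dice_loss(b), tolerance = 1e-5)
  expect_error(focal_tversky_loss(pair_batch(A, B, gamma = 4)), "gamma")
})

test_that("Focal-Tversky matches an exhaustive-summation oracle", {
  pred <- matrix(c(0.9, 0.1, 0.4, 0.8, 0, 1, 0.3, 0.6,
                   0.2, 0.5, 0.7, 0.1, 0.9, 0.05, 0.5, 0.8), 4, 4)
  truth <- matrix(c(1, 0, 0, 1, 0, 1, 0, 1, 0, 1, 1, 0, 1, 0, 0, 1), 4, 4)
  a <- 0.7; bta <- 0.3; gam <- 4 / 3; eps <- 1e-6
  # pixel-by-pixel accumulation
  tp <- fp <- fn <- 0
  for (i in 1:4) for (j in 1:4) {
    tp <- tp + pred[i, j] * truth[i, j]
    fp <- fp + pred[i, j] * (1 - truth[i, j])
    fn <- fn + (1 - pred[i, j]) * truth[i, j]
  }
  ti <- (tp + eps) / (tp + a * fp + bta * fn + eps)
  b <- pair_batch(pred, truth, tversky_alpha = a, tversky_beta = bta, gamma = gam)
  expect_equal(focal_tversky_loss(b), (1 - ti)^(1 / gam), tolerance = 1e-12)
})

test_that("signed distance maps have the level-set sign convention", {
  m <- matrix(0, 5, 5); m[3, 3] <- 1
  phi <- signed_distance_map(m)
  expect_equal(phi[3, 3], 0)                        # the pixel is boundary
  expect_equal(phi[2, 3], 1); expect_equal(phi[3, 4], 1)
  expect_equal(phi[1, 1], sqrt(8))
  # strict interior is negative
  sq <- matrix(0, 7, 7); sq[2:6, 2:6] <- 1
  phi2 <- signed_distance_map(sq)
  expect_true(all(phi2[3:5, 3:5] < 0))
  expect_true(all(phi2[sq == 0] > 0))
  expect_error(signed_distance_map(matrix(0, 3, 3)), "degenerate")
  expect_error(signed_distance_map(matrix(1, 3, 3)), "degenerate")
})

test_that("signed distance maps match the all-pairs brute-force oracle", {
  set.seed(13)
  for (rep in 1:3) {
    m <- matrix(0, 16, 16)
    m[sample(256, 40)] <- 1
    if (!any(m > 0) || all(m > 0)) next
    expect_equal(signed_distance_map(m), sdm_oracle(m), tolerance = 1e-9)
  }
})

test_that("boundary loss follows the level-set integral", {
  sq <- matrix(0, 8, 8); sq[3:6, 3:6] <- 1
  phi <- signed_distance_map(sq)
  zero_pred <- matrix(0, 64, 2); zero_pred[, 1] <- 1
  g2 <- cbind(1 - as.numeric(sq), as.numeric(sq))
  b0 <- loss_batch(zero_pred, g2, phi = cbind(0, as.numeric(phi)))
  expect_equal(boundary_loss(b0), 0)
  # probability mass on a strictly interior pixel decreases the loss
  interior_px <- which(as.numeric(phi) < 0)[1]
  p1 <- zero_pred; p1[interior_px, ] <- c(0.5, 0.5)
  b1 <- loss_batch(p1, g2, phi = cbind(0, as.numeric(phi)))
  expect_lt(boundary_loss(b1), boundary_loss(b0))
  expect_error(boundary_loss(loss_batch(p1, g2)), "phi")
  # random pair equals the exhaustive sum
  set.seed(5)
  s <- matrix(runif(64), 64, 1); s <- cbind(1 - s, s)
  m <- matrix(0, 16, 4); m[4:9, 2:3] <- 1  # 16x4 grid mask
  phi_m <- signed_distance_map(m)
  bb <- loss_batch(s, cbind(1 - as.numeric(m), as.numeric(m)),
                   phi = cbind(0, as.numeric(phi_m)))
  oracle <- sum(as.numeric(phi_m) * s[, 2])
  expect_equal(boundary_loss(bb), oracle, tolerance = 1e-12)
})

test_that("compound recipes sum their members and reject unknown names", {
  set.seed(21)
  A <- matrix(rbinom(64, 1, 0.3), 8, 8)
  B <- matrix(rbinom(64, 1, 0.3), 8, 8)
  b <- pair_batch(A, B)
  expect_equal(compound_loss(b, "wce+dice"), wce_loss(b) + dice_loss(b))
  g <- cbind(c(1, 0), c(0, 1))
  perfect <- loss_batch(g, g)
  expect_equal(compound_loss(perfect, "wce+dice"), 0, tolerance = 1e-6)
  # dice+boundary on an all-zero prediction: dice ~ 1, boundary 0
  m <- matrix(0, 8, 8); m[3:5, 3:5] <- 1
  zero <- cbind(1, matrix(0, 64, 1))
  bz <- loss_batch(zero, cbind(1 - as.numeric(m), as.numeric(m)),
                   phi = cbind(0, as.numeric(signed_distance_map(m))))
  expect_equal(compound_loss(bz, "dice+boundary"), dice_loss(bz), tolerance = 1e-9)
  expect_gt(dice_loss(bz), 0.99)
  expect_error(compound_loss(b, "dice+surface"), "unknown loss recipe")
})

test_that("analytic loss gradients match finite differences for every recipe", {
  set.seed(31)
  n <- 30; C <- 4
  logits <- matrix(rnorm(n * C), n, C)
  probs <- exp(logits) / rowSums(exp(logits))
  lab <- sample(0:(C - 1), n, replace = TRUE)
  onehot <- matrix(0, n, C); onehot[cbind(1:n, lab + 1)] <- 1
  phi <- matrix(rnorm(n * C), n, C)
  w <- runif(C, 0.5, 2)
  for (recipe in c("wce", "dice", "ftl", "wce+dice", "dice+boundary")) {
    mk <- function(p) loss_batch(p, onehot, class_weights = w, phi = phi,
                                 validate = FALSE)
    lg <- loss_grad(mk(probs), recipe)
    eps <- 1e-6
    set.seed(100)
    for (k in sample(n * C, 6)) {
      pp <- probs; pp[k] <- pp[k] + eps
      pm <- probs; pm[k] <- pm[k] - eps
      num <- (compound_loss(mk(pp), recipe) - compound_loss(mk(pm), recipe)) / (2 * eps)
      expect_equal(lg$grad[k], num, tolerance = 1e-4,
                   label = paste("grad of", recipe, "at", k))
    }
  }
})

test_that("losses are permutation invariant and respect their ranges", {
  set.seed(41)
  n <- 50
  logits <- matrix(rnorm(n * 3), n, 3)
  probs <- exp(logits) / rowSums(exp(logits))
  onehot <- matrix(0, n, 3); onehot[cbind(1:n, sample(1:3, n, TRUE))] <- 1
  phi <- matrix(rnorm(n * 3), n, 3)
  b <- loss_batch(probs, onehot, phi = phi)
  perm <- sample(n)
  bp <- loss_batch(probs[perm, ], onehot[perm, ], phi = phi[perm, ])
  for (f in list(wce_loss, dice_loss, iou_loss, focal_tversky_loss, boundary_loss))
    expect_equal(f(b), f(bp), tolerance = 1e-12)
  expect_gte(wce_loss(b), 0)
  expect_true(dice_loss(b) >= 0 && dice_loss(b) <= 1)
  expect_true(iou_loss(b) >= 0 && iou_loss(b) <= 1)
  expect_gte(focal_tversky_loss(b), 0)
})

test_that("moving probability mass onto the true class never hurts", {
  set.seed(51)
  n <- 20; C <- 3
  logits <- matrix(rnorm(n * C), n, C)
  probs <- exp(logits) / rowSums(exp(logits))
  lab <- sample(0:(C - 1), n, TRUE)
  onehot <- matrix(0, n, C); onehot[cbind(1:n, lab + 1)] <- 1
  better <- probs
  for (i in 1:n) {
    wrong <- which(onehot[i, ] == 0)[1]
    shift <- 0.5 * better[i, wrong]
    better[i, wrong] <- better[i, wrong] - shift
    better[i, lab[i] + 1] <- better[i, lab[i] + 1] + shift
  }
  b0 <- loss_batch(probs, onehot); b1 <- loss_batch(better, onehot)
  expect_lte(wce_loss(b1), wce_loss(b0))
  expect_lte(dice_loss(b1), dice_loss(b0))
  expect_lte(iou_loss(b1), iou_loss(b0))
  expect_lte(focal_tversky_loss(b1), focal_tversky_loss(b0))
})

test_that("Dice and IOU satisfy the metric relation on binary pairs", {
  set.seed(61)
  for (rep in 1:10) {
    A <- matrix(rbinom(49, 1, 0.4), 7, 7)
    B <- matrix(rbinom(49, 1, 0.4), 7, 7)
    if (sum(A) + sum(B) == 0) next
    b <- pair_batch(A, B, eps = 1e-12)
    d <- 1 - dice_loss(b)
    expect_equal(iou_loss(b), 1 - d / (2 - d), tolerance = 1e-6)
  }
})

test_that("inverse-frequency class weights normalise to mean one", {
  lab <- c(rep(0L, 900), rep(1L, 90), rep(2L, 10))
  w <- class_weights_from_labels(lab, n_class = 3)
  expect_equal(mean(w), 1)
  expect_true(w[1] < w[2] && w[2] < w[3])
  # absent classes get the largest weight
  w9 <- class_weights_from_labels(lab, n_class = 4)
  expect_equal(w9[4], max(w9))
})
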