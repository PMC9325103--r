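## Segmentation losses: weighted cross-entropy, Dice, IOU, Focal-Tversky,
## boundary loss on signed distance maps, and their compounds. Every loss
## accepts a `loss_batch` and returns a scalar; `loss_grad()` returns the
## analytic gradient with respect to the predicted probabilities, which the
## U-net trainer chains through its softmax.
##
## Conventions. Class column 1 is background. Dice, IOU and Focal-Tversky
## are computed over the eight foreground classes only (background overlap
## would otherwise dominate); Dice is macro-averaged, IOU pools the
## foreground sums, Focal-Tversky sums per-class terms. Weighted
## cross-entropy runs over all nine classes. The Dice loss carries the
## conventional factor 2 in its numerator so that perfect overlap scores 0.

#' Assemble a loss batch
#'
#' Bundles predicted per-pixel class probabilities, one-hot ground truth,
#' class weights and loss hyper-parameters for one training step. Inputs may
#' be matrices `(pixels x classes)` or arrays with the class as final
#' dimension; they are flattened to pixel rows.
#'
#' @param probs predicted probabilities, rows summing to 1 (tolerance 1e-5)
#' @param onehot ground truth in `{0,1}`, same shape as `probs`
#' @param class_weights non-negative weights, one per class; default 1
#' @param epsilon Dice/Tversky smoothing, > 0 (default 1e-6)
#' @param tversky_alpha,tversky_beta false-positive / false-negative
#'   trade-off, must sum to 1 (defaults 0.7 / 0.3)
#' @param gamma Focal-Tversky focusing exponent in `[1, 3]` (default 4/3)
#' @param phi optional signed distance maps `(pixels x classes)` for the
#'   boundary loss, negative inside the ground-truth region
#' @param validate check probability normalisation and binary truth (the
#'   trainer disables this on its own softmax outputs)
#' @return a `loss_batch`
#' @export
loss_batch <- function(probs, onehot, class_weights = NULL, epsilon = 1e-6,
                       tversky_alpha = 0.7, tversky_beta = 0.3, gamma = 4 / 3,
                       phi = NULL, validate = TRUE) {
  to_mat <- function(x) {
    if (is.matrix(x)) return(x)
    d <- dim(x)
    matrix(x, nrow = prod(d[-length(d)]), ncol = d[length(d)])
  }
  probs <- to_mat(probs); onehot <- to_mat(onehot)
  if (!identical(dim(probs), dim(onehot))) stop("probs/onehot shape mismatch")
  C <- ncol(probs)
  if (is.null(class_weights)) class_weights <- rep(1, C)
  if (length(class_weights) != C) stop("need one class weight per class")
  if (any(class_weights < 0)) stop("class weights must be non-negative")
  if (epsilon <= 0) stop("epsilon must be > 0")
  if (abs(tversky_alpha + tversky_beta - 1) > 1e-9)
    stop("tversky_alpha + tversky_beta must equal 1")
  if (validate) {
    rs <- rowSums(probs)
    if (max(abs(rs - 1)) > 1e-5)
      stop("per-pixel class probabilities must sum to 1 (max deviation ",
           format(max(abs(rs - 1))), ")")
    if (!all(onehot %in% c(0, 1))) stop("onehot must be binary")
  }
  if (!is.null(phi)) {
    phi <- to_mat(phi)
    if (!identical(dim(phi), dim(probs))) stop("phi shape mismatch")
  }
  structure(list(probs = probs, onehot = onehot, class_weights = class_weights,
                 epsilon = epsilon, tversky_alpha = tversky_alpha,
                 tversky_beta = tversky_beta, gamma = gamma, phi = phi,
                 N = nrow(probs), true_col = max.col(onehot, "first")),
            class = "loss_batch")
}

.fg <- function(batch) 2:ncol(batch$probs)

#' Weighted cross-entropy loss
#'
#' `-(1/N) sum_c sum_i w_c g log s`, probabilities floored at 1e-12 before
#' the logarithm; N is the pixel count. Zero iff the prediction is the
#' one-hot truth.
#'
#' @param batch a [loss_batch()]
#' @return scalar >= 0
#' @export
wce_loss <- function(batch) {
  stopifnot(inherits(batch, "loss_batch"))
  # one-hot truth: only the true-class probability of each pixel contributes
  p_true <- pmax(batch$probs[cbind(seq_len(batch$N), batch$true_col)], 1e-12)
  -sum(batch$class_weights[batch$true_col] * log(p_true)) / batch$N
}

#' Dice (overlap) loss
#'
#' Soft Dice per foreground class,
#' `1 - (2 sum(p g) + eps) / (sum(p) + sum(g) + eps)`, macro-averaged.
#'
#' @param batch a [loss_batch()]
#' @param per_class return the per-class vector instead of the mean
#' @return scalar in `[0, 1]` (or vector when `per_class`)
#' @export
dice_loss <- function(batch, per_class = FALSE) {
  stopifnot(inherits(batch, "loss_batch"))
  fg <- .fg(batch); eps <- batch$epsilon
  p <- batch$probs[, fg, drop = FALSE]; g <- batch$onehot[, fg, drop = FALSE]
  num <- 2 * colSums(p * g) + eps
  den <- colSums(p) + colSums(g) + eps
  d <- 1 - num / den
  if (per_class) d else mean(d)
}

#' IOU (Jaccard) loss
#'
#' `1 - sum(g p) / sum(g + p - g p)`, with sums pooled over the foreground
#' classes.
#'
#' @param batch a [loss_batch()]
#' @return scalar in `[0, 1]`
#' @export
iou_loss <- function(batch) {
  stopifnot(inherits(batch, "loss_batch"))
  fg <- .fg(batch)
  p <- batch$probs[, fg, drop = FALSE]; g <- batch$onehot[, fg, drop = FALSE]
  i <- sum(g * p); u <- sum(g + p - g * p)
  if (u == 0) return(0)
  1 - i / u
}

#' Focal-Tversky loss
#'
#' `sum_c (1 - TI_c)^(1/gamma)` over foreground classes, where
#' `TI_c = (sum pg + eps) / (sum pg + alpha sum p(1-g) + beta sum (1-p)g + eps)`.
#' With `alpha = beta = 0.5` and `gamma = 1` each term reduces to the Dice
#' loss of that class.
#'
#' @param batch a [loss_batch()]; `gamma` must lie in `[1, 3]`
#' @return scalar >= 0
#' @export
focal_tversky_loss <- function(batch) {
  stopifnot(inherits(batch, "loss_batch"))
  if (batch$gamma < 1 || batch$gamma > 3)
    stop("gamma must lie in [1, 3]")
  fg <- .fg(batch); eps <- batch$epsilon
  p <- batch$probs[, fg, drop = FALSE]; g <- batch$onehot[, fg, drop = FALSE]
  i <- colSums(p * g)
  d <- i + batch$tversky_alpha * colSums(p * (1 - g)) +
    batch$tversky_beta * colSums((1 - p) * g)
  ti <- (i + eps) / (d + eps)
  sum((1 - ti)^(1 / batch$gamma))
}

#' Signed Euclidean distance map of a binary mask
#'
#' Level-set representation of the region boundary: zero exactly on the
#' boundary pixels of the mask (mask pixels 4-adjacent to background or to
#' the image border), negative in the strict interior, positive outside;
#' magnitudes are exact Euclidean distances to the nearest boundary pixel.
#'
#' @param mask binary 2D matrix, neither empty nor all-ones
#' @return numeric matrix of signed distances (pixel units)
#' @export
signed_distance_map <- function(mask) {
  mask <- mask > 0
  if (!any(mask) || all(mask))
    stop("degenerate mask: signed distance map needs a non-empty, non-full mask")
  n <- nrow(mask); m <- ncol(mask)
  pad <- matrix(FALSE, n + 2, m + 2); pad[2:(n + 1), 2:(m + 1)] <- mask
  interior <- pad[2:(n + 1), 1:m] & pad[2:(n + 1), 3:(m + 2)] &
    pad[1:n, 2:(m + 1)] & pad[3:(n + 2), 2:(m + 1)]
  boundary <- mask & !interior
  # distance of every pixel to the boundary set (EBImage: distance of
  # non-zero pixels to the nearest zero pixel)
  dist <- EBImage::distmap(matrix(as.numeric(!boundary), n, m))
  phi <- as.numeric(dist)
  dim(phi) <- c(n, m)
  phi[mask & !boundary] <- -phi[mask & !boundary]
  phi
}

#' Boundary loss
#'
#' `sum_p phi_G(p) s(p)` per foreground class, averaged over the classes
#' whose signed distance map is defined (classes absent from the batch are
#' skipped). Negative values reward probability mass strictly inside the
#' ground-truth region.
#'
#' @param batch a [loss_batch()] with `phi` populated
#' @return scalar (may be negative)
#' @export
boundary_loss <- function(batch) {
  stopifnot(inherits(batch, "loss_batch"))
  if (is.null(batch$phi)) stop("boundary loss needs phi (signed distance maps) in the batch")
  fg <- .fg(batch)
  keep <- fg[colSums(batch$onehot[, fg, drop = FALSE]) > 0]
  if (!length(keep)) return(0)
  mean(colSums(batch$phi[, keep, drop = FALSE] * batch$probs[, keep, drop = FALSE]))
}

.loss_recipes <- c("wce", "dice", "wce+dice", "ftl", "dice+boundary")

.recipe_members <- function(recipe) {
  if (!recipe %in% .loss_recipes)
    stop("unknown loss recipe '", recipe, "'; available: ",
         paste(.loss_recipes, collapse = ", "))
  strsplit(recipe, "+", fixed = TRUE)[[1]]
}

#' Compound (and single) loss by recipe
#'
#' Recipes mirror the training-protocol list: `wce`, `dice`, `wce+dice`,
#' `ftl`, `dice+boundary`. Compound members are combined with weight 1 each;
#' `boundary_weight` optionally scales the boundary member (used for the
#' linear ramp-in during training).
#'
#' @param batch a [loss_batch()]
#' @param recipe one of the recipe strings above
#' @param boundary_weight multiplier on the boundary member (default 1)
#' @return scalar loss
#' @export
compound_loss <- function(batch, recipe, boundary_weight = 1) {
  members <- .recipe_members(recipe)
  vals <- vapply(members, function(m) switch(m,
    wce = wce_loss(batch),
    dice = dice_loss(batch),
    iou = iou_loss(batch),
    ftl = focal_tversky_loss(batch),
    boundary = boundary_weight * boundary_loss(batch)), 0)
  sum(vals)
}

#' Loss gradient with respect to the predicted probabilities
#'
#' Analytic `d loss / d probs` for any recipe accepted by
#' [compound_loss()]; same shape as `batch$probs`. Used by the trainer,
#' which chains it through the network softmax.
#'
#' @inheritParams compound_loss
#' @return list with `loss` (scalar), `members` (named member values) and
#'   `grad` (matrix, pixels x classes)
#' @export
loss_grad <- function(batch, recipe, boundary_weight = 1) {
  members <- .recipe_members(recipe)
  p <- batch$probs; g <- batch$onehot
  fg <- .fg(batch); eps <- batch$epsilon
  grad <- matrix(0, nrow(p), ncol(p))
  vals <- numeric(0)
  for (m in members) {
    if (m == "wce") {
      v <- wce_loss(batch)
      gm <- matrix(0, nrow(p), ncol(p))
      ij <- cbind(seq_len(batch$N), batch$true_col)
      gm[ij] <- -batch$class_weights[batch$true_col] / pmax(p[ij], 1e-12) / batch$N
    } else if (m == "dice") {
      v <- dice_loss(batch)
      gm <- matrix(0, nrow(p), ncol(p))
      k <- length(fg)
      for (c in fg) {
        I <- sum(p[, c] * g[, c]); S <- sum(p[, c]) + sum(g[, c])
        gm[, c] <- -(2 * g[, c] * (S + eps) - (2 * I + eps)) / (S + eps)^2 / k
      }
    } else if (m == "ftl") {
      v <- focal_tversky_loss(batch)
      gm <- matrix(0, nrow(p), ncol(p))
      a <- batch$tversky_alpha; b <- batch$tversky_beta; gam <- batch$gamma
      for (c in fg) {
        I <- sum(p[, c] * g[, c])
        D <- I + a * sum(p[, c] * (1 - g[, c])) + b * sum((1 - p[, c]) * g[, c])
        ti <- (I + eps) / (D + eps)
        dD <- g[, c] + a * (1 - g[, c]) - b * g[, c]
        dti <- (g[, c] * (D + eps) - (I + eps) * dD) / (D + eps)^2
        gm[, c] <- -(1 / gam) * (1 - ti)^(1 / gam - 1) * dti
      }
    } else if (m == "boundary") {
      v <- boundary_weight * boundary_loss(batch)
      gm <- matrix(0, nrow(p), ncol(p))
      keep <- fg[colSums(g[, fg, drop = FALSE]) > 0]
      if (length(keep))
        gm[, keep] <- boundary_weight * batch$phi[, keep, drop = FALSE] / length(keep)
    } else stop("no gradient for member '", m, "'")
    vals[m] <- v
    grad <- grad + gm
  }
  list(loss = sum(vals), members = vals, grad = grad)
}

#' Inverse-frequency class weights
#'
#' Weight per class proportional to the inverse of its relative pixel
#' frequency over a training label set, normalised to mean 1. Classes absent
#' from the set receive the largest observed weight.
#'
#' @param labels integer vector/array(s) of labels 0..8, or a list of them
#' @param n_class total number of classes (default 9)
#' @return numeric weight vector of length `n_class`
#' @export
class_weights_from_labels <- function(labels, n_class = n_classes()) {
  if (is.list(labels)) labels <- unlist(labels, use.names = FALSE)
  counts <- tabulate(as.integer(labels) + 1L, nbins = n_class)
  freq <- counts / sum(counts)
  w <- ifelse(freq > 0, 1 / freq, NA)
  w[is.na(w)] <- max(w, na.rm = TRUE)
  w / mean(w)
}
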