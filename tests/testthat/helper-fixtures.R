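# Shared fixtures, built lazily and cached for the whole test session.

.fixtures <- new.env(parent = emptyenv())

fixture_phantom <- function(seed = 42) {
  key <- paste0("ph", seed)
  if (is.null(.fixtures[[key]]))
    .fixtures[[key]] <- generate_phantom(phantom_spec(seed = seed))
  .fixtures[[key]]
}

# a small prepared cohort (resampled + windowed) for training-related tests
fixture_studies <- function(n = 4, seed = 123) {
  key <- paste0("studies", n, "_", seed)
  if (is.null(.fixtures[[key]])) {
    cohort <- phantom_cohort(n, seed = seed)
    .fixtures[[key]] <- lapply(cohort, function(ph) prepare_study(ph$ct, ph$labels))
  }
  .fixtures[[key]]
}

# rasterise a binary ellipse/disk mask on a unit grid (test-side oracle input)
raster_ellipse <- function(n, center, a, b, angle_deg) {
  th <- angle_deg * pi / 180
  g <- expand.grid(r = seq_len(n) - 0.5, c = seq_len(n) - 0.5)
  dr <- g$r - center[1]; dc <- g$c - center[2]
  u <- dr * cos(th) + dc * sin(th)
  v <- -dr * sin(th) + dc * cos(th)
  matrix((u / a)^2 + (v / b)^2 <= 1, n, n)
}

# exhaustive rotating-caliper width oracle: minimum over directions of the
# projection width of the pixel-corner point set (independent of the
# rotating-calipers implementation under test)
caliper_width_oracle <- function(mask, spacing = c(1, 1), angles = 0:179) {
  w <- which(mask, arr.ind = TRUE)
  corners <- rbind(cbind(w[, 1] - 1, w[, 2] - 1), cbind(w[, 1] - 1, w[, 2]),
                   cbind(w[, 1], w[, 2] - 1), cbind(w[, 1], w[, 2]))
  pts <- cbind(corners[, 1] * spacing[1], corners[, 2] * spacing[2])
  widths <- sapply(angles, function(a) {
    th <- a * pi / 180
    p <- pts[, 1] * cos(th) + pts[, 2] * sin(th)
    max(p) - min(p)
  })
  min(widths)
}

# brute-force signed distance oracle: all-pairs distances to boundary pixels
sdm_oracle <- function(mask) {
  mask <- mask > 0
  n <- nrow(mask); m <- ncol(mask)
  pad <- matrix(FALSE, n + 2, m + 2); pad[2:(n + 1), 2:(m + 1)] <- mask
  interior <- pad[2:(n + 1), 1:m] & pad[2:(n + 1), 3:(m + 2)] &
    pad[1:n, 2:(m + 1)] & pad[3:(n + 2), 2:(m + 1)]
  boundary <- which(mask & !interior, arr.ind = TRUE)
  phi <- matrix(0, n, m)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    d <- sqrt(min((boundary[, 1] - i)^2 + (boundary[, 2] - j)^2))
    phi[i, j] <- if (mask[i, j] && interior[i, j]) -d else d
  }
  phi
}

# construct a binary-pair loss batch with one foreground class
pair_batch <- function(pred, truth, eps = 1e-6, ...) {
  p <- as.numeric(pred); g <- as.numeric(truth)
  loss_batch(cbind(1 - p, p), cbind(1 - g, g), epsilon = eps, ...)
}
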