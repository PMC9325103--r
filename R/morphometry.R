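## Muscle size measurement from multiclass label volumes: per-slice
## thickness from the minimum-area rotated rectangle enclosing the muscle
## cross-section, per-slice area from the pixel count, and per-muscle
## maxima across slices.

#' Minimum-area rotated rectangle of a point set
#'
#' Rotating-calipers search over the convex hull: the minimum-area
#' enclosing rectangle has one side collinear with a hull edge, so
#' examining every hull edge is exact. Coordinates may be in any unit
#' (morphometry passes pixel corners scaled to mm).
#'
#' @param pts two-column matrix of (row, col) coordinates
#' @return list with `center`, `long`, `short`, `angle_deg` (direction of
#'   the long side, degrees from the row axis)
#' @export
min_area_rect <- function(pts) {
  pts <- as.matrix(pts)
  if (nrow(pts) < 2 ||
      (diff(range(pts[, 1])) == 0 && diff(range(pts[, 2])) == 0))
    stop("need at least two distinct points")
  h <- grDevices::chull(pts)
  hull <- pts[h, , drop = FALSE]
  n <- nrow(hull)
  edges <- hull[c(2:n, 1), , drop = FALSE] - hull
  best <- NULL
  for (i in seq_len(n)) {
    e <- edges[i, ]
    len <- sqrt(sum(e^2))
    if (len < 1e-12) next
    u <- e / len
    v <- c(-u[2], u[1])
    pu <- hull %*% u; pv <- hull %*% v
    du <- max(pu) - min(pu); dv <- max(pv) - min(pv)
    if (is.null(best) || du * dv < best$area - 1e-12) {
      ctr_u <- (max(pu) + min(pu)) / 2; ctr_v <- (max(pv) + min(pv)) / 2
      best <- list(area = du * dv,
                   center = as.numeric(ctr_u * u + ctr_v * v),
                   sides = c(du, dv), u = u, v = v)
    }
  }
  long <- max(best$sides); short <- min(best$sides)
  dir_long <- if (best$sides[1] >= best$sides[2]) best$u else best$v
  list(center = best$center, long = long, short = short,
       angle_deg = (atan2(dir_long[2], dir_long[1]) * 180 / pi) %% 180)
}

## pixel-corner point set of a binary mask, scaled to physical mm.
## Pixels are unit squares: pixel (r, c) covers [r-1, r] x [c-1, c], so a
## w x h pixel block measures exactly w, h.
.mask_corners_mm <- function(mask, spacing) {
  # the hull only depends on boundary pixels; duplicates are harmless
  n <- nrow(mask); m <- ncol(mask)
  pad <- matrix(FALSE, n + 2, m + 2); pad[2:(n + 1), 2:(m + 1)] <- mask
  interior <- pad[2:(n + 1), 1:m] & pad[2:(n + 1), 3:(m + 2)] &
    pad[1:n, 2:(m + 1)] & pad[3:(n + 2), 2:(m + 1)]
  w <- which(mask & !interior, arr.ind = TRUE)
  corners <- rbind(cbind(w[, 1] - 1L, w[, 2] - 1L), cbind(w[, 1] - 1L, w[, 2]),
                   cbind(w[, 1], w[, 2] - 1L), cbind(w[, 1], w[, 2]))
  cbind(corners[, 1] * spacing[1], corners[, 2] * spacing[2])
}

## largest 8-connected component of a binary mask
.largest_component <- function(mask) {
  lbl <- EBImage::bwlabel(matrix(as.numeric(mask), nrow(mask), ncol(mask)))
  lbl <- round(as.numeric(lbl)); dim(lbl) <- dim(mask)
  counts <- tabulate(lbl[lbl > 0])
  if (length(counts) > 1L)
    mask <- lbl == which.max(counts)
  mask
}

#' Per-slice muscle thickness
#'
#' Thickness of one muscle cross-section on one coronal slice: the short
#' side of the minimum-area rotated rectangle enclosing the pixel corners of
#' the largest connected component, in mm. Anisotropic pixel spacing is
#' handled by mapping corners to physical coordinates before fitting.
#'
#' @param mask binary 2D matrix (one muscle class on one slice)
#' @param pixel_spacing mm per pixel (row, col); a scalar is recycled
#' @return list with `thickness_mm` (NA for an empty mask — an absent
#'   muscle is a signal, not an error) and `rect` (the fitted rectangle)
#' @export
slice_thickness <- function(mask, pixel_spacing = 1) {
  pixel_spacing <- rep_len(as.numeric(pixel_spacing), 2L)
  mask <- mask > 0
  if (!any(mask)) return(list(thickness_mm = NA_real_, rect = NULL))
  mask <- .largest_component(mask)
  rect <- min_area_rect(.mask_corners_mm(mask, pixel_spacing))
  list(thickness_mm = rect$short, rect = rect)
}

#' Per-slice cross-sectional area
#'
#' Pixel count times pixel area; an empty mask has area 0.
#'
#' @param mask binary 2D matrix
#' @param pixel_spacing mm per pixel (row, col); scalar recycled
#' @return area in mm^2
#' @export
slice_area <- function(mask, pixel_spacing = 1) {
  pixel_spacing <- rep_len(as.numeric(pixel_spacing), 2L)
  sum(mask > 0) * pixel_spacing[1] * pixel_spacing[2]
}

#' Measure per-muscle thickness and area over a label volume
#'
#' For every muscle class: per-slice thickness and area profiles, and the
#' maxima across coronal slices with the slice indices achieving them (the
#' reported muscle thickness and cross-sectional area). Classes absent from
#' the whole volume are reported as absent, not as zero.
#'
#' @param labels a [label_volume()] (typically on the native grid, after
#'   [restore_native_grid()])
#' @return a `size_report`: list with `table` (one row per muscle class:
#'   thickness_mm, thickness_slice, area_mm2, area_slice, present) and
#'   `profiles` (per-class data.frames with slice, thickness_mm, area_mm2,
#'   n_pixels)
#' @export
measure_volume <- function(labels) {
  stopifnot(inherits(labels, "label_volume"))
  sp <- labels$pixel_spacing
  nz <- dim(labels$labels)[3]
  profiles <- list()
  tab <- NULL
  for (cls in muscle_classes()) {
    t_prof <- rep(NA_real_, nz); a_prof <- numeric(nz); n_prof <- integer(nz)
    for (k in seq_len(nz)) {
      mask <- labels$labels[, , k] == cls
      n_prof[k] <- sum(mask)
      a_prof[k] <- slice_area(mask, sp)
      if (n_prof[k] > 0) t_prof[k] <- slice_thickness(mask, sp)$thickness_mm
    }
    present <- any(n_prof > 0)
    profiles[[class_name(cls)]] <- data.frame(
      slice = seq_len(nz), thickness_mm = t_prof, area_mm2 = a_prof,
      n_pixels = n_prof)
    tab <- rbind(tab, data.frame(
      class = cls, name = class_name(cls), present = present,
      thickness_mm = if (present) max(t_prof, na.rm = TRUE) else NA_real_,
      thickness_slice = if (present) which.max(t_prof) else NA_integer_,
      area_mm2 = if (present) max(a_prof) else NA_real_,
      area_slice = if (present) which.max(a_prof) else NA_integer_,
      stringsAsFactors = FALSE))
  }
  structure(list(table = tab, profiles = profiles,
                 pixel_spacing = sp, source_id = labels$source_id),
            class = "size_report")
}

#' @export
print.size_report <- function(x, ...) {
  cat("size_report for '", x$source_id, "':\n", sep = "")
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Export a size report
#'
#' CSV carries one row per muscle class (maximum thickness and area plus the
#' slices achieving them); JSON additionally carries the full per-slice
#' profiles.
#'
#' @param report a `size_report`
#' @param csv,json output paths (either may be `NULL`)
#' @return invisibly, the paths written
#' @export
write_size_report <- function(report, csv = NULL, json = NULL) {
  stopifnot(inherits(report, "size_report"))
  if (!is.null(csv))
    utils::write.csv(report$table, csv, row.names = FALSE)
  if (!is.null(json))
    jsonlite::write_json(list(table = report$table, profiles = report$profiles,
                              source_id = report$source_id),
                         json, dataframe = "rows", digits = NA, na = "null")
  invisible(c(csv = csv, json = json))
}
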