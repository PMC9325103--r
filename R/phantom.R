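## Synthetic orbital CT phantom.
##
## Emulates contrast-enhanced coronal CT of the orbits: two orbits per
## slice, each bounded by a high-HU bony rim, filled with low-HU fat,
## containing a globe and four near-elliptical rectus-muscle cross-sections
## whose sizes taper towards the tendinous origin (posterior) and the globe
## insertion (anterior). Every phantom comes with a voxel-exact label volume
## and the analytic per-muscle size parameters (the oracle that morphometry
## must recover).

.tbl_thickness_mean <- c(4.87, 5.50, 4.79, 5.23, 4.74, 5.62, 4.85, 5.13)
.tbl_thickness_sd   <- c(0.84, 1.13, 0.93, 1.07, 0.66, 1.41, 1.04, 1.08)
.tbl_area_mean      <- c(38.93, 46.03, 38.29, 41.57, 38.14, 47.20, 40.10, 42.38)
.tbl_area_sd        <- c(8.54, 10.03, 9.66, 11.78, 6.88, 14.29, 13.79, 14.24)

#' Phantom specification
#'
#' Collects every knob of the synthetic orbital CT generator. Defaults are
#' calibrated to normative adult extraocular-muscle sizes (belly thickness
#' means 4.7-5.9 mm, maximum cross-sectional areas 38-50 mm^2), a 3 mm
#' coronal reconstruction, and mildly anisotropic in-plane pixel spacing.
#'
#' @param n_slices number of coronal slices (default 16)
#' @param in_plane_spacing mm per pixel (row, col), each in `[0.3, 0.5]`
#' @param slice_spacing mm between coronal slices (default 3)
#' @param fov_mm in-plane field of view in mm (square, default 144)
#' @param thickness_mm named or ordered numeric(8): belly short-axis
#'   diameter per muscle class in canonical order
#' @param long_axis_mm numeric(8): belly long-axis diameter; default derived
#'   from the target areas via the ellipse model `A = pi/4 * t * l`
#' @param area_mm2 numeric(8): target belly cross-sectional areas used to
#'   derive `long_axis_mm` when the latter is not given
#' @param muscle_hu,fat_hu,bone_hu,globe_hu mean tissue intensities in HU
#' @param noise_sd_hu Gaussian intensity noise added to the HU image
#' @param taper_profile fractional size multiplier per muscle-bearing slice
#'   (values in (0,1], maximum 1 in the central third), or `NULL` for the
#'   default smooth belly profile
#' @param orientation_jitter_deg max absolute rotation jitter of each
#'   muscle's long axis away from its anatomical direction (default 15)
#' @param seed integer seed; identical seeds give bit-identical phantoms
#' @return a `phantom_spec` list
#' @export
phantom_spec <- function(n_slices = 16L,
                         in_plane_spacing = c(0.4, 0.45),
                         slice_spacing = 3,
                         fov_mm = 144,
                         thickness_mm = .tbl_thickness_mean,
                         long_axis_mm = NULL,
                         area_mm2 = .tbl_area_mean,
                         muscle_hu = 70, fat_hu = -80, bone_hu = 700, globe_hu = 35,
                         noise_sd_hu = 8,
                         taper_profile = NULL,
                         orientation_jitter_deg = 15,
                         seed = 1L) {
  if (is.null(long_axis_mm)) long_axis_mm <- 4 * area_mm2 / (pi * thickness_mm)
  spec <- list(n_slices = as.integer(n_slices),
               in_plane_spacing = as.numeric(in_plane_spacing),
               slice_spacing = slice_spacing, fov_mm = fov_mm,
               thickness_mm = as.numeric(thickness_mm),
               long_axis_mm = as.numeric(long_axis_mm),
               muscle_hu = muscle_hu, fat_hu = fat_hu,
               bone_hu = bone_hu, globe_hu = globe_hu,
               noise_sd_hu = noise_sd_hu,
               taper_profile = taper_profile,
               orientation_jitter_deg = orientation_jitter_deg,
               seed = as.integer(seed))
  class(spec) <- "phantom_spec"
  validate_phantom_spec(spec)
  spec
}

#' @rdname phantom_spec
#' @param spec object to validate
#' @export
validate_phantom_spec <- function(spec) {
  if (length(spec$thickness_mm) != 8L) stop("invalid phantom spec field 'thickness_mm': need 8 values")
  if (length(spec$long_axis_mm) != 8L) stop("invalid phantom spec field 'long_axis_mm': need 8 values")
  if (any(spec$thickness_mm > spec$long_axis_mm + 1e-9))
    stop("invalid phantom spec field 'thickness_mm': thickness_mm must be <= long_axis_mm for every muscle")
  if (length(spec$in_plane_spacing) != 2L ||
      any(spec$in_plane_spacing < 0.3 - 1e-9) || any(spec$in_plane_spacing > 0.5 + 1e-9))
    stop("invalid phantom spec field 'in_plane_spacing': each spacing must lie in [0.3, 0.5] mm")
  if (spec$muscle_hu < -75 || spec$muscle_hu > 175)
    stop("invalid phantom spec field 'muscle_hu': must lie inside the display window [-75, 175]")
  if (spec$n_slices < 5L) stop("invalid phantom spec field 'n_slices': need at least 5 slices")
  if (spec$noise_sd_hu < 0) stop("invalid phantom spec field 'noise_sd_hu': must be >= 0")
  if (!is.null(spec$taper_profile)) {
    tp <- spec$taper_profile
    n <- length(tp)
    if (any(tp <= 0) || any(tp > 1))
      stop("invalid phantom spec field 'taper_profile': values must lie in (0, 1]")
    central <- seq.int(floor(n / 3) + 1L, ceiling(2 * n / 3))
    if (abs(max(tp) - 1) > 1e-9 || max(tp[central]) < max(tp) - 1e-9)
      stop("invalid phantom spec field 'taper_profile': maximum must be 1 and lie in the central third")
  }
  invisible(spec)
}

## default smooth taper over n muscle-bearing slices: thin near insertion
## and origin, belly (multiplier 1) at the centre
.default_taper <- function(n) {
  tp <- 0.45 + 0.55 * sin(pi * (seq_len(n) - 0.5) / n)^0.7
  tp / max(tp)
}

## anatomical layout of the 8 muscle classes: side, in-orbit direction of the
## muscle centre, and long-axis direction (degrees from the vertical/row axis).
## Thickness of medial/lateral recti is horizontal => long axis vertical (0);
## thickness of superior/inferior is vertical => long axis horizontal (90).
.muscle_layout <- function() {
  data.frame(
    class = 1:8,
    side = rep(c("L", "R"), each = 4),
    # unit direction (drow, dcol) from the orbit centre towards the muscle;
    # medial = towards the midline, which for the left orbit is +col
    drow = rep(c(0, 0, -1, 1), 2),
    dcol = c(1, -1, 0, 0, -1, 1, 0, 0),
    long_axis_deg = rep(c(0, 0, 90, 90), 2)
  )
}

#' Generate one synthetic orbital CT phantom
#'
#' @param spec a [phantom_spec()]
#' @return list with components `ct` ([ct_volume()]), `labels`
#'   ([label_volume()]) and `truth` (data.frame with one row per muscle
#'   class: analytic belly `thickness_mm`, `long_axis_mm`, `area_mm2` and
#'   the 1-based `belly_slice` index)
#' @export
generate_phantom <- function(spec) {
  validate_phantom_spec(spec)
  restore <- .seed_guard(spec$seed)
  on.exit(restore())

  sp <- spec$in_plane_spacing
  nd <- as.integer(.round_half_up(spec$fov_mm / sp))   # rows, cols
  nz <- spec$n_slices
  ctr <- spec$fov_mm / 2
  orbit_off <- 26                       # orbit centres at fov/2 -/+ 26 mm
  orbit_ctr <- list(L = c(ctr, ctr - orbit_off), R = c(ctr, ctr + orbit_off))

  muscle_slices <- 2:(nz - 1)
  n_m <- length(muscle_slices)
  tp <- spec$taper_profile
  if (is.null(tp)) tp <- .default_taper(n_m)
  if (length(tp) != n_m)
    stop("invalid phantom spec field 'taper_profile': need one value per muscle-bearing slice (", n_m, ")")
  belly_local <- which.max(tp)

  lay <- .muscle_layout()
  jit <- stats::runif(8, -spec$orientation_jitter_deg, spec$orientation_jitter_deg)
  angles <- lay$long_axis_deg + jit
  # straight muscle paths converging towards the orbital apex posteriorly
  radius_path <- seq(12.5, 9, length.out = n_m)

  rows_mm <- (seq_len(nd[1]) - 0.5) * sp[1]
  cols_mm <- (seq_len(nd[2]) - 0.5) * sp[2]

  labels <- array(0L, c(nd, nz))
  hu <- array(spec$fat_hu, c(nd, nz))

  ## ellipse rasteriser on the physical grid, evaluated inside its bbox only
  paint_ellipse <- function(ctr_rc, a, b, phi_deg) {
    th <- phi_deg * pi / 180
    ext <- max(a, b) + max(sp)
    ri <- which(rows_mm >= ctr_rc[1] - ext & rows_mm <= ctr_rc[1] + ext)
    ci <- which(cols_mm >= ctr_rc[2] - ext & cols_mm <= ctr_rc[2] + ext)
    if (!length(ri) || !length(ci)) return(NULL)
    dr <- rows_mm[ri] - ctr_rc[1]; dc <- cols_mm[ci] - ctr_rc[2]
    u <- outer(dr, dc, function(r, c)  r * cos(th) + c * sin(th))
    v <- outer(dr, dc, function(r, c) -r * sin(th) + c * cos(th))
    inside <- (u / a)^2 + (v / b)^2 <= 1
    list(ri = ri, ci = ci, inside = inside)
  }

  globe_ctr_slice <- 2.5
  globe_r <- 10.5

  for (k in seq_len(nz)) {
    sl <- labels[, , k]

    ## bony orbital rim: annulus, wide anteriorly, narrowing to the apex
    frac <- (k - 1) / (nz - 1)
    r_in <- 19 - 5 * frac
    r_out <- r_in + 3.5
    for (side in c("L", "R")) {
      oc <- orbit_ctr[[side]]
      dr <- rows_mm - oc[1]
      dc <- cols_mm - oc[2]
      rad2 <- outer(dr^2, dc^2, "+")
      ring <- rad2 >= r_in^2 & rad2 <= r_out^2
      hu_k <- hu[, , k]; hu_k[ring] <- spec$bone_hu; hu[, , k] <- hu_k

      ## globe: sphere centred a few slices into the stack
      dz <- (k - globe_ctr_slice) * spec$slice_spacing
      if (abs(dz) < globe_r) {
        gr <- sqrt(globe_r^2 - dz^2)
        gl <- rad2 <= gr^2
        hu_k <- hu[, , k]; hu_k[gl] <- spec$globe_hu; hu[, , k] <- hu_k
      }
    }

    ## muscles (painted last so labels partition the voxels)
    mi <- match(k, muscle_slices)
    if (!is.na(mi)) {
      scl <- tp[mi]
      for (m in 1:8) {
        oc <- orbit_ctr[[lay$side[m]]]
        cc <- c(oc[1] + lay$drow[m] * radius_path[mi],
                oc[2] + lay$dcol[m] * radius_path[mi])
        a <- spec$long_axis_mm[m] / 2 * scl
        b <- spec$thickness_mm[m] / 2 * scl
        pe <- paint_ellipse(cc, a, b, angles[m])
        if (!is.null(pe)) {
          sub <- sl[pe$ri, pe$ci]
          sub[pe$inside] <- m
          sl[pe$ri, pe$ci] <- sub
          hu_k <- hu[, , k]
          hsub <- hu_k[pe$ri, pe$ci]; hsub[pe$inside] <- spec$muscle_hu
          hu_k[pe$ri, pe$ci] <- hsub; hu[, , k] <- hu_k
        }
      }
    }
    labels[, , k] <- sl
  }

  if (spec$noise_sd_hu > 0)
    hu <- hu + array(stats::rnorm(length(hu), 0, spec$noise_sd_hu), dim(hu))

  truth <- data.frame(
    class = 1:8,
    name = class_name(1:8),
    thickness_mm = spec$thickness_mm,
    long_axis_mm = spec$long_axis_mm,
    area_mm2 = pi / 4 * spec$thickness_mm * spec$long_axis_mm,
    belly_slice = muscle_slices[belly_local],
    stringsAsFactors = FALSE
  )

  sid <- sprintf("phantom_%08d", spec$seed %% 1e8)
  list(ct = ct_volume(hu, sp, spec$slice_spacing, source_id = sid),
       labels = label_volume(labels, sp, spec$slice_spacing, source_id = sid),
       truth = truth,
       spec = spec)
}

#' Generate a cohort of phantoms with subject-level size variability
#'
#' Draws `n` independent phantoms whose per-muscle belly thickness and area
#' targets are sampled around the base specification (Gaussian, truncated to
#' anatomically sensible ranges), with the long axis re-derived from the
#' ellipse area model. In-plane spacings are jittered within +/- 0.05 mm of
#' the base values.
#'
#' @param n cohort size, >= 1
#' @param base_spec a [phantom_spec()]; its `thickness_mm` / area targets act
#'   as the population means
#' @param thickness_sd,area_sd numeric(8) (or scalar) population standard
#'   deviations; defaults follow the normative calibration; set 0 for
#'   identical subjects
#' @param spacing_jitter max absolute deviation of each in-plane spacing
#'   from the base value (default 0.05 mm; spacings stay inside [0.3, 0.5])
#' @param seed integer cohort seed
#' @param specs_only return only the per-subject `phantom_spec`s without
#'   rasterising the volumes (for sampling-distribution checks on the drawn
#'   size targets)
#' @return list of `n` phantom triples as returned by [generate_phantom()]
#'   (or of `phantom_spec`s when `specs_only`)
#' @export
phantom_cohort <- function(n, base_spec = phantom_spec(),
                           thickness_sd = .tbl_thickness_sd,
                           area_sd = .tbl_area_sd,
                           spacing_jitter = 0.05,
                           seed = 1L, specs_only = FALSE) {
  if (!is.numeric(n) || n < 1) stop("cohort size n must be >= 1")
  n <- as.integer(n)
  thickness_sd <- rep_len(thickness_sd, 8L)
  area_sd <- rep_len(area_sd, 8L)
  base_area <- pi / 4 * base_spec$thickness_mm * base_spec$long_axis_mm
  restore <- .seed_guard(seed)
  on.exit(restore())
  seeds <- sample.int(.Machine$integer.max - 1L, n)
  lapply(seq_len(n), function(i) {
    th <- pmin(pmax(stats::rnorm(8, base_spec$thickness_mm, thickness_sd), 3), 9)
    ar <- pmin(pmax(stats::rnorm(8, base_area, area_sd), 20), 85)
    la <- pmax(4 * ar / (pi * th), th)
    sp2 <- base_spec$in_plane_spacing +
      stats::runif(2, -spacing_jitter, spacing_jitter)
    sp2 <- pmin(pmax(sp2, 0.3), 0.5)
    spec_i <- base_spec
    spec_i$thickness_mm <- th
    spec_i$long_axis_mm <- la
    spec_i$in_plane_spacing <- sp2
    spec_i$seed <- seeds[i]
    validate_phantom_spec(spec_i)
    if (specs_only) spec_i else generate_phantom(spec_i)
  })
}

#' Write a phantom to disk
#'
#' Writes the HU image (`<stem>_image.nii.gz`, float32), the label volume
#' (`<stem>_labels.nii.gz`, uint8) and the analytic truth table
#' (`<stem>_truth.json`).
#'
#' @param ph a phantom triple from [generate_phantom()]
#' @param dir output directory (created if needed)
#' @param stem filename stem; defaults to the phantom's source id
#' @return named character vector of the three paths, invisibly
#' @export
write_phantom <- function(ph, dir, stem = ph$ct$source_id) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p_img <- file.path(dir, paste0(stem, "_image.nii.gz"))
  p_lab <- file.path(dir, paste0(stem, "_labels.nii.gz"))
  p_tru <- file.path(dir, paste0(stem, "_truth.json"))
  write_ct_nifti(ph$ct, p_img)
  write_labels_nifti(ph$labels, p_lab)
  jsonlite::write_json(ph$truth, p_tru, dataframe = "rows", digits = NA)
  invisible(c(image = p_img, labels = p_lab, truth = p_tru))
}
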