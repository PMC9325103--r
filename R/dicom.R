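## Minimal DICOM support for coronal CT series.
##
## No DICOM package ships with this toolchain, so the package carries a
## deliberately small reader/writer pair restricted to what CT series need:
## single-frame monochrome images, uncompressed little-endian transfer
## syntaxes (explicit VR 1.2.840.10008.1.2.1 and implicit VR 1.2.840.10008.1.2),
## 16-bit pixel data with rescale slope/intercept. Compressed or big-endian
## syntaxes are rejected with a clear error.

.dcm_explicit_uid <- "1.2.840.10008.1.2.1"
.dcm_implicit_uid <- "1.2.840.10008.1.2"
.dcm_ct_sop_class <- "1.2.840.10008.5.1.4.1.1.2"

.dcm_pad <- function(x, pad = as.raw(0x20)) {
  if (length(x) %% 2L == 1L) x <- c(x, pad)
  x
}

.dcm_str <- function(s, ui = FALSE) {
  .dcm_pad(charToRaw(s), pad = if (ui) as.raw(0) else as.raw(0x20))
}

.dcm_u16 <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
.dcm_u32 <- function(x) {
  # unsigned 32-bit little-endian without integer overflow
  x <- as.numeric(x)
  as.raw(c(x %% 256, (x %/% 256) %% 256, (x %/% 65536) %% 256, (x %/% 16777216) %% 256))
}

## one explicit-VR element as raw bytes
.dcm_elem <- function(group, elem, vr, value_raw) {
  n <- length(value_raw)
  head <- c(.dcm_u16(group), .dcm_u16(elem), charToRaw(vr))
  if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
    c(head, as.raw(c(0, 0)), .dcm_u32(n), value_raw)
  } else {
    if (n > 65535) stop("element too long for short-form VR")
    c(head, .dcm_u16(n), value_raw)
  }
}

#' Write a CT volume as a DICOM series
#'
#' One explicit-VR little-endian file per coronal slice, with PixelSpacing,
#' SpacingBetweenSlices, ImagePositionPatient and HU rescale tags populated,
#' suitable for [read_volume()] and for third-party DICOM tooling.
#'
#' @param vol a [ct_volume()]
#' @param dir output directory (created if needed); files named `slice_###.dcm`
#' @return character vector of file paths, invisibly
#' @export
write_dicom_series <- function(vol, dir) {
  stopifnot(inherits(vol, "ct_volume"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  d <- dim(vol$voxels)
  uid_base <- sprintf("1.2.826.0.1.3680043.9.7433.%d", sample.int(1e8, 1))
  paths <- character(d[3])
  for (k in seq_len(d[3])) {
    sl <- vol$voxels[, , k]
    # HU stored as signed 16-bit with identity rescale
    raw_px <- writeBin(as.integer(round(as.vector(t(sl)))), raw(), size = 2, endian = "little")
    ds <- c(
      .dcm_elem(0x0008, 0x0016, "UI", .dcm_str(.dcm_ct_sop_class, ui = TRUE)),
      .dcm_elem(0x0008, 0x0018, "UI", .dcm_str(sprintf("%s.%d", uid_base, k), ui = TRUE)),
      .dcm_elem(0x0008, 0x0060, "CS", .dcm_str("CT")),
      .dcm_elem(0x0020, 0x000D, "UI", .dcm_str(paste0(uid_base, ".s"), ui = TRUE)),
      .dcm_elem(0x0020, 0x000E, "UI", .dcm_str(paste0(uid_base, ".se"), ui = TRUE)),
      .dcm_elem(0x0020, 0x0013, "IS", .dcm_str(sprintf("%d", k))),
      # coronal: slice index advances along the anteroposterior (y) axis
      .dcm_elem(0x0020, 0x0032, "DS",
                .dcm_str(sprintf("0\\%.10g\\0", (k - 1) * vol$slice_spacing))),
      .dcm_elem(0x0018, 0x0050, "DS", .dcm_str(sprintf("%.10g", vol$slice_spacing))),
      .dcm_elem(0x0018, 0x0088, "DS", .dcm_str(sprintf("%.10g", vol$slice_spacing))),
      .dcm_elem(0x0028, 0x0002, "US", .dcm_u16(1)),
      .dcm_elem(0x0028, 0x0004, "CS", .dcm_str("MONOCHROME2")),
      .dcm_elem(0x0028, 0x0010, "US", .dcm_u16(d[1])),
      .dcm_elem(0x0028, 0x0011, "US", .dcm_u16(d[2])),
      .dcm_elem(0x0028, 0x0030, "DS",
                .dcm_str(sprintf("%.10g\\%.10g", vol$pixel_spacing[1], vol$pixel_spacing[2]))),
      .dcm_elem(0x0028, 0x0100, "US", .dcm_u16(16)),
      .dcm_elem(0x0028, 0x0101, "US", .dcm_u16(16)),
      .dcm_elem(0x0028, 0x0102, "US", .dcm_u16(15)),
      .dcm_elem(0x0028, 0x0103, "US", .dcm_u16(1)),
      .dcm_elem(0x0028, 0x1052, "DS", .dcm_str("0")),
      .dcm_elem(0x0028, 0x1053, "DS", .dcm_str("1")),
      .dcm_elem(0x7FE0, 0x0010, "OW", raw_px)
    )
    meta_body <- c(
      .dcm_elem(0x0002, 0x0002, "UI", .dcm_str(.dcm_ct_sop_class, ui = TRUE)),
      .dcm_elem(0x0002, 0x0003, "UI", .dcm_str(sprintf("%s.%d", uid_base, k), ui = TRUE)),
      .dcm_elem(0x0002, 0x0010, "UI", .dcm_str(.dcm_explicit_uid, ui = TRUE))
    )
    meta <- c(.dcm_elem(0x0002, 0x0000, "UL", .dcm_u32(length(meta_body))), meta_body)
    paths[k] <- file.path(dir, sprintf("slice_%03d.dcm", k))
    con <- file(paths[k], "wb")
    writeBin(c(raw(128), charToRaw("DICM"), meta, ds), con)
    close(con)
  }
  invisible(paths)
}


## strip trailing NUL/space padding from a raw string value
.dcm_rawstr <- function(r) {
  while (length(r) && (r[length(r)] == as.raw(0) || r[length(r)] == as.raw(0x20)))
    r <- r[-length(r)]
  if (!length(r)) "" else rawToChar(r)
}

## parse one DICOM file into a named list of the tags the reader needs
.dcm_parse_file <- function(path) {
  bytes <- readBin(path, "raw", file.info(path)$size)
  if (length(bytes) < 140 || rawToChar(bytes[129:132]) != "DICM")
    stop("not a DICOM part-10 file: ", path)
  u16 <- function(i) as.integer(bytes[i]) + 256L * as.integer(bytes[i + 1L])
  u32 <- function(i) sum(as.numeric(bytes[i + 0:3]) * c(1, 256, 65536, 16777216))
  pos <- 133L
  explicit <- TRUE   # file meta group is always explicit VR
  syntax <- NULL
  out <- list()
  long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  while (pos + 7L <= length(bytes)) {
    group <- u16(pos); elem <- u16(pos + 2L)
    if (group != 0x0002) {
      # file meta group is always explicit VR; the dataset follows the
      # negotiated transfer syntax
      if (is.null(syntax)) stop("no TransferSyntaxUID in file meta group: ", path)
      if (!(syntax %in% c(.dcm_explicit_uid, .dcm_implicit_uid)))
        stop("unsupported transfer syntax '", syntax, "' in ", path)
      explicit <- syntax == .dcm_explicit_uid
    }
    if (explicit) {
      vr <- rawToChar(bytes[(pos + 4L):(pos + 5L)])
      if (vr %in% long_vrs) {
        len <- u32(pos + 8L); body <- pos + 12L
      } else {
        len <- u16(pos + 6L); body <- pos + 8L
      }
    } else {
      vr <- "UN"; len <- u32(pos + 4L); body <- pos + 8L
    }
    if (len == 4294967295) stop("undefined-length elements are not supported: ", path)
    val_idx <- if (len > 0) body + seq_len(len) - 1L else integer(0)
    key <- sprintf("%04X,%04X", group, elem)
    if (key == "0002,0010") {
      syntax <- .dcm_rawstr(bytes[val_idx])
    } else if (key %in% c("0028,0030", "0020,0032", "0020,0013", "0018,0050",
                          "0018,0088", "0028,1052", "0028,1053")) {
      out[[key]] <- trimws(.dcm_rawstr(bytes[val_idx]))
    } else if (key %in% c("0028,0010", "0028,0011", "0028,0100", "0028,0103")) {
      out[[key]] <- u16(body)
    } else if (key == "7FE0,0010") {
      out[["pixeldata"]] <- bytes[val_idx]
      break
    }
    pos <- body + len
  }
  out
}

#' @rdname read_volume
#' @param dir DICOM series directory
#' @export
read_dicom_series <- function(dir, source_id = basename(dir)) {
  files <- list.files(dir, pattern = "\\.dcm$", full.names = TRUE)
  if (length(files) == 0) files <- list.files(dir, full.names = TRUE)
  files <- files[!dir.exists(files)]
  if (length(files) == 0) stop("no DICOM files in ", dir)
  parsed <- lapply(files, .dcm_parse_file)

  spacing_str <- vapply(parsed, function(p) p[["0028,0030"]] %||% NA_character_, "")
  if (anyNA(spacing_str))
    stop("DICOM metadata error: PixelSpacing (0028,0030) missing in series ", dir)
  if (length(unique(spacing_str)) != 1L)
    stop("DICOM metadata error: mixed PixelSpacing values within series ", dir)
  spacing <- as.numeric(strsplit(spacing_str[1], "\\\\")[[1]])  # row mm, col mm

  zpos <- vapply(parsed, function(p) {
    ipp <- p[["0020,0032"]]
    if (is.null(ipp)) NA_real_ else as.numeric(strsplit(ipp, "\\\\")[[1]])[2]
  }, 0)
  if (anyNA(zpos))
    zpos <- vapply(parsed, function(p) as.numeric(p[["0020,0013"]] %||% NA), 0)
  if (anyNA(zpos)) stop("cannot order DICOM slices: no ImagePositionPatient or InstanceNumber")
  ord <- order(zpos)
  parsed <- parsed[ord]; zpos <- zpos[ord]

  slice_spacing <- if (length(zpos) > 1 && diff(range(diff(zpos))) < 1e-6 && diff(zpos)[1] > 0)
    diff(zpos)[1]
  else as.numeric(parsed[[1]][["0018,0088"]] %||% parsed[[1]][["0018,0050"]] %||% NA)
  if (!is.finite(slice_spacing) || slice_spacing <= 0)
    stop("DICOM metadata error: cannot determine slice spacing in ", dir)

  rows <- parsed[[1]][["0028,0010"]]; cols <- parsed[[1]][["0028,0011"]]
  bits <- parsed[[1]][["0028,0100"]] %||% 16L
  if (bits != 16L) stop("only 16-bit DICOM pixel data is supported")
  signed <- (parsed[[1]][["0028,0103"]] %||% 1L) == 1L

  vox <- array(0, dim = c(rows, cols, length(parsed)))
  for (k in seq_along(parsed)) {
    p <- parsed[[k]]
    px <- readBin(p$pixeldata, "integer", n = rows * cols, size = 2,
                  signed = signed, endian = "little")
    slope <- as.numeric(p[["0028,1053"]] %||% "1")
    inter <- as.numeric(p[["0028,1052"]] %||% "0")
    vox[, , k] <- matrix(px * slope + inter, nrow = rows, byrow = TRUE)
  }
  ct_volume(vox, pixel_spacing = spacing, slice_spacing = slice_spacing,
            source_id = source_id)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
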