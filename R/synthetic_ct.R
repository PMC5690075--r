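## ---- Minimal DICOM I/O (explicit VR little endian, CT image module) ----
##
## No DICOM package ships with this R stack, so the few pieces of the
## standard the synthetic-CT pathway needs are implemented here: Part-10
## files with preamble + file meta group, explicit-VR little-endian
## encoding, the geometry and pixel modules of a CT slice, uncompressed
## 16-bit signed pixels. This is not a general DICOM implementation.

.dcm_uid_root <- "1.2.826.0.1.3680043.9.7435"

.dcm_element <- function(group, element, vr, value) {
  con <- rawConnection(raw(0), "wb")
  on.exit(close(con))
  writeBin(as.integer(c(group, element)), con, size = 2, endian = "little")
  writeChar(vr, con, nchars = 2, eos = NULL)
  if (vr %in% c("OB", "OW", "SQ", "UN", "UT")) {
    writeBin(as.integer(0), con, size = 2, endian = "little")
    writeBin(length(value), con, size = 4, endian = "little")
    writeBin(value, con)
  } else if (vr == "US") {
    writeBin(2L, con, size = 2, endian = "little")
    writeBin(as.integer(value), con, size = 2, endian = "little")
  } else {
    b <- charToRaw(as.character(value))
    if (length(b) %% 2 == 1) {
      ## even-length padding: NUL for UIDs, space for text VRs
      b <- c(b, if (vr == "UI") as.raw(0) else charToRaw(" "))
    }
    writeBin(length(b), con, size = 2, endian = "little")
    writeBin(b, con)
  }
  rawConnectionValue(con)
}

.dcm_write_slice <- function(path, pixels, instance, position, spacing,
                             thickness, series_uid, study_uid) {
  sop_class <- "1.2.840.10008.5.1.4.1.1.2"
  sop_uid <- paste0(.dcm_uid_root, ".", instance, ".",
                    abs(sum(as.integer(pixels[1:100]))) %% 99999)
  el <- .dcm_element
  ds <- function(x) paste(format(x, trim = TRUE, scientific = FALSE),
                          collapse = "\\")
  meta_body <- c(
    el(0x0002, 0x0001, "OB", as.raw(c(0, 1))),
    el(0x0002, 0x0002, "UI", sop_class),
    el(0x0002, 0x0003, "UI", sop_uid),
    el(0x0002, 0x0010, "UI", "1.2.840.10008.1.2.1"),
    el(0x0002, 0x0012, "UI", paste0(.dcm_uid_root, ".1"))
  )
  pix <- writeBin(as.integer(pixels), raw(), size = 2, endian = "little")
  body <- c(
    el(0x0008, 0x0016, "UI", sop_class),
    el(0x0008, 0x0018, "UI", sop_uid),
    el(0x0008, 0x0060, "CS", "CT"),
    el(0x0018, 0x0050, "DS", ds(thickness)),
    el(0x0020, 0x000D, "UI", study_uid),
    el(0x0020, 0x000E, "UI", series_uid),
    el(0x0020, 0x0013, "IS", as.character(instance)),
    el(0x0020, 0x0032, "DS", ds(position)),
    el(0x0020, 0x0037, "DS", ds(c(1, 0, 0, 0, 1, 0))),
    el(0x0028, 0x0002, "US", 1),
    el(0x0028, 0x0004, "CS", "MONOCHROME2"),
    el(0x0028, 0x0010, "US", nrow(pixels)),
    el(0x0028, 0x0011, "US", ncol(pixels)),
    el(0x0028, 0x0030, "DS", ds(spacing)),
    el(0x0028, 0x0100, "US", 16),
    el(0x0028, 0x0101, "US", 16),
    el(0x0028, 0x0102, "US", 15),
    el(0x0028, 0x0103, "US", 1),
    el(0x0028, 0x1052, "DS", "0"),
    el(0x0028, 0x1053, "DS", "1"),
    el(0x7FE0, 0x0010, "OW", pix)
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128), con)
  writeChar("DICM", con, nchars = 4, eos = NULL)
  ## (0002,0000) UL group length of the file meta group
  con2 <- rawConnection(raw(0), "wb")
  writeBin(as.integer(c(0x0002, 0x0000)), con2, size = 2, endian = "little")
  writeChar("UL", con2, nchars = 2, eos = NULL)
  writeBin(4L, con2, size = 2, endian = "little")
  writeBin(length(meta_body), con2, size = 4, endian = "little")
  grp_len <- rawConnectionValue(con2)
  close(con2)
  writeBin(c(grp_len, meta_body), con)
  writeBin(body, con)
  invisible(path)
}

.dcm_read_file <- function(path) {
  raw_all <- readBin(path, raw(), file.size(path))
  if (rawToChar(raw_all[129:132]) != "DICM") {
    stop(path, " is not a Part-10 DICOM file", call. = FALSE)
  }
  pos <- 133L
  u16 <- function(at) sum(as.integer(raw_all[at:(at + 1)]) * c(1L, 256L))
  u32 <- function(at) sum(as.numeric(raw_all[at:(at + 3)]) * 256^(0:3))
  out <- list()
  while (pos + 7 <= length(raw_all)) {
    group <- u16(pos); element <- u16(pos + 2)
    vr <- rawToChar(raw_all[(pos + 4):(pos + 5)])
    if (vr %in% c("OB", "OW", "SQ", "UN", "UT")) {
      len <- u32(pos + 8)
      val_at <- pos + 12
    } else {
      len <- u16(pos + 6)
      val_at <- pos + 8
    }
    key <- sprintf("%04x,%04x", group, element)
    val_raw <- raw_all[val_at:(val_at + len - 1)]
    out[[key]] <- if (vr %in% c("OB", "OW")) {
      val_raw
    } else if (vr == "US") {
      u16(val_at)
    } else {
      while (length(val_raw) &&
             val_raw[length(val_raw)] %in% as.raw(c(0L, 32L))) {
        val_raw <- val_raw[-length(val_raw)]
      }
      rawToChar(val_raw)
    }
    pos <- val_at + len
    if (group == 0x7FE0 && element == 0x0010) break
  }
  out
}

#' Synthetic head-CT specification
#'
#' Parameters of the synthetic DICOM CT series that stands in for the
#' patient head scan of the imaging pathway (the real scan is not
#' distributable): 10 contiguous slices of 512 x 512 pixels at
#' 0.97 x 0.97 mm^2 and 2 mm slice thickness, containing a soft-tissue head
#' ellipse, a bony orbit ring, a globe with a lens, and Gaussian HU noise.
#' The globe sits deep to the anterior surface so that a 100.51 MeV beam
#' degraded by a 46 mm PMMA shifter stops inside it.
#'
#' @param n_slices Number of slices.
#' @param matrix_size In-plane matrix (square).
#' @param pixel_spacing In-plane pixel size, mm.
#' @param slice_thickness Slice thickness, mm.
#' @param eye_center Eye centre as `c(row, col)` pixel indices.
#' @param seed RNG seed for the HU noise.
#' @param noise_sigma Gaussian HU noise s.d.
#' @return A `synthetic_head_spec`.
#' @export
synthetic_head_spec <- function(n_slices = 10, matrix_size = 512,
                                pixel_spacing = 0.97, slice_thickness = 2,
                                eye_center = c(190, 216), seed = 1,
                                noise_sigma = 10) {
  stopifnot(pixel_spacing > 0, slice_thickness > 0, n_slices >= 1)
  if (any(eye_center < 44) || any(eye_center > matrix_size - 43)) {
    stop("eye_center must leave room for the 86 x 86 crop window",
         call. = FALSE)
  }
  structure(list(n_slices = n_slices, matrix_size = matrix_size,
                 pixel_spacing = pixel_spacing,
                 slice_thickness = slice_thickness,
                 eye_center = eye_center, seed = seed,
                 noise_sigma = noise_sigma),
            class = "synthetic_head_spec")
}

#' Generate a synthetic head CT as a DICOM series
#'
#' Builds the HU volume of [synthetic_head_spec()] and writes one DICOM
#' file per slice. HU content: air background (-1000), soft-tissue head
#' ellipse (+40), bony orbit ring (+700), globe (+15), lens (+80), plus
#' seeded Gaussian noise. Regenerating with the same spec gives identical
#' pixels.
#'
#' @param spec A [synthetic_head_spec()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, a list with the written `files` and the HU `volume`
#'   (rows x cols x slices array).
#' @export
generate_head_ct <- function(spec = synthetic_head_spec(), dir) {
  stopifnot(inherits(spec, "synthetic_head_spec"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  n <- spec$matrix_size
  ps <- spec$pixel_spacing
  er <- spec$eye_center[1]; ec <- spec$eye_center[2]
  rows <- matrix(seq_len(n), n, n)
  cols <- matrix(seq_len(n), n, n, byrow = TRUE)
  ## head ellipse: centred behind the eye so the orbit sits at its surface
  hc_r <- er + 120; hc_c <- ec + 40
  head_mask <- ((rows - hc_r) / 158)^2 + ((cols - hc_c) / 110)^2 <= 1
  globe_r_mm <- 12.2
  lens_r <- er - 7
  zc <- (seq_len(spec$n_slices) - (spec$n_slices + 1) / 2) *
    spec$slice_thickness
  set.seed(spec$seed)
  vol <- array(0L, dim = c(n, n, spec$n_slices))
  for (k in seq_len(spec$n_slices)) {
    hu <- matrix(-1000, n, n)
    hu[head_mask] <- 40
    rg2 <- globe_r_mm^2 - zc[k]^2
    d2 <- ((rows - er)^2 + (cols - ec)^2) * ps^2
    if (rg2 > 0) {
      ## bony orbit: ring around the globe, 4 mm thick
      ring <- d2 > (sqrt(rg2) + 1)^2 & d2 <= (sqrt(rg2) + 5)^2 & head_mask
      hu[ring] <- 700
      globe <- d2 <= rg2
      hu[globe] <- 15
      lr2 <- 25 - zc[k]^2 / 4
      if (lr2 > 0) {
        lens <- ((rows - lens_r)^2 * 4 + (cols - ec)^2) * ps^2 <= lr2
        hu[lens & globe] <- 80
      }
    }
    hu <- hu + round(stats::rnorm(n * n, 0, spec$noise_sigma))
    vol[, , k] <- as.integer(pmax(pmin(hu, 3000), -1024))
  }
  series_uid <- paste0(.dcm_uid_root, ".2.", spec$seed)
  study_uid <- paste0(.dcm_uid_root, ".3.", spec$seed)
  files <- file.path(dir, sprintf("slice%03d.dcm", seq_len(spec$n_slices)))
  for (k in seq_len(spec$n_slices)) {
    .dcm_write_slice(files[k], vol[, , k], instance = k,
                     position = c(-(n / 2) * ps, -(n / 2) * ps, zc[k]),
                     spacing = c(ps, ps), thickness = spec$slice_thickness,
                     series_uid = series_uid, study_uid = study_uid)
  }
  invisible(list(files = files, volume = vol))
}

#' Read a DICOM CT series
#'
#' Reads every `.dcm` file in a directory (explicit VR little endian,
#' uncompressed), sorts by instance number and assembles the HU volume.
#'
#' @param dir Directory containing the series.
#' @return List with `hu` (rows x cols x slices integer array),
#'   `pixel_spacing`, `slice_thickness`, `positions`.
#' @export
read_dicom_series <- function(dir) {
  files <- list.files(dir, pattern = "\\.dcm$", full.names = TRUE)
  if (length(files) == 0) stop("no .dcm files in ", dir, call. = FALSE)
  slices <- lapply(files, .dcm_read_file)
  inst <- vapply(slices, function(s) as.integer(s[["0020,0013"]]), 0L)
  ord <- order(inst)
  slices <- slices[ord]
  rows <- slices[[1]][["0028,0010"]]
  cols <- slices[[1]][["0028,0011"]]
  spacing <- as.numeric(strsplit(slices[[1]][["0028,0030"]], "\\\\")[[1]])
  thick <- as.numeric(slices[[1]][["0018,0050"]])
  hu <- array(0L, dim = c(rows, cols, length(slices)))
  pos <- matrix(0, length(slices), 3)
  for (k in seq_along(slices)) {
    pix <- readBin(slices[[k]][["7fe0,0010"]], integer(),
                   n = rows * cols, size = 2, endian = "little")
    hu[, , k] <- matrix(pix, rows, cols)
    pos[k, ] <- as.numeric(strsplit(slices[[k]][["0020,0032"]],
                                    "\\\\")[[1]])
  }
  list(hu = hu, pixel_spacing = spacing, slice_thickness = thick,
       positions = pos)
}

#' Crop the eye region of interest from a CT series
#'
#' Extracts an 86 x 86 pixel window (all slices) around the eye. Index
#' bookkeeping follows the published convention: crop voxel index 43 along
#' each in-plane axis corresponds to the isocenter.
#'
#' @param series A [read_dicom_series()] result (or a bare HU array).
#' @param center Window centre `c(row, col)`; the crop spans
#'   `center - 43 + 1:86`.
#' @param size Window size in pixels (default 86).
#' @return An `hu_grid`: `hu` array, `voxel_size`, `origin` (beam frame,
#'   isocenter at crop centre).
#' @export
crop_roi <- function(series, center, size = 86) {
  hu <- if (is.list(series)) series$hu else series
  ps <- if (is.list(series)) series$pixel_spacing[1] else 0.97
  th <- if (is.list(series)) series$slice_thickness else 2
  half <- floor(size / 2)
  ridx <- (center[1] - half + 1):(center[1] - half + size)
  cidx <- (center[2] - half + 1):(center[2] - half + size)
  if (min(ridx) < 1 || min(cidx) < 1 || max(ridx) > dim(hu)[1] ||
      max(cidx) > dim(hu)[2]) {
    stop("crop window outside the slice bounds", call. = FALSE)
  }
  nz <- dim(hu)[3]
  structure(
    list(hu = hu[ridx, cidx, , drop = FALSE],
         voxel_size = c(ps, ps, th),
         origin = c(-(half - 0.5) * ps, -(half - 0.5) * ps,
                    -(nz - 1) / 2 * th)),
    class = "hu_grid"
  )
}

#' Convert HU values to density and water-equivalent ratio
#'
#' Documented piecewise-linear calibration anchored at the universal
#' points: air (-1000 HU, density 0.001) and water (0 HU, density 1).
#' Between them the ramp is linear; above 100 HU a shallower bone slope
#' (0.0005 g/cm^3 per HU) applies. The WER equals the density for soft
#' tissue and is reduced 15% relative to the density excess for bone-like
#' voxels (stopping power rises more slowly than density). Values outside
#' [-1024, 3000] are clamped with a warning.
#'
#' @param hu Numeric array/vector of HU values.
#' @return List with `density` and `wer` arrays matching `hu`.
#' @export
hu_to_density_wer <- function(hu) {
  if (any(hu < -1024 | hu > 3000)) {
    warning("HU outside [-1024, 3000] clamped", call. = FALSE)
    hu <- pmax(pmin(hu, 3000), -1024)
  }
  density <- ifelse(hu <= 0,
                    pmax(1 + hu / 1000, 0.001),
                    ifelse(hu <= 100, 1 + hu / 1000,
                           1.1 + (hu - 100) * 5e-4))
  wer <- ifelse(hu <= 100, density, 1.1 + (density - 1.1) * 0.85)
  if (!is.null(dim(hu))) {
    density <- array(density, dim(hu))
    wer <- array(wer, dim(hu))
  }
  list(density = density, wer = wer)
}

#' Turn an HU grid into a dose-engine target
#'
#' Labels voxels into air / soft tissue / bone bands and attaches the
#' per-voxel density and WER from [hu_to_density_wer()]. Beam direction is
#' the first (row) axis of the crop.
#'
#' @param hu_grid An `hu_grid` from [crop_roi()].
#' @return A `labeled_grid`.
#' @export
ct_target_grid <- function(hu_grid) {
  stopifnot(inherits(hu_grid, "hu_grid"))
  conv <- hu_to_density_wer(hu_grid$hu)
  labels <- array(2L, dim(hu_grid$hu))
  labels[hu_grid$hu < -500] <- 1L
  labels[hu_grid$hu > 150] <- 3L
  structure(
    list(labels = labels, structures = c("air", "tissue", "bone"),
         density = conv$density, wer = conv$wer,
         voxel_size = hu_grid$voxel_size, origin = hu_grid$origin),
    class = "labeled_grid"
  )
}
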