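#' Structure set: named contoured structures in patient coordinates
#'
#' Container mirroring the DICOM RT Structure Set: an ordered collection of
#' named structures, each a list of closed planar (axial) polygons given as
#' n x 3 matrices of patient coordinates in mm.
#'
#' @param structures list; each entry `list(name = , contours = )` where
#'   `contours` is a list of n x 3 numeric matrices (n >= 3, constant z).
#' @param frame_of_reference identifier string.
#' @return An object of class `structure_set`.
#' @export
structure_set <- function(structures, frame_of_reference = "") {
  for (s in structures) {
    if (is.null(s$name) || !nzchar(s$name)) {
      stop_validation("every structure needs a non-empty name")
    }
    for (ct in s$contours) {
      if (!is.matrix(ct) || ncol(ct) != 3L || nrow(ct) < 3L) {
        stop_validation(sprintf(
          "structure '%s': contours must be n x 3 matrices with n >= 3",
          s$name))
      }
      if (diff(range(ct[, 3])) > 1e-3) {
        stop_validation(sprintf(
          "structure '%s': contour vertices must share one axial plane",
          s$name))
      }
    }
  }
  structure(list(structures = structures,
                 frame_of_reference = as.character(frame_of_reference)),
            class = "structure_set")
}

#' @export
print.structure_set <- function(x, ...) {
  cat(sprintf("<structure_set> %d structures\n", length(x$structures)))
  for (s in x$structures) {
    cat(sprintf("  %-24s %d contour(s)\n", s$name, length(s$contours)))
  }
  invisible(x)
}

#' Names of the structures in a structure set
#' @param set a [structure_set()].
#' @return Character vector of raw structure names, in file order.
#' @export
structure_names <- function(set) {
  vapply(set$structures, function(s) s$name, character(1))
}

# ---- RTDOSE ---------------------------------------------------------------

#' Read a DICOM RT Dose file into a dose grid
#'
#' Applies the dose-grid scaling so values are absolute dose in Gy, and
#' canonicalises axis-aligned orientations (sign flips / axis permutations)
#' into identity orientation, adjusting the origin accordingly.  Oblique
#' grids, non-uniform frame offsets and non-Gy dose units are rejected as
#' unsupported dialects.
#'
#' @param path path to an RTDOSE file.
#' @return A [dose_grid()] in Gy.
#' @export
read_rtdose <- function(path) {
  ds <- read_dicom_file(path)
  modality <- dcm_string(ds, "00080060")
  if (is.null(modality) || modality != "RTDOSE") {
    stop_format(sprintf("%s is not an RT Dose object (Modality = %s)",
                        path, modality %||% "<missing>"))
  }
  units <- dcm_required(dcm_string(ds, "30040002"), "DoseUnits (3004,0002)")
  if (units != "GY") {
    stop_dialect(sprintf(
      "unsupported DoseUnits '%s': only absolute dose in GY is accepted",
      units))
  }
  rows <- dcm_required(dcm_us(ds, "00280010"), "Rows (0028,0010)")
  cols <- dcm_required(dcm_us(ds, "00280011"), "Columns (0028,0011)")
  nframes <- as.integer(dcm_required(dcm_numbers(ds, "00280008"),
                                     "NumberOfFrames (0028,0008)"))
  ipp <- dcm_required(dcm_numbers(ds, "00200032"),
                      "ImagePositionPatient (0020,0032)")
  iop <- dcm_required(dcm_numbers(ds, "00200037"),
                      "ImageOrientationPatient (0020,0037)")
  pixsp <- dcm_required(dcm_numbers(ds, "00280030"),
                        "PixelSpacing (0028,0030)")
  offsets <- dcm_required(dcm_numbers(ds, "3004000C"),
                          "GridFrameOffsetVector (3004,000C)")
  scaling <- dcm_required(dcm_numbers(ds, "3004000E"),
                          "DoseGridScaling (3004,000E)")
  if (length(offsets) != nframes) {
    stop_dialect("GridFrameOffsetVector length does not match NumberOfFrames")
  }
  if (nframes < 2) {
    stop_dialect("single-frame RTDOSE grids are not supported")
  }
  steps <- diff(offsets)
  if (max(abs(steps - steps[1])) > 1e-3 || abs(steps[1]) < 1e-6) {
    stop_dialect(
      "non-uniform GridFrameOffsetVector (3004,000C): irregular slice spacing")
  }
  pix <- dcm_required(ds[["7FE00010"]], "PixelData (7FE0,0010)")$value
  bits <- dcm_required(dcm_us(ds, "00280100"), "BitsAllocated (0028,0100)")
  pixrep <- dcm_us(ds, "00280103") %||% 0L
  if (pixrep != 0L) {
    stop_dialect("signed RTDOSE pixel data is not supported")
  }
  npix <- as.numeric(rows) * cols * nframes
  stored <- switch(as.character(bits),
    "32" = dec_u32_vec(pix),
    "16" = readBin(pix, "integer", n = length(pix) / 2L, size = 2L,
                   signed = FALSE, endian = "little"),
    stop_dialect(sprintf("unsupported BitsAllocated = %d", bits)))
  if (length(stored) != npix) {
    stop_format("PixelData size does not match Rows x Columns x NumberOfFrames")
  }
  # pixel order: within a frame x (columns) varies fastest, then y (rows)
  vol <- array(as.numeric(stored) * scaling[1], dim = c(cols, rows, nframes))

  row_dir <- iop[1:3]   # direction of increasing column index
  col_dir <- iop[4:6]   # direction of increasing row index
  if (any(abs(row_dir) > 1e-6 & abs(abs(row_dir) - 1) > 1e-6) ||
      any(abs(col_dir) > 1e-6 & abs(abs(col_dir) - 1) > 1e-6)) {
    stop_dialect(
      "oblique ImageOrientationPatient (0020,0037): only axis-aligned grids are supported")
  }
  normal <- c(row_dir[2] * col_dir[3] - row_dir[3] * col_dir[2],
              row_dir[3] * col_dir[1] - row_dir[1] * col_dir[3],
              row_dir[1] * col_dir[2] - row_dir[2] * col_dir[1])
  affine <- cbind(row_dir * pixsp[2], col_dir * pixsp[1], normal * steps[1])
  origin <- ipp + offsets[1] * normal
  canon <- canonicalize_volume(vol, affine, origin)
  dose_grid(canon$vol, canon$origin, canon$spacing,
            frame_of_reference = dcm_string(ds, "00200052") %||% "")
}

# Reorder/flip an axis-aligned volume so the affine becomes diagonal
# positive (identity orientation, positive spacing).
canonicalize_volume <- function(vol, affine, origin) {
  d <- dim(vol)
  perm <- integer(3)
  spacing <- numeric(3)
  for (a in 1:3) {
    p <- which(abs(affine[, a]) > 1e-6)
    if (length(p) != 1L) {
      stop_dialect("grid axes are not aligned with the patient axes")
    }
    if (affine[p, a] < 0) {
      idx <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
      idx[[a]] <- rev(idx[[a]])
      vol <- vol[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
      origin <- origin + affine[, a] * (d[a] - 1)
      affine[, a] <- -affine[, a]
    }
    perm[p] <- a
    spacing[p] <- affine[p, a]
  }
  if (any(perm == 0)) {
    stop_dialect("grid axes are not a permutation of the patient axes")
  }
  list(vol = aperm(vol, perm), origin = origin, spacing = spacing)
}

#' Write a dose grid as a DICOM RT Dose file
#'
#' Stores dose as 32-bit unsigned integers with a dose-grid scaling chosen
#' so quantisation error is below 1e-9 of the maximum dose; [read_rtdose()]
#' round-trips the result.  No timestamps are written and instance UIDs are
#' derived from the grid content, so identical grids produce byte-identical
#' files.
#'
#' @param grid a [dose_grid()]; values must be finite and >= 0.
#' @param path output file path.
#' @return The path, invisibly.
#' @export
write_rtdose <- function(grid, path) {
  if (!inherits(grid, "dose_grid")) {
    grid <- do.call(dose_grid, grid)   # validates invariants
  }
  v <- grid$values
  if (any(v < 0) || any(!is.finite(v))) {
    stop_validation("dose values must be finite and >= 0 Gy")
  }
  d <- dim(v)
  maxv <- max(v)
  scaling <- if (maxv > 0) maxv / (2^32 - 1) else 1
  stored <- round(as.vector(v) / scaling)
  uid <- content_uid("rtdose", d, grid$origin, grid$spacing, sum(v),
                     maxv, v[1], v[length(v)])
  elements <- list(
    el_str(0x0008, 0x0016, "UI", UID_RTDOSE_STORAGE),
    el_str(0x0008, 0x0018, "UI", uid),
    el_str(0x0008, 0x0060, "CS", "RTDOSE"),
    el_str(0x0020, 0x000D, "UI", content_uid("study", uid)),
    el_str(0x0020, 0x000E, "UI", content_uid("series", uid)),
    el_ds(0x0020, 0x0032, grid$origin),
    el_ds(0x0020, 0x0037, c(1, 0, 0, 0, 1, 0)),
    el_str(0x0020, 0x0052, "UI",
           if (nzchar(grid$frame_of_reference)) grid$frame_of_reference
           else content_uid("for", uid)),
    el_us(0x0028, 0x0002, 1L),
    el_str(0x0028, 0x0004, "CS", "MONOCHROME2"),
    el_is(0x0028, 0x0008, d[3]),
    dcm_el(0x0028, 0x0009, "AT", enc_u16(c(0x3004, 0x000C))),
    el_us(0x0028, 0x0010, d[2]),
    el_us(0x0028, 0x0011, d[1]),
    el_ds(0x0028, 0x0030, c(grid$spacing[2], grid$spacing[1])),
    el_us(0x0028, 0x0100, 32L),
    el_us(0x0028, 0x0101, 32L),
    el_us(0x0028, 0x0102, 31L),
    el_us(0x0028, 0x0103, 0L),
    el_str(0x3004, 0x0002, "CS", "GY"),
    el_str(0x3004, 0x0004, "CS", "PHYSICAL"),
    el_str(0x3004, 0x000A, "CS", "PLAN"),
    el_ds(0x3004, 0x000C, (seq_len(d[3]) - 1) * grid$spacing[3]),
    el_str(0x3004, 0x000E, "DS", sprintf("%.10e", scaling)),
    dcm_el(0x7FE0, 0x0010, "OW", enc_u32(stored))
  )
  write_dicom_file(path, UID_RTDOSE_STORAGE, uid, elements)
}

# ---- RTSTRUCT -------------------------------------------------------------

#' Read a DICOM RT Structure Set
#'
#' Returns every ROI with its raw name and planar contours in patient mm
#' coordinates, preserving ROI order.  ROIs with no contour data are kept
#' with an empty contour list (clinical sets contain point/empty ROIs);
#' degenerate contours with fewer than 3 points are dropped.  Both cases
#' produce a warning.
#'
#' @param path path to an RTSTRUCT file.
#' @return A [structure_set()].
#' @export
read_rtstruct <- function(path) {
  ds <- read_dicom_file(path)
  modality <- dcm_string(ds, "00080060")
  if (is.null(modality) || modality != "RTSTRUCT") {
    stop_format(sprintf("%s is not an RT Structure Set (Modality = %s)",
                        path, modality %||% "<missing>"))
  }
  roi_seq <- ds[["30060020"]]
  if (is.null(roi_seq)) {
    stop_format("StructureSetROISequence (3006,0020) missing")
  }
  rois <- lapply(roi_seq$value, function(item) {
    list(number = as.integer(dcm_numbers(item, "30060022")),
         name = dcm_string(item, "30060026") %||% "")
  })
  contour_items <- if (!is.null(ds[["30060039"]])) ds[["30060039"]]$value
                   else list()
  contours_by_roi <- list()
  for (item in contour_items) {
    num <- as.integer(dcm_numbers(item, "30060084"))
    polys <- list()
    for (ct in (if (!is.null(item[["30060040"]])) item[["30060040"]]$value
                else list())) {
      xyz <- dcm_numbers(ct, "30060050")
      if (is.null(xyz) || length(xyz) %% 3 != 0) next
      m <- matrix(xyz, ncol = 3, byrow = TRUE)
      if (nrow(m) < 3) {
        warn(sprintf("ROI %d: dropping degenerate contour with %d point(s)",
                     num, nrow(m)))
        next
      }
      polys[[length(polys) + 1L]] <- m
    }
    contours_by_roi[[as.character(num)]] <- polys
  }
  structures <- lapply(rois, function(r) {
    polys <- contours_by_roi[[as.character(r$number)]]
    if (is.null(polys) || length(polys) == 0L) {
      warn(sprintf("ROI '%s' has no contour data; returned empty", r$name))
      polys <- list()
    }
    list(name = r$name, contours = polys)
  })
  structure_set(structures,
                frame_of_reference = dcm_string(ds, "00200052") %||% "")
}

#' Write a structure set as a DICOM RT Structure Set
#'
#' @param set a [structure_set()] with at least one structure.
#' @param geometry a [dose_grid()]; all contour vertices must lie inside its
#'   bounding box (voxel extent).
#' @param path output file path.
#' @return The path, invisibly.
#' @export
write_rtstruct <- function(set, geometry, path) {
  if (!inherits(set, "structure_set")) {
    stop_validation("`set` must be a structure_set")
  }
  if (length(set$structures) == 0L) {
    stop_validation("cannot write an empty structure collection")
  }
  d <- dim(geometry$values)
  lo <- geometry$origin - geometry$spacing / 2
  hi <- geometry$origin + (d - 0.5) * geometry$spacing
  for (s in set$structures) {
    for (ct in s$contours) {
      if (any(t(ct) < lo - 1e-6) || any(t(ct) > hi + 1e-6)) {
        stop_validation(sprintf(
          "structure '%s' has contour vertices outside the grid bounding box",
          s$name))
      }
    }
  }
  for_uid <- if (nzchar(set$frame_of_reference)) set$frame_of_reference
             else content_uid("for-struct", structure_names(set))
  uid <- content_uid("rtstruct", structure_names(set),
                     vapply(set$structures,
                            function(s) sum(unlist(s$contours)), numeric(1)))
  roi_items <- list()
  contour_items <- list()
  for (i in seq_along(set$structures)) {
    s <- set$structures[[i]]
    roi_items[[i]] <- list(
      el_is(0x3006, 0x0022, i),
      el_str(0x3006, 0x0024, "UI", for_uid),
      el_str(0x3006, 0x0026, "LO", s$name),
      el_str(0x3006, 0x0036, "CS", "MANUAL")
    )
    ct_items <- lapply(s$contours, function(m) {
      list(
        el_str(0x3006, 0x0042, "CS", "CLOSED_PLANAR"),
        el_is(0x3006, 0x0046, nrow(m)),
        el_ds(0x3006, 0x0050, as.vector(t(m)))
      )
    })
    contour_items[[i]] <- list(
      dcm_el(0x3006, 0x0040, "SQ", ct_items),
      el_is(0x3006, 0x0084, i)
    )
  }
  elements <- list(
    el_str(0x0008, 0x0005, "CS", "ISO_IR 192"),
    el_str(0x0008, 0x0016, "UI", UID_RTSTRUCT_STORAGE),
    el_str(0x0008, 0x0018, "UI", uid),
    el_str(0x0008, 0x0060, "CS", "RTSTRUCT"),
    el_str(0x0020, 0x000D, "UI", content_uid("study", uid)),
    el_str(0x0020, 0x000E, "UI", content_uid("series", uid)),
    el_str(0x0020, 0x0052, "UI", for_uid),
    el_str(0x3006, 0x0002, "SH", "STRUCTGAMMA"),
    dcm_el(0x3006, 0x0020, "SQ", roi_items),
    dcm_el(0x3006, 0x0039, "SQ", contour_items)
  )
  write_dicom_file(path, UID_RTSTRUCT_STORAGE, uid, elements)
}

# ---- CT (map backgrounds only) -------------------------------------------

#' Read one DICOM CT slice for use as a map background
#'
#' Reads only what the gamma-map renderer needs: the pixel matrix with
#' rescale slope/intercept applied (Hounsfield units), plus in-plane
#' geometry.
#'
#' @param path path to a CT image file.
#' @return A matrix (x by y) of Hounsfield units with attributes `origin`
#'   and `spacing` (mm).
#' @export
read_ct_slice <- function(path) {
  ds <- read_dicom_file(path)
  rows <- dcm_required(dcm_us(ds, "00280010"), "Rows (0028,0010)")
  cols <- dcm_required(dcm_us(ds, "00280011"), "Columns (0028,0011)")
  slope <- (dcm_numbers(ds, "00281053") %||% 1)[1]
  intercept <- (dcm_numbers(ds, "00281052") %||% 0)[1]
  pix <- dcm_required(ds[["7FE00010"]], "PixelData (7FE0,0010)")$value
  pixrep <- dcm_us(ds, "00280103") %||% 0L
  stored <- if (pixrep == 1L) dec_i16_vec(pix) else {
    readBin(pix, "integer", n = length(pix) / 2L, size = 2L,
            signed = FALSE, endian = "little")
  }
  if (length(stored) != rows * cols) {
    stop_format("CT PixelData size does not match Rows x Columns")
  }
  hu <- matrix(stored * slope + intercept, nrow = cols, ncol = rows)
  ipp <- dcm_numbers(ds, "00200032") %||% c(0, 0, 0)
  pixsp <- dcm_numbers(ds, "00280030") %||% c(1, 1)
  attr(hu, "origin") <- ipp
  attr(hu, "spacing") <- c(pixsp[2], pixsp[1])
  hu
}

# CT slice writer: uniform-background overlay fixtures only (int16 + rescale).
write_ct_slice <- function(hu, path, origin = c(0, 0, 0), spacing = c(1, 1)) {
  stored <- as.integer(round(hu + 1024))
  uid <- content_uid("ct", dim(hu), sum(hu))
  elements <- list(
    el_str(0x0008, 0x0016, "UI", UID_CT_STORAGE),
    el_str(0x0008, 0x0018, "UI", uid),
    el_str(0x0008, 0x0060, "CS", "CT"),
    el_ds(0x0020, 0x0032, origin),
    el_ds(0x0020, 0x0037, c(1, 0, 0, 0, 1, 0)),
    el_us(0x0028, 0x0002, 1L),
    el_str(0x0028, 0x0004, "CS", "MONOCHROME2"),
    el_us(0x0028, 0x0010, ncol(hu)),
    el_us(0x0028, 0x0011, nrow(hu)),
    el_ds(0x0028, 0x0030, c(spacing[2], spacing[1])),
    el_us(0x0028, 0x0100, 16L),
    el_us(0x0028, 0x0101, 16L),
    el_us(0x0028, 0x0102, 15L),
    el_us(0x0028, 0x0103, 0L),
    el_ds(0x0028, 0x1052, -1024),
    el_ds(0x0028, 0x1053, 1),
    dcm_el(0x7FE0, 0x0010, "OW", enc_u16(stored))
  )
  write_dicom_file(path, UID_CT_STORAGE, uid, elements)
}
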