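#' Dose grid: a 3D absorbed-dose volume with patient-space geometry
#'
#' The fundamental container of the package: a 3D array of absorbed dose in
#' gray (Gy) together with the geometry that places each voxel in patient
#' coordinates.  Axis 1 of the array runs along patient x (left-right),
#' axis 2 along patient y (anterior-posterior) and axis 3 along patient z
#' (inferior-superior); `origin` is the patient coordinate (mm) of the
#' *center* of voxel `[1, 1, 1]`.
#'
#' @param values 3D numeric array of dose in Gy; all finite and >= 0.
#' @param origin numeric length-3, mm: patient coordinates of the center of
#'   the first voxel.
#' @param spacing numeric length-3, mm per voxel along each axis; all > 0.
#' @param orientation 3x3 direction-cosine matrix mapping index axes to
#'   patient axes.  Must be orthonormal; the package canonicalises grids to
#'   identity orientation on read.
#' @param frame_of_reference opaque identifier string tying dose and
#'   structures to one patient coordinate frame.
#'
#' @return An object of class `dose_grid`.
#' @examples
#' g <- dose_grid(array(10, dim = c(4, 4, 4)), origin = c(0, 0, 0),
#'                spacing = c(2, 2, 2))
#' dim(g$values)
#' @export
dose_grid <- function(values, origin, spacing, orientation = diag(3),
                      frame_of_reference = "") {
  if (!is.array(values) || length(dim(values)) != 3L) {
    stop_validation("`values` must be a 3D array")
  }
  storage.mode(values) <- "double"
  if (anyNA(values) || any(!is.finite(values))) {
    stop_validation("dose values must all be finite")
  }
  if (any(values < 0)) {
    stop_validation("dose values must be >= 0 Gy")
  }
  origin <- as.numeric(origin)
  spacing <- as.numeric(spacing)
  if (length(origin) != 3L || length(spacing) != 3L) {
    stop_validation("`origin` and `spacing` must have length 3")
  }
  if (any(spacing <= 0)) {
    stop_validation("`spacing` components must be strictly positive")
  }
  orientation <- matrix(as.numeric(orientation), 3, 3)
  if (max(abs(crossprod(orientation) - diag(3))) > 1e-6) {
    stop_validation("`orientation` must be orthonormal within 1e-6")
  }
  structure(
    list(values = values, origin = origin, spacing = spacing,
         orientation = orientation,
         frame_of_reference = as.character(frame_of_reference)),
    class = "dose_grid"
  )
}

#' @export
print.dose_grid <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf(
    "<dose_grid> %d x %d x %d voxels, spacing %s mm, origin %s mm\n",
    d[1], d[2], d[3],
    paste(format(x$spacing, digits = 4), collapse = " x "),
    paste(format(x$origin, digits = 6), collapse = ", ")))
  cat(sprintf("  dose range [%.4g, %.4g] Gy\n",
              min(x$values), max(x$values)))
  invisible(x)
}

#' Patient coordinates of voxel centers along each grid axis
#'
#' @param grid a [dose_grid()].
#' @return A list with numeric vectors `x`, `y`, `z` of voxel-center
#'   coordinates in mm.
#' @export
grid_axes <- function(grid) {
  d <- dim(grid$values)
  list(
    x = grid$origin[1] + (seq_len(d[1]) - 1) * grid$spacing[1],
    y = grid$origin[2] + (seq_len(d[2]) - 1) * grid$spacing[2],
    z = grid$origin[3] + (seq_len(d[3]) - 1) * grid$spacing[3]
  )
}

#' Test whether two dose grids share one geometry
#'
#' Congruent grids have identical dimensions and geometry within `tol` mm,
#' a prerequisite of the gamma engine (evaluated doses are produced on the
#' same grid as the reference).
#'
#' @param a,b [dose_grid()] objects.
#' @param tol geometric tolerance in mm.
#' @return Logical scalar.
#' @export
grids_congruent <- function(a, b, tol = 1e-3) {
  identical(dim(a$values), dim(b$values)) &&
    max(abs(a$origin - b$origin)) <= tol &&
    max(abs(a$spacing - b$spacing)) <= tol &&
    max(abs(a$orientation - b$orientation)) <= 1e-6
}

stopifnot_congruent <- function(a, b, what = "grids") {
  if (!grids_congruent(a, b)) {
    stop_validation(sprintf("%s are not congruent (geometry mismatch)", what))
  }
  invisible(TRUE)
}

#' Trilinearly resample a dose grid onto another grid's geometry
#'
#' Optional pre-step for evaluated doses that were not computed on the
#' reference grid.  Off by default in the workflow: the intended inputs
#' share one grid.  Points outside the source grid get dose 0.
#'
#' @param grid the [dose_grid()] to resample.
#' @param target a [dose_grid()] supplying the output geometry.
#' @return A [dose_grid()] congruent with `target`.
#' @export
resample_to_grid <- function(grid, target) {
  ax <- grid_axes(target)
  d <- dim(target$values)
  # fractional source indices (1-based) of every target voxel center
  fx <- (ax$x - grid$origin[1]) / grid$spacing[1] + 1
  fy <- (ax$y - grid$origin[2]) / grid$spacing[2] + 1
  fz <- (ax$z - grid$origin[3]) / grid$spacing[3] + 1
  out <- trilinear_sample(grid$values, fx, fy, fz)
  out[is.na(out)] <- 0
  dose_grid(array(out, dim = d), target$origin, target$spacing,
            target$orientation, grid$frame_of_reference)
}

# Vectorised trilinear sampling on the tensor grid of fractional 1-based
# indices (fx x fy x fz).  Returns NA outside the source domain.
trilinear_sample <- function(vol, fx, fy, fz) {
  d <- dim(vol)
  clampi <- function(i, n) pmin(pmax(i, 1L), n)
  i0 <- floor(fx); j0 <- floor(fy); k0 <- floor(fz)
  tx <- fx - i0; ty <- fy - j0; tz <- fz - k0
  ok_x <- fx >= 1 - 1e-9 & fx <= d[1] + 1e-9
  ok_y <- fy >= 1 - 1e-9 & fy <= d[2] + 1e-9
  ok_z <- fz >= 1 - 1e-9 & fz <= d[3] + 1e-9
  i0 <- clampi(i0, d[1] - 1L); j0 <- clampi(j0, d[2] - 1L)
  k0 <- clampi(k0, d[3] - 1L)
  tx <- fx - i0; ty <- fy - j0; tz <- fz - k0
  nx <- length(fx); ny <- length(fy); nz <- length(fz)
  out <- array(NA_real_, dim = c(nx, ny, nz))
  # accumulate the 8 corners with outer-product weights
  for (dz in 0:1) {
    wz <- if (dz == 0) 1 - tz else tz
    for (dy in 0:1) {
      wy <- if (dy == 0) 1 - ty else ty
      for (dx in 0:1) {
        wx <- if (dx == 0) 1 - tx else tx
        corner <- vol[i0 + dx, j0 + dy, k0 + dz, drop = FALSE]
        w <- outer(outer(wx, wy), wz)
        if (dx == 0 && dy == 0 && dz == 0) {
          acc <- w * corner
        } else {
          acc <- acc + w * corner
        }
      }
    }
  }
  out[] <- acc
  bad <- !(outer(outer(ok_x, ok_y, `&`), ok_z, `&`))
  out[bad] <- NA_real_
  out
}
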