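#' Point-in-polygon test (even-odd rule)
#'
#' The rasteriser's inside test: even-odd (crossing number) with boundary
#' points counting as inside.  A point within `boundary_tol` mm of any
#' polygon edge is inside, making the test deterministic for voxel centers
#' that fall exactly on a contour.
#'
#' @param point numeric length-2, mm.
#' @param polygon n x 2 numeric matrix of vertices (closed implicitly;
#'   the last vertex connects back to the first), n >= 3.
#' @param boundary_tol points within this distance (mm) of an edge count as
#'   inside.
#' @return Logical scalar.
#' @export
point_in_polygon <- function(point, polygon, boundary_tol = 1e-6) {
  if (!is.matrix(polygon) || ncol(polygon) < 2L || nrow(polygon) < 3L) {
    stop_validation("`polygon` must be an n x 2 matrix with n >= 3")
  }
  if (polygon_area(polygon) < 1e-12) {
    warn("degenerate polygon with zero area: no point is inside")
    return(FALSE)
  }
  as.vector(points_in_polygon(point[1], point[2], polygon[, 1], polygon[, 2],
                              boundary_tol))
}

# Shoelace area (absolute)
polygon_area <- function(polygon) {
  x <- polygon[, 1]; y <- polygon[, 2]
  xs <- c(x[-1], x[1]); ys <- c(y[-1], y[1])
  abs(sum(x * ys - xs * y)) / 2
}

# Vectorised even-odd test of many points against one polygon.
points_in_polygon <- function(px, py, vx, vy, boundary_tol = 1e-6) {
  n <- length(vx)
  inside <- rep(FALSE, length(px))
  on_edge <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    x1 <- vx[j]; y1 <- vy[j]; x2 <- vx[i]; y2 <- vy[i]
    crosses <- (y1 > py) != (y2 > py)
    if (any(crosses)) {
      xint <- x1 + (py - y1) * (x2 - x1) / (y2 - y1)
      inside <- xor(inside, crosses & (px < xint))
    }
    # distance from each point to segment (x1,y1)-(x2,y2)
    ex <- x2 - x1; ey <- y2 - y1
    len2 <- ex * ex + ey * ey
    if (len2 > 0) {
      t <- pmin(pmax(((px - x1) * ex + (py - y1) * ey) / len2, 0), 1)
      dx <- px - (x1 + t * ex); dy <- py - (y1 + t * ey)
    } else {
      dx <- px - x1; dy <- py - y1
    }
    on_edge <- on_edge | (dx * dx + dy * dy) <= boundary_tol^2
    j <- i
  }
  inside | on_edge
}

#' Rasterise a structure's contours onto a dose grid
#'
#' A voxel belongs to the structure iff its *center* is inside the even-odd
#' combination of the polygons assigned to its slice.  Each contour is
#' assigned to the nearest grid slice by its plane coordinate (ties go to
#' the lower slice index); multiple polygons on one slice combine by the
#' even-odd rule, so rings (holes) and disjoint parts work naturally.
#'
#' @param contours list of n x 3 contour matrices (patient mm, constant z),
#'   or a single structure entry from a [structure_set()].
#' @param grid a [dose_grid()] supplying the voxel geometry.
#' @param name canonical or raw structure name recorded on the mask.
#' @return An object of class `structure_mask`: list with `inside` (logical
#'   3D array congruent with `grid`), `structure_name`, `voxel_count`.
#' @export
rasterize_structure <- function(contours, grid, name = "") {
  if (is.list(contours) && !is.null(contours$contours)) {
    if (!nzchar(name)) name <- contours$name
    contours <- contours$contours
  }
  d <- dim(grid$values)
  ax <- grid_axes(grid)
  inside <- array(FALSE, dim = d)
  if (length(contours) > 0) {
    slice_of <- integer(length(contours))
    for (ci in seq_along(contours)) {
      zc <- contours[[ci]][1, 3]
      dz <- abs(ax$z - zc)
      k <- which.min(dz)          # which.min takes the lower index on ties
      if (dz[k] > grid$spacing[3] + 1e-6) {
        stop_validation(sprintf(
          "structure '%s': contour at z = %.3f mm is farther than one slice spacing from every grid slice",
          name, zc))
      }
      slice_of[ci] <- k
    }
    px <- rep(ax$x, times = d[2])
    py <- rep(ax$y, each = d[1])
    for (k in unique(slice_of)) {
      acc <- rep(FALSE, d[1] * d[2])
      for (ci in which(slice_of == k)) {
        poly <- contours[[ci]]
        if (polygon_area(poly[, 1:2, drop = FALSE]) < 1e-12) {
          warn(sprintf("structure '%s': skipping zero-area contour", name))
          next
        }
        acc <- xor(acc, points_in_polygon(px, py, poly[, 1], poly[, 2]))
      }
      inside[, , k] <- acc
    }
  }
  structure(list(inside = inside, structure_name = name,
                 voxel_count = sum(inside)),
            class = "structure_mask")
}

#' @export
print.structure_mask <- function(x, ...) {
  cat(sprintf("<structure_mask> '%s': %d voxels inside\n",
              x$structure_name, x$voxel_count))
  invisible(x)
}

#' Zero the dose outside a structure
#'
#' The structure-masked dose dataset: equal to the input inside the mask,
#' exactly zero outside; geometry unchanged.
#'
#' @param grid a [dose_grid()].
#' @param mask a [rasterize_structure()] mask congruent with `grid`.
#' @return A [dose_grid()].
#' @export
mask_dose <- function(grid, mask) {
  if (!identical(dim(grid$values), dim(mask$inside))) {
    stop_validation("mask shape does not match the dose grid")
  }
  v <- grid$values
  v[!mask$inside] <- 0
  dose_grid(v, grid$origin, grid$spacing, grid$orientation,
            grid$frame_of_reference)
}
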