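#' Specify a synthetic QA phantom
#'
#' Describes a fully synthetic test case with an analytically known dose
#' field: a co-registered reference/evaluated dose grid pair and a set of
#' contoured "organs", with a controlled perturbation applied to the
#' evaluated dose.  Because the field is analytic, the gamma behaviour of
#' the phantom is known in closed form (recorded in the manifest written by
#' [write_phantom()]).
#'
#' Fields:
#' * `flat(dose)` — uniform dose everywhere.
#' * `wedge(gradient, axis, base)` — linear ramp `base + gradient * s`
#'   along one patient axis (`s` measured from the grid origin).
#' * `gaussian_target(center, width, peak, background)` — an isotropic
#'   Gaussian dose peak over a uniform background, emulating a target
#'   dose distribution.
#'
#' Perturbations:
#' * `none`
#' * `offset(gy)` — uniform additive offset.
#' * `scale(factor)` — uniform multiplicative scaling.
#' * `shift(mm)` — rigid shift, applied by resampling the *analytic* field
#'   (exact, no interpolation error).
#' * `local_error(structure, amplitude_gy, fraction)` — adds
#'   `amplitude_gy` to a random `fraction` of the voxels inside one named
#'   structure (chosen with the phantom seed), so the expected failing
#'   fraction is exact by construction.
#'
#' @param grid_shape integer length-3, voxels per axis (all >= 4).
#' @param spacing mm per voxel, length 3 (or scalar).
#' @param field list: `list(type = "flat", dose = )`,
#'   `list(type = "wedge", gradient = , axis = , base = )` or
#'   `list(type = "gaussian_target", center = , width = , peak = ,
#'   background = )`.
#' @param structures list of `list(name = , shape = "sphere", center = ,
#'   radius = )` or `list(name = , shape = "box", corner = , size = )`
#'   (mm, patient coordinates); must fit inside the grid.
#' @param perturbation list with `type` in `c("none", "offset", "scale",
#'   "shift", "local_error")` and the matching parameters.
#' @param seed integer seed driving every random element.
#' @param origin patient coordinates (mm) of the first voxel center.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(20, 20, 20), spacing = c(2, 2, 2),
                         field = list(type = "flat", dose = 10),
                         structures = list(),
                         perturbation = list(type = "none"),
                         seed = 1L, origin = c(0, 0, 0)) {
  grid_shape <- as.integer(grid_shape)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3)
  if (length(grid_shape) != 3L || any(grid_shape < 4L)) {
    stop_validation("`grid_shape` must be three components, all >= 4")
  }
  if (any(spacing <= 0)) stop_validation("`spacing` must be > 0")
  field$type <- match.arg(field$type, c("flat", "wedge", "gaussian_target"))
  perturbation$type <- match.arg(perturbation$type,
                                 c("none", "offset", "scale", "shift",
                                   "local_error"))
  if (perturbation$type == "local_error") {
    fr <- perturbation$fraction
    if (is.null(fr) || fr <= 0 || fr > 1) {
      stop_validation("local_error `fraction` must be in (0, 1]")
    }
    if (!any(vapply(structures, function(s) s$name, character(1)) ==
             perturbation$structure)) {
      stop_validation(sprintf("local_error names unknown structure '%s'",
                              perturbation$structure))
    }
  }
  extent_lo <- origin - spacing / 2
  extent_hi <- origin + (grid_shape - 0.5) * spacing
  for (s in structures) {
    s$shape <- match.arg(s$shape, c("sphere", "box"))
    bb <- if (s$shape == "sphere") {
      rbind(s$center - s$radius, s$center + s$radius)
    } else {
      rbind(s$corner, s$corner + s$size)
    }
    if (any(bb[1, ] < extent_lo) || any(bb[2, ] > extent_hi)) {
      stop_validation(sprintf("structure '%s' does not fit inside the grid",
                              s$name))
    }
  }
  structure(list(grid_shape = grid_shape, spacing = as.numeric(spacing),
                 field = field, structures = structures,
                 perturbation = perturbation, seed = as.integer(seed),
                 origin = as.numeric(origin)),
            class = "phantom_spec")
}

# analytic dose field at arbitrary patient coordinates (vectorised over a
# tensor grid given by axis vectors)
eval_field <- function(field, x, y, z, origin) {
  nx <- length(x); ny <- length(y); nz <- length(z)
  switch(field$type,
    flat = array(field$dose, dim = c(nx, ny, nz)),
    wedge = {
      base <- field$base %||% 0
      s <- switch(field$axis, x = x - origin[1], y = y - origin[2],
                  z = z - origin[3])
      along <- base + field$gradient * s
      arr <- array(0, dim = c(nx, ny, nz))
      arr[] <- switch(field$axis,
        x = rep(along, times = ny * nz),
        y = rep(rep(along, each = nx), times = nz),
        z = rep(along, each = nx * ny))
      arr
    },
    gaussian_target = {
      d2 <- outer(outer((x - field$center[1])^2, (y - field$center[2])^2,
                        `+`),
                  (z - field$center[3])^2, `+`)
      bg <- field$background %||% 0
      bg + (field$peak - bg) * exp(-d2 / (2 * field$width^2))
    })
}

#' Generate a phantom's dose grids and structure set
#'
#' Deterministic for a fixed spec (including its seed).  The reference
#' field is the analytic field sampled at voxel centers; the evaluated
#' field is the reference transformed by the perturbation.  Spheres are
#' contoured per slice as inscribed 64-gons.
#'
#' @param spec a [phantom_spec()].
#' @return A list with `reference` and `evaluated` ([dose_grid()]s),
#'   `structures` ([structure_set()]) and `manifest` (list of ground-truth
#'   numbers; see [write_phantom()]).
#' @export
make_phantom <- function(spec) {
  if (!inherits(spec, "phantom_spec")) spec <- do.call(phantom_spec, spec)
  d <- spec$grid_shape
  ax <- list(x = spec$origin[1] + (seq_len(d[1]) - 1) * spec$spacing[1],
             y = spec$origin[2] + (seq_len(d[2]) - 1) * spec$spacing[2],
             z = spec$origin[3] + (seq_len(d[3]) - 1) * spec$spacing[3])
  ref_vals <- eval_field(spec$field, ax$x, ax$y, ax$z, spec$origin)
  if (any(ref_vals < 0)) {
    stop_validation("field produces negative dose; adjust base/background")
  }
  for_uid <- content_uid("phantom-frame", spec$grid_shape, spec$seed)
  reference <- dose_grid(ref_vals, spec$origin, spec$spacing,
                         frame_of_reference = for_uid)
  structures <- structure_set(
    lapply(spec$structures, function(s) {
      list(name = s$name,
           contours = phantom_contours(s, ax, spec$spacing))
    }),
    frame_of_reference = for_uid)

  p <- spec$perturbation
  evl_vals <- switch(p$type,
    none = ref_vals,
    offset = ref_vals + p$gy,
    scale = ref_vals * p$factor,
    shift = eval_field(spec$field, ax$x - p$mm[1], ax$y - p$mm[2],
                       ax$z - p$mm[3], spec$origin),
    local_error = {
      si <- which(vapply(spec$structures, function(s) s$name,
                         character(1)) == p$structure)
      mask <- rasterize_structure(structures$structures[[si]], reference)
      inside_idx <- which(mask$inside)
      n_bad <- max(1L, round(p$fraction * length(inside_idx)))
      set.seed(spec$seed)
      bad <- sample(inside_idx, n_bad)
      v <- ref_vals
      v[bad] <- v[bad] + p$amplitude_gy
      attr(v, "affected_voxels") <- n_bad
      attr(v, "mask_voxels") <- length(inside_idx)
      v
    })
  affected <- attr(evl_vals, "affected_voxels")
  mask_n <- attr(evl_vals, "mask_voxels")
  attributes(evl_vals) <- list(dim = d)
  if (any(evl_vals < 0)) {
    stop_validation("perturbation produces negative dose")
  }
  evaluated <- dose_grid(evl_vals, spec$origin, spec$spacing,
                         frame_of_reference = for_uid)

  crit <- gamma_criteria()
  manifest <- list(
    seed = spec$seed,
    field = spec$field,
    perturbation = p,
    max_reference_dose = max(ref_vals),
    structure_names = vapply(spec$structures, function(s) s$name,
                             character(1))
  )
  if (p$type == "offset") {
    # flat-field closed form: |gamma| = |offset| / (dd% x norm), DTA useless
    manifest$expected_gamma_global <-
      abs(p$gy) / ((crit$dose_percent / 100) * max(ref_vals))
  }
  if (p$type == "shift" && spec$field$type == "wedge") {
    g <- spec$field$gradient
    s_mm <- sqrt(sum(p$mm^2))
    dd <- (crit$dose_percent / 100)
    manifest$expected_gamma_shift <- function_free_shift_gamma(
      s_mm, g, dd * manifest$max_reference_dose, crit$dta_mm)
  }
  if (p$type == "local_error") {
    manifest$affected_voxels <- affected
    manifest$structure_mask_voxels <- mask_n
    manifest$expected_failing_fraction <- affected / mask_n
  }
  list(reference = reference, evaluated = evaluated,
       structures = structures, manifest = manifest)
}

# shifted-gradient closed form: gamma = s.g / sqrt(dD^2 + g^2 dta^2)
function_free_shift_gamma <- function(shift_mm, gradient, dd_abs, dta_mm) {
  shift_mm * gradient / sqrt(dd_abs^2 + gradient^2 * dta_mm^2)
}

phantom_contours <- function(s, ax, spacing) {
  contours <- list()
  if (s$shape == "sphere") {
    theta <- 2 * pi * (seq_len(64) - 1) / 64
    for (k in seq_along(ax$z)) {
      dz <- ax$z[k] - s$center[3]
      if (abs(dz) >= s$radius) next
      r_k <- sqrt(s$radius^2 - dz^2)
      if (r_k < 1e-6) next
      contours[[length(contours) + 1L]] <- cbind(
        s$center[1] + r_k * cos(theta),
        s$center[2] + r_k * sin(theta),
        ax$z[k])
    }
  } else {
    x0 <- s$corner[1]; y0 <- s$corner[2]
    x1 <- x0 + s$size[1]; y1 <- y0 + s$size[2]
    zs <- ax$z[ax$z >= s$corner[3] - 1e-9 &
               ax$z <= s$corner[3] + s$size[3] + 1e-9]
    for (z in zs) {
      contours[[length(contours) + 1L]] <- cbind(
        c(x0, x1, x1, x0), c(y0, y0, y1, y1), z)
    }
  }
  contours
}

#' Write a phantom to DICOM files with a ground-truth manifest
#'
#' Writes the reference and evaluated RTDOSE and the RTSTRUCT via the
#' package's DICOM writers, plus a JSON manifest recording the spec and the
#' analytic ground truths (e.g. the expected flat-offset gamma and the
#' expected failing fraction of a local error).  Fully deterministic:
#' the same spec produces byte-identical files.
#'
#' @param spec a [phantom_spec()].
#' @param directory output directory (created if needed).
#' @return Named character vector of the file paths, invisibly (the
#'   RTSTRUCT entry is omitted for structure-free specs).
#' @export
write_phantom <- function(spec, directory) {
  if (!inherits(spec, "phantom_spec")) spec <- do.call(phantom_spec, spec)
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  ph <- make_phantom(spec)
  paths <- c(
    reference = file.path(directory, "reference_rtdose.dcm"),
    evaluated = file.path(directory, "evaluated_rtdose.dcm"),
    structures = file.path(directory, "rtstruct.dcm"),
    manifest = file.path(directory, "manifest.json")
  )
  write_rtdose(ph$reference, paths[["reference"]])
  write_rtdose(ph$evaluated, paths[["evaluated"]])
  if (length(ph$structures$structures) > 0) {
    write_rtstruct(ph$structures, ph$reference, paths[["structures"]])
  } else {
    paths <- paths[names(paths) != "structures"]
  }
  manifest <- c(list(spec = unclass(spec)), ph$manifest)
  jsonlite::write_json(manifest, paths[["manifest"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}
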