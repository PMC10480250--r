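#' Gamma evaluation criteria
#'
#' The acceptance criteria of the gamma index: dose-difference percentage
#' (of the normalisation dose), distance-to-agreement in mm, the low-dose
#' threshold below which reference voxels are excluded, and the search
#' discretisation.  The defaults are the clinical 2%/2 mm with a zero
#' threshold.
#'
#' @param dose_percent dose-difference criterion, % of the normalisation
#'   dose.
#' @param dta_mm distance-to-agreement criterion, mm.
#' @param low_dose_threshold Gy; reference voxels must be *strictly* above
#'   this to enter the statistics.  With the default 0 the zeros outside a
#'   masked structure are automatically excluded.
#' @param pass_cutoff a voxel passes when `|gamma| <= pass_cutoff`.
#' @param search_step_fraction the DTA search samples the evaluated dose at
#'   step `dta_mm / search_step_fraction`.
#' @param max_search_mm search radius; defaults to `2 * dta_mm`.  Points
#'   whose true minimum lies beyond it report the best value inside the
#'   radius (hence > 1, failing).
#' @return An object of class `gamma_criteria`.
#' @export
gamma_criteria <- function(dose_percent = 2, dta_mm = 2,
                           low_dose_threshold = 0, pass_cutoff = 1,
                           search_step_fraction = 10,
                           max_search_mm = 2 * dta_mm) {
  vals <- c(dose_percent = dose_percent, dta_mm = dta_mm,
            pass_cutoff = pass_cutoff,
            search_step_fraction = search_step_fraction,
            max_search_mm = max_search_mm)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop_validation("all gamma criteria must be finite and > 0")
  }
  if (!is.finite(low_dose_threshold) || low_dose_threshold < 0) {
    stop_validation("`low_dose_threshold` must be >= 0")
  }
  structure(list(dose_percent = dose_percent, dta_mm = dta_mm,
                 low_dose_threshold = low_dose_threshold,
                 pass_cutoff = pass_cutoff,
                 search_step_fraction = search_step_fraction,
                 max_search_mm = max_search_mm),
            class = "gamma_criteria")
}

#' @export
print.gamma_criteria <- function(x, ...) {
  cat(sprintf(
    "<gamma_criteria> %g%% / %g mm, threshold %g Gy, pass |gamma| <= %g\n",
    x$dose_percent, x$dta_mm, x$low_dose_threshold, x$pass_cutoff))
  invisible(x)
}

# per-voxel absolute dose-difference criterion (Gy)
dd_abs_volume <- function(reference, criteria, norm) {
  f <- criteria$dose_percent / 100
  if (norm$mode == "local") f * reference$values
  else array(f * norm$value, dim = dim(reference$values))
}

new_gamma_result <- function(signed_gamma, structure_name, normalization,
                             criteria) {
  finite <- !is.na(signed_gamma)
  n_eval <- sum(finite)
  pass_rate <- if (n_eval == 0) NA_real_ else {
    100 * sum(abs(signed_gamma[finite]) <= criteria$pass_cutoff) / n_eval
  }
  structure(list(signed_gamma = signed_gamma,
                 structure_name = structure_name,
                 normalization = normalization, criteria = criteria,
                 evaluated_voxel_count = n_eval, pass_rate = pass_rate),
            class = "gamma_result")
}

#' @export
print.gamma_result <- function(x, ...) {
  cat(sprintf("<gamma_result> '%s' (%s mode): %d voxels evaluated\n",
              x$structure_name, x$normalization$mode,
              x$evaluated_voxel_count))
  if (is.na(x$pass_rate)) {
    cat("  pass rate undefined (no evaluated voxels)\n")
  } else {
    cat(sprintf("  pass rate %.1f%% (|gamma| <= %g)\n",
                x$pass_rate, x$criteria$pass_cutoff))
  }
  invisible(x)
}

#' Compute the structure-restricted 3D gamma index
#'
#' Evaluates the signed gamma index at every reference voxel that is inside
#' the mask and strictly above the low-dose threshold.  The evaluated-dose
#' search domain is by default the structure-masked evaluated grid (zeros
#' outside the structure participate in the search, mirroring the masked
#' per-structure datasets of the workflow); set `search_unmasked = TRUE` to
#' search the full evaluated grid instead.
#'
#' The sign of each gamma value is the sign of the dose difference
#' (evaluated minus reference) at the reference voxel itself: positive
#' where the evaluated dose is hotter, negative where colder.
#'
#' @param reference,evaluated congruent [dose_grid()] objects.
#' @param mask a [rasterize_structure()] mask congruent with the grids.
#'   `NULL` evaluates the whole grid.
#' @param criteria a [gamma_criteria()].
#' @param norm a [normalization_spec()].
#' @param search_unmasked if `TRUE`, the DTA search samples the unmasked
#'   evaluated grid.
#' @return A `gamma_result`: signed gamma array (NaN outside evaluated
#'   voxels), the criteria and normalisation used, the evaluated voxel
#'   count and the pass rate in percent.
#' @export
compute_gamma <- function(reference, evaluated, mask = NULL,
                          criteria = gamma_criteria(),
                          norm = resolve_normalization("global",
                                                       reference = reference),
                          search_unmasked = FALSE) {
  gamma_dispatch(reference, evaluated, mask, criteria, norm,
                 search_unmasked, engine = "fast")
}

#' Exhaustive-search gamma oracle
#'
#' Identical contract to [compute_gamma()] but minimising over a dense
#' offset lattice (step `dta_mm / 50`).  Ground truth for verification;
#' refuses grids larger than ~30^3 voxels.
#'
#' @inheritParams compute_gamma
#' @return A `gamma_result`.
#' @export
brute_force_gamma <- function(reference, evaluated, mask = NULL,
                              criteria = gamma_criteria(),
                              norm = resolve_normalization("global",
                                                           reference = reference),
                              search_unmasked = FALSE) {
  if (prod(dim(reference$values)) > 30^3) {
    stop_validation(
      "brute_force_gamma is a verification oracle: grids above ~30^3 voxels are refused")
  }
  gamma_dispatch(reference, evaluated, mask, criteria, norm,
                 search_unmasked, engine = "brute")
}

gamma_dispatch <- function(reference, evaluated, mask, criteria, norm,
                           search_unmasked, engine) {
  stopifnot_congruent(reference, evaluated, "reference and evaluated grids")
  d <- dim(reference$values)
  if (is.null(mask)) {
    mask <- structure(list(inside = array(TRUE, dim = d),
                           structure_name = "<all>",
                           voxel_count = prod(d)),
                      class = "structure_mask")
  }
  if (!identical(dim(mask$inside), d)) {
    stop_validation("mask shape does not match the dose grids")
  }
  if (inherits(norm, "gamma_skip")) {
    stop_validation(sprintf("normalisation skipped: %s", norm$reason))
  }
  ref_masked <- mask_dose(reference, mask)
  evl_search <- if (search_unmasked) evaluated else mask_dose(evaluated, mask)
  dd_abs <- dd_abs_volume(reference, criteria, norm)
  eligible <- mask$inside & (reference$values > criteria$low_dose_threshold)
  n_zero_inside <- sum(mask$inside &
                       !(reference$values > criteria$low_dose_threshold))
  if (n_zero_inside > 0 && criteria$low_dose_threshold == 0) {
    warn(sprintf(
      "%d voxel(s) inside '%s' have zero reference dose and are excluded by the strict threshold",
      n_zero_inside, mask$structure_name))
  }
  if (!any(eligible)) {
    warn(sprintf(
      "no evaluable voxels for structure '%s' (empty mask or all at/below the %g Gy threshold)",
      mask$structure_name, criteria$low_dose_threshold))
    return(new_gamma_result(array(NaN, dim = d), mask$structure_name,
                            norm, criteria))
  }
  args <- list(as.vector(ref_masked$values), as.vector(evl_search$values),
               as.vector(eligible), as.integer(d),
               as.numeric(reference$spacing), as.vector(dd_abs),
               criteria$dta_mm)
  g <- if (engine == "fast") {
    do.call(gamma_engine_cpp, c(args, list(
      criteria$dta_mm / criteria$search_step_fraction,
      criteria$max_search_mm, criteria$low_dose_threshold)))
  } else {
    do.call(gamma_brute_cpp, c(args, list(
      criteria$max_search_mm, criteria$low_dose_threshold)))
  }
  g <- array(g, dim = d)
  g[is.na(g)] <- NaN
  new_gamma_result(g, mask$structure_name, norm, criteria)
}

#' Signed gamma at a single reference voxel
#'
#' @param ref_point integer length-3 voxel index (1-based).
#' @inheritParams compute_gamma
#' @param norm_dose normalisation dose in Gy at this point.
#' @return Signed gamma value (numeric scalar).
#' @export
gamma_point <- function(ref_point, reference, evaluated,
                        criteria = gamma_criteria(), norm_dose) {
  if (!is.finite(norm_dose) || norm_dose <= 0) {
    stop_validation("`norm_dose` must be a positive dose in Gy")
  }
  d <- dim(reference$values)
  ref_point <- as.integer(ref_point)
  if (any(ref_point < 1L) || any(ref_point > d)) {
    stop_validation("`ref_point` is outside the grid")
  }
  msk <- array(FALSE, dim = d)
  msk[ref_point[1], ref_point[2], ref_point[3]] <- TRUE
  mask <- structure(list(inside = msk, structure_name = "<point>",
                         voxel_count = 1L),
                    class = "structure_mask")
  criteria$low_dose_threshold <- -Inf  # the point itself always evaluates
  res <- suppressWarnings(compute_gamma(
    reference, evaluated, mask, criteria,
    normalization_spec("global", norm_dose), search_unmasked = TRUE))
  res$signed_gamma[ref_point[1], ref_point[2], ref_point[3]]
}

#' Structure-based gamma evaluation of a whole plan
#'
#' The full workflow: filter planning structures (ring/couch/bolus/
#' artifact), rasterise each kept structure onto the dose grid, mask both
#' dose volumes per structure, resolve the normalisation dose for each
#' requested mode (skipping structure-mode pairs with no tolerance), and
#' compute the structure-restricted gamma.
#'
#' @param reference,evaluated congruent [dose_grid()] objects (reference =
#'   e.g. the TPS dose, evaluated = the independent calculation).
#' @param structures a [structure_set()].
#' @param tables list of [tolerance_table()] objects for the `quantec` and
#'   `ro` modes (a missing QUANTEC table falls back to the shipped one).
#' @param criteria a [gamma_criteria()].
#' @param modes character vector from `c("global", "local", "quantec",
#'   "ro")`.
#' @param name_table a [default_name_table()].
#' @param search_unmasked passed to [compute_gamma()].
#' @return An object of class `structural_gamma`: a list with `results`
#'   (tibble: one row per structure x mode with pass rate, normalisation
#'   dose, voxel counts, skip reason, and the `gamma_result` in a list
#'   column) and `exclusions` (the [select_structures()] table).
#' @export
structural_gamma <- function(reference, evaluated, structures,
                             tables = list(quantec_table()),
                             criteria = gamma_criteria(),
                             modes = c("global", "local", "quantec", "ro"),
                             name_table = default_name_table(),
                             search_unmasked = FALSE) {
  stopifnot_congruent(reference, evaluated, "reference and evaluated grids")
  modes <- match.arg(modes, c("global", "local", "quantec", "ro"),
                     several.ok = TRUE)
  selection <- select_structures(structures, name_table)
  kept <- selection[selection$kept, ]
  if (nrow(kept) == 0L) {
    stop_validation("no structures remain after planning-structure filtering")
  }
  rows <- list()
  for (si in seq_len(nrow(kept))) {
    s <- structures$structures[[kept$index[si]]]
    canonical <- kept$canonical[si]
    mask <- tryCatch(
      rasterize_structure(s$contours, reference, name = s$name),
      structgamma_error = function(e) e)
    for (mode in modes) {
      row <- tibble(
        structure = s$name,
        canonical = canonical,
        mode = mode,
        norm_dose = NA_real_,
        evaluated_voxels = NA_integer_,
        pass_rate = NA_real_,
        skip_reason = NA_character_,
        result = list(NULL)
      )
      if (inherits(mask, "condition")) {
        row$skip_reason <- conditionMessage(mask)
        rows[[length(rows) + 1L]] <- row
        next
      }
      norm <- resolve_normalization(mode, canonical, reference, tables)
      if (inherits(norm, "gamma_skip")) {
        row$skip_reason <- norm$reason
        rows[[length(rows) + 1L]] <- row
        next
      }
      res <- tryCatch(
        suppressWarnings(compute_gamma(reference, evaluated, mask,
                                       criteria, norm,
                                       search_unmasked = search_unmasked)),
        structgamma_error = function(e) e)
      if (inherits(res, "condition")) {
        row$skip_reason <- conditionMessage(res)
      } else {
        row$norm_dose <- norm$value
        row$evaluated_voxels <- res$evaluated_voxel_count
        row$pass_rate <- res$pass_rate
        row$result <- list(res)
        if (res$evaluated_voxel_count == 0L) {
          row$skip_reason <- "no evaluable voxels (empty mask or all below threshold)"
        }
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  structure(list(results = dplyr::bind_rows(rows), exclusions = selection,
                 criteria = criteria),
            class = "structural_gamma")
}

#' @export
print.structural_gamma <- function(x, ...) {
  cat(sprintf("<structural_gamma> %d structure-mode evaluations\n",
              nrow(x$results)))
  print(tidy(x))
  invisible(x)
}

#' @rdname structural_gamma
#' @param x a `structural_gamma` object.
#' @param ... unused.
#' @export
tidy.structural_gamma <- function(x, ...) {
  dplyr::select(x$results, -"result")
}

#' @rdname structural_gamma
#' @export
glance.structural_gamma <- function(x, ...) {
  r <- x$results
  tibble(
    n_structures = length(unique(r$structure)),
    n_evaluations = sum(!is.na(r$pass_rate)),
    n_skipped = sum(is.na(r$pass_rate)),
    mean_pass_rate = mean(r$pass_rate, na.rm = TRUE),
    min_pass_rate = if (all(is.na(r$pass_rate))) NA_real_
                    else min(r$pass_rate, na.rm = TRUE)
  )
}

#' Tidy per-voxel gamma table
#'
#' Columnar export of one structure's gamma volume for downstream tools.
#'
#' @param x a `gamma_result`.
#' @param ... unused.
#' @return A tibble with `structure`, voxel indices `i`, `j`, `k`, and
#'   `gamma` for every evaluated voxel.
#' @export
tidy.gamma_result <- function(x, ...) {
  idx <- which(!is.na(x$signed_gamma), arr.ind = TRUE)
  tibble(structure = x$structure_name,
         i = idx[, 1], j = idx[, 2], k = idx[, 3],
         gamma = x$signed_gamma[idx])
}

#' @rdname tidy.gamma_result
#' @export
glance.gamma_result <- function(x, ...) {
  tibble(structure = x$structure_name, mode = x$normalization$mode,
         norm_dose = x$normalization$value,
         evaluated_voxels = x$evaluated_voxel_count,
         pass_rate = x$pass_rate,
         max_abs_gamma = if (x$evaluated_voxel_count == 0) NA_real_
                         else max(abs(x$signed_gamma), na.rm = TRUE))
}
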