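#' Shipped QUANTEC organ-at-risk dose tolerances
#'
#' Point-dose (dmax) tolerance per organ, in Gy, for the 17 organs the
#' package standardises.  Where the QUANTEC compendium lists several
#' tolerance levels, the conservative value (lowest toxicity level) is
#' used.  These are the normalisation doses of the `quantec` gamma mode.
#'
#' @return A `tolerance_table`: tibble of `name`, `dose_gy` with attributes
#'   `source = "QUANTEC"`.
#' @export
quantec_table <- function() {
  entries <- tibble(
    name = c("BLADDER", "BRAINSTEM", "COCHLEA", "FEMORAL HEAD", "HEART",
             "LARYNX", "LENS", "LUNG", "MANDIBLE", "OESOPHAGUS",
             "OPTIC NERVE", "ORAL CAVITY", "PAROTID", "PHARYNX", "RECTUM",
             "SMALL BOWEL", "SPINAL CORD"),
    dose_gy = c(65, 54, 45, 50, 26,
                44, 10, 7, 50, 34,
                55, 30, 20, 50, 50,
                45, 50)
  )
  tolerance_table(entries, source = "QUANTEC")
}

#' Build a tolerance table
#'
#' @param entries tibble/data frame with columns `name` (canonical,
#'   upper-case) and `dose_gy` (> 0).
#' @param source label, e.g. `"QUANTEC"` or `"RO"`.
#' @param prescription_dose optional prescription dose in Gy (used for the
#'   PTV rule of RO tables).
#' @return An object of class `tolerance_table` (a tibble).
#' @export
tolerance_table <- function(entries, source, prescription_dose = NULL) {
  entries <- as_tibble(entries)[, c("name", "dose_gy")]
  if (any(is.na(entries$dose_gy)) || any(entries$dose_gy <= 0)) {
    stop_validation("all tolerance doses must be > 0 Gy")
  }
  if (any(entries$name != toupper(entries$name)) ||
      any(!nzchar(entries$name))) {
    stop_validation("canonical structure names must be non-empty upper-case")
  }
  if (anyDuplicated(entries$name)) {
    stop_validation("duplicate structure in tolerance table")
  }
  structure(entries,
            class = c("tolerance_table", class(tibble())),
            source = source,
            prescription_dose = prescription_dose)
}

#' Look up the shipped QUANTEC tolerance for one organ
#'
#' @param name canonical structure name.
#' @return Dose in Gy, or `NA` for organs not in the table (including PTV,
#'   which has no QUANTEC tolerance).
#' @examples
#' quantec_tolerance("BLADDER")  # 65
#' quantec_tolerance("PTV")      # NA
#' @export
quantec_tolerance <- function(name) {
  tab <- quantec_table()
  i <- match(toupper(name), tab$name)
  if (is.na(i)) NA_real_ else tab$dose_gy[i]
}

#' Load clinician (RO) specified dose tolerances
#'
#' Reads a plain-text file of per-patient constraints, one
#' `NAME = dose_Gy` per line (`#` comments).  A PTV entry is auto-filled
#' with the prescription dose when the file has none: PTV dose-difference
#' normalisation in RO mode is relative to the prescribed dose.
#'
#' @param path file path.
#' @param prescription_dose prescription dose in Gy for the PTV rule.
#' @return A [tolerance_table()] with source `"RO"`.
#' @export
load_ro_tolerances <- function(path, prescription_dose = NULL) {
  kv <- read_keyvalue_file(path)
  nm <- toupper(names(kv))
  dose <- suppressWarnings(as.numeric(kv))
  for (i in seq_along(dose)) {
    if (is.na(dose[i]) || dose[i] <= 0) {
      stop_validation(sprintf(
        "tolerance for '%s' in %s must be a positive dose in Gy (got '%s')",
        nm[i], path, kv[i]))
    }
  }
  known <- c(quantec_table()$name, "PTV")
  unknown <- setdiff(nm, known)
  if (length(unknown) > 0) {
    warn(sprintf("RO tolerance file lists structures outside the standard table (kept): %s",
                 paste(unknown, collapse = ", ")))
  }
  if (!"PTV" %in% nm && !is.null(prescription_dose)) {
    nm <- c(nm, "PTV")
    dose <- c(dose, prescription_dose)
  }
  tolerance_table(tibble(name = nm, dose_gy = unname(dose)),
                  source = "RO", prescription_dose = prescription_dose)
}

#' Normalisation specification for the dose-difference criterion
#'
#' @param mode one of `"global"`, `"local"`, `"quantec"`, `"ro"`.
#' @param value normalisation dose in Gy, or `NA` for local mode (the
#'   per-point marker: each reference point normalises to its own dose).
#' @param description free-text record of what was used.
#' @return An object of class `normalization_spec`.
#' @export
normalization_spec <- function(mode, value = NA_real_, description = "") {
  mode <- match.arg(mode, c("global", "local", "quantec", "ro"))
  if (mode == "local") {
    value <- NA_real_
  } else if (is.na(value) || value <= 0) {
    stop_validation(sprintf(
      "normalisation mode '%s' needs a single positive dose in Gy", mode))
  }
  structure(list(mode = mode, value = value, description = description),
            class = "normalization_spec")
}

#' @export
print.normalization_spec <- function(x, ...) {
  cat(sprintf("<normalization> %s: %s\n", x$mode,
              if (x$mode == "local") "per-point local dose"
              else sprintf("%.4g Gy", x$value)))
  if (nzchar(x$description)) cat(" ", x$description, "\n")
  invisible(x)
}

#' Resolve the normalisation dose for one structure and mode
#'
#' `global` uses the maximum of the *unmasked* reference dose volume (so it
#' is the same for every structure); `local` normalises each point to its
#' own reference dose; `quantec`/`ro` use the structure's tolerance dose
#' from the matching table.  A structure with no tolerance in the requested
#' table yields a skip: that structure-mode pair is not evaluated (e.g. the
#' RO specified no constraint for the organ; PTV has no QUANTEC tolerance).
#'
#' @param mode `"global"`, `"local"`, `"quantec"` or `"ro"`.
#' @param structure canonical structure name (may be `NA` for unmatched
#'   names; tolerance modes then skip).
#' @param reference the unmasked reference [dose_grid()].
#' @param tables list of [tolerance_table()] objects (sources consulted by
#'   their `source` attribute).
#' @return A [normalization_spec()], or an object of class `gamma_skip`
#'   with a `reason` field.
#' @export
resolve_normalization <- function(mode, structure = NA_character_,
                                  reference = NULL, tables = list()) {
  mode <- match.arg(mode, c("global", "local", "quantec", "ro"))
  if (mode == "global") {
    if (is.null(reference)) {
      stop_validation("global mode needs the reference dose grid")
    }
    dmax <- max(reference$values)
    if (dmax <= 0) stop_validation("reference dose volume is all zero")
    return(normalization_spec("global", dmax,
      sprintf("global maximum of the unmasked reference volume: %.4g Gy",
              dmax)))
  }
  if (mode == "local") {
    return(normalization_spec("local",
      description = "per-point local reference dose"))
  }
  want <- if (mode == "quantec") "QUANTEC" else "RO"
  tab <- NULL
  for (t in tables) {
    if (identical(attr(t, "source"), want)) tab <- t
  }
  if (mode == "quantec" && is.null(tab)) tab <- quantec_table()
  if (is.null(tab)) {
    return(gamma_skip(sprintf("no %s tolerance table supplied", want)))
  }
  i <- if (is.na(structure)) NA_integer_ else match(structure, tab$name)
  if (is.na(i)) {
    return(gamma_skip(sprintf(
      "no %s dose tolerance specified for structure '%s'", want,
      if (is.na(structure)) "<unmatched>" else structure)))
  }
  normalization_spec(mode, tab$dose_gy[i],
                     sprintf("%s tolerance for %s: %.4g Gy (dmax)",
                             want, structure, tab$dose_gy[i]))
}

gamma_skip <- function(reason) {
  structure(list(reason = reason), class = "gamma_skip")
}

#' @export
print.gamma_skip <- function(x, ...) {
  cat("<gamma_skip>", x$reason, "\n")
  invisible(x)
}
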