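#' Structure-name standardisation table
#'
#' Clinical plans name the same organ many ways ("Parotid_L", "LT PAROTID",
#' "parotid lt").  The name table maps raw-name patterns to canonical
#' upper-case organ names so tolerance lookup works across plans, and holds
#' the exclusion patterns for planning structures (ring, couch, bolus,
#' artifact) that are dropped before gamma evaluation.
#'
#' Matching is case-insensitive after stripping non-alphanumeric characters,
#' and laterality markers (L/R/LT/RT/LEFT/RIGHT and sided suffixes) map to
#' the unsided canonical organ.  A raw name starting with "PTV" maps to
#' canonical "PTV" (needed for the prescription-dose tolerance rule).
#'
#' @param extra optional named character vector of additional
#'   `pattern = canonical` entries (patterns squashed like raw names).
#' @param extra_exclusions optional character vector of additional exclusion
#'   substrings.
#' @return An object of class `name_table`.
#' @export
default_name_table <- function(extra = NULL, extra_exclusions = NULL) {
  entries <- c(
    BLADDER = "BLADDER", URINARYBLADDER = "BLADDER",
    BRAINSTEM = "BRAINSTEM", BRAINSTEM0 = "BRAINSTEM",
    COCHLEA = "COCHLEA",
    FEMORALHEAD = "FEMORAL HEAD", FEMHEAD = "FEMORAL HEAD",
    FEMURHEAD = "FEMORAL HEAD",
    HEART = "HEART",
    LARYNX = "LARYNX",
    LENS = "LENS",
    LUNG = "LUNG", LUNGS = "LUNG",
    MANDIBLE = "MANDIBLE",
    OESOPHAGUS = "OESOPHAGUS", ESOPHAGUS = "OESOPHAGUS",
    OPTICNERVE = "OPTIC NERVE", OPTICNRV = "OPTIC NERVE",
    ORALCAVITY = "ORAL CAVITY",
    PAROTID = "PAROTID", PAROTIDGLAND = "PAROTID",
    PHARYNX = "PHARYNX",
    RECTUM = "RECTUM",
    SMALLBOWEL = "SMALL BOWEL", BOWELSMALL = "SMALL BOWEL",
    SPINALCORD = "SPINAL CORD", CORD = "SPINAL CORD",
    SPINALCANAL = "SPINAL CORD"
  )
  if (!is.null(extra)) {
    extra <- setNames(toupper(as.character(extra)),
                      squash_name(names(extra)))
    dup <- intersect(names(extra), names(entries))
    conflict <- dup[entries[dup] != extra[dup]]
    if (length(conflict) > 0) {
      stop_validation(sprintf(
        "pattern(s) %s would map to two canonical names",
        paste(conflict, collapse = ", ")))
    }
    entries <- c(entries, extra[!names(extra) %in% names(entries)])
  }
  exclusions <- unique(c("ring", "couch", "bolus", "artifact",
                         tolower(extra_exclusions %||% character(0))))
  structure(list(entries = entries, exclusions = exclusions),
            class = "name_table")
}

#' Read name-table extensions from a plain-text file
#'
#' One `pattern = CANONICAL` per line; `#` starts a comment.  Lines whose
#' canonical name is `EXCLUDE` add the pattern to the exclusion list.
#'
#' @param path file path.
#' @return A `name_table` extending [default_name_table()].
#' @export
read_name_table <- function(path) {
  kv <- read_keyvalue_file(path)
  excl <- names(kv)[toupper(kv) == "EXCLUDE"]
  keep <- kv[toupper(kv) != "EXCLUDE"]
  default_name_table(extra = keep, extra_exclusions = excl)
}

# uppercase and strip everything non-alphanumeric
squash_name <- function(x) gsub("[^A-Z0-9]", "", toupper(x))

# drop laterality tokens, then squash
strip_laterality <- function(x) {
  tokens <- strsplit(toupper(x), "[^A-Z0-9]+")[[1]]
  tokens <- tokens[!tokens %in% c("L", "R", "LT", "RT", "LEFT", "RIGHT",
                                  "BILAT", "BILATERAL")]
  paste(tokens, collapse = "")
}

#' Map a raw structure name to its canonical organ name
#'
#' @param raw raw structure name from the plan.
#' @param table a [default_name_table()].
#' @return Canonical upper-case name, or `NA_character_` when no pattern
#'   matches.
#' @examples
#' standardize_name("Parotid_L")    # "PAROTID"
#' standardize_name("spinal cord")  # "SPINAL CORD"
#' standardize_name("zzz_opti_shell3")  # NA
#' @export
standardize_name <- function(raw, table = default_name_table()) {
  squashed <- squash_name(raw)
  if (startsWith(squashed, "PTV")) return("PTV")
  for (key in c(squashed, strip_laterality(raw))) {
    if (nzchar(key) && !is.na(table$entries[key])) {
      return(unname(table$entries[key]))
    }
  }
  NA_character_
}

#' Filter a structure set for gamma evaluation
#'
#' Drops planning structures whose raw name contains an exclusion pattern
#' (ring, couch, bolus, artifact; case-insensitive substring) and keeps
#' everything else, including PTVs and names with no canonical match.
#'
#' @param set a [structure_set()] (or the bare list of structures).
#' @param table a [default_name_table()].
#' @return A tibble with one row per structure: `raw_name`, `canonical`
#'   (NA when unmatched), `kept`, `reason` (the matched exclusion pattern,
#'   NA when kept), and `index` into the original set.
#' @export
select_structures <- function(set, table = default_name_table()) {
  structures <- if (inherits(set, "structure_set")) set$structures else set
  if (length(structures) == 0L) {
    return(tibble(raw_name = character(0), canonical = character(0),
                  kept = logical(0), reason = character(0),
                  index = integer(0)))
  }
  raw <- vapply(structures, function(s) s$name, character(1))
  reason <- vapply(raw, function(nm) {
    hit <- table$exclusions[vapply(table$exclusions,
                                   function(p) grepl(p, nm, ignore.case = TRUE),
                                   logical(1))]
    if (length(hit) > 0) hit[1] else NA_character_
  }, character(1))
  tibble(
    raw_name = raw,
    canonical = unname(vapply(raw, standardize_name, character(1),
                              table = table)),
    kept = unname(is.na(reason)),
    reason = unname(reason),
    index = seq_along(raw)
  )
}

# shared parser for "KEY = value" files with "#" comments
read_keyvalue_file <- function(path) {
  if (!file.exists(path)) {
    stop_format(sprintf("file does not exist: %s", path))
  }
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  keep <- nzchar(lines)
  out <- character(0)
  for (i in which(keep)) {
    parts <- strsplit(lines[i], "=", fixed = TRUE)[[1]]
    if (length(parts) != 2) {
      stop_validation(sprintf("line %d of %s is not 'KEY = value': '%s'",
                              i, path, lines[i]))
    }
    out[trimws(parts[1])] <- trimws(parts[2])
  }
  out
}
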