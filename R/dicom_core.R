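# Minimal DICOM file-format layer: explicit/implicit VR little-endian,
# nested sequences with defined or undefined lengths.  Covers the RT Dose,
# RT Structure Set and CT attributes the workflow needs; it is not a
# general DICOM toolkit.

UID_EXPLICIT_LE <- "1.2.840.10008.1.2.1"
UID_IMPLICIT_LE <- "1.2.840.10008.1.2"
UID_RTDOSE_STORAGE <- "1.2.840.10008.5.1.4.1.1.481.2"
UID_RTSTRUCT_STORAGE <- "1.2.840.10008.5.1.4.1.1.481.3"
UID_CT_STORAGE <- "1.2.840.10008.5.1.4.1.1.2"

# tag -> VR dictionary (implicit-VR reads and all writes)
DCM_DICT <- local({
  d <- c(
    "00020000" = "UL", "00020001" = "OB", "00020002" = "UI",
    "00020003" = "UI", "00020010" = "UI", "00020012" = "UI",
    "00080005" = "CS", "00080016" = "UI", "00080018" = "UI",
    "00080060" = "CS",
    "0020000D" = "UI", "0020000E" = "UI",
    "00200032" = "DS", "00200037" = "DS", "00200052" = "UI",
    "00280002" = "US", "00280004" = "CS", "00280008" = "IS",
    "00280009" = "AT", "00280010" = "US", "00280011" = "US",
    "00280030" = "DS", "00280100" = "US", "00280101" = "US",
    "00280102" = "US", "00280103" = "US",
    "00281052" = "DS", "00281053" = "DS",
    "30040002" = "CS", "30040004" = "CS", "3004000A" = "CS",
    "3004000C" = "DS", "3004000E" = "DS",
    "30060002" = "SH", "30060020" = "SQ", "30060022" = "IS",
    "30060024" = "UI", "30060026" = "LO", "30060036" = "CS",
    "30060039" = "SQ", "30060040" = "SQ", "30060042" = "CS",
    "30060046" = "IS", "30060050" = "DS", "30060084" = "IS",
    "7FE00010" = "OW"
  )
  d
})

tag_key <- function(group, element) sprintf("%04X%04X", group, element)

# ---- byte-level primitives ------------------------------------------------

u16_at <- function(bytes, pos) {
  as.integer(bytes[pos]) + 256L * as.integer(bytes[pos + 1L])
}
u32_at <- function(bytes, pos) {
  # double-valued: DICOM undefined length 0xFFFFFFFF exceeds .Machine$integer.max
  as.numeric(bytes[pos]) + 256 * as.numeric(bytes[pos + 1L]) +
    65536 * as.numeric(bytes[pos + 2L]) + 16777216 * as.numeric(bytes[pos + 3L])
}
enc_u16 <- function(x) {
  x <- as.integer(round(x))
  as.raw(rbind(x %% 256L, x %/% 256L))
}
enc_u32 <- function(x) {
  x <- as.numeric(x)
  b0 <- x %% 256; x <- x %/% 256
  b1 <- x %% 256; x <- x %/% 256
  b2 <- x %% 256; b3 <- x %/% 256
  as.raw(rbind(b0, b1, b2, b3))
}
dec_u32_vec <- function(bytes) {
  m <- matrix(as.numeric(bytes), nrow = 4L)
  m[1, ] + 256 * m[2, ] + 65536 * m[3, ] + 16777216 * m[4, ]
}
dec_i16_vec <- function(bytes) {
  readBin(bytes, what = "integer", n = length(bytes) / 2L, size = 2L,
          signed = TRUE, endian = "little")
}

LONG_VRS <- c("OB", "OW", "OF", "SQ", "UT", "UN")

# ---- parsing --------------------------------------------------------------

# Returns list(elements = named list, pos).  Each element:
# list(group, element, vr, value) with value raw bytes, or for SQ a list of
# item datasets (named element lists).
dcm_parse_elements <- function(bytes, pos, end, explicit,
                               stop_group = NULL) {
  elements <- list()
  n <- length(bytes)
  while (pos + 7 <= end && pos + 7 <= n) {
    group <- u16_at(bytes, pos)
    element <- u16_at(bytes, pos + 2L)
    if (group == 0xFFFE && element %in% c(0xE00D, 0xE0DD)) break
    if (!is.null(stop_group) && group != stop_group) break
    key <- tag_key(group, element)
    if (explicit && group != 0xFFFE) {
      vr <- rawToChar(bytes[(pos + 4L):(pos + 5L)])
      if (vr %in% LONG_VRS) {
        len <- u32_at(bytes, pos + 8L)
        data_pos <- pos + 12L
      } else {
        len <- u16_at(bytes, pos + 6L)
        data_pos <- pos + 8L
      }
    } else {
      vr <- DCM_DICT[[key]] %||% "UN"
      len <- u32_at(bytes, pos + 4L)
      data_pos <- pos + 8L
    }
    undefined <- len == 4294967295
    if (vr == "SQ" || (undefined && vr == "UN")) {
      parsed <- dcm_parse_items(bytes, data_pos,
                                if (undefined) n else data_pos + len - 1,
                                explicit, undefined)
      elements[[key]] <- list(group = group, element = element, vr = "SQ",
                              value = parsed$items)
      pos <- parsed$pos
    } else {
      if (undefined) {
        stop_dialect(sprintf(
          "undefined-length non-sequence element %s is not supported", key))
      }
      value <- if (len > 0) bytes[data_pos:(data_pos + len - 1L)] else raw(0)
      elements[[key]] <- list(group = group, element = element, vr = vr,
                              value = value)
      pos <- data_pos + len
    }
  }
  list(elements = elements, pos = pos)
}

dcm_parse_items <- function(bytes, pos, end, explicit, undefined) {
  items <- list()
  n <- length(bytes)
  repeat {
    if (pos + 7 > n || (!undefined && pos > end)) break
    group <- u16_at(bytes, pos)
    element <- u16_at(bytes, pos + 2L)
    len <- u32_at(bytes, pos + 4L)
    pos <- pos + 8L
    if (group == 0xFFFE && element == 0xE0DD) break   # sequence delimiter
    if (!(group == 0xFFFE && element == 0xE000)) {
      stop_format("malformed sequence: expected an item tag")
    }
    item_undefined <- len == 4294967295
    item_end <- if (item_undefined) n else pos + len - 1
    parsed <- dcm_parse_elements(bytes, pos, item_end, explicit)
    items[[length(items) + 1L]] <- parsed$elements
    pos <- parsed$pos
    if (item_undefined) pos <- pos + 8L   # skip item delimiter
  }
  list(items = items, pos = pos)
}

#' @noRd
read_dicom_file <- function(path) {
  if (!file.exists(path)) {
    stop_format(sprintf("file does not exist: %s", path))
  }
  bytes <- readBin(path, what = "raw", n = file.size(path))
  if (length(bytes) < 132 ||
      !identical(rawToChar(bytes[129:132]), "DICM")) {
    stop_format(sprintf("not a DICOM file (missing DICM magic): %s", path))
  }
  meta <- dcm_parse_elements(bytes, 133L, length(bytes), explicit = TRUE,
                             stop_group = 0x0002)
  ts <- dcm_string(meta$elements, "00020010")
  if (is.null(ts)) {
    stop_dialect("file meta lacks TransferSyntaxUID (0002,0010)")
  }
  explicit <- switch(ts,
    "1.2.840.10008.1.2.1" = TRUE,
    "1.2.840.10008.1.2" = FALSE,
    stop_dialect(sprintf("unsupported transfer syntax %s", ts))
  )
  body <- dcm_parse_elements(bytes, meta$pos, length(bytes), explicit)
  c(meta$elements, body$elements)
}

# ---- value decoding -------------------------------------------------------

dcm_string <- function(ds, key) {
  el <- ds[[key]]
  if (is.null(el)) return(NULL)
  v <- el$value
  while (length(v) > 0 && v[length(v)] == as.raw(0L)) v <- v[-length(v)]
  s <- rawToChar(v)
  Encoding(s) <- "UTF-8"
  sub(" +$", "", s)
}
dcm_numbers <- function(ds, key) {
  s <- dcm_string(ds, key)
  if (is.null(s) || !nzchar(s)) return(NULL)
  as.numeric(strsplit(s, "\\\\")[[1]])
}
dcm_us <- function(ds, key) {
  el <- ds[[key]]
  if (is.null(el)) return(NULL)
  readBin(el$value, "integer", n = length(el$value) / 2L, size = 2L,
          signed = FALSE, endian = "little")
}
dcm_required <- function(value, attr_name) {
  if (is.null(value)) {
    stop_dialect(sprintf("required DICOM attribute missing: %s", attr_name))
  }
  value
}

# ---- encoding -------------------------------------------------------------

fmt_ds <- function(x) {
  # DS values are <= 16 characters; shrink precision until they fit
  vapply(x, function(v) {
    for (digits in c(12, 10, 8, 6)) {
      s <- formatC(v, digits = digits, format = "g")
      if (nchar(s) <= 16) return(s)
    }
    s
  }, character(1))
}

dcm_el <- function(group, element, vr, value) {
  list(group = group, element = element, vr = vr, value = value)
}
el_str <- function(group, element, vr, s) {
  dcm_el(group, element, vr, charToRaw(enc2utf8(s)))
}
el_ds <- function(group, element, x) {
  el_str(group, element, "DS", paste(fmt_ds(x), collapse = "\\"))
}
el_is <- function(group, element, x) {
  el_str(group, element, "IS", paste(as.integer(round(x)), collapse = "\\"))
}
el_us <- function(group, element, x) {
  dcm_el(group, element, "US", enc_u16(x))
}

pad_even <- function(bytes, vr) {
  if (length(bytes) %% 2L == 1L) {
    pad <- if (vr %in% c("UI", "OB", "OW", "UN")) as.raw(0L) else as.raw(0x20)
    bytes <- c(bytes, pad)
  }
  bytes
}

# Serialise one element (explicit VR LE, defined lengths throughout).
dcm_encode_element <- function(el) {
  if (el$vr == "SQ") {
    items_bytes <- lapply(el$value, function(item) {
      body <- do.call(c, c(lapply(item, dcm_encode_element), list(raw(0))))
      c(enc_u16(0xFFFE), enc_u16(0xE000), enc_u32(length(body)), body)
    })
    data <- do.call(c, c(items_bytes, list(raw(0))))
  } else {
    data <- pad_even(el$value, el$vr)
  }
  header <- c(enc_u16(el$group), enc_u16(el$element), charToRaw(el$vr))
  if (el$vr %in% LONG_VRS) {
    c(header, as.raw(c(0L, 0L)), enc_u32(length(data)), data)
  } else {
    if (length(data) > 65535) {
      stop_validation(sprintf(
        "element (%04X,%04X) value too long for a short-form VR",
        el$group, el$element))
    }
    c(header, enc_u16(length(data)), data)
  }
}

# elements: unnamed list of dcm_el(), already sorted by caller or not
write_dicom_file <- function(path, sop_class_uid, sop_instance_uid,
                             elements) {
  ord <- order(vapply(elements, function(e) e$group * 2^16 + e$element,
                      numeric(1)))
  elements <- elements[ord]
  meta <- list(
    dcm_el(0x0002, 0x0001, "OB", as.raw(c(0L, 1L))),
    el_str(0x0002, 0x0002, "UI", sop_class_uid),
    el_str(0x0002, 0x0003, "UI", sop_instance_uid),
    el_str(0x0002, 0x0010, "UI", UID_EXPLICIT_LE),
    el_str(0x0002, 0x0012, "UI", "2.25.73.1")
  )
  meta_bytes <- do.call(c, lapply(meta, dcm_encode_element))
  group_len <- dcm_encode_element(
    dcm_el(0x0002, 0x0000, "UL", enc_u32(length(meta_bytes))))
  body <- do.call(c, lapply(elements, dcm_encode_element))
  out <- c(as.raw(rep(0L, 128)), charToRaw("DICM"),
           group_len, meta_bytes, body)
  con <- tryCatch(file(path, "wb"), condition = function(e) {
    abort(sprintf("cannot open %s for writing", path),
          class = c("structgamma_io_error", "structgamma_error"))
  })
  on.exit(close(con))
  writeBin(out, con)
  invisible(path)
}

# Deterministic content-derived UID (no timestamps anywhere in the files,
# so identical inputs produce byte-identical output).
content_uid <- function(...) {
  sig <- paste(vapply(list(...), function(x)
    paste(format(x, digits = 12), collapse = ","), character(1)),
    collapse = ";")
  h <- 5381
  for (c in utf8ToInt(sig)) h <- (h * 33 + c) %% 1e15
  sprintf("2.25.%.0f", h)
}
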