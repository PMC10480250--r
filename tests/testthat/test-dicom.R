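test_that("RTDOSE files round-trip dose values and geometry", {
  td <- withr::local_tempdir()
  set.seed(11)
  for (trial in 1:5) {
    vals <- array(runif(8 * 8 * 8, 0.5, 60), dim = c(8, 8, 8))
    g <- dose_grid(vals, origin = runif(3, -50, 50),
                   spacing = runif(3, 1, 3))
    path <- file.path(td, sprintf("d%d.dcm", trial))
    write_rtdose(g, path)
    back <- read_rtdose(path)
    expect_lt(max(abs(back$values - g$values) / pmax(g$values, 1e-9)), 1e-4)
    expect_lt(max(abs(back$origin - g$origin)), 1e-3)
    expect_lt(max(abs(back$spacing - g$spacing)), 1e-3)
    # voxel-center patient coordinates survive the round trip
    axg <- grid_axes(g); axb <- grid_axes(back)
    expect_lt(max(abs(axg$x - axb$x), abs(axg$y - axb$y),
                  abs(axg$z - axb$z)), 1e-3)
  }
})

test_that("constant and all-zero grids round-trip exactly", {
  td <- withr::local_tempdir()
  g <- dose_grid(array(10, dim = c(20, 20, 20)), c(0, 0, 0), c(2, 2, 2))
  write_rtdose(g, file.path(td, "c.dcm"))
  back <- read_rtdose(file.path(td, "c.dcm"))
  expect_lt(max(abs(back$values - 10)), 10 * 1e-4)

  z <- dose_grid(array(0, dim = c(4, 4, 4)), c(0, 0, 0), c(1, 1, 1))
  write_rtdose(z, file.path(td, "z.dcm"))
  expect_identical(unique(as.vector(read_rtdose(file.path(td, "z.dcm"))$values)), 0)
})

test_that("negative dose is rejected before writing", {
  v <- array(1, dim = c(4, 4, 4)); v[1] <- -0.5
  expect_error(
    write_rtdose(list(values = v, origin = c(0, 0, 0), spacing = c(1, 1, 1)),
                 tempfile()),
    class = "structgamma_validation_error")
})

# low-level fixture writer for dialect tests
hand_rtdose <- function(path, stored, dims, scaling, offsets,
                        bits = 16L, units = "GY",
                        iop = c(1, 0, 0, 0, 1, 0), ipp = c(0, 0, 0)) {
  el_str <- structgamma:::el_str; el_ds <- structgamma:::el_ds
  el_us <- structgamma:::el_us; el_is <- structgamma:::el_is
  dcm_el <- structgamma:::dcm_el
  pix <- if (bits == 16L) structgamma:::enc_u16(stored)
         else structgamma:::enc_u32(stored)
  structgamma:::write_dicom_file(path, structgamma:::UID_RTDOSE_STORAGE,
    "2.25.1", list(
      el_str(0x0008, 0x0016, "UI", structgamma:::UID_RTDOSE_STORAGE),
      el_str(0x0008, 0x0018, "UI", "2.25.1"),
      el_str(0x0008, 0x0060, "CS", "RTDOSE"),
      el_ds(0x0020, 0x0032, ipp),
      el_ds(0x0020, 0x0037, iop),
      el_us(0x0028, 0x0002, 1L),
      el_is(0x0028, 0x0008, dims[3]),
      el_us(0x0028, 0x0010, dims[2]),
      el_us(0x0028, 0x0011, dims[1]),
      el_ds(0x0028, 0x0030, c(1, 1)),
      el_us(0x0028, 0x0100, bits),
      el_us(0x0028, 0x0103, 0L),
      el_str(0x3004, 0x0002, "CS", units),
      el_ds(0x3004, 0x000C, offsets),
      el_str(0x3004, 0x000E, "DS", format(scaling)),
      dcm_el(0x7FE0, 0x0010, "OW", pix)))
}

test_that("dose-grid scaling is applied to stored integers", {
  path <- withr::local_tempfile(fileext = ".dcm")
  dims <- c(2L, 2L, 2L)
  hand_rtdose(path, stored = rep(50400L, 8), dims = dims, scaling = 0.001,
              offsets = c(0, 1))
  g <- read_rtdose(path)
  expect_equal(unique(as.vector(g$values)), 50.4)
})

test_that("unsupported RTDOSE dialects are rejected with named attributes", {
  dims <- c(2L, 2L, 3L)
  p1 <- withr::local_tempfile(fileext = ".dcm")
  hand_rtdose(p1, rep(1L, 12), dims, 0.01, offsets = c(0, 1, 2.5))
  expect_error(read_rtdose(p1), "GridFrameOffsetVector",
               class = "structgamma_dialect_error")

  p2 <- withr::local_tempfile(fileext = ".dcm")
  hand_rtdose(p2, rep(1L, 12), dims, 0.01, offsets = c(0, 1, 2),
              units = "RELATIVE")
  expect_error(read_rtdose(p2), "GY", class = "structgamma_dialect_error")

  p3 <- withr::local_tempfile(fileext = ".dcm")
  hand_rtdose(p3, rep(1L, 12), dims, 0.01, offsets = c(0, 1, 2),
              iop = c(sqrt(0.5), sqrt(0.5), 0, 0, 0, 1))
  expect_error(read_rtdose(p3), "axis-aligned",
               class = "structgamma_dialect_error")

  expect_error(read_rtdose(withr::local_tempfile(fileext = ".dcm")),
               class = "structgamma_format_error")
})

test_that("flipped axis-aligned orientations are canonicalised on read", {
  path <- withr::local_tempfile(fileext = ".dcm")
  dims <- c(3L, 2L, 2L)
  vals <- array(seq_len(12), dim = dims)
  # rows run toward -y from y = 4; the slice normal (row x col) then points
  # toward -z, so the frames advance downward from z = 0
  flipped <- vals[, 2:1, ]
  hand_rtdose(path, as.vector(flipped) * 100, dims, 0.01,
              offsets = c(0, 2), iop = c(1, 0, 0, 0, -1, 0),
              ipp = c(0, 4, 0))
  g <- read_rtdose(path)
  expect_equal(g$origin, c(0, 3, -2))
  expect_equal(g$values, flipped[, 2:1, 2:1], tolerance = 1e-6)
  expect_equal(g$orientation, diag(3))
  expect_true(all(g$spacing > 0))
})

test_that("RTSTRUCT files round-trip names and vertices", {
  td <- withr::local_tempdir()
  geom <- dose_grid(array(1, dim = c(30, 30, 12)), c(0, 0, 0), c(2, 2, 2))
  sq <- function(z, r = 10, c0 = c(20, 20)) {
    cbind(c0[1] + c(-r, r, r, -r), c0[2] + c(-r, -r, r, r), z)
  }
  set <- structure_set(list(
    list(name = "PAROTID", contours = lapply(seq(0, 18, by = 2), sq)),
    list(name = "couch", contours = list(sq(4))),
    list(name = "Kørper", contours = list(sq(6)))   # unicode name
  ))
  path <- file.path(td, "rs.dcm")
  write_rtstruct(set, geom, path)
  back <- read_rtstruct(path)
  # names byte-exact, order preserved, couch NOT filtered by the reader
  expect_identical(structure_names(back), structure_names(set))
  expect_length(back$structures[[1]]$contours, 10)
  for (i in seq_along(set$structures)) {
    for (j in seq_along(set$structures[[i]]$contours)) {
      expect_lt(max(abs(back$structures[[i]]$contours[[j]] -
                        set$structures[[i]]$contours[[j]])), 1e-3)
    }
  }
})

test_that("degenerate and missing contours are tolerated with warnings", {
  td <- withr::local_tempdir()
  geom <- dose_grid(array(1, dim = c(20, 20, 6)), c(0, 0, 0), c(2, 2, 2))
  tri <- cbind(c(4, 30, 16), c(4, 4, 30), 2)
  set <- structure_set(list(list(name = "BRAINSTEM", contours = list(tri))))
  path <- file.path(td, "rs.dcm")
  write_rtstruct(set, geom, path)

  # splice a 2-point contour into a fresh ROI by rewriting at element level
  ds <- structgamma:::read_dicom_file(path)
  el_is <- structgamma:::el_is; el_str <- structgamma:::el_str
  el_ds <- structgamma:::el_ds; dcm_el <- structgamma:::dcm_el
  cont2 <- list(dcm_el(0x3006, 0x0040, "SQ", list(list(
                  el_str(0x3006, 0x0042, "CS", "CLOSED_PLANAR"),
                  el_is(0x3006, 0x0046, 2),
                  el_ds(0x3006, 0x0050, c(0, 0, 2, 1, 1, 2))))),
                el_is(0x3006, 0x0084, 2))
  rebuild <- list(
    el_str(0x0008, 0x0016, "UI", structgamma:::UID_RTSTRUCT_STORAGE),
    el_str(0x0008, 0x0018, "UI", "2.25.2"),
    el_str(0x0008, 0x0060, "CS", "RTSTRUCT"),
    dcm_el(0x3006, 0x0020, "SQ", list(
      list(el_is(0x3006, 0x0022, 1),
           el_str(0x3006, 0x0026, "LO", "BRAINSTEM")),
      list(el_is(0x3006, 0x0022, 2),
           el_str(0x3006, 0x0026, "LO", "LENS")),
      list(el_is(0x3006, 0x0022, 3),
           el_str(0x3006, 0x0026, "LO", "REF PT")))),
    dcm_el(0x3006, 0x0039, "SQ", list(
      ds[["30060039"]]$value[[1]], cont2)))
  path2 <- file.path(td, "rs2.dcm")
  structgamma:::write_dicom_file(path2, structgamma:::UID_RTSTRUCT_STORAGE,
                                 "2.25.2", rebuild)
  w <- capture_warnings(back <- read_rtstruct(path2))
  expect_true(any(grepl("degenerate", w)))
  expect_true(any(grepl("no contour data", w)))
  expect_identical(structure_names(back), c("BRAINSTEM", "LENS", "REF PT"))
  expect_length(back$structures[[1]]$contours, 1)   # kept
  expect_length(back$structures[[2]]$contours, 0)   # degenerate dropped
  expect_length(back$structures[[3]]$contours, 0)   # no contour data at all
})

test_that("empty structure collections cannot be written", {
  geom <- dose_grid(array(1, dim = c(4, 4, 4)), c(0, 0, 0), c(1, 1, 1))
  expect_error(write_rtstruct(structure_set(list()), geom, tempfile()),
               class = "structgamma_validation_error")
})

test_that("our DICOM dialect interoperates with an independent reader", {
  td <- withr::local_tempdir()
  spec <- phantom_spec(
    grid_shape = c(10, 12, 8), spacing = c(2, 2, 3),
    field = list(type = "gaussian_target", center = c(9, 11, 10),
                 width = 6, peak = 50, background = 1),
    structures = list(list(name = "PAROTID_L", shape = "sphere",
                           center = c(9, 11, 10), radius = 6)))
  paths <- write_phantom(spec, td)
  ph <- make_phantom(spec)
  py <- file.path(td, "check.py")
  writeLines(c(
    "import sys, json, pydicom, numpy as np",
    sprintf("d = %s", deparse(td)),
    "ds = pydicom.dcmread(d + '/reference_rtdose.dcm')",
    "arr = ds.pixel_array * ds.DoseGridScaling  # (frames, rows, cols)",
    "ss = pydicom.dcmread(d + '/rtstruct.dcm')",
    "out = {",
    " 'modality': str(ds.Modality), 'units': str(ds.DoseUnits),",
    " 'maxdose': float(arr.max()),",
    " 'dose_234': float(arr[3, 2, 1]),",
    " 'rois': [str(r.ROIName) for r in ss.StructureSetROISequence],",
    " 'ncontours': len(ss.ROIContourSequence[0].ContourSequence)}",
    "pydicom.dcmread(d + '/evaluated_rtdose.dcm').save_as(",
    " d + '/rewritten.dcm', enforce_file_format=True)",
    "print(json.dumps(out))"), py)
  res <- system2("python", py, stdout = TRUE, stderr = TRUE)
  info <- jsonlite::fromJSON(res[length(res)])
  expect_identical(info$modality, "RTDOSE")
  expect_identical(info$units, "GY")
  expect_equal(info$maxdose, max(ph$reference$values), tolerance = 1e-6)
  # pydicom indexes (frame, row, col) = our [i=2, j=3, k=4]
  expect_equal(info$dose_234, ph$reference$values[2, 3, 4],
               tolerance = 1e-6)
  expect_identical(info$rois, "PAROTID_L")
  expect_identical(info$ncontours,
                   length(ph$structures$structures[[1]]$contours))
  # and a pydicom-written file comes back through our reader
  back <- read_rtdose(file.path(td, "rewritten.dcm"))
  expect_equal(back$values, ph$evaluated$values, tolerance = 1e-6)
})
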