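test_that("identical distributions give gamma == 0 and pass rate 100", {
  ph <- flat_offset_phantom(offset = 0)
  for (norm in list(normalization_spec("global", 10),
                    normalization_spec("local"),
                    normalization_spec("quantec", 65))) {
    r <- compute_gamma(ph$reference, ph$evaluated, norm = norm)
    expect_true(all(r$signed_gamma[!is.na(r$signed_gamma)] == 0))
    expect_equal(r$pass_rate, 100)
    expect_identical(r$evaluated_voxel_count, 512L)
  }
})

test_that("a uniform offset on a flat field matches the closed form", {
  ph <- flat_offset_phantom(dose = 10, offset = 0.2)
  # norm 10 Gy, 2%: Delta-D = 0.2 Gy exactly -> gamma = +1.0 at every voxel
  r <- compute_gamma(ph$reference, ph$evaluated,
                     norm = normalization_spec("global", 10))
  gv <- r$signed_gamma[!is.na(r$signed_gamma)]
  expect_equal(max(abs(gv - 1)), 0)
  expect_equal(r$pass_rate, 100)  # gamma = 1.0 passes (boundary passes)

  # norm 65 Gy: gamma = 0.2 / 1.3 within 1e-9
  r65 <- compute_gamma(ph$reference, ph$evaluated,
                       norm = normalization_spec("global", 65))
  gv65 <- r65$signed_gamma[!is.na(r65$signed_gamma)]
  expect_lt(max(abs(gv65 - 0.2 / (0.02 * 65))), 1e-9)

  # manifest closed form agrees with the computation
  expect_equal(ph$manifest$expected_gamma_global, 1, tolerance = 1e-12)
})

test_that("the sign follows the local dose difference (cold is negative)", {
  ph <- flat_offset_phantom(dose = 10, offset = 0.2)
  cold <- compute_gamma(ph$evaluated, ph$reference,  # swapped: now colder
                        norm = normalization_spec("global", 10))
  gv <- cold$signed_gamma[!is.na(cold$signed_gamma)]
  # flat fields: DTA cannot reduce a uniform offset, so gamma = -0.2/0.2
  expect_true(all(abs(gv + 1) < 1e-12))
  # zero difference resolves to a positive sign
  same <- flat_offset_phantom(offset = 0)
  r0 <- compute_gamma(same$reference, same$evaluated,
                      norm = normalization_spec("global", 10))
  expect_true(all(sign(r0$signed_gamma[!is.na(r0$signed_gamma)]) >= 0))
})

test_that("a shifted linear wedge matches the DTA closed form", {
  spec <- phantom_spec(
    grid_shape = c(20, 20, 20), spacing = 1,
    field = list(type = "wedge", gradient = 1, axis = "x", base = 2),
    structures = list(list(name = "CORE", shape = "box",
                           corner = c(4.5, 4.5, 4.5), size = c(10, 10, 10))),
    perturbation = list(type = "shift", mm = c(1, 0, 0)))
  ph <- make_phantom(spec)
  mask <- rasterize_structure(ph$structures$structures[[1]], ph$reference)
  r <- compute_gamma(ph$reference, ph$evaluated, mask,
                     norm = normalization_spec("global", 50),
                     search_unmasked = TRUE)
  gv <- r$signed_gamma[!is.na(r$signed_gamma)]
  # gamma = s*g / sqrt(dD^2 + g^2 dta^2) = 1/sqrt(5)
  expect_lt(max(abs(abs(gv) - 1 / sqrt(5))), 0.02)
  expect_equal(r$evaluated_voxel_count, mask$voxel_count)
})

test_that("local normalisation blows up where the reference dose is low", {
  # a fixed 0.5 Gy error in a low-dose (~2 Gy) organ far from the target:
  # harmless against the ~50 Gy global maximum, huge against the local dose
  spec <- phantom_spec(
    grid_shape = c(20, 10, 10), spacing = 2,
    field = list(type = "gaussian_target", center = c(4, 9, 9),
                 width = 8, peak = 50, background = 2),
    structures = list(list(name = "FarOrgan", shape = "sphere",
                           center = c(30, 9, 9), radius = 7)),
    perturbation = list(type = "local_error", structure = "FarOrgan",
                        amplitude_gy = 0.5, fraction = 1), seed = 4)
  ph <- make_phantom(spec)
  mask <- rasterize_structure(ph$structures$structures[[1]], ph$reference)
  glob <- compute_gamma(ph$reference, ph$evaluated, mask,
                        norm = resolve_normalization("global",
                                                     reference = ph$reference))
  loc <- compute_gamma(ph$reference, ph$evaluated, mask,
                       norm = normalization_spec("local"))
  expect_equal(glob$pass_rate, 100)
  expect_lt(loc$pass_rate, glob$pass_rate)
  # 0.5 Gy against a ~2 Gy local dose is far beyond the 2% criterion
  expect_gt(max(abs(loc$signed_gamma), na.rm = TRUE), 1)
})

test_that("raising the normalisation dose never lowers gamma or pass rates", {
  for (seed in 1:4) {
    ph <- random_qa_phantom(seed)
    doses <- c(20, 40, 65)
    res <- lapply(doses, function(dn)
      compute_gamma(ph$reference, ph$evaluated,
                    norm = normalization_spec("quantec", dn)))
    for (i in 1:2) {
      a <- res[[i + 1]]; b <- res[[i]]
      expect_true(all(abs(a$signed_gamma) <= abs(b$signed_gamma) + 1e-12,
                      na.rm = TRUE))
      expect_gte(a$pass_rate, b$pass_rate)
    }
  }
})

test_that("loosening either criterion never lowers the pass rate", {
  ph <- random_qa_phantom(11)
  norm <- normalization_spec("global", max(ph$reference$values))
  base <- compute_gamma(ph$reference, ph$evaluated,
                        criteria = gamma_criteria(2, 2), norm = norm)
  wider_dd <- compute_gamma(ph$reference, ph$evaluated,
                            criteria = gamma_criteria(3, 2), norm = norm)
  wider_dta <- compute_gamma(ph$reference, ph$evaluated,
                             criteria = gamma_criteria(2, 3), norm = norm)
  expect_gte(wider_dd$pass_rate, base$pass_rate)
  expect_gte(wider_dta$pass_rate, base$pass_rate)
})

test_that("translating grids and mask together leaves gamma unchanged", {
  ph <- random_qa_phantom(21)
  shift_grid <- function(g, s) {
    dose_grid(g$values, g$origin + s, g$spacing, g$orientation,
              g$frame_of_reference)
  }
  s <- c(2, -4, 6)  # whole-voxel multiples of the 2 mm spacing
  r1 <- compute_gamma(ph$reference, ph$evaluated,
                      norm = normalization_spec("global", 50))
  r2 <- compute_gamma(shift_grid(ph$reference, s),
                      shift_grid(ph$evaluated, s),
                      norm = normalization_spec("global", 50))
  expect_identical(r1$signed_gamma, r2$signed_gamma)
})

test_that("masked-out and zero-dose voxels stay out of the statistics", {
  spec <- phantom_spec(
    grid_shape = c(16, 16, 8), spacing = 2,
    field = list(type = "flat", dose = 10),
    structures = list(list(name = "ORGAN", shape = "box",
                           corner = c(4, 4, 2), size = c(12, 12, 8))),
    perturbation = list(type = "offset", gy = 0.1))
  ph <- make_phantom(spec)
  mask <- rasterize_structure(ph$structures$structures[[1]], ph$reference)
  r <- compute_gamma(ph$reference, ph$evaluated, mask,
                     norm = normalization_spec("global", 10))
  expect_identical(r$evaluated_voxel_count, mask$voxel_count)
  expect_true(all(is.na(r$signed_gamma[!mask$inside])))

  # a threshold above the dose excludes everything, with a warning not a crash
  expect_warning(
    r2 <- compute_gamma(ph$reference, ph$evaluated, mask,
                        criteria = gamma_criteria(low_dose_threshold = 20),
                        norm = normalization_spec("global", 10)),
    "no evaluable")
  expect_true(is.na(r2$pass_rate))
  expect_identical(r2$evaluated_voxel_count, 0L)
})

test_that("gamma_point matches the volumetric engine at single voxels", {
  ph <- random_qa_phantom(31)
  r <- compute_gamma(ph$reference, ph$evaluated,
                     norm = normalization_spec("global", 50),
                     search_unmasked = TRUE)
  for (pt in list(c(3, 4, 5), c(6, 6, 6), c(10, 2, 8))) {
    expect_equal(gamma_point(pt, ph$reference, ph$evaluated, norm_dose = 50),
                 r$signed_gamma[pt[1], pt[2], pt[3]])
  }
  expect_error(gamma_point(c(1, 1, 1), ph$reference, ph$evaluated,
                           norm_dose = -1),
               class = "structgamma_validation_error")
})

test_that("the oracle refuses oversized grids and reproduces closed forms", {
  big <- dose_grid(array(1, dim = c(31, 31, 31)), c(0, 0, 0), c(1, 1, 1))
  expect_error(brute_force_gamma(big, big),
               class = "structgamma_validation_error")
  ph <- flat_offset_phantom(dose = 10, offset = 0.2)
  rb <- brute_force_gamma(ph$reference, ph$evaluated,
                          norm = normalization_spec("global", 10))
  gv <- rb$signed_gamma[!is.na(rb$signed_gamma)]
  expect_lt(max(abs(gv - 1)), 1e-6)
})

test_that("structural gamma evaluates per structure across modes", {
  spec <- three_organ_spec()
  ph <- make_phantom(spec)
  ro <- tolerance_table(
    tibble::tibble(name = c("BRAINSTEM", "PTV"), dose_gy = c(20, 50)),
    source = "RO")
  sg <- structural_gamma(ph$reference, ph$evaluated, ph$structures,
                         tables = list(quantec_table(), ro))
  res <- tidy(sg)
  # identical dose pair: every computed pass rate is 100
  expect_true(all(res$pass_rate[!is.na(res$pass_rate)] == 100))
  # PTV has no QUANTEC tolerance -> skipped with a reason
  expect_true(is.na(res$pass_rate[res$canonical == "PTV" &
                                  res$mode == "quantec"]))
  expect_match(res$skip_reason[res$canonical == "PTV" &
                               res$mode == "quantec"], "QUANTEC")
  # PAROTID has no RO tolerance in this table -> skipped
  expect_match(res$skip_reason[res$canonical == "PAROTID" &
                               res$mode == "ro"], "PAROTID")
  # global normalisation recorded identically for every structure
  expect_length(unique(res$norm_dose[res$mode == "global"]), 1L)
  g <- glance(sg)
  expect_identical(g$n_structures, 3L)
})

test_that("an error confined to one structure leaves the others at 100%", {
  spec <- three_organ_spec(
    perturbation = list(type = "local_error", structure = "Brainstem",
                        amplitude_gy = 20, fraction = 1), seed = 9)
  ph <- make_phantom(spec)
  sg <- structural_gamma(ph$reference, ph$evaluated, ph$structures,
                         modes = c("global", "local", "quantec"))
  res <- tidy(sg)
  bad <- res[res$structure == "Brainstem" & !is.na(res$pass_rate), ]
  others <- res[res$structure != "Brainstem" & !is.na(res$pass_rate), ]
  expect_true(all(bad$pass_rate < 100))
  expect_true(all(others$pass_rate == 100))
})

test_that("a tolerance above the global maximum can only help the pass rate", {
  # bladder-style case: tolerance 65 Gy > global max ~50 Gy
  spec <- phantom_spec(
    grid_shape = c(20, 14, 10), spacing = 2,
    field = list(type = "gaussian_target", center = c(8, 13, 9),
                 width = 6, peak = 50.4, background = 2),
    structures = list(list(name = "Bladder", shape = "sphere",
                           center = c(28, 13, 9), radius = 8)),
    perturbation = list(type = "offset", gy = 1.2), seed = 2)
  ph <- make_phantom(spec)
  sg <- structural_gamma(ph$reference, ph$evaluated, ph$structures,
                         modes = c("global", "quantec"))
  res <- tidy(sg)
  g <- res$pass_rate[res$mode == "global"]
  q <- res$pass_rate[res$mode == "quantec"]
  expect_gt(quantec_tolerance("BLADDER"), max(ph$reference$values))
  expect_gte(q, g)
  expect_lt(g, 100)  # the comparison is non-trivial
})

test_that("incongruent inputs are rejected", {
  a <- dose_grid(array(1, dim = c(6, 6, 6)), c(0, 0, 0), c(2, 2, 2))
  b <- dose_grid(array(1, dim = c(6, 6, 6)), c(1, 0, 0), c(2, 2, 2))
  expect_error(compute_gamma(a, b), class = "structgamma_validation_error")
  # but resampling onto the reference geometry makes them congruent
  b2 <- resample_to_grid(b, a)
  expect_true(grids_congruent(a, b2))
})
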