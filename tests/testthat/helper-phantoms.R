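# Shared fixtures, all generated in code.

# A smooth random QA case: Gaussian target dose with a random mild
# perturbation, on a small grid so the exhaustive oracle stays cheap.
random_qa_phantom <- function(seed, grid_shape = c(12, 12, 12), spacing = 2) {
  set.seed(seed)
  extent <- (grid_shape - 1) * spacing
  ctr <- runif(3, 0.25, 0.75) * extent
  pert <- switch(sample(c("scale", "offset", "shift"), 1),
    scale = list(type = "scale", factor = runif(1, 0.97, 1.03)),
    offset = list(type = "offset", gy = runif(1, 0, 1)),
    shift = list(type = "shift", mm = runif(3, -1.5, 1.5)))
  make_phantom(phantom_spec(
    grid_shape = grid_shape, spacing = spacing,
    field = list(type = "gaussian_target", center = ctr,
                 width = runif(1, 4, 10), peak = runif(1, 30, 60),
                 background = 2),
    perturbation = pert, seed = seed))
}

# flat-field phantom pair with a uniform evaluated-dose offset
flat_offset_phantom <- function(dose = 10, offset = 0.2,
                                grid_shape = c(8, 8, 8), spacing = 2) {
  make_phantom(phantom_spec(
    grid_shape = grid_shape, spacing = spacing,
    field = list(type = "flat", dose = dose),
    perturbation = if (offset == 0) list(type = "none")
                   else list(type = "offset", gy = offset)))
}

# independent point-in-polygon oracle: winding number by signed-angle sum
winding_number_inside <- function(p, poly) {
  v <- sweep(poly, 2, p)
  n <- nrow(v)
  total <- 0
  for (i in seq_len(n)) {
    a <- v[i, ]
    b <- v[if (i == n) 1L else i + 1L, ]
    total <- total + atan2(a[1] * b[2] - a[2] * b[1],
                           a[1] * b[1] + a[2] * b[2])
  }
  abs(total) > pi
}

# star-shaped simple polygon around a center (always non-self-intersecting)
random_star_polygon <- function(n_vertices = 8, center = c(0, 0),
                                r_range = c(2, 10)) {
  ang <- sort(runif(n_vertices, 0, 2 * pi))
  r <- runif(n_vertices, r_range[1], r_range[2])
  cbind(center[1] + r * cos(ang), center[2] + r * sin(ang))
}

# three disjoint sphere "organs" in one grid, well separated
three_organ_spec <- function(perturbation = list(type = "none"), seed = 1) {
  phantom_spec(
    grid_shape = c(26, 14, 12), spacing = 2,
    field = list(type = "gaussian_target", center = c(25, 13, 11),
                 width = 20, peak = 50, background = 5),
    structures = list(
      list(name = "PTV_50", shape = "sphere", center = c(10, 13, 11),
           radius = 6),
      list(name = "Brainstem", shape = "sphere", center = c(25, 13, 11),
           radius = 5),
      list(name = "Parotid_L", shape = "sphere", center = c(40, 13, 11),
           radius = 6)),
    perturbation = perturbation, seed = seed)
}
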