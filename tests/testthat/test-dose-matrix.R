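# a slab phantom with a gantry-0 beam gives closed-form depths: the body
# spans y in [-70, 70], the beam enters from +y
slab_setup <- function() {
  ph <- build_phantom(slab_spec())
  beams <- preset_beams(0)
  aps <- design_apertures(ph, beams,
    margin = 10, min_per_beam = 1,
    max_per_beam = 1, pad = 20
  )
  list(ph = ph, beams = beams, aps = aps)
}

manual_points <- function(coords, labels) {
  structure(
    list(
      coords = coords, structure = labels,
      point_id = sprintf("P%05d", seq_along(labels)),
      density = NA_real_, seed = NA_integer_
    ),
    class = "sample_point_set"
  )
}

test_that("a surface point under an open field receives phi0 exactly", {
  s <- slab_setup()
  # on the beam axis at the entrance surface (y = 70, beam from +y)
  pts <- manual_points(rbind(c(0, 69.9, 0)), "ptv")
  D <- compute_dose_matrix(s$ph, s$aps, pts, kernel = dose_kernel(phi0 = 1))
  expect_equal(unname(D$values[1, 1]), 1, tolerance = 1e-9)
})

test_that("attenuation at 10 cm depth equals exp(-0.5) for mu = 0.05/cm", {
  s <- slab_setup()
  pts <- manual_points(rbind(c(0, -30, 0)), "ptv") # 100 mm below the surface
  D <- compute_dose_matrix(s$ph, s$aps, pts,
    kernel = dose_kernel(phi0 = 1, mu = 0.05, sigma = 3, step = 1)
  )
  expect_equal(unname(D$values[1, 1]), exp(-0.5), tolerance = 1e-9)
})

test_that("transmission far outside the aperture projection is negligible", {
  s <- slab_setup()
  # 45 mm off-axis: >> both the 10 mm half-field and sigma = 3 mm penumbra
  pts <- manual_points(rbind(c(45, 69.9, 0), c(0, 69.9, 0)), c("body", "ptv"))
  D <- compute_dose_matrix(s$ph, s$aps, pts, kernel = dose_kernel(phi0 = 1))
  expect_lt(unname(D$values[1, 1]), 1e-6)
})

test_that("generated matrices are non-negative, finite and label-complete", {
  for (seed in c(11, 12)) {
    ph <- coarse_plan()$phantom
    pts <- place_sample_points(ph, density = 0.3, seed = seed)
    D <- compute_dose_matrix(ph, coarse_plan()$apertures, pts)
    expect_true(all(is.finite(D$values)))
    expect_true(all(D$values >= 0))
    expect_true(all(colSums(D$values > 0) > 0))
    expect_length(D$structure, nrow(D$values))
  }
})

test_that("the dose matrix is bit-reproducible for fixed inputs", {
  plan <- coarse_plan()
  D1 <- compute_dose_matrix(plan$phantom, plan$apertures, plan$points)
  D2 <- compute_dose_matrix(plan$phantom, plan$apertures, plan$points)
  expect_identical(D1$values, D2$values)
})

test_that("shrinking an aperture's opening never increases any entry in its column", {
  s <- slab_setup()
  pts <- place_sample_points(s$ph, density = 0.5, seed = 21)
  big <- s$aps
  small <- s$aps
  small[[1]]$open <- small[[1]]$open & (row(small[[1]]$open) %% 2 == 0)
  Db <- compute_dose_matrix(s$ph, big, pts)
  Ds <- compute_dose_matrix(s$ph, small, pts)
  expect_true(all(Ds$values <= Db$values + 1e-12))
})

test_that("points outside the body are refused", {
  s <- slab_setup()
  pts <- manual_points(rbind(c(0, 75, 0)), "body")
  expect_error(compute_dose_matrix(s$ph, s$aps, pts), "outside the body")
})

test_that("the matrix constructor enforces its invariants", {
  expect_error(
    dose_influence_matrix(matrix(c(1, -0.1), 2, 1), c("a", "a")),
    "non-negative"
  )
  expect_error(
    dose_influence_matrix(matrix(0, 2, 1), c("a", "a")),
    "positive dose"
  )
  expect_error(
    dose_influence_matrix(matrix(1, 2, 1), "a"),
    "label every row"
  )
})
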