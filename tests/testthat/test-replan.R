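test_that("trials are appended with consecutive indices and are deterministic", {
  plan <- coarse_plan()
  s <- plan_session(plan$D0, plan$objective, goals = plan$goals)
  recs <- lapply(1:6, function(i) run_trial(s))
  expect_equal(vapply(recs, `[[`, integer(1), "trial_index"), 1:6)
  expect_length(s$trials, 6)
  # unchanged penalties reproduce the previous trial bit-exactly
  costs <- vapply(recs, `[[`, numeric(1), "cost_final")
  expect_true(all(costs == costs[1]))
  expect_true(all(c("structure", "achieved", "pass") %in% names(recs[[1]]$goal_pass)))
})

test_that("raising one OAR's penalty does not increase that OAR's cost share", {
  plan <- coarse_plan()
  s <- plan_session(plan$D0, plan$objective)
  r1 <- run_trial(s)
  r2 <- run_trial(s, c(cord = 50))
  share1 <- r1$result$cost_final_report$per_structure[["cord"]]
  share2 <- r2$result$cost_final_report$per_structure[["cord"]]
  expect_lte(share2, share1 + 1e-9)
})

test_that("penalty updates are validated", {
  plan <- coarse_plan()
  s <- plan_session(plan$D0, plan$objective)
  expect_error(run_trial(s, c(cord = -1)), "non-negative")
  expect_error(run_trial(s, c(nothere = 1)), "no goal")
  expect_error(run_trial(s, stats::setNames(1, "")), "named")
})

test_that("nested aperture sweeps have non-increasing surrogate cost", {
  plan <- coarse_plan()
  sw <- aperture_sweep(plan$phantom, plan$beams, plan$objective,
    per_beam_counts = 1:5, seed = 3, density = 0.5
  )
  expect_equal(nrow(sw), 5)
  expect_true(all(diff(sw$surrogate) <= 1e-8 * sw$surrogate[1]))
  expect_true(all(sw$total_apertures == sw$apertures_per_beam * length(plan$beams)))
})

test_that("a single-count sweep reproduces a direct solve on the same set", {
  plan <- coarse_plan()
  sw <- aperture_sweep(plan$phantom, plan$beams, plan$objective,
    per_beam_counts = 3L, seed = 3, density = 0.5
  )
  expect_equal(nrow(sw), 1)
  aps <- design_apertures(plan$phantom, plan$beams,
    min_per_beam = 3, max_per_beam = 3
  )
  pts <- place_sample_points(plan$phantom, density = 0.5, seed = 3)
  D0 <- compute_dose_matrix(plan$phantom, aps, pts)
  res <- optimize_weights(D0, plan$objective, lambda = 0, nonneg = FALSE)
  expect_equal(sw$cost_final, res$cost_final, tolerance = 1e-9)
})

test_that("counts beyond the anatomy's aperture budget are capped with a warning", {
  ph <- build_phantom(slab_spec()) # conformal + 4 splits at most
  obj <- dose_objective(
    structure_goal("ptv", "target", prescription = 50, d_min = 50, d_max = 55),
    structure_goal("body", "oar", d_max = 50, penalty = 0.1)
  )
  expect_warning(
    sw <- aperture_sweep(ph, preset_beams(c(0, 90)), obj,
      per_beam_counts = c(1L, 12L), seed = 2, density = 0.3
    ),
    "capping"
  )
  expect_lt(max(sw$apertures_per_beam), 12)
})

test_that("saved sessions replay bit-exactly", {
  plan <- coarse_plan()
  s <- plan_session(plan$D0, plan$objective)
  run_trial(s)
  run_trial(s, c(cord = 20))
  run_trial(s, c(body = 1, cord = 20))
  path <- tempfile(fileext = ".json")
  save_session(s, path, matrix_ref = "coarse-preset")
  rp <- replay_session(path, plan$D0)
  got <- vapply(rp$session$trials, `[[`, numeric(1), "cost_final")
  expect_identical(got, rp$saved_costs)
})
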