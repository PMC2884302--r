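#' Preset dose objectives for the packaged phantoms
#'
#' Case A (head-and-neck-like): 50.4 Gy prescription to the horseshoe
#' target with a strict 45 Gy maximum on the central cord and 20 Gy-level
#' sparing goals on the lateral parotids. Case B (brain-like): 50 Gy
#' prescription with tight maxima on brainstem and chiasm. Unclassified
#' normal tissue (the body label) carries a loose maximum with a small
#' penalty to control spillage.
#'
#' @param name `"case_a"` or `"case_b"`
#' @return a [dose_objective()]
#' @export
preset_objective <- function(name = c("case_a", "case_b")) {
  name <- match.arg(name)
  if (name == "case_a") {
    dose_objective(
      structure_goal("ptv", "target",
        prescription = 50.4, d_min = 50.4, d_max = 55, penalty = 1
      ),
      structure_goal("cord", "oar", d_max = 45, penalty = 5),
      structure_goal("parotid_l", "oar", d_max = 20, penalty = 1),
      structure_goal("parotid_r", "oar", d_max = 20, penalty = 1),
      structure_goal("body", "oar", d_max = 50, penalty = 0.1)
    )
  } else {
    dose_objective(
      structure_goal("ptv", "target",
        prescription = 50, d_min = 50, d_max = 55, penalty = 1
      ),
      structure_goal("brainstem", "oar", d_max = 50, penalty = 5),
      structure_goal("chiasm", "oar", d_max = 50, penalty = 5),
      structure_goal("body", "oar", d_max = 50, penalty = 0.1)
    )
  }
}

#' Preset clinical goal checks
#'
#' Coverage and sparing checks of the kind used to judge each replanning
#' trial: target coverage at the prescription dose and OAR volume limits.
#'
#' @param name `"case_a"` or `"case_b"`
#' @return list of [dose_goal()] objects
#' @export
preset_goals <- function(name = c("case_a", "case_b")) {
  name <- match.arg(name)
  if (name == "case_a") {
    list(
      dose_goal("ptv", 50.4, ">=", 95),
      dose_goal("ptv", 60, "<=", 0),
      dose_goal("cord", 45, "<=", 0),
      dose_goal("parotid_l", 20, "<=", 40),
      dose_goal("parotid_r", 20, "<=", 40)
    )
  } else {
    list(
      dose_goal("ptv", 50, ">=", 95),
      dose_goal("ptv", 60, "<=", 0),
      dose_goal("brainstem", 50, "<=", 0),
      dose_goal("chiasm", 50, "<=", 0)
    )
  }
}

#' Build a complete preset plan
#'
#' Convenience wrapper running the whole simulation pipeline for one of the
#' packaged presets: phantom, beams, anatomy-based apertures, seeded sample
#' points and the dose-influence matrix, bundled with the preset objective
#' and goal checks.
#'
#' @param name `"case_a"` or `"case_b"`
#' @param spacing voxel spacing, mm
#' @param density sampling density, points per cc
#' @param seed sample-placement seed
#' @param margin aperture margin, mm
#' @param min_per_beam,max_per_beam apertures per beam
#' @param kernel dose kernel parameters
#' @return list with `phantom`, `beams`, `apertures`, `points`, `D0`,
#'   `objective`, `goals`, `name`
#' @examples
#' \donttest{
#' plan <- preset_plan("case_a", spacing = 4)
#' res <- optimize_weights(plan$D0, plan$objective)
#' res$cost_final < res$cost_initial
#' }
#' @export
preset_plan <- function(name = c("case_a", "case_b"), spacing = 2,
                        density = 1, seed = 1L, margin = 5,
                        min_per_beam = 3, max_per_beam = 5,
                        kernel = dose_kernel()) {
  name <- match.arg(name)
  phantom <- build_phantom(phantom_preset_spec(name, spacing = spacing))
  beams <- preset_beams()
  apertures <- design_apertures(phantom, beams,
    margin = margin,
    min_per_beam = min_per_beam, max_per_beam = max_per_beam
  )
  points <- place_sample_points(phantom, density = density, seed = seed)
  D0 <- compute_dose_matrix(phantom, apertures, points, kernel = kernel)
  list(
    name = name, phantom = phantom, beams = beams, apertures = apertures,
    points = points, D0 = D0,
    objective = preset_objective(name), goals = preset_goals(name)
  )
}
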