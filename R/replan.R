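#' Start an interactive-style replanning session
#'
#' The optimizer solves in well under a second, so planning proceeds as a
#' loop: inspect the plan, edit per-structure penalties, re-optimize.
#' A session holds the fixed inputs (dose-influence matrix, labels,
#' objective, solver options, clinical goal checks) and an append-only
#' trial history. Sessions are environments: [run_trial()] mutates the
#' history in place and returns the new trial record.
#'
#' @param D0 a [dose_influence_matrix()]
#' @param objective a [dose_objective()]
#' @param labels per-point structure labels (default: labels stored in `D0`)
#' @param goals optional list of [dose_goal()] checks evaluated per trial
#' @param lambda,nonneg,nnls solver options passed to [optimize_weights()]
#' @param mu_per_weight MU calibration for per-trial plan metrics
#' @return an environment of class `plan_session` with fields `trials`
#'   (list of trial records) and the session inputs
#' @export
plan_session <- function(D0, objective, labels = NULL, goals = list(),
                         lambda = NULL, nonneg = TRUE, nnls = TRUE,
                         mu_per_weight = 1) {
  if (is.null(labels)) labels <- D0$structure
  s <- new.env(parent = emptyenv())
  s$D0 <- D0
  s$labels <- labels
  s$objective <- objective
  s$goals <- goals
  s$options <- list(
    lambda = lambda, nonneg = nonneg, nnls = nnls,
    mu_per_weight = mu_per_weight
  )
  s$trials <- list()
  class(s) <- "plan_session"
  s
}

#' @export
print.plan_session <- function(x, ...) {
  cat(
    "Planning session:", nrow(x$D0$values), "points x", ncol(x$D0$values),
    "apertures,", length(x$trials), "trial(s)\n"
  )
  for (tr in x$trials) {
    cat(sprintf(
      "  trial %d: cost %g, %s\n", tr$trial_index, tr$cost_final,
      if (all(tr$goal_pass$pass)) "all goals met" else
        paste(sum(!tr$goal_pass$pass), "goal(s) failed")
    ))
  }
  invisible(x)
}

#' Run one optimization trial with edited penalties
#'
#' Applies the penalty updates to the session objective, re-runs
#' [optimize_weights()], evaluates the session's clinical goal checks and
#' appends a record to the trial history. With no updates the trial
#' reproduces the previous one exactly (the solve is deterministic).
#'
#' @param session a [plan_session()]
#' @param penalty_update named numeric vector: structure name -> new
#'   penalty (non-negative)
#' @return the new trial record (invisibly also stored in
#'   `session$trials`): `trial_index`, `objective` snapshot, `result`,
#'   `cost_final`, `metrics`, `goal_pass`
#' @export
run_trial <- function(session, penalty_update = numeric(0)) {
  stopifnot(inherits(session, "plan_session"))
  session$objective <- set_penalties(session$objective, penalty_update)
  res <- optimize_weights(
    session$D0, session$objective, session$labels,
    lambda = session$options$lambda,
    nonneg = session$options$nonneg, nnls = session$options$nnls
  )
  gp <- if (length(session$goals)) {
    evaluate_goals(res$doses, session$labels, session$goals)
  } else {
    data.frame(pass = logical(0))
  }
  rec <- list(
    trial_index = length(session$trials) + 1L,
    objective = session$objective,
    penalties = session$objective$penalty,
    result = res,
    cost_final = res$cost_final,
    metrics = plan_metrics(res, mu_per_weight = session$options$mu_per_weight),
    goal_pass = gp
  )
  session$trials[[rec$trial_index]] <- rec
  rec
}

#' Final cost as a function of apertures per beam
#'
#' Re-optimizes the plan for an ascending series of aperture counts per
#' beam. Aperture sets are nested by construction — the set with k
#' apertures per beam contains the set with k - 1 (apertures are ordered
#' conformal, OAR-blocked, splits within each beam) — so the weighted
#' least-squares surrogate attainable with k apertures can never exceed
#' that with k - 1. Counts beyond what the anatomy supports are capped
#' with a warning.
#'
#' @param phantom a [build_phantom()] result
#' @param beams list of beams
#' @param objective a [dose_objective()]
#' @param per_beam_counts ascending positive integers
#' @param seed sample-placement seed
#' @param density sampling density, points per cc
#' @param margin aperture margin, mm
#' @param kernel dose kernel parameters
#' @param lambda Tikhonov smoothing (default 0 for the sweep)
#' @param nonneg clamp weights (default FALSE: the monotone-surrogate
#'   guarantee is a property of the unconstrained minimum)
#' @return data frame with one row per count: `apertures_per_beam`,
#'   `total_apertures`, `cost_final` (one-sided penalty cost),
#'   `surrogate` (weighted least-squares value at the solution)
#' @export
aperture_sweep <- function(phantom, beams, objective, per_beam_counts,
                           seed = 1L, density = 1, margin = 5,
                           kernel = dose_kernel(), lambda = 0,
                           nonneg = FALSE) {
  counts <- as.integer(per_beam_counts)
  if (any(counts < 1L) || is.unsorted(counts, strictly = TRUE)) {
    stop("per-beam counts must be ascending positive integers", call. = FALSE)
  }
  kmax <- max(counts)
  avail <- kmax
  apertures <- NULL
  while (is.null(apertures) && avail >= 1L) {
    apertures <- tryCatch(
      design_apertures(phantom, beams,
        margin = margin,
        min_per_beam = avail, max_per_beam = avail
      ),
      error = function(e) NULL
    )
    if (is.null(apertures)) avail <- avail - 1L
  }
  if (is.null(apertures)) stop("no feasible aperture set for these beams", call. = FALSE)
  if (kmax > avail) {
    warning("requested up to ", kmax, " apertures per beam; anatomy supports ",
      avail, " - capping",
      call. = FALSE
    )
  }
  slots <- vapply(apertures, `[[`, integer(1), "slot")
  points <- place_sample_points(phantom, density = density, seed = seed)
  D0 <- compute_dose_matrix(phantom, apertures, points, kernel = kernel)
  # one prescribed-dose vector for the whole sweep (anchored at the full
  # set's uniform-weight reference): the monotone-surrogate guarantee needs
  # every count to minimise the same objective over nested column sets
  reference <- drop(D0$values %*% rep(1, ncol(D0$values)))
  pdv <- prescribed_dose_vector(objective, reference, D0$structure)
  rows <- lapply(counts, function(k) {
    keep <- slots <= k
    V <- D0$values[, keep, drop = FALSE]
    sys <- build_normal_system(V, pdv$targets, pdv$weights, lambda = lambda)
    w <- gaussian_eliminate(sys$A, sys$b)
    if (nonneg && any(w < 0)) {
      free <- w > 0
      if (any(free)) {
        sub <- build_normal_system(V[, free, drop = FALSE], pdv$targets,
          pdv$weights,
          lambda = lambda
        )
        ws <- gaussian_eliminate(sub$A, sub$b)
        w <- numeric(ncol(V))
        w[free] <- pmax(ws, 0)
      } else {
        w <- numeric(ncol(V))
      }
    }
    data.frame(
      apertures_per_beam = min(k, avail), total_apertures = sum(keep),
      cost_final = plan_cost(drop(V %*% w), objective, D0$structure)$total,
      surrogate = wls_surrogate(V, w, pdv$targets, pdv$weights, lambda)
    )
  })
  do.call(rbind, rows)
}

#' Save a replanning session to JSON
#'
#' The session file records the objective, solver options, the per-trial
#' penalty snapshots and final costs, and a reference to (not a copy of)
#' the dose matrix, so a saved loop can be replayed against the same
#' matrix and verified bit-exactly.
#'
#' @param session a [plan_session()]
#' @param path output JSON path
#' @param matrix_ref optional string identifying the dose matrix (e.g. a
#'   CSV path or content hash)
#' @export
save_session <- function(session, path, matrix_ref = NA_character_) {
  doc <- list(
    matrix_ref = matrix_ref,
    objective = objective_to_df(session$objective),
    options = session$options,
    trials = lapply(session$trials, function(tr) {
      list(
        trial_index = tr$trial_index,
        penalties = as.list(tr$penalties),
        cost_final = tr$cost_final
      )
    })
  )
  # I(17) significant digits: costs must survive the JSON round trip
  # bit-exactly so a replay can be verified by identity
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17), null = "null")
  invisible(path)
}

#' Replay a saved session against a dose matrix
#'
#' Re-runs every recorded trial (same penalties, same solver options) and
#' returns the new session together with the saved final costs for
#' comparison.
#'
#' @param path session JSON from [save_session()]
#' @param D0 the dose-influence matrix the session was recorded against
#' @return list with `session` (the replayed [plan_session()]) and
#'   `saved_costs` (numeric, one per recorded trial)
#' @export
replay_session <- function(path, D0) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  objective <- df_to_objective(doc$objective)
  opts <- doc$options
  session <- plan_session(D0, objective,
    lambda = opts$lambda,
    nonneg = isTRUE(opts$nonneg), nnls = isTRUE(opts$nnls),
    mu_per_weight = opts$mu_per_weight %||% 1
  )
  trials <- doc$trials
  saved <- numeric(0)
  for (i in seq_len(nrow_or_len(trials))) {
    tr <- if (is.data.frame(trials)) trials[i, ] else trials[[i]]
    pen <- unlist(tr$penalties)
    run_trial(session, pen)
    saved <- c(saved, as.numeric(tr$cost_final))
  }
  list(session = session, saved_costs = saved)
}

nrow_or_len <- function(x) if (is.data.frame(x)) nrow(x) else length(x)
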