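#' Cumulative dose-volume histogram for one structure
#'
#' `V(t)` is the percentage of the structure's sample points receiving at
#' least dose `t`, evaluated at fixed-width bin edges from 0 Gy.
#'
#' @param doses per-point doses for a single structure, Gy (non-empty)
#' @param bin_width bin width in Gy (default 0.1)
#' @param structure optional structure name carried in the output
#' @return object of class `dvh_curve`: `structure`, `dose` (bin edges,
#'   Gy), `volume` (percent, non-increasing, `volume[1] == 100`)
#' @export
dvh <- function(doses, bin_width = 0.1, structure = NA_character_) {
  if (length(doses) == 0) stop("dvh of an empty structure", call. = FALSE)
  if (bin_width <= 0) stop("bin_width must be positive", call. = FALSE)
  edges <- seq(0, max(doses, 0) + bin_width, by = bin_width)
  # bin edges accumulate float error (e.g. 500 * 0.1); keep "dose == edge"
  # points on the covered side
  eps <- 1e-9 * max(1, max(doses, 0))
  vol <- vapply(edges, function(t) 100 * mean(doses >= t - eps), numeric(1))
  structure(
    list(structure = structure, dose = edges, volume = vol),
    class = "dvh_curve"
  )
}

#' @export
print.dvh_curve <- function(x, ...) {
  cat(
    "DVH", if (!is.na(x$structure)) paste0("[", x$structure, "]"), ":",
    length(x$dose), "bins up to", max(x$dose), "Gy\n"
  )
  invisible(x)
}

#' @export
as.data.frame.dvh_curve <- function(x, ...) {
  data.frame(structure = x$structure, dose = x$dose, volume_percent = x$volume)
}

#' Dose-volume indices
#'
#' @param doses per-point doses, Gy (non-empty)
#' @param kind `"V_at_dose"` (percent of points at or above `threshold`),
#'   `"D_max"` or `"D_mean"`
#' @param threshold dose threshold in Gy, required for `V_at_dose`
#' @return the index value (percent for `V_at_dose`, Gy otherwise)
#' @export
dose_volume_index <- function(doses, kind = c("V_at_dose", "D_max", "D_mean"),
                              threshold = NULL) {
  if (length(doses) == 0) stop("dose-volume index of an empty structure", call. = FALSE)
  kind <- match.arg(kind)
  switch(kind,
    V_at_dose = {
      if (is.null(threshold)) {
        stop("V_at_dose requires a dose threshold", call. = FALSE)
      }
      100 * mean(doses >= threshold)
    },
    D_max = max(doses),
    D_mean = mean(doses)
  )
}

#' Plan-delivery metrics from an optimization result
#'
#' Monitor units are modelled as proportional to aperture weight through a
#' single calibration constant. Apertures whose weight falls below
#' `drop_tol * max(weight)` are treated as dropped from the deliverable
#' plan and excluded from the aperture count.
#'
#' @param result an [optimize_weights()] result, or a bare numeric weight
#'   vector
#' @param mu_per_weight monitor units per unit aperture weight (default 1)
#' @param drop_tol relative weight threshold below which an aperture is
#'   dropped (default 1e-6)
#' @param indices optional data frame of dose-volume indices to attach
#'   (columns structure, kind, threshold, value)
#' @return object of class `plan_metrics`: `total_mu`, `n_apertures`,
#'   `dropped`, `indices`
#' @export
plan_metrics <- function(result, mu_per_weight = 1, drop_tol = 1e-6,
                         indices = NULL) {
  if (mu_per_weight <= 0) stop("mu_per_weight must be positive", call. = FALSE)
  w <- if (inherits(result, "optimization_result")) result$weights else as.numeric(result)
  keep <- if (any(w > 0)) w > drop_tol * max(w) else rep(FALSE, length(w))
  structure(
    list(
      total_mu = mu_per_weight * sum(w),
      n_apertures = sum(keep),
      dropped = sum(!keep),
      indices = indices
    ),
    class = "plan_metrics"
  )
}

#' @export
print.plan_metrics <- function(x, ...) {
  cat(sprintf(
    "Plan: %.1f MU over %d apertures (%d dropped)\n",
    x$total_mu, x$n_apertures, x$dropped
  ))
  if (!is.null(x$indices)) print(x$indices, row.names = FALSE)
  invisible(x)
}

#' Compare a plan against a reference plan
#'
#' Reductions are `100 * (reference - test) / reference`, reported both
#' unrounded and rounded to the nearest integer for display — the arithmetic
#' used when quoting, e.g., MU or segment-count savings of an
#' aperture-based plan over a beamlet-based one.
#'
#' @param test the plan under evaluation ([plan_metrics()])
#' @param reference the reference plan; must have positive MU and at least
#'   one aperture
#' @return list with `mu_reduction` and `aperture_reduction` (each a
#'   `percent_reduction` list) and, when both plans carry matching
#'   `indices`, a per-index `delta` data frame (test - reference)
#' @export
compare_plans <- function(test, reference) {
  if (reference$total_mu <= 0 || reference$n_apertures <= 0) {
    stop("reference plan must have positive MU and apertures", call. = FALSE)
  }
  out <- list(
    mu_reduction = percent_reduction(reference$total_mu, test$total_mu),
    aperture_reduction = percent_reduction(reference$n_apertures, test$n_apertures)
  )
  if (!is.null(test$indices) && !is.null(reference$indices)) {
    key <- function(d) paste(d$structure, d$kind, d$threshold)
    i <- match(key(test$indices), key(reference$indices))
    ok <- !is.na(i)
    out$delta <- data.frame(
      structure = test$indices$structure[ok],
      kind = test$indices$kind[ok],
      threshold = test$indices$threshold[ok],
      test = test$indices$value[ok],
      reference = reference$indices$value[i[ok]],
      delta = test$indices$value[ok] - reference$indices$value[i[ok]]
    )
  }
  out
}

#' Dose-volume goal check
#'
#' A clinical goal of the form "V_dose op volume_percent", e.g. at least
#' 95% of the target at or above 50.4 Gy, or no more than 0% of the cord at
#' or above 45 Gy. Comparisons are inclusive.
#'
#' @param structure structure name
#' @param dose dose threshold, Gy
#' @param op `">="` (coverage goal) or `"<="` (sparing goal)
#' @param volume_percent volume threshold in percent
#' @return object of class `dose_goal`
#' @export
dose_goal <- function(structure, dose, op = c(">=", "<="), volume_percent) {
  op <- match.arg(op)
  structure(
    list(structure = structure, dose = dose, op = op, volume_percent = volume_percent),
    class = "dose_goal"
  )
}

#' Evaluate dose-volume goals on a dose distribution
#'
#' @param doses per-point doses, Gy
#' @param labels per-point structure labels
#' @param goals list of [dose_goal()] objects
#' @return data frame with one row per goal: structure, dose, op,
#'   volume_percent, achieved (the measured V), pass (logical)
#' @export
evaluate_goals <- function(doses, labels, goals) {
  rows <- lapply(goals, function(g) {
    d <- doses[labels == g$structure]
    if (length(d) == 0) {
      stop("no sample points for structure '", g$structure, "'", call. = FALSE)
    }
    v <- dose_volume_index(d, "V_at_dose", threshold = g$dose)
    data.frame(
      structure = g$structure, dose = g$dose, op = g$op,
      volume_percent = g$volume_percent, achieved = v,
      pass = if (g$op == ">=") v >= g$volume_percent else v <= g$volume_percent
    )
  })
  do.call(rbind, rows)
}
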