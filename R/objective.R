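#' Per-structure dose goal
#'
#' One structure's contribution to the quadratic penalty objective. Target
#' structures are penalised on both sides (above `d_max` and below `d_min`)
#' and carry a prescription dose; organs at risk are penalised only above
#' `d_max`.
#'
#' @param structure structure name (must match the sample-point labels)
#' @param role `"target"` or `"oar"`
#' @param d_max maximum dose, Gy
#' @param d_min minimum dose, Gy (targets only; default 0)
#' @param prescription prescription dose, Gy (targets only); must satisfy
#'   `d_min <= prescription <= d_max`
#' @param penalty non-negative penalty multiplier for this structure's
#'   quadratic violation terms
#' @return object of class `structure_goal`
#' @export
structure_goal <- function(structure, role = c("target", "oar"),
                           d_max = Inf, d_min = 0, prescription = NULL,
                           penalty = 1) {
  role <- match.arg(role)
  if (!is.numeric(penalty) || length(penalty) != 1 || penalty < 0) {
    stop("penalty must be a single non-negative number", call. = FALSE)
  }
  if (role == "target") {
    if (is.null(prescription)) {
      stop("target goals require a prescription dose", call. = FALSE)
    }
    if (!(d_min <= prescription && prescription <= d_max)) {
      stop("target goal must satisfy d_min <= prescription <= d_max", call. = FALSE)
    }
  } else {
    prescription <- NA_real_
    d_min <- NA_real_
  }
  structure(
    list(
      structure = structure, role = role, d_min = d_min, d_max = d_max,
      prescription = prescription, penalty = penalty
    ),
    class = "structure_goal"
  )
}

#' Assemble a dose objective from per-structure goals
#'
#' @param ... `structure_goal` objects (or a single list of them), exactly
#'   one per structure
#' @return object of class `dose_objective` with lookup vectors keyed by
#'   structure name
#' @export
dose_objective <- function(...) {
  goals <- list(...)
  if (length(goals) == 1L && !inherits(goals[[1]], "structure_goal")) {
    goals <- goals[[1]]
  }
  stopifnot(all(vapply(goals, inherits, logical(1), "structure_goal")))
  nms <- vapply(goals, `[[`, character(1), "structure")
  if (anyDuplicated(nms)) {
    stop("each structure may have exactly one goal", call. = FALSE)
  }
  names(goals) <- nms
  structure(
    list(
      goals = goals,
      role = stats::setNames(vapply(goals, `[[`, character(1), "role"), nms),
      d_min = stats::setNames(vapply(goals, `[[`, numeric(1), "d_min"), nms),
      d_max = stats::setNames(vapply(goals, `[[`, numeric(1), "d_max"), nms),
      prescription = stats::setNames(vapply(goals, `[[`, numeric(1), "prescription"), nms),
      penalty = stats::setNames(vapply(goals, `[[`, numeric(1), "penalty"), nms)
    ),
    class = "dose_objective"
  )
}

#' @export
print.dose_objective <- function(x, ...) {
  df <- data.frame(
    structure = names(x$goals), role = unname(x$role),
    d_min = unname(x$d_min), d_max = unname(x$d_max),
    prescription = unname(x$prescription), penalty = unname(x$penalty)
  )
  print(df, row.names = FALSE)
  invisible(x)
}

#' Replace penalties in a dose objective
#'
#' @param objective a [dose_objective()]
#' @param update named numeric vector of new penalties (names are structure
#'   names present in the objective)
#' @return the updated objective
#' @export
set_penalties <- function(objective, update) {
  if (length(update) == 0) return(objective)
  if (is.null(names(update)) || any(!nzchar(names(update)))) {
    stop("penalty updates must be named by structure", call. = FALSE)
  }
  unknown <- setdiff(names(update), names(objective$goals))
  if (length(unknown)) {
    stop("no goal for structure(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (any(!is.finite(update)) || any(update < 0)) {
    stop("penalties must be non-negative", call. = FALSE)
  }
  for (nm in names(update)) {
    objective$goals[[nm]]$penalty <- unname(update[[nm]])
    objective$penalty[[nm]] <- unname(update[[nm]])
  }
  objective
}

# map per-point labels to goal indices, erroring on unlabelled structures
match_goals <- function(objective, labels) {
  i <- match(labels, names(objective$goals))
  if (anyNA(i)) {
    stop("no goal configured for structure(s): ",
      paste(unique(labels[is.na(i)]), collapse = ", "),
      call. = FALSE
    )
  }
  i
}

#' Evaluate the one-sided quadratic penalty cost
#'
#' Target points contribute `p * (D - d_max)^2` when overdosed and
#' `p * (D - d_min)^2` when underdosed; OAR points contribute
#' `p * (D - d_max)^2` only when overdosed. The total is the sum over all
#' sample points. This is the cost used for reporting and plan comparison;
#' the exact solve minimises the symmetric surrogate of
#' [prescribed_dose_vector()].
#'
#' @param doses numeric vector of per-point doses, Gy
#' @param objective a [dose_objective()]
#' @param labels per-point structure labels
#' @return object of class `cost_report`: `total`, `per_structure` (named),
#'   `violated_points`
#' @export
plan_cost <- function(doses, objective, labels) {
  if (any(!is.finite(doses))) stop("doses must be finite", call. = FALSE)
  i <- match_goals(objective, labels)
  role <- objective$role[i]
  p <- objective$penalty[i]
  dmax <- objective$d_max[i]
  dmin <- objective$d_min[i]
  over <- pmax(doses - dmax, 0)
  under <- ifelse(role == "target", pmax(dmin - doses, 0), 0)
  contrib <- p * (over^2 + under^2)
  per <- tapply(contrib, factor(labels, levels = names(objective$goals)), sum,
    default = 0
  )
  structure(
    list(
      total = sum(contrib),
      per_structure = stats::setNames(as.numeric(per), names(per)),
      violated_points = sum(contrib > 0)
    ),
    class = "cost_report"
  )
}

#' @export
print.cost_report <- function(x, ...) {
  cat("Cost:", format(x$total), "(", x$violated_points, "violated points )\n")
  for (nm in names(x$per_structure)) {
    cat(sprintf("  %-12s %g\n", nm, x$per_structure[[nm]]))
  }
  invisible(x)
}

#' Per-point prescribed doses and weights for the linear solve
#'
#' Translates the per-structure goals into the per-point prescribed-dose
#' vector and weight (penalty) vector the weighted least-squares system is
#' built from. Target points are anchored at the prescription dose. OAR
#' points take `min(reference dose, d_max)`: a point already compliant at
#' the uniform-weight reference plan is anchored at its current dose, so
#' the symmetric least-squares pull cannot push it up toward the limit,
#' while a violating point is pulled down to the limit.
#'
#' @param objective a [dose_objective()]
#' @param reference_doses per-point doses at the uniform-weight starting
#'   plan, Gy
#' @param labels per-point structure labels
#' @return list with `targets` (per-point Gy) and `weights` (per-point
#'   penalties, zeros allowed)
#' @export
prescribed_dose_vector <- function(objective, reference_doses, labels) {
  i <- match_goals(objective, labels)
  role <- objective$role[i]
  tgt <- ifelse(role == "target",
    objective$prescription[i],
    pmin(reference_doses, objective$d_max[i])
  )
  list(targets = unname(tgt), weights = unname(objective$penalty[i]))
}

#' Percent reduction between an initial and final cost
#'
#' @param initial initial cost (must be positive)
#' @param final final cost
#' @return list with `percent` (nearest integer, for display) and `value`
#'   (unrounded)
#' @export
percent_reduction <- function(initial, final) {
  if (!is.numeric(initial) || initial <= 0) {
    stop("initial value must be positive", call. = FALSE)
  }
  v <- 100 * (initial - final) / initial
  list(percent = round(v), value = v)
}
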