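#' Assemble the weighted normal-equations system
#'
#' The per-point dose system `D0 %*% w = d` has many more equations (sample
#' points) than unknowns (aperture weights), so the exact elimination solve
#' is applied to its weighted normal form:
#' `A = t(D0) P D0 + lambda I`, `b = t(D0) P d`, where `P` is the diagonal
#' matrix of per-point penalties and `lambda >= 0` a Tikhonov smoothing
#' term on the weights.
#'
#' @param D0 a [dose_influence_matrix()] or plain numeric matrix (m x n)
#' @param targets per-point prescribed doses, Gy (length m)
#' @param penalties per-point non-negative weights (length m)
#' @param lambda Tikhonov smoothing scalar, >= 0
#' @return object of class `linear_system`: `A` (n x n symmetric), `b`
#'   (length n), `n`, `conditioning` (2-norm condition estimate of `A`)
#' @export
build_normal_system <- function(D0, targets, penalties, lambda = 0) {
  V <- if (inherits(D0, "dose_influence_matrix")) D0$values else as.matrix(D0)
  m <- nrow(V)
  n <- ncol(V)
  stopifnot(length(targets) == m, length(penalties) == m)
  if (any(penalties < 0)) stop("penalties must be non-negative", call. = FALSE)
  if (!any(penalties > 0)) {
    stop("degenerate system: all per-point penalties are zero", call. = FALSE)
  }
  if (lambda < 0) stop("lambda must be non-negative", call. = FALSE)
  WD <- V * penalties # row-scaled: diag(p) %*% D0
  A <- crossprod(V, WD)
  A <- (A + t(A)) / 2 # enforce exact symmetry
  if (lambda > 0) A <- A + diag(lambda, n)
  b <- drop(crossprod(WD, targets))
  structure(
    list(A = A, b = b, n = n, conditioning = kappa(A, exact = FALSE)),
    class = "linear_system"
  )
}

#' Solve a linear system by Gaussian elimination with back-substitution
#'
#' A direct, non-iterative dense solver: forward elimination with partial
#' (maximum-magnitude column) pivoting, ties broken by the lowest row
#' index, followed by back-substitution. This is the package's own
#' implementation of the elimination pass at the heart of the optimizer.
#'
#' @param A square numeric matrix
#' @param b right-hand-side vector (or single-column matrix)
#' @param tol relative singularity threshold: elimination stops with an
#'   error when a pivot magnitude falls below `tol * max(abs(A))`
#' @return the solution vector `x` with `A %*% x = b`
#' @export
gaussian_eliminate <- function(A, b, tol = 1e-12) {
  A <- as.matrix(A)
  b <- as.numeric(b)
  n <- nrow(A)
  if (ncol(A) != n) stop("A must be square", call. = FALSE)
  if (length(b) != n) stop("length(b) must match nrow(A)", call. = FALSE)
  scale <- max(abs(A))
  if (scale == 0) stop("singular system: A is the zero matrix", call. = FALSE)
  M <- cbind(A, b, deparse.level = 0)
  for (k in seq_len(n)) {
    piv <- which.max(abs(M[k:n, k])) + k - 1L # which.max takes the first tie
    if (abs(M[piv, k]) < tol * scale) {
      stop("singular system: pivot below tolerance at elimination step ", k,
        call. = FALSE
      )
    }
    if (piv != k) M[c(k, piv), ] <- M[c(piv, k), ]
    if (k < n) {
      rows <- (k + 1L):n
      f <- M[rows, k] / M[k, k]
      M[rows, k:(n + 1L)] <- M[rows, k:(n + 1L), drop = FALSE] -
        tcrossprod(f, M[k, k:(n + 1L)])
      M[rows, k] <- 0
    }
  }
  x <- numeric(n)
  for (i in n:1) {
    s <- if (i < n) sum(M[i, (i + 1L):n] * x[(i + 1L):n]) else 0
    x[i] <- (M[i, n + 1L] - s) / M[i, i]
  }
  x
}

#' Optimize aperture weights in one exact pass
#'
#' The end-to-end solve: reference doses are computed at uniform weights
#' (all ones), the per-point prescribed-dose and weight vectors are built
#' from the objective, the weighted normal system is assembled and solved
#' by [gaussian_eliminate()], and doses are reconstructed by
#' [reconstruct_doses()]. The solve itself involves no iteration. Physical
#' non-negativity of the weights is enforced by clamping negative weights
#' to zero and re-solving over the remaining apertures; by default
#' (`nnls = TRUE`) the clamp-and-refit is repeated until all weights are
#' non-negative (at most n exact passes, an active-set non-negative
#' least-squares scheme). `nnls = FALSE` stops after a single
#' clamp-and-refit pass — cheaper, but when several correcting apertures
#' clamp at once the refit can land far from the constrained optimum on
#' strongly concave geometries.
#'
#' @param D0 a [dose_influence_matrix()] (or plain matrix plus `labels`)
#' @param objective a [dose_objective()] covering every structure label
#' @param labels per-point structure labels; defaults to the labels stored
#'   in `D0`
#' @param lambda Tikhonov smoothing scalar; default
#'   `1e-6 * trace(t(D)PD) / n`, a small ridge relative to the system scale
#' @param nonneg enforce non-negative weights by clamp-and-refit
#' @param nnls repeat the clamp-and-refit until all weights are
#'   non-negative (default); `FALSE` performs a single pass
#' @return object of class `optimization_result`: `weights`, `doses`,
#'   `reference_doses`, `cost_initial`, `cost_final` (both one-sided
#'   penalty costs, at uniform and optimized weights), `smoothing_lambda`,
#'   `active_apertures`, `conditioning`, `elapsed` (seconds)
#' @export
optimize_weights <- function(D0, objective, labels = NULL, lambda = NULL,
                             nonneg = TRUE, nnls = TRUE) {
  t0 <- proc.time()[["elapsed"]]
  V <- if (inherits(D0, "dose_influence_matrix")) D0$values else as.matrix(D0)
  if (is.null(labels)) {
    if (!inherits(D0, "dose_influence_matrix")) {
      stop("`labels` is required when D0 is a plain matrix", call. = FALSE)
    }
    labels <- D0$structure
  }
  n <- ncol(V)
  reference <- drop(V %*% rep(1, n))
  pdv <- prescribed_dose_vector(objective, reference, labels)
  if (!any(pdv$weights > 0)) {
    stop("infeasible objective: no sample point has a positive penalty",
      call. = FALSE
    )
  }
  sys0 <- build_normal_system(V, pdv$targets, pdv$weights, lambda = 0)
  if (is.null(lambda)) lambda <- 1e-6 * sum(diag(sys0$A)) / n
  A <- sys0$A + if (lambda > 0) diag(lambda, n) else 0
  w <- gaussian_eliminate(A, sys0$b)

  if (nonneg && any(w < 0)) {
    free <- w > 0
    repeat {
      if (!any(free)) {
        w <- numeric(n)
        break
      }
      sub <- build_normal_system(
        V[, free, drop = FALSE], pdv$targets, pdv$weights,
        lambda = lambda
      )
      ws <- gaussian_eliminate(sub$A, sub$b)
      w <- numeric(n)
      w[free] <- ws
      if (!nnls || all(ws >= 0)) {
        w[w < 0] <- 0 # single clamp pass keeps the solve non-iterative
        break
      }
      free[free] <- ws > 0
    }
  }

  doses <- unname(drop(V %*% w))
  cost_i <- plan_cost(reference, objective, labels)
  cost_f <- plan_cost(doses, objective, labels)
  structure(
    list(
      weights = stats::setNames(w, colnames(V)),
      doses = doses, reference_doses = reference,
      labels = labels,
      cost_initial = cost_i$total, cost_final = cost_f$total,
      cost_initial_report = cost_i, cost_final_report = cost_f,
      surrogate = wls_surrogate(V, w, pdv$targets, pdv$weights, lambda),
      smoothing_lambda = lambda,
      active_apertures = sum(w > 0),
      conditioning = sys0$conditioning,
      nonneg = nonneg, nnls = nnls,
      elapsed = proc.time()[["elapsed"]] - t0
    ),
    class = "optimization_result"
  )
}

# weighted least-squares surrogate value (with ridge term)
wls_surrogate <- function(V, w, targets, penalties, lambda) {
  r <- drop(V %*% w) - targets
  sum(penalties * r^2) + lambda * sum(w^2)
}

#' @export
print.optimization_result <- function(x, ...) {
  pr <- percent_reduction(x$cost_initial, x$cost_final)
  cat(sprintf(
    paste0(
      "Aperture-weight optimization: %d apertures (%d active)\n",
      "  cost %g -> %g  (%d%% reduction)\n",
      "  lambda = %g, solve time %.3f s\n"
    ),
    length(x$weights), x$active_apertures,
    x$cost_initial, x$cost_final, pr$percent,
    x$smoothing_lambda, x$elapsed
  ))
  invisible(x)
}

#' Reconstruct per-point doses from aperture weights
#'
#' Doses after optimization are obtained directly from the pre-computed
#' reference dose matrix — the forward operation of the linear dose model —
#' with no further dose-engine call.
#'
#' @param D0 a [dose_influence_matrix()] or plain matrix
#' @param weights aperture weight vector (length = number of apertures)
#' @return per-point doses in Gy
#' @export
reconstruct_doses <- function(D0, weights) {
  V <- if (inherits(D0, "dose_influence_matrix")) D0$values else as.matrix(D0)
  if (length(weights) != ncol(V)) {
    stop("length(weights) must equal the number of apertures", call. = FALSE)
  }
  unname(drop(V %*% as.numeric(weights)))
}
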