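# Shared fixtures, built once per test run. Coarse (4 mm) presets keep the
# geometry pipeline fast; solver tests use small random systems.

coarse_plan <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- preset_plan("case_a", spacing = 4)
    cache
  }
})

coarse_plan_b <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- preset_plan("case_b", spacing = 4)
    cache
  }
})

# full-resolution (2 mm) presets, built lazily and cached for the run
full_plan <- local({
  cache <- list()
  function(name) {
    if (is.null(cache[[name]])) cache[[name]] <<- preset_plan(name, spacing = 2)
    cache[[name]]
  }
})

# slab phantom: rectangular body with a centred box target; depth along a
# gantry-0 beam (from +y) is known in closed form
slab_spec <- function() {
  list(
    grid = c(60L, 80L, 30L), spacing = c(2, 2, 2),
    structures = list(
      body = list(
        role = "body",
        shape = list(type = "box", lower = c(-55, -70, -28), upper = c(55, 70, 28))
      ),
      ptv = list(
        role = "target",
        shape = list(type = "box", lower = c(-10, -10, -10), upper = c(10, 10, 10))
      )
    )
  )
}

# well-conditioned random square system (diagonally dominated)
random_system <- function(n, seed) {
  set.seed(seed)
  A <- matrix(runif(n * n, -1, 1), n, n) + diag(n, n)
  b <- runif(n, -5, 5)
  list(A = A, b = b)
}

# independent Cramer's-rule oracle for small systems
cramer_solve <- function(A, b) {
  dA <- det(A)
  vapply(seq_len(ncol(A)), function(i) {
    Ai <- A
    Ai[, i] <- b
    det(Ai) / dA
  }, numeric(1))
}

# random consistent aperture-weight recovery instance: d = D0 %*% w_true
# with non-negative weights and a full-column-rank non-negative matrix
recovery_instance <- function(m, n, seed) {
  set.seed(seed)
  D0 <- matrix(runif(m * n, 0, 2), m, n)
  w_true <- runif(n, 0.2, 3)
  list(D0 = D0, w_true = w_true, d = drop(D0 %*% w_true))
}

# per-point objective whose prescribed-dose vector equals `d` exactly:
# every point is its own target structure anchored at d_m
pointwise_objective <- function(d) {
  labs <- sprintf("v%05d", seq_along(d))
  goals <- lapply(seq_along(d), function(i) {
    structure_goal(labs[i], "target",
      prescription = d[i], d_min = 0, d_max = Inf, penalty = 1
    )
  })
  list(objective = dose_objective(goals), labels = labs)
}
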