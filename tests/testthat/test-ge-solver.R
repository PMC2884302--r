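test_that("the normal system propagates identity and hand-computed cases", {
  # D0 = I -> A = I, b = targets
  n <- 4
  sys <- build_normal_system(diag(n), targets = 1:4, penalties = rep(1, n))
  expect_equal(sys$A, diag(n))
  expect_equal(sys$b, as.numeric(1:4))
  # D0 = (1,1)^T, targets (1,3) -> A = [2], b = [4]
  sys2 <- build_normal_system(matrix(1, 2, 1), c(1, 3), c(1, 1))
  expect_equal(as.numeric(sys2$A), 2)
  expect_equal(sys2$b, 4)
  # doubling penalties doubles A (net of the ridge) and b
  D <- matrix(runif(12), 4, 3)
  t1 <- runif(4)
  s1 <- build_normal_system(D, t1, rep(1, 4), lambda = 0.5)
  s2 <- build_normal_system(D, t1, rep(2, 4), lambda = 0.5)
  expect_equal(s2$A - diag(0.5, 3), 2 * (s1$A - diag(0.5, 3)))
  expect_equal(s2$b, 2 * s1$b)
  expect_error(build_normal_system(D, t1, rep(0, 4)), "degenerate")
})

test_that("elimination solves identity and diagonal systems exactly", {
  expect_equal(gaussian_eliminate(diag(2), c(3, 5)), c(3, 5))
  expect_equal(gaussian_eliminate(diag(c(2, 4)), c(2, 8)), c(1, 2))
  expect_equal(gaussian_eliminate(matrix(7), 21), 3)
})

test_that("elimination matches a Cramer's-rule oracle on 200 seeded systems", {
  worst <- 0
  for (seed in 1:200) {
    n <- 2 + (seed %% 7) # sizes 2..8
    s <- random_system(n, seed)
    x <- gaussian_eliminate(s$A, s$b)
    ref <- cramer_solve(s$A, s$b)
    worst <- max(worst, max(abs(x - ref)) / max(abs(ref)))
  }
  expect_lt(worst, 1e-8)
})

test_that("residuals stay below 1e-8 relative for systems up to n = 50", {
  for (n in c(20, 35, 50)) {
    s <- random_system(n, 1000 + n)
    x <- gaussian_eliminate(s$A, s$b)
    expect_lt(
      max(abs(s$A %*% x - s$b)), 1e-8 * (1 + max(abs(s$b))),
      label = paste0("residual at n = ", n)
    )
  }
})

test_that("pivoting handles zero leading pivots and flags singular systems", {
  A <- matrix(c(0, 1, 1, 0), 2, 2) # needs the row swap
  expect_equal(gaussian_eliminate(A, c(2, 3)), c(3, 2))
  expect_error(
    gaussian_eliminate(matrix(c(1, 2, 2, 4), 2, 2), c(1, 1)),
    "singular.*step 2"
  )
  expect_error(gaussian_eliminate(matrix(0, 2, 2), c(1, 1)), "singular")
  expect_error(gaussian_eliminate(matrix(1, 2, 3), 1:2), "square")
})

test_that("consistent systems recover the generating weights", {
  inst <- recovery_instance(m = 60, n = 8, seed = 7)
  po <- pointwise_objective(inst$d)
  res <- optimize_weights(
    dose_influence_matrix(inst$D0, po$labels),
    po$objective,
    lambda = 0, nonneg = FALSE
  )
  expect_lt(
    max(abs(res$weights - inst$w_true)) / max(inst$w_true), 1e-6
  )
  expect_equal(res$cost_final, 0, tolerance = 1e-8)
})

test_that("the solution satisfies weighted least-squares stationarity", {
  plan <- coarse_plan()
  V <- plan$D0$values
  ref <- drop(V %*% rep(1, ncol(V)))
  pdv <- prescribed_dose_vector(plan$objective, ref, plan$D0$structure)
  res <- optimize_weights(plan$D0, plan$objective, nonneg = FALSE)
  grad <- drop(crossprod(V, pdv$weights * (drop(V %*% res$weights) - pdv$targets))) +
    res$smoothing_lambda * res$weights
  scale <- max(abs(crossprod(V, pdv$weights * pdv$targets)))
  expect_lt(max(abs(grad)), 1e-6 * scale)
})

test_that("smoothing shrinks weights monotonically and lambda = 0 is unsmoothed", {
  plan <- coarse_plan()
  norms <- vapply(
    c(0, 1, 10, 100, 1000),
    function(l) {
      sqrt(sum(optimize_weights(plan$D0, plan$objective,
        lambda = l,
        nonneg = FALSE
      )$weights^2))
    },
    numeric(1)
  )
  expect_true(all(diff(norms) < 0))
  inst <- recovery_instance(m = 40, n = 6, seed = 9)
  po <- pointwise_objective(inst$d)
  Dm <- dose_influence_matrix(inst$D0, po$labels)
  w0 <- optimize_weights(Dm, po$objective, lambda = 0, nonneg = FALSE)$weights
  expect_equal(unname(w0), inst$w_true, tolerance = 1e-8)
})

test_that("non-negativity clamping yields non-negative weights and keeps descent", {
  plan <- coarse_plan()
  res <- optimize_weights(plan$D0, plan$objective) # default: iterated clamp
  expect_true(all(res$weights >= 0))
  expect_lt(res$cost_final, res$cost_initial)
  expect_equal(res$active_apertures, sum(res$weights > 0))
  single <- optimize_weights(plan$D0, plan$objective, nnls = FALSE)
  expect_true(all(single$weights >= 0))
})

test_that("repeated solves are bit-identical", {
  plan <- coarse_plan()
  r1 <- optimize_weights(plan$D0, plan$objective)
  r2 <- optimize_weights(plan$D0, plan$objective)
  expect_identical(r1$weights, r2$weights)
  expect_identical(r1$cost_final, r2$cost_final)
})

test_that("dose reconstruction equals explicit per-point summation", {
  set.seed(31)
  V <- matrix(runif(20 * 6), 20, 6)
  D <- dose_influence_matrix(V, rep("s", 20))
  expect_equal(reconstruct_doses(D, rep(0, 6)), rep(0, 20))
  expect_equal(reconstruct_doses(D, rep(1, 6)), rowSums(V))
  w <- runif(6)
  naive <- vapply(
    seq_len(nrow(V)),
    function(m) sum(V[m, ] * w), numeric(1)
  )
  expect_equal(reconstruct_doses(D, w), naive, tolerance = 1e-12)
  expect_error(reconstruct_doses(D, 1:3), "number of apertures")
})
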