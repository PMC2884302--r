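simple_objective <- function() {
  dose_objective(
    structure_goal("ptv", "target",
      prescription = 50, d_min = 48, d_max = 52, penalty = 2
    ),
    structure_goal("oar1", "oar", d_max = 45, penalty = 1),
    structure_goal("oar2", "oar", d_max = 30, penalty = 1)
  )
}

test_that("one-sided penalties follow the target/OAR rules", {
  obj <- dose_objective(
    structure_goal("ptv", "target", prescription = 50, d_min = 48, d_max = 52),
    structure_goal("oar1", "oar", d_max = 45, penalty = 1)
  )
  # one OAR point overdosed by 5 Gy at unit penalty
  expect_equal(plan_cost(50, obj, "oar1")$total, 25)
  # within-bounds doses cost nothing
  rep <- plan_cost(c(48, 52, 50, 45, 0), obj, c(rep("ptv", 3), "oar1", "oar1"))
  expect_equal(rep$total, 0)
  expect_equal(rep$violated_points, 0L)
  # OAR points are never penalised for underdose
  expect_equal(plan_cost(0, obj, "oar1")$total, 0)
  # target points are penalised on both sides
  expect_equal(plan_cost(c(53, 47), obj, c("ptv", "ptv"))$total, 1 + 1)
})

test_that("a hand-summed three-point case evaluates exactly", {
  # penalties (2, 1, 1); violations (+3, -2, 0) Gy -> 2*9 + 1*4 + 0 = 22
  obj <- simple_objective()
  doses <- c(52 + 3, 48 - 2, 50)
  rep <- plan_cost(doses, obj, c("ptv", "ptv", "ptv"))
  expect_equal(rep$total, 2 * 9 + 2 * 4) # structure penalty 2 on both rows
  obj2 <- dose_objective(
    structure_goal("a", "target", prescription = 50, d_min = 48, d_max = 52, penalty = 2),
    structure_goal("b", "target", prescription = 50, d_min = 48, d_max = 52, penalty = 1),
    structure_goal("c", "oar", d_max = 45, penalty = 1)
  )
  expect_equal(plan_cost(c(55, 46, 40), obj2, c("a", "b", "c"))$total, 22)
})

test_that("cost splits by structure and flags violated points", {
  obj <- simple_objective()
  rep <- plan_cost(c(55, 46, 35), obj, c("ptv", "oar1", "oar2"))
  expect_equal(rep$total, sum(rep$per_structure))
  expect_equal(unname(rep$per_structure[["ptv"]]), 2 * 9)
  expect_equal(unname(rep$per_structure[["oar1"]]), 1)
  expect_equal(unname(rep$per_structure[["oar2"]]), 25)
  expect_equal(rep$violated_points, 3L)
  expect_error(plan_cost(10, obj, "unknown"), "no goal")
})

test_that("cost is convex in dose and scales linearly with penalties", {
  obj <- simple_objective()
  set.seed(17)
  labels <- sample(c("ptv", "oar1", "oar2"), 40, replace = TRUE)
  for (i in 1:20) {
    d1 <- runif(40, 0, 80)
    d2 <- runif(40, 0, 80)
    a <- runif(1)
    mix <- plan_cost(a * d1 + (1 - a) * d2, obj, labels)$total
    expect_lte(
      mix,
      a * plan_cost(d1, obj, labels)$total +
        (1 - a) * plan_cost(d2, obj, labels)$total + 1e-9
    )
  }
  d <- runif(40, 0, 80)
  base <- plan_cost(d, obj, labels)$total
  scaled <- set_penalties(obj, c(ptv = 2 * 2, oar1 = 2, oar2 = 2))
  expect_equal(plan_cost(d, scaled, labels)$total, 2 * base)
})

test_that("prescribed doses anchor targets at prescription and compliant OARs at their current dose", {
  obj <- simple_objective()
  ref <- c(49.0, 30, 60, 10)
  labels <- c("ptv", "oar1", "oar1", "oar2")
  pdv <- prescribed_dose_vector(obj, ref, labels)
  expect_equal(pdv$targets, c(50, 30, 45, 10))
  expect_equal(pdv$weights, c(2, 1, 1, 1))
})

test_that("goal validation catches inconsistent dose limits", {
  expect_error(
    structure_goal("t", "target", prescription = 60, d_min = 48, d_max = 52),
    "d_min <= prescription <= d_max"
  )
  expect_error(structure_goal("t", "target"), "prescription")
  expect_error(structure_goal("o", "oar", penalty = -1), "non-negative")
  expect_error(
    dose_objective(
      structure_goal("o", "oar", d_max = 10),
      structure_goal("o", "oar", d_max = 20)
    ),
    "exactly one goal"
  )
})

test_that("percent reduction rounds for display and keeps the exact value", {
  pr <- percent_reduction(1225, 270)
  expect_equal(pr$percent, 78)
  expect_equal(pr$value, 100 * 955 / 1225)
  expect_equal(percent_reduction(1678, 330)$percent, 80)
  expect_equal(percent_reduction(5, 5)$percent, 0)
  expect_error(percent_reduction(0, 1), "positive")
  expect_error(percent_reduction(-3, 1), "positive")
})
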