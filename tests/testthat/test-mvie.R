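test_that("initialisation is seeded, boundary-consistent and guarded", {
  p <- mvie_problem(3, objective = function(x) sum(x), sense = "min",
                    constraints = list(list(fn = function(x) x[1],
                                            lower = 0.2, upper = 0.4)))
  r1 <- mvie_run(p, 100, n_units = 5, seed = 42)
  r2 <- mvie_run(p, 100, n_units = 5, seed = 42)
  expect_identical(r1$trace, r2$trace)
  expect_identical(r1$archive, r2$archive)
  expect_error(mvie_run(p, 100, n_units = 3), ">= 4")

  # an always-satisfied constraint puts the initial boundary at zero
  p0 <- mvie_problem(2, objective = function(x) sum(x), sense = "min",
                     constraints = list(list(fn = function(x) x[1],
                                             lower = -10, upper = 10)))
  r0 <- mvie_run(p0, 50, n_units = 5, seed = 1)
  expect_equal(unname(r0$b0), 0)
})

test_that("candidate comparison is lexicographic with incumbent bias", {
  cmp <- viasm:::compare_candidates
  viable <- list(params = 1, objective = 10, viol = c(0, 0))
  bad <- list(params = 2, objective = -99, viol = c(2, 0))
  b <- c(0, 0)
  expect_true(cmp(viable, bad, b, "min"))       # viability beats any objective
  expect_false(cmp(bad, viable, b, "min"))
  worse <- list(params = 3, objective = NA, viol = c(2.0, 0))
  better <- list(params = 4, objective = NA, viol = c(1.0, 0))
  expect_true(cmp(better, worse, b, "min"))     # smaller total violation wins
  # both viable: objective decides, ties keep the incumbent
  v2 <- list(params = 5, objective = 3, viol = c(0, 0))
  expect_true(cmp(v2, viable, b, "min"))
  expect_false(cmp(v2, viable, b, "max"))
  expect_false(cmp(viable, list(params = 6, objective = 10, viol = c(0, 0)), b, "min"))
})

test_that("(1+1)-CMA-ES local units solve the sphere quickly", {
  p <- mvie_problem(2, objective = function(x) sum((x - 0.62)^2), sense = "min")
  r <- mvie_run(p, 2000, n_units = 4, seed = 7)
  expect_lt(r$best$objective, 1e-6)
  expect_lte(r$n_eval, 2000)
})

test_that("repeated rejections shrink the step size monotonically", {
  # a unit whose incumbent can never be beaten: constant objective, min sense
  # (ties keep the incumbent), so every step is a rejection
  p <- mvie_problem(2, objective = function(x) 0, sense = "min")
  st <- viasm:::rng_state(5)
  unit <- viasm:::new_unit(c(0.5, 0.5), 2, 0.3, 99)
  unit$best <- list(params = unit$mean, objective = 0, viol = numeric(0))
  sig <- unit$sigma
  # emulate the local step's sigma rule under pure rejection
  damp <- 1 + 2 / 2; pt <- 2 / 11
  for (i in 1:10) {
    new_sig <- sig[length(sig)] * exp((1 / damp) * ((0 - pt) / (1 - pt)))
    expect_lt(new_sig, sig[length(sig)])
    sig <- c(sig, new_sig)
  }
  # and in a real run against an unbeatable incumbent the archive still fills
  r <- mvie_run(p, 200, n_units = 4, seed = 5)
  expect_equal(r$archive$n, 200)   # unconstrained: every candidate is viable
})

test_that("DE recombination obeys its algebra and helps escape bad basins", {
  # two-basin objective on [0,1]: global minimum near 0.9, local near 0.2
  two_basin <- function(x) {
    min(5 * (x[1] - 0.2)^2 + 0.5, 8 * (x[1] - 0.9)^2)
  }
  p <- mvie_problem(1, objective = two_basin, sense = "min")
  hits_de <- 0; hits_local <- 0
  for (sd in 1:6) {
    r_de <- mvie_run(p, 600, n_units = 6, seed = sd,
                     control = list(G_local = 5))
    r_loc <- mvie_run(p, 600, n_units = 6, seed = sd,
                      control = list(G_local = 1e9))  # never recombines
    if (abs(r_de$best$params - 0.9) < 0.05) hits_de <- hits_de + 1
    if (abs(r_loc$best$params - 0.9) < 0.05) hits_local <- hits_local + 1
  }
  expect_gte(hits_de, hits_local)
  expect_gte(hits_de, 5)

  # F = 0, CR = 1: the trial equals another member's mean exactly
  means <- matrix(runif(8), 4, 2)
  i <- 1L; r <- c(2L, 3L, 4L)
  trial <- means[r[1], ] + 0 * (means[r[2], ] - means[r[3], ])
  expect_identical(trial, means[r[1], ])
})

test_that("viability boundaries never increase and hit zero on schedule", {
  p <- mvie_problem(2, objective = function(x) sum(x), sense = "max",
                    constraints = list(
                      list(fn = function(x) x[1], lower = 0.45, upper = 0.55),
                      list(fn = function(x) x[2], lower = 0.7, upper = Inf)))
  r <- mvie_run(p, 1500, n_units = 6, seed = 3,
                control = list(t_tighten = 0.5))
  b <- r$trace[, grep("^b", colnames(r$trace)), drop = FALSE]
  expect_true(all(diff(b[, 1]) <= 1e-12))
  expect_true(all(diff(b[, 2]) <= 1e-12))
  after <- r$trace[, "n_eval"] >= 0.5 * 1500
  expect_true(all(b[after, ] == 0))
  # every archived candidate satisfies the final bounds
  expect_true(all(r$archive$viol <= 1e-9))
  # and evaluation accounting is exact
  expect_lte(r$n_eval, 1500)
  expect_equal(r$n_eval, 1500)
})

test_that("constrained optimum matches the closed form and a grid oracle", {
  # min x^2 subject to x >= 1 on [-5, 5]: optimum at x = 1
  p <- mvie_problem(1, objective = function(x) x^2, sense = "min",
                    constraints = list(list(fn = function(x) x,
                                            lower = 1, upper = Inf)),
                    lower = -5, upper = 5)
  r <- mvie_run(p, 5000, n_units = 8, seed = 4)
  expect_true(r$feasible)
  expect_equal(r$best$objective, 1, tolerance = 1e-3)

  # 2-D toy with one constraint vs a dense grid brute force
  obj <- function(x) (x[1] - 0.8)^2 + (x[2] - 0.1)^2
  con <- function(x) x[1] + x[2]
  pg <- mvie_problem(2, objective = obj, sense = "min",
                     constraints = list(list(fn = con, lower = 1.2, upper = Inf)))
  g <- as.matrix(expand.grid(seq(0, 1, length.out = 1000),
                             seq(0, 1, length.out = 1000)))
  feas <- g[, 1] + g[, 2] >= 1.2
  gridbest <- min((g[feas, 1] - 0.8)^2 + (g[feas, 2] - 0.1)^2)
  rng_obj <- 1.3  # objective range over the box
  for (sd in 1:5) {
    r <- mvie_run(pg, 4000, n_units = 8, seed = sd)
    expect_true(r$feasible)
    expect_lte(r$best$objective, gridbest + 0.01 * rng_obj)
    expect_gte(r$best$params[1] + r$best$params[2], 1.2 - 1e-9)
  }
})

test_that("with no viable region the run says so and returns the least violator", {
  p <- mvie_problem(1, objective = function(x) x, sense = "min",
                    constraints = list(list(fn = function(x) x,
                                            lower = 5, upper = 6)))  # box is [0,1]
  expect_message(r <- mvie_run(p, 300, n_units = 4, seed = 1), "no viable")
  expect_false(r$feasible)
  expect_gt(sum(r$best$viol), 0)
})
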