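test_that("9-6 Lennard-Jones has its closed-form zero, minimum and cutoff", {
  p <- lj_params()
  expect_equal(lj_96(4.7, p), 0)
  rmin <- 4.7 * (3 / 2)^(1 / 3)
  expect_equal(lj_96(rmin, p), -16 / 27, tolerance = 1e-12)
  # numeric scan confirms rmin is the argmin
  r <- seq(4, 12, by = 1e-4)
  expect_equal(r[which.min(lj_96(r, p))], rmin, tolerance = 1e-3)
  expect_equal(lj_96(12, p), 0)      # truncation, not the tail value
  expect_equal(lj_96(13, p), 0)
  expect_error(lj_96(0, p), "r > 0")
  # scaling with epsilon
  expect_equal(lj_96(rmin, lj_params(epsilon = 3)), 3 * -16 / 27)
})

test_that("assembly steric energy sums inter-subunit pairs only", {
  one_ca <- function(xyz, chain) data.frame(
    elety = "CA", resno = 1L, chain = chain, resid = "ALA",
    x = xyz[1], y = xyz[2], z = xyz[3])
  two <- function(d) viasm_structure(rbind(one_ca(c(0, 0, 0), "A"),
                                           one_ca(c(d, 0, 0), "B")))
  expect_equal(e_phys(two(20)), 0)                    # beyond cutoff
  expect_equal(e_phys(two(4.7)), 0)                   # at sigma
  rmin <- 4.7 * (3 / 2)^(1 / 3)
  expect_equal(e_phys(two(rmin)), -16 / 27, tolerance = 1e-12)
  expect_warning(e0 <- e_phys(build_symmetric(toy_helix(), assembly_params(), 1)),
                 "single-subunit")
  expect_equal(e0, 0)
  # three copies at mutual distance rmin: three inter-copy pairs
  tri <- viasm_structure(rbind(one_ca(c(0, 0, 0), "A"),
                               one_ca(c(rmin, 0, 0), "B"),
                               one_ca(c(rmin / 2, rmin * sqrt(3) / 2, 0), "C")))
  expect_equal(e_phys(tri), 3 * -16 / 27, tolerance = 1e-12)
})

test_that("restraint distances, violations and E_data follow their definitions", {
  ref <- ref_c5()
  cons <- derive_constraints(ref$assembly, 3, seed = 3)
  cd <- constraint_distances(ref$assembly, cons)
  expect_equal(cd$violation, rep(0, 3))               # truth satisfies its own restraints

  c1 <- distance_constraint(1, 2, target = 5, tolerance = 2)
  expect_equal(viasm:::cons_violation(10, c1$lower, c1$upper), 3)
  expect_equal(viasm:::cons_violation(5, c1$lower, c1$upper), 0)
  expect_equal(viasm:::cons_violation(1, c1$lower, c1$upper), 2)

  expect_equal(e_data(c(3, 4), c(0, 0)), 5)
  expect_equal(e_data(5, 3), 2)
  expect_equal(e_data(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_error(e_data(1:3, 1:2), "equal length")
  # norm properties over deviation vectors
  set.seed(1)
  for (i in 1:20) {
    u <- rnorm(4); v <- rnorm(4)
    expect_lte(e_data(u + v, numeric(4)),
               e_data(u, numeric(4)) + e_data(v, numeric(4)) + 1e-12)
    a <- runif(1, -3, 3)
    expect_equal(e_data(a * u, numeric(4)), abs(a) * e_data(u, numeric(4)))
  }

  expect_error(constraint_distances(ref$assembly,
                                    distance_constraint(999, 1, 5)), "constraint 1")
})

test_that("aggregated reference fitness is the stated convex combination", {
  expect_equal(aggregated_fitness(0, 0), 0)
  expect_equal(aggregated_fitness(-1, 2, w = 0.2), 0.2 * -1 + 0.8 * 2)
  expect_equal(aggregated_fitness(-1, 2, w = 0.2), 1.4)
  expect_equal(aggregated_fitness(-7, 99, w = 1), -7)
  expect_equal(aggregated_fitness(-7, 99, w = 0), 99)
  expect_error(aggregated_fitness(0, 0, w = 1.2), "w")
})

test_that("population diversity matches hand computations and scales linearly", {
  X <- matrix(c(0.5, 0.5), 1)
  expect_equal(diversity(c(0.5, 0.5), X), 0)
  expect_equal(diversity(c(3.5, 4.5), X), 5)          # single member at distance 5
  X2 <- rbind(c(3, 4), c(0, 5))                        # both at distance 5 from x
  x <- c(0, 0)
  expect_equal(diversity(x, X2), sqrt(25 + 25) / 2)
  expect_equal(diversity(x, X2), 3.5355, tolerance = 1e-4)
  # linear scaling of all deviations
  set.seed(2)
  P <- matrix(runif(12), 4)
  xx <- runif(3)
  expect_equal(diversity(xx * 3, P * 3), 3 * diversity(xx, P))
  expect_error(diversity(xx, P[0, , drop = FALSE]), "empty")
})

test_that("precision of restraint satisfaction is TP/(TP+FP)", {
  expect_equal(ppv(2, 0), 1.0)
  expect_equal(ppv(2, 2), 0.5)
  expect_equal(ppv(0, 1), 0)
  expect_error(ppv(0, 0), "undefined")
  # full enumeration, and monotonicity in fp
  for (tp in 0:6) for (fp in 0:(6 - tp)) {
    if (tp + fp == 0) next
    expect_equal(ppv(tp, fp), tp / (tp + fp))
    expect_gte(ppv(tp, fp), 0); expect_lte(ppv(tp, fp), 1)
    if (fp > 0 && tp + fp > 1) expect_lte(ppv(tp, fp), ppv(tp, fp - 1))
  }
})

test_that("pearson matches the product-moment formula and guards degeneracy", {
  x <- c(1, 2, 3, 4)
  expect_equal(pearson(x, 2 * x + 1), 1)
  expect_equal(pearson(x, -x), -1)
  expect_equal(pearson(c(1, 2, 3), c(1, 3, 2)), 0.5)
  expect_error(pearson(c(1, 1, 1), x[1:3]), "zero variance")
  expect_error(pearson(1:2, 1:2), ">= 3")
})

test_that("crosslink objective correlates profile with inter-subunit Cbeta distances", {
  ref <- ref_dimer()
  # profile the residues spanning the interface (the responsive band of the
  # logistic), as a disulfide scan of an interface helix would
  resn <- profiled_residues(ref$assembly)
  prof0 <- synth_crosslink_profile(ref$assembly, resn, noise_sd = 0, seed = 1)
  xl <- crosslink_objective(ref$assembly, prof0)
  expect_gte(xl$abs_R, 0.9)                  # noiseless monotone construction
  expect_lt(xl$R, 0)                         # more crosslinking at shorter distance
  # fractions strictly decrease with distance (noiseless logistic)
  o <- order(xl$table$distance)
  expect_true(all(diff(xl$table$fraction[o]) < 0))

  # brute-force recomputation agrees exactly
  ch <- unique(ref$assembly$atoms$chain)
  d <- sqrt(rowSums((atom_coords(ref$assembly, prof0$resno, "CB", ch[1]) -
                       atom_coords(ref$assembly, prof0$resno, "CB", ch[2]))^2))
  expect_equal(xl$R, cor(prof0$fraction, d))
  expect_equal(xl$table$distance, unname(d))

  expect_error(crosslink_objective(ref$assembly,
                                   crosslink_profile(resn, rep(0.5, length(resn)))),
               "zero variance")
  expect_error(crosslink_objective(ref$assembly, prof0[1:2, ]), ">= 3")
})

test_that("scores are invariant under global rigid motion", {
  ref <- ref_c5()
  cons <- derive_constraints(ref$assembly, 3, seed = 3)
  set.seed(11)
  for (i in 1:3) {
    pose <- c(runif(3, 0, 2 * pi), runif(3, -40, 40))
    moved <- apply_global_pose(ref$assembly, pose)
    expect_equal(e_phys(moved), e_phys(ref$assembly), tolerance = 1e-9)
    expect_equal(constraint_distances(moved, cons)$observed,
                 constraint_distances(ref$assembly, cons)$observed,
                 tolerance = 1e-9)
  }
})

test_that("restraint and profile tables round-trip through their text formats", {
  cons <- constraint_set(
    distance_constraint(3, 9, 6.5, 2, "CA", TRUE),
    distance_constraint(4, 12, 7.25, 1.5, "CB", FALSE))
  f <- withr::local_tempfile(fileext = ".txt")
  write_constraints(cons, f)
  back <- read_constraints(f)
  expect_equal(as.data.frame(back), as.data.frame(cons), ignore_attr = TRUE)

  prof <- crosslink_profile(c(2, 5, 9), c(0.9, 0.5, 0.05))
  write_crosslink_profile(prof, f)
  expect_equal(as.data.frame(read_crosslink_profile(f)), as.data.frame(prof),
               ignore_attr = TRUE)
})
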