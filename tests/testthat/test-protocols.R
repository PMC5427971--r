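# Protocol smoke tests run at reduced budgets; the full-budget experiments
# live in test-acceptance.R.

test_that("configs validate their mode requirements", {
  sub <- toy_helix()
  expect_error(protocol_config("diversity", sub, 5), "constraints")
  cons <- derive_constraints(ref_c5()$assembly, 2, seed = 1)
  expect_error(protocol_config("diversity", sub, 5, constraints = cons),
               "density map")
  expect_error(protocol_config("crosslink", sub, 2), "profile")
  expect_error(protocol_config("nonsense", sub), "arg")
})

test_that("diversity protocol returns viable, constraint-satisfying models", {
  ref <- ref_c5()
  cons <- derive_constraints(ref$assembly, 3, seed = 3)
  map <- simulate_map(ref$assembly, 15)
  cfg <- protocol_config("diversity", toy_helix(), 5, constraints = cons,
                         map = map, budget = 3000, seed = 1)
  res <- protocol_diversity(cfg)
  expect_true(res$feasible)
  # the central viability guarantee: every returned model satisfies every
  # restraint interval and has attractive energy
  for (mod in res$models) {
    cd <- constraint_distances(mod, cons)
    expect_true(all(cd$violation <= 1e-9))
    expect_lt(e_phys(mod), 0)
  }
  expect_true(all(res$clusters$max_rmsd < 1))
  # determinism per seed
  res2 <- protocol_diversity(cfg)
  expect_identical(res$ranked$ranking, res2$ranked$ranking)
})

test_that("unsatisfiable restraints produce an explicit failure report", {
  ref <- ref_c5()
  bad <- constraint_set(
    distance_constraint(1, 2, target = 4, tolerance = 0.1),
    distance_constraint(1, 2, target = 40, tolerance = 0.1))  # disjoint demands
  map <- simulate_map(ref$assembly, 15)
  cfg <- protocol_config("diversity", toy_helix(), 5, constraints = bad,
                         map = map, budget = 800, seed = 1)
  expect_message(res <- protocol_diversity(cfg), "no viable")
  expect_false(res$feasible)
  expect_match(res$message, "no viable")
})

test_that("energy-objective protocol beats a coarse grid oracle on a dimer", {
  ref <- ref_dimer()
  cons <- derive_constraints(ref$assembly, 1, tolerance = 2, seed = 2)
  cfg <- protocol_config("energy_objective", toy_compact(), 2,
                         constraints = cons, budget = 4000, seed = 1)
  res <- protocol_energy_objective(cfg)
  expect_true(res$feasible)
  best_e <- res$run$best$objective
  expect_lt(best_e, 0)

  # coarse 4-D grid oracle over the same decoded space
  scn <- viasm:::make_scene(cfg)
  gr <- seq(0.05, 0.95, length.out = 7)
  gbest <- Inf
  for (a in gr) for (b in gr) for (g in gr) for (x in gr) {
    u <- c(a, b, g, x)
    xyz <- viasm:::scene_xyz(scn, u)
    d <- viasm:::scene_cons_dist(scn, xyz)
    if (all(viasm:::cons_violation(d, scn$cons_lower, scn$cons_upper) <= 0))
      gbest <- min(gbest, viasm:::scene_ephys(scn, xyz))
  }
  expect_lte(best_e, gbest + 1e-9)
  # same seed, same result
  expect_equal(protocol_energy_objective(cfg)$run$best$objective, best_e)
})

test_that("ccc-objective protocol fixes its own map and respects the refit cadence", {
  ref <- ref_c5()
  cons <- derive_constraints(ref$assembly, 1, seed = 4)
  map <- simulate_map(ref$assembly, 15)
  cfg <- protocol_config("ccc_objective", toy_helix(), 5, constraints = cons,
                         map = map, budget = 900, seed = 2)  # < 1000: no refits
  res <- protocol_ccc_objective(cfg)
  expect_s3_class(res, "viasm_protocol")
  if (res$feasible) expect_true(all(res$run$archive$viol <= 1e-9))

  # a model scored against the map simulated from itself reaches ccc 1
  m_self <- simulate_map(ref$assembly, 15)
  expect_equal(ccc(m_self, simulate_map(ref$assembly, 15)), 1)
})

test_that("blind docking respects the energy constraint and map degeneracies", {
  ref <- make_reference_assembly(toy_compact(), 2, seed = 5)
  map <- simulate_map(ref$assembly, 15)
  cfg <- protocol_config("blind_dock", toy_compact(), 2, map = map,
                         budget = 3000, seed = 1)
  res <- protocol_blind_dock(cfg)
  expect_true(res$feasible)
  for (mod in res$models) expect_lt(e_phys(mod), 0)
  # budget accounting is exact
  expect_equal(res$run$n_eval, 3000)
})

test_that("crosslink protocol recovers a correlated interface on a toy dimer", {
  ref <- ref_dimer()
  resn <- profiled_residues(ref$assembly)
  prof <- synth_crosslink_profile(ref$assembly, resn, noise_sd = 0.03, seed = 2)
  top <- prof$resno[which.max(prof$fraction)]
  ch <- unique(ref$assembly$atoms$chain)
  d_top <- sqrt(sum((atom_coords(ref$assembly, top, "CB", ch[1]) -
                       atom_coords(ref$assembly, top, "CB", ch[2]))^2))
  cfg <- protocol_config("crosslink", toy_compact(), 2, profile = prof,
                         anchor = list(residue = top, lower = max(d_top - 2, 1),
                                       upper = d_top + 2),
                         budget = 4000, seed = 1)
  res <- protocol_crosslink(cfg)
  expect_true(res$feasible)
  expect_gte(res$abs_R, 0.5)
  expect_lt(e_phys(res$model), 0)
  # reported table is the model's own geometry
  expect_equal(res$table$fraction, prof$fraction)

  # negative control: profile uncorrelated with geometry gets flagged
  set.seed(99)
  rnd <- crosslink_profile(resn, runif(length(resn)))
  cfg2 <- protocol_config("crosslink", toy_compact(), 2, profile = rnd,
                          anchor = list(residue = top, lower = max(d_top - 2, 1),
                                        upper = d_top + 2),
                          budget = 2000, seed = 3)
  res2 <- protocol_crosslink(cfg2)
  if (res2$feasible) expect_lt(res2$abs_R, res$abs_R)
})

test_that("aggregated reference mode reduces to its limiting objectives", {
  ref <- ref_c5()
  cons <- derive_constraints(ref$assembly, 3, seed = 3)
  cfg0 <- protocol_config("aggregated_reference", toy_helix(), 5,
                          constraints = cons, budget = 1500, seed = 1, w = 0)
  res0 <- protocol_aggregated_reference(cfg0)
  # w = 0: pure E_data minimisation; the optimum satisfies the restraints
  u <- res0$run$best$params
  scn <- viasm:::make_scene(cfg0)
  d <- viasm:::scene_cons_dist(scn, viasm:::scene_xyz(scn, u))
  expect_lt(e_data(d, cons$target), 1.5)

  cfg1 <- protocol_config("aggregated_reference", toy_helix(), 5,
                          constraints = cons, budget = 1500, seed = 1, w = 1)
  res1 <- protocol_aggregated_reference(cfg1)
  # w = 1: pure E_phys minimisation, data term ignored
  expect_lt(res1$run$best$objective, 0)
})
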