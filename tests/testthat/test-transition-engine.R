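# transition_engine: matrices, propagation, trajectories

test_that("mortality lookup uses age band and group class", {
  ps <- load_case_study()
  expect_equal(unname(mortality_prob(ps, "G4", 86)), 0.068)
  expect_equal(unname(mortality_prob(ps, "G2", 96)), 0.092)
  expect_equal(mortality_prob(ps, "G3", 86), mortality_prob(ps, "G5", 86))
  expect_equal(unname(mortality_prob(ps, "G2", 65)), 0.055)
  expect_equal(unname(mortality_prob(ps, "G2", 74.99)), 0.055)
  expect_equal(unname(mortality_prob(ps, "G2", 75)), 0.056)
  expect_error(mortality_prob(ps, "G2", 64), "65")
})

test_that("cycle matrix composes mortality, group and care-stage moves", {
  ps <- load_case_study()
  ss <- state_space(ps$settings$included_groups)
  for (comp in c("independent", "shift")) {
    M <- build_cycle_matrix(ps, "conventional", 86, group_change_cs = comp)
    expect_equal(unname(rowSums(M)), rep(1, ss$n), tolerance = 1e-12)
    expect_equal(unname(M["dead", "dead"]), 1)
    expect_true(all(M["dead", ss$labels != "dead"] == 0))
    # death probability appears unchanged in the dead column
    expect_equal(unname(M["G2:CS2", "dead"]), 0.069)
  }
  # the literal movers-deteriorate composition: worked products
  M <- build_cycle_matrix(ps, "conventional", 86, group_change_cs = "shift")
  expect_equal(unname(M["G2:CS2", "G3:CS3"]), (1 - 0.069) * 0.063 * 0.90,
               tolerance = 1e-9)                     # 0.052787
  expect_equal(unname(M["G2:CS2", "G2:CS2"]), 0.931 * 0.935 * 0.45,
               tolerance = 1e-9)                     # 0.391722
  # movers already in the worst care stage stay there
  expect_equal(unname(M["G2:CS3", "G3:CS3"]), (1 - 0.069) * 0.063)
  expect_equal(unname(M["G2:CS3", "G3:CS2"]), 0)
  # independent composition: group and care-stage moves factorize
  Mi <- build_cycle_matrix(ps, "conventional", 86, group_change_cs = "independent")
  expect_equal(unname(Mi["G2:CS2", "G3:CS1"]),
               0.931 * 0.063 * ps$cs_transition$conventional["CS2", "CS1"],
               tolerance = 1e-12)
})

test_that("propagation conserves mass and advances age", {
  ps <- toy_params()
  ss <- state_space(ps$settings$included_groups)
  occ <- c(rep(1 / ss$n_alive, ss$n_alive), 0)
  st <- cohort_state(occ, 86)
  # identity matrix leaves occupancy unchanged, age advances
  st2 <- propagate(st, diag(ss$n), cycle_length = 1 / 6)
  expect_equal(st2$occupancy, st$occupancy)
  expect_equal(st2$age, 86 + 1 / 6)
  # a real cycle matrix conserves total mass
  M <- build_cycle_matrix(ps, "dht", 86)
  st3 <- propagate(st, M)
  expect_equal(sum(st3$occupancy), 1, tolerance = 1e-12)
  expect_error(propagate(st, diag(3)), "dimension")
})

test_that("cohort run starts from the product of the initial margins", {
  ps <- load_case_study()
  traj <- run_cohort(ps, "conventional")
  occ0 <- traj$occupancy[1, ]
  expect_equal(unname(occ0["G2:CS1"]), 0.21 * 0.16, tolerance = 1e-12)
  expect_equal(unname(occ0["G6:CS3"]), 0.05 * 0.37, tolerance = 1e-12)
  expect_equal(unname(occ0["dead"]), 0)
  expect_true(traj$converged)
})

test_that("survival is non-increasing, mass conserved, structural zeros hold", {
  for (seed in c(3, 14)) {
    ps <- generate_synthetic_params(seed)
    for (arm in strategies()) {
      traj <- run_cohort(ps, arm)
      expect_true(all(diff(traj$survival) <= 1e-12))
      expect_true(all(traj$survival >= -1e-12 & traj$survival <= 1 + 1e-12))
      expect_equal(unname(rowSums(traj$occupancy)), rep(1, nrow(traj$occupancy)),
                   tolerance = 1e-9)
      expect_true(all(traj$occupancy >= -1e-12))
      # age advances one cycle length per cycle
      expect_equal(unique(round(diff(traj$ages), 10)),
                   round(ps$settings$cycle_length, 10))
    }
  }
  # no mass ever flows back to a lower-indexed group (mass in the lowest
  # included group can only shrink relative to pure survival)
  ps <- load_case_study()
  traj <- run_cohort(ps, "dht", group_change_cs = "shift")
  g2 <- rowSums(traj$occupancy[, paste0("G2:", care_stages())])
  expect_true(all(diff(g2) <= 1e-12))
  # under the shift composition, group-movers in CS3 stay in CS3: mass in
  # (G6, CS1/CS2) can only arrive via G6-stayers' own care-stage moves
  M <- build_cycle_matrix(ps, "dht", 86, group_change_cs = "shift")
  expect_equal(unname(M["G5:CS3", "G6:CS2"]), 0)
  expect_equal(unname(M["G5:CS3", "G6:CS1"]), 0)
})

test_that("zero mortality with identity transitions freezes the cohort", {
  ps <- toy_params(mortality = 0, max_cycles = 6)
  ident <- diag(3); dimnames(ident) <- dimnames(ps$cs_transition$dht)
  ps$cs_transition$dht <- ident
  gident <- diag(2); dimnames(gident) <- dimnames(ps$group_transition)
  ps$group_transition <- gident
  expect_warning(traj <- run_cohort(ps, "dht"), "not extinct")
  expect_false(traj$converged)
  for (t in seq_len(nrow(traj$occupancy))) {
    expect_equal(traj$occupancy[t, ], traj$occupancy[1, ], tolerance = 1e-12)
  }
})

test_that("skin-health rows come back normalized and strategy-specific", {
  ps <- load_case_study()
  expect_equal(unname(shl_distribution(ps, "conventional", "CS3")),
               c(0.875, 0.075, 0.016, 0.016, 0.013) / 0.995, tolerance = 1e-12)
  expect_equal(unname(shl_distribution(ps, "dht", "CS1")), c(1, 0, 0, 0, 0))
  for (arm in strategies()) for (cs in care_stages()) {
    expect_equal(sum(shl_distribution(ps, arm, cs)), 1, tolerance = 1e-12)
  }
})

test_that("trajectory tidy export matches the occupancy record", {
  ps <- toy_params(max_cycles = 240)
  traj <- run_cohort(ps, "conventional")
  df <- as.data.frame(traj)
  expect_setequal(names(df), c("cycle", "state", "group", "cs", "mass", "age",
                               "survival"))
  expect_equal(nrow(df), nrow(traj$occupancy) * traj$state_space$n)
  at <- df[df$cycle == 5 & df$state == "G2:CS2", ]
  expect_equal(at$mass, unname(traj$occupancy[6, "G2:CS2"]))
})
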