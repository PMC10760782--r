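# analysis: deterministic CE, OWSA, PSA, CEAC -------------------------------

test_that("incremental comparison classifies dominance correctly", {
  ps <- load_case_study(economics = "synthetic")
  ce <- run_deterministic(ps)
  expect_s3_class(ce, "tcc_ce")
  expect_equal(ce$delta_qaly,
               ce$qaly$dht$total_qalys - ce$qaly$conventional$total_qalys)
  expect_equal(ce$delta_cost,
               unname(ce$cost$dht["total"] - ce$cost$conventional["total"]))
  expect_true(ce$label %in% c("dominant", "dominated", "icer", "null"))
  if (ce$label == "icer") expect_equal(ce$icer, ce$delta_cost / ce$delta_qaly)

  # force a dominant configuration: make the DHT arm free of technology and
  # product costs, and conventional care expensive
  ps_dom <- ps
  ps_dom$economics$technology_cost_per_person_year$dht <- 0
  ps_dom$economics$task_freq_per_day$dht[] <- 0
  ps_dom$economics$products$daily_count$dht[] <- 0
  ce_dom <- run_deterministic(ps_dom)
  expect_lt(ce_dom$delta_cost, 0)
  expect_equal(ce_dom$label, "dominant")
  expect_true(is.na(ce_dom$icer))

  # degenerate: identical arms -> null label
  ps_same <- ps
  ps_same$cs_transition$dht <- ps_same$cs_transition$conventional
  ps_same$shl_given_cs$dht <- ps_same$shl_given_cs$conventional
  ps_same$event_rates$dht <- ps_same$event_rates$conventional
  ps_same$economics$task_freq_per_day$dht <- ps_same$economics$task_freq_per_day$conventional
  ps_same$economics$products$price_per_piece$dht <- ps_same$economics$products$price_per_piece$conventional
  ps_same$economics$products$daily_count$dht <- ps_same$economics$products$daily_count$conventional
  ps_same$economics$hygiene_cost_per_application$dht <- ps_same$economics$hygiene_cost_per_application$conventional
  ps_same$economics$technology_cost_per_person_year$dht <- 0
  ce_same <- run_deterministic(ps_same)
  expect_equal(ce_same$delta_qaly, 0, tolerance = 1e-12)
  expect_equal(ce_same$label, "null")

  # effect-only mode works without an economics block
  ce_eff <- run_deterministic(load_case_study())
  expect_equal(ce_eff$label, "effect_only")
  expect_true(is.na(ce_eff$delta_cost))
})

test_that("moment matching recovers the documented shape parameters", {
  expect_equal(unname(beta_shapes(0.5, 0.1)), c(12, 12))
  g <- gamma_shapes(10, 2)
  expect_equal(unname(g), c(25, 10 / 25))
  # moment match round-trips mean and SE
  b <- beta_shapes(0.2, 0.05)
  expect_equal(unname(b[1] / sum(b)), 0.2)
  expect_equal(sqrt(prod(b) / (sum(b)^2 * (sum(b) + 1))), 0.05, tolerance = 1e-12)
})

test_that("Dirichlet rows preserve means and structural zeros", {
  set.seed(5)
  p <- c(0.935, 0.063, 0.002, 0, 0)
  draws <- t(replicate(4000, rdirichlet_row(p)))
  expect_true(all(draws[, 4:5] == 0))
  expect_equal(unname(rowSums(draws)), rep(1, 4000), tolerance = 1e-12)
  expect_equal(unname(colMeans(draws)[1]), 0.935, tolerance = 0.01)
  expect_equal(unname(colMeans(draws)[2]), 0.063, tolerance = 0.01)
  # a degenerate row is returned unchanged
  expect_equal(rdirichlet_row(c(0, 1, 0)), c(0, 1, 0))
})

test_that("one-way analysis brackets the base case and skips fixed parameters", {
  ps <- load_case_study()
  specs <- default_param_specs(ps)
  expect_true(specs$fixed[specs$id == "utilities.d_cs.CS1"])
  expect_true(specs$fixed[specs$id == "utilities.d_shl.SHL1"])
  expect_true(specs$fixed[specs$id == "utilities.d_event.pu1"])
  # restrict to a few parameters to keep the run small
  sub <- specs[specs$id %in% c("utilities.d_cs.CS3", "utilities.d_cs.CS2",
                               "utilities.group.G3", "event_rates.dht.uti",
                               "utilities.d_cs.CS1"), ]
  ow <- run_owsa(ps, specs = sub)
  expect_equal(nrow(ow), 4)  # CS1 decrement skipped as fixed
  base <- attr(ow, "base")
  # monotone scalar parameters bracket the base case
  cs3 <- ow[ow$id == "utilities.d_cs.CS3", ]
  expect_true(min(cs3$delta_qaly_lo, cs3$delta_qaly_hi) <= base$delta_qaly + 1e-12)
  expect_true(max(cs3$delta_qaly_lo, cs3$delta_qaly_hi) >= base$delta_qaly - 1e-12)
  # zero-width bounds reproduce the base case at both ends
  degen <- sub[sub$id == "utilities.group.G3", ]
  degen$lo <- degen$mean; degen$hi <- degen$mean
  ow0 <- run_owsa(ps, specs = degen)
  expect_equal(ow0$delta_qaly_lo, base$delta_qaly, tolerance = 1e-12)
  expect_equal(ow0$delta_qaly_hi, base$delta_qaly, tolerance = 1e-12)
})

test_that("tornado entries for linear unit costs are exactly linear in the bound", {
  ps <- load_case_study(economics = "synthetic")
  specs <- default_param_specs(ps)
  row <- specs[specs$id == "econ.event_costs.uti", ]
  ow <- run_owsa(ps, specs = row)
  mid <- run_deterministic(set_param(ps, row$id, (row$lo + row$hi) / 2))
  expect_equal(mid$delta_cost, (ow$delta_cost_lo + ow$delta_cost_hi) / 2,
               tolerance = 1e-9)
})

test_that("PSA is seed-reproducible and collapses to the deterministic result", {
  ps <- load_case_study()
  p1 <- run_psa(ps, n_iter = 30, seed = 4)
  p2 <- run_psa(ps, n_iter = 30, seed = 4)
  expect_identical(p1$samples, p2$samples)
  p3 <- run_psa(ps, n_iter = 30, seed = 5)
  expect_false(identical(p1$samples$delta_qaly, p3$samples$delta_qaly))

  base <- run_deterministic(ps)
  p0 <- run_psa(ps, n_iter = 10, seed = 4, se_scale = 0)
  expect_true(all(abs(p0$samples$delta_qaly - base$delta_qaly) < 1e-6))
})

test_that("PSA sample means stabilise as 1/sqrt(n)", {
  ps <- load_case_study()
  p_small <- run_psa(ps, n_iter = 40, seed = 8)
  p_large <- run_psa(ps, n_iter = 160, seed = 8)
  sd_iter <- sd(p_large$samples$delta_qaly)
  # the two estimates agree within combined Monte-Carlo error
  expect_lt(abs(p_small$means["delta_qaly"] - p_large$means["delta_qaly"]),
            4 * sd_iter / sqrt(40))
})

test_that("quadrant shares partition the CE plane and the CEAC is coherent", {
  ps <- load_case_study(economics = "synthetic")
  psa <- run_psa(ps, n_iter = 120, seed = 3)
  expect_equal(sum(psa$quadrant_shares), 1, tolerance = 1e-12)
  expect_equal(nrow(psa$samples), 120)

  curve <- ceac(psa, lambdas = c(0, 25000, 50000, 1e7))
  expect_true(all(curve$prob >= 0 & curve$prob <= 1))
  # lambda = 0: probability of cost savings = SW + SE quadrants
  expect_equal(curve$prob[1],
               unname(psa$quadrant_shares["se"] + psa$quadrant_shares["sw"]),
               tolerance = 1e-12)
  # at an extreme threshold, effects dominate the decision
  expect_equal(curve$prob[4], mean(psa$samples$delta_qaly > 0 |
                                     (psa$samples$delta_qaly == 0 &
                                        psa$samples$delta_cost <= 0)),
               tolerance = 0.02)
  expect_error(ceac(run_psa(load_case_study(), n_iter = 5, seed = 1)), "costs")
})
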