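# outcomes_costs: per-state costing, accumulation, physical resources -------

econ_ps <- function() load_case_study(economics = "synthetic")

test_that("per-state cycle cost decomposes and a worked labour product checks out", {
  ps <- econ_ps()
  cc <- cycle_cost(ps, "conventional", "G3", "CS2")
  expect_equal(unname(cc["total"]), sum(cc[cost_categories()]), tolerance = 1e-9)
  expect_true(all(cc >= 0))
  # one G3 product change at an illustrative 0.50/min wage: 10.2 min x 1.3 staff
  ps50 <- ps
  ps50$economics$wage_formal_per_min <- 0.50
  one_change <- ps50$economics$task_minutes["product_change", "G3"] *
    ps50$economics$staff_per_task["product_change", "G3"] * 0.50
  expect_equal(unname(one_change), 6.63)
  # labour scales linearly with the change frequency at that wage
  base <- cycle_cost(ps50, "conventional", "G3", "CS2")
  ps2 <- ps50
  ps2$economics$task_freq_per_day$conventional["product_change", "CS2"] <-
    ps2$economics$task_freq_per_day$conventional["product_change", "CS2"] + 1
  bumped <- cycle_cost(ps2, "conventional", "G3", "CS2")
  expect_equal(unname(bumped["labour"] - base["labour"]),
               unname(one_change * ps$settings$days_per_cycle), tolerance = 1e-9)
  # technology cost accrues in the DHT arm only
  expect_equal(unname(cycle_cost(ps, "conventional", "G2", "CS1")["technology"]), 0)
  expect_equal(unname(cycle_cost(ps, "dht", "G2", "CS1")["technology"]),
               ps$economics$technology_cost_per_person_year$dht / 6, tolerance = 1e-9)
})

test_that("zero unit costs zero every category", {
  ps <- econ_ps()
  ps$economics$wage_formal_per_min <- 0
  ps$economics$wage_informal_per_min <- 0
  for (arm in strategies()) {
    ps$economics$products$price_per_piece[[arm]][] <- 0
    ps$economics$hygiene_cost_per_application[[arm]] <- 0
    ps$economics$technology_cost_per_person_year[[arm]] <- 0
  }
  ps$economics$disposal_tariff_per_kg <- 0
  ps$economics$event_costs[] <- 0
  ps$economics$shl5_treatment$unit_cost_per_application <- 0
  cc <- cycle_cost(ps, "dht", "G4", "CS3")
  expect_equal(unname(cc["total"]), 0)
})

test_that("accumulated costs are additive and linear in unit costs", {
  ps <- econ_ps()
  traj <- run_cohort(ps, "conventional")
  costs <- accumulate_costs(traj, ps)
  expect_equal(unname(costs["total"]), sum(costs[cost_categories()]),
               tolerance = 1e-6)
  expect_true(all(costs >= 0))

  # linear in the wage (labour), the tariff (disposal) and an event cost
  scale_field <- function(ps, fn) { ps2 <- ps; ps2$economics <- fn(ps2$economics); ps2 }
  ps_w <- scale_field(ps, function(e) { e$wage_formal_per_min <- 2 * e$wage_formal_per_min; e })
  c_w <- accumulate_costs(run_cohort(ps_w, "conventional"), ps_w)
  expect_equal(unname(c_w["labour"]), unname(2 * costs["labour"]), tolerance = 1e-9)

  ps_t <- scale_field(ps, function(e) { e$disposal_tariff_per_kg <- 3 * e$disposal_tariff_per_kg; e })
  c_t <- accumulate_costs(run_cohort(ps_t, "conventional"), ps_t)
  expect_equal(unname(c_t["disposal"]), unname(3 * costs["disposal"]), tolerance = 1e-9)

  ps_e <- scale_field(ps, function(e) { e$event_costs["uti"] <- 2 * e$event_costs["uti"]; e })
  c_e <- accumulate_costs(run_cohort(ps_e, "conventional"), ps_e)
  uti_base <- costs["care_consequences"]
  # doubling one event cost raises only the consequence category
  expect_gt(unname(c_e["care_consequences"]), unname(uti_base))
  expect_equal(unname(c_e["labour"]), unname(costs["labour"]), tolerance = 1e-9)

  # discounting strictly shrinks positive cost streams
  ps0 <- ps
  ps0$settings$discount_rate <- 0
  c0 <- accumulate_costs(run_cohort(ps0, "conventional"), ps0)
  expect_gt(unname(c0["total"]), unname(costs["total"]))
})

test_that("care hours and disposal mass are physical: discount-invariant", {
  ps <- econ_ps()
  res <- accumulate_resources(run_cohort(ps, "dht"), ps)
  expect_true(all(res$care_hours >= 0) && all(res$disposal_kg >= 0))
  expect_equal(res$total_hours, sum(res$care_hours))
  ps0 <- ps
  ps0$settings$discount_rate <- 0
  res0 <- accumulate_resources(run_cohort(ps0, "dht"), ps0)
  expect_equal(res0$total_hours, res$total_hours, tolerance = 1e-9)
  expect_equal(res0$total_kg, res$total_kg, tolerance = 1e-9)
})

test_that("full informal care at zero rate removes labour cost but not hours", {
  ps <- econ_ps()
  ps$economics$informal_share <- 1
  ps$economics$wage_informal_per_min <- 0
  traj <- run_cohort(ps, "conventional")
  costs <- accumulate_costs(traj, ps)
  expect_equal(unname(costs["labour"]), 0)
  res <- accumulate_resources(traj, ps)
  ps_f <- econ_ps()
  res_f <- accumulate_resources(run_cohort(ps_f, "conventional"), ps_f)
  expect_equal(res$total_hours, res_f$total_hours, tolerance = 1e-9)
})

test_that("zero frequencies and product counts zero hours and mass", {
  ps <- econ_ps()
  for (arm in strategies()) {
    ps$economics$task_freq_per_day[[arm]][] <- 0
    ps$economics$products$daily_count[[arm]][] <- 0
  }
  res <- accumulate_resources(run_cohort(ps, "dht"), ps)
  expect_equal(res$total_hours, 0)
  expect_equal(res$total_kg, 0)
})
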