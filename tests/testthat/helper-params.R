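# Small in-code fixtures for fast unit tests --------------------------------

# two-group toy parameter set (G2, G3) with simple round numbers
toy_params <- function(mortality = 0.08, group_change_cs = "independent",
                       economics = NULL, max_cycles = 240) {
  groups <- c("G2", "G3")
  gt <- matrix(c(0.9, 0.1,
                 0.0, 1.0), 2, 2, byrow = TRUE, dimnames = list(groups, groups))
  mort <- matrix(mortality, 4, 3,
                 dimnames = list(c("65-74", "75-84", "85-94", "95+"),
                                 c("G1", "G4", "other")))
  cs_t <- lapply(setNames(strategies(), strategies()), function(a)
    matrix(c(0.8, 0.2, 0.0,
             0.1, 0.8, 0.1,
             0.0, 0.2, 0.8), 3, 3, byrow = TRUE,
           dimnames = list(care_stages(), care_stages())))
  shl <- lapply(setNames(strategies(), strategies()), function(a)
    matrix(c(1.0, 0, 0, 0, 0,
             0.9, 0.05, 0.03, 0.01, 0.01,
             0.8, 0.1, 0.05, 0.03, 0.02), 3, 5, byrow = TRUE,
           dimnames = list(care_stages(), shl_levels())))
  ev <- lapply(setNames(strategies(), strategies()), function(a)
    c(fracture_g2_g4 = 0.002, fracture_g5_g6 = 0, uti = 0.05,
      constipation = 0.08, pu1 = 0.2, pu2 = 0.05, pu3 = 0.01, pu4 = 0.01))
  parameter_set(
    settings = list(included_groups = groups, start_age = 86,
                    group_change_cs = group_change_cs, max_cycles = max_cycles),
    initial = list(group = c(G2 = 0.6, G3 = 0.4),
                   cs = c(CS1 = 0.3, CS2 = 0.4, CS3 = 0.3),
                   shl = c(SHL1 = 0.9, SHL2 = 0.05, SHL3 = 0.03,
                           SHL4 = 0.01, SHL5 = 0.01)),
    group_transition = gt,
    mortality = list(mean = mort, lo = mort * 0.9, hi = pmin(mort * 1.1, 1)),
    cs_transition = cs_t, shl_given_cs = shl, event_rates = ev,
    utilities = list(
      group = c(G1 = 0.8, G2 = 0.7, G3 = 0.6, G4 = 0.5, G5 = 0.4, G6 = 0.3),
      d_cs = c(CS1 = 0, CS2 = 0.01, CS3 = 0.03),
      d_shl = c(SHL1 = 0, SHL2 = 0.02, SHL3 = 0.03, SHL4 = 0.04, SHL5 = 0.05),
      d_event = c(fracture = 0.1, uti = 0.09, constipation = 0.03,
                  pu1 = 0, pu2 = 0.04, pu3 = 0.04, pu4 = 0.04)),
    economics = economics,
    meta = list(label = "toy"))
}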