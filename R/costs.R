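# Cost and physical-resource accumulation -----------------------------------

cost_categories <- function() c("technology", "labour", "absorbent_products",
                                "hygiene", "disposal", "care_consequences",
                                "shl5_treatment")

.require_econ <- function(ps) {
  if (is.null(ps$economics)) {
    stop("economics block not populated: load the parameter set with ",
         "`economics = \"synthetic\"` (or a transcribed file) for cost analyses",
         call. = FALSE)
  }
  needed <- c("wage_formal_per_min", "wage_informal_per_min", "informal_share",
              "task_minutes", "staff_per_task", "task_freq_per_day", "products",
              "hygiene_cost_per_application", "disposal_tariff_per_kg",
              "event_costs", "technology_cost_per_person_year", "shl5_treatment")
  missing <- needed[vapply(needed, function(f) is.null(ps$economics[[f]]), logical(1))]
  if (length(missing)) {
    stop("economics fields not populated: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  invisible(ps$economics)
}

.blended_wage <- function(econ) {
  econ$informal_share * econ$wage_informal_per_min +
    (1 - econ$informal_share) * econ$wage_formal_per_min
}

#' Per-person per-cycle cost of an alive state
#'
#' Costs per resident spending one cycle in `(group, cs)` under a strategy,
#' undiscounted, split into the seven reporting categories:
#' \describe{
#'   \item{labour}{task frequency/day x days/cycle x minutes per task x staff
#'     per task x blended wage per minute (formal/informal mix).}
#'   \item{absorbent_products}{daily product count for the care stage x
#'     days x price per piece.}
#'   \item{hygiene}{perineal hygiene performed at every product change:
#'     change count x per-application cost.}
#'   \item{disposal}{daily count x dry weight per piece x tariff per kg.}
#'   \item{care_consequences}{per-cycle event probabilities x cost per
#'     occurrence.}
#'   \item{shl5_treatment}{probability of severe skin problems this cycle x
#'     one 7-day treated episode (one application per product change:
#'     1 minute of labour plus the consumable cost each).}
#'   \item{technology}{per-person-year acquisition price x cycle length
#'     (zero for conventional care).}
#' }
#'
#' @inheritParams cycle_utility
#' @return Named numeric over the seven categories plus `total`.
#' @export
cycle_cost <- function(ps, strategy, group, cs) {
  econ <- .require_econ(ps)
  days <- ps$settings$days_per_cycle
  wage <- .blended_wage(econ)
  tasks <- setdiff(task_labels(), "shl5_treatment")

  freq <- econ$task_freq_per_day[[strategy]][tasks, cs]
  labour <- sum(freq * days * econ$task_minutes[tasks, group] *
                  econ$staff_per_task[tasks, group]) * wage

  n_daily <- econ$products$daily_count[[strategy]][cs]
  absorbent <- n_daily * days * econ$products$price_per_piece[[strategy]][cs]
  hygiene <- econ$task_freq_per_day[[strategy]]["product_change", cs] * days *
    econ$hygiene_cost_per_application[[strategy]]
  disposal <- n_daily * days * econ$products$dry_weight_kg[cs] *
    econ$disposal_tariff_per_kg

  rates <- .event_rate_matrix(ps, strategy)[, group]
  consequences <- sum(rates[event_labels()] * econ$event_costs[event_labels()])

  p_shl5 <- ps$shl_given_cs[[strategy]][cs, "SHL5"]
  apps <- econ$task_freq_per_day[[strategy]]["product_change", cs] *
    econ$shl5_treatment$duration_days
  shl5 <- p_shl5 * apps *
    (econ$task_minutes["shl5_treatment", group] *
       econ$staff_per_task["shl5_treatment", group] * wage +
       econ$shl5_treatment$unit_cost_per_application)

  technology <- econ$technology_cost_per_person_year[[strategy]] *
    ps$settings$cycle_length

  out <- c(technology = unname(technology), labour = unname(labour),
           absorbent_products = unname(absorbent), hygiene = unname(hygiene),
           disposal = unname(disposal), care_consequences = unname(consequences),
           shl5_treatment = unname(shl5))
  c(out, total = sum(out))
}

# category x alive-state matrix of per-cycle costs (cost streams are
# time-constant, so this is computed once per accumulation)
.state_cost_matrix <- function(ps, strategy) {
  ss <- state_space(ps$settings$included_groups)
  vapply(seq_len(ss$n_alive), function(i)
    cycle_cost(ps, strategy, ss$states$group[i], ss$states$cs[i]),
    numeric(length(cost_categories()) + 1))
}

#' Accumulate discounted costs over a trajectory
#'
#' Occupancy-weighted, half-cycle-corrected, discounted sum of the per-cycle
#' state costs, per category. Costs are expressed per modelled resident in
#' the fixture's currency and price year. The per-cycle cost of a state is
#' divided by the cycle length inside the accumulator's value-per-year
#' convention, so totals are plain currency amounts.
#'
#' @inheritParams accumulate_effects
#' @return Object of class `tcc_costs`: named numeric over the seven cost
#'   categories plus `total` (equal to their sum), with attributes
#'   `strategy` and `synthetic` (whether the economics block is the
#'   placeholder fixture).
#' @export
accumulate_costs <- function(traj, ps, strategy = traj$strategy) {
  .check_fingerprint(traj, ps)
  cm <- .state_cost_matrix(ps, strategy)
  r <- ps$settings$discount_rate
  per_cat <- vapply(cost_categories(), function(cat)
    .accumulate(traj, cm[cat, ] / ps$settings$cycle_length, r), numeric(1))
  structure(c(per_cat, total = sum(per_cat)), class = "tcc_costs",
            strategy = strategy, synthetic = isTRUE(ps$economics$synthetic))
}

#' @export
print.tcc_costs <- function(x, ...) {
  cat(sprintf("<tcc_costs> %s%s\n", attr(x, "strategy"),
              if (isTRUE(attr(x, "synthetic"))) "  [synthetic economics fixture]" else ""))
  print(round(unclass(x), 2))
  invisible(x)
}

#' Accumulate physical care hours and disposal mass
#'
#' Undiscounted, half-cycle-corrected totals per group over the lifetime
#' horizon: staff time on continence care tasks (task frequency x minutes x
#' staff, plus severe-skin treatment applications) in hours, and absorbent
#' product disposal mass (daily count x dry weight) in kg. Being physical
#' quantities, they are invariant to the discount rate by construction.
#'
#' @inheritParams accumulate_effects
#' @return Object of class `tcc_resources`: list with per-group named
#'   vectors `care_hours` and `disposal_kg`, plus `total_hours`, `total_kg`.
#' @export
accumulate_resources <- function(traj, ps, strategy = traj$strategy) {
  .check_fingerprint(traj, ps)
  econ <- .require_econ(ps)
  ss <- traj$state_space
  days <- ps$settings$days_per_cycle
  tasks <- setdiff(task_labels(), "shl5_treatment")

  per_state <- vapply(seq_len(ss$n_alive), function(i) {
    g <- ss$states$group[i]; cs <- ss$states$cs[i]
    mins <- sum(econ$task_freq_per_day[[strategy]][tasks, cs] * days *
                  econ$task_minutes[tasks, g] * econ$staff_per_task[tasks, g])
    apps <- ps$shl_given_cs[[strategy]][cs, "SHL5"] *
      econ$task_freq_per_day[[strategy]]["product_change", cs] *
      econ$shl5_treatment$duration_days
    mins <- mins + apps * econ$task_minutes["shl5_treatment", g] *
      econ$staff_per_task["shl5_treatment", g]
    kg <- econ$products$daily_count[[strategy]][cs] * days *
      econ$products$dry_weight_kg[cs]
    c(hours = unname(mins) / 60, kg = unname(kg))
  }, numeric(2))

  by_group <- function(v) {
    per_year <- v / ps$settings$cycle_length
    acc <- vapply(seq_len(ss$n_alive), function(i) {
      x <- rep(0, ss$n_alive); x[i] <- per_year[i]
      .accumulate(traj, x, 0)
    }, numeric(1))
    tapply(acc, ss$states$group, sum)[ps$settings$included_groups]
  }
  hours <- by_group(per_state["hours", ])
  kg <- by_group(per_state["kg", ])
  structure(list(care_hours = hours, disposal_kg = kg,
                 total_hours = sum(hours), total_kg = sum(kg),
                 strategy = strategy), class = "tcc_resources")
}

#' @export
print.tcc_resources <- function(x, ...) {
  cat(sprintf("<tcc_resources> %s: %.0f care hours, %.0f kg disposed\n",
              x$strategy, x$total_hours, x$total_kg))
  invisible(x)
}
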