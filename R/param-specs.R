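# Flat addressing of scalar parameters + default uncertainty specs ----------
#
# Scalar parameters are addressed by dotted ids ("utilities.d_cs.CS3",
# "event_rates.dht.uti", "econ.task_freq.conventional.product_change.CS2", ...)
# so one-way sensitivity analysis and the PSA can get/set them generically.
# Stochastic rows (initial distributions and transition tables) are varied
# jointly as Dirichlet rows in the PSA and are not part of the scalar table.

#' Read or replace a scalar model parameter by id
#'
#' @param ps A [parameter_set()].
#' @param id Dotted parameter id as produced by [default_param_specs()].
#' @param value Replacement value.
#' @return `get_param` returns the scalar; `set_param` the modified set.
#' @keywords internal
#' @export
get_param <- function(ps, id) {
  p <- strsplit(id, ".", fixed = TRUE)[[1]]
  switch(p[1],
    settings = ps$settings[[p[2]]],
    mortality = ps$mortality$mean[p[2], p[3]],
    utilities = ps$utilities[[p[2]]][[p[3]]],
    event_rates = ps$event_rates[[p[2]]][[p[3]]],
    econ = {
      e <- ps$economics
      switch(p[2],
        task_minutes = e$task_minutes[p[3], p[4]],
        staff_per_task = e$staff_per_task[p[3], p[4]],
        task_freq = e$task_freq_per_day[[p[3]]][p[4], p[5]],
        price = e$products$price_per_piece[[p[3]]][p[4]],
        daily_count = e$products$daily_count[[p[3]]][p[4]],
        dry_weight = e$products$dry_weight_kg[p[3]],
        hygiene = e$hygiene_cost_per_application[[p[3]]],
        event_costs = e$event_costs[[p[3]]],
        technology = e$technology_cost_per_person_year[[p[3]]],
        shl5_unit_cost = e$shl5_treatment$unit_cost_per_application,
        e[[p[2]]])
    },
    stop("unknown parameter id: ", id, call. = FALSE))
}

#' @rdname get_param
#' @export
set_param <- function(ps, id, value) {
  p <- strsplit(id, ".", fixed = TRUE)[[1]]
  switch(p[1],
    settings = ps$settings[[p[2]]] <- value,
    mortality = ps$mortality$mean[p[2], p[3]] <- value,
    utilities = ps$utilities[[p[2]]][[p[3]]] <- value,
    event_rates = ps$event_rates[[p[2]]][[p[3]]] <- value,
    econ = {
      switch(p[2],
        task_minutes = ps$economics$task_minutes[p[3], p[4]] <- value,
        staff_per_task = ps$economics$staff_per_task[p[3], p[4]] <- value,
        task_freq = ps$economics$task_freq_per_day[[p[3]]][p[4], p[5]] <- value,
        price = ps$economics$products$price_per_piece[[p[3]]][p[4]] <- value,
        daily_count = ps$economics$products$daily_count[[p[3]]][p[4]] <- value,
        dry_weight = ps$economics$products$dry_weight_kg[p[3]] <- value,
        hygiene = ps$economics$hygiene_cost_per_application[[p[3]]] <- value,
        event_costs = ps$economics$event_costs[[p[3]]] <- value,
        technology = ps$economics$technology_cost_per_person_year[[p[3]]] <- value,
        shl5_unit_cost = ps$economics$shl5_treatment$unit_cost_per_application <- value,
        ps$economics[[p[2]]] <- value)
    },
    stop("unknown parameter id: ", id, call. = FALSE))
  ps
}

#' Default uncertainty specification for every scalar parameter
#'
#' Builds the table of scalar parameters with their distribution family,
#' mean, standard error and one-way bounds:
#' * mortality probabilities: Normal with the standard error implied by the
#'   tabulated 95% CI, bounds at the CI limits; shared between arms;
#' * group baseline utilities and group/care-stage/skin-health decrement
#'   magnitudes: Normal, SE 20% of the mean, truncated to the admissible
#'   range; shared;
#' * adverse-event decrements and per-cycle event probabilities:
#'   moment-matched Beta, SE 20% of the mean (event rates are arm-specific);
#' * start age: Normal with SE 1 year (the order of a trial cohort's
#'   standard error of the mean age);
#' * all economics quantities (wages, task minutes, frequencies, product
#'   prices/counts/weights, unit costs, technology price): moment-matched
#'   Gamma, SE 20% of the mean.
#'
#' Held fixed, and therefore excluded or flagged: cycle length, horizon,
#' discount rate, the zero decrements of CS1 and SHL1, staffing counts for
#' G2-G3, and any parameter with mean zero.
#'
#' @param ps A [parameter_set()].
#' @return Data frame with columns `id`, `family`, `mean`, `se`, `lo`, `hi`,
#'   `shared`, `fixed`, `range_lo`, `range_hi`.
#' @export
default_param_specs <- function(ps) {
  rows <- list()
  add <- function(id, family, mean, se = 0.2 * mean, lo = NULL, hi = NULL,
                  shared = TRUE, fixed = FALSE, range = c(-Inf, Inf)) {
    if (mean == 0 || se == 0) fixed <- TRUE
    if (is.null(lo)) lo <- max(mean - 1.96 * se, range[1])
    if (is.null(hi)) hi <- min(mean + 1.96 * se, range[2])
    rows[[length(rows) + 1]] <<- data.frame(
      id = id, family = family, mean = mean, se = se, lo = lo, hi = hi,
      shared = shared, fixed = fixed, range_lo = range[1], range_hi = range[2])
  }

  add("settings.start_age", "normal", ps$settings$start_age, se = 1,
      range = c(65, 110))

  for (band in rownames(ps$mortality$mean)) {
    for (cls in colnames(ps$mortality$mean)) {
      m <- ps$mortality$mean[band, cls]
      ci <- c(ps$mortality$lo[band, cls], ps$mortality$hi[band, cls])
      add(paste("mortality", band, cls, sep = "."), "normal", m,
          se = (ci[2] - ci[1]) / (2 * 1.96), lo = ci[1], hi = ci[2],
          range = c(0, 1))
    }
  }

  for (g in names(ps$utilities$group)) {
    add(paste0("utilities.group.", g), "normal", ps$utilities$group[[g]],
        range = c(0, 1))
  }
  for (cs in care_stages()) {
    add(paste0("utilities.d_cs.", cs), "normal", ps$utilities$d_cs[[cs]],
        fixed = cs == "CS1", range = c(0, 1))
  }
  for (l in shl_levels()) {
    add(paste0("utilities.d_shl.", l), "normal", ps$utilities$d_shl[[l]],
        fixed = l == "SHL1", range = c(0, 1))
  }
  for (e in event_labels()) {
    add(paste0("utilities.d_event.", e), "beta", ps$utilities$d_event[[e]],
        range = c(0, 1))
  }
  for (arm in param_arms(ps)) {
    for (e in names(ps$event_rates[[arm]])) {
      add(paste("event_rates", arm, e, sep = "."), "beta",
          ps$event_rates[[arm]][[e]], shared = FALSE, range = c(0, 1))
    }
  }

  if (!is.null(ps$economics)) {
    econ <- ps$economics
    add("econ.wage_formal_per_min", "gamma", econ$wage_formal_per_min, range = c(0, Inf))
    add("econ.wage_informal_per_min", "gamma", econ$wage_informal_per_min, range = c(0, Inf))
    add("econ.disposal_tariff_per_kg", "gamma", econ$disposal_tariff_per_kg, range = c(0, Inf))
    for (task in rownames(econ$task_minutes)) {
      for (g in colnames(econ$task_minutes)) {
        add(paste("econ.task_minutes", task, g, sep = "."), "gamma",
            econ$task_minutes[task, g], range = c(0, Inf))
        add(paste("econ.staff_per_task", task, g, sep = "."), "gamma",
            econ$staff_per_task[task, g], fixed = g %in% c("G2", "G3"),
            range = c(0, Inf))
      }
    }
    for (arm in names(econ$task_freq_per_day)) {
      for (task in rownames(econ$task_freq_per_day[[arm]])) {
        for (cs in care_stages()) {
          add(paste("econ.task_freq", arm, task, cs, sep = "."), "gamma",
              econ$task_freq_per_day[[arm]][task, cs], shared = FALSE,
              range = c(0, Inf))
        }
      }
      for (cs in care_stages()) {
        add(paste("econ.price", arm, cs, sep = "."), "gamma",
            econ$products$price_per_piece[[arm]][cs], shared = FALSE, range = c(0, Inf))
        add(paste("econ.daily_count", arm, cs, sep = "."), "gamma",
            econ$products$daily_count[[arm]][cs], shared = FALSE, range = c(0, Inf))
      }
      add(paste("econ.hygiene", arm, sep = "."), "gamma",
          econ$hygiene_cost_per_application[[arm]], shared = FALSE, range = c(0, Inf))
      add(paste("econ.technology", arm, sep = "."), "gamma",
          econ$technology_cost_per_person_year[[arm]], shared = FALSE, range = c(0, Inf))
    }
    for (cs in care_stages()) {
      add(paste("econ.dry_weight", cs, sep = "."), "gamma",
          econ$products$dry_weight_kg[cs], range = c(0, Inf))
    }
    for (e in names(econ$event_costs)) {
      add(paste("econ.event_costs", e, sep = "."), "gamma",
          econ$event_costs[[e]], range = c(0, Inf))
    }
    add("econ.shl5_unit_cost", "gamma", econ$shl5_treatment$unit_cost_per_application,
        range = c(0, Inf))
  }

  do.call(rbind, rows)
}
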