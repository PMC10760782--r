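# Cohort transition engine --------------------------------------------------
#
# The Markov state space is (care-need group x care stage) for the included
# groups plus one absorbing dead state, ordered group-major / care-stage-minor
# with dead last. Skin health is deliberately NOT part of the state: each
# cycle, survivors in a care stage are assigned a skin-health level from a
# strategy-specific mixture, so skin health affects outcomes but never the
# dynamics, shrinking the state space from 90 to 16 states for G2-G6.

#' Construct the model state space
#'
#' @param included_groups Character vector of group labels, a subset of
#'   [need_groups()].
#' @return Object of class `tcc_state_space`: list with `states` (data frame
#'   of `group`, `cs` for the alive states in group-major order), `labels`
#'   (alive-state labels plus `"dead"`), `n_alive`, and `n`.
#' @export
state_space <- function(included_groups = paste0("G", 2:6)) {
  stopifnot(all(included_groups %in% need_groups()))
  states <- expand.grid(cs = care_stages(), group = included_groups,
                        stringsAsFactors = FALSE)[, c("group", "cs")]
  labels <- paste(states$group, states$cs, sep = ":")
  structure(list(states = states, labels = c(labels, "dead"),
                 n_alive = nrow(states), n = nrow(states) + 1L),
            class = "tcc_state_space")
}

#' Per-cycle probability of death
#'
#' Looks up the mortality table row for the age band containing `age`
#' (bands `[65,75)`, `[75,85)`, `[85,95)`, `[95,Inf)`) and the group class
#' (`G1`, `G4`, or the shared class covering G2, G3, G5 and G6).
#'
#' @param ps A [parameter_set()].
#' @param group Group label.
#' @param age Age in years, at least 65.
#' @param which Which table to read: `"mean"` (default), `"lo"` or `"hi"`.
#' @return Probability of death per cycle.
#' @examples
#' ps <- load_case_study()
#' mortality_prob(ps, "G4", 86)    # 0.068
#' @export
mortality_prob <- function(ps, group, age, which = "mean") {
  if (any(age < 65)) stop("mortality table starts at age 65", call. = FALSE)
  band <- findInterval(age, age_band_breaks())
  ps$mortality[[which]][band, mortality_class_of(group)]
}

# care-stage shift kernel for group-movers: p_stay in place, p_worsen to the
# next worse stage; the worst stage absorbs
.shift_kernel <- function(cs_shift) {
  k <- diag(3) * cs_shift$p_stay
  worse <- pmin(1:3 + 1L, 3L)
  for (i in 1:3) k[i, worse[i]] <- k[i, worse[i]] + cs_shift$p_worsen
  k
}

#' Build the one-cycle transition matrix
#'
#' Composes, for a given cohort age, (i) survival against the age-band and
#' group-class mortality, (ii) the group-transition row, and (iii) the
#' care-stage update, into one row-stochastic matrix over the alive states
#' plus the absorbing dead state.
#'
#' Two compositions of the care-stage update are supported, isolated here so
#' both can be tested:
#' \describe{
#'   \item{`"independent"` (package default)}{every survivor's care stage
#'     moves by the strategy's care-stage transition row, independently of
#'     whether the group changed. This product structure reproduces the case
#'     study's published cohort movement.}
#'   \item{`"shift"`}{group-stayers use the strategy's care-stage row;
#'     group-movers instead stay in their care stage with probability
#'     `cs_shift$p_stay` (0.10) and move to the next worse stage with
#'     `cs_shift$p_worsen` (0.90), the worst stage absorbing — the literal
#'     reading of the movers-deteriorate assumption.}
#' }
#'
#' @inheritParams mortality_prob
#' @param strategy Strategy label.
#' @param age Cohort age in years at the start of the cycle.
#' @param group_change_cs `"independent"` or `"shift"`; defaults to the
#'   parameter set's `settings$group_change_cs`.
#' @return A `(n_alive + 1)` square row-stochastic matrix; rows sum to 1
#'   within 1e-12 and the dead row is the identity.
#' @export
build_cycle_matrix <- function(ps, strategy, age, group_change_cs = NULL) {
  group_change_cs <- group_change_cs %||% ps$settings$group_change_cs
  ss <- state_space(ps$settings$included_groups)
  groups <- ps$settings$included_groups
  ng <- length(groups)
  gt <- as.matrix(ps$group_transition)[groups, groups, drop = FALSE]
  cst <- ps$cs_transition[[strategy]]
  if (is.null(cst)) stop("no care-stage transitions for strategy ", strategy, call. = FALSE)

  if (group_change_cs == "independent") {
    alive <- gt %x% cst
  } else if (group_change_cs == "shift") {
    shift <- .shift_kernel(ps$cs_shift)
    alive <- matrix(0, ss$n_alive, ss$n_alive)
    for (gi in seq_len(ng)) for (gj in seq_len(ng)) {
      if (gt[gi, gj] == 0) next
      blk <- if (gi == gj) cst else shift
      alive[(gi - 1) * 3 + 1:3, (gj - 1) * 3 + 1:3] <- gt[gi, gj] * blk
    }
  } else {
    stop("unknown group_change_cs composition: ", group_change_cs, call. = FALSE)
  }

  m <- mortality_prob(ps, ss$states$group, age)
  M <- matrix(0, ss$n, ss$n, dimnames = list(ss$labels, ss$labels))
  M[seq_len(ss$n_alive), seq_len(ss$n_alive)] <- (1 - m) * alive
  M[seq_len(ss$n_alive), ss$n] <- m
  M[ss$n, ss$n] <- 1
  stopifnot(max(abs(rowSums(M) - 1)) < 1e-12)
  M
}

#' Create a cohort state
#'
#' @param occupancy Non-negative probability mass per state (alive states
#'   plus dead), summing to 1 within 1e-9.
#' @param age Cohort age in years.
#' @return Object of class `tcc_cohort_state`.
#' @export
cohort_state <- function(occupancy, age) {
  if (any(occupancy < -1e-12) || abs(sum(occupancy) - 1) > 1e-9) {
    stop("occupancy must be non-negative and sum to 1 within 1e-9", call. = FALSE)
  }
  structure(list(occupancy = occupancy, age = age), class = "tcc_cohort_state")
}

#' Advance a cohort state by one cycle
#'
#' @param state A [cohort_state()].
#' @param M A one-cycle transition matrix from [build_cycle_matrix()].
#' @param cycle_length Cycle length in years (the age increment).
#' @return The cohort state after one cycle; mass is conserved within 1e-9.
#' @export
propagate <- function(state, M, cycle_length = 1 / 6) {
  if (length(state$occupancy) != nrow(M)) {
    stop("dimension mismatch between cohort state and transition matrix", call. = FALSE)
  }
  occ <- drop(state$occupancy %*% M)
  if (abs(sum(occ) - 1) > 1e-9) stop("mass not conserved by transition matrix", call. = FALSE)
  cohort_state(occ, state$age + cycle_length)
}

#' Run the cohort to extinction
#'
#' Starts from the product of the initial group and care-stage margins
#' (assumed independent), then repeatedly applies [build_cycle_matrix()] —
#' rebuilt whenever the cohort crosses a mortality age band — until survival
#' drops below `settings$survival_epsilon` or `settings$max_cycles` is
#' reached (in which case a non-convergence warning is recorded on the
#' trajectory).
#'
#' @inheritParams build_cycle_matrix
#' @return Object of class `tcc_trajectory`: `occupancy` (matrix, one row per
#'   cycle 0..T over the state space), `ages`, `survival`, `strategy`,
#'   `state_space`, `cycle_length`, `converged`, and the parameter-set
#'   `fingerprint` the outcome accumulators verify against.
#' @examples
#' ps <- load_case_study()
#' traj <- run_cohort(ps, "dht")
#' surviving_cs_shares(traj, cycle = 12)
#' @export
run_cohort <- function(ps, strategy, group_change_cs = NULL) {
  s <- ps$settings
  ss <- state_space(s$included_groups)
  init <- as.vector(outer(ps$initial$cs[care_stages()],
                          ps$initial$group[s$included_groups]))
  occ <- c(init / sum(init), 0)

  occupancy <- matrix(NA_real_, s$max_cycles + 1, ss$n,
                      dimnames = list(NULL, ss$labels))
  occupancy[1, ] <- occ
  ages <- s$start_age + (0:s$max_cycles) * s$cycle_length

  M <- NULL
  band <- -1L
  t <- 0L
  while (t < s$max_cycles && (1 - occ[ss$n]) >= s$survival_epsilon) {
    b <- findInterval(ages[t + 1], age_band_breaks())
    if (b != band) {
      M <- build_cycle_matrix(ps, strategy, ages[t + 1], group_change_cs)
      band <- b
    }
    occ <- drop(occ %*% M)
    t <- t + 1L
    occupancy[t + 1, ] <- occ
  }
  converged <- (1 - occ[ss$n]) < s$survival_epsilon
  if (!converged) {
    warning("cohort not extinct at max_cycles = ", s$max_cycles,
            "; survival ", signif(1 - occ[ss$n], 3), call. = FALSE)
  }
  occupancy <- occupancy[seq_len(t + 1), , drop = FALSE]
  structure(list(occupancy = occupancy, ages = ages[seq_len(t + 1)],
                 survival = 1 - occupancy[, ss$n], strategy = strategy,
                 state_space = ss, cycle_length = s$cycle_length,
                 discount_rate = s$discount_rate, converged = converged,
                 fingerprint = param_fingerprint(ps)),
            class = "tcc_trajectory")
}

#' @export
print.tcc_trajectory <- function(x, ...) {
  cat(sprintf("<tcc_trajectory> %s: %d cycles, survival %.2g -> %.2g%s\n",
              x$strategy, nrow(x$occupancy) - 1, x$survival[1],
              x$survival[length(x$survival)],
              if (x$converged) "" else " (not extinct)"))
  invisible(x)
}

#' Tidy per-cycle export of a trajectory
#'
#' @param x A `tcc_trajectory`.
#' @param ... Unused.
#' @return Data frame with columns `cycle`, `state`, `group`, `cs`, `mass`,
#'   `age`, `survival` — one row per cycle and state, suitable for
#'   cohort-movement plots.
#' @export
as.data.frame.tcc_trajectory <- function(x, ...) {
  ss <- x$state_space
  n_cyc <- nrow(x$occupancy)
  data.frame(
    cycle = rep(0:(n_cyc - 1), times = ss$n),
    state = rep(ss$labels, each = n_cyc),
    group = rep(c(ss$states$group, NA), each = n_cyc),
    cs = rep(c(ss$states$cs, NA), each = n_cyc),
    mass = as.vector(x$occupancy),
    age = rep(x$ages, times = ss$n),
    survival = rep(x$survival, times = ss$n),
    row.names = NULL)
}

#' Care-stage shares among survivors at a cycle
#'
#' @param traj A `tcc_trajectory`.
#' @param cycle Cycle index (0 = baseline).
#' @return Named probability vector over `CS1`-`CS3`, conditional on being
#'   alive at that cycle.
#' @export
surviving_cs_shares <- function(traj, cycle) {
  occ <- traj$occupancy[cycle + 1, seq_len(traj$state_space$n_alive)]
  shares <- tapply(occ, traj$state_space$states$cs, sum)[care_stages()]
  shares / sum(shares)
}

#' Skin-health shares among survivors at a cycle
#'
#' Weights the surviving care-stage distribution by the strategy's per-cycle
#' skin-health mixture.
#'
#' @inheritParams surviving_cs_shares
#' @param ps The [parameter_set()] the trajectory was run under.
#' @param strategy Strategy label; defaults to the trajectory's.
#' @return Named probability vector over `SHL1`-`SHL5`.
#' @export
surviving_shl_shares <- function(traj, ps, cycle, strategy = traj$strategy) {
  cs <- surviving_cs_shares(traj, cycle)
  drop(cs %*% ps$shl_given_cs[[strategy]])
}

#' Per-cycle skin-health mixture for a care stage
#'
#' @inheritParams build_cycle_matrix
#' @param cs Care-stage label.
#' @return Named probability vector over `SHL1`-`SHL5`; sums to 1.
#' @export
shl_distribution <- function(ps, strategy, cs) {
  ps$shl_given_cs[[strategy]][cs, ]
}
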