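# Deterministic cost-effectiveness comparison -------------------------------

#' Deterministic incremental cost-effectiveness analysis
#'
#' Runs both strategy arms to cohort extinction, accumulates effects (and,
#' when an economics block is populated, costs), and classifies the
#' incremental result: the technology is *dominant* when it is cheaper and
#' more effective, *dominated* when costlier and less effective, otherwise
#' the ICER `delta_cost / delta_qaly` is reported. Increments are
#' `dht - conventional`.
#'
#' @param ps A two-arm [parameter_set()] providing the conventional arm (and
#'   the DHT arm when `ps_dht` is omitted).
#' @param ps_dht Optional separate parameter set for the DHT arm; defaults
#'   to `ps`, which keeps all shared inputs identical across arms.
#' @param costs `TRUE`/`FALSE` to force a full-cost or effect-only
#'   comparison; defaults to full-cost when the economics block is present.
#' @return Object of class `tcc_ce`: `delta_cost`, `delta_qaly`, `icer`,
#'   `label` (`"dominant"`, `"dominated"`, `"icer"`, `"null"`, or
#'   `"effect_only"`), plus per-arm `qaly` and `cost` results.
#' @examples
#' ce <- run_deterministic(load_case_study())
#' ce$delta_qaly
#' @export
run_deterministic <- function(ps, ps_dht = NULL, costs = NULL) {
  ps_dht <- ps_dht %||% ps
  if (is.null(costs)) costs <- !is.null(ps$economics) && !is.null(ps_dht$economics)

  traj_c <- run_cohort(ps, "conventional")
  traj_d <- run_cohort(ps_dht, "dht")
  q_c <- accumulate_effects(traj_c, ps)
  q_d <- accumulate_effects(traj_d, ps_dht)
  delta_qaly <- q_d$total_qalys - q_c$total_qalys

  cost <- list(conventional = NULL, dht = NULL)
  delta_cost <- NA_real_
  if (costs) {
    cost$conventional <- accumulate_costs(traj_c, ps)
    cost$dht <- accumulate_costs(traj_d, ps_dht)
    delta_cost <- unname(cost$dht["total"] - cost$conventional["total"])
  }

  label <- if (!costs) "effect_only"
    else if (delta_cost < 0 && delta_qaly > 0) "dominant"
    else if (delta_cost > 0 && delta_qaly < 0) "dominated"
    else if (delta_cost == 0 && delta_qaly == 0) "null"
    else "icer"
  icer <- if (label == "icer") delta_cost / delta_qaly else NA_real_

  structure(list(delta_cost = delta_cost, delta_qaly = delta_qaly,
                 icer = icer, label = label,
                 qaly = list(conventional = q_c, dht = q_d), cost = cost),
            class = "tcc_ce")
}

#' @export
print.tcc_ce <- function(x, ...) {
  cat("<tcc_ce> DHT vs conventional care\n")
  cat(sprintf("  incremental QALYs: %+.4f\n", x$delta_qaly))
  if (!is.na(x$delta_cost)) {
    cat(sprintf("  incremental cost:  %+.0f\n", x$delta_cost))
  }
  cat("  result:", switch(x$label,
    dominant = "DHT dominant (cheaper, more effective)",
    dominated = "DHT dominated (costlier, less effective)",
    null = "no incremental difference",
    effect_only = "effect-only comparison (no economics block)",
    icer = sprintf("ICER %.0f per QALY", x$icer)), "\n")
  invisible(x)
}

# One-way (tornado) sensitivity analysis -------------------------------------

#' One-way sensitivity analysis
#'
#' Re-runs the deterministic comparison with each non-fixed scalar parameter
#' set to its lower and upper bound (the reported 95% CI where available,
#' otherwise `mean +/- 1.96 se` with the 20%-of-mean default SE), holding
#' everything else at base. Shared parameters are moved in both arms at
#' once; arm-specific parameters per arm. Entries are sorted by the width of
#' the incremental-effect range (falling back to the cost range when
#' effects are untouched), ready for tornado plotting.
#'
#' @inheritParams run_deterministic
#' @param specs Spec table from [default_param_specs()]; fixed rows are
#'   skipped with a log note.
#' @param verbose Print a note for each skipped (fixed) parameter.
#' @return Data frame of class `tcc_owsa`: one row per parameter with the
#'   bound values and the incremental cost/effect at each bound.
#' @export
run_owsa <- function(ps, specs = default_param_specs(ps), costs = NULL,
                     verbose = FALSE) {
  base <- run_deterministic(ps, costs = costs)
  vary <- specs[!specs$fixed, , drop = FALSE]
  if (verbose && any(specs$fixed)) {
    message("holding fixed: ", paste(specs$id[specs$fixed], collapse = ", "))
  }
  out <- lapply(seq_len(nrow(vary)), function(i) {
    row <- vary[i, ]
    at <- function(value) {
      run_deterministic(set_param(ps, row$id, value), costs = costs)
    }
    lo <- at(row$lo)
    hi <- at(row$hi)
    data.frame(id = row$id, lo = row$lo, hi = row$hi,
               delta_qaly_lo = lo$delta_qaly, delta_qaly_hi = hi$delta_qaly,
               delta_cost_lo = lo$delta_cost, delta_cost_hi = hi$delta_cost,
               qaly_range = abs(hi$delta_qaly - lo$delta_qaly),
               cost_range = abs(hi$delta_cost - lo$delta_cost))
  })
  out <- do.call(rbind, out)
  key <- ifelse(is.na(out$cost_range), 0, out$cost_range) +
    out$qaly_range * 1e5   # effects on a comparable monetary-ish scale
  out <- out[order(-key), ]
  attr(out, "base") <- base
  class(out) <- c("tcc_owsa", "data.frame")
  out
}

# Probabilistic sensitivity analysis ----------------------------------------

#' Draw one probabilistic parameter set
#'
#' Draws every non-fixed parameter from its uncertainty distribution:
#' moment-matched Beta for probabilities, moment-matched Gamma for costs and
#' resource use, truncated Normal for age, mortality and utility decrements,
#' and Dirichlet rows for the initial distributions and all transition
#' tables (group, care stage, skin health). Shared parameters — mortality,
#' group transitions, initial distributions, utilities — take a single draw
#' applied to both arms; arm-specific tables are drawn independently per
#' arm. Draws use the current RNG state; seed via `set.seed()` or
#' [run_psa()] for reproducibility.
#'
#' @inheritParams run_owsa
#' @param se_scale Multiplier on every standard error (and Dirichlet
#'   spread); `0` collapses all draws onto the base values.
#' @return A drawn [parameter_set()]-shaped object (revalidated lazily by
#'   use; construction-level invariants are preserved by the families).
#' @export
psa_draw <- function(ps, specs = default_param_specs(ps), se_scale = 1) {
  drawn <- ps
  if (se_scale > 0) {
    # plain-vector access: this loop dominates the PSA run time
    ids <- specs$id; fam <- specs$family; mu <- specs$mean
    se <- specs$se * se_scale; fixed <- specs$fixed
    rlo <- specs$range_lo; rhi <- specs$range_hi
    for (i in seq_along(ids)) {
      if (fixed[i]) next
      spec <- list(family = fam[i], mean = mu[i], se = se[i],
                   range = c(rlo[i], rhi[i]))
      drawn <- set_param(drawn, ids[i], draw_scalar(spec))
    }
    dir_row <- function(p) {
      if (se_scale == 1) rdirichlet_row(p)
      else p + se_scale * (rdirichlet_row(p) - p)
    }
    gt <- drawn$group_transition
    for (g in rownames(gt)) gt[g, ] <- dir_row(gt[g, ])
    drawn$group_transition <- gt
    drawn$initial$group <- dir_row(drawn$initial$group)
    drawn$initial$cs <- dir_row(drawn$initial$cs)
    if (!is.null(drawn$initial$shl)) drawn$initial$shl <- dir_row(drawn$initial$shl)
    for (arm in param_arms(drawn)) {
      for (cs in care_stages()) {
        drawn$cs_transition[[arm]][cs, ] <- dir_row(drawn$cs_transition[[arm]][cs, ])
        drawn$shl_given_cs[[arm]][cs, ] <- dir_row(drawn$shl_given_cs[[arm]][cs, ])
      }
    }
  }
  drawn
}

#' Run the probabilistic sensitivity analysis
#'
#' `n_iter` independent [psa_draw()] evaluations of the deterministic
#' comparison, storing every incremental (cost, QALY) pair. Quadrant shares
#' summarise the cost-effectiveness plane: `se` (more effective, cheaper:
#' the technology dominates), `ne` (more effective, costlier), `sw` (less
#' effective, cheaper), `nw` (less effective, costlier: dominated).
#'
#' @inheritParams psa_draw
#' @param n_iter Number of iterations (default 5000).
#' @param seed Integer seed; the whole run is reproducible given it.
#' @return Object of class `tcc_psa`: `samples` (data frame `iter`,
#'   `delta_cost`, `delta_qaly`), `means`, `quadrant_shares`, `n_iter`,
#'   `seed`, `costs`.
#' @export
run_psa <- function(ps, n_iter = 5000, seed = 1,
                    specs = default_param_specs(ps), costs = NULL,
                    se_scale = 1) {
  stopifnot(n_iter >= 1)
  if (is.null(costs)) costs <- !is.null(ps$economics)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)

  dc <- de <- numeric(n_iter)
  for (i in seq_len(n_iter)) {
    drawn <- psa_draw(ps, specs, se_scale = se_scale)
    ce <- run_deterministic(drawn, costs = costs)
    dc[i] <- ce$delta_cost
    de[i] <- ce$delta_qaly
  }
  samples <- data.frame(iter = seq_len(n_iter), delta_cost = dc, delta_qaly = de)
  quad <- if (costs) {
    c(se = mean(de > 0 & dc < 0), ne = mean(de > 0 & dc >= 0),
      sw = mean(de <= 0 & dc < 0), nw = mean(de <= 0 & dc >= 0))
  } else c(se = NA_real_, ne = NA_real_, sw = NA_real_, nw = NA_real_)
  structure(list(samples = samples,
                 means = c(delta_cost = mean(dc), delta_qaly = mean(de)),
                 quadrant_shares = quad, n_iter = n_iter, seed = seed,
                 costs = costs),
            class = "tcc_psa")
}

#' @export
print.tcc_psa <- function(x, ...) {
  cat(sprintf("<tcc_psa> %d iterations (seed %d)\n", x$n_iter, x$seed))
  cat(sprintf("  mean incremental QALYs %.4f", x$means["delta_qaly"]))
  if (x$costs) {
    cat(sprintf(", mean incremental cost %.0f\n", x$means["delta_cost"]))
    cat("  CE-plane shares:",
        paste(sprintf("%s %.0f%%", names(x$quadrant_shares),
                      100 * x$quadrant_shares), collapse = ", "), "\n")
  } else cat(" (effect-only)\n")
  invisible(x)
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay threshold, the fraction of PSA samples with
#' non-negative net monetary benefit `lambda * delta_qaly - delta_cost`.
#' At `lambda = 0` this is the probability of cost savings.
#'
#' @param psa A [run_psa()] result with costs.
#' @param lambdas Willingness-to-pay grid in currency per QALY.
#' @return Data frame of class `tcc_ceac` with columns `lambda`, `prob`.
#' @export
ceac <- function(psa, lambdas = seq(0, 150000, by = 1000)) {
  if (!isTRUE(psa$costs)) stop("CEAC needs a PSA run with costs", call. = FALSE)
  s <- psa$samples
  prob <- vapply(lambdas, function(l)
    mean(l * s$delta_qaly - s$delta_cost >= 0), numeric(1))
  structure(data.frame(lambda = lambdas, prob = prob),
            class = c("tcc_ceac", "data.frame"))
}
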