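# Independent per-individual microsimulation oracle -------------------------
#
# Simulates n individuals with per-person pseudo-random draws under the same
# rules as the cohort engine but implemented independently (sampling, not
# matrix algebra). Returns state masses per cycle for comparison against the
# cohort propagation within Monte-Carlo error.

microsim_masses <- function(ps, strategy, n = 1e5, n_cycles = 12, seed = 99,
                            group_change_cs = NULL) {
  group_change_cs <- if (is.null(group_change_cs)) ps$settings$group_change_cs
                     else group_change_cs
  groups <- ps$settings$included_groups
  ng <- length(groups)
  set.seed(seed)

  g <- sample.int(ng, n, replace = TRUE, prob = ps$initial$group[groups])
  cs <- sample.int(3, n, replace = TRUE, prob = ps$initial$cs)
  alive <- rep(TRUE, n)
  age <- ps$settings$start_age

  sample_rows <- function(mat, idx) {
    # one categorical draw per individual from the row mat[idx[i], ]
    u <- stats::runif(length(idx))
    cum <- t(apply(mat, 1, cumsum))
    out <- integer(length(idx))
    for (r in sort(unique(idx))) {
      sel <- idx == r
      out[sel] <- findInterval(u[sel], cum[r, ], left.open = TRUE) + 1L
    }
    out
  }

  record <- matrix(0, n_cycles + 1, 3 * ng + 1)
  tally <- function(t) {
    idx <- ifelse(alive, (g - 1) * 3 + cs, 3 * ng + 1)
    record[t + 1, ] <<- tabulate(idx, nbins = 3 * ng + 1) / n
  }
  tally(0)

  for (t in seq_len(n_cycles)) {
    m <- vapply(seq_len(ng), function(gi)
      mortality_prob(ps, groups[gi], age), numeric(1))
    dies <- alive & (stats::runif(n) < m[g])
    alive <- alive & !dies

    if (any(alive)) {
      ia <- which(alive)
      g_new <- sample_rows(as.matrix(ps$group_transition)[groups, groups], g[ia])
      cst <- ps$cs_transition[[strategy]]
      if (group_change_cs == "independent") {
        cs_new <- sample_rows(cst, cs[ia])
      } else {
        moved <- g_new != g[ia]
        cs_new <- integer(length(ia))
        cs_new[!moved] <- sample_rows(cst, cs[ia][!moved])
        if (any(moved)) {
          stay <- stats::runif(sum(moved)) < ps$cs_shift$p_stay
          cs_new[moved] <- ifelse(stay, cs[ia][moved], pmin(cs[ia][moved] + 1L, 3L))
        }
      }
      g[ia] <- g_new
      cs[ia] <- cs_new
    }
    age <- age + ps$settings$cycle_length
    tally(t)
  }
  record
}
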