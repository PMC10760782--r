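# ParameterSet: every model input in one validated container ---------------

#' Construct a model parameter set
#'
#' Bundles every input the cohort engine, outcome accumulators and
#' sensitivity analyses need: cycle settings, initial distributions,
#' the group-transition matrix, per-cycle mortality by age band and group
#' class, strategy-specific care-stage transitions, skin-health mixtures and
#' adverse-event rates, utilities and utility decrements, and (optionally)
#' the economics block with unit costs and resource-use frequencies.
#'
#' Stochastic rows (group transitions, care-stage transitions, skin-health
#' mixtures, initial distributions) are renormalised on construction when
#' their sums deviate from 1 by no more than `settings$row_tol` — printed
#' source tables are rounded, so e.g. a row summing to 1.01 is accepted and
#' rescaled. Larger deviations are errors.
#'
#' Utility decrements are stored as non-negative magnitudes and subtracted
#' during utility computation.
#'
#' @param settings List: `cycle_length` (years, default 1/6), `discount_rate`
#'   (annual, default 0.05), `start_age` (years, default 86), `max_cycles`
#'   (default 240), `survival_epsilon` (default 1e-6), `included_groups`
#'   (default `G2`-`G6`), `group_change_cs` (`"independent"` or `"shift"`,
#'   see [build_cycle_matrix()]), `row_tol` (default 0.02),
#'   `days_per_cycle` (default 365 * cycle_length).
#' @param initial List of initial probability vectors `group`, `cs`, `shl`.
#' @param group_transition Row-stochastic matrix over the included groups;
#'   zero probability to any lower-indexed group (disability never improves).
#' @param mortality List of band-by-class matrices `mean`, and optionally
#'   `lo`/`hi` (95% CI) used for sensitivity analysis.
#' @param cs_transition Named list per strategy of 3x3 row-stochastic
#'   care-stage transition matrices.
#' @param shl_given_cs Named list per strategy of 3x5 matrices giving the
#'   per-cycle skin-health mixture for each care stage.
#' @param event_rates Named list per strategy: named numeric with entries
#'   `fracture_g2_g4`, `fracture_g5_g6`, `uti`, `constipation`, `pu1`-`pu4`
#'   (per-cycle probabilities).
#' @param utilities List: `group` (baseline utility per group, 0-1), `d_cs`
#'   (decrement magnitudes per care stage), `d_shl` (per skin-health level),
#'   `d_event` (per adverse event).
#' @param cs_shift List with `p_stay` and `p_worsen` governing the optional
#'   care-stage shift applied to group-movers under the `"shift"` composition.
#' @param economics Optional economics block (see
#'   [load_economics_synthetic()] for the field layout), or `NULL` for
#'   effect-only analyses.
#' @param meta Free-form metadata (label, currency, price year, provenance).
#'
#' @return An object of class `tcc_params`.
#' @seealso [validate_parameter_set()], [load_case_study()],
#'   [generate_synthetic_params()]
#' @export
parameter_set <- function(settings = list(), initial, group_transition, mortality,
                          cs_transition, shl_given_cs, event_rates, utilities,
                          cs_shift = list(p_stay = 0.1, p_worsen = 0.9),
                          economics = NULL, meta = list()) {
  defaults <- list(cycle_length = 1 / 6, discount_rate = 0.05, start_age = 86,
                   max_cycles = 240, survival_epsilon = 1e-6,
                   included_groups = paste0("G", 2:6),
                   group_change_cs = "independent", row_tol = 0.02,
                   days_per_cycle = NULL)
  settings <- modifyList(defaults, settings)
  if (is.null(settings$days_per_cycle)) {
    settings$days_per_cycle <- 365 * settings$cycle_length
  }

  tol <- settings$row_tol
  group_transition <- normalize_rows(group_transition, tol)
  cs_transition <- lapply(cs_transition, normalize_rows, tol = tol)
  shl_given_cs <- lapply(shl_given_cs, normalize_rows, tol = tol)
  initial$group <- drop(normalize_rows(rbind(initial$group), tol))
  initial$cs <- drop(normalize_rows(rbind(initial$cs), tol))
  if (!is.null(initial$shl)) initial$shl <- drop(normalize_rows(rbind(initial$shl), tol))

  ps <- structure(list(settings = settings, initial = initial,
                       group_transition = group_transition, mortality = mortality,
                       cs_shift = cs_shift, cs_transition = cs_transition,
                       shl_given_cs = shl_given_cs, event_rates = event_rates,
                       utilities = utilities, economics = economics, meta = meta),
                  class = "tcc_params")
  rep <- validate_parameter_set(ps)
  if (length(rep$errors)) {
    stop("invalid parameter set:\n  - ", paste(rep$errors, collapse = "\n  - "),
         call. = FALSE)
  }
  ps
}

#' Strategy arms present in a parameter set
#' @param ps A `tcc_params` object.
#' @return Character vector of strategy labels with populated tables.
#' @export
param_arms <- function(ps) names(ps$cs_transition)

#' Renormalise the rows of a probability table
#'
#' Printed source tables carry rounded probabilities, so rows may sum to
#' slightly more or less than 1. Rows within `tol` of 1 are divided by their
#' sum (making the table exactly row-stochastic, idempotently); rows further
#' away indicate a transcription error and raise a failure naming the row.
#'
#' @param rows Numeric matrix whose rows are probability vectors.
#' @param tol Maximum tolerated absolute deviation of a row sum from 1.
#' @return The matrix with exactly row-stochastic rows.
#' @examples
#' normalize_rows(rbind(c(0.38, 0.63, 0)))        # sums to 1.01 -> rescaled
#' @export
normalize_rows <- function(rows, tol = 0.02) {
  rows <- as.matrix(rows)
  s <- rowSums(rows)
  bad <- which(abs(s - 1) > tol + 1e-12)
  if (length(bad)) {
    lab <- if (!is.null(rownames(rows))) rownames(rows)[bad] else as.character(bad)
    stop(sprintf("row sum out of tolerance (tol = %g): %s (sum %s)", tol,
                 paste(lab, collapse = ", "),
                 paste(signif(s[bad], 6), collapse = ", ")), call. = FALSE)
  }
  rows / s
}

# internal: collect row-sum warnings without mutating
.row_sum_warnings <- function(rows, what, tol) {
  s <- rowSums(as.matrix(rows))
  off <- which(abs(s - 1) > 1e-9 & abs(s - 1) <= tol + 1e-12)
  if (!length(off)) return(character())
  lab <- if (!is.null(rownames(as.matrix(rows)))) rownames(as.matrix(rows))[off] else off
  sprintf("%s row %s sums to %.4g (renormalizable)", what, lab, s[off])
}

.prob_errors <- function(x, what) {
  x <- unlist(x)
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    sprintf("%s contains values outside [0, 1]", what)
  } else character()
}

#' Validate a parameter set
#'
#' Checks every structural invariant the cohort engine relies on and returns
#' a report rather than failing: probabilities in \[0, 1\], row sums within
#' tolerance of 1 (exact 1 is required of the stored tables; near-misses are
#' reported as renormalisable warnings), utilities in \[0, 1\], decrement
#' magnitudes and all economic quantities non-negative, and no
#' group-transition probability towards a lower-indexed (less dependent)
#' group. An empty `errors` field means the set is usable by the engine.
#'
#' @param ps A `tcc_params` object (or a plain list with the same fields).
#' @return Object of class `tcc_validation`: list with character vectors
#'   `errors` and `warnings` and logical `ok`.
#' @export
validate_parameter_set <- function(ps) {
  errors <- character()
  warnings <- character()
  tol <- ps$settings$row_tol %||% 0.02
  arms <- names(ps$cs_transition)

  if (!length(arms)) errors <- c(errors, "no strategy arm populated")
  for (tbl in c("shl_given_cs", "event_rates")) {
    missing <- setdiff(arms, names(ps[[tbl]]))
    if (length(missing)) {
      errors <- c(errors, sprintf("%s missing for strategy %s", tbl,
                                  paste(missing, collapse = ", ")))
    }
  }

  # probability bounds
  errors <- c(errors, .prob_errors(ps$initial, "initial distributions"))
  errors <- c(errors, .prob_errors(ps$group_transition, "group transitions"))
  errors <- c(errors, .prob_errors(ps$mortality$mean, "mortality probabilities"))
  errors <- c(errors, .prob_errors(ps$cs_transition, "care-stage transitions"))
  errors <- c(errors, .prob_errors(ps$shl_given_cs, "skin-health mixtures"))
  errors <- c(errors, .prob_errors(ps$event_rates, "event rates"))
  errors <- c(errors, .prob_errors(ps$cs_shift, "care-stage shift probabilities"))

  # row-stochasticity (warnings when renormalizable, errors beyond tolerance)
  chk_rows <- function(rows, what) {
    s <- rowSums(as.matrix(rows))
    out <- which(abs(s - 1) > tol + 1e-12)
    if (length(out)) {
      errors <<- c(errors, sprintf("%s row sums out of tolerance: %s", what,
                                   paste(signif(s[out], 6), collapse = ", ")))
    }
    warnings <<- c(warnings, .row_sum_warnings(rows, what, tol))
  }
  chk_rows(ps$group_transition, "group transition")
  chk_rows(rbind(ps$initial$group), "initial group distribution")
  chk_rows(rbind(ps$initial$cs), "initial care-stage distribution")
  if (!is.null(ps$initial$shl)) chk_rows(rbind(ps$initial$shl), "initial skin-health distribution")
  for (a in arms) {
    chk_rows(ps$cs_transition[[a]], paste("care-stage transition", a))
    if (!is.null(ps$shl_given_cs[[a]])) chk_rows(ps$shl_given_cs[[a]], paste("skin-health mixture", a))
  }

  # monotone disability: no flow to lower-indexed groups
  gt <- as.matrix(ps$group_transition)
  if (nrow(gt) == ncol(gt) && nrow(gt) > 1) {
    low <- gt[lower.tri(gt)]
    if (any(low > 0)) {
      errors <- c(errors, "group transition has positive probability to a lower-indexed group")
    }
  }

  # utilities and decrements
  u <- unlist(ps$utilities$group)
  if (any(!is.finite(u)) || any(u < 0) || any(u > 1)) {
    errors <- c(errors, "group utilities outside [0, 1]")
  }
  for (d in c("d_cs", "d_shl", "d_event")) {
    v <- unlist(ps$utilities[[d]])
    if (any(!is.finite(v)) || any(v < 0)) {
      errors <- c(errors, sprintf("utility decrements %s must be non-negative magnitudes", d))
    }
  }

  # economics: everything non-negative; flag placeholders
  if (!is.null(ps$economics)) {
    ev <- unlist(ps$economics[!vapply(ps$economics, is.character, logical(1))])
    ev <- ev[vapply(ev, is.numeric, logical(1))]
    if (any(!is.finite(ev)) || any(ev < 0)) {
      errors <- c(errors, "economics block contains negative or non-finite values")
    }
    if (isTRUE(ps$economics$synthetic)) {
      warnings <- c(warnings, "economics block is a synthetic placeholder fixture")
    }
  }

  structure(list(errors = errors, warnings = warnings, ok = !length(errors)),
            class = "tcc_validation")
}

#' @export
print.tcc_validation <- function(x, ...) {
  cat(if (x$ok) "Parameter set OK" else "Parameter set INVALID", "\n")
  if (length(x$errors)) cat("errors:\n", paste0("  - ", x$errors, "\n"), sep = "")
  if (length(x$warnings)) cat("warnings:\n", paste0("  - ", x$warnings, "\n"), sep = "")
  invisible(x)
}

#' @export
print.tcc_params <- function(x, ...) {
  s <- x$settings
  cat("<tcc_params>", x$meta$label %||% "", "\n")
  cat(sprintf("  arms: %s | groups: %s\n", paste(param_arms(x), collapse = ", "),
              paste(s$included_groups, collapse = ", ")))
  cat(sprintf("  cycle %.3g y, discount %.1f%%/y, start age %g, composition '%s'\n",
              s$cycle_length, 100 * s$discount_rate, s$start_age, s$group_change_cs))
  cat(sprintf("  economics: %s\n",
              if (is.null(x$economics)) "absent (effect-only)"
              else if (isTRUE(x$economics$synthetic)) "synthetic placeholder"
              else "populated"))
  invisible(x)
}

# parameter-set fingerprint: content hash of everything the engine reads
param_fingerprint <- function(ps) {
  rlang::hash(ps[c("settings", "initial", "group_transition", "mortality",
                   "cs_shift", "cs_transition", "shl_given_cs", "event_rates",
                   "utilities", "economics")])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
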