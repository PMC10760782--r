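# Synthetic parameter generator ---------------------------------------------

.runif_simplex <- function(n, names = NULL) {
  g <- rgamma(n, shape = 1)
  setNames(g / sum(g), names)
}

#' Generate a fully valid random parameter set
#'
#' Testing support: produces a parameter set that always passes
#' [validate_parameter_set()] with zero errors, deterministically for a
#' given seed (the caller's RNG state is untouched).
#'
#' With a `template`, stochastic rows are drawn from Dirichlet distributions
#' centred on the template's rows and scalars are perturbed within their
#' default uncertainty spec (see [psa_draw()]), so ensemble means converge
#' to the template values. Without a template, rows are uniform on their
#' admissible simplex — group-transition rows respect the
#' no-improvement structural zeros — and scalars are drawn from broad
#' plausible ranges; the economics block is omitted.
#'
#' @param seed Integer seed.
#' @param template Optional [parameter_set()] to centre the draw on.
#' @return A validated [parameter_set()].
#' @examples
#' sp <- generate_synthetic_params(42)
#' validate_parameter_set(sp)$ok
#' @export
generate_synthetic_params <- function(seed, template = NULL) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)

  if (!is.null(template)) {
    drawn <- psa_draw(template, default_param_specs(template))
    drawn$meta$label <- sprintf("synthetic-from-template-seed-%d", seed)
    rep <- validate_parameter_set(drawn)
    stopifnot(rep$ok)
    return(drawn)
  }

  groups <- paste0("G", 2:6)
  ng <- length(groups)
  gt <- matrix(0, ng, ng, dimnames = list(groups, groups))
  for (i in seq_len(ng)) gt[i, i:ng] <- .runif_simplex(ng - i + 1)

  bands <- age_band_labels()
  mort <- matrix(sort(stats::runif(length(bands) * 3, 0.02, 0.12)),
                 length(bands), 3, dimnames = list(bands, mortality_classes()))
  cs_t <- lapply(setNames(strategies(), strategies()), function(a) {
    m <- t(vapply(1:3, function(i) .runif_simplex(3), numeric(3)))
    dimnames(m) <- list(care_stages(), care_stages())
    m
  })
  shl <- lapply(setNames(strategies(), strategies()), function(a) {
    m <- t(vapply(1:3, function(i) .runif_simplex(5), numeric(5)))
    dimnames(m) <- list(care_stages(), shl_levels())
    m
  })
  ev <- lapply(setNames(strategies(), strategies()), function(a)
    setNames(stats::runif(8, 0, 0.3),
             c("fracture_g2_g4", "fracture_g5_g6", "uti", "constipation",
               paste0("pu", 1:4))))

  parameter_set(
    settings = list(included_groups = groups,
                    start_age = stats::runif(1, 70, 90)),
    initial = list(group = .runif_simplex(ng, groups),
                   cs = .runif_simplex(3, care_stages()),
                   shl = .runif_simplex(5, shl_levels())),
    group_transition = gt,
    mortality = list(mean = mort, lo = mort * 0.9, hi = pmin(mort * 1.1, 1)),
    cs_transition = cs_t,
    shl_given_cs = shl,
    event_rates = ev,
    utilities = list(
      group = setNames(sort(stats::runif(6, 0.2, 0.9), decreasing = TRUE),
                       need_groups()),
      d_cs = setNames(c(0, sort(stats::runif(2, 0, 0.05))), care_stages()),
      d_shl = setNames(c(0, sort(stats::runif(4, 0, 0.05))), shl_levels()),
      d_event = setNames(stats::runif(7, 0, 0.15), event_labels())),
    meta = list(label = sprintf("synthetic-seed-%d", seed)))
}
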