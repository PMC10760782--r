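# Parameter uncertainty: distribution specs and moment-matched draws --------

#' Describe the uncertainty of one parameter
#'
#' A distribution spec pairs a parameter with the family used to draw it in
#' probabilistic sensitivity analysis and the bounds used in one-way
#' sensitivity analysis. When no confidence interval is reported for a
#' parameter, the standard error defaults to 20% of the mean, and one-way
#' bounds to `mean +/- 1.96 se`.
#'
#' @param family `"beta"` (parameters on \[0, 1\]), `"gamma"` (non-negative
#'   costs and resource use), `"normal"` (truncated by resampling to the
#'   admissible range), `"dirichlet_row"` (jointly for a stochastic row), or
#'   `"fixed"`.
#' @param mean Parameter mean (for `dirichlet_row`, the mean row vector).
#' @param se Standard error; defaults to `0.2 * mean` for scalar families.
#' @param lo,hi One-way sensitivity bounds; default `mean -/+ 1.96 * se`,
#'   clipped to the family's admissible range.
#' @param range Admissible range for normal truncation, e.g. `c(0, 1)`.
#' @return Object of class `tcc_dist_spec`.
#' @export
dist_spec <- function(family = c("beta", "gamma", "normal", "dirichlet_row", "fixed"),
                      mean, se = NULL, lo = NULL, hi = NULL, range = c(-Inf, Inf)) {
  family <- match.arg(family)
  if (family != "dirichlet_row" && family != "fixed") {
    if (is.null(se)) se <- 0.2 * mean
    if (is.null(lo)) lo <- max(mean - 1.96 * se, range[1])
    if (is.null(hi)) hi <- min(mean + 1.96 * se, range[2])
    if (family == "beta") range <- c(max(range[1], 0), min(range[2], 1))
    if (family == "gamma") range <- c(max(range[1], 0), range[2])
  }
  structure(list(family = family, mean = mean, se = se, lo = lo, hi = hi,
                 range = range), class = "tcc_dist_spec")
}

#' Moment-matched distribution shapes
#'
#' Method-of-moments parameterisations used for PSA draws: Beta shapes with
#' `shape1 + shape2 = mean (1 - mean) / se^2 - 1`, and Gamma with
#' `shape = (mean / se)^2`, `scale = se^2 / mean`.
#'
#' @param mean,se Target mean and standard error.
#' @return Named numeric of the two distribution parameters.
#' @examples
#' beta_shapes(0.5, 0.1)    # shape1 = shape2 = 12
#' gamma_shapes(10, 2)      # shape 25, scale mean/25
#' @export
beta_shapes <- function(mean, se) {
  stopifnot(mean > 0, mean < 1, se^2 < mean * (1 - mean))
  nu <- mean * (1 - mean) / se^2 - 1
  c(shape1 = mean * nu, shape2 = (1 - mean) * nu)
}

#' @rdname beta_shapes
#' @export
gamma_shapes <- function(mean, se) {
  stopifnot(mean > 0, se > 0)
  c(shape = (mean / se)^2, scale = se^2 / mean)
}

#' One Dirichlet draw centred on a stochastic row
#'
#' Draws a row-stochastic vector with mean `p`. Concentration is set so the
#' largest-mean component has SE equal to 20% of `min(mu_max, 1 - mu_max)` —
#' the 20%-of-mean convention, kept feasible near the simplex boundary.
#' Structural zeros stay zero; degenerate rows (a component of 1) are
#' returned unchanged.
#'
#' @param p Non-negative weights (normalised internally).
#' @return One draw on the simplex, zeros preserved.
#' @export
rdirichlet_row <- function(p) {
  p <- p / sum(p)
  mu_max <- max(p)
  if (mu_max >= 1 - 1e-12) return(p)
  se_target <- 0.2 * min(mu_max, 1 - mu_max)
  a0 <- mu_max * (1 - mu_max) / se_target^2 - 1
  g <- ifelse(p > 0, rgamma(length(p), shape = p * a0, rate = 1), 0)
  if (sum(g) <= 0) return(p)
  out <- g / sum(g)
  names(out) <- names(p)
  out
}

# scalar draw per family, truncating normals by resampling
draw_scalar <- function(spec) {
  m <- spec$mean
  se <- spec$se
  switch(spec$family,
    fixed = m,
    beta = {
      if (m <= 0 || m >= 1 || se <= 0) m
      else { sh <- beta_shapes(m, se); rbeta(1, sh[1], sh[2]) }
    },
    gamma = {
      if (m <= 0 || se <= 0) m
      else { sh <- gamma_shapes(m, se); rgamma(1, shape = sh["shape"], scale = sh["scale"]) }
    },
    normal = {
      if (se <= 0) return(m)
      for (i in 1:1000) {
        x <- rnorm(1, m, se)
        if (x >= spec$range[1] && x <= spec$range[2]) return(x)
      }
      min(max(m, spec$range[1]), spec$range[2])
    },
    stop("cannot draw scalar from family ", spec$family, call. = FALSE))
}
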