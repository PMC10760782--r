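# Static plot helpers -------------------------------------------------------

#' Cost-effectiveness plane
#'
#' Scatter of the PSA's incremental (QALY, cost) pairs with the origin
#' marked; the south-east quadrant (more effective, cheaper) is where the
#' technology dominates.
#'
#' @param psa A [run_psa()] result with costs.
#' @return A ggplot object.
#' @export
plot_ce_plane <- function(psa) {
  if (!isTRUE(psa$costs)) stop("CE plane needs a PSA run with costs", call. = FALSE)
  s <- psa$samples
  ggplot2::ggplot(s, ggplot2::aes(x = .data$delta_qaly, y = .data$delta_cost)) +
    ggplot2::geom_point(alpha = 0.25, size = 0.6) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(x = "Incremental QALYs", y = "Incremental cost",
                  title = "Cost-effectiveness plane") +
    ggplot2::theme_minimal()
}

#' Cost-effectiveness acceptability curve plot
#'
#' @param curve A [ceac()] result.
#' @return A ggplot object.
#' @export
plot_ceac <- function(curve) {
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$lambda, y = .data$prob)) +
    ggplot2::geom_line() +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "Willingness to pay per QALY",
                  y = "Probability cost-effective",
                  title = "Cost-effectiveness acceptability curve") +
    ggplot2::theme_minimal()
}

#' Cohort-movement plot across care stages
#'
#' Stacked area of the surviving cohort's care-stage composition over time,
#' with the dead fraction on top.
#'
#' @param traj A [run_cohort()] trajectory.
#' @return A ggplot object.
#' @export
plot_cohort_movement <- function(traj) {
  df <- as.data.frame(traj)
  df$bucket <- ifelse(is.na(df$cs), "dead", df$cs)
  agg <- stats::aggregate(mass ~ cycle + bucket, df, sum)
  agg$bucket <- factor(agg$bucket, levels = c("dead", rev(care_stages())))
  ggplot2::ggplot(agg, ggplot2::aes(x = .data$cycle, y = .data$mass,
                                    fill = .data$bucket)) +
    ggplot2::geom_area() +
    ggplot2::labs(x = "Cycle (2 months)", y = "Cohort share", fill = NULL,
                  title = paste("Cohort movement:", traj$strategy)) +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
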