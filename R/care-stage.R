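# Absorbency-based care-stage classification ------------------------------

#' Care-stage absorbency cut-offs
#'
#' Care stages are operationalised by the total absorbency (Rothwell value,
#' ISO 11948-1, in mL) of the absorbent products an individual uses over 24
#' hours. Two thresholds per resident-size class split the line into CS1
#' (below the lower cut-off), CS2 (the closed central band), and CS3 (above
#' the upper cut-off).
#'
#' @param size_class `"average"` or `"large"`.
#' @return Numeric vector of two strictly increasing thresholds.
#' @export
cs_absorbency_cutoffs <- function(size_class = c("average", "large")) {
  size_class <- match.arg(size_class)
  switch(size_class, average = c(3800, 5700), large = c(4500, 6750))
}

#' Classify a 24-hour total absorbency into a care stage
#'
#' Band endpoints belong to CS2, so the three stages partition the
#' non-negative line exhaustively: CS1 strictly below the lower cut-off,
#' CS3 strictly above the upper one.
#'
#' @param total_absorbency_24h Total 24-hour absorbency in Rothwell units
#'   (mL); non-negative, vectorised.
#' @param size_class `"average"` or `"large"`.
#' @return Character vector of care-stage labels (`"CS1"`, `"CS2"`, `"CS3"`).
#' @examples
#' classify_care_stage(c(3799, 3800, 5700, 5701), "average")
#' classify_care_stage(6751, "large")
#' @export
classify_care_stage <- function(total_absorbency_24h, size_class = c("average", "large")) {
  if (any(!is.finite(total_absorbency_24h)) || any(total_absorbency_24h < 0)) {
    stop("`total_absorbency_24h` must be finite and non-negative", call. = FALSE)
  }
  cut <- cs_absorbency_cutoffs(size_class)
  ifelse(total_absorbency_24h < cut[1], "CS1",
         ifelse(total_absorbency_24h <= cut[2], "CS2", "CS3"))
}
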