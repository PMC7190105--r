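# Weighted quartile means on the empirical distribution. "poor" averages the
# observations at or below the lower quartile, "optimal" those at or above
# the upper quartile; quartiles are inclusive cut points of the weighted
# CDF: Q1 is the smallest value with cumulative weight >= 0.25, Q3 the
# largest value with tail weight >= 0.25 (the mirror-image convention, so
# the two tails are treated symmetrically).
quartile_means <- function(x, w) {
  keep <- w > 0
  if (!any(keep)) {
    return(c(poor = 0, average = 0, optimal = 0))
  }
  x <- x[keep]; w <- w[keep]
  o <- order(x)
  x <- x[o]; w <- w[o]
  cw <- cumsum(w) / sum(w)
  tw <- rev(cumsum(rev(w))) / sum(w)
  q1 <- x[which(cw >= 0.25)[1]]
  q3 <- x[max(which(tw >= 0.25))]
  c(poor = weighted.mean(x[x <= q1], w[x <= q1]),
    average = weighted.mean(x, w),
    optimal = weighted.mean(x[x >= q3], w[x >= q3]))
}

#' FPU-level yield shifters at three tailoring levels
#'
#' Farmers differ in how well they tailor a practice to local conditions.
#' Within each FPU x crop, the distribution of adopted yield gains is
#' summarised at three proficiency levels: *poor* is the (area-weighted)
#' mean of the lower quartile of gains, *average* the mean of the whole
#' distribution, and *optimal* the mean of the upper quartile, so
#' poor <= average <= optimal always holds.
#'
#' @param gains Tibble with columns `fpu_id`, `crop`, `gain` (fractional
#'   yield delta of the adopted practice) and `weight` (adopted area, ha;
#'   use 1 for cell-count weighting).
#' @param complete Optional tibble of `fpu_id` x `crop` combinations to
#'   complete; combinations with no adopting cells get shifter 0 at every
#'   level.
#'
#' @return A tibble `fpu_id`, `crop`, `tailoring`
#'   (poor/average/optimal), `shifter`.
#' @export
#' @examples
#' g <- tibble::tibble(fpu_id = "F1", crop = "maize",
#'                     gain = c(.01, .02, .03, .04), weight = 1)
#' fpu_shifters(g)  # poor .01, average .025, optimal .04
fpu_shifters <- function(gains, complete = NULL) {
  need <- c("fpu_id", "crop", "gain", "weight")
  if (!all(need %in% names(gains))) {
    stopf("csascen_config_error",
          "gains needs columns fpu_id, crop, gain, weight.")
  }
  if (any(gains$weight < 0)) {
    stopf("csascen_domain_error", "weights must be >= 0.")
  }
  out <- gains |>
    dplyr::group_by(.data$fpu_id, .data$crop) |>
    dplyr::summarise(
      shifter = list(unname(quartile_means(.data$gain, .data$weight))),
      .groups = "drop"
    ) |>
    dplyr::mutate(tailoring = list(csa_tailorings)) |>
    tidyr::unnest(c("shifter", "tailoring")) |>
    dplyr::select("fpu_id", "crop", "tailoring", "shifter")
  if (!is.null(complete)) {
    out <- tidyr::crossing(
      dplyr::distinct(complete, .data$fpu_id, .data$crop),
      tailoring = csa_tailorings
    ) |>
      dplyr::left_join(out, by = c("fpu_id", "crop", "tailoring")) |>
      dplyr::mutate(shifter = dplyr::coalesce(.data$shifter, 0))
  }
  out
}

#' Apply a yield shifter to a supply trajectory parameter
#'
#' A shifter can enter the supply side either as a one-off level shift
#' (first-year yields multiplied by `1 + shifter`) or spread over the
#' projection horizon as an annualised growth adjustment: the annual growth
#' factor is multiplied by `(1 + shifter)^(1/horizon)`, so the
#' end-of-horizon yield ratio over the unshifted path is exactly
#' `1 + shifter` (at zero baseline growth this is the familiar increment
#' `(1 + shifter)^(1/horizon) - 1`). Growth mode is the default, matching
#' shifters that act on yield growth rates.
#'
#' @param bau_growth Baseline annual yield growth (fraction/yr).
#' @param shifter Fractional yield shifter.
#' @param mode `"growth"` or `"level"`.
#' @param horizon Years over which growth mode spreads the shifter.
#'
#' @return Growth mode: the adjusted annual growth rate. Level mode: the
#'   first-year multiplier `1 + shifter` (growth unchanged).
#' @export
#' @examples
#' shift_supply(0.01, 0.10)            # growth rate absorbing +10% by 2050
#' shift_supply(0.01, 0.10, "level")   # 1.1 multiplier on the first year
shift_supply <- function(bau_growth, shifter, mode = c("growth", "level"),
                         horizon = 40) {
  mode <- match.arg(mode)
  if (mode == "growth") {
    (1 + bau_growth) * (1 + shifter)^(1 / horizon) - 1
  } else {
    1 + shifter
  }
}
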