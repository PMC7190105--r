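#' Economics of alternate wetting and drying
#'
#' Parameters of the AWD cost break-even: the share of production costs that
#' irrigation represents, the fraction of irrigation cost AWD saves, and the
#' ratio of production cost to gross revenue. Literature ranges put the
#' irrigation cost share between 3% and 36% of production costs and the AWD
#' saving at up to 30%; defaults take the upper cost share of 30% with the
#' 30% saving and cost equal to revenue.
#'
#' @param irrigation_cost_share Fraction of production costs that is
#'   irrigation (default 0.30; documented range 0.03-0.36).
#' @param irrigation_cost_reduction Fraction of irrigation cost AWD saves
#'   (default 0.30).
#' @param cost_revenue_ratio Production cost over gross revenue (default 1).
#'
#' @return An `awd_economics` list.
#' @export
awd_economics <- function(irrigation_cost_share = 0.30,
                          irrigation_cost_reduction = 0.30,
                          cost_revenue_ratio = 1.0) {
  if (irrigation_cost_share < 0 || irrigation_cost_share > 1 ||
      irrigation_cost_reduction < 0 || irrigation_cost_reduction > 1) {
    stopf("csascen_config_error", "cost shares must lie in [0, 1].")
  }
  if (cost_revenue_ratio <= 0 || cost_revenue_ratio > 2) {
    stopf("csascen_config_error", "cost_revenue_ratio must lie in (0, 2].")
  }
  structure(list(irrigation_cost_share = irrigation_cost_share,
                 irrigation_cost_reduction = irrigation_cost_reduction,
                 cost_revenue_ratio = cost_revenue_ratio),
            class = c("awd_economics", "list"))
}

#' Break-even yield decline for AWD adoption
#'
#' The largest fractional yield decline at which AWD is still at least as
#' profitable as the current practice: the revenue lost to the decline just
#' equals the irrigation-cost saving. With revenue R, cost C = ratio x R,
#' irrigation share s and saving r, break-even satisfies
#' `R d = C s r`, so `d* = s * r * (C/R)`. The default parameters give the
#' familiar 9% tolerance.
#'
#' @param econ An [awd_economics()].
#'
#' @return Maximum tolerable fractional yield decline (e.g. 0.09).
#' @export
#' @examples
#' awd_breakeven(awd_economics())                       # 0.09
#' awd_breakeven(awd_economics(0.36, 0.30, 1.0))        # 0.108
awd_breakeven <- function(econ = awd_economics()) {
  econ$irrigation_cost_share * econ$irrigation_cost_reduction *
    econ$cost_revenue_ratio
}

#' Adoption rule specification
#'
#' Four rule variants drive the scenarios. `rule1`: adopt the compatible
#' practice with the largest yield gain, provided the gain is strictly
#' positive. `rule2`: additionally require a decrease in emission intensity
#' relative to current practice. `rule1_rates`: rule 1 followed by
#' country x practice adoption-rate caps on the adopted area fraction.
#' `rule2_awdcost`: rule 2, except AWD also qualifies with a yield *decline*
#' smaller than the cost break-even (see [awd_breakeven()]), still subject
#' to the intensity condition.
#'
#' @param rule_id One of `"rule1"`, `"rule2"`, `"rule1_rates"`,
#'   `"rule2_awdcost"`.
#' @param rate_table For `rule1_rates`: tibble with `country_id`, `practice`,
#'   `rate` in \[0, 1\]. Required.
#' @param awd_econ For `rule2_awdcost`: an [awd_economics()]; defaults to the
#'   standard parameterisation.
#'
#' @return An `adoption_rule` list.
#' @export
adoption_rule <- function(rule_id = c("rule1", "rule2", "rule1_rates",
                                      "rule2_awdcost"),
                          rate_table = NULL, awd_econ = NULL) {
  rule_id <- match.arg(rule_id)
  if (rule_id == "rule1_rates") {
    if (is.null(rate_table)) {
      stopf("csascen_config_error", "rule1_rates requires a rate_table.")
    }
    validate_rate_table(rate_table)
  }
  if (rule_id == "rule2_awdcost" && is.null(awd_econ)) {
    awd_econ <- awd_economics()
  }
  structure(list(rule_id = rule_id, rate_table = rate_table,
                 awd_econ = awd_econ),
            class = c("adoption_rule", "list"))
}

validate_rate_table <- function(rate_table) {
  need <- c("country_id", "practice", "rate")
  if (!all(need %in% names(rate_table))) {
    stopf("csascen_config_error",
          "rate_table needs columns country_id, practice, rate.")
  }
  if (any(rate_table$rate < 0 | rate_table$rate > 1)) {
    stopf("csascen_config_error", "adoption rates must lie in [0, 1].")
  }
  invisible(rate_table)
}

#' Placeholder adoption-rate table
#'
#' Expert-elicited country x practice adoption rates are not part of this
#' package's data; this helper builds a uniform placeholder table (default
#' 40% everywhere) so the rate-capped scenario can run. Replace with real
#' rates for any substantive use.
#'
#' @param world A `csa_world`.
#' @param rate Uniform rate in \[0, 1\].
#'
#' @return A tibble `country_id` x `practice` with constant `rate`.
#' @export
default_adoption_rates <- function(world, rate = 0.4) {
  tidyr::crossing(country_id = unique(world$cells$country_id),
                  practice = csa_practices) |>
    dplyr::mutate(rate = rate)
}

#' Decide adoption per grid cell
#'
#' Applies one adoption rule to every cell: among the practice responses
#' compatible with the cell (and not excluded, as no-till is in the excluded
#' countries), keep those passing the rule's eligibility test, then adopt
#' the one with the largest yield gain on 100% of the cell's area. Ties are
#' broken by the fixed practice order no_till < isfm < nue < awd. Cells with
#' no eligible alternative retain their current practice (adopted fraction
#' 0). For `rule1_rates` the country x practice rate caps are applied to the
#' adopted fractions afterwards (see [apply_adoption_rates()]).
#'
#' @param cells World cells.
#' @param responses Practice responses for a single climate path.
#' @param ledger_bau Current-practice ledger from [emission_ledger()].
#' @param ledger_alt Ledger of the candidate responses (same climate).
#' @param rule An [adoption_rule()].
#' @param excluded_countries Country ids where no-till is ineligible.
#'
#' @return A tibble `cell_id`, `rule_id`, `chosen` (practice or
#'   `"retain_current"`), `yield_delta` of the chosen practice (0 when
#'   retaining) and `adopted_fraction`.
#' @export
decide_cells <- function(cells, responses, ledger_bau, ledger_alt,
                         rule = adoption_rule("rule1"),
                         excluded_countries = character()) {
  stopifnot(inherits(rule, "adoption_rule"))
  cand <- responses |>
    dplyr::inner_join(
      dplyr::select(cells, "cell_id", "country_id", "crop", "water_system"),
      by = "cell_id"
    ) |>
    dplyr::filter(
      purrr::map2_lgl(.data$crop, .data$practice,
                      ~ .y %in% practice_compat[[.x]]),
      !(.data$practice == "awd" & .data$water_system != "irrigated"),
      !(.data$practice == "no_till" &
          .data$country_id %in% excluded_countries)
    )

  bau_int <- ledger_bau |>
    dplyr::select("cell_id", intensity_bau = "intensity",
                  intensity_bau_defined = "intensity_defined")
  alt_int <- ledger_alt |>
    dplyr::select("cell_id", "practice", intensity_alt = "intensity",
                  intensity_alt_defined = "intensity_defined")
  n_before <- nrow(cand)
  cand <- cand |>
    dplyr::inner_join(bau_int, by = "cell_id") |>
    dplyr::inner_join(alt_int, by = c("cell_id", "practice"))
  if (nrow(cand) < n_before) {
    stopf("csascen_join_error",
          "emission ledger missing for some candidate practices.")
  }

  intensity_ok <- cand$intensity_alt_defined & cand$intensity_bau_defined &
    cand$intensity_alt < cand$intensity_bau
  eligible <- switch(
    rule$rule_id,
    rule1 = ,
    rule1_rates = cand$yield_delta > 0,
    rule2 = cand$yield_delta > 0 & intensity_ok,
    rule2_awdcost = intensity_ok &
      (cand$yield_delta > 0 |
         (cand$practice == "awd" &
            cand$yield_delta > -awd_breakeven(rule$awd_econ)))
  )

  chosen <- cand[eligible, , drop = FALSE] |>
    dplyr::mutate(
      practice_rank = match(.data$practice, csa_practices)
    ) |>
    dplyr::arrange(.data$cell_id, dplyr::desc(.data$yield_delta),
                   .data$practice_rank) |>
    dplyr::distinct(.data$cell_id, .keep_all = TRUE) |>
    dplyr::select("cell_id", chosen = "practice", "yield_delta")

  decisions <- cells |>
    dplyr::select("cell_id") |>
    dplyr::left_join(chosen, by = "cell_id") |>
    dplyr::mutate(
      rule_id = rule$rule_id,
      chosen = dplyr::coalesce(.data$chosen, "retain_current"),
      yield_delta = dplyr::coalesce(.data$yield_delta, 0),
      adopted_fraction = ifelse(.data$chosen == "retain_current", 0, 1)
    ) |>
    dplyr::relocate("rule_id", .after = "cell_id")

  if (rule$rule_id == "rule1_rates") {
    decisions <- apply_adoption_rates(decisions, rule$rate_table, cells)
  }
  decisions
}

#' Cap adopted fractions by exogenous adoption rates
#'
#' Scales each adopted cell's `adopted_fraction` by the country x practice
#' rate; retained cells are untouched. Combinations absent from the table
#' default to a rate of 1 (no cap).
#'
#' @param decisions Output of [decide_cells()].
#' @param rate_table Tibble `country_id`, `practice`, `rate` in \[0, 1\].
#' @param cells World cells (for the country lookup).
#'
#' @return `decisions` with scaled `adopted_fraction`.
#' @export
apply_adoption_rates <- function(decisions, rate_table, cells) {
  validate_rate_table(rate_table)
  decisions |>
    dplyr::left_join(dplyr::select(cells, "cell_id", "country_id"),
                     by = "cell_id") |>
    dplyr::left_join(rate_table,
                     by = c("country_id", chosen = "practice")) |>
    dplyr::mutate(
      rate = dplyr::coalesce(.data$rate, 1),
      adopted_fraction = ifelse(.data$chosen == "retain_current",
                                .data$adopted_fraction,
                                .data$adopted_fraction * .data$rate)
    ) |>
    dplyr::select(-"country_id", -"rate")
}

#' Adopted area by group
#'
#' Total hectares under each adopted practice: the cell's harvested area
#' times its adopted fraction, grouped as requested.
#'
#' @param decisions Output of [decide_cells()].
#' @param cells World cells.
#' @param by `"world"`, `"practice"`, `"country"` or `"fpu"`.
#'
#' @return A tibble with the grouping columns and `area_ha`.
#' @export
adopted_area <- function(decisions, cells,
                         by = c("world", "practice", "country", "fpu")) {
  by <- match.arg(by)
  dat <- decisions |>
    dplyr::inner_join(
      dplyr::select(cells, "cell_id", "fpu_id", "country_id", "area"),
      by = "cell_id"
    ) |>
    dplyr::mutate(adopted_ha = .data$area * .data$adopted_fraction)
  key <- switch(by, world = character(), practice = "chosen",
                country = "country_id", fpu = "fpu_id")
  dat |>
    dplyr::group_by(dplyr::across(dplyr::all_of(key))) |>
    dplyr::summarise(area_ha = sum(.data$adopted_ha), .groups = "drop")
}
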