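#' Build the scenario matrix
#'
#' Enumerates the full simulation design: one business-as-usual run per
#' climate path, plus every adoption scheme crossed with climate path and
#' tailoring level. The default design (2 climates, 4 schemes, 3
#' tailorings) yields 2 + 4 x 2 x 3 = 26 simulations.
#'
#' @param climates Climate path ids.
#' @param schemes Adoption scheme ids (subset of `rule1`, `rule2`,
#'   `rule1_rates`, `rule2_awdcost`); may be empty for BAU-only designs.
#' @param tailorings Tailoring levels.
#' @param climate_change_on Apply climate trend modifiers?
#'
#' @return A tibble of scenario specs in deterministic order: `scenario`,
#'   `climate_id`, `tailoring` (`NA` for BAU), `climate_change_on`.
#' @export
#' @examples
#' nrow(build_scenario_matrix())  # 26
build_scenario_matrix <- function(climates = csa_climates,
                                  schemes = c("rule1", "rule2",
                                              "rule1_rates",
                                              "rule2_awdcost"),
                                  tailorings = csa_tailorings,
                                  climate_change_on = TRUE) {
  if (length(climates) < 1) {
    stopf("csascen_config_error", "need at least one climate path.")
  }
  bad <- setdiff(schemes, c("rule1", "rule2", "rule1_rates",
                            "rule2_awdcost"))
  if (length(bad)) {
    stopf("csascen_config_error", "unknown adoption scheme: %s",
          paste(bad, collapse = ", "))
  }
  bau <- tibble::tibble(scenario = "bau", climate_id = climates,
                        tailoring = NA_character_)
  rest <- tidyr::crossing(scenario = schemes, climate_id = climates,
                          tailoring = tailorings)
  dplyr::bind_rows(bau, rest) |>
    dplyr::mutate(climate_change_on = climate_change_on) |>
    dplyr::arrange(match(.data$scenario, c("bau", schemes)),
                   .data$climate_id,
                   match(.data$tailoring, csa_tailorings))
}

#' Run one scenario end to end
#'
#' Executes the pipeline in order: adoption decisions, FPU tailoring
#' shifters, region mapping, market projection, emission accounting against
#' business as usual, food-security indicators, and the livestock-feed
#' feedback. BAU runs skip the adoption and tailoring stages.
#'
#' @param world A `csa_world`.
#' @param scenario `"bau"` or an adoption scheme id.
#' @param climate_id Climate path.
#' @param tailoring Tailoring level (ignored for BAU).
#' @param climate_change_on Apply climate trend modifiers?
#' @param rate_table Country x practice adoption rates (used by
#'   `rule1_rates`); defaults to [default_adoption_rates()].
#' @param awd_econ [awd_economics()] for `rule2_awdcost`.
#' @param ef [emission_factors()].
#' @param hunger,child Food-security parameter objects.
#' @param link [livestock_link()] for the feed feedback.
#' @param excluded_countries Country ids where no-till is ineligible;
#'   defaults to the world's configured exclusion set (empty if the world
#'   carries no config).
#' @param years Projection years.
#' @param mode Shifter entry mode (`"growth"` or `"level"`).
#'
#' @return A `csa_run` list: `spec`, `decisions`, `shifters` (all tailoring
#'   levels), `region_shifters`, `states`, `states_bau`, `emissions`
#'   (totals + abatement), `indicators`, `indicators_bau`, `report`,
#'   `adopted`, `livestock`.
#' @export
run_scenario <- function(world, scenario = "bau",
                         climate_id = csa_climates[1],
                         tailoring = "average", climate_change_on = TRUE,
                         rate_table = NULL, awd_econ = NULL,
                         ef = emission_factors(),
                         hunger = hunger_params(), child = child_params(),
                         link = livestock_link(),
                         excluded_countries = NULL,
                         years = 2010:2050, mode = "growth") {
  if (is.null(excluded_countries)) {
    excluded_countries <- world$config$no_till_excluded_countries
    if (is.null(excluded_countries)) excluded_countries <- character()
  }
  states_bau <- project_market(world, NULL, climate_id, years,
                               climate_change_on, mode = mode)
  ledger_bau <- emission_ledger(world$cells, NULL, ef)
  bau_total <- aggregate_emissions(ledger_bau, world$cells, "world")$total

  if (scenario == "bau") {
    decisions <- world$cells |>
      dplyr::transmute(.data$cell_id, rule_id = "bau",
                       chosen = "retain_current", yield_delta = 0,
                       adopted_fraction = 0)
    shifters <- tibble::tibble(fpu_id = character(), crop = character(),
                               tailoring = character(), shifter = numeric())
    rshift <- NULL
    states <- states_bau
    scn_total <- bau_total
  } else {
    rule <- adoption_rule(
      scenario,
      rate_table = if (scenario == "rule1_rates") {
        if (is.null(rate_table)) default_adoption_rates(world) else rate_table
      },
      awd_econ = awd_econ
    )
    responses <- dplyr::filter(world$responses,
                               .data$climate_id == !!climate_id)
    ledger_alt <- emission_ledger(world$cells, responses, ef)
    decisions <- decide_cells(world$cells, responses, ledger_bau,
                              ledger_alt, rule, excluded_countries)

    gains <- decisions |>
      dplyr::filter(.data$chosen != "retain_current") |>
      dplyr::inner_join(
        dplyr::select(world$cells, "cell_id", "fpu_id", "crop", "area"),
        by = "cell_id"
      ) |>
      dplyr::transmute(.data$fpu_id, .data$crop, gain = .data$yield_delta,
                       weight = .data$area * .data$adopted_fraction)
    shifters <- fpu_shifters(gains)
    level <- dplyr::filter(shifters, .data$tailoring == !!tailoring) |>
      dplyr::select("fpu_id", "crop", "shifter")
    rshift <- region_shifters(level, decisions, world$cells)
    states <- project_market(world, rshift, climate_id, years,
                             climate_change_on, mode = mode)

    # per-ha emissions blend current practice with the adopted practice in
    # proportion to the adopted area fraction
    blended <- decisions |>
      dplyr::left_join(
        dplyr::select(ledger_bau, "cell_id", co2e_bau = "co2e_total"),
        by = "cell_id"
      ) |>
      dplyr::left_join(
        dplyr::select(ledger_alt, "cell_id", chosen = "practice",
                      co2e_alt = "co2e_total"),
        by = c("cell_id", "chosen")
      ) |>
      dplyr::mutate(
        co2e_total = .data$adopted_fraction *
          dplyr::coalesce(.data$co2e_alt, .data$co2e_bau) +
          (1 - .data$adopted_fraction) * .data$co2e_bau,
        practice = .data$chosen
      )
    scn_total <- aggregate_emissions(blended, world$cells, "world")$total
  }

  indicators <- food_security_indicators(states, hunger, child)
  indicators_bau <- food_security_indicators(states_bau, hunger, child)

  y1 <- max(years)
  feed_w <- states_bau |>
    dplyr::filter(.data$year == y1) |>
    dplyr::group_by(.data$crop) |>
    dplyr::summarise(w = sum(.data$demand * .data$feed_share),
                     price_bau = .data$price[1], .groups = "drop")
  feed_p <- states |>
    dplyr::filter(.data$year == y1) |>
    dplyr::distinct(.data$crop, .data$price)
  feed <- dplyr::inner_join(feed_w, feed_p, by = "crop")
  price_ratio <- sum(feed$w * feed$price) / sum(feed$w * feed$price_bau)
  livestock <- livestock_feedback(price_ratio, link) |>
    dplyr::mutate(feed_price_ratio = price_ratio, .before = 1)

  out <- list(
    spec = tibble::tibble(scenario = scenario, climate_id = climate_id,
                          tailoring = ifelse(scenario == "bau",
                                             NA_character_, tailoring),
                          climate_change_on = climate_change_on),
    decisions = decisions,
    shifters = shifters,
    region_shifters = rshift,
    states = states,
    states_bau = states_bau,
    emissions = tibble::tibble(
      bau_total = bau_total, scenario_total = scn_total,
      abatement = bau_total - scn_total
    ),
    indicators = indicators,
    indicators_bau = indicators_bau,
    report = production_report(states, states_bau),
    adopted = adopted_area(decisions, world$cells, "practice"),
    livestock = livestock
  )
  class(out) <- c("csa_run", "list")
  out
}

#' Run every scenario in a matrix
#'
#' @param world A `csa_world`.
#' @param matrix Scenario specs from [build_scenario_matrix()].
#' @param ... Passed on to [run_scenario()] (emission factors, parameter
#'   objects, rate tables, years).
#'
#' @return A `csa_runs` list of [run_scenario()] results, in matrix order.
#' @export
run_matrix <- function(world, matrix = build_scenario_matrix(), ...) {
  runs <- purrr::pmap(
    matrix,
    function(scenario, climate_id, tailoring, climate_change_on) {
      run_scenario(world, scenario, climate_id,
                   tailoring = if (is.na(tailoring)) "average" else tailoring,
                   climate_change_on = climate_change_on, ...)
    }
  )
  class(runs) <- c("csa_runs", "list")
  runs
}

#' @export
print.csa_run <- function(x, ...) {
  s <- x$spec
  cat("<csa_run>", s$scenario, "/", s$climate_id,
      if (!is.na(s$tailoring)) paste("/", s$tailoring), "\n")
  cat("  abatement:", format(x$emissions$abatement, big.mark = ","),
      "t CO2e/yr vs BAU\n")
  invisible(x)
}

#' Summarise runs in the mean-plus-range convention
#'
#' For every scheme and metric, reports the mean over the climate paths at
#' average tailoring, together with the minimum and maximum over all
#' climate x tailoring combinations — the reporting convention
#' "mean (lowest-highest)".
#'
#' @param runs A `csa_runs` list from [run_matrix()].
#'
#' @return A `csa_summary` tibble: `scenario`, `metric`, `mean`, `min`,
#'   `max` with `min <= mean <= max`. Runs missing the average-tailoring
#'   combination fall back to the mean over all available runs, with a
#'   warning.
#' @export
summarize_runs <- function(runs) {
  long <- purrr::map(runs, tidy) |> purrr::list_rbind()
  out <- long |>
    dplyr::group_by(.data$scenario, .data$metric) |>
    dplyr::summarise(
      mean = if (any(.data$tailoring %in% "average" | is.na(.data$tailoring))) {
        mean(.data$value[.data$tailoring %in% "average" |
                           is.na(.data$tailoring)])
      } else {
        mean(.data$value)
      },
      min = min(.data$value),
      max = max(.data$value),
      .groups = "drop"
    )
  missing_avg <- long |>
    dplyr::distinct(.data$scenario, .data$tailoring) |>
    dplyr::group_by(.data$scenario) |>
    dplyr::summarise(ok = any(.data$tailoring %in% "average" |
                                is.na(.data$tailoring)))
  if (any(!missing_avg$ok)) {
    warn(sprintf("no average-tailoring run for: %s; using all-run mean.",
                 paste(missing_avg$scenario[!missing_avg$ok],
                       collapse = ", ")))
  }
  class(out) <- c("csa_summary", class(out))
  out
}
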