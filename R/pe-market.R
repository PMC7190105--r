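#' Clear one commodity market
#'
#' Finds the world price at which total constant-elasticity supply equals
#' total constant-elasticity demand for a single commodity:
#' `sum_r s_r P^es_r = sum_r d_r P^ed_r` with supply elasticities >= 0 and
#' demand elasticities <= 0. The log excess-supply function is monotone in
#' log price, so the root is unique; it is found by safeguarded
#' root-bracketing on log price and verified to a relative excess demand
#' below `tol`.
#'
#' @param supply_coef,demand_coef Positive coefficient vectors (one entry
#'   per region).
#' @param supply_elast,demand_elast Elasticity vectors (recycled).
#' @param tol Relative excess-demand tolerance.
#'
#' @return The clearing price (scalar).
#' @export
#' @examples
#' clear_market(1, 0.3, 2, -0.5)   # (b/a)^(1/(es - ed)) = 2^(1/0.8)
clear_market <- function(supply_coef, supply_elast, demand_coef,
                         demand_elast, tol = 1e-10) {
  if (any(supply_coef <= 0) || any(demand_coef <= 0)) {
    stopf("csascen_config_error", "market coefficients must be positive.")
  }
  if (any(supply_elast < 0) || any(demand_elast > 0)) {
    stopf("csascen_config_error",
          "supply elasticities must be >= 0 and demand elasticities <= 0.")
  }
  s_tot <- function(lp) sum(supply_coef * exp(supply_elast * lp))
  d_tot <- function(lp) sum(demand_coef * exp(demand_elast * lp))
  f <- function(lp) log(s_tot(lp)) - log(d_tot(lp))
  if (abs(f(0)) < .Machine$double.eps * 8) return(1)
  root <- uniroot(f, interval = c(-30, 30), extendInt = "upX",
                  tol = .Machine$double.eps^0.75, maxiter = 2000)
  lp <- root$root
  resid <- abs(s_tot(lp) - d_tot(lp)) / d_tot(lp)
  if (resid > tol) {
    stopf("csascen_solver_error",
          "market failed to clear: relative excess %.3e > %.3e.", resid, tol)
  }
  exp(lp)
}

# area-weighted FPU->region climate trend modifiers for one climate path
region_trend <- function(world, climate_id) {
  wts <- world$cells |>
    dplyr::group_by(region_id = .data$country_id, .data$fpu_id, .data$crop) |>
    dplyr::summarise(area = sum(.data$area), .groups = "drop")
  world$climate |>
    dplyr::filter(.data$climate_id == !!climate_id) |>
    dplyr::inner_join(wts, by = c("fpu_id", "crop")) |>
    dplyr::group_by(.data$region_id, .data$crop) |>
    dplyr::summarise(trend = weighted.mean(.data$trend_delta, .data$area),
                     .groups = "drop")
}

#' Map FPU shifters to market regions
#'
#' The market operates at region (country) level while shifters are computed
#' per FPU over the *adopting* area. Each FPU's shifter is first diluted by
#' the share of the FPU's crop area that adopts, then FPUs are aggregated to
#' their region by crop-area weighting, giving the effective region x crop
#' supply shifter.
#'
#' @param shifters Output of [fpu_shifters()] filtered to one tailoring
#'   level.
#' @param decisions Output of [decide_cells()].
#' @param cells World cells.
#'
#' @return Tibble `region_id`, `crop`, `shifter`.
#' @export
region_shifters <- function(shifters, decisions, cells) {
  areas <- cells |>
    dplyr::left_join(dplyr::select(decisions, "cell_id", "adopted_fraction"),
                     by = "cell_id") |>
    dplyr::mutate(
      adopted_fraction = dplyr::coalesce(.data$adopted_fraction, 0)
    ) |>
    dplyr::group_by(region_id = .data$country_id, .data$fpu_id, .data$crop) |>
    dplyr::summarise(
      area = sum(.data$area),
      adopted = sum(.data$area * .data$adopted_fraction),
      .groups = "drop"
    )
  areas |>
    dplyr::left_join(shifters, by = c("fpu_id", "crop")) |>
    dplyr::mutate(
      shifter = dplyr::coalesce(.data$shifter, 0),
      effective = .data$shifter * ifelse(.data$area > 0,
                                         .data$adopted / .data$area, 0)
    ) |>
    dplyr::group_by(.data$region_id, .data$crop) |>
    dplyr::summarise(shifter = weighted.mean(.data$effective, .data$area),
                     .groups = "drop")
}

#' Project market trajectories 2010-2050
#'
#' Solves the annual multi-region equilibrium for every crop and year.
#' Supply per region is `area_base * P^area_elast * yield(t)` with yield
#' compounding at the exogenous growth rate plus the climate trend modifier
#' (when climate change is on) plus the annualised shifter increment (growth
#' mode; level mode multiplies the whole path by `1 + shifter`). Demand per
#' region is `demand_base * P^demand_elast * pop(t)/pop(0) *
#' (inc(t)/inc(0))^income_elast`. Prices are world prices (one trade pool
#' per commodity); regional net trade sums to zero by construction of the
#' clearing price.
#'
#' @param world A `csa_world`.
#' @param shifters Optional tibble `region_id`, `crop`, `shifter`
#'   (see [region_shifters()]); `NULL` means no shift (business as usual).
#' @param climate_id Which climate path's trend modifiers to use.
#' @param years Years to solve (default 2010:2050).
#' @param climate_change_on If `FALSE`, climate trend modifiers are zeroed
#'   (the no-climate-change counterfactual).
#' @param mode Shifter entry mode, `"growth"` (default) or `"level"`.
#' @param base_year Year at which growth factors equal 1.
#' @param horizon Years over which growth mode spreads the shifter.
#'
#' @return A `csa_states` tibble: `year`, `climate_id`, `region_id`, `crop`,
#'   `price`, `area`, `yield`, `production`, `demand`, `net_trade`,
#'   `population`, `feed_share`.
#' @export
project_market <- function(world, shifters = NULL,
                           climate_id = csa_climates[1],
                           years = 2010:2050, climate_change_on = TRUE,
                           mode = c("growth", "level"), base_year = 2010,
                           horizon = 40) {
  mode <- match.arg(mode)
  params <- world$market_params |>
    dplyr::left_join(region_trend(world, climate_id),
                     by = c("region_id", "crop")) |>
    dplyr::mutate(trend = dplyr::coalesce(.data$trend, 0))
  if (is.null(shifters)) {
    params$shifter <- 0
  } else {
    params <- params |>
      dplyr::left_join(shifters, by = c("region_id", "crop")) |>
      dplyr::mutate(shifter = dplyr::coalesce(.data$shifter, 0))
  }
  params <- params |>
    dplyr::left_join(
      dplyr::select(world$macro, "region_id", "base_population",
                    "pop_growth", "income_growth"),
      by = "region_id"
    ) |>
    dplyr::mutate(
      g_eff = if (mode == "growth") {
        shift_supply(.data$yield_growth, .data$shifter, "growth", horizon) +
          .data$trend * climate_change_on
      } else {
        .data$yield_growth + .data$trend * climate_change_on
      },
      level_mult = if (mode == "level") 1 + .data$shifter else 1
    )

  solve_one_year <- function(y) {
    dt <- y - base_year
    yr <- params |>
      dplyr::mutate(
        yield_t = .data$yield_base * .data$level_mult *
          (1 + .data$g_eff)^dt,
        supply_coef = .data$area_base * .data$yield_t,
        popf = (1 + .data$pop_growth)^dt,
        incf = (1 + .data$income_growth)^dt,
        demand_coef = .data$demand_base * .data$popf *
          .data$incf^.data$income_elast
      )
    yr |>
      dplyr::group_by(.data$crop) |>
      dplyr::mutate(price = clear_market(.data$supply_coef,
                                         .data$area_elast,
                                         .data$demand_coef,
                                         .data$demand_elast)) |>
      dplyr::ungroup() |>
      dplyr::transmute(
        year = y, climate_id = climate_id,
        region_id = .data$region_id, crop = .data$crop,
        price = .data$price,
        area = .data$area_base * .data$price^.data$area_elast,
        yield = .data$yield_t,
        production = .data$area * .data$yield,
        demand = .data$demand_coef * .data$price^.data$demand_elast,
        net_trade = .data$production - .data$demand,
        population = .data$base_population * .data$popf,
        feed_share = .data$feed_share
      )
  }
  out <- purrr::map(years, solve_one_year) |> purrr::list_rbind()
  class(out) <- c("csa_states", class(out))
  out
}

#' Solve a single market year
#'
#' Convenience wrapper around [project_market()] for one year.
#'
#' @inheritParams project_market
#' @param year The year to solve.
#' @return A one-year `csa_states` tibble.
#' @export
solve_year <- function(world, shifters = NULL, year = 2010, ...) {
  project_market(world, shifters, years = year, ...)
}

#' Livestock herd link
#'
#' Cheaper feed grain supports a larger herd: the herd responds to the feed
#' price with a (negative) constant elasticity, and extra animals carry
#' per-head emissions.
#'
#' @param base_herd Baseline herd size, head.
#' @param feed_price_elast Herd elasticity to the feed price (<= 0).
#' @param emissions_per_head t CO2e/head/yr (>= 0).
#'
#' @return A `livestock_link` list.
#' @export
livestock_link <- function(base_herd = 1.5e9, feed_price_elast = -0.2,
                           emissions_per_head = 2.0) {
  if (feed_price_elast > 0) {
    stopf("csascen_config_error", "feed_price_elast must be <= 0.")
  }
  check_nonneg(emissions_per_head, "emissions_per_head")
  structure(list(base_herd = base_herd,
                 feed_price_elast = feed_price_elast,
                 emissions_per_head = emissions_per_head),
            class = c("livestock_link", "list"))
}

#' Livestock-feed price feedback on cattle emissions
#'
#' @param price_ratio Feed price relative to the business-as-usual feed
#'   price (> 0); below 1 means cheaper feed.
#' @param link A [livestock_link()].
#'
#' @return One-row tibble: `herd`, `herd_delta` (head) and `emission_delta`
#'   (t CO2e/yr; positive when cheaper feed expands the herd).
#' @export
#' @examples
#' livestock_feedback(0.9, livestock_link())  # herd grows by ~2.1%
livestock_feedback <- function(price_ratio, link = livestock_link()) {
  if (any(price_ratio <= 0)) {
    stopf("csascen_domain_error", "price_ratio must be positive.")
  }
  herd <- link$base_herd * price_ratio^link$feed_price_elast
  tibble::tibble(
    herd = herd,
    herd_delta = herd - link$base_herd,
    emission_delta = (herd - link$base_herd) * link$emissions_per_head
  )
}

#' Production and price report against business as usual
#'
#' Per-crop percent changes between the first and last projected year, for
#' the scenario and its counterfactual, plus end-of-horizon scenario-minus-
#' counterfactual comparisons.
#'
#' @param states Scenario `csa_states` from [project_market()].
#' @param states_bau Counterfactual states on the same world, years and
#'   regions.
#' @param level `"world"` (default) or `"region"`.
#'
#' @return A tidy tibble: scope columns, `crop`, `metric`, `value` where
#'   metrics are `production_change_pct` and `price_change_pct` (first vs
#'   last year), and `production_vs_bau_pct`, `price_vs_bau_pct`
#'   (last-year scenario vs counterfactual, percent).
#' @export
production_report <- function(states, states_bau, level = c("world",
                                                            "region")) {
  level <- match.arg(level)
  key <- if (level == "world") "crop" else c("region_id", "crop")
  chk <- function(s) {
    s |>
      dplyr::group_by(dplyr::across(dplyr::all_of(key)), .data$year) |>
      dplyr::summarise(production = sum(.data$production),
                       price = .data$price[1], .groups = "drop")
  }
  a <- chk(states)
  b <- chk(states_bau)
  if (!identical(dim(a), dim(b)) ||
      !identical(a[c(key, "year")], b[c(key, "year")])) {
    stopf("csascen_config_error",
          "scenario and counterfactual runs do not share a world/horizon.")
  }
  y0 <- min(a$year); y1 <- max(a$year)
  pick <- function(s, y) dplyr::filter(s, .data$year == y)
  joined <- pick(a, y1) |>
    dplyr::left_join(pick(a, y0), by = key, suffix = c("", "_base")) |>
    dplyr::left_join(pick(b, y1), by = key, suffix = c("", "_bau"))
  joined |>
    dplyr::transmute(
      dplyr::across(dplyr::all_of(key)),
      production_change_pct =
        100 * (.data$production / .data$production_base - 1),
      price_change_pct = 100 * (.data$price / .data$price_base - 1),
      production_vs_bau_pct =
        100 * (.data$production / .data$production_bau - 1),
      price_vs_bau_pct = 100 * (.data$price / .data$price_bau - 1)
    ) |>
    tidyr::pivot_longer(cols = -dplyr::all_of(key), names_to = "metric",
                        values_to = "value")
}
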