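#' IPCC Tier-1 emission factors for cropland accounting
#'
#' Bundles every coefficient of the greenhouse-gas arithmetic. Direct N2O:
#' 1% of mineral-fertiliser N, 1% of organic-amendment N and 1% of N
#' mineralised from soil organic matter are emitted as N2O-N; the
#' crop-residue channel uses the residue-specific 0.7% by default (set
#' `ef_n_residue = 0.01` for the uniform-1% reading); flooded rice soils use
#' 0.3% of applied (mineral + manure) N. Rice CH4 follows the Tier-1 form
#' `baseline x water-regime scaling x organic-amendment scaling x days`:
#' baseline 1.3 kg CH4/ha/day, scaling 1 for continuous flooding and 0.52
#' for multiple drainage, amendment scaling `(1 + straw + 0.14 fym)^0.59`
#' (straw in t/ha with conversion factor 1, farmyard manure with conversion
#' factor 0.14, exponent 0.59).
#'
#' Gas masses become CO2 equivalents with 100-yr global warming potentials;
#' defaults are the AR5 values including climate-carbon feedbacks (CH4 34,
#' N2O 298) and are configurable.
#'
#' @param ef_n_mineral,ef_n_organic,ef_n_mineralized Fraction of the channel's
#'   N emitted as N2O-N (non-flooded soils).
#' @param ef_n_residue Fraction for the crop-residue channel.
#' @param ef_n_flooded Fraction of applied N for flooded rice soils.
#' @param ch4_ef_base Baseline CH4 emission factor, kg CH4/ha/day.
#' @param sf_continuous,sf_multiple_drainage Water-regime scaling factors.
#' @param straw_param Exponent of the organic-amendment scaling.
#' @param cfoa_fym Conversion factor of farmyard manure relative to straw.
#' @param gwp_ch4,gwp_n2o 100-yr global warming potentials.
#'
#' @return An `emission_factors` list.
#' @export
#' @examples
#' ef <- emission_factors()
#' ch4_season(100, "continuous_flooding", ef = ef)  # 130 kg CH4/ha
emission_factors <- function(ef_n_mineral = 0.01, ef_n_organic = 0.01,
                             ef_n_mineralized = 0.01, ef_n_residue = 0.007,
                             ef_n_flooded = 0.003,
                             ch4_ef_base = 1.3, sf_continuous = 1.0,
                             sf_multiple_drainage = 0.52,
                             straw_param = 0.59, cfoa_fym = 0.14,
                             gwp_ch4 = 34, gwp_n2o = 298) {
  ef <- as.list(environment())
  vals <- unlist(ef)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    stopf("csascen_config_error", "all emission factors must be >= 0.")
  }
  if (ef$sf_multiple_drainage > ef$sf_continuous) {
    stopf("csascen_config_error",
          "sf_multiple_drainage may not exceed sf_continuous.")
  }
  structure(ef, class = c("emission_factors", "list"))
}

#' Direct N2O emissions from nitrogen inputs
#'
#' Emission-factor arithmetic per hectare and year. On non-flooded soils the
#' four N channels contribute independently; on flooded rice soils a single
#' factor applies to applied N (mineral + manure). Linear in every input and
#' vectorised.
#'
#' @param n_mineral,n_manure,n_residue,n_mineralized N inputs, kg N/ha.
#' @param flooded Logical; flooded rice soil?
#' @param ef An [emission_factors()].
#'
#' @return kg N2O-N/ha (multiply by 44/28 for kg N2O/ha).
#' @export
#' @examples
#' n2o_direct(100, 0, 0, 0)          # 1.0 kg N2O-N/ha
#' n2o_direct(0, 0, 50, 0)           # 0.35: residue channel at 0.7%
#' n2o_direct(100, 20, 0, 0, flooded = TRUE)  # 0.003 * 120
n2o_direct <- function(n_mineral, n_manure = 0, n_residue = 0,
                       n_mineralized = 0, flooded = FALSE,
                       ef = emission_factors()) {
  check_nonneg(n_mineral, "n_mineral")
  check_nonneg(n_manure, "n_manure")
  check_nonneg(n_residue, "n_residue")
  check_nonneg(n_mineralized, "n_mineralized")
  ifelse(flooded,
         ef$ef_n_flooded * (n_mineral + n_manure),
         ef$ef_n_mineral * n_mineral + ef$ef_n_organic * n_manure +
           ef$ef_n_residue * n_residue +
           ef$ef_n_mineralized * n_mineralized)
}

#' Seasonal rice CH4 emissions (Tier-1)
#'
#' `ch4 = ch4_ef_base * sf(regime) * (1 + straw + cfoa_fym * fym)^straw_param
#' * season_days`. The regime `"none"` (upland / non-rice) emits nothing.
#'
#' @param season_days Growing-season length, days.
#' @param regime One of `"continuous_flooding"`, `"multiple_drainage"`,
#'   `"none"`.
#' @param straw_rate Rice straw incorporated, t/ha.
#' @param fym_rate Farmyard manure applied, t/ha.
#' @param ef An [emission_factors()].
#'
#' @return kg CH4/ha over the season.
#' @export
#' @examples
#' ch4_season(100, "continuous_flooding")                   # 130
#' ch4_season(100, "multiple_drainage") / ch4_season(100, "continuous_flooding")
ch4_season <- function(season_days, regime, straw_rate = 0, fym_rate = 0,
                       ef = emission_factors()) {
  check_nonneg(season_days, "season_days")
  check_nonneg(straw_rate, "straw_rate")
  check_nonneg(fym_rate, "fym_rate")
  bad <- setdiff(unique(regime), csa_regimes)
  if (length(bad)) {
    stopf("csascen_domain_error", "unknown water regime: %s",
          paste(bad, collapse = ", "))
  }
  sf_w <- dplyr::case_when(
    regime == "continuous_flooding" ~ ef$sf_continuous,
    regime == "multiple_drainage" ~ ef$sf_multiple_drainage,
    .default = 0
  )
  sf_o <- (1 + straw_rate + ef$cfoa_fym * fym_rate)^ef$straw_param
  ef$ch4_ef_base * sf_w * sf_o * season_days
}

#' Convert gas masses and soil-carbon change to CO2 equivalents
#'
#' `(gwp_n2o * n2o_mass + gwp_ch4 * ch4_mass) / 1000 - soc_delta * 44/12`:
#' gains in soil organic carbon count as negative emissions through the
#' C -> CO2 stoichiometric ratio.
#'
#' @param n2o_mass kg N2O/ha/yr.
#' @param ch4_mass kg CH4/ha/yr.
#' @param soc_delta Soil organic carbon change, t C/ha/yr (gain positive).
#' @param ef An [emission_factors()] supplying the warming potentials.
#'
#' @return t CO2e/ha/yr (net; may be negative).
#' @export
#' @examples
#' to_co2e(0, 1000, 0)   # 34 t with the default GWP
#' to_co2e(0, 0, 1)      # -44/12
to_co2e <- function(n2o_mass, ch4_mass, soc_delta = 0,
                    ef = emission_factors()) {
  check_nonneg(n2o_mass, "n2o_mass")
  check_nonneg(ch4_mass, "ch4_mass")
  (ef$gwp_n2o * n2o_mass + ef$gwp_ch4 * ch4_mass) / 1000 -
    soc_delta * 44 / 12
}

#' Per-cell emission ledger
#'
#' Composes [n2o_direct()], [ch4_season()] and [to_co2e()] over a table of
#' grid cells, either under current practice (`responses = NULL`, one
#' business-as-usual row per cell) or under the supplied practice responses
#' (one row per response; responses may override the water regime and N
#' channels). Emission intensity is net CO2e per tonne of fresh output,
#' `co2e_total / (yield_base * (1 + yield_delta))`; when realised yield is
#' non-positive, intensity is `NA` and flagged rather than an error.
#'
#' @param cells World cells tibble (see [generate_world()]).
#' @param responses Optional practice-response tibble, already filtered to a
#'   single climate path; `NULL` means current practice.
#' @param ef An [emission_factors()].
#'
#' @return A tibble, one row per cell x practice: gas masses, `soc_delta`,
#'   `co2e_total` (t CO2e/ha/yr), realised `yield_out` (t/ha), `intensity`
#'   (t CO2e/t) and `intensity_defined`.
#' @export
emission_ledger <- function(cells, responses = NULL,
                            ef = emission_factors()) {
  if (is.null(responses)) {
    dat <- cells |>
      dplyr::mutate(practice = "bau", yield_delta = 0, soc_delta = 0,
                    regime = .data$water_regime)
  } else {
    dat <- responses |>
      dplyr::inner_join(cells, by = "cell_id") |>
      dplyr::mutate(
        n_mineral = dplyr::coalesce(.data$n_mineral_new, .data$n_mineral),
        n_manure = dplyr::coalesce(.data$n_manure_new, .data$n_manure),
        regime = .data$water_regime_out
      )
    if (nrow(dat) < nrow(responses)) {
      stopf("csascen_join_error",
            "responses reference cell_ids absent from `cells`.")
    }
  }
  dat |>
    dplyr::mutate(
      flooded = .data$regime != "none",
      n2o_n = n2o_direct(.data$n_mineral, .data$n_manure, .data$n_residue,
                         .data$n_mineralized, .data$flooded, ef),
      n2o_mass = .data$n2o_n * 44 / 28,
      ch4_mass = ifelse(
        .data$crop == "rice",
        ch4_season(.data$season_days, .data$regime, .data$straw_rate,
                   .data$fym_rate, ef),
        0
      ),
      co2e_total = to_co2e(.data$n2o_mass, .data$ch4_mass, .data$soc_delta,
                           ef),
      yield_out = .data$yield_base * (1 + .data$yield_delta),
      intensity_defined = .data$yield_out > 0,
      intensity = ifelse(.data$intensity_defined,
                         .data$co2e_total / .data$yield_out, NA_real_)
    ) |>
    dplyr::select("cell_id", "practice",
                  dplyr::any_of("climate_id"), "n2o_n", "n2o_mass",
                  "ch4_mass", "soc_delta", "co2e_total", "yield_out",
                  "intensity", "intensity_defined")
}

#' Aggregate per-hectare emissions to totals
#'
#' Multiplies each ledger row's net per-hectare CO2e by the cell's harvested
#' area and sums by the requested grouping. Group totals partition the world
#' total exactly.
#'
#' @param ledger A ledger from [emission_ledger()] (one row per cell).
#' @param cells World cells supplying `area`, `fpu_id`, `country_id`.
#' @param level `"cell"`, `"fpu"`, `"country"` or `"world"`.
#' @param weight Name of the ledger column scaled by area (default
#'   `"co2e_total"`; any per-ha gas column works).
#'
#' @return A tibble with the grouping id and `total` (t CO2e/yr for the
#'   default weight).
#' @export
aggregate_emissions <- function(ledger, cells,
                                level = c("world", "country", "fpu", "cell"),
                                weight = "co2e_total") {
  level <- match.arg(level)
  joined <- ledger |>
    dplyr::inner_join(
      dplyr::select(cells, "cell_id", "fpu_id", "country_id", "area"),
      by = "cell_id"
    )
  if (nrow(joined) < nrow(ledger)) {
    stopf("csascen_join_error", "area missing for some ledger rows.")
  }
  joined <- dplyr::mutate(joined, contrib = .data[[weight]] * .data$area)
  key <- switch(level, cell = "cell_id", fpu = "fpu_id",
                country = "country_id", world = NULL)
  if (is.null(key)) {
    tibble::tibble(level = "world", total = sum(joined$contrib))
  } else {
    joined |>
      dplyr::group_by(dplyr::across(dplyr::all_of(key))) |>
      dplyr::summarise(total = sum(.data$contrib), .groups = "drop")
  }
}
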