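#' Configuration for the synthetic world generator
#'
#' Describes the statistical structure of the synthetic gridded world that
#' stands in for real crop-allocation grids, crop-model runs and climate
#' rasters: grid size, administrative nesting (cells within food production
#' units, FPUs, within countries), the crop mix, baseline agronomy
#' distributions, per-practice response distributions, two contrasting
#' pseudo-climate paths and SSP2-style macro growth.
#'
#' Yield deltas are drawn per practice from truncated normal distributions
#' (bounds `yield_delta_bounds`) so that both gains and losses occur; the
#' adoption rules do the filtering. Manure N is log-normal across cells,
#' mimicking a skewed site-specific application raster.
#'
#' @param n_cells Number of grid cells (cell x crop x water-system production
#'   units). Default 2000: large enough for quartile statistics per FPU,
#'   small enough for seconds-scale runs.
#' @param n_fpus Number of food production units. Each FPU belongs to exactly
#'   one country and receives at least one cell.
#' @param n_countries Number of countries (also the market regions).
#' @param crop_weights Named sampling weights over `maize`, `wheat`, `rice`.
#' @param irrigated_share Named per-crop probability that a cell is irrigated.
#' @param area_meanlog,area_sdlog Log-normal parameters for harvested area (ha).
#' @param yield_mean,yield_sd Named per-crop baseline yield distribution
#'   (t fresh matter/ha), truncated below at `yield_floor`.
#' @param yield_floor Lower truncation for baseline yields (t/ha), must be > 0.
#' @param n_mineral_mean,n_mineral_sd Mineral fertiliser N (kg N/ha), per crop.
#' @param n_manure_meanlog,n_manure_sdlog Log-normal manure N (kg N/ha).
#' @param n_residue_mean,n_residue_sd Crop-residue N returned (kg N/ha).
#' @param n_mineralized_mean,n_mineralized_sd N mineralised from soil organic
#'   matter (kg N/ha).
#' @param season_days_range Named list of per-crop `c(min, max)` growing-season
#'   lengths (days); values are clamped to \[60, 250\].
#' @param straw_meanlog,straw_sdlog Log-normal rice straw incorporation (t/ha).
#' @param fym_meanlog,fym_sdlog Log-normal farmyard-manure amendment (t/ha),
#'   rice cells only.
#' @param practices Named list (one entry per practice) of lists with
#'   `yield_delta_mean`, `yield_delta_sd`, `soc_delta_mean`, `soc_delta_sd`
#'   (t C/ha/yr). Defaults encode the qualitative practice evidence: no-till
#'   and ISFM mostly gain yield and build soil carbon; NUE gains modestly;
#'   AWD is yield-neutral-to-slightly-negative with large CH4 benefits
#'   handled by the water regime, not by `soc_delta`.
#' @param yield_delta_bounds Truncation bounds for yield deltas (fraction).
#' @param isfm_extra_manure_meanlog,isfm_extra_manure_sdlog Log-normal extra
#'   manure N (kg N/ha) that ISFM adds on top of the baseline channels.
#' @param climate_trends Named list (one per climate path) of
#'   `list(mean, sd)` annual baseline-yield trend modifiers (fraction/yr)
#'   drawn per FPU x crop. The "hot" path is more damaging on average than
#'   the "dry/cool" path.
#' @param pop_growth Annual population growth (fraction/yr), SSP2-style 0.006.
#' @param income_growth Annual per-capita income growth (fraction/yr), ~0.02.
#' @param base_population_meanlog,base_population_sdlog Log-normal base-year
#'   regional population.
#' @param base_income_meanlog,base_income_sdlog Log-normal base-year per-capita
#'   income.
#' @param no_till_excluded_countries Country ids where no-till is never
#'   eligible (six high-historical-adoption countries in the study design).
#' @param market Named list of market-parameter draw ranges:
#'   `area_elast` (own-price area elasticity, >= 0), `demand_elast`
#'   (own-price demand elasticity, <= 0), `income_elast`, `yield_growth`
#'   (exogenous yield trend, fraction/yr) and per-crop `feed_share` ranges
#'   (share of demand used as livestock feed).
#'
#' @return A `csa_config` list, validated.
#' @export
#' @examples
#' cfg <- world_config(n_cells = 200, n_fpus = 10, n_countries = 5)
#' cfg$n_cells
world_config <- function(
    n_cells = 2000,
    n_fpus = 40,
    n_countries = 15,
    crop_weights = c(maize = 0.40, wheat = 0.35, rice = 0.25),
    irrigated_share = c(maize = 0.25, wheat = 0.35, rice = 0.60),
    area_meanlog = log(5e4),
    area_sdlog = 0.8,
    yield_mean = c(maize = 4.5, wheat = 3.0, rice = 4.2),
    yield_sd = c(maize = 1.2, wheat = 0.8, rice = 1.0),
    yield_floor = 0.3,
    n_mineral_mean = c(maize = 110, wheat = 90, rice = 100),
    n_mineral_sd = c(maize = 35, wheat = 30, rice = 30),
    n_manure_meanlog = log(12),
    n_manure_sdlog = 0.7,
    n_residue_mean = 25,
    n_residue_sd = 8,
    n_mineralized_mean = 20,
    n_mineralized_sd = 6,
    season_days_range = list(
      maize = c(100, 160), wheat = c(120, 220), rice = c(95, 165)
    ),
    straw_meanlog = log(2.0),
    straw_sdlog = 0.4,
    fym_meanlog = log(1.0),
    fym_sdlog = 0.6,
    practices = list(
      no_till = list(yield_delta_mean = 0.02, yield_delta_sd = 0.06,
                     soc_delta_mean = 0.15, soc_delta_sd = 0.15),
      isfm    = list(yield_delta_mean = 0.05, yield_delta_sd = 0.06,
                     soc_delta_mean = 0.20, soc_delta_sd = 0.15),
      nue     = list(yield_delta_mean = 0.04, yield_delta_sd = 0.05,
                     soc_delta_mean = 0.02, soc_delta_sd = 0.05),
      awd     = list(yield_delta_mean = -0.01, yield_delta_sd = 0.04,
                     soc_delta_mean = 0.00, soc_delta_sd = 0.03)
    ),
    yield_delta_bounds = c(-0.5, 0.5),
    isfm_extra_manure_meanlog = log(20),
    isfm_extra_manure_sdlog = 0.4,
    climate_trends = list(
      pseudo_dry_cool = list(mean = -0.0010, sd = 0.0020),
      pseudo_hot      = list(mean = -0.0030, sd = 0.0025)
    ),
    pop_growth = 0.006,
    income_growth = 0.02,
    base_population_meanlog = log(5e7),
    base_population_sdlog = 0.9,
    base_income_meanlog = log(8e3),
    base_income_sdlog = 0.7,
    no_till_excluded_countries = sprintf("C%02d", 1:6),
    market = list(
      area_elast = c(0.10, 0.40),
      demand_elast = c(-0.60, -0.25),
      income_elast = c(0.20, 0.60),
      yield_growth = c(0.005, 0.012),
      feed_share = list(
        maize = c(0.35, 0.55), wheat = c(0.10, 0.25), rice = c(0.00, 0.05)
      )
    )) {
  cfg <- as.list(environment())
  class(cfg) <- c("csa_config", "list")
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  if (cfg$n_fpus > cfg$n_cells) {
    stopf("csascen_config_error",
          "n_fpus (%d) may not exceed n_cells (%d).", cfg$n_fpus, cfg$n_cells)
  }
  if (cfg$n_countries > cfg$n_fpus) {
    stopf("csascen_config_error",
          "n_countries (%d) may not exceed n_fpus (%d).",
          cfg$n_countries, cfg$n_fpus)
  }
  if (any(cfg$yield_mean <= 0) || cfg$yield_floor <= 0) {
    stopf("csascen_config_error", "baseline yields must be positive.")
  }
  if (!setequal(names(cfg$crop_weights), csa_crops)) {
    stopf("csascen_config_error",
          "crop_weights must be named over maize, wheat, rice.")
  }
  missing_pr <- setdiff(csa_practices, names(cfg$practices))
  if (length(missing_pr)) {
    stopf("csascen_config_error",
          "practices must define: %s.", paste(missing_pr, collapse = ", "))
  }
  invisible(cfg)
}

#' Alternate wetting and drying water-cycle specification
#'
#' The AWD water regime alternates flooding and soil drying: the paddy is
#' flooded to `flood_depth`, the water table falls at `drawdown_rate` to
#' `min_level` below the surface, then the field is re-flooded at
#' `reflood_rate` back to `flood_depth`. Defaults are the standard
#' 10 cm / -0.5 cm per day / -5 cm / +0.5 cm per day cycle.
#'
#' @param flood_depth Initial flood depth, cm (> min_level).
#' @param drawdown_rate Water-level fall rate during drydown, cm/day (> 0).
#' @param min_level Level at which re-flooding starts, cm (may be negative:
#'   below the soil surface).
#' @param reflood_rate Water-level rise rate during re-flooding, cm/day (> 0).
#'
#' @return An `awd_water_spec` list.
#' @seealso [awd_cycle()]
#' @export
awd_water_spec <- function(flood_depth = 10, drawdown_rate = 0.5,
                           min_level = -5, reflood_rate = 0.5) {
  if (!is.finite(drawdown_rate) || drawdown_rate <= 0 ||
      !is.finite(reflood_rate) || reflood_rate <= 0) {
    stopf("csascen_invalid_spec",
          "drawdown_rate and reflood_rate must be positive.")
  }
  if (!is.finite(flood_depth) || !is.finite(min_level) ||
      min_level > flood_depth) {
    stopf("csascen_invalid_spec", "min_level may not exceed flood_depth.")
  }
  structure(list(flood_depth = flood_depth, drawdown_rate = drawdown_rate,
                 min_level = min_level, reflood_rate = reflood_rate),
            class = c("awd_water_spec", "list"))
}

#' Length and frequency of the AWD wet-dry cycle
#'
#' Computes, from an [awd_water_spec()], the number of days one drydown takes,
#' the length of a full dry-reflood cycle, and (when `season_days` is given)
#' how many complete drainage events fit into a growing season. Drydown time
#' is `(flood_depth - min_level) / drawdown_rate`; the reflood leg is the
#' analogous quotient; drainage events per season are
#' `floor(season_days / cycle_days)`.
#'
#' @param spec An [awd_water_spec()].
#' @param season_days Optional vector of growing-season lengths (days).
#'
#' @return A tibble with `drydown_days`, `reflood_days`, `cycle_days` and,
#'   when `season_days` is supplied, one row per season length with
#'   `season_days` and `drainage_events`.
#' @export
#' @examples
#' awd_cycle(awd_water_spec())            # 30-day drydown, 60-day cycle
#' awd_cycle(awd_water_spec(), 150)       # 2 drainage events in 150 days
awd_cycle <- function(spec = awd_water_spec(), season_days = NULL) {
  if (!inherits(spec, "awd_water_spec")) {
    spec <- do.call(awd_water_spec, as.list(spec))
  }
  drop <- spec$flood_depth - spec$min_level
  drydown <- drop / spec$drawdown_rate
  reflood <- drop / spec$reflood_rate
  cycle <- drydown + reflood
  out <- tibble::tibble(
    drydown_days = drydown, reflood_days = reflood, cycle_days = cycle
  )
  if (!is.null(season_days)) {
    check_nonneg(season_days, "season_days", "csascen_invalid_spec")
    out <- tidyr::crossing(out, season_days = season_days) |>
      dplyr::mutate(
        drainage_events = ifelse(.data$cycle_days > 0,
                                 floor(.data$season_days / .data$cycle_days),
                                 0)
      )
  }
  out
}
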