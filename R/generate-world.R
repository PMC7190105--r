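# truncated-normal draws by inverse-CDF so the draw count is fixed
# (keeps the generator bitwise reproducible for a given config + seed)
rtnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  plo <- pnorm(lower, mean, sd)
  phi <- pnorm(upper, mean, sd)
  qnorm(runif(n, plo, phi), mean, sd)
}

with_preserved_rng <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Generate a seeded synthetic world
#'
#' Builds the full synthetic data layer the scenario pipeline runs on: grid
#' cells nested in food production units (FPUs) and countries, baseline
#' agronomy per cell, per-practice responses under two pseudo-climate paths,
#' FPU-level climate trend modifiers, SSP2-style macro trajectories, and
#' calibrated market parameters. Identical `(config, seed)` yields a
#' byte-identical world; the caller's RNG state is left untouched.
#'
#' Structural guarantees: every cell belongs to exactly one FPU and one
#' country; every FPU has at least one cell and belongs to one country;
#' practice responses only attach to compatible cells (no-till/ISFM to
#' maize and wheat, NUE to rice, AWD to irrigated rice); only rice may
#' carry a flooded water regime.
#'
#' Market calibration: base-year supply per region x crop comes from the
#' generated cells (total area x area-weighted yield); base-year demand is
#' allocated across regions in proportion to population and scaled so that
#' world supply equals world demand at a unit price, making the base year an
#' exact equilibrium at price 1 for every crop.
#'
#' @param config A [world_config()].
#' @param seed Integer seed; the only source of randomness.
#'
#' @return A `csa_world` list of tibbles: `cells`, `responses`, `climate`,
#'   `macro`, `market_params`, plus the `config` and `seed` used.
#' @export
#' @examples
#' w <- generate_world(world_config(n_cells = 300, n_fpus = 12,
#'                                  n_countries = 6), seed = 42)
#' dplyr::count(w$cells, crop)
generate_world <- function(config = world_config(), seed = 1L) {
  validate_config(config)
  with_preserved_rng(seed, build_world(config, seed))
}

build_world <- function(cfg, seed) {
  n <- cfg$n_cells
  countries <- sprintf("C%02d", seq_len(cfg$n_countries))
  fpus <- sprintf("F%03d", seq_len(cfg$n_fpus))
  fpu_country <- tibble::tibble(
    fpu_id = fpus,
    country_id = rep_len(countries, cfg$n_fpus)
  )

  # first n_fpus cells get one FPU each so no FPU is empty
  fpu_id <- c(fpus, sample(fpus, n - cfg$n_fpus, replace = TRUE))
  crop <- sample(csa_crops, n, replace = TRUE,
                 prob = cfg$crop_weights[csa_crops])
  irrigated <- runif(n) < cfg$irrigated_share[crop]

  season <- numeric(n)
  for (cr in csa_crops) {
    idx <- crop == cr
    rng <- pmin(pmax(cfg$season_days_range[[cr]], 60), 250)
    season[idx] <- round(runif(sum(idx), rng[1], rng[2]))
  }

  is_rice <- crop == "rice"
  cells <- tibble::tibble(
    cell_id = sprintf("cell%05d", seq_len(n)),
    fpu_id = fpu_id,
    crop = crop,
    water_system = ifelse(irrigated, "irrigated", "rainfed"),
    # only irrigated rice is paddy-flooded in the baseline
    water_regime = ifelse(is_rice & irrigated, "continuous_flooding", "none"),
    area = rlnorm(n, cfg$area_meanlog, cfg$area_sdlog),
    yield_base = rtnorm(n, cfg$yield_mean[crop], cfg$yield_sd[crop],
                        lower = cfg$yield_floor),
    n_mineral = rtnorm(n, cfg$n_mineral_mean[crop], cfg$n_mineral_sd[crop],
                       lower = 0),
    n_manure = rlnorm(n, cfg$n_manure_meanlog, cfg$n_manure_sdlog),
    n_residue = rtnorm(n, cfg$n_residue_mean, cfg$n_residue_sd, lower = 0),
    n_mineralized = rtnorm(n, cfg$n_mineralized_mean, cfg$n_mineralized_sd,
                           lower = 0),
    season_days = season,
    straw_rate = ifelse(is_rice, rlnorm(n, cfg$straw_meanlog, cfg$straw_sdlog),
                        0),
    fym_rate = ifelse(is_rice, rlnorm(n, cfg$fym_meanlog, cfg$fym_sdlog), 0)
  ) |>
    dplyr::left_join(fpu_country, by = "fpu_id") |>
    dplyr::relocate("country_id", .after = "cell_id")

  responses <- build_responses(cells, cfg)
  climate <- build_climate(cfg)
  macro <- tibble::tibble(
    region_id = countries,
    base_population = rlnorm(cfg$n_countries, cfg$base_population_meanlog,
                             cfg$base_population_sdlog),
    base_income = rlnorm(cfg$n_countries, cfg$base_income_meanlog,
                         cfg$base_income_sdlog),
    pop_growth = cfg$pop_growth,
    income_growth = cfg$income_growth
  )
  market_params <- build_market_params(cells, macro, cfg)

  structure(
    list(cells = cells, responses = responses, climate = climate,
         macro = macro, market_params = market_params,
         config = cfg, seed = seed),
    class = c("csa_world", "list")
  )
}

build_responses <- function(cells, cfg) {
  elig <- cells |>
    dplyr::select("cell_id", "crop", "water_system", "n_manure") |>
    dplyr::mutate(practice = purrr::map(.data$crop, ~ practice_compat[[.x]])) |>
    tidyr::unnest("practice") |>
    dplyr::filter(!(.data$practice == "awd" &
                      .data$water_system != "irrigated"))
  elig <- tidyr::crossing(elig, climate_id = csa_climates) |>
    dplyr::arrange(.data$cell_id, .data$practice, .data$climate_id)

  m <- nrow(elig)
  pr <- cfg$practices
  ydm <- purrr::map_dbl(pr, "yield_delta_mean")[elig$practice]
  yds <- purrr::map_dbl(pr, "yield_delta_sd")[elig$practice]
  scm <- purrr::map_dbl(pr, "soc_delta_mean")[elig$practice]
  scs <- purrr::map_dbl(pr, "soc_delta_sd")[elig$practice]
  bnd <- cfg$yield_delta_bounds

  elig |>
    dplyr::mutate(
      yield_delta = rtnorm(m, ydm, yds, bnd[1], bnd[2]),
      soc_delta = rnorm(m, scm, scs),
      water_regime_out = dplyr::case_when(
        .data$practice == "awd" ~ "multiple_drainage",
        .data$crop == "rice" & .data$water_system == "irrigated" ~
          "continuous_flooding",
        .default = "none"
      ),
      # ISFM layers organic amendment on top of the baseline manure channel
      n_manure_new = ifelse(
        .data$practice == "isfm",
        .data$n_manure + rlnorm(m, cfg$isfm_extra_manure_meanlog,
                                cfg$isfm_extra_manure_sdlog),
        NA_real_
      ),
      n_mineral_new = NA_real_
    ) |>
    dplyr::select("cell_id", "practice", "climate_id", "yield_delta",
                  "soc_delta", "water_regime_out", "n_mineral_new",
                  "n_manure_new")
}

build_climate <- function(cfg) {
  grid <- tidyr::crossing(
    climate_id = names(cfg$climate_trends),
    fpu_id = sprintf("F%03d", seq_len(cfg$n_fpus)),
    crop = csa_crops
  ) |> dplyr::arrange(.data$climate_id, .data$fpu_id, .data$crop)
  mu <- purrr::map_dbl(cfg$climate_trends, "mean")[grid$climate_id]
  sg <- purrr::map_dbl(cfg$climate_trends, "sd")[grid$climate_id]
  grid$trend_delta <- rnorm(nrow(grid), mu, sg)
  grid
}

build_market_params <- function(cells, macro, cfg) {
  base <- cells |>
    dplyr::group_by(region_id = .data$country_id, .data$crop) |>
    dplyr::summarise(
      area_base = sum(.data$area),
      yield_base = weighted.mean(.data$yield_base, .data$area),
      .groups = "drop"
    )
  grid <- tidyr::crossing(region_id = macro$region_id, crop = csa_crops) |>
    dplyr::left_join(base, by = c("region_id", "crop")) |>
    dplyr::mutate(
      area_base = dplyr::coalesce(.data$area_base, 1e3),
      yield_base = dplyr::coalesce(.data$yield_base,
                                   cfg$yield_mean[.data$crop])
    )
  mk <- cfg$market
  k <- nrow(grid)
  fs_lo <- purrr::map_dbl(mk$feed_share, 1)[grid$crop]
  fs_hi <- purrr::map_dbl(mk$feed_share, 2)[grid$crop]
  grid <- grid |>
    dplyr::mutate(
      area_elast = runif(k, mk$area_elast[1], mk$area_elast[2]),
      demand_elast = runif(k, mk$demand_elast[1], mk$demand_elast[2]),
      income_elast = runif(k, mk$income_elast[1], mk$income_elast[2]),
      yield_growth = runif(k, mk$yield_growth[1], mk$yield_growth[2]),
      feed_share = runif(k, fs_lo, fs_hi)
    )
  # demand intercepts: regional shares follow population; world totals match
  # base supply so P = 1 clears every crop market in the base year
  pop <- macro |> dplyr::select("region_id", "base_population")
  grid |>
    dplyr::left_join(pop, by = "region_id") |>
    dplyr::group_by(.data$crop) |>
    dplyr::mutate(
      supply_base = .data$area_base * .data$yield_base,
      demand_base = sum(.data$supply_base) *
        .data$base_population / sum(.data$base_population)
    ) |>
    dplyr::ungroup() |>
    dplyr::select(-"base_population")
}

#' @export
print.csa_world <- function(x, ...) {
  cat("<csa_world> seed", x$seed, "\n")
  cat("  cells:     ", nrow(x$cells), "(",
      length(unique(x$cells$fpu_id)), "FPUs,",
      length(unique(x$cells$country_id)), "countries )\n")
  cat("  responses: ", nrow(x$responses), "practice x climate rows\n")
  cat("  climates:  ", paste(unique(x$climate$climate_id), collapse = ", "),
      "\n")
  invisible(x)
}
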