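# Shared fixtures, all generated in code.

tiny_world <- function(n_cells = 300, n_fpus = 12, n_countries = 6,
                       seed = 101, ...) {
  generate_world(world_config(n_cells = n_cells, n_fpus = n_fpus,
                              n_countries = n_countries, ...), seed = seed)
}

# a hand-built cell table covering every crop/water-system case
manual_cells <- function() {
  tibble::tibble(
    cell_id = c("a", "b", "c", "d"),
    country_id = c("C01", "C01", "C02", "C02"),
    fpu_id = c("F1", "F1", "F2", "F2"),
    crop = c("maize", "wheat", "rice", "rice"),
    water_system = c("rainfed", "irrigated", "irrigated", "rainfed"),
    water_regime = c("none", "none", "continuous_flooding", "none"),
    area = c(10, 20, 30, 40),
    yield_base = c(4, 3, 5, 2.5),
    n_mineral = c(100, 80, 90, 40),
    n_manure = c(10, 5, 20, 0),
    n_residue = c(20, 25, 15, 10),
    n_mineralized = c(15, 10, 25, 20),
    season_days = c(120, 150, 130, 110),
    straw_rate = c(0, 0, 2, 1),
    fym_rate = c(0, 0, 1, 0)
  )
}

# one response row per named argument override
manual_response <- function(cell_id, practice, yield_delta,
                            soc_delta = 0, climate_id = "pseudo_dry_cool",
                            water_regime_out = "none",
                            n_mineral_new = NA_real_,
                            n_manure_new = NA_real_) {
  tibble::tibble(cell_id = cell_id, practice = practice,
                 climate_id = climate_id, yield_delta = yield_delta,
                 soc_delta = soc_delta, water_regime_out = water_regime_out,
                 n_mineral_new = n_mineral_new, n_manure_new = n_manure_new)
}
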