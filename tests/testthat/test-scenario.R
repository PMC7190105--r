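test_that("the scenario matrix enumerates the full design", {
  m <- build_scenario_matrix()
  expect_identical(nrow(m), 26L)
  expect_identical(sum(m$scenario == "bau"), 2L)
  expect_identical(nrow(dplyr::distinct(m)), 26L)
  expect_true(all(is.na(m$tailoring[m$scenario == "bau"])))
  # reduced designs
  m2 <- build_scenario_matrix(climates = "pseudo_hot",
                              tailorings = "average")
  expect_identical(nrow(m2), 5L)
  m3 <- build_scenario_matrix(schemes = character())
  expect_identical(nrow(m3), 2L)
  expect_true(all(m3$scenario == "bau"))
  expect_error(build_scenario_matrix(schemes = "rule9"),
               class = "csascen_config_error")
  expect_error(build_scenario_matrix(climates = character()),
               class = "csascen_config_error")
})

test_that("a world with no improving practice collapses to BAU outputs", {
  losing <- lapply(
    stats::setNames(csa_practices, csa_practices),
    function(p) list(yield_delta_mean = -0.25, yield_delta_sd = 0.03,
                     soc_delta_mean = 0, soc_delta_sd = 0.05)
  )
  w <- generate_world(world_config(n_cells = 150, n_fpus = 6,
                                   n_countries = 3, practices = losing),
                      seed = 8)
  # truncation keeps deltas below zero with this configuration
  expect_true(all(w$responses$yield_delta < 0))
  bau <- run_scenario(w, "bau", "pseudo_hot", years = 2010:2025)
  r1 <- run_scenario(w, "rule1", "pseudo_hot", "average",
                     years = 2010:2025)
  expect_true(all(r1$decisions$chosen == "retain_current"))
  expect_equal(r1$states, bau$states)
  expect_equal(r1$emissions$abatement, 0)
  expect_equal(r1$indicators, bau$indicators)
})

test_that("scenario runs are deterministic", {
  w <- tiny_world(n_cells = 150, n_fpus = 6, n_countries = 3)
  a <- run_scenario(w, "rule2", "pseudo_dry_cool", "poor",
                    years = 2010:2020)
  b <- run_scenario(w, "rule2", "pseudo_dry_cool", "poor",
                    years = 2010:2020)
  expect_equal(a, b)
})

test_that("tailoring levels order production and prices monotonically", {
  w <- tiny_world(n_cells = 400, n_fpus = 10, n_countries = 5)
  runs <- lapply(c("poor", "average", "optimal"), function(tl) {
    run_scenario(w, "rule1", "pseudo_dry_cool", tl)
  })
  prod2050 <- sapply(runs, function(r) {
    sum(dplyr::filter(r$states, year == 2050)$production)
  })
  price2050 <- sapply(runs, function(r) {
    mean(dplyr::distinct(dplyr::filter(r$states, year == 2050),
                         crop, price)$price)
  })
  expect_true(all(diff(prod2050) >= 0))
  expect_true(all(diff(price2050) <= 0))
  # FPU shifters themselves are ordered poor <= average <= optimal
  sh <- runs[[1]]$shifters |>
    tidyr::pivot_wider(names_from = "tailoring", values_from = "shifter")
  expect_true(all(sh$poor <= sh$average + 1e-12))
  expect_true(all(sh$average <= sh$optimal + 1e-12))
})

test_that("partial adoption rates shrink both market and emission deltas", {
  w <- tiny_world(n_cells = 300, n_fpus = 10, n_countries = 5)
  full <- run_scenario(w, "rule1", "pseudo_hot", "average")
  capped <- run_scenario(w, "rule1_rates", "pseudo_hot", "average",
                         rate_table = default_adoption_rates(w, 0.4))
  expect_lt(adopted_area(capped$decisions, w$cells)$area_ha,
            adopted_area(full$decisions, w$cells)$area_ha)
  expect_lte(abs(capped$emissions$abatement),
             abs(full$emissions$abatement))
  delta <- function(r, m) {
    dplyr::filter(tidy(r), metric == m)$value
  }
  for (m in c("production_vs_bau_pct_rice", "production_vs_bau_pct_maize",
              "price_vs_bau_pct_rice")) {
    expect_lte(abs(delta(capped, m)), abs(delta(full, m)) + 1e-9)
  }
})

test_that("removing climate change lifts production where trends harm", {
  cfg <- world_config(
    n_cells = 150, n_fpus = 6, n_countries = 3,
    climate_trends = list(
      pseudo_dry_cool = list(mean = -0.004, sd = 0.001),
      pseudo_hot = list(mean = -0.006, sd = 0.001)
    )
  )
  w <- generate_world(cfg, seed = 21)
  expect_true(all(w$climate$trend_delta < 0))
  on <- run_scenario(w, "bau", "pseudo_hot", climate_change_on = TRUE)
  off <- run_scenario(w, "bau", "pseudo_hot", climate_change_on = FALSE)
  p_on <- sum(dplyr::filter(on$states, year == 2050)$production)
  p_off <- sum(dplyr::filter(off$states, year == 2050)$production)
  expect_gt(p_off, p_on)
})

test_that("summaries follow the mean-plus-range convention", {
  w <- tiny_world(n_cells = 200, n_fpus = 8, n_countries = 4)
  m <- build_scenario_matrix(schemes = c("rule1", "rule2"))
  runs <- run_matrix(w, m, years = 2010:2030)
  expect_length(runs, 14)
  s <- summarize_runs(runs)
  expect_true(all(s$min <= s$mean + 1e-9))
  expect_true(all(s$mean <= s$max + 1e-9))
  # the mean is the two-climate average at average tailoring
  long <- purrr::map(runs, tidy) |> purrr::list_rbind()
  one <- dplyr::filter(long, scenario == "rule1",
                       tailoring == "average",
                       metric == "abatement_mt_co2e")
  expect_identical(nrow(one), 2L)
  expect_equal(
    dplyr::filter(s, scenario == "rule1",
                  metric == "abatement_mt_co2e")$mean,
    mean(one$value)
  )
  # the range spans climate x tailoring
  allr1 <- dplyr::filter(long, scenario == "rule1",
                         metric == "abatement_mt_co2e")
  expect_equal(dplyr::filter(s, scenario == "rule1",
                             metric == "abatement_mt_co2e")$min,
               min(allr1$value))
  expect_equal(dplyr::filter(s, scenario == "rule1",
                             metric == "abatement_mt_co2e")$max,
               max(allr1$value))
  # degenerate: identical runs collapse mean = min = max
  same <- suppressWarnings(
    summarize_runs(structure(list(runs[[3]], runs[[3]]),
                             class = c("csa_runs", "list")))
  )
  expect_equal(same$min, same$mean)
  expect_equal(same$max, same$mean)
})

test_that("reported world production equals the sum of regional states", {
  w <- tiny_world(n_cells = 150, n_fpus = 6, n_countries = 3)
  r <- run_scenario(w, "rule1", "pseudo_dry_cool", "average",
                    years = 2010:2030)
  prod_change <- dplyr::filter(r$report, crop == "maize",
                               metric == "production_change_pct")$value
  st <- r$states
  direct <- 100 * (sum(st$production[st$year == 2030 &
                                       st$crop == "maize"]) /
                     sum(st$production[st$year == 2010 &
                                         st$crop == "maize"]) - 1)
  expect_equal(prod_change, direct, tolerance = 1e-12)
})

test_that("world serialisation round-trips through CSV", {
  w <- tiny_world(n_cells = 80, n_fpus = 5, n_countries = 5)
  dir <- withr::local_tempdir()
  write_world(w, dir)
  expect_setequal(list.files(dir),
                  c("cells.csv", "responses.csv", "climate.csv",
                    "macro.csv", "market_params.csv"))
  w2 <- read_world(dir)
  for (tb in c("cells", "responses", "climate", "macro",
               "market_params")) {
    expect_equal(as.data.frame(w2[[tb]]), as.data.frame(w[[tb]]),
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
  expect_error(read_world(file.path(dir, "missing")),
               class = "csascen_io_error")
})

test_that("tidiers and plots expose the run results", {
  w <- tiny_world(n_cells = 100, n_fpus = 5, n_countries = 5)
  r <- run_scenario(w, "rule1", "pseudo_hot", "average",
                    years = 2010:2020)
  td <- tidy(r)
  expect_in(c("adopted_area_mha", "abatement_mt_co2e",
              "at_risk_delta_m", "price_vs_bau_pct_rice"), td$metric)
  gl <- glance(r)
  expect_identical(nrow(gl), 1L)
  expect_equal(gl$abatement_mt_co2e,
               td$value[td$metric == "abatement_mt_co2e"])
  expect_s3_class(glance(w), "tbl_df")
  expect_identical(tidy(w, "cells"), w$cells)
  p1 <- ggplot2::autoplot(r$states)
  expect_s3_class(p1, "ggplot")
  runs <- structure(list(r), class = c("csa_runs", "list"))
  p2 <- suppressWarnings(ggplot2::autoplot(summarize_runs(runs)))
  expect_s3_class(p2, "ggplot")
  p3 <- plot_adoption_gains(r$decisions)
  expect_s3_class(p3, "ggplot")
})
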