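#' Tidy a scenario run into long headline metrics
#'
#' One row per metric: total adopted area (Mha), emission abatement versus
#' business as usual (Mt CO2e/yr), per-crop production and price changes
#' between the first and last projected year and versus BAU (percent),
#' end-of-horizon changes in the population at risk of hunger and in
#' undernourished children versus BAU (millions; negative is an
#' improvement), and the livestock feedback on cattle emissions
#' (Mt CO2e/yr).
#'
#' @param x A `csa_run`.
#' @param ... Unused.
#' @return A tibble `scenario`, `climate_id`, `tailoring`, `metric`,
#'   `value`.
#' @exportS3Method generics::tidy
tidy.csa_run <- function(x, ...) {
  y1 <- max(x$states$year)
  final <- function(ind) dplyr::filter(ind, .data$year == y1)
  at_risk_delta <- sum(final(x$indicators)$at_risk) -
    sum(final(x$indicators_bau)$at_risk)
  children_delta <- sum(final(x$indicators)$children) -
    sum(final(x$indicators_bau)$children)

  report_metrics <- x$report |>
    dplyr::transmute(metric = paste0(.data$metric, "_", .data$crop),
                     value = .data$value)
  metrics <- dplyr::bind_rows(
    tibble::tibble(
      metric = c("adopted_area_mha", "abatement_mt_co2e",
                 "at_risk_delta_m", "children_delta_m",
                 "livestock_emission_delta_mt"),
      value = c(sum(x$adopted$area_ha[x$adopted$chosen !=
                                        "retain_current"]) / 1e6,
                x$emissions$abatement / 1e6,
                at_risk_delta / 1e6,
                children_delta / 1e6,
                x$livestock$emission_delta / 1e6)
    ),
    report_metrics
  )
  tibble::tibble(
    scenario = x$spec$scenario,
    climate_id = x$spec$climate_id,
    tailoring = x$spec$tailoring,
    metrics
  )
}

#' One-row summary of a scenario run
#'
#' @param x A `csa_run`.
#' @param ... Unused.
#' @return A one-row wide tibble of the [tidy.csa_run()] metrics.
#' @exportS3Method generics::glance
glance.csa_run <- function(x, ...) {
  tidy(x) |>
    tidyr::pivot_wider(names_from = "metric", values_from = "value")
}

#' Tidy a synthetic world
#'
#' @param x A `csa_world`.
#' @param table Which table to return.
#' @param ... Unused.
#' @return The requested world tibble.
#' @exportS3Method generics::tidy
tidy.csa_world <- function(x, table = c("cells", "responses", "climate",
                                        "macro", "market_params"), ...) {
  x[[match.arg(table)]]
}

#' One-row structural summary of a synthetic world
#'
#' @param x A `csa_world`.
#' @param ... Unused.
#' @return A one-row tibble: counts of cells, FPUs, countries, responses,
#'   total area and the seed.
#' @exportS3Method generics::glance
glance.csa_world <- function(x, ...) {
  tibble::tibble(
    n_cells = nrow(x$cells),
    n_fpus = length(unique(x$cells$fpu_id)),
    n_countries = length(unique(x$cells$country_id)),
    n_responses = nrow(x$responses),
    total_area_mha = sum(x$cells$area) / 1e6,
    seed = x$seed
  )
}
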