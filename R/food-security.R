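#' Hunger-risk mapping parameters
#'
#' The share of a region's population at risk of hunger is a decreasing
#' function of its relative food availability (kilocalories per capita
#' relative to a reference level): `share = s0 * rel^(-eta)`, clipped to
#' \[0, 1\]. `s0` anchors the share at relative availability 1 and `eta > 0`
#' sets how fast risk falls as food becomes more available.
#'
#' @param s0 Share at relative availability 1 (default 0.11).
#' @param eta Elasticity of the hunger share to availability (> 0).
#' @param kcal_per_t Named kcal content per tonne of fresh output; defaults
#'   are standard cereal food-composition values.
#'
#' @return A `hunger_params` list.
#' @export
hunger_params <- function(s0 = 0.11, eta = 3,
                          kcal_per_t = c(maize = 3.56e6, wheat = 3.34e6,
                                         rice = 2.80e6)) {
  if (s0 < 0 || s0 > 1 || eta <= 0) {
    stopf("csascen_config_error", "need s0 in [0,1] and eta > 0.")
  }
  structure(list(s0 = s0, eta = eta, kcal_per_t = kcal_per_t),
            class = c("hunger_params", "list"))
}

#' Child-undernourishment model parameters
#'
#' Linear index for the share of children under five who are undernourished,
#' driven by calorie availability and three social covariates: women's
#' secondary-education access, the female-to-male life-expectancy ratio and
#' a health-and-sanitation index. Each coefficient multiplies the deviation
#' of its covariate from a reference level; the calorie coefficient must be
#' negative (more food, fewer undernourished children).
#'
#' @param base_share Share at all-reference covariates.
#' @param c_kcal Change in share per extra kcal/capita/day (< 0).
#' @param c_edu,c_life,c_san Coefficients on the covariate deviations
#'   (expected <= 0: improvements reduce undernourishment).
#' @param ref_kcal,ref_edu,ref_life,ref_san Reference covariate levels.
#' @param child_share Children under five as a share of population.
#'
#' @return A `child_params` list.
#' @export
child_params <- function(base_share = 0.18, c_kcal = -8e-5,
                         c_edu = -0.15, c_life = -0.5, c_san = -0.12,
                         ref_kcal = 2800, ref_edu = 0.6, ref_life = 1.05,
                         ref_san = 0.6, child_share = 0.09) {
  if (c_kcal > 0) {
    stopf("csascen_config_error",
          "the calorie coefficient must be <= 0.")
  }
  structure(as.list(environment()), class = c("child_params", "list"))
}

#' Kilocalorie availability per capita per day
#'
#' `sum_c consumption_c * kcal_per_t_c / population / 365`; linear in
#' consumption.
#'
#' @param consumption Tibble with columns `crop` and `consumption_t`
#'   (t/yr), or a named numeric vector of t/yr by crop.
#' @param kcal_per_t Named kcal content per tonne.
#' @param population Population (> 0).
#'
#' @return kcal per capita per day (scalar).
#' @export
#' @examples
#' kcal_per_capita(c(rice = 1), c(rice = 3.65e6), 10)  # 1000
kcal_per_capita <- function(consumption, kcal_per_t, population) {
  if (any(population <= 0)) {
    stopf("csascen_domain_error", "population must be positive.")
  }
  if (is.data.frame(consumption)) {
    cons <- consumption$consumption_t
    names(cons) <- consumption$crop
  } else {
    cons <- consumption
  }
  check_nonneg(cons, "consumption")
  miss <- setdiff(names(cons), names(kcal_per_t))
  if (length(miss)) {
    stopf("csascen_config_error", "kcal content missing for: %s",
          paste(miss, collapse = ", "))
  }
  sum(cons * kcal_per_t[names(cons)]) / population / 365
}

#' Share of the population at risk of hunger
#'
#' Monotone decreasing map from relative availability to the
#' undernourished share (see [hunger_params()]).
#'
#' @param rel_availability kcal availability relative to the reference
#'   level (> 0); vectorised.
#' @param params A [hunger_params()].
#'
#' @return Share in \[0, 1\].
#' @export
#' @examples
#' share_at_risk(1)                   # the anchor share
#' share_at_risk(c(0.8, 1.2))
share_at_risk <- function(rel_availability, params = hunger_params()) {
  if (any(rel_availability <= 0)) {
    stopf("csascen_domain_error", "relative availability must be > 0.")
  }
  pmin(1, pmax(0, params$s0 * rel_availability^(-params$eta)))
}

#' Undernourished children under five
#'
#' Linear index of the undernourished-child share in calorie availability
#' and social covariates, clipped to \[0, 1\] and scaled by the child
#' population.
#'
#' @param kcal kcal per capita per day.
#' @param education Women's secondary-education access index in \[0, 1\].
#' @param lifeexp_ratio Female-to-male life expectancy ratio.
#' @param sanitation Health-and-sanitation index in \[0, 1\].
#' @param params A [child_params()].
#' @param child_population Children under five (head).
#'
#' @return Tibble with `share` and `children` (same units as
#'   `child_population`).
#' @export
undernourished_children <- function(kcal, education, lifeexp_ratio,
                                    sanitation, params = child_params(),
                                    child_population) {
  share <- params$base_share +
    params$c_kcal * (kcal - params$ref_kcal) +
    params$c_edu * (education - params$ref_edu) +
    params$c_life * (lifeexp_ratio - params$ref_life) +
    params$c_san * (sanitation - params$ref_san)
  share <- pmin(1, pmax(0, share))
  tibble::tibble(share = share, children = share * child_population)
}

#' Food-security indicators per region and year
#'
#' Converts market states into indicator trajectories: food consumption is
#' the non-feed share of demand; kilocalorie availability follows from crop
#' energy contents and population; the hunger share uses relative
#' availability against the first-year world-average availability of the
#' run; child undernourishment adds exogenously improving social covariates
#' (linear drifts per year from their reference levels).
#'
#' @param states A `csa_states` tibble from [project_market()].
#' @param hunger A [hunger_params()].
#' @param child A [child_params()].
#' @param covariate_drift Named annual increments for `education`,
#'   `lifeexp_ratio`, `sanitation`.
#'
#' @return Tibble per region x year: `kcal_pc_day`, `rel_availability`,
#'   `hunger_share`, `at_risk` (head), `child_share`, `children` (head).
#' @export
food_security_indicators <- function(states, hunger = hunger_params(),
                                     child = child_params(),
                                     covariate_drift = c(
                                       education = 0.004,
                                       lifeexp_ratio = 0.0005,
                                       sanitation = 0.004)) {
  y0 <- min(states$year)
  per_region <- states |>
    dplyr::mutate(
      food_t = .data$demand * (1 - .data$feed_share),
      kcal = .data$food_t * hunger$kcal_per_t[.data$crop]
    ) |>
    dplyr::group_by(.data$region_id, .data$year) |>
    dplyr::summarise(
      kcal_pc_day = sum(.data$kcal) / .data$population[1] / 365,
      population = .data$population[1],
      .groups = "drop"
    )
  ref <- per_region |>
    dplyr::filter(.data$year == y0) |>
    dplyr::summarise(
      ref = sum(.data$kcal_pc_day * .data$population) / sum(.data$population)
    ) |>
    dplyr::pull(ref)
  per_region |>
    dplyr::mutate(
      rel_availability = .data$kcal_pc_day / ref,
      hunger_share = share_at_risk(.data$rel_availability, hunger),
      at_risk = .data$hunger_share * .data$population,
      dt = .data$year - y0,
      child_res = undernourished_children(
        kcal = .data$kcal_pc_day,
        education = child$ref_edu + covariate_drift[["education"]] * .data$dt,
        lifeexp_ratio = child$ref_life +
          covariate_drift[["lifeexp_ratio"]] * .data$dt,
        sanitation = child$ref_san +
          covariate_drift[["sanitation"]] * .data$dt,
        params = child,
        child_population = child$child_share * .data$population
      ),
      child_share = .data$child_res$share,
      children = .data$child_res$children
    ) |>
    dplyr::select(-"dt", -"child_res")
}
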