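test_that("the AWD break-even is the product of its three factors", {
  expect_equal(awd_breakeven(awd_economics(0.30, 0.30, 1.0)), 0.09)
  expect_equal(awd_breakeven(awd_economics(0.36, 0.30, 1.0)), 0.108)
  expect_equal(awd_breakeven(awd_economics(0.2, 0, 1.5)), 0)
  # linear in each argument
  base <- awd_breakeven(awd_economics(0.2, 0.25, 0.8))
  expect_equal(awd_breakeven(awd_economics(0.4, 0.25, 0.8)), 2 * base)
  expect_equal(awd_breakeven(awd_economics(0.2, 0.5, 0.8)), 2 * base)
  expect_equal(awd_breakeven(awd_economics(0.2, 0.25, 1.6)), 2 * base)
  expect_error(awd_economics(1.2, 0.3, 1),
               class = "csascen_config_error")
})

# small deterministic decision problem reused below
decision_fixture <- function() {
  cells <- manual_cells()
  resp <- dplyr::bind_rows(
    manual_response("a", "no_till", 0.05),
    manual_response("a", "isfm", 0.02, n_manure_new = 60),
    manual_response("b", "no_till", -0.03),
    manual_response("b", "isfm", -0.01, n_manure_new = 40),
    manual_response("c", "nue", 0.04,
                    water_regime_out = "continuous_flooding"),
    manual_response("c", "awd", -0.05,
                    water_regime_out = "multiple_drainage"),
    manual_response("d", "nue", 0.06)
  )
  bau <- emission_ledger(cells)
  alt <- emission_ledger(cells, resp)
  list(cells = cells, resp = resp, bau = bau, alt = alt)
}

test_that("rule 1 adopts the best positive yield gain, else retains", {
  fx <- decision_fixture()
  d <- decide_cells(fx$cells, fx$resp, fx$bau, fx$alt,
                    adoption_rule("rule1"))
  expect_identical(nrow(d), 4L)
  get <- function(id) d[d$cell_id == id, ]
  expect_identical(get("a")$chosen, "no_till")   # 0.05 beats 0.02
  expect_equal(get("a")$adopted_fraction, 1)
  expect_identical(get("b")$chosen, "retain_current")  # no positive gain
  expect_equal(get("b")$adopted_fraction, 0)
  expect_identical(get("c")$chosen, "nue")
  expect_identical(get("d")$chosen, "nue")
})

test_that("rule 2 additionally requires an emission-intensity decrease", {
  fx <- decision_fixture()
  # ISFM on cell a: positive yield but extra manure raises emissions; make
  # it the top yielder and check the two rules disagree
  resp <- dplyr::bind_rows(
    manual_response("a", "isfm", 0.02, n_manure_new = 300)
  )
  alt <- emission_ledger(fx$cells, resp)
  d1 <- decide_cells(fx$cells, resp, fx$bau, alt, adoption_rule("rule1"))
  d2 <- decide_cells(fx$cells, resp, fx$bau, alt, adoption_rule("rule2"))
  expect_identical(d1$chosen[d1$cell_id == "a"], "isfm")
  expect_identical(d2$chosen[d2$cell_id == "a"], "retain_current")
})

test_that("no-till is never adopted in excluded countries", {
  fx <- decision_fixture()
  d <- decide_cells(fx$cells, fx$resp, fx$bau, fx$alt,
                    adoption_rule("rule1"), excluded_countries = "C01")
  # cell a falls back to the next-best eligible practice (isfm, +0.02)
  expect_identical(d$chosen[d$cell_id == "a"], "isfm")
  only_nt <- dplyr::filter(fx$resp, practice == "no_till")
  alt_nt <- emission_ledger(fx$cells, only_nt)
  d2 <- decide_cells(fx$cells, only_nt, fx$bau, alt_nt,
                     adoption_rule("rule1"), excluded_countries = "C01")
  expect_identical(d2$chosen[d2$cell_id == "a"], "retain_current")
})

test_that("the cost extension admits AWD within the break-even decline", {
  fx <- decision_fixture()
  # cell c: AWD loses 5% yield but cuts CH4 by half -> intensity falls
  resp <- dplyr::filter(fx$resp, cell_id == "c", practice == "awd")
  alt <- emission_ledger(fx$cells, resp)
  d2 <- decide_cells(fx$cells, resp, fx$bau, alt, adoption_rule("rule2"))
  dx <- decide_cells(fx$cells, resp, fx$bau, alt,
                     adoption_rule("rule2_awdcost"))
  expect_identical(d2$chosen[d2$cell_id == "c"], "retain_current")
  expect_identical(dx$chosen[dx$cell_id == "c"], "awd")
  # a decline beyond the tolerance stays retained
  resp_big <- manual_response("c", "awd", -0.12,
                              water_regime_out = "multiple_drainage")
  alt_big <- emission_ledger(fx$cells, resp_big)
  dy <- decide_cells(fx$cells, resp_big, fx$bau, alt_big,
                     adoption_rule("rule2_awdcost"))
  expect_identical(dy$chosen[dy$cell_id == "c"], "retain_current")
})

test_that("decisions are deterministic and candidate-order invariant", {
  fx <- decision_fixture()
  d1 <- decide_cells(fx$cells, fx$resp, fx$bau, fx$alt,
                     adoption_rule("rule1"))
  shuffled <- fx$resp[rev(seq_len(nrow(fx$resp))), ]
  d2 <- decide_cells(fx$cells, shuffled, fx$bau, fx$alt,
                     adoption_rule("rule1"))
  expect_equal(d1, d2)
  # exact ties break by the fixed practice order (no_till before isfm)
  tie <- dplyr::bind_rows(
    manual_response("a", "isfm", 0.05, n_manure_new = 11),
    manual_response("a", "no_till", 0.05)
  )
  alt <- emission_ledger(fx$cells, tie)
  dt <- decide_cells(fx$cells, tie, fx$bau, alt, adoption_rule("rule1"))
  expect_identical(dt$chosen[dt$cell_id == "a"], "no_till")
})

test_that("rule-2 adopters are a subset of rule-1 adopters on random worlds", {
  for (seed in c(3, 17)) {
    w <- tiny_world(seed = seed)
    resp <- dplyr::filter(w$responses, climate_id == "pseudo_dry_cool")
    bau <- emission_ledger(w$cells)
    alt <- emission_ledger(w$cells, resp)
    d1 <- decide_cells(w$cells, resp, bau, alt, adoption_rule("rule1"))
    d2 <- decide_cells(w$cells, resp, bau, alt, adoption_rule("rule2"))
    a1 <- d1$cell_id[d1$chosen != "retain_current"]
    a2 <- d2$cell_id[d2$chosen != "retain_current"]
    expect_in(a2, a1)
    expect_lte(adopted_area(d2, w$cells)$area_ha,
               adopted_area(d1, w$cells)$area_ha)
  }
})

test_that("adoption-rate caps scale fractions and keep monotonicity", {
  fx <- decision_fixture()
  d <- decide_cells(fx$cells, fx$resp, fx$bau, fx$alt,
                    adoption_rule("rule1"))
  rates <- tidyr::crossing(country_id = c("C01", "C02"),
                           practice = c("no_till", "isfm", "nue", "awd")) |>
    dplyr::mutate(rate = 0.4)
  capped <- apply_adoption_rates(d, rates, fx$cells)
  expect_equal(capped$adopted_fraction[capped$cell_id == "a"], 0.4)
  expect_equal(capped$adopted_fraction[capped$cell_id == "b"], 0)

  # zero rates collapse the adopted area to zero (BAU)
  zero <- dplyr::mutate(rates, rate = 0)
  expect_equal(adopted_area(apply_adoption_rates(d, zero, fx$cells),
                            fx$cells)$area_ha, 0)

  # elementwise-smaller rates never increase total adopted area
  set.seed(4)
  for (i in 1:5) {
    r2 <- dplyr::mutate(rates, rate = runif(dplyr::n()))
    r1 <- dplyr::mutate(r2, rate = rate * runif(dplyr::n()))
    a1 <- adopted_area(apply_adoption_rates(d, r1, fx$cells),
                       fx$cells)$area_ha
    a2 <- adopted_area(apply_adoption_rates(d, r2, fx$cells),
                       fx$cells)$area_ha
    expect_lte(a1, a2)
  }
  expect_error(apply_adoption_rates(d, dplyr::mutate(rates, rate = 1.2),
                                    fx$cells),
               class = "csascen_config_error")
})

test_that("adopted area sums area times fraction by group", {
  fx <- decision_fixture()
  d <- decide_cells(fx$cells, fx$resp, fx$bau, fx$alt,
                    adoption_rule("rule1"))
  # cells a (10 ha), c (30 ha), d (40 ha) adopt fully
  expect_equal(adopted_area(d, fx$cells)$area_ha, 80)
  by_cty <- adopted_area(d, fx$cells, "country")
  expect_equal(sum(by_cty$area_ha), 80)
  # all-retain world has zero adopted area
  d0 <- dplyr::mutate(d, chosen = "retain_current", adopted_fraction = 0)
  expect_equal(adopted_area(d0, fx$cells)$area_ha, 0)
})

test_that("rule constructors enforce their requirements", {
  expect_error(adoption_rule("rule1_rates"),
               class = "csascen_config_error")
  expect_s3_class(adoption_rule("rule2_awdcost")$awd_econ,
                  "awd_economics")
  fx <- decision_fixture()
  expect_error(
    decide_cells(fx$cells, fx$resp, fx$bau, fx$alt[-1, ],
                 adoption_rule("rule1")),
    class = "csascen_join_error"
  )
})
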