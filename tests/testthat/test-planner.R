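test_that("threshold crossings solve the linear-model algebra", {
  m <- example_linear_models()
  sva <- function(oa) evaluate_linear(m, oa, "sva_mm")
  pt <- function(oa) evaluate_linear(m, oa, "pt_deg")
  tpa <- function(oa) evaluate_linear(m, oa, "tpa_deg")

  expect_equal(
    threshold_crossing(sva, 50, "falls_below", oa_cap_deg = 40),
    (223.8 - 50) / 8.3,
    tolerance = 1e-5
  )
  expect_equal(
    threshold_crossing(pt, 20, "rises_above", oa_cap_deg = 40),
    32,
    tolerance = 1e-5
  )
  expect_equal(
    threshold_crossing(tpa, 14, "falls_below", oa_cap_deg = 40),
    13 / 0.6,
    tolerance = 1e-5
  )

  # already satisfied at zero -> crossing at 0; never met -> NA
  expect_equal(threshold_crossing(function(oa) rep(40, length(oa)), 50, "falls_below"), 0)
  expect_true(is.na(threshold_crossing(sva, -500, "falls_below", oa_cap_deg = 40)))

  # non-monotone predictors are refused by name
  expect_error(
    threshold_crossing(function(oa) sin(oa), 0.5, "falls_below", name = "wobble"),
    "wobble"
  )
})

test_that("the planner reproduces the example-model feasible interval", {
  m <- example_linear_models()
  crit <- criteria(pi_minus_ll_max_deg = NA)
  plan <- feasible_oa_range(linear_engine(m), crit)
  expect_true(plan$feasible)
  expect_equal(plan$oa_min_deg, 13 / 0.6, tolerance = 1e-4)
  expect_equal(plan$oa_max_deg, 32, tolerance = 1e-4)
  expect_equal(plan$binding_lower, "tpa_max")
  expect_equal(plan$binding_upper, "pt_max")

  g <- glance(plan)
  expect_true(g$feasible)
  expect_equal(g$oa_min_deg, plan$oa_min_deg)
  expect_true("tpa_max" %in% tidy(plan)$constraint)
})

test_that("impossible criteria yield an infeasible result, not an error", {
  m <- example_linear_models()
  plan <- feasible_oa_range(
    linear_engine(m),
    criteria(tpa_max_deg = -999, pi_minus_ll_max_deg = NA)
  )
  expect_false(plan$feasible)
  expect_true(is.na(plan$oa_min_deg))
})

test_that("oracle-engine plans verify on a fine grid and at the bounds", {
  # a moderately compensated deformity for which all four criteria can be met
  lm <- make_patient(patient_spec(pi_deg = 55, pt_deg = 8, sva_mm = 120, ll_deg = 40))
  crit <- criteria(oa_cap_deg = 40)
  plan <- feasible_oa_range(oracle_engine(lm, 40), crit)
  expect_true(plan$feasible)
  eng <- oracle_engine(lm, 40)
  grid <- seq(plan$oa_min_deg, plan$oa_max_deg, by = 0.1)
  vals <- eng(grid)
  expect_true(all(vals$sva_mm <= crit$sva_max_mm + 1e-3))
  expect_true(all(vals$sva_mm >= crit$sva_min_mm - 1e-3))
  expect_true(all(vals$tpa_deg <= crit$tpa_max_deg + 1e-3))
  expect_true(all(vals$pt_deg <= crit$pt_max_deg + 1e-3))
  expect_true(all(vals$pi_minus_ll_deg <= crit$pi_minus_ll_max_deg + 1e-3))

  # the closed-form engine agrees with the oracle engine on the same patient
  plan_cf <- feasible_oa_range(closed_form_engine(derive_geometry(lm), 40), crit)
  expect_equal(plan_cf$oa_min_deg, plan$oa_min_deg, tolerance = 1e-4)
  expect_equal(plan_cf$oa_max_deg, plan$oa_max_deg, tolerance = 1e-4)
})

test_that("tightening any single threshold never widens the interval", {
  m <- example_linear_models()
  base <- feasible_oa_range(linear_engine(m), criteria(pi_minus_ll_max_deg = NA))
  tighter <- list(
    criteria(sva_max_mm = 30, pi_minus_ll_max_deg = NA),
    criteria(tpa_max_deg = 10, pi_minus_ll_max_deg = NA),
    criteria(pt_max_deg = 18, pi_minus_ll_max_deg = NA),
    criteria(sva_min_mm = -20, pi_minus_ll_max_deg = NA)
  )
  for (crit in tighter) {
    plan <- feasible_oa_range(linear_engine(m), crit)
    if (plan$feasible) {
      expect_gte(plan$oa_min_deg, base$oa_min_deg - 1e-6)
      expect_lte(plan$oa_max_deg, base$oa_max_deg + 1e-6)
    }
  }
})

test_that("reports summarise plans deterministically", {
  m <- example_linear_models()
  eng <- linear_engine(m, ll_deg = 30)
  crit <- criteria(pi_minus_ll_max_deg = NA)
  plan <- feasible_oa_range(eng, crit)
  tab <- eng(0:40)
  tab$pi_minus_ll_deg <- tab$pi_deg - 30
  tab$ss_deg <- NA_real_
  rep1 <- build_report(plan, tab, crit)
  expect_true(any(grepl("feasible opening-angle range", rep1)))
  expect_true(any(grepl("21.67", rep1)))
  expect_identical(unclass(rep1), unclass(build_report(plan, tab, crit)))

  infeasible <- feasible_oa_range(
    eng, criteria(tpa_max_deg = -999, pi_minus_ll_max_deg = NA)
  )
  rep2 <- build_report(infeasible, tab, crit)
  expect_true(any(grepl("INFEASIBLE", rep2)))
  expect_true(any(grepl("tpa_max", rep2)))

  expect_error(build_report(plan, tab[0, ], crit), "empty")
})
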