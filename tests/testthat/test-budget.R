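test_that("N flux is transport flux times N stoichiometry", {
  m <- metabolic_model("mini", "sA",
    rbind(metabolite("gln[sA]", formula = "C5H10N2O3", compartment = "sA"),
          metabolite("glc[sA]", formula = "C6H12O6", compartment = "sA")),
    list())
  prof <- structure(list(compartment = "sA",
                         imports = c(gln = 1.0, glc = 2.0),
                         exports = numeric(0)),
                    class = "sbf_exchange_profile")
  sol <- structure(list(status = "optimal", flux = numeric(0)),
                   class = "sbf_fba")
  led <- nitrogen_ledger(prof, m, sol)
  expect_equal(led$N_in, 2.0)      # glutamine carries 2 N, glucose none
  expect_equal(led$N_out_eaa, 0)
  expect_equal(led$N_biomass, 0)
})

test_that("toy ledgers match the closed form and the balance closes", {
  for (seed in c(1, 22, 35)) {
    b <- generate_toy_symbiosis(toy_symbiosis_spec(seed = seed))
    sol <- solve_fba(b$model)
    prof <- classify_exchanges(b$model, sol)
    for (cc in c("sA", "sB")) {
      led <- nitrogen_ledger(prof[[cc]], b$model, sol)
      want <- b$expected$ledger[[cc]]
      expect_equal(led$N_in, want$N_in, tolerance = 1e-8)
      expect_equal(led$N_out_eaa, want$N_out_eaa, tolerance = 1e-8)
      expect_equal(led$N_out_other, want$N_out_other, tolerance = 1e-8)
      expect_equal(led$N_biomass, want$N_biomass, tolerance = 1e-8)
      expect_equal(led$efficiency, want$efficiency, tolerance = 1e-8)
      expect_true(led$efficiency >= 0 && led$efficiency <= 1)
      expect_lt(abs(led$N_in - led$N_out_eaa - led$N_out_other - led$N_biomass),
                1e-6)
    }
  }
})

test_that("recycling efficiency is invariant under flux rescaling", {
  base <- toy_symbiosis_spec(seed = 23)
  k <- 3
  scaled <- toy_symbiosis_spec(seed = 23,
                               glucose_cap = base$glucose_cap * k,
                               nh3_cap = base$nh3_cap * k,
                               o2_cap = base$o2_cap * k,
                               eaa_cap_range = base$eaa_cap_range * k,
                               biomass_floor = base$biomass_floor * k)
  eff <- function(spec) {
    b <- generate_toy_symbiosis(spec)
    sol <- solve_fba(b$model)
    prof <- classify_exchanges(b$model, sol)
    vapply(c("sA", "sB"), function(cc)
      nitrogen_ledger(prof[[cc]], b$model, sol)$efficiency, 0)
  }
  expect_equal(eff(base), eff(scaled), tolerance = 1e-8)
})

test_that("a transported metabolite without a formula is a hard ledger error", {
  fx <- degenerate_case_suite()$missing_formula
  b <- fx$bundle
  sol <- solve_fba(b$model)
  prof <- classify_exchanges(b$model, sol)
  expect_error(nitrogen_ledger(prof$sA, b$model, sol), "xint")
})

test_that("maintenance cost equals the designed drain relief and is never negative", {
  b <- generate_toy_symbiosis(toy_symbiosis_spec(seed = 1))
  for (s in c("symA", "symB")) {
    mc <- maintenance_cost(b$model, s)
    expect_identical(mc$status, "optimal")
    expect_gte(mc$cost_absolute, -1e-8)
    expect_equal(mc$cost_absolute, b$expected$maintenance_cost[[s]],
                 tolerance = 1e-8)
    expect_equal(mc$cost_relative, mc$cost_absolute / mc$host_growth_full,
                 tolerance = 1e-12)
    # nutrients were capped at their observed uptakes
    expect_true(all(c("glc", "nh3") %in% names(mc$observed_uptakes)))
  }
})

test_that("cost non-negativity holds across random capacities", {
  for (seed in c(2, 9, 27)) {
    b <- generate_toy_symbiosis(toy_symbiosis_spec(seed = seed))
    for (s in c("symA", "symB")) {
      mc <- maintenance_cost(b$model, s)
      expect_gte(mc$cost_absolute, -1e-8)
    }
  }
})

test_that("with no biomass floor there is nothing to pay for", {
  b <- generate_toy_symbiosis(toy_symbiosis_spec(seed = 3, biomass_floor = 0))
  mc <- maintenance_cost(b$model, "symB")
  expect_equal(mc$cost_absolute, 0, tolerance = 1e-8)
})
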