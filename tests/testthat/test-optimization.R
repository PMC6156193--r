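test_that("a single bottleneck caps the FBA optimum", {
  sol <- solve_fba(chain_model(cap = 5))
  expect_identical(sol$status, "optimal")
  expect_equal(sol$objective, 5, tolerance = 1e-9)
  expect_equal(unname(sol$flux), c(-5, 5, 5), tolerance = 1e-9)

  # contradictory constraints: a demanded objective behind a blocked pathway
  sol <- solve_fba(chain_model(cap = 5, conv_ub = 0, obj_lb = 0.01))
  expect_identical(sol$status, "infeasible")
  expect_true(is.na(sol$objective))

  expect_error(solve_fba(degenerate_case_suite()$zero_objective$model),
               "empty objective")
})

test_that("optimal solutions satisfy steady state and bounds", {
  b <- generate_toy_symbiosis(toy_symbiosis_spec(seed = 12))
  sol <- solve_fba(b$model)
  S <- build_matrix(b$model)
  expect_lt(max(abs(S %*% sol$flux)), 1e-9 * max(1, max(abs(sol$flux))))
  bd <- model_bounds(b$model)
  expect_true(all(sol$flux >= bd$lb - 1e-9))
  expect_true(all(sol$flux <= bd$ub + 1e-9))
  # determinism: identical run gives identical fluxes
  expect_identical(sol$flux, solve_fba(b$model)$flux)
})

test_that("the simplex agrees with brute-force vertex enumeration on random models", {
  for (seed in 1:20) {
    rm <- random_small_model(seed)
    sol <- solve_fba(rm$model)
    expect_identical(sol$status, "optimal")
    oracle <- vertex_enum_opt(rm$S, rm$lb, rm$ub, rm$obj)
    expect_equal(sol$objective, oracle, tolerance = 1e-8,
                 label = sprintf("seed %d", seed))
  }
})

test_that("FVA brackets the FBA flux and collapses on determined chains", {
  m <- chain_model(cap = 5)
  sol <- solve_fba(m)
  fva <- solve_fva(m)
  expect_true(all(fva$min <= fva$max + 1e-9))
  expect_equal(fva$min, unname(sol$flux[fva$reaction]), tolerance = 1e-6)
  expect_equal(fva$max, unname(sol$flux[fva$reaction]), tolerance = 1e-6)

  b <- generate_toy_symbiosis(toy_symbiosis_spec(seed = 13))
  solt <- solve_fba(b$model)
  fvat <- solve_fva(b$model)
  v <- solt$flux[fvat$reaction]
  expect_true(all(v >= fvat$min - 1e-6 & v <= fvat$max + 1e-6))

  expect_error(solve_fva(chain_model(cap = 5, conv_ub = 0, obj_lb = 0.01)),
               "infeasible")
})

test_that("parallel equivalent routes each range over the joint capacity", {
  fx <- degenerate_case_suite()$parallel_routes
  fva <- solve_fva(fx$model)
  for (r in c("R1", "R2")) {
    expect_equal(fva$min[fva$reaction == r], 0, tolerance = 1e-6)
    expect_equal(fva$max[fva$reaction == r], 5, tolerance = 1e-6)
  }
  # relaxing the objective fraction widens the sink's feasible window
  fva50 <- solve_fva(fx$model, objective_fraction = 0.5)
  expect_equal(fva50$min[fva50$reaction == "OBJ"], 2.5, tolerance = 1e-4)
})

test_that("re-solving with a reaction pinned inside its FVA interval preserves the optimum", {
  b <- generate_toy_symbiosis(toy_symbiosis_spec(seed = 13))
  sol <- solve_fba(b$model)
  fva <- solve_fva(b$model, reactions = "T_nh3_h_sA")
  mid <- (fva$min + fva$max) / 2
  m2 <- b$model
  m2$reactions[["T_nh3_h_sA"]]$lb <- mid
  m2$reactions[["T_nh3_h_sA"]]$ub <- mid
  sol2 <- solve_fba(m2)
  expect_equal(sol2$objective, sol$objective, tolerance = 1e-6)
})

test_that("scaling all bounds scales the optimum (LP homogeneity)", {
  base <- toy_symbiosis_spec(seed = 14)
  k <- 2.5
  scaled <- toy_symbiosis_spec(seed = 14,
                               glucose_cap = base$glucose_cap * k,
                               nh3_cap = base$nh3_cap * k,
                               o2_cap = base$o2_cap * k,
                               eaa_cap_range = base$eaa_cap_range * k,
                               biomass_floor = base$biomass_floor * k)
  z1 <- solve_fba(generate_toy_symbiosis(base)$model)$objective
  z2 <- solve_fba(generate_toy_symbiosis(scaled)$model)$objective
  expect_equal(z2, k * z1, tolerance = 1e-8)
})

test_that("stabilized mode removes futile cycling at the same optimum", {
  mets <- rbind(metabolite("a[h]", formula = "C", compartment = "h"),
                metabolite("b[h]", formula = "C", compartment = "h"))
  m <- metabolic_model("cyc", "h", mets, list(
    reaction("EX_a", c(`a[h]` = -1), lb = -5, ub = 1000, kind = "exchange"),
    reaction("FWD", c(`a[h]` = -1, `b[h]` = 1), lb = -1000, ub = 1000),
    reaction("BCK", c(`b[h]` = -1, `a[h]` = 1), lb = -1000, ub = 1000),
    reaction("OBJ", c(`b[h]` = -1), lb = 0, ub = 1000, kind = "objective")),
    objective = c(OBJ = 1))
  plain <- solve_fba(m)
  stab <- solve_fba(m, stabilize = TRUE)
  expect_equal(stab$objective, plain$objective, tolerance = 1e-6)
  expect_equal(sum(abs(stab$flux)), 15, tolerance = 1e-6) # 5 + 5 + 5 + 0
  expect_lte(sum(abs(stab$flux)), sum(abs(plain$flux)) + 1e-6)
})

test_that("flux range and transport variation summaries follow their definitions", {
  fva <- structure(data.frame(reaction = c("r1", "r2", "T_x"),
                              min = c(0, 0, 1.0), max = c(0, 2, 1.01)),
                   class = c("sbf_fva", "data.frame"))
  rs <- flux_range_summary(fva, threshold = 1.0)
  expect_equal(rs$fraction_below, 2 / 3)
  expect_equal(unname(rs$ranges), c(0, 2, 0.01))

  sol <- structure(list(status = "optimal",
                        flux = c(r1 = 0, r2 = 1, T_x = 1.0)),
                   class = "sbf_fba")
  tv <- transport_flux_variation(fva, sol, transports = "T_x")
  expect_equal(tv$percent, 1.0, tolerance = 1e-9)

  # zero-flux transports are undefined and excluded from the fraction
  fva2 <- structure(data.frame(reaction = c("T_a", "T_b"),
                               min = c(0, 0), max = c(0, 0.001)),
                    class = c("sbf_fva", "data.frame"))
  sol2 <- structure(list(status = "optimal", flux = c(T_a = 0, T_b = 2)),
                    class = "sbf_fba")
  tv2 <- transport_flux_variation(fva2, sol2, transports = c("T_a", "T_b"))
  expect_true(is.na(tv2$percent[tv2$reaction == "T_a"]))
  expect_false(tv2$defined[tv2$reaction == "T_a"])
  expect_equal(attr(tv2, "fraction_below"), 1) # only T_b counts: 0.05% < 1%
})
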