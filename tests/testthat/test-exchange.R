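make_fake_multi <- function() {
  # two-compartment scaffold with a registry, for direct threshold tests
  host <- metabolic_model("h", "h",
    rbind(metabolite("m1[h]", formula = "C", compartment = "h"),
          metabolite("fe[h]", formula = "Fe", compartment = "h",
                     tags = "mineral")),
    list(reaction("S1", c(`m1[h]` = -1), kind = "exchange")))
  symA <- metabolic_model("a", "sA",
    rbind(metabolite("m1[sA]", formula = "C", compartment = "sA"),
          metabolite("fe[sA]", formula = "Fe", compartment = "sA",
                     tags = "mineral")),
    list(reaction("S2", c(`m1[sA]` = -1), kind = "exchange")))
  symB <- metabolic_model("b", "sB",
    metabolite("m2[sB]", formula = "C", compartment = "sB"),
    list(reaction("S3", c(`m2[sB]` = -1), kind = "exchange")))
  ts <- data.frame(metabolite = c("m1", "fe"), donor = "h", recipient = "sA",
                   reversible = TRUE)
  build_multicompartment(host, symA, symB, ts)
}

test_that("sub-threshold fluxes are excluded unless the metabolite is exempt", {
  m <- make_fake_multi()
  sol <- structure(list(status = "optimal",
                        flux = stats::setNames(numeric(length(m$reactions)),
                                               names(m$reactions))),
                   class = "sbf_fba")
  sol$flux["T_m1_h_sA"] <- 1e-7   # below 1e-6: dropped
  sol$flux["T_fe_h_sA"] <- 1e-7   # mineral: retained and flagged
  prof <- classify_exchanges(m, sol)
  expect_false("m1" %in% names(prof$sA$imports))
  expect_true("fe" %in% names(prof$sA$imports))
  expect_true("fe" %in% prof$sA$exempt)

  sol$flux["T_m1_h_sA"] <- 2e-6
  prof <- classify_exchanges(m, sol)
  expect_equal(prof$sA$imports[["m1"]], 2e-6)
  expect_equal(prof$h$exports[["m1"]], 2e-6)
})

test_that("toy bundle exchange profiles equal the generator's designed tables", {
  for (seed in c(1, 17, 31)) {
    b <- generate_toy_symbiosis(toy_symbiosis_spec(seed = seed))
    stopifnot(b$expected$unique_vertex)
    sol <- solve_fba(b$model)
    prof <- classify_exchanges(b$model, sol)
    for (cc in c("sA", "sB")) {
      expect_profile_equal(prof[[cc]]$imports, b$expected$exchange[[cc]]$imports)
      expect_profile_equal(prof[[cc]]$exports, b$expected$exchange[[cc]]$exports)
    }
  }
})

test_that("interface conservation: total exports equal total imports per species", {
  b <- generate_toy_symbiosis(toy_symbiosis_spec(seed = 18))
  sol <- solve_fba(b$model)
  prof <- classify_exchanges(b$model, sol,
                             compartments = b$model$compartments)
  species <- unique(unlist(lapply(prof, function(p)
    c(names(p$imports), names(p$exports)))))
  for (sp in species) {
    tot_in <- sum(vapply(prof, function(p)
      if (sp %in% names(p$imports)) p$imports[[sp]] else 0, 0))
    tot_out <- sum(vapply(prof, function(p)
      if (sp %in% names(p$exports)) p$exports[[sp]] else 0, 0))
    expect_equal(tot_in, tot_out, tolerance = 1e-5, label = sp)
  }
})

test_that("raising the threshold never increases import/export counts", {
  b <- generate_toy_symbiosis(toy_symbiosis_spec(seed = 19))
  sol <- solve_fba(b$model)
  counts <- vapply(c(1e-6, 1e-3, 1, 50), function(thr) {
    prof <- classify_exchanges(b$model, sol, threshold = thr)
    sum(vapply(prof, function(p)
      length(p$imports) + length(p$exports), 0L))
  }, 0L)
  expect_true(all(diff(counts) <= 0))
})

test_that("shared and unique metabolite sets follow set algebra", {
  b <- generate_toy_symbiosis(toy_symbiosis_spec(seed = 20))
  sol <- solve_fba(b$model)
  prof <- classify_exchanges(b$model, sol)
  su <- shared_unique_sets(prof$sA, prof$sB, "imports")
  want_shared <- intersect(names(b$expected$exchange$sA$imports),
                           names(b$expected$exchange$sB$imports))
  expect_setequal(su$shared, want_shared)
  expect_setequal(su$uniqueA,
                  setdiff(names(b$expected$exchange$sA$imports), want_shared))
  # disjoint profiles share nothing
  su2 <- shared_unique_sets(prof$sA, prof$sB, "exports")
  expect_false(any(sprintf("eaaA%d", 1:7) %in% names(prof$sB$exports)))
  expect_true(all(sprintf("eaaA%d", 1:7) %in% su2$uniqueA))
})

test_that("designed cross-feeding is recovered exactly, with no false positives", {
  hits <- 0L
  for (seed in 1:15) {
    b <- generate_toy_symbiosis(toy_symbiosis_spec(seed = seed))
    sol <- solve_fba(b$model)
    prof <- classify_exchanges(b$model, sol)
    cfd <- detect_cross_feeding(prof[c("h", "sA", "sB")], host = "h")
    expect_identical(nrow(cfd), 1L)
    expect_identical(cfd$metabolite, "xint")
    expect_identical(cfd$donor, "sA")
    expect_identical(cfd$recipient, "sB")
    expect_equal(cfd$flux, b$expected$objective, tolerance = 1e-8)
    hits <- hits + 1L

    b0 <- generate_toy_symbiosis(toy_symbiosis_spec(seed = seed,
                                                    cross_feed = FALSE))
    sol0 <- solve_fba(b0$model)
    prof0 <- classify_exchanges(b0$model, sol0)
    cfd0 <- detect_cross_feeding(prof0[c("h", "sA", "sB")], host = "h")
    expect_identical(nrow(cfd0), 0L)
  }
  expect_identical(hits, 15L)
})

test_that("EAA release accounting reports shares and host sink fractions", {
  b <- generate_toy_symbiosis(toy_symbiosis_spec(seed = 21))
  sol <- solve_fba(b$model)
  prof <- classify_exchanges(b$model, sol)
  acc <- eaa_release_accounting(prof[c("h", "sA", "sB")], model = b$model,
                                host = "h")
  expect_equal(acc$total_flux, b$expected$eaa_total_flux, tolerance = 1e-8)
  expect_equal(acc$share[["sA"]], b$expected$eaa_share[["symA"]],
               tolerance = 1e-8)
  expect_equal(acc$share[["sB"]], b$expected$eaa_share[["symB"]],
               tolerance = 1e-8)
  # the host is the only sink in the toy topology
  expect_true(all(abs(acc$per_eaa$host_sink_fraction - 1) < 1e-8))

  # zero total release: shares undefined, reported as such
  empty <- structure(list(compartment = "sA", imports = numeric(0),
                          exports = numeric(0)), class = "sbf_exchange_profile")
  empty2 <- structure(list(compartment = "sB", imports = numeric(0),
                           exports = numeric(0)), class = "sbf_exchange_profile")
  hostp <- structure(list(compartment = "h", imports = numeric(0),
                          exports = numeric(0)), class = "sbf_exchange_profile")
  acc0 <- eaa_release_accounting(list(h = hostp, sA = empty, sB = empty2),
                                 eaa = c("eaaA1"), host = "h")
  expect_true(acc0$undefined)
  expect_true(all(is.na(acc0$share)))
})
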