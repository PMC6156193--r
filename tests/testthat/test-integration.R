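test_that("merging adds transports and exchanges with full bookkeeping", {
  b <- generate_toy_symbiosis(toy_symbiosis_spec(seed = 8))
  m <- build_multicompartment(b$host, b$symA, b$symB, b$transport_spec)
  n_parts <- length(b$host$reactions) + length(b$symA$reactions) +
    length(b$symB$reactions)
  n_ext <- sum(m$metabolites$compartment == "e")
  expect_identical(length(m$reactions),
                   n_parts + nrow(b$transport_spec) + n_ext)
  # merged metabolite count = per-compartment uniques + created external ones
  expect_identical(nrow(m$metabolites),
                   nrow(b$host$metabolites) + nrow(b$symA$metabolites) +
                     nrow(b$symB$metabolites) + n_ext)
  expect_setequal(unique(m$provenance),
                  c("host", "symA", "symB", "transport", "external"))
  # registry rows map to real 1:1 reactions
  for (i in seq_len(nrow(m$transports))) {
    r <- m$reactions[[m$transports$reaction_id[i]]]
    expect_identical(r$kind, "transport")
    expect_equal(sort(unname(r$stoichiometry)), c(-1, 1))
  }
})

test_that("transport reactions are built 1:1 and cost-free with requested direction", {
  mets_h <- metabolite("gln[h]", formula = "C5H10N2O3", compartment = "h")
  mets_a <- metabolite("gln[sA]", formula = "C5H10N2O3", compartment = "sA")
  mets_b <- metabolite("x[sB]", formula = "C", compartment = "sB")
  host <- metabolic_model("h", "h", mets_h,
                          list(reaction("EX0", c(`gln[h]` = -1), kind = "exchange")))
  symA <- metabolic_model("a", "sA", mets_a,
                          list(reaction("EX1", c(`gln[sA]` = -1), kind = "exchange")))
  symB <- metabolic_model("b", "sB", mets_b,
                          list(reaction("EX2", c(`x[sB]` = -1), kind = "exchange")))
  ts <- data.frame(metabolite = "gln", donor = "h", recipient = "sA",
                   reversible = FALSE)
  m <- build_multicompartment(host, symA, symB, ts)
  tr <- m$reactions[["T_gln_h_sA"]]
  expect_equal(tr$stoichiometry, c(`gln[h]` = -1, `gln[sA]` = 1))
  expect_equal(c(tr$lb, tr$ub), c(0, 1000))
  # no cost metabolites: exactly the two endpoints
  expect_length(tr$stoichiometry, 2L)
  # balanced by construction (same species, 1:1)
  expect_true(all(check_mass_balance(tr, m)$imbalance == 0))

  bad <- data.frame(metabolite = "gln", donor = "h", recipient = "sB",
                    reversible = TRUE)
  expect_error(build_multicompartment(host, symA, symB, bad),
               "gln.*sB|sB.*gln")
})

test_that("compartment collisions are refused; disjoint suffixes double-count cleanly", {
  b <- generate_toy_symbiosis(toy_symbiosis_spec(seed = 8))
  expect_error(build_multicompartment(b$host, b$symA, b$symA, b$transport_spec),
               "disjoint")
  # the same symbiont model under a different suffix merges without collision
  clone <- b$symA
  clone$compartments <- "sC"
  clone$metabolites$id <- sub("\\[sA\\]", "[sC]", clone$metabolites$id)
  clone$metabolites$compartment <- "sC"
  clone$reactions <- lapply(clone$reactions, function(r) {
    names(r$stoichiometry) <- sub("\\[sA\\]", "[sC]", names(r$stoichiometry))
    r$id <- paste0(r$id, "_c"); r
  })
  ts <- b$transport_spec[b$transport_spec$recipient != "sB" &
                           b$transport_spec$donor != "sB", ]
  m <- build_multicompartment(b$host, b$symA, clone, ts)
  expect_identical(sum(m$provenance == "symB"), length(b$symA$reactions))
})

test_that("the medium opens capped uptakes and closes amino-acid sources", {
  b <- generate_toy_symbiosis(toy_symbiosis_spec(seed = 9))
  m <- b$model
  expect_equal(m$reactions[["EX_o2"]]$lb, -20)
  expect_equal(m$reactions[["EX_o2"]]$ub, 1000)
  expect_equal(m$reactions[["EX_glc"]]$lb, -100)
  expect_equal(m$reactions[["EX_nh3"]]$lb, -100)

  # an EAA present in the external medium list is still refused as a source
  host <- metabolic_model("h", "h",
    rbind(metabolite("lys[h]", formula = "C6H14N2O2", compartment = "h",
                     tags = "eaa")),
    list(reaction("SINK", c(`lys[h]` = -1), lb = 0, ub = 1000,
                  kind = "objective")),
    objective = c(SINK = 1))
  dummyA <- metabolic_model("a", "sA",
    metabolite("z[sA]", formula = "C", compartment = "sA"),
    list(reaction("ZX", c(`z[sA]` = -1), kind = "exchange")))
  dummyB <- metabolic_model("b", "sB",
    metabolite("z2[sB]", formula = "C", compartment = "sB"),
    list(reaction("ZX2", c(`z2[sB]` = -1), kind = "exchange")))
  ts <- data.frame(metabolite = "lys", donor = "e", recipient = "h",
                   reversible = TRUE)
  mm <- build_multicompartment(host, dummyA, dummyB, ts)
  mm <- apply_medium(mm, medium_spec(c(lys = 50)))
  expect_equal(mm$reactions[["EX_lys"]]$lb, 0)
  # and FVA confirms no uptake flux is feasible through it
  fva <- solve_fva(mm, reactions = "EX_lys")
  expect_gte(fva$min, -1e-9)

  expect_error(apply_medium(b$model, medium_spec(c(unobtainium = 1))),
               "unobtainium")
})

test_that("biomass objective coefficients follow composition and molecular weight", {
  spec <- build_objective(c(glycine = 0.075, leucine = 0.925),
                          vitamins = "riboflavin")
  expect_equal(spec$coefficient[spec$component == "glycine"],
               1000 * 0.075 / 75.07, tolerance = 1e-9)
  expect_equal(spec$coefficient[spec$component == "glycine"], 0.999,
               tolerance = 1e-3)
  expect_equal(spec$coefficient[spec$component == "riboflavin"], 0.00005)
  expect_identical(spec$provenance,
                   c("amino_acid_composition", "amino_acid_composition",
                     "b_vitamin"))

  # equal fractions over equal molecular weights give equal coefficients
  sp2 <- build_objective(c(leucine = 0.5, isoleucine = 0.5))
  expect_equal(sp2$coefficient[1], sp2$coefficient[2])

  expect_error(build_objective(c(glycine = 0.5)), "sum to 1")
  expect_error(build_objective(c(glycine = 0.5, kryptonite = 0.5)),
               "kryptonite")
})

test_that("attach_objective wires the biomass spec into the model", {
  mets <- rbind(metabolite("glycine[h]", formula = "C2H5NO2", compartment = "h"),
                metabolite("leucine[h]", formula = "C6H13NO2", compartment = "h"))
  m <- metabolic_model("hobj", "h", mets, list(
    reaction("SRC", c(`glycine[h]` = 1, `leucine[h]` = 1),
             lb = 0, ub = 3, kind = "internal")))
  spec <- build_objective(c(glycine = 0.5, leucine = 0.5))
  m <- attach_objective(m, spec, "h")
  expect_identical(names(m$objective), "BIOMASS_host")
  st <- m$reactions$BIOMASS_host$stoichiometry
  expect_equal(unname(st["glycine[h]"]), -1000 * 0.5 / 75.07, tolerance = 1e-9)
  expect_error(attach_objective(m, build_objective(c(valine = 1)), "h"),
               "valine")
})

test_that("symbiont biomass floors are enforced and can make FBA infeasible", {
  b <- generate_toy_symbiosis(toy_symbiosis_spec(seed = 10))
  m <- fix_symbiont_biomass(b$model, floor = 0.5)
  expect_equal(m$reactions$BIOMASS_symA$lb, 0.5)
  expect_equal(m$reactions$BIOMASS_symB$lb, 0.5)
  expect_equal(m$reactions$BIOMASS_symA$ub, 1000)

  # a floor that exceeds the upper bound is refused outright
  expect_error(fix_symbiont_biomass(b$model, floor = 2000), "exceeds")

  # a feasible-looking floor above the network's capacity shows up in FBA
  m2 <- fix_symbiont_biomass(b$model, floor = 900)
  expect_identical(solve_fba(m2)$status, "infeasible")
})
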