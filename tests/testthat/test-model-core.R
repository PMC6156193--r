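test_that("the stoichiometric matrix reproduces reaction columns exactly", {
  mets <- rbind(metabolite("a[h]", formula = "C", compartment = "h"),
                metabolite("b[h]", formula = "C", compartment = "h"))
  m <- metabolic_model("tiny", "h", mets,
                       list(reaction("r", c(`a[h]` = -1, `b[h]` = 1))))
  S <- build_matrix(m)
  expect_equal(dim(S), c(2L, 1L))
  expect_equal(as.numeric(S[, "r"]), c(-1, 1))

  # degenerate: empty model
  empty <- metabolic_model("none", character(0),
                           data.frame(id = character(0), name = character(0),
                                      formula = character(0),
                                      compartment = character(0),
                                      tags = character(0)),
                           list())
  expect_equal(dim(build_matrix(empty)), c(0L, 0L))
})

test_that("toy bundle matrix equals the generator's hand-constructed matrix", {
  b <- generate_toy_symbiosis(toy_symbiosis_spec(seed = 11))
  S <- as.matrix(build_matrix(b$model))
  expect_equal(S, b$expected$S)
  # round trip: columns reconstruct the original stoichiometries
  for (rid in names(b$model$reactions)) {
    col <- S[, rid]
    st <- col[col != 0]
    orig <- b$model$reactions[[rid]]$stoichiometry
    expect_equal(st[sort(names(st))], orig[sort(names(orig))])
  }
})

test_that("referential-integrity violations are reported with ids", {
  mets <- metabolite("a[h]", formula = "C", compartment = "h")
  expect_error(
    metabolic_model("bad", "h", mets,
                    list(reaction("r", c(`a[h]` = -1, `ghost[h]` = 1)))),
    "ghost")
  expect_error(
    metabolic_model("bad2", "h", mets,
                    list(reaction("r", c(`a[h]` = -1), kind = "exchange")),
                    objective = c(nope = 1)),
    "nope")
  expect_error(
    metabolic_model("bad3", "x", mets,
                    list(reaction("r", c(`a[h]` = -1), kind = "exchange"))),
    "undeclared")
})

test_that("mass balance detects balanced and imbalanced reactions", {
  mets <- rbind(
    metabolite("glu[h]", formula = "C5H9NO4", compartment = "h"),
    metabolite("nh3[h]", formula = "NH3", compartment = "h"),
    metabolite("gln[h]", formula = "C5H10N2O3", compartment = "h"),
    metabolite("h2o[h]", formula = "H2O", compartment = "h"),
    metabolite("a1[h]", formula = "C", compartment = "h"),
    metabolite("b2[h]", formula = "C2", compartment = "h"))
  m <- metabolic_model("mb", "h", mets, list(
    reaction("GLNS", c(`glu[h]` = -1, `nh3[h]` = -1, `gln[h]` = 1, `h2o[h]` = 1)),
    reaction("BAD", c(`a1[h]` = -1, `b2[h]` = 1)),
    reaction("EX_glu", c(`glu[h]` = -1), kind = "exchange")))

  res <- check_mass_balance("GLNS", m)
  expect_identical(res$status, "checked")
  expect_true(all(res$imbalance == 0))

  res <- check_mass_balance("BAD", m)
  expect_equal(res$imbalance[["C"]], 1)

  res <- check_mass_balance("EX_glu", m)
  expect_identical(res$status, "unchecked")
  expect_match(res$reason, "exchange")
})

test_that("every internal and transport reaction of toy bundles is elementally balanced", {
  for (seed in c(1, 7, 23)) {
    b <- generate_toy_symbiosis(toy_symbiosis_spec(seed = seed))
    for (rid in names(b$model$reactions)) {
      r <- b$model$reactions[[rid]]
      if (!r$kind %in% c("internal", "transport")) next
      res <- check_mass_balance(r, b$model)
      expect_identical(res$status, "checked")
      for (el in c("C", "H", "N", "O", "S")) {
        v <- if (el %in% names(res$imbalance)) res$imbalance[[el]] else 0
        expect_equal(v, 0, label = sprintf("%s imbalance of %s", el, rid))
      }
    }
  }
})

test_that("model counts are consistent with the collections", {
  b <- generate_toy_symbiosis(toy_symbiosis_spec(seed = 4))
  cts <- model_counts(b$model)
  expect_identical(cts$n_reactions, length(b$model$reactions))
  expect_identical(cts$n_metabolites, nrow(b$model$metabolites))
  expect_identical(cts$n_genes, 0L) # toy reactions are orphans
})
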