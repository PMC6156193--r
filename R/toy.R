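# Parameterized toy three-compartment symbioses with analytically known FBA
# optima. The topology is fixed (linear essential-amino-acid pathways fed by
# host-supplied precursor and nitrogen, an optional cross-fed intermediate
# made by the primary symbiont, and ammonia overflow from the co-primary
# symbiont); randomness enters only through pathway capacities, so the
# optimum stays derivable in closed form as a minimum over bottlenecks.
#
# Chemistry (C/H/N/O alphabet, every internal reaction elementally balanced):
#   glucose  C6H12O6  ->  2 precursor C3H6O3                      (host)
#   precursor + NH3   ->  EAA C3H9NO3                             (primary)
#   precursor + m NH3 ->  amino donor C3H(6+3m)N(m)O3             (host)
#   amino donor       ->  EAA + (m-1) NH3                         (co-primary)
#   precursor + NH3   ->  cross-fed intermediate C3H9NO3          (primary)
#   intermediate      ->  EAA (isomerization)                     (co-primary)
# The integer m >= 1 encodes the ammonia overflow rate r = (m-1)/m: each
# co-primary EAA made from the amino donor returns m-1 of its m nitrogen
# atoms to the host as ammonia.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Specify a toy symbiosis
#'
#' Defaults reproduce the study conditions: uptake caps of 100 mmol gDW^-1
#' h^-1 for glucose and ammonia, oxygen capped at 20, symbiont biomass floors
#' of 0.01, amino acids excluded from the medium, and an exchange threshold
#' handled downstream. Per-EAA synthesis capacities are drawn uniformly from
#' `eaa_cap_range`; the default interval [15, 30] keeps them slack so the
#' nitrogen budget is the designed bottleneck and the optimal flux
#' distribution is a unique vertex.
#'
#' @param n_eaa_primary,n_eaa_coprimary EAAs synthesized by the primary /
#'   co-primary symbiont (defaults 7 and 3, the spittlebug partitioning).
#' @param cross_feed Include the designed cross-fed intermediate (the
#'   co-primary's last EAA is then made from it).
#' @param ammonia_overflow_rate Fraction of amino-donor nitrogen returned as
#'   ammonia by the co-primary symbiont, in [0, 1); mapped to the integer
#'   carrier stoichiometry m = round(1/(1-rate)).
#' @param biomass_floor Symbiont biomass lower bound (0.01).
#' @param glucose_cap,nh3_cap,o2_cap Medium uptake caps (100/100/20).
#' @param eaa_cap_range Interval for per-EAA capacity draws.
#' @param biomass_drain_A,biomass_drain_B Precursor and ammonia consumed per
#'   unit symbiont biomass, c(precursor=, ammonia=).
#' @param seed Integer seed fixing all randomized choices.
#' @return List of class \code{"sbf_toy_spec"}.
#' @export
toy_symbiosis_spec <- function(n_eaa_primary = 7, n_eaa_coprimary = 3,
                               cross_feed = TRUE, ammonia_overflow_rate = 0.5,
                               biomass_floor = 0.01,
                               glucose_cap = 100, nh3_cap = 100, o2_cap = 20,
                               eaa_cap_range = c(15, 30),
                               biomass_drain_A = c(precursor = 2, ammonia = 1),
                               biomass_drain_B = c(precursor = 3, ammonia = 2),
                               seed = 1L) {
  stopifnot(n_eaa_primary >= 1, n_eaa_coprimary >= 1,
            ammonia_overflow_rate >= 0, ammonia_overflow_rate < 1,
            biomass_floor >= 0, glucose_cap > 0, nh3_cap > 0,
            eaa_cap_range[1] > 0, eaa_cap_range[2] >= eaa_cap_range[1],
            all(biomass_drain_A > 0), all(biomass_drain_B > 0))
  m <- max(1L, as.integer(round(1 / (1 - ammonia_overflow_rate))))
  structure(list(n_eaa_primary = n_eaa_primary,
                 n_eaa_coprimary = n_eaa_coprimary,
                 cross_feed = isTRUE(cross_feed),
                 ammonia_overflow_rate = ammonia_overflow_rate,
                 carrier_n = m,
                 biomass_floor = biomass_floor,
                 glucose_cap = glucose_cap, nh3_cap = nh3_cap, o2_cap = o2_cap,
                 eaa_cap_range = eaa_cap_range,
                 biomass_drain_A = biomass_drain_A,
                 biomass_drain_B = biomass_drain_B,
                 seed = as.integer(seed)),
            class = "sbf_toy_spec")
}

#' Generate a toy three-compartment symbiosis with known optimum
#'
#' Builds host, primary-symbiont and co-primary-symbiont models, the
#' transport specification and medium, assembles the integrated model, and
#' computes all expected results (optimal objective, exchange profiles,
#' cross-feeding records, nitrogen ledgers, maintenance costs, and the
#' stoichiometric matrix) by independent closed-form bottleneck arithmetic --
#' never by the LP engine.
#'
#' @param spec An \code{sbf_toy_spec}.
#' @return List of class \code{"sbf_toy_bundle"}: `host`, `symA`, `symB`
#'   (single-organism models), `transport_spec`, `medium`, `model` (the
#'   medium-applied integrated model, ready for [solve_fba()]), `spec`, and
#'   `expected` (see details).
#' @export
generate_toy_symbiosis <- function(spec = toy_symbiosis_spec()) {
  stopifnot(inherits(spec, "sbf_toy_spec"))
  nA <- spec$n_eaa_primary; nB <- spec$n_eaa_coprimary
  cf <- as.integer(spec$cross_feed)
  m <- spec$carrier_n
  f <- spec$biomass_floor
  aA <- spec$biomass_drain_A[["precursor"]]; bA <- spec$biomass_drain_A[["ammonia"]]
  aB <- spec$biomass_drain_B[["precursor"]]; bB <- spec$biomass_drain_B[["ammonia"]]
  nB_ad <- nB - cf # co-primary EAAs made from the amino donor
  E <- nA + nB     # precursor (and N) demand per unit objective

  caps <- with_seed(spec$seed,
                    stats::runif(E, spec$eaa_cap_range[1], spec$eaa_cap_range[2]))
  capsA <- caps[seq_len(nA)]; capsB <- caps[nA + seq_len(nB)]

  # closed-form bottleneck optimum
  z_glc <- (2 * spec$glucose_cap - f * (aA + aB)) / E
  z_nh3 <- (spec$nh3_cap - f * (bA + bB)) / E
  z_cap <- min(caps)
  z <- min(z_cap, z_glc, z_nh3)
  if (z < 0) {
    stop(sprintf(paste("infeasible toy spec: biomass floors demand more",
                       "precursor/nitrogen than the medium supplies",
                       "(bottlenecks: glucose %.4g, ammonia %.4g)"),
                 z_glc, z_nh3))
  }

  ad_formula <- sprintf("C3H%dN%sO3", 6 + 3 * m, if (m == 1) "" else m)
  eaaA <- sprintf("eaaA%d", seq_len(nA))
  eaaB <- sprintf("eaaB%d", seq_len(nB))
  use_ad <- m >= 2 && nB_ad >= 1

  mk_mets <- function(comp, species, formulas, tags) {
    do.call(rbind, Map(function(sp, fo, tg)
      metabolite(paste0(sp, "[", comp, "]"), name = sp, formula = fo,
                 compartment = comp, tags = tg),
      species, formulas, tags))
  }

  # --- host ---
  h_species <- c("glc", "nh3", "o2", "so4", "prec",
                 if (use_ad) "ad", if (cf) "xint", eaaA, eaaB)
  h_form <- c("C6H12O6", "NH3", "O2", "O4S", "C3H6O3",
              if (use_ad) ad_formula, if (cf) "C3H9NO3",
              rep("C3H9NO3", nA + nB))
  h_tags <- c("central_carbon", "mineral", "mineral", "mineral", "central_carbon",
              if (use_ad) "other", if (cf) "other", rep("eaa", nA + nB))
  q <- function(sp, comp) paste0(sp, "[", comp, "]")
  h_rxns <- list(
    reaction("GLC2P_h", stats::setNames(c(-1, 2), c(q("glc", "h"), q("prec", "h"))),
             lb = 0, ub = 1000))
  if (use_ad) {
    h_rxns <- c(h_rxns, list(
      reaction("ADSYN_h", stats::setNames(c(-1, -m, 1),
                                          c(q("prec", "h"), q("nh3", "h"), q("ad", "h"))),
               lb = 0, ub = 1000)))
  }
  h_rxns <- c(h_rxns, list(
    reaction("BIOMASS_host", stats::setNames(rep(-1, nA + nB),
                                             q(c(eaaA, eaaB), "h")),
             lb = 0, ub = 1000, kind = "objective")))
  host <- metabolic_model("toy_host", "h", mk_mets("h", h_species, h_form, h_tags),
                          h_rxns, objective = c(BIOMASS_host = 1))

  # --- primary symbiont ---
  a_species <- c("prec", "nh3", if (cf) "xint", eaaA)
  a_form <- c("C3H6O3", "NH3", if (cf) "C3H9NO3", rep("C3H9NO3", nA))
  a_tags <- c("central_carbon", "mineral", if (cf) "other", rep("eaa", nA))
  a_rxns <- lapply(seq_len(nA), function(i)
    reaction(sprintf("EAASYN_A%d", i),
             stats::setNames(c(-1, -1, 1),
                             c(q("prec", "sA"), q("nh3", "sA"), q(eaaA[i], "sA"))),
             lb = 0, ub = capsA[i]))
  if (cf) {
    a_rxns <- c(a_rxns, list(
      reaction("XSYN_A", stats::setNames(c(-1, -1, 1),
                                         c(q("prec", "sA"), q("nh3", "sA"),
                                           q("xint", "sA"))),
               lb = 0, ub = 1000)))
  }
  a_rxns <- c(a_rxns, list(
    reaction("BIOMASS_symA", stats::setNames(c(-aA, -bA),
                                             c(q("prec", "sA"), q("nh3", "sA"))),
             lb = f, ub = 1000, kind = "biomass")))
  symA <- metabolic_model("toy_symA", "sA",
                          mk_mets("sA", a_species, a_form, a_tags),
                          a_rxns)

  # --- co-primary symbiont ---
  b_species <- c("prec", "nh3", if (use_ad) "ad", if (cf) "xint", eaaB)
  b_form <- c("C3H6O3", "NH3", if (use_ad) ad_formula, if (cf) "C3H9NO3",
              rep("C3H9NO3", nB))
  b_tags <- c("central_carbon", "mineral", if (use_ad) "other", if (cf) "other",
              rep("eaa", nB))
  b_rxns <- lapply(seq_len(nB_ad), function(j) {
    if (use_ad) {
      st <- stats::setNames(c(-1, 1, m - 1),
                            c(q("ad", "sB"), q(eaaB[j], "sB"), q("nh3", "sB")))
    } else {
      st <- stats::setNames(c(-1, -1, 1),
                            c(q("prec", "sB"), q("nh3", "sB"), q(eaaB[j], "sB")))
    }
    reaction(sprintf("EAASYN_B%d", j), st[st != 0], lb = 0, ub = capsB[j])
  })
  if (cf) {
    b_rxns <- c(b_rxns, list(
      reaction(sprintf("EAASYN_B%d", nB),
               stats::setNames(c(-1, 1), c(q("xint", "sB"), q(eaaB[nB], "sB"))),
               lb = 0, ub = capsB[nB])))
  }
  b_rxns <- c(b_rxns, list(
    reaction("BIOMASS_symB", stats::setNames(c(-aB, -bB),
                                             c(q("prec", "sB"), q("nh3", "sB"))),
             lb = f, ub = 1000, kind = "biomass")))
  symB <- metabolic_model("toy_symB", "sB",
                          mk_mets("sB", b_species, b_form, b_tags),
                          b_rxns)

  # --- transports and medium ---
  tr <- function(mets, donor, recipient) data.frame(
    metabolite = mets, donor = donor, recipient = recipient,
    reversible = TRUE, stringsAsFactors = FALSE)
  transport_spec <- rbind(
    tr(c("glc", "nh3", "o2", "so4"), "e", "h"),
    tr(c("prec", "nh3"), "h", "sA"),
    tr(c("prec", "nh3"), "h", "sB"),
    if (use_ad) tr("ad", "h", "sB"),
    if (cf) tr("xint", "sA", "h"),
    if (cf) tr("xint", "h", "sB"),
    tr(eaaA, "sA", "h"),
    tr(eaaB, "sB", "h"))

  medium <- medium_spec(c(glc = spec$glucose_cap, nh3 = spec$nh3_cap, so4 = 100),
                        o2_cap = spec$o2_cap)

  model <- build_multicompartment(host, symA, symB, transport_spec,
                                  id = "toy_symbiosis")
  model <- apply_medium(model, medium)

  # --- expected values, by closed-form arithmetic only ---
  unique_vertex <- min(z_glc, z_nh3) < z_cap - 1e-9
  overflow <- if (use_ad) (m - 1) * nB_ad * z else 0
  nh3_B_net_in <- f * bB - overflow + (if (use_ad) 0 else nB_ad * z)
  exp_sA <- list(
    imports = c(prec = (nA + cf) * z + f * aA, nh3 = (nA + cf) * z + f * bA),
    exports = c(stats::setNames(rep(z, nA), eaaA),
                if (cf) c(xint = z)))
  imp_B <- c(prec = f * aB + (if (use_ad) 0 else nB_ad * z),
             if (use_ad) c(ad = nB_ad * z),
             if (cf) c(xint = z),
             if (nh3_B_net_in > 1e-12) c(nh3 = nh3_B_net_in))
  exp_B <- c(stats::setNames(rep(z, nB), eaaB),
             if (nh3_B_net_in < -1e-12) c(nh3 = -nh3_B_net_in))
  exp_sB <- list(imports = imp_B, exports = exp_B)

  ledger_sA <- list(N_in = exp_sA$imports[["nh3"]],
                    N_out_eaa = nA * z, N_out_other = cf * z, N_biomass = f * bA)
  ledger_sA$efficiency <- ledger_sA$N_out_eaa / ledger_sA$N_in
  n_in_B <- (if (use_ad) m * nB_ad * z else 0) + cf * z +
    max(0, nh3_B_net_in)
  ledger_sB <- list(N_in = n_in_B, N_out_eaa = nB * z,
                    N_out_other = max(0, -nh3_B_net_in), N_biomass = f * bB)
  ledger_sB$efficiency <- ledger_sB$N_out_eaa / ledger_sB$N_in

  cost <- function(aX, bX) {
    z_off <- min(z_cap, z + f * aX / E, z + f * bX / E, z_glc + f * aX / E,
                 z_nh3 + f * bX / E)
    max(0, z_off - z)
  }

  cross_feed_expected <- if (cf) {
    data.frame(metabolite = "xint", donor = "sA", recipient = "sB",
               flux = z, stringsAsFactors = FALSE)
  } else {
    data.frame(metabolite = character(0), donor = character(0),
               recipient = character(0), flux = numeric(0),
               stringsAsFactors = FALSE)
  }

  # hand-constructed stoichiometric matrix (independent of build_matrix)
  S_exp <- matrix(0, nrow(model$metabolites), length(model$reactions),
                  dimnames = list(model$metabolites$id, names(model$reactions)))
  for (rid in names(model$reactions)) {
    st <- model$reactions[[rid]]$stoichiometry
    for (mm in names(st)) S_exp[mm, rid] <- S_exp[mm, rid] + st[[mm]]
  }

  expected <- list(
    objective = z,
    bottlenecks = c(capacity = z_cap, glucose = z_glc, nitrogen = z_nh3),
    unique_vertex = unique_vertex,
    exchange = list(sA = exp_sA, sB = exp_sB),
    cross_feed = cross_feed_expected,
    ledger = list(sA = ledger_sA, sB = ledger_sB),
    maintenance_cost = c(symA = cost(aA, bA), symB = cost(aB, bB)),
    eaa_share = c(symA = nA * z / (E * z), symB = nB * z / (E * z)),
    eaa_total_flux = E * z,
    S = S_exp)

  structure(list(spec = spec, host = host, symA = symA, symB = symB,
                 transport_spec = transport_spec, medium = medium,
                 model = model, expected = expected),
            class = "sbf_toy_bundle")
}

#' Generate a synthetic TPM expression table
#'
#' Log-normal TPM draws across replicates, with a designated fraction of
#' genes set to zero in every replicate (emulating very-low-abundance
#' transcripts). Deterministic per seed.
#'
#' @param n_genes,n_replicates Table dimensions.
#' @param zero_fraction Fraction of all-zero genes, in [0, 1).
#' @param seed Integer seed.
#' @return data.frame with `gene_id` and replicate columns `rep1..repk`.
#' @export
generate_expression_table <- function(n_genes, n_replicates = 3,
                                      zero_fraction = 0.1, seed = 1L) {
  stopifnot(n_genes >= 1, n_replicates >= 1,
            zero_fraction >= 0, zero_fraction < 1)
  with_seed(seed, {
    tpm <- matrix(stats::rlnorm(n_genes * n_replicates, meanlog = 3, sdlog = 1.5),
                  nrow = n_genes)
    n_zero <- floor(zero_fraction * n_genes)
    if (n_zero > 0) {
      zi <- sample.int(n_genes, n_zero)
      tpm[zi, ] <- 0
    }
    out <- data.frame(gene_id = sprintf("g%04d", seq_len(n_genes)))
    for (j in seq_len(n_replicates)) out[[sprintf("rep%d", j)]] <- tpm[, j]
    out
  })
}

#' Degenerate fixtures with known behavior
#'
#' A small suite of pathological models exercising the solver and analysis
#' contracts: a blocked-pathway infeasible model, a parallel-route model with
#' known FVA ranges, a zero-objective model, and a toy bundle whose
#' cross-fed metabolite lacks a formula (the nitrogen ledger must refuse it).
#'
#' @return Named list; each entry carries the fixture and an `expected`
#'   description/values.
#' @export
degenerate_case_suite <- function() {
  chain <- function(conv_ub, obj_lb = 0) {
    mets <- rbind(metabolite("a[h]", formula = "C", compartment = "h"),
                  metabolite("b[h]", formula = "C", compartment = "h"))
    metabolic_model("chain", "h", mets, list(
      reaction("EX_a", c(`a[h]` = -1), lb = -5, ub = 1000, kind = "exchange"),
      reaction("CONV", c(`a[h]` = -1, `b[h]` = 1), lb = 0, ub = conv_ub),
      reaction("OBJ", c(`b[h]` = -1), lb = obj_lb, ub = 1000, kind = "objective")),
      objective = c(OBJ = 1))
  }
  parallel <- {
    mets <- rbind(metabolite("a[h]", formula = "C", compartment = "h"),
                  metabolite("b[h]", formula = "C", compartment = "h"))
    metabolic_model("parallel", "h", mets, list(
      reaction("EX_a", c(`a[h]` = -1), lb = -5, ub = 1000, kind = "exchange"),
      reaction("R1", c(`a[h]` = -1, `b[h]` = 1), lb = 0, ub = 1000),
      reaction("R2", c(`a[h]` = -1, `b[h]` = 1), lb = 0, ub = 1000),
      reaction("OBJ", c(`b[h]` = -1), lb = 0, ub = 1000, kind = "objective")),
      objective = c(OBJ = 1))
  }
  noformula <- generate_toy_symbiosis(toy_symbiosis_spec(seed = 99L))
  i <- match("xint[sA]", noformula$model$metabolites$id)
  noformula$model$metabolites$formula[i] <- ""

  list(
    blocked = list(model = chain(conv_ub = 0, obj_lb = 0.01),
                   expected = "solve_fba status infeasible"),
    parallel_routes = list(model = parallel,
                           expected = list(objective = 5,
                                           fva_range = c(R1 = 5, R2 = 5))),
    zero_objective = list(model = {
      m <- chain(conv_ub = 1000); m$objective <- numeric(0); m
    }, expected = "solve_fba errors: empty objective"),
    missing_formula = list(bundle = noformula,
                           expected = "nitrogen_ledger errors on xint"))
  }
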