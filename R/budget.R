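# Elemental nitrogen bookkeeping per symbiont and the host's cost of
# maintaining each symbiont's biomass production.

#' Nitrogen ledger for one compartment
#'
#' Multiplies each transported metabolite's flux by its N stoichiometry
#' (atom count from the elemental formula): N into the compartment, N out in
#' essential amino acids, N out in everything else (ammonia included), plus N
#' retained in biomass (biomass flux times the N content of consumed biomass
#' components). Recycling efficiency = EAA-N out / N in. The full balance
#' closes on elementally balanced models: N_in = N_out_total + N_biomass.
#'
#' @param profile An \code{sbf_exchange_profile} (thresholded).
#' @param model The \code{sbf_multi} supplying formulas and biomass
#'   stoichiometry.
#' @param sol The optimal \code{sbf_fba} the profile came from (for biomass
#'   flux).
#' @param element Element symbol (default "N").
#' @return List of class \code{"sbf_nitrogen_ledger"}: N_in, N_out_eaa,
#'   N_out_other, N_biomass, efficiency, and per-metabolite rows.
#' @export
nitrogen_ledger <- function(profile, model, sol, element = "N") {
  comp <- profile$compartment
  qual <- function(sp) paste0(sp, "[", comp, "]")
  species <- c(names(profile$imports), names(profile$exports))
  formulas <- vapply(species, function(sp) met_row(model, qual(sp))$formula, "")
  if (any(!nzchar(formulas))) {
    stop("transported metabolites without formulas: ",
         paste(species[!nzchar(formulas)], collapse = ", "))
  }
  ncount <- vapply(formulas, function(f) element_count(f, element), 0L)
  is_eaa <- vapply(species, function(sp) "eaa" %in% met_tags(model, qual(sp)), TRUE)

  rows <- data.frame(
    metabolite = species,
    direction = c(rep("import", length(profile$imports)),
                  rep("export", length(profile$exports))),
    flux = c(unname(profile$imports), unname(profile$exports)),
    n_atoms = unname(ncount),
    stringsAsFactors = FALSE)
  rows$n_flux <- rows$flux * rows$n_atoms

  n_in <- sum(rows$n_flux[rows$direction == "import"])
  n_out_eaa <- sum(rows$n_flux[rows$direction == "export" & is_eaa[rows$metabolite]])
  n_out_other <- sum(rows$n_flux[rows$direction == "export" & !is_eaa[rows$metabolite]])

  # biomass retention: flux through this compartment's biomass reaction(s)
  # times element content of consumed components (formula-less
  # pseudo-components excluded from elemental budgets)
  n_biomass <- 0
  for (rid in names(model$reactions)) {
    r <- model$reactions[[rid]]
    if (r$kind != "biomass") next
    in_comp <- vapply(names(r$stoichiometry), function(m)
      met_row(model, m)$compartment == comp, TRUE)
    if (!any(in_comp)) next
    consumed <- r$stoichiometry[r$stoichiometry < 0 & in_comp]
    for (m in names(consumed)) {
      f <- met_row(model, m)$formula
      if (nzchar(f)) {
        n_biomass <- n_biomass + sol$flux[[rid]] * (-consumed[[m]]) *
          element_count(f, element)
      }
    }
  }

  structure(list(compartment = comp, element = element,
                 N_in = n_in, N_out_eaa = n_out_eaa, N_out_other = n_out_other,
                 N_biomass = n_biomass,
                 efficiency = if (n_in > 0) n_out_eaa / n_in else NA_real_,
                 rows = rows),
            class = "sbf_nitrogen_ledger")
}

#' Symbiont maintenance cost
#'
#' Cost of maintaining one symbiont's biomass production, computed as the
#' difference between host growth yields in the presence and absence of that
#' symbiont's biomass flux. The uptakes of the main C/N/P/S sources are first
#' capped at their observed fluxes in the full model (both symbionts
#' growing); the target symbiont's biomass reaction is then fixed to zero
#' while all its other reactions stay open (the host keeps access to the
#' symbiont's amino acids), the other symbiont's floor stays active, and FBA
#' is re-solved.
#'
#' @param model An \code{sbf_multi} with both symbiont biomass floors active.
#' @param symbiont Which symbiont to switch off: provenance role "symA" or
#'   "symB".
#' @param capped_nutrients Species ids whose exchange uptakes are capped at
#'   observed values (defaults cover glucose, fructose, ammonia/ammonium,
#'   phosphate and sulfate under common naming).
#' @param stabilize Passed to [solve_fba()] for both solves.
#' @return List of class \code{"sbf_maintenance_cost"}: symbiont,
#'   host_growth_full, host_growth_symbiont_off, cost_absolute (off - full),
#'   cost_relative (fraction of full growth), observed_uptakes, and `status`
#'   of the knockout solve (an infeasible knockout is reported, not an
#'   error).
#' @export
maintenance_cost <- function(model, symbiont = c("symA", "symB"),
                             capped_nutrients = c("glc", "glucose", "fru",
                                                  "fructose", "nh3", "nh4",
                                                  "pi", "so4"),
                             stabilize = FALSE) {
  symbiont <- match.arg(symbiont)
  full <- solve_fba(model, stabilize = stabilize)
  if (full$status != "optimal") {
    stop("full three-compartment model is not feasible (status: ", full$status, ")")
  }
  observed <- numeric(0)
  for (rid in names(model$reactions)) {
    r <- model$reactions[[rid]]
    if (r$kind != "exchange") next
    sp <- species_id(names(r$stoichiometry))
    if (!sp %in% capped_nutrients) next
    uptake <- max(0, -full$flux[[rid]])
    observed[sp] <- uptake
    model$reactions[[rid]]$lb <- -uptake
  }
  bids <- symbiont_biomass_ids(model, symbiont)
  if (length(bids) == 0L) stop("no biomass reaction found for ", symbiont)
  for (rid in bids) {
    model$reactions[[rid]]$lb <- 0
    model$reactions[[rid]]$ub <- 0
  }
  off <- solve_fba(model, stabilize = stabilize)
  cost_abs <- if (off$status == "optimal") off$objective - full$objective else NA_real_
  structure(list(symbiont = symbiont,
                 host_growth_full = full$objective,
                 host_growth_symbiont_off = off$objective,
                 cost_absolute = cost_abs,
                 cost_relative = cost_abs / full$objective,
                 observed_uptakes = observed,
                 status = off$status),
            class = "sbf_maintenance_cost")
}
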