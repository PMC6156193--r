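# Integration of per-organism models into one three-compartment network:
# host + primary symbiont + co-primary symbiont, joined by cost-free 1:1
# transport reactions, plus an external medium compartment with exchange
# reactions. Convention: exchange reactions are export-positive (met[e] ->
# nothing), so uptake is negative flux bounded by the medium cap.

#' Molecular weights of the 20 proteinogenic amino acids (g/mol, free form)
#' @format Named numeric vector keyed by lowercase amino-acid name.
#' @export
AA_MW <- c(
  alanine = 89.09, arginine = 174.20, asparagine = 132.12, aspartate = 133.10,
  cysteine = 121.16, glutamine = 146.15, glutamate = 147.13, glycine = 75.07,
  histidine = 155.15, isoleucine = 131.17, leucine = 131.17, lysine = 146.19,
  methionine = 149.21, phenylalanine = 165.19, proline = 115.13,
  serine = 105.09, threonine = 119.12, tryptophan = 204.23,
  tyrosine = 181.19, valine = 117.15)

#' Specify the external medium
#'
#' The minimal hemolymph-like medium: named nutrient caps (mmol gDW^-1 h^-1)
#' on uptake, an oxygen cap, and a default cap for listed nutrients without
#' an explicit value. Metabolites tagged with any of `excluded_tags`
#' (amino acids by default) are refused as nutrient sources even if listed.
#'
#' @param nutrients Character vector of external species ids, or a named
#'   numeric vector of caps (NA = use `default_cap`).
#' @param o2_cap Maximum oxygen uptake flux (default 20).
#' @param default_cap Maximum uptake flux for other nutrients (default 100).
#' @param o2_id Species id of oxygen (default "o2").
#' @param excluded_tags Metabolite tags excluded as nutrient sources.
#' @return A \code{list} of class \code{"sbf_medium"}.
#' @export
medium_spec <- function(nutrients, o2_cap = 20, default_cap = 100,
                        o2_id = "o2", excluded_tags = "eaa") {
  if (is.character(nutrients)) {
    nutrients <- stats::setNames(rep(NA_real_, length(nutrients)), nutrients)
  }
  stopifnot(!is.null(names(nutrients)), o2_cap >= 0, default_cap >= 0)
  if (any(!is.na(nutrients) & nutrients < 0)) stop("uptake caps must be >= 0")
  nutrients[is.na(nutrients)] <- default_cap
  explicit <- names(nutrients)
  if (o2_id %in% names(nutrients)) nutrients[[o2_id]] <- min(nutrients[[o2_id]], o2_cap)
  else nutrients[[o2_id]] <- o2_cap
  structure(list(uptake = nutrients, o2_cap = o2_cap, default_cap = default_cap,
                 o2_id = o2_id, excluded_tags = excluded_tags,
                 explicit = explicit),
            class = "sbf_medium")
}

#' Merge host and symbiont models into a three-compartment model
#'
#' Concatenates the three single-organism models (their compartments must be
#' disjoint and metabolite ids compartment-suffixed, so no collisions occur),
#' adds one cost-free 1:1 transport reaction per `transport_spec` row, creates
#' the external compartment's metabolites for transports touching it, and an
#' export-positive exchange reaction (initially closed for uptake) for each
#' external metabolite. Per-reaction provenance and a transport registry are
#' recorded.
#'
#' @param host,symA,symB \code{sbf_model}s (host, primary symbiont,
#'   co-primary symbiont).
#' @param transport_spec data.frame with columns `metabolite` (species id,
#'   no compartment suffix), `donor`, `recipient` (compartment ids, the
#'   external compartment allowed), and optional `reversible` (default TRUE:
#'   direction resolved by FBA).
#' @param external External compartment id (default "e").
#' @param id Integrated model id.
#' @param transport_bound Magnitude of transport flux bounds (default 1000).
#' @return An \code{sbf_model} that is also class \code{"sbf_multi"}, with
#'   `$provenance` (reaction id -> host/symA/symB/transport/external) and
#'   `$transports` (registry: metabolite, donor, recipient, reaction_id).
#' @export
build_multicompartment <- function(host, symA, symB, transport_spec,
                                   external = "e",
                                   id = paste(host$id, symA$id, symB$id, sep = "+"),
                                   transport_bound = 1000) {
  organisms <- list(host = host, symA = symA, symB = symB)
  allcomp <- unlist(lapply(organisms, `[[`, "compartments"), use.names = FALSE)
  if (anyDuplicated(c(allcomp, external))) {
    stop("compartment ids of host/symA/symB/external must be disjoint")
  }
  mets <- do.call(rbind, lapply(organisms, `[[`, "metabolites"))
  rownames(mets) <- NULL
  rxns <- list(); prov <- character(0)
  for (role in names(organisms)) {
    for (r in organisms[[role]]$reactions) {
      rxns[[r$id]] <- r
      prov[r$id] <- role
    }
  }
  objective <- do.call(c, unname(lapply(organisms, `[[`, "objective")))
  if (is.null(objective)) objective <- numeric(0)

  stopifnot(is.data.frame(transport_spec),
            all(c("metabolite", "donor", "recipient") %in% names(transport_spec)))
  if (!"reversible" %in% names(transport_spec)) transport_spec$reversible <- TRUE

  qual <- function(sp, comp) paste0(sp, "[", comp, "]")
  registry <- transport_spec[, c("metabolite", "donor", "recipient")]
  registry$reaction_id <- NA_character_

  for (i in seq_len(nrow(transport_spec))) {
    sp <- transport_spec$metabolite[i]
    dn <- transport_spec$donor[i]; rc <- transport_spec$recipient[i]
    for (comp in c(dn, rc)) {
      mid <- qual(sp, comp)
      if (!mid %in% mets$id) {
        if (comp != external) {
          stop(sprintf("transport endpoint missing: metabolite '%s' in compartment '%s'",
                       sp, comp))
        }
        # clone species metadata from the internal endpoint
        other <- qual(sp, setdiff(c(dn, rc), external))
        src <- mets[match(other, mets$id), , drop = FALSE]
        if (nrow(src) == 0L || is.na(src$id[1])) {
          stop(sprintf("transport endpoint missing: metabolite '%s' in compartment '%s'",
                       sp, setdiff(c(dn, rc), external)))
        }
        src$id <- mid; src$compartment <- external
        mets <- rbind(mets, src)
      }
    }
    tid <- sprintf("T_%s_%s_%s", sp, dn, rc)
    lb <- if (isTRUE(transport_spec$reversible[i])) -transport_bound else 0
    rxns[[tid]] <- reaction(tid, stats::setNames(c(-1, 1), c(qual(sp, dn), qual(sp, rc))),
                            lb = lb, ub = transport_bound, kind = "transport")
    prov[tid] <- "transport"
    registry$reaction_id[i] <- tid
  }

  ext_mets <- mets$id[mets$compartment == external]
  for (mid in ext_mets) {
    eid <- sprintf("EX_%s", species_id(mid))
    rxns[[eid]] <- reaction(eid, stats::setNames(-1, mid), lb = 0, ub = 1000,
                            kind = "exchange")
    prov[eid] <- "external"
  }

  m <- metabolic_model(id = id,
                       compartments = c(allcomp, external),
                       metabolites = mets, reactions = rxns,
                       objective = objective)
  m$provenance <- prov
  m$transports <- registry
  m$external <- external
  class(m) <- c("sbf_multi", class(m))
  m
}

#' Apply a medium specification to the integrated model
#'
#' Opens uptake (negative lower bound) on the exchange reactions of listed
#' nutrients at their caps, caps oxygen at the oxygen cap, closes uptake on
#' every other exchange, and refuses uptake of metabolites carrying an
#' excluded tag (amino acids are not nutrient sources).
#'
#' @param model An \code{sbf_multi} from [build_multicompartment()].
#' @param medium An \code{sbf_medium} from [medium_spec()].
#' @return The model with medium bounds applied.
#' @export
apply_medium <- function(model, medium) {
  stopifnot(inherits(model, "sbf_multi"), inherits(medium, "sbf_medium"))
  ex_ids <- names(model$reactions)[vapply(model$reactions, function(r)
    r$kind == "exchange", TRUE)]
  ex_species <- species_id(vapply(model$reactions[ex_ids], function(r)
    names(r$stoichiometry), ""))
  # oxygen is an implicit medium entry; only explicitly listed nutrients
  # must have an exchange reaction
  missing <- setdiff(medium$explicit, ex_species)
  if (length(missing)) {
    stop("medium metabolites with no exchange reaction: ",
         paste(missing, collapse = ", "))
  }
  for (k in seq_along(ex_ids)) {
    rid <- ex_ids[k]; sp <- ex_species[k]
    mid <- names(model$reactions[[rid]]$stoichiometry)
    excluded <- length(intersect(met_tags(model, mid), medium$excluded_tags)) > 0
    if (!excluded && sp %in% names(medium$uptake)) {
      model$reactions[[rid]]$lb <- -medium$uptake[[sp]]
    } else {
      model$reactions[[rid]]$lb <- 0
    }
  }
  model$medium <- medium
  model
}

#' Build the host biomass objective composition
#'
#' Translates the amino-acid mass composition of whole-insect protein into
#' biomass coefficients (mmol amino acid per g protein, scaled by protein
#' mass per gDW), and appends B-vitamin components at a small fixed
#' coefficient.
#'
#' @param aa_mass_fractions Named numeric vector of mass fractions by
#'   amino-acid name (must sum to 1 within 1e-6).
#' @param vitamins Character vector of B-vitamin component ids.
#' @param vitamin_coeff Coefficient for each vitamin component (default
#'   0.00005).
#' @param protein_per_gdw Grams of protein per gDW (default 1; only relative
#'   fluxes matter downstream).
#' @param mw Molecular-weight lookup (g/mol), defaults to [AA_MW].
#' @return data.frame (component, coefficient, provenance) of class
#'   \code{"sbf_biomass_spec"}.
#' @export
build_objective <- function(aa_mass_fractions, vitamins = character(0),
                            vitamin_coeff = 0.00005, protein_per_gdw = 1,
                            mw = AA_MW) {
  stopifnot(!is.null(names(aa_mass_fractions)))
  if (abs(sum(aa_mass_fractions) - 1) > 1e-6) {
    stop("amino-acid mass fractions must sum to 1 (got ",
         format(sum(aa_mass_fractions)), ")")
  }
  unknown <- setdiff(names(aa_mass_fractions), names(mw))
  if (length(unknown)) stop("unknown amino acid name(s): ",
                            paste(unknown, collapse = ", "))
  coef <- 1000 * aa_mass_fractions / mw[names(aa_mass_fractions)] * protein_per_gdw
  out <- data.frame(component = c(names(aa_mass_fractions), vitamins),
                    coefficient = c(unname(coef),
                                    rep(vitamin_coeff, length(vitamins))),
                    provenance = c(rep("amino_acid_composition",
                                       length(aa_mass_fractions)),
                                   rep("b_vitamin", length(vitamins))),
                    stringsAsFactors = FALSE)
  if (any(out$coefficient <= 0)) stop("all biomass coefficients must be > 0")
  class(out) <- c("sbf_biomass_spec", class(out))
  out
}

#' Attach a biomass-spec objective reaction to a model
#'
#' Adds a pseudo-reaction consuming each component (in the given compartment)
#' at its coefficient and makes it the model's (maximized) objective.
#'
#' @param model An \code{sbf_model}.
#' @param spec An \code{sbf_biomass_spec} from [build_objective()].
#' @param compartment Compartment holding the component metabolites.
#' @param id Reaction id (default "BIOMASS_host").
#' @return The model with the objective reaction appended.
#' @export
attach_objective <- function(model, spec, compartment, id = "BIOMASS_host") {
  mids <- paste0(spec$component, "[", compartment, "]")
  missing <- setdiff(mids, model$metabolites$id)
  if (length(missing)) stop("objective components missing from model: ",
                            paste(missing, collapse = ", "))
  rx <- reaction(id, stats::setNames(-spec$coefficient, mids), lb = 0, ub = 1000,
                 kind = "objective")
  model$reactions[[id]] <- rx
  if (inherits(model, "sbf_multi")) model$provenance[id] <- "host"
  model$objective <- stats::setNames(1, id)
  validate_model(model)
  model
}

#' Fix symbiont biomass floors
#'
#' Sets the lower bound of each symbiont's biomass reaction to `floor`
#' (default 0.01 mmol gDW^-1 h^-1, equal biomass proportions assumed for the
#' two symbionts); upper bounds are unchanged.
#'
#' @param model An \code{sbf_multi}.
#' @param floor Biomass lower bound.
#' @param biomass_ids Optional explicit reaction ids; by default all
#'   kind-"biomass" reactions with symbiont provenance.
#' @return The model with floors applied.
#' @export
fix_symbiont_biomass <- function(model, floor = 0.01, biomass_ids = NULL) {
  stopifnot(floor >= 0)
  if (is.null(biomass_ids)) {
    biomass_ids <- names(model$reactions)[vapply(model$reactions, function(r)
      r$kind == "biomass", TRUE)]
    biomass_ids <- biomass_ids[model$provenance[biomass_ids] %in% c("symA", "symB")]
  }
  if (length(biomass_ids) == 0L) stop("no symbiont biomass reactions found")
  for (rid in biomass_ids) {
    if (!rid %in% names(model$reactions)) stop("missing biomass reaction: ", rid)
    if (model$reactions[[rid]]$ub < floor) {
      stop(sprintf("biomass floor %g exceeds upper bound of '%s'", floor, rid))
    }
    model$reactions[[rid]]$lb <- floor
  }
  model
}

#' Promote an integrated model read from disk to a multi-compartment model
#'
#' A three-compartment model loaded from SBML or the tabular dialect is a
#' plain \code{sbf_model}; this reconstructs the transport registry from its
#' kind-"transport" reactions and assigns per-reaction provenance from the
#' compartments each reaction touches, given the role mapping.
#'
#' @param model An \code{sbf_model} whose transport reactions are 1:1 between
#'   compartments.
#' @param roles Named character vector mapping roles to compartment ids,
#'   e.g. \code{c(host = "h", symA = "sA", symB = "sB")}.
#' @param external External compartment id (default "e").
#' @return An \code{sbf_multi}.
#' @export
as_multicompartment <- function(model, roles, external = "e") {
  stopifnot(all(c("host", "symA", "symB") %in% names(roles)))
  comp_role <- stats::setNames(names(roles), roles)
  prov <- character(0)
  reg <- list()
  for (rid in names(model$reactions)) {
    r <- model$reactions[[rid]]
    comps <- unique(model$metabolites$compartment[
      match(names(r$stoichiometry), model$metabolites$id)])
    if (r$kind == "transport") {
      prov[rid] <- "transport"
      st <- r$stoichiometry
      donor_met <- names(st)[st < 0][1]; rec_met <- names(st)[st > 0][1]
      reg[[length(reg) + 1L]] <- data.frame(
        metabolite = species_id(donor_met),
        donor = model$metabolites$compartment[match(donor_met, model$metabolites$id)],
        recipient = model$metabolites$compartment[match(rec_met, model$metabolites$id)],
        reaction_id = rid, stringsAsFactors = FALSE)
    } else if (r$kind == "exchange" || all(comps == external)) {
      prov[rid] <- "external"
    } else {
      role <- unique(comp_role[intersect(comps, names(comp_role))])
      prov[rid] <- if (length(role) == 1L) role else "host"
    }
  }
  model$provenance <- prov
  model$transports <- if (length(reg)) do.call(rbind, reg) else
    data.frame(metabolite = character(0), donor = character(0),
               recipient = character(0), reaction_id = character(0))
  model$external <- external
  if (!inherits(model, "sbf_multi")) class(model) <- c("sbf_multi", class(model))
  model
}

# Symbiont biomass reaction ids by provenance role ("symA"/"symB").
symbiont_biomass_ids <- function(model, role = c("symA", "symB")) {
  role <- match.arg(role)
  ids <- names(model$reactions)[vapply(model$reactions, function(r)
    r$kind == "biomass", TRUE)]
  ids[model$provenance[ids] == role]
}
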