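#' Construct a metabolite record
#'
#' @param id Unique metabolite id. By convention compartment-qualified ids
#'   carry a \code{"[compartment]"} suffix, e.g. \code{"gln[h]"}.
#' @param name Human-readable name.
#' @param formula Hill-style elemental formula; \code{""} only for abstract
#'   biomass/pseudo-metabolites (excluded from elemental budgets).
#' @param compartment Compartment id the metabolite lives in.
#' @param tags Character vector of class labels from
#'   \code{c("mineral","cofactor","eaa","b_vitamin","central_carbon","other")}.
#' @return A one-row data.frame (tags collapsed with ";").
#' @export
metabolite <- function(id, name = id, formula = "", compartment, tags = "other") {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  bad <- setdiff(tags, METABOLITE_TAGS)
  if (length(bad)) stop("unknown metabolite tags: ", paste(bad, collapse = ", "))
  if (nzchar(formula)) parse_formula(formula) # validate early
  data.frame(id = id, name = name, formula = formula,
             compartment = compartment,
             tags = paste(tags, collapse = ";"),
             stringsAsFactors = FALSE)
}

METABOLITE_TAGS <- c("mineral", "cofactor", "eaa", "b_vitamin",
                     "central_carbon", "other")

REACTION_KINDS <- c("internal", "transport", "exchange", "biomass", "objective")

#' Construct a reaction
#'
#' @param id,name Identifiers.
#' @param stoichiometry Named numeric vector of metabolite coefficients
#'   (negative = consumed). Exchange reactions may touch a single metabolite;
#'   all others need at least two entries.
#' @param lb,ub Flux bounds in mmol gDW^-1 h^-1; \code{lb <= ub}.
#' @param gpr Gene association as a boolean expression string over gene ids
#'   using \code{and}/\code{or} and parentheses; \code{""} for orphan
#'   reactions.
#' @param kind One of \code{"internal"}, \code{"transport"},
#'   \code{"exchange"}, \code{"biomass"}, \code{"objective"}.
#' @return A list of class \code{"sbf_reaction"}.
#' @export
reaction <- function(id, stoichiometry, lb = -1000, ub = 1000, name = id,
                     gpr = "", kind = "internal") {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  kind <- match.arg(kind, REACTION_KINDS)
  if (is.null(names(stoichiometry)) || any(!nzchar(names(stoichiometry)))) {
    stop(sprintf("reaction '%s': stoichiometry must be a named vector", id))
  }
  stoichiometry <- stoichiometry[stoichiometry != 0]
  if (length(stoichiometry) == 0L) {
    stop(sprintf("reaction '%s': empty stoichiometry", id))
  }
  if (kind != "exchange" && length(stoichiometry) < 2L &&
      !kind %in% c("biomass", "objective")) {
    stop(sprintf("reaction '%s': non-exchange reactions need >= 2 metabolites", id))
  }
  if (!is.finite(lb) || !is.finite(ub)) {
    stop(sprintf("reaction '%s': bounds must be finite (use +/-1000 as 'unbounded')", id))
  }
  if (lb > ub) stop(sprintf("reaction '%s': lower bound %g exceeds upper bound %g", id, lb, ub))
  structure(list(id = id, name = name, stoichiometry = stoichiometry,
                 lb = lb, ub = ub, gpr = gpr, kind = kind),
            class = "sbf_reaction")
}

#' Construct a metabolic model
#'
#' A compartmentalized metabolic network: metabolites (with elemental
#' formulas), bounded reactions and a linear objective. Referential integrity
#' is validated on construction.
#'
#' @param id Model id.
#' @param compartments Character vector of compartment ids.
#' @param metabolites data.frame with columns id, name, formula, compartment,
#'   tags (rbind of [metabolite()] rows).
#' @param reactions List of [reaction()] objects.
#' @param objective Named numeric vector of objective coefficients keyed by
#'   reaction id (may be empty).
#' @return An object of class \code{"sbf_model"}.
#' @export
metabolic_model <- function(id, compartments, metabolites, reactions,
                            objective = numeric(0)) {
  names(reactions) <- vapply(reactions, `[[`, "", "id")
  m <- structure(list(id = id, compartments = compartments,
                      metabolites = metabolites, reactions = reactions,
                      objective = objective),
                 class = "sbf_model")
  validate_model(m)
  m
}

#' Validate a model's referential integrity
#'
#' Checks: unique metabolite/reaction ids, declared compartments, every
#' reaction references existing metabolites, objective references existing
#' reactions.
#'
#' @param model An \code{sbf_model}.
#' @return The model, invisibly; errors list the offending ids.
#' @export
validate_model <- function(model) {
  mets <- model$metabolites
  if (anyDuplicated(mets$id)) {
    stop("duplicate metabolite ids: ",
         paste(unique(mets$id[duplicated(mets$id)]), collapse = ", "))
  }
  rids <- names(model$reactions)
  if (anyDuplicated(rids)) {
    stop("duplicate reaction ids: ",
         paste(unique(rids[duplicated(rids)]), collapse = ", "))
  }
  badc <- setdiff(mets$compartment, model$compartments)
  if (length(badc)) stop("undeclared compartments: ", paste(badc, collapse = ", "))
  dangling <- unique(unlist(lapply(model$reactions, function(r) {
    setdiff(names(r$stoichiometry), mets$id)
  })))
  if (length(dangling)) {
    stop("reactions reference unknown metabolites: ",
         paste(dangling, collapse = ", "))
  }
  badobj <- setdiff(names(model$objective), rids)
  if (length(badobj)) {
    stop("objective references unknown reactions: ",
         paste(badobj, collapse = ", "))
  }
  invisible(model)
}

#' Model size counts
#'
#' @param model An \code{sbf_model}.
#' @return List with n_reactions, n_metabolites and n_genes (distinct gene
#'   ids appearing in gene associations).
#' @export
model_counts <- function(model) {
  genes <- unique(unlist(lapply(model$reactions, function(r) gpr_genes(r$gpr))))
  list(n_reactions = length(model$reactions),
       n_metabolites = nrow(model$metabolites),
       n_genes = length(genes))
}

#' @export
print.sbf_model <- function(x, ...) {
  cts <- model_counts(x)
  cat(sprintf("<metabolic model '%s'>: %d reactions, %d metabolites, %d genes; compartments: %s\n",
              x$id, cts$n_reactions, cts$n_metabolites, cts$n_genes,
              paste(x$compartments, collapse = ", ")))
  invisible(x)
}

# Bound vectors in model reaction order.
model_bounds <- function(model) {
  list(lb = vapply(model$reactions, `[[`, 0, "lb"),
       ub = vapply(model$reactions, `[[`, 0, "ub"))
}

# Dense objective vector in reaction order.
model_objective_vector <- function(model) {
  cvec <- stats::setNames(numeric(length(model$reactions)), names(model$reactions))
  cvec[names(model$objective)] <- model$objective
  cvec
}

met_row <- function(model, met_id) {
  i <- match(met_id, model$metabolites$id)
  if (is.na(i)) stop("unknown metabolite: ", met_id)
  model$metabolites[i, , drop = FALSE]
}

met_tags <- function(model, met_id) {
  strsplit(met_row(model, met_id)$tags, ";", fixed = TRUE)[[1]]
}

#' Strip the compartment suffix from a metabolite id
#'
#' \code{"gln[h]"} becomes \code{"gln"}; ids without a suffix are returned
#' unchanged. Used to compare metabolite species across compartments.
#'
#' @param ids Character vector of metabolite ids.
#' @return Character vector of species ids.
#' @export
species_id <- function(ids) sub("\\[[^][]*\\]$", "", ids)

#' Assemble the stoichiometric matrix
#'
#' Builds the sparse matrix S with one row per metabolite and one column per
#' reaction; entry (m, r) is reaction r's signed coefficient for metabolite m.
#'
#' @param model An \code{sbf_model} passing [validate_model()].
#' @return A \code{Matrix::dgCMatrix} with metabolite/reaction dimnames.
#' @export
build_matrix <- function(model) {
  validate_model(model)
  mids <- model$metabolites$id
  rids <- names(model$reactions)
  if (length(mids) == 0L || length(rids) == 0L) {
    return(Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                                dims = c(length(mids), length(rids)),
                                dimnames = list(mids, rids)))
  }
  ii <- jj <- integer(0); xx <- numeric(0)
  for (j in seq_along(rids)) {
    st <- model$reactions[[j]]$stoichiometry
    ii <- c(ii, match(names(st), mids))
    jj <- c(jj, rep.int(j, length(st)))
    xx <- c(xx, unname(st))
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                       dims = c(length(mids), length(rids)),
                       dimnames = list(mids, rids))
}

#' Check elemental mass balance of a reaction
#'
#' Sums coefficient-weighted element counts over the reaction's metabolites.
#' A balanced reaction returns all-zero imbalances. Exchange, biomass and
#' objective reactions are boundary/pseudo reactions and are reported as
#' unchecked, as is any reaction touching a metabolite without a formula.
#'
#' @param rxn An \code{sbf_reaction} (or reaction id present in `model`).
#' @param model The model supplying metabolite formulas.
#' @return List with `status` ("checked"/"unchecked"), `reason` for
#'   unchecked, and `imbalance` (named numeric per element; empty when
#'   unchecked).
#' @export
check_mass_balance <- function(rxn, model) {
  if (is.character(rxn)) rxn <- model$reactions[[rxn]]
  if (is.null(rxn)) stop("unknown reaction")
  if (rxn$kind %in% c("exchange", "biomass", "objective")) {
    return(list(status = "unchecked",
                reason = sprintf("%s reaction (boundary/pseudo)", rxn$kind),
                imbalance = numeric(0)))
  }
  formulas <- vapply(names(rxn$stoichiometry),
                     function(m) met_row(model, m)$formula, "")
  if (any(!nzchar(formulas))) {
    return(list(status = "unchecked",
                reason = paste("missing formulas:",
                               paste(names(formulas)[!nzchar(formulas)], collapse = ", ")),
                imbalance = numeric(0)))
  }
  counts <- lapply(formulas, parse_formula)
  elements <- sort(unique(unlist(lapply(counts, names))))
  imb <- stats::setNames(numeric(length(elements)), elements)
  for (k in seq_along(counts)) {
    ck <- counts[[k]]
    imb[names(ck)] <- imb[names(ck)] + rxn$stoichiometry[[k]] * ck
  }
  list(status = "checked", reason = "", imbalance = imb)
}
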