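# Tabular model dialect: a reaction list TSV (reaction_id, name, equation,
# lower_bound, upper_bound, gene_association, subsystem, kind) plus a
# metabolite list TSV (id, name, formula, compartment, tags). Equations use
# "[compartment]"-suffixed metabolite ids, " + "-separated terms with
# optional numeric coefficients, and "-->" (irreversible) or "<=>"
# (reversible) arrows.

parse_equation_side <- function(side, line = NA) {
  side <- trimws(side)
  if (!nzchar(side)) return(stats::setNames(numeric(0), character(0)))
  terms <- strsplit(side, "\\s+\\+\\s+")[[1]]
  coefs <- numeric(0)
  for (term in terms) {
    m <- regmatches(term, regexec("^\\s*([0-9.]+\\s+)?(\\S+)\\s*$", term))[[1]]
    if (length(m) == 0L) {
      stop(sprintf("cannot parse equation term '%s'%s", term,
                   if (is.na(line)) "" else sprintf(" (line %d)", line)))
    }
    cf <- if (nzchar(trimws(m[2]))) as.numeric(trimws(m[2])) else 1
    if (is.na(cf)) stop(sprintf("bad coefficient in term '%s'", term))
    met <- m[3]
    coefs[met] <- if (met %in% names(coefs)) coefs[[met]] + cf else cf
  }
  coefs
}

#' Parse a textual reaction equation
#'
#' @param equation E.g. \code{"atp[h] + h2o[h] <=> adp[h] + pi[h]"} or
#'   \code{"glc[e] --> glc[h]"}. \code{"<=>"} means reversible (default
#'   bounds \code{(-ub, ub)}), \code{"-->"} irreversible (\code{(0, ub)}).
#' @param line Optional line number for error messages.
#' @return List with `stoichiometry` (named numeric, consumed negative) and
#'   `reversible`.
#' @export
parse_equation <- function(equation, line = NA) {
  rev_split <- regexpr("<=>", equation, fixed = TRUE)
  irr_split <- regexpr("-->", equation, fixed = TRUE)
  if (rev_split > 0) {
    sides <- strsplit(equation, "<=>", fixed = TRUE)[[1]]
    reversible <- TRUE
  } else if (irr_split > 0) {
    sides <- strsplit(equation, "-->", fixed = TRUE)[[1]]
    reversible <- FALSE
  } else {
    stop(sprintf("equation '%s' has no '-->' or '<=>' arrow%s", equation,
                 if (is.na(line)) "" else sprintf(" (line %d)", line)))
  }
  if (length(sides) > 2L) {
    stop(sprintf("equation '%s' has multiple arrows", equation))
  }
  lhs <- parse_equation_side(sides[1], line)
  rhs <- if (length(sides) == 2L) parse_equation_side(sides[2], line)
         else stats::setNames(numeric(0), character(0))
  st <- stats::setNames(numeric(0), character(0))
  for (m in names(lhs)) st[m] <- -lhs[[m]]
  for (m in names(rhs)) st[m] <- (if (m %in% names(st)) st[[m]] else 0) + rhs[[m]]
  list(stoichiometry = st[st != 0], reversible = reversible)
}

format_equation <- function(rxn) {
  st <- rxn$stoichiometry
  fmt <- function(v) {
    paste(vapply(names(v), function(m) {
      cf <- abs(v[[m]])
      if (cf == 1) m else paste(format(cf, digits = 12, scientific = FALSE), m)
    }, ""), collapse = " + ")
  }
  arrow <- if (rxn$lb < 0) "<=>" else "-->"
  paste(fmt(st[st < 0]), arrow, fmt(st[st > 0]))
}

# Infer reaction kind from structure when the dialect omits it.
infer_kind <- function(st) {
  mets <- names(st)
  if (length(st) == 1L) return("exchange")
  comps <- unique(sub("^.*\\[([^][]*)\\]$", "\\1", mets))
  if (length(st) == 2L && length(comps) == 2L &&
      identical(species_id(mets)[1], species_id(mets)[2]) &&
      sum(st) == 0 && all(abs(st) == abs(st[1]))) {
    return("transport")
  }
  "internal"
}

#' Read a model from the tabular reaction-list dialect
#'
#' @param reactions Path to the reaction list TSV. Required columns:
#'   \code{reaction_id}, \code{equation}; optional: \code{name},
#'   \code{lower_bound}, \code{upper_bound}, \code{gene_association},
#'   \code{subsystem}, \code{kind}, \code{objective_coefficient}. Arrow
#'   reversibility sets default bounds; explicit bound columns override.
#' @param metabolites Optional path to the metabolite list TSV (columns id,
#'   name, formula, compartment, tags). When absent, metabolites are inferred
#'   from equations with empty formulas.
#' @param id Model id; defaults to the reaction file name.
#' @param default_ub Default magnitude for absent bounds (1000).
#' @return An \code{sbf_model}.
#' @export
read_model_table <- function(reactions, metabolites = NULL,
                             id = tools::file_path_sans_ext(basename(reactions)),
                             default_ub = 1000) {
  rt <- utils::read.delim(reactions, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("reaction_id", "equation")
  if (!all(need %in% names(rt))) {
    stop("reaction table must have columns: ", paste(need, collapse = ", "))
  }
  rxns <- vector("list", nrow(rt))
  objective <- numeric(0)
  for (i in seq_len(nrow(rt))) {
    eq <- tryCatch(parse_equation(rt$equation[i], line = i + 1L),
                   error = function(e) stop(sprintf(
                     "line %d (%s): %s", i + 1L, rt$reaction_id[i], conditionMessage(e)),
                     call. = FALSE))
    ub <- if ("upper_bound" %in% names(rt) && !is.na(rt$upper_bound[i]))
            rt$upper_bound[i] else default_ub
    lb <- if ("lower_bound" %in% names(rt) && !is.na(rt$lower_bound[i]))
            rt$lower_bound[i] else if (eq$reversible) -ub else 0
    kind <- if ("kind" %in% names(rt) && !is.na(rt$kind[i]) && nzchar(rt$kind[i]))
              rt$kind[i] else infer_kind(eq$stoichiometry)
    gpr <- if ("gene_association" %in% names(rt) && !is.na(rt$gene_association[i]))
             rt$gene_association[i] else ""
    nm <- if ("name" %in% names(rt) && !is.na(rt$name[i]) && nzchar(rt$name[i]))
            rt$name[i] else rt$reaction_id[i]
    rxns[[i]] <- reaction(rt$reaction_id[i], eq$stoichiometry, lb = lb, ub = ub,
                          name = nm, gpr = gpr, kind = kind)
    if ("objective_coefficient" %in% names(rt) &&
        !is.na(rt$objective_coefficient[i]) && rt$objective_coefficient[i] != 0) {
      objective[rt$reaction_id[i]] <- rt$objective_coefficient[i]
    }
  }
  used <- unique(unlist(lapply(rxns, function(r) names(r$stoichiometry))))
  if (!is.null(metabolites)) {
    mt <- utils::read.delim(metabolites, stringsAsFactors = FALSE, check.names = FALSE)
    if (!all(c("id", "compartment") %in% names(mt))) {
      stop("metabolite table must have columns: id, compartment")
    }
    if (!"name" %in% names(mt)) mt$name <- mt$id
    if (!"formula" %in% names(mt)) mt$formula <- ""
    if (!"tags" %in% names(mt)) mt$tags <- "other"
    mt$formula[is.na(mt$formula)] <- ""
    mt$tags[is.na(mt$tags) | !nzchar(mt$tags)] <- "other"
    mets <- mt[, c("id", "name", "formula", "compartment", "tags")]
  } else {
    mets <- data.frame(id = used, name = used, formula = "",
                       compartment = sub("^.*\\[([^][]*)\\]$", "\\1", used),
                       tags = "other", stringsAsFactors = FALSE)
  }
  metabolic_model(id = id,
                  compartments = unique(mets$compartment),
                  metabolites = mets, reactions = rxns, objective = objective)
}

#' Write a model in the tabular dialect
#'
#' @param model An \code{sbf_model}.
#' @param reactions,metabolites Output TSV paths.
#' @return Invisibly, the two paths.
#' @export
write_model_table <- function(model, reactions, metabolites) {
  rt <- data.frame(
    reaction_id = names(model$reactions),
    name = vapply(model$reactions, `[[`, "", "name"),
    equation = vapply(model$reactions, format_equation, ""),
    lower_bound = vapply(model$reactions, `[[`, 0, "lb"),
    upper_bound = vapply(model$reactions, `[[`, 0, "ub"),
    gene_association = vapply(model$reactions, `[[`, "", "gpr"),
    kind = vapply(model$reactions, `[[`, "", "kind"),
    objective_coefficient = unname(model_objective_vector(model)),
    stringsAsFactors = FALSE)
  utils::write.table(rt, reactions, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(model$metabolites, metabolites, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(reactions, metabolites))
}

#' Read a gene-expression (TPM) table
#'
#' @param path TSV with a \code{gene_id} column and one numeric column of
#'   nonnegative TPM values per replicate.
#' @return data.frame with unique gene ids; replicate labels preserved.
#' @export
read_expression_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"gene_id" %in% names(tab)) stop("expression table needs a 'gene_id' column")
  reps <- setdiff(names(tab), "gene_id")
  if (length(reps) == 0L) stop("expression table needs >= 1 replicate column")
  if (anyDuplicated(tab$gene_id)) stop("duplicate gene ids in expression table")
  for (r in reps) {
    if (!is.numeric(tab[[r]])) stop(sprintf("replicate '%s' is not numeric", r))
    if (any(is.na(tab[[r]]))) stop(sprintf("replicate '%s' has missing values", r))
    if (any(tab[[r]] < 0)) stop(sprintf("replicate '%s' has negative TPM values", r))
  }
  tab
}

#' Write a gene-expression table
#'
#' @param table data.frame as returned by [read_expression_table()].
#' @param path Output TSV path.
#' @export
write_expression_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
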