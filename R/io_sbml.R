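# SBML I/O: Level 3 Version 1 core plus the fbc-v2 subset needed for
# constraint-based models (species chemical formulas, flux-bound parameters,
# a linear objective, gene-product associations). Groups, units, rules and
# events are out of scope. Metabolite/reaction/gene ids are mapped to valid
# SBML SIds by prefixing (M_/R_/G_) and hex-escaping forbidden characters,
# reversibly, so "gln[h]" round-trips exactly.

sid_encode <- function(id, prefix) {
  chars <- strsplit(id, "", fixed = TRUE)[[1]]
  enc <- vapply(chars, function(ch) {
    if (grepl("^[A-Za-z0-9_]$", ch)) ch else sprintf("_x%02x_", utf8ToInt(ch))
  }, "")
  paste0(prefix, paste(enc, collapse = ""))
}

sid_decode <- function(sid, prefix) {
  s <- sub(paste0("^", prefix), "", sid)
  m <- gregexpr("_x([0-9a-f]{2})_", s)
  regmatches(s, m) <- lapply(regmatches(s, m), function(hits) {
    vapply(hits, function(h) {
      intToUtf8(strtoi(sub("_x([0-9a-f]{2})_", "\\1", h), base = 16L))
    }, "")
  })
  s
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  gsub("\"", "&quot;", x, fixed = TRUE)
}

notes_block <- function(kv, indent) {
  if (length(kv) == 0L) return("")
  ps <- paste0(indent, "    <p>", names(kv), ": ", xml_escape(unlist(kv)), "</p>",
               collapse = "\n")
  paste0(indent, "<notes>\n", indent,
         "  <body xmlns=\"http://www.w3.org/1999/xhtml\">\n",
         ps, "\n", indent, "  </body>\n", indent, "</notes>\n")
}

gpr_to_fbc <- function(gpr, indent) {
  node <- gpr_parse(gpr)
  if (is.null(node)) return("")
  render <- function(n, ind) {
    if (n$op == "gene") {
      sprintf("%s<fbc:geneProductRef fbc:geneProduct=\"%s\"/>",
              ind, sid_encode(n$gene, "G_"))
    } else {
      tag <- if (n$op == "or") "fbc:or" else "fbc:and"
      inner <- paste(vapply(n$args, render, "", paste0(ind, "  ")), collapse = "\n")
      sprintf("%s<%s>\n%s\n%s</%s>", ind, tag, inner, ind, tag)
    }
  }
  paste0(indent, "<fbc:geneProductAssociation>\n",
         render(node, paste0(indent, "  ")), "\n",
         indent, "</fbc:geneProductAssociation>\n")
}

#' Write a model as SBML (Level 3 + fbc v2 subset)
#'
#' Flux bounds become shared parameters, the objective an fbc objective,
#' metabolite formulas fbc:chemicalFormula attributes; reaction kinds and
#' metabolite tags are preserved in notes so that [read_sbml()] restores the
#' model exactly. A model with an empty objective is written without an
#' objective list.
#'
#' @param model An \code{sbf_model}.
#' @param path Output .xml path.
#' @return Invisibly, `path`.
#' @export
write_sbml <- function(model, path) {
  validate_model(model)
  out <- c(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    paste0("<sbml xmlns=\"http://www.sbml.org/sbml/level3/version1/core\" ",
           "xmlns:fbc=\"http://www.sbml.org/sbml/level3/version1/fbc/version2\" ",
           "level=\"3\" version=\"1\" fbc:required=\"false\">"),
    sprintf("  <model id=\"%s\" fbc:strict=\"true\">", sid_encode(model$id, "")))

  out <- c(out, "    <listOfCompartments>",
           sprintf("      <compartment id=\"%s\" constant=\"true\"/>",
                   vapply(model$compartments, sid_encode, "", prefix = "C_")),
           "    </listOfCompartments>")

  out <- c(out, "    <listOfSpecies>")
  for (i in seq_len(nrow(model$metabolites))) {
    m <- model$metabolites[i, ]
    ff <- if (nzchar(m$formula)) sprintf(" fbc:chemicalFormula=\"%s\"", m$formula) else ""
    out <- c(out,
      sprintf(paste0("      <species id=\"%s\" name=\"%s\" compartment=\"%s\"%s ",
                     "hasOnlySubstanceUnits=\"false\" boundaryCondition=\"false\" ",
                     "constant=\"false\">"),
              sid_encode(m$id, "M_"), xml_escape(m$name),
              sid_encode(m$compartment, "C_"), ff),
      notes_block(list(tags = m$tags), "        "),
      "      </species>")
  }
  out <- c(out, "    </listOfSpecies>")

  bounds <- unique(c(vapply(model$reactions, `[[`, 0, "lb"),
                     vapply(model$reactions, `[[`, 0, "ub")))
  bid <- function(v) sprintf("bnd_%s", gsub("[^0-9A-Za-z]", "_",
                                            format(v, digits = 15, scientific = FALSE)))
  out <- c(out, "    <listOfParameters>",
           sprintf("      <parameter id=\"%s\" value=\"%s\" constant=\"true\"/>",
                   vapply(bounds, bid, ""),
                   vapply(bounds, format, "", digits = 15, scientific = FALSE)),
           "    </listOfParameters>")

  out <- c(out, "    <listOfReactions>")
  for (r in model$reactions) {
    st <- r$stoichiometry
    out <- c(out,
      sprintf(paste0("      <reaction id=\"%s\" name=\"%s\" reversible=\"%s\" ",
                     "fast=\"false\" fbc:lowerFluxBound=\"%s\" fbc:upperFluxBound=\"%s\">"),
              sid_encode(r$id, "R_"), xml_escape(r$name),
              tolower(r$lb < 0), bid(r$lb), bid(r$ub)),
      notes_block(list(kind = r$kind), "        "))
    side <- function(v, tag) {
      if (length(v) == 0L) return(character(0))
      c(sprintf("        <listOf%s>", tag),
        sprintf(paste0("          <speciesReference species=\"%s\" ",
                       "stoichiometry=\"%s\" constant=\"true\"/>"),
                vapply(names(v), sid_encode, "", prefix = "M_"),
                vapply(abs(unname(v)), format, "", digits = 15, scientific = FALSE)),
        sprintf("        </listOf%s>", tag))
    }
    out <- c(out, side(st[st < 0], "Reactants"), side(st[st > 0], "Products"),
             if (nzchar(r$gpr)) gpr_to_fbc(r$gpr, "        "),
             "      </reaction>")
  }
  out <- c(out, "    </listOfReactions>")

  genes <- unique(unlist(lapply(model$reactions, function(r) gpr_genes(r$gpr))))
  if (length(genes)) {
    out <- c(out, "    <fbc:listOfGeneProducts>",
             sprintf("      <fbc:geneProduct fbc:id=\"%s\" fbc:label=\"%s\"/>",
                     vapply(genes, sid_encode, "", prefix = "G_"),
                     xml_escape(genes)),
             "    </fbc:listOfGeneProducts>")
  }

  if (length(model$objective)) {
    out <- c(out,
      "    <fbc:listOfObjectives fbc:activeObjective=\"obj\">",
      "      <fbc:objective fbc:id=\"obj\" fbc:type=\"maximize\">",
      "        <fbc:listOfFluxObjectives>",
      sprintf("          <fbc:fluxObjective fbc:reaction=\"%s\" fbc:coefficient=\"%s\"/>",
              vapply(names(model$objective), sid_encode, "", prefix = "R_"),
              vapply(unname(model$objective), format, "", digits = 15,
                     scientific = FALSE)),
      "        </fbc:listOfFluxObjectives>",
      "      </fbc:objective>",
      "    </fbc:listOfObjectives>")
  }

  out <- c(out, "  </model>", "</sbml>")
  txt <- paste(out[nzchar(out)], collapse = "\n")
  xml2::read_xml(txt) # well-formedness check before touching disk
  writeLines(txt, path, useBytes = TRUE)
  invisible(path)
}

xp <- function(node, path) xml2::xml_find_all(node, path)
lname <- function(nm) sprintf(".//*[local-name()='%s']", nm)

notes_kv <- function(node) {
  ps <- xp(node, "./*[local-name()='notes']//*[local-name()='p']")
  txt <- xml2::xml_text(ps)
  kv <- regmatches(txt, regexec("^\\s*([^:]+):\\s*(.*)$", txt))
  out <- list()
  for (m in kv) if (length(m) == 3L) out[[trimws(m[2])]] <- trimws(m[3])
  out
}

fbc_attr <- function(node, name) {
  at <- xml2::xml_attrs(node)
  hit <- at[names(at) %in% c(name, paste0("fbc:", name))]
  if (length(hit)) unname(hit[1]) else NA_character_
}

fbc_to_gpr <- function(node, top = TRUE) {
  nm <- xml2::xml_name(node)
  if (nm == "geneProductRef") return(sid_decode(fbc_attr(node, "geneProduct"), "G_"))
  kids <- xml2::xml_children(node)
  parts <- vapply(kids, fbc_to_gpr, "", top = FALSE)
  joined <- paste(parts, collapse = if (nm == "and") " and " else " or ")
  if (top) joined else paste0("(", joined, ")")
}

#' Read a model from SBML (Level 3 + fbc subset)
#'
#' @param path SBML .xml file written by [write_sbml()] or any SBML L3 file
#'   using fbc flux bounds and objectives. Reactions without fbc bound
#'   references default to +/-1000 (or 0/1000 when marked irreversible) with
#'   a warning; a missing objective list yields an empty objective with a
#'   warning.
#' @param id Optional model id override.
#' @return An \code{sbf_model}.
#' @export
read_sbml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("unparsable SBML file: ",
                                           conditionMessage(e), call. = FALSE))
  mnode <- xp(doc, "/*[local-name()='sbml']/*[local-name()='model']")
  if (length(mnode) != 1L) stop("SBML format error: expected a single <model>")
  mnode <- mnode[[1]]
  model_id <- sid_decode(xml2::xml_attr(mnode, "id"), "")

  comps <- vapply(xp(mnode, lname("compartment")), function(n)
    sid_decode(xml2::xml_attr(n, "id"), "C_"), "")

  sp <- xp(mnode, lname("species"))
  mets <- do.call(rbind, lapply(sp, function(n) {
    kv <- notes_kv(n)
    f <- fbc_attr(n, "chemicalFormula")
    data.frame(id = sid_decode(xml2::xml_attr(n, "id"), "M_"),
               name = xml2::xml_attr(n, "name"),
               formula = if (is.na(f)) "" else f,
               compartment = sid_decode(xml2::xml_attr(n, "compartment"), "C_"),
               tags = if (is.null(kv$tags)) "other" else kv$tags,
               stringsAsFactors = FALSE)
  }))
  if (is.null(mets)) stop("SBML format error: no species")
  mets$name[is.na(mets$name)] <- mets$id[is.na(mets$name)]

  pars <- xp(mnode, "./*[local-name()='listOfParameters']/*[local-name()='parameter']")
  parval <- stats::setNames(as.numeric(xml2::xml_attr(pars, "value")),
                            xml2::xml_attr(pars, "id"))

  warned_bounds <- FALSE
  rxns <- lapply(xp(mnode, "./*[local-name()='listOfReactions']/*[local-name()='reaction']"),
                 function(n) {
    rid <- sid_decode(xml2::xml_attr(n, "id"), "R_")
    getside <- function(tag, sign) {
      refs <- xp(n, sprintf("./*[local-name()='%s']/*[local-name()='speciesReference']", tag))
      stats::setNames(sign * as.numeric(xml2::xml_attr(refs, "stoichiometry")),
                      vapply(xml2::xml_attr(refs, "species"), sid_decode, "", prefix = "M_"))
    }
    st <- c(getside("listOfReactants", -1), getside("listOfProducts", +1))
    st <- tapply(st, names(st), sum) # merge duplicated species refs
    st <- stats::setNames(as.numeric(st), names(st))
    lbid <- fbc_attr(n, "lowerFluxBound"); ubid <- fbc_attr(n, "upperFluxBound")
    reversible <- identical(xml2::xml_attr(n, "reversible"), "true")
    if (is.na(lbid) || is.na(ubid) || !lbid %in% names(parval) ||
        !ubid %in% names(parval)) {
      warned_bounds <<- TRUE
      lb <- if (reversible) -1000 else 0; ub <- 1000
    } else {
      lb <- parval[[lbid]]; ub <- parval[[ubid]]
    }
    gnode <- xp(n, "./*[local-name()='geneProductAssociation']")
    gpr <- if (length(gnode)) fbc_to_gpr(xml2::xml_children(gnode[[1]])[[1]]) else ""
    kv <- notes_kv(n)
    kind <- if (!is.null(kv$kind)) kv$kind else infer_kind(st)
    reaction(rid, st, lb = lb, ub = ub, name = xml2::xml_attr(n, "name"),
             gpr = gpr, kind = kind)
  })
  if (warned_bounds) {
    warning("some reactions lacked flux-bound parameters; defaulted to +/-1000")
  }

  fo <- xp(mnode, lname("fluxObjective"))
  if (length(fo)) {
    objective <- stats::setNames(
      as.numeric(vapply(fo, fbc_attr, "", name = "coefficient")),
      vapply(vapply(fo, fbc_attr, "", name = "reaction"), sid_decode, "", prefix = "R_"))
  } else {
    warning("SBML file has no objective; model objective left empty")
    objective <- numeric(0)
  }

  metabolic_model(id = model_id, compartments = unique(c(comps, mets$compartment)),
                  metabolites = mets, reactions = rxns, objective = objective)
}
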