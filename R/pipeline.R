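# End-to-end orchestration: load -> (optional) expression constraints ->
# integrate -> medium -> objective -> FBA -> FVA -> exchange classification
# -> shared/unique -> cross-feeding -> EAA accounting -> nitrogen ledgers ->
# maintenance costs, with deterministic TSV/JSON report emission.

#' Pipeline configuration
#'
#' Two input modes: three single-organism models to integrate in-house
#' (`host`/`symA`/`symB` plus `transport`), or one pre-assembled integrated
#' model (`integrated`, an \code{sbf_multi} or SBML/tabular path trio
#' produced by this package).
#'
#' @param host,symA,symB \code{sbf_model}s or file paths (.xml SBML, or .tsv
#'   reaction list).
#' @param transport Transport spec data.frame or TSV path (columns
#'   metabolite, donor, recipient, reversible).
#' @param integrated A ready \code{sbf_multi} (e.g. from
#'   [generate_toy_symbiosis()]'s `$model`); overrides the three-model mode.
#' @param medium An \code{sbf_medium} (ignored when `integrated` already has
#'   one applied).
#' @param expression Expression table (data.frame or TSV path) used to bound
#'   host reactions; optional.
#' @param objective An \code{sbf_biomass_spec} plus `objective_compartment`,
#'   to attach a host objective; optional when models already carry one.
#' @param objective_compartment Compartment for [attach_objective()].
#' @param biomass_floor Symbiont biomass floor (0.01).
#' @param threshold_exchange Exchange classification threshold (1e-6).
#' @param threshold_fva_range FVA range threshold (1 mmol gDW^-1 h^-1).
#' @param threshold_transport_pct Transport variation threshold (1 percent).
#' @param default_bound Expression default bound (10).
#' @param stabilize Minimal-total-flux FBA mode (default FALSE).
#' @param run_fva Set FALSE to skip the FVA stage.
#' @param out_dir Output directory for reports (NULL = in-memory only).
#' @param seed Integer recorded for provenance.
#' @return List of class \code{"sbf_config"}.
#' @export
pipeline_config <- function(host = NULL, symA = NULL, symB = NULL,
                            transport = NULL, integrated = NULL,
                            medium = NULL, expression = NULL,
                            objective = NULL, objective_compartment = NULL,
                            biomass_floor = 0.01,
                            threshold_exchange = 1e-6,
                            threshold_fva_range = 1.0,
                            threshold_transport_pct = 1.0,
                            default_bound = 10,
                            stabilize = FALSE, run_fva = TRUE,
                            out_dir = NULL, seed = 1L) {
  stopifnot(threshold_exchange > 0, threshold_fva_range > 0,
            threshold_transport_pct > 0, biomass_floor >= 0)
  structure(as.list(environment()), class = "sbf_config")
}

load_model_input <- function(x, what) {
  if (inherits(x, "sbf_model")) return(x)
  if (is.character(x)) {
    if (!file.exists(x)) stop(sprintf("%s model path does not exist: %s", what, x))
    if (grepl("\\.xml$", x, ignore.case = TRUE)) return(read_sbml(x))
    # companion metabolite list: <stem>_mets.<ext>, as written by
    # write_model_table() conventions in this package's examples
    mets <- sub("(\\.[^.]+)$", "_mets\\1", x)
    return(read_model_table(x, metabolites = if (file.exists(mets)) mets))
  }
  stop(sprintf("cannot interpret %s model input", what))
}

#' Run the full analysis pipeline
#'
#' Executes every stage on the configured inputs and returns (and optionally
#' writes) the report bundle. Any stage failure halts with the stage name in
#' the error message.
#'
#' @param config An \code{sbf_config} from [pipeline_config()].
#' @return List with the integrated model, FBA/FVA results, exchange
#'   profiles, shared/unique sets, cross-feeding records, EAA accounting,
#'   nitrogen ledgers, maintenance costs, and summary statistics.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "sbf_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  model <- if (!is.null(config$integrated)) {
    stage("load", {
      m <- config$integrated
      if (!inherits(m, "sbf_multi")) stop("`integrated` must be an sbf_multi model")
      m
    })
  } else {
    host <- stage("load", load_model_input(config$host, "host"))
    symA <- stage("load", load_model_input(config$symA, "symA"))
    symB <- stage("load", load_model_input(config$symB, "symB"))
    if (!is.null(config$expression)) {
      expr_tab <- stage("expression", {
        x <- config$expression
        if (is.character(x)) read_expression_table(x) else x
      })
      lv <- stage("expression", normalize_expression(expr_tab))
      host <- stage("expression",
                    apply_expression_bounds(host, lv, config$default_bound))
    }
    tspec <- stage("integrate", {
      x <- config$transport
      if (is.null(x)) stop("three-model mode requires a transport spec")
      if (is.character(x)) utils::read.delim(x, stringsAsFactors = FALSE) else x
    })
    m <- stage("integrate", build_multicompartment(host, symA, symB, tspec))
    if (!is.null(config$medium)) m <- stage("medium", apply_medium(m, config$medium))
    if (!is.null(config$objective)) {
      m <- stage("objective",
                 attach_objective(m, config$objective, config$objective_compartment))
    }
    stage("biomass_floor", fix_symbiont_biomass(m, config$biomass_floor))
  }

  fba <- stage("fba", solve_fba(model, stabilize = config$stabilize))
  if (fba$status != "optimal") {
    stop("pipeline stage 'fba' failed: model is ", fba$status)
  }
  fva <- if (isTRUE(config$run_fva)) stage("fva", solve_fva(model)) else NULL

  profiles <- stage("exchanges",
                    classify_exchanges(model, fba,
                                       threshold = config$threshold_exchange))
  roles <- c(host = "host", symA = "symA", symB = "symB")
  comp_of <- function(role) {
    rids <- names(model$provenance)[model$provenance == role]
    mets <- unlist(lapply(model$reactions[rids], function(r) names(r$stoichiometry)))
    comps <- unique(model$metabolites$compartment[match(mets, model$metabolites$id)])
    intersect(comps, names(profiles))[1]
  }
  comps <- vapply(roles, comp_of, "")
  prof3 <- profiles[comps]
  names(prof3) <- comps

  shared <- stage("shared_unique",
                  lapply(c(imports = "imports", exports = "exports"), function(s)
                    shared_unique_sets(prof3[[comps[["symA"]]]],
                                       prof3[[comps[["symB"]]]], s)))
  crossfeed <- stage("cross_feeding",
                     detect_cross_feeding(prof3, host = comps[["host"]]))
  eaa <- stage("eaa_accounting",
               eaa_release_accounting(prof3, model = model,
                                      host = comps[["host"]]))
  ledgers <- stage("nitrogen_ledger",
                   lapply(comps[c("symA", "symB")], function(cc)
                     nitrogen_ledger(prof3[[cc]], model, fba)))
  costs <- stage("maintenance_cost",
                 lapply(c(symA = "symA", symB = "symB"), function(s)
                   maintenance_cost(model, s, stabilize = config$stabilize)))

  summaries <- list()
  if (!is.null(fva)) {
    summaries$flux_ranges <- flux_range_summary(fva, config$threshold_fva_range)
    summaries$transport_variation <-
      transport_flux_variation(fva, fba, transports = model$transports$reaction_id,
                               threshold_pct = config$threshold_transport_pct)
  }

  results <- list(config = config, model = model, fba = fba, fva = fva,
                  profiles = profiles, compartments = comps,
                  shared_unique = shared, cross_feeding = crossfeed,
                  eaa_accounting = eaa, nitrogen_ledgers = ledgers,
                  maintenance_costs = costs, summaries = summaries)
  if (!is.null(config$out_dir)) emit_report(results, config$out_dir)
  results
}

fmt6 <- function(x) {
  ifelse(is.na(x), "NA", formatC(signif(x, 6), format = "g", digits = 6))
}

#' Write the pipeline report bundle
#'
#' Emits TSV tables (fluxes, FVA, per-compartment exchanges, cross-feeding,
#' EAA accounting, nitrogen ledgers, maintenance costs) and a JSON summary.
#' Column orders are stable and floats are written at 6 significant digits,
#' so rerunning on identical inputs yields byte-identical files.
#'
#' @param results Return value of [run_pipeline()].
#' @param dir Output directory (created if needed).
#' @param formats Subset of c("tsv", "json").
#' @return Invisibly, the paths written.
#' @export
emit_report <- function(results, dir, formats = c("tsv", "json")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  wt <- function(df, file) {
    p <- file.path(dir, file)
    num <- vapply(df, is.numeric, TRUE)
    df[num] <- lapply(df[num], fmt6)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <<- c(paths, p)
  }

  if ("tsv" %in% formats) {
    model <- results$model
    wt(data.frame(reaction = names(results$fba$flux),
                  flux = unname(results$fba$flux),
                  kind = vapply(model$reactions, `[[`, "", "kind"),
                  provenance = unname(model$provenance[names(results$fba$flux)]),
                  stringsAsFactors = FALSE), "fluxes.tsv")
    if (!is.null(results$fva)) {
      fva <- results$fva
      v <- results$fba$flux[fva$reaction]
      wt(data.frame(reaction = fva$reaction, flux = unname(v),
                    min = fva$min, max = fva$max, range = fva$max - fva$min,
                    stringsAsFactors = FALSE), "fva.tsv")
    }
    ex <- do.call(rbind, lapply(results$profiles, function(p) {
      mk <- function(v, dirn) if (length(v)) data.frame(
        compartment = p$compartment, direction = dirn, metabolite = names(v),
        flux = unname(v), stringsAsFactors = FALSE) else NULL
      rbind(mk(p$imports, "import"), mk(p$exports, "export"))
    }))
    if (is.null(ex)) ex <- data.frame(compartment = character(0),
                                      direction = character(0),
                                      metabolite = character(0),
                                      flux = numeric(0))
    wt(ex[order(ex$compartment, ex$direction, ex$metabolite), , drop = FALSE],
       "exchanges.tsv")
    wt(results$cross_feeding, "cross_feeding.tsv")
    wt(results$eaa_accounting$per_eaa, "eaa_accounting.tsv")
    led <- do.call(rbind, lapply(results$nitrogen_ledgers, function(l)
      data.frame(compartment = l$compartment, N_in = l$N_in,
                 N_out_eaa = l$N_out_eaa, N_out_other = l$N_out_other,
                 N_biomass = l$N_biomass, efficiency = l$efficiency,
                 stringsAsFactors = FALSE)))
    wt(led, "nitrogen_ledger.tsv")
    mc <- do.call(rbind, lapply(results$maintenance_costs, function(m)
      data.frame(symbiont = m$symbiont, host_growth_full = m$host_growth_full,
                 host_growth_symbiont_off = m$host_growth_symbiont_off,
                 cost_absolute = m$cost_absolute,
                 cost_relative = m$cost_relative, status = m$status,
                 stringsAsFactors = FALSE)))
    wt(mc, "maintenance_cost.tsv")
  }

  if ("json" %in% formats) {
    cfg <- results$config
    cfg_txt <- jsonlite::toJSON(list(
      biomass_floor = cfg$biomass_floor,
      threshold_exchange = cfg$threshold_exchange,
      threshold_fva_range = cfg$threshold_fva_range,
      threshold_transport_pct = cfg$threshold_transport_pct,
      stabilize = cfg$stabilize, seed = cfg$seed), auto_unbox = TRUE)
    cfg_path <- file.path(dir, "config.json")
    writeLines(cfg_txt, cfg_path)
    summ <- list(
      package_version = as.character(utils::packageVersion("symbioflux")),
      seed = cfg$seed,
      config_hash = unname(tools::md5sum(cfg_path)),
      objective = signif(results$fba$objective, 6),
      n_reactions = length(results$model$reactions),
      n_metabolites = nrow(results$model$metabolites),
      eaa_total_flux = signif(results$eaa_accounting$total_flux, 6),
      eaa_share = lapply(as.list(results$eaa_accounting$share), signif, 6),
      n_cross_fed = nrow(results$cross_feeding),
      efficiency = lapply(results$nitrogen_ledgers, function(l)
        signif(l$efficiency, 6)),
      maintenance_cost = lapply(results$maintenance_costs, function(m)
        signif(m$cost_absolute, 6)))
    if (!is.null(results$fva)) {
      summ$fraction_fva_range_below <-
        signif(results$summaries$flux_ranges$fraction_below, 6)
      summ$fraction_transport_variation_below <-
        signif(attr(results$summaries$transport_variation, "fraction_below"), 6)
    }
    p <- file.path(dir, "report.json")
    jsonlite::write_json(summ, p, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    paths <- c(paths, cfg_path, p)
  }
  invisible(paths)
}
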