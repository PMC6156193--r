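# Classification of per-compartment metabolite imports/exports from an
# optimal flux solution, shared/unique sets, symbiont-symbiont cross-feeding,
# and essential-amino-acid release accounting.

#' Classify per-compartment metabolite exchanges
#'
#' Sums, for each (metabolite species, compartment), the net flux over all
#' transport reactions touching that compartment; a net above the threshold
#' is an import, below the negative threshold an export (net accounting: a
#' species is never both for one compartment). Metabolites carrying an exempt
#' tag (minerals and cofactor-pathway species, which are required in small
#' quantities) are retained regardless of magnitude and flagged.
#'
#' @param model An \code{sbf_multi} with a transport registry.
#' @param sol An optimal \code{sbf_fba}.
#' @param threshold Flux threshold (default 1e-6 mmol gDW^-1 h^-1).
#' @param exempt_tags Tags retained regardless of magnitude.
#' @param compartments Compartments to profile (default: all non-external).
#' @return Named list of exchange profiles, each a list(compartment, imports,
#'   exports, exempt, class_counts) of class \code{"sbf_exchange_profile"};
#'   imports/exports are named flux vectors (positive magnitudes) keyed by
#'   species id.
#' @export
classify_exchanges <- function(model, sol, threshold = 1e-6,
                               exempt_tags = c("mineral", "cofactor"),
                               compartments = NULL) {
  stopifnot(inherits(model, "sbf_multi"))
  if (sol$status != "optimal") stop("exchange classification needs an optimal solution")
  if (is.null(compartments)) {
    compartments <- setdiff(model$compartments, model$external)
  }
  reg <- model$transports
  out <- list()
  for (comp in compartments) {
    net <- numeric(0) # species -> net flux into `comp`
    tagmap <- character(0)
    for (i in seq_len(nrow(reg))) {
      if (reg$donor[i] != comp && reg$recipient[i] != comp) next
      v <- sol$flux[[reg$reaction_id[i]]]
      signed <- if (reg$recipient[i] == comp) v else -v
      sp <- reg$metabolite[i]
      net[sp] <- (if (sp %in% names(net)) net[[sp]] else 0) + signed
      qualified <- paste0(sp, "[", comp, "]")
      if (qualified %in% model$metabolites$id) {
        tagmap[sp] <- met_row(model, qualified)$tags
      }
    }
    exempt <- vapply(names(net), function(sp) {
      length(intersect(strsplit(tagmap[[sp]], ";")[[1]], exempt_tags)) > 0
    }, TRUE)
    eff_thr <- ifelse(exempt, 1e-9, threshold)
    imports <- net[net > eff_thr]
    exports <- -net[net < -eff_thr]
    tag1 <- vapply(strsplit(tagmap, ";"), `[`, "", 1)
    class_counts <- list(
      imports = table(tag1[names(imports)]),
      exports = table(tag1[names(exports)]))
    out[[comp]] <- structure(
      list(compartment = comp, imports = imports, exports = exports,
           exempt = names(net)[exempt], class_counts = class_counts,
           threshold = threshold),
      class = "sbf_exchange_profile")
  }
  out
}

#' Shared and unique exchanged metabolites between two compartments
#'
#' Set algebra on species ids of one side (imports or exports) of two
#' exchange profiles from the same solution.
#'
#' @param profA,profB \code{sbf_exchange_profile}s.
#' @param side "imports" or "exports".
#' @return List with `shared`, `uniqueA`, `uniqueB` (character vectors).
#' @export
shared_unique_sets <- function(profA, profB, side = c("imports", "exports")) {
  side <- match.arg(side)
  a <- names(profA[[side]]); b <- names(profB[[side]])
  list(shared = sort(intersect(a, b)),
       uniqueA = sort(setdiff(a, b)),
       uniqueB = sort(setdiff(b, a)))
}

#' Detect symbiont-symbiont cross-feeding
#'
#' A metabolite is cross-fed from one symbiont to the other when the donor
#' exports it, the recipient imports it, and the host neither consumes nor
#' produces it net of transport (all transport in the model topology passes
#' the host interface, so a relayed metabolite shows zero net host flux and
#' is absent from the host profile).
#'
#' @param profiles Named list of profiles from [classify_exchanges()]
#'   containing entries for the host and both symbiont compartments.
#' @param host,symbionts Compartment ids; by default the first profile is the
#'   host and the remaining two the symbionts.
#' @return data.frame (metabolite, donor, recipient, flux); zero rows when
#'   there is no exclusive symbiont-to-symbiont transfer.
#' @export
detect_cross_feeding <- function(profiles, host = names(profiles)[1],
                                 symbionts = setdiff(names(profiles), host)) {
  stopifnot(length(symbionts) == 2L)
  hostp <- profiles[[host]]
  host_touched <- c(names(hostp$imports), names(hostp$exports))
  rec <- list()
  for (x in symbionts) {
    y <- setdiff(symbionts, x)
    ex <- profiles[[x]]$exports
    im <- profiles[[y]]$imports
    fed <- setdiff(intersect(names(ex), names(im)), host_touched)
    for (m in fed) {
      rec[[length(rec) + 1L]] <- data.frame(
        metabolite = m, donor = x, recipient = y,
        flux = unname(im[[m]]), stringsAsFactors = FALSE)
    }
  }
  if (length(rec) == 0L) {
    return(data.frame(metabolite = character(0), donor = character(0),
                      recipient = character(0), flux = numeric(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rec)
  out[order(out$metabolite), , drop = FALSE]
}

#' Essential-amino-acid release accounting
#'
#' Totals the EAA export fluxes from the symbionts, each symbiont's share of
#' the total, and the host's sink fraction per EAA (host import of the EAA
#' divided by its total release).
#'
#' @param profiles Named list of profiles from [classify_exchanges()].
#' @param eaa Character vector of EAA species ids; by default every species
#'   tagged "eaa" in the model.
#' @param model Model used to derive `eaa` from tags when not given.
#' @param host,symbionts Compartment roles as in [detect_cross_feeding()].
#' @return List: `per_eaa` (data.frame eaa x symbiont release flux, host sink
#'   fraction), `total_flux`, `share` (named fraction per symbiont). When the
#'   total release is zero, shares are NA and flagged `undefined`.
#' @export
eaa_release_accounting <- function(profiles, eaa = NULL, model = NULL,
                                   host = names(profiles)[1],
                                   symbionts = setdiff(names(profiles), host)) {
  if (is.null(eaa)) {
    if (is.null(model)) stop("supply either `eaa` or `model`")
    tagged <- vapply(strsplit(model$metabolites$tags, ";"),
                     function(t) "eaa" %in% t, TRUE)
    eaa <- unique(species_id(model$metabolites$id[tagged]))
  }
  rel <- sapply(symbionts, function(s) {
    ex <- profiles[[s]]$exports
    vapply(eaa, function(m) if (m %in% names(ex)) ex[[m]] else 0, 0)
  })
  rel <- matrix(rel, nrow = length(eaa),
                dimnames = list(eaa, symbionts))
  total_per_eaa <- rowSums(rel)
  host_im <- profiles[[host]]$imports
  sink <- vapply(eaa, function(m) {
    if (total_per_eaa[[m]] <= 0) return(NA_real_)
    (if (m %in% names(host_im)) host_im[[m]] else 0) / total_per_eaa[[m]]
  }, 0)
  total <- sum(rel)
  share <- if (total > 0) colSums(rel) / total
           else stats::setNames(rep(NA_real_, length(symbionts)), symbionts)
  list(per_eaa = data.frame(eaa = eaa, rel, total = total_per_eaa,
                            host_sink_fraction = sink,
                            row.names = NULL, check.names = FALSE),
       total_flux = total,
       share = share,
       undefined = total <= 0)
}
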