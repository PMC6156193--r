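# Gene-protein-reaction (GPR) rules and transcriptome-derived flux bounds.
#
# GPR grammar: gene ids, AND/OR (case-insensitive), parentheses. Evaluation
# against integer expression levels uses OR = sum (isozymes add capacity)
# and AND = min (a complex is limited by its scarcest subunit).

gpr_tokenize <- function(gpr) {
  gpr <- gsub("([()])", " \\1 ", gpr)
  toks <- strsplit(trimws(gpr), "\\s+")[[1]]
  toks[nzchar(toks)]
}

# Recursive-descent parser -> nested list(op = "or"/"and"/"gene", args/gene)
gpr_parse <- function(gpr) {
  toks <- gpr_tokenize(gpr)
  if (length(toks) == 0L) return(NULL)
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[pos] else NA_character_
  take <- function() { t <- toks[pos]; pos <<- pos + 1L; t }
  parse_or <- function() {
    args <- list(parse_and())
    while (!is.na(peek()) && tolower(peek()) == "or") {
      take(); args <- c(args, list(parse_and()))
    }
    if (length(args) == 1L) args[[1]] else list(op = "or", args = args)
  }
  parse_and <- function() {
    args <- list(parse_atom())
    while (!is.na(peek()) && tolower(peek()) == "and") {
      take(); args <- c(args, list(parse_atom()))
    }
    if (length(args) == 1L) args[[1]] else list(op = "and", args = args)
  }
  parse_atom <- function() {
    t <- peek()
    if (is.na(t)) stop("malformed gene association: unexpected end of rule")
    if (t == "(") {
      take(); node <- parse_or()
      if (is.na(peek()) || take() != ")") stop("malformed gene association: missing ')'")
      return(node)
    }
    if (t == ")" || tolower(t) %in% c("and", "or")) {
      stop(sprintf("malformed gene association: unexpected token '%s'", t))
    }
    list(op = "gene", gene = take())
  }
  node <- parse_or()
  if (pos <= length(toks)) {
    stop(sprintf("malformed gene association: trailing token '%s'", toks[pos]))
  }
  node
}

# All gene ids mentioned by a GPR string.
gpr_genes <- function(gpr) {
  if (is.null(gpr) || is.na(gpr) || !nzchar(gpr)) return(character(0))
  node <- gpr_parse(gpr)
  collect <- function(n) {
    if (n$op == "gene") n$gene else unlist(lapply(n$args, collect))
  }
  unique(collect(node))
}

# Capacity of a GPR under integer levels. Genes absent from `levels`
# contribute 0 to OR and are dropped from AND (min over matched subunits);
# NA when no gene in the rule matched at all.
gpr_capacity <- function(gpr, levels) {
  node <- gpr_parse(gpr)
  if (is.null(node)) return(NA_real_)
  ev <- function(n) {
    if (n$op == "gene") {
      if (n$gene %in% names(levels)) as.numeric(levels[[n$gene]]) else NA_real_
    } else {
      vals <- vapply(n$args, ev, 0)
      if (all(is.na(vals))) return(NA_real_)
      if (n$op == "or") sum(vals, na.rm = TRUE) else min(vals, na.rm = TRUE)
    }
  }
  ev(node)
}

#' Normalize a TPM expression table to integer levels
#'
#' Implements the bacteriocyte transcriptome normalization: genes with zero
#' TPM in a replicate are first assigned that replicate's lowest nonzero TPM;
#' mean TPM per gene is then divided by the lowest nonzero mean and rounded
#' half-up to an integer, so the least-expressed gene gets level 1 and every
#' other gene an integer multiple of it.
#'
#' @param table An expression table from [read_expression_table()] or
#'   [generate_expression_table()]: data.frame with `gene_id` plus one
#'   numeric column per replicate.
#' @return Named integer vector of levels (min = 1).
#' @export
normalize_expression <- function(table) {
  stopifnot(is.data.frame(table), "gene_id" %in% names(table), nrow(table) >= 1L)
  reps <- setdiff(names(table), "gene_id")
  if (length(reps) == 0L) stop("expression table has no replicate columns")
  tpm <- as.matrix(table[reps])
  if (any(tpm < 0)) stop("negative TPM values are not allowed")
  if (all(tpm == 0)) stop("all-zero expression table: no nonzero floor exists")
  for (j in seq_len(ncol(tpm))) {
    nz <- tpm[, j][tpm[, j] > 0]
    if (length(nz) == 0L) {
      stop(sprintf("replicate '%s' is all zero: no nonzero floor exists", reps[j]))
    }
    tpm[tpm[, j] == 0, j] <- min(nz)
  }
  means <- rowMeans(tpm)
  lvl <- floor(means / min(means[means > 0]) + 0.5) # round half-up
  lvl <- pmax(lvl, 1)
  stats::setNames(as.integer(lvl), table$gene_id)
}

#' Constrain host reaction bounds from expression levels
#'
#' For each internal reaction with a gene association the GPR capacity L
#' (OR = sum of levels, AND = min) becomes the upper bound, and the lower
#' bound -L if the reaction was reversible (0 otherwise). Internal reactions
#' whose rule matches no transcript (and orphans) get the default bound
#' instead. Transport, exchange and biomass/objective reactions are left
#' untouched.
#'
#' @param model An \code{sbf_model}.
#' @param expr Named integer levels from [normalize_expression()].
#' @param default_bound Flux bound for unmatched reactions (mmol gDW^-1
#'   h^-1); 10 by default.
#' @return The model with updated bounds; unmatched gene ids are reported via
#'   attribute \code{"unmatched_genes"}.
#' @export
apply_expression_bounds <- function(model, expr, default_bound = 10) {
  stopifnot(default_bound > 0)
  unmatched <- character(0)
  for (rid in names(model$reactions)) {
    r <- model$reactions[[rid]]
    if (r$kind != "internal") next
    reversible <- r$lb < 0
    cap <- if (nzchar(r$gpr)) {
      unmatched <- c(unmatched, setdiff(gpr_genes(r$gpr), names(expr)))
      gpr_capacity(r$gpr, expr)
    } else NA_real_
    if (is.na(cap)) cap <- default_bound
    model$reactions[[rid]]$ub <- cap
    model$reactions[[rid]]$lb <- if (reversible) -cap else 0
  }
  attr(model, "unmatched_genes") <- unique(unmatched)
  model
}
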