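#' Parse an elemental formula
#'
#' Parses a Hill-style elemental formula (e.g. \code{"C5H10N2O3"}) into
#' integer element counts. The accepted grammar is a sequence of element
#' symbols (one capital letter optionally followed by one lowercase letter)
#' each followed by an optional positive integer count (absent = 1). No
#' charges, isotopes or parentheses.
#'
#' @param formula A single non-empty formula string.
#' @return Named integer vector of element counts. Repeated elements are
#'   summed.
#' @examples
#' parse_formula("NH3")
#' parse_formula("C5H10N2O3")
#' @export
parse_formula <- function(formula) {
  if (!is.character(formula) || length(formula) != 1L || is.na(formula)) {
    stop("`formula` must be a single character string")
  }
  if (!nzchar(formula)) {
    stop("cannot parse an empty formula")
  }
  counts <- integer(0)
  pos <- 1L
  n <- nchar(formula)
  while (pos <= n) {
    rest <- substr(formula, pos, n)
    m <- regmatches(rest, regexec("^([A-Z][a-z]?)([0-9]*)", rest))[[1]]
    if (length(m) == 0L || !nzchar(m[2])) {
      stop(sprintf("malformed formula '%s': unexpected character '%s' at position %d",
                   formula, substr(formula, pos, pos), pos))
    }
    elem <- m[2]
    cnt <- if (nzchar(m[3])) as.integer(m[3]) else 1L
    if (is.na(cnt) || cnt <= 0L) {
      stop(sprintf("malformed formula '%s': invalid count at position %d",
                   formula, pos + nchar(elem)))
    }
    counts[elem] <- if (elem %in% names(counts)) counts[[elem]] + cnt else cnt
    pos <- pos + nchar(m[1])
  }
  counts
}

#' Count atoms of one element in a metabolite
#'
#' @param met A metabolite: either a formula string, or a row from a model's
#'   metabolite table (a list/data.frame with a `formula` field).
#' @param element Element symbol, e.g. \code{"N"}.
#' @return Integer count; 0 if the element is absent from the formula.
#'   A metabolite with an empty formula (pseudo-metabolite) is an error,
#'   not 0 -- elemental budgets must not silently treat it as element-free.
#' @examples
#' element_count("C5H10N2O3", "N") # glutamine -> 2
#' element_count("C6H12O6", "N")   # glucose -> 0
#' @export
element_count <- function(met, element) {
  f <- if (is.character(met)) met else met$formula
  if (is.null(f) || is.na(f) || !nzchar(f)) {
    id <- if (is.character(met)) met else met$id
    stop(sprintf("metabolite '%s' has no formula; cannot count element '%s'",
                 if (is.null(id)) "<unnamed>" else id, element))
  }
  counts <- parse_formula(f)
  if (element %in% names(counts)) unname(counts[[element]]) else 0L
}
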