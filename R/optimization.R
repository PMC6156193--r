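# Linear programming for FBA/FVA. The engine solves
#   optimize c.v  s.t.  S.v = 0,  lb <= v <= ub
# with a two-phase bounded-variable primal simplex using Bland's rule
# (smallest-index pivoting), which terminates on the heavily degenerate,
# rank-deficient systems that stoichiometric matrices produce (conserved
# moieties, many zero fluxes at the optimum) and is fully deterministic for
# a fixed reaction ordering, which we take from the model. All bounds must
# be finite; +/-1000 is the conventional "unbounded" placeholder, so the LPs
# are always bounded and feasibility is decided by phase 1.

FEAS_TOL <- 1e-9

# Bounded-variable primal simplex, maximize cc.x s.t. A x = b, l <= x <= u.
# Phase 1 minimizes artificial infeasibility (artificials are then pinned to
# zero), so rank-deficient A and b in any sign are handled. Returns
# list(status, x, value).
simplex_bounded <- function(A, b, l, u, cc, maximize = TRUE,
                            tol = 1e-9, max_iter = 100000L) {
  A <- as.matrix(A)
  m <- nrow(A); n <- ncol(A)
  if (!maximize) cc <- -cc
  # start structurals at the finite bound of smaller magnitude
  at_upper <- abs(u) < abs(l)
  x <- ifelse(at_upper, u, l)
  r <- b - as.vector(A %*% x)
  # artificial columns +/- e_i, value |r_i|, bounds [0, |r_i|]
  Af <- cbind(A, diag(ifelse(r >= 0, 1, -1), m))
  lf <- c(l, rep(0, m)); uf <- c(u, abs(r) + 1)
  xf <- c(x, abs(r))
  basis <- n + seq_len(m)
  nonbasic_upper <- c(at_upper, rep(FALSE, m)) # tracked for nonbasic vars
  Binv <- diag(ifelse(r >= 0, 1, -1), m)       # inverse of artificial basis

  run_phase <- function(cost, xf, basis, nonbasic_upper, Binv, iter_budget) {
    it <- 0L
    repeat {
      it <- it + 1L
      if (it > iter_budget) stop("LP solver did not converge (iteration limit)")
      if (it %% 64L == 0L) { # refactorize to control drift
        Binv <- solve(Af[, basis, drop = FALSE])
      }
      y <- as.vector(crossprod(Binv, cost[basis]))
      in_basis <- logical(n + m); in_basis[basis] <- TRUE
      d <- cost - as.vector(crossprod(Af, y))
      elig <- !in_basis & (lf < uf) &
        ((!nonbasic_upper & d > tol) | (nonbasic_upper & d < -tol))
      entering <- if (any(elig)) which(elig)[1L] else 0L # Bland: smallest index
      enter_dir <- if (entering && nonbasic_upper[entering]) -1 else 1
      if (entering == 0L) {
        return(list(x = xf, basis = basis, nonbasic_upper = nonbasic_upper,
                    Binv = Binv, value = sum(cost[seq_len(n)] * xf[seq_len(n)])))
      }
      w <- as.vector(Binv %*% Af[, entering]) * enter_dir
      # ratio test: entering moves by t >= 0, basics move by -w t
      t_best <- uf[entering] - lf[entering]
      leave_pos <- 0L
      for (i in seq_len(m)) {
        bi <- basis[i]
        ti <- if (w[i] > tol) (xf[bi] - lf[bi]) / w[i]
              else if (w[i] < -tol) (uf[bi] - xf[bi]) / (-w[i])
              else next
        if (ti < t_best - tol ||
            (ti < t_best + tol && (leave_pos == 0L || bi < basis[leave_pos]))) {
          t_best <- ti; leave_pos <- i
        }
      }
      t_best <- max(t_best, 0)
      xf[entering] <- xf[entering] + enter_dir * t_best
      if (t_best > 0) xf[basis] <- xf[basis] - w * t_best
      if (leave_pos == 0L) { # bound-to-bound flip
        nonbasic_upper[entering] <- !nonbasic_upper[entering]
        next
      }
      leaving <- basis[leave_pos]
      nonbasic_upper[leaving] <- w[leave_pos] < 0 # left at upper bound
      xf[leaving] <- if (w[leave_pos] > 0) lf[leaving] else uf[leaving]
      basis[leave_pos] <- entering
      # product-form update of Binv
      wcol <- as.vector(Binv %*% Af[, entering])
      piv <- wcol[leave_pos]
      Binv[leave_pos, ] <- Binv[leave_pos, ] / piv
      for (i in seq_len(m)) {
        if (i != leave_pos && abs(wcol[i]) > 0) {
          Binv[i, ] <- Binv[i, ] - wcol[i] * Binv[leave_pos, ]
        }
      }
    }
  }

  # phase 1: minimize sum of artificials (maximize the negative)
  c1 <- c(rep(0, n), rep(-1, m))
  ph1 <- run_phase(c1, xf, basis, nonbasic_upper, Binv, max_iter)
  if (sum(ph1$x[n + seq_len(m)]) > 1e-7) {
    return(list(status = "infeasible", x = rep(NA_real_, n), value = NA_real_))
  }
  uf[n + seq_len(m)] <- 0 # pin artificials
  ph1$x[n + seq_len(m)] <- 0
  c2 <- c(cc, rep(0, m))
  ph2 <- run_phase(c2, ph1$x, ph1$basis, ph1$nonbasic_upper, ph1$Binv, max_iter)
  x <- ph2$x[seq_len(n)]
  val <- sum(cc * x)
  list(status = "optimal", x = x, value = if (maximize) val else -val)
}

# Solve optimize(obj . v) s.t. S v = 0, lb <= v <= ub, and optional extra
# rows  a . v (dir) rhs  with dir in c("<=", ">="), encoded as equalities
# with bounded slack variables. Returns list(status, value, v).
solve_lp <- function(S, lb, ub, obj, maximize = TRUE,
                     extra_A = NULL, extra_dir = character(0),
                     extra_rhs = numeric(0)) {
  n <- length(lb)
  stopifnot(length(ub) == n, length(obj) == n)
  if (any(!is.finite(lb)) || any(!is.finite(ub))) {
    stop("LP requires finite bounds on every reaction")
  }
  S <- as.matrix(S)
  keep <- rowSums(abs(S)) > 0
  S <- S[keep, , drop = FALSE]
  # drop linearly dependent balance rows (conserved moieties); the dropped
  # equalities are implied by the kept ones since the rhs is 0
  if (nrow(S) > 1) {
    qs <- qr(t(S))
    if (qs$rank < nrow(S)) S <- S[qs$pivot[seq_len(qs$rank)], , drop = FALSE]
  }
  A <- S; b <- rep(0, nrow(S))
  l <- lb; u <- ub; cc <- obj
  if (!is.null(extra_A)) {
    extra_A <- matrix(extra_A, ncol = n)
    span <- sum(pmax(abs(lb), abs(ub))) + 1
    for (i in seq_len(nrow(extra_A))) {
      a <- extra_A[i, ]; rr <- extra_rhs[i]
      big <- sum(abs(a)) * span + abs(rr) + 1
      # a.v + s = rhs with s >= 0 ("<=") or s <= 0 (">=")
      sl <- if (extra_dir[i] == "<=") c(0, big) else c(-big, 0)
      a <- c(a, rep(0, ncol(A) - n)) # pad for slacks added so far
      A <- cbind(rbind(A, a), c(rep(0, nrow(A)), 1))
      b <- c(b, rr)
      l <- c(l, sl[1]); u <- c(u, sl[2]); cc <- c(cc, 0)
    }
  }
  res <- simplex_bounded(A, b, l, u, cc, maximize = maximize)
  if (res$status != "optimal") {
    return(list(status = res$status, value = NA_real_, v = rep(NA_real_, n)))
  }
  v <- res$x[seq_len(n)]
  list(status = "optimal", value = sum(obj * v), v = v)
}

#' Flux balance analysis
#'
#' Maximizes the model objective c.v subject to steady state S.v = 0 and the
#' flux bounds. Deterministic for a fixed reaction ordering. With
#' `stabilize = TRUE` a second LP minimizes total absolute flux while holding
#' the objective at its optimum, selecting a parsimonious representative
#' among alternate optima.
#'
#' @param model An \code{sbf_model} with a nonempty objective.
#' @param sense "max" (default) or "min".
#' @param stabilize Minimal-total-flux secondary objective (default FALSE:
#'   plain FBA).
#' @return List of class \code{"sbf_fba"}: `status` ("optimal"/"infeasible"),
#'   `objective` value, and named `flux` vector.
#' @export
solve_fba <- function(model, sense = c("max", "min"), stabilize = FALSE) {
  sense <- match.arg(sense)
  if (length(model$objective) == 0L) stop("model has an empty objective")
  S <- build_matrix(model)
  b <- model_bounds(model)
  cvec <- model_objective_vector(model)
  res <- solve_lp(S, b$lb, b$ub, cvec, maximize = (sense == "max"))
  flux <- stats::setNames(res$v, names(model$reactions))
  if (res$status == "optimal" && stabilize) {
    flux <- stats::setNames(
      pfba_flux(S, b$lb, b$ub, cvec, res$value, maximize = (sense == "max")),
      names(model$reactions))
    res$value <- sum(cvec * flux)
  }
  structure(list(status = res$status, objective = res$value, flux = flux),
            class = "sbf_fba")
}

# Minimize sum |v| subject to the original constraints and c.v at the fixed
# optimum (within tolerance). Split v = p - q with p, q >= 0.
pfba_flux <- function(S, lb, ub, cvec, opt, maximize = TRUE) {
  n <- length(lb)
  S <- as.matrix(S)
  S2 <- cbind(S, -S)            # S p - S q = 0
  lb2 <- rep(0, 2 * n)
  ub2 <- c(pmax(ub, 0), pmax(-lb, 0))
  obj2 <- rep(1, 2 * n)
  tol <- max(FEAS_TOL, 1e-6 * abs(opt))
  # v = p - q within original bounds, and objective pinned
  extra_A <- rbind(cbind(diag(n), -diag(n)),     # v <= ub
                   cbind(diag(n), -diag(n)),     # v >= lb
                   c(cvec, -cvec))
  extra_dir <- c(rep("<=", n), rep(">=", n), if (maximize) ">=" else "<=")
  extra_rhs <- c(ub, lb, if (maximize) opt - tol else opt + tol)
  res <- solve_lp(S2, lb2, ub2, obj2, maximize = FALSE,
                  extra_A = extra_A, extra_dir = extra_dir, extra_rhs = extra_rhs)
  if (res$status != "optimal") stop("flux stabilization LP failed: ", res$status)
  res$v[seq_len(n)] - res$v[n + seq_len(n)]
}

#' Flux variability analysis
#'
#' For each reaction, minimizes and maximizes its flux subject to the
#' original constraints plus the objective held at (a fraction of) the FBA
#' optimum. 2n independent LPs; any execution order gives identical results.
#'
#' @param model An \code{sbf_model}; [solve_fba()] must be feasible.
#' @param objective_fraction Fraction of the optimum to maintain, in (0, 1]
#'   (default 1: fixed maximal objective, up to numerical tolerance).
#' @param reactions Reaction ids to analyze (default all).
#' @return data.frame of class \code{"sbf_fva"} with columns reaction, min,
#'   max; attribute `objective` records the pinned optimum.
#' @export
solve_fva <- function(model, objective_fraction = 1.0, reactions = NULL) {
  stopifnot(objective_fraction > 0, objective_fraction <= 1)
  fba <- solve_fba(model)
  if (fba$status != "optimal") {
    stop("FVA requires a feasible model (FBA status: ", fba$status, ")")
  }
  S <- build_matrix(model)
  b <- model_bounds(model)
  cvec <- model_objective_vector(model)
  tol <- max(FEAS_TOL, 1e-6 * abs(fba$objective))
  target <- objective_fraction * fba$objective - tol
  rids <- if (is.null(reactions)) names(model$reactions) else reactions
  n <- length(b$lb)
  lo <- hi <- stats::setNames(numeric(length(rids)), rids)
  for (rid in rids) {
    e <- stats::setNames(numeric(n), names(model$reactions)); e[rid] <- 1
    for (dir in c("min", "max")) {
      res <- solve_lp(S, b$lb, b$ub, e, maximize = (dir == "max"),
                      extra_A = cvec, extra_dir = ">=", extra_rhs = target)
      if (res$status != "optimal") {
        stop(sprintf("FVA subproblem %s(%s) not optimal: %s", dir, rid, res$status))
      }
      if (dir == "min") lo[rid] <- res$value else hi[rid] <- res$value
    }
  }
  out <- data.frame(reaction = rids, min = unname(lo), max = unname(hi),
                    stringsAsFactors = FALSE)
  attr(out, "objective") <- fba$objective
  attr(out, "objective_fraction") <- objective_fraction
  class(out) <- c("sbf_fva", class(out))
  out
}

#' Summarize FVA flux ranges
#'
#' Flux range = max - min per reaction at the fixed objective. Reports the
#' fraction of reactions whose range is below `threshold` (1 mmol gDW^-1
#' h^-1 by default) plus the range histogram.
#'
#' @param fva An \code{sbf_fva}.
#' @param threshold Range threshold.
#' @return List: `fraction_below`, `threshold`, `ranges` (named), `histogram`.
#' @export
flux_range_summary <- function(fva, threshold = 1.0) {
  ranges <- stats::setNames(fva$max - fva$min, fva$reaction)
  list(fraction_below = mean(ranges < threshold),
       threshold = threshold,
       ranges = ranges,
       histogram = graphics::hist(ranges, plot = FALSE))
}

#' Relative flux variation of transport reactions
#'
#' Per transport reaction: 100 * (max - min) / |v_FBA|. Reactions with
#' near-zero optimal flux (|v| < 1e-9) are reported as undefined and excluded
#' from the summary fraction.
#'
#' @param fva An \code{sbf_fva} covering the transport reactions.
#' @param sol An optimal \code{sbf_fba} solution.
#' @param transports Transport reaction ids (default: the model registry ids
#'   recorded in `fva` rows whose id starts with "T_").
#' @param threshold_pct Summary threshold in percent (default 1).
#' @return data.frame (reaction, flux, range, percent, defined) with
#'   attribute `fraction_below`: fraction of defined transports varying by
#'   less than `threshold_pct`.
#' @export
transport_flux_variation <- function(fva, sol, transports = NULL,
                                     threshold_pct = 1.0) {
  stopifnot(sol$status == "optimal")
  if (is.null(transports)) transports <- grep("^T_", fva$reaction, value = TRUE)
  idx <- match(transports, fva$reaction)
  if (anyNA(idx)) stop("FVA result does not cover all transport reactions")
  rng <- fva$max[idx] - fva$min[idx]
  v <- sol$flux[transports]
  defined <- abs(v) >= 1e-9
  pct <- ifelse(defined, 100 * rng / abs(v), NA_real_)
  out <- data.frame(reaction = transports, flux = unname(v), range = rng,
                    percent = pct, defined = defined, stringsAsFactors = FALSE)
  attr(out, "fraction_below") <- if (any(defined))
    mean(pct[defined] < threshold_pct) else NA_real_
  attr(out, "threshold_pct") <- threshold_pct
  out
}
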