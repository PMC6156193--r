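# Independent brute-force LP oracle: enumerates every basic point of
# {S v = 0, lb <= v <= ub} (each variable free / at lb / at ub; free block
# solved uniquely by QR) and returns the best feasible objective. Exponential
# in n, usable for n <= 8; deliberately shares no code with the simplex path.
vertex_enum_opt <- function(S, lb, ub, obj, tol = 1e-9) {
  S <- as.matrix(S)
  n <- ncol(S)
  combos <- as.matrix(expand.grid(rep(list(0:2), n)))
  best <- -Inf
  for (k in seq_len(nrow(combos))) {
    dig <- combos[k, ]
    v <- numeric(n)
    v[dig == 1] <- lb[dig == 1]
    v[dig == 2] <- ub[dig == 2]
    free <- which(dig == 0)
    if (length(free)) {
      A <- S[, free, drop = FALSE]
      qa <- qr(A)
      if (qa$rank < length(free)) next # not a vertex: free block underdetermined
      rhs <- if (length(free) < n)
        -S[, -free, drop = FALSE] %*% v[-free] else matrix(0, nrow(S), 1)
      x <- qr.coef(qa, rhs)
      if (anyNA(x)) next
      v[free] <- x
    }
    if (max(abs(S %*% v)) > 1e-7) next
    if (any(v < lb - 1e-7) || any(v > ub + 1e-7)) next
    best <- max(best, sum(obj * v))
  }
  best
}

# Random small feasible bounded model (0 is always feasible: lb <= 0 <= ub).
random_small_model <- function(seed) {
  set.seed(seed)
  n <- sample(3:8, 1)
  m <- sample(1:3, 1)
  repeat {
    S <- matrix(sample(c(-2, -1, 0, 1, 2), m * n, replace = TRUE,
                       prob = c(.1, .25, .3, .25, .1)), m, n)
    if (all(colSums(abs(S)) > 0)) break
  }
  lb <- ifelse(stats::runif(n) < 0.5, -round(stats::runif(n, 1, 10), 2), 0)
  ub <- round(stats::runif(n, 0.5, 10), 2)
  obj <- round(stats::rnorm(n), 2)
  mets <- do.call(rbind, lapply(seq_len(m), function(i)
    metabolite(sprintf("m%d[h]", i), compartment = "h", formula = "C")))
  rxns <- lapply(seq_len(n), function(j) {
    st <- stats::setNames(S[, j], sprintf("m%d[h]", seq_len(m)))
    st <- st[st != 0]
    reaction(sprintf("r%d", j), st, lb = lb[j], ub = ub[j],
             kind = if (length(st) == 1L) "exchange" else "internal")
  })
  list(model = metabolic_model(sprintf("rand%d", seed), "h", mets, rxns,
                               objective = stats::setNames(obj, sprintf("r%d", seq_len(n)))),
       S = S, lb = lb, ub = ub, obj = obj)
}

# Linear chain: uptake (cap) -> a -> b -> objective sink.
chain_model <- function(cap = 5, conv_ub = 1000, obj_lb = 0) {
  mets <- rbind(metabolite("a[h]", formula = "C", compartment = "h"),
                metabolite("b[h]", formula = "C", compartment = "h"))
  metabolic_model("chain", "h", mets, list(
    reaction("EX_a", c(`a[h]` = -1), lb = -cap, ub = 1000, kind = "exchange"),
    reaction("CONV", c(`a[h]` = -1, `b[h]` = 1), lb = 0, ub = conv_ub),
    reaction("OBJ", c(`b[h]` = -1), lb = obj_lb, ub = 1000, kind = "objective")),
    objective = c(OBJ = 1))
}

expect_model_equal <- function(a, b) {
  expect_identical(sort(a$metabolites$id), sort(b$metabolites$id))
  ord <- match(a$metabolites$id, b$metabolites$id)
  expect_identical(a$metabolites$formula, b$metabolites$formula[ord])
  expect_identical(a$metabolites$tags, b$metabolites$tags[ord])
  expect_identical(a$metabolites$compartment, b$metabolites$compartment[ord])
  expect_identical(names(a$reactions), names(b$reactions))
  for (rid in names(a$reactions)) {
    ra <- a$reactions[[rid]]; rb <- b$reactions[[rid]]
    expect_equal(ra$stoichiometry[sort(names(ra$stoichiometry))],
                 rb$stoichiometry[sort(names(rb$stoichiometry))],
                 tolerance = 1e-12, label = rid)
    expect_equal(ra$lb, rb$lb, tolerance = 1e-12, label = paste0(rid, " lb"))
    expect_equal(ra$ub, rb$ub, tolerance = 1e-12, label = paste0(rid, " ub"))
    expect_identical(ra$kind, rb$kind, label = paste0(rid, " kind"))
    expect_identical(ra$gpr, rb$gpr, label = paste0(rid, " gpr"))
  }
  expect_equal(a$objective[sort(names(a$objective))],
               b$objective[sort(names(b$objective))], tolerance = 1e-12)
}

# Sorted named-vector comparison for exchange profiles.
expect_profile_equal <- function(got, want, tolerance = 1e-8) {
  expect_setequal(names(got), names(want))
  want <- want[names(got)]
  expect_equal(unname(got), unname(want), tolerance = tolerance)
}

tmpf <- function(ext) tempfile(fileext = ext)
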