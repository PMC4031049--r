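#' Solve a bounded linear program over a stoichiometric equality system
#'
#' Optimizes \code{c'v} subject to \code{S v = 0} and \code{lb <= v <= ub}.
#' This is the computational core behind all flux balance and flux
#' variability computations in the package. Two interchangeable backends are
#' provided: \code{"primal"}, a dense two-phase primal simplex with Bland's
#' anti-cycling rule written for this package (deterministic vertex
#' solutions, which makes activity calls reproducible), and \code{"highs"},
#' which hands the problem to the HiGHS solver through the bundled Python
#' helper (\code{inst/python/lp_highs.py}, requires \code{python} with scipy
#' on the PATH) -- useful as an independent cross-check.
#'
#' All variable bounds must be finite: a metabolic model always carries
#' finite default bounds, and an unbounded objective would indicate a missing
#' exchange constraint rather than a meaningful optimum.
#'
#' @param obj numeric objective coefficients, one per column of \code{S}.
#' @param S constraint matrix (rows are balanced metabolites).
#' @param lb,ub numeric lower/upper variable bounds, finite.
#' @param maximize logical; maximize (default) or minimize.
#' @param backend \code{"primal"} or \code{"highs"}.
#' @param tol feasibility/pivot tolerance.
#' @return list with \code{status} (\code{"optimal"} or \code{"infeasible"}),
#'   \code{objective} and \code{solution} (numeric vector, \code{NA} when
#'   infeasible).
#' @keywords internal
lp_solve <- function(obj, S, lb, ub, maximize = TRUE,
                     backend = c("primal", "highs"), tol = 1e-9) {
  backend <- match.arg(backend)
  S <- as.matrix(S)
  n <- ncol(S)
  stopifnot(length(obj) == n, length(lb) == n, length(ub) == n)
  if (any(lb > ub + tol)) {
    return(list(status = "infeasible", objective = NA_real_, solution = rep(NA_real_, n)))
  }
  if (!all(is.finite(lb)) || !all(is.finite(ub))) {
    stop("lp_solve requires finite variable bounds; found infinite bound ",
         "(missing exchange constraint?)")
  }
  # numerically equal bounds confuse the ratio test; snap them
  eq <- ub - lb < tol
  ub[eq] <- lb[eq]
  if (backend == "primal") {
    lp_solve_primal(obj, S, lb, ub, maximize, tol)
  } else {
    lp_solve_highs(obj, S, lb, ub, maximize)
  }
}

# Two-phase dense primal simplex on the shifted problem x = v - lb >= 0:
#   S x = -S lb  (equality rows, artificials)
#   x_j <= ub_j - lb_j  (upper-bound rows, slacks)
# Bland's rule throughout: deterministic and cycle-free. Problems solved here
# are small (toy networks), so the dense tableau is the simple, robust choice.
lp_solve_primal <- function(obj, S, lb, ub, maximize, tol) {
  n <- ncol(S)
  m <- nrow(S)
  cvec <- if (maximize) -as.numeric(obj) else as.numeric(obj) # minimize internally
  u <- ub - lb
  b_eq <- as.numeric(-S %*% lb)
  # drop upper-bound rows for fixed variables (u == 0): variable is frozen at 0
  free <- which(u > tol)
  ns <- length(free)
  nart <- m
  ncols <- n + ns + nart
  # sign-flip equality rows so rhs >= 0
  flip <- b_eq < 0
  A_eq <- S
  A_eq[flip, ] <- -A_eq[flip, , drop = FALSE]
  b_eq[flip] <- -b_eq[flip]
  nrows <- m + ns
  T <- matrix(0, nrows, ncols + 1L)
  T[seq_len(m), seq_len(n)] <- A_eq
  T[seq_len(m), n + ns + seq_len(nart)] <- diag(1, m)
  T[seq_len(m), ncols + 1L] <- b_eq
  if (ns > 0L) {
    T[cbind(m + seq_len(ns), free)] <- 1
    T[cbind(m + seq_len(ns), n + seq_len(ns))] <- 1
    T[m + seq_len(ns), ncols + 1L] <- u[free]
  }
  basis <- c(n + ns + seq_len(nart), if (ns > 0L) n + seq_len(ns))
  frozen <- setdiff(seq_len(n), free) # variables with u == 0 never enter

  pivot <- function(T, r, j) {
    T[r, ] <- T[r, ] / T[r, j]
    other <- setdiff(seq_len(nrow(T)), r)
    T[other, ] <- T[other, ] - outer(T[other, j], T[r, ])
    T
  }
  run_simplex <- function(T, basis, cost, allowed) {
    # reduced costs maintained from scratch each iteration (small problems)
    repeat {
      cb <- cost[basis]
      red <- cost - as.numeric(crossprod(cb, T[, seq_len(ncols), drop = FALSE]))
      enter_cand <- allowed[red[allowed] < -tol]
      if (length(enter_cand) == 0L) {
        return(list(T = T, basis = basis, status = "optimal"))
      }
      j <- enter_cand[1L] # Bland: smallest index
      col <- T[, j]
      pos <- which(col > tol)
      if (length(pos) == 0L) {
        return(list(T = T, basis = basis, status = "unbounded"))
      }
      ratio <- T[pos, ncols + 1L] / col[pos]
      rmin <- min(ratio)
      ties <- pos[ratio <= rmin + tol]
      r <- ties[which.min(basis[ties])] # Bland tie-break on leaving index
      T <- pivot(T, r, j)
      basis[r] <- j
    }
  }

  # phase 1: drive artificials to zero
  cost1 <- c(rep(0, n + ns), rep(1, nart))
  allowed1 <- setdiff(seq_len(ncols), frozen)
  res <- run_simplex(T, basis, cost1, allowed1)
  T <- res$T; basis <- res$basis
  art_rows <- which(basis > n + ns)
  p1val <- if (length(art_rows)) sum(T[art_rows, ncols + 1L]) else 0
  if (res$status != "optimal" || p1val > 1e-7) {
    return(list(status = "infeasible", objective = NA_real_,
                solution = rep(NA_real_, n)))
  }
  # pivot residual zero-level artificials out where possible
  for (r in which(basis > n + ns)) {
    j <- which(abs(T[r, seq_len(n + ns)]) > tol)
    j <- setdiff(j, frozen)
    if (length(j)) {
      T <- pivot(T, r, j[1L])
      basis[r] <- j[1L]
    }
  }
  # phase 2: original objective, artificials barred from entering
  cost2 <- c(cvec, rep(0, ns), rep(0, nart))
  allowed2 <- setdiff(seq_len(n + ns), frozen)
  res <- run_simplex(T, basis, cost2, allowed2)
  if (res$status == "unbounded") {
    stop("linear program unbounded despite finite variable bounds; ",
         "numerical degeneracy in the model matrix")
  }
  T <- res$T; basis <- res$basis
  x <- numeric(ncols)
  x[basis] <- T[, ncols + 1L]
  v <- x[seq_len(n)] + lb
  objective <- sum(obj * v)
  list(status = "optimal", objective = objective, solution = v)
}

# HiGHS backend: serialize the problem to JSON, solve through the bundled
# scipy helper, read the result back. One subprocess per LP -- meant for
# cross-checks and small problems, not for tight screening loops.
lp_solve_highs <- function(obj, S, lb, ub, maximize) {
  script <- system.file("python", "lp_highs.py", package = "synlethal")
  if (!nzchar(script)) stop("bundled lp_highs.py not found; reinstall the package")
  if (Sys.which("python") == "") {
    stop("the 'highs' backend needs a python interpreter with scipy on the PATH")
  }
  fin <- tempfile(fileext = ".json"); fout <- tempfile(fileext = ".json")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  jsonlite::write_json(
    list(obj = as.numeric(obj), S = as.numeric(t(S)), m = nrow(S), n = ncol(S),
         lb = as.numeric(lb), ub = as.numeric(ub), maximize = maximize),
    fin, digits = NA, auto_unbox = TRUE)
  code <- system2("python", c(script, fin, fout), stdout = FALSE, stderr = FALSE)
  if (code != 0 || !file.exists(fout)) {
    stop("HiGHS backend failed (exit code ", code, ")")
  }
  res <- jsonlite::read_json(fout, simplifyVector = TRUE)
  if (res$status == "unbounded") {
    stop("linear program unbounded despite finite variable bounds")
  }
  if (res$status != "optimal") {
    return(list(status = "infeasible", objective = NA_real_,
                solution = rep(NA_real_, length(obj))))
  }
  list(status = "optimal", objective = res$objective,
       solution = as.numeric(res$solution))
}
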