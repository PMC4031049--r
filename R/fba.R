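#' Flux balance analysis
#'
#' Maximizes the biomass flux subject to the steady-state balance
#' \code{S v = 0} and the flux bounds of the model (a medium should have been
#' applied first). Plain FBA optima are usually degenerate: which fluxes the
#' solver reports for non-objective reactions depends on the vertex it lands
#' on. Because the plasticity/redundancy classification reads per-reaction
#' activity off the reference solution, the default mode
#' \code{"flux_minimized"} performs a secondary minimization of total
#' absolute flux at the fixed optimal biomass value (parsimonious FBA),
#' giving deterministic, backend-independent activity calls. Mode
#' \code{"raw"} returns the first-stage vertex unchanged.
#'
#' @param model a \code{metabolic_model} with its medium applied.
#' @param mode \code{"flux_minimized"} (default) or \code{"raw"}.
#' @param backend LP backend, see [lp_solve()].
#' @return object of class \code{flux_state}: list with \code{fluxes} (named
#'   numeric), \code{objective_value} (biomass flux), \code{status}
#'   (\code{"optimal"}/\code{"infeasible"}) and \code{mode}.
#' @export
fba <- function(model, mode = c("flux_minimized", "raw"),
                backend = c("primal", "highs")) {
  mode <- match.arg(mode)
  backend <- match.arg(backend)
  S <- stoich_matrix(model)
  rxn <- model$reactions
  obj <- as.numeric(rxn$is_biomass)
  res <- lp_solve(obj, S, rxn$lower_bound, rxn$upper_bound,
                  maximize = TRUE, backend = backend)
  if (res$status != "optimal") {
    return(structure(list(fluxes = stats::setNames(rep(NA_real_, nrow(rxn)), rxn$id),
                          objective_value = NA_real_, status = "infeasible",
                          mode = mode), class = "flux_state"))
  }
  nu <- res$objective
  fluxes <- stats::setNames(res$solution, rxn$id)
  if (mode == "flux_minimized") {
    fluxes <- minimize_total_flux(model, S, nu, backend)
  }
  structure(list(fluxes = fluxes, objective_value = nu, status = "optimal",
                 mode = mode), class = "flux_state")
}

# Secondary LP: fix biomass at nu*, minimize sum |v| via the split
# v = p - q with p, q >= 0. At the optimum p and q are never simultaneously
# positive, so v recovers exactly.
minimize_total_flux <- function(model, S, nu, backend) {
  rxn <- model$reactions
  n <- nrow(rxn)
  lb <- rxn$lower_bound
  ub <- rxn$upper_bound
  bm <- which(rxn$is_biomass)
  lb[bm] <- nu
  ub[bm] <- max(nu, ub[bm]) # guard: nu may exceed ub by solver tolerance
  lb[bm] <- min(lb[bm], ub[bm])
  p_lb <- pmax(lb, 0); p_ub <- pmax(ub, 0)
  q_lb <- pmax(-ub, 0); q_ub <- pmax(-lb, 0)
  S2 <- cbind(S, -S)
  obj <- rep(1, 2 * n)
  res <- lp_solve(obj, S2, c(p_lb, q_lb), c(p_ub, q_ub),
                  maximize = FALSE, backend = backend)
  if (res$status != "optimal") {
    stop("flux minimization infeasible at fixed biomass ", signif(nu, 6),
         "; solver tolerance issue")
  }
  v <- res$solution[seq_len(n)] - res$solution[n + seq_len(n)]
  stats::setNames(v, rxn$id)
}

#' @export
print.flux_state <- function(x, ...) {
  cat("<flux_state> status=", x$status, " mode=", x$mode,
      " biomass=", signif(x$objective_value, 6), "\n", sep = "")
  invisible(x)
}

#' Flux variability analysis
#'
#' For every reaction, minimizes and maximizes its flux subject to the
#' steady-state balance, the model bounds and a growth constraint
#' \code{v_biomass >= growth_fraction * nu*}, where \code{nu*} is the FBA
#' optimum. Two LPs per reaction.
#'
#' @param model a \code{metabolic_model} with medium applied.
#' @param growth_fraction number in [0, 1]; 0 leaves growth unconstrained
#'   (beyond nonnegativity).
#' @param reactions optional subset of reaction ids (default all).
#' @param backend LP backend.
#' @return object of class \code{flux_range}: data.frame with columns
#'   \code{reaction_id}, \code{min_flux}, \code{max_flux}; the growth
#'   constraint in force is recorded in \code{attr(, "constraint_note")}.
#' @export
fva <- function(model, growth_fraction = 1.0, reactions = NULL,
                backend = c("primal", "highs")) {
  backend <- match.arg(backend)
  stopifnot(growth_fraction >= 0, growth_fraction <= 1)
  wt <- fba(model, mode = "raw", backend = backend)
  if (wt$status != "optimal") stop("FVA: model infeasible, cannot fix growth")
  nu <- wt$objective_value
  floor_v <- growth_fraction * nu
  fva_at_floor(model, floor_v, reactions, backend,
               note = sprintf("v_biomass >= %.6g (%.3g of optimum %.6g)",
                              floor_v, growth_fraction, nu))
}

fva_at_floor <- function(model, floor_v, reactions, backend, note) {
  rxn <- model$reactions
  if (is.null(reactions)) reactions <- rxn$id
  miss <- setdiff(reactions, rxn$id)
  if (length(miss)) stop("FVA: unknown reaction id ", miss[1])
  S <- stoich_matrix(model)
  lb <- rxn$lower_bound
  ub <- rxn$upper_bound
  bm <- which(rxn$is_biomass)
  lb[bm] <- max(lb[bm], floor_v)
  if (lb[bm] > ub[bm]) stop("FVA: growth floor ", signif(floor_v, 6),
                            " exceeds the biomass upper bound")
  n <- nrow(rxn)
  mins <- maxs <- numeric(length(reactions))
  for (k in seq_along(reactions)) {
    j <- match(reactions[k], rxn$id)
    obj <- numeric(n); obj[j] <- 1
    lo <- lp_solve(obj, S, lb, ub, maximize = FALSE, backend = backend)
    hi <- lp_solve(obj, S, lb, ub, maximize = TRUE, backend = backend)
    if (lo$status != "optimal" || hi$status != "optimal") {
      stop("FVA infeasible at the requested growth constraint (", note, ")")
    }
    mins[k] <- lo$objective
    maxs[k] <- hi$objective
  }
  out <- data.frame(reaction_id = reactions, min_flux = mins, max_flux = maxs,
                    stringsAsFactors = FALSE)
  attr(out, "constraint_note") <- note
  class(out) <- c("flux_range", "data.frame")
  out
}

#' Biomass-unconstrained flux variability
#'
#' The conservative variant of FVA used to build the candidate space: flux
#' ranges are computed with only \code{v_biomass >= 0} imposed, so the result
#' captures every reaction that can carry flux in the medium at \emph{any}
#' nonnegative growth rate, not just at the optimum. A reaction is
#' "active-capable" iff its range extends beyond \code{flux_epsilon} on
#' either side. The active-capable set is a superset of the reactions active
#' in any maximum-growth solution.
#'
#' @param model a \code{metabolic_model} with medium applied.
#' @param reactions optional subset of reaction ids.
#' @param flux_epsilon zero-flux tolerance.
#' @param backend LP backend.
#' @return a \code{flux_range} with an extra logical column
#'   \code{active_capable}.
#' @export
unconstrained_growth_fva <- function(model, reactions = NULL, flux_epsilon = 1e-9,
                                     backend = c("primal", "highs")) {
  backend <- match.arg(backend)
  out <- fva_at_floor(model, 0, reactions, backend,
                      note = "v_biomass >= 0 (growth unconstrained)")
  out$active_capable <- abs(out$min_flux) > flux_epsilon |
    abs(out$max_flux) > flux_epsilon
  out
}

#' Viability call for an FBA solution
#'
#' A mutant is viable iff its FBA optimum is feasible and its growth exceeds
#' a small fraction of the wild-type growth. The threshold is relative so
#' that the call does not depend on the scale of the biomass equation.
#'
#' @param state a \code{flux_state}.
#' @param wild_type_growth wild-type biomass flux (> 0).
#' @param growth_epsilon relative no-growth threshold (default 1e-6).
#' @return logical.
#' @export
is_viable <- function(state, wild_type_growth, growth_epsilon = 1e-6) {
  stopifnot(inherits(state, "flux_state"), wild_type_growth > 0)
  state$status == "optimal" &&
    state$objective_value > growth_epsilon * wild_type_growth
}

#' Growth after deleting a set of reactions
#'
#' Convenience wrapper: knockout + raw FBA (growth values are independent of
#' the secondary flux minimization).
#'
#' @param model a \code{metabolic_model}.
#' @param rxns reaction ids to delete (possibly empty).
#' @param backend LP backend.
#' @return biomass flux (0 when infeasible).
#' @export
deletion_growth <- function(model, rxns = character(0),
                            backend = c("primal", "highs")) {
  backend <- match.arg(backend)
  st <- fba(knockout(model, rxns), mode = "raw", backend = backend)
  if (st$status != "optimal") 0 else st$objective_value
}

#' Serialize a flux state or flux range to TSV
#' @param x a \code{flux_state} or \code{flux_range}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_fluxes_tsv <- function(x, path) {
  d <- if (inherits(x, "flux_state")) {
    data.frame(reaction_id = names(x$fluxes), flux = unname(x$fluxes),
               stringsAsFactors = FALSE)
  } else {
    as.data.frame(x)
  }
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
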