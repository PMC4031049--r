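#' In-silico essential reactions
#'
#' A reaction is essential when zeroing both of its flux bounds (deleting
#' the forward and reverse direction together) abolishes growth below the
#' viability threshold.
#'
#' @param model a \code{metabolic_model} with medium applied and wild-type
#'   growth > 0.
#' @param reactions reaction ids to test (default all).
#' @param growth_epsilon relative no-growth threshold.
#' @param backend LP backend.
#' @return character vector of essential reaction ids.
#' @export
essential_reactions <- function(model, reactions = NULL, growth_epsilon = 1e-6,
                                backend = c("primal", "highs")) {
  backend <- match.arg(backend)
  if (is.null(reactions)) reactions <- model$reactions$id
  wt <- deletion_growth(model, backend = backend)
  if (wt <= 0) stop("wild-type growth is zero; apply a viable medium first")
  ess <- vapply(reactions, function(r) {
    g <- deletion_growth(model, r, backend = backend)
    g <= growth_epsilon * wt
  }, logical(1))
  sort(reactions[ess])
}

#' Candidate reactions for the synthetic-lethal pair screen
#'
#' The candidate space is the intersection of three filters:
#' \enumerate{
#'   \item gene-associated (a nonempty GPR; exchanges and the biomass
#'     pseudo-reaction are excluded), see [filter_gene_associated()];
#'   \item active-capable in the applied medium under biomass-unconstrained
#'     flux variability, see [unconstrained_growth_fva()] -- this captures
#'     reactions usable at any growth level, not only at the optimum;
#'   \item not essential as a single deletion.
#' }
#'
#' @param model a \code{metabolic_model} with medium applied.
#' @param flux_epsilon zero-flux tolerance for active-capability.
#' @param growth_epsilon relative no-growth threshold for essentiality.
#' @param backend LP backend.
#' @return object of class \code{candidate_set}: character vector of
#'   reaction ids (sorted), with a \code{provenance} attribute -- a
#'   data.frame recording for every reaction which filters it passed.
#' @export
candidate_reactions <- function(model, flux_epsilon = 1e-9, growth_epsilon = 1e-6,
                                backend = c("primal", "highs")) {
  backend <- match.arg(backend)
  fg <- filter_gene_associated(model)
  gene_assoc <- fg$model$reactions$gene_associated
  ids <- model$reactions$id
  ranges <- unconstrained_growth_fva(model, flux_epsilon = flux_epsilon,
                                     backend = backend)
  active <- ranges$active_capable[match(ids, ranges$reaction_id)]
  # essentiality only needs testing where the other two filters pass
  test <- ids[gene_assoc & active]
  ess <- if (length(test)) {
    essential_reactions(model, test, growth_epsilon, backend)
  } else character(0)
  nonessential <- !(ids %in% ess)
  keep <- gene_assoc & active & nonessential
  prov <- data.frame(reaction_id = ids, gene_associated = gene_assoc,
                     active_capable = active,
                     nonessential = ifelse(ids %in% test, nonessential, NA),
                     candidate = keep, stringsAsFactors = FALSE)
  out <- sort(ids[keep])
  if (length(out) == 0L) {
    warning("candidate set is empty; the pair screen will return no pairs")
  }
  structure(out, provenance = prov, class = c("candidate_set", "character"))
}

#' Exhaustive double-deletion screen
#'
#' Runs one FBA per unordered pair of candidate reactions with both
#' reactions' bounds zeroed. Pair order is deterministic (lexicographic), so
#' outputs are reproducible. Solver failures on individual pairs are
#' recorded (\code{failed = TRUE}) and the screen continues.
#'
#' @param model a \code{metabolic_model} with medium applied.
#' @param candidates character vector of candidate reaction ids (length >= 2),
#'   typically from [candidate_reactions()].
#' @param growth_epsilon relative no-growth threshold.
#' @param backend LP backend.
#' @return data.frame with one row per unordered pair: \code{rxn_a},
#'   \code{rxn_b} (a < b), \code{growth}, \code{viable}, \code{failed};
#'   wild-type growth in \code{attr(, "wild_type_growth")}.
#' @export
double_deletion_screen <- function(model, candidates, growth_epsilon = 1e-6,
                                   backend = c("primal", "highs")) {
  backend <- match.arg(backend)
  candidates <- sort(unique(as.character(candidates)))
  if (length(candidates) < 2L) {
    stop("need at least two candidate reactions to form pairs")
  }
  miss <- setdiff(candidates, model$reactions$id)
  if (length(miss)) stop("unknown candidate reaction: ", miss[1])
  wt <- deletion_growth(model, backend = backend)
  if (wt <= 0) stop("wild-type growth is zero; apply a viable medium first")
  # defensive: candidates must be individually nonessential
  for (r in candidates) {
    if (deletion_growth(model, r, backend = backend) <= growth_epsilon * wt) {
      stop("candidate ", r, " is essential as a single deletion; ",
           "build candidates with candidate_reactions()")
    }
  }
  combs <- utils::combn(candidates, 2L)
  n <- ncol(combs)
  growth <- rep(NA_real_, n)
  failed <- logical(n)
  for (k in seq_len(n)) {
    g <- tryCatch(deletion_growth(model, combs[, k], backend = backend),
                  error = function(e) NA_real_)
    if (is.na(g)) failed[k] <- TRUE else growth[k] <- g
  }
  out <- data.frame(rxn_a = combs[1, ], rxn_b = combs[2, ], growth = growth,
                    viable = !failed & growth > growth_epsilon * wt,
                    failed = failed, stringsAsFactors = FALSE)
  if (any(failed)) {
    warning(sum(failed), " pair(s) failed in the LP backend; see 'failed' column")
  }
  attr(out, "wild_type_growth") <- wt
  attr(out, "growth_epsilon") <- growth_epsilon
  out
}

#' Synthetic lethal pairs from screen results
#'
#' The inviable pairs of an exhaustive double-deletion screen: both members
#' are individually nonessential (by construction of the candidate set), yet
#' their simultaneous deletion shows a no-growth phenotype.
#'
#' @param results data.frame from [double_deletion_screen()].
#' @return data.frame with columns \code{rxn_a}, \code{rxn_b},
#'   \code{growth}; zero rows when the screen found none.
#' @export
synthetic_lethal_pairs <- function(results) {
  stopifnot(all(c("rxn_a", "rxn_b", "viable") %in% names(results)))
  out <- results[!results$viable & !results$failed,
                 c("rxn_a", "rxn_b", "growth"), drop = FALSE]
  rownames(out) <- NULL
  attr(out, "wild_type_growth") <- attr(results, "wild_type_growth")
  out
}
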