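#' Classify synthetic lethal pairs into plasticity and redundancy subtypes
#'
#' A synthetic lethal pair is \strong{PSL} (plasticity) when exactly one of
#' its members carries flux in the reference solution: the silent member is
#' a backup that switches on only when its active partner is removed. It is
#' \strong{RSL} (redundancy) when both members carry flux in parallel. The
#' activity calls are read off the reference FBA solution, which should be
#' computed in \code{flux_minimized} mode so they do not depend on which
#' degenerate optimum the solver returned. A pair with both members at zero
#' flux contradicts its candidacy (both are active-capable) and raises an
#' error prompting a mode review -- this can happen under \code{raw} mode.
#'
#' For every pair the single-knockout growths of both members are recorded,
#' and for RSL pairs the fitness comparison is stored: \code{fitness_increased}
#' is \code{TRUE} when wild-type growth strictly exceeds the best
#' single-knockout growth, i.e. the parallel use of both reactions buys
#' extra fitness.
#'
#' @param pairs data.frame with columns \code{rxn_a}, \code{rxn_b}
#'   (from [synthetic_lethal_pairs()]).
#' @param model the \code{metabolic_model} the screen ran on (medium applied).
#' @param wt reference \code{flux_state}; computed with
#'   \code{fba(model, "flux_minimized")} when omitted.
#' @param flux_epsilon zero-flux tolerance.
#' @param tol strict-inequality tolerance for the fitness comparison.
#' @param backend LP backend.
#' @return data.frame of class \code{sl_pairs}, one row per pair:
#'   \code{rxn_a}, \code{rxn_b}, \code{subtype} ("PSL"/"RSL"),
#'   \code{active_reaction}, \code{backup_reaction} (NA for RSL),
#'   \code{wt_flux_a}, \code{wt_flux_b}, \code{growth_wt},
#'   \code{growth_ko_a}, \code{growth_ko_b}, \code{fitness_increased}
#'   (NA for PSL), \code{genes_a}, \code{genes_b}, \code{pathway_a},
#'   \code{pathway_b}.
#' @export
classify_pairs <- function(pairs, model, wt = NULL, flux_epsilon = 1e-9,
                           tol = 1e-9, backend = c("primal", "highs")) {
  backend <- match.arg(backend)
  stopifnot(all(c("rxn_a", "rxn_b") %in% names(pairs)))
  if (is.null(wt)) wt <- fba(model, mode = "flux_minimized", backend = backend)
  if (wt$status != "optimal") stop("reference FBA solution is infeasible")
  rxn <- model$reactions
  n <- nrow(pairs)
  if (n == 0L) {
    out <- data.frame(
      rxn_a = character(0), rxn_b = character(0), subtype = character(0),
      active_reaction = character(0), backup_reaction = character(0),
      wt_flux_a = numeric(0), wt_flux_b = numeric(0), growth_wt = numeric(0),
      growth_ko_a = numeric(0), growth_ko_b = numeric(0),
      fitness_increased = logical(0), genes_a = character(0),
      genes_b = character(0), pathway_a = character(0),
      pathway_b = character(0), stringsAsFactors = FALSE)
    class(out) <- c("sl_pairs", "data.frame")
    attr(out, "mode") <- wt$mode
    return(out)
  }
  out <- data.frame(
    rxn_a = pairs$rxn_a, rxn_b = pairs$rxn_b,
    subtype = character(n), active_reaction = NA_character_,
    backup_reaction = NA_character_, wt_flux_a = NA_real_, wt_flux_b = NA_real_,
    growth_wt = wt$objective_value, growth_ko_a = NA_real_, growth_ko_b = NA_real_,
    fitness_increased = NA, genes_a = NA_character_, genes_b = NA_character_,
    pathway_a = NA_character_, pathway_b = NA_character_,
    stringsAsFactors = FALSE
  )
  for (k in seq_len(n)) {
    a <- pairs$rxn_a[k]; b <- pairs$rxn_b[k]
    fa <- wt$fluxes[[a]]; fb <- wt$fluxes[[b]]
    za <- abs(fa) <= flux_epsilon; zb <- abs(fb) <= flux_epsilon
    if (za && zb) {
      stop("pair {", a, ", ", b, "}: both members at zero flux in the ",
           "reference solution; reclassify under flux_minimized mode")
    }
    out$wt_flux_a[k] <- fa; out$wt_flux_b[k] <- fb
    if (za || zb) {
      out$subtype[k] <- "PSL"
      out$active_reaction[k] <- if (za) b else a
      out$backup_reaction[k] <- if (za) a else b
    } else {
      out$subtype[k] <- "RSL"
    }
    out$growth_ko_a[k] <- deletion_growth(model, a, backend = backend)
    out$growth_ko_b[k] <- deletion_growth(model, b, backend = backend)
    if (out$subtype[k] == "RSL") {
      out$fitness_increased[k] <-
        out$growth_wt[k] > max(out$growth_ko_a[k], out$growth_ko_b[k]) + tol
    }
    ia <- match(a, rxn$id); ib <- match(b, rxn$id)
    out$genes_a[k] <- rxn$gpr[ia]; out$genes_b[k] <- rxn$gpr[ib]
    out$pathway_a[k] <- rxn$subsystem[ia]; out$pathway_b[k] <- rxn$subsystem[ib]
  }
  class(out) <- c("sl_pairs", "data.frame")
  attr(out, "mode") <- wt$mode
  out
}

#' Verify the backup law of a plasticity pair
#'
#' For a PSL pair: deleting the active member must yield a viable optimum in
#' which the backup carries flux (it "turns on"), generally at lowered
#' growth; deleting the backup must leave growth at the wild-type level,
#' since the backup carried no flux to begin with.
#'
#' @param pair one-row slice of a classified \code{sl_pairs} table with
#'   subtype \code{"PSL"}.
#' @param model the model the pair was classified on.
#' @param flux_epsilon zero-flux tolerance.
#' @param backend LP backend.
#' @return list with \code{backup_flux_after_ko}, \code{growth_after_ko}
#'   (active member deleted) and \code{growth_after_backup_ko}.
#' @export
backup_activation_check <- function(pair, model, flux_epsilon = 1e-9,
                                    backend = c("primal", "highs")) {
  backend <- match.arg(backend)
  if (!pair$subtype[1] %in% c("PSL", "PSL_I")) {
    stop("backup_activation_check applies to plasticity (PSL) pairs only")
  }
  act <- pair$active_reaction[1]; bak <- pair$backup_reaction[1]
  st <- fba(knockout(model, act), mode = "flux_minimized", backend = backend)
  if (st$status != "optimal") {
    stop("deletion of the active member is infeasible; not a true PSL pair")
  }
  bf <- st$fluxes[[bak]]
  if (abs(bf) <= flux_epsilon && st$objective_value > 0) {
    stop("backup ", bak, " did not activate after deleting ", act,
         "; invariant violation")
  }
  list(backup_flux_after_ko = bf,
       growth_after_ko = st$objective_value,
       growth_after_backup_ko = deletion_growth(model, bak, backend = backend))
}

#' Fitness comparison for a redundancy pair
#'
#' \code{TRUE} iff the simultaneous use of both reactions increases fitness
#' (maximal biomass production) compared to either reaction operating alone,
#' i.e. wild-type growth strictly exceeds both single-knockout growths.
#'
#' @param pair one-row slice of a classified \code{sl_pairs} table with
#'   subtype \code{"RSL"}.
#' @param tol strict-inequality tolerance.
#' @return logical; \code{NA} (not applicable) for PSL pairs.
#' @export
fitness_comparison <- function(pair, tol = 1e-9) {
  if (!pair$subtype[1] %in% c("RSL", "RSL_I")) return(NA)
  pair$growth_wt[1] > max(pair$growth_ko_a[1], pair$growth_ko_b[1]) + tol
}

#' Flag inconsistencies against experimental gene essentiality
#'
#' A computationally predicted synthetic lethal pair contradicts experiment
#' when one of its members is governed by a gene reported essential in vivo:
#' both members must be individually dispensable for the pair to make sense.
#' The rules:
#' \enumerate{
#'   \item both members' genes nonessential: the subtype stands;
#'   \item one member carries an experimentally essential gene: the pair is
#'     inconsistent iff that gene regulates only this one reaction (if it
#'     regulates several, the essentiality may refer to the others);
#'   \item both members carry essential genes: consistent only when every
#'     such gene regulates more than one reaction.
#' }
#' Additionally, PSL pairs whose members are associated through isoenzymes
#' or through a single multifunctional enzyme are flagged inconsistent:
#' a single enzyme (or isoenzyme family) behind both reactions means the
#' reaction-level double knockout does not correspond to a double gene
#' knockout. Detection is heuristic (identical single-gene GPRs =
#' multifunctional; identical OR-only gene families of size >= 2 =
#' isoenzymes) with an explicit list as the faithful fallback.
#'
#' @param pairs classified \code{sl_pairs} table.
#' @param ann an [essentiality_annotation()].
#' @param model the model (for the gene-to-reaction map).
#' @param isoenzyme_pairs optional data.frame with columns \code{rxn_a},
#'   \code{rxn_b}: pairs to flag as isoenzyme/multifunctional inconsistencies
#'   regardless of the heuristic.
#' @return the \code{sl_pairs} table with subtypes possibly promoted to
#'   \code{"PSL_I"}/\code{"RSL_I"} and a logical column
#'   \code{enzyme_inconsistency} marking the isoenzyme/multifunctional rule.
#' @export
flag_inconsistencies <- function(pairs, ann, model, isoenzyme_pairs = NULL) {
  stopifnot(inherits(pairs, "sl_pairs"), inherits(ann, "essentiality_annotation"))
  gene2rxn <- gene_reaction_map(model)
  excused <- function(g) length(gene2rxn[[g]]) > 1L
  pairs$enzyme_inconsistency <- FALSE
  for (k in seq_len(nrow(pairs))) {
    a <- pairs$rxn_a[k]; b <- pairs$rxn_b[k]
    ga <- model$gpr[[a]]$genes; gb <- model$gpr[[b]]$genes
    ess_a <- ga[is_gene_essential(ann, ga)]
    ess_b <- gb[is_gene_essential(ann, gb)]
    inconsistent <- FALSE
    all_ess <- c(ess_a, ess_b)
    if (length(all_ess)) {
      # cases 2 and 3 share one criterion: every essential gene involved must
      # be excusable by regulating more than one reaction
      inconsistent <- !all(vapply(unique(all_ess), excused, logical(1)))
    }
    base <- sub("_I$", "", pairs$subtype[k])
    if (base == "PSL") {
      enz <- enzyme_association(model, a, b)
      if (!is.null(isoenzyme_pairs) && nrow(isoenzyme_pairs)) {
        listed <- any((isoenzyme_pairs$rxn_a == a & isoenzyme_pairs$rxn_b == b) |
                      (isoenzyme_pairs$rxn_a == b & isoenzyme_pairs$rxn_b == a))
        enz <- enz || listed
      }
      if (enz) {
        pairs$enzyme_inconsistency[k] <- TRUE
        inconsistent <- TRUE
      }
    }
    pairs$subtype[k] <- if (inconsistent) paste0(base, "_I") else base
  }
  pairs
}

# map gene id -> reaction ids whose GPR mentions it
gene_reaction_map <- function(model) {
  m <- list()
  for (r in model$reactions$id) {
    for (g in model$gpr[[r]]$genes) m[[g]] <- c(m[[g]], r)
  }
  m
}

# isoenzyme / multifunctional-enzyme association between two reactions:
# identical single-gene GPRs (one enzyme catalyzing both reactions) or
# identical OR-only families of >= 2 genes (shared isoenzyme family).
enzyme_association <- function(model, a, b) {
  ga <- model$gpr[[a]]; gb <- model$gpr[[b]]
  if (is.null(ga$expression) || is.null(gb$expression)) return(FALSE)
  if (!identical(ga$genes, gb$genes)) return(FALSE)
  if (length(ga$genes) == 1L) return(TRUE) # multifunctional enzyme
  gpr_is_or_only(ga) && gpr_is_or_only(gb) # isoenzyme family
}

#' Reaction and gene-unit counts per subtype
#'
#' Counts, for each subtype present, the distinct reactions participating in
#' its pairs and the distinct gene units controlling them, where a gene unit
#' is a maximal AND-subtree of a GPR (an enzyme complex counts once,
#' OR-alternatives count separately), see [gpr_units()].
#'
#' @param pairs classified \code{sl_pairs} table.
#' @param model the model.
#' @return data.frame with columns \code{subtype}, \code{n_pairs},
#'   \code{n_reactions}, \code{n_gene_units}.
#' @export
count_genes_and_complexes <- function(pairs, model) {
  subtypes <- sort(unique(pairs$subtype))
  do.call(rbind, lapply(subtypes, function(s) {
    p <- pairs[pairs$subtype == s, ]
    rxns <- unique(c(p$rxn_a, p$rxn_b))
    units <- unique(unlist(lapply(rxns, function(r) gpr_units(model$gpr[[r]]))))
    data.frame(subtype = s, n_pairs = nrow(p), n_reactions = length(rxns),
               n_gene_units = length(units), stringsAsFactors = FALSE)
  }))
}

#' Export a classified pair table to TSV
#' @param pairs classified \code{sl_pairs} table.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_pairs_tsv <- function(pairs, path) {
  utils::write.table(as.data.frame(pairs), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
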