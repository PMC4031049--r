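#' Build a panel of minimal media
#'
#' A minimal medium is an invariant set of mineral salts plus one source
#' compound for each of the four basic elements (C, N, P, S). The panel is
#' built by varying the source of one element at a time over its candidate
#' compounds while the other three stay at the reference choice; the
#' reference medium itself is included. Media in which the model cannot grow
#' are filtered out by FBA but kept in the construction log.
#'
#' @param salts a \code{\link{medium}} fragment with the invariant salt
#'   uptake bounds.
#' @param sources named list (\code{C}, \code{N}, \code{P}, \code{S}) of
#'   character vectors of candidate exchange reaction ids.
#' @param reference named character vector giving the reference exchange id
#'   per element (e.g. glucose, ammonium, phosphate, sulfate).
#' @param model the \code{metabolic_model} used for viability filtering.
#' @param uptake_bound uptake lower bound for source compounds (default -10).
#' @param growth_epsilon relative viability threshold (vs the reference
#'   medium's growth).
#' @param backend LP backend.
#' @return list of class \code{media_panel}: \code{media} (named list of
#'   viable media, reference first), \code{log} (data.frame with one row per
#'   constructed medium: \code{medium_label}, \code{varied_element},
#'   \code{compound}, \code{growth}, \code{viable}) and \code{reference}
#'   (label of the reference medium).
#' @export
build_minimal_media_panel <- function(salts, sources, reference, model,
                                      uptake_bound = -10, growth_epsilon = 1e-6,
                                      backend = c("primal", "highs")) {
  backend <- match.arg(backend)
  stopifnot(inherits(salts, "medium"))
  elements <- names(sources)
  stopifnot(all(names(reference) %in% elements))
  compose <- function(choice, label) {
    ub <- c(salts$uptake_bounds,
            stats::setNames(rep(uptake_bound, length(choice)), unname(choice)))
    medium(ub[!duplicated(names(ub))], label = label)
  }
  ref_medium <- compose(reference, "reference")
  ref_growth <- panel_growth(model, ref_medium, backend)
  if (ref_growth <= 0) stop("reference medium is inviable; check its composition")
  media <- list(reference = ref_medium)
  log <- data.frame(medium_label = "reference", varied_element = "none",
                    compound = NA_character_, growth = ref_growth, viable = TRUE,
                    stringsAsFactors = FALSE)
  for (el in elements) {
    for (cmp in setdiff(sources[[el]], reference[[el]])) {
      choice <- reference
      choice[[el]] <- cmp
      lab <- paste0(el, ":", cmp)
      m <- compose(choice, lab)
      g <- if (cmp %in% exchange_ids(model)) panel_growth(model, m, backend) else 0
      ok <- g > growth_epsilon * ref_growth
      log <- rbind(log, data.frame(medium_label = lab, varied_element = el,
                                   compound = cmp, growth = g, viable = ok,
                                   stringsAsFactors = FALSE))
      if (ok) media[[lab]] <- m
    }
  }
  structure(list(media = media, log = log, reference = "reference"),
            class = "media_panel")
}

panel_growth <- function(model, m, backend) {
  st <- tryCatch(fba(apply_medium(model, m), mode = "raw", backend = backend),
                 error = function(e) NULL)
  if (is.null(st) || st$status != "optimal") 0 else st$objective_value
}

#' @export
print.media_panel <- function(x, ...) {
  cat("<media_panel> ", nrow(x$log), " constructed, ", length(x$media),
      " viable (reference: ", x$reference, ")\n", sep = "")
  invisible(x)
}

#' Enrich a medium with additional compounds
#'
#' Adds uptake of the listed exchange reactions at \code{uptake_bound}
#' while preserving the base medium. Compounds without a matching exchange
#' reaction in the model are skipped with a warning (some compounds of a
#' published recipe simply cannot be taken up by a given reconstruction).
#'
#' @param base a \code{medium}.
#' @param compounds character vector of exchange reaction ids.
#' @param uptake_bound lower bound for the added exchanges (default -10
#'   mmol/(gDW h)).
#' @param model optional \code{metabolic_model}; when given, unknown
#'   exchanges are detected against it.
#' @param label label of the enriched medium.
#' @return a new \code{medium}; skipped compounds in
#'   \code{attr(, "skipped")}.
#' @export
enrich_medium <- function(base, compounds, uptake_bound = -10, model = NULL,
                          label = paste0(base$label, "+enriched")) {
  stopifnot(inherits(base, "medium"))
  skipped <- character(0)
  if (!is.null(model)) {
    known <- compounds %in% exchange_ids(model)
    skipped <- compounds[!known]
    for (s in skipped) {
      warning("compound ", s, " has no exchange reaction in the model; skipped")
    }
    compounds <- compounds[known]
  }
  ub <- base$uptake_bounds
  for (cmp in compounds) {
    # never tighten an uptake allowance the base medium already grants
    ub[[cmp]] <- if (cmp %in% names(base$uptake_bounds)) {
      min(base$uptake_bounds[[cmp]], uptake_bound)
    } else uptake_bound
  }
  out <- medium(ub, label = label)
  attr(out, "skipped") <- skipped
  out
}

#' Overconstrain a medium to lower maximal growth
#'
#' Two ways of relaxing the growth-maximization requirement by tightening
#' uptake bounds, both driven by flux variability analysis:
#' \describe{
#'   \item{\code{mineral_salts}}{fix biomass at \code{fraction} of its
#'     maximum, read off each salt exchange's maximal uptake (the most
#'     negative flux it can carry at that growth), and set those as the new
#'     salt bounds; all other compounds keep their reference bounds.}
#'   \item{\code{basic_sources}}{run FVA at maximal growth to find the upper
#'     uptake limit of each element-source exchange, scale those limits to
#'     \code{fraction}, and keep the salts at reference.}
#' }
#'
#' @param model a \code{metabolic_model}.
#' @param reference the reference \code{medium}.
#' @param fraction number in (0, 1]; growth (or uptake) scale factor.
#' @param target \code{"mineral_salts"} or \code{"basic_sources"}.
#' @param salts character vector of the salt exchange ids (for
#'   \code{mineral_salts}) or the four source exchange ids (for
#'   \code{basic_sources}).
#' @param backend LP backend.
#' @return the overconstrained \code{medium}.
#' @export
overconstrain_by_growth <- function(model, reference, fraction,
                                    target = c("mineral_salts", "basic_sources"),
                                    salts, backend = c("primal", "highs")) {
  target <- match.arg(target)
  backend <- match.arg(backend)
  stopifnot(fraction > 0, fraction <= 1)
  m <- apply_medium(model, reference)
  wt <- fba(m, mode = "raw", backend = backend)
  if (wt$status != "optimal" || wt$objective_value <= 0) {
    stop("reference medium is inviable; cannot overconstrain")
  }
  miss <- setdiff(salts, exchange_ids(model))
  if (length(miss)) stop("not an exchange reaction of the model: ", miss[1])
  ub <- reference$uptake_bounds
  if (target == "mineral_salts") {
    # biomass is *fixed* at fraction * nu (not merely floored): the question
    # is which uptakes the reduced growth still requires
    m2 <- m
    bm <- which(m2$reactions$is_biomass)
    nu <- fraction * wt$objective_value
    m2$reactions$lower_bound[bm] <- nu
    m2$reactions$upper_bound[bm] <- nu
    rng <- fva_at_floor(m2, nu, salts, backend,
                        note = sprintf("v_biomass = %.6g", nu))
    new_lb <- rng$min_flux # maximal uptake at the reduced growth
  } else {
    rng <- fva(m, growth_fraction = 1, reactions = salts, backend = backend)
    new_lb <- fraction * rng$min_flux
  }
  ub[salts] <- pmin(new_lb, 0)
  medium(ub, label = sprintf("%s|%s@%.2g", reference$label, target, fraction))
}

#' Sensitivity of synthetic lethal pairs to medium composition
#'
#' Re-tests every pair of the reference screen in every medium of a panel:
#' the double knockout is re-run (lethality may be medium-specific), and in
#' media where the pair stays lethal the subtype is re-read off that
#' medium's reference solution, computed in the same FBA mode as the
#' original screen so that subtype switches reflect the medium and not
#' solver drift. Media in which a member reaction is itself blocked or the
#' solver fails are excluded from the pair's denominator.
#'
#' @param model the \code{metabolic_model} (no medium applied, or any; each
#'   panel medium is applied in turn).
#' @param pairs classified \code{sl_pairs} table from the reference medium.
#' @param panel a \code{media_panel} (or plain list of media).
#' @param flux_epsilon zero-flux tolerance for subtype calls.
#' @param growth_epsilon relative no-growth threshold.
#' @param backend LP backend.
#' @return data.frame of class \code{sensitivity_profile}: per pair,
#'   \code{n_media_tested}, \code{n_media_lethal}, \code{n_media_psl},
#'   \code{fraction_lethal}, \code{fraction_psl} (PSL fraction among lethal
#'   media; NA when never lethal), ordered by decreasing
#'   \code{fraction_lethal}; the per-medium calls are attached as
#'   \code{attr(, "calls")}.
#' @export
media_sensitivity <- function(model, pairs, panel, flux_epsilon = 1e-9,
                              growth_epsilon = 1e-6,
                              backend = c("primal", "highs")) {
  backend <- match.arg(backend)
  media <- if (inherits(panel, "media_panel")) panel$media else panel
  calls <- list()
  for (lab in names(media)) {
    mm <- apply_medium(model, media[[lab]])
    wt <- tryCatch(fba(mm, mode = "flux_minimized", backend = backend),
                   error = function(e) NULL)
    ok_medium <- !is.null(wt) && wt$status == "optimal" && wt$objective_value > 0
    for (k in seq_len(nrow(pairs))) {
      a <- pairs$rxn_a[k]; b <- pairs$rxn_b[k]
      if (!ok_medium) {
        calls[[length(calls) + 1L]] <- data.frame(
          rxn_a = a, rxn_b = b, medium = lab, tested = FALSE, lethal = NA,
          subtype = NA_character_, stringsAsFactors = FALSE)
        next
      }
      g2 <- tryCatch(deletion_growth(mm, c(a, b), backend = backend),
                     error = function(e) NA_real_)
      if (is.na(g2)) {
        calls[[length(calls) + 1L]] <- data.frame(
          rxn_a = a, rxn_b = b, medium = lab, tested = FALSE, lethal = NA,
          subtype = NA_character_, stringsAsFactors = FALSE)
        next
      }
      lethal <- g2 <= growth_epsilon * wt$objective_value
      subtype <- NA_character_
      if (lethal) {
        za <- abs(wt$fluxes[[a]]) <= flux_epsilon
        zb <- abs(wt$fluxes[[b]]) <= flux_epsilon
        subtype <- if (xor(za, zb)) "PSL" else if (!za && !zb) "RSL" else "blocked"
      }
      calls[[length(calls) + 1L]] <- data.frame(
        rxn_a = a, rxn_b = b, medium = lab, tested = TRUE, lethal = lethal,
        subtype = subtype, stringsAsFactors = FALSE)
    }
  }
  calls <- do.call(rbind, calls)
  prof <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(k) {
    cc <- calls[calls$rxn_a == pairs$rxn_a[k] & calls$rxn_b == pairs$rxn_b[k] &
                calls$tested, ]
    nl <- sum(cc$lethal)
    np <- sum(cc$lethal & cc$subtype == "PSL", na.rm = TRUE)
    data.frame(rxn_a = pairs$rxn_a[k], rxn_b = pairs$rxn_b[k],
               n_media_tested = nrow(cc), n_media_lethal = nl, n_media_psl = np,
               fraction_lethal = if (nrow(cc)) nl / nrow(cc) else NA_real_,
               fraction_psl = if (nl) np / nl else NA_real_,
               stringsAsFactors = FALSE)
  }))
  prof <- prof[order(-prof$fraction_lethal, prof$rxn_a, prof$rxn_b), ]
  rownames(prof) <- NULL
  attr(prof, "calls") <- calls
  class(prof) <- c("sensitivity_profile", "data.frame")
  prof
}

#' Compare synthetic lethal pair sets between two conditions
#'
#' Partitions the reference pairs into \code{conserved} (lethal in both
#' conditions) and \code{rescued} (lethal in the reference only), and the
#' alternative-only pairs into \code{novel}. Among conserved pairs it
#' detects subtype switches (PSL <-> RSL, on the base subtype, ignoring
#' inconsistency flags) and, for pairs that are PSL in both conditions,
#' active/backup role swaps.
#'
#' @param reference,alternative classified \code{sl_pairs} tables over the
#'   same model under two conditions.
#' @return list of class \code{pair_set_comparison} with elements
#'   \code{conserved}, \code{rescued}, \code{novel} (data.frames of pairs),
#'   \code{subtype_switches} (with \code{direction}) and
#'   \code{activity_switches}.
#' @export
compare_pair_sets <- function(reference, alternative) {
  key <- function(p) paste(pmin(p$rxn_a, p$rxn_b), pmax(p$rxn_a, p$rxn_b))
  kr <- key(reference); ka <- key(alternative)
  conserved <- reference[kr %in% ka, , drop = FALSE]
  rescued <- reference[!(kr %in% ka), , drop = FALSE]
  novel <- alternative[!(ka %in% kr), , drop = FALSE]
  base <- function(x) sub("_I$", "", x)
  switches <- list(); act_sw <- list()
  for (k in seq_len(nrow(conserved))) {
    i <- match(key(conserved[k, ]), ka)
    s_ref <- base(conserved$subtype[k]); s_alt <- base(alternative$subtype[i])
    if (s_ref != s_alt) {
      switches[[length(switches) + 1L]] <- data.frame(
        rxn_a = conserved$rxn_a[k], rxn_b = conserved$rxn_b[k],
        direction = paste0(s_ref, "->", s_alt), stringsAsFactors = FALSE)
    } else if (s_ref == "PSL" &&
               !identical(conserved$active_reaction[k],
                          alternative$active_reaction[i])) {
      act_sw[[length(act_sw) + 1L]] <- data.frame(
        rxn_a = conserved$rxn_a[k], rxn_b = conserved$rxn_b[k],
        active_reference = conserved$active_reaction[k],
        active_alternative = alternative$active_reaction[i],
        stringsAsFactors = FALSE)
    }
  }
  empty_sw <- data.frame(rxn_a = character(0), rxn_b = character(0),
                         direction = character(0), stringsAsFactors = FALSE)
  empty_act <- data.frame(rxn_a = character(0), rxn_b = character(0),
                          active_reference = character(0),
                          active_alternative = character(0),
                          stringsAsFactors = FALSE)
  structure(list(
    conserved = conserved, rescued = rescued, novel = novel,
    subtype_switches = if (length(switches)) do.call(rbind, switches) else empty_sw,
    activity_switches = if (length(act_sw)) do.call(rbind, act_sw) else empty_act
  ), class = "pair_set_comparison")
}

#' @export
print.pair_set_comparison <- function(x, ...) {
  cat("<pair_set_comparison> conserved=", nrow(x$conserved),
      " rescued=", nrow(x$rescued), " novel=", nrow(x$novel),
      " subtype_switches=", nrow(x$subtype_switches),
      " activity_switches=", nrow(x$activity_switches), "\n", sep = "")
  invisible(x)
}
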