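#' Run the full synthetic-lethality analysis and write a report bundle
#'
#' End-to-end orchestration: candidate-space construction, exhaustive
#' double-deletion screen, plasticity/redundancy classification (with
#' optional inconsistency flagging), network distances, pathway
#' entanglement, and -- when a media panel or an alternative medium is
#' supplied -- media sensitivity and pair-set comparison. All tables are
#' written as TSV with stable lexicographic ordering; the entanglement graph
#' is additionally exported as GraphML; a JSON run summary holds the
#' four-class histogram counts and the settings used.
#'
#' @param model a \code{metabolic_model}.
#' @param medium reference \code{medium} to apply.
#' @param out_dir output directory (created).
#' @param mode FBA mode for the reference solution, see [fba()].
#' @param essentiality optional [essentiality_annotation()] for
#'   inconsistency flagging.
#' @param panel optional \code{media_panel} (or named list of media) for the
#'   sensitivity stage.
#' @param alternative optional second \code{medium}; the screen is repeated
#'   there and compared with the reference via [compare_pair_sets()].
#' @param flux_epsilon,growth_epsilon tolerances, see [candidate_reactions()].
#' @param backend LP backend.
#' @return (invisibly) list with every intermediate result: \code{wild_type},
#'   \code{candidates}, \code{screen}, \code{pairs}, \code{distances},
#'   \code{entanglement}, \code{sensitivity}, \code{comparison},
#'   \code{summary}.
#' @export
run_full_analysis <- function(model, medium, out_dir,
                              mode = c("flux_minimized", "raw"),
                              essentiality = NULL, panel = NULL,
                              alternative = NULL,
                              flux_epsilon = 1e-9, growth_epsilon = 1e-6,
                              backend = c("primal", "highs")) {
  mode <- match.arg(mode)
  backend <- match.arg(backend)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- proc.time()[["elapsed"]]
  stage <- list()
  tick <- function(name, t_prev) {
    stage[[name]] <<- round(proc.time()[["elapsed"]] - t_prev, 3)
    proc.time()[["elapsed"]]
  }

  m <- apply_medium(model, medium)
  wt <- fba(m, mode = mode, backend = backend)
  if (wt$status != "optimal" || wt$objective_value <= 0) {
    stop("model is inviable in medium '", medium$label, "'")
  }
  t1 <- tick("wild_type", t0)

  cand <- candidate_reactions(m, flux_epsilon, growth_epsilon, backend)
  utils::write.table(attr(cand, "provenance"),
                     file.path(out_dir, "candidates.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  t2 <- tick("candidates", t1)

  classified <- screen_and_classify(m, cand, wt, essentiality,
                                    flux_epsilon, growth_epsilon, backend)
  screen <- attr(classified, "screen")
  utils::write.table(screen, file.path(out_dir, "screen.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_pairs_tsv(classified, file.path(out_dir, "sl_pairs.tsv"))
  t3 <- tick("screen_classify", t2)

  graph <- build_bipartite_graph(m)
  dist <- mean_pair_distance(classified, graph)
  utils::write.table(attr(dist, "distances"),
                     file.path(out_dir, "distances.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  ent <- entanglement_graph(classified)
  write_entanglement(ent, file.path(out_dir, "entanglement.tsv"))
  if (nrow(ent$edges)) {
    write_entanglement(ent, file.path(out_dir, "entanglement.graphml"))
  }
  t4 <- tick("topology", t3)

  sens <- NULL
  if (!is.null(panel)) {
    sens <- media_sensitivity(model, classified, panel, flux_epsilon,
                              growth_epsilon, backend)
    utils::write.table(as.data.frame(sens),
                       file.path(out_dir, "sensitivity.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    t4 <- tick("sensitivity", t4)
  }
  comparison <- NULL
  if (!is.null(alternative)) {
    m_alt <- apply_medium(model, alternative)
    wt_alt <- fba(m_alt, mode = mode, backend = backend)
    cand_alt <- candidate_reactions(m_alt, flux_epsilon, growth_epsilon, backend)
    cl_alt <- screen_and_classify(m_alt, cand_alt, wt_alt, essentiality,
                                  flux_epsilon, growth_epsilon, backend)
    comparison <- compare_pair_sets(classified, cl_alt)
    utils::write.table(
      data.frame(category = c("conserved", "rescued", "novel",
                              "subtype_switches", "activity_switches"),
                 count = c(nrow(comparison$conserved), nrow(comparison$rescued),
                           nrow(comparison$novel),
                           nrow(comparison$subtype_switches),
                           nrow(comparison$activity_switches))),
      file.path(out_dir, "comparison.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    t4 <- tick("comparison", t4)
  }

  counts <- table(factor(classified$subtype,
                         levels = c("RSL", "RSL_I", "PSL", "PSL_I")))
  summary <- list(
    model = model$id, medium = medium$label, mode = mode, backend = backend,
    flux_epsilon = flux_epsilon, growth_epsilon = growth_epsilon,
    wild_type_growth = wt$objective_value,
    n_candidates = length(cand), n_pairs_screened = nrow(screen),
    n_sl_pairs = nrow(classified),
    class_counts = as.list(counts),
    stage_seconds = stage
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(wild_type = wt, candidates = cand, screen = screen,
                 pairs = classified, distances = dist, entanglement = ent,
                 sensitivity = sens, comparison = comparison,
                 summary = summary))
}

# screen + classify + optional inconsistency flagging on an applied-medium model
screen_and_classify <- function(m, cand, wt, essentiality,
                                flux_epsilon, growth_epsilon, backend) {
  if (length(cand) < 2L) {
    empty <- data.frame(rxn_a = character(0), rxn_b = character(0),
                        subtype = character(0), stringsAsFactors = FALSE)
    class(empty) <- c("sl_pairs", "data.frame")
    attr(empty, "screen") <- data.frame()
    return(empty)
  }
  screen <- double_deletion_screen(m, cand, growth_epsilon, backend)
  sl <- synthetic_lethal_pairs(screen)
  classified <- classify_pairs(sl, m, wt, flux_epsilon, backend = backend)
  if (!is.null(essentiality)) {
    classified <- flag_inconsistencies(classified, essentiality, m)
  }
  attr(classified, "screen") <- screen
  classified
}
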