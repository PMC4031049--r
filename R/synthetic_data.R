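#' Generate a toy metabolic model with planted motifs and known truth
#'
#' Builds a small stoichiometric network in which every synthetic-lethal
#' pair, essential reaction and candidate reaction is known by construction,
#' so the whole screening pipeline can be validated without external model
#' downloads. Each motif hangs off the shared biomass reaction through its
#' own private metabolites (motifs do not interact), and the biomass
#' pseudo-reaction \code{BM} consumes one unit of every motif's terminal
#' metabolite, so wild-type growth equals the common uptake rate \code{u}
#' and each motif's failure mode caps growth by a closed-form value.
#'
#' Motifs (all quantities in mmol/(gDW h)):
#' \describe{
#'   \item{\code{linear_chain}}{an unbranched chain of \code{length}
#'     reactions; every chain reaction (and the motif's uptake exchange) is
#'     essential.}
#'   \item{\code{psl_backup}}{two routes of unequal yield: the efficient
#'     route \code{R_hi} (1 substrate per product) and a backup \code{R_lo}
#'     needing \code{yield_ratio} > 1 substrates per product. The pair is
#'     plasticity synthetic lethal: \code{R_lo} is silent at optimum,
#'     deleting \code{R_hi} drops growth to \code{u / yield_ratio}.}
#'   \item{\code{rsl_parallel}}{two parallel routes with capacities
#'     \code{capacities[1]}, \code{capacities[2]}, each below the demand
#'     \code{u} but jointly sufficient: both must run in parallel
#'     (redundancy synthetic lethal), single knockouts cap growth at the
#'     surviving capacity, so the parallel use always increases fitness.}
#'   \item{\code{isoenzyme_pair}}{a \code{psl_backup} whose two reactions
#'     share the isoenzyme rule \code{"gX or gY"}; the pair is flagged an
#'     enzyme-level inconsistency by [flag_inconsistencies()].}
#'   \item{\code{dead_branch}}{a gene-associated reaction between two
#'     otherwise disconnected metabolites; it can never carry flux and must
#'     be excluded from the candidate space.}
#'   \item{\code{medium_dependent_backup}}{a \code{psl_backup} plus a rescue
#'     route from a nutrient whose exchange is closed in the reference
#'     medium; the planted pair is lethal only in media lacking that
#'     nutrient. The generated \code{truth$media} holds a two-medium panel
#'     with per-medium lethality.}
#' }
#'
#' Randomization (active when \code{seed} is given) only permutes
#' identifiers, row order and motif parameters within their safe ranges --
#' never the motif topology -- so the planted truth stays derivable in
#' closed form.
#'
#' @param motifs list of motif specifications; each element a list with
#'   \code{type} and the motif's parameters (\code{length},
#'   \code{yield_ratio}, \code{capacities}, \code{pathway},
#'   \code{active_pathway}, \code{backup_pathway}, \code{tag}).
#' @param uptake common uptake rate \code{u} (default 10).
#' @param seed optional integer for reproducible randomization.
#' @param id model id.
#' @return list with \code{model} (medium already applied), \code{medium}
#'   (the reference medium), \code{truth} (see Details) and, when a
#'   \code{medium_dependent_backup} motif is present, additional media in
#'   \code{truth$media} with per-medium lethality in
#'   \code{truth$media_lethality}.
#' @examples
#' fx <- make_toy_model(list(list(type = "psl_backup", yield_ratio = 2)))
#' fx$truth$sl_pairs
#' @export
make_toy_model <- function(motifs, uptake = 10, seed = NULL, id = "toy") {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    }
    set.seed(seed)
  }
  randomize <- !is.null(seed)
  mets <- list(); rxns <- list(); stoich <- list()
  bm_inputs <- character(0)
  ess <- character(0); cand <- character(0)
  pair_rows <- list(); media_rows <- list()
  rescue_media <- list()

  add_met <- function(mid) mets[[mid]] <<- data.frame(
    id = mid, name = mid, compartment = "c", is_external = FALSE,
    stringsAsFactors = FALSE)
  add_rxn <- function(rid, st, lb = 0, ub = 1000, gpr = paste0("g_", rid),
                      subsystem = "", is_exchange = FALSE, is_biomass = FALSE) {
    rxns[[rid]] <<- data.frame(id = rid, lower_bound = lb, upper_bound = ub,
                               gpr = gpr, subsystem = subsystem,
                               is_exchange = is_exchange, is_biomass = is_biomass,
                               stringsAsFactors = FALSE)
    stoich[[rid]] <<- st
  }

  uptake_exchanges <- character(0)
  for (i in seq_along(motifs)) {
    mo <- motifs[[i]]
    tag <- mo$tag %||% if (randomize) {
      paste0(paste(sample(letters, 3, replace = TRUE), collapse = ""), i)
    } else paste0("m", i)
    pw <- mo$pathway %||% paste0("Pathway ", toupper(tag))
    type <- match.arg(mo$type, c("linear_chain", "psl_backup", "rsl_parallel",
                                 "isoenzyme_pair", "dead_branch",
                                 "medium_dependent_backup"))
    if (type == "dead_branch") {
      d1 <- paste0("D_", tag); d2 <- paste0("X_", tag)
      add_met(d1); add_met(d2)
      rid <- paste0("RD_", tag)
      add_rxn(rid, stats::setNames(c(-1, 1), c(d1, d2)), subsystem = pw)
      next
    }
    a <- paste0("A_", tag); b <- paste0("B_", tag)
    add_met(a); add_met(b)
    ex <- paste0("EX_", tag)
    add_rxn(ex, stats::setNames(-1, a), lb = -uptake, gpr = "",
            is_exchange = TRUE)
    uptake_exchanges <- c(uptake_exchanges, ex)
    bm_inputs <- c(bm_inputs, b)
    ess <- c(ess, ex)
    if (type == "linear_chain") {
      len <- mo$length %||% if (randomize) sample(2:4, 1) else 3
      prev <- a
      for (s in seq_len(len)) {
        nxt <- if (s == len) b else paste0("M_", tag, "_", s)
        if (nxt != b) add_met(nxt)
        rid <- paste0("C_", tag, "_", s)
        # chains are reversible: the reverse direction is never profitable
        # (no downstream source), but it gives the bipartite graph nontrivial
        # finite distances
        add_rxn(rid, stats::setNames(c(-1, 1), c(prev, nxt)), lb = -1000,
                subsystem = pw)
        ess <- c(ess, rid)
        prev <- nxt
      }
    } else if (type %in% c("psl_backup", "isoenzyme_pair",
                           "medium_dependent_backup")) {
      r <- mo$yield_ratio %||% if (randomize) sample(c(1.25, 2, 2.5, 4, 5), 1) else 2
      stopifnot(r > 1)
      hi <- paste0("R_hi_", tag); lo <- paste0("R_lo_", tag)
      pw_act <- mo$active_pathway %||% pw
      pw_bak <- mo$backup_pathway %||%
        if (type == "psl_backup") paste0("Backup ", toupper(tag)) else pw
      iso_gpr <- paste0("gx_", tag, " or gy_", tag)
      add_rxn(hi, stats::setNames(c(-1, 1), c(a, b)), subsystem = pw_act,
              gpr = if (type == "isoenzyme_pair") iso_gpr else paste0("g_", hi))
      add_rxn(lo, stats::setNames(c(-r, 1), c(a, b)), subsystem = pw_bak,
              gpr = if (type == "isoenzyme_pair") iso_gpr else paste0("g_", lo))
      cand <- c(cand, hi, lo)
      p <- sort(c(hi, lo))
      pair_rows[[length(pair_rows) + 1L]] <- data.frame(
        rxn_a = p[1], rxn_b = p[2], subtype = "PSL",
        active = hi, backup = lo,
        growth_ko_a = if (p[1] == hi) uptake / r else uptake,
        growth_ko_b = if (p[2] == hi) uptake / r else uptake,
        fitness_increased = NA,
        enzyme_inconsistency = type == "isoenzyme_pair",
        stringsAsFactors = FALSE)
      if (type == "medium_dependent_backup") {
        cn <- paste0("C_", tag)
        add_met(cn)
        exr <- paste0("EX_resc_", tag)
        add_rxn(exr, stats::setNames(-1, cn), lb = 0, gpr = "", is_exchange = TRUE)
        resc <- paste0("R_resc_", tag)
        add_rxn(resc, stats::setNames(c(-2, 1), c(cn, b)), subsystem = pw)
        rescue_media[[paste0("rescue_", tag)]] <- exr
        media_rows[[length(media_rows) + 1L]] <- data.frame(
          rxn_a = p[1], rxn_b = p[2],
          medium = c("reference", paste0("rescue_", tag)),
          lethal = c(TRUE, FALSE), stringsAsFactors = FALSE)
      }
    } else if (type == "rsl_parallel") {
      caps <- mo$capacities %||% if (randomize) {
        c1 <- sample(6:9, 1); c(c1, sample(seq(max(10 - c1, 2), 9), 1))
      } else c(6, 6)
      stopifnot(length(caps) == 2, all(caps < uptake), sum(caps) >= uptake)
      q1 <- paste0("R_q1_", tag); q2 <- paste0("R_q2_", tag)
      add_rxn(q1, stats::setNames(c(-1, 1), c(a, b)), ub = caps[1], subsystem = pw)
      add_rxn(q2, stats::setNames(c(-1, 1), c(a, b)), ub = caps[2], subsystem = pw)
      cand <- c(cand, q1, q2)
      p <- sort(c(q1, q2))
      pair_rows[[length(pair_rows) + 1L]] <- data.frame(
        rxn_a = p[1], rxn_b = p[2], subtype = "RSL",
        active = NA_character_, backup = NA_character_,
        growth_ko_a = if (p[1] == q1) caps[2] else caps[1],
        growth_ko_b = if (p[2] == q1) caps[2] else caps[1],
        fitness_increased = TRUE, enzyme_inconsistency = FALSE,
        stringsAsFactors = FALSE)
    }
  }
  if (length(bm_inputs) == 0L) {
    stop("at least one supply motif (chain/psl/rsl/isoenzyme/medium-dependent) ",
         "is required for a viable model")
  }
  add_rxn("BM", stats::setNames(rep(-1, length(bm_inputs)), bm_inputs),
          gpr = "", is_biomass = TRUE)
  ess <- c(ess, "BM")

  met_df <- do.call(rbind, mets)
  rxn_df <- do.call(rbind, rxns)
  if (randomize) {
    met_df <- met_df[sample(nrow(met_df)), , drop = FALSE]
    rxn_df <- rxn_df[sample(nrow(rxn_df)), , drop = FALSE]
  }
  rownames(met_df) <- rownames(rxn_df) <- NULL
  model <- metabolic_model(met_df, rxn_df, stoich, id = id)
  ref <- medium(stats::setNames(rep(-uptake, length(uptake_exchanges)),
                                uptake_exchanges), label = "reference")
  model <- apply_medium(model, ref)
  media <- c(list(reference = ref), lapply(rescue_media, function(exr) {
    medium(c(ref$uptake_bounds, stats::setNames(-uptake, exr)), label = "rescue")
  }))
  for (lab in names(rescue_media)) media[[lab]]$label <- lab
  sl <- if (length(pair_rows)) do.call(rbind, pair_rows) else data.frame(
    rxn_a = character(0), rxn_b = character(0), subtype = character(0),
    active = character(0), backup = character(0), growth_ko_a = numeric(0),
    growth_ko_b = numeric(0), fitness_increased = logical(0),
    enzyme_inconsistency = logical(0), stringsAsFactors = FALSE)
  sl <- sl[order(sl$rxn_a, sl$rxn_b), , drop = FALSE]
  rownames(sl) <- NULL
  truth <- list(
    growth_wt = uptake,
    essential = sort(ess),
    candidates = sort(cand),
    sl_pairs = sl,
    media = media,
    media_lethality = if (length(media_rows)) do.call(rbind, media_rows) else NULL
  )
  list(model = model, medium = ref, truth = truth)
}

#' Canonical two-metabolite parallel-branch fixture
#'
#' Four reactions, two internal metabolites: an uptake exchange (bound -10),
#' two parallel conversion branches capped at 6 each, and the biomass sink.
#' Both branches must run in parallel at optimum (growth 10, each branch
#' between 4 and 6); deleting either drops growth to 6, deleting both kills
#' the model -- the minimal redundancy synthetic lethal pair.
#'
#' @return as [make_toy_model()].
#' @export
toy_rsl_model <- function() {
  make_toy_model(list(list(type = "rsl_parallel", capacities = c(6, 6), tag = "p")),
                 id = "toy_rsl")
}

#' Canonical backup-route fixture
#'
#' An efficient route (1:1 yield) and a silent backup needing 2 substrates
#' per product. Growth 10 with the backup at zero flux; deleting the
#' efficient route halves growth to 5 via the backup; deleting both is
#' lethal -- the minimal plasticity synthetic lethal pair.
#'
#' @param yield_ratio substrate cost of the backup route (default 2).
#' @return as [make_toy_model()].
#' @export
toy_psl_model <- function(yield_ratio = 2) {
  make_toy_model(list(list(type = "psl_backup", yield_ratio = yield_ratio,
                           tag = "p")), id = "toy_psl")
}

#' Entangled three-route fixture (shared intermediate)
#'
#' Three routes from two independent nutrients into one shared terminal
#' metabolite. No reaction pair is synthetic lethal (any two deletions leave
#' the third route), although all three routes share a metabolite -- a
#' negative control verifying that the screen does not over-count pairs
#' whose motifs overlap.
#'
#' @return as [make_toy_model()]; \code{truth$sl_pairs} has zero rows.
#' @export
toy_entangled_model <- function() {
  mets <- data.frame(id = c("A_e", "C_e", "B_e"), name = c("A_e", "C_e", "B_e"),
                     compartment = "c", is_external = FALSE,
                     stringsAsFactors = FALSE)
  rxns <- data.frame(
    id = c("EX_a", "EX_c", "R1_e", "R2_e", "R3_e", "BM"),
    lower_bound = c(-10, -10, 0, 0, 0, 0),
    upper_bound = 1000,
    gpr = c("", "", "g_R1_e", "g_R2_e", "g_R3_e", ""),
    subsystem = c("", "", "Route A", "Route A", "Route C", ""),
    is_exchange = c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE),
    is_biomass = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE),
    stringsAsFactors = FALSE)
  stoich <- list(
    EX_a = c(A_e = -1), EX_c = c(C_e = -1),
    R1_e = c(A_e = -1, B_e = 1), R2_e = c(A_e = -2, B_e = 1),
    R3_e = c(C_e = -2, B_e = 1), BM = c(B_e = -1))
  model <- metabolic_model(mets, rxns, stoich, id = "toy_entangled")
  ref <- medium(c(EX_a = -10, EX_c = -10), label = "reference")
  model <- apply_medium(model, ref)
  truth <- list(
    growth_wt = 15, # 10 via R1 plus 5 via R3
    essential = c("BM"),
    candidates = sort(c("R1_e", "R2_e", "R3_e")),
    sl_pairs = data.frame(rxn_a = character(0), rxn_b = character(0),
                          subtype = character(0), stringsAsFactors = FALSE),
    media = list(reference = ref), media_lethality = NULL)
  list(model = model, medium = ref, truth = truth)
}

#' Write a deterministic suite of fixture models to disk
#'
#' Generates \code{n_models} randomized toy models (motif composition and
#' parameters drawn under \code{seed}), plus one kitchen-sink model
#' combining every motif type and one medium-dependent model with its
#' two-medium panel. Each model gets its own directory with the tsv-triplet
#' files, \code{medium.tsv} (long format, all media of the fixture) and the
#' planted truth (\code{truth_pairs.tsv}, \code{truth_sets.tsv}, and
#' \code{truth_media.tsv} where applicable). Output is deterministic: the
#' same seed reproduces byte-identical files.
#'
#' @param seed integer.
#' @param n_models number of randomized models.
#' @param dir output directory.
#' @return character vector of model directories, invisibly.
#' @export
fixture_suite <- function(seed, n_models, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fixtures <- fixture_specs(seed, n_models)
  out <- character(0)
  for (nm in names(fixtures)) {
    fx <- fixtures[[nm]]
    mdir <- file.path(dir, nm)
    write_model_tsv(fx$model, mdir)
    write_media_tsv(fx$truth$media, file.path(mdir, "medium.tsv"))
    utils::write.table(fx$truth$sl_pairs, file.path(mdir, "truth_pairs.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    set_rows <- function(set, vals) {
      if (length(vals) == 0L) return(NULL)
      data.frame(set = set, reaction_id = as.character(vals),
                 stringsAsFactors = FALSE)
    }
    sets <- rbind(set_rows("essential", fx$truth$essential),
                  set_rows("candidate", fx$truth$candidates),
                  set_rows("growth_wt", fx$truth$growth_wt))
    utils::write.table(sets, file.path(mdir, "truth_sets.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(fx$truth$media_lethality)) {
      utils::write.table(fx$truth$media_lethality,
                         file.path(mdir, "truth_media.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    out <- c(out, mdir)
  }
  invisible(out)
}

#' In-memory fixture battery
#'
#' The fixture set behind [fixture_suite()], returned as in-memory objects:
#' \code{n_models} randomized motif compositions (seeded), plus the
#' deterministic \code{kitchen_sink} model combining every motif type and
#' the \code{medium_dependent} model with its two-medium panel.
#'
#' @param seed integer; drives motif composition, parameters and id
#'   permutation.
#' @param n_models number of randomized models (0 gives just the two
#'   deterministic ones).
#' @return named list of fixtures, each as returned by [make_toy_model()].
#' @export
fixture_specs <- function(seed, n_models) {
  fixtures <- list()
  for (i in seq_len(n_models)) {
    sub_seed <- (seed * 1000L + i) %% .Machine$integer.max
    set.seed(sub_seed)
    types <- c("linear_chain", "psl_backup", "rsl_parallel", "isoenzyme_pair")
    chosen <- sample(types, sample(1:3, 1), replace = TRUE)
    if (stats::runif(1) < 0.4) chosen <- c(chosen, "dead_branch")
    motifs <- lapply(chosen, function(t) list(type = t))
    fixtures[[sprintf("model_%03d", i)]] <-
      make_toy_model(motifs, seed = sub_seed, id = sprintf("model_%03d", i))
  }
  fixtures[["kitchen_sink"]] <- make_toy_model(list(
    list(type = "linear_chain", length = 3),
    list(type = "psl_backup", yield_ratio = 2),
    list(type = "rsl_parallel", capacities = c(6, 6)),
    list(type = "isoenzyme_pair", yield_ratio = 2),
    list(type = "dead_branch"),
    list(type = "medium_dependent_backup", yield_ratio = 2)
  ), id = "kitchen_sink")
  fixtures[["medium_dependent"]] <- make_toy_model(list(
    list(type = "medium_dependent_backup", yield_ratio = 2)
  ), id = "medium_dependent")
  fixtures
}
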