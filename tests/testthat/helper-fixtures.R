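# Shared in-code fixtures. All models are built programmatically; nothing is
# read from disk except files the tests themselves write to tempdirs.

# hand-built five-internal-reaction model with two GPR-less reactions,
# used by the gene-association filter tests
model_mixed_gpr <- function() {
  mets <- data.frame(id = c("A", "M1", "M2", "B"), stringsAsFactors = FALSE)
  rxns <- data.frame(
    id = c("EX_A", "R1", "R2", "R3", "R4", "R5", "BM"),
    lower_bound = c(-10, 0, 0, 0, 0, 0, 0),
    upper_bound = 1000,
    gpr = c("", "g1", "", "g3 and g4", "", "g5 or g6", ""),
    subsystem = "",
    is_exchange = c(TRUE, rep(FALSE, 6)),
    is_biomass = c(rep(FALSE, 6), TRUE),
    stringsAsFactors = FALSE)
  stoich <- list(
    EX_A = c(A = -1),
    R1 = c(A = -1, M1 = 1), R2 = c(A = -1, M1 = 1),
    R3 = c(M1 = -1, M2 = 1), R4 = c(M1 = -1, M2 = 1),
    R5 = c(M2 = -1, B = 1), BM = c(B = -1))
  metabolic_model(mets, rxns, stoich, id = "mixed_gpr")
}

# reversible loop model with finite distances between parallel branches:
# A <-> B by two reversible isomerases feeding a biomass sink on B
model_reversible_pair <- function() {
  mets <- data.frame(id = c("A", "B"), stringsAsFactors = FALSE)
  rxns <- data.frame(
    id = c("EX_A", "I1", "I2", "BM"),
    lower_bound = c(-10, -1000, -1000, 0),
    upper_bound = c(1000, 1000, 1000, 1000),
    gpr = c("", "g_i1", "g_i2", ""),
    subsystem = c("", "Isomerase", "Isomerase", ""),
    is_exchange = c(TRUE, FALSE, FALSE, FALSE),
    is_biomass = c(FALSE, FALSE, FALSE, TRUE),
    stringsAsFactors = FALSE)
  stoich <- list(EX_A = c(A = -1), I1 = c(A = -1, B = 1),
                 I2 = c(A = -1, B = 1), BM = c(B = -1))
  metabolic_model(mets, rxns, stoich, id = "reversible_pair")
}

# classified pair table stub for bookkeeping-only tests
pair_table <- function(rxn_a, rxn_b, subtype,
                       active = NA_character_, backup = NA_character_,
                       pathway_a = "P1", pathway_b = "P2") {
  n <- length(rxn_a)
  active <- rep_len(active, n); backup <- rep_len(backup, n)
  pathway_a <- rep_len(pathway_a, n); pathway_b <- rep_len(pathway_b, n)
  out <- data.frame(rxn_a = rxn_a, rxn_b = rxn_b, subtype = subtype,
                    active_reaction = active, backup_reaction = backup,
                    wt_flux_a = rep(NA_real_, n), wt_flux_b = rep(NA_real_, n),
                    growth_wt = rep(NA_real_, n), growth_ko_a = rep(NA_real_, n),
                    growth_ko_b = rep(NA_real_, n), fitness_increased = rep(NA, n),
                    genes_a = rep(NA_character_, n), genes_b = rep(NA_character_, n),
                    pathway_a = pathway_a, pathway_b = pathway_b,
                    stringsAsFactors = FALSE)
  class(out) <- c("sl_pairs", "data.frame")
  out
}

# run the reference pipeline (candidates -> screen -> classify) on a fixture
pipeline_pairs <- function(fx, backend = "primal") {
  wt <- fba(fx$model, mode = "flux_minimized", backend = backend)
  cand <- suppressWarnings(candidate_reactions(fx$model, backend = backend))
  if (length(cand) < 2L) {
    return(list(wt = wt, candidates = cand,
                pairs = pair_table(character(0), character(0), character(0))))
  }
  scr <- double_deletion_screen(fx$model, cand, backend = backend)
  sl <- synthetic_lethal_pairs(scr)
  list(wt = wt, candidates = cand, screen = scr,
       pairs = classify_pairs(sl, fx$model, wt, backend = backend))
}
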