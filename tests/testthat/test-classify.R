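test_that("activity in the reference optimum separates PSL from RSL", {
  psl <- toy_psl_model()
  res <- pipeline_pairs(psl)
  expect_equal(res$pairs$subtype, "PSL")
  expect_equal(res$pairs$active_reaction, "R_hi_p")
  expect_equal(res$pairs$backup_reaction, "R_lo_p")

  rsl <- toy_rsl_model()
  res <- pipeline_pairs(rsl)
  expect_equal(res$pairs$subtype, "RSL")
  expect_true(is.na(res$pairs$active_reaction))
  expect_true(abs(res$pairs$wt_flux_a) > 1e-9 && abs(res$pairs$wt_flux_b) > 1e-9)

  # threshold semantics: a 1e-12 flux is zero
  wt <- fba(psl$model)
  wt$fluxes[["R_lo_p"]] <- 1e-12
  cl <- classify_pairs(data.frame(rxn_a = "R_hi_p", rxn_b = "R_lo_p"),
                       psl$model, wt)
  expect_equal(cl$subtype, "PSL")

  # both-zero contradicts candidacy and raises a mode-review error
  wt$fluxes[["R_hi_p"]] <- 0
  wt$fluxes[["R_lo_p"]] <- 0
  expect_error(classify_pairs(data.frame(rxn_a = "R_hi_p", rxn_b = "R_lo_p"),
                              psl$model, wt), "flux_minimized")
})

test_that("the backup law holds: silent member takes over at lowered growth", {
  psl <- toy_psl_model(yield_ratio = 2)
  res <- pipeline_pairs(psl)
  chk <- backup_activation_check(res$pairs[1, ], psl$model)
  expect_equal(chk$backup_flux_after_ko, 5, tolerance = 1e-9)  # 10 / ratio
  expect_equal(chk$growth_after_ko, 5, tolerance = 1e-9)
  expect_equal(chk$growth_after_backup_ko, 10, tolerance = 1e-9) # unperturbed
  expect_error(backup_activation_check(pipeline_pairs(toy_rsl_model())$pairs[1, ],
                                       toy_rsl_model()$model), "PSL")
  # other yield ratios: growth after active KO = uptake / ratio
  for (r in c(1.25, 4)) {
    fx <- toy_psl_model(yield_ratio = r)
    chk <- backup_activation_check(pipeline_pairs(fx)$pairs[1, ], fx$model)
    expect_equal(chk$growth_after_ko, 10 / r, tolerance = 1e-9)
  }
})

test_that("fitness comparison flags parallel use that buys growth", {
  rsl <- toy_rsl_model()
  res <- pipeline_pairs(rsl)
  expect_true(res$pairs$fitness_increased)     # 10 > 6
  expect_true(fitness_comparison(res$pairs[1, ]))
  expect_equal(res$pairs$growth_ko_a, 6, tolerance = 1e-9)
  # PSL pairs: not applicable
  expect_true(is.na(fitness_comparison(pipeline_pairs(toy_psl_model())$pairs[1, ])))
  # equal-capacity branches with capacity >= demand never both run at a
  # vertex optimum: the degenerate equal-yield limit classifies as PSL with
  # growth unchanged after the active knockout
  wide <- make_toy_model(list(list(type = "psl_backup", yield_ratio = 1.0001,
                                   tag = "w")))
  res <- pipeline_pairs(wide)
  expect_equal(res$pairs$subtype, "PSL")
  chk <- backup_activation_check(res$pairs[1, ], wide$model)
  expect_equal(chk$growth_after_ko, 10 / 1.0001, tolerance = 1e-6)
})

test_that("gene-essentiality inconsistency rules follow the three cases", {
  # two independent backup motifs; manipulate annotations per case
  fx <- make_toy_model(list(list(type = "psl_backup", tag = "u"),
                            list(type = "psl_backup", tag = "v")))
  res <- pipeline_pairs(fx)
  genes <- fx$model$genes
  noness <- stats::setNames(rep("nonessential", length(genes)), genes)

  # case 1: all genes nonessential -> subtype stands
  fl <- flag_inconsistencies(res$pairs, essentiality_annotation(noness), fx$model)
  expect_equal(fl$subtype, c("PSL", "PSL"))

  # case 2a: one member's sole gene essential, gene maps to one reaction
  # -> inconsistent
  st <- noness; st["g_R_hi_u"] <- "essential"
  fl <- flag_inconsistencies(res$pairs, essentiality_annotation(st), fx$model)
  expect_equal(sort(fl$subtype), c("PSL", "PSL_I"))

  # case 2b: the essential gene regulates two reactions -> excused
  m <- fx$model
  m$reactions$gpr[m$reactions$id == "R_lo_v"] <- "g_R_hi_u"
  m2 <- metabolic_model(m$metabolites, m$reactions, m$stoichiometry)
  fl <- flag_inconsistencies(res$pairs, essentiality_annotation(st), m2)
  expect_equal(fl$subtype, c("PSL", "PSL"))

  # case 3: both members essential-gene-governed; inconsistent unless every
  # such gene regulates more than one reaction
  st2 <- noness; st2[c("g_R_hi_u", "g_R_lo_u")] <- "essential"
  fl <- flag_inconsistencies(res$pairs, essentiality_annotation(st2), fx$model)
  expect_true("PSL_I" %in% fl$subtype)
  fl <- flag_inconsistencies(res$pairs, essentiality_annotation(st2), m2)
  # g_R_hi_u excused (3 reactions) but g_R_lo_u still single-reaction
  expect_equal(sort(fl$subtype), c("PSL", "PSL_I"))
})

test_that("isoenzyme and multifunctional plasticity pairs are inconsistencies", {
  iso <- make_toy_model(list(list(type = "isoenzyme_pair", tag = "i")))
  res <- pipeline_pairs(iso)
  noness <- stats::setNames(rep("nonessential", length(iso$model$genes)),
                            iso$model$genes)
  fl <- flag_inconsistencies(res$pairs, essentiality_annotation(noness), iso$model)
  expect_equal(fl$subtype, "PSL_I")
  expect_true(fl$enzyme_inconsistency)

  # multifunctional: identical single-gene GPR on both members
  mf <- toy_psl_model()
  m <- mf$model
  m$reactions$gpr[m$reactions$id %in% c("R_hi_p", "R_lo_p")] <- "g_multi"
  m2 <- metabolic_model(m$metabolites, m$reactions, m$stoichiometry)
  res <- pipeline_pairs(list(model = m2))
  fl <- flag_inconsistencies(res$pairs,
                             essentiality_annotation(c(g_multi = "nonessential")),
                             m2)
  expect_equal(fl$subtype, "PSL_I")

  # distinct single genes are NOT an enzyme association
  plain <- pipeline_pairs(toy_psl_model())
  fl <- flag_inconsistencies(plain$pairs, essentiality_annotation(), toy_psl_model()$model)
  expect_equal(fl$subtype, "PSL")

  # the explicit-list path flags regardless of the heuristic
  fl <- flag_inconsistencies(plain$pairs, essentiality_annotation(),
                             toy_psl_model()$model,
                             isoenzyme_pairs = data.frame(rxn_a = "R_lo_p",
                                                          rxn_b = "R_hi_p"))
  expect_equal(fl$subtype, "PSL_I")
})

test_that("gene-unit counting collapses complexes and splits isoenzymes", {
  fx <- make_toy_model(list(list(type = "psl_backup", tag = "u"),
                            list(type = "rsl_parallel", tag = "v")))
  m <- fx$model
  m$reactions$gpr[m$reactions$id == "R_hi_u"] <- "g1 and g2" # one complex
  m$reactions$gpr[m$reactions$id == "R_lo_u"] <- "g3 or g4"  # two isoenzymes
  m2 <- metabolic_model(m$metabolites, m$reactions, m$stoichiometry)
  res <- pipeline_pairs(list(model = m2))
  counts <- count_genes_and_complexes(res$pairs, m2)
  psl_row <- counts[counts$subtype == "PSL", ]
  expect_equal(psl_row$n_reactions, 2)
  expect_equal(psl_row$n_gene_units, 3) # {g1+g2}, {g3}, {g4}
  rsl_row <- counts[counts$subtype == "RSL", ]
  expect_equal(rsl_row$n_reactions, 2)
  expect_equal(rsl_row$n_gene_units, 2)
  # shared reactions across pairs are counted once
  tab <- pair_table(c("R1", "R2"), c("R2", "R3"), c("RSL", "RSL"))
  fake_model <- list(gpr = list(R1 = parse_gpr("a"), R2 = parse_gpr("b"),
                                R3 = parse_gpr("c")),
                     reactions = data.frame(id = c("R1", "R2", "R3")))
  expect_equal(count_genes_and_complexes(tab, fake_model)$n_reactions, 3)
})
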