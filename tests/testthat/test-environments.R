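# two-nutrient model for media-panel tests: carbon via A or C (C with half
# yield), plus a "nitrogen" nutrient N required stoichiometrically by biomass
panel_model <- function() {
  mets <- data.frame(id = c("A", "C", "N", "B"), stringsAsFactors = FALSE)
  rxns <- data.frame(
    id = c("EX_A", "EX_C", "EX_N", "R_a", "R_c", "BM"),
    lower_bound = c(-10, 0, -10, 0, 0, 0), upper_bound = 1000,
    gpr = c("", "", "", "g_a", "g_c", ""), subsystem = "",
    is_exchange = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE),
    is_biomass = c(rep(FALSE, 5), TRUE), stringsAsFactors = FALSE)
  stoich <- list(EX_A = c(A = -1), EX_C = c(C = -1), EX_N = c(N = -1),
                 R_a = c(A = -1, B = 1), R_c = c(C = -2, B = 1),
                 BM = c(B = -1, N = -1))
  metabolic_model(mets, rxns, stoich, id = "panel_model")
}

test_that("minimal-media panels enumerate sources and filter inviable media", {
  m <- panel_model()
  panel <- build_minimal_media_panel(
    salts = medium(c(EX_N = -10), label = "salts"),
    sources = list(C = c("EX_A", "EX_C", "EX_missing")),
    reference = c(C = "EX_A"), model = m)
  # reference + EX_C viable; EX_missing constructed but inviable
  expect_equal(nrow(panel$log), 3)
  expect_named(panel$media, c("reference", "C:EX_C"))
  expect_false(panel$log$viable[panel$log$compound %in% "EX_missing"])
  expect_equal(panel$log$growth[panel$log$medium_label == "reference"], 10)
  expect_equal(panel$log$growth[panel$log$medium_label == "C:EX_C"], 5)
  # every retained medium is viable by construction
  for (md in panel$media) {
    expect_gt(fba(apply_medium(m, md), mode = "raw")$objective_value, 0)
  }
  # an inviable reference is a configuration error
  expect_error(build_minimal_media_panel(
    medium(label = "empty"), list(C = "EX_C"), c(C = "EX_C"), m), "inviable")
})

test_that("medium enrichment adds uptakes, skips unknowns, never hurts growth", {
  m <- panel_model()
  base <- medium(c(EX_A = -10, EX_N = -10), label = "min")
  e <- enrich_medium(base, "EX_C", model = m)
  expect_equal(e$uptake_bounds[["EX_C"]], -10)
  expect_equal(e$uptake_bounds[["EX_A"]], -10) # base preserved
  expect_identical(enrich_medium(base, character(0))$uptake_bounds,
                   base$uptake_bounds)
  expect_warning(e2 <- enrich_medium(base, c("EX_C", "EX_nope"), model = m),
                 "EX_nope")
  expect_identical(attr(e2, "skipped"), "EX_nope")
  # enrichment monotonicity across fixtures
  for (fx in unname(fixture_specs(19, 2))) {
    g0 <- fba(apply_medium(fx$model, fx$medium), mode = "raw")$objective_value
    extra <- setdiff(exchange_ids(fx$model), names(fx$medium$uptake_bounds))
    enr <- enrich_medium(fx$medium, extra, model = fx$model)
    g1 <- fba(apply_medium(fx$model, enr), mode = "raw")$objective_value
    expect_gte(g1, g0 - 1e-9)
  }
})

test_that("overconstraining by growth rescales uptakes as the FVA prescribes", {
  fx <- toy_rsl_model()
  # fixing biomass at 30% forces the single uptake to exactly 30%
  oc <- overconstrain_by_growth(fx$model, fx$medium, 0.3, "mineral_salts",
                                salts = "EX_p")
  expect_equal(oc$uptake_bounds[["EX_p"]], -3, tolerance = 1e-9)
  expect_equal(fba(apply_medium(fx$model, oc))$objective_value, 3,
               tolerance = 1e-9)
  # basic_sources: scale the maximal-growth uptake limits
  oc2 <- overconstrain_by_growth(fx$model, fx$medium, 0.3, "basic_sources",
                                 salts = "EX_p")
  expect_equal(oc2$uptake_bounds[["EX_p"]], -3, tolerance = 1e-9)
  # fraction 1.0 leaves maximal growth unchanged
  oc3 <- overconstrain_by_growth(fx$model, fx$medium, 1.0, "mineral_salts",
                                 salts = "EX_p")
  expect_equal(fba(apply_medium(fx$model, oc3))$objective_value, 10,
               tolerance = 1e-8)
  # single-reaction essentiality is conserved under mild overconstraining
  ks <- fixture_specs(29, 0)$kitchen_sink
  oc4 <- overconstrain_by_growth(ks$model, ks$medium, 0.3, "mineral_salts",
                                 salts = exchange_ids(ks$model))
  m_oc <- apply_medium(ks$model, oc4)
  expect_identical(essential_reactions(m_oc), ks$truth$essential)
  expect_error(overconstrain_by_growth(fx$model, fx$medium, 0.3,
                                       "mineral_salts", salts = "R_q1_p"),
               "not an exchange")
})

test_that("media sensitivity re-tests lethality and subtype per medium", {
  md <- fixture_specs(37, 0)$medium_dependent
  res <- pipeline_pairs(md)
  sens <- media_sensitivity(md$model, res$pairs, md$truth$media)
  expect_equal(nrow(sens), 1)
  expect_equal(sens$n_media_tested, 2)
  expect_equal(sens$n_media_lethal, 1)  # rescued where the extra nutrient opens
  expect_equal(sens$fraction_lethal, 0.5)
  expect_equal(sens$fraction_psl, 1)    # PSL wherever lethal
  # bookkeeping invariant: psl <= lethal <= tested
  expect_true(all(sens$n_media_psl <= sens$n_media_lethal &
                  sens$n_media_lethal <= sens$n_media_tested))
  calls <- attr(sens, "calls")
  expect_false(calls$lethal[calls$medium != "reference"])
  # a pair lethal in every medium scores 1
  ks <- fixture_specs(37, 0)$kitchen_sink
  res_ks <- pipeline_pairs(ks)
  sens_ks <- media_sensitivity(ks$model, res_ks$pairs,
                               list(reference = ks$medium))
  expect_true(all(sens_ks$fraction_lethal == 1))
})

test_that("pair-set comparison partitions into conserved/rescued/novel", {
  ref <- pair_table(c("r1", "r3", "r5"), c("r2", "r4", "r6"),
                    c("PSL", "RSL", "PSL"),
                    active = c("r1", NA, "r5"), backup = c("r2", NA, "r6"))
  # identical sets: all conserved
  cmp <- compare_pair_sets(ref, ref)
  expect_equal(nrow(cmp$conserved), 3)
  expect_equal(nrow(cmp$rescued) + nrow(cmp$novel) +
               nrow(cmp$subtype_switches) + nrow(cmp$activity_switches), 0)
  # one pair rescued, one novel, one subtype switch, one activity swap
  alt <- pair_table(c("r1", "r5", "r7"), c("r2", "r6", "r8"),
                    c("RSL", "PSL", "PSL"),
                    active = c(NA, "r6", "r7"), backup = c(NA, "r5", "r8"))
  cmp <- compare_pair_sets(ref, alt)
  expect_equal(nrow(cmp$conserved), 2)
  expect_equal(cmp$rescued$rxn_a, "r3")
  expect_equal(cmp$novel$rxn_a, "r7")
  expect_equal(cmp$subtype_switches$direction, "PSL->RSL")
  expect_equal(cmp$activity_switches$active_alternative, "r6")
  # conserved + rescued = reference count
  expect_equal(nrow(cmp$conserved) + nrow(cmp$rescued), nrow(ref))
})

test_that("an end-to-end medium comparison detects the planted rescue", {
  md <- fixture_specs(41, 0)$medium_dependent
  res_ref <- pipeline_pairs(md)
  rescue <- md$truth$media[[2]]
  m_alt <- apply_medium(md$model, rescue)
  wt_alt <- fba(m_alt)
  cand_alt <- candidate_reactions(m_alt)
  scr <- double_deletion_screen(m_alt, cand_alt)
  pairs_alt <- classify_pairs(synthetic_lethal_pairs(scr), m_alt, wt_alt)
  cmp <- compare_pair_sets(res_ref$pairs, pairs_alt)
  expect_equal(nrow(cmp$rescued), 1) # the backup pair is rescued
  expect_equal(nrow(cmp$conserved), 0)
})
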