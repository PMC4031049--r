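test_that("tsv-triplet write/read round-trips models exactly", {
  fixtures <- list(toy_rsl_model(), toy_psl_model(),
                   make_toy_model(list(list(type = "linear_chain", length = 3),
                                       list(type = "isoenzyme_pair"),
                                       list(type = "dead_branch"))))
  for (fx in fixtures) {
    d <- tempfile("roundtrip_")
    write_model_tsv(fx$model, d)
    m2 <- read_model(d, format = "tsv-triplet")
    expect_identical(m2$reactions$id, fx$model$reactions$id)
    expect_equal(m2$reactions$lower_bound, fx$model$reactions$lower_bound)
    expect_equal(m2$reactions$upper_bound, fx$model$reactions$upper_bound)
    expect_identical(m2$reactions$gpr, fx$model$reactions$gpr)
    expect_identical(m2$reactions$subsystem, fx$model$reactions$subsystem)
    expect_identical(m2$metabolites$id, fx$model$metabolites$id)
    for (r in m2$reactions$id) {
      expect_equal(m2$stoichiometry[[r]], fx$model$stoichiometry[[r]])
    }
    expect_equal(stoich_matrix(m2), stoich_matrix(fx$model))
    unlink(d, recursive = TRUE)
  }
})

test_that("model validation names the offending element", {
  mets <- data.frame(id = c("A", "B"), stringsAsFactors = FALSE)
  good_rxns <- data.frame(
    id = c("EX_A", "R1", "BM"), lower_bound = c(-10, 0, 0), upper_bound = 1000,
    gpr = "", subsystem = "", is_exchange = c(TRUE, FALSE, FALSE),
    is_biomass = c(FALSE, FALSE, TRUE), stringsAsFactors = FALSE)
  stoich <- list(EX_A = c(A = -1), R1 = c(A = -1, B = 1), BM = c(B = -1))
  expect_s3_class(metabolic_model(mets, good_rxns, stoich), "metabolic_model")

  no_bm <- good_rxns; no_bm$is_biomass <- FALSE
  expect_error(metabolic_model(mets, no_bm, stoich), "biomass")
  bad_bounds <- good_rxns; bad_bounds$lower_bound[2] <- 5; bad_bounds$upper_bound[2] <- 1
  expect_error(metabolic_model(mets, bad_bounds, stoich), "R1")
  bad_met <- stoich; bad_met$R1 <- c(A = -1, Z = 1)
  expect_error(metabolic_model(mets, good_rxns, bad_met), "Z")
})

test_that("BiGG-style JSON models parse with GPRs, bounds and objective", {
  j <- list(
    id = "toy_json",
    metabolites = list(list(id = "A", compartment = "c"),
                       list(id = "B", compartment = "c")),
    reactions = list(
      list(id = "EX_A", metabolites = list(A = -1), lower_bound = -10,
           upper_bound = 1000, gene_reaction_rule = ""),
      list(id = "R_hi", metabolites = list(A = -1, B = 1), lower_bound = 0,
           upper_bound = 1000, gene_reaction_rule = "(g1 and g2) or g3",
           subsystem = "Toy Pathway"),
      list(id = "BM", metabolites = list(B = -1), lower_bound = 0,
           upper_bound = 1000, objective_coefficient = 1)),
    genes = list(list(id = "g1"), list(id = "g2"), list(id = "g3")))
  path <- tempfile(fileext = ".json")
  jsonlite::write_json(j, path, auto_unbox = TRUE)
  m <- read_model(path, format = "json")
  expect_identical(biomass_id(m), "BM")
  expect_identical(exchange_ids(m), "EX_A")
  expect_false(m$reactions$is_exchange[m$reactions$id == "BM"])
  expect_setequal(m$gpr[["R_hi"]]$genes, c("g1", "g2", "g3"))
  expect_identical(m$reactions$subsystem[m$reactions$id == "R_hi"], "Toy Pathway")
  expect_equal(fba(m)$objective_value, 10)

  # missing objective is a model error
  j$reactions[[3]]$objective_coefficient <- NULL
  jsonlite::write_json(j, path, auto_unbox = TRUE)
  expect_error(read_model(path, format = "json"), "objective")
})

test_that("SBML-FBC models parse bounds, GPR trees and the active objective", {
  sbml <- '<?xml version="1.0" encoding="UTF-8"?>
<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core"
      xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2"
      level="3" version="1" fbc:required="false">
 <model id="toy_sbml" fbc:strict="true">
  <listOfCompartments><compartment id="c" constant="true"/></listOfCompartments>
  <listOfSpecies>
   <species id="A" compartment="c" boundaryCondition="false" constant="false" hasOnlySubstanceUnits="false"/>
   <species id="B" compartment="c" boundaryCondition="false" constant="false" hasOnlySubstanceUnits="false"/>
  </listOfSpecies>
  <listOfParameters>
   <parameter id="lb_m10" value="-10" constant="true"/>
   <parameter id="lb_0" value="0" constant="true"/>
   <parameter id="ub_1000" value="1000" constant="true"/>
  </listOfParameters>
  <fbc:listOfGeneProducts>
   <fbc:geneProduct fbc:id="G_g1" fbc:label="g1"/>
   <fbc:geneProduct fbc:id="G_g2" fbc:label="g2"/>
   <fbc:geneProduct fbc:id="G_g3" fbc:label="g3"/>
  </fbc:listOfGeneProducts>
  <listOfReactions>
   <reaction id="EX_A" reversible="true" fast="false" fbc:lowerFluxBound="lb_m10" fbc:upperFluxBound="ub_1000">
    <listOfReactants><speciesReference species="A" stoichiometry="1" constant="true"/></listOfReactants>
   </reaction>
   <reaction id="R_hi" reversible="false" fast="false" fbc:lowerFluxBound="lb_0" fbc:upperFluxBound="ub_1000">
    <listOfReactants><speciesReference species="A" stoichiometry="1" constant="true"/></listOfReactants>
    <listOfProducts><speciesReference species="B" stoichiometry="1" constant="true"/></listOfProducts>
    <fbc:geneProductAssociation>
     <fbc:or>
      <fbc:and>
       <fbc:geneProductRef fbc:geneProduct="G_g1"/>
       <fbc:geneProductRef fbc:geneProduct="G_g2"/>
      </fbc:and>
      <fbc:geneProductRef fbc:geneProduct="G_g3"/>
     </fbc:or>
    </fbc:geneProductAssociation>
   </reaction>
   <reaction id="BM" reversible="false" fast="false" fbc:lowerFluxBound="lb_0" fbc:upperFluxBound="ub_1000">
    <listOfReactants><speciesReference species="B" stoichiometry="1" constant="true"/></listOfReactants>
   </reaction>
  </listOfReactions>
  <fbc:listOfObjectives fbc:activeObjective="obj">
   <fbc:objective fbc:id="obj" fbc:type="maximize">
    <fbc:listOfFluxObjectives>
     <fbc:fluxObjective fbc:reaction="BM" fbc:coefficient="1"/>
    </fbc:listOfFluxObjectives>
   </fbc:objective>
  </fbc:listOfObjectives>
 </model>
</sbml>'
  path <- tempfile(fileext = ".xml")
  writeLines(sbml, path)
  m <- read_model(path, format = "sbml-fbc")
  expect_identical(biomass_id(m), "BM")
  expect_identical(exchange_ids(m), "EX_A")
  expect_equal(m$reactions$lower_bound[m$reactions$id == "EX_A"], -10)
  expect_setequal(m$gpr[["R_hi"]]$genes, c("g1", "g2", "g3"))
  expect_length(gpr_units(m$gpr[["R_hi"]]), 2) # complex + isoenzyme
  expect_equal(fba(m)$objective_value, 10)

  # no objective -> model error
  broken <- sub('fbc:coefficient="1"', 'fbc:coefficient="0"', sbml)
  writeLines(broken, path)
  expect_error(read_model(path, format = "sbml-fbc"), "objective")
})

test_that("apply_medium overwrites exchanges, closes the rest, and is idempotent", {
  fx <- toy_rsl_model()
  m <- fx$model
  m1 <- apply_medium(m, medium(c(EX_p = -10), "glc"))
  expect_equal(m1$reactions$lower_bound[m1$reactions$id == "EX_p"], -10)
  m2 <- apply_medium(m1, medium(c(EX_p = -10), "glc"))
  expect_identical(m1$reactions, m2$reactions)
  # empty medium closes all uptakes: starvation
  m0 <- apply_medium(m, medium())
  expect_true(all(m0$reactions$lower_bound[m0$reactions$is_exchange] == 0))
  expect_equal(fba(m0, mode = "raw")$objective_value, 0)
  # non-exchange key is a configuration error
  expect_error(apply_medium(m, medium(c(BM = -1))), "not an exchange")
  # non-exchange bounds untouched
  expect_equal(m1$reactions$upper_bound[m1$reactions$id == "R_q1_p"], 6)
})

test_that("gene-association filter removes only GPR-less internal reactions", {
  m <- model_mixed_gpr()
  fg <- filter_gene_associated(m)
  expect_setequal(fg$removed, c("R2", "R4"))
  # biomass and exchanges are never removed
  expect_false(any(c("EX_A", "BM") %in% fg$removed))
  # fluxes remain available: growth unchanged by the filter
  m_app <- apply_medium(fg$model, medium(c(EX_A = -10)))
  expect_equal(fba(m_app)$objective_value, 10)
  # all-GPR model removes nothing
  fx <- toy_psl_model()
  expect_length(filter_gene_associated(fx$model)$removed, 0)
  # drop = TRUE zeroes the removed reactions' bounds
  dropped <- filter_gene_associated(m, drop = TRUE)$model
  expect_equal(dropped$reactions$upper_bound[dropped$reactions$id == "R2"], 0)
})

test_that("media and essentiality TSV files read back correctly", {
  fx <- fixture_specs(7, 0)$medium_dependent
  path <- tempfile(fileext = ".tsv")
  write_media_tsv(fx$truth$media, path)
  panel <- read_medium_tsv(path)
  expect_named(panel, names(fx$truth$media))
  expect_equal(panel$reference$uptake_bounds, fx$truth$media$reference$uptake_bounds)

  ess_path <- tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tstatus", "g1\tessential", "g2\tnonessential",
               "g3\tunknown"), ess_path)
  ann <- read_essentiality_tsv(ess_path)
  expect_equal(is_gene_essential(ann, c("g1", "g2", "g3", "g4")),
               c(TRUE, FALSE, FALSE, FALSE))
  strict <- read_essentiality_tsv(ess_path, unknown_policy = "strict")
  expect_error(is_gene_essential(strict, "g3"), "strict")
  writeLines(c("gene_id\tflag", "g1\t1"), ess_path)
  expect_error(read_essentiality_tsv(ess_path), "missing column")
})
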