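test_that("toy network reproduces its printed mode and cut-set facts", {
  toy <- make_toy()
  ems <- enumerate_ems(toy)
  expect_equal(n_modes(ems), 3)
  expect_setequal(
    vapply(ems$supports, function(s) paste(reaction_ids(toy)[s], collapse = ","), ""),
    c("R1,R2,R4", "R1,R3,R4", "R1,R5"))
})

test_that("lumped product and biomass stoichiometries are the printed ones", {
  pc <- make_photocore(photocore_params())
  coef <- function(met, rxn) {
    -pc$stoich[match(met, pc$mets$id), match(rxn, reaction_ids(pc))]
  }
  expect_true(coef("ATP", "ETH") == rq(7))
  expect_true(coef("NADPH", "ETH") == rq(6))
  expect_true(coef("ATP", "IBU") == rq(12))
  expect_true(coef("NADPH", "IBU") == rq(12))
  expect_true(coef("ATP", "BIO") == rq(151))
  expect_true(coef("NADPH", "BIO") == rq(100))
  # parameter invariant: LEF ATP:NADPH = protons_per_nadph * atp_per_proton
  p <- photocore_params()
  expect_true(p$protons_per_nadph_lef * p$atp_per_proton == as_rq("9/7"))
})

test_that("mechanistic ethanol nets the same demand as the lumped reaction", {
  pm <- make_photocore(photocore_params(variant = "mechanistic"))
  r <- atp_nadph_pathway_ratio(pm, "ADH")
  expect_true(r$atp == rq(7))
  expect_true(r$nadph == rq(6))
})

test_that("an inconsistent biomass ratio warns instead of erroring", {
  expect_warning(photocore_params(biomass_atp_nadph_ratio = "6/5"),
                 "coupling cannot be enforced")
})

test_that("night model ferments to ethanol when respiration is cut", {
  pcn <- make_photocore(photocore_params(products = "ethanol",
                                         regime = "night"))
  expect_equal(unname(pcn$rxns$ub[match("EX_PHOTON", reaction_ids(pcn))]), 0)
  cutn <- apply_knockouts(pcn, c("NDH1", "COX", "CYD"))
  r <- fba(cutn, "ATPM", upper = c(GLYC_MOB = 1))
  expect_equal(r$status, "optimal")
  expect_true(r$objval > rq(0))                        # ATP still possible
  expect_true(flux_of(r, "ADH") > rq(0))               # ... only with ethanol
  r2 <- fba(cutn, "ATPM", upper = c(GLYC_MOB = 1, ADH = 0))
  expect_true(r2$objval == rq(0))
  # without cuts, respiration makes ethanol-free ATP possible
  r3 <- fba(pcn, "ATPM", upper = c(GLYC_MOB = 1, ADH = 0))
  expect_true(r3$objval > rq(0))
})

test_that("perturbation is deterministic and only adds modes", {
  toy <- make_toy()
  expect_identical(perturb_model(toy, 1, 0), toy)
  a <- perturb_model(toy, 5, 2)
  b <- perturb_model(toy, 5, 2)
  expect_true(isTRUE(models_equal(a, b)))
  expect_false(isTRUE(models_equal(a, perturb_model(toy, 6, 2))))
  base_keys <- support_keys(lapply(enumerate_ems(toy)$supports, function(s)
    reaction_ids(toy)[s]))
  pert <- perturb_model(toy, 3, 2)
  pert_keys <- support_keys(lapply(enumerate_ems(pert)$supports, function(s)
    reaction_ids(pert)[s]))
  expect_gte(length(pert_keys), length(base_keys))
  expect_true(all(base_keys %in% pert_keys))
})
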