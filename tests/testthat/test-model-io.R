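test_that("model construction enforces its invariants", {
  mets <- data.frame(id = c("A", "B"), external = c(FALSE, TRUE))
  expect_error(network_model(rbind(mets, mets), list()), "duplicate metabolite")
  expect_error(network_model(mets, list(
    list(id = "R1", stoich = c(A = -1)),
    list(id = "R1", stoich = c(A = 1)))), "duplicate reaction")
  expect_error(network_model(mets, list(
    list(id = "R1", stoich = c(Z = -1)))), "undeclared metabolites: Z")
  expect_error(network_model(mets, list(
    list(id = "R1", stoich = c(A = -1), tags = "biomass"),
    list(id = "R2", stoich = c(A = -1), tags = "biomass"))),
    "more than one reaction tagged 'biomass'")
  # internal + external = species count
  m <- make_photocore(photocore_params())
  expect_equal(length(internal_metabolites(m)) + sum(m$mets$external),
               n_metabolites(m))
  expect_equal(dim(balance_matrix(m))[1], length(internal_metabolites(m)))
})

test_that("knockouts zero bounds, keep indices, and compose", {
  toy <- make_toy()
  expect_identical(apply_knockouts(toy, character(0)), toy)
  expect_error(apply_knockouts(toy, "R9"), "unknown reaction id")
  cut <- apply_knockouts(toy, "R4")
  expect_equal(n_reactions(cut), 5)   # column retained
  # no P1-producing flux remains
  expect_false(flux_feasible(cut, lower = c(R4 = 1)))
  # all reactions cut: only the zero vector (any demanded flux infeasible)
  allcut <- apply_knockouts(toy, reaction_ids(toy))
  for (r in reaction_ids(toy))
    expect_false(flux_feasible(allcut, lower = stats::setNames(1, r)))
  # knockout composition: A u B equals sequential application
  ab <- apply_knockouts(toy, c("R2", "R3"))
  seqab <- apply_knockouts(apply_knockouts(toy, "R2"), "R3")
  expect_true(isTRUE(models_equal(ab, seqab)))
})

test_that("TSV dialect round-trips exactly and validates input", {
  toy <- make_toy()
  pc <- make_photocore(photocore_params())
  for (m in list(toy, pc)) {
    path <- withr::local_tempfile(fileext = ".tsv")
    write_tsv_model(m, path)
    back <- read_tsv_model(path)
    expect_true(isTRUE(models_equal(m, back)))
  }
  # hand-written 5-line toy: check parsed stoichiometry against the text
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# metabolites",
               "S\tsubstrate\t1", "A\ta\t0", "B\tb\t0", "P1\tp1\t1", "P2\tp2\t1",
               "# reactions",
               "R1\tS => A\t0\t\t\t",
               "R2\tA => B\t0\t\t\t",
               "R3\tA => B\t0\t\t\t",
               "R4\tB => P1\t0\t\t\t",
               "R5\tA => P2\t0\t\t\t"), path)
  m <- read_tsv_model(path)
  expect_true(isTRUE(models_equal(m, make_toy())))
  # fractional coefficient stored exactly, not as a float
  path2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# metabolites", "H\th\t0", "ATP\tatp\t1",
               "# reactions", "ASE\t14 H => 3 ATP\t0\t\t\t",
               "ASE2\t1 H => 3/14 ATP\t0\t\t\t"), path2)
  m2 <- read_tsv_model(path2)
  expect_true(m2$stoich[2, 2] == as_rq("3/14"))
  # empty reaction section
  path3 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# metabolites", "A\ta\t0", "# reactions"), path3)
  m3 <- read_tsv_model(path3)
  expect_equal(n_reactions(m3), 0)
  expect_equal(dim(balance_matrix(m3))[2], 0)
  # errors: duplicate id, bad coefficient names the row
  path4 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# metabolites", "A\ta\t0", "B\tb\t1", "# reactions",
               "R1\tA => B\t0\t\t\t", "R1\tA => B\t0\t\t\t"), path4)
  expect_error(read_tsv_model(path4), "duplicate reaction")
  path5 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# metabolites", "A\ta\t0", "B\tb\t1", "# reactions",
               "R1\tA => B\t0\t\t\t", "R2\tq A => B\t0\t\t\t"), path5)
  expect_error(read_tsv_model(path5), "row 2.*non-numeric coefficient")
})

test_that("SBML round-trips losslessly including tags, bounds, rationals", {
  for (m in list(make_toy(),
                 make_photocore(photocore_params()),
                 make_photocore(photocore_params(variant = "mechanistic",
                                                 regime = "night")))) {
    path <- withr::local_tempfile(fileext = ".xml")
    write_sbml(m, path)
    back <- read_sbml(path)
    expect_true(isTRUE(models_equal(m, back)))
  }
})

test_that("SBML reading handles foreign conventions and bad input", {
  # boundary species flag: one boundary species -> one fewer balance row
  path <- withr::local_tempfile(fileext = ".xml")
  writeLines(c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level2" level="2" version="4">',
    '<model id="mini"><listOfCompartments><compartment id="c"/></listOfCompartments>',
    '<listOfSpecies>',
    '<species id="Sext" compartment="c" boundaryCondition="true"/>',
    '<species id="A" compartment="c"/>',
    '</listOfSpecies>',
    '<listOfReactions><reaction id="R1" reversible="false">',
    '<listOfReactants><speciesReference species="Sext" stoichiometry="1"/></listOfReactants>',
    '<listOfProducts><speciesReference species="A" stoichiometry="2"/></listOfProducts>',
    '<kineticLaw><listOfParameters><parameter id="LOWER_BOUND" value="0"/>',
    '<parameter id="UPPER_BOUND" value="50"/></listOfParameters></kineticLaw>',
    '</reaction></listOfReactions></model></sbml>'), path)
  m <- read_sbml(path)
  expect_equal(n_metabolites(m), 2)
  expect_equal(dim(balance_matrix(m))[1], 1)
  expect_false(m$rxns$reversible[1])
  expect_equal(m$rxns$ub[1], 50)
  expect_true(m$stoich[2, 1] == rq(2))
  # undeclared species in a reaction
  path2 <- withr::local_tempfile(fileext = ".xml")
  writeLines(gsub('species="A"', 'species="ZZ"',
                  readLines(path), fixed = TRUE), path2)
  expect_error(read_sbml(path2), "undeclared species: ZZ")
  # malformed XML
  path3 <- withr::local_tempfile(fileext = ".xml")
  writeLines("<sbml><model>", path3)
  expect_error(read_sbml(path3))
})
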