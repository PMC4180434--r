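test_that("a single irreversible chain has exactly one mode", {
  m <- network_model(
    data.frame(id = c("S", "A", "P"), external = c(TRUE, FALSE, TRUE)),
    list(list(id = "R1", stoich = c(S = -1, A = 1)),
         list(id = "R2", stoich = c(A = -1, P = 1))))
  ems <- enumerate_ems(m)
  expect_equal(n_modes(ems), 1)
  expect_equal(ems$supports[[1]], c(1L, 2L))
})

test_that("enumeration equals the brute-force oracle on random networks", {
  for (seed in c(3, 7, 21, 33)) {
    net <- random_network(seed, n_internal = 4, n_rxns = 9)
    got <- support_keys(enumerate_ems(net)$supports)
    want <- support_keys(brute_force_em_supports(net))
    expect_equal(got, want, info = paste("seed", seed))
  }
  # a larger instance with reversible steps
  net <- random_network(13, n_internal = 5, n_rxns = 12)
  expect_equal(support_keys(enumerate_ems(net)$supports),
               support_keys(brute_force_em_supports(net)))
})

test_that("modes satisfy steady state exactly and are support-minimal", {
  pc <- make_photocore(photocore_params())
  ems <- enumerate_ems(pc)      # verify = TRUE re-checks internally
  S <- balance_matrix(pc)
  for (r in seq_len(n_modes(ems))) {
    resid <- rq_matvec(S, ems$flux[, r])
    expect_true(all(resid$n == 0))
  }
  # no two modes share a support, count is stable across runs
  keys <- support_keys(ems$supports)
  expect_equal(anyDuplicated(keys), 0L)
  expect_equal(support_keys(enumerate_ems(pc)$supports), keys)
})

test_that("mode normalization pins the photon flux to one", {
  pc <- make_photocore(photocore_params())
  ems <- enumerate_ems(pc)
  pidx <- match("EX_PHOTON", ems$rxn_ids)
  for (r in seq_len(n_modes(ems))) {
    ph <- ems$flux[pidx, r]
    expect_true(ph == rq(0) || ph == rq(1))
  }
})

test_that("yields are exact ratios with a division guard", {
  pc <- make_photocore(photocore_params())
  ems <- enumerate_ems(pc)
  self <- mode_yields(ems, "ETH", "ETH")
  expect_true(all(!self$defined | as.numeric(self$value) == 1))
  yl <- mode_yields(ems, "ETH", "EX_PHOTON")
  expect_true(max(as.numeric(yl$value)[yl$defined]) == 1 / 24)
  # LP bound: no mode exceeds the FBA maximum at photon = 1
  lpmax <- fba(pc, "ETH", fixed = c(EX_PHOTON = 1))$objval
  expect_true(all(yl$value[yl$defined] <= lpmax))
  # night modes have zero photon flux: undefined, not NaN
  pcn <- make_photocore(photocore_params(regime = "night"))
  yn <- mode_yields(enumerate_ems(pcn), "ATPM", "EX_PHOTON")
  expect_false(any(yn$defined))
})

test_that("phase plane spans the two single-objective optima", {
  pc <- make_photocore(photocore_params(products = "ethanol"))
  ems <- enumerate_ems(pc)
  pp <- phase_plane(ems, c("BIO", "EX_PHOTON"), c("ETH", "EX_PHOTON"))
  hull_pts <- pp$points[pp$hull, ]
  max_eth <- as.numeric(fba(pc, "ETH", fixed = c(EX_PHOTON = 1))$objval)
  max_bio <- as.numeric(fba(pc, "BIO", fixed = c(EX_PHOTON = 1))$objval)
  expect_true(any(abs(hull_pts$y - max_eth) < 1e-12 & hull_pts$x < 1e-12))
  expect_true(any(abs(hull_pts$x - max_bio) < 1e-12))
  expect_equal(unname(pp$maxima["y"]), max_eth)
  expect_equal(unname(pp$maxima["x"]), max_bio)
  # single mode: hull is that point
  one <- enumerate_ems(apply_knockouts(make_toy(), c("R2", "R3")))
  pp1 <- phase_plane(one, c("R5", "R1"), c("R4", "R1"))
  expect_equal(nrow(pp1$points), 1)
  expect_equal(pp1$hull, 1L)
  # no defined yields: empty table with a warning
  pcn <- make_photocore(photocore_params(regime = "night"))
  emn <- enumerate_ems(pcn)
  expect_warning(ppn <- phase_plane(emn, c("BIO", "EX_PHOTON"),
                                    c("ETH", "EX_PHOTON")),
                 "no modes")
  expect_equal(nrow(ppn$points), 0)
})

test_that("the mode-count ceiling raises a partial-result error", {
  pc <- make_photocore(photocore_params())
  expect_error(enumerate_ems(pc, max_modes = 3), "ceiling exceeded")
})
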