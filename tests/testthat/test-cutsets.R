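toy_targets <- function() {
  toy <- make_toy()
  ems <- enumerate_ems(toy)
  p1 <- which(vapply(ems$supports, function(s)
    match("R4", reaction_ids(toy)) %in% s, TRUE))
  lapply(ems$supports[p1], function(s) reaction_ids(toy)[s])
}

test_that("Berge hitting sets reproduce the worked example and edge cases", {
  expect_equal(cutset_keys(mcs_berge(toy_targets())),
               c("R1", "R2,R3", "R4"))
  expect_equal(cutset_keys(mcs_berge(list(c("a", "b")))), c("a", "b"))
  expect_error(mcs_berge(toy_targets(), excludable = c("R1", "R2", "R3", "R4")),
               "excludable")
})

test_that("Berge equals the exhaustive hitting-set oracle on random instances", {
  set.seed(3)
  universe <- letters[1:8]
  for (trial in 1:6) {
    targets <- lapply(seq_len(8), function(i)
      sample(universe, sample(2:4, 1)))
    got <- cutset_keys(mcs_berge(targets))
    want <- cutset_keys(brute_force_hitting_sets(targets, universe))
    expect_equal(got, want)
  }
})

test_that("hitting property and minimality hold for every returned set", {
  targets <- toy_targets()
  fam <- mcs_berge(targets)
  for (cs in fam) {
    expect_true(all(vapply(targets, function(tg)
      length(intersect(tg, cs$cuts)) > 0, TRUE)))
    for (r in cs$cuts) {   # dropping any cut leaves some target unhit
      rest <- setdiff(cs$cuts, r)
      expect_true(any(vapply(targets, function(tg)
        length(intersect(tg, rest)) == 0, TRUE)))
    }
  }
  # no returned set contains another
  for (i in seq_along(fam)) for (j in seq_along(fam)) if (i != j)
    expect_false(all(fam[[i]]$cuts %in% fam[[j]]$cuts))
})

test_that("constrained filtering keeps exactly the sets sparing P2", {
  toy <- make_toy()
  des <- list(flux_behavior(toy, lower = c(R5 = 1), label = "P2"))
  cmcs <- filter_constrained(mcs_berge(toy_targets()), des)
  expect_equal(cutset_keys(cmcs), c("R2,R3", "R4"))
  expect_true(all(vapply(cmcs, function(cs) isTRUE(cs$valid_constrained), TRUE)))
  expect_true(all(vapply(cmcs, function(cs) !is.null(cs$witnesses$P2), TRUE)))
  # cMCS is a subset of MCS
  expect_true(all(cutset_keys(cmcs) %in% cutset_keys(mcs_berge(toy_targets()))))
  # desired infeasible even without cuts: empty result plus warning
  impossible <- list(flux_behavior(toy, lower = c(R4 = 1), upper = c(R1 = 0),
                                   label = "impossible"))
  expect_warning(out <- filter_constrained(mcs_berge(toy_targets()), impossible),
                 "infeasible even without cuts")
  expect_length(out, 0)
})

test_that("smallest-first enumeration emits sets in size order", {
  toy <- make_toy()
  tgt <- flux_behavior(toy, lower = c(R4 = 1), label = "P1")
  des <- list(flux_behavior(toy, lower = c(R5 = 1), label = "P2"))
  sc <- smallest_cmcs(tgt, des, cuttable = reaction_ids(toy), k_max = 3)
  expect_equal(lapply(sc, `[[`, "cuts"), list("R4", c("R2", "R3")))
  # k_max = 0: empty result with proven lower bound 1
  sc0 <- smallest_cmcs(tgt, des, cuttable = reaction_ids(toy), k_max = 0)
  expect_length(sc0, 0)
  expect_equal(attr(sc0, "lower_bound"), 1)
})

test_that("enumerated and implicit routes agree on the ethanol core design", {
  pcs <- photocore_ethanol_pair()
  spec <- intervention_spec(product = "ETH", theta_prod = 0.025)
  via_ems <- design_coupled(pcs$day, spec, night_model = pcs$night,
                            method = "enumerate")
  via_ihs <- design_coupled(pcs$day, spec, night_model = pcs$night,
                            method = "implicit")
  expect_equal(cutset_keys(via_ems), cutset_keys(via_ihs))
  expect_equal(via_ems[[1]]$cuts,
               sort(c("NDH1", "FQR", "MEHLER", "COX", "CYD")))
  # exhaustive check over all subsets of the five alternate flows: no
  # smaller subset blocks the targets
  beh <- cyanodesign:::spec_behaviors(pcs$day, spec, pcs$night)
  aefs <- tagged_reactions(pcs$day, "aef")
  for (k in 1:4) {
    combs <- utils::combn(aefs, k)
    for (ci in seq_len(ncol(combs)))
      expect_true(cyanodesign:::behavior_probe(beh$target,
                                               cuts = combs[, ci])$feasible)
  }
})

test_that("essential cuts and size histogram summarize a family", {
  fam <- list(cyanodesign:::new_cut_set(c("a", "b")),
              cyanodesign:::new_cut_set(c("a", "c", "d")),
              cyanodesign:::new_cut_set(c("a", "b", "e")))
  expect_equal(essential_cuts(fam), "a")
  expect_equal(cut_size_histogram(fam), c("2" = 1L, "3" = 2L))
  one <- list(cyanodesign:::new_cut_set(c("x", "y")))
  expect_equal(sort(essential_cuts(one)), c("x", "y"))
  toy_fam <- list(cyanodesign:::new_cut_set(c("R2", "R3")),
                  cyanodesign:::new_cut_set("R4"))
  expect_length(essential_cuts(toy_fam), 0)
})

test_that("minimum guaranteed yield reflects coupling", {
  pc <- make_photocore(photocore_params(products = "ethanol"))
  aefs <- tagged_reactions(pc, "aef")
  mg <- min_guaranteed_yield(pc, aefs, product = "ETH")
  expect_true(mg$growth_feasible)
  expect_true(mg$yield == as_rq("157/5768"))   # about 0.0272 per photon
  # uncut model: a zero-ethanol growth mode survives
  mg0 <- min_guaranteed_yield(pc, character(0), product = "ETH")
  expect_true(mg0$yield == rq(0))
  # growth destroyed: flagged, not an error
  mgx <- min_guaranteed_yield(pc, c(aefs, "FNR"), product = "ETH")
  expect_false(mgx$growth_feasible)
})
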