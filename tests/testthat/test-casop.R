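toy_casop_config <- function(...) {
  casop_config(product = "R4", wt_objective = "R5", reference = "R1", ...)
}

test_that("boundary scores are exact on the toy network", {
  ems <- enumerate_ems(make_toy())
  sc <- casop_scores(ems, toy_casop_config())
  s <- stats::setNames(sc$scores$score, sc$scores$reaction)
  # hand evaluation: desired = the two P1 modes (weight 1 each), wild type
  # = the P2 mode; R4 in all desired and no wild-type mode, R5 vice versa
  expect_equal(unname(s["R4"]), 1)
  expect_equal(unname(s["R5"]), -1)
  expect_equal(unname(s["R1"]), 0)     # in every mode of both sets
  expect_equal(unname(s["R2"]), 0.5)
  expect_equal(unname(s["R3"]), 0.5)
  expect_equal(sc$ranking_knockout[1], "R5")
  expect_equal(sc$ranking_overexpr[1], "R4")
})

test_that("scores stay within [-1, 1] for any weighting exponent", {
  pc <- make_photocore(photocore_params(products = "ethanol"))
  ems <- enumerate_ems(pc)
  for (g in c(0, 0.5, 1, 2, 5)) {
    sc <- casop_scores(ems, casop_config(product = "ETH", wt_objective = "BIO",
                                         reference = "EX_PHOTON", gamma = g))
    expect_true(all(sc$scores$score >= -1 - 1e-12))
    expect_true(all(sc$scores$score <= 1 + 1e-12))
    # reactions absent from every mode of both sets score zero
    used <- unique(unlist(ems$supports[c(sc$wt_modes, sc$desired_modes)]))
    unused <- setdiff(seq_along(ems$rxn_ids), used)
    expect_true(all(abs(sc$scores$score[unused]) < 1e-12))
  }
})

test_that("gamma = 0 reduces to the participation-frequency difference", {
  pc <- make_photocore(photocore_params(products = "ethanol"))
  ems <- enumerate_ems(pc)
  cfg <- casop_config(product = "ETH", wt_objective = "BIO",
                      reference = "EX_PHOTON", gamma = 0)
  sc <- casop_scores(ems, cfg)
  # independent direct computation of participation frequencies
  freq <- function(idx) {
    f <- numeric(length(ems$rxn_ids))
    for (i in idx) f[ems$supports[[i]]] <- f[ems$supports[[i]]] + 1
    f / length(idx)
  }
  expect_equal(sc$scores$score,
               freq(sc$desired_modes) - freq(sc$wt_modes), tolerance = 1e-12)
})

test_that("signs on the photoautotrophic core follow the coupling logic", {
  pc <- make_photocore(photocore_params(products = "ethanol"))
  ems <- enumerate_ems(pc)
  sc <- casop_scores(ems, casop_config(product = "ETH", wt_objective = "BIO",
                                       reference = "EX_PHOTON"))
  s <- stats::setNames(sc$scores$score, sc$scores$reaction)
  for (a in tagged_reactions(pc, "aef"))
    expect_lt(unname(s[a]), 0)          # alternate flows: knockout candidates
  expect_gt(unname(s["ETH"]), 0)        # product path: overexpression
  expect_gt(unname(s["ATPM"]), 0)       # ATP wasting helps the product side
})

test_that("empty ensembles are reported by name", {
  ems <- enumerate_ems(make_toy())
  expect_error(
    casop_scores(ems, casop_config(product = "R4", wt_objective = "R2",
                                   reference = "R1", wt_exclude_product = TRUE)),
    "wild-type")
})
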