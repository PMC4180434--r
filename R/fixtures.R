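#' The five-reaction worked example
#'
#' A minimal branched network used throughout the documentation and tests:
#' substrate S is converted via internal pools A and B to two exported
#' products P1 and P2 by five irreversible reactions (R1: S -> A,
#' R2/R3: parallel A -> B, R4: B -> P1, R5: A -> P2). It is the smallest
#' topology on which elementary modes, minimal cut sets and constrained
#' minimal cut sets all differ instructively: it has exactly three
#' elementary modes (two producing P1, one producing P2); the minimal cut
#' sets blocking P1 are \{R1\}, \{R2,R3\} and \{R4\}; and demanding that P2
#' stay producible leaves the two constrained cut sets \{R2,R3\} and \{R4\}.
#'
#' @return a [network_model].
#' @export
make_toy <- function() {
  network_model(
    data.frame(id = c("S", "A", "B", "P1", "P2"),
               external = c(TRUE, FALSE, FALSE, TRUE, TRUE)),
    list(
      list(id = "R1", stoich = c(S = -1, A = 1)),
      list(id = "R2", stoich = c(A = -1, B = 1)),
      list(id = "R3", stoich = c(A = -1, B = 1)),
      list(id = "R4", stoich = c(B = -1, P1 = 1)),
      list(id = "R5", stoich = c(A = -1, P2 = 1))),
    id = "toy")
}

#' Parameters of the photoautotrophic core model
#'
#' Defaults encode the textbook stoichiometry of oxygenic photosynthesis in
#' cyanobacteria: the ATP synthase makes 3 ATP per 14 lumen protons;
#' linear electron flow deposits 6 lumen protons per NADPH (2 from water
#' splitting at PSII plus 4 from the cytochrome b6f Q-cycle, per 2
#' electrons) and needs 4 photons per NADPH (2 quanta per electron). Those
#' defaults give linear electron flow an ATP:NADPH output ratio of exactly
#' `6 * 3/14 = 9/7` (about 1.28). Biomass synthesis is parameterised to
#' demand ATP and NADPH in ratio 1.51 -- above what linear flow can supply,
#' which is the stoichiometric root of growth-coupled product synthesis in
#' this organism class.
#'
#' @param atp_per_proton ATP made per lumen proton (fraction string or
#'   number), default `"3/14"`.
#' @param protons_per_nadph_lef lumen protons deposited per NADPH by linear
#'   electron flow, default 6.
#' @param photons_per_nadph photons absorbed per NADPH via linear flow,
#'   default 4.
#' @param biomass_atp_nadph_ratio ATP:NADPH demand ratio of the biomass
#'   pseudo-reaction, default `"151/100"`.
#' @param photon_uptake_max day photon uptake bound, mmol photons/gDW/h.
#' @param include_aefs which alternate electron flow reactions to include.
#' @param variant `"lumped"` (one net reaction per product) or
#'   `"mechanistic"` (explicit CBB / lower glycolysis / decarboxylase /
#'   dehydrogenase steps).
#' @param regime `"day"` (photon uptake open) or `"night"` (photons closed,
#'   glycogen mobilization and respiratory/fermentative routes open).
#' @param products which product pathways to include.
#' @return a list of class `photocore_params`.
#' @export
photocore_params <- function(atp_per_proton = "3/14",
                             protons_per_nadph_lef = 6,
                             photons_per_nadph = 4,
                             biomass_atp_nadph_ratio = "151/100",
                             photon_uptake_max = 100,
                             include_aefs = c("NDH1", "FQR", "MEHLER", "COX", "CYD"),
                             variant = c("lumped", "mechanistic"),
                             regime = c("day", "night"),
                             products = c("ethanol", "isobutanol")) {
  p <- list(atp_per_proton = as_rq(atp_per_proton),
            protons_per_nadph_lef = as_rq(protons_per_nadph_lef),
            photons_per_nadph = as_rq(photons_per_nadph),
            biomass_atp_nadph_ratio = as_rq(biomass_atp_nadph_ratio),
            photon_uptake_max = photon_uptake_max,
            include_aefs = if (length(include_aefs)) match.arg(include_aefs,
              c("NDH1", "FQR", "MEHLER", "COX", "CYD"), several.ok = TRUE)
              else character(0),
            variant = match.arg(variant),
            regime = match.arg(regime),
            products = match.arg(products, c("ethanol", "isobutanol"),
                                 several.ok = TRUE))
  lef_ratio <- p$protons_per_nadph_lef * p$atp_per_proton
  if (p$biomass_atp_nadph_ratio <= lef_ratio)
    warning("biomass ATP:NADPH ratio (", format(p$biomass_atp_nadph_ratio),
            ") does not exceed the linear-electron-flow ratio (",
            format(lef_ratio), "); growth coupling cannot be enforced")
  class(p) <- "photocore_params"
  p
}

#' Build the photoautotrophic core model
#'
#' Constructs "PhotoCore", a compact model of the cyanobacterial electron
#' transport chain (PSII, cytochrome b6f, PSI, FNR, ATP synthase), the five
#' classical alternate electron flows (NDH-1 cyclic flow, FQR cyclic flow,
#' the Mehler water-water cycle, and respiration via cytochrome c oxidase
#' and the bd-quinol oxidase), carbon sinks for ethanol, isobutanol and
#' biomass, an ATP maintenance drain, and photon/CO2/O2 exchanges. All
#' coefficients are exact rationals. The lumped variant condenses each
#' carbon pathway to its net ATP/NADPH demand (ethanol: 7 ATP + 6 NADPH per
#' molecule; isobutanol: 12 + 12; biomass: 151 ATP per 100 NADPH); the
#' mechanistic variant resolves carbon fixation into CBB, lower glycolysis,
#' pyruvate decarboxylase and alcohol dehydrogenase steps. The night regime
#' closes photon and CO2 uptake and opens glycogen mobilization plus a
#' respiratory pyruvate-oxidation lump, so that dark maintenance ATP can be
#' made either by respiration or by fermentation to ethanol.
#'
#' @param params a [photocore_params] object (or arguments passed on to it).
#' @param ... passed to [photocore_params()] when `params` is missing.
#' @return a [network_model].
#' @export
make_photocore <- function(params = photocore_params(...), ...) {
  p <- params
  stopifnot(inherits(p, "photocore_params"))
  q <- p$atp_per_proton          # ATP per lumen proton, e.g. 3/14
  atp_n <- q$n; atp_d <- q$d     # ATPase: atp_d Hlum + atp_n ADP -> atp_n ATP
  night <- p$regime == "night"

  mets <- data.frame(
    id = c("photon", "CO2", "O2", "PQ", "PQH2", "PCox", "PCred",
           "Fdox", "Fdred", "NADP", "NADPH", "ADP", "ATP", "Hlum",
           "H2O", "ethanol", "isobutanol", "biomass", "glycogen",
           "PYR", "AcAld"),
    external = c(rep(FALSE, 14), TRUE, TRUE, TRUE, TRUE, TRUE,
                 FALSE, FALSE),
    stringsAsFactors = FALSE)

  rx <- list(
    list(id = "EX_PHOTON", stoich = c(photon = 1),
         lb = 0, ub = if (night) 0 else p$photon_uptake_max,
         tags = c("photon_uptake", "exchange")),
    list(id = "EX_CO2", stoich = c(CO2 = 1), reversible = TRUE,
         ub = if (night) 0 else Inf, tags = "exchange"),
    list(id = "EX_O2", stoich = c(O2 = -1), reversible = TRUE,
         tags = "exchange"),
    list(id = "PSII", stoich = c(H2O = -2, PQ = -2, photon = -4,
                                 O2 = 1, PQH2 = 2, Hlum = 4)),
    list(id = "B6F", stoich = c(PQH2 = -1, PCox = -2,
                                PQ = 1, PCred = 2, Hlum = 4)),
    list(id = "PSI", stoich = c(PCred = -2, Fdox = -2, photon = -2,
                                PCox = 2, Fdred = 2)),
    list(id = "FNR", stoich = c(Fdred = -2, NADP = -1,
                                Fdox = 2, NADPH = 1)),
    list(id = "ATPASE", stoich = stats::setNames(
      c(-atp_d, -atp_n, atp_n),
      c("Hlum", "ADP", "ATP"))))

  aef <- list(
    NDH1 = list(id = "NDH1", stoich = c(NADPH = -1, PQ = -1,
                                        NADP = 1, PQH2 = 1, Hlum = 4),
                tags = "aef"),
    FQR = list(id = "FQR", stoich = c(Fdred = -2, PQ = -1,
                                      Fdox = 2, PQH2 = 1), tags = "aef"),
    MEHLER = list(id = "MEHLER", stoich = c(Fdred = -4, O2 = -1,
                                            Fdox = 4, H2O = 2), tags = "aef"),
    COX = list(id = "COX", stoich = c(PCred = -4, O2 = -1,
                                      PCox = 4, Hlum = 4, H2O = 2), tags = "aef"),
    CYD = list(id = "CYD", stoich = c(PQH2 = -2, O2 = -1,
                                      PQ = 2, Hlum = 4, H2O = 2), tags = "aef"))
  rx <- c(rx, unname(aef[p$include_aefs]))

  bio_atp <- p$biomass_atp_nadph_ratio * 100
  if (bio_atp$d != 1) stop("biomass ATP:NADPH ratio must have denominator <= 100")
  rx <- c(rx, list(
    list(id = "BIO", stoich = stats::setNames(
      c(-100, -bio_atp$n, -100, bio_atp$n, 100, 1),
      c("CO2", "ATP", "NADPH", "ADP", "NADP", "biomass")),
      tags = "biomass"),
    list(id = "ATPM", stoich = c(ATP = -1, H2O = -1, ADP = 1),
         tags = "atp_maintenance")))

  if (p$variant == "lumped") {
    if ("ethanol" %in% p$products)
      rx <- c(rx, list(list(id = "ETH",
        stoich = c(CO2 = -2, ATP = -7, NADPH = -6,
                   ethanol = 1, ADP = 7, NADP = 6),
        tags = "product_export")))
    if ("isobutanol" %in% p$products)
      rx <- c(rx, list(list(id = "IBU",
        stoich = c(CO2 = -4, ATP = -12, NADPH = -12,
                   isobutanol = 1, ADP = 12, NADP = 12),
        tags = "product_export")))
  } else {
    rx <- c(rx, list(
      list(id = "CBB", stoich = c(CO2 = -3, ATP = -9, NADPH = -6,
                                  GAP = 1, ADP = 9, NADP = 6)),
      list(id = "GLYLOW", stoich = c(GAP = -1, ADP = -2, NADP = -1,
                                     PYR = 1, ATP = 2, NADPH = 1))))
    if ("ethanol" %in% p$products)
      rx <- c(rx, list(
        list(id = "PDC", stoich = c(PYR = -1, AcAld = 1, CO2 = 1)),
        list(id = "ADH", stoich = c(AcAld = -1, NADPH = -1,
                                    ethanol = 1, NADP = 1),
             tags = "product_export")))
    if ("isobutanol" %in% p$products)
      rx <- c(rx, list(list(id = "IBUS",
        stoich = c(PYR = -2, NADPH = -2, isobutanol = 1, NADP = 2, CO2 = 2),
        tags = "product_export")))
    mets <- rbind(mets, data.frame(id = "GAP", external = FALSE))
  }

  if (night) {
    rx <- c(rx, list(
      list(id = "GLYC_MOB",
           stoich = c(glycogen = -1, ADP = -3, NADP = -2,
                      PYR = 2, ATP = 3, NADPH = 2),
           tags = "glycogen_mobilization"),
      list(id = "PYROX", stoich = c(PYR = -1, NADP = -5, ADP = -1,
                                    CO2 = 3, NADPH = 5, ATP = 1))))
    if (p$variant == "lumped" && "ethanol" %in% p$products)
      rx <- c(rx, list(
        list(id = "PDC", stoich = c(PYR = -1, AcAld = 1, CO2 = 1)),
        list(id = "ADH", stoich = c(AcAld = -1, NADPH = -1,
                                    ethanol = 1, NADP = 1))))
  }

  network_model(mets, rx,
                id = paste("photocore", p$variant, p$regime, sep = "_"))
}

#' Randomized bypass perturbation
#'
#' Adds `n_extra` random single-substrate, single-product bypass reactions
#' between existing internal metabolites, deterministically from `seed`.
#' Used by property tests: adding reactions can only add elementary modes,
#' never remove existing ones.
#'
#' @param model a [network_model].
#' @param seed integer seed.
#' @param n_extra number of bypasses to add (>= 0).
#' @return the perturbed [network_model].
#' @export
perturb_model <- function(model, seed, n_extra) {
  stopifnot(n_extra >= 0)
  if (n_extra == 0) return(model)
  ints <- internal_metabolites(model)
  if (length(ints) < 2) stop("need at least two internal metabolites")
  old <- local({
    if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  })
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  for (k in seq_len(n_extra)) {
    pair <- sample(ints, 2)
    model <- add_reaction(model, sprintf("BYP%d", k),
                          stats::setNames(c(-1, 1), pair))
  }
  model
}
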