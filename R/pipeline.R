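#' Intervention problem specification
#'
#' Bundles the thresholds of the growth-coupled design problem: the minimum
#' desired product yield (mmol product per mmol photons), the minimum
#' desired biomass yield (gDW per mmol photons), the photon-uptake bound
#' (mmol photons/gDW/h), a lower bound on the ATP-maintenance flux
#' (mmol/gDW/h), and whether night maintenance must stay feasible. Defaults
#' follow the ethanol design problem: yield thresholds 0.03 and 0.0001,
#' photon cap 100, no enforced maintenance flux.
#'
#' @param product product reaction id.
#' @param theta_prod minimum desired product yield; modes at or below it
#'   are targets.
#' @param theta_bio minimum desired biomass yield.
#' @param photon_max photon uptake bound.
#' @param atpm_min lower bound on ATP maintenance flux.
#' @param night_required must night ATP regeneration stay feasible?
#' @param epsilon_strict relative slack converting the strict desired-yield
#'   inequality `Y > theta` into the LP constraint `Y >= theta*(1+eps)`.
#' @return a list of class `intervention_spec`.
#' @export
intervention_spec <- function(product = "ETH", theta_prod = 0.03,
                              theta_bio = 1e-4, photon_max = 100,
                              atpm_min = 0, night_required = TRUE,
                              epsilon_strict = 1e-6) {
  structure(list(product = product, theta_prod = theta_prod,
                 theta_bio = theta_bio, photon_max = photon_max,
                 atpm_min = atpm_min, night_required = night_required,
                 epsilon_strict = epsilon_strict),
            class = "intervention_spec")
}

# photon normalization: target/desired behaviors are scale-free apart from
# rate bounds (photon cap, ATPm floor); any feasible photon-positive
# behavior can be rescaled up to the photon cap, so the probes pin the
# photon flux there.
spec_behaviors <- function(model, spec, night_model = NULL) {
  photon <- tagged_reactions(model, "photon_uptake")
  bio <- tagged_reactions(model, "biomass")
  atpm <- tagged_reactions(model, "atp_maintenance")
  if (!length(photon) || !length(bio)) stop("model must tag photon_uptake and biomass")
  vP <- if (is.finite(spec$photon_max)) spec$photon_max else 1
  lowers <- if (length(atpm) && spec$atpm_min > 0)
    stats::setNames(spec$atpm_min, atpm) else NULL
  target <- flux_behavior(model,
    fixed = stats::setNames(vP, photon), lower = lowers,
    constraints = list(list(coef = stats::setNames(1, spec$product),
                            rel = "<=", rhs = spec$theta_prod * vP)),
    label = "target (low product yield, photoautotrophic)")
  desired_day <- flux_behavior(model,
    fixed = stats::setNames(vP, photon), lower = lowers,
    constraints = list(
      list(coef = stats::setNames(1, spec$product), rel = ">=",
           rhs = spec$theta_prod * vP * (1 + spec$epsilon_strict)),
      list(coef = stats::setNames(1, bio), rel = ">=",
           rhs = spec$theta_bio * vP)),
    label = "desired day (high product yield with growth)")
  desired <- list(desired_day)
  if (spec$night_required) {
    if (is.null(night_model)) stop("night_required = TRUE but no night model given")
    natpm <- tagged_reactions(night_model, "atp_maintenance")
    if (!length(natpm)) stop("night model must tag atp_maintenance")
    desired <- c(desired, list(flux_behavior(night_model,
      lower = stats::setNames(1, natpm),
      label = "desired night (ATP from glycogen)")))
  }
  list(target = target, desired = desired)
}

default_excludable <- function(model) {
  unique(c(tagged_reactions(model, "exchange"),
           tagged_reactions(model, "biomass"),
           tagged_reactions(model, "atp_maintenance"),
           tagged_reactions(model, "photon_uptake")))
}

#' Classify day modes into target / desired / neither
#'
#' Photon-positive modes are partitioned by the yield thresholds: product
#' yield at or below `theta_prod` makes a mode a target (to be blocked);
#' product yield above `theta_prod` together with biomass yield at least
#' `theta_bio` makes it desired; the rest are neither. Photon-free modes
#' are reported separately and take part in neither class.
#'
#' @param modes a `mode_set` of the day model.
#' @param spec an [intervention_spec].
#' @return list of mode index vectors: `target`, `desired_day`, `neither`,
#'   `nonphoton`.
#' @export
classify_modes <- function(modes, spec) {
  photon <- modeset_tagged(modes, "photon_uptake")
  bio <- modeset_tagged(modes, "biomass")
  if (is.na(photon)) stop("mode set's model has no photon_uptake tag")
  if (is.na(bio)) stop("mode set's model has no biomass tag")
  yp <- mode_yields(modes, spec$product, photon)
  yb <- mode_yields(modes, bio, photon)
  nm <- n_modes(modes)
  nonphoton <- which(!yp$defined)
  tp <- as_rq(spec$theta_prod)
  tb <- as_rq(spec$theta_bio)
  target <- integer(0); desired <- integer(0); neither <- integer(0)
  for (r in setdiff(seq_len(nm), nonphoton)) {
    if (yp$value[r] <= tp) target <- c(target, r)
    else if (yb$defined[r] && yb$value[r] >= tb) desired <- c(desired, r)
    else neither <- c(neither, r)
  }
  list(target = target, desired_day = desired, neither = neither,
       nonphoton = nonphoton)
}

modeset_tagged <- function(modes, tag) {
  hit <- vapply(strsplit(modes$rxn_tags, ","), function(tg) tag %in% tg, TRUE)
  if (!any(hit)) return(NA_character_)
  modes$rxn_ids[which(hit)[1]]
}

#' End-to-end growth-coupled design
#'
#' Runs the full constrained-minimal-cut-set workflow: checks that the
#' desired day behavior is feasible at all, then either (a) enumerates the
#' day elementary modes, classifies them against the spec's thresholds,
#' computes minimal hitting sets of the target supports and filters them
#' against the desired day and night behaviors, or (b) at scale or with a
#' nonzero ATP-maintenance floor, runs the implicit smallest-first
#' enumeration ([smallest_cmcs()]). Both routes return the same family on
#' models where both apply.
#'
#' @param model day-regime [network_model].
#' @param spec an [intervention_spec].
#' @param night_model night-regime model (required when
#'   `spec$night_required`).
#' @param excludable reaction ids that may not be cut; defaults to
#'   exchanges, biomass, ATP maintenance and photon uptake.
#' @param method `"auto"`, `"enumerate"` or `"implicit"`.
#' @param k_max,count_max passed to [smallest_cmcs()] for the implicit
#'   route.
#' @return list of `cut_set`s ordered by size then lexicographically.
#' @export
design_coupled <- function(model, spec, night_model = NULL,
                           excludable = default_excludable(model),
                           method = c("auto", "enumerate", "implicit"),
                           k_max = 16, count_max = Inf) {
  method <- match.arg(method)
  beh <- spec_behaviors(model, spec, night_model)
  if (!behavior_probe(beh$desired[[1]])$feasible)
    stop("no desired day behavior exists at the given thresholds")
  if (method == "auto")
    method <- if (spec$atpm_min == 0 && n_reactions(model) <= 60)
      "enumerate" else "implicit"
  cuttable <- setdiff(reaction_ids(model), excludable)
  if (method == "enumerate") {
    ems <- enumerate_ems(model)
    cls <- classify_modes(ems, spec)
    if (!length(cls$target)) return(list())
    targets <- lapply(cls$target, function(r) model$rxns$id[ems$supports[[r]]])
    mcs <- mcs_berge(targets, excludable = excludable)
    out <- filter_constrained(mcs, beh$desired)
  } else {
    out <- smallest_cmcs(beh$target, beh$desired, cuttable,
                         k_max = k_max, count_max = count_max)
  }
  out[order(vapply(out, `[[`, 0L, "size"),
            vapply(out, function(cs) paste(cs$cuts, collapse = ","), ""))]
}

#' ATP and NADPH demand of a pathway
#'
#' Measures the net ATP:NADPH requirement of synthesizing one unit of a
#' sink (product or biomass) from CO2: photon uptake and all alternate
#' electron flows are disabled, ATP and NADPH are supplied by external
#' source reactions, the sink flux is fixed to 1, and two exact LPs
#' minimize the ATP and the NADPH supply respectively.
#'
#' @param model a [network_model].
#' @param sink reaction id whose flux is fixed to 1.
#' @param stop_at internal metabolite ids at which the measured pathway
#'   ends: each is given a one-way export drain and all its consuming
#'   reactions are disabled (e.g. `stop_at = "GAP"` measures the demand of
#'   the carbon-fixation step alone, instead of the cheapest full pathway
#'   through it).
#' @return list with exact rationals `atp`, `nadph`, `ratio`.
#' @export
atp_nadph_pathway_ratio <- function(model, sink, stop_at = character()) {
  off <- c(tagged_reactions(model, "photon_uptake"),
           tagged_reactions(model, "aef"))
  mod <- apply_knockouts(model, off)
  for (m in stop_at) {
    mi <- match(m, mod$mets$id)
    if (is.na(mi)) stop("unknown metabolite id: ", m)
    consumers <- mod$rxns$id[mod$stoich$n[mi, ] < 0]
    mod <- apply_knockouts(mod, setdiff(consumers, sink))
    mod <- add_reaction(mod, paste0("DRAIN_", m), stats::setNames(-1, m))
  }
  mod <- add_reaction(mod, "SUP_ATP", c(ADP = -1, ATP = 1))
  mod <- add_reaction(mod, "SUP_NADPH", c(NADP = -1, NADPH = 1))
  probe <- function(objective) {
    res <- fba(mod, objective, maximize = FALSE,
               fixed = stats::setNames(1, sink))
    if (res$status != "optimal")
      stop("sink ", sink, " infeasible with external ATP/NADPH supply")
    res$objval
  }
  atp <- probe("SUP_ATP")
  nadph <- probe("SUP_NADPH")
  list(atp = atp, nadph = nadph, ratio = atp / nadph)
}

#' Maximal ATP:NADPH output ratio of the electron transport chain
#'
#' Measures how much ATP the (possibly knocked-out) photosynthetic chain
#' can deliver per NADPH: all reactions consuming ATP or NADPH outside the
#' chain (carbon fixation, product synthesis, biomass) are disabled, an
#' NADPH drain is fixed to 1, the photon cap is lifted, and the ATP
#' maintenance flux is maximized. With all alternate electron flows intact
#' the ratio is unbounded (`Inf`): cyclic flows generate ATP without net
#' NADPH. With every alternate flow cut, only linear electron flow remains
#' and the ratio collapses to exactly
#' `protons_per_nadph_lef * atp_per_proton` (9/7 with defaults) -- the
#' stoichiometric fact that makes growth coupling possible.
#'
#' @param model a [network_model] with tagged `atp_maintenance` reaction.
#' @return an [rq], or `Inf` when the ratio is unbounded.
#' @export
chain_atp_nadph_ratio <- function(model) {
  atpm <- tagged_reactions(model, "atp_maintenance")
  if (!length(atpm)) stop("model has no atp_maintenance-tagged reaction")
  aefs <- tagged_reactions(model, "aef")
  atp_i <- match("ATP", model$mets$id)
  nadph_i <- match("NADPH", model$mets$id)
  consumers <- model$rxns$id[model$stoich$n[atp_i, ] < 0 |
                             model$stoich$n[nadph_i, ] < 0]
  off <- setdiff(consumers, c(atpm, aefs))
  mod <- apply_knockouts(model, off)
  mod <- add_reaction(mod, "D_NADPH", c(NADPH = -1, NADP = 1))
  photon <- tagged_reactions(mod, "photon_uptake")
  res <- fba(mod, atpm, fixed = c(D_NADPH = 1),
             upper = stats::setNames(Inf, photon))
  if (res$status == "unbounded") return(Inf)
  if (res$status != "optimal") stop("electron chain cannot supply NADPH")
  res$objval
}

#' Minimum ATP:NADPH supply ratio for biomass synthesis
#'
#' The smallest ratio r such that biomass synthesis stays feasible when ATP
#' and NADPH are provided externally in ratio r (photosynthesis and
#' respiration disabled). With an ATP-maintenance drain present, surplus
#' ATP can always be wasted, so the minimum feasible ratio equals the ratio
#' of the two minimal supplies; both are computed exactly.
#'
#' @param model a [network_model] with a biomass-tagged reaction.
#' @return an exact rational [rq].
#' @export
min_biomass_ratio <- function(model) {
  bio <- tagged_reactions(model, "biomass")
  if (!length(bio)) stop("model has no biomass-tagged reaction")
  atp_nadph_pathway_ratio(model, bio)$ratio
}

#' ATP-maintenance by yield-threshold intervention sweep
#'
#' For every combination of an enforced ATP-maintenance flux (grid over
#' `atpm_range`) and a requested minimum product yield (grid over
#' `theta_range`), computes the minimum number of reaction knockouts that
#' enforce growth-coupled product synthesis, via the implicit
#' smallest-first enumeration. Cells where no coupling is possible are
#' `Inf`: above a critical maintenance flux the electron chain cannot
#' cover the ATP demand at the photon cap and coupling is lost.
#'
#' @param model day-regime model.
#' @param spec an [intervention_spec] (its `atpm_min`/`theta_prod` are
#'   overridden cell by cell).
#' @param night_model night-regime model if `spec$night_required`.
#' @param atpm_range,theta_range grid endpoints (inclusive).
#' @param n grid resolution per axis.
#' @param k_max largest cut-set size searched per cell.
#' @return object of class `sweep_result`: `atpm`, `theta`, and `min_size`
#'   (an `n x n` matrix, rows = ATPm values, columns = yield thresholds).
#' @export
atpm_sweep <- function(model, spec, night_model = NULL,
                       atpm_range = c(0, 14), theta_range = c(0.002, 0.04),
                       n = 20, k_max = 8) {
  atpm <- seq(atpm_range[1], atpm_range[2], length.out = n)
  theta <- seq(theta_range[1], theta_range[2], length.out = n)
  cuttable <- setdiff(reaction_ids(model), default_excludable(model))
  msize <- matrix(Inf, n, n, dimnames = list(signif(atpm, 4), signif(theta, 4)))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      sp <- spec
      sp$atpm_min <- atpm[i]
      sp$theta_prod <- theta[j]
      beh <- spec_behaviors(model, sp, night_model)
      if (!all(vapply(beh$desired, function(b) behavior_probe(b)$feasible, TRUE)))
        next   # desired behavior impossible: coupling infeasible here
      res <- smallest_cmcs(beh$target, beh$desired, cuttable,
                           k_max = k_max, count_max = 1)
      if (length(res)) msize[i, j] <- res[[1]]$size
    }
  }
  structure(list(atpm = atpm, theta = theta, min_size = msize),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat("ATPm x yield-threshold sweep (", length(x$atpm), "x",
      length(x$theta), " cells)\n", sep = "")
  feas <- is.finite(x$min_size)
  cat(sum(feas), "feasible cells; minimal sizes",
      if (any(feas)) paste(range(x$min_size[feas]), collapse = "-") else "-", "\n")
  invisible(x)
}

#' Frozen alternate-electron-flow ATP-drain experiment
#'
#' Emulates a cell that has tuned its electron flows for optimal growth and
#' cannot re-adjust them when an artificial ATP drain is switched on:
#' (1) find the growth-optimal flux state at the photon cap (taking the
#' parsimonious optimum -- minimal total irreversible flux among
#' growth-optimal solutions -- for determinism), (2) freeze the alternate
#' electron flow fluxes at their optimal values, (3) raise the lower bound
#' of the ATP-maintenance flux step by step, and (4) re-maximize growth.
#' Forced ATP consumption under frozen electron flows makes the product an
#' obligatory electron sink: the product rate rises as growth falls.
#'
#' @param model day-regime model with `aef`-tagged reactions.
#' @param atpm_values increasing ATP-maintenance lower bounds (mmol/gDW/h).
#' @param product product reaction id (default first `product_export` tag).
#' @param photon_max optional override of the photon-uptake bound.
#' @return data.frame with columns `atpm`, `growth`, `product_rate`,
#'   `product_yield`, `status`.
#' @export
frozen_aef_experiment <- function(model, atpm_values = 0:5, product = NULL,
                                  photon_max = NULL) {
  photon <- tagged_reactions(model, "photon_uptake")
  bio <- tagged_reactions(model, "biomass")
  atpm <- tagged_reactions(model, "atp_maintenance")
  aefs <- tagged_reactions(model, "aef")
  if (!length(aefs)) stop("model has no aef-tagged reactions to freeze")
  if (is.null(product)) product <- tagged_reactions(model, "product_export")[1]
  if (!is.null(photon_max)) model <- set_bounds(model, photon, ub = photon_max)
  opt <- fba(model, bio, arithmetic = "double")
  if (opt$status != "optimal") stop("initial growth optimization infeasible")
  mu_max <- opt$objval
  irrev <- model$rxns$id[!model$rxns$reversible]
  pars <- fba(model, stats::setNames(rep(1, length(irrev)), irrev),
              maximize = FALSE, fixed = stats::setNames(mu_max, bio),
              arithmetic = "double")
  frozen <- pars$flux[aefs]
  frozen[abs(frozen) < 1e-9] <- 0
  out <- data.frame()
  for (a in atpm_values) {
    res <- fba(model, bio, fixed = frozen,
               lower = stats::setNames(a, atpm), arithmetic = "double")
    row <- if (res$status == "optimal") {
      data.frame(atpm = a, growth = res$objval,
                 product_rate = unname(res$flux[product]),
                 product_yield = unname(res$flux[product] / res$flux[photon]),
                 status = "optimal")
    } else {
      data.frame(atpm = a, growth = NA_real_, product_rate = NA_real_,
                 product_yield = NA_real_, status = res$status)
    }
    out <- rbind(out, row)
  }
  out
}
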