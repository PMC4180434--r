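#' Flux behaviors as LP feasibility problems
#'
#' Target and desired metabolic behaviors (e.g. "photoautotrophic flux with
#' ethanol yield below threshold", "night ATP regeneration from glycogen")
#' are described declaratively as LP feasibility problems over a model:
#' optional flux fixings, bound overrides and extra linear constraints.
#' Cut-set routines probe these behaviors on knocked-out models.
#'
#' @param model a [network_model].
#' @param fixed,lower,upper named flux fixings / bound overrides.
#' @param constraints extra linear constraints (see [fba()]).
#' @param label free-text description used in messages.
#' @return an object of class `flux_behavior`.
#' @export
flux_behavior <- function(model, fixed = NULL, lower = NULL, upper = NULL,
                          constraints = list(), label = "behavior") {
  structure(list(model = model, fixed = fixed, lower = lower, upper = upper,
                 constraints = constraints, label = label),
            class = "flux_behavior")
}

# probe a behavior under knockouts; returns feasibility and a witness flux
behavior_probe <- function(beh, cuts = character(),
                           arithmetic = "double", tol = 1e-8) {
  mod <- apply_knockouts(beh$model, intersect(cuts, reaction_ids(beh$model)))
  res <- fba(mod, stats::setNames(0, reaction_ids(mod)[1]), maximize = FALSE,
             fixed = beh$fixed, lower = beh$lower, upper = beh$upper,
             constraints = beh$constraints, arithmetic = arithmetic)
  if (res$status != "optimal") return(list(feasible = FALSE, flux = NULL,
                                           support = character()))
  fl <- res$flux
  supp <- reaction_ids(mod)[abs(fl) > tol]
  list(feasible = TRUE, flux = fl, support = supp)
}

new_cut_set <- function(cuts, valid = NA, witnesses = NULL) {
  structure(list(cuts = sort(cuts), size = length(cuts),
                 valid_constrained = valid, witnesses = witnesses),
            class = "cut_set")
}

#' @export
print.cut_set <- function(x, ...) {
  cat("{", paste(x$cuts, collapse = ", "), "} (size ", x$size,
      if (isTRUE(x$valid_constrained)) ", constrained-valid" else "",
      ")\n", sep = "")
  invisible(x)
}

#' Minimal cut sets as minimal hitting sets (Berge algorithm)
#'
#' Given the supports of the target elementary modes, computes the complete
#' family of minimal hitting sets: every returned set intersects every
#' target support, no returned set contains another, and the family is
#' complete. Reactions listed in `excludable` are never cut.
#'
#' @param targets list of character vectors (target mode supports).
#' @param excludable reaction ids that may never be cut.
#' @return list of `cut_set` objects, sorted by size then lexicographically.
#' @examples
#' toy <- make_toy()
#' ems <- enumerate_ems(toy)
#' p1 <- which(vapply(ems$supports, function(s) 4L %in% s, TRUE))
#' mcs_berge(lapply(ems$supports[p1], function(s) reaction_ids(toy)[s]))
#' @export
mcs_berge <- function(targets, excludable = character()) {
  if (!length(targets)) stop("no target supports given")
  fam <- list(character(0))
  for (ti in seq_along(targets)) {
    tg <- setdiff(targets[[ti]], excludable)
    if (!length(tg))
      stop("target ", ti, " can only be hit via excludable reactions")
    hit <- vapply(fam, function(h) length(intersect(h, tg)) > 0, TRUE)
    expanded <- list()
    for (h in fam[!hit]) for (r in tg) {
      expanded[[length(expanded) + 1]] <- sort(c(h, r))
    }
    cand <- c(fam[hit], unique(expanded))
    fam <- minimal_family(cand)
  }
  fam <- fam[order(lengths(fam), vapply(fam, function(s) paste(s, collapse = ","), ""))]
  lapply(fam, new_cut_set)
}

# drop sets that strictly contain another set of the family
minimal_family <- function(sets) {
  if (length(sets) <= 1) return(sets)
  sets <- sets[order(lengths(sets))]
  keep <- logical(length(sets))
  kept <- list()
  for (i in seq_along(sets)) {
    s <- sets[[i]]
    dominated <- any(vapply(kept, function(k) all(k %in% s), TRUE))
    if (!dominated) { keep[i] <- TRUE; kept[[length(kept) + 1]] <- s }
  }
  out <- sets[keep]
  out[!duplicated(vapply(out, function(s) paste(s, collapse = ","), ""))]
}

#' Constrain minimal cut sets against desired behaviors
#'
#' Keeps exactly the cut sets whose application leaves every desired
#' behavior LP-feasible (the constrained minimal cut sets); surviving
#' witness flux vectors are stored on each returned set.
#'
#' @param mcs list of `cut_set` objects (e.g. from [mcs_berge()]).
#' @param desired list of [flux_behavior] objects that must all survive
#'   (typically one photoautotrophic day behavior and one night
#'   ATP-from-glycogen behavior).
#' @return the surviving subset, with `valid_constrained = TRUE` and
#'   `witnesses` filled in.
#' @export
filter_constrained <- function(mcs, desired) {
  if (!length(desired)) stop("no desired behaviors given")
  feas0 <- vapply(desired, function(b) behavior_probe(b)$feasible, TRUE)
  if (!all(feas0))
    warning("desired behavior(s) infeasible even without cuts: ",
            paste(vapply(desired[!feas0], `[[`, "", "label"), collapse = ", "))
  out <- list()
  for (cs in mcs) {
    probes <- lapply(desired, behavior_probe, cuts = cs$cuts)
    if (all(vapply(probes, `[[`, TRUE, "feasible"))) {
      wit <- lapply(probes, `[[`, "flux")
      names(wit) <- vapply(desired, `[[`, "", "label")
      out[[length(out) + 1]] <- new_cut_set(cs$cuts, valid = TRUE,
                                            witnesses = wit)
    }
  }
  out
}

#' Smallest-first constrained cut sets without full mode enumeration
#'
#' Enumerates minimal cut sets in order of increasing size using an
#' implicit hitting-set loop: a candidate hitting set of the target-behavior
#' witnesses collected so far is proposed (smallest first), an LP separation
#' oracle then either certifies that the candidate blocks every target
#' behavior or returns a surviving target flux vector whose support becomes
#' a new set to hit. Certified blockers are checked against the desired
#' behaviors; those surviving are emitted as constrained minimal cut sets.
#' Every minimal cut set of size up to the last emitted size is either
#' emitted or was rejected by the desired-behavior filter.
#'
#' @param target a [flux_behavior] describing the flux states to block.
#' @param desired list of [flux_behavior]s that must remain feasible.
#' @param cuttable character vector of knockable reaction ids.
#' @param k_max largest cut-set size to search.
#' @param count_max stop after this many constrained sets.
#' @return list of `cut_set`s in non-decreasing size order. When empty, the
#'   attribute `lower_bound` carries the proven minimal size of any cut set
#'   (`k_max + 1` meaning none of size `<= k_max` exists).
#' @export
smallest_cmcs <- function(target, desired, cuttable,
                          k_max = 16, count_max = Inf) {
  witnesses <- list()
  blockers <- list()    # all certified MCSs (valid or not), block re-emission
  results <- list()
  lower_bound <- 0
  t0 <- behavior_probe(target)
  if (!t0$feasible) return(structure(list(), lower_bound = 0))
  repeat {
    cands <- if (!length(witnesses)) list(character(0))
             else lapply(mcs_berge(witnesses,
                    excludable = setdiff(reaction_ids(target$model), cuttable)),
                    `[[`, "cuts")
    cands <- Filter(function(cn)
      !any(vapply(blockers, function(b) all(b %in% cn), TRUE)), cands)
    if (!length(cands)) break
    sizes <- lengths(cands)
    lower_bound <- min(sizes)
    if (lower_bound > k_max) break
    ord <- order(sizes, vapply(cands, function(s) paste(s, collapse = ","), ""))
    cand <- cands[[ord[1]]]
    tp <- behavior_probe(target, cuts = cand)
    if (tp$feasible) {
      wit <- intersect(tp$support, cuttable)
      if (!length(wit))
        stop("a target behavior uses no cuttable reaction; it cannot be blocked")
      witnesses[[length(witnesses) + 1]] <- wit
    } else {
      blockers[[length(blockers) + 1]] <- cand
      probes <- lapply(desired, behavior_probe, cuts = cand)
      if (all(vapply(probes, `[[`, TRUE, "feasible"))) {
        wit <- lapply(probes, `[[`, "flux")
        names(wit) <- vapply(desired, `[[`, "", "label")
        results[[length(results) + 1]] <- new_cut_set(cand, valid = TRUE,
                                                      witnesses = wit)
        if (length(results) >= count_max) break
      }
    }
  }
  structure(results, lower_bound = max(lower_bound, 1))
}

#' Essential cuts and size distribution of a cut-set family
#'
#' Essential cuts are reactions contained in every constrained minimal cut
#' set of the family; they must be knocked out in any viable strain design.
#'
#' @param cmcs list of `cut_set` objects.
#' @return [essential_cuts()]: character vector;
#'   [cut_size_histogram()]: named integer vector (size -> count).
#' @export
essential_cuts <- function(cmcs) {
  if (!length(cmcs)) stop("empty cut-set family")
  Reduce(intersect, lapply(cmcs, `[[`, "cuts"))
}

#' @rdname essential_cuts
#' @export
cut_size_histogram <- function(cmcs) {
  if (!length(cmcs)) stop("empty cut-set family")
  tab <- table(vapply(cmcs, `[[`, 0L, "size"))
  stats::setNames(as.integer(tab), names(tab))
}

#' Minimum guaranteed product yield under knockouts
#'
#' After applying the cuts, every remaining elementary mode with a biomass
#' yield of at least `theta_bio` (per photon) is inspected; the function
#' returns the smallest product-per-photon yield among them -- the yield the
#' mutant is guaranteed to reach at any growth state. Returns 0 when an
#' uncoupled (zero-product) growth mode survives.
#'
#' @param model a [network_model] (day regime).
#' @param cuts character vector of reaction ids to knock out.
#' @param product product reaction id (default: tagged `product_export`).
#' @param theta_bio biomass-yield floor defining a growth mode.
#' @return list with `yield` (an [rq], or `NULL`) and `growth_feasible`.
#' @export
min_guaranteed_yield <- function(model, cuts, product = NULL,
                                 theta_bio = 1e-4) {
  if (is.null(product)) {
    product <- tagged_reactions(model, "product_export")[1]
    if (is.na(product)) stop("no product_export-tagged reaction in model")
  }
  photon <- tagged_reactions(model, "photon_uptake")
  if (!length(photon)) stop("model has no photon_uptake-tagged reaction")
  bio <- tagged_reactions(model, "biomass")
  cut_model <- apply_knockouts(model, cuts)
  ems <- enumerate_ems(cut_model)
  yb <- mode_yields(ems, bio, photon)
  yp <- mode_yields(ems, product, photon)
  growth <- which(yb$defined & as.numeric(yb$value) >= theta_bio)
  if (!length(growth)) return(list(yield = NULL, growth_feasible = FALSE))
  best <- NULL
  for (g in growth) {
    v <- yp$value[g]
    if (is.null(best) || v < best) best <- v
  }
  list(yield = best, growth_feasible = TRUE)
}
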