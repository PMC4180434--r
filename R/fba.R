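#' Flux-balance optimization over a network model
#'
#' Solves `max/min sum(obj_r * v_r)` subject to steady state
#' (`S v = 0` over internal metabolites), the model's flux bounds, optional
#' per-call bound overrides, flux fixings, and optional extra linear
#' constraints over fluxes (e.g. a yield inequality
#' `v_product - theta * v_photon <= 0`).
#'
#' @param model a [network_model].
#' @param objective named numeric/character/[rq] vector of objective
#'   coefficients over reaction ids, or a single reaction id (coefficient 1).
#' @param maximize logical.
#' @param fixed named vector of fluxes to pin (`lb = ub = value`).
#' @param lower,upper named vectors of bound overrides.
#' @param constraints list of extra constraints, each
#'   `list(coef = <named vector>, rel = "<="|">="|"==", rhs = <value>)`.
#' @param arithmetic `"exact"` or `"double"` (see [solve_lp()]).
#' @return list with `status`, `objval` and `flux` (named over reaction ids;
#'   [rq] for exact arithmetic).
#' @export
fba <- function(model, objective, maximize = TRUE, fixed = NULL,
                lower = NULL, upper = NULL, constraints = list(),
                arithmetic = c("exact", "double")) {
  arithmetic <- match.arg(arithmetic)
  rids <- reaction_ids(model)
  nr <- length(rids)
  if (is.character(objective) && is.null(names(objective)) &&
      length(objective) == 1 && objective %in% rids) {
    objective <- stats::setNames(1, objective)
  }
  Sint <- balance_matrix(model)
  nint <- dim(Sint)[1]
  ncon <- length(constraints)
  nslack <- sum(vapply(constraints, function(cn) cn$rel != "==", TRUE))
  n <- nr + nslack
  A <- rq_zeros(nint + ncon, n)
  if (nint > 0) A[seq_len(nint), seq_len(nr)] <- Sint
  b <- rq_zeros(nint + ncon)
  lb <- model$rxns$lb
  ub <- model$rxns$ub
  apply_named <- function(vec, target) {
    if (is.null(vec)) return(target)
    idx <- rxn_index(model, names(vec))
    target[idx] <- as.numeric(vec)
    target
  }
  lb <- apply_named(lower, lb)
  ub <- apply_named(upper, ub)
  if (!is.null(fixed)) {
    idx <- rxn_index(model, names(fixed))
    lb[idx] <- as.numeric(fixed)
    ub[idx] <- as.numeric(fixed)
  }
  sl <- 0
  for (ci in seq_along(constraints)) {
    cn <- constraints[[ci]]
    idx <- rxn_index(model, names(cn$coef))
    A[nint + ci, idx] <- as_rq(unname(cn$coef))
    if (cn$rel == "<=") { sl <- sl + 1; A[nint + ci, nr + sl] <- rq(1) }
    else if (cn$rel == ">=") { sl <- sl + 1; A[nint + ci, nr + sl] <- rq(-1) }
    else if (cn$rel != "==") stop("constraint relation must be <=, >= or ==")
    b[nint + ci] <- as_rq(cn$rhs)
  }
  obj <- rq_zeros(n)
  oidx <- rxn_index(model, names(objective))
  obj[oidx] <- as_rq(unname(objective))
  lbf <- c(lb, rep(0, nslack))
  ubf <- c(ub, rep(Inf, nslack))
  res <- if (arithmetic == "double") {
    solve_lp(as.numeric(obj), as.numeric(A), as.numeric(b), lbf, ubf,
             maximize = maximize, arithmetic = "double")
  } else {
    solve_lp(obj, A, b, lbf, ubf, maximize = maximize)
  }
  flux <- NULL
  if (res$status == "optimal") {
    flux <- res$x[seq_len(nr)]
    if (!is_rq(flux)) names(flux) <- rids
  }
  list(status = res$status, objval = res$objval, flux = flux, rxn_ids = rids)
}

#' Steady-state feasibility check
#'
#' @inheritParams fba
#' @return `TRUE` if a flux vector satisfying all constraints exists.
#' @export
flux_feasible <- function(model, fixed = NULL, lower = NULL, upper = NULL,
                          constraints = list(), arithmetic = "double") {
  res <- fba(model, stats::setNames(0, reaction_ids(model)[1]),
             maximize = FALSE, fixed = fixed, lower = lower, upper = upper,
             constraints = constraints, arithmetic = arithmetic)
  res$status == "optimal"
}

# named rq flux accessor for exact results
flux_of <- function(res, id) {
  i <- match(id, res$rxn_ids)
  if (is.na(i)) stop("unknown reaction id: ", id)
  if (is_rq(res$flux)) res$flux[i] else unname(res$flux[i])
}
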