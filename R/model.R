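#' Stoichiometric network models
#'
#' A `network_model` holds a metabolic network: metabolites (internal ones
#' are balanced at steady state, external ones are source/sink pools),
#' reactions with exact rational stoichiometry, reversibility, flux bounds
#' in mmol/gDW/h, and role tags. The convention follows photoautotrophic
#' models in which water and cytoplasmic protons are treated as external
#' while thylakoid-lumen protons are explicitly balanced.
#'
#' Recognised reaction tags: `photon_uptake`, `product_export`, `biomass`,
#' `atp_maintenance`, `aef` (alternate electron flow),
#' `glycogen_mobilization`, `exchange`. At most one reaction may carry each
#' of `photon_uptake`, `biomass` and `atp_maintenance`.
#'
#' @param metabolites data.frame with columns `id`, and optionally `name`,
#'   `external` (logical, default `FALSE`) and `compartment`.
#' @param reactions list of reaction descriptions; each a list with `id`,
#'   `stoich` (named vector, names = metabolite ids, values numeric or
#'   fraction strings like `"3/14"`; negative = consumed), and optionally
#'   `reversible`, `lb`, `ub`, `tags`.
#' @param id optional model identifier.
#' @return an object of class `network_model`.
#' @examples
#' m <- network_model(
#'   data.frame(id = c("S", "A", "P"), external = c(TRUE, FALSE, TRUE)),
#'   list(list(id = "R1", stoich = c(S = -1, A = 1)),
#'        list(id = "R2", stoich = c(A = -1, P = 1))))
#' n_reactions(m)
#' @export
network_model <- function(metabolites, reactions, id = "model") {
  mets <- as.data.frame(metabolites, stringsAsFactors = FALSE)
  if (is.null(mets$id)) stop("metabolites need an 'id' column")
  if (anyDuplicated(mets$id)) stop("duplicate metabolite ids: ",
    paste(unique(mets$id[duplicated(mets$id)]), collapse = ", "))
  if (is.null(mets$name)) mets$name <- mets$id
  if (is.null(mets$external)) mets$external <- FALSE
  if (is.null(mets$compartment)) mets$compartment <- NA_character_
  mets <- mets[, c("id", "name", "external", "compartment")]

  rids <- vapply(reactions, function(r) r$id, "")
  if (anyDuplicated(rids)) stop("duplicate reaction ids: ",
    paste(unique(rids[duplicated(rids)]), collapse = ", "))
  nr <- length(reactions)
  nm <- nrow(mets)
  st <- rq_zeros(nm, max(nr, 1))
  if (nr == 0) st <- rq_zeros(nm, 0)
  rev <- logical(nr); lb <- numeric(nr); ub <- numeric(nr); tags <- character(nr)
  for (k in seq_len(nr)) {
    r <- reactions[[k]]
    sv <- r$stoich
    bad <- setdiff(names(sv), mets$id)
    if (length(bad)) stop("reaction ", r$id, " references undeclared metabolites: ",
                          paste(bad, collapse = ", "))
    idx <- match(names(sv), mets$id)
    st[idx, k] <- if (is.character(sv)) as_rq(unname(sv)) else as_rq(unname(sv))
    rev[k] <- isTRUE(r$reversible)
    lb[k] <- if (!is.null(r$lb)) r$lb else if (rev[k]) -Inf else 0
    ub[k] <- if (!is.null(r$ub)) r$ub else Inf
    tags[k] <- paste(r$tags %||% character(), collapse = ",")
    if (!rev[k] && lb[k] < 0) stop("irreversible reaction ", r$id, " with negative lower bound")
  }
  for (tg in c("photon_uptake", "biomass", "atp_maintenance")) {
    if (sum(grepl(tg, tags, fixed = TRUE)) > 1)
      stop("more than one reaction tagged '", tg, "'")
  }
  structure(list(
    id = id,
    mets = mets,
    rxns = data.frame(id = rids, reversible = rev, lb = lb, ub = ub,
                      tags = tags, stringsAsFactors = FALSE),
    stoich = st), class = "network_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.network_model <- function(x, ...) {
  cat("network_model '", x$id, "': ", nrow(x$rxns), " reactions, ",
      sum(!x$mets$external), " internal + ", sum(x$mets$external),
      " external metabolites\n", sep = "")
  invisible(x)
}

#' @rdname network_model
#' @param model a `network_model`.
#' @export
n_reactions <- function(model) nrow(model$rxns)

#' @rdname network_model
#' @export
n_metabolites <- function(model) nrow(model$mets)

#' @rdname network_model
#' @export
reaction_ids <- function(model) model$rxns$id

#' @rdname network_model
#' @export
internal_metabolites <- function(model) model$mets$id[!model$mets$external]

#' Steady-state balance matrix
#'
#' Returns the exact rational stoichiometric matrix restricted to internal
#' (balanced) metabolites; rows follow [internal_metabolites()], columns
#' follow [reaction_ids()].
#'
#' @param model a `network_model`.
#' @return an [rq] matrix.
#' @export
balance_matrix <- function(model) {
  model$stoich[which(!model$mets$external), , drop = FALSE]
}

rxn_index <- function(model, ids, context = "reaction") {
  idx <- match(ids, model$rxns$id)
  if (anyNA(idx)) stop("unknown ", context, " id(s): ",
                       paste(ids[is.na(idx)], collapse = ", "))
  idx
}

#' Find reactions carrying a tag
#'
#' @param model a `network_model`.
#' @param tag a tag string, e.g. `"aef"` or `"photon_uptake"`.
#' @return character vector of reaction ids.
#' @export
tagged_reactions <- function(model, tag) {
  hit <- vapply(strsplit(model$rxns$tags, ","),
                function(tg) tag %in% tg, TRUE)
  model$rxns$id[hit]
}

#' Knock out reactions
#'
#' Constrains the named reactions to zero flux. Columns are retained in the
#' stoichiometric matrix so reaction indices (and hence reported cut sets)
#' stay stable.
#'
#' @param model a `network_model`.
#' @param cuts character vector of reaction ids (may be empty).
#' @return the modified `network_model`.
#' @export
apply_knockouts <- function(model, cuts) {
  if (!length(cuts)) return(model)
  idx <- rxn_index(model, cuts)
  model$rxns$lb[idx] <- 0
  model$rxns$ub[idx] <- 0
  model
}

#' Adjust flux bounds of one reaction
#'
#' @param model a `network_model`.
#' @param id reaction id.
#' @param lb,ub new bounds (omit to keep).
#' @export
set_bounds <- function(model, id, lb = NULL, ub = NULL) {
  idx <- rxn_index(model, id)
  if (!is.null(lb)) model$rxns$lb[idx] <- lb
  if (!is.null(ub)) model$rxns$ub[idx] <- ub
  model
}

# reactions currently forced to zero (knocked out) -- treated as absent by
# the enumeration layers but kept in all indices
blocked_reactions <- function(model) {
  model$rxns$id[model$rxns$lb == 0 & model$rxns$ub == 0]
}

#' Compare two models for structural equality
#'
#' Exact comparison of ids, external flags, rational stoichiometry,
#' reversibility, bounds and tags (order-sensitive). Used by the
#' serialization round-trip guarantees.
#'
#' @param a,b `network_model` objects.
#' @return `TRUE` or a character description of the first difference.
#' @export
models_equal <- function(a, b) {
  if (!identical(a$mets$id, b$mets$id)) return("metabolite ids differ")
  if (!identical(a$mets$external, b$mets$external)) return("external flags differ")
  if (!identical(a$rxns$id, b$rxns$id)) return("reaction ids differ")
  if (!identical(a$rxns$reversible, b$rxns$reversible)) return("reversibility differs")
  if (!isTRUE(all.equal(a$rxns$lb, b$rxns$lb)) ||
      !isTRUE(all.equal(a$rxns$ub, b$rxns$ub))) return("bounds differ")
  ta <- lapply(strsplit(a$rxns$tags, ","), sort)
  tb <- lapply(strsplit(b$rxns$tags, ","), sort)
  if (!identical(ta, tb)) return("tags differ")
  if (!all(a$stoich == b$stoich)) return("stoichiometry differs")
  TRUE
}

#' Add a reaction to a model
#'
#' @param model a `network_model`.
#' @param id new reaction id.
#' @param stoich named vector (numeric or fraction strings).
#' @param reversible logical.
#' @param lb,ub bounds (defaults by reversibility).
#' @param tags character vector of tags.
#' @export
add_reaction <- function(model, id, stoich, reversible = FALSE,
                         lb = NULL, ub = NULL, tags = character()) {
  rx <- c(model_to_reaction_list(model),
          list(list(id = id, stoich = stoich, reversible = reversible,
                    lb = lb, ub = ub, tags = tags)))
  network_model(model$mets, rx, id = model$id)
}

model_to_reaction_list <- function(model) {
  lapply(seq_len(n_reactions(model)), function(k) {
    nz <- which(model$stoich$n[, k] != 0)
    sv <- format(model$stoich[nz, k])
    names(sv) <- model$mets$id[nz]
    list(id = model$rxns$id[k], stoich = sv,
         reversible = model$rxns$reversible[k],
         lb = model$rxns$lb[k], ub = model$rxns$ub[k],
         tags = setdiff(strsplit(model$rxns$tags[k], ",")[[1]], ""))
  })
}
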