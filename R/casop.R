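#' CASOP-style reaction scoring
#'
#' Compares reaction participation between two elementary-mode ensembles --
#' the wild-type behavior (growth) and the desired production phenotype --
#' and assigns each reaction a score in `[-1, 1]`. A reaction present in
#' every desired mode but no wild-type mode scores +1 (overexpression
#' candidate); one present only in wild-type modes scores -1 (knockout
#' candidate). Modes are weighted by a power `gamma` of their yield, so
#' high-yield routes dominate the comparison:
#' `score(r) = Omega_des(r) - Omega_wt(r)` with
#' `Omega_X(r) = sum_{e in X, r in supp(e)} w(e) / sum_{e in X} w(e)` and
#' `w(e) = yield(e)^gamma`. With `gamma = 0` the score reduces to the
#' difference of unweighted participation frequencies.
#'
#' @param gamma nonnegative weighting exponent (default 1).
#' @param product product reaction id (desired-set weight: product yield).
#' @param wt_objective wild-type objective reaction id, usually biomass
#'   (wild-type weight: its yield).
#' @param reference yield denominator reaction id, usually photon uptake.
#' @param min_biomass_in_desired minimum wild-type-objective yield a mode
#'   needs to count as desired (default 0: any product-forming mode).
#' @param wt_exclude_product drop product-forming modes from the wild-type
#'   set (default `TRUE`).
#' @return `casop_config()`: a config list. `casop_scores()`: an object of
#'   class `casop_scores` with `scores` (data.frame `reaction`, `score`),
#'   `ranking_knockout` (ascending score) and `ranking_overexpr`
#'   (descending).
#' @export
casop_config <- function(product, wt_objective, reference, gamma = 1,
                         min_biomass_in_desired = 0,
                         wt_exclude_product = TRUE) {
  stopifnot(gamma >= 0)
  structure(list(product = product, wt_objective = wt_objective,
                 reference = reference, gamma = gamma,
                 min_biomass_in_desired = min_biomass_in_desired,
                 wt_exclude_product = wt_exclude_product),
            class = "casop_config")
}

#' @rdname casop_config
#' @param modes a `mode_set` (see [enumerate_ems()]).
#' @param config a `casop_config`.
#' @export
casop_scores <- function(modes, config) {
  stopifnot(inherits(config, "casop_config"))
  yp <- mode_yields(modes, config$product, config$reference)
  yb <- mode_yields(modes, config$wt_objective, config$reference)
  p <- ifelse(yp$defined, as.numeric(yp$value), 0)
  b <- ifelse(yb$defined, as.numeric(yb$value), 0)
  wt <- which(yb$defined & b > 0 & (!config$wt_exclude_product | p == 0))
  des <- which(yp$defined & p > 0 & b >= config$min_biomass_in_desired)
  if (!length(wt)) stop("wild-type mode set is empty")
  if (!length(des)) stop("desired mode set is empty")
  omega <- function(idx, w) {
    w <- w / sum(w)
    part <- numeric(length(modes$rxn_ids))
    for (k in seq_along(idx)) {
      s <- modes$supports[[idx[k]]]
      part[s] <- part[s] + w[k]
    }
    part
  }
  score <- omega(des, p[des]^config$gamma) - omega(wt, b[wt]^config$gamma)
  df <- data.frame(reaction = modes$rxn_ids, score = score,
                   stringsAsFactors = FALSE)
  structure(list(scores = df,
                 ranking_knockout = df$reaction[order(df$score)],
                 ranking_overexpr = df$reaction[order(-df$score)],
                 wt_modes = wt, desired_modes = des),
            class = "casop_scores")
}

#' @export
print.casop_scores <- function(x, ...) {
  cat("CASOP scores over", nrow(x$scores), "reactions (",
      length(x$wt_modes), "wild-type /", length(x$desired_modes),
      "desired modes )\n")
  top <- x$scores[order(x$scores$score), ]
  cat("top knockout candidates:\n")
  print(utils::head(top[top$score < 0, ], 5), row.names = FALSE)
  cat("top overexpression candidates:\n")
  print(utils::head(top[rev(seq_len(nrow(top))), ][top[rev(seq_len(nrow(top))), ]$score > 0, ], 5),
        row.names = FALSE)
  invisible(x)
}
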