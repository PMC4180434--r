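#' Elementary-mode enumeration
#'
#' Enumerates all elementary flux modes (EMs) of a network: support-minimal
#' nonzero steady-state flux vectors respecting irreversibility. The
#' algorithm is the classical double-description tableau iteration: starting
#' from the identity over (direction-split) reactions, each internal
#' metabolite's balance is imposed in turn by combining positive/negative
#' ray pairs, with the combinatorial adjacency test (no third ray's support
#' inside the union) filtering non-elementary combinations. All arithmetic
#' is on integers with gcd reduction, so mode counts and supports are exact
#' combinatorial facts. Reversible reactions are split into irreversible
#' pairs; spurious two-cycles are dropped on re-merging. Each returned mode
#' is re-verified independently (exact steady-state residual and a
#' rank-based support-minimality check).
#'
#' Modes are normalized so that the photon-uptake flux equals 1 where it is
#' nonzero, otherwise the first nonzero flux in reaction order equals 1;
#' output order is lexicographic by support over reaction index.
#'
#' @param model a [network_model]. Reactions constrained to `[0,0]`
#'   (knockouts) are excluded from the enumeration but retained in indices.
#' @param max_modes ceiling on the number of candidate rays; exceeding it
#'   raises an error that carries the count reached.
#' @param verify re-check each mode's steady state and minimality
#'   independently of the tableau (default `TRUE`).
#' @return an object of class `mode_set`: fields `flux` (exact rational
#'   matrix, reactions x modes), `rxn_ids`, `supports`, `model_id`.
#' @examples
#' n_modes(enumerate_ems(make_toy()))   # 3
#' @export
enumerate_ems <- function(model, max_modes = 2e5, verify = TRUE) {
  rids <- reaction_ids(model)
  nr <- length(rids)
  blocked <- model$rxns$lb == 0 & model$rxns$ub == 0
  active <- which(!blocked)
  Sint <- balance_matrix(model)
  nint <- dim(Sint)[1]
  # column-scale to integers: S'_j = S_j * s_j, flux v_j = s_j * w_j
  scales <- vector("list", length(active))
  Si <- matrix(0, nint, length(active))
  for (jj in seq_along(active)) {
    col <- Sint[, active[jj]]
    if (all(col$n == 0)) { scales[[jj]] <- rq(1); next }
    iv <- rq_to_integer_vector(col)
    # recover the column scale: iv = col * s  =>  s = iv_k / col_k, s > 0
    k <- which(col$n != 0)[1]
    s <- rq(iv[k]) / col[k]
    if (s$n < 0) { iv <- -iv; s <- -s }
    Si[, jj] <- iv
    scales[[jj]] <- s
  }
  # direction handling: irreversible-forward (lb >= 0), plus split columns
  rev_here <- model$rxns$reversible[active] & model$rxns$lb[active] < 0
  cols <- Si
  split_src <- seq_along(active)
  split_dir <- rep(1, length(active))
  if (any(rev_here)) {
    cols <- cbind(cols, -Si[, rev_here, drop = FALSE])
    split_src <- c(split_src, which(rev_here))
    split_dir <- c(split_dir, rep(-1, sum(rev_here)))
  }
  ns <- ncol(cols)
  R <- diag(ns)                       # rays x split-reactions, integer
  for (m in seq_len(nint)) {
    srow <- cols[m, ]
    if (all(srow == 0)) next
    act <- as.vector(R %*% srow)
    zero <- which(act == 0)
    posi <- which(act > 0)
    negi <- which(act < 0)
    newR <- R[zero, , drop = FALSE]
    if (length(posi) && length(negi)) {
      supp <- R != 0
      keep_rows <- list()
      for (i in posi) for (j in negi) {
        u <- supp[i, ] | supp[j, ]
        # adjacency: no third ray's support within the union
        others <- which(rowSums(supp[, !u, drop = FALSE] ) == 0)
        others <- setdiff(others, c(i, j))
        if (length(others)) next
        comb <- act[i] * R[j, ] - act[j] * R[i, ]
        g <- 0
        for (v in abs(comb)) g <- gcd_num(g, v)
        if (g > 1) comb <- comb / g
        if (any(abs(comb) >= RQ_MAX)) stop("integer overflow in mode tableau")
        keep_rows[[length(keep_rows) + 1]] <- comb
      }
      if (length(keep_rows))
        newR <- rbind(newR, do.call(rbind, keep_rows))
    }
    R <- newR
    if (nrow(R) > max_modes)
      stop("elementary-mode ceiling exceeded: ", nrow(R),
           " candidate rays (max_modes = ", max_modes, ")")
    if (nrow(R) == 0) break
  }
  # merge split directions back: w_orig = w_fwd - w_bwd
  W <- matrix(0, nrow(R), length(active))
  for (k in seq_len(ns)) W[, split_src[k]] <- W[, split_src[k]] + split_dir[k] * R[, k]
  nzrow <- rowSums(W != 0) > 0
  W <- W[nzrow, , drop = FALSE]
  # dedupe identical supports+direction (reversible-only modes appear twice)
  if (nrow(W) > 1) {
    key <- apply(W, 1, function(w) {
      k <- which(w != 0)[1]
      paste(w / abs(w[k]), collapse = ",")
    })
    W <- W[!duplicated(key), , drop = FALSE]
  }
  # rebuild exact fluxes on the full reaction index and normalize
  photon <- tagged_reactions(model, "photon_uptake")
  photon_idx <- if (length(photon)) match(photon, rids) else NA_integer_
  modes <- list()
  for (r in seq_len(nrow(W))) {
    v <- rq_zeros(nr)
    nzj <- which(W[r, ] != 0)
    for (jj in nzj)
      v[active[jj]] <- rq(W[r, jj]) * scales[[jj]]
    # normalizer: photon flux, else first nonzero irreversible flux (so the
    # scaling never flips irreversible directions), else first nonzero
    irrev_nz <- which(v$n != 0 & (!model$rxns$reversible | model$rxns$lb >= 0))
    normi <- if (!is.na(photon_idx) && v$n[photon_idx] != 0) photon_idx
             else if (length(irrev_nz)) irrev_nz[1]
             else which(v$n != 0)[1]
    v <- v / v[normi]
    modes[[r]] <- v
  }
  supports <- lapply(modes, function(v) which(v$n != 0))
  ord <- order(vapply(supports, function(s)
    paste(sprintf("%03d", s), collapse = ""), ""))
  modes <- modes[ord]
  supports <- supports[ord]
  if (verify && length(modes)) verify_modes(model, modes, supports)
  flux <- rq_zeros(nr, length(modes))
  for (r in seq_along(modes)) flux[, r] <- modes[[r]]
  structure(list(flux = flux, rxn_ids = rids, supports = supports,
                 rxn_tags = model$rxns$tags, model_id = model$id),
            class = "mode_set")
}

verify_modes <- function(model, modes, supports) {
  Sint <- balance_matrix(model)
  irrev <- !model$rxns$reversible | model$rxns$lb >= 0
  for (r in seq_along(modes)) {
    v <- modes[[r]]
    resid <- rq_matvec(Sint, v)
    if (any(resid$n != 0)) stop("mode ", r, " violates steady state")
    if (any(v$n[irrev] < 0)) stop("mode ", r, " violates irreversibility")
    sub <- Sint[, supports[[r]], drop = FALSE]
    if (kernel_dim_rq(sub) != 1)
      stop("mode ", r, " fails the support-minimality rank check")
  }
  invisible(TRUE)
}

# kernel dimension of an rq matrix via exact Gaussian elimination
kernel_dim_rq <- function(A) {
  nr <- dim(A)[1]; nc <- dim(A)[2]
  # exact elimination on rationals carried as num/den pair matrices
  N <- A$n; D <- A$d
  rank <- 0; row <- 1
  for (col in seq_len(nc)) {
    piv <- which(N[row:nr, col] != 0)
    if (!length(piv)) next
    piv <- piv[1] + row - 1
    if (piv != row) { N[c(piv, row), ] <- N[c(row, piv), ]; D[c(piv, row), ] <- D[c(row, piv), ] }
    pn <- N[row, col]; pd <- D[row, col]
    below <- which(N[, col] != 0)
    below <- below[below > row]
    for (i in below) {
      fn <- N[i, col] * pd; fd <- D[i, col] * pn
      # row_i <- row_i - (fn/fd) * row_row, elementwise rationals
      nn <- N[i, ] * fd * D[row, ] - fn * N[row, ] * D[i, ]
      dd <- D[i, ] * fd * D[row, ]
      g <- gcd_num(abs(nn), abs(dd)); g[g == 0] <- 1
      N[i, ] <- nn / g; D[i, ] <- dd / g
      if (any(abs(N[i, ]) >= RQ_MAX) || any(abs(D[i, ]) >= RQ_MAX))
        stop("overflow in exact rank computation")
    }
    rank <- rank + 1
    row <- row + 1
    if (row > nr) break
  }
  nc - rank
}

#' @rdname enumerate_ems
#' @param modes a `mode_set`.
#' @export
n_modes <- function(modes) length(modes$supports)

#' @export
print.mode_set <- function(x, ...) {
  cat("mode_set:", n_modes(x), "elementary modes over", length(x$rxn_ids),
      "reactions (model", x$model_id, ")\n")
  invisible(x)
}

#' Per-mode yield
#'
#' The exact ratio `flux[numerator] / flux[denominator]` for each mode.
#' Modes whose denominator flux is zero are flagged undefined rather than
#' propagated as NaN.
#'
#' @param modes a `mode_set`.
#' @param numerator,denominator reaction ids.
#' @return list with `value` (an [rq] vector; entries where `defined` is
#'   `FALSE` are placeholders) and `defined` (logical).
#' @export
mode_yields <- function(modes, numerator, denominator) {
  ni <- match(numerator, modes$rxn_ids)
  di <- match(denominator, modes$rxn_ids)
  if (is.na(ni) || is.na(di)) stop("unknown reaction id")
  nm <- n_modes(modes)
  value <- rq_zeros(nm)
  defined <- logical(nm)
  for (r in seq_len(nm)) {
    den <- modes$flux[di, r]
    if (den$n != 0) {
      value[r] <- modes$flux[ni, r] / den
      defined[r] <- TRUE
    }
  }
  list(value = value, defined = defined)
}

#' Phenotypic phase plane of a mode set
#'
#' Projects every mode onto two yield axes and computes the convex hull of
#' the resulting point cloud; the hull bounds all steady-state yield
#' combinations reachable by conical combinations of the modes.
#'
#' @param modes a `mode_set`.
#' @param x,y axis specifications: `c(numerator_id, denominator_id)`.
#' @return list with `points` (data.frame `mode`, `x`, `y`, one row per
#'   mode with both yields defined), `hull` (row indices of hull vertices in
#'   counterclockwise order) and `maxima` (named numeric: max of each axis).
#' @export
phase_plane <- function(modes, x, y) {
  yx <- mode_yields(modes, x[1], x[2])
  yy <- mode_yields(modes, y[1], y[2])
  ok <- yx$defined & yy$defined
  if (!any(ok)) {
    warning("no modes with both yields defined")
    return(list(points = data.frame(mode = integer(), x = numeric(),
                                    y = numeric()), hull = integer(),
                maxima = c(x = NA_real_, y = NA_real_)))
  }
  pts <- data.frame(mode = which(ok),
                    x = as.numeric(yx$value)[ok],
                    y = as.numeric(yy$value)[ok])
  hull <- if (nrow(pts) >= 3) rev(grDevices::chull(pts$x, pts$y))
          else seq_len(nrow(pts))
  list(points = pts, hull = hull,
       maxima = c(x = max(pts$x), y = max(pts$y)))
}
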