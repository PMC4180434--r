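#' Linear programming with exact rational or floating-point arithmetic
#'
#' All flux-balance computations in the package go through this two-phase
#' primal simplex. Bland's anti-cycling rule makes it finite and fully
#' deterministic. Two arithmetic backends are provided:
#'
#' * `"exact"`: every tableau entry is an exact rational ([rq]). Optima such
#'   as the 9/7 ATP:NADPH ratio of linear electron flow or the 7:6 demand of
#'   ethanol synthesis come out as exact fractions, with no tolerance.
#' * `"double"`: ordinary floating point with a 1e-9 pivot tolerance, used
#'   in the inner loops of the intervention sweep where thousands of small
#'   feasibility LPs are solved.
#'
#' The problem is `min/max obj'x` subject to `A x = b` and `lb <= x <= ub`
#' (entries of `lb`/`ub` may be infinite).
#'
#' @param obj objective coefficients (length n); numeric, character
#'   fractions or [rq].
#' @param A equality-constraint matrix (m x n).
#' @param b right-hand side (length m).
#' @param lb,ub variable bounds, recycled to length n; `-Inf`/`Inf` allowed.
#' @param maximize maximize instead of minimize.
#' @param arithmetic `"exact"` or `"double"`.
#' @return a list with `status` (`"optimal"`, `"infeasible"`, `"unbounded"`),
#'   `objval` ([rq] for exact arithmetic, numeric otherwise) and `x`, the
#'   primal solution in the original variables.
#' @export
solve_lp <- function(obj, A, b, lb = 0, ub = Inf, maximize = FALSE,
                     arithmetic = c("exact", "double")) {
  arithmetic <- match.arg(arithmetic)
  n <- if (is_rq(obj)) length(obj) else length(obj)
  m <- if (is_rq(A)) dim(A)[1] else nrow(A)
  lb <- rep_len(lb, n)
  ub <- rep_len(ub, n)
  if (any(lb > ub)) return(list(status = "infeasible", objval = NULL, x = NULL))
  if (arithmetic == "double") {
    return(solve_lp_dbl(to_num(obj), to_num(A), to_num(b), lb, ub, maximize))
  }
  solve_lp_rq(as_rq_vec(obj), as_rq_mat(A, m, n), as_rq_vec(b), lb, ub, maximize)
}

to_num <- function(x) if (is_rq(x)) as.numeric(x) else x
as_rq_vec <- function(x) if (is_rq(x)) x else as_rq(x)
as_rq_mat <- function(x, m, n) {
  if (is_rq(x)) return(x)
  out <- as_rq(x)
  dim(out) <- c(m, n)
  out
}

# ---- exact rational backend ------------------------------------------------

rq_outer <- function(a, b) {
  rq_reduce(structure(list(n = outer(as.vector(a$n), as.vector(b$n)),
                           d = outer(as.vector(a$d), as.vector(b$d))),
                      class = "rq"))
}

# standard-form conversion shared by both backends (returns plain lists;
# exact backend converts pieces to rq afterwards)
lp_standardize <- function(A, b, obj, lb, ub) {
  n <- length(obj)
  cols <- list(); ccoef <- list(); map <- list()
  shift <- numeric(n)          # x_j = sign_j * y_k + shift_j (or y+ - y-)
  ubrow_var <- integer(0); ubrow_val <- numeric(0)
  k <- 0
  for (j in seq_len(n)) {
    if (is.finite(lb[j])) {
      k <- k + 1
      cols[[k]] <- list(j = j, sgn = 1)
      shift[j] <- lb[j]
      if (is.finite(ub[j])) { ubrow_var <- c(ubrow_var, k); ubrow_val <- c(ubrow_val, ub[j] - lb[j]) }
      map[[j]] <- list(kind = "shift", k = k, sgn = 1)
    } else if (is.finite(ub[j])) {
      k <- k + 1
      cols[[k]] <- list(j = j, sgn = -1)
      shift[j] <- ub[j]
      map[[j]] <- list(kind = "shift", k = k, sgn = -1)
    } else {
      k <- k + 1
      cols[[k]] <- list(j = j, sgn = 1)
      k <- k + 1
      cols[[k]] <- list(j = j, sgn = -1)
      map[[j]] <- list(kind = "free", kplus = k - 1, kminus = k)
    }
  }
  list(cols = cols, map = map, shift = shift, nvar = k,
       ubrow_var = ubrow_var, ubrow_val = ubrow_val)
}

solve_lp_rq <- function(obj, A, b, lb, ub, maximize) {
  n <- length(obj)
  m <- dim(A)[1]
  sf <- lp_standardize(as.numeric(A), as.numeric(b), as.numeric(obj), lb, ub)
  nv <- sf$nvar
  nub <- length(sf$ubrow_var)
  M <- m + nub
  N <- nv + nub
  # build standard-form data in rationals
  As <- rq_zeros(M, N)
  bs <- rq_zeros(M)
  cs <- rq_zeros(N)
  if (maximize) obj <- -obj
  for (k in seq_len(nv)) {
    cl <- sf$cols[[k]]
    colv <- A[, cl$j]
    if (cl$sgn < 0) colv <- -colv
    As[seq_len(m), k] <- colv
    cs[k] <- if (cl$sgn < 0) -obj[cl$j] else obj[cl$j]
  }
  shift <- as_rq(vapply(sf$shift, identity, 0))
  bs[seq_len(m)] <- b - rq_matvec(A, shift)
  const <- rq(0)
  for (j in seq_len(n)) if (sf$shift[j] != 0) const <- const + obj[j] * shift[j]
  if (nub > 0) {
    for (r in seq_len(nub)) {
      As[m + r, sf$ubrow_var[r]] <- rq(1)
      As[m + r, nv + r] <- rq(1)
      bs[m + r] <- as_rq(sf$ubrow_val[r])
    }
  }
  res <- simplex_rq(As, bs, cs)
  if (res$status != "optimal")
    return(list(status = res$status, objval = NULL, x = NULL))
  # map back
  x <- rq_zeros(n)
  for (j in seq_len(n)) {
    mp <- sf$map[[j]]
    if (mp$kind == "shift") {
      v <- res$x[mp$k]
      if (mp$sgn < 0) v <- -v
      x[j] <- v + as_rq(sf$shift[j])
    } else {
      x[j] <- res$x[mp$kplus] - res$x[mp$kminus]
    }
  }
  objval <- res$objval + const
  if (maximize) objval <- -objval
  list(status = "optimal", objval = objval, x = x)
}

# two-phase simplex, min c'y s.t. As y = bs, y >= 0, exact rationals
simplex_rq <- function(As, bs, cs) {
  M <- dim(As)[1]; N <- dim(As)[2]
  neg <- which(bs < 0)
  if (length(neg)) {
    As[neg, ] <- -As[neg, , drop = FALSE]
    bs[neg] <- -bs[neg]
  }
  # phase 1 tableau: columns = structural + artificial, plus rhs
  Tb <- rq_zeros(M + 1, N + M + 1)
  Tb[seq_len(M), seq_len(N)] <- As
  for (i in seq_len(M)) Tb[i, N + i] <- rq(1)
  Tb[seq_len(M), N + M + 1] <- bs
  basis <- N + seq_len(M)
  # phase-1 objective: sum of artificials; z-row = -(sum of constraint rows)
  for (j in seq_len(N + M + 1)) {
    s <- rq(0)
    for (i in seq_len(M)) if (Tb$n[i, j] != 0) s <- s + Tb[i, j]
    Tb[M + 1, j] <- -s
  }
  for (i in seq_len(M)) Tb[M + 1, N + i] <- rq(0)
  out <- simplex_iterate_rq(Tb, basis, ncol_active = N + M)
  Tb <- out$Tb; basis <- out$basis
  if (Tb$n[M + 1, N + M + 1] != 0)  # phase-1 optimum < 0 => infeasible
    return(list(status = "infeasible"))
  # drive artificials out of the basis where possible; drop redundant rows
  keep <- rep(TRUE, M)
  for (i in seq_len(M)) {
    if (basis[i] > N) {
      piv <- which(Tb$n[i, seq_len(N)] != 0)
      if (length(piv)) {
        Tb <- pivot_rq(Tb, i, piv[1])
        basis[i] <- piv[1]
      } else keep[i] <- FALSE   # redundant constraint (row is all zeros)
    }
  }
  rows <- c(which(keep), M + 1)
  Tb <- Tb[rows, c(seq_len(N), N + M + 1), drop = FALSE]
  basis <- basis[keep]
  M2 <- length(basis)
  # phase 2 objective row
  z <- rq_zeros(N + 1)
  z[seq_len(N)] <- cs
  for (i in seq_len(M2)) {
    cb <- cs[basis[i]]
    if (cb$n != 0) {
      for (j in seq_len(N + 1)) {
        if (Tb$n[i, j] != 0) z[j] <- z[j] - cb * Tb[i, j]
      }
    }
  }
  Tb[M2 + 1, ] <- z
  out <- simplex_iterate_rq(Tb, basis, ncol_active = N)
  if (out$status == "unbounded") return(list(status = "unbounded"))
  Tb <- out$Tb; basis <- out$basis
  x <- rq_zeros(N)
  rhs <- Tb[seq_len(M2), N + 1]
  for (i in seq_len(M2)) x[basis[i]] <- rhs[i]
  list(status = "optimal", objval = -Tb[M2 + 1, N + 1], x = x)
}

simplex_iterate_rq <- function(Tb, basis, ncol_active) {
  M <- dim(Tb)[1] - 1
  rhs_col <- dim(Tb)[2]
  repeat {
    # Bland: first column with negative reduced cost
    zn <- Tb$n[M + 1, seq_len(ncol_active)]
    q <- which(zn < 0)
    if (!length(q)) return(list(status = "optimal", Tb = Tb, basis = basis))
    q <- q[1]
    coln <- Tb$n[seq_len(M), q]
    pos <- which(coln > 0)
    if (!length(pos)) return(list(status = "unbounded", Tb = Tb, basis = basis))
    # ratio test with Bland tie-break on basis index
    best <- -1; best_ratio <- NULL
    for (i in pos) {
      r <- Tb[i, rhs_col] / Tb[i, q]
      if (best < 0 || r < best_ratio ||
          (r == best_ratio && basis[i] < basis[best])) {
        best <- i; best_ratio <- r
      }
    }
    Tb <- pivot_rq(Tb, best, q)
    basis[best] <- q
  }
}

pivot_rq <- function(Tb, p, q) {
  prow <- Tb[p, , drop = TRUE]
  prow <- prow / prow[q]
  colv <- Tb[, q, drop = TRUE]
  colv[p] <- rq(0)
  upd <- rq_outer(colv, prow)
  Tb <- Tb - upd
  Tb[p, ] <- prow
  Tb
}

# ---- double-precision backend ----------------------------------------------

LP_EPS <- 1e-9

solve_lp_dbl <- function(obj, A, b, lb, ub, maximize) {
  n <- length(obj)
  m <- nrow(A)
  sf <- lp_standardize(A, b, obj, lb, ub)
  nv <- sf$nvar
  nub <- length(sf$ubrow_var)
  M <- m + nub; N <- nv + nub
  if (maximize) obj <- -obj
  As <- matrix(0, M, N); bs <- numeric(M); cs <- numeric(N)
  for (k in seq_len(nv)) {
    cl <- sf$cols[[k]]
    As[seq_len(m), k] <- cl$sgn * A[, cl$j]
    cs[k] <- cl$sgn * obj[cl$j]
  }
  bs[seq_len(m)] <- b - as.vector(A %*% sf$shift)
  const <- sum(obj * sf$shift)
  if (nub > 0) {
    for (r in seq_len(nub)) {
      As[m + r, sf$ubrow_var[r]] <- 1
      As[m + r, nv + r] <- 1
      bs[m + r] <- sf$ubrow_val[r]
    }
  }
  res <- simplex_dbl(As, bs, cs)
  if (res$status != "optimal")
    return(list(status = res$status, objval = NULL, x = NULL))
  x <- numeric(n)
  for (j in seq_len(n)) {
    mp <- sf$map[[j]]
    x[j] <- if (mp$kind == "shift") mp$sgn * res$x[mp$k] + sf$shift[j]
            else res$x[mp$kplus] - res$x[mp$kminus]
  }
  objval <- res$objval + const
  if (maximize) objval <- -objval
  list(status = "optimal", objval = objval, x = x)
}

simplex_dbl <- function(As, bs, cs) {
  M <- nrow(As); N <- ncol(As)
  neg <- bs < -LP_EPS
  As[neg, ] <- -As[neg, , drop = FALSE]
  bs[neg] <- -bs[neg]
  Tb <- cbind(As, diag(M), bs)
  z <- -colSums(Tb)
  z[N + seq_len(M)] <- 0
  Tb <- rbind(Tb, z)
  basis <- N + seq_len(M)
  out <- simplex_iterate_dbl(Tb, basis, N + M)
  Tb <- out$Tb; basis <- out$basis
  if (Tb[M + 1, N + M + 1] < -1e-7) return(list(status = "infeasible"))
  keep <- rep(TRUE, M)
  for (i in seq_len(M)) {
    if (basis[i] > N) {
      piv <- which(abs(Tb[i, seq_len(N)]) > LP_EPS)
      if (length(piv)) {
        Tb <- pivot_dbl(Tb, i, piv[1]); basis[i] <- piv[1]
      } else keep[i] <- FALSE
    }
  }
  Tb <- Tb[c(which(keep), M + 1), c(seq_len(N), N + M + 1), drop = FALSE]
  basis <- basis[keep]
  M2 <- length(basis)
  z <- c(cs, 0)
  for (i in seq_len(M2)) if (abs(cs[basis[i]]) > 0) z <- z - cs[basis[i]] * Tb[i, ]
  Tb[M2 + 1, ] <- z
  out <- simplex_iterate_dbl(Tb, basis, N)
  if (out$status == "unbounded") return(list(status = "unbounded"))
  Tb <- out$Tb; basis <- out$basis
  x <- numeric(N)
  x[basis] <- Tb[seq_len(M2), N + 1]
  list(status = "optimal", objval = -Tb[M2 + 1, N + 1], x = x)
}

simplex_iterate_dbl <- function(Tb, basis, ncol_active) {
  M <- nrow(Tb) - 1
  rhs <- ncol(Tb)
  repeat {
    q <- which(Tb[M + 1, seq_len(ncol_active)] < -LP_EPS)
    if (!length(q)) return(list(status = "optimal", Tb = Tb, basis = basis))
    q <- q[1]
    pos <- which(Tb[seq_len(M), q] > LP_EPS)
    if (!length(pos)) return(list(status = "unbounded", Tb = Tb, basis = basis))
    ratios <- Tb[pos, rhs] / Tb[pos, q]
    rmin <- min(ratios)
    cand <- pos[ratios <= rmin + LP_EPS]
    p <- cand[which.min(basis[cand])]
    Tb <- pivot_dbl(Tb, p, q)
    basis[p] <- q
  }
}

pivot_dbl <- function(Tb, p, q) {
  prow <- Tb[p, ] / Tb[p, q]
  Tb <- Tb - outer(Tb[, q], prow)
  Tb[p, ] <- prow
  Tb[abs(Tb) < 1e-12] <- 0
  Tb
}
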