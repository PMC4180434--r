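#' Exact rational arithmetic
#'
#' Stoichiometric coefficients, elementary-mode flux vectors and cut-set
#' validity checks are combinatorial facts: whether a coefficient is exactly
#' `3/14` or a support is exactly minimal must not depend on floating-point
#' drift. The package therefore carries an exact rational number type through
#' the whole tableau pipeline. Numerators and denominators are stored as
#' integer-valued doubles, which are exact up to 2^53; every operation
#' reduces by the gcd and aborts loudly if that range is ever exceeded.
#'
#' `rq()` builds a rational vector (or matrix, if `num` has a `dim`
#' attribute), `as_rq()` converts numerics and strings like `"3/14"`.
#'
#' @param num integer-valued numerators (vector or matrix).
#' @param den integer-valued denominators, recycled against `num`.
#' @return an object of class `rq` with fields `n` and `d`.
#' @examples
#' rq(3, 14) + rq(1, 7)   # 5/14
#' as_rq("9/7") > as_rq(1.28)
#' @export
rq <- function(num, den = 1) {
  if (length(den) != length(num)) den <- rep_len(den, length(num))
  if (!is.null(dim(num))) dim(den) <- dim(num)
  storage.mode(num) <- "double"
  storage.mode(den) <- "double"
  rq_reduce(structure(list(n = num, d = den), class = "rq"))
}

RQ_MAX <- 2^53

rq_reduce <- function(x) {
  if (any(x$d == 0)) stop("rational with zero denominator")
  # overflow must be caught before reduction: beyond 2^53 the raw products
  # feeding this reduction are no longer exact integers
  if (any(abs(x$n) >= RQ_MAX) || any(abs(x$d) >= RQ_MAX))
    stop("rational arithmetic overflow (coefficient exceeds 2^53)")
  neg <- x$d < 0
  if (any(neg)) {
    x$n[neg] <- -x$n[neg]
    x$d[neg] <- -x$d[neg]
  }
  g <- gcd_num(abs(x$n), x$d)
  g[g == 0] <- 1
  x$n <- x$n / g
  x$d <- x$d / g
  x
}

# vectorized Euclid on nonnegative integer-valued doubles
gcd_num <- function(a, b) {
  repeat {
    act <- which(b != 0)
    if (!length(act)) return(a)
    r <- a[act] %% b[act]
    a[act] <- b[act]
    b[act] <- r
  }
}

#' @export
is_rq <- function(x) inherits(x, "rq")

#' @rdname rq
#' @param x numeric, character (e.g. `"3/14"`, `"-2"`) or `rq`.
#' @export
as_rq <- function(x) {
  if (is_rq(x)) return(x)
  if (is.character(x)) {
    parts <- strsplit(x, "/", fixed = TRUE)
    n <- suppressWarnings(vapply(parts, function(p) as.numeric(p[[1]]), 0))
    d <- suppressWarnings(vapply(parts, function(p)
      if (length(p) > 1) as.numeric(p[[2]]) else 1, 0))
    if (any(is.na(n)) || any(is.na(d)) || any(n != trunc(n)) || any(d != trunc(d)))
      stop("cannot parse as exact rational: ",
           paste(x[is.na(n) | is.na(d) | n != trunc(n) | d != trunc(d)], collapse = ", "))
    out <- rq(n, d)
    if (!is.null(dim(x))) dim(out) <- dim(x)
    return(out)
  }
  if (!is.numeric(x)) stop("cannot convert to rational")
  if (all(x == trunc(x))) return(rq(x))
  # short decimals are exact in base 10; scale by a power of ten
  k <- 0
  y <- x
  while (any(y != trunc(y)) && k < 12) {
    y <- y * 10
    k <- k + 1
    y <- round(y, 12 - k)
  }
  if (any(y != trunc(y))) stop("numeric value is not a short decimal; pass a string fraction instead")
  out <- rq(y, 10^k)
  if (!is.null(dim(x))) dim(out) <- dim(x)
  out
}

#' @export
length.rq <- function(x) length(x$n)

#' @export
dim.rq <- function(x) dim(x$n)

#' @export
`dim<-.rq` <- function(x, value) {
  dim(x$n) <- value
  dim(x$d) <- value
  x
}

#' @export
`[.rq` <- function(x, i, j, drop = TRUE) {
  if (is.null(dim(x)) || missing(j) && nargs() < 3) {
    structure(list(n = x$n[i], d = x$d[i]), class = "rq")
  } else {
    structure(list(n = x$n[i, j, drop = drop],
                   d = x$d[i, j, drop = drop]), class = "rq")
  }
}

#' @export
`[<-.rq` <- function(x, i, j, value) {
  value <- as_rq(value)
  if (is.null(dim(x)) || nargs() < 4) {
    x$n[i] <- value$n
    x$d[i] <- value$d
  } else {
    x$n[i, j] <- value$n
    x$d[i, j] <- value$d
  }
  x
}

#' @export
Ops.rq <- function(e1, e2) {
  if (.Generic %in% c("+", "-", "*", "/")) {
    if (missing(e2)) {
      if (.Generic == "-") return(rq_reduce(structure(list(n = -e1$n, d = e1$d),
                                                      class = "rq")))
      return(e1)
    }
    e1 <- as_rq(e1); e2 <- as_rq(e2)
    out <- switch(.Generic,
      "+" = list(n = e1$n * e2$d + e2$n * e1$d, d = e1$d * e2$d),
      "-" = list(n = e1$n * e2$d - e2$n * e1$d, d = e1$d * e2$d),
      "*" = list(n = e1$n * e2$n, d = e1$d * e2$d),
      "/" = {
        if (any(e2$n == 0)) stop("rational division by zero")
        list(n = e1$n * e2$d, d = e1$d * e2$n)
      })
    return(rq_reduce(structure(out, class = "rq")))
  }
  if (.Generic %in% c("==", "!=", "<", "<=", ">", ">=")) {
    e1 <- as_rq(e1); e2 <- as_rq(e2)
    lhs <- e1$n * e2$d
    rhs <- e2$n * e1$d
    return(get(.Generic)(lhs, rhs))
  }
  stop("operation ", .Generic, " not defined for rationals")
}

#' @export
as.double.rq <- function(x, ...) x$n / x$d

#' @export
as.numeric.rq <- function(x, ...) x$n / x$d

#' @export
format.rq <- function(x, ...) {
  out <- ifelse(x$d == 1, format(x$n, scientific = FALSE, trim = TRUE),
                paste0(format(x$n, scientific = FALSE, trim = TRUE), "/",
                       format(x$d, scientific = FALSE, trim = TRUE)))
  dim(out) <- dim(x)
  out
}

#' @export
print.rq <- function(x, ...) {
  print(format(x), quote = FALSE)
  invisible(x)
}

#' @export
c.rq <- function(...) {
  xs <- lapply(list(...), as_rq)
  structure(list(n = unlist(lapply(xs, `[[`, "n")),
                 d = unlist(lapply(xs, `[[`, "d"))), class = "rq")
}

#' @export
sum.rq <- function(x, ..., na.rm = FALSE) {
  acc <- rq(0)
  for (i in seq_len(length(x))) acc <- acc + x[i]
  acc
}

rq_rep <- function(value, times) {
  value <- as_rq(value)
  structure(list(n = rep(value$n, length.out = times),
                 d = rep(value$d, length.out = times)), class = "rq")
}

rq_zeros <- function(nr, nc = NULL) {
  if (is.null(nc)) return(rq(numeric(nr)))
  rq(matrix(0, nr, nc))
}

# common denominator scaling: returns integer vector proportional to x
rq_to_integer_vector <- function(x) {
  if (length(x) == 0) return(numeric(0))
  l <- 1
  for (dd in unique(x$d)) l <- l / gcd_num(l, dd) * dd
  v <- x$n * (l / x$d)
  g <- 0
  for (vv in abs(v)) g <- gcd_num(g, vv)
  if (g > 1) v <- v / g
  if (any(abs(v) >= RQ_MAX)) stop("rational arithmetic overflow while clearing denominators")
  v
}

# rational matrix product (A: rq matrix, x: rq vector) -> rq vector
rq_matvec <- function(A, x) {
  nr <- dim(A)[1]; nc <- dim(A)[2]
  stopifnot(length(x) == nc)
  out_n <- numeric(nr); out_d <- rep(1, nr)
  for (i in seq_len(nr)) {
    acc_n <- 0; acc_d <- 1
    nz <- which(A$n[i, ] != 0 & x$n != 0)
    for (j in nz) {
      pn <- A$n[i, j] * x$n[j]
      pd <- A$d[i, j] * x$d[j]
      nn <- acc_n * pd + pn * acc_d
      nd <- acc_d * pd
      g <- gcd_num(abs(nn), nd); if (g == 0) g <- 1
      acc_n <- nn / g; acc_d <- nd / g
      if (abs(acc_n) >= RQ_MAX || acc_d >= RQ_MAX)
        stop("rational arithmetic overflow in matrix product")
    }
    out_n[i] <- acc_n; out_d[i] <- acc_d
  }
  structure(list(n = out_n, d = out_d), class = "rq")
}
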