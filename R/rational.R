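# Exact rational arithmetic on numerator/denominator pairs stored as doubles.
# All quantities arising here (scaling exponents, constraint coefficients) are
# small integers or ratios of small integers; a guard aborts before the
# integer-exact range of doubles (2^53) could be exceeded.

.RAT_MAX <- 2^48

.gcd2 <- function(a, b) {
  a <- abs(a); b <- abs(b)
  while (b > 0) {
    tmp <- a %% b
    a <- b
    b <- tmp
  }
  a
}

.rat_guard <- function(x) {
  if (any(abs(x) > .RAT_MAX)) {
    stop(errorCondition("rational arithmetic overflow (coefficients too large)",
                        class = c("scalesid_overflow", "scalesid_error")))
  }
  x
}

#' @noRd
rq <- function(num, den = rep(1, length(num))) {
  if (any(den == 0)) stop("zero denominator in rational")
  if (any(num != round(num)) || any(den != round(den)))
    stop("rational components must be integers")
  s <- ifelse(den < 0, -1, 1)
  num <- num * s; den <- den * s
  g <- mapply(.gcd2, num, den)
  g[g == 0] <- 1
  structure(list(num = .rat_guard(num / g), den = den / g), class = "scalesid_rq")
}

rq_len <- function(x) length(x$num)

rq_add <- function(a, b) rq(a$num * b$den + b$num * a$den, a$den * b$den)
rq_sub <- function(a, b) rq(a$num * b$den - b$num * a$den, a$den * b$den)
rq_mul <- function(a, b) rq(a$num * b$num, a$den * b$den)
rq_div <- function(a, b) {
  if (any(b$num == 0)) stop("division by rational zero")
  rq(a$num * b$den, a$den * b$num)
}
rq_neg <- function(a) rq(-a$num, a$den)
rq_is_zero <- function(a) a$num == 0
rq_eq <- function(a, b) (a$num * b$den) == (b$num * a$den)
rq_num <- function(a) a$num / a$den

rq_c <- function(...) {
  xs <- list(...)
  rq(unlist(lapply(xs, `[[`, "num")), unlist(lapply(xs, `[[`, "den")))
}

rq_slice <- function(a, i) rq(a$num[i], a$den[i])

# integer-exponent power of a scalar rational
rq_pow <- function(a, e) {
  stopifnot(e == round(e))
  if (e >= 0) rq(a$num^e, a$den^e) else {
    if (a$num == 0) stop("division by rational zero")
    rq(a$den^(-e), a$num^(-e))
  }
}

# double -> exact rational via continued fractions (used for decimal literals)
rq_from_double <- function(x, max_den = 1e6, tol = 1e-12) {
  if (x == round(x)) return(rq(x, 1))
  p0 <- 0; q0 <- 1; p1 <- 1; q1 <- 0
  r <- x
  for (i in 1:64) {
    a <- floor(r)
    p <- a * p1 + p0; q <- a * q1 + q0
    if (q > max_den) break
    p0 <- p1; q0 <- q1; p1 <- p; q1 <- q
    if (abs(p / q - x) < tol * max(1, abs(x))) return(rq(p, q))
    frac <- r - a
    if (frac < 1e-15) break
    r <- 1 / frac
  }
  stop(errorCondition(sprintf("cannot represent %g as a small exact rational", x),
                      class = c("scalesid_inexact_constant", "scalesid_error")))
}

# ---- rational matrices: list(num = matrix, den = matrix) --------------------

rqm <- function(num, den = NULL) {
  if (is.null(den)) den <- matrix(1, nrow(num), ncol(num))
  r <- rq(as.vector(num), as.vector(den))
  list(num = matrix(r$num, nrow(num)), den = matrix(r$den, nrow(num)))
}

rqm_nrow <- function(m) nrow(m$num)
rqm_ncol <- function(m) ncol(m$num)

rqm_rbind <- function(a, b) {
  if (is.null(a)) return(b)
  list(num = rbind(a$num, b$num), den = rbind(a$den, b$den))
}

rqm_get <- function(m, i, j) rq(m$num[i, j], m$den[i, j])

rqm_row <- function(m, i) rq(m$num[i, ], m$den[i, ])

rqm_from_rows <- function(rows, ncol) {
  if (length(rows) == 0) return(rqm(matrix(0, 0, ncol)))
  list(num = do.call(rbind, lapply(rows, `[[`, "num")),
       den = do.call(rbind, lapply(rows, `[[`, "den")))
}

rqm_to_double <- function(m) m$num / m$den

#' Reduced row-echelon form of an exact rational matrix.
#' @return list(mat = RREF matrix, pivots = pivot column indices)
#' @noRd
rqm_rref <- function(m) {
  nr <- rqm_nrow(m); nc <- rqm_ncol(m)
  num <- m$num; den <- m$den
  pivots <- integer(0)
  r <- 1
  for (col in seq_len(nc)) {
    if (r > nr) break
    pr <- which(num[r:nr, col] != 0)
    if (length(pr) == 0) next
    pr <- pr[1] + r - 1
    if (pr != r) {
      num[c(r, pr), ] <- num[c(pr, r), ]
      den[c(r, pr), ] <- den[c(pr, r), ]
    }
    piv <- rq(num[r, col], den[r, col])
    row_r <- rq_div(rq(num[r, ], den[r, ]), piv)
    num[r, ] <- row_r$num; den[r, ] <- row_r$den
    for (i in seq_len(nr)) {
      if (i == r || num[i, col] == 0) next
      fac <- rq(num[i, col], den[i, col])
      upd <- rq_sub(rq(num[i, ], den[i, ]), rq_mul(fac, row_r))
      num[i, ] <- upd$num; den[i, ] <- upd$den
    }
    pivots <- c(pivots, col)
    r <- r + 1
  }
  list(mat = list(num = num, den = den), pivots = pivots)
}

#' Exact rational nullspace basis (list of rational vectors, length ncol).
#' @noRd
rqm_nullspace <- function(m) {
  nc <- rqm_ncol(m)
  if (rqm_nrow(m) == 0) {
    return(lapply(seq_len(nc), function(j) {
      v <- numeric(nc); v[j] <- 1; rq(v)
    }))
  }
  rr <- rqm_rref(m)
  pivots <- rr$pivots
  free <- setdiff(seq_len(nc), pivots)
  lapply(free, function(j) {
    vn <- numeric(nc); vd <- rep(1, nc)
    vn[j] <- 1
    # pivot rows: x_pivot = -coef * x_free
    for (k in seq_along(pivots)) {
      entry <- rqm_get(rr$mat, k, j)
      if (!rq_is_zero(entry)) {
        e <- rq_neg(entry)
        vn[pivots[k]] <- e$num; vd[pivots[k]] <- e$den
      }
    }
    rq(vn, vd)
  })
}

#' Scale a rational vector to a primitive integer vector, first nonzero > 0.
#' @noRd
rq_primitive <- function(v) {
  if (all(v$num == 0)) return(rep(0L, rq_len(v)))
  l <- Reduce(function(a, b) a / .gcd2(a, b) * b, v$den[v$num != 0], accumulate = FALSE)
  ints <- .rat_guard(v$num * (l / v$den))
  g <- Reduce(.gcd2, abs(ints[ints != 0]))
  ints <- ints / g
  if (ints[which(ints != 0)[1]] < 0) ints <- -ints
  ints
}

# dot product of a rational matrix row with an integer/rational vector
rq_dot <- function(a, b) {
  acc <- rq(0)
  for (i in seq_len(rq_len(a))) {
    acc <- rq_add(acc, rq_mul(rq_slice(a, i), rq_slice(b, i)))
  }
  acc
}
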