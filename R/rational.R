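# Exact rational arithmetic for stoichiometric matrices.
#
# Stoichiometric coefficients are stored as numerator/denominator pairs so
# that rank and null-space computations (free-flux accounting, conservation
# checks) are exact rather than tolerance-based.  Numerators stay far below
# 2^53 for any realistic network, so doubles holding integers are safe.

gcd2 <- function(a, b) {
  a <- abs(a); b <- abs(b)
  while (b > 0) { t <- a %% b; a <- b; b <- t }
  a
}

rat_reduce <- function(num, den) {
  stopifnot(all(den != 0))
  sign_fix <- den < 0
  num[sign_fix] <- -num[sign_fix]
  den[sign_fix] <- -den[sign_fix]
  for (i in seq_along(num)) {
    if (num[i] == 0) { den[i] <- 1; next }
    g <- gcd2(num[i], den[i])
    num[i] <- num[i] / g
    den[i] <- den[i] / g
  }
  list(num = num, den = den)
}

#' Parse a stoichiometric coefficient into an exact rational
#'
#' Accepts integers, doubles that are exact ratios with small denominator
#' (detected up to denominator 48), or strings like `"-3/2"`.
#'
#' @param x Scalar number or string.
#' @return List with integer-valued `num` and `den`.
#' @keywords internal
rat_parse <- function(x) {
  if (is.character(x)) {
    if (grepl("/", x, fixed = TRUE)) {
      parts <- strsplit(x, "/", fixed = TRUE)[[1]]
      if (length(parts) != 2L) stop("malformed rational coefficient: ", x)
      return(rat_reduce(as.numeric(parts[1]), as.numeric(parts[2])))
    }
    x <- as.numeric(x)
  }
  if (x == round(x)) return(list(num = x, den = 1))
  for (d in 2:48) if (abs(x * d - round(x * d)) < 1e-9) {
    return(rat_reduce(round(x * d), d))
  }
  stop("coefficient ", x, " is not an exact small rational; write it as \"p/q\"")
}

# Fraction-free reduced row echelon form of a rational matrix given as
# numerator/denominator matrices.  Returns the rref pair plus pivot columns.
rat_rref <- function(num, den) {
  nr <- nrow(num); nc <- ncol(num)
  pivots <- integer(0)
  row <- 1L
  add_scaled <- function(ni, di, nj, dj, fn, fd) {
    # row_i <- row_i - (fn/fd) * row_j, elementwise on rational pairs
    out_n <- ni * di * 0
    out_d <- out_n + 1
    for (k in seq_len(nc)) {
      # a/b - (fn/fd)*(c/d) = (a*fd*d - fn*c*b) / (b*fd*d)
      a <- ni[k]; b <- di[k]; c <- nj[k]; d <- dj[k]
      rn <- a * fd * d - fn * c * b
      rd <- b * fd * d
      r <- rat_reduce(rn, rd)
      out_n[k] <- r$num; out_d[k] <- r$den
    }
    list(num = out_n, den = out_d)
  }
  for (col in seq_len(nc)) {
    if (row > nr) break
    piv <- which(num[row:nr, col] != 0)
    if (length(piv) == 0L) next
    p <- row + piv[1L] - 1L
    if (p != row) {
      num[c(row, p), ] <- num[c(p, row), ]
      den[c(row, p), ] <- den[c(p, row), ]
    }
    # normalize pivot row to leading 1
    pn <- num[row, col]; pd <- den[row, col]
    r <- rat_reduce(num[row, ] * pd, den[row, ] * pn)
    num[row, ] <- r$num; den[row, ] <- r$den
    for (i in seq_len(nr)) {
      if (i == row || num[i, col] == 0) next
      upd <- add_scaled(num[i, ], den[i, ], num[row, ], den[row, ],
                        num[i, col], den[i, col])
      num[i, ] <- upd$num; den[i, ] <- upd$den
    }
    pivots <- c(pivots, col)
    row <- row + 1L
  }
  list(num = num, den = den, pivots = pivots)
}

#' Exact rank of a rational matrix
#' @param num,den Numerator and denominator matrices (same shape).
#' @keywords internal
rat_rank <- function(num, den = NULL) {
  if (is.null(den)) den <- matrix(1, nrow(num), ncol(num))
  if (nrow(num) == 0L || ncol(num) == 0L) return(0L)
  length(rat_rref(num, den)$pivots)
}

#' Exact null-space basis of a rational matrix
#'
#' Returns a rational basis (columns) of `{x : M x = 0}` via the RREF free
#' columns, as a numerator/denominator pair of `ncol(M) x f` matrices.
#' @keywords internal
rat_nullspace <- function(num, den = NULL) {
  if (is.null(den)) den <- matrix(1, nrow(num), ncol(num))
  nc <- ncol(num)
  if (nrow(num) == 0L) {
    return(list(num = diag(nc), den = matrix(1, nc, nc)))
  }
  r <- rat_rref(num, den)
  free_cols <- setdiff(seq_len(nc), r$pivots)
  f <- length(free_cols)
  bn <- matrix(0, nc, f)
  bd <- matrix(1, nc, f)
  for (j in seq_along(free_cols)) {
    fc <- free_cols[j]
    bn[fc, j] <- 1
    for (i in seq_along(r$pivots)) {
      # pivot row i has leading 1 in column pivots[i]; x_piv = -coef * x_free
      bn[r$pivots[i], j] <- -r$num[i, fc]
      bd[r$pivots[i], j] <- r$den[i, fc]
    }
  }
  red <- rat_reduce(bn, bd)
  list(num = matrix(red$num, nc, f), den = matrix(red$den, nc, f))
}
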