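# Exact rational arithmetic on machine doubles used as arbitrary-precision-free
# integers. Every value is kept strictly below 2^53 and any operation that
# would leave that range aborts, so floating point never silently rounds and
# never decides a sign. Rational vectors/matrices are stored as a list with
# components `n` (numerators) and `d` (positive denominators), always reduced.

.INT_MAX_EXACT <- 2^53

.chk_exact <- function(x) {
  if (any(!is.finite(x)) || any(abs(x) >= .INT_MAX_EXACT)) {
    stop("exact integer overflow in rational arithmetic", call. = FALSE)
  }
  x
}

.gcd2 <- function(a, b) {
  a <- abs(a); b <- abs(b)
  while (any(b != 0)) {
    t <- b
    b <- ifelse(b != 0, a %% b, 0)
    a <- ifelse(t != 0, t, a)
  }
  a
}

.lcm2 <- function(a, b) {
  g <- .gcd2(a, b)
  .chk_exact(ifelse(g == 0, 0, abs(a / g * b)))
}

#' @noRd
rat <- function(n, d = rep(1, length(n))) {
  rat_norm(list(n = as.numeric(n), d = as.numeric(d)))
}

rat_norm <- function(x) {
  n <- .chk_exact(x$n); d <- .chk_exact(x$d)
  if (any(d == 0)) stop("zero denominator", call. = FALSE)
  s <- ifelse(d < 0, -1, 1)
  n <- n * s; d <- d * s
  g <- .gcd2(n, d)
  g[g == 0] <- 1
  list(n = n / g, d = d / g)
}

rat_add <- function(a, b) rat_norm(list(n = .chk_exact(a$n * b$d + b$n * a$d), d = .chk_exact(a$d * b$d)))
rat_sub <- function(a, b) rat_add(a, list(n = -b$n, d = b$d))
rat_mul <- function(a, b) {
  # cross-reduce first to keep magnitudes down
  g1 <- .gcd2(a$n, b$d); g1[g1 == 0] <- 1
  g2 <- .gcd2(b$n, a$d); g2[g2 == 0] <- 1
  rat_norm(list(n = .chk_exact((a$n / g1) * (b$n / g2)), d = .chk_exact((a$d / g2) * (b$d / g1))))
}
rat_div <- function(a, b) {
  if (any(b$n == 0)) stop("division by zero rational", call. = FALSE)
  rat_mul(a, rat_norm(list(n = b$d * ifelse(b$n < 0, -1, 1), d = abs(b$n))))
}

rat_sum <- function(a) {
  # a: rational vector; exact sum
  acc <- list(n = 0, d = 1)
  for (i in seq_along(a$n)) {
    acc <- rat_add(acc, list(n = a$n[i], d = a$d[i]))
  }
  acc
}

rat_el <- function(a, i) list(n = a$n[i], d = a$d[i])

# Exact reduced row-echelon form of a rational matrix.
# Returns list(n, d, pivots, rank).
rref_rat <- function(n, d = NULL) {
  if (is.null(d)) d <- array(1, dim(n))
  n <- as.matrix(n) * 1; d <- as.matrix(d) * 1
  nr <- nrow(n); nc <- ncol(n)
  pivots <- integer(0)
  row <- 1L
  for (col in seq_len(nc)) {
    if (row > nr) break
    pr <- which(n[row:nr, col] != 0)
    if (length(pr) == 0) next
    pr <- pr[1] + row - 1L
    if (pr != row) {
      n[c(row, pr), ] <- n[c(pr, row), ]
      d[c(row, pr), ] <- d[c(pr, row), ]
    }
    # scale pivot row to leading 1
    pn <- n[row, col]; pd <- d[row, col]
    sc <- rat_norm(list(n = rep(pd, nc), d = rep(pn, nc)))
    rr <- rat_mul(list(n = n[row, ], d = d[row, ]), sc)
    n[row, ] <- rr$n; d[row, ] <- rr$d
    # eliminate in all other rows
    for (i in seq_len(nr)) {
      if (i == row || n[i, col] == 0) next
      f <- list(n = rep(n[i, col], nc), d = rep(d[i, col], nc))
      sub <- rat_sub(list(n = n[i, ], d = d[i, ]), rat_mul(f, list(n = n[row, ], d = d[row, ])))
      n[i, ] <- sub$n; d[i, ] <- sub$d
    }
    pivots <- c(pivots, col)
    row <- row + 1L
  }
  list(n = n, d = d, pivots = pivots, rank = length(pivots))
}

# Rank over Q of an integer matrix (exact).
rank_int <- function(M) {
  if (length(M) == 0 || nrow(M) == 0 || ncol(M) == 0) return(0L)
  rref_rat(M)$rank
}

# Row-reduced basis of the left kernel {w : w M = 0} of an integer matrix M,
# returned as a rational matrix in reduced row-echelon form with pivot indices.
left_kernel_rref <- function(M) {
  n <- nrow(M)
  R <- rref_rat(t(M))
  piv <- R$pivots
  free <- setdiff(seq_len(n), piv)
  k <- length(free)
  if (k == 0) {
    return(list(n = matrix(0, 0, n), d = matrix(1, 0, n), pivots = integer(0), rank = 0L))
  }
  Kn <- matrix(0, k, n); Kd <- matrix(1, k, n)
  for (j in seq_len(k)) {
    f <- free[j]
    Kn[j, f] <- 1
    if (length(piv)) {
      Kn[j, piv] <- -R$n[seq_along(piv), f]
      Kd[j, piv] <- R$d[seq_along(piv), f]
    }
  }
  W <- rref_rat(Kn, Kd)
  list(n = W$n, d = W$d, pivots = W$pivots, rank = W$rank)
}

# Clear denominators of each row of a rational matrix: returns integer matrix
# plus the positive rational scale per row (row_i(int) = scale_i * row_i(rat)).
clear_rows <- function(n, d) {
  nr <- nrow(n)
  out <- matrix(0, nr, ncol(n))
  scale_num <- rep(1, nr); scale_den <- rep(1, nr)
  for (i in seq_len(nr)) {
    l <- 1
    for (j in seq_len(ncol(n))) l <- .lcm2(l, d[i, j])
    r <- .chk_exact(n[i, ] * (l / d[i, ]))
    g <- 0
    for (v in r) g <- .gcd2(g, v)
    if (g > 1) { r <- r / g } else { g <- 1 }
    out[i, ] <- r
    scale_num[i] <- l; scale_den[i] <- g
  }
  list(mat = out, scale_num = scale_num, scale_den = scale_den)
}

# Exact determinant of a square rational matrix by fraction-free style
# Gauss elimination in rationals (matrices here are tiny).
det_rat <- function(n, d = NULL) {
  if (is.null(d)) d <- array(1, dim(n))
  n <- as.matrix(n) * 1; d <- as.matrix(d) * 1
  k <- nrow(n)
  if (k == 0) return(list(n = 1, d = 1))
  sign <- 1
  det <- list(n = 1, d = 1)
  for (col in seq_len(k)) {
    pr <- which(n[col:k, col] != 0)
    if (length(pr) == 0) return(list(n = 0, d = 1))
    pr <- pr[1] + col - 1L
    if (pr != col) {
      n[c(col, pr), ] <- n[c(pr, col), ]
      d[c(col, pr), ] <- d[c(pr, col), ]
      sign <- -sign
    }
    p <- list(n = n[col, col], d = d[col, col])
    det <- rat_mul(det, p)
    if (col < k) {
      for (i in (col + 1L):k) {
        if (n[i, col] == 0) next
        f <- rat_div(list(n = rep(n[i, col], k), d = rep(d[i, col], k)),
                     list(n = rep(p$n, k), d = rep(p$d, k)))
        sub <- rat_sub(list(n = n[i, ], d = d[i, ]), rat_mul(f, list(n = n[col, ], d = d[col, ])))
        n[i, ] <- sub$n; d[i, ] <- sub$d
      }
    }
  }
  list(n = sign * det$n, d = det$d)
}

# Primitive integer form of a rational vector (positive multiple, gcd 1).
primitive_int <- function(n, d) {
  l <- 1
  for (x in d) l <- .lcm2(l, x)
  v <- .chk_exact(n * (l / d))
  g <- 0
  for (x in v) g <- .gcd2(g, x)
  if (g > 1) v <- v / g
  v
}
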