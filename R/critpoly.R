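# The critical polynomial (-1)^s det Mtilde(h, lambda) of the convex
# parametrization, its signed support, and the numeric sign oracle g(x, kappa).

#' Build the convex-parametrization matrix M̃(h, λ)
#'
#' Forms `N diag(E λ) A^T diag(h)` — the Jacobian of the mass-action vector
#' field evaluated along the convex parametrization — and replaces row `i_j`
#' (the pivot of the `j`th conservation relation) by row `j` of `W`.
#' Entries are linear in each `h_i` and in each `λ_k`.
#'
#' @param sd a `stoich_data` from [stoichiometry()].
#' @param fc a `flux_cone` from [extreme_rays()]; must be consistent.
#' @return An object of class `convex_matrix`: for each entry either an exact
#'   rational `W` value or the vector of `λ`-coefficients of the linear form
#'   multiplying `h_j`.
#' @export
build_convex_matrix <- function(sd, fc) {
  stopifnot(inherits(sd, "stoich_data"), inherits(fc, "flux_cone"))
  if (fc$l == 0) stop("flux cone has no extreme rays (l = 0); the convex parametrization does not exist", call. = FALSE)
  n <- nrow(sd$N); l <- fc$l
  pivots <- sd$pivots
  entries <- vector("list", n)
  wrow <- 0L
  for (i in seq_len(n)) {
    entries[[i]] <- vector("list", n)
    if (i %in% pivots) {
      wrow <- which(pivots == i)
      for (j in seq_len(n)) {
        entries[[i]][[j]] <- list(type = "W",
                                  n = sd$W_num[wrow, j], d = sd$W_den[wrow, j])
      }
    } else {
      for (j in seq_len(n)) {
        coefs <- numeric(l)
        for (m in seq_len(ncol(sd$N))) {
          if (sd$N[i, m] == 0 || sd$A[j, m] == 0) next
          coefs <- coefs + sd$N[i, m] * sd$A[j, m] * fc$E[m, ]
        }
        .chk_exact(coefs)
        entries[[i]][[j]] <- list(type = "J", coefs = coefs)
      }
    }
  }
  structure(list(entries = entries, n = n, l = l, pivots = pivots, sd = sd, fc = fc),
            class = "convex_matrix")
}

.format_linform <- function(coefs, hname) {
  idx <- which(coefs != 0)
  if (length(idx) == 0) return("0")
  parts <- character(0)
  for (k in idx) {
    c0 <- coefs[k]
    term <- if (abs(c0) == 1) paste0("l", k) else paste0(abs(c0), "*l", k)
    parts <- c(parts, paste0(if (c0 < 0) "-" else if (length(parts)) "+" else "", term))
  }
  f <- paste(parts, collapse = "")
  if (length(idx) > 1) f <- paste0("(", f, ")")
  paste0(f, "*", hname)
}

#' @export
format.convex_matrix <- function(x, ...) {
  out <- matrix("", x$n, x$n)
  for (i in seq_len(x$n)) for (j in seq_len(x$n)) {
    e <- x$entries[[i]][[j]]
    if (e$type == "W") {
      out[i, j] <- if (e$d == 1) as.character(e$n) else paste0(e$n, "/", e$d)
    } else {
      out[i, j] <- .format_linform(e$coefs, paste0("h", j))
    }
  }
  out
}

#' @export
print.convex_matrix <- function(x, ...) {
  cat("M~(h, l):", x$n, "x", x$n, "\n")
  print(format(x), quote = FALSE)
  invisible(x)
}

#' Compute the critical polynomial
#'
#' Expands \eqn{(-1)^s \det \tilde M(h, \lambda)} exactly. Along the convex
#' parametrization this polynomial has the same sign as the determinant
#' criterion for multistationarity: negative values certify parameter pairs
#' that enable multistationarity. Every monomial has degree `s` in `h`
#' (exponents 0/1) and degree `s` in `λ`. Coefficients are exact rationals
#' with a common denominator (integer whenever `W` is integer).
#'
#' @inheritParams build_convex_matrix
#' @param term_budget resource limit on the number of stored monomials during
#'   expansion; exceeding it raises an error suggesting network reduction.
#' @return An object of class `critical_poly`: `exponents` (terms x (n+l)
#'   integer matrix, `h` columns first), `coef_num`, `coef_den` (scalar),
#'   `n`, `l`, `s`, `varnames`.
#' @export
critical_polynomial <- function(sd, fc, term_budget = 1e6) {
  stopifnot(inherits(sd, "stoich_data"), inherits(fc, "flux_cone"))
  if (fc$l == 0) stop("flux cone has no extreme rays (l = 0)", call. = FALSE)
  n <- nrow(sd$N)
  cw <- clear_rows(sd$W_num, sd$W_den)
  Wint <- cw$mat
  res <- cpp_critical_polynomial(
    matrix(as.integer(sd$N), nrow(sd$N)), matrix(as.integer(sd$A), nrow(sd$A)),
    matrix(as.integer(fc$E), nrow(fc$E)),
    matrix(as.integer(Wint), nrow(Wint)),
    as.integer(sd$pivots), term_budget
  )
  # scaled-W determinant = prod(scale_num/scale_den) * true determinant
  num <- res$coef
  den <- 1
  for (i in seq_along(cw$scale_num)) {
    num <- .chk_exact(num * cw$scale_den[i])
    den <- .chk_exact(den * cw$scale_num[i])
  }
  g <- den
  for (v in num) g <- .gcd2(g, v)
  if (g > 1) { num <- num / g; den <- den / g }
  expo <- res$exponents
  colnames(expo) <- c(paste0("h", seq_len(n)), paste0("l", seq_len(fc$l)))
  structure(list(exponents = expo, coef_num = num, coef_den = den,
                 n = n, l = fc$l, s = sd$s,
                 varnames = colnames(expo)),
            class = "critical_poly")
}

.monomial_string <- function(e, varnames) {
  idx <- which(e != 0)
  if (length(idx) == 0) return("1")
  paste(vapply(idx, function(k) {
    if (e[k] == 1) varnames[k] else paste0(varnames[k], "^", e[k])
  }, character(1)), collapse = "*")
}

#' @export
print.critical_poly <- function(x, max_terms = 25, ...) {
  m <- nrow(x$exponents)
  cat("Critical polynomial in", x$n, "h-variables and", x$l, "lambda-variables;",
      m, "terms\n")
  show <- seq_len(min(m, max_terms))
  parts <- character(0)
  for (i in show) {
    c0 <- x$coef_num[i]
    mono <- .monomial_string(x$exponents[i, ], x$varnames)
    cstr <- if (abs(c0) == 1) "" else paste0(abs(c0), "*")
    parts <- c(parts, paste0(if (c0 < 0) "- " else if (length(parts)) "+ " else "", cstr, mono))
  }
  cat(" ", paste(parts, collapse = " "))
  if (x$coef_den != 1) cat(" ) /", x$coef_den)
  if (m > max_terms) cat(" + ...", m - max_terms, "more terms")
  cat("\n")
  invisible(x)
}

#' @export
#' @importFrom generics tidy
#' @rdname tidy.reaction_network
tidy.critical_poly <- function(x, ...) {
  tibble::tibble(
    term = vapply(seq_len(nrow(x$exponents)),
                  function(i) .monomial_string(x$exponents[i, ], x$varnames), character(1)),
    coef_num = x$coef_num,
    coef_den = x$coef_den,
    sign = ifelse(x$coef_num > 0, "+", "-")
  )
}

#' @export
#' @importFrom generics glance
glance.critical_poly <- function(x, ...) {
  tibble::tibble(
    n = x$n, l = x$l, s = x$s,
    terms = nrow(x$exponents),
    n_positive = sum(x$coef_num > 0),
    n_negative = sum(x$coef_num < 0)
  )
}

#' Signed support of a polynomial
#'
#' Partitions the exponent vectors of a polynomial by coefficient sign into
#' \eqn{\sigma_+} and \eqn{\sigma_-}. Accepts a `critical_poly` or raw
#' exponents/coefficients.
#'
#' @param cp a `critical_poly`, or an exponent matrix when `coef` is given.
#' @param coef coefficient vector when `cp` is a plain matrix.
#' @return An object of class `signed_support`: `positive`, `negative`
#'   (exponent matrices), `k` (dimension).
#' @export
signed_support <- function(cp, coef = NULL) {
  if (inherits(cp, "critical_poly")) {
    expo <- cp$exponents; coef <- cp$coef_num
  } else {
    expo <- as.matrix(cp)
    if (is.null(coef)) stop("coef required for a plain exponent matrix", call. = FALSE)
  }
  if (any(coef == 0)) stop("zero coefficients are not part of a support", call. = FALSE)
  structure(list(positive = expo[coef > 0, , drop = FALSE],
                 negative = expo[coef < 0, , drop = FALSE],
                 k = ncol(expo)),
            class = "signed_support")
}

#' @export
print.signed_support <- function(x, ...) {
  cat("Signed support in dimension", x$k, ":",
      nrow(x$positive), "positive,", nrow(x$negative), "negative exponents\n")
  invisible(x)
}

#' @export
#' @rdname tidy.reaction_network
tidy.signed_support <- function(x, ...) {
  expo <- rbind(x$positive, x$negative)
  tb <- tibble::as_tibble(expo, .name_repair = "minimal")
  tb$sign <- rep(c("+", "-"), c(nrow(x$positive), nrow(x$negative)))
  tb
}

# exact rational power of a rational scalar
.rat_pow <- function(a, e) {
  out <- list(n = 1, d = 1)
  for (i in seq_len(e)) out <- rat_mul(out, a)
  out
}

.as_rat_vec <- function(x) {
  if (is.list(x) && !is.null(x$n)) return(rat_norm(x))
  x <- as.numeric(x)
  if (any(x != round(x))) {
    stop("exact evaluation requires integer or rational (list(n=, d=)) input", call. = FALSE)
  }
  rat(x)
}

#' Evaluate the multistationarity sign function g(x, κ)
#'
#' Computes \eqn{(-1)^s \det M_\kappa(x)} where \eqn{M_\kappa(x)} is the
#' Jacobian of the mass-action vector field at `x`, with the pivot rows
#' replaced by the rows of `W`. By the determinant criterion, a negative
#' value at a positive steady state certifies that the corresponding
#' parameter pair enables multistationarity.
#'
#' With integer or rational input the computation is exact and the returned
#' value carries the exact rational as attribute `rational`; with plain
#' floating-point input a numeric determinant is returned (never used for
#' sign decisions in the pipeline).
#'
#' @param net a [reaction_network].
#' @param sd its [stoichiometry()] (optional).
#' @param x positive concentration vector (length n).
#' @param kappa positive rate-constant vector (length r).
#' @return A numeric scalar; exact inputs also attach attribute `rational`.
#' @export
evaluate_g <- function(net, sd = NULL, x, kappa) {
  if (is.null(sd)) sd <- stoichiometry(net)
  n <- n_species(net); r <- n_reactions(net)
  lx <- if (is.list(x)) length(x$n) else length(x)
  lk <- if (is.list(kappa)) length(kappa$n) else length(kappa)
  if (lx != n || lk != r) stop("dimension mismatch", call. = FALSE)
  exact <- (is.list(x) || all(as.numeric(x) == round(as.numeric(x)))) &&
    (is.list(kappa) || all(as.numeric(kappa) == round(as.numeric(kappa))))
  if (exact) {
    xv <- .as_rat_vec(x); kv <- .as_rat_vec(kappa)
    if (any(xv$n <= 0) || any(kv$n <= 0)) stop("x and kappa must be strictly positive", call. = FALSE)
    # monomials x^{A_m}
    xa <- vector("list", r)
    for (m in seq_len(r)) {
      acc <- list(n = 1, d = 1)
      for (i in seq_len(n)) {
        if (sd$A[i, m] > 0) acc <- rat_mul(acc, .rat_pow(rat_el(xv, i), sd$A[i, m]))
      }
      xa[[m]] <- acc
    }
    Mn <- matrix(0, n, n); Md <- matrix(1, n, n)
    for (i in seq_len(n)) {
      if (i %in% sd$pivots) {
        j0 <- which(sd$pivots == i)
        Mn[i, ] <- sd$W_num[j0, ]; Md[i, ] <- sd$W_den[j0, ]
      } else {
        for (j in seq_len(n)) {
          acc <- list(n = 0, d = 1)
          for (m in seq_len(r)) {
            if (sd$N[i, m] == 0 || sd$A[j, m] == 0) next
            t1 <- rat_mul(rat_el(kv, m), xa[[m]])
            t1 <- rat_mul(t1, list(n = sd$N[i, m] * sd$A[j, m], d = 1))
            t1 <- rat_div(t1, rat_el(xv, j))
            acc <- rat_add(acc, t1)
          }
          Mn[i, j] <- acc$n; Md[i, j] <- acc$d
        }
      }
    }
    dt <- det_rat(Mn, Md)
    val <- list(n = (-1)^sd$s * dt$n, d = dt$d)
    out <- val$n / val$d
    attr(out, "rational") <- val
    out
  } else {
    x <- as.numeric(x); kappa <- as.numeric(kappa)
    if (any(x <= 0) || any(kappa <= 0)) stop("x and kappa must be strictly positive", call. = FALSE)
    M <- matrix(0, n, n)
    xa <- vapply(seq_len(r), function(m) prod(x^sd$A[, m]), numeric(1))
    for (i in seq_len(n)) {
      if (i %in% sd$pivots) {
        M[i, ] <- sd$W[which(sd$pivots == i), ]
      } else {
        for (j in seq_len(n)) {
          M[i, j] <- sum(sd$N[i, ] * kappa * sd$A[j, ] * xa) / x[j]
        }
      }
    }
    (-1)^sd$s * det(M)
  }
}

#' Evaluate a critical polynomial at an exact rational point
#'
#' @param cp a `critical_poly`.
#' @param h,lambda positive integer or rational (`list(n=, d=)`) vectors.
#' @return numeric value with exact `rational` attribute.
#' @export
evaluate_critical_polynomial <- function(cp, h, lambda) {
  hv <- .as_rat_vec(h); lv <- .as_rat_vec(lambda)
  if (length(hv$n) != cp$n || length(lv$n) != cp$l) stop("dimension mismatch", call. = FALSE)
  vals <- list(n = c(hv$n, lv$n), d = c(hv$d, lv$d))
  acc <- list(n = 0, d = 1)
  for (i in seq_len(nrow(cp$exponents))) {
    term <- list(n = cp$coef_num[i], d = cp$coef_den)
    e <- cp$exponents[i, ]
    for (k in which(e != 0)) {
      term <- rat_mul(term, .rat_pow(rat_el(vals, k), e[k]))
    }
    acc <- rat_add(acc, term)
  }
  out <- acc$n / acc$d
  attr(out, "rational") <- acc
  out
}

#' Rates of the convex parametrization
#'
#' For a point `(h, λ)` of the convex parametrization, returns the
#' corresponding `(x, κ)`: `x = 1/h` and `κ_j = (Eλ)_j h^{A_j}`, so that
#' `v_κ(x) = Eλ` lies in the flux cone and `x` is a positive steady state.
#'
#' @param sd a `stoich_data`; `fc` a `flux_cone`.
#' @param fc flux cone.
#' @param h,lambda positive integer/rational vectors.
#' @return list with rational vectors `x` and `kappa`.
#' @export
convex_parametrization_point <- function(sd, fc, h, lambda) {
  hv <- .as_rat_vec(h); lv <- .as_rat_vec(lambda)
  n <- nrow(sd$N); r <- ncol(sd$N)
  x <- rat_div(rat(rep(1, n)), hv)
  # E lambda (integer E)
  el <- vector("list", r)
  kappa <- list(n = numeric(r), d = numeric(r))
  for (m in seq_len(r)) {
    acc <- list(n = 0, d = 1)
    for (k in seq_len(fc$l)) {
      if (fc$E[m, k] == 0) next
      acc <- rat_add(acc, rat_mul(list(n = fc$E[m, k], d = 1), rat_el(lv, k)))
    }
    for (i in seq_len(n)) {
      if (sd$A[i, m] > 0) acc <- rat_mul(acc, .rat_pow(rat_el(hv, i), sd$A[i, m]))
    }
    kappa$n[m] <- acc$n; kappa$d[m] <- acc$d
  }
  list(x = x, kappa = kappa)
}

#' Mass-action rate vector v_kappa(x)
#'
#' @param net a [reaction_network]; `x`, `kappa` rational/integer vectors.
#' @param x concentrations.
#' @param kappa rate constants.
#' @return rational vector `list(n=, d=)` of length r.
#' @export
rate_function <- function(net, x, kappa) {
  xv <- .as_rat_vec(x); kv <- .as_rat_vec(kappa)
  A <- net$reactant
  r <- ncol(A); n <- nrow(A)
  out <- list(n = numeric(r), d = numeric(r))
  for (m in seq_len(r)) {
    acc <- rat_el(kv, m)
    for (i in seq_len(n)) {
      if (A[i, m] > 0) acc <- rat_mul(acc, .rat_pow(rat_el(xv, i), A[i, m]))
    }
    out$n[m] <- acc$n; out$d[m] <- acc$d
  }
  out
}
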