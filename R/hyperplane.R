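# Strict separating hyperplanes of a signed support, decided by exact
# rational linear programming.

#' Find a strict separating hyperplane of a signed support
#'
#' Decides whether there is a hyperplane `v . mu = a` with every positive
#' exponent on the side `v . alpha <= a`, every negative exponent on the side
#' `v . beta >= a`, and not all negative exponents on the hyperplane
#' (\eqn{\sum_{\beta} (v\cdot\beta - a) > 0}). Existence certifies that the
#' region where the polynomial is negative on the positive orthant is path
#' connected, with closure equal to the nonpositivity region.
#'
#' The decision is one exact rational feasibility problem: the two side
#' conditions together with the normalized slack condition
#' \eqn{\sum_\beta (v\cdot\beta - a) \ge 1} (scale invariance of the cone cut
#' out by the side conditions makes this equivalent to `> 0`). Feasibility is
#' decided by an exact phase-1 simplex; infeasibility proves — by the
#' relative-interior argument — that every hyperplane weakly separating the
#' support contains all negative exponents, so no strict separator exists.
#'
#' @param ss a `signed_support` from [signed_support()]; `negative` must be
#'   nonempty.
#' @return A `hyperplane` object (list with exact rational `v` and `a` and
#'   numeric approximations), or `NULL` when no strict separating hyperplane
#'   exists.
#' @export
find_strict_separating_hyperplane <- function(ss) {
  stopifnot(inherits(ss, "signed_support"))
  np <- nrow(ss$positive); nn <- nrow(ss$negative)
  if (nn == 0) stop("signed support has no negative exponents", call. = FALSE)
  k <- ss$k
  if (np == 0) {
    # any direction works; put all negative exponents strictly above a
    v <- c(1, rep(0, k - 1))
    a <- min(ss$negative %*% v) - 1
    return(.hyperplane(rat(v), rat(a), k))
  }
  # variables z = (v, a)
  G <- rbind(
    cbind(-ss$positive, 1),          # a - v.alpha >= 0
    cbind(ss$negative, -1),          # v.beta - a >= 0
    c(colSums(ss$negative), -nn)     # sum_beta (v.beta - a) >= 1
  )
  g <- c(rep(0, np + nn), 1)
  z <- .lp_feasible(G, g, max_iter = 1e6)
  if (is.null(z)) return(NULL)
  v <- list(n = z$n[seq_len(k)], d = z$d[seq_len(k)])
  a <- list(n = z$n[k + 1], d = z$d[k + 1])
  hp <- .hyperplane(v, a, k)
  if (!verify_hyperplane(hp, ss)) stop("internal error: certificate failed exact verification")
  hp
}

.hyperplane <- function(v, a, k) {
  structure(list(v = v, a = a, k = k,
                 v_num = v$n / v$d, a_num = a$n / a$d),
            class = "hyperplane")
}

#' Construct a hyperplane certificate from plain values
#'
#' @param v numeric (integer-valued) normal vector; `a` numeric offset.
#' @param a offset.
#' @return A `hyperplane` object.
#' @export
hyperplane <- function(v, a) {
  .hyperplane(rat(v), rat(a), length(v))
}

#' @export
print.hyperplane <- function(x, ...) {
  vs <- ifelse(x$v$d == 1, as.character(x$v$n), paste0(x$v$n, "/", x$v$d))
  as_ <- if (x$a$d == 1) as.character(x$a$n) else paste0(x$a$n, "/", x$a$d)
  cat("Separating hyperplane: (", paste(vs, collapse = ", "), ") . mu = ", as_, "\n", sep = "")
  invisible(x)
}

#' Verify a strict-separation certificate exactly
#'
#' Checks the three certificate conditions in exact rational arithmetic:
#' `v . alpha <= a` for every positive exponent, `v . beta >= a` for every
#' negative exponent, and `sum(v . beta - a) > 0`.
#'
#' @param hp a `hyperplane` (or list with `v`, `a` as rational lists).
#' @param ss a `signed_support`.
#' @return `TRUE` or `FALSE`.
#' @export
verify_hyperplane <- function(hp, ss) {
  stopifnot(inherits(ss, "signed_support"))
  if (length(hp$v$n) != ss$k) stop("dimension mismatch", call. = FALSE)
  if (all(hp$v$n == 0)) return(FALSE)
  dotr <- function(e) { # exact v.e for integer exponent row e
    acc <- list(n = 0, d = 1)
    for (i in which(e != 0)) {
      acc <- rat_add(acc, rat_mul(rat_el(hp$v, i), list(n = e[i], d = 1)))
    }
    acc
  }
  slack_sum <- list(n = 0, d = 1)
  for (i in seq_len(nrow(ss$positive))) {
    dv <- dotr(ss$positive[i, ])
    if (rat_sub(dv, hp$a)$n > 0) return(FALSE)
  }
  for (i in seq_len(nrow(ss$negative))) {
    dv <- dotr(ss$negative[i, ])
    d2 <- rat_sub(dv, hp$a)
    if (d2$n < 0) return(FALSE)
    slack_sum <- rat_add(slack_sum, d2)
  }
  slack_sum$n > 0
}

#' Plot a signed support with its separation certificate
#'
#' Projects every exponent onto the certificate direction: the x axis shows
#' `v . mu` for each exponent `mu`, with positive exponents below/at the
#' threshold `a` and negative exponents above/at it (strictly above for at
#' least one) when the certificate is valid.
#'
#' @param object a `signed_support`.
#' @param hyperplane optional `hyperplane`; computed when missing.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.signed_support <- function(object, hyperplane = NULL, ...) {
  if (is.null(hyperplane)) hyperplane <- find_strict_separating_hyperplane(object)
  if (is.null(hyperplane)) stop("no strict separating hyperplane exists for this support", call. = FALSE)
  v <- hyperplane$v_num; a <- hyperplane$a_num
  df <- tibble::tibble(
    projection = c(as.numeric(object$positive %*% v), as.numeric(object$negative %*% v)),
    sign = rep(c("positive", "negative"), c(nrow(object$positive), nrow(object$negative)))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$projection, y = .data$sign, colour = .data$sign)) +
    ggplot2::geom_jitter(width = 0, height = 0.15, alpha = 0.6) +
    ggplot2::geom_vline(xintercept = a, linetype = 2) +
    ggplot2::labs(x = "v . exponent", y = NULL,
                  title = "Signed support projected on the separating direction") +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}
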