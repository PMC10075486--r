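# Independent oracles used to cross-check the exact polyhedral and
# combinatorial computations on small instances.

# all minimal siphons by explicit enumeration of every nonempty species subset
brute_minimal_siphons <- function(net) {
  n <- length(net$species)
  stopifnot(n <= 12)
  A <- net$reactant; B <- net$product
  is_siphon <- function(z) {
    for (i in z) {
      for (j in which(B[i, ] > 0)) {
        rs <- which(A[, j] > 0)
        if (!any(rs %in% z)) return(FALSE)
      }
    }
    TRUE
  }
  all_s <- list()
  for (code in seq_len(2^n - 1)) {
    z <- which(bitwAnd(code, 2^(seq_len(n) - 1)) > 0)
    if (is_siphon(z)) all_s[[length(all_s) + 1L]] <- z
  }
  ord <- order(vapply(all_s, length, integer(1)))
  all_s <- all_s[ord]
  minimal <- list()
  for (z in all_s) {
    if (!any(vapply(minimal, function(m) all(m %in% z), logical(1)))) {
      minimal[[length(minimal) + 1L]] <- z
    }
  }
  keys <- vapply(minimal, function(z) paste(sprintf("%04d", z), collapse = ","), character(1))
  minimal[order(vapply(minimal, length, integer(1)), keys)]
}

# extreme rays of ker(N) over the nonnegative orthant by minimal-support
# search over all support patterns: S is a ray support iff the kernel of the
# column-submatrix N[, S] is one-dimensional and spanned by a strictly
# one-signed vector, and no smaller found support is contained in S
brute_extreme_rays <- function(N) {
  r <- ncol(N)
  stopifnot(r <= 8)
  found <- list(); supports <- list()
  codes <- order(vapply(seq_len(2^r - 1), function(code) sum(bitwAnd(code, 2^(seq_len(r) - 1)) > 0), numeric(1)))
  for (code in codes) {
    S <- which(bitwAnd(code, 2^(seq_len(r) - 1)) > 0)
    if (any(vapply(supports, function(s) all(s %in% S), logical(1)))) next
    Ns <- N[, S, drop = FALSE]
    # kernel of Ns via exact RREF of t(null basis): reuse package rationals
    K <- crnconnect:::left_kernel_rref(t(Ns))
    if (K$rank != 1) next
    v <- K$n[1, ] / K$d[1, ]
    if (any(v == 0)) next
    if (all(v > 0) || all(v < 0)) {
      ray <- numeric(r)
      ray[S] <- crnconnect:::primitive_int(abs(K$n[1, ]), K$d[1, ])
      found[[length(found) + 1L]] <- ray
      supports[[length(supports) + 1L]] <- S
    }
  }
  E <- if (length(found)) do.call(cbind, found) else matrix(0, r, 0)
  if (ncol(E) > 1) {
    keys <- apply(E, 2, function(v) paste(sprintf("%06d", v), collapse = ","))
    E <- E[, order(keys), drop = FALSE]
  }
  E
}

# random small mass-action network (used for property tests)
random_network <- function(n, r, max_coef = 2) {
  repeat {
    A <- matrix(sample(0:max_coef, n * r, replace = TRUE, prob = c(0.6, 0.3, 0.1)[seq_len(max_coef + 1)]), n, r)
    B <- matrix(sample(0:max_coef, n * r, replace = TRUE, prob = c(0.6, 0.3, 0.1)[seq_len(max_coef + 1)]), n, r)
    ok <- all(colSums(abs(B - A)) > 0) && all(colSums(A + B) > 0)
    if (ok) break
  }
  reaction_network(paste0("X", seq_len(n)), A, B)
}

# signed support of the polynomial printed alongside the separating-hyperplane
# discussion: x1^2 - x1^2 x2 + 2 x1 x2 + x1^3 + x2^2
fig_support <- function() {
  signed_support(rbind(c(2, 0), c(1, 1), c(3, 0), c(0, 2), c(2, 1)),
                 coef = c(1, 2, 1, 1, -1))
}

# inequality rows of the weak-separation cone C for a signed support
cone_rows <- function(ss) {
  rbind(cbind(-ss$positive, 1), cbind(ss$negative, -1))
}
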