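# Exact polyhedral computations: extreme rays of the flux cone
# ker(N) ∩ R^r_{>=0}, consistency, and relative interior points of general
# homogeneous cones given by inequalities.

#' Extreme rays of the flux cone
#'
#' Computes the extreme rays of `ker(N)` intersected with the nonnegative
#' orthant by exact double description: starting from the orthant's unit
#' rays, each equation of a row-reduced basis of the row space of `N` is
#' imposed in turn; candidate rays are combined pairwise across the equation
#' and non-minimal supports are pruned (for these cones a nonnegative kernel
#' vector is extreme iff its support is minimal). Rays are returned as
#' primitive integer vectors (gcd 1), pairwise non-proportional, sorted
#' lexicographically, as the columns of `E`.
#'
#' @param N integer stoichiometric matrix without zero columns (or a
#'   [reaction_network], which is converted).
#' @return An object of class `flux_cone`: list with `E` (r x l integer
#'   matrix) and `l`.
#' @export
extreme_rays <- function(N) {
  if (inherits(N, "reaction_network")) N <- N$product - N$reactant
  N <- as.matrix(N)
  r <- ncol(N)
  if (any(colSums(abs(N)) == 0)) stop("N has a zero column", call. = FALSE)
  # row-reduced equations (exact); each row imposed in turn
  R <- rref_rat(N)
  eqs <- list()
  if (R$rank > 0) {
    for (i in seq_len(R$rank)) {
      eqs[[i]] <- primitive_int(R$n[i, ], R$d[i, ])
    }
  }
  rays <- lapply(seq_len(r), function(i) { v <- numeric(r); v[i] <- 1; v })
  for (w in eqs) {
    val <- vapply(rays, function(u) sum(w * u), numeric(1))
    .chk_exact(val)
    zero <- rays[val == 0]
    pos <- which(val > 0); neg <- which(val < 0)
    comb <- list()
    for (p in pos) for (q in neg) {
      u <- rays[[p]]; v <- rays[[q]]
      newv <- .chk_exact(val[p] * v - val[q] * u)
      g <- 0
      for (x in newv) g <- .gcd2(g, x)
      if (g > 1) newv <- newv / g
      comb[[length(comb) + 1L]] <- newv
    }
    cand <- c(zero, comb)
    rays <- .minimal_support_filter(cand)
  }
  E <- if (length(rays)) do.call(cbind, rays) else matrix(0, r, 0)
  # canonical order: ascending lexicographic columns
  if (ncol(E) > 1) {
    keys <- apply(E, 2, function(v) paste(sprintf("%06d", v), collapse = ","))
    E <- E[, order(keys), drop = FALSE]
  }
  storage.mode(E) <- "double"
  structure(list(E = E, l = ncol(E)), class = "flux_cone")
}

# keep vectors whose support is minimal; drop duplicates (proportional vectors
# with equal support are identical after primitive normalization)
.minimal_support_filter <- function(cand) {
  if (length(cand) == 0) return(cand)
  supps <- lapply(cand, function(v) which(v != 0))
  keys <- vapply(supps, function(s) paste(s, collapse = ","), character(1))
  keep <- !duplicated(keys)
  cand <- cand[keep]; supps <- supps[keep]
  sizes <- vapply(supps, length, integer(1))
  ord <- order(sizes)
  cand <- cand[ord]; supps <- supps[ord]; sizes <- sizes[ord]
  out <- list(); outs <- list()
  for (i in seq_along(cand)) {
    dominated <- FALSE
    for (s in outs) {
      if (all(s %in% supps[[i]])) { dominated <- TRUE; break }
    }
    if (!dominated) {
      out[[length(out) + 1L]] <- cand[[i]]
      outs[[length(outs) + 1L]] <- supps[[i]]
    }
  }
  out
}

#' @export
print.flux_cone <- function(x, ...) {
  cat("Flux cone with", x$l, "extreme rays\n")
  if (x$l > 0) print(x$E)
  invisible(x)
}

#' Consistency of a network
#'
#' A network is consistent when `ker(N)` contains a strictly positive vector;
#' equivalently the matrix of extreme rays has no zero row. Only then is the
#' convex parametrization surjective onto the positive steady-state set.
#'
#' @param fc a `flux_cone` from [extreme_rays()].
#' @return `TRUE` or `FALSE`.
#' @export
is_consistent <- function(fc) {
  stopifnot(inherits(fc, "flux_cone"))
  fc$l > 0 && all(rowSums(abs(fc$E)) > 0)
}

#' Relative interior point of a polyhedral cone
#'
#' For the homogeneous cone `C = {x : G x >= 0}`, computes a generator
#' representation (lineality space + extreme rays of the pointed quotient) by
#' exact double description and returns the sum of the rays — a strictly
#' positive combination of rays lies in the relative interior of `C`. The
#' lineality component is zero, so the zero vector is returned exactly when
#' `C` is a linear space (trivial pointed part).
#'
#' @param G integer matrix of inequality normals, one row per inequality
#'   `G[i, ] %*% x >= 0`.
#' @return An exact rational vector as `list(n=, d=)`, plus attributes
#'   `rays` (matrix of primitive integer rays as columns) and `lineality`
#'   (basis matrix).
#' @export
relative_interior_point <- function(G) {
  G <- as.matrix(G)
  d <- ncol(G)
  # start: lineality = R^d (identity basis), no rays
  lin <- lapply(seq_len(d), function(i) { v <- numeric(d); v[i] <- 1; v })
  rays <- list()
  zsets <- list()  # per ray: indices of processed inequalities tight at the ray
  processed <- 0L
  for (irow in seq_len(nrow(G))) {
    gv <- G[irow, ]
    lv <- vapply(lin, function(b) sum(gv * b), numeric(1))
    .chk_exact(lv)
    if (any(lv != 0)) {
      # pivot a lineality direction out: b0 with g.b0 > 0
      i0 <- which(lv != 0)[1]
      b0 <- lin[[i0]]; v0 <- lv[i0]
      if (v0 < 0) { b0 <- -b0; v0 <- -v0 }
      newlin <- list()
      for (i in seq_along(lin)) {
        if (i == i0) next
        b <- .chk_exact(v0 * lin[[i]] - lv[i] * b0)
        b <- .reduce_gcd(b)
        newlin[[length(newlin) + 1L]] <- b
      }
      lin <- newlin
      # project rays onto g = 0 and add b0 as a ray
      rv <- vapply(rays, function(u) sum(gv * u), numeric(1))
      if (length(rays)) .chk_exact(rv)
      newrays <- list(); newz <- list()
      for (i in seq_along(rays)) {
        u <- .chk_exact(v0 * rays[[i]] - rv[i] * b0)
        u <- .reduce_gcd(u)
        newrays[[length(newrays) + 1L]] <- u
        newz[[length(newz) + 1L]] <- c(zsets[[i]], irow)
      }
      newrays[[length(newrays) + 1L]] <- .reduce_gcd(b0)
      newz[[length(newz) + 1L]] <- integer(0)
      rays <- newrays; zsets <- newz
      # recompute zero sets of the new generator for processed inequalities
      zsets[[length(rays)]] <- .tight_set(G, seq_len(processed), rays[[length(rays)]])
    } else {
      rv <- vapply(rays, function(u) sum(gv * u), numeric(1))
      if (length(rays)) .chk_exact(rv)
      keepz <- which(rv == 0); pos <- which(rv > 0); neg <- which(rv < 0)
      newrays <- list(); newz <- list()
      for (i in c(keepz, pos)) {
        newrays[[length(newrays) + 1L]] <- rays[[i]]
        z <- zsets[[i]]
        if (rv[i] == 0) z <- c(z, irow)
        newz[[length(newz) + 1L]] <- z
      }
      for (p in pos) for (q in neg) {
        if (!.dd_adjacent(zsets[[p]], zsets[[q]], zsets, p, q)) next
        u <- .chk_exact(rv[p] * rays[[q]] - rv[q] * rays[[p]])
        u <- .reduce_gcd(u)
        newrays[[length(newrays) + 1L]] <- u
        newz[[length(newz) + 1L]] <- c(intersect(zsets[[p]], zsets[[q]]), irow)
      }
      rays <- newrays; zsets <- newz
    }
    processed <- irow
  }
  point <- if (length(rays)) Reduce(`+`, rays) else numeric(d)
  E <- if (length(rays)) do.call(cbind, rays) else matrix(0, d, 0)
  L <- if (length(lin)) do.call(cbind, lin) else matrix(0, d, 0)
  out <- rat(point)
  attr(out, "rays") <- E
  attr(out, "lineality") <- L
  out
}

.reduce_gcd <- function(v) {
  g <- 0
  for (x in v) g <- .gcd2(g, x)
  if (g > 1) v / g else v
}

.tight_set <- function(G, idx, v) {
  if (length(idx) == 0) return(integer(0))
  vals <- as.numeric(G[idx, , drop = FALSE] %*% v)
  idx[vals == 0]
}

# combinatorial adjacency test: rays p, q adjacent iff no other ray's tight
# set contains the intersection of theirs
.dd_adjacent <- function(zp, zq, zsets, p, q) {
  zi <- intersect(zp, zq)
  for (i in seq_along(zsets)) {
    if (i == p || i == q) next
    if (all(zi %in% zsets[[i]])) return(FALSE)
  }
  TRUE
}
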