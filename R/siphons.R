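# Minimal siphons and the boundary-steady-state criterion (Step 1).

#' Enumerate the minimal siphons of a network
#'
#' A siphon is a nonempty set `Z` of species such that every reaction that
#' produces a species of `Z` has a reactant species in `Z`. "Produces" is
#' understood grossly, in the Petri-net sense: reaction `j` produces species
#' `i` when `b_ij > 0`, even if the species is also consumed.
#'
#' Enumeration is a depth-first search with closure propagation: starting from
#' each single species, violated siphon conditions are repaired by branching
#' over the reactant species of the violating reaction; completed siphons are
#' then filtered for inclusion-minimality.
#'
#' @param net a [reaction_network].
#' @param max_species enumeration bound; networks with more species raise an
#'   error signalling that the check must be done externally.
#' @return A list of integer vectors (species indices, each sorted), ordered
#'   canonically by size then lexicographically.
#' @export
minimal_siphons <- function(net, max_species = 22) {
  n <- n_species(net)
  if (n > max_species) {
    stop("siphon enumeration bound exceeded (", n, " species > ", max_species, ")",
         call. = FALSE)
  }
  B <- net$product
  A <- net$reactant
  r <- ncol(A)
  # producers[[i]]: reactions with b_ij > 0; reactants[[j]]: species in reactant
  producers <- lapply(seq_len(n), function(i) which(B[i, ] > 0))
  reactants <- lapply(seq_len(r), function(j) which(A[, j] > 0))

  found <- list()
  visited <- new.env(parent = emptyenv())

  # find a violated condition: species in Z produced by a reaction whose
  # reactant misses Z; returns the reaction index or 0.  Unproducible species
  # (no producing reaction) and reactions with an empty reactant are handled
  # by the same scan: an empty-reactant producer can never be repaired.
  violation <- function(zmask) {
    for (i in which(zmask)) {
      for (j in producers[[i]]) {
        rs <- reactants[[j]]
        if (length(rs) == 0) return(-1L)       # irreparable: 0 -> ... produces i
        if (!any(zmask[rs])) return(j)
      }
    }
    0L
  }

  grow <- function(zmask) {
    key <- paste(which(zmask), collapse = ",")
    if (!is.null(visited[[key]])) return(invisible())
    assign(key, TRUE, envir = visited)
    j <- violation(zmask)
    if (j == -1L) return(invisible())
    if (j == 0L) {
      found[[length(found) + 1L]] <<- which(zmask)
      return(invisible())
    }
    # close deterministically while the violating reaction has a single
    # candidate repair; branch otherwise
    for (x in reactants[[j]]) {
      z2 <- zmask; z2[x] <- TRUE
      grow(z2)
    }
    invisible()
  }

  for (i in seq_len(n)) {
    z <- rep(FALSE, n); z[i] <- TRUE
    grow(z)
  }

  # minimality filter
  ord <- order(vapply(found, length, integer(1)))
  found <- found[ord]
  minimal <- list()
  for (z in found) {
    ismin <- !any(vapply(minimal, function(m) all(m %in% z), logical(1)))
    if (ismin) minimal[[length(minimal) + 1L]] <- z
  }
  # canonical sort: size, then lexicographic
  keys <- vapply(minimal, function(z) paste(sprintf("%04d", z), collapse = ","), character(1))
  sizes <- vapply(minimal, length, integer(1))
  minimal[order(sizes, keys)]
}

#' Exclude relevant boundary steady states via siphons
#'
#' Sufficient criterion: for every minimal siphon `Z` there is a conservation
#' vector `w >= 0` with `w N = 0` whose positive entries are exactly the
#' species in `Z` (exact rational feasibility of `w N = 0`, `w_i >= 1` on `Z`,
#' `w_i = 0` off `Z`). `TRUE` certifies that no stoichiometric compatibility
#' class intersecting the positive orthant contains a boundary steady state;
#' `FALSE` means the criterion is inconclusive, not that such states exist.
#'
#' @param net a [reaction_network].
#' @param sd optional precomputed [stoichiometry()] of `net`.
#' @param max_species passed to [minimal_siphons()].
#' @param verbose print each minimal siphon and its witness.
#' @return `TRUE` or `FALSE`.
#' @export
excludes_boundary_steady_states <- function(net, sd = NULL, max_species = 22,
                                            verbose = FALSE) {
  if (is.null(sd)) sd <- stoichiometry(net)
  sips <- minimal_siphons(net, max_species = max_species)
  N <- sd$N
  for (z in sips) {
    # restrict to coordinates in z (others fixed to 0)
    Nz <- N[z, , drop = FALSE]
    r <- ncol(Nz); k <- length(z)
    G <- rbind(t(Nz), -t(Nz), diag(k))
    g <- c(rep(0, 2 * r), rep(1, k))
    w <- .lp_feasible(G, g)
    if (is.null(w)) {
      if (verbose) message("siphon {", paste(net$species[z], collapse = ", "),
                           "}: no conservation witness")
      return(FALSE)
    }
    if (verbose) {
      message("siphon {", paste(net$species[z], collapse = ", "), "}: witness ",
              paste(sprintf("%g/%g", w$n, w$d), collapse = " "))
    }
  }
  TRUE
}
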