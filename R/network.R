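#' Construct a mass-action reaction network
#'
#' A reaction network is an ordered list of species together with reactions
#' \eqn{a_{1j}X_1 + \dots + a_{nj}X_n \rightarrow b_{1j}X_1 + \dots + b_{nj}X_n}
#' with nonnegative integer stoichiometric coefficients. Reactions with equal
#' reactant and product are not allowed, so the stoichiometric matrix has no
#' zero column.
#'
#' @param species character vector of unique species names, in order.
#' @param reactant,product nonnegative integer matrices, one column per
#'   reaction, rows indexed by `species`.
#' @param labels rate-constant labels, one per reaction; defaults to
#'   `k1, ..., kr` in column order.
#' @return An object of class `reaction_network`.
#' @seealso [parse_network()], [stoichiometry()]
#' @export
reaction_network <- function(species, reactant, product, labels = NULL) {
  species <- as.character(species)
  if (anyDuplicated(species)) stop("duplicate species names", call. = FALSE)
  reactant <- as.matrix(reactant); product <- as.matrix(product)
  storage.mode(reactant) <- "double"; storage.mode(product) <- "double"
  if (nrow(reactant) != length(species) || !identical(dim(reactant), dim(product))) {
    stop("reactant/product matrices must be species x reactions", call. = FALSE)
  }
  if (any(reactant < 0) || any(product < 0) ||
      any(reactant != round(reactant)) || any(product != round(product))) {
    stop("stoichiometric coefficients must be nonnegative integers", call. = FALSE)
  }
  r <- ncol(reactant)
  same <- vapply(seq_len(r), function(j) all(reactant[, j] == product[, j]), logical(1))
  if (any(same)) {
    stop("reaction ", which(same)[1], " has equal reactant and product", call. = FALSE)
  }
  if (is.null(labels)) labels <- paste0("k", seq_len(r))
  if (length(labels) != r) stop("one label per reaction required", call. = FALSE)
  rownames(reactant) <- rownames(product) <- species
  structure(
    list(species = species, reactant = reactant, product = product,
         labels = as.character(labels)),
    class = "reaction_network"
  )
}

#' Number of species / reactions
#' @param net a `reaction_network`.
#' @return integer count.
#' @export
n_species <- function(net) length(net$species)

#' @rdname n_species
#' @export
n_reactions <- function(net) ncol(net$reactant)

.parse_complex <- function(txt, lineno) {
  txt <- trimws(txt)
  if (txt == "0") return(list())
  terms <- strsplit(txt, "\\s\\+\\s|^\\+\\s|\\s\\+$")[[1]]
  terms <- trimws(terms)
  terms <- terms[nzchar(terms)]
  if (length(terms) == 0) {
    stop("line ", lineno, ": empty complex (use 0 for the empty complex)", call. = FALSE)
  }
  out <- list()
  for (tm in terms) {
    m <- regmatches(tm, regexec("^([0-9]+)?\\s*([^0-9[:space:]]\\S*)$", tm))[[1]]
    if (length(m) == 0) {
      stop("line ", lineno, ": malformed term '", tm, "'", call. = FALSE)
    }
    coef <- if (nzchar(m[2])) as.numeric(m[2]) else 1
    name <- m[3]
    if (coef != round(coef) || coef < 0) {
      stop("line ", lineno, ": coefficient of '", name, "' is not a nonnegative integer", call. = FALSE)
    }
    out[[length(out) + 1L]] <- list(name = name, coef = coef)
  }
  out
}

#' Parse a plain-text reaction network
#'
#' Reads one reaction (or one reversible pair) per line. Each line has the
#' form `<complex> -> <complex>` or `<complex> <-> <complex>`; a complex is a
#' `" + "`-separated list of terms `[coef] Name` (omitted coefficient means 1,
#' `0` denotes the empty complex). Lines starting with `#` are comments. An
#' optional header line `species: A B C` fixes the species order; otherwise
#' species are ordered by first appearance. Reversible lines expand to a
#' forward reaction followed by its reverse, with consecutive rate labels.
#'
#' @param text a single string (possibly multi-line) or character vector of lines.
#' @return A [reaction_network].
#' @examples
#' net <- parse_network("X1 -> X2
#'                       X2 -> X1
#'                       2 X1 + X2 -> 3 X1")
#' n_reactions(net)
#' @export
parse_network <- function(text) {
  lines <- unlist(strsplit(text, "\n", fixed = TRUE), use.names = FALSE)
  lines_raw <- sub("#.*$", "", lines)
  species_order <- NULL
  rxn <- list() # list of list(reactant=named num, product=named num)
  seen <- character(0)
  for (i in seq_along(lines_raw)) {
    ln <- trimws(lines_raw[i])
    if (!nzchar(ln)) next
    if (grepl("^species\\s*:", ln)) {
      hdr <- trimws(sub("^species\\s*:", "", ln))
      sp <- strsplit(hdr, "\\s+")[[1]]
      if (anyDuplicated(sp)) stop("line ", i, ": duplicate species in header", call. = FALSE)
      species_order <- sp
      next
    }
    rev <- grepl("<->", ln, fixed = TRUE)
    parts <- if (rev) strsplit(ln, "<->", fixed = TRUE)[[1]] else strsplit(ln, "->", fixed = TRUE)[[1]]
    if (length(parts) != 2) stop("line ", i, ": malformed reaction '", ln, "'", call. = FALSE)
    lhs <- .parse_complex(parts[1], i)
    rhs <- .parse_complex(parts[2], i)
    tovec <- function(cx) {
      v <- numeric(0)
      for (t in cx) v[t$name] <- (if (t$name %in% names(v)) v[[t$name]] else 0) + t$coef
      v
    }
    lv <- tovec(lhs); rv <- tovec(rhs)
    for (nm in c(names(lv), names(rv))) if (!(nm %in% seen)) seen <- c(seen, nm)
    eq <- identical(sort(names(lv)), sort(names(rv))) &&
      all(lv[sort(names(lv))] == rv[sort(names(lv))])
    if (eq) stop("line ", i, ": reactant equals product", call. = FALSE)
    rxn[[length(rxn) + 1L]] <- list(reactant = lv, product = rv)
    if (rev) rxn[[length(rxn) + 1L]] <- list(reactant = rv, product = lv)
  }
  if (length(rxn) == 0) stop("no reactions found", call. = FALSE)
  species <- if (is.null(species_order)) seen else species_order
  missing <- setdiff(seen, species)
  if (length(missing)) {
    stop("species not in header: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  r <- length(rxn)
  reactant <- matrix(0, length(species), r, dimnames = list(species, NULL))
  product <- matrix(0, length(species), r, dimnames = list(species, NULL))
  for (j in seq_len(r)) {
    reactant[names(rxn[[j]]$reactant), j] <- rxn[[j]]$reactant
    product[names(rxn[[j]]$product), j] <- rxn[[j]]$product
  }
  reaction_network(species, reactant, product)
}

.format_complex <- function(v, species) {
  idx <- which(v != 0)
  if (length(idx) == 0) return("0")
  paste(vapply(idx, function(i) {
    if (v[i] == 1) species[i] else paste(v[i], species[i])
  }, character(1)), collapse = " + ")
}

#' Serialize a network to the plain-text reaction format
#'
#' The output re-parses to an identical network (species header included so
#' the species order is preserved).
#'
#' @param net a [reaction_network].
#' @return A single string.
#' @export
serialize_network <- function(net) {
  lines <- c(paste("species:", paste(net$species, collapse = " ")))
  for (j in seq_len(n_reactions(net))) {
    lines <- c(lines, paste(
      .format_complex(net$reactant[, j], net$species), "->",
      .format_complex(net$product[, j], net$species)
    ))
  }
  paste(lines, collapse = "\n")
}

#' @export
print.reaction_network <- function(x, ...) {
  cat("Reaction network:", n_species(x), "species,", n_reactions(x), "reactions\n")
  for (j in seq_len(n_reactions(x))) {
    cat(sprintf("  %s: %s -> %s\n", x$labels[j],
                .format_complex(x$reactant[, j], x$species),
                .format_complex(x$product[, j], x$species)))
  }
  invisible(x)
}

#' Tidy a reaction network into a tibble of reactions
#'
#' @param x a [reaction_network].
#' @param ... unused.
#' @return A tibble with one row per reaction: label, reactant, product.
#' @export
#' @importFrom generics tidy
tidy.reaction_network <- function(x, ...) {
  tibble::tibble(
    reaction = seq_len(n_reactions(x)),
    label = x$labels,
    reactant = vapply(seq_len(n_reactions(x)),
                      function(j) .format_complex(x$reactant[, j], x$species), character(1)),
    product = vapply(seq_len(n_reactions(x)),
                     function(j) .format_complex(x$product[, j], x$species), character(1))
  )
}

#' Stoichiometric data of a network
#'
#' Assembles the stoichiometric matrix `N = B - A` (one column per reaction),
#' the reactant-coefficient matrix `A`, the rank `s` of `N` over the
#' rationals, and a matrix of conservation relations `W`: the reduced
#' row-echelon basis of the left kernel of `N`, with the pivot indices
#' (first nonzero column of each row) recorded. All computations are exact.
#'
#' @param net a [reaction_network].
#' @return An object of class `stoich_data` with fields `N`, `A`, `s`, `W`
#'   (numeric matrix; exact values, possibly rational), `W_num`/`W_den`
#'   (exact numerator/denominator matrices) and `pivots`.
#' @export
stoichiometry <- function(net) {
  stopifnot(inherits(net, "reaction_network"))
  N <- net$product - net$reactant
  A <- net$reactant
  K <- left_kernel_rref(N)
  s <- n_species(net) - K$rank
  structure(
    list(N = N, A = A, s = s,
         W = K$n / K$d, W_num = K$n, W_den = K$d,
         pivots = K$pivots, species = net$species),
    class = "stoich_data"
  )
}

#' @export
print.stoich_data <- function(x, ...) {
  cat("Stoichiometric data: n =", nrow(x$N), " r =", ncol(x$N),
      " rank s =", x$s, " conservation laws:", nrow(x$W), "\n")
  invisible(x)
}

# exact LP feasibility wrapper: G z >= g with z free, all integer input
.lp_feasible <- function(G, g, max_iter = 200000) {
  res <- cpp_lp_feasible(G, as.numeric(g), max_iter)
  if (!isTRUE(res$feasible)) return(NULL)
  list(n = res$num, d = res$den)
}

#' Test conservativity of a network
#'
#' A network is conservative when a strictly positive row vector `w` with
#' `w N = 0` exists; then every stoichiometric compatibility class is compact.
#' The decision solves the exact feasibility problem `w N = 0`, `w >= 1`
#' (scale invariance makes `>= 1` equivalent to `> 0`).
#'
#' @param sd a `stoich_data` (or a [reaction_network], which is converted).
#' @return A list with `conservative` (logical) and, when `TRUE`, `witness`:
#'   an exact positive rational vector (`list(n=, d=)`) with `witness N = 0`.
#' @export
is_conservative <- function(sd) {
  if (inherits(sd, "reaction_network")) sd <- stoichiometry(sd)
  N <- sd$N
  n <- nrow(N); r <- ncol(N)
  G <- rbind(t(N), -t(N), diag(n))
  g <- c(rep(0, 2 * r), rep(1, n))
  w <- .lp_feasible(G, g)
  if (is.null(w)) {
    list(conservative = FALSE, witness = NULL)
  } else {
    list(conservative = TRUE, witness = w)
  }
}
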