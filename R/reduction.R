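# Network reduction: removing the reverse reaction of a reversible binding
# step whose intermediate species occurs in exactly three reactions lifts
# path-connectivity conclusions from the reduced to the original network.

#' Reverse reactions removable by the intermediate-species reduction
#'
#' Finds reactions `R` such that: `R` is the reverse of a reaction `P` whose
#' product is a single species `X` with coefficient 1; `X` participates in
#' exactly three reactions — `P`, `R`, and one irreversible reaction consuming
#' `X` alone — and appears in no other reactant or product (in particular not
#' in the complexes of its own pattern). Matching is purely syntactic on the
#' stoichiometry; species matching several patterns cannot occur (three
#' reactions admit at most one role assignment), and distinct intermediates
#' give disjoint patterns, so all matches are removed in one pass.
#'
#' @param net a [reaction_network].
#' @return Integer vector of reaction indices (possibly empty), sorted.
#' @export
removable_reverse_reactions <- function(net) {
  A <- net$reactant; B <- net$product
  n <- n_species(net); r <- n_reactions(net)
  out <- integer(0)
  for (i in seq_len(n)) {
    touch <- which(A[i, ] > 0 | B[i, ] > 0)
    if (length(touch) != 3) next
    # P: produces X alone with coefficient 1, X not in its reactant
    isP <- vapply(touch, function(j) {
      B[i, j] == 1 && sum(B[, j]) == 1 && A[i, j] == 0
    }, logical(1))
    if (sum(isP) != 1) next
    P <- touch[isP]
    rest <- setdiff(touch, P)
    # R: exact reverse of P
    isR <- vapply(rest, function(j) {
      all(A[, j] == B[, P]) && all(B[, j] == A[, P])
    }, logical(1))
    if (sum(isR) != 1) next
    R <- rest[isR]
    Tn <- setdiff(rest, R)
    # T: consumes X alone, X not in its product
    okT <- A[i, Tn] == 1 && sum(A[, Tn]) == 1 && B[i, Tn] == 0
    if (!okT) next
    out <- c(out, R)
  }
  sort(out)
}

#' Remove reactions from a network
#'
#' Removes the given reactions (validated against
#' [removable_reverse_reactions()]), keeping species order and the original
#' rate labels of the remaining reactions.
#'
#' @param net a [reaction_network].
#' @param indices reaction indices to remove; defaults to all removable
#'   reverse reactions.
#' @return The reduced [reaction_network].
#' @export
reduce_network <- function(net, indices = removable_reverse_reactions(net)) {
  if (length(indices) == 0) return(net)
  removable <- removable_reverse_reactions(net)
  if (!all(indices %in% removable)) {
    stop("indices not removable: ", paste(setdiff(indices, removable), collapse = ", "),
         call. = FALSE)
  }
  keep <- setdiff(seq_len(n_reactions(net)), indices)
  reaction_network(net$species,
                   net$reactant[, keep, drop = FALSE],
                   net$product[, keep, drop = FALSE],
                   labels = net$labels[keep])
}
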