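# Orchestration: the full connectivity check.

#' Check path connectivity of the multistationarity region
#'
#' Runs the complete procedure on a mass-action network:
#' \enumerate{
#'   \item verify that the network is conservative and that minimal siphons
#'     exclude relevant boundary steady states;
#'   \item compute the extreme rays of the flux cone and, if the network is
#'     consistent, the critical polynomial of the convex parametrization;
#'   \item decide existence of a strict separating hyperplane of the signed
#'     support;
#'   \item on failure (no hyperplane, or the symbolic determinant exceeds the
#'     term budget), optionally repeat on the reduced network obtained by
#'     removing removable reverse reactions — a positive verdict there lifts
#'     to the original network.
#' }
#'
#' Verdicts: `PATH_CONNECTED` (hyperplane found for the original network or a
#' valid reduction), `EMPTY_REGION` (no negative coefficients — no parameter
#' pair enables multistationarity, so the region is empty and trivially path
#' connected; also used when the network is inconsistent and thus has no
#' positive steady states), `PRECONDITION_FAILED` (conservativity or the
#' siphon criterion could not be established; inconclusive), `INCONCLUSIVE`
#' (no strict separating hyperplane found). Only `PATH_CONNECTED` is a claim
#' about the region; the others never assert disconnectedness.
#'
#' @param net a [reaction_network] or a string in the plain-text reaction
#'   format (parsed with [parse_network()]).
#' @param reduce one of `"auto"` (original first, reduction as fallback),
#'   `"never"`, `"first"` (reduce before analysing).
#' @param term_budget passed to [critical_polynomial()].
#' @param siphon_bound passed to [minimal_siphons()].
#' @param verbose log steps to stderr.
#' @return A `connectivity_report`.
#' @export
check_connectivity <- function(net, reduce = c("auto", "never", "first"),
                               term_budget = 1e6, siphon_bound = 22,
                               verbose = FALSE) {
  reduce <- match.arg(reduce)
  if (is.character(net)) net <- parse_network(net)
  stopifnot(inherits(net, "reaction_network"))
  say <- function(...) if (verbose) message(...)

  removed <- integer(0)
  analysed <- net
  if (reduce == "first") {
    removed <- removable_reverse_reactions(net)
    if (length(removed)) {
      say("reducing first: removing reactions ", paste(net$labels[removed], collapse = ", "))
      analysed <- reduce_network(net, removed)
    }
  }

  rep1 <- .connectivity_once(analysed, term_budget, siphon_bound, say)
  rep1$network <- net
  rep1$n <- n_species(net); rep1$r <- n_reactions(net)
  rep1$reduced_used <- reduce == "first" && length(removed) > 0
  rep1$removed_labels <- if (rep1$reduced_used) net$labels[removed] else character(0)

  if (reduce == "auto" && identical(rep1$verdict, "INCONCLUSIVE")) {
    removed <- removable_reverse_reactions(net)
    if (length(removed)) {
      say("falling back to the reduced network: removing reactions ",
          paste(net$labels[removed], collapse = ", "))
      red <- reduce_network(net, removed)
      rep2 <- .connectivity_once(red, term_budget, siphon_bound, say)
      rep1$reduced_report <- rep2
      if (identical(rep2$verdict, "PATH_CONNECTED")) {
        # a positive verdict on the reduced network lifts to the original;
        # a negative one does not overwrite anything
        rep1$verdict <- "PATH_CONNECTED"
        rep1$reduced_used <- TRUE
        rep1$removed_labels <- net$labels[removed]
        rep1$hyperplane <- rep2$hyperplane
        rep1$l_reduced <- rep2$l
      }
    }
  }
  class(rep1) <- "connectivity_report"
  rep1
}

.connectivity_once <- function(net, term_budget, siphon_bound, say) {
  sd <- stoichiometry(net)
  out <- list(n = n_species(net), r = n_reactions(net), l = NA_integer_,
              conservative = NA, no_boundary_steady_states = NA, consistent = NA,
              sigma_plus_count = NA_integer_, sigma_minus_count = NA_integer_,
              hyperplane = NULL, reduced_used = FALSE, verdict = NULL,
              reason = NULL)
  cons <- is_conservative(sd)
  out$conservative <- cons$conservative
  if (!cons$conservative) {
    out$verdict <- "PRECONDITION_FAILED"
    out$reason <- "the network is not conservative"
    return(out)
  }
  say("conservative: witness found")
  nbss <- tryCatch(excludes_boundary_steady_states(net, sd, max_species = siphon_bound),
                   error = function(e) stop(e))
  out$no_boundary_steady_states <- nbss
  if (!nbss) {
    out$verdict <- "PRECONDITION_FAILED"
    out$reason <- "the siphon criterion could not exclude relevant boundary steady states"
    return(out)
  }
  say("no relevant boundary steady states (siphon criterion)")
  fc <- extreme_rays(sd$N)
  out$l <- fc$l
  out$consistent <- is_consistent(fc)
  if (!out$consistent) {
    out$verdict <- "EMPTY_REGION"
    out$reason <- "the network is not consistent: no positive steady states exist"
    return(out)
  }
  cp <- tryCatch(critical_polynomial(sd, fc, term_budget = term_budget),
                 error = function(e) e)
  if (inherits(cp, "error")) {
    out$verdict <- "INCONCLUSIVE"
    out$reason <- conditionMessage(cp)
    return(out)
  }
  ss <- signed_support(cp)
  out$sigma_plus_count <- nrow(ss$positive)
  out$sigma_minus_count <- nrow(ss$negative)
  say("critical polynomial: ", out$sigma_plus_count, " positive, ",
      out$sigma_minus_count, " negative coefficients")
  if (out$sigma_minus_count == 0) {
    out$verdict <- "EMPTY_REGION"
    out$reason <- "the critical polynomial has no negative coefficients: no parameter pair enables multistationarity"
    return(out)
  }
  hp <- find_strict_separating_hyperplane(ss)
  if (!is.null(hp)) {
    out$hyperplane <- hp
    out$verdict <- "PATH_CONNECTED"
  } else {
    out$verdict <- "INCONCLUSIVE"
    out$reason <- "no strict separating hyperplane of the signed support exists"
  }
  out
}

#' @export
print.connectivity_report <- function(x, ...) {
  cat(sprintf("n = %d\n", x$n))
  cat(sprintf("r = %d\n", x$r))
  if (isTRUE(x$conservative)) {
    cat("The reaction network is conservative.\n")
  } else if (identical(x$conservative, FALSE)) {
    cat("The reaction network could not be shown to be conservative.\n")
  }
  if (isTRUE(x$no_boundary_steady_states)) {
    cat("There are no relevant boundary steady states.\n")
  } else if (identical(x$no_boundary_steady_states, FALSE)) {
    cat("Relevant boundary steady states could not be excluded.\n")
  }
  if (!is.na(x$l)) cat(sprintf("l = %d\n", x$l))
  if (!is.na(x$sigma_plus_count)) {
    cat(sprintf("Number of positive coefficients: %d\n", x$sigma_plus_count))
    cat(sprintf("Number of negative coefficients: %d\n", x$sigma_minus_count))
  }
  if (!is.null(x$hyperplane)) {
    cat("The support set has a strict separating hyperplane.\n")
  } else if (identical(x$verdict, "INCONCLUSIVE")) {
    cat("The support set has no strict separating hyperplane.\n")
  }
  if (isTRUE(x$reduced_used)) {
    cat("(Conclusion obtained on the reduced network; it lifts to the original network.)\n")
  }
  switch(x$verdict,
    PATH_CONNECTED = {
      cat("All the conditions are satisfied.\n")
      cat("We conclude that the parameter region of multistationarity\nis path connected.\n")
    },
    EMPTY_REGION = {
      cat(x$reason, "\n")
      cat("The parameter region of multistationarity is empty\n(and trivially path connected).\n")
    },
    PRECONDITION_FAILED = {
      cat(x$reason, "\n")
      cat("The algorithm is inconclusive.\n")
    },
    INCONCLUSIVE = {
      cat("The algorithm is inconclusive.\n")
    }
  )
  invisible(x)
}

#' One-row summary of a connectivity report
#'
#' @param x a `connectivity_report`.
#' @param ... unused.
#' @return A one-row tibble.
#' @export
#' @importFrom generics glance
glance.connectivity_report <- function(x, ...) {
  tibble::tibble(
    n = x$n, r = x$r, l = x$l,
    conservative = x$conservative,
    no_boundary_steady_states = x$no_boundary_steady_states,
    consistent = x$consistent,
    sigma_plus = x$sigma_plus_count,
    sigma_minus = x$sigma_minus_count,
    separating_hyperplane = !is.null(x$hyperplane),
    reduced_used = isTRUE(x$reduced_used),
    verdict = x$verdict
  )
}

#' Serialize a connectivity report to JSON
#'
#' @param x a `connectivity_report`.
#' @return A JSON string mirroring the report fields.
#' @export
report_json <- function(x) {
  stopifnot(inherits(x, "connectivity_report"))
  hp <- if (!is.null(x$hyperplane)) {
    list(v_num = x$hyperplane$v$n, v_den = x$hyperplane$v$d,
         a_num = x$hyperplane$a$n, a_den = x$hyperplane$a$d)
  } else NULL
  jsonlite::toJSON(list(
    n = x$n, r = x$r, l = x$l,
    conservative = x$conservative,
    no_boundary_steady_states = x$no_boundary_steady_states,
    consistent = x$consistent,
    sigma_plus_count = x$sigma_plus_count,
    sigma_minus_count = x$sigma_minus_count,
    hyperplane = hp,
    reduced_used = isTRUE(x$reduced_used),
    verdict = x$verdict,
    reason = x$reason
  ), auto_unbox = TRUE, null = "null", digits = NA)
}
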