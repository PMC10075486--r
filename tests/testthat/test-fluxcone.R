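test_that("extreme rays reproduce the printed ray matrices", {
  # running example: rays (1,0,1) and (1,1,0)
  fc <- extreme_rays(stoichiometry(example_network("running_example"))$N)
  expect_equal(unname(fc$E), matrix(c(1, 0, 1, 1, 1, 0), 3, 2))

  # cell cycle: printed 6x3 matrix of 0/1 vectors, in printed column order
  fc2 <- extreme_rays(stoichiometry(example_network("cell_cycle"))$N)
  Eref <- matrix(c(0, 0, 1,
                   0, 1, 0,
                   0, 0, 1,
                   1, 0, 0,
                   0, 1, 0,
                   1, 0, 0), 6, 3, byrow = TRUE)
  expect_equal(unname(fc2$E), Eref)

  # hybrid histidine kinase: printed 6x2 matrix
  fc3 <- extreme_rays(stoichiometry(example_network("hybrid_histidine_kinase"))$N)
  expect_equal(unname(fc3$E), matrix(c(0, 1, 1, 1, 1, 0, 0, 1, 1, 0, 1, 1), 6, 2, byrow = TRUE))

  # reduced shared-kinase cascade: printed 10x3 matrix up to column order
  fc4 <- extreme_rays(stoichiometry(example_network("shared_kinase_reduced"))$N)
  Eref4 <- matrix(c(0, 0, 1, 0, 0, 1, 0, 0, 1, 0, 0, 1,
                    1, 0, 0, 1, 0, 0, 0, 1, 0, 0, 1, 0,
                    1, 1, 0, 1, 1, 0), 10, 3, byrow = TRUE)
  perm_ok <- FALSE
  for (p in list(1:3, c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))) {
    if (identical(unname(fc4$E[, p]), Eref4)) perm_ok <- TRUE
  }
  expect_true(perm_ok)
})

test_that("extreme rays agree with the minimal-support oracle on random matrices", {
  withr::local_seed(53)
  for (i in 1:20) {
    net <- random_network(sample(2:4, 1), sample(3:6, 1))
    N <- net$product - net$reactant
    got <- extreme_rays(N)$E
    want <- brute_extreme_rays(N)
    expect_equal(unname(got), unname(want))
  }
})

test_that("consistency is equivalent to the absence of zero rows in E", {
  expect_true(is_consistent(extreme_rays(stoichiometry(example_network("running_example"))$N)))
  fc <- extreme_rays(matrix(c(-1, 1), 2, 1))       # single irreversible A -> B
  expect_equal(fc$l, 0)
  expect_false(is_consistent(fc))
  fc2 <- extreme_rays(matrix(c(-1, 1, 1, -1), 2, 2)) # reversible pair
  expect_equal(unname(fc2$E), matrix(c(1, 1), 2, 1))
  expect_true(is_consistent(fc2))
})

test_that("reversible pairs always contribute their indicator ray", {
  # the last two reactions reverse to each other -> (0,...,0,1,1) is a ray
  nets <- list(example_network("allosteric_regulation"),
               example_network("phospho_cycle", m = 2),
               example_network("weakly_irrev_dephos"))
  for (net in nets) {
    N <- net$product - net$reactant
    r <- ncol(N)
    # locate all reverse pairs
    for (j in seq_len(r - 1)) {
      for (k in (j + 1):r) {
        if (all(N[, j] == -N[, k]) &&
            all(net$reactant[, j] == net$product[, k])) {
          ind <- numeric(r); ind[c(j, k)] <- 1
          E <- extreme_rays(N)$E
          hit <- any(apply(E, 2, function(col) all(col == ind)))
          expect_true(hit)
        }
      }
    }
  }
})

test_that("reduced-network rays embed into the full cone (zero-padded)", {
  for (name in c("shared_kinase", "allosteric_regulation", "erk")) {
    net <- example_network(name)
    idx <- removable_reverse_reactions(net)
    red <- reduce_network(net, idx)
    keep <- setdiff(seq_len(n_reactions(net)), idx)
    Ered <- extreme_rays(red$product - red$reactant)$E
    Efull <- extreme_rays(net$product - net$reactant)$E
    for (c0 in seq_len(ncol(Ered))) {
      v <- numeric(n_reactions(net))
      v[keep] <- Ered[, c0]
      expect_true(any(apply(Efull, 2, function(col) all(col == v))))
    }
    expect_gte(ncol(Efull), ncol(Ered) + length(idx))
  }
})

test_that("positive combinations of rays are strictly positive flux vectors", {
  withr::local_seed(59)
  for (name in c("running_example", "cell_cycle", "shared_kinase_reduced")) {
    fc <- extreme_rays(stoichiometry(example_network(name))$N)
    lambda <- sample(1:9, fc$l, replace = TRUE)
    v <- as.numeric(fc$E %*% lambda)
    expect_true(all(v > 0))
  }
})

test_that("relative interior points land strictly inside the cone", {
  # nonnegative quadrant: sum of the unit rays
  p <- relative_interior_point(diag(2))
  expect_equal(p$n / p$d, c(1, 1))

  # halfplane {x >= 0} in Q^2: lineality in the second coordinate
  p2 <- relative_interior_point(matrix(c(1, 0), 1, 2))
  expect_gt((p2$n / p2$d)[1], 0)
  expect_equal((p2$n / p2$d)[2], 0)

  # weak-separation cones of worked supports: the returned point satisfies
  # every inequality, strictly exactly on the non-implicit ones (decided
  # independently by exact feasibility)
  supports <- list(fig_support(),
                   signed_support(critical_polynomial(
                     stoichiometry(example_network("running_example")),
                     extreme_rays(stoichiometry(example_network("running_example"))$N))))
  for (ss in supports) {
    G <- cone_rows(ss)
    p <- relative_interior_point(G)
    vals <- as.numeric(G %*% (p$n / p$d))
    expect_true(all(vals >= -1e-12))
    for (i in seq_len(nrow(G))) {
      # inequality i is non-implicit iff some point of the cone satisfies it strictly
      z <- crnconnect:::.lp_feasible(rbind(G, G[i, ]), c(rep(0, nrow(G)), 1))
      nonimplicit <- !is.null(z)
      expect_identical(vals[i] > 1e-12, nonimplicit)
    }
  }
})
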