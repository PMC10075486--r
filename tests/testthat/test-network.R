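test_that("parsing handles coefficients, reversible arrows and round-trips", {
  net <- parse_network("2 X1 + X2 -> 3 X1")
  expect_equal(unname(net$reactant[, 1]), c(2, 1))
  expect_equal(unname(net$product[, 1]), c(3, 0))

  rev <- parse_network("A <-> B")
  expect_equal(n_reactions(rev), 2)
  expect_equal(unname(rev$reactant), matrix(c(1, 0, 0, 1), 2))
  expect_equal(rev$labels, c("k1", "k2"))

  run <- example_network("running_example")
  back <- parse_network(serialize_network(run))
  expect_identical(back$species, run$species)
  expect_identical(unname(back$reactant), unname(run$reactant))
  expect_identical(unname(back$product), unname(run$product))
})

test_that("malformed input is rejected with line-level errors", {
  expect_error(parse_network("species: A A\nA -> B"), "duplicate species")
  expect_error(parse_network("A -> A"), "reactant equals product")
  expect_error(parse_network("A -> B C"), "malformed")
  expect_error(parse_network("A -> 1.5 B"), "malformed|coefficient")
  expect_error(reaction_network("A", matrix(1, 1, 1), matrix(-1, 1, 1)), "nonnegative")
})

test_that("stoichiometry reproduces the printed matrices of the worked networks", {
  # six-species cell cycle module, species order C, C+, M, M+, W, W+
  sd <- stoichiometry(example_network("cell_cycle"))
  Nref <- matrix(c(0, 1, 0, 0, -1, 0,
                   0, -1, 0, 0, 1, 0,
                   1, 0, -1, 0, 0, 0,
                   -1, 0, 1, 0, 0, 0,
                   0, 0, 0, -1, 0, 1,
                   0, 0, 0, 1, 0, -1), 6, 6, byrow = TRUE)
  expect_equal(unname(sd$N), Nref)
  expect_equal(unname(sd$W), matrix(c(1, 1, 0, 0, 0, 0,
                                      0, 0, 1, 1, 0, 0,
                                      0, 0, 0, 0, 1, 1), 3, 6, byrow = TRUE))
  expect_equal(sd$pivots, c(1L, 3L, 5L))
  expect_equal(sd$s, 3)

  # running example
  sd2 <- stoichiometry(example_network("running_example"))
  expect_equal(dim(sd2$N), c(2L, 3L))
  expect_equal(sd2$s, 1)
  expect_equal(unname(sd2$W), matrix(c(1, 1), 1))

  # hybrid histidine kinase: two conservation relations, pivots 1 and 5
  sd3 <- stoichiometry(example_network("hybrid_histidine_kinase"))
  expect_equal(unname(sd3$W), matrix(c(1, 1, 1, 1, 0, 0,
                                       0, 0, 0, 0, 1, 1), 2, 6, byrow = TRUE))
  expect_equal(sd3$pivots, c(1L, 5L))
})

test_that("stoichiometric identities hold on random networks", {
  withr::local_seed(11)
  for (i in 1:20) {
    net <- random_network(sample(2:5, 1), sample(2:5, 1))
    sd <- stoichiometry(net)
    expect_equal(sd$N, net$product - net$reactant)
    if (nrow(sd$W) > 0) {
      # W N = 0 exactly (clear denominators first)
      cw <- crnconnect:::clear_rows(sd$W_num, sd$W_den)
      expect_true(all(cw$mat %*% sd$N == 0))
    }
    expect_equal(nrow(sd$W) + sd$s, n_species(net))
  }
})

test_that("conservativity matches the definition and produces exact witnesses", {
  res <- is_conservative(stoichiometry(example_network("running_example")))
  expect_true(res$conservative)
  w <- res$witness
  expect_true(all(w$n / w$d > 0))
  # witness proportional to (1, 1)
  expect_equal(w$n[1] * w$d[2], w$n[2] * w$d[1])

  expect_true(is_conservative(stoichiometry(example_network("cell_cycle")))$conservative)

  ab <- parse_network("A -> B")
  resab <- is_conservative(stoichiometry(ab))
  expect_true(resab$conservative)
  wab <- resab$witness
  expect_equal(wab$n[1] * wab$d[2], wab$n[2] * wab$d[1]) # w = (1,1) up to scale

  expect_false(is_conservative(stoichiometry(parse_network("A -> 2 A")))$conservative)
})

test_that("conservativity agrees with a positive-combination search over W rows", {
  withr::local_seed(23)
  for (i in 1:15) {
    net <- random_network(sample(2:4, 1), sample(2:4, 1))
    sd <- stoichiometry(net)
    got <- is_conservative(sd)$conservative
    # brute force: some nonnegative integer combination of the rows of W with
    # all entries positive (coefficients 0..6; exact on rationals)
    k <- nrow(sd$W)
    found <- FALSE
    if (k > 0) {
      grid <- as.matrix(expand.grid(rep(list(0:6), k)))
      for (g in seq_len(nrow(grid))) {
        v <- colSums(sd$W * grid[g, ])
        if (all(v > 1e-12)) { found <- TRUE; break }
      }
    }
    expect_identical(got, found)
    if (got) {
      w <- is_conservative(sd)$witness
      expect_true(all(abs((w$n / w$d) %*% sd$N) < 1e-12))
    }
  }
})
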