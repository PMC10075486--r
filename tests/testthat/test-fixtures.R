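# Structural gates for the whole corpus: species/reaction/extreme-ray counts,
# conservativity and exclusion of boundary steady states.

test_that("all fixtures have the published sizes and ray counts", {
  cases <- list(
    list("cell_cycle", NULL, 6, 6, 3),
    list("hybrid_histidine_kinase", NULL, 6, 6, 2),
    list("allosteric_regulation", NULL, 9, 10, 5),
    list("covalent_regulation", NULL, 12, 14, 7),
    list("phospho_cycle", 2, 9, 12, 6),
    list("phospho_cycle", 3, 12, 18, 9),
    list("phospho_cycle", 4, 15, 24, 12),
    list("phospho_diff_phosphatases", 2, 10, 12, 6),
    list("phospho_diff_phosphatases", 3, 14, 18, 9),
    list("phospho_diff_phosphatases", 4, 18, 24, 12),
    list("weakly_irrev_dephos", NULL, 11, 16, 8),
    list("fully_weakly_irrev", NULL, 13, 20, 10),
    list("shared_kinase", NULL, 12, 15, 8),
    list("mapk_two_layer", NULL, 14, 18, 9),
    list("erk", NULL, 12, 18, 9),
    list("running_example", NULL, 2, 3, 2),
    list("allosteric_reduced", NULL, 9, 8, 3),
    list("shared_kinase_reduced", NULL, 12, 10, 3)
  )
  for (cs in cases) {
    net <- if (is.null(cs[[2]])) example_network(cs[[1]]) else example_network(cs[[1]], m = cs[[2]])
    expect_equal(n_species(net), cs[[3]], label = paste(cs[[1]], cs[[2]], "n"))
    expect_equal(n_reactions(net), cs[[4]], label = paste(cs[[1]], cs[[2]], "r"))
    fc <- extreme_rays(net$product - net$reactant)
    expect_equal(fc$l, cs[[5]], label = paste(cs[[1]], cs[[2]], "l"))
    expect_true(is_consistent(fc), label = paste(cs[[1]], cs[[2]], "consistent"))
  }
})

test_that("reduced ray counts match the published reductions", {
  cases <- list(
    list("cell_cycle", NULL, 3), list("hybrid_histidine_kinase", NULL, 2),
    list("allosteric_regulation", NULL, 3), list("covalent_regulation", NULL, 3),
    list("phospho_cycle", 2, 2), list("phospho_cycle", 3, 3), list("phospho_cycle", 4, 4),
    list("phospho_diff_phosphatases", 2, 2), list("phospho_diff_phosphatases", 3, 3),
    list("phospho_diff_phosphatases", 4, 4),
    list("weakly_irrev_dephos", NULL, 4), list("fully_weakly_irrev", NULL, 6),
    list("shared_kinase", NULL, 3), list("mapk_two_layer", NULL, 3), list("erk", NULL, 5)
  )
  for (cs in cases) {
    net <- if (is.null(cs[[2]])) example_network(cs[[1]]) else example_network(cs[[1]], m = cs[[2]])
    red <- reduce_network(net)
    fc <- extreme_rays(red$product - red$reactant)
    expect_equal(fc$l, cs[[3]], label = paste(cs[[1]], cs[[2]], "l-reduced"))
  }
})

test_that("all fixtures are conservative and exclude boundary steady states", {
  # cell_cycle is absent: its catalytic siphon {C, M} admits a genuine
  # relevant boundary steady state, so the exclusion criterion honestly fails
  names <- c("running_example", "hybrid_histidine_kinase",
             "weakly_irrev_dephos", "fully_weakly_irrev", "erk",
             "shared_kinase", "shared_kinase_reduced", "mapk_two_layer",
             "covalent_regulation", "allosteric_regulation", "allosteric_reduced")
  for (name in names) {
    net <- example_network(name)
    sd <- stoichiometry(net)
    expect_true(is_conservative(sd)$conservative, label = paste(name, "conservative"))
    expect_true(excludes_boundary_steady_states(net, sd), label = paste(name, "boundary"))
  }
  for (m in 2:4) {
    for (fam in c("phospho_cycle", "phospho_diff_phosphatases")) {
      net <- example_network(fam, m = m)
      sd <- stoichiometry(net)
      expect_true(is_conservative(sd)$conservative)
      expect_true(excludes_boundary_steady_states(net, sd))
    }
  }
})

test_that("unknown fixtures and bad site counts are rejected", {
  expect_error(example_network("no_such_network"))
  expect_error(example_network("phospho_cycle", m = 0), "m must be")
})

test_that("the full shared-kinase cascade extends the printed reduced one", {
  full <- example_network("shared_kinase")
  red <- example_network("shared_kinase_reduced")
  keep <- setdiff(seq_len(15), c(3, 6, 9, 12, 15))
  expect_identical(unname(full$reactant[, keep]), unname(red$reactant))
  expect_identical(unname(full$product[, keep]), unname(red$product))
  # removed columns are the reverses of the binding reactions
  for (j in c(3, 6, 9, 12, 15)) {
    expect_identical(unname(full$reactant[, j]), unname(full$product[, j - 1]))
    expect_identical(unname(full$product[, j]), unname(full$reactant[, j - 1]))
  }
})
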