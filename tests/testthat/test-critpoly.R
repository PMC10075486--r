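test_that("the convex matrix of the running example matches the worked form", {
  sd <- stoichiometry(example_network("running_example"))
  fc <- extreme_rays(sd$N)
  cm <- build_convex_matrix(sd, fc)
  f <- format(cm)
  expect_equal(f[1, ], c("1", "1"))
  expect_equal(f[2, ], c("(-l1+l2)*h1", "(-l1-l2)*h2"))
})

test_that("the convex matrix places conservation rows at the pivots", {
  sd <- stoichiometry(example_network("cell_cycle"))
  fc <- extreme_rays(sd$N)
  cm <- build_convex_matrix(sd, fc)
  for (i in c(1, 3, 5)) {
    expect_true(all(vapply(cm$entries[[i]], function(e) e$type == "W", logical(1))))
  }
  for (i in c(2, 4, 6)) {
    expect_true(all(vapply(cm$entries[[i]], function(e) e$type == "J", logical(1))))
  }
  expect_error(build_convex_matrix(stoichiometry(parse_network("A -> B")),
                                   extreme_rays(matrix(c(-1, 1), 2, 1))),
               "no extreme rays")
})

test_that("the running-example critical polynomial equals the worked expansion", {
  sd <- stoichiometry(example_network("running_example"))
  fc <- extreme_rays(sd$N)
  cp <- critical_polynomial(sd, fc)
  # h1*l2 - h1*l1 + h2*l1 + h2*l2, variables (h1, h2, l1, l2)
  got <- cbind(cp$exponents, coef = cp$coef_num)
  want <- rbind(c(1, 0, 1, 0, -1), c(1, 0, 0, 1, 1), c(0, 1, 1, 0, 1), c(0, 1, 0, 1, 1))
  ord <- function(m) m[do.call(order, as.data.frame(m)), , drop = FALSE]
  expect_equal(unname(ord(got)), unname(ord(want)))
  expect_equal(cp$coef_den, 1)
})

test_that("signed supports partition by coefficient sign", {
  ss <- fig_support()
  expect_equal(nrow(ss$positive), 4)
  expect_equal(unname(ss$negative), matrix(c(2, 1), 1))

  cp <- critical_polynomial(stoichiometry(example_network("running_example")),
                            extreme_rays(stoichiometry(example_network("running_example"))$N))
  ss2 <- signed_support(cp)
  expect_equal(nrow(ss2$positive), 3)
  expect_equal(nrow(ss2$negative), 1)

  allpos <- signed_support(rbind(c(1, 0), c(0, 1)), coef = c(2, 3))
  expect_equal(nrow(allpos$negative), 0)
})

test_that("every monomial has degree s in h and in lambda", {
  for (name in c("running_example", "cell_cycle", "hybrid_histidine_kinase",
                 "allosteric_reduced", "shared_kinase_reduced")) {
    sd <- stoichiometry(example_network(name))
    fc <- extreme_rays(sd$N)
    cp <- critical_polynomial(sd, fc)
    hdeg <- rowSums(cp$exponents[, seq_len(cp$n), drop = FALSE])
    ldeg <- rowSums(cp$exponents[, cp$n + seq_len(cp$l), drop = FALSE])
    expect_true(all(hdeg == sd$s))
    expect_true(all(ldeg == sd$s))
  }
  # for the cell cycle every lambda exponent is exactly (1,1,1)
  sd <- stoichiometry(example_network("cell_cycle"))
  cp <- critical_polynomial(sd, extreme_rays(sd$N))
  expect_true(all(cp$exponents[, 7:9] == 1))
})

test_that("the convex parametrization maps onto steady states and the
           critical polynomial agrees with the determinant oracle", {
  withr::local_seed(61)
  fixtures <- c("running_example", "cell_cycle", "hybrid_histidine_kinase",
                "allosteric_reduced", "shared_kinase_reduced")
  for (name in fixtures) {
    net <- example_network(name)
    sd <- stoichiometry(net)
    fc <- extreme_rays(sd$N)
    cp <- critical_polynomial(sd, fc)
    small <- n_species(net) <= 9
    for (rep in 1:50) {
      if (small && rep %% 2 == 0) {
        h <- list(n = sample(1:5, cp$n, TRUE), d = sample(1:3, cp$n, TRUE))
        lam <- list(n = sample(1:5, cp$l, TRUE), d = sample(1:2, cp$l, TRUE))
      } else {
        h <- sample(1:3, cp$n, TRUE)
        lam <- sample(1:3, cp$l, TRUE)
      }
      pt <- convex_parametrization_point(sd, fc, h, lam)
      # the rate vector at (x, kappa) is E lambda, hence in ker(N): x is a
      # positive steady state (checked through the actual rate function)
      v <- rate_function(net, pt$x, pt$kappa)
      resid <- sd$N %*% (v$n / v$d)
      expect_true(all(abs(resid) < 1e-9))
      # identity: critical polynomial at (h, lambda) = g(x, kappa)
      lhs <- attr(evaluate_critical_polynomial(cp, h, lam), "rational")
      rhs <- attr(evaluate_g(net, sd, pt$x, pt$kappa), "rational")
      expect_equal(lhs$n * rhs$d, rhs$n * lhs$d)
    }
  }
})

test_that("the sign function g matches the worked closed form", {
  net <- example_network("running_example")
  sd <- stoichiometry(net)
  # (-1)^s det M_kappa(x) = k3 x1^2 - 2 k3 x1 x2 + k1 + k2
  withr::local_seed(67)
  for (i in 1:20) {
    x <- sample(1:6, 2, TRUE)
    k <- sample(1:6, 3, TRUE)
    want <- k[3] * x[1]^2 - 2 * k[3] * x[1] * x[2] + k[1] + k[2]
    got <- evaluate_g(net, sd, x, k)
    expect_equal(as.numeric(got), want)
    r <- attr(got, "rational")
    expect_equal(r$n / r$d, want)
  }
})

test_that("a negative sign at a steady state detects multistationarity", {
  net <- example_network("running_example")
  sd <- stoichiometry(net)
  # steady states on the class x1 + x2 = 3 for kappa = (18, 1, 10) solve
  # -18 x1 + (3 - x1) + 10 x1^2 (3 - x1) = 0; there are three of them, and
  # the sign function is negative at the middle (unstable) one
  f <- function(x1) -18 * x1 + (3 - x1) + 10 * x1^2 * (3 - x1)
  roots <- sort(c(uniroot(f, c(0.05, 0.4), tol = 1e-12)$root,
                  uniroot(f, c(0.4, 1.0), tol = 1e-12)$root,
                  uniroot(f, c(1.0, 2.9), tol = 1e-12)$root))
  expect_equal(roots[1], 0.2448, tolerance = 1e-3)
  g <- evaluate_g(net, sd, c(roots[2], 3 - roots[2]), c(18, 1, 10))
  expect_lt(as.numeric(g), 0)
})

test_that("rescaling a ray leaves the signed support sizes unchanged", {
  sd <- stoichiometry(example_network("hybrid_histidine_kinase"))
  fc <- extreme_rays(sd$N)
  fc2 <- fc
  fc2$E[, 1] <- 3 * fc2$E[, 1]
  ss <- signed_support(critical_polynomial(sd, fc))
  ss2 <- signed_support(critical_polynomial(sd, fc2))
  expect_equal(nrow(ss$positive), nrow(ss2$positive))
  expect_equal(nrow(ss$negative), nrow(ss2$negative))
})

test_that("the symbolic expansion respects its term budget", {
  sd <- stoichiometry(example_network("phospho_cycle", m = 3))
  fc <- extreme_rays(sd$N)
  expect_error(critical_polynomial(sd, fc, term_budget = 100), "term budget")
})
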