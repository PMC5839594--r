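# Thermodynamic model evaluation, steady states and Taylor expansions.

test_that("conformation probabilities follow the normalised ensemble form", {
  m <- make_fixture("cross_repression")
  # only the unbound term survives at zero repressor concentration
  expect_equal(conformation_probabilities(m, "g1", c(0.3, 0)), c(1, 0))
  # closed form at the steady state: free weight / (free + bound * x2)
  y <- motif_steady_state()
  p <- conformation_probabilities(m, "g1", y)
  free <- motif_pars$w1 / (motif_pars$w1 + motif_pars$wp2 * y["g2"])
  expect_equal(unname(p), unname(c(free, 1 - free)), tolerance = 1e-12)
  # normalisation on random non-negative states, several fixtures
  for (fx in c("cross_repression", "cross_repression_bistable")) {
    mf <- make_fixture(fx)
    set.seed(7)
    for (r in 1:100) {
      x <- stats::runif(length(mf$proteins), 0, 5)
      for (g in mf$proteins) {
        pr <- conformation_probabilities(mf, g, x)
        expect_equal(sum(pr), 1, tolerance = 1e-12)
        expect_true(all(pr >= 0 & pr <= 1))
      }
    }
  }
})

test_that("degenerate ensemble denominators are reported with the gene name", {
  m <- grn_model(c("g1", "g2"), list(
    list(name = "g1", beta = 1, conformations = list(
      list(bound = c(g2 = 1), weight = 1, alpha = 1))),
    list(name = "g2", beta = 1, conformations = list(
      list(bound = NULL, weight = 1, alpha = 1)))))
  expect_error(conformation_probabilities(m, "g1", c(1, 0)), "g1")
  expect_error(time_derivative(m, c(1, 0)), "g1")
})

test_that("time derivative is production minus decay", {
  um <- unregulated_model(a = 2, b = 0.8)
  expect_equal(time_derivative(um, 3), c(g1 = 2 - 0.8 * 3))
  m <- make_fixture("cross_repression")
  expect_equal(unname(time_derivative(m, c(0, 0))), c(0.5, 0.5))
  y <- motif_one_state(m)
  expect_lt(max(abs(time_derivative(m, y))), 1e-9)
})

test_that("full simulation matches closed forms and stays non-negative", {
  um <- unregulated_model(a = 2, b = 0.8)
  tg <- seq(0, 10, 0.1)
  tr <- simulate_full(um, 5, tg, tol = 1e-10)
  expect_equal(tr$g1, 2.5 + (5 - 2.5) * exp(-0.8 * tg), tolerance = 1e-7)
  m <- make_fixture("cross_repression")
  tr2 <- simulate_full(m, c(0, 0), seq(0, 60, 1))
  expect_equal(as.numeric(tail(tr2, 1)[-1]), unname(motif_steady_state()),
               tolerance = 1e-6)
  # single-binding-site motif is not bistable: distinct starts, same end
  tr3 <- simulate_full(m, c(3, 0.1), seq(0, 60, 1))
  expect_equal(as.numeric(tail(tr3, 1)[-1]), as.numeric(tail(tr2, 1)[-1]),
               tolerance = 1e-6)
  expect_true(all(as.matrix(tr2[-1]) >= -1e-7))
})

test_that("steady-state search finds and classifies roots deterministically", {
  um <- unregulated_model(a = 2, b = 0.8)
  ss <- find_steady_states(um, rbind(0, 4))
  expect_length(ss, 1)
  expect_equal(unname(ss[[1]]$y), 2.5, tolerance = 1e-9)
  expect_true(ss[[1]]$stable)

  m <- make_fixture("cross_repression")
  ss <- find_steady_states(m, rbind(c(0, 0), c(3, 3), c(0.5, 1)))
  expect_length(ss, 1)
  expect_equal(unname(ss[[1]]$y), unname(motif_steady_state()),
               tolerance = 1e-9)
  expect_true(ss[[1]]$stable)

  mb <- make_fixture("cross_repression_bistable")
  grid <- as.matrix(expand.grid(seq(0, 4, 1), seq(0, 4, 1)))
  ssb <- find_steady_states(mb, grid)
  expect_length(ssb, 3)
  expect_equal(sum(vapply(ssb, `[[`, TRUE, "stable")), 2)
  # deterministic lexicographic order and stability/spectrum consistency
  ymat <- do.call(rbind, lapply(ssb, `[[`, "y"))
  expect_equal(order(ymat[, 1]), 1:3)
  for (r in ssb)
    expect_identical(r$stable, all(Re(r$eigenvalues) < 0))
})

test_that("analytic linearisation matches closed form and finite differences", {
  m <- make_fixture("cross_repression")
  y <- motif_one_state(m)
  L <- linearize(m, y)$L
  expect_equal(L, motif_L(y), tolerance = 1e-9)
  # unregulated gene: diagonal is exactly -beta
  um <- unregulated_model(b = 0.8)
  expect_equal(linearize(um, 2.5)$L[1, 1], -0.8)
  # finite-difference agreement on random models and random states
  for (s in 1:5) {
    mr <- random_grn_model(3, max_sites = 2, seed = 100 + s)
    set.seed(s)
    x <- stats::runif(3, 0.2, 2)
    L <- suppressWarnings(linearize(mr, x, check_steady = FALSE))$L
    h <- 1e-6
    for (k in 1:3) {
      e <- numeric(3); e[k] <- h
      fd <- (time_derivative(mr, x + e) - time_derivative(mr, x - e)) / (2 * h)
      expect_equal(unname(L[k, ]), unname(fd),
                   tolerance = 1e-6 * max(1, max(abs(fd))))
    }
  }
})

test_that("quadratic expansion has the canonical pair convention", {
  # a gene with constant production has no quadratic terms
  um <- unregulated_model()
  te <- quadratic_expansion(um, 2.5)
  expect_true(all(te$Q == 0))

  m <- make_fixture("cross_repression")
  y <- motif_one_state(m)
  te <- quadratic_expansion(m, y)
  p <- motif_pars
  q221 <- p$a1 * p$wp2^2 / (p$w1 + p$wp2 * y["g2"])^3  # half the 2nd deriv
  expect_equal(unname(te$Q["(g2,g2)", "g1"]), unname(q221),
               tolerance = 1e-9)
  # second central differences as an independent check
  h <- 1e-4
  d2 <- (time_derivative(m, y + c(0, h)) - 2 * time_derivative(m, y) +
           time_derivative(m, y - c(0, h))) / h^2
  expect_equal(unname(te$Q["(g2,g2)", ]), unname(d2 / 2), tolerance = 1e-5)
})

test_that("linear plus quadratic terms reconstruct the dynamics to cubic order", {
  m <- make_fixture("cross_repression_bistable")
  ss <- find_steady_states(m, as.matrix(expand.grid(0:4, 0:4)))
  y <- ss[[1]]$y
  te <- quadratic_expansion(m, y)
  predict_change <- function(d) {
    quad <- vapply(seq_len(ncol(te$L)), function(i)
      sum(te$Q[, i] * d[te$pairs[, 1]] * d[te$pairs[, 2]]), 0)
    as.numeric(d %*% te$L) + quad
  }
  set.seed(11)
  d <- stats::rnorm(2); d <- d / sqrt(sum(d^2))
  errs <- vapply(c(1e-2, 5e-3, 2.5e-3), function(eps) {
    f <- time_derivative(m, y + eps * d) - time_derivative(m, y)
    max(abs(f - predict_change(eps * d)))
  }, 0)
  # residual is O(eps^3): halving eps cuts it by about 8
  expect_lt(errs[2] / errs[1], 0.2)
  expect_lt(errs[3] / errs[2], 0.2)
})

test_that("model validation rejects bad specifications", {
  expect_error(grn_model("g1", list(list(name = "g1", beta = 0,
    conformations = list(list(bound = NULL, weight = 1, alpha = 1))))),
    "beta")
  expect_error(grn_model("g1", list(list(name = "g1", beta = 1,
    conformations = list(list(bound = NULL, weight = 0, alpha = 1))))),
    "weight > 0")
  expect_error(grn_model("g1", list(list(name = "g1", beta = 1,
    conformations = list(list(bound = NULL, weight = 1, alpha = 1),
                         list(bound = NULL, weight = 2, alpha = 0))))),
    "duplicate")
  expect_error(grn_model("g1", list(list(name = "g1", beta = 1,
    conformations = list(list(bound = NULL, weight = 1, alpha = 1)))),
    inputs = c(g1 = 1)), "clamped")
})
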