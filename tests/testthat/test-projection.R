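# Observable bookkeeping, rate matrix, memory functions and channel
# decomposition.

test_that("observable index enumerates blocks exhaustively and disjointly", {
  idx <- observable_index(c("a", "b", "c"), "a", order = "quadratic")
  expect_equal(nrow(idx$obs), 3 + 6)  # N + N(N+1)/2
  expect_setequal(c(idx$S, idx$B), seq_len(9))
  expect_length(intersect(idx$S, idx$B), 0)
  # S holds the linear subnetwork species and subnetwork-only products
  expect_setequal(idx$obs$name[idx$S], c("a", "(a,a)"))
  # any product touching a bulk species is a bulk observable
  expect_true(all(c("(a,b)", "(a,c)", "(b,c)") %in% idx$obs$name[idx$B]))
})

test_that("extended matrix implements the truncated product rule", {
  L <- random_stable_L(2, seed = 5)
  expn <- structure(list(y = c(0, 0), L = L,
                         Q = matrix(0, 3, 2), pairs = rbind(c(1, 1), c(1, 2),
                                                            c(2, 2))),
                    class = "grn_taylor")
  Lext <- build_extended_L(expn, "quadratic")
  expect_equal(dim(Lext), c(5, 5))
  # coefficient of dx1^2 in d/dt(dx1^2) is 2 L11
  expect_equal(Lext[3, 3], 2 * L[1, 1])
  # trajectory of dx1 dx2 for a fully linear network equals the product of
  # the linear solutions (oracle: matrix exponentials of L and Lext)
  z0 <- c(0.3, -0.2)
  for (t in c(0.5, 1.5)) {
    lin <- as.numeric(z0 %*% expm_mat(L * t))
    zt <- as.numeric(c(z0, z0[1]^2, z0[1] * z0[2], z0[2]^2) %*%
                       expm_mat(Lext * t))
    expect_equal(zt[4], lin[1] * lin[2], tolerance = 1e-9)
    expect_equal(zt[3], lin[1]^2, tolerance = 1e-9)
  }
})

test_that("rate matrix is the subnetwork block and ignores bulk internals", {
  m <- make_fixture("cross_repression")
  y <- motif_one_state(m)
  proj <- project_subnetwork(m, y, "g1", order = "linear")
  expect_equal(unname(rate_matrix(proj)), matrix(-0.5))
  # empty bulk: the rate matrix is the full matrix
  pl <- projection_from_matrix(random_stable_L(3, seed = 2), 1:3)
  expect_equal(rate_matrix(pl), pl$expansion$L)
  # perturbing bulk-internal entries leaves the rate matrix unchanged
  L <- random_stable_L(3, seed = 9)
  L2 <- L; L2[2:3, 2:3] <- L2[2:3, 2:3] + 0.3
  expect_equal(rate_matrix(projection_from_matrix(L, 1)),
               rate_matrix(projection_from_matrix(L2, 1)))
})

test_that("memory functions match the bulk impulse response", {
  # M(0) = L_SB L_BS
  L <- random_stable_L(4, seed = 13)
  pl <- projection_from_matrix(L, 1:2)
  amp <- memory_amplitude(pl)
  expect_equal(unname(amp),
               unname(L[1:2, 3:4] %*% L[3:4, 1:2]), tolerance = 1e-12)
  # oracle: integrate the bulk ODE block from unit impulses
  dt <- seq(0, 4, 0.5)
  M <- memory_function(pl, dt)
  B <- L[3:4, 3:4]
  for (j in 1:2) {
    imp <- deSolve::ode(y = c(1, 0)[order(c(j, setdiff(1:2, j)))],
                        times = dt,
                        func = function(t, x, p) list(as.numeric(x %*% B)),
                        parms = NULL, rtol = 1e-12, atol = 1e-14)
    for (i in seq_along(dt)) {
      eB <- as.numeric(imp[i, -1])
      expect_equal(unname(M[, , i][, , drop = FALSE]),
                   unname((L[1:2, 3:4] %*% expm_mat(B * dt[i]) %*%
                             L[3:4, 1:2])), tolerance = 1e-10)
      expect_equal(as.numeric(L[1:2, 3:4] %*% eB),
                   as.numeric(L[1:2, 3:4] %*% expm_mat(B * dt[i])[j, ]),
                   tolerance = 1e-8)
    }
  }
  # no feedback from the bulk: memory vanishes identically
  L0 <- L; L0[3:4, 1:2] <- 0
  M0 <- memory_function(projection_from_matrix(L0, 1:2), dt)
  expect_equal(max(abs(M0)), 0)
})

test_that("cross-repression self-memory is a positive decaying exponential", {
  m <- make_fixture("cross_repression")
  y <- motif_one_state(m)
  proj <- project_subnetwork(m, y, "g1", order = "quadratic")
  dt <- seq(0, 10, 0.02)
  M <- memory_function(proj, dt)
  Lcf <- motif_L()
  a0 <- Lcf["g1", "g2"] * Lcf["g2", "g1"]    # = 0.02403
  expect_equal(M["g1", "g1", ], a0 * exp(-0.5 * dt), tolerance = 1e-9)
  expect_true(all(M["g1", "g1", ] > 0))
  # decay rate equals the bulk decay rate (log-slope at large time diff)
  slope <- diff(log(M["g1", "g1", c(301, 501)])) / (dt[501] - dt[301])
  expect_equal(slope, -0.5, tolerance = 1e-9)
  # nonlinear self-memory amplitude is negative
  expect_lt(memory_amplitude(proj)["(g1,g1)", "g1"], 0)
})

test_that("channels partition the memory exactly", {
  # single bulk species: one channel equal to the total
  m <- make_fixture("cross_repression")
  y <- motif_one_state(m)
  proj <- project_subnetwork(m, y, "g1", order = "linear")
  dt <- seq(0, 5, 0.1)
  ch <- channel_decomposition(proj, dt)
  expect_length(ch, 1)
  expect_equal(ch$g2, memory_function(proj, dt), tolerance = 1e-14)

  # several bulk species (quadratic order): channels sum to the total
  mr <- random_grn_model(4, max_sites = 2, seed = 77)
  ss <- suppressWarnings(find_steady_states(mr, matrix(1, 1, 4)))
  pr <- project_subnetwork(mr, ss[[1]]$y, mr$proteins[1], "quadratic")
  tot <- memory_function(pr, dt)
  chs <- channel_decomposition(pr, dt)
  expect_lt(max(abs(Reduce(`+`, chs) - tot)), 1e-12)
  expect_error(channel_decomposition(pr, dt, channels = "nope"), "unknown")
})

test_that("entry attribution assigns chain memory to the entry species", {
  # s feeds b1, b1 feeds b2, only b2 feeds back to s
  L <- matrix(0, 3, 3, dimnames = rep(list(c("s", "b1", "b2")), 2))
  diag(L) <- c(-1, -0.8, -1.2)
  L["s", "b1"] <- 0.5; L["b1", "b2"] <- 0.4; L["b2", "s"] <- 0.3
  pl <- projection_from_matrix(L, "s")
  dt <- seq(0, 6, 0.1)
  ch <- channel_decomposition(pl, dt)
  expect_equal(max(abs(ch$b2)), 0)  # signal enters the bulk through b1
  # oracle: closed form of the 2x2 bulk exponential
  B <- L[2:3, 2:3]
  orc <- vapply(dt, function(t)
    as.numeric(L["s", 2:3, drop = FALSE] %*% expm_mat(B * t) %*%
                 L[2:3, "s", drop = FALSE]), 0)
  expect_equal(as.numeric(ch$b1["s", "s", ]), orc, tolerance = 1e-12)
  # exit attribution moves the same total to the exit species
  chx <- channel_decomposition(pl, dt, attribution = "exit")
  expect_equal(max(abs(chx$b1)), 0)
  expect_equal(as.numeric(chx$b2["s", "s", ]), orc, tolerance = 1e-12)
})

test_that("projection is invariant under bulk relabelling", {
  L <- random_stable_L(4, seed = 31)
  pl <- projection_from_matrix(L, 1)
  perm <- c(1, 4, 2, 3)
  pl2 <- projection_from_matrix(L[perm, perm], "x1")
  dt <- seq(0, 3, 0.25)
  expect_equal(memory_function(pl, dt)[1, 1, ],
               memory_function(pl2, dt)[1, 1, ], tolerance = 1e-12)
  expect_equal(rate_matrix(pl)[1, 1], rate_matrix(pl2)[1, 1])
})

test_that("a quadratic-order projection of a linear network has no nonlinear memory", {
  L <- random_stable_L(3, seed = 17)
  Q <- matrix(0, 6, 3)
  pq <- projection_from_matrix(L, 1, Q = Q)
  M <- memory_function(pq, seq(0, 2, 0.5))
  q_rows <- grep("\\(", dimnames(M)[[1]])
  expect_equal(max(abs(M[q_rows, , ])), 0)
  expect_equal(max(abs(pq$Omega_qs)), 0)
})
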