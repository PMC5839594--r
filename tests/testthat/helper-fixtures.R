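# Shared fixtures and independent oracles.

# Cross-repression motif parameters (alpha1 = alpha2 = 1,
# w_p1 = 1, w_p2 = 2, w1 = w2 = 2, beta = 1/2): production of gene 1 is
# alpha1 / (w1 + wp2 x2), and conversely. The steady state solves
# x1^2 + 3 x1 - 2 = 0 (substituting one nullcline into the other).
motif_pars <- list(a1 = 1, a2 = 1, wp1 = 1, wp2 = 2, w1 = 2, w2 = 2,
                  beta = 0.5)

motif_steady_state <- function() {
  x1 <- (-3 + sqrt(17)) / 2
  c(g1 = x1, g2 = 2 / (2 + x1))
}

# Closed-form Jacobian of the motif (row = source, column = target).
motif_L <- function(y = motif_steady_state()) {
  p <- motif_pars
  matrix(c(-p$beta, -p$a2 * p$wp1 / (p$w2 + p$wp1 * y[1])^2,
           -p$a1 * p$wp2 / (p$w1 + p$wp2 * y[2])^2, -p$beta),
         2, 2, byrow = TRUE,
         dimnames = list(c("g1", "g2"), c("g1", "g2")))
}

# Single unregulated gene: one conformation, closed-form dynamics
# x(t) = a/b + (x0 - a/b) exp(-b t).
unregulated_model <- function(a = 2, b = 0.8) {
  grn_model("g1", list(list(name = "g1", beta = b, conformations = list(
    list(bound = NULL, weight = 1, alpha = a)))))
}

# Random stable matrix in row = source orientation, for linear-network
# oracles.
random_stable_L <- function(n, seed, coupling = 0.4) {
  set.seed(seed)
  L <- matrix(stats::rnorm(n * n, 0, coupling), n, n)
  diag(L) <- -(1 + stats::runif(n))
  dimnames(L) <- list(paste0("x", seq_len(n)), paste0("x", seq_len(n)))
  L
}

expm_mat <- function(A) as.matrix(Matrix::expm(A))

motif_one_state <- function(m = make_fixture("cross_repression"))
  find_steady_states(m, rbind(c(1, 1)))[[1]]$y

# Trapezoidal quadrature of the memory kernel and its first moment for one
# (source row, first linear target) entry; horizon set by the bulk decay.
kernel_moment_quadrature <- function(proj, h = 0.002) {
  absc <- max(Re(eigen(proj$blocks$L_BB, only.values = TRUE)$values))
  t_max <- min(40 / abs(absc), 500)
  dt <- seq(0, t_max, h)
  K <- memory_function(proj, dt)
  m0 <- m1 <- numeric(dim(K)[1])
  for (r in seq_len(dim(K)[1])) {
    k <- K[r, 1, ]
    m0[r] <- sum((k[-1] + k[-length(k)]) / 2) * h
    tk <- dt * k
    m1[r] <- sum((tk[-1] + tk[-length(tk)]) / 2) * h
  }
  list(M0 = m0, M1 = m1)
}
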