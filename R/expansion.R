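# Expansion of a thermodynamic model into a mass-action network of protein
# and DNA-conformation species, with detailed-balance rate constants and a
# fast rate factor gamma, plus the QSS elimination of the fast block.

#' Expand a thermodynamic model into a mass-action network
#'
#' Each (gene, conformation) pair becomes a DNA species with dimensionless
#' fractional concentration; binding/unbinding reactions connect
#' conformations differing by one bound protein copy. Detailed balance fixes
#' only the ratio of rate constants to the affinity-weight ratio, so the
#' unbinding rates are a free convention (default 1 for every unbinding
#' reaction; randomising them leaves all projected quantities unchanged).
#'
#' @param model a \code{grn_model}.
#' @param kminus unbinding rate constants: a single number applied to every
#'   unbinding reaction, or a function(n_transitions) returning a vector
#'   (useful for randomisation tests).
#' @return object of class \code{grn_expanded} with the DNA species table,
#'   the transition table (gene, from/to conformation, binding species,
#'   kplus, kminus) and a reference to the base model.
#' @export
expand_network <- function(model, kminus = 1) {
  species <- c(model$proteins, names(model$inputs))
  dna <- data.frame(gene = integer(0), conf = integer(0), name = character(0),
                    stringsAsFactors = FALSE)
  trans <- list()
  for (gi in seq_along(model$genes)) {
    g <- model$genes[[gi]]
    cg <- model$compiled[[gi]]
    nc <- nrow(cg$N)
    dna <- rbind(dna, data.frame(
      gene = gi, conf = seq_len(nc),
      name = paste0(g$name, "DNA[", apply(cg$N, 1, paste, collapse = ""), "]"),
      stringsAsFactors = FALSE))
    # transitions: conformation pairs differing by +1 copy of one species
    for (c1 in seq_len(nc)) for (c2 in seq_len(nc)) {
      d <- cg$N[c2, ] - cg$N[c1, ]
      if (sum(abs(d)) == 1 && sum(d) == 1) {
        p <- which(d == 1)
        if (cg$w[c1] <= 0)
          stop("gene '", g$name, "': transition from a zero-weight ",
               "conformation has no detailed-balance ratio")
        trans[[length(trans) + 1]] <- data.frame(
          gene = gi, from = c1, to = c2, sp = p,
          ratio = cg$w[c2] / cg$w[c1], stringsAsFactors = FALSE)
      }
    }
    # connectivity of the conformation lattice under single add/remove
    edges <- NULL
    if (length(trans)) {
      edges <- do.call(rbind, trans)
      edges <- edges[edges$gene == gi, , drop = FALSE]
    }
    reach <- rep(FALSE, nc); reach[1] <- TRUE
    repeat {
      new <- reach
      if (!is.null(edges) && nrow(edges) > 0)
        for (e in seq_len(nrow(edges))) {
          if (reach[edges$from[e]]) new[edges$to[e]] <- TRUE
          if (reach[edges$to[e]]) new[edges$from[e]] <- TRUE
        }
      if (identical(new, reach)) break
      reach <- new
    }
    if (!all(reach))
      stop("gene '", g$name, "': unreachable conformation(s) ",
           paste(which(!reach), collapse = ", "),
           " in the binding/unbinding lattice")
  }
  trans <- do.call(rbind, trans)
  km <- if (is.function(kminus)) kminus(nrow(trans)) else
    rep(kminus, nrow(trans))
  stopifnot(length(km) == nrow(trans), all(km > 0))
  trans$kminus <- km
  trans$kplus <- trans$ratio * km
  structure(list(model = model, species = species, dna = dna,
                 transitions = trans),
            class = "grn_expanded")
}

#' @export
print.grn_expanded <- function(x, ...) {
  cat("Expanded mass-action network:", length(x$model$proteins), "proteins,",
      nrow(x$dna), "DNA species,", nrow(x$transitions),
      "binding/unbinding pairs\n")
  invisible(x)
}

# State layout for the expanded dynamics: proteins first, DNA fractions after,
# in the order of net$dna.
expanded_state_names <- function(net) c(net$model$proteins, net$dna$name)

# QSS initial DNA fractions for protein concentrations x0.
qss_dna <- function(net, x0) {
  unlist(lapply(seq_along(net$model$genes), function(gi)
    conformation_probabilities(net$model, gi, x0)), use.names = FALSE)
}

# Time derivative of the expanded network. DNA equations carry the fast
# factor gamma; the binding drain on proteins carries gamma/gamma_prime
# (equal by default, so the drain is the O(1) net binding flux which
# vanishes as the DNA approaches its QSS).
expanded_derivative <- function(net, state, gamma, gamma_prime = gamma) {
  m <- net$model
  np <- length(m$proteins)
  x <- state[seq_len(np)]
  xf <- c(x, as.numeric(m$inputs))
  dna <- state[-seq_len(np)]
  dna_off <- c(0, cumsum(vapply(m$compiled, function(cg) nrow(cg$N), 0)))
  dx <- numeric(np)
  for (i in seq_len(np)) {
    cg <- m$compiled[[i]]
    idx <- dna_off[i] + seq_len(nrow(cg$N))
    dx[i] <- sum(dna[idx] * cg$a) - m$genes[[i]]$beta * x[i]
  }
  ddna <- numeric(length(dna))
  drain_fac <- gamma / gamma_prime
  tr <- net$transitions
  for (e in seq_len(nrow(tr))) {
    i_from <- dna_off[tr$gene[e]] + tr$from[e]
    i_to <- dna_off[tr$gene[e]] + tr$to[e]
    p <- tr$sp[e]
    flux <- tr$kplus[e] * dna[i_from] * xf[p] - tr$kminus[e] * dna[i_to]
    ddna[i_from] <- ddna[i_from] - gamma * flux
    ddna[i_to] <- ddna[i_to] + gamma * flux
    if (p <= np) dx[p] <- dx[p] - drain_fac * flux
  }
  c(dx, ddna)
}

# Analytic Jacobian of the expanded dynamics, row = source orientation
# (L[j, i] = dF_i/dstate_j). Used by the stiff integrator (transposed) and
# by the QSS elimination / equivalence machinery.
linearize_expanded <- function(net, state, gamma, gamma_prime = gamma) {
  m <- net$model
  np <- length(m$proteins)
  nd <- nrow(net$dna)
  n <- np + nd
  x <- state[seq_len(np)]
  xf <- c(x, as.numeric(m$inputs))
  dna <- state[-seq_len(np)]
  dna_off <- c(0, cumsum(vapply(m$compiled, function(cg) nrow(cg$N), 0)))
  L <- matrix(0, n, n,
              dimnames = list(expanded_state_names(net),
                              expanded_state_names(net)))
  for (i in seq_len(np)) {
    cg <- m$compiled[[i]]
    idx <- np + dna_off[i] + seq_len(nrow(cg$N))
    L[idx, i] <- cg$a                       # production from DNA fractions
    L[i, i] <- L[i, i] - m$genes[[i]]$beta  # decay
  }
  drain_fac <- gamma / gamma_prime
  tr <- net$transitions
  for (e in seq_len(nrow(tr))) {
    i_from <- np + dna_off[tr$gene[e]] + tr$from[e]
    i_to <- np + dna_off[tr$gene[e]] + tr$to[e]
    p <- tr$sp[e]
    kp <- tr$kplus[e]; km <- tr$kminus[e]
    # flux = kp * dna_from * x_p - km * dna_to
    # d flux / d dna_from = kp x_p ; / d dna_to = -km ; / d x_p = kp dna_from
    dfl_from <- kp * xf[p]
    dfl_to <- -km
    L[i_from, i_from] <- L[i_from, i_from] - gamma * dfl_from
    L[i_to, i_from] <- L[i_to, i_from] - gamma * dfl_to
    L[i_from, i_to] <- L[i_from, i_to] + gamma * dfl_from
    L[i_to, i_to] <- L[i_to, i_to] + gamma * dfl_to
    if (p <= np) {
      dfl_xp <- kp * dna[i_from - np]
      L[p, i_from] <- L[p, i_from] - gamma * dfl_xp
      L[p, i_to] <- L[p, i_to] + gamma * dfl_xp
      # drain on protein p
      L[i_from, p] <- L[i_from, p] - drain_fac * dfl_from
      L[i_to, p] <- L[i_to, p] - drain_fac * dfl_to
      L[p, p] <- L[p, p] - drain_fac * dfl_xp
    }
  }
  L
}

#' Simulate the expanded mass-action network
#'
#' Integrates protein and DNA-fraction equations with a stiff solver and the
#' analytic Jacobian. DNA fractions are initialised at the quasi-steady-state
#' occupancy distribution of the initial protein concentrations unless
#' overridden. The protein equations include the O(1/gamma') net binding
#' drain of free protein, which vanishes in the fast-binding limit.
#'
#' @param net a \code{grn_expanded}.
#' @param gamma fast rate factor (>= 1) multiplying all DNA reactions.
#' @param x0 initial protein concentrations.
#' @param t_grid strictly increasing time vector.
#' @param tol relative integration tolerance.
#' @param atol absolute tolerance (applied to DNA fractions and proteins).
#' @param dna0 optional initial DNA fractions (defaults to QSS of x0).
#' @param gamma_prime DNA concentration-scale factor; defaults to gamma.
#' @return data.frame with columns time, proteins, DNA fractions.
#' @export
simulate_expanded <- function(net, gamma, x0, t_grid, tol = 1e-9,
                              atol = 1e-11, dna0 = NULL,
                              gamma_prime = gamma) {
  stopifnot(gamma >= 1, all(diff(t_grid) > 0))
  if (is.null(dna0)) dna0 <- qss_dna(net, x0)
  y0 <- c(as.numeric(x0), dna0)
  names(y0) <- expanded_state_names(net)
  rhs <- function(t, y, p)
    list(expanded_derivative(net, y, gamma, gamma_prime))
  jac <- function(t, y, p)
    t(linearize_expanded(net, y, gamma, gamma_prime))
  sol <- deSolve::ode(y = y0, times = t_grid, func = rhs, parms = NULL,
                      jacfunc = jac, jactype = "fullusr",
                      method = "lsoda", rtol = tol, atol = atol)
  if (attr(sol, "istate")[1] < 0)
    stop("stiff integration failed at time ",
         signif(max(sol[, "time"]), 6),
         "; consider lowering gamma or tightening the tolerance")
  as.data.frame(unclass(sol))
}

#' Eliminate fast species from a linearised network (QSS reduction)
#'
#' Given the full Jacobian of a linearised network in row = source
#' orientation and the index set of fast species, sets the fast equations to
#' quasi-steady state and substitutes back, yielding the effective matrix
#' over the slow species:
#' \code{L_eff = L[slow, slow] - L[slow, fast] \%*\% solve(L[fast, fast]) \%*\% L[fast, slow]}.
#'
#' @param L full matrix, row = source, column = target.
#' @param fast integer or logical index of fast species (rows/columns of L).
#' @return effective matrix over the slow species.
#' @export
effective_L_qss <- function(L, fast) {
  n <- nrow(L)
  fast_idx <- if (is.logical(fast)) which(fast) else as.integer(fast)
  if (!length(fast_idx)) return(L)
  slow_idx <- setdiff(seq_len(n), fast_idx)
  Lff <- L[fast_idx, fast_idx, drop = FALSE]
  kap <- kappa(Lff, exact = FALSE)
  if (!is.finite(kap) || kap > 1e12) {
    ns <- svd(Lff)
    near_null <- ns$u[, which.min(ns$d)]
    warning("fast-fast block is ill-conditioned (condition number ",
            signif(kap, 3), "); near-null conformation combination: ",
            paste(signif(near_null, 3), collapse = ", "))
  }
  inv <- tryCatch(solve(Lff), error = function(e)
    stop("singular fast-fast block; near-null conformation combination: ",
         paste(signif(svd(Lff)$u[, ncol(Lff)], 3), collapse = ", ")))
  L[slow_idx, slow_idx, drop = FALSE] -
    L[slow_idx, fast_idx, drop = FALSE] %*% inv %*%
    L[fast_idx, slow_idx, drop = FALSE]
}

#' Effective protein-level matrix of an expanded network at a steady state
#'
#' Convenience wrapper: linearises the expanded network at the protein
#' steady state (DNA at its QSS occupancies) and QSS-eliminates the DNA
#' species. Because the DNA fractions of each gene are conserved (they sum
#' to one), the raw fast block is singular along the conservation
#' direction; one reference conformation per gene is therefore eliminated
#' first (its deviation is minus the sum of the others), which makes the
#' fast block invertible without changing the dynamics. By the equivalence
#' theorem the result equals the direct linearisation of the thermodynamic
#' model, independent of gamma and of the unbinding rate convention.
#'
#' @param net a \code{grn_expanded}.
#' @param y protein steady state.
#' @param gamma fast rate factor used in the linearisation (cancels in the
#'   elimination; kept as an argument for transparency).
#' @return effective matrix over the proteins, row = source orientation.
#' @export
effective_protein_L <- function(net, y, gamma = 100) {
  state <- c(as.numeric(y), qss_dna(net, y))
  Lfull <- linearize_expanded(net, state, gamma)
  np <- length(net$model$proteins)
  nd <- nrow(net$dna)
  # reduced coordinates: drop the first conformation of each gene and
  # impose that its deviation equals minus the sum of the remaining ones
  ref <- np + which(!duplicated(net$dna$gene))
  keep <- setdiff(seq_len(np + nd), ref)
  J <- t(Lfull)                      # column-vector orientation
  Tm <- matrix(0, np + nd, length(keep))
  for (ci in seq_along(keep)) Tm[keep[ci], ci] <- 1
  for (r in ref) {
    g <- net$dna$gene[r - np]
    same <- which(net$dna$gene == g) + np
    Tm[r, match(setdiff(same, r), keep)] <- -1
  }
  J_red <- J[keep, , drop = FALSE] %*% Tm
  L_red <- t(J_red)
  fast <- which(keep > np)
  effective_L_qss(L_red, fast)[seq_len(np), seq_len(np), drop = FALSE]
}

#' Export the expanded reaction table
#'
#' One row per elementary reaction (binding and unbinding separately), with
#' reactants, products, base rate constant and gamma-scaling class.
#'
#' @param net a \code{grn_expanded}.
#' @return data.frame with columns reactants, products, rate, scaling.
#' @export
reaction_table <- function(net) {
  m <- net$model
  species <- c(m$proteins, names(m$inputs))
  tr <- net$transitions
  rows <- lapply(seq_len(nrow(tr)), function(e) {
    gn <- tr$gene[e]
    from <- net$dna$name[net$dna$gene == gn & net$dna$conf == tr$from[e]]
    to <- net$dna$name[net$dna$gene == gn & net$dna$conf == tr$to[e]]
    p <- species[tr$sp[e]]
    rbind(
      data.frame(reactants = paste(from, p, sep = " + "), products = to,
                 rate = tr$kplus[e], scaling = "gamma",
                 stringsAsFactors = FALSE),
      data.frame(reactants = to, products = paste(from, p, sep = " + "),
                 rate = tr$kminus[e], scaling = "gamma",
                 stringsAsFactors = FALSE))
  })
  do.call(rbind, rows)
}
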