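# Thermodynamic state-ensemble GRN models: construction, evaluation,
# simulation, steady states, and Taylor expansion of the deviation dynamics.

#' Construct a thermodynamic state-ensemble GRN model
#'
#' A gene's production rate is a weighted average over its DNA binding
#' conformations. Each conformation is described by an occupancy vector
#' (how many copies of each protein are bound), an affinity weight, and a
#' production rate. The probability of a conformation follows the
#' state-ensemble (Boltzmann-like) form: weight times the mass-action product
#' of regulator concentrations, normalised over all conformations of the gene.
#'
#' @param proteins character vector of dynamic protein species, one per gene.
#' @param genes list of gene specifications, one per protein. Each element is
#'   a list with fields \code{name} (matching a protein), \code{beta}
#'   (decay rate, must be > 0) and \code{conformations}, itself a list of
#'   conformations with fields \code{bound} (named non-negative integer
#'   vector of bound copy counts; empty or NULL for the unbound state),
#'   \code{weight} (affinity weight >= 0) and \code{alpha} (production
#'   rate >= 0 for that conformation).
#' @param inputs named numeric vector of clamped species (e.g. a morphogen
#'   effector). Clamped species can appear in occupancy vectors but have no
#'   dynamics and are never produced.
#'
#' @return An object of class \code{grn_model}.
#' @export
grn_model <- function(proteins, genes, inputs = numeric(0)) {
  stopifnot(is.character(proteins), length(proteins) >= 1,
            !anyDuplicated(proteins))
  if (length(inputs)) {
    stopifnot(is.numeric(inputs), !is.null(names(inputs)),
              all(nzchar(names(inputs))), all(is.finite(inputs)),
              all(inputs >= 0))
    if (any(names(inputs) %in% proteins))
      stop("clamped inputs cannot also be dynamic proteins")
  }
  species <- c(proteins, names(inputs))

  gene_names <- vapply(genes, function(g) g$name %||% NA_character_, "")
  if (!setequal(gene_names, proteins) || anyDuplicated(gene_names))
    stop("genes must be given exactly once for each protein")
  genes <- genes[match(proteins, gene_names)]

  genes <- lapply(genes, function(g) {
    if (is.null(g$beta) || !is.finite(g$beta) || g$beta <= 0)
      stop("gene '", g$name, "': decay rate beta must be finite and > 0")
    if (length(g$conformations) < 1)
      stop("gene '", g$name, "' has no conformations")
    g$conformations <- lapply(g$conformations, function(cf) {
      b <- cf$bound
      if (is.null(b) || length(b) == 0) b <- integer(0)
      if (length(b)) {
        if (is.null(names(b)) || !all(names(b) %in% species))
          stop("gene '", g$name, "': occupancy names must be known species")
        if (any(b < 0) || any(b != round(b)))
          stop("gene '", g$name, "': occupancies must be non-negative integers")
        b <- b[b > 0]
      }
      if (is.null(cf$weight) || cf$weight < 0 || !is.finite(cf$weight))
        stop("gene '", g$name, "': conformation weight must be >= 0")
      if (is.null(cf$alpha) || cf$alpha < 0 || !is.finite(cf$alpha))
        stop("gene '", g$name, "': production rate alpha must be >= 0")
      list(bound = b, weight = as.numeric(cf$weight),
           alpha = as.numeric(cf$alpha))
    })
    keys <- vapply(g$conformations, function(cf) occ_key(cf$bound, species), "")
    if (anyDuplicated(keys))
      stop("gene '", g$name, "': duplicate binding conformations")
    if (!any(vapply(g$conformations, function(cf) cf$weight > 0, TRUE)))
      stop("gene '", g$name, "': needs at least one conformation with weight > 0")
    g
  })

  m <- structure(list(proteins = proteins, inputs = inputs, genes = genes),
                 class = "grn_model")
  m$compiled <- compile_model(m)
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

occ_key <- function(bound, species) {
  n <- integer(length(species))
  names(n) <- species
  if (length(bound)) n[names(bound)] <- as.integer(bound)
  paste(n, collapse = ",")
}

# Per-gene occupancy matrix (conformations x species), weights and alphas,
# cached on the model for repeated evaluation.
compile_model <- function(m) {
  species <- c(m$proteins, names(m$inputs))
  lapply(m$genes, function(g) {
    nc <- length(g$conformations)
    N <- matrix(0L, nc, length(species), dimnames = list(NULL, species))
    for (c in seq_len(nc)) {
      b <- g$conformations[[c]]$bound
      if (length(b)) N[c, names(b)] <- as.integer(b)
    }
    list(N = N,
         w = vapply(g$conformations, `[[`, 0, "weight"),
         a = vapply(g$conformations, `[[`, 0, "alpha"))
  })
}

#' @export
print.grn_model <- function(x, ...) {
  cat("Thermodynamic GRN model:", length(x$proteins), "proteins (",
      paste(x$proteins, collapse = ", "), ")\n", sep = "")
  if (length(x$inputs))
    cat("Clamped inputs:",
        paste(sprintf("%s=%g", names(x$inputs), x$inputs), collapse = ", "),
        "\n")
  for (i in seq_along(x$genes)) {
    g <- x$genes[[i]]
    cat(sprintf("  gene %s: beta=%g, %d conformations\n",
                g$name, g$beta, length(g$conformations)))
  }
  invisible(x)
}

# Full species vector (dynamic proteins followed by clamped inputs).
full_state <- function(model, x) {
  np <- length(model$proteins)
  if (length(x) != np)
    stop("state must have one entry per protein (", np, ")")
  c(as.numeric(x), as.numeric(model$inputs))
}

#' Conformation probabilities of a gene
#'
#' Evaluates the state-ensemble occupancy distribution of a gene's DNA:
#' each conformation's weight times the mass-action product of regulator
#' concentrations, normalised by the sum over all conformations.
#'
#' @param model a \code{grn_model}.
#' @param gene gene name or index.
#' @param state numeric vector of protein concentrations (>= 0), aligned
#'   with \code{model$proteins}.
#' @return numeric probability vector over the gene's conformations
#'   (entries in [0, 1], summing to 1).
#' @export
conformation_probabilities <- function(model, gene, state) {
  gi <- if (is.character(gene)) match(gene, model$proteins) else as.integer(gene)
  if (is.na(gi) || gi < 1 || gi > length(model$genes))
    stop("unknown gene: ", gene)
  if (any(state < 0)) stop("protein concentrations must be >= 0")
  xf <- full_state(model, state)
  cg <- model$compiled[[gi]]
  terms <- cg$w * monomials(cg$N, xf)
  s <- sum(terms)
  if (s <= 0)
    stop("degenerate conformation-ensemble denominator for gene '",
         model$genes[[gi]]$name, "' (all weighted terms are zero)")
  terms / s
}

# Mass-action monomials prod_i x_i^{n_i} for each conformation row.
# Relies on 0^0 == 1 so the unbound state evaluates to 1 at x = 0.
monomials <- function(N, xf) {
  nc <- nrow(N)
  out <- numeric(nc)
  for (c in seq_len(nc)) out[c] <- prod(xf^N[c, ])
  out
}

#' Time derivative of the thermodynamic dynamics
#'
#' Production from the conformation ensemble minus linear decay:
#' \eqn{\partial_t x_j = \sum_n x_{(j,n)} \alpha_{(j,n)} - \beta_j x_j}.
#'
#' @inheritParams conformation_probabilities
#' @return numeric vector of time derivatives, one per protein.
#' @export
time_derivative <- function(model, state) {
  xf <- full_state(model, state)
  np <- length(model$proteins)
  out <- numeric(np)
  for (i in seq_len(np)) {
    cg <- model$compiled[[i]]
    terms <- cg$w * monomials(cg$N, xf)
    s <- sum(terms)
    if (s <= 0)
      stop("degenerate conformation-ensemble denominator for gene '",
           model$genes[[i]]$name, "'")
    out[i] <- sum(terms * cg$a) / s - model$genes[[i]]$beta * xf[i]
  }
  names(out) <- model$proteins
  out
}

# d/dx_k of the monomial of conformation c; handles x = 0 through 0^0 = 1.
monomial_grad <- function(nrow_vec, xf, k) {
  nk <- nrow_vec[k]
  if (nk == 0) return(0)
  rest <- prod(xf[-k]^nrow_vec[-k])
  nk * xf[k]^(nk - 1) * rest
}

monomial_hess <- function(nrow_vec, xf, k, l) {
  if (k == l) {
    nk <- nrow_vec[k]
    if (nk < 2) return(0)
    rest <- prod(xf[-k]^nrow_vec[-k])
    return(nk * (nk - 1) * xf[k]^(nk - 2) * rest)
  }
  nk <- nrow_vec[k]; nl <- nrow_vec[l]
  if (nk == 0 || nl == 0) return(0)
  rest <- prod(xf[-c(k, l)]^nrow_vec[-c(k, l)])
  nk * nl * xf[k]^(nk - 1) * xf[l]^(nl - 1) * rest
}

# Analytic gradient (and optionally Hessian) of each gene's production term
# g_i = u_i / v_i with u = sum(a w m), v = sum(w m), by the quotient rule.
production_derivs <- function(model, state, hessian = FALSE) {
  xf <- full_state(model, state)
  np <- length(model$proteins)
  grad <- matrix(0, np, np,
                 dimnames = list(model$proteins, model$proteins))
  hess <- if (hessian) array(0, c(np, np, np)) else NULL
  for (i in seq_len(np)) {
    cg <- model$compiled[[i]]
    nc <- nrow(cg$N)
    m <- monomials(cg$N, xf)
    u <- sum(cg$a * cg$w * m)
    v <- sum(cg$w * m)
    if (v <= 0)
      stop("degenerate conformation-ensemble denominator for gene '",
           model$genes[[i]]$name, "'")
    dm <- matrix(0, nc, np)
    for (c in seq_len(nc)) for (k in seq_len(np))
      dm[c, k] <- monomial_grad(cg$N[c, ], xf, k)
    uk <- colSums(cg$a * cg$w * dm)
    vk <- colSums(cg$w * dm)
    grad[, i] <- (uk * v - u * vk) / v^2
    if (hessian) {
      for (k in seq_len(np)) for (l in k:np) {
        d2 <- vapply(seq_len(nc),
                     function(c) monomial_hess(cg$N[c, ], xf, k, l), 0)
        ukl <- sum(cg$a * cg$w * d2)
        vkl <- sum(cg$w * d2)
        gkl <- ukl / v - (uk[k] * vk[l] + uk[l] * vk[k]) / v^2 -
          u * vkl / v^2 + 2 * u * vk[k] * vk[l] / v^3
        hess[k, l, i] <- gkl
        hess[l, k, i] <- gkl
      }
    }
  }
  list(grad = grad, hess = hess)
}

#' Linearise the thermodynamic dynamics around a state
#'
#' Analytic Jacobian of the deviation dynamics in the row = source,
#' column = target orientation: \eqn{\partial_t \delta x^T = \delta x^T L},
#' i.e. \code{L[j, i]} is the coefficient of \eqn{\delta x_j} in the
#' equation for species i.
#'
#' @param model a \code{grn_model}.
#' @param y expansion point, usually a steady state. A warning is issued if
#'   \code{y} is not a steady state within \code{residual_tol} (the expansion
#'   is still computed).
#' @param residual_tol tolerance on \code{max(abs(time_derivative))} used for
#'   the steady-state warning.
#' @param check_steady set \code{FALSE} to skip the steady-state check (used
#'   internally by root finding).
#' @return list of class \code{grn_taylor} with fields \code{y}, \code{L}
#'   (and \code{Q = NULL}).
#' @export
linearize <- function(model, y, residual_tol = 1e-6, check_steady = TRUE) {
  if (check_steady) {
    res <- max(abs(time_derivative(model, y)))
    if (res > residual_tol)
      warning("expansion point is not a steady state (residual ", signif(res, 3), ")")
  }
  d <- production_derivs(model, y, hessian = FALSE)
  L <- d$grad
  diag(L) <- diag(L) - vapply(model$genes, `[[`, 0, "beta")
  structure(list(y = as.numeric(y), L = L, Q = NULL), class = "grn_taylor")
}

# Canonical ordering of quadratic observable pairs (j <= k), row-bound to the
# convention used across the projection machinery.
pair_index <- function(n) {
  ps <- which(upper.tri(matrix(0, n, n), diag = TRUE), arr.ind = TRUE)
  ps <- ps[order(ps[, "row"], ps[, "col"]), , drop = FALSE]
  cbind(j = ps[, "row"], k = ps[, "col"])
}

#' Quadratic Taylor expansion of the deviation dynamics
#'
#' Extends \code{\link{linearize}} with the quadratic coefficients
#' \code{Q[(j,k), i]}: the coefficient of \eqn{\delta x_j \delta x_k}
#' (canonical ordering j <= k) in the equation for species i, so that
#' \code{Q[(j,j), i]} equals half the second partial derivative.
#'
#' @inheritParams linearize
#' @return \code{grn_taylor} with fields \code{y}, \code{L}, \code{Q}
#'   (matrix of size n(n+1)/2 by n, rows in canonical pair order) and
#'   \code{pairs} (the pair index).
#' @export
quadratic_expansion <- function(model, y, residual_tol = 1e-6,
                                check_steady = TRUE) {
  te <- linearize(model, y, residual_tol, check_steady)
  d <- production_derivs(model, y, hessian = TRUE)
  np <- length(model$proteins)
  pr <- pair_index(np)
  Q <- matrix(0, nrow(pr), np)
  pair_names <- paste0("(", model$proteins[pr[, 1]], ",",
                       model$proteins[pr[, 2]], ")")
  dimnames(Q) <- list(pair_names, model$proteins)
  for (p in seq_len(nrow(pr))) {
    j <- pr[p, 1]; k <- pr[p, 2]
    Q[p, ] <- if (j == k) 0.5 * d$hess[j, j, ] else d$hess[j, k, ]
  }
  te$Q <- Q
  te$pairs <- pr
  te
}

#' Simulate the full thermodynamic dynamics
#'
#' Integrates the nonlinear production/decay equations with a stiff-capable
#' solver and the analytic Jacobian.
#'
#' @param model a \code{grn_model}.
#' @param x0 initial protein concentrations (>= 0).
#' @param t_grid strictly increasing time vector (including the start time).
#' @param tol relative integration tolerance.
#' @param atol absolute integration tolerance.
#' @return data.frame with columns \code{time} and one per protein.
#' @export
simulate_full <- function(model, x0, t_grid, tol = 1e-8, atol = 1e-10) {
  stopifnot(all(diff(t_grid) > 0))
  if (any(x0 < 0)) stop("initial concentrations must be >= 0")
  x0 <- as.numeric(x0)
  names(x0) <- model$proteins
  rhs <- function(t, x, p) list(time_derivative(model, x))
  jac <- function(t, x, p)
    t(linearize(model, x, check_steady = FALSE)$L)
  sol <- deSolve::ode(y = x0, times = t_grid, func = rhs, parms = NULL,
                      jacfunc = jac, jactype = "fullusr",
                      method = "lsoda", rtol = tol, atol = atol)
  if (attr(sol, "istate")[1] < 0)
    stop("integrator failure; last accepted time ",
         signif(max(sol[, "time"]), 6))
  as.data.frame(unclass(sol))
}

# Damped Newton iteration for roots of the time derivative.
newton_root <- function(model, x0, tol = 1e-12, maxit = 200) {
  x <- pmax(as.numeric(x0), 0)
  f <- tryCatch(time_derivative(model, x), error = function(e) NULL)
  if (is.null(f)) return(NULL)
  for (it in seq_len(maxit)) {
    if (max(abs(f)) < tol) break
    J <- t(linearize(model, x, check_steady = FALSE)$L)
    step <- tryCatch(solve(J, -f), error = function(e) NULL)
    if (is.null(step) || !all(is.finite(step))) return(NULL)
    lam <- 1
    fn2 <- sum(f^2)
    repeat {
      xn <- x + lam * step
      fnew <- tryCatch(time_derivative(model, xn), error = function(e) NULL)
      ok <- !is.null(fnew) && all(is.finite(fnew))
      if (ok && (sum(fnew^2) < fn2 || lam < 1e-8)) {
        x <- xn; f <- fnew; break
      }
      lam <- lam / 2
      if (lam < 1e-12) return(NULL)
    }
  }
  if (max(abs(f)) > sqrt(tol)) return(NULL)
  # tiny negative components from the root search are clamped and re-checked
  if (min(x) < -1e-8) return(NULL)
  x <- pmax(x, 0)
  if (max(abs(time_derivative(model, x))) > sqrt(tol)) return(NULL)
  x
}

#' Locate steady states of the thermodynamic dynamics
#'
#' Runs damped Newton searches from a grid of seeds augmented with long-time
#' endpoints of the full dynamics, deduplicates the roots, and classifies
#' stability from the spectrum of the Jacobian.
#'
#' @param model a \code{grn_model}.
#' @param seeds matrix of starting states (rows) or list of numeric vectors.
#' @param tol residual tolerance for accepting a root.
#' @param dedup_tol max-norm distance below which two roots are considered
#'   identical (ties keep the smaller residual).
#' @param ode_seeds also seed from the long-time endpoint of the full
#'   dynamics started at each seed (default TRUE).
#' @return list of steady-state records, each with fields \code{y},
#'   \code{residual}, \code{eigenvalues}, \code{stable}; ordered
#'   lexicographically by concentration vector. Empty list (with a warning)
#'   if no root is found.
#' @export
find_steady_states <- function(model, seeds, tol = 1e-10, dedup_tol = 1e-6,
                               ode_seeds = TRUE) {
  if (is.list(seeds)) seeds <- do.call(rbind, seeds)
  seeds <- matrix(as.numeric(seeds), ncol = length(model$proteins))
  if (nrow(seeds) == 0) stop("seed grid must be non-empty")
  starts <- seeds
  if (ode_seeds) {
    t_end <- 50 / min(vapply(model$genes, `[[`, 0, "beta"))
    for (r in seq_len(nrow(seeds))) {
      tr <- tryCatch(
        simulate_full(model, pmax(seeds[r, ], 0), c(0, t_end)),
        error = function(e) NULL)
      if (!is.null(tr))
        starts <- rbind(starts, as.numeric(tr[nrow(tr), -1]))
    }
  }
  roots <- list()
  for (r in seq_len(nrow(starts))) {
    x <- newton_root(model, starts[r, ], tol = tol^2)
    if (is.null(x)) next
    res <- max(abs(time_derivative(model, x)))
    if (res > tol) next
    ev <- eigen(t(linearize(model, x, check_steady = FALSE)$L),
                only.values = TRUE)$values
    rec <- list(y = stats::setNames(x, model$proteins), residual = res,
                eigenvalues = ev, stable = all(Re(ev) < 0))
    dup <- FALSE
    for (q in seq_along(roots)) {
      if (max(abs(roots[[q]]$y - x)) < dedup_tol) {
        dup <- TRUE
        if (res < roots[[q]]$residual) roots[[q]] <- rec
        break
      }
    }
    if (!dup) roots[[length(roots) + 1]] <- rec
  }
  if (!length(roots)) {
    warning("no steady state found from any seed")
    return(list())
  }
  ymat <- do.call(rbind, lapply(roots, `[[`, "y"))
  ord <- do.call(order, as.data.frame(ymat))
  roots[ord]
}
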